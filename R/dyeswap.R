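#' Orient ratios to patient/reference and collapse duplicate spots
#'
#' Each slide's normalized log2 ratio `M_norm` is `log2(ch1/ch2)`; the
#' oriented ratio is `M_norm` when the patient sample is in channel 1 and
#' `-M_norm` otherwise, so every slide reports log2(patient/reference).
#' Duplicate spots of a gene are collapsed by the mean (or median) of the
#' unflagged duplicates; a gene is missing on a slide when all its spots
#' are flagged.
#'
#' @param norm_slides named list of `normalized_slide` objects, names being
#'   slide ids.
#' @param design validated experiment design.
#' @param collapse `"mean"` or `"median"` over unflagged duplicates.
#' @return data frame: `gene_id`, one column per slide of oriented log2
#'   ratios (NA when the gene is missing on that slide).
#' @export
orient_and_collapse <- function(norm_slides, design,
                                collapse = c("mean", "median")) {
  collapse <- match.arg(collapse)
  validate_design(design)
  missing_slides <- setdiff(design$slide_id, names(norm_slides))
  if (length(missing_slides))
    stop("no normalized slide for design slide(s): ",
         paste(missing_slides, collapse = ", "), call. = FALSE)
  agg_fun <- if (collapse == "mean") mean else stats::median

  genes <- sort(unique(norm_slides[[design$slide_id[1]]]$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(design))) {
    sl <- design$slide_id[i]
    ns <- norm_slides[[sl]]
    sign_or <- if (design$orientation[i] == "patient_in_ch1") 1 else -1
    val <- sign_or * ns$M_norm  # NA already for flagged spots
    agg <- tapply(val, ns$gene_id, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else agg_fun(v)
    })
    out[[sl]] <- as.numeric(agg[match(genes, names(agg))])
  }
  out
}

#' Dye-swap concordance (3 SD) filter for one pair
#'
#' For a swap pair, `R1` and `R2` are the oriented patient/reference ratios
#' from the two slides; `delta = log2(R1/R2)` (equivalently the difference
#' of the oriented log2 ratios). The SD of delta is computed over all genes
#' of the pair with both values defined, and a gene is flagged discordant
#' when its centered delta exceeds `k_sd` SDs:
#' `|delta - mean(delta)| > k_sd * SD`. When the SD is exactly 0 nothing
#' strictly exceeds it and all genes are retained.
#'
#' @param r1,r2 named-compatible numeric vectors of oriented log2 ratios
#'   (same gene order).
#' @param k_sd SD multiple (default 3).
#' @return list: `delta`, `concordant` (logical, NA when delta undefined),
#'   `mean_delta`, `sd_delta`.
#' @export
concordance_filter <- function(r1, r2, k_sd = 3) {
  delta <- r1 - r2
  ok <- is.finite(delta)
  if (sum(ok) < 2L)
    stop("concordance filter: need >= 2 genes with both ratios defined",
         call. = FALSE)
  mu <- mean(delta[ok])
  sdv <- stats::sd(delta[ok])
  conc <- rep(NA, length(delta))
  conc[ok] <- abs(delta[ok] - mu) <= k_sd * sdv
  list(delta = delta, concordant = conc, mean_delta = mu, sd_delta = sdv)
}

#' Per-patient gene summary: log2 of the geometric-mean ratio
#'
#' The patient value is the arithmetic mean of the two oriented log2 ratios
#' of the swap pair — identically the log2 of the geometric mean of the raw
#' ratios R1 and R2. Genes flagged discordant, or missing either slide, get
#' NA.
#'
#' @param r1,r2 oriented log2 ratios of the pair's two slides.
#' @param concordant logical from [concordance_filter()].
#' @return numeric vector of per-gene patient values.
#' @export
summarize_patient <- function(r1, r2, concordant = NULL) {
  v <- (r1 + r2) / 2
  if (!is.null(concordant)) v[!(concordant %in% TRUE)] <- NA_real_
  v
}

#' Assemble the genes-by-patients ratio matrix with drop provenance
#'
#' Applies the concordance filter within each pair, summarizes each patient
#' by the geometric-mean log2 ratio, and records why each gene left the
#' analysis: `dropped_concordance` (discordant in at least one pair),
#' `dropped_missing` (no value for some patient for any other reason), or
#' `kept` pending the pattern filter.
#'
#' @param oriented output of [orient_and_collapse()].
#' @param design validated experiment design.
#' @param k_sd SD multiple for the concordance filter.
#' @return list of class `"ratio_matrix"`: `values` (genes x patients
#'   matrix), `status`, `direction` (NA until the pattern filter runs),
#'   `pair_stats` (per-pair delta mean/SD and discordant count).
#' @export
build_ratio_matrix <- function(oriented, design, k_sd = 3) {
  validate_design(design)
  genes <- oriented$gene_id
  pairs <- unique(design$pair_id)
  patients <- vapply(pairs, function(pr)
    design$patient_id[design$pair_id == pr][1], character(1))
  values <- matrix(NA_real_, nrow = length(genes), ncol = length(pairs),
                   dimnames = list(genes, patients))
  discordant_any <- rep(FALSE, length(genes))
  pair_stats <- data.frame(pair_id = pairs, patient_id = patients,
                           mean_delta = NA_real_, sd_delta = NA_real_,
                           n_discordant = NA_integer_,
                           stringsAsFactors = FALSE)
  for (j in seq_along(pairs)) {
    sl <- design$slide_id[design$pair_id == pairs[j]]
    r1 <- oriented[[sl[1]]]
    r2 <- oriented[[sl[2]]]
    cf <- concordance_filter(r1, r2, k_sd = k_sd)
    discordant_any <- discordant_any | (cf$concordant %in% FALSE)
    values[, j] <- summarize_patient(r1, r2, cf$concordant)
    pair_stats$mean_delta[j] <- cf$mean_delta
    pair_stats$sd_delta[j] <- cf$sd_delta
    pair_stats$n_discordant[j] <- sum(cf$concordant %in% FALSE)
  }
  complete <- rowSums(!is.finite(values)) == 0L
  status <- ifelse(complete, "kept",
                   ifelse(discordant_any, "dropped_concordance",
                          "dropped_missing"))
  structure(list(values = values,
                 status = stats::setNames(status, genes),
                 direction = stats::setNames(rep(NA_character_,
                                                 length(genes)), genes),
                 pair_stats = pair_stats),
            class = "ratio_matrix")
}

#' Cross-patient expression-pattern consistency filter
#'
#' Keeps a gene only if the sign of its summarized ratio is strictly the
#' same (all positive or all negative) in every patient; any zero value has
#' no sign and drops the gene. Only the genes changed in the same direction
#' in all patients enter the significance analysis.
#'
#' @param rm a `ratio_matrix` from [build_ratio_matrix()].
#' @return the `ratio_matrix` with `status` updated (`dropped_pattern`) and
#'   `direction` set to `"up"`/`"down"` for kept genes.
#' @export
pattern_consistency_filter <- function(rm) {
  stopifnot(inherits(rm, "ratio_matrix"))
  kept <- names(rm$status)[rm$status == "kept"]
  for (g in kept) {
    v <- rm$values[g, ]
    if (all(v > 0)) {
      rm$direction[g] <- "up"
    } else if (all(v < 0)) {
      rm$direction[g] <- "down"
    } else {
      rm$status[g] <- "dropped_pattern"
    }
  }
  rm
}

#' Extract the SAM input matrix of kept genes
#' @param rm a pattern-filtered `ratio_matrix`.
#' @return numeric matrix (kept genes x patients).
#' @export
kept_matrix <- function(rm) {
  stopifnot(inherits(rm, "ratio_matrix"))
  rm$values[rm$status == "kept", , drop = FALSE]
}
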