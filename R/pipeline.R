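#' Run the full dye-swap differential-expression pipeline
#'
#' Executes, in order: per-slide Z-score low-intensity filtering and LOWESS
#' balancing; ratio orientation and duplicate collapse; per-pair dye-swap
#' concordance (3 SD) filtering; cross-patient pattern-consistency
#' filtering; geometric-mean aggregation; one-class SAM at the requested
#' FDR ceiling; and, when gene sets are supplied, hypergeometric
#' over-representation of the called genes. Every filter decision is
#' tallied in the run report; identical inputs and seed give identical
#' outputs.
#'
#' @param slides named list of slide tables (names = slide ids).
#' @param design validated experiment design.
#' @param gene_sets optional `gene_set_collection` for enrichment.
#' @param z_threshold,span,outlier_k,background,floor preprocessing
#'   parameters (see [lowess_normalize()]).
#' @param k_sd concordance-filter SD multiple.
#' @param collapse duplicate-collapse statistic (`"mean"`/`"median"`).
#' @param s0,n_perm,fdr_max,pi0 SAM parameters (see [sam_one_class()]).
#' @param granularity SAM input granularity: `"patient"` (default; genes x
#'   patients matrix of geometric-mean summarized ratios, n = number of
#'   patients) or `"slide"` (genes x slides matrix of oriented per-slide
#'   ratios for the same kept genes, giving a richer sign-flip null).
#' @param universe enrichment universe: `"filtered"` (genes entering SAM)
#'   or `"all"` (all genes on the array).
#' @param seed integer seed (sampled permutations).
#' @param out_dir optional directory; when given, every intermediate table
#'   is written there as TSV.
#' @return list of class `"pipeline_result"`: `normalized` (per-slide),
#'   `oriented`, `ratio_matrix`, `sam`, `enrichment` (or NULL), `report`.
#' @export
run_pipeline <- function(slides, design, gene_sets = NULL,
                         z_threshold = -2, span = 0.3, outlier_k = 4,
                         background = c("subtract", "ignore"), floor = 1,
                         k_sd = 3, collapse = "mean",
                         s0 = "auto", n_perm = "exhaustive", fdr_max = 0,
                         pi0 = 1, granularity = c("patient", "slide"),
                         universe = c("filtered", "all"),
                         seed = 1L, out_dir = NULL) {
  background <- match.arg(background)
  universe <- match.arg(universe)
  granularity <- match.arg(granularity)
  validate_design(design)

  stage <- "normalize"
  result <- tryCatch({
    normalized <- lapply(stats::setNames(design$slide_id, design$slide_id),
                         function(sl) {
      lowess_normalize(slides[[sl]], span = span, outlier_k = outlier_k,
                       z_threshold = z_threshold, background = background,
                       floor = floor)
    })

    stage <- "orient_collapse"
    oriented <- orient_and_collapse(normalized, design, collapse = collapse)

    stage <- "concordance_consistency"
    rm0 <- build_ratio_matrix(oriented, design, k_sd = k_sd)
    rmat <- pattern_consistency_filter(rm0)
    sam_input <- kept_matrix(rmat)
    if (granularity == "slide") {
      # same kept genes, but one column per slide (pre-summarization
      # oriented ratios) so the sign-flip null has 2^(2*patients) states
      kept_genes <- rownames(sam_input)
      m8 <- as.matrix(oriented[match(kept_genes, oriented$gene_id),
                               design$slide_id, drop = FALSE])
      rownames(m8) <- kept_genes
      sam_input <- m8[rowSums(!is.finite(m8)) == 0L, , drop = FALSE]
    }

    stage <- "sam"
    sam <- sam_one_class(sam_input, s0 = s0, n_perm = n_perm,
                         fdr_max = fdr_max, pi0 = pi0, seed = seed)

    stage <- "enrichment"
    enr <- NULL
    if (!is.null(gene_sets) && nrow(sam$called) > 0) {
      univ <- if (universe == "filtered") rownames(sam_input) else
        oriented$gene_id
      enr <- hypergeometric_enrichment(sam$called$gene_id, univ, gene_sets)
    }

    n_spots <- vapply(normalized, nrow, integer(1))
    n_low <- vapply(normalized, function(x) sum(x$flag_low_intensity),
                    integer(1))
    n_out <- vapply(normalized, function(x) sum(x$flag_lowess_outlier),
                    integer(1))
    status <- rmat$status
    called_up <- sum(sam$called$direction == "up")
    called_down <- sum(sam$called$direction == "down")
    report <- list(
      n_genes = nrow(oriented),
      n_slides = nrow(design),
      n_patients = length(unique(design$patient_id)),
      spots_total = sum(n_spots),
      spots_flagged_low_intensity = sum(n_low),
      spots_flagged_lowess_outlier = sum(n_out),
      genes_dropped_concordance = sum(status == "dropped_concordance"),
      genes_dropped_missing = sum(status == "dropped_missing"),
      genes_dropped_pattern = sum(status == "dropped_pattern"),
      genes_into_sam = sum(status == "kept"),
      s0 = sam$s0,
      called_total = nrow(sam$called),
      called_up = called_up,
      called_down = called_down,
      delta = attr(sam$called, "delta"),
      fdr = attr(sam$called, "fdr"),
      parameters = list(z_threshold = z_threshold, span = span,
                        outlier_k = outlier_k, background = background,
                        floor = floor, k_sd = k_sd, collapse = collapse,
                        s0 = s0, n_perm = n_perm, fdr_max = fdr_max,
                        pi0 = pi0, granularity = granularity,
                        universe = universe, seed = seed)
    )
    stopifnot(report$called_up + report$called_down == report$called_total)

    structure(list(normalized = normalized, oriented = oriented,
                   ratio_matrix = rmat, sam = sam, enrichment = enr,
                   report = report),
              class = "pipeline_result")
  }, error = function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(c("FAILED", stage, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sl in names(result$normalized))
      write_normalized_slide(result$normalized[[sl]],
                             file.path(out_dir,
                                       sprintf("normalized_%s.tsv", sl)))
    utils::write.table(result$oriented,
                       file.path(out_dir, "oriented_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ratio_matrix(result$ratio_matrix,
                       file.path(out_dir, "ratio_matrix.tsv"))
    if (!is.null(result$sam$stats)) {
      st <- result$sam$stats
      sam_tab <- data.frame(gene_id = rownames(st), st,
                            called = rownames(st) %in%
                              result$sam$called$gene_id,
                            stringsAsFactors = FALSE)
      utils::write.table(sam_tab, file.path(out_dir, "sam_statistics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(result$sam$delta_table,
                         file.path(out_dir, "sam_delta_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(result$sam$called,
                         file.path(out_dir, "called_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(result$enrichment))
      utils::write.table(result$enrichment,
                         file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(format_run_report(result$report),
               file.path(out_dir, "run_report.txt"))
  }
  result
}

#' Format a run report as text lines
#' @param report the `report` component of a `pipeline_result`.
#' @return character vector of report lines.
#' @export
format_run_report <- function(report) {
  p <- report$parameters
  c(
    sprintf("genes on array: %d; slides: %d; patients: %d",
            report$n_genes, report$n_slides, report$n_patients),
    sprintf("spots: %d total, %d flagged low-intensity, %d flagged LOWESS outlier",
            report$spots_total, report$spots_flagged_low_intensity,
            report$spots_flagged_lowess_outlier),
    sprintf("genes dropped: %d concordance, %d missing, %d pattern",
            report$genes_dropped_concordance, report$genes_dropped_missing,
            report$genes_dropped_pattern),
    sprintf("genes into SAM: %d (s0 = %.6g)", report$genes_into_sam,
            report$s0),
    sprintf("called: %d differentially expressed (%d up, %d down) at FDR <= %g",
            report$called_total, report$called_up, report$called_down,
            p$fdr_max),
    sprintf("parameters: z_threshold=%g span=%g outlier_k=%g background=%s k_sd=%g collapse=%s s0=%s n_perm=%s fdr_max=%g pi0=%g granularity=%s universe=%s seed=%d",
            p$z_threshold, p$span, p$outlier_k, p$background, p$k_sd,
            p$collapse, as.character(p$s0), as.character(p$n_perm),
            p$fdr_max, p$pi0, p$granularity, p$universe, as.integer(p$seed))
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(format_run_report(x$report), collapse = "\n"), "\n")
  invisible(x)
}
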