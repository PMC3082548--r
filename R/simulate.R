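#' Configuration for a synthetic dye-swap experiment
#'
#' Bundles and validates every parameter of the synthetic two-channel
#' experiment generator. The defaults emulate a four-patient dye-swap study
#' against a pooled reference: each patient is hybridized on two slides with
#' opposite dye orientation (8 slides total), every gene is spotted in
#' duplicate, an intensity-dependent dye bias is attached to the channels,
#' a small fraction of spots sit near background, and a small fraction of
#' genes carry an artifactual shift on exactly one slide of a swap pair.
#'
#' @param n_genes number of genes on the array.
#' @param n_patients number of patients; each contributes one dye-swap pair
#'   (two slides).
#' @param duplicates_per_gene spots per gene per slide.
#' @param de_fraction fraction of genes planted as differentially expressed
#'   (split evenly up/down).
#' @param de_log2fc planted absolute log2 fold change of DE genes.
#' @param noise_sd standard deviation of the per-spot log2-ratio noise.
#' @param dye_bias_coeffs polynomial coefficients (intercept first) of the
#'   channel-attached dye bias in M as a function of A.
#' @param low_intensity_fraction fraction of spots per slide forced to
#'   near-background intensity.
#' @param discordant_fraction fraction of genes per swap pair given a large
#'   artifactual ratio shift on exactly one slide of the pair.
#' @param discordant_shift absolute size (log2 units) of the artifactual
#'   shift applied to discordant genes.
#' @param baseline_log_intensity_range range (log2 units) of per-gene mean
#'   spot brightness.
#' @param background_level mean additive background intensity per channel.
#' @param seed integer seed; all stochastic draws flow from it.
#'
#' @return A validated list of class `"simulation_config"`.
#' @seealso [simulate_experiment()]
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_patients = 4L,
                              duplicates_per_gene = 2L,
                              de_fraction = 0.05,
                              de_log2fc = 1,
                              noise_sd = 0.25,
                              dye_bias_coeffs = c(-5, 0.5),
                              low_intensity_fraction = 0.02,
                              discordant_fraction = 0.01,
                              discordant_shift = 4,
                              baseline_log_intensity_range = c(6, 16),
                              background_level = 50,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_patients = as.integer(n_patients),
    duplicates_per_gene = as.integer(duplicates_per_gene),
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    noise_sd = noise_sd,
    dye_bias_coeffs = as.numeric(dye_bias_coeffs),
    low_intensity_fraction = low_intensity_fraction,
    discordant_fraction = discordant_fraction,
    discordant_shift = discordant_shift,
    baseline_log_intensity_range = as.numeric(baseline_log_intensity_range),
    background_level = background_level,
    seed = as.integer(seed)
  )
  bad <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) bad("n_genes", "must be >= 1")
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) bad("n_patients", "must be >= 1")
  if (is.na(cfg$duplicates_per_gene) || cfg$duplicates_per_gene < 1L)
    bad("duplicates_per_gene", "must be >= 1")
  for (f in c("de_fraction", "low_intensity_fraction", "discordant_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      bad(f, "must be a proportion in [0, 1]")
  }
  if (!is.numeric(cfg$noise_sd) || is.na(cfg$noise_sd) || cfg$noise_sd < 0)
    bad("noise_sd", "must be >= 0")
  if (!is.numeric(cfg$de_log2fc) || is.na(cfg$de_log2fc))
    bad("de_log2fc", "must be a finite number")
  if (length(cfg$dye_bias_coeffs) < 1L || any(!is.finite(cfg$dye_bias_coeffs)))
    bad("dye_bias_coeffs", "must be finite polynomial coefficients")
  r <- cfg$baseline_log_intensity_range
  if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
    bad("baseline_log_intensity_range", "must be a finite interval [lo, hi]")
  if (!is.finite(cfg$background_level) || cfg$background_level < 0)
    bad("background_level", "must be >= 0")
  if (!is.finite(cfg$discordant_shift))
    bad("discordant_shift", "must be finite")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  class(cfg) <- "simulation_config"
  cfg
}

# Evaluate the dye-bias polynomial (intercept-first coefficients) at A.
dye_bias_curve <- function(a, coeffs) {
  out <- numeric(length(a))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * a^(k - 1)
  out
}

#' Generate a complete synthetic dye-swap experiment
#'
#' Produces per-slide spot tables, the experiment design, and the planted
#' ground truth. Each patient gets one swap pair: on slide 1 the patient
#' sample is in channel 1, on slide 2 in channel 2. The dye bias is attached
#' to the channels — the same curve in M-vs-A is added to raw M on both
#' slides of a pair regardless of which sample sits in which channel — so it
#' does not cancel in oriented ratios until LOWESS normalization removes it.
#' Planted DE genes carry a true patient/reference log2 ratio of
#' `±de_log2fc` in every patient; discordant genes get an additive shift to
#' the oriented ratio on exactly one slide of their pair; low-intensity
#' spots have their brightness forced near background.
#'
#' @param config a [simulation_config()].
#' @return A list with components:
#'   \describe{
#'     \item{slides}{named list of slide tables (`spot_id`, `gene_id`,
#'       `ch1_fg`, `ch1_bg`, `ch2_fg`, `ch2_bg`).}
#'     \item{design}{data frame `slide_id`, `patient_id`, `pair_id`,
#'       `orientation`.}
#'     \item{truth}{list: `de_up`, `de_down` (gene ids), `planted_discordant`
#'       (data frame gene_id/pair_id/slide_id), `planted_low_intensity`
#'       (data frame slide_id/spot_id), `true_log2fc` (named vector).}
#'   }
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  n_de <- round(cfg$n_genes * cfg$de_fraction)
  de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
  n_up <- ceiling(n_de / 2)
  de_up <- de_genes[seq_len(n_up)]
  de_down <- setdiff(de_genes, de_up)
  tau <- stats::setNames(numeric(cfg$n_genes), genes)
  tau[de_up] <- cfg$de_log2fc
  tau[de_down] <- -cfg$de_log2fc

  lo <- cfg$baseline_log_intensity_range[1]
  hi <- cfg$baseline_log_intensity_range[2]
  mu <- stats::setNames(stats::runif(cfg$n_genes, lo, hi), genes)

  design <- data.frame(
    slide_id = sprintf("s%02d", seq_len(2L * cfg$n_patients)),
    patient_id = rep(sprintf("p%d", seq_len(cfg$n_patients)), each = 2L),
    pair_id = rep(sprintf("pair%d", seq_len(cfg$n_patients)), each = 2L),
    orientation = rep(c("patient_in_ch1", "patient_in_ch2"), cfg$n_patients),
    stringsAsFactors = FALSE
  )

  # Pre-draw discordant genes per pair: an additive shift to the oriented
  # ratio on exactly one slide of the pair.
  n_disc <- round(cfg$n_genes * cfg$discordant_fraction)
  disc <- list()
  for (p in seq_len(cfg$n_patients)) {
    if (n_disc == 0) next
    dg <- sample(genes, n_disc)
    side <- sample(c(1L, 2L), n_disc, replace = TRUE)
    sgn <- sample(c(-1, 1), n_disc, replace = TRUE)
    disc[[p]] <- data.frame(
      gene_id = dg,
      pair_id = sprintf("pair%d", p),
      slide_id = design$slide_id[2L * (p - 1L) + side],
      shift = sgn * cfg$discordant_shift,
      stringsAsFactors = FALSE
    )
  }
  disc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(gene_id = character(0), pair_id = character(0),
               slide_id = character(0), shift = numeric(0))

  spot_gene <- rep(genes, each = cfg$duplicates_per_gene)
  spot_id <- sprintf("%s_r%d", spot_gene,
                     rep(seq_len(cfg$duplicates_per_gene), times = cfg$n_genes))
  n_spots <- length(spot_id)

  slides <- vector("list", nrow(design))
  names(slides) <- design$slide_id
  low_planted <- list()

  for (i in seq_len(nrow(design))) {
    sl <- design$slide_id[i]
    orient <- if (design$orientation[i] == "patient_in_ch1") 1 else -1

    a <- mu[spot_gene]
    # low-intensity spots: brightness forced near background
    n_low <- round(n_spots * cfg$low_intensity_fraction)
    if (n_low > 0) {
      idx_low <- sample.int(n_spots, n_low)
      a[idx_low] <- stats::runif(n_low, 1, 3)
      low_planted[[sl]] <- data.frame(slide_id = sl,
                                      spot_id = spot_id[idx_low],
                                      stringsAsFactors = FALSE)
    }

    eps <- if (cfg$noise_sd > 0) stats::rnorm(n_spots, 0, cfg$noise_sd) else
      numeric(n_spots)
    m_oriented <- tau[spot_gene] + eps
    dsl <- disc[disc$slide_id == sl, , drop = FALSE]
    if (nrow(dsl) > 0) {
      hit <- spot_gene %in% dsl$gene_id
      m_oriented[hit] <- m_oriented[hit] +
        dsl$shift[match(spot_gene[hit], dsl$gene_id)]
    }
    # channel-attached bias: added to raw M (ch1 - ch2) on every slide
    m_raw <- orient * m_oriented + dye_bias_curve(a, cfg$dye_bias_coeffs)

    l1 <- a + m_raw / 2
    l2 <- a - m_raw / 2
    bg1 <- stats::runif(n_spots, 0.8, 1.2) * cfg$background_level
    bg2 <- stats::runif(n_spots, 0.8, 1.2) * cfg$background_level
    slides[[sl]] <- data.frame(
      spot_id = spot_id,
      gene_id = spot_gene,
      ch1_fg = 2^l1 + bg1,
      ch1_bg = bg1,
      ch2_fg = 2^l2 + bg2,
      ch2_bg = bg2,
      stringsAsFactors = FALSE
    )
  }

  truth <- list(
    de_up = sort(de_up),
    de_down = sort(de_down),
    planted_discordant = disc[, c("gene_id", "pair_id", "slide_id")],
    planted_low_intensity = if (length(low_planted))
      do.call(rbind, c(low_planted, list(make.row.names = FALSE))) else
      data.frame(slide_id = character(0), spot_id = character(0)),
    true_log2fc = tau
  )
  list(slides = slides, design = design, truth = truth)
}

#' Generate synthetic gene sets over a gene universe
#'
#' Builds a flat gene-set collection (GMT-style) for exercising
#' over-representation analysis: some sets are enriched for a supplied
#' "interesting" gene list, the rest are random draws from the universe.
#'
#' @param genes character vector, the gene universe.
#' @param enriched_in genes to over-represent in the enriched sets.
#' @param n_sets total number of sets.
#' @param n_enriched_sets how many of them are enriched.
#' @param set_size members per set.
#' @param enrichment_weight fraction of an enriched set drawn from
#'   `enriched_in` (the remainder is random).
#' @param seed integer seed.
#' @return named list of class `"gene_set_collection"`; each element has
#'   `description` and `members`.
#' @export
simulate_gene_sets <- function(genes, enriched_in = character(0),
                               n_sets = 20L, n_enriched_sets = 5L,
                               set_size = 30L, enrichment_weight = 0.5,
                               seed = 1L) {
  set.seed(seed)
  enriched_in <- intersect(enriched_in, genes)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  for (j in seq_len(n_sets)) {
    if (j <= n_enriched_sets && length(enriched_in) > 0) {
      k <- min(round(set_size * enrichment_weight), length(enriched_in))
      core <- sample(enriched_in, k)
      rest <- sample(setdiff(genes, core), set_size - k)
      members <- c(core, rest)
      desc <- "enriched synthetic set"
    } else {
      members <- sample(genes, min(set_size, length(genes)))
      desc <- "random synthetic set"
    }
    sets[[j]] <- list(description = desc, members = sort(members))
  }
  structure(sets, class = "gene_set_collection")
}
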