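#' @name assays
#' @title Validation and phenotype assay quantifications
#' @description Closed-form quantifications used alongside the microarray
#'   analysis: relative qPCR quantities by the efficiency-free 2^-dCt
#'   model, fold changes versus a control group, microarray/qPCR platform
#'   concordance, radioactive-incorporation normalization to DNA content,
#'   exponential doubling time from two timepoints, MTT viability
#'   percentages, and the standard two-group tests.
NULL

#' Relative qPCR quantity (2^-dCt)
#'
#' Replicate Ct values of target and reference gene are collapsed (mean by
#' default) and the relative quantity in arbitrary units is
#' `2^-(Ct_target - Ct_reference)` — the efficiency-free delta-Ct model,
#' normalizing the target to the reference transcript content.
#'
#' @param ct_target numeric vector of target-gene Ct replicates.
#' @param ct_reference numeric vector of reference-gene Ct replicates
#'   (e.g. HMBS).
#' @param collapse `"mean"` or `"median"` over Ct replicates.
#' @param efficiency amplification efficiency base (2 = perfect doubling).
#' @return relative quantity (arbitrary units ratio).
#' @export
qpcr_relative_quantity <- function(ct_target, ct_reference,
                                   collapse = c("mean", "median"),
                                   efficiency = 2) {
  collapse <- match.arg(collapse)
  if (length(ct_target) < 1L) stop("no target Ct values", call. = FALSE)
  if (length(ct_reference) < 1L)
    stop("missing reference-gene Ct values", call. = FALSE)
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)) ||
      any(ct_target <= 0) || any(ct_reference <= 0))
    stop("Ct values must be finite and > 0", call. = FALSE)
  f <- if (collapse == "mean") mean else stats::median
  dct <- f(ct_target) - f(ct_reference)
  efficiency^(-dct)
}

#' Fold change of a sample group versus a control group
#'
#' `FC = mean(sample) / mean(control)`; by construction the control group
#' itself maps to 1.
#'
#' @param sample_au numeric vector of sample arbitrary-unit quantities.
#' @param control_au numeric vector of control arbitrary-unit quantities.
#' @return fold change.
#' @export
fold_change_vs_control <- function(sample_au, control_au) {
  m <- mean(control_au)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be > 0", call. = FALSE)
  mean(sample_au) / m
}

#' Pearson concordance between microarray and qPCR fold changes
#'
#' Correlates the two platforms' per-gene fold changes over the shared
#' genes, on the log2 scale by default (symmetric treatment of up- and
#' down-regulation).
#'
#' @param fc_array named numeric vector of microarray fold changes.
#' @param fc_qpcr named numeric vector of qPCR fold changes.
#' @param log2_scale correlate log2 fold changes (default) or raw.
#' @return Pearson correlation coefficient.
#' @export
platform_concordance <- function(fc_array, fc_qpcr, log2_scale = TRUE) {
  shared <- intersect(names(fc_array), names(fc_qpcr))
  if (length(shared) < 3L)
    stop("need >= 3 shared genes for concordance", call. = FALSE)
  x <- fc_array[shared]
  y <- fc_qpcr[shared]
  if (log2_scale) {
    x <- log2(x)
    y <- log2(y)
  }
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite fold changes", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in fold changes; correlation undefined",
         call. = FALSE)
  stats::cor(x, y)
}

#' Doubling time from two timepoints under exponential growth
#'
#' With viable-cell signals at time 0 and after `interval` hours,
#' `T = interval * ln(2) / ln(signal_t1 / signal_t0)` — the only
#' two-point-identifiable growth model. The growth ratio must exceed 1.
#'
#' @param signal_t0 viable-cell signal at time 0 (> 0).
#' @param signal_t1 viable-cell signal after `interval` hours (> 0).
#' @param interval elapsed time in hours (> 0).
#' @return doubling time in hours.
#' @export
doubling_time <- function(signal_t0, signal_t1, interval = 72) {
  if (!is.finite(signal_t0) || signal_t0 <= 0 ||
      !is.finite(signal_t1) || signal_t1 <= 0)
    stop("signals must be finite and > 0", call. = FALSE)
  if (!is.finite(interval) || interval <= 0)
    stop("interval must be > 0", call. = FALSE)
  if (signal_t1 <= signal_t0)
    stop("no net growth; doubling time undefined", call. = FALSE)
  interval * log(2) / log(signal_t1 / signal_t0)
}

#' Viability percentage from reference-corrected optical densities
#'
#' MTT-style readout: absorbance at the measurement wavelength minus the
#' reference wavelength, treated over untreated, as a percentage.
#'
#' @param treated_od550,treated_od620 treated-well ODs (measurement and
#'   reference wavelength).
#' @param untreated_od550,untreated_od620 untreated-well ODs.
#' @return percent viability (100 = same as untreated).
#' @export
viability_percent <- function(treated_od550, treated_od620,
                              untreated_od550, untreated_od620) {
  denom <- untreated_od550 - untreated_od620
  if (!is.finite(denom) || denom <= 0)
    stop("nonpositive untreated corrected OD", call. = FALSE)
  100 * (treated_od550 - treated_od620) / denom
}

#' Normalize radioactive incorporation to DNA content
#'
#' `cpm / OD260`: counts per minute divided by the DNA absorbance, so the
#' incorporation readout is independent of cell number.
#'
#' @param cpm counts per minute (>= 0).
#' @param dna_od260 DNA absorbance at 260 nm (> 0).
#' @return normalized incorporation.
#' @export
normalize_cpm_to_dna <- function(cpm, dna_od260) {
  if (!is.finite(dna_od260) || dna_od260 <= 0)
    stop("dna_od260 must be > 0", call. = FALSE)
  cpm / dna_od260
}

#' Two-group comparison (unpaired t or Mann-Whitney, two-tailed)
#'
#' @param a,b numeric vectors (the two groups).
#' @param method `"t_unpaired_two_tailed"` (classical equal-variance
#'   Student's t) or `"mann_whitney_two_tailed"` (exact when no ties and
#'   groups are small).
#' @return list: `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(a, b,
                           method = c("t_unpaired_two_tailed",
                                      "mann_whitney_two_tailed")) {
  method <- match.arg(method)
  if (method == "t_unpaired_two_tailed") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t test needs >= 2 values per group", call. = FALSE)
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
      stop("zero pooled variance; t undefined", call. = FALSE)
    ht <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  } else {
    if (length(a) < 1L || length(b) < 1L)
      stop("Mann-Whitney needs >= 1 value per group", call. = FALSE)
    ht <- stats::wilcox.test(a, b, alternative = "two.sided")
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method)
}
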