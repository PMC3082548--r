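#' Working intensities under the background policy
#'
#' The raw tables carry foreground and background per channel; whether
#' background is subtracted is a preprocessing decision. Under
#' `"subtract"`, working intensity is `max(fg - bg, floor)`; under
#' `"ignore"` it is the foreground. The floor keeps log2 defined.
#'
#' @param slide slide table.
#' @param background `"subtract"` or `"ignore"`.
#' @param floor lower bound applied after subtraction.
#' @return list with numeric vectors `ch1` and `ch2`.
#' @export
working_intensities <- function(slide, background = c("subtract", "ignore"),
                                floor = 1) {
  background <- match.arg(background)
  if (background == "subtract") {
    list(ch1 = pmax(slide$ch1_fg - slide$ch1_bg, floor),
         ch2 = pmax(slide$ch2_fg - slide$ch2_bg, floor))
  } else {
    list(ch1 = pmax(slide$ch1_fg, floor), ch2 = pmax(slide$ch2_fg, floor))
  }
}

#' Flag low-intensity spots by per-channel Z-score
#'
#' Transforms each channel's working intensities to log2 and standardizes
#' per channel per slide; a spot is flagged when its z-score falls below
#' `z_threshold` in either channel. Flagged spots are excluded from all
#' later stages of that slide. If a channel has zero spread, all its
#' z-scores are defined as 0 (degenerate input flags nothing).
#'
#' @param slide slide table.
#' @param z_threshold flag spots with z below this (default -2, i.e. more
#'   than 2 SD below the channel mean on the log scale).
#' @param background,floor see [working_intensities()].
#' @return logical vector, `TRUE` for flagged spots.
#' @export
filter_low_intensity <- function(slide, z_threshold = -2,
                                 background = c("subtract", "ignore"),
                                 floor = 1) {
  if (nrow(slide) == 0L) stop("empty slide", call. = FALSE)
  w <- working_intensities(slide, background, floor)
  zscore <- function(x) {
    lx <- log2(x)
    s <- stats::sd(lx)
    if (!is.finite(s) || s == 0) return(rep(0, length(lx)))
    (lx - mean(lx)) / s
  }
  flag <- zscore(w$ch1) < z_threshold | zscore(w$ch2) < z_threshold
  if (all(flag)) stop("no spots survive intensity filter", call. = FALSE)
  flag
}

#' LOWESS intensity balancing of one slide
#'
#' Computes per-spot `A = (log2 ch1' + log2 ch2')/2` and
#' `M_raw = log2 ch1' - log2 ch2'` from the working intensities, flags
#' low-intensity spots, fits a robust LOWESS of M on A over the unflagged
#' spots, and subtracts the fit: `M_norm = M_raw - fit(A)`. Spots whose
#' final residual exceeds `outlier_k` residual SDs are flagged
#' `lowess_outlier` and their `M_norm` withheld. The residual scale is, by
#' default, the classical SD over all residuals: artifact contamination
#' then widens the outlier band, whereas a highly resistant scale (MAD,
#' available via `scale = "mad"`) shrinks the band onto the noise floor and
#' discards genuinely regulated spots whose log ratios sit a few noise SDs
#' off zero. Normalization is location-only in M: A values and spot count
#' are unchanged — spots are flagged, never deleted.
#'
#' @param slide slide table.
#' @param span LOWESS smoother span (fraction of points per local fit).
#' @param robust_iters robustness iterations of the LOWESS fit.
#' @param outlier_k residuals beyond this many residual SDs are discarded.
#' @param scale residual scale estimator for the outlier rule: `"sd"`
#'   (classical, default) or `"mad"` (median absolute deviation about 0,
#'   scaled to the normal).
#' @param z_threshold,background,floor passed to [filter_low_intensity()].
#' @param min_spots minimum unflagged spots required to fit.
#' @return data frame of class `"normalized_slide"`: `spot_id`, `gene_id`,
#'   `A`, `M_raw`, `M_norm`, `flag_low_intensity`, `flag_lowess_outlier`.
#' @export
lowess_normalize <- function(slide, span = 0.3, robust_iters = 3,
                             outlier_k = 4, z_threshold = -2,
                             background = c("subtract", "ignore"),
                             floor = 1, min_spots = 20L,
                             scale = c("sd", "mad")) {
  background <- match.arg(background)
  scale <- match.arg(scale)
  w <- working_intensities(slide, background, floor)
  low <- filter_low_intensity(slide, z_threshold, background, floor)
  a <- (log2(w$ch1) + log2(w$ch2)) / 2
  m <- log2(w$ch1) - log2(w$ch2)

  use <- which(!low)
  if (length(use) < min_spots)
    stop(sprintf("only %d spots survive the intensity filter (< %d needed)",
                 length(use), min_spots), call. = FALSE)

  fit_at <- rep(NA_real_, nrow(slide))
  if (stats::sd(m[use]) == 0) {
    # constant M: the trend is that constant; nothing to smooth
    fit_at[use] <- m[use][1]
  } else {
    lw <- stats::lowess(a[use], m[use], f = span, iter = robust_iters)
    if (any(!is.finite(lw$y))) stop("non-finite LOWESS fit", call. = FALSE)
    ux <- !duplicated(lw$x)
    if (sum(ux) == 1L) {
      fit_at[use] <- lw$y[ux]
    } else {
      fit_at[use] <- stats::approx(lw$x[ux], lw$y[ux], xout = a[use],
                                   rule = 2)$y
    }
  }
  resid <- m - fit_at

  rsd <- if (scale == "sd") stats::sd(resid[use]) else
    stats::mad(resid[use], center = 0)
  out_flag <- rep(FALSE, nrow(slide))
  # a numerically zero residual scale means a perfect fit, not outliers
  if (is.finite(rsd) && rsd > 1e-8)
    out_flag[use] <- abs(resid[use]) > outlier_k * rsd

  m_norm <- resid
  m_norm[low | out_flag] <- NA_real_
  res <- data.frame(
    spot_id = slide$spot_id,
    gene_id = slide$gene_id,
    A = a,
    M_raw = m,
    M_norm = m_norm,
    flag_low_intensity = low,
    flag_lowess_outlier = out_flag,
    stringsAsFactors = FALSE
  )
  class(res) <- c("normalized_slide", "data.frame")
  res
}

#' Write a normalized slide as TSV
#' @param norm a `normalized_slide`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_normalized_slide <- function(norm, path) {
  utils::write.table(norm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
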