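#' SAM relative-difference statistic (one-class)
#'
#' For each gene with replicate values x_1..x_n, the statistic is
#' `d = x_bar / (se + s0)` where `x_bar` is the mean, `se = sd/sqrt(n)` is
#' the standard error of the mean, and `s0 >= 0` is the fudge factor that
#' stabilizes genes with tiny variance. With `s0 = 0`, d is exactly the
#' classical one-sample t statistic.
#'
#' @param mat numeric matrix, genes x replicates (n >= 2), all finite.
#' @param s0 fudge factor (>= 0).
#' @return data frame: `x_bar`, `se`, `d` (rownames = gene ids).
#' @export
sam_statistic <- function(mat, s0 = 0) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n < 2L) stop("need >= 2 replicates per gene", call. = FALSE)
  if (any(!is.finite(mat))) stop("non-finite values in SAM input", call. = FALSE)
  if (!is.finite(s0) || s0 < 0) stop("s0 must be >= 0", call. = FALSE)
  x_bar <- rowMeans(mat)
  se <- sqrt(pmax(rowSums((mat - x_bar)^2), 0) / (n - 1)) / sqrt(n)
  denom <- se + s0
  d <- numeric(nrow(mat))
  zero <- denom == 0
  if (any(zero & x_bar != 0))
    stop("degenerate statistic: se + s0 = 0 with nonzero mean", call. = FALSE)
  d[!zero] <- x_bar[!zero] / denom[!zero]
  data.frame(x_bar = x_bar, se = se, d = d,
             row.names = rownames(mat), stringsAsFactors = FALSE)
}

#' Choose the SAM fudge factor s0
#'
#' Candidates are the percentiles of the per-gene standard errors from the
#' 0th to the 100th in steps of 5. Genes are binned into se-quantile
#' windows; for each candidate, the scale (MAD) of the d statistics within
#' each window is computed, and the candidate minimizing the coefficient of
#' variation of these window scales is chosen — the value that makes the
#' spread of d most independent of se. Ties go to the smallest candidate.
#'
#' @param mat genes x replicates matrix.
#' @param n_windows number of se-quantile windows.
#' @return list: `s0` (chosen value), `candidates`, `cv` (per candidate).
#' @export
choose_s0 <- function(mat, n_windows = 10L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 genes to select s0", call. = FALSE)
  st <- sam_statistic(mat, s0 = 0)
  se <- st$se
  probs <- seq(0, 1, by = 0.05)
  candidates <- unname(stats::quantile(se, probs, type = 7))
  if (length(unique(se)) == 1L)
    return(list(s0 = se[1], candidates = candidates,
                cv = rep(NA_real_, length(candidates))))
  breaks <- unique(stats::quantile(se, seq(0, 1, length.out = n_windows + 1L),
                                   type = 7))
  win <- cut(se, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(candidates, function(s0c) {
    d <- st$x_bar / (se + s0c)
    v <- tapply(d, win, function(di)
      if (length(di) >= 2L) stats::mad(di) else NA_real_)
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  list(s0 = candidates[which.min(cv)], candidates = candidates, cv = cv)
}

# All 2^n sign vectors as an n-column matrix (exhaustive one-class null).
sign_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), n), KEEP.OUT.ATTRS = FALSE))
}

#' One-class permutation null: expected order statistics
#'
#' The one-class null hypothesis is mean zero, so the permutation group is
#' the set of sign assignments to replicates: for each permutation, every
#' gene's replicate vector is multiplied by the same +/-1 sign vector and d
#' is recomputed with s0 held fixed at its observed-data value. The
#' expected order statistic `d_bar_(i)` is the mean over permutations of
#' the i-th smallest permuted d.
#'
#' @param mat genes x replicates matrix.
#' @param s0 fudge factor (fixed from observed data).
#' @param n_perm `"exhaustive"` (all 2^n sign vectors, allowed when
#'   2^n <= `exhaustive_cap`) or a count of sign vectors sampled without
#'   replacement.
#' @param seed integer seed for sampled mode.
#' @param exhaustive_cap largest 2^n still enumerated exhaustively.
#' @return list: `expected` (sorted expected order statistics),
#'   `perm_d_sorted` (permutations x genes matrix of sorted permuted d),
#'   `signs` (the sign vectors used).
#' @export
permutation_null <- function(mat, s0, n_perm = "exhaustive", seed = 1L,
                             exhaustive_cap = 4096L) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  total <- 2^n
  if (identical(n_perm, "exhaustive")) {
    if (total > exhaustive_cap)
      stop(sprintf("exhaustive null needs 2^%d <= %d sign vectors", n,
                   exhaustive_cap), call. = FALSE)
    signs <- sign_vectors(n)
  } else {
    n_perm <- as.integer(n_perm)
    if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
    set.seed(seed)
    if (total <= exhaustive_cap) {
      all_signs <- sign_vectors(n)
      idx <- sample.int(nrow(all_signs), min(n_perm, nrow(all_signs)))
      signs <- all_signs[idx, , drop = FALSE]
    } else {
      # sample distinct sign vectors without materializing all 2^n
      seen <- new.env(hash = TRUE)
      rows <- vector("list", n_perm)
      got <- 0L
      while (got < n_perm) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        key <- paste(s, collapse = "")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          rows[[got]] <- s
        }
      }
      signs <- do.call(rbind, rows)
    }
  }
  ss <- rowSums(mat^2)
  perm_d <- matrix(NA_real_, nrow = nrow(signs), ncol = nrow(mat))
  for (b in seq_len(nrow(signs))) {
    xbar <- as.numeric(mat %*% signs[b, ]) / n
    se <- sqrt(pmax(ss - n * xbar^2, 0) / (n - 1)) / sqrt(n)
    denom <- se + s0
    d <- ifelse(denom == 0, 0, xbar / denom)
    perm_d[b, ] <- sort(d)
  }
  list(expected = colMeans(perm_d), perm_d_sorted = perm_d, signs = signs)
}

# Asymmetric cutpoints for a given delta (original SAM definition).
# d_sorted and expected are the sorted observed and expected order
# statistics; i0 is the index where the expected null crosses zero.
sam_cutpoints <- function(d_sorted, expected, delta) {
  g <- length(d_sorted)
  i0 <- which.min(abs(expected))
  diff <- d_sorted - expected
  up_idx <- which(seq_len(g) >= i0 & diff >= delta)
  lo_idx <- which(seq_len(g) <= i0 & -diff >= delta)
  list(cut_up = if (length(up_idx)) d_sorted[min(up_idx)] else Inf,
       cut_low = if (length(lo_idx)) d_sorted[max(lo_idx)] else -Inf)
}

#' Delta / FDR table for a SAM analysis
#'
#' For each delta, the asymmetric cutpoints are the smallest observed
#' (sorted) d whose displacement above the expected order statistic
#' reaches delta on the upper side, and the largest on the lower side.
#' Genes beyond the cutpoints are called; the false-call count of each
#' permutation is the number of its d values beyond the same cutpoints;
#' the FDR estimate is `pi0 * median(false calls) / n_called`, defined as 0
#' when nothing is called, clamped to [0, 1].
#'
#' @param d observed per-gene d statistics.
#' @param null output of [permutation_null()].
#' @param deltas increasing thresholds to tabulate; default: every distinct
#'   observed |displacement| (plus 0), so every achievable calling set
#'   appears in the table.
#' @param pi0 multiplier for the fraction of truly null genes (default 1,
#'   no correction).
#' @return data frame of class `"sam_delta_table"`: `delta`, `cut_low`,
#'   `cut_up`, `n_called`, `median_false`, `fdr`.
#' @export
fdr_table <- function(d, null, deltas = NULL, pi0 = 1) {
  d_sorted <- sort(d)
  expected <- null$expected
  stopifnot(length(d_sorted) == length(expected))
  if (is.null(deltas)) {
    deltas <- sort(unique(c(0, abs(d_sorted - expected))))
    if (length(deltas) > 512L)
      deltas <- unique(c(0, stats::quantile(abs(d_sorted - expected),
                                            seq(0, 1, length.out = 512L),
                                            names = FALSE)))
  }
  if (length(deltas) == 0L) stop("empty delta list", call. = FALSE)
  deltas <- sort(deltas)
  perm <- null$perm_d_sorted
  n_perm <- nrow(perm)
  res <- data.frame(delta = deltas, cut_low = NA_real_, cut_up = NA_real_,
                    n_called = NA_integer_, median_false = NA_real_,
                    fdr = NA_real_)
  for (k in seq_along(deltas)) {
    cp <- sam_cutpoints(d_sorted, expected, deltas[k])
    called <- d >= cp$cut_up | d <= cp$cut_low
    n_called <- sum(called)
    false_counts <- vapply(seq_len(n_perm), function(b) {
      row <- perm[b, ]
      sum(row >= cp$cut_up) + sum(row <= cp$cut_low)
    }, numeric(1))
    med_false <- stats::median(false_counts)
    fdr <- if (n_called == 0L) 0 else min(1, max(0, pi0 * med_false / n_called))
    res$cut_low[k] <- cp$cut_low
    res$cut_up[k] <- cp$cut_up
    res$n_called[k] <- n_called
    res$median_false[k] <- med_false
    res$fdr[k] <- fdr
  }
  class(res) <- c("sam_delta_table", "data.frame")
  res
}

#' Call genes at an FDR ceiling
#'
#' Selects the smallest delta whose estimated FDR is at or below `fdr_max`
#' (the default 0 implements "only genes with 0% FDR": the median
#' false-call count must be zero) and partitions the called genes by the
#' sign of d.
#'
#' @param stats data frame from [sam_statistic()] (rownames = gene ids).
#' @param table a `sam_delta_table`.
#' @param fdr_max FDR ceiling in [0, 1].
#' @return data frame: `gene_id`, `d`, `direction` (`"up"`/`"down"`), plus
#'   attributes `delta`, `fdr`, `cut_low`, `cut_up`. Empty (with a warning)
#'   when no delta meets the ceiling.
#' @export
call_genes <- function(stats, table, fdr_max = 0) {
  ok <- which(table$fdr <= fdr_max & table$n_called > 0)
  empty <- data.frame(gene_id = character(0), d = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (nrow(stats) == 0L) {
    warning("empty SAM input; nothing to call", call. = FALSE)
    return(empty)
  }
  if (length(ok) == 0L) {
    warning(sprintf("no delta achieves FDR <= %g; empty call set", fdr_max),
            call. = FALSE)
    attr(empty, "delta") <- NA_real_
    attr(empty, "fdr") <- NA_real_
    return(empty)
  }
  k <- ok[1]
  called <- stats$d >= table$cut_up[k] | stats$d <= table$cut_low[k]
  out <- data.frame(gene_id = rownames(stats)[called],
                    d = stats$d[called],
                    direction = ifelse(stats$d[called] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$d)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "delta") <- table$delta[k]
  attr(out, "fdr") <- table$fdr[k]
  attr(out, "cut_low") <- table$cut_low[k]
  attr(out, "cut_up") <- table$cut_up[k]
  out
}

#' One-class SAM analysis
#'
#' Convenience wrapper: chooses (or accepts) s0, computes the observed
#' statistics, builds the sign-flip permutation null, tabulates the
#' delta/FDR curve, and calls genes at the requested FDR ceiling.
#'
#' @param mat genes x replicates matrix of summarized log2 ratios.
#' @param s0 `"auto"` (CV-minimizing percentile of se) or a fixed value.
#' @param n_perm `"exhaustive"` or a count (see [permutation_null()]).
#' @param fdr_max FDR ceiling for calling (default 0).
#' @param deltas optional delta grid.
#' @param pi0 null-fraction multiplier (default 1).
#' @param seed seed for sampled permutations.
#' @return list of class `"sam_result"`: `stats`, `s0`, `null`,
#'   `delta_table`, `called`.
#' @export
sam_one_class <- function(mat, s0 = "auto", n_perm = "exhaustive",
                          fdr_max = 0, deltas = NULL, pi0 = 1, seed = 1L) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L) {
    warning("empty SAM input; nothing to call", call. = FALSE)
    return(structure(list(stats = NULL, s0 = NA_real_, null = NULL,
                          delta_table = NULL,
                          called = data.frame(gene_id = character(0),
                                              d = numeric(0),
                                              direction = character(0))),
                     class = "sam_result"))
  }
  s0_val <- if (identical(s0, "auto")) choose_s0(mat)$s0 else as.numeric(s0)
  st <- sam_statistic(mat, s0 = s0_val)
  null <- permutation_null(mat, s0 = s0_val, n_perm = n_perm, seed = seed)
  tab <- fdr_table(st$d, null, deltas = deltas, pi0 = pi0)
  called <- call_genes(st, tab, fdr_max = fdr_max)
  structure(list(stats = st, s0 = s0_val, null = null, delta_table = tab,
                 called = called),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("One-class SAM result\n")
  if (is.null(x$stats)) {
    cat("  (empty input)\n")
    return(invisible(x))
  }
  cat(sprintf("  genes: %d, replicates: %d, s0 = %.6g\n",
              nrow(x$stats), ncol(x$null$signs), x$s0))
  cat(sprintf("  called: %d (up %d, down %d) at delta = %.4g, FDR = %.4g\n",
              nrow(x$called), sum(x$called$direction == "up"),
              sum(x$called$direction == "down"),
              attr(x$called, "delta"), attr(x$called, "fdr")))
  invisible(x)
}
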