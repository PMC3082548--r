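# Independent brute-force oracles, written with plain loops so they share
# no code path with the package implementation.

naive_d <- function(values, s0) {
  xbar <- mean(values)
  se <- sd(values) / sqrt(length(values))
  if (se + s0 == 0) return(0)
  xbar / (se + s0)
}

# Every sign assignment of the replicates, enumerated explicitly.
naive_null <- function(mat, s0) {
  n <- ncol(mat)
  combos <- expand.grid(rep(list(c(-1, 1)), n))
  perm_d <- t(apply(combos, 1, function(s) {
    sort(apply(sweep(mat, 2, as.numeric(s), "*"), 1, naive_d, s0 = s0))
  }))
  list(expected = colMeans(perm_d), perm_d_sorted = perm_d)
}

# Naive asymmetric-cutpoint FDR for one delta.
naive_fdr_row <- function(d, null, delta) {
  ds <- sort(d)
  dbar <- null$expected
  i0 <- which.min(abs(dbar))
  cut_up <- Inf
  for (i in seq(i0, length(ds)))
    if (ds[i] - dbar[i] >= delta) { cut_up <- ds[i]; break }
  cut_low <- -Inf
  for (i in seq(i0, 1))
    if (dbar[i] - ds[i] >= delta) { cut_low <- ds[i]; break }
  n_called <- sum(d >= cut_up | d <= cut_low)
  falses <- apply(null$perm_d_sorted, 1,
                  function(row) sum(row >= cut_up | row <= cut_low))
  med <- median(falses)
  list(n_called = n_called, median_false = med,
       fdr = if (n_called == 0) 0 else min(1, med / n_called))
}
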