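make_norm <- function(gene_id, m_norm, flags = rep(FALSE, length(m_norm))) {
  structure(data.frame(
    spot_id = sprintf("s%03d", seq_along(m_norm)),
    gene_id = gene_id,
    A = rep(10, length(m_norm)),
    M_raw = m_norm,
    M_norm = ifelse(flags, NA_real_, m_norm),
    flag_low_intensity = rep(FALSE, length(m_norm)),
    flag_lowess_outlier = flags,
    stringsAsFactors = FALSE
  ), class = c("normalized_slide", "data.frame"))
}

test_that("duplicate spots collapse by mean over unflagged spots with orientation sign", {
  design <- tiny_design()[1:2, ]
  n1 <- make_norm(c("g1", "g1"), c(1.0, 1.2))
  n2 <- make_norm(c("g1", "g1"), c(1.0, 1.2))
  o <- orient_and_collapse(list(s01 = n1, s02 = n2), design)
  expect_equal(o$s01[o$gene_id == "g1"], 1.1)   # patient in ch1
  expect_equal(o$s02[o$gene_id == "g1"], -1.1)  # patient in ch2: sign flip

  n3 <- make_norm(c("g1", "g1"), c(0.5, 0.8), flags = c(TRUE, FALSE))
  o <- orient_and_collapse(list(s01 = n3, s02 = n2), design)
  expect_equal(o$s01[o$gene_id == "g1"], 0.8)   # mean over unflagged only

  n4 <- make_norm(c("g1", "g1"), c(0.5, 0.8), flags = c(TRUE, TRUE))
  o <- orient_and_collapse(list(s01 = n4, s02 = n2), design)
  expect_true(is.na(o$s01[o$gene_id == "g1"]))  # all spots flagged: missing

  expect_error(orient_and_collapse(list(s01 = n1), design),
               "no normalized slide")
})

test_that("the 3SD concordance rule removes exactly a planted discordant gene", {
  set.seed(5)
  n <- 1001
  delta <- c(rnorm(n - 1, 0, 0.1), 10)
  r2 <- rnorm(n, 0, 0.3)
  r1 <- r2 + delta
  cf <- concordance_filter(r1, r2, k_sd = 3)
  # oracle: mean and SD computed over all deltas, planted one included
  mu <- mean(delta); sdv <- sd(delta)
  oracle_drop <- which(abs(delta - mu) > 3 * sdv)
  expect_equal(which(!cf$concordant), oracle_drop)
  expect_equal(which(!cf$concordant), n)

  # perfect concordance is always retained
  expect_true(cf$concordant[which(abs(delta) < 1e-3)[1]])

  # degenerate SD: identical deltas, nothing strictly exceeds 0, all kept
  cf0 <- concordance_filter(rep(2, 10) + 0.5, rep(2, 10) - 0.5, k_sd = 3)
  expect_true(all(cf0$concordant))

  expect_error(concordance_filter(c(1, NA), c(NA, 1)), ">= 2 genes")
})

test_that("patient summary is the log2 geometric mean of the pair ratios", {
  # ratios {2, 8}: GM 4, log2 = 2
  expect_equal(summarize_patient(log2(2), log2(8)), 2)
  # reciprocal pair {0.5, 2}: GM 1, log2 = 0
  expect_equal(summarize_patient(log2(0.5), log2(2)), 0)
  # log/GM identity to near machine precision
  set.seed(2)
  r1 <- runif(50, 0.1, 10); r2 <- runif(50, 0.1, 10)
  v <- summarize_patient(log2(r1), log2(r2))
  expect_equal(2^v, sqrt(r1 * r2), tolerance = 1e-12)
  # discordant genes are withheld
  expect_true(is.na(summarize_patient(1, 2, concordant = FALSE)))
})

test_that("pattern consistency keeps strictly same-signed genes only", {
  vals <- rbind(g1 = c(0.4, 1.1, 0.2, 0.9),
                g2 = c(0.4, 1.1, -0.2, 0.9),
                g3 = c(0.4, 0, 0.2, 0.9),
                g4 = c(-0.4, -1.1, -0.2, -0.9))
  rm <- structure(list(
    values = vals,
    status = setNames(rep("kept", 4), rownames(vals)),
    direction = setNames(rep(NA_character_, 4), rownames(vals)),
    pair_stats = NULL), class = "ratio_matrix")
  out <- pattern_consistency_filter(rm)
  expect_equal(unname(out$status),
               c("kept", "dropped_pattern", "dropped_pattern", "kept"))
  expect_equal(unname(out$direction[c("g1", "g4")]), c("up", "down"))
  expect_equal(rownames(kept_matrix(out)), c("g1", "g4"))
})

test_that("dye-swap symmetry: swapping channels and orientation labels leaves ratios unchanged", {
  cfg <- simulation_config(n_genes = 80, n_patients = 1, de_fraction = 0.1,
                           noise_sd = 0, dye_bias_coeffs = 0,
                           low_intensity_fraction = 0,
                           discordant_fraction = 0, seed = 21)
  ex <- simulate_experiment(cfg)
  norm <- lapply(ex$slides, lowess_normalize, background = "subtract")
  o1 <- orient_and_collapse(norm, ex$design)

  swap_channels <- function(sl) {
    data.frame(spot_id = sl$spot_id, gene_id = sl$gene_id,
               ch1_fg = sl$ch2_fg, ch1_bg = sl$ch2_bg,
               ch2_fg = sl$ch1_fg, ch2_bg = sl$ch1_bg,
               stringsAsFactors = FALSE)
  }
  flipped <- lapply(ex$slides, swap_channels)
  design2 <- ex$design
  design2$orientation <- ifelse(design2$orientation == "patient_in_ch1",
                                "patient_in_ch2", "patient_in_ch1")
  norm2 <- lapply(flipped, lowess_normalize, background = "subtract")
  o2 <- orient_and_collapse(norm2, design2)
  expect_equal(o1, o2, tolerance = 1e-9)
})

test_that("the filter chain shrinks the kept set monotonically", {
  cfg <- simulation_config(n_genes = 400, n_patients = 3, seed = 13)
  ex <- simulate_experiment(cfg)
  norm <- lapply(ex$slides, lowess_normalize)
  oriented <- orient_and_collapse(norm, ex$design)
  rm0 <- build_ratio_matrix(oriented, ex$design)
  rm1 <- pattern_consistency_filter(rm0)
  complete_genes <- oriented$gene_id[rowSums(is.na(oriented[, -1])) == 0]
  kept0 <- names(rm0$status)[rm0$status == "kept"]
  kept1 <- names(rm1$status)[rm1$status == "kept"]
  expect_true(all(kept0 %in% complete_genes))
  expect_true(all(kept1 %in% kept0))
  # every dropped gene has exactly one recorded reason
  expect_true(all(rm1$status %in% c("kept", "dropped_concordance",
                                    "dropped_missing", "dropped_pattern")))
})
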