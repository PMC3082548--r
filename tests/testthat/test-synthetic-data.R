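test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(de_fraction = 1.5), "de_fraction")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(duplicates_per_gene = 0), "duplicates_per_gene")
  expect_error(simulation_config(baseline_log_intensity_range = c(10, 5)),
               "baseline_log_intensity_range")
})

test_that("no signal, no noise, no bias gives oriented ratios of zero on every slide", {
  ex <- simulate_experiment(simulation_config(
    n_genes = 50, n_patients = 2, de_fraction = 0, noise_sd = 0,
    dye_bias_coeffs = 0, low_intensity_fraction = 0,
    discordant_fraction = 0, seed = 3))
  for (i in seq_len(nrow(ex$design))) {
    sl <- ex$slides[[ex$design$slide_id[i]]]
    r <- raw_oriented_ratios(sl, ex$design$orientation[i])
    # exact up to float rounding of foreground = signal + background
    expect_lt(max(abs(r)), 1e-9)
  }
})

test_that("planted effects are conserved exactly through noise-free generation", {
  cfg <- simulation_config(n_genes = 200, n_patients = 2, de_fraction = 0.1,
                           de_log2fc = 1.5, noise_sd = 0, dye_bias_coeffs = 0,
                           low_intensity_fraction = 0,
                           discordant_fraction = 0, seed = 11)
  ex <- simulate_experiment(cfg)
  tau <- ex$truth$true_log2fc
  expect_length(union(ex$truth$de_up, ex$truth$de_down),
                round(200 * 0.1))
  expect_length(intersect(ex$truth$de_up, ex$truth$de_down), 0)
  for (i in seq_len(nrow(ex$design))) {
    sl <- ex$slides[[ex$design$slide_id[i]]]
    r <- raw_oriented_ratios(sl, ex$design$orientation[i])
    expect_lt(max(abs(r - tau[sl$gene_id])), 1e-9)
  }
})

test_that("dye bias is additive in raw M and attached to the channels", {
  coeffs <- c(-5, 0.5)
  cfg <- simulation_config(n_genes = 100, n_patients = 2, de_fraction = 0.1,
                           noise_sd = 0, dye_bias_coeffs = coeffs,
                           low_intensity_fraction = 0,
                           discordant_fraction = 0, seed = 5)
  ex <- simulate_experiment(cfg)
  tau <- ex$truth$true_log2fc
  for (i in seq_len(nrow(ex$design))) {
    sl <- ex$slides[[ex$design$slide_id[i]]]
    l1 <- log2(sl$ch1_fg - sl$ch1_bg)
    l2 <- log2(sl$ch2_fg - sl$ch2_bg)
    a <- (l1 + l2) / 2
    m_raw <- l1 - l2
    orient <- if (ex$design$orientation[i] == "patient_in_ch1") 1 else -1
    bias <- coeffs[1] + coeffs[2] * a
    # raw M minus the bias curve equals the oriented true ratio; the bias
    # term itself does not change sign with orientation (it follows the dye)
    expect_lt(max(abs((m_raw - bias) - orient * tau[sl$gene_id])), 1e-8)
  }
})

test_that("planted up-gene ratios average to the planted effect within sampling error", {
  cfg <- simulation_config(n_genes = 2000, de_fraction = 0.05, de_log2fc = 1,
                           noise_sd = 0.25, dye_bias_coeffs = 0,
                           low_intensity_fraction = 0,
                           discordant_fraction = 0, seed = 101)
  ex <- simulate_experiment(cfg)
  up <- ex$truth$de_up
  # per-gene mean over the 8 slides (duplicates collapsed per slide)
  per_slide <- sapply(seq_len(nrow(ex$design)), function(i) {
    sl <- ex$slides[[ex$design$slide_id[i]]]
    r <- raw_oriented_ratios(sl, ex$design$orientation[i])
    tapply(r, sl$gene_id, mean)[up]
  })
  gene_means <- rowMeans(per_slide)
  expect_true(all(abs(gene_means - 1) < 3 * 0.25 / sqrt(8)))
  expect_lt(abs(mean(gene_means) - 1), 0.05)
})

test_that("the generator is deterministic given the seed", {
  cfg <- simulation_config(n_genes = 60, n_patients = 2, seed = 77)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex1$slides, ex2$slides)
  expect_identical(ex1$design, ex2$design)
  expect_identical(ex1$truth, ex2$truth)
})

test_that("planted artifacts respect their configured frequencies and placement", {
  cfg <- simulation_config(n_genes = 500, n_patients = 3,
                           low_intensity_fraction = 0.02,
                           discordant_fraction = 0.01, seed = 9)
  ex <- simulate_experiment(cfg)
  disc <- ex$truth$planted_discordant
  expect_equal(nrow(disc), round(500 * 0.01) * 3)
  # each discordant entry names exactly one slide of its pair
  for (k in seq_len(nrow(disc))) {
    pair_slides <- ex$design$slide_id[ex$design$pair_id == disc$pair_id[k]]
    expect_true(disc$slide_id[k] %in% pair_slides)
  }
  low <- ex$truth$planted_low_intensity
  expect_equal(nrow(low), round(500 * 2 * 0.02) * 6)
})

test_that("synthetic gene sets are reproducible and enriched sets carry the target genes", {
  genes <- sprintf("g%05d", 1:300)
  hits <- genes[1:30]
  gs1 <- simulate_gene_sets(genes, enriched_in = hits, seed = 4)
  gs2 <- simulate_gene_sets(genes, enriched_in = hits, seed = 4)
  expect_identical(gs1, gs2)
  n_hit <- vapply(gs1, function(s) length(intersect(s$members, hits)),
                  integer(1))
  expect_true(all(n_hit[1:5] >= 10))  # enriched sets: half the members
})
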