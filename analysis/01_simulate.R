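#!/usr/bin/env Rscript
# Generate the synthetic experiment all later steps analyze: a 4-patient
# dye-swap study against a pooled reference (8 slides, 2,000 genes spotted
# in duplicate), with channel-attached dye bias M = 0.5*A - 5, spot noise
# SD 0.25, 5% planted DE genes at |log2FC| = 1, 1% discordant genes per
# pair and 2% near-background spots — plus gene sets and assay tables for
# the validation steps.

library(dyeswapr)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1L)
ex <- simulate_experiment(cfg)

for (sl in names(ex$slides))
  write_slide_table(ex$slides[[sl]],
                    sprintf("results/data/slide_%s.tsv", sl))
write_design(ex$design, "results/data/design.tsv")

truth <- data.frame(
  gene_id = names(ex$truth$true_log2fc),
  truth_class = ifelse(names(ex$truth$true_log2fc) %in% ex$truth$de_up, "up",
                ifelse(names(ex$truth$true_log2fc) %in% ex$truth$de_down,
                       "down", "null")),
  true_log2fc = unname(ex$truth$true_log2fc)
)
write.table(truth, "results/data/ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

gs <- simulate_gene_sets(truth$gene_id,
                         enriched_in = c(ex$truth$de_up, ex$truth$de_down),
                         n_sets = 25, n_enriched_sets = 6, seed = 2L)
write_gene_sets(gs, "results/data/gene_sets.gmt")

# qPCR validation panel: 11 transcripts measured in 4 patient and 3 control
# cultures, duplicate Ct values per reaction, one reference gene per sample.
set.seed(3)
panel <- truth$gene_id[truth$truth_class != "null"][1:11]
qpcr <- do.call(rbind, lapply(c(sprintf("p%d", 1:4), sprintf("c%d", 1:3)),
  function(smp) {
    is_patient <- startsWith(smp, "p")
    rows <- lapply(panel, function(g) {
      fc <- truth$true_log2fc[truth$gene_id == g]
      ct <- 25 - (if (is_patient) fc else 0) + rnorm(2, 0, 0.15)
      data.frame(sample_id = smp, gene = g, ct = round(ct, 3),
                 is_reference = FALSE)
    })
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = smp, gene = "REF",
      ct = round(20 + rnorm(2, 0, 0.1), 3), is_reference = TRUE)
    do.call(rbind, rows)
  }))
write.csv(qpcr, "results/data/qpcr_ct.csv", row.names = FALSE)

# two-timepoint growth assay (luminescence at 0 h and 72 h)
growth <- data.frame(
  sample_id = c(sprintf("p%d", 1:4), sprintf("c%d", 1:3)),
  signal_t0 = 1000,
  signal_t1 = round(1000 * 2^(72 / c(95, 105, 118, 72, 70, 74, 68)), 1),
  interval_h = 72
)
write.csv(growth, "results/data/growth.csv", row.names = FALSE)

# MTT viability plate: treated and untreated corrected ODs per sample
set.seed(4)
viab <- expand.grid(sample_id = c(sprintf("p%d", 1:4), sprintf("c%d", 1:3)),
                    condition = c("untreated", "drugA", "drugB"),
                    stringsAsFactors = FALSE)
viab$od620 <- round(runif(nrow(viab), 0.04, 0.06), 3)
base <- ifelse(viab$condition == "untreated", 1.0,
        ifelse(viab$condition == "drugA",
               ifelse(startsWith(viab$sample_id, "p"), 0.85, 0.55), 0.70))
viab$od550 <- round(viab$od620 + base + rnorm(nrow(viab), 0, 0.03), 3)
write.csv(viab, "results/data/viability.csv", row.names = FALSE)

cat(sprintf(
  "wrote %d slides (%d spots each), %d planted DE genes (%d up / %d down),\n",
  length(ex$slides), nrow(ex$slides[[1]]),
  length(ex$truth$de_up) + length(ex$truth$de_down),
  length(ex$truth$de_up), length(ex$truth$de_down)))
cat(sprintf("%d gene sets, qPCR panel of %d transcripts, growth and viability tables under results/data/\n",
            length(gs), length(panel)))
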