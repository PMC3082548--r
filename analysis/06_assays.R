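#!/usr/bin/env Rscript
# Validation and phenotype assays: relative qPCR quantities (2^-dCt against
# the reference transcript), fold changes versus the control group,
# microarray-vs-qPCR Pearson concordance, doubling times from the
# two-timepoint growth assay, and MTT viability percentages with two-group
# tests.

library(dyeswapr)

qpcr <- read.csv("results/data/qpcr_ct.csv")
truth <- read.delim("results/data/ground_truth.tsv")
rmat <- read.delim("results/ratio_matrix.tsv", check.names = FALSE)

# per-sample, per-gene arbitrary-units quantities
au <- do.call(rbind, lapply(split(qpcr, qpcr$sample_id), function(sub) {
  ref <- sub$ct[sub$is_reference]
  genes <- unique(sub$gene[!sub$is_reference])
  data.frame(sample_id = sub$sample_id[1], gene = genes,
             au = vapply(genes, function(g)
               qpcr_relative_quantity(sub$ct[sub$gene == g], ref),
               numeric(1)))
}))

panel <- unique(au$gene)
fc_qpcr <- vapply(panel, function(g) {
  fold_change_vs_control(au$au[au$gene == g & startsWith(au$sample_id, "p")],
                         au$au[au$gene == g & startsWith(au$sample_id, "c")])
}, numeric(1))

patients <- setdiff(names(rmat), c("gene_id", "status", "direction"))
fc_array <- vapply(panel, function(g) {
  v <- as.numeric(rmat[rmat$gene_id == g, patients])
  2^mean(v)
}, numeric(1))
shared <- panel[is.finite(fc_array)]
r <- platform_concordance(fc_array[shared], fc_qpcr[shared])

qout <- data.frame(gene = panel, fc_qpcr = round(fc_qpcr, 3),
                   fc_array = round(fc_array, 3))
write.table(qout, "results/qpcr_fold_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("microarray vs qPCR fold changes over %d shared transcripts: Pearson r = %.2f (log2 scale)\n",
            length(shared), r))

growth <- read.csv("results/data/growth.csv")
growth$doubling_h <- round(mapply(doubling_time, growth$signal_t0,
                                  growth$signal_t1, growth$interval_h), 1)
write.table(growth, "results/doubling_times.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
pat <- growth$doubling_h[startsWith(growth$sample_id, "p")]
ctl <- growth$doubling_h[startsWith(growth$sample_id, "c")]
tt <- compare_groups(pat, ctl)
cat(sprintf("doubling times: patients %s h vs controls %s h (t = %.2f, p = %.3f)\n",
            paste(pat, collapse = "/"), paste(ctl, collapse = "/"),
            tt$statistic, tt$p_value))

viab <- read.csv("results/data/viability.csv")
untr <- viab[viab$condition == "untreated", ]
rows <- lapply(setdiff(unique(viab$condition), "untreated"), function(cond) {
  sub <- viab[viab$condition == cond, ]
  pct <- mapply(function(sid, od5, od6) {
    u <- untr[untr$sample_id == sid, ]
    viability_percent(od5, od6, u$od550, u$od620)
  }, sub$sample_id, sub$od550, sub$od620)
  data.frame(condition = cond, sample_id = sub$sample_id,
             viability_pct = round(pct, 1))
})
viab_out <- do.call(rbind, rows)
write.table(viab_out, "results/viability_percent.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (cond in unique(viab_out$condition)) {
  sub <- viab_out[viab_out$condition == cond, ]
  a <- sub$viability_pct[startsWith(sub$sample_id, "p")]
  b <- sub$viability_pct[startsWith(sub$sample_id, "c")]
  mw <- compare_groups(a, b, method = "mann_whitney_two_tailed")
  cat(sprintf("%s: patient viability %.0f%% vs control %.0f%% (Mann-Whitney p = %.2f)\n",
              cond, mean(a), mean(b), mw$p_value))
}
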