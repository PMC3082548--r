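#!/usr/bin/env Rscript
# Over-representation of the called genes in the synthetic gene sets:
# one-sided hypergeometric test against the filtered-gene universe,
# reported as changed/total counts with p-values, plus the up/down
# category summary of the called list.

library(dyeswapr)

sets <- read_gene_sets("results/data/gene_sets.gmt")
st <- read.delim("results/sam_statistics.tsv")
called_tab <- read.delim("results/called_genes.tsv")

universe <- st$gene_id
enr <- hypergeometric_enrichment(called_tab$gene_id, universe, sets,
                                 adjust = TRUE)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("top gene sets by over-representation (changed/total, one-sided p):\n")
top <- head(enr, 8)
top$p_value <- signif(top$p_value, 3)
top$adjusted_p <- signif(top$adjusted_p, 3)
print(top, row.names = FALSE)

cmap <- lapply(sets, function(s) s$members)
summ <- summarize_categories(called_tab, cmap)
summ <- summ[summ$n_total > 0, ]
write.table(summ, "results/category_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d categories contain called genes; up/down split written to results/category_summary.tsv\n",
            sum(summ$category != "unclassified")))
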