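#!/usr/bin/env Rscript
# Stage 5: single-sample enrichment. KS-walk scores of the polarization
# signatures and module categories per sample, plus chi-squared category
# enrichment of the active-cohort DE list.

library(slemod)

fx <- "results/fixtures"
eset <- read_expression_tsv(file.path(fx, "expr.tsv"), file.path(fx, "meta.tsv"))
cats <- read_gmt(file.path(fx, "categories.gmt"))

st <- gene_level_stats(eset)
scores <- score_gene_sets(st, cats)
write.table(data.frame(sample_id = rownames(scores), scores),
            "results/gsva_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
coh <- eset$samples$cohort
for (s in colnames(scores)) {
  cat(sprintf("%-12s mean score: HC %+.2f, inactive %+.2f, active %+.2f\n", s,
              mean(scores[coh == "HC", s]),
              mean(scores[coh == "SLE_inactive", s]),
              mean(scores[coh == "SLE_active", s])))
}

de_a <- read.delim("results/de_active.tsv")
ce <- category_enrichment(de_a$gene, rownames(eset$values), cats)
print(ce[, c("category", "n_de_in", "n_bg_in", "chi2", "p", "significant")],
      row.names = FALSE)
write.table(ce, "results/category_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
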