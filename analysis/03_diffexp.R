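#!/usr/bin/env Rscript
# Stage 3: moderated-t differential expression of each SLE cohort against
# healthy controls at FDR < 0.2, M1/M2 polarization fractions, and the
# fold-change comparison of genes upregulated in both cohorts.

library(slemod)

fx <- "results/fixtures"
eset <- read_expression_tsv(file.path(fx, "expr.tsv"), file.path(fx, "meta.tsv"))
pol <- read_gmt(file.path(fx, "polarization.gmt"))

ids <- eset$samples$sample_id
hc <- ids[eset$samples$cohort == "HC"]
active <- ids[eset$samples$cohort == "SLE_active"]
inactive <- ids[eset$samples$cohort == "SLE_inactive"]

de_a <- fit_moderated_t(eset, active, hc)
de_i <- fit_moderated_t(eset, inactive, hc)
sel_a <- select_de(de_a, fdr_cut = 0.2)
sel_i <- select_de(de_i, fdr_cut = 0.2)
cat(sprintf("DE genes at FDR<0.2: active %d, inactive %d (of %d)\n",
            nrow(sel_a), nrow(sel_i), nrow(eset$values)))
write.table(sel_a, "results/de_active.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sel_i, "results/de_inactive.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pf <- rbind(cbind(cohort = "SLE_active", polarization_fraction(sel_a, pol)),
            cbind(cohort = "SLE_inactive", polarization_fraction(sel_i, pol)))
print(pf, row.names = FALSE)
write.table(pf, "results/polarization_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- common_foldchange_compare(sel_a, sel_i, signatures = pol)
cat(sprintf("commonly upregulated genes: %d; median delta M1 %+.2f, M2 %+.2f\n",
            nrow(cmp),
            median(cmp$delta[cmp$signature == "M1"]),
            median(cmp$delta[cmp$signature == "M2"])))
write.table(cmp, "results/common_foldchange.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
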