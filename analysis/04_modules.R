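#!/usr/bin/env Rscript
# Stage 4: weighted co-expression modules. Soft threshold by scale-free
# fit, TOM, branch-cut module detection with eigengene merging and kME
# reassignment, module quality, and module-trait correlations against
# SLEDAI and cohort.

library(slemod)

fx <- "results/fixtures"
eset <- read_expression_tsv(file.path(fx, "expr.tsv"), file.path(fx, "meta.tsv"))

beta <- pick_soft_threshold(eset)
cat(sprintf("soft threshold: power %d (scale-free R^2 %.2f)\n", beta,
            attr(beta, "fit_table")$r_squared[
              attr(beta, "fit_table")$power == as.numeric(beta)]))

tom <- compute_tom(eset, beta)
ms <- compute_kme_and_reassign(eset, detect_modules(tom, eset))
sizes <- table(ms$assignment[ms$assignment != "grey"])
cat("modules:", paste(names(sizes), sizes, collapse = ", "),
    "| unassigned:", sum(ms$assignment == "grey"), "\n")
cat("mean kME:", paste(names(ms$mean_kme), round(ms$mean_kme, 2),
                       collapse = ", "), "\n")

kme_own <- rep(NA_real_, length(ms$assignment))
assigned <- ms$assignment != "grey"
kme_own[assigned] <- ms$kme[cbind(names(ms$assignment)[assigned],
                                  ms$assignment[assigned])]
assign_tab <- data.frame(gene = names(ms$assignment),
                         module = unname(ms$assignment),
                         kme_own = kme_own)
write.table(assign_tab, "results/module_assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(ms$me), ms$me),
            "results/module_eigengenes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

samples <- eset$samples
samples$active <- samples$cohort == "SLE_active"
mt <- correlate_module_traits(ms, samples, c("sledai", "active"))
print(mt, row.names = FALSE)
write.table(mt, "results/module_trait_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
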