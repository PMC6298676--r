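#!/usr/bin/env Rscript
# Stage 1: generate the synthetic myeloid-cell study.
#
# One single-cohort dataset (healthy / inactive SLE / active SLE, 20 each)
# carrying three planted co-expression modules (SLEDAI correlations +0.8,
# -0.6, 0) and M1/M2 polarization signatures (M1 up in both SLE cohorts,
# stronger in active; M2 up in both, stronger in inactive), plus a
# 3-dataset collection with per-gene batch offsets for the merge and
# classification stages. Everything downstream reads these files.

library(slemod)

seed <- 1L
outdir <- "results/fixtures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config()  # the study's default conditions
manifest <- write_fixtures(cfg, outdir, seed = seed)
cat("fixture files:", paste(unlist(manifest$files), collapse = ", "), "\n")

# multi-dataset collection for merge/classification
cfg_coll <- synthetic_config(
  n_hc = 2, n_inactive = 40, n_active = 40, n_genes = 600,
  modules = c(list(module_spec(50, 0.8, 0.8)),
              lapply(1:5, function(i) module_spec(50, 0.8, 0))),
  m1_genes = 0, m2_genes = 0, n_datasets = 3, batch_shift_sd = 1)
coll <- generate_collection(cfg_coll, seed = seed)
for (i in seq_along(coll)) {
  write_expression_tsv(coll[[i]]$eset,
                       file.path(outdir, sprintf("coll_expr_%d.tsv", i)),
                       file.path(outdir, sprintf("coll_meta_%d.tsv", i)))
}
truth <- coll[[1]]$truth$module_of_gene
mods <- lapply(paste0("mod", 1:6), function(m) names(truth)[truth == m])
names(mods) <- paste0("CT_", paste0("mod", 1:6))
write_gmt(mods, file.path(outdir, "coll_modules.gmt"))
jsonlite::write_json(list(seed = seed, n_datasets = length(coll),
                          linked_module = "CT_mod1"),
                     file.path(outdir, "coll_provenance.json"),
                     auto_unbox = TRUE)
cat("collection:", length(coll), "datasets x",
    ncol(coll[[1]]$eset$values), "samples\n")
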