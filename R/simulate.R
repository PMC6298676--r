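#' Specification of one planted co-expression module
#'
#' @param size Number of member genes (at least 3).
#' @param factor_loading Loading of member genes on the module's latent
#'   factor, in (0, 1] (log2 units per factor SD).
#' @param trait_corr Target Pearson correlation between the module factor
#'   and SLEDAI, in (-1, 1).
#' @return A \code{module_spec} list.
#' @export
module_spec <- function(size, factor_loading = 0.8, trait_corr = 0) {
  stopifnot(size >= 3, factor_loading > 0, factor_loading <= 1)
  if (abs(trait_corr) >= 1) stop("trait_corr magnitude must be below 1")
  structure(list(size = as.integer(size), factor_loading = factor_loading,
                 trait_corr = trait_corr), class = "module_spec")
}

#' Configuration of the synthetic expression generator
#'
#' Defaults emulate a purified myeloid-cell case/control study: three
#' cohorts (healthy controls, inactive SLE with SLEDAI 0-5, active SLE with
#' SLEDAI 6-20), a handful of planted co-expression modules whose latent
#' factors track disease activity, M1/M2 polarization signature genes whose
#' log2 fold changes versus healthy follow the observed pattern (M1 up in
#' both SLE cohorts and larger in active disease; M2 up in both but larger
#' in inactive disease), and optional multi-dataset structure with additive
#' per-gene batch offsets.
#'
#' @param n_hc,n_inactive,n_active Samples per cohort.
#' @param n_genes Total genes (module + signature sizes must fit within).
#' @param modules List of \code{\link{module_spec}}s.
#' @param m1_genes,m2_genes Number of M1 / M2 signature genes.
#' @param lfc Named numeric vector of log2 fold changes vs healthy controls:
#'   \code{M1_inactive}, \code{M1_active}, \code{M2_inactive},
#'   \code{M2_active}.
#' @param noise_sd Residual SD in log2 units.
#' @param n_datasets Number of datasets for \code{\link{generate_collection}}.
#' @param batch_shift_sd SD of the per-dataset, per-gene additive offset.
#' @param seed Default RNG seed.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_hc = 20, n_inactive = 20, n_active = 20,
                             n_genes = 2000,
                             modules = list(
                               module_spec(100, 0.8, 0.8),
                               module_spec(100, 0.8, -0.6),
                               module_spec(100, 0.8, 0)
                             ),
                             m1_genes = 50, m2_genes = 50,
                             lfc = c(M1_inactive = 1.0, M1_active = 2.0,
                                     M2_inactive = 1.5, M2_active = 0.4),
                             noise_sd = 1, n_datasets = 2,
                             batch_shift_sd = 1, seed = 1L) {
  stopifnot(n_hc > 0, n_inactive > 0, n_active > 0, n_genes > 0,
            m1_genes >= 0, m2_genes >= 0, noise_sd > 0,
            n_datasets >= 1, batch_shift_sd >= 0)
  stopifnot(all(c("M1_inactive", "M1_active", "M2_inactive", "M2_active") %in%
                  names(lfc)))
  msize <- sum(vapply(modules, `[[`, 0L, "size"))
  if (msize + m1_genes + m2_genes > n_genes) {
    stop("module and signature sizes exceed n_genes")
  }
  structure(list(n_hc = n_hc, n_inactive = n_inactive, n_active = n_active,
                 n_genes = n_genes, modules = modules,
                 m1_genes = m1_genes, m2_genes = m2_genes, lfc = lfc,
                 noise_sd = noise_sd, n_datasets = n_datasets,
                 batch_shift_sd = batch_shift_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic RNG scope
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# gene-level structure shared across datasets of one collection
build_structure <- function(config, seed) {
  with_rng(seed, {
    g_ids <- sprintf("G%05d", seq_len(config$n_genes))
    module_of_gene <- rep("none", config$n_genes)
    pos <- 1L
    for (i in seq_along(config$modules)) {
      sz <- config$modules[[i]]$size
      module_of_gene[pos:(pos + sz - 1L)] <- paste0("mod", i)
      pos <- pos + sz
    }
    signature_of_gene <- rep("none", config$n_genes)
    if (config$m1_genes > 0) {
      signature_of_gene[pos:(pos + config$m1_genes - 1L)] <- "M1"
      pos <- pos + config$m1_genes
    }
    if (config$m2_genes > 0) {
      signature_of_gene[pos:(pos + config$m2_genes - 1L)] <- "M2"
    }
    list(gene_ids = g_ids,
         module_of_gene = stats::setNames(module_of_gene, g_ids),
         signature_of_gene = stats::setNames(signature_of_gene, g_ids),
         mu = stats::setNames(stats::runif(config$n_genes, 6, 10), g_ids))
  })
}

#' Generate one synthetic expression dataset with planted truth
#'
#' Expression follows \eqn{x_{gs} = \mu_g + \lambda_g f_{m(g),s} +
#' \beta_{g,cohort(s)} + \epsilon_{gs}} with Gaussian residuals. Each module
#' factor is coupled to SLEDAI through a Gaussian copula on ranks: the
#' normal-scores transform of SLEDAI is mixed with independent noise at a
#' weight calibrated so the realized Pearson correlation with SLEDAI matches
#' the module's \code{trait_corr} target. SLEDAI is 0 for healthy controls,
#' an integer in 0-5 for inactive SLE and 6-20 for active SLE. M1/M2
#' signature genes receive cohort-specific additive shifts from
#' \code{config$lfc}.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param seed RNG seed (defaults to \code{config$seed}); identical
#'   (config, seed) pairs give bit-identical output.
#' @param dataset_id Dataset label stamped into the sample metadata.
#' @param sample_prefix Prefix for generated sample ids.
#' @param structure Internal: pre-built gene structure shared across the
#'   datasets of a collection.
#' @return A list with \code{eset} (an \code{\link{expr_set}}) and
#'   \code{truth} (module and signature membership, latent factors, cohort
#'   labels, SLEDAI, seed).
#' @export
generate_dataset <- function(config, seed = config$seed, dataset_id = "DS1",
                             sample_prefix = "S", structure = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  for (m in config$modules) {
    if (abs(m$trait_corr) >= 1) stop("trait_corr magnitude must be below 1")
  }
  if (is.null(structure)) structure <- build_structure(config, seed)
  n <- config$n_hc + config$n_inactive + config$n_active
  with_rng(seed + 1L, {
    cohort <- c(rep("HC", config$n_hc),
                rep("SLE_inactive", config$n_inactive),
                rep("SLE_active", config$n_active))
    sledai <- c(rep(0, config$n_hc),
                sample(0:5, config$n_inactive, replace = TRUE),
                sample(6:20, config$n_active, replace = TRUE))
    # normal-scores transform of SLEDAI (midranks for ties)
    zt <- stats::qnorm(rank(sledai, ties.method = "average") / (n + 1))
    zt <- as.vector(scale(zt))
    c_attain <- stats::cor(zt, sledai)  # attainable correlation through the copula
    K <- length(config$modules)
    fac <- matrix(0, n, K)
    if (K > 0) colnames(fac) <- paste0("mod", seq_len(K))
    for (i in seq_len(K)) {
      rho <- config$modules[[i]]$trait_corr
      a <- rho / c_attain
      if (abs(a) > 1) {
        warning("trait_corr ", rho, " exceeds the attainable copula ",
                "correlation ", round(c_attain, 3), "; using the maximum")
        a <- sign(a)
      }
      fac[, i] <- a * zt + sqrt(1 - a^2) * stats::rnorm(n)
    }
    beta <- matrix(0, config$n_genes, n)
    sig <- structure$signature_of_gene
    for (s in c("M1", "M2")) {
      rows <- which(sig == s)
      if (!length(rows)) next
      beta[rows, cohort == "SLE_inactive"] <- config$lfc[[paste0(s, "_inactive")]]
      beta[rows, cohort == "SLE_active"] <- config$lfc[[paste0(s, "_active")]]
    }
    lambda <- numeric(config$n_genes)
    fmat <- matrix(0, config$n_genes, n)
    mod <- structure$module_of_gene
    for (i in seq_len(K)) {
      rows <- which(mod == paste0("mod", i))
      lambda[rows] <- config$modules[[i]]$factor_loading
      fmat[rows, ] <- matrix(fac[, i], length(rows), n, byrow = TRUE)
    }
    eps <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                  config$n_genes, n)
    vals <- structure$mu + lambda * fmat + beta + eps
    sample_ids <- sprintf("%s%03d", sample_prefix, seq_len(n))
    dimnames(vals) <- list(structure$gene_ids, sample_ids)
    meta <- data.frame(sample_id = sample_ids,
                       dataset_id = dataset_id,
                       cohort = cohort,
                       sledai = sledai,
                       stringsAsFactors = FALSE)
    truth <- list(module_of_gene = structure$module_of_gene,
                  signature_of_gene = structure$signature_of_gene,
                  latent_factors = fac,
                  labels = stats::setNames(cohort, sample_ids),
                  sledai = stats::setNames(sledai, sample_ids),
                  seed = seed)
    list(eset = expr_set(vals, meta, row_level = "gene"), truth = truth)
  })
}

#' Generate a multi-dataset collection with batch effects
#'
#' All datasets share the gene structure (baselines, module membership,
#' signature effects) but have independent samples, and each dataset
#' receives an independent per-gene additive batch offset drawn from
#' \eqn{N(0, batch\_shift\_sd^2)}.
#'
#' @param config A \code{\link{synthetic_config}} with
#'   \code{n_datasets >= 2}.
#' @param seed Base RNG seed (defaults to \code{config$seed}).
#' @return A list of \code{list(eset, truth)} pairs, one per dataset, with
#'   dataset ids \code{DS1, DS2, ...} and disjoint sample ids.
#' @export
generate_collection <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"), config$n_datasets >= 2)
  structure <- build_structure(config, seed)
  lapply(seq_len(config$n_datasets), function(d) {
    ds <- generate_dataset(config, seed = seed + 1000L * d,
                           dataset_id = paste0("DS", d),
                           sample_prefix = sprintf("DS%d_S", d),
                           structure = structure)
    shift <- with_rng(seed + 1000L * d + 500L,
                      stats::rnorm(config$n_genes, sd = config$batch_shift_sd))
    ds$eset$values <- ds$eset$values + shift
    ds$truth$batch_shift <- stats::setNames(shift, rownames(ds$eset$values))
    ds
  })
}

#' Write a synthetic fixture directory
#'
#' Emits \code{expr.tsv}, \code{meta.tsv}, \code{polarization.gmt} (the M1
#' and M2 signature gene lists), \code{categories.gmt} (each planted module
#' plus the signatures as functional categories), \code{truth.json} and
#' \code{manifest.json}.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param outdir Output directory (created if absent).
#' @param seed RNG seed.
#' @return Invisibly, the manifest list (files and seed).
#' @export
write_fixtures <- function(config = synthetic_config(), outdir,
                           seed = config$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config, seed = seed)
  paths <- file.path(outdir, c("expr.tsv", "meta.tsv", "polarization.gmt",
                               "categories.gmt", "truth.json", "manifest.json"))
  names(paths) <- c("expr", "meta", "polarization", "categories", "truth",
                    "manifest")
  write_expression_tsv(ds$eset, paths[["expr"]], paths[["meta"]])
  sig <- ds$truth$signature_of_gene
  pol <- list(M1 = names(sig)[sig == "M1"], M2 = names(sig)[sig == "M2"])
  attr(pol, "descriptions") <- c(M1 = "proinflammatory polarization signature",
                                 M2 = "anti-inflammatory polarization signature")
  write_gmt(pol, paths[["polarization"]])
  mod <- ds$truth$module_of_gene
  cats <- lapply(sort(unique(mod[mod != "none"])),
                 function(m) names(mod)[mod == m])
  names(cats) <- sort(unique(mod[mod != "none"]))
  cats <- c(cats, pol)
  write_gmt(cats, paths[["categories"]])
  truth_json <- list(module_of_gene = as.list(ds$truth$module_of_gene),
                     signature_of_gene = as.list(ds$truth$signature_of_gene),
                     labels = as.list(ds$truth$labels),
                     sledai = as.list(ds$truth$sledai),
                     seed = seed)
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(files = as.list(stats::setNames(basename(paths[-6]),
                                                   names(paths)[-6])),
                   seed = seed)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE)
  invisible(manifest)
}
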