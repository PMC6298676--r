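#' Rank-based gene-level statistics for single-sample enrichment
#'
#' Each gene's values across samples are converted to midranks, mapped to
#' (0, 1) as rank/(n + 1), and passed through the standard normal quantile
#' function. The resulting z-like statistic is invariant to any strictly
#' monotone per-gene transform of the input; a constant gene yields 0 for
#' every sample.
#'
#' @param eset A gene-level \code{\link{expr_set}} with at least 4 samples.
#' @return Genes x samples numeric matrix.
#' @export
gene_level_stats <- function(eset) {
  stopifnot(inherits(eset, "expr_set"), ncol(eset$values) >= 4)
  n <- ncol(eset$values)
  out <- t(apply(eset$values, 1L, function(x) {
    stats::qnorm(rank(x, ties.method = "average") / (n + 1))
  }))
  dimnames(out) <- dimnames(eset$values)
  out
}

# KS-like random walk for one sample: genes ranked by decreasing statistic
# (ties broken by position for determinism); up-steps |stat|^tau
# (normalized) at in-set genes, down-steps 1/(N - |S|) elsewhere. Returns
# c(es_pos, es_neg) as magnitudes. The signed ordering is what lets the
# score distinguish coordinately up- from down-shifted samples.
ks_walk <- function(stat, in_set, tau) {
  ord <- order(stat, decreasing = TRUE)
  inset <- in_set[ord]
  w <- abs(stat[ord])^tau
  up <- ifelse(inset, w, 0)
  tot_up <- sum(up)
  if (tot_up <= 0) up[inset] <- 1 / sum(inset) else up <- up / tot_up
  down <- ifelse(inset, 0, 1 / (length(stat) - sum(in_set)))
  walk <- cumsum(up - down)
  c(es_pos = max(c(0, walk)), es_neg = max(c(0, -walk)))
}

#' Single-sample gene-set scores via a KS-like random walk
#'
#' Per sample, genes are ranked by decreasing statistic and a
#' Kolmogorov-Smirnov-like random walk is run: up-steps weighted by
#' |statistic|^tau at in-set genes, uniform down-steps elsewhere. With \code{mode = "diff"} the score
#' is the maximum positive deviation minus the maximum negative deviation
#' magnitude; with \code{mode = "maxabs"} it is the single deviation
#' largest in magnitude, with its sign. Scores lie in [-1, 1].
#'
#' @param stats_matrix Genes x samples matrix from
#'   \code{\link{gene_level_stats}}.
#' @param collection Named list of gene-symbol vectors; each set is
#'   intersected with the matrix rows before scoring (overlap sizes are
#'   attached as an attribute) and a set with empty overlap yields
#'   \code{NA} scores. A set covering every gene is an error.
#' @param tau Weight exponent on |statistic| for the up-steps.
#' @param mode Score mode, \code{"diff"} or \code{"maxabs"}.
#' @return Samples x gene-sets matrix of scores with attribute
#'   \code{overlap} (genes per set actually used).
#' @export
score_gene_sets <- function(stats_matrix, collection, tau = 1,
                            mode = c("diff", "maxabs")) {
  mode <- match.arg(mode)
  genes <- rownames(stats_matrix)
  n_genes <- nrow(stats_matrix)
  overlap <- vapply(collection, function(s) sum(genes %in% s), 0L)
  if (any(overlap == n_genes)) {
    stop("gene set covering all genes: ",
         paste(names(collection)[overlap == n_genes], collapse = ", "))
  }
  scores <- matrix(NA_real_, ncol(stats_matrix), length(collection),
                   dimnames = list(colnames(stats_matrix), names(collection)))
  for (j in seq_along(collection)) {
    if (overlap[j] == 0L) next
    in_set <- genes %in% collection[[j]]
    for (s in seq_len(ncol(stats_matrix))) {
      es <- ks_walk(stats_matrix[, s], in_set, tau)
      scores[s, j] <- if (mode == "diff") es[1L] - es[2L]
                      else if (es[1L] >= es[2L]) es[1L] else -es[2L]
    }
  }
  attr(scores, "overlap") <- overlap
  attr(scores, "tau") <- tau
  attr(scores, "mode") <- mode
  scores
}

#' Chi-squared functional-category enrichment of a DE gene list
#'
#' For each category a 2x2 table (DE / not DE x in / out of category) is
#' built over the background and tested with a 1-df chi-squared statistic
#' without continuity correction; categories with p < 0.05 are flagged
#' significant. When any expected cell count falls below 1 the chi-squared
#' test is replaced by Fisher's exact test and the row is flagged
#' \code{exact}.
#'
#' @param de_genes Character vector of DE gene symbols (subset of
#'   \code{background}).
#' @param background Character vector of all tested gene symbols.
#' @param categories Named list of gene-symbol vectors.
#' @return data.frame: category, n_de_in, n_de_out, n_bg_in, n_bg_out,
#'   chi2, p, exact, significant.
#' @export
category_enrichment <- function(de_genes, background, categories) {
  background <- unique(background)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% background)) stop("de_genes must be a subset of background")
  is_de <- background %in% de_genes
  res <- lapply(names(categories), function(nm) {
    in_cat <- background %in% categories[[nm]]
    tab <- table(factor(is_de, c(FALSE, TRUE)), factor(in_cat, c(FALSE, TRUE)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      p <- stats::fisher.test(tab)$p.value
      chi2 <- NA_real_
      exact <- TRUE
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      chi2 <- unname(ct$statistic)
      p <- ct$p.value
      exact <- FALSE
    }
    data.frame(category = nm,
               n_de_in = sum(is_de & in_cat), n_de_out = sum(is_de & !in_cat),
               n_bg_in = sum(in_cat), n_bg_out = sum(!in_cat),
               chi2 = chi2, p = p, exact = exact,
               significant = p < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
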