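# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to moment-match the prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Moderated two-group differential expression
#'
#' Per-gene two-sample contrast with empirical-Bayes variance moderation:
#' the pooled residual variance \eqn{s^2} (with \eqn{d = n_a + n_b - 2}
#' degrees of freedom) is shrunk toward a prior variance \eqn{s_0^2} with
#' prior degrees of freedom \eqn{d_0}, both estimated by moment matching on
#' \eqn{\log s^2} (digamma/trigamma inversion). The posterior variance is
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)} and the moderated t
#' statistic \eqn{\Delta / (\tilde{s} \sqrt{1/n_a + 1/n_b})} is referred to
#' a t distribution with \eqn{d + d_0} degrees of freedom.
#'
#' @param eset An \code{\link{expr_set}}.
#' @param group_a,group_b Disjoint character vectors of sample ids; the
#'   contrast is mean(a) - mean(b), so pass the disease cohort as
#'   \code{group_a} and healthy controls as \code{group_b} for fold changes
#'   "versus HC".
#' @return A data.frame (one row per gene): \code{gene}, \code{log2fc},
#'   \code{s2}, \code{df}, \code{t}, \code{p}, \code{fdr},
#'   \code{direction}; attributes \code{d0} and \code{s02} hold the
#'   hyperparameters.
#' @export
fit_moderated_t <- function(eset, group_a, group_b) {
  stopifnot(inherits(eset, "expr_set"))
  ids <- eset$samples$sample_id
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (!all(c(group_a, group_b) %in% ids)) stop("unknown sample id(s)")
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  xa <- eset$values[, group_a, drop = FALSE]
  xb <- eset$values[, group_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  d <- na + nb - 2
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / d
  # moment matching on log s^2 (genes with s^2 = 0 excluded from fitting)
  z <- log(s2[s2 > 0])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))
  delta <- ma - mb
  tstat <- delta / sqrt(s2_post * (1 / na + 1 / nb))
  # total df capped at the pooled residual df across genes: moderation can
  # never claim more information than the experiment contains
  df_total <- min(d + d0, d * nrow(eset$values))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = rownames(eset$values),
                    log2fc = unname(delta),
                    s2 = unname(s2),
                    df = d,
                    t = unname(tstat),
                    p = unname(p),
                    fdr = adjust_bh(unname(p)),
                    direction = ifelse(delta >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validates the inputs and applies the Benjamini-Hochberg step-up
#' procedure: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted values (FDR), same length and order.
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gate a differential-expression table at an FDR cut and collapse probes
#'
#' Rows with FDR strictly below \code{fdr_cut} are retained. If the table is
#' probe-level and a probe-to-gene map is supplied, only the most
#' significant probe per gene is kept (smallest p; ties broken by smallest
#' probe id).
#'
#' @param de A data.frame from \code{\link{fit_moderated_t}} (or any table
#'   with \code{gene}, \code{p}, \code{fdr} columns).
#' @param fdr_cut FDR threshold in (0, 1]; the gate is strict (\code{<}).
#' @param probe_map Optional named character vector probe id -> gene symbol;
#'   when given, \code{de$gene} is interpreted as probe ids.
#' @return The filtered (and possibly collapsed) table.
#' @export
select_de <- function(de, fdr_cut = 0.2, probe_map = NULL) {
  stopifnot(fdr_cut > 0, fdr_cut <= 1)
  out <- de[de$fdr < fdr_cut, , drop = FALSE]
  if (!is.null(probe_map)) {
    gene <- probe_map[out$gene]
    if (any(is.na(gene))) stop("probe(s) missing from probe_map")
    out$probe_id <- out$gene
    out$gene <- unname(gene)
    ord <- order(out$gene, out$p, out$probe_id)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$gene), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fraction of signature genes upregulated among DE genes
#'
#' For each signature gene set, counts the overlap with the DE table and the
#' fraction of overlapping genes called "up". Genes absent from the DE table
#' do not enter the denominator; a signature with no overlap reports
#' \code{NA}.
#'
#' @param de_table A gated DE table with \code{gene} and \code{direction}.
#' @param signatures Named list of gene symbol vectors (e.g. M1 and M2 sets
#'   from \code{\link{read_gmt}}).
#' @return data.frame: \code{signature}, \code{n_in_de}, \code{n_up},
#'   \code{fraction_up}.
#' @export
polarization_fraction <- function(de_table, signatures) {
  res <- lapply(names(signatures), function(nm) {
    hit <- de_table[de_table$gene %in% signatures[[nm]], , drop = FALSE]
    n <- nrow(hit)
    nup <- sum(hit$direction == "up")
    data.frame(signature = nm, n_in_de = n, n_up = nup,
               fraction_up = if (n > 0) nup / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare fold changes of genes upregulated in both SLE cohorts
#'
#' Intersects the genes called up in both DE tables (each a contrast versus
#' the same healthy baseline), reports both log2 fold changes and their
#' difference, and tags each gene with its polarization signature.
#'
#' @param de_active,de_inactive Gated DE tables versus healthy controls.
#' @param signatures Optional named list with \code{M1} and \code{M2} gene
#'   sets used to tag genes; untagged genes are "other".
#' @return data.frame: \code{gene}, \code{lfc_active}, \code{lfc_inactive},
#'   \code{delta} (active minus inactive), \code{signature}.
#' @export
common_foldchange_compare <- function(de_active, de_inactive,
                                      signatures = NULL) {
  up_a <- de_active[de_active$direction == "up", , drop = FALSE]
  up_i <- de_inactive[de_inactive$direction == "up", , drop = FALSE]
  common <- intersect(up_a$gene, up_i$gene)
  out <- data.frame(
    gene = common,
    lfc_active = up_a$log2fc[match(common, up_a$gene)],
    lfc_inactive = up_i$log2fc[match(common, up_i$gene)],
    stringsAsFactors = FALSE
  )
  out$delta <- out$lfc_active - out$lfc_inactive
  tag <- rep("other", nrow(out))
  if (!is.null(signatures)) {
    if (!is.null(signatures$M1)) tag[out$gene %in% signatures$M1] <- "M1"
    if (!is.null(signatures$M2)) tag[out$gene %in% signatures$M2] <- "M2"
  }
  out$signature <- tag
  out
}
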