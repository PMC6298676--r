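#' Remove low-intensity probes
#'
#' Microarray intensity histograms are typically bimodal: a low mode of
#' unexpressed probes and a high mode of expressed ones. The threshold is
#' placed at the trough between the modes. The interactive "pick the trough
#' by eye" step is automated as the first local minimum of a kernel density
#' estimate of per-row mean intensities; if the density has no interior
#' minimum (unimodal data), the method falls back to a quantile threshold
#' with a warning.
#'
#' @param eset Probe-level \code{\link{expr_set}}.
#' @param strategy \code{"valley"} (KDE trough) or \code{"quantile"}.
#' @param quantile_q Quantile used by the quantile strategy (and the valley
#'   fallback); \code{0} keeps everything.
#' @return Filtered \code{expr_set} with attributes \code{threshold},
#'   \code{strategy} and \code{n_removed} recording provenance.
#' @export
filter_low_intensity <- function(eset, strategy = c("valley", "quantile"),
                                 quantile_q = 0.25) {
  stopifnot(inherits(eset, "expr_set"))
  strategy <- match.arg(strategy)
  m <- rowMeans(eset$values)
  used <- strategy
  if (strategy == "valley") {
    d <- stats::density(m)
    y <- d$y
    interior <- which(diff(sign(diff(y))) == 2) + 1L  # strict local minima
    # ignore minima in the extreme tails where the KDE is near zero
    interior <- interior[y[interior] > 1e-4 * max(y)]
    if (length(interior)) {
      thr <- d$x[interior[1L]]
    } else {
      warning("density of row means is unimodal; falling back to quantile threshold")
      thr <- stats::quantile(m, quantile_q, names = FALSE)
      used <- "quantile_fallback"
    }
  } else {
    thr <- stats::quantile(m, quantile_q, names = FALSE)
  }
  keep <- if (used == "quantile" && quantile_q == 0) rep(TRUE, length(m)) else m >= thr
  out <- expr_set(eset$values[keep, , drop = FALSE], eset$samples, eset$row_level)
  attr(out, "threshold") <- thr
  attr(out, "strategy") <- used
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Merge primary and custom probe annotations
#'
#' Probes annotated by the primary (array-vendor) source keep that
#' annotation. Probes lacking a primary annotation but present in the custom
#' source are rescued with the custom gene symbol. Probes that the two
#' sources map to different genes are excluded outright. When both sources
#' agree the primary annotation is kept.
#'
#' @param primary_map,custom_map Named character vectors, probe id to gene
#'   symbol.
#' @return A list of class \code{probe_annotation} with elements
#'   \code{entries} (data.frame: probe_id, gene_symbol, source),
#'   \code{excluded} (character vector of conflicting probes) and
#'   \code{counts} (primary_kept, custom_rescued, excluded).
#' @export
merge_probe_annotations <- function(primary_map, custom_map) {
  primary_map <- unlist(primary_map)
  custom_map <- unlist(custom_map)
  all_probes <- union(names(primary_map), names(custom_map))
  in_p <- all_probes %in% names(primary_map)
  in_c <- all_probes %in% names(custom_map)
  p_gene <- primary_map[all_probes]
  c_gene <- custom_map[all_probes]
  conflict <- in_p & in_c & p_gene != c_gene
  keep_primary <- in_p & !conflict
  rescue <- !in_p & in_c
  entries <- data.frame(
    probe_id = c(all_probes[keep_primary], all_probes[rescue]),
    gene_symbol = c(unname(p_gene[keep_primary]), unname(c_gene[rescue])),
    source = c(rep("primary", sum(keep_primary)), rep("custom", sum(rescue))),
    stringsAsFactors = FALSE
  )
  entries <- entries[order(entries$probe_id), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(
    entries = entries,
    excluded = sort(all_probes[conflict]),
    counts = c(primary_kept = sum(keep_primary),
               custom_rescued = sum(rescue),
               excluded = sum(conflict))
  ), class = "probe_annotation")
}

#' Collapse duplicate probes to one row per gene by interquartile range
#'
#' When several probes interrogate the same gene, the probe with the largest
#' interquartile range across samples is retained (ties broken by the
#' lexicographically smallest probe id), and rows are re-labelled by gene
#' symbol.
#'
#' @param eset Probe-level \code{\link{expr_set}}.
#' @param annotation A \code{probe_annotation} from
#'   \code{\link{merge_probe_annotations}} (or any object with an
#'   \code{entries} data.frame).
#' @return Gene-level \code{expr_set}; attribute \code{probe_of_gene} maps
#'   each retained gene to its winning probe.
#' @export
collapse_probes_iqr <- function(eset, annotation) {
  stopifnot(inherits(eset, "expr_set"))
  entries <- annotation$entries
  probes <- rownames(eset$values)
  unknown <- setdiff(probes, entries$probe_id)
  if (length(unknown)) {
    stop("probe(s) in matrix without annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  gene <- entries$gene_symbol[match(probes, entries$probe_id)]
  iqr <- apply(eset$values, 1L, stats::IQR)
  ord <- order(gene, -iqr, probes)  # per gene: largest IQR first, then probe id
  first <- ord[!duplicated(gene[ord])]
  first <- first[order(match(first, seq_along(probes)))]  # original row order
  vals <- eset$values[first, , drop = FALSE]
  keep_probe <- probes[first]
  rownames(vals) <- gene[first]
  out <- expr_set(vals, eset$samples, row_level = "gene")
  attr(out, "probe_of_gene") <- stats::setNames(keep_probe, gene[first])
  out
}

# One-step parametric empirical-Bayes location/scale batch adjustment of a
# genes x samples matrix. Per gene: standardize against batch-structured
# mean/variance, estimate per-batch additive (gamma) and multiplicative
# (delta^2) effects, shrink them toward across-gene means via moment-matched
# normal / inverse-gamma priors, then remove and back-transform.
eb_batch_adjust <- function(x, batch, eb = TRUE) {
  batch <- as.factor(batch)
  nb <- table(batch)
  if (any(nb < 2)) stop("every batch needs at least 2 samples")
  G <- nrow(x); N <- ncol(x)
  lev <- levels(batch)
  # per-gene per-batch means and pooled residual variance
  m <- vapply(lev, function(b) rowMeans(x[, batch == b, drop = FALSE]), numeric(G))
  alpha <- as.vector(m %*% (as.numeric(nb) / N))
  resid <- x - m[, as.integer(batch), drop = FALSE]
  sigma2 <- rowSums(resid^2) / N
  sigma2 <- pmax(sigma2, 1e-12)
  z <- (x - alpha) / sqrt(sigma2)
  out <- z
  for (b in lev) {
    idx <- batch == b
    n_b <- sum(idx)
    zg <- z[, idx, drop = FALSE]
    gamma_hat <- rowMeans(zg)
    delta2_hat <- pmax(apply(zg, 1L, stats::var), 1e-12)
    if (eb && G >= 3) {
      gamma_bar <- mean(gamma_hat)
      tau2 <- stats::var(gamma_hat)
      md <- mean(delta2_hat)
      vd <- stats::var(delta2_hat)
      gamma_star <- if (tau2 > 0) {
        (n_b * tau2 * gamma_hat + delta2_hat * gamma_bar) /
          (n_b * tau2 + delta2_hat)
      } else gamma_hat
      if (vd > 0) {
        lambda <- md^2 / vd + 2           # inverse-gamma shape, moment-matched
        theta <- md * (lambda - 1)        # inverse-gamma scale
        ss <- rowSums((zg - gamma_star)^2)
        delta2_star <- (theta + ss / 2) / (n_b / 2 + lambda - 1)
      } else delta2_star <- delta2_hat
    } else {
      gamma_star <- gamma_hat
      delta2_star <- delta2_hat
    }
    out[, idx] <- (zg - gamma_star) / sqrt(pmax(delta2_star, 1e-12))
  }
  out * sqrt(sigma2) + alpha
}

#' Merge gene-level datasets with empirical-Bayes batch adjustment
#'
#' Restricts each dataset to the shared gene symbols, concatenates samples,
#' and (optionally) removes per-dataset batch effects with a per-gene
#' empirical-Bayes location/scale adjustment: batch means and variances are
#' estimated on standardized data and shrunk toward their across-gene means
#' (normal prior on location, inverse-gamma prior on scale, both
#' moment-matched) before being subtracted/rescaled. Cohort labels and
#' SLEDAI values are untouched.
#'
#' @param esets List of two or more gene-level \code{\link{expr_set}}s with
#'   distinct, filled \code{dataset_id} metadata.
#' @param adjust Apply batch adjustment? If \code{FALSE} the shared-gene
#'   matrices are simply concatenated.
#' @param method \code{"eb"} for the empirical-Bayes scheme,
#'   \code{"standardize"} for plain per-batch location/scale standardization
#'   (no shrinkage; debugging aid).
#' @return Merged gene-level \code{expr_set}; attribute \code{batch} holds
#'   the per-sample dataset id used as batch.
#' @export
merge_datasets <- function(esets, adjust = TRUE, method = c("eb", "standardize")) {
  method <- match.arg(method)
  stopifnot(length(esets) >= 2)
  for (e in esets) {
    stopifnot(inherits(e, "expr_set"))
    if (e$row_level != "gene") stop("merge_datasets needs gene-level sets")
    if (any(!nzchar(e$samples$dataset_id))) stop("dataset_id must be filled")
  }
  genes <- Reduce(intersect, lapply(esets, function(e) rownames(e$values)))
  if (!length(genes)) stop("no genes shared across datasets")
  vals <- do.call(cbind, lapply(esets, function(e) e$values[genes, , drop = FALSE]))
  meta <- do.call(rbind, lapply(esets, function(e) e$samples))
  rownames(meta) <- NULL
  if (anyDuplicated(meta$sample_id)) stop("sample ids collide across datasets")
  batch <- meta$dataset_id
  if (any(table(batch) < 2)) stop("every dataset must contribute at least 2 samples")
  if (adjust) {
    vals <- eb_batch_adjust(vals, batch, eb = (method == "eb"))
  }
  out <- expr_set(vals, meta, row_level = "gene")
  attr(out, "batch") <- batch
  attr(out, "adjusted") <- adjust
  out
}
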