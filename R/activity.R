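#' Build module-enrichment features for the activity classifier
#'
#' Scores every (cell type, module) gene list against the merged expression
#' set with the single-sample KS-walk scorer; one feature column per module
#' list, provenance preserved in the column names. Modules with no overlap
#' with the merged genes are dropped with a warning.
#'
#' @param merged Gene-level \code{\link{expr_set}} (typically from
#'   \code{\link{merge_datasets}}).
#' @param modules_by_celltype Named list of gene-symbol vectors; names
#'   should carry the cell-type provenance (e.g. "CD14_yellow").
#' @param tau,mode Passed to \code{\link{score_gene_sets}}.
#' @return Samples x modules score matrix.
#' @export
build_features <- function(merged, modules_by_celltype, tau = 1,
                           mode = "diff") {
  stopifnot(inherits(merged, "expr_set"))
  genes <- rownames(merged$values)
  overlap <- vapply(modules_by_celltype, function(s) sum(genes %in% s), 0L)
  if (any(overlap == 0L)) {
    warning("dropping module(s) with no gene overlap: ",
            paste(names(modules_by_celltype)[overlap == 0L], collapse = ", "))
    modules_by_celltype <- modules_by_celltype[overlap > 0L]
  }
  if (!length(modules_by_celltype)) stop("no scorable modules")
  stats_mat <- gene_level_stats(merged)
  score_gene_sets(stats_mat, modules_by_celltype, tau = tau, mode = mode)
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, n_folds, seed) {
  foldid <- integer(length(labels))
  with_rng(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  foldid
}

#' Fit a penalized logistic model of disease activity
#'
#' Elastic-net logistic regression of active vs inactive disease on
#' module-enrichment scores; the penalty strength is chosen by stratified
#' cross-validated binomial deviance with the 1-SE rule. Deterministic
#' given the seed.
#'
#' @param features Samples x modules score matrix.
#' @param labels Binary labels (logical, 0/1, or the cohort strings
#'   \code{"SLE_active"} / \code{"SLE_inactive"}); \code{TRUE}/1/active is
#'   the positive class.
#' @param alpha Elastic-net mixing parameter in [0, 1].
#' @param n_folds Cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @return An \code{activity_model}: list with \code{fit} (the cv.glmnet
#'   object), \code{coefficients} (at lambda.1se), \code{lambda},
#'   \code{alpha}, \code{n_folds}, \code{seed}, \code{feature_names}.
#' @export
fit_activity_glm <- function(features, labels, alpha = 0.5, n_folds = 5,
                             seed = 1L) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(y) < 2 * n_folds) stop("need at least 2 samples per fold")
  foldid <- stratified_folds(y, n_folds, seed)
  fit <- glmnet::cv.glmnet(x = as.matrix(features), y = y,
                           family = "binomial", alpha = alpha,
                           foldid = foldid, type.measure = "deviance")
  co <- as.matrix(stats::coef(fit, s = "lambda.1se"))[, 1L]
  structure(list(fit = fit, coefficients = co,
                 lambda = fit$lambda.1se, alpha = alpha,
                 n_folds = n_folds, seed = seed,
                 feature_names = colnames(features)),
            class = "activity_model")
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    known <- c(SLE_active = 1, SLE_inactive = 0, active = 1, inactive = 0)
    if (!all(labels %in% names(known))) stop("unrecognized label value(s)")
    unname(known[labels])
  } else as.numeric(as.logical(labels))
}

#' Predicted activity probabilities
#'
#' @param object An \code{activity_model}.
#' @param newdata Samples x modules score matrix.
#' @param ... Unused.
#' @return Numeric vector of P(active).
#' @export
predict.activity_model <- function(object, newdata, ...) {
  as.vector(stats::predict(object$fit, newx = as.matrix(newdata),
                           s = "lambda.1se", type = "response"))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score threshold, records false- and true-positive
#' rates, and integrates by the trapezoid rule; the result equals the
#' normalized Mann-Whitney U statistic (ties counted one half).
#'
#' @param scores Numeric prediction scores (higher = more likely active).
#' @param labels Binary labels (see \code{\link{fit_activity_glm}}).
#' @return A \code{roc_result}: list with \code{thresholds}, \code{fpr},
#'   \code{tpr}, \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- !duplicated(ss, fromLast = TRUE)  # one point per distinct threshold
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, ss[last]), fpr = fpr, tpr = tpr,
                 auc = auc), class = "roc_result")
}

#' Binary per-sample module enrichment calls
#'
#' A sample is called enriched for a module when the module's expected
#' direction of association with activity times its score exceeds the
#' threshold.
#'
#' @param scores Samples x modules score matrix.
#' @param direction Named numeric vector (+1 / -1) giving each module's
#'   expected sign of association with active disease; every scored module
#'   must be present.
#' @param threshold Calling threshold on the direction-signed score.
#' @return Logical samples x modules matrix.
#' @export
call_enrichment <- function(scores, direction, threshold = 0) {
  miss <- setdiff(colnames(scores), names(direction))
  if (length(miss)) stop("no expected direction for module(s): ",
                         paste(miss, collapse = ", "))
  d <- direction[colnames(scores)]
  if (!all(d %in% c(-1, 1))) stop("directions must be +1 or -1")
  sweep(scores, 2L, d, `*`) > threshold
}

#' Per-module odds ratios for active disease
#'
#' Applies the odds-ratio formula
#' \deqn{OR = \frac{enriched_{active} \times nonenriched_{inactive}}
#'   {nonenriched_{active} \times enriched_{inactive}}}
#' to each module's 2x2 enrichment-by-activity table. If any cell is zero,
#' 0.5 is added to every cell (Haldane-Anscombe) and the row is flagged.
#' 95\% confidence intervals use the log-OR normal approximation
#' \eqn{\exp(\log OR \pm 1.96 \sqrt{\sum 1/cell})}.
#'
#' @param enriched Logical samples x modules matrix from
#'   \code{\link{call_enrichment}}.
#' @param labels Binary activity labels.
#' @return data.frame: module, enriched_active, nonenriched_active,
#'   enriched_inactive, nonenriched_inactive, odds_ratio, ci_low, ci_high,
#'   corrected.
#' @export
odds_ratio_active <- function(enriched, labels) {
  y <- as_binary_labels(labels)
  res <- lapply(colnames(enriched), function(m) {
    e <- enriched[, m]
    ea <- sum(e & y == 1); na_ <- sum(!e & y == 1)
    ei <- sum(e & y == 0); ni <- sum(!e & y == 0)
    cells <- c(ea, na_, ei, ni)
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    data.frame(module = m, enriched_active = ea, nonenriched_active = na_,
               enriched_inactive = ei, nonenriched_inactive = ni,
               odds_ratio = or,
               ci_low = exp(log(or) - 1.96 * se),
               ci_high = exp(log(or) + 1.96 * se),
               corrected = corrected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Train/test evaluation of the activity classifier
#'
#' Stratified split of samples into train and test sets, elastic-net fit on
#' the training portion, ROC/AUC on the held-out portion. Deterministic
#' given the seed.
#'
#' @param features Samples x modules score matrix.
#' @param labels Binary activity labels.
#' @param test_frac Fraction of each class held out.
#' @param alpha,n_folds Passed to \code{\link{fit_activity_glm}}.
#' @param seed RNG seed (split and fold assignment).
#' @return List: \code{model}, \code{roc} (on held-out samples),
#'   \code{test_idx}.
#' @export
evaluate_activity_model <- function(features, labels, test_frac = 0.3,
                                    alpha = 0.5, n_folds = 5, seed = 1L) {
  y <- as_binary_labels(labels)
  test_idx <- with_rng(seed, {
    unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(test_frac * length(idx))))
    }))
  })
  model <- fit_activity_glm(features[-test_idx, , drop = FALSE], y[-test_idx],
                            alpha = alpha, n_folds = n_folds, seed = seed + 1L)
  pred <- predict(model, features[test_idx, , drop = FALSE])
  list(model = model, roc = roc_auc(pred, y[test_idx]), test_idx = test_idx)
}
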