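# Independent oracles used across the suite. Each is a deliberately naive
# (brute-force / closed-form) computation kept separate from the package's
# own code paths.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Benjamini-Hochberg step-up by exhaustive minima over j >= i
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# triple-loop topological overlap from an expression matrix (genes x samples)
tom_brute <- function(x, power) {
  a <- abs(stats::cor(t(x)))^power
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# first-PC variance-explained share by plain power iteration on the
# standardized member matrix
pc1_var_share_power_iter <- function(x, iters = 2000) {
  xs <- t(scale(t(x)))
  cc <- crossprod(xs)            # samples x samples
  v <- rep(1, ncol(cc)) / sqrt(ncol(cc))
  for (i in seq_len(iters)) {
    v2 <- cc %*% v
    v <- v2 / sqrt(sum(v2^2))
  }
  lambda1 <- as.numeric(t(v) %*% cc %*% v)
  lambda1 / sum(diag(cc))
}

# AUC as the normalized pairwise concordance count (ties worth 1/2)
auc_brute <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + (p > n) + 0.5 * (p == n)
  }
  conc / (length(pos) * length(neg))
}

# chi-squared statistic from the (observed - expected)^2 / expected sum
chi2_brute <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# odds ratio from the printed formula with Haldane-Anscombe correction
or_brute <- function(ea, na_, ei, ni) {
  cells <- c(ea, na_, ei, ni)
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

# small expression set with explicit metadata, for contract tests
tiny_eset <- function(values, cohort = NULL, dataset_id = "DS1",
                      sledai = NULL, row_level = "gene") {
  n <- ncol(values)
  if (is.null(cohort)) cohort <- rep("HC", n)
  if (is.null(sledai)) {
    sledai <- ifelse(cohort == "SLE_active", 8, ifelse(cohort == "SLE_inactive", 2, 0))
  }
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  meta <- data.frame(sample_id = colnames(values), dataset_id = dataset_id,
                     cohort = cohort, sledai = sledai,
                     stringsAsFactors = FALSE)
  expr_set(values, meta, row_level = row_level)
}
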