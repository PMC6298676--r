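# standard module colour palette (decreasing-size assignment order);
# "grey" is reserved for unassigned genes
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3"
)

#' Pick a soft-threshold power for approximate scale-free topology
#'
#' For each candidate power the unsigned adjacency
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} is formed, connectivities
#' \eqn{k_i = \sum_{j \ne i} a_{ij}} are binned (10 bins), and the
#' scale-free fit \eqn{R^2} is the squared correlation of
#' \eqn{\log_{10} p(k)} with \eqn{\log_{10} k} over non-empty bins. A power
#' only qualifies when the connectivity distribution also spans a minimal
#' range (\code{max(k)/min(k) >= k_spread_min}); without spread, a high
#' \eqn{R^2} reflects a narrow near-Gaussian connectivity distribution, not
#' heavy-tailed topology. The smallest qualifying power is returned; if
#' none qualifies, the power with maximal \eqn{R^2} is returned with a
#' note.
#'
#' @param eset An \code{\link{expr_set}} (no constant gene rows).
#' @param candidate_powers Positive powers to scan.
#' @param r2_target Scale-free fit target.
#' @param nbins Connectivity bins for the fit.
#' @param k_spread_min Minimal max/min connectivity ratio for a power to
#'   qualify.
#' @return The selected power, with attributes \code{fit_table} (power,
#'   r_squared, mean_k) and \code{reached_target}.
#' @export
pick_soft_threshold <- function(eset, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.8, nbins = 10,
                                k_spread_min = 2) {
  stopifnot(inherits(eset, "expr_set"), all(candidate_powers > 0),
            ncol(eset$values) >= 8)
  sds <- apply(eset$values, 1L, stats::sd)
  if (any(sds == 0)) stop("constant gene rows present; remove before calling")
  C <- abs(stats::cor(t(eset$values)))
  diag(C) <- 0
  fits <- vapply(candidate_powers, function(b) {
    k <- rowSums(C^b)
    k <- k[k > 0]
    if (length(unique(k)) < 2) return(c(0, mean(k), 1))
    spread <- max(k) / min(k)
    bins <- cut(k, breaks = nbins)
    dk <- tapply(k, bins, mean)
    pk <- tapply(k, bins, length) / length(k)
    ok <- !is.na(dk) & dk > 0 & pk > 0
    if (sum(ok) < 3) return(c(0, mean(k), spread))
    r2 <- stats::cor(log10(dk[ok]), log10(pk[ok]))^2
    c(r2, mean(k), spread)
  }, numeric(3))
  tab <- data.frame(power = candidate_powers, r_squared = fits[1, ],
                    mean_k = fits[2, ], k_spread = fits[3, ])
  hit <- which(tab$r_squared >= r2_target & tab$k_spread >= k_spread_min)
  if (length(hit)) {
    beta <- tab$power[hit[1L]]
    reached <- TRUE
  } else {
    beta <- tab$power[which.max(tab$r_squared)]
    reached <- FALSE
    message("no candidate power reached R^2 >= ", r2_target,
            "; using the best (", beta, ")")
  }
  structure(beta, fit_table = tab, reached_target = reached)
}

#' Topological overlap matrix of an unsigned weighted network
#'
#' Adjacency \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}; topological overlap
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}},\qquad TOM_{ii} = 1,}
#' which measures how much of the two genes' network neighbourhood is
#' shared. Values lie in [0, 1] and the matrix is symmetric.
#'
#' @param eset An \code{\link{expr_set}} with no constant gene rows.
#' @param power Soft-threshold exponent \eqn{\beta}.
#' @return A \code{tom_matrix}: list with \code{genes}, \code{power},
#'   \code{tom}.
#' @export
compute_tom <- function(eset, power) {
  stopifnot(inherits(eset, "expr_set"), power > 0)
  sds <- apply(eset$values, 1L, stats::sd)
  if (any(sds == 0)) stop("constant gene rows present; remove before calling")
  A <- abs(stats::cor(t(eset$values)))^power
  diag(A) <- 0
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  tom <- pmin(pmax(tom, 0), 1)
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(eset$values), rownames(eset$values))
  structure(list(genes = rownames(eset$values), power = power, tom = tom),
            class = "tom_matrix")
}

#' Module eigengene (first principal component of a module)
#'
#' Member genes are standardized across samples; the eigengene is the
#' unit-norm first right singular vector of the standardized member matrix,
#' oriented so that its mean correlation with the member genes is
#' non-negative.
#'
#' @param eset An \code{\link{expr_set}}.
#' @param member_genes Character vector of at least 2 member gene ids;
#'   constant genes are dropped with a warning.
#' @return Numeric vector (one value per sample, unit norm) with attribute
#'   \code{var_explained} (share of member variance carried by the first
#'   component).
#' @export
module_eigengene <- function(eset, member_genes) {
  stopifnot(inherits(eset, "expr_set"), length(member_genes) >= 2)
  x <- eset$values[member_genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s) from eigengene")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 non-constant member genes")
  }
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  me <- sv$v[, 1L]
  if (mean(stats::cor(t(xs), me)) < 0) me <- -me
  attr(me, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  stats::setNames(me, colnames(eset$values))
}

# average 1-TOM distance from each gene to each cluster's members
avg_cluster_dist <- function(diss, cluster_members) {
  vapply(cluster_members, function(mem) rowMeans(diss[, mem, drop = FALSE]),
         numeric(nrow(diss)))
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on 1 - TOM, followed by a
#' deterministic branch cut: every internal node of the dendrogram is a
#' candidate branch, and a branch becomes a module when (a) it holds at
#' least \code{min_size} genes, (b) it completes below \code{detect_cut},
#' and (c) it stays separate from the rest of the tree over a height gap of
#' at least \code{max(0.01, 0.05 * height spread)} before merging onwards
#' (so loosely chained background genes never form a branch, and the tree
#' root is never a module). Maximal qualifying branches are taken in
#' decreasing size order. An optional partitioning-around-medoids-like pass
#' then moves assigned genes to the cluster with smallest average 1 - TOM
#' distance when strictly closer than their own, and attaches unassigned
#' genes to their nearest cluster when within that cluster's member
#' distance range (mean + 2 SD of member-to-cluster average distances).
#' Module eigengenes are computed and module pairs with eigengene
#' dissimilarity \eqn{1 - cor(ME_a, ME_b) <} \code{merge_cut} are merged
#' iteratively. Merged modules must pass a quality gate: the eigengene has
#' to explain at least twice the member-variance share expected of the
#' first principal component of a same-sized pure-noise matrix,
#' \eqn{(1 + \sqrt{p/n})^2 / p}; branches failing it dissolve to
#' unassigned. Unassigned genes with kME of at least \code{kme_attach} to
#' a surviving module then join it. Final modules are labelled with colours
#' in decreasing size order; unassigned genes are "grey".
#'
#' @param tom A \code{tom_matrix} from \code{\link{compute_tom}}.
#' @param eset The matching \code{\link{expr_set}}.
#' @param detect_cut Detection cut height on the 1 - TOM dendrogram.
#' @param merge_cut Eigengene-dissimilarity merge threshold.
#' @param min_size Minimum module size.
#' @param pam Run the medoid-style reassignment pass?
#' @param kme_attach Final-membership threshold: after merging, unassigned
#'   genes whose best module-eigengene correlation (kME) reaches this value
#'   join that module; \code{NA} disables the rescue.
#' @return A \code{module_set}: list with \code{assignment} (gene ->
#'   colour, "grey" = unassigned), \code{me} (samples x modules, unit-norm
#'   columns), \code{kme} (genes x modules), \code{mean_kme},
#'   \code{low_quality} flags (mean kME < 0.3), and \code{params}.
#' @export
detect_modules <- function(tom, eset, detect_cut = 1, merge_cut = 0.2,
                           min_size = 30, pam = TRUE, kme_attach = 0.5) {
  stopifnot(inherits(tom, "tom_matrix"), inherits(eset, "expr_set"),
            identical(tom$genes, rownames(eset$values)))
  genes <- tom$genes
  n <- length(genes)
  if (n < min_size) {
    return(finalize_modules(eset, stats::setNames(rep(0L, n), genes),
                            detect_cut, merge_cut, min_size, kme_attach))
  }
  diss <- 1 - tom$tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- cut_branches(hc, n, detect_cut, min_size)
  if (pam && any(cl > 0)) {
    members <- split(which(cl > 0), cl[cl > 0])
    dmat <- avg_cluster_dist(diss, members)
    radius <- vapply(seq_along(members), function(j) {
      dj <- dmat[members[[j]], j]
      mean(dj) + 2 * stats::sd(dj)
    }, 0)
    lab <- as.integer(names(members))
    for (g in seq_len(n)) {
      j_best <- which.min(dmat[g, ])
      if (cl[g] > 0) {
        j_own <- match(cl[g], lab)
        if (dmat[g, j_best] < dmat[g, j_own]) cl[g] <- lab[j_best]
      } else if (dmat[g, j_best] <= radius[j_best]) {
        cl[g] <- lab[j_best]
      }
    }
    cl <- dissolve_small(cl, min_size)
  }
  finalize_modules(eset, stats::setNames(cl, genes), detect_cut, merge_cut,
                   min_size, kme_attach)
}

# Branch-based cut of an average-linkage 1-TOM tree. A branch (internal
# node) qualifies as a module candidate when it has >= min_size leaves,
# completes below detect_cut, and is separated from the rest of the tree on
# the topological-overlap similarity scale: (1 - h) / (1 - h_parent) >=
# ratio_min. Background (chained) branches sit at ratios near 1 while real
# co-expression branches exceed the margin. The root never qualifies.
# Qualifying branches are taken deepest-first; over-splitting this causes
# is healed downstream by the medoid pass and the eigengene merge.
cut_branches <- function(hc, n, detect_cut, min_size, ratio_min = 1.02) {
  m <- nrow(hc$merge)
  leaves <- vector("list", m)
  size <- integer(m)
  for (i in seq_len(m)) {
    kids <- hc$merge[i, ]
    lv <- integer(0)
    for (k in kids) lv <- c(lv, if (k < 0) -k else leaves[[k]])
    leaves[[i]] <- lv
    size[i] <- length(lv)
  }
  parent_h <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    for (k in hc$merge[i, ]) if (k > 0) parent_h[k] <- hc$height[i]
  }
  ratio <- (1 - hc$height + 1e-12) / (1 - parent_h + 1e-12)
  ok <- size >= min_size & hc$height <= detect_cut &
    !is.na(parent_h) & ratio >= ratio_min
  cl <- integer(n)
  lab <- 0L
  for (node in which(ok)[order(hc$height[ok])]) {
    if (any(cl[leaves[[node]]] > 0)) next  # overlaps a taken branch
    lab <- lab + 1L
    cl[leaves[[node]]] <- lab
  }
  cl
}

dissolve_small <- function(cl, min_size) {
  sizes <- table(cl[cl > 0])
  small <- as.integer(names(sizes)[sizes < min_size])
  cl[cl %in% small] <- 0L
  cl
}

# eigengene computation, iterative ME-correlation merging, kME rescue of
# unassigned genes, colour labelling
finalize_modules <- function(eset, cl, detect_cut, merge_cut, min_size,
                             kme_attach = 0.5) {
  genes <- names(cl)
  labs <- sort(unique(cl[cl > 0]))
  members <- lapply(labs, function(l) genes[cl == l])
  # iterative merge of the closest eigengene pair below merge_cut
  repeat {
    if (length(members) < 2) break
    me <- vapply(members, function(m) as.vector(module_eigengene(eset, m)),
                 numeric(ncol(eset$values)))
    cc <- stats::cor(me)
    dd <- 1 - cc
    diag(dd) <- Inf
    mi <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    if (dd[mi[1L], mi[2L]] >= merge_cut) break
    a <- min(mi); b <- max(mi)
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- NULL
  }
  # quality gate: a real module's eigengene must explain clearly more
  # member variance than the first PC of a same-sized random matrix,
  # (1 + sqrt(p/n))^2 / p; branches below twice that share are dissolved
  if (length(members)) {
    n_samp <- ncol(eset$values)
    keep <- vapply(members, function(mm) {
      ve <- attr(module_eigengene(eset, mm), "var_explained")
      ve >= 2 * (1 + sqrt(length(mm) / n_samp))^2 / length(mm)
    }, TRUE)
    members <- members[keep]
  }
  # final membership by correlation with the module eigengene: unassigned
  # genes with kME >= kme_attach join their best-correlated module
  if (length(members) && is.finite(kme_attach)) {
    me <- vapply(members, function(m) as.vector(module_eigengene(eset, m)),
                 numeric(ncol(eset$values)))
    free <- setdiff(genes, unlist(members))
    if (length(free)) {
      km <- stats::cor(t(eset$values[free, , drop = FALSE]), me)
      best <- max.col(km, ties.method = "first")
      take <- km[cbind(seq_along(free), best)] >= kme_attach
      for (j in seq_along(members)) {
        members[[j]] <- c(members[[j]], free[take & best == j])
      }
    }
  }
  if (length(members)) {
    ord <- order(-vapply(members, length, 0L),
                 vapply(members, function(m) match(m[1L], genes), 0L))
    members <- members[ord]
    nlab <- length(members)
    cols <- c(module_colors, sprintf("module%d", seq_len(max(0, nlab - length(module_colors)))))[seq_len(nlab)]
    assignment <- stats::setNames(rep("grey", length(genes)), genes)
    me <- matrix(0, ncol(eset$values), nlab,
                 dimnames = list(colnames(eset$values), cols))
    var_expl <- numeric(nlab)
    for (j in seq_len(nlab)) {
      assignment[members[[j]]] <- cols[j]
      ev <- module_eigengene(eset, members[[j]])
      me[, j] <- ev
      var_expl[j] <- attr(ev, "var_explained")
    }
  } else {
    assignment <- stats::setNames(rep("grey", length(genes)), genes)
    me <- matrix(0, ncol(eset$values), 0,
                 dimnames = list(colnames(eset$values), NULL))
    var_expl <- numeric(0)
  }
  out <- structure(list(assignment = assignment, me = me,
                        kme = NULL, mean_kme = NULL, low_quality = NULL,
                        var_explained = var_expl,
                        params = list(detect_cut = detect_cut,
                                      merge_cut = merge_cut,
                                      min_size = min_size,
                                      kme_attach = kme_attach)),
                   class = "module_set")
  compute_kme(eset, out)
}

# kME matrix and per-module quality (no reassignment)
compute_kme <- function(eset, module_set) {
  if (ncol(module_set$me) == 0) {
    module_set$kme <- matrix(0, nrow(eset$values), 0,
                             dimnames = list(rownames(eset$values), NULL))
    module_set$mean_kme <- numeric(0)
    module_set$low_quality <- logical(0)
    return(module_set)
  }
  kme <- stats::cor(t(eset$values), module_set$me)
  module_set$kme <- kme
  cols <- colnames(module_set$me)
  module_set$mean_kme <- vapply(cols, function(m) {
    mean(kme[names(module_set$assignment)[module_set$assignment == m], m])
  }, 0)
  module_set$low_quality <- module_set$mean_kme < 0.3
  module_set
}

#' Compute kME and reassign genes to their best-correlated module
#'
#' kME is the Pearson correlation of each gene with each module eigengene.
#' Every assigned gene is moved to the module where its kME is maximal
#' (ties keep the current assignment); per-module mean kME quality is then
#' recomputed and modules with mean kME below 0.3 are flagged low quality.
#'
#' @param eset An \code{\link{expr_set}}.
#' @param module_set A \code{module_set} from \code{\link{detect_modules}}.
#' @return The updated \code{module_set}.
#' @export
compute_kme_and_reassign <- function(eset, module_set) {
  stopifnot(inherits(module_set, "module_set"))
  if (ncol(module_set$me) == 0) return(compute_kme(eset, module_set))
  kme <- stats::cor(t(eset$values), module_set$me)
  cols <- colnames(module_set$me)
  assignment <- module_set$assignment
  for (g in names(assignment)) {
    if (assignment[g] == "grey") next
    best <- cols[which.max(kme[g, ])]
    if (kme[g, best] > kme[g, assignment[g]]) assignment[g] <- best
  }
  module_set$assignment <- assignment
  compute_kme(eset, module_set)
}

#' Grand mean module quality across datasets
#'
#' The grand mean is the mean over datasets of each dataset's mean kME for
#' the module(s) in question.
#'
#' @param mean_kme_list List (one element per dataset) of named mean-kME
#'   vectors.
#' @return Named vector over module labels present in every dataset.
#' @export
grand_mean_kme <- function(mean_kme_list) {
  common <- Reduce(intersect, lapply(mean_kme_list, names))
  vapply(common, function(m) {
    mean(vapply(mean_kme_list, `[[`, 0, m))
  }, 0)
}

#' Correlate module eigengenes with sample traits
#'
#' Continuous traits use Pearson correlation; dichotomous traits
#' (two-valued factors/characters, coded 0/1) use the point-biserial
#' correlation, which is the Pearson correlation on the 0/1 coding.
#' Two-sided p-values come from \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with
#' \eqn{n - 2} degrees of freedom.
#'
#' @param module_set A \code{module_set} with eigengenes.
#' @param samples Sample metadata data.frame (rows aligned with the
#'   eigengene matrix).
#' @param traits Character vector of column names in \code{samples}.
#' @return data.frame: \code{module}, \code{trait}, \code{trait_kind},
#'   \code{r}, \code{p}, \code{n}.
#' @export
correlate_module_traits <- function(module_set, samples, traits) {
  stopifnot(inherits(module_set, "module_set"),
            nrow(samples) == nrow(module_set$me))
  res <- list()
  for (tr in traits) {
    v <- samples[[tr]]
    if (is.null(v)) stop("trait not found in samples: ", tr)
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) != 2) stop("dichotomous trait must have exactly 2 levels: ", tr)
      v <- as.numeric(as.character(v) == lev[2L])
      kind <- "dichotomous"
    } else kind <- "continuous"
    if (stats::sd(v) == 0) stop("zero-variance trait: ", tr)
    for (m in colnames(module_set$me)) {
      r <- stats::cor(module_set$me[, m], v)
      n <- length(v)
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      res[[length(res) + 1L]] <- data.frame(
        module = m, trait = tr, trait_kind = kind, r = r,
        p = min(max(p, .Machine$double.xmin), 1), n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
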