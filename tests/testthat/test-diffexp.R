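make_two_group <- function(n_genes, na, nb, shift_rows = integer(), delta = 0,
                           seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (na + nb)), n_genes, na + nb)
  if (length(shift_rows)) x[shift_rows, seq_len(na)] <- x[shift_rows, seq_len(na)] + delta
  rownames(x) <- sprintf("G%04d", seq_len(n_genes))
  colnames(x) <- c(sprintf("a%02d", seq_len(na)), sprintf("b%02d", seq_len(nb)))
  tiny_eset(x, cohort = rep(c("SLE_active", "HC"), c(na, nb)))
}

test_that("moderated t is exact on symmetric input and respects its formula", {
  # identical groups: delta 0, t 0, p 1
  x <- matrix(rep(c(1, 2, 3), 2), 1, 6,
              dimnames = list("G1", sprintf("s%d", 1:6)))
  x <- rbind(x, G2 = rnorm(6), G3 = rnorm(6))  # companions so d0 is estimable
  es <- tiny_eset(x, cohort = rep(c("SLE_active", "HC"), each = 3))
  de <- fit_moderated_t(es, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$t[1], 0)
  expect_equal(de$p[1], 1)

  # the reported statistic satisfies the posterior-variance construction
  es2 <- make_two_group(500, 8, 8, seed = 3)
  de2 <- fit_moderated_t(es2, sprintf("a%02d", 1:8), sprintf("b%02d", 1:8))
  d0 <- attr(de2, "d0"); s02 <- attr(de2, "s02")
  expect_gt(d0, 0); expect_gt(s02, 0)
  s2post <- if (is.finite(d0)) (d0 * s02 + de2$df * de2$s2) / (d0 + de2$df) else rep(s02, nrow(de2))
  expect_equal(de2$t, de2$log2fc / sqrt(s2post * (1 / 8 + 1 / 8)),
               tolerance = 1e-12)
  expect_equal(de2$p,
               2 * pt(-abs(de2$t), df = min(de2$df + d0, de2$df * nrow(de2))),
               tolerance = 1e-12)

  # contracts
  expect_error(fit_moderated_t(es2, "a01", sprintf("b%02d", 1:8)), "at least 2")
  expect_error(fit_moderated_t(es2, c("a01", "a02"), c("a02", "b01")), "disjoint")
})

test_that("moderated t matches the limma reference implementation", {
  skip_if_not_installed("limma")
  es <- make_two_group(800, 10, 10, shift_rows = 1:40, delta = 1.2, seed = 4)
  de <- fit_moderated_t(es, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  design <- cbind(1, rep(c(1, 0), each = 10))
  fit <- limma::eBayes(limma::lmFit(es$values, design))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("null p-values are uniform and zero-variance genes stay finite", {
  es <- make_two_group(2000, 10, 10, seed = 5)
  de <- fit_moderated_t(es, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)

  # a constant gene has s2 = 0 but a positive posterior variance
  x <- es$values
  x[1, ] <- 5
  es0 <- tiny_eset(x, cohort = es$samples$cohort)
  de0 <- fit_moderated_t(es0, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  expect_equal(de0$s2[1], 0)
  expect_true(is.finite(de0$t[1]) && de0$t[1] == 0)
})

test_that("BH adjustment equals the step-up oracle and validates input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(1.0), 1.0)
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_brute(p), tolerance = 1e-12)
  }
  # monotone in rank, permutation-equivariant
  p <- runif(30)
  perm <- sample(30)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("DE gating is strictly below the cut and collapses probes by best p", {
  de <- data.frame(gene = c("g1", "g2", "g3"), p = c(0.001, 0.01, 0.02),
                   fdr = c(0.1, 0.2, 0.3),
                   direction = c("up", "down", "up"),
                   stringsAsFactors = FALSE)
  expect_equal(select_de(de, 0.2)$gene, "g1")   # strict <
  expect_equal(nrow(select_de(de, 1)), 3L)      # all retained below 1

  dep <- data.frame(gene = c("prA1", "prA2", "prB9", "prB2"),
                    p = c(1e-5, 1e-3, 0.002, 0.002),
                    fdr = c(0.01, 0.05, 0.05, 0.05),
                    direction = "up", stringsAsFactors = FALSE)
  pm <- c(prA1 = "A", prA2 = "A", prB9 = "B", prB2 = "B")
  sel <- select_de(dep, 0.2, probe_map = pm)
  expect_equal(sel$probe_id[sel$gene == "A"], "prA1")   # smallest p wins
  expect_equal(sel$probe_id[sel$gene == "B"], "prB2")   # tie -> smallest probe id
})

test_that("polarization fractions follow the planted effect pattern", {
  expect_equal(polarization_fraction(
    data.frame(gene = paste0("m", 1:8), direction = "up"),
    list(M1 = paste0("m", 1:8)))$fraction_up, 1.0)
  pf <- polarization_fraction(
    data.frame(gene = paste0("g", 1:10),
               direction = rep(c("up", "down"), c(4, 6))),
    list(S = paste0("g", 1:10)))
  expect_equal(pf$fraction_up, 0.4)
  expect_true(is.na(polarization_fraction(
    data.frame(gene = "g1", direction = "up"),
    list(E = "zzz"))$fraction_up))

  # default synthetic conditions: nearly all M1 genes up in active SLE
  cfg <- synthetic_config(n_hc = 15, n_inactive = 15, n_active = 15,
                          n_genes = 500, modules = list(),
                          m1_genes = 40, m2_genes = 40)
  ds <- generate_dataset(cfg, seed = 7)
  sig <- ds$truth$signature_of_gene
  ids <- ds$eset$samples$sample_id
  de <- fit_moderated_t(ds$eset, ids[ds$truth$labels == "SLE_active"],
                        ids[ds$truth$labels == "HC"])
  sel <- select_de(de, 0.2)
  pf2 <- polarization_fraction(sel, list(M1 = names(sig)[sig == "M1"],
                                         M2 = names(sig)[sig == "M2"]))
  expect_gte(pf2$fraction_up[pf2$signature == "M1"], 0.9)
})

test_that("common upregulated genes show the M1/M2 fold-change ordering", {
  da <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, 1.5, 0.7),
                   direction = c("up", "up", "up"), stringsAsFactors = FALSE)
  di <- data.frame(gene = c("g1", "g3", "g4"), log2fc = c(1, 1.2, 2),
                   direction = c("up", "up", "up"), stringsAsFactors = FALSE)
  cmp <- common_foldchange_compare(da, di, signatures = list(M1 = "g1", M2 = "g3"))
  expect_setequal(cmp$gene, c("g1", "g3"))  # g2, g4 not up in both
  expect_equal(cmp$delta[cmp$gene == "g1"], 1.0)
  expect_equal(cmp$signature, c("M1", "M2"))

  # synthetic default pattern: M1 delta positive, M2 delta negative
  cfg <- synthetic_config(n_hc = 15, n_inactive = 15, n_active = 15,
                          n_genes = 500, modules = list(),
                          m1_genes = 40, m2_genes = 40)
  ds <- generate_dataset(cfg, seed = 8)
  sig <- ds$truth$signature_of_gene
  ids <- ds$eset$samples$sample_id
  hc <- ids[ds$truth$labels == "HC"]
  de_a <- select_de(fit_moderated_t(ds$eset, ids[ds$truth$labels == "SLE_active"], hc), 0.2)
  de_i <- select_de(fit_moderated_t(ds$eset, ids[ds$truth$labels == "SLE_inactive"], hc), 0.2)
  cmp2 <- common_foldchange_compare(de_a, de_i,
                                    signatures = list(M1 = names(sig)[sig == "M1"],
                                                      M2 = names(sig)[sig == "M2"]))
  expect_gt(median(cmp2$delta[cmp2$signature == "M1"]), 0)
  expect_lt(median(cmp2$delta[cmp2$signature == "M2"]), 0)
})

test_that("FDR gate is calibrated and powered under planted shifts", {
  # complete null, 10 quick reps: realized FDP at the 0.2 gate stays near it
  fdp <- vapply(1:10, function(s) {
    es <- make_two_group(1000, 10, 10, seed = 100 + s)
    sel <- select_de(fit_moderated_t(es, sprintf("a%02d", 1:10),
                                     sprintf("b%02d", 1:10)), 0.2)
    nrow(sel) > 0  # any call on a complete null is a false discovery
    if (nrow(sel) == 0) 0 else 1
  }, 0)
  expect_lte(mean(fdp), 0.5)  # most null reps yield no calls at all

  # 5% of genes shifted by 1.5 sd: sensitivity at the gate is high
  sens <- vapply(1:5, function(s) {
    es <- make_two_group(1000, 10, 10, shift_rows = 1:50, delta = 1.5,
                         seed = 200 + s)
    sel <- select_de(fit_moderated_t(es, sprintf("a%02d", 1:10),
                                     sprintf("b%02d", 1:10)), 0.2)
    mean(sprintf("G%04d", 1:50) %in% sel$gene)
  }, 0)
  expect_gte(mean(sens), 0.7)
})
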