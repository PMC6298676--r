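test_that("cohort assignment is a step function of SLEDAI with breakpoint 6", {
  expect_equal(assign_cohort(5, TRUE), "SLE_inactive")
  expect_equal(assign_cohort(6, TRUE), "SLE_active")
  expect_equal(assign_cohort(0, FALSE), "HC")
  # total step function over a grid
  grid <- seq(0, 25, by = 0.5)
  out <- assign_cohort(grid, TRUE)
  expect_true(all(out[grid < 6] == "SLE_inactive"))
  expect_true(all(out[grid >= 6] == "SLE_active"))
  expect_equal(assign_cohort(grid, FALSE), rep("HC", length(grid)))
  expect_error(assign_cohort(-1, TRUE), "non-negative")
})

test_that("expression TSV round trip preserves values and metadata order", {
  x <- matrix(rnorm(6, sd = 3) + 8, 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  es <- tiny_eset(x, cohort = c("HC", "SLE_active"))
  d <- withr::local_tempdir()
  write_expression_tsv(es, file.path(d, "e.tsv"), file.path(d, "m.tsv"))
  back <- read_expression_tsv(file.path(d, "e.tsv"), file.path(d, "m.tsv"))
  expect_equal(dim(back$values), c(3L, 2L))
  expect_equal(back$values, es$values, tolerance = 1e-12)
  expect_equal(back$samples$cohort, es$samples$cohort)

  # sample missing from metadata is an error
  meta_bad <- es$samples[1, , drop = FALSE]
  utils::write.table(meta_bad, file.path(d, "m1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_expression_tsv(file.path(d, "e.tsv"), file.path(d, "m1.tsv")),
               "absent from metadata")

  # non-numeric cell is an error
  writeLines(c("row_id\ts1\ts2", "A\t1.0\tx", "B\t2\t3", "C\t4\t5"),
             file.path(d, "e2.tsv"))
  expect_error(read_expression_tsv(file.path(d, "e2.tsv"), file.path(d, "m.tsv")),
               "non-numeric")
})

test_that("expr_set enforces its invariants", {
  x <- matrix(1:4 + 0.5, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), dataset_id = "D",
                     cohort = c("SLE_active", "HC"), sledai = c(8, 0))
  expect_s3_class(expr_set(x, meta), "expr_set")
  # cohort label inconsistent with SLEDAI rule
  meta_bad <- meta; meta_bad$sledai[1] <- 3
  expect_error(expr_set(x, meta_bad), "inconsistent")
  # non-finite values rejected
  x2 <- x; x2[1, 1] <- NA
  expect_error(expr_set(x2, meta), "finite")
  # duplicated row ids rejected
  x3 <- x; rownames(x3) <- c("A", "A")
  expect_error(expr_set(x3, meta), "duplicated")
})

test_that("GMT round trip, dedup, and malformed-line contracts", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sets.gmt")
  writeLines(c("M1\tsrc\tSTAT1\tSOCS3", "M2\tsrc\tSTAT3\tSTAT6\tCD163\tSTAT3"), p)
  sets <- read_gmt(p)
  expect_equal(sets$M1, c("STAT1", "SOCS3"))
  expect_equal(sets$M2, c("STAT3", "STAT6", "CD163"))  # duplicate removed

  writeLines("M1\tsrc", file.path(d, "short.gmt"))
  expect_error(read_gmt(file.path(d, "short.gmt")), "fewer than 3")
  writeLines(c("A\ts\tG1", "A\ts\tG2"), file.path(d, "dup.gmt"))
  expect_error(read_gmt(file.path(d, "dup.gmt")), "duplicate")

  p2 <- file.path(d, "roundtrip.gmt")
  write_gmt(sets, p2)
  back <- read_gmt(p2)
  expect_identical(back$M1, sets$M1)
  expect_identical(back$M2, sets$M2)
})

test_that("low-intensity filtering finds the density trough of bimodal means", {
  set.seed(41)
  # 300 unexpressed rows near 3, 700 expressed near 8 -> valley near 5.5
  means <- c(rnorm(300, 3, 0.5), rnorm(700, 8, 0.7))
  x <- matrix(rnorm(1000 * 10, mean = means, sd = 0.1), 1000, 10,
              dimnames = list(sprintf("P%04d", 1:1000), NULL))
  es <- tiny_eset(x)
  filt <- filter_low_intensity(es, "valley")
  thr <- attr(filt, "threshold")
  # oracle: exhaustive scan of KDE minima between the modes
  dd <- density(rowMeans(x))
  mins <- dd$x[which(diff(sign(diff(dd$y))) == 2) + 1]
  expect_true(any(abs(mins - thr) < 1e-9))
  expect_gt(thr, 4); expect_lt(thr, 7)
  expect_true(all(rowMeans(filt$values) >= thr))
  expect_equal(attr(filt, "n_removed"), 1000L - nrow(filt$values))
  expect_true(all(rownames(filt$values) %in% rownames(x)))

  # quantile q = 0 keeps everything
  id <- filter_low_intensity(es, "quantile", quantile_q = 0)
  expect_equal(dim(id$values), dim(es$values))

  # unimodal data falls back to the quantile with a warning
  set.seed(42)
  uni <- tiny_eset(matrix(rnorm(200 * 8, 8), 200, 8))
  expect_warning(fb <- filter_low_intensity(uni, "valley"), "unimodal")
  expect_equal(attr(fb, "strategy"), "quantile_fallback")

  # all rows above threshold: no-op
  hi <- filter_low_intensity(es, "quantile", quantile_q = 0.2)
  hi2 <- filter_low_intensity(hi, "quantile", quantile_q = 0)
  expect_equal(hi2$values, hi$values)
})

test_that("annotation merge partitions probes into kept / rescued / excluded", {
  out <- merge_probe_annotations(c(p1 = "A"), c(p1 = "A", p2 = "C"))
  expect_equal(out$entries$gene_symbol[out$entries$probe_id == "p1"], "A")
  expect_equal(out$entries$source[out$entries$probe_id == "p1"], "primary")
  expect_equal(out$entries$source[out$entries$probe_id == "p2"], "custom")
  expect_length(out$excluded, 0)

  confl <- merge_probe_annotations(c(p1 = "A"), c(p1 = "B"))
  expect_equal(confl$excluded, "p1")
  expect_equal(nrow(confl$entries), 0L)

  rescue <- merge_probe_annotations(character(), c(p2 = "C"))
  expect_equal(rescue$entries$probe_id, "p2")
  expect_equal(rescue$entries$source, "custom")

  # counts partition the union of probes
  set.seed(7)
  probes <- sprintf("p%03d", 1:200)
  prim <- setNames(sample(LETTERS, 150, replace = TRUE), sample(probes, 150))
  cust <- setNames(sample(LETTERS, 120, replace = TRUE), sample(probes, 120))
  m <- merge_probe_annotations(prim, cust)
  expect_equal(sum(m$counts), length(union(names(prim), names(cust))))
  expect_length(intersect(m$entries$probe_id, m$excluded), 0)
})

test_that("probe collapse keeps the largest-IQR probe per gene", {
  set.seed(11)
  x <- rbind(pA1 = rnorm(10, sd = 2), pA2 = rnorm(10, sd = 0.2),
             pB1 = rnorm(10))
  es <- tiny_eset(x, row_level = "probe")
  ann <- merge_probe_annotations(c(pA1 = "A", pA2 = "A", pB1 = "B"), character())
  coll <- collapse_probes_iqr(es, ann)
  expect_equal(coll$row_level, "gene")
  expect_equal(unname(attr(coll, "probe_of_gene")["A"]),
               names(which.max(apply(x[1:2, ], 1, IQR))))
  expect_equal(unname(coll$values["B", ]), unname(x["pB1", ]))  # single probe passes through

  # probe missing from the annotation is an error
  ann2 <- merge_probe_annotations(c(pA1 = "A", pA2 = "A"), character())
  expect_error(collapse_probes_iqr(es, ann2), "without annotation")

  # 50-gene fixture with 2-4 probes each: winners match brute-force ranking
  set.seed(12)
  genes <- sprintf("g%02d", 1:50)
  nprobe <- sample(2:4, 50, replace = TRUE)
  pid <- unlist(lapply(seq_along(genes), function(i) {
    sprintf("%s_pr%d", genes[i], seq_len(nprobe[i]))
  }))
  gmap <- setNames(rep(genes, nprobe), pid)
  xx <- matrix(rnorm(length(pid) * 12, sd = runif(length(pid), 0.1, 3)),
               length(pid), 12, dimnames = list(pid, NULL))
  es2 <- tiny_eset(xx, row_level = "probe")
  coll2 <- collapse_probes_iqr(es2, list(entries = data.frame(
    probe_id = pid, gene_symbol = unname(gmap), stringsAsFactors = FALSE)))
  iqr <- apply(xx, 1, IQR)
  for (g in genes) {
    mine <- gmap == g
    want <- names(sort(iqr[mine], decreasing = TRUE))[1]
    expect_equal(unname(attr(coll2, "probe_of_gene")[g]), want)
  }
})

test_that("dataset merge adjusts batch location/scale and respects contracts", {
  set.seed(21)
  base <- matrix(rnorm(100 * 20, 8), 100, 20,
                 dimnames = list(sprintf("G%03d", 1:100), sprintf("a%02d", 1:20)))
  e1 <- tiny_eset(base, dataset_id = "D1")
  shifted <- base + 2
  colnames(shifted) <- sprintf("b%02d", 1:20)
  e2 <- tiny_eset(shifted, dataset_id = "D2")

  # +2 offset removed: with plain per-batch standardization the per-gene
  # batch means coincide (the mean-centering oracle); the EB mode shrinks
  # per-gene effects toward the shared +2 and removes the bulk of the offset
  m <- merge_datasets(list(e1, e2), adjust = TRUE, method = "standardize")
  bm <- apply(m$values, 1, function(x) tapply(x, m$samples$dataset_id, mean))
  expect_lt(max(abs(bm[1, ] - bm[2, ])), 0.05)
  m_eb <- merge_datasets(list(e1, e2), adjust = TRUE, method = "eb")
  bm_eb <- apply(m_eb$values, 1, function(x) tapply(x, m_eb$samples$dataset_id, mean))
  expect_lt(mean(abs(bm_eb[1, ] - bm_eb[2, ])), 0.3)  # vs raw offset of 2

  # adjust off is plain concatenation over shared genes
  raw <- merge_datasets(list(e1, e2), adjust = FALSE)
  expect_equal(raw$values[, 1:20], base)
  expect_equal(ncol(raw$values), 40L)

  # three batches with no true batch effect: adjustment barely moves values
  set.seed(22)
  es3 <- lapply(1:3, function(d) {
    v <- matrix(rnorm(100 * 50, 8), 100, 50,
                dimnames = list(sprintf("G%03d", 1:100),
                                sprintf("d%d_%02d", d, 1:50)))
    tiny_eset(v, dataset_id = paste0("D", d))
  })
  m3 <- merge_datasets(es3, adjust = TRUE)
  raw3 <- merge_datasets(es3, adjust = FALSE)
  rms <- sqrt(mean((m3$values - raw3$values)^2))
  expect_lt(rms, 0.2)

  # contracts
  e_dis <- tiny_eset(matrix(rnorm(20, 8), 10, 2,
                            dimnames = list(sprintf("X%02d", 1:10), c("q1", "q2"))),
                     dataset_id = "D9")
  expect_error(merge_datasets(list(e1, e_dis)), "no genes shared")
  e_small <- tiny_eset(base[, 1, drop = FALSE], dataset_id = "D3")
  e_small$samples$sample_id <- "z1"
  colnames(e_small$values) <- "z1"
  expect_error(merge_datasets(list(e1, e_small)), "at least 2 samples")
})

test_that("empirical-Bayes batch adjustment agrees with the ComBat reference", {
  skip_if_not_installed("sva")
  set.seed(31)
  x <- matrix(rnorm(200 * 30, 8), 200, 30,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("s%02d", 1:30)))
  batch <- rep(c("A", "B"), c(14, 16))
  x[, batch == "B"] <- x[, batch == "B"] * 1.3 + 1.5
  mine <- slemod:::eb_batch_adjust(x, batch)
  ref <- sva::ComBat(x, batch = batch)
  # same family of adjustment (one-step vs iterated EB): results close
  expect_lt(sqrt(mean((mine - ref)^2)), 0.1)
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.999)
})
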