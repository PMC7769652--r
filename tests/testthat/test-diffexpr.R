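test_that("quantile normalization maps columns onto mean quantiles", {
  # hand calculation: columns (1,2) and (3,6); reference quantiles (2,4)
  v <- matrix(c(1, 2, 3, 6), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  x <- expression_matrix(v, c(s1 = "case", s2 = "control"))
  nm <- normalize_quantile(x)
  expect_equal(unname(nm$values), matrix(c(2, 4, 2, 4), 2, 2))

  # permuted-column matrix is a fixed point (no ties)
  base <- c(1, 3, 7, 20)
  v2 <- cbind(s1 = base, s2 = rev(base), s3 = base[c(2, 4, 1, 3)])
  rownames(v2) <- paste0("p", 1:4)
  x2 <- expression_matrix(v2, c(s1 = "case", s2 = "case", s3 = "control"))
  expect_error(normalize_quantile(x2), NA)
  expect_equal(normalize_quantile(x2)$values, v2)

  # column means equalize; agrees with limma on tie-free random data
  # (limma resolves ties by rank interpolation, not the group mean pinned
  # here, so the oracle comparison uses distinct values)
  set.seed(5)
  v3 <- matrix(2^rnorm(200, 8), 40, 5)
  dimnames(v3) <- list(paste0("p", 1:40), paste0("s", 1:5))
  x3 <- expression_matrix(v3, setNames(rep(c("case", "control"), c(3, 2)),
                                       colnames(v3)))
  nm3 <- normalize_quantile(x3)
  expect_equal(diff(range(colMeans(nm3$values))), 0, tolerance = 1e-9)
  expect_equal(unname(nm3$values),
               unname(limma::normalizeQuantiles(v3, ties = TRUE)),
               tolerance = 1e-12)

  # tie handling by hand: column (1,1,4) against reference quantiles;
  # the two tied entries share the mean of the two lowest quantiles
  vt <- cbind(s1 = c(1, 1, 4), s2 = c(2, 6, 10))
  rownames(vt) <- paste0("p", 1:3)
  xt <- expression_matrix(vt, c(s1 = "case", s2 = "control"))
  ref <- rowMeans(apply(vt, 2, sort))            # (1.5, 3.5, 7)
  nt <- normalize_quantile(xt)
  expect_equal(unname(nt$values[, "s1"]),
               unname(c(mean(ref[1:2]), mean(ref[1:2]), ref[3])))
  expect_equal(unname(nt$values[, "s2"]), unname(ref))
})

test_that("per-probe t-test matches brute force and handles degeneracy", {
  x <- tiny_matrix()
  res <- t_test_unpaired(x, "p4")
  lv <- log2(x$values["p4", ])
  oracle <- brute_pooled_t(lv[1:3], lv[4:5])
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_identical(res$df, 3)

  # identical group values: t = 0, P = 1
  same <- t_test_unpaired(x, "p3")
  expect_identical(c(same$t, same$p_value), c(0, 1))

  # matches stats::t.test with var.equal on random vectors
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(3)
    mine <- t_test_pooled(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("fold change is the absolute ratio with direction label", {
  x <- tiny_matrix()
  expect_equal(fold_change(x, "p1"), list(fc = 4, regulation = "Up"))
  expect_equal(fold_change(x, "p2"), list(fc = 4, regulation = "Down"))
  expect_equal(fold_change(x, "p3"), list(fc = 1, regulation = "Up"))

  # antisymmetry: swapping group labels swaps Up/Down, fc unchanged
  set.seed(4)
  v <- matrix(2^rnorm(50, 8), 10, 5,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:5)))
  g1 <- setNames(rep(c("case", "control"), c(3, 2)), colnames(v))
  g2 <- setNames(rep(c("control", "case"), c(3, 2)), colnames(v))
  x1 <- expression_matrix(v, g1); x2 <- expression_matrix(v, g2)
  for (p in rownames(v)) {
    f1 <- fold_change(x1, p); f2 <- fold_change(x2, p)
    expect_equal(f1$fc, f2$fc, tolerance = 1e-12)
    expect_true(f1$regulation != f2$regulation)
  }
})

test_that("bh_fdr matches hand values and validates input", {
  expect_identical(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.5, 10)), rep(0.5, 10))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("screen gate uses strict inequalities and annotation", {
  # probe at fc exactly 2 is excluded; planted noiseless probe included
  s0 <- simulate_expression(2, n_lnc = 50, n_mrna = 30, frac_de = 0.1,
                            fc_log2_range = c(2, 2), sigma_log2 = 0)
  # build an exact-boundary probe: case mean = 2 * control mean, zero noise
  v <- s0$matrix$values
  v["ASHGV00001", ] <- c(rep(512, 5), rep(256, 3))
  x <- expression_matrix(v, s0$matrix$groups)
  de <- screen_de(x, s0$annotation)
  hits <- c(de$up$probe_name, de$down$probe_name)
  expect_false("ASHGV00001" %in% hits)   # fc == 2, strict > excludes
  planted <- setdiff(s0$truth$de_probes$probe_name, "ASHGV00001")
  expect_true(all(planted %in% hits))
  expect_length(intersect(de$up$probe_name, de$down$probe_name), 0)
  expect_true(all(de$up$fc > 2 & de$up$p_value < 0.05))
  expect_identical(unique(de$down$regulation), "Down")
  expect_true(all(c("seqname", "chrom", "strand") %in% names(de$up)))

  expect_error(screen_de(x, s0$annotation[-1, ]), "unannotated")
})

test_that("recovery scenario meets sensitivity and FDR bounds", {
  # planted log2FC = 2, sigma = 0.25, 5 vs 3: gate recovers >= 80%,
  # empirical FDR among gated probes <= 0.25
  tp <- fp <- fn <- 0
  for (seed in 1:10) {
    s <- simulate_expression(seed, n_lnc = 400, n_mrna = 240,
                             frac_de = 0.05, fc_log2_range = c(2, 2),
                             sigma_log2 = 0.25)
    de <- screen_de(s$matrix, s$annotation)
    hits <- c(de$up$probe_name, de$down$probe_name)
    planted <- s$truth$de_probes$probe_name
    tp <- tp + length(intersect(hits, planted))
    fp <- fp + length(setdiff(hits, planted))
    fn <- fn + length(setdiff(planted, hits))
  }
  expect_gte(tp / (tp + fn), 0.8)
  expect_lte(fp / max(tp + fp, 1), 0.25)
})

test_that("top_table ranks by fc, then P, then seqname", {
  rec <- data.frame(seqname = c("c", "a", "b", "d"),
                    fc = c(5, 9, 7, 7), p_value = c(0.01, 0.02, 0.02, 0.01))
  out <- top_table(rec, k = 10)
  expect_identical(out$fc, c(9, 7, 7, 5))
  expect_identical(out$seqname[2:3], c("d", "b"))  # p tie-break first
  expect_identical(nrow(top_table(rec, k = 2)), 2L)
  expect_error(top_table(rec, k = 0), "k must be > 0")
})
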