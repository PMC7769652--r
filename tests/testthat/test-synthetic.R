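test_that("expression generator is deterministic and honors its contracts", {
  a <- simulate_expression(7, n_lnc = 100, n_mrna = 60)
  b <- simulate_expression(7, n_lnc = 100, n_mrna = 60)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)

  # count arithmetic: frac_de applied per biotype
  s <- simulate_expression(1, n_lnc = 1000, n_mrna = 500, frac_de = 0.1)
  expect_identical(sum(s$truth$de_probes$biotype == "lncRNA"), 100L)
  expect_identical(sum(s$truth$de_probes$biotype == "mRNA"), 50L)

  # noiseless limit: planted log2FC = 2 gives empirical fold change exactly 4
  s0 <- simulate_expression(1, n_lnc = 50, n_mrna = 30, frac_de = 0.1,
                            fc_log2_range = c(2, 2), sigma_log2 = 0)
  for (p in s0$truth$de_probes$probe_name)
    expect_equal(fold_change(s0$matrix, p)$fc, 4.0, tolerance = 1e-12)

  expect_error(simulate_expression(1, n_case = 1), "design error")
  expect_error(simulate_expression(1, frac_de = 0.6), "frac_de")
})

test_that("generator leaves the caller's RNG state untouched", {
  set.seed(99); before <- .Random.seed
  invisible(simulate_expression(1, n_lnc = 10, n_mrna = 10))
  expect_identical(.Random.seed, before)
})

test_that("planted coexpression pairs hit the target correlation", {
  expect_error(simulate_coexpression(1, tiny_matrix(), NULL, rho = 1),
               "rho")
  s <- simulate_expression(11, n_lnc = 250, n_mrna = 250, frac_de = 0.05)
  cx <- simulate_coexpression(12, s$matrix, s$annotation, pairs = 200,
                              rho = 0.99)
  lv <- log2(cx$matrix$values)
  r <- vapply(seq_len(200), function(k)
    cor(lv[cx$truth$lnc_probe[k], ], lv[cx$truth$mrna_probe[k], ]), 0)
  expect_lt(abs(mean(r) - 0.99), 0.02)        # Monte-Carlo expectation
  expect_gte(mean(abs(r) >= 0.97), 0.8)       # power at the |r| gate, n = 8
})

test_that("miRNA target generator plants exact shared counts", {
  lnc <- paste0("L", 1:8); mrna <- paste0("M", 1:8)
  tg <- simulate_mirna_targets(3, n_mirna = 200, lnc_ids = lnc,
                               mrna_ids = mrna, sponge_pairs = 3,
                               shared_per_pair = 5, background_rate = 0.02)
  for (k in 1:3) {
    sm <- shared_mirnas(tg$targets, tg$truth$lnc[k], tg$truth$mrna[k])
    expect_identical(sm$c, 5L)
    expect_lt(cerna_p(200, sm$K, sm$n, sm$c), 0.05)  # Eq-style tail
  }
  expect_identical(
    simulate_mirna_targets(3, n_mirna = 200, lnc_ids = lnc,
                           mrna_ids = mrna, sponge_pairs = 3,
                           shared_per_pair = 5,
                           background_rate = 0.02)$targets,
    tg$targets)  # determinism

  # background_rate = 0: only planted pairs share anything
  tg0 <- simulate_mirna_targets(4, n_mirna = 50, lnc_ids = lnc,
                                mrna_ids = mrna, sponge_pairs = 2,
                                shared_per_pair = 4, background_rate = 0)
  present <- unique(tg0$targets$target_id)
  for (a in intersect(lnc, present)) for (b in intersect(mrna, present)) {
    planted <- any(tg0$truth$lnc == a & tg0$truth$mrna == b)
    expect_identical(shared_mirnas(tg0$targets, a, b)$c,
                     if (planted) 4L else 0L)
  }
  expect_error(simulate_mirna_targets(1, n_mirna = 3, lnc_ids = lnc,
                                      mrna_ids = mrna, shared_per_pair = 5),
               "infeasible")
})

test_that("locus generator plants recoverable classes", {
  ll <- simulate_loci(5, per_class = 1)
  cl <- classify_all(ll$lnc, ll$genes)
  expect_identical(sort(unname(cl$counts)), rep(1L, 6))
  expect_identical(cl$table$class,
                   ll$truth$class[match(cl$table$lnc, ll$truth$lnc)])
  # intergenic loci stay far beyond the bidirectional window of any gene
  ig <- ll$lnc[ll$truth$lnc[ll$truth$class == "intergenic"]]
  d <- min(abs(tss(ll$genes) - tss(ig)))
  expect_gt(d, 1000)
  expect_error(simulate_loci(1, per_class = 10, genome_length = 1e5),
               "placement error")
})

test_that("Ct table generator plants the requested effect", {
  ct <- simulate_ct_table(8, n_case = 4, n_ctrl = 4, true_log2_ratio = -1,
                          ct_sd = 0)
  rel <- ddct(ct, "T181556", "ACTB")
  expect_equal(rel$rq[rel$group == "case"], rep(0.5, 4), tolerance = 1e-12)
  expect_identical(simulate_ct_table(8, n_case = 4, n_ctrl = 4,
                                     true_log2_ratio = -1, ct_sd = 0), ct)
  expect_error(simulate_ct_table(1, ct_sd = -1), "ct_sd")
  expect_error(simulate_ct_table(1, n_case = 1), "design error")
})

test_that("null Ct simulation has calibrated type-I error", {
  # true_log2_ratio = 0: group t-test P should be ~Uniform(0,1)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    ct <- simulate_ct_table(1000 + i, n_case = 12, n_ctrl = 11,
                            true_log2_ratio = 0, ct_sd = 0.2)
    compare_groups(ddct(ct, "T181556", "ACTB"))$p_value
  }, 0)
  rej <- mean(p < 0.05)
  # binomial 99% band around 0.05 at 400 reps
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("null expression simulation gives uniform raw P over probes", {
  s <- simulate_expression(21, n_lnc = 3000, n_mrna = 2000, frac_de = 0)
  expect_identical(nrow(s$truth$de_probes), 0L)
  res <- screen_de(s$matrix, s$annotation)
  expect_gt(stats::ks.test(res$all$p_value, "punif")$p.value, 0.01)
})
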