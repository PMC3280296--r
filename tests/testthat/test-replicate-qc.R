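test_that("log10 Pearson: self-correlation, scale invariance, textbook oracle", {
  set.seed(2)
  a <- qa_from_net(setNames(rlnorm(30, 6, 1), sprintf("G%02d", 1:30)))
  expect_equal(pearson_log10(a, a), 1.0, tolerance = 1e-12)

  b <- qa_from_net(setNames(rlnorm(30, 6, 1), sprintf("G%02d", 1:30)))
  scaled <- qa_from_net(net_b <- 4.2 * setNames(b$genes$net, b$genes$gene_id))
  expect_equal(pearson_log10(a, b), pearson_log10(a, scaled), tolerance = 1e-12)
  expect_equal(pearson_log10(a, qa_from_net(2.5 * setNames(a$genes$net, a$genes$gene_id))),
               1.0, tolerance = 1e-12)

  # 10 hand-listed pairs against the sum-formula oracle
  x <- c(120, 340, 98, 1500, 720, 55, 210, 800, 430, 95)
  y <- c(130, 310, 105, 1300, 900, 60, 260, 650, 380, 120)
  qa <- qa_from_net(setNames(x, sprintf("G%02d", 1:10)))
  qb <- qa_from_net(setNames(y, sprintf("G%02d", 1:10)))
  expect_equal(pearson_log10(qa, qb), oracle_pearson(log10(x), log10(y)),
               tolerance = 1e-12)

  # undetected genes are excluded pairwise
  xa <- setNames(c(10, 20, 30, NA), sprintf("G%d", 1:4))
  xb <- setNames(c(11, 19, NA, 40), sprintf("G%d", 1:4))
  expect_error(pearson_log10(qa_from_net(xa), qa_from_net(xb)),
               class = "arrayprep_insufficient_data_error")
})

test_that("fold-change concordance counts co-detected genes within the band", {
  a <- qa_from_net(setNames(c(100, 100, 100, NA), sprintf("G%d", 1:4)))
  expect_equal(fold_change_concordance(a, a), 1.0)

  b <- qa_from_net(setNames(c(200, 150, 400, 50), sprintf("G%d", 1:4)))
  # ratios: 2 (inclusive boundary), 1.5, 4 -> 2 of 3 concordant
  expect_equal(fold_change_concordance(a, b), 2 / 3)
  expect_equal(fold_change_concordance(b, a), 2 / 3) # symmetric

  c3 <- qa_from_net(setNames(c(150, 250, 400), sprintf("G%d", 1:3)))
  base <- qa_from_net(setNames(c(100, 100, 100), sprintf("G%d", 1:3)))
  expect_equal(fold_change_concordance(base, c3), 1 / 3)
})

test_that("undetected fraction covers the gene universe, per array and consensus", {
  full <- qa_from_net(setNames(rep(100, 10), sprintf("G%02d", 1:10)))
  expect_equal(undetected_fraction(full), 0.0)

  half <- setNames(c(rep(100, 5), rep(NA, 5)), sprintf("G%02d", 1:10))
  expect_equal(undetected_fraction(qa_from_net(half)), 0.5)

  # consensus rule over replicates: detected in >= 2 of 3
  r1 <- qa_from_net(setNames(c(100, 100, NA), sprintf("G%d", 1:3)))
  r2 <- qa_from_net(setNames(c(100, NA, NA), sprintf("G%d", 1:3)))
  r3 <- qa_from_net(setNames(c(100, 100, NA), sprintf("G%d", 1:3)))
  expect_equal(undetected_fraction(list(r1, r2, r3), 0.67), 1 / 3)
})

test_that("replicate CV: hand arithmetic, detection filters, scale invariance", {
  reps <- list(
    qa_from_net(setNames(c(80, 50, NA), sprintf("G%d", 1:3))),
    qa_from_net(setNames(c(100, 50, NA), sprintf("G%d", 1:3))),
    qa_from_net(setNames(c(120, 50, 10), sprintf("G%d", 1:3)))
  )
  cv <- replicate_cv(reps, min_detection_fraction = 0.67)
  # G1: sd(80,100,120) = 20, mean 100 -> CV 0.20 (sample sd); G2 constant -> 0
  expect_equal(cv$per_gene_cv[["G1"]], 0.20, tolerance = 1e-12)
  expect_equal(cv$per_gene_cv[["G2"]], 0.0)
  expect_false("G3" %in% names(cv$per_gene_cv)) # detected 1 of 3 < threshold 2
  expect_equal(cv$n_genes_used, 2L)
  expect_equal(cv$detection_threshold, 2L) # ceil(0.67 * 3)

  # the printed thresholds: 3-of-5 at 60%, 2-of-3 at 67%
  expect_equal(ceiling(0.6 * 5), 3)
  five <- replicate(5, qa_from_net(setNames(runif(4, 50, 150), sprintf("G%d", 1:4))),
                    simplify = FALSE)
  expect_equal(replicate_cv(five, 0.6)$detection_threshold, 3L)

  # CV invariant under common positive scaling
  scaled <- lapply(reps, function(q) {
    qa_from_net(7.7 * setNames(q$genes$net, q$genes$gene_id))
  })
  cv_s <- replicate_cv(scaled, min_detection_fraction = 0.67)
  expect_equal(cv_s$per_gene_cv, cv$per_gene_cv, tolerance = 1e-12)

  none <- list(qa_from_net(setNames(NA_real_, "G1")),
               qa_from_net(setNames(NA_real_, "G1")))
  expect_error(replicate_cv(none), class = "arrayprep_insufficient_data_error")
})

test_that("median per-gene CV recovers the simulated multiplicative noise", {
  meds <- sapply(1:3, function(s) {
    cfg <- study_config(
      n_genes = 500, n_blanks = 50, seed = s,
      fraction_expressed = 1, abundance_log10_mean = 2.5,
      noise = noise_model(multiplicative_cv = 0.15, background_mean = 100,
                          background_sd = 0, blank_outlier_fraction = 0))
    feats <- generate_gene_features(500, derive_seed(s, "features"))
    x <- generate_true_abundances(feats, cfg, "UHRR", s)
    reps <- lapply(1:5, function(r) {
      quantify_scan(simulate_array_scan(x, cfg, "UHRR", "non_amp", r,
                                        derive_seed(s, "scan", r)))
    })
    replicate_cv(reps, 0.6)$median_cv
  })
  expect_equal(median(meds), 0.15, tolerance = 0.2)
})
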