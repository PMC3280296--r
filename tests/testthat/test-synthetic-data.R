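test_that("gene feature generation honours size, determinism and invariants", {
  one <- generate_gene_features(1, seed = 11)
  expect_equal(nrow(one), 1L)
  expect_true(one$gc_content >= 0 && one$gc_content <= 1)
  expect_true(one$transcript_length > 0)
  expect_true(one$polyA_length >= 0 && one$hairpin_count >= 0)

  a <- generate_gene_features(250, seed = 42)
  b <- generate_gene_features(250, seed = 42)
  expect_identical(a, b)
  expect_false(anyDuplicated(a$gene_id) > 0)

  big <- generate_gene_features(1000, seed = 7)
  expect_gt(mean(big$gc_content), 0.45) # uniform(0.3, 0.7) Monte-Carlo check
  expect_lt(mean(big$gc_content), 0.55)
  expect_true(all(big$transcript_length >= 500 & big$transcript_length <= 10000))

  expect_error(generate_gene_features(0, seed = 1), class = "arrayprep_input_error")
})

test_that("true abundances: expression fraction, sample effects, dynamic range", {
  feats <- generate_gene_features(400, seed = 3)
  cfg <- study_config(n_genes = 400, n_blanks = 20,
                      abundance_log10_sd = 0, fraction_expressed = 1,
                      sample_effect_log10_sd = 0, seed = 3)
  x <- generate_true_abundances(feats, cfg, "UHRR", seed = 3)
  expect_true(all(x > 0))
  expect_equal(length(unique(x)), 1L) # degenerate sd: one shared abundance

  cfg2 <- study_config(n_genes = 400, n_blanks = 20, seed = 3)
  u <- generate_true_abundances(feats, cfg2, "UHRR", seed = 3)
  h <- generate_true_abundances(feats, cfg2, "HBRR", seed = 3)
  expect_true(any(u != h)) # per-sample random effect
  expect_equal(names(u), feats$gene_id)
  # expressed set is shared across samples
  expect_identical(u > 0, h > 0)
  expect_equal(mean(u > 0), cfg2$fraction_expressed, tolerance = 0.1)

  # 99% central range of log10 abundance spans >= 5 decades at sd = 1.25
  feats_big <- generate_gene_features(10000, seed = 5)
  cfg_big <- study_config(n_genes = 10000, n_blanks = 20,
                          abundance_log10_sd = 1.25, fraction_expressed = 1,
                          seed = 5)
  xb <- generate_true_abundances(feats_big, cfg_big, "UHRR", seed = 5)
  rng <- diff(quantile(log10(xb), c(0.005, 0.995)))
  expect_gt(rng, 5)

  expect_error(
    generate_true_abundances(feats, cfg2, "UHRR", 3, always_expressed = "nope"),
    class = "arrayprep_input_error")
})

test_that("amplification: identity at rounds = 0, exact ratio preservation unbiased", {
  feats <- generate_gene_features(200, seed = 9)
  cfg <- study_config(n_genes = 200, n_blanks = 20, seed = 9)
  x <- generate_true_abundances(feats, cfg, "UHRR", seed = 9)

  expect_identical(simulate_amplification(x, feats, 0, bias_model(), 1), x)

  amp <- simulate_amplification(x, feats, 2, unbiased_bias_model(), seed = 1)
  pos <- x > 0
  ratios_in <- x[pos] / x[pos][1]
  ratios_out <- amp[pos] / amp[pos][1]
  expect_equal(ratios_out, ratios_in, tolerance = 1e-12)
  expect_equal(sum(amp), sum(x), tolerance = 1e-12) # mass renormalization

  expect_error(simulate_amplification(x, feats, 3, bias_model(), 1),
               class = "arrayprep_input_error")
})

test_that("amplification compresses expression ratios, more with more rounds", {
  med_ratio <- function(a, b) {
    k <- a > 0 & b > 0
    median(abs(log2(a[k] / b[k])))
  }
  res <- sapply(1:5, function(s) {
    feats <- generate_gene_features(500, seed = s)
    cfg <- study_config(n_genes = 500, n_blanks = 20, seed = s)
    a <- generate_true_abundances(feats, cfg, "A", seed = s)
    b <- generate_true_abundances(feats, cfg, "B", seed = s)
    bm <- bias_model()
    a1 <- simulate_amplification(a, feats, 1, bm, derive_seed(s, "rA"))
    b1 <- simulate_amplification(b, feats, 1, bm, derive_seed(s, "rB"))
    a2 <- simulate_amplification(a, feats, 2, bm, derive_seed(s, "rA"))
    b2 <- simulate_amplification(b, feats, 2, bm, derive_seed(s, "rB"))
    c(truth = med_ratio(a, b), one = med_ratio(a1, b1), two = med_ratio(a2, b2))
  })
  med <- apply(res, 1, median)
  expect_lt(med[["one"]], med[["truth"]])
  expect_lt(med[["two"]], med[["one"]])
})

test_that("array scans: noiseless affine mapping, blank counts, randomized layout", {
  cfg <- noiseless_config(n_genes = 50, n_blanks = 25)
  x <- setNames(10^runif(50, 0, 3), sprintf("G%06d", 1:50))
  scan <- simulate_array_scan(x, cfg, "UHRR", "non_amp", 1, seed = 4)
  g <- scan$records[scan$records$spot_type == "gene", ]
  expect_equal(setNames(g$foreground, g$gene_id)[names(x)],
               cfg$scale * x + cfg$noise$background_mean, tolerance = 1e-12)
  expect_equal(sum(scan$records$spot_type == "blank"), 25L)
  expect_false(anyDuplicated(scan$records[c("block", "row", "col")]) > 0)

  # determinism
  scan2 <- simulate_array_scan(x, cfg, "UHRR", "non_amp", 1, seed = 4)
  expect_identical(scan$records, scan2$records)
})

test_that("zero-abundance gene spots are indistinguishable from blanks", {
  cfg <- study_config(n_genes = 1000, n_blanks = 1000, seed = 2,
                      noise = noise_model(blank_outlier_fraction = 0))
  x <- setNames(rep(0, 1000), sprintf("G%06d", 1:1000))
  scan <- simulate_array_scan(x, cfg, "null", "non_amp", 1, seed = 2)
  g <- scan$records$foreground[scan$records$spot_type == "gene"]
  b <- scan$records$foreground[scan$records$spot_type == "blank"]
  expect_gt(suppressWarnings(ks.test(g, b))$p.value, 0.01)
})

test_that("Ct simulation follows the log2 slope and quadruplicate averaging", {
  genes <- sprintf("G%06d", 1:4)
  ref <- genes[1]
  ab <- setNames(c(1000, 100, 200, 400), genes)
  p0 <- pcr_params(ct_sd = 0)
  ct <- simulate_ct_table(list(S1 = ab, S2 = 2 * ab), p0, ref, seed = 1)
  s1 <- ct$ct[ct$sample == "S1"]
  s2 <- ct$ct[ct$sample == "S2"]
  expect_equal(s1 - s2, rep(1, 4), tolerance = 1e-12) # doubling: Ct drops by 1
  expect_equal(s1, p0$intercept - log2(ab), ignore_attr = TRUE, tolerance = 1e-12)

  # unexpressed genes carry the not-detected marker
  ab0 <- ab; ab0[3] <- 0
  ct0 <- simulate_ct_table(list(S1 = ab0), p0, ref, seed = 1)
  expect_true(is.na(ct0$ct[ct0$gene_id == genes[3]]))

  # reference must be expressed everywhere
  bad <- ab; bad[1] <- 0
  expect_error(simulate_ct_table(list(S1 = bad), p0, ref, seed = 1),
               class = "arrayprep_input_error")

  # quadruplicate averaging: sd of (mean Ct - noiseless Ct) ~ ct_sd / 2
  n <- 500
  gn <- sprintf("G%06d", 1:n)
  abn <- setNames(rep(100, n), gn)
  pn <- pcr_params(ct_sd = 0.2)
  ctn <- simulate_ct_table(list(S1 = abn), pn, gn[1], seed = 8)
  noiseless <- pn$intercept - log2(abn)
  dev <- ctn$ct - noiseless
  expect_equal(sd(dev), 0.1, tolerance = 0.12)
})

test_that("generate_study writes a complete, reproducible bundle", {
  cfg <- study_config(n_genes = 50, n_blanks = 20,
                      samples = c("UHRR", "HBRR"),
                      replicates_per_method = c(non_amp = 2L, amp1 = 2L, amp2 = 2L),
                      panel_size = 10, n_bias_susceptible = 4, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t0 <- Sys.time()
  b1 <- generate_study(cfg, d1)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  b2 <- generate_study(cfg, d2)

  n_arrays <- length(cfg$samples) * sum(cfg$replicates_per_method)
  expect_equal(length(b1$manifest$files$spots), n_arrays)
  expect_true(all(file.exists(b1$spot_paths)))
  expect_equal(length(b1$panel), 10L)
  expect_equal(length(b1$bias_susceptible), 4L)

  # byte-identical reproduction, manifest included
  rel <- c("annotation.tsv", "truth.tsv", "ct.tsv", "manifest.json",
           vapply(b1$manifest$files$spots, `[[`, character(1), "path"))
  for (f in rel) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  ann <- read_annotation_table(b1$annotation_path)
  expect_equal(sum(ann$panel), 10L)
  expect_equal(sum(ann$bias_susceptible), 4L)
  expect_false(ann$panel[ann$is_reference])
})
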