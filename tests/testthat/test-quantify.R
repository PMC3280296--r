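test_that("trimmed background matches the sort/slice oracle on crafted cases", {
  # constant blanks: degenerate spread
  scan <- make_scan(setNames(500, "G1"), rep(100, 20))
  bg <- estimate_background(scan)
  expect_equal(bg$trimmed_mean, 100)
  expect_equal(bg$trimmed_sd, 0)
  expect_equal(bg$upper_limit, 100)
  expect_equal(bg$n_blanks_used, 18L) # 20 - 2 * floor(0.05 * 20)

  # one extreme value per tail: exactly one dropped from each
  blanks <- c(1, seq(90, 124, by = 2), 5000)
  expect_length(blanks, 20)
  scan2 <- make_scan(setNames(500, "G1"), blanks)
  bg2 <- estimate_background(scan2)
  oracle <- oracle_trimmed_background(blanks)
  expect_equal(bg2$trimmed_mean, oracle$mean)
  expect_equal(bg2$trimmed_sd, oracle$sd)
  expect_equal(bg2$upper_limit, oracle$upper)
  expect_lt(bg2$trimmed_mean, max(blanks))
  expect_gt(bg2$trimmed_mean, min(blanks))

  # floor arithmetic of the trim count
  scan3 <- make_scan(setNames(500, "G1"), rnorm(100, 100, 10))
  expect_equal(estimate_background(scan3)$n_blanks_used, 90L)

  # guard rails
  scan4 <- make_scan(setNames(500, "G1"), rep(100, 19))
  expect_error(estimate_background(scan4), class = "arrayprep_input_error")
})

test_that("trimmed background equals the oracle across random blank vectors", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(20:500, 1)
    blanks <- rlnorm(n, log(100), 0.4)
    scan <- make_scan(setNames(500, "G1"), blanks)
    bg <- estimate_background(scan)
    oracle <- oracle_trimmed_background(blanks)
    expect_equal(bg$trimmed_mean, oracle$mean, tolerance = 1e-12)
    expect_equal(bg$trimmed_sd, oracle$sd, tolerance = 1e-12)
    expect_equal(bg$n_blanks_used, oracle$n)
    expect_equal(bg$upper_limit, oracle$upper, tolerance = 1e-12)
  }
})

test_that("detection calls use a strict threshold and are monotone", {
  blanks <- rep(100, 20) # upper limit exactly 100
  gene_fg <- c(G1 = 100, G2 = 100.0001, G3 = 99, G4 = 5000)
  scan <- make_scan(gene_fg, blanks)
  bg <- estimate_background(scan)
  det <- call_detection(scan, bg)
  expect_identical(det, c(G1 = FALSE, G2 = TRUE, G3 = FALSE, G4 = TRUE))

  # raising any foreground never flips detected -> undetected
  set.seed(5)
  blanks2 <- rnorm(50, 100, 10)
  fg <- setNames(runif(30, 50, 200), sprintf("G%02d", 1:30))
  s1 <- make_scan(fg, blanks2)
  d1 <- call_detection(s1, estimate_background(s1))
  bumped <- fg + runif(30, 0, 100)
  s2 <- make_scan(bumped, blanks2)
  d2 <- call_detection(s2, estimate_background(s2))
  expect_true(all(d2[d1]))
})

test_that("background subtraction emits net values for detected genes only", {
  blanks <- rep(100, 20)
  gene_fg <- c(G1 = 500, G2 = 99, G3 = 100.5)
  scan <- make_scan(gene_fg, blanks)
  bg <- estimate_background(scan)
  det <- call_detection(scan, bg)
  net <- subtract_background(scan, bg, det)
  expect_equal(net[["G1"]], 400)
  expect_true(is.na(net[["G2"]]))
  expect_equal(net[["G3"]], 0.5) # detected at the boundary, positive net kept

  # a detected gene with non-positive net is demoted
  det2 <- det; det2[["G2"]] <- TRUE
  net2 <- subtract_background(scan, bg, det2)
  expect_true(is.na(net2[["G2"]]))
})

test_that("global median normalization hits the target and is scale-invariant", {
  set.seed(11)
  a <- setNames(c(rlnorm(50, 5, 1), NA, NA), sprintf("G%02d", 1:52))
  b <- a * 3.7

  na <- normalize_global_median(list(a = a, b = b), target = 1000)
  for (v in na$arrays) {
    expect_equal(median(v, na.rm = TRUE), 1000, tolerance = 1e-9)
  }
  # identical up to a scalar -> identical after normalization
  expect_equal(na$arrays$a, na$arrays$b, tolerance = 1e-12)

  # already at target -> factor 1; idempotent
  pre <- a * (1000 / median(a, na.rm = TRUE))
  n2 <- normalize_global_median(pre, target = 1000)
  expect_equal(unname(n2$factors), 1, tolerance = 1e-12)
  n3 <- normalize_global_median(n2$arrays, target = 1000)
  expect_equal(n3$arrays, n2$arrays, tolerance = 1e-12)

  all_na <- setNames(rep(NA_real_, 5), sprintf("G%d", 1:5))
  expect_error(normalize_global_median(all_na),
               class = "arrayprep_insufficient_data_error")
})

test_that("quantify_scan preserves abundance ranking in the noiseless limit", {
  cfg <- noiseless_config(n_genes = 80, n_blanks = 30)
  x <- setNames(10^runif(80, 0.5, 4), sprintf("G%06d", 1:80))
  scan <- simulate_array_scan(x, cfg, "UHRR", "non_amp", 1, seed = 6)
  q <- quantify_scan(scan)
  expect_true(all(q$genes$detected))
  net <- setNames(q$genes$net, q$genes$gene_id)[names(x)]
  expect_identical(order(net), order(x))
  expect_equal(median(net), 1000, tolerance = 1e-9)
  # detected=false <=> net absent
  expect_identical(is.na(q$genes$net), !q$genes$detected)
})

test_that("a frozen fixture scan quantifies to its golden snapshot", {
  path <- test_path("fixtures", "scan_golden.tsv")
  q <- quantify_scan(read_spot_table(path))
  expect_equal(q$background$trimmed_mean, 89.0702610, tolerance = 1e-7)
  expect_equal(q$background$upper_limit, 123.0138200, tolerance = 1e-7)
  expect_equal(sum(q$genes$detected), 48L)
  expect_equal(q$normalization_factor, 0.161255530, tolerance = 1e-7)
  net <- setNames(q$genes$net, q$genes$gene_id)
  expect_equal(unname(net[c("G000003", "G000010", "G000027")]),
               c(75982.2998630, 44.9072010, 362.9010163), tolerance = 1e-6)
})
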