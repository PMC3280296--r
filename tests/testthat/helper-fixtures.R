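# Fixtures built in code: hand-assembled scans and quantified arrays small
# enough to reason about by eye.

# a scan from explicit gene/blank foregrounds
make_scan <- function(gene_fg, blank_fg, sample = "S1", method = "non_amp",
                      replicate = 1) {
  if (is.null(names(gene_fg))) {
    names(gene_fg) <- sprintf("G%06d", seq_along(gene_fg))
  }
  n <- length(gene_fg) + length(blank_fg)
  records <- data.frame(
    block = 1L,
    row = ((seq_len(n) - 1L) %/% 100L) + 1L,
    col = ((seq_len(n) - 1L) %% 100L) + 1L,
    probe_id = c(names(gene_fg), sprintf("BLANK_%03d", seq_along(blank_fg))),
    gene_id = c(names(gene_fg), rep("", length(blank_fg))),
    spot_type = c(rep("gene", length(gene_fg)), rep("blank", length(blank_fg))),
    foreground = c(unname(gene_fg), unname(blank_fg)),
    stringsAsFactors = FALSE
  )
  array_scan(records, sample = sample, method = method, replicate = replicate)
}

# a quantified array directly from net intensities (NA = undetected),
# bypassing the scan pipeline, for QC-statistics tests
qa_from_net <- function(net, sample = "S1", method = "non_amp", replicate = 1) {
  stopifnot(!is.null(names(net)))
  structure(list(
    genes = data.frame(gene_id = names(net),
                       foreground = unname(net),
                       detected = !is.na(net),
                       net = unname(net),
                       stringsAsFactors = FALSE),
    background = NULL, normalization_factor = 1, norm_target = NA_real_,
    sample = sample, method = method, replicate = replicate
  ), class = "quantified_array")
}

# noise-free study settings: exact affine scanner, constant background
noiseless_config <- function(n_genes = 60, n_blanks = 30, seed = 1, ...) {
  study_config(
    n_genes = n_genes, n_blanks = n_blanks, seed = seed,
    noise = noise_model(multiplicative_cv = 0, background_mean = 100,
                        background_sd = 0, blank_outlier_fraction = 0),
    pcr = pcr_params(ct_sd = 0),
    ...
  )
}

# bias-free amplification: one common gain factor for every gene
unbiased_bias_model <- function(...) {
  bias_model(beta_gc = 0, beta_len = 0, beta_polyA = 0, beta_hairpin = 0,
             efficiency_noise_sd = 0, saturation_capacity = Inf, ...)
}

# independent sort/slice oracle for the trimmed background (no shared code
# with estimate_background beyond base R)
oracle_trimmed_background <- function(blanks, trim_fraction = 0.05, alpha = 0.05) {
  srt <- sort(blanks)
  k <- floor(trim_fraction * length(srt))
  kept <- srt[seq.int(k + 1, length(srt) - k)]
  m <- sum(kept) / length(kept)
  s <- if (length(kept) > 1) sqrt(sum((kept - m)^2) / (length(kept) - 1)) else 0
  t_real <- k / length(srt)
  corr <- if (t_real > 0) {
    a <- qnorm(1 - t_real)
    sqrt(1 - 2 * a * dnorm(a) / (1 - 2 * t_real))
  } else 1
  list(mean = m, sd = s, n = length(kept),
       upper = m + qnorm(1 - alpha) * s / corr)
}

# textbook Pearson from the sum formula (oracle for cor())
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
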