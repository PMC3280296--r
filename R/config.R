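# Study configuration constructors: the knobs of the synthetic-study
# generator and their validated defaults.

#' Amplification bias model
#'
#' Parameters of the in-vitro-transcription (IVT) amplification bias
#' mechanism used by [simulate_amplification()]. Each amplification round
#' multiplies a gene's abundance by a gain with two phases:
#'
#' * a **linear phase** lasting `linear_minutes_round1` (first round) or
#'   `linear_minutes_round2` (second round), during which yield is
#'   proportional to the per-gene transcription efficiency
#'   `e_g = exp(beta . features + eps_g)`, and
#' * a **saturating phase** filling the rest of `total_minutes`, whose
#'   per-gene yield is capacity-bounded, so abundant transcripts gain
#'   proportionally less — the mechanism behind fold-change compression
#'   under amplification.
#'
#' The efficiency covariates are centred transforms of the gene feature
#' table: GC fraction minus 0.5, log10 transcript length minus 3.35 (the
#' midpoint of the generator's 500–10,000 nt range; longer transcripts lose
#' more 3'-distal signal), (poly-A length − 20)/20, and hairpin count minus
#' 2. With all `beta_*` at zero, no efficiency noise and infinite capacity,
#' every gene receives the same gain and amplification is distortion-free.
#'
#' `eps_g` is drawn independently for every round of every amplification
#' reaction with standard deviation `efficiency_noise_sd`, so two samples
#' amplified separately acquire independent stochastic distortions, as
#' separate IVT reactions do.
#'
#' @param beta_gc,beta_len,beta_polyA,beta_hairpin unitless coefficients of
#'   log-efficiency on the centred features.
#' @param efficiency_noise_sd standard deviation (natural-log scale) of the
#'   per-gene, per-round efficiency noise; `>= 0`.
#' @param linear_minutes_round1 duration (minutes) of the linear phase in
#'   the first amplification round; default 40.
#' @param linear_minutes_round2 as above for the second round; default 50.
#' @param total_minutes total IVT incubation time per round (minutes);
#'   default 240 (protocols recommend 4–14 h, leaving a long non-linear
#'   phase).
#' @param saturation_capacity capacity bound of the non-linear phase, in
#'   abundance-minutes; smaller values compress high-abundance genes more.
#' @return an object of class `bias_model` (a validated list).
#' @export
#' @examples
#' bias_model()                         # defaults
#' bias_model(beta_gc = 0, beta_len = 0, beta_polyA = 0, beta_hairpin = 0,
#'            efficiency_noise_sd = 0, saturation_capacity = Inf)  # unbiased
bias_model <- function(beta_gc = -3.6,
                       beta_len = -1.5,
                       beta_polyA = -0.45,
                       beta_hairpin = -0.30,
                       efficiency_noise_sd = 0.12,
                       linear_minutes_round1 = 40,
                       linear_minutes_round2 = 50,
                       total_minutes = 240,
                       saturation_capacity = 1e5) {
  stopifnot_scalar_number(beta_gc, "beta_gc")
  stopifnot_scalar_number(beta_len, "beta_len")
  stopifnot_scalar_number(beta_polyA, "beta_polyA")
  stopifnot_scalar_number(beta_hairpin, "beta_hairpin")
  stopifnot_scalar_number(efficiency_noise_sd, "efficiency_noise_sd", min = 0)
  stopifnot_scalar_number(linear_minutes_round1, "linear_minutes_round1", min = 0)
  stopifnot_scalar_number(linear_minutes_round2, "linear_minutes_round2", min = 0)
  stopifnot_scalar_number(total_minutes, "total_minutes", min = 0)
  if (linear_minutes_round1 > total_minutes || linear_minutes_round2 > total_minutes) {
    abort_input("linear-phase minutes cannot exceed `total_minutes`")
  }
  if (!is.numeric(saturation_capacity) || length(saturation_capacity) != 1L ||
      is.na(saturation_capacity) || saturation_capacity <= 0) {
    abort_input("`saturation_capacity` must be a single positive number (Inf allowed)")
  }
  structure(list(
    beta_gc = beta_gc, beta_len = beta_len, beta_polyA = beta_polyA,
    beta_hairpin = beta_hairpin,
    efficiency_noise_sd = efficiency_noise_sd,
    linear_minutes_round1 = linear_minutes_round1,
    linear_minutes_round2 = linear_minutes_round2,
    total_minutes = total_minutes,
    saturation_capacity = saturation_capacity
  ), class = "bias_model")
}

#' Spot-level noise model
#'
#' Technical noise applied by [simulate_array_scan()]: per-spot lognormal
#' multiplicative noise on the signal, an additive Gaussian background
#' shared by gene and blank spots, and a small fraction of blank spots
#' replaced by extreme outliers (dust/scratch analogues) so that the
#' trimmed background estimator is exercised.
#'
#' @param multiplicative_cv coefficient of variation of the per-spot
#'   lognormal technical noise (fraction, `>= 0`).
#' @param background_mean,background_sd mean and sd of the additive
#'   background (intensity units, `>= 0`).
#' @param blank_outlier_fraction fraction of blank spots replaced by
#'   extreme values, in `[0, 0.05]`; must stay below the background trim
#'   fraction so trimming can suppress the outliers.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_cv = 0.15,
                        background_mean = 100,
                        background_sd = 30,
                        blank_outlier_fraction = 0.02) {
  stopifnot_scalar_number(multiplicative_cv, "multiplicative_cv", min = 0)
  stopifnot_scalar_number(background_mean, "background_mean", min = 0)
  stopifnot_scalar_number(background_sd, "background_sd", min = 0)
  stopifnot_scalar_number(blank_outlier_fraction, "blank_outlier_fraction",
                          min = 0, max = 0.05)
  structure(list(
    multiplicative_cv = multiplicative_cv,
    background_mean = background_mean,
    background_sd = background_sd,
    blank_outlier_fraction = blank_outlier_fraction
  ), class = "noise_model")
}

#' qRT-PCR simulation parameters
#'
#' @param intercept threshold-cycle value of a transcript at unit abundance
#'   (cycles); Ct decreases by one per doubling of abundance.
#' @param ct_sd per-replicate Ct noise sd (cycles).
#' @param n_replicates technical qPCR replicates averaged into the reported
#'   mean Ct; default 4 (quadruplicate).
#' @return an object of class `pcr_params`.
#' @export
pcr_params <- function(intercept = 38, ct_sd = 0.2, n_replicates = 4) {
  stopifnot_scalar_number(intercept, "intercept", min = 0)
  stopifnot_scalar_number(ct_sd, "ct_sd", min = 0)
  stopifnot_scalar_number(n_replicates, "n_replicates", min = 1)
  structure(list(intercept = intercept, ct_sd = ct_sd,
                 n_replicates = as.integer(n_replicates)),
            class = "pcr_params")
}

#' Full synthetic-study configuration
#'
#' Bundles every parameter needed to generate a complete study with
#' [generate_study()]: platform size, sample panel, replicate design,
#' abundance distribution, amplification-bias and noise models, the qRT-PCR
#' panel design, and the master seed.
#'
#' Defaults mirror the evaluated study design: four RNA samples (UHRR,
#' HBRR, breast, colon), three preparation methods (`non_amp`, `amp1` = one
#' IVT round, `amp2` = two rounds) with 5/5/3 replicates, expressed-gene
#' log10 abundances ~ Normal(2, 1.25) — a 99% central range of ~6.4 decades,
#' spanning five orders of magnitude — with 8% of genes unexpressed, and a
#' 42-gene qRT-PCR panel of which 17 genes are chosen for susceptibility to
#' amplification bias.
#'
#' @param n_genes number of gene spots on the array.
#' @param n_blanks number of blank spots (`>= 20`, so 5% trimming removes at
#'   least one spot per tail).
#' @param samples character vector of sample labels.
#' @param replicates_per_method named integer vector, one entry per method
#'   in `c("non_amp", "amp1", "amp2")`; all `>= 2`.
#' @param abundance_log10_mean,abundance_log10_sd log10-scale mean and sd of
#'   expressed-gene abundances.
#' @param fraction_expressed fraction of genes with non-zero abundance, in
#'   `(0, 1]`.
#' @param sample_effect_log10_sd sd (log10) of the per-sample random effect
#'   that differentiates samples around the shared base profile.
#' @param scale intensity units per abundance unit on the scanner.
#' @param bias a [bias_model()].
#' @param noise a [noise_model()].
#' @param pcr a [pcr_params()].
#' @param panel_size number of genes on the qRT-PCR comparison panel.
#' @param n_bias_susceptible how many panel genes are picked for extreme
#'   predicted amplification bias (the remainder are drawn at random).
#' @param seed master integer seed; every stage derives sub-seeds from it
#'   via [derive_seed()].
#' @return an object of class `study_config`.
#' @export
#' @examples
#' cfg <- study_config(n_genes = 200, n_blanks = 40, seed = 7)
#' cfg$replicates_per_method
study_config <- function(n_genes = 2000,
                         n_blanks = 200,
                         samples = c("UHRR", "HBRR", "breast", "colon"),
                         replicates_per_method = c(non_amp = 5L, amp1 = 5L, amp2 = 3L),
                         abundance_log10_mean = 2,
                         abundance_log10_sd = 1.25,
                         fraction_expressed = 0.92,
                         sample_effect_log10_sd = 0.4,
                         scale = 100,
                         bias = bias_model(),
                         noise = noise_model(),
                         pcr = pcr_params(),
                         panel_size = 42,
                         n_bias_susceptible = 17,
                         seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", min = 1)
  stopifnot_scalar_number(n_blanks, "n_blanks", min = 20)
  if (!is.character(samples) || length(samples) < 1L || anyDuplicated(samples)) {
    abort_input("`samples` must be a non-empty character vector of unique labels")
  }
  if (is.null(names(replicates_per_method)) ||
      !setequal(names(replicates_per_method), ARRAY_METHODS)) {
    abort_input("`replicates_per_method` must be named with exactly: non_amp, amp1, amp2")
  }
  if (any(replicates_per_method < 2)) {
    abort_input("all replicate counts must be >= 2")
  }
  stopifnot_scalar_number(abundance_log10_mean, "abundance_log10_mean")
  stopifnot_scalar_number(abundance_log10_sd, "abundance_log10_sd", min = 0)
  stopifnot_scalar_number(fraction_expressed, "fraction_expressed", min = 1e-12, max = 1)
  stopifnot_scalar_number(sample_effect_log10_sd, "sample_effect_log10_sd", min = 0)
  stopifnot_scalar_number(scale, "scale", min = 1e-12)
  if (!inherits(bias, "bias_model")) abort_input("`bias` must be a bias_model()")
  if (!inherits(noise, "noise_model")) abort_input("`noise` must be a noise_model()")
  if (!inherits(pcr, "pcr_params")) abort_input("`pcr` must be a pcr_params()")
  stopifnot_scalar_number(panel_size, "panel_size", min = 3)
  stopifnot_scalar_number(n_bias_susceptible, "n_bias_susceptible", min = 0)
  if (n_bias_susceptible > panel_size) {
    abort_input("`n_bias_susceptible` cannot exceed `panel_size`")
  }
  if (panel_size > n_genes) abort_input("`panel_size` cannot exceed `n_genes`")
  if (noise$blank_outlier_fraction > 0 && noise$blank_outlier_fraction >= 0.05) {
    abort_input("`blank_outlier_fraction` must stay below the 5% trim fraction")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_blanks = as.integer(n_blanks),
    samples = samples,
    replicates_per_method = as.integer(replicates_per_method[ARRAY_METHODS]) |>
      stats::setNames(ARRAY_METHODS),
    abundance_log10_mean = abundance_log10_mean,
    abundance_log10_sd = abundance_log10_sd,
    fraction_expressed = fraction_expressed,
    sample_effect_log10_sd = sample_effect_log10_sd,
    scale = scale,
    bias = bias, noise = noise, pcr = pcr,
    panel_size = as.integer(panel_size),
    n_bias_susceptible = as.integer(n_bias_susceptible),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genes: %d + %d blanks; samples: %s\n",
              x$n_genes, x$n_blanks, paste(x$samples, collapse = ", ")))
  cat(sprintf("  replicates: %s\n",
              paste(sprintf("%s=%d", names(x$replicates_per_method),
                            x$replicates_per_method), collapse = ", ")))
  cat(sprintf("  log10 abundance ~ N(%.2f, %.2f); %.0f%% expressed\n",
              x$abundance_log10_mean, x$abundance_log10_sd,
              100 * x$fraction_expressed))
  cat(sprintf("  qRT-PCR panel: %d genes (%d bias-susceptible); seed %d\n",
              x$panel_size, x$n_bias_susceptible, x$seed))
  invisible(x)
}

#' Read a study configuration from a YAML file
#'
#' The YAML schema mirrors the arguments of [study_config()], with `bias`,
#' `noise` and `pcr` as nested maps passed to [bias_model()],
#' [noise_model()] and [pcr_params()].
#'
#' @param path path to a YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bias)) raw$bias <- do.call(bias_model, raw$bias)
  if (!is.null(raw$noise)) raw$noise <- do.call(noise_model, raw$noise)
  if (!is.null(raw$pcr)) raw$pcr <- do.call(pcr_params, raw$pcr)
  if (!is.null(raw$replicates_per_method)) {
    raw$replicates_per_method <- unlist(raw$replicates_per_method)
  }
  if (!is.null(raw$samples)) raw$samples <- as.character(unlist(raw$samples))
  do.call(study_config, raw)
}
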