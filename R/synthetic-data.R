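# Synthetic-study generator: gene features, true abundances, IVT
# amplification with sequence-feature bias, array scans, and qRT-PCR Ct
# tables. Everything is a pure function of (inputs, seed).

# Centring constants for the bias covariates; these are the means of the
# feature-generator distributions, so beta . features has mean ~0 and the
# unbiased limit is exactly beta = 0.
.GC_CENTER <- 0.5
.LOG10_LEN_CENTER <- 3.35   # midpoint of log10-uniform [500, 10000]
.POLYA_CENTER <- 20
.HAIRPIN_CENTER <- 2

#' Generate a gene feature (annotation) table
#'
#' Draws per-gene sequence features that drive amplification bias: GC
#' content ~ Uniform(0.3, 0.7), transcript length ~ log-uniform(500,
#' 10,000) nt, poly-A stretch length ~ Geometric(mean 20) nt, and hairpin
#' count ~ Poisson(2).
#'
#' @param n_genes number of genes (`>= 1`).
#' @param seed integer seed; the same `(n_genes, seed)` always reproduces
#'   the same table.
#' @return a `data.frame` with columns `gene_id`, `gc_content`,
#'   `transcript_length`, `polyA_length`, `hairpin_count`.
#' @export
#' @examples
#' head(generate_gene_features(10, seed = 1))
generate_gene_features <- function(n_genes, seed) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || is.na(n_genes) || n_genes < 1) {
    abort_input("`n_genes` must be a positive integer")
  }
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    data.frame(
      gene_id = sprintf("G%06d", seq_len(n_genes)),
      gc_content = stats::runif(n_genes, 0.3, 0.7),
      transcript_length = as.integer(round(
        10^stats::runif(n_genes, log10(500), log10(10000)))),
      polyA_length = stats::rgeom(n_genes, prob = 1 / (.POLYA_CENTER + 1)),
      hairpin_count = stats::rpois(n_genes, lambda = .HAIRPIN_CENTER),
      stringsAsFactors = FALSE
    )
  })
}

validate_features <- function(features) {
  required <- c("gene_id", "gc_content", "transcript_length",
                "polyA_length", "hairpin_count")
  missing <- setdiff(required, names(features))
  if (length(missing)) {
    abort_input(sprintf("feature table missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(features) == 0L) abort_input("feature table is empty")
  if (anyDuplicated(features$gene_id)) abort_input("duplicate gene_id in feature table")
  if (any(features$gc_content < 0 | features$gc_content > 1)) {
    abort_input("gc_content must lie in [0, 1]")
  }
  if (any(features$transcript_length <= 0) || any(features$polyA_length < 0) ||
      any(features$hairpin_count < 0)) {
    abort_input("lengths and counts must be non-negative (length > 0)")
  }
  invisible(features)
}

# Linear predictor of log amplification efficiency (centred covariates).
bias_linear_predictor <- function(features, bias) {
  validate_features(features)
  bias$beta_gc * (features$gc_content - .GC_CENTER) +
    bias$beta_len * (log10(features$transcript_length) - .LOG10_LEN_CENTER) +
    bias$beta_polyA * ((features$polyA_length - .POLYA_CENTER) / .POLYA_CENTER) +
    bias$beta_hairpin * (features$hairpin_count - .HAIRPIN_CENTER)
}

#' Generate true transcript abundances for one sample
#'
#' Expressed genes (a `fraction_expressed` share, chosen once per study so
#' all samples share the expressed set) receive
#' `log10(abundance) = base + sample effect`, where the base profile is
#' Normal(`abundance_log10_mean`, `abundance_log10_sd`) shared across
#' samples and the sample effect is Normal(0, `sample_effect_log10_sd`)
#' drawn from a seed derived from the sample label. Distinct samples are
#' therefore correlated but not identical, giving HBRR-vs-UHRR-style log
#' ratios with sd `sqrt(2) * sample_effect_log10_sd` (log10). Unexpressed
#' genes sit at exactly zero.
#'
#' @param features feature table from [generate_gene_features()].
#' @param config a [study_config()] (only the abundance fields are used).
#' @param sample_label character label; part of the random-effect seed.
#' @param seed study-level integer seed.
#' @param always_expressed gene ids treated as stable housekeeping genes
#'   (e.g. the qRT-PCR reference, a PolR2A analogue): expressed in every
#'   sample at a fixed level of `10^(abundance_log10_mean + 1)` with no
#'   sample effect. Must exist in `features`.
#' @return named numeric vector of linear-scale abundances (0 = unexpressed).
#' @export
generate_true_abundances <- function(features, config, sample_label, seed,
                                     always_expressed = character()) {
  validate_features(features)
  unknown <- setdiff(always_expressed, features$gene_id)
  if (length(unknown)) {
    abort_input(sprintf("unknown gene id(s) in `always_expressed`: %s",
                        paste(unknown, collapse = ", ")))
  }
  n <- nrow(features)
  base <- with_seed(derive_seed(seed, "abundance_base"), {
    list(
      log10_abundance = stats::rnorm(n, config$abundance_log10_mean,
                                     config$abundance_log10_sd),
      expressed = stats::runif(n) < config$fraction_expressed
    )
  })
  effect <- with_seed(derive_seed(seed, "abundance_sample", sample_label),
                      stats::rnorm(n, 0, config$sample_effect_log10_sd))
  x <- ifelse(base$expressed, 10^(base$log10_abundance + effect), 0)
  x[features$gene_id %in% always_expressed] <- 10^(config$abundance_log10_mean + 1)
  stats::setNames(x, features$gene_id)
}

#' Simulate in-vitro-transcription amplification of a sample
#'
#' Applies `rounds` (0, 1 or 2) rounds of IVT amplification to a true
#' abundance vector. Each round multiplies gene g's abundance x_g by
#'
#'   gain_g = L * e_g + T_nl * e_g / (1 + x_g * e_g * T_nl / K)
#'
#' where `e_g = exp(beta . features_g + eps_g)` is the per-gene efficiency
#' (`eps_g ~ N(0, efficiency_noise_sd)`, fresh per round), `L` is the
#' linear-phase duration for that round (40 min for the first, 50 for the
#' second), `T_nl = total_minutes - L` is the non-linear phase, and `K` is
#' the saturation capacity. The second term has diminishing returns in
#' `x_g`, so abundant transcripts gain less — compressing expression ratios
#' — while the feature-dependent `e_g` reorders genes. After each round the
#' output is rescaled to the input's total mass, so methods differ in
#' profile shape, not gross scale.
#'
#' With `rounds = 0` the input is returned unchanged. With all betas zero,
#' no efficiency noise and infinite capacity, every gene gets one common
#' gain factor and all pairwise ratios are preserved exactly.
#'
#' @param abundance named abundance vector (names = gene ids), as produced
#'   by [generate_true_abundances()].
#' @param features matching feature table.
#' @param rounds integer in {0, 1, 2}.
#' @param bias a [bias_model()].
#' @param seed integer seed for the per-round efficiency noise.
#' @return named abundance vector after amplification, same total mass.
#' @export
simulate_amplification <- function(abundance, features, rounds, bias, seed) {
  if (!is.numeric(rounds) || length(rounds) != 1L || is.na(rounds) ||
      !rounds %in% c(0, 1, 2)) {
    abort_input("`rounds` must be 0, 1 or 2")
  }
  validate_features(features)
  if (!identical(names(abundance), features$gene_id)) {
    if (!setequal(names(abundance), features$gene_id)) {
      abort_input("`abundance` names must match the feature table's gene ids")
    }
    abundance <- abundance[features$gene_id]
  }
  if (rounds == 0) return(abundance)
  lp <- bias_linear_predictor(features, bias)
  x <- abundance
  total_in <- sum(x)
  for (r in seq_len(rounds)) {
    L <- if (r == 1) bias$linear_minutes_round1 else bias$linear_minutes_round2
    t_nl <- bias$total_minutes - L
    eps <- if (bias$efficiency_noise_sd > 0) {
      with_seed(derive_seed(seed, "amp_round", r),
                stats::rnorm(length(x), 0, bias$efficiency_noise_sd))
    } else {
      0
    }
    e <- exp(lp + eps)
    sat <- if (is.infinite(bias$saturation_capacity)) {
      t_nl * e
    } else {
      t_nl * e / (1 + x * e * t_nl / bias$saturation_capacity)
    }
    x <- x * (L * e + sat)
    x <- x * (total_in / sum(x))
  }
  x
}

#' Simulate one array hybridization (an ArrayScan)
#'
#' Maps a (possibly amplified) abundance vector to per-spot foreground
#' intensities. Gene spots receive
#' `scale * abundance * lognormal(cv) + N(background_mean, background_sd)`,
#' truncated at zero; blank spots receive background-only draws, with a
#' `blank_outlier_fraction` share of blanks replaced by extreme high values
#' (dust analogues) that the trimmed background estimator must absorb. Spot
#' order on the grid is randomized by the seed.
#'
#' @param abundance named abundance vector.
#' @param config a [study_config()] (uses `n_blanks`, `scale`, `noise`).
#' @param sample_label sample metadata recorded on the scan.
#' @param method one of `"non_amp"`, `"amp1"`, `"amp2"`.
#' @param replicate replicate index (`>= 1`).
#' @param seed integer seed.
#' @return an [array_scan()] object.
#' @export
simulate_array_scan <- function(abundance, config, sample_label, method,
                                replicate, seed) {
  match_method(method)
  noise <- config$noise
  n_genes <- length(abundance)
  n_blanks <- config$n_blanks
  if (is.null(names(abundance)) || anyDuplicated(names(abundance))) {
    abort_input("`abundance` must be named with unique gene ids")
  }
  with_seed(seed, {
    sdlog <- sqrt(log1p(noise$multiplicative_cv^2))
    mult <- if (sdlog > 0) {
      # mean-one lognormal so expected signal is scale * abundance
      stats::rlnorm(n_genes, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, n_genes)
    }
    gene_fg <- pmax(0, config$scale * abundance * mult +
                      stats::rnorm(n_genes, noise$background_mean, noise$background_sd))
    blank_fg <- pmax(0, stats::rnorm(n_blanks, noise$background_mean,
                                     noise$background_sd))
    n_out <- round(noise$blank_outlier_fraction * n_blanks)
    if (n_out > 0) {
      idx <- sample.int(n_blanks, n_out)
      blank_fg[idx] <- noise$background_mean +
        stats::runif(n_out, 10, 30) * max(noise$background_sd, 1)
    }
    records <- data.frame(
      probe_id = c(names(abundance), sprintf("BLANK_%05d", seq_len(n_blanks))),
      gene_id = c(names(abundance), rep("", n_blanks)),
      spot_type = c(rep("gene", n_genes), rep("blank", n_blanks)),
      foreground = c(gene_fg, blank_fg),
      stringsAsFactors = FALSE
    )
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    n_col <- ceiling(sqrt(nrow(records)))
    records <- cbind(
      data.frame(block = 1L,
                 row = ((seq_len(nrow(records)) - 1L) %/% n_col) + 1L,
                 col = ((seq_len(nrow(records)) - 1L) %% n_col) + 1L),
      records
    )
    rownames(records) <- NULL
    array_scan(records, sample = sample_label, method = method,
               replicate = replicate, platform_size = n_genes)
  })
}

#' Simulate a qRT-PCR Ct table for a set of samples
#'
#' For each expressed gene and sample, per-replicate threshold cycles are
#' `Ct = intercept - log2(abundance) + N(0, ct_sd)`; the table stores the
#' mean over `n_replicates` (default quadruplicate) Ct values. Unexpressed
#' genes are recorded as not detected (`NA`, written as `ND` on disk).
#'
#' @param abundances named list: sample label -> named abundance vector (all
#'   vectors over the same gene ids).
#' @param pcr a [pcr_params()].
#' @param reference_gene gene id that must be expressed in every sample
#'   (the PolR2A analogue used later for delta-Ct normalization).
#' @param seed integer seed.
#' @return a [ct_table()] (long `data.frame`: `gene_id`, `sample`, `ct`).
#' @export
simulate_ct_table <- function(abundances, pcr, reference_gene, seed) {
  if (!is.list(abundances) || is.null(names(abundances)) || !length(abundances)) {
    abort_input("`abundances` must be a named list of abundance vectors")
  }
  genes <- names(abundances[[1]])
  for (s in names(abundances)) {
    if (!identical(names(abundances[[s]]), genes)) {
      abort_input("all abundance vectors must share the same gene ids, in order")
    }
    if (!reference_gene %in% genes || abundances[[s]][reference_gene] <= 0) {
      abort_input(sprintf(
        "reference gene '%s' must be expressed (abundance > 0) in sample '%s'",
        reference_gene, s))
    }
  }
  rows <- with_seed(seed, {
    do.call(rbind, lapply(names(abundances), function(s) {
      x <- abundances[[s]]
      ct <- rep(NA_real_, length(x))
      pos <- x > 0
      if (any(pos)) {
        noiseless <- pcr$intercept - log2(x[pos])
        reps <- matrix(stats::rnorm(sum(pos) * pcr$n_replicates, 0, pcr$ct_sd),
                       nrow = sum(pos))
        ct[pos] <- noiseless + rowMeans(reps)
      }
      data.frame(gene_id = genes, sample = s, ct = ct, stringsAsFactors = FALSE)
    }))
  })
  ct_table(rows, replicate_count = pcr$n_replicates)
}

#' Generate a complete synthetic study on disk
#'
#' Writes, under `out_dir`: one spot table per sample x method x replicate
#' (`spots/<sample>_<method>_rep<k>.tsv`), the gene annotation table
#' (`annotation.tsv`, features plus qRT-PCR panel flags), the true-abundance
#' table (`truth.tsv`, genes x samples), the simulated qRT-PCR Ct table
#' (`ct.tsv`, panel genes plus the reference gene), and a JSON `manifest`
#' listing every file with its generation seed. Rerunning with the same
#' config produces byte-identical files.
#'
#' The qRT-PCR panel contains `panel_size` expressed genes:
#' `n_bias_susceptible` of them are the expressed genes with the most
#' extreme predicted amplification bias (largest `|beta . features|`), the
#' rest are drawn at random; the reference gene (the first gene, playing the
#' role of PolR2A) is forced to be expressed in every sample and is not
#' part of the panel.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a `study_bundle`: paths, the panel, and the manifest.
#' @export
generate_study <- function(config, out_dir) {
  if (!inherits(config, "study_config")) abort_input("`config` must be a study_config()")
  dir.create(file.path(out_dir, "spots"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_input(sprintf("cannot create output dir: %s", out_dir))
  seed <- config$seed

  features <- generate_gene_features(config$n_genes, derive_seed(seed, "features"))
  reference_gene <- features$gene_id[1L]

  truths <- lapply(config$samples, function(s) {
    generate_true_abundances(features, config, s, seed,
                             always_expressed = reference_gene)
  })
  names(truths) <- config$samples

  # qRT-PCR panel: expressed in every sample; most-biased + random members
  expressed_all <- features$gene_id[Reduce(`&`, lapply(truths, function(x) x > 0))]
  expressed_all <- setdiff(expressed_all, reference_gene)
  if (length(expressed_all) < config$panel_size) {
    abort_input("too few genes expressed in all samples to form the qRT-PCR panel")
  }
  lp <- abs(bias_linear_predictor(features, config$bias))
  names(lp) <- features$gene_id
  susceptible <- expressed_all[order(lp[expressed_all], decreasing = TRUE)]
  susceptible <- susceptible[seq_len(config$n_bias_susceptible)]
  pool <- setdiff(expressed_all, susceptible)
  random_members <- with_seed(derive_seed(seed, "panel"), {
    sort(sample(pool, config$panel_size - config$n_bias_susceptible))
  })
  panel <- c(random_members, susceptible)

  annotation <- features
  annotation$is_reference <- annotation$gene_id == reference_gene
  annotation$panel <- annotation$gene_id %in% panel
  annotation$bias_susceptible <- annotation$gene_id %in% susceptible

  rounds_of <- c(non_amp = 0L, amp1 = 1L, amp2 = 2L)
  manifest_rows <- list()
  for (s in config$samples) {
    for (m in ARRAY_METHODS) {
      amp <- simulate_amplification(truths[[s]], features, rounds_of[[m]],
                                    config$bias,
                                    derive_seed(seed, "amplification", s, m))
      for (r in seq_len(config$replicates_per_method[[m]])) {
        scan_seed <- derive_seed(seed, "scan", s, m, r)
        scan <- simulate_array_scan(amp, config, s, m, r, scan_seed)
        rel <- file.path("spots", sprintf("%s_%s_rep%d.tsv", s, m, r))
        write_spot_table(scan, file.path(out_dir, rel))
        manifest_rows[[length(manifest_rows) + 1L]] <-
          list(path = rel, sample = s, method = m, replicate = r, seed = scan_seed)
      }
    }
  }

  ct_genes <- c(reference_gene, panel)
  ct <- simulate_ct_table(lapply(truths, function(x) x[ct_genes]),
                          config$pcr, reference_gene,
                          derive_seed(seed, "ct"))

  annotation_path <- file.path(out_dir, "annotation.tsv")
  write_annotation_table(annotation, annotation_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  truth_df <- data.frame(gene_id = features$gene_id, stringsAsFactors = FALSE)
  for (s in config$samples) truth_df[[s]] <- truths[[s]]
  write_tsv_deterministic(truth_df, truth_path)
  ct_path <- file.path(out_dir, "ct.tsv")
  write_ct_table(ct, ct_path)

  manifest <- list(
    package = "arrayprep",
    seed = seed,
    n_genes = config$n_genes,
    n_blanks = config$n_blanks,
    samples = as.list(config$samples),
    replicates_per_method = as.list(config$replicates_per_method),
    reference_gene = reference_gene,
    panel = as.list(panel),
    bias_susceptible = as.list(susceptible),
    files = list(
      annotation = "annotation.tsv", truth = "truth.tsv", ct = "ct.tsv",
      spots = manifest_rows
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(structure(list(
    out_dir = out_dir, config = config, manifest = manifest,
    manifest_path = manifest_path,
    annotation_path = annotation_path, truth_path = truth_path,
    ct_path = ct_path,
    spot_paths = vapply(manifest_rows, function(r) file.path(out_dir, r$path),
                        character(1)),
    reference_gene = reference_gene, panel = panel,
    bias_susceptible = susceptible
  ), class = "study_bundle"))
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic study bundle\n")
  cat(sprintf("  directory: %s\n", x$out_dir))
  cat(sprintf("  %d spot tables; reference gene %s; %d-gene qRT-PCR panel\n",
              length(x$spot_paths), x$reference_gene, length(x$panel)))
  invisible(x)
}
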