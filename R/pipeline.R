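# End-to-end study runner: simulate -> quantify -> replicate QC ->
# method concordance -> qRT-PCR accuracy, with one consolidated report.

#' Run a complete synthetic study end to end
#'
#' Generates a synthetic study with [generate_study()], reads every spot
#' table back from disk, quantifies each array with [quantify_scan()], and
#' computes the full evaluation suite:
#'
#' * per-method replicate QC on the first sample (pairwise Pearson on log10
#'   intensities, two-fold concordance, undetected fractions, CV summary
#'   under the replicate-detection filter),
#' * inter-method Pearson and the three-way Venn partition of
#'   consensus-detected genes,
#' * Spearman concordance of reference-normalized log2 array values with
#'   simulated qRT-PCR delta-Ct per sample and method, and the two-sample
#'   differential-ratio comparison (first versus second sample) per method.
#'
#' The report directory receives the generated study, an expression matrix
#' per sample, `qc_report.tsv`, `venn.tsv`, `accuracy_report.tsv` and a JSON
#' `run_report.json` echoing the configuration and every analysis option
#' (trim fraction, alpha, upper-confidence-limit mode, normalization
#' target, detection filters), so a run is fully reproducible from its
#' report.
#'
#' @param config a [study_config()], or the path to a YAML file readable by
#'   [read_study_config()].
#' @param out_dir output directory.
#' @param trim_fraction,alpha,ucl_mode,norm_target per-array quantification
#'   options, see [quantify_scan()].
#' @param fold fold-change band for duplicate concordance (default 2).
#' @param min_detection_fraction replicate-detection filter (default 0.6).
#' @return an object of class `run_report` (all tables and summary
#'   statistics as R objects, plus output paths).
#' @export
run_study <- function(config, out_dir,
                      trim_fraction = 0.05, alpha = 0.05,
                      ucl_mode = c("sd", "sem"), norm_target = 1000,
                      fold = 2, min_detection_fraction = 0.6) {
  ucl_mode <- match.arg(ucl_mode)
  if (is.character(config)) config <- read_study_config(config)
  if (!inherits(config, "study_config")) {
    abort_input("`config` must be a study_config or a path to a YAML config")
  }
  study_dir <- file.path(out_dir, "study")
  bundle <- generate_study(config, study_dir)

  # read every array back from disk so the on-disk contract is the one
  # actually analyzed
  quants <- list()
  for (row in bundle$manifest$files$spots) {
    scan <- read_spot_table(file.path(study_dir, row$path))
    q <- quantify_scan(scan, trim_fraction = trim_fraction, alpha = alpha,
                       ucl_mode = ucl_mode, norm_target = norm_target)
    quants[[row$sample]][[row$method]][[row$replicate]] <- q
  }

  qc_sample <- config$samples[1]
  qc_rows <- list()
  cv_summaries <- list()
  for (m in ARRAY_METHODS) {
    set <- quants[[qc_sample]][[m]]
    pairs <- utils::combn(length(set), 2)
    r <- apply(pairs, 2, function(ij) pearson_log10(set[[ij[1]]], set[[ij[2]]]))
    conc <- apply(pairs, 2, function(ij) {
      fold_change_concordance(set[[ij[1]]], set[[ij[2]]], fold = fold)
    })
    cv <- replicate_cv(set, min_detection_fraction)
    cv_summaries[[m]] <- cv
    qc_rows[[m]] <- data.frame(
      method = m, sample = qc_sample, n_replicates = length(set),
      mean_pairwise_pearson_log10 = mean(r),
      min_pairwise_pearson_log10 = min(r),
      mean_fold_concordance = mean(conc),
      undetected_fraction_per_array = mean(vapply(set, undetected_fraction,
                                                  numeric(1))),
      undetected_fraction_consensus = undetected_fraction(set,
                                                          min_detection_fraction),
      median_cv = cv$median_cv, sd_cv = cv$sd_cv,
      cv_n_genes = cv$n_genes_used,
      stringsAsFactors = FALSE
    )
  }
  qc_report <- do.call(rbind, qc_rows)
  rownames(qc_report) <- NULL

  consensus <- lapply(ARRAY_METHODS, function(m) {
    consensus_detection(quants[[qc_sample]][[m]], min_detection_fraction)
  })
  names(consensus) <- ARRAY_METHODS
  venn <- venn_partition(consensus$non_amp, consensus$amp1, consensus$amp2,
                         universe = consensus$non_amp$universe)
  method_pairs <- list(c("non_amp", "amp1"), c("amp1", "amp2"),
                       c("non_amp", "amp2"))
  inter_r <- vapply(method_pairs, function(p) {
    inter_method_pearson(quants[[qc_sample]][[p[1]]],
                         quants[[qc_sample]][[p[2]]])$mean_r
  }, numeric(1))
  names(inter_r) <- vapply(method_pairs, paste, character(1), collapse = "_vs_")

  ct <- read_ct_table(bundle$ct_path)
  dct <- compute_delta_ct(ct, bundle$reference_gene)
  acc_rows <- list()
  for (s in config$samples) {
    dcv <- delta_ct_vector(dct, s)
    for (m in ARRAY_METHODS) {
      rel <- reference_normalized_mean_log2(quants[[s]][[m]],
                                            bundle$reference_gene,
                                            min_detection_fraction)
      sp <- spearman_accuracy(rel, dcv, gene_panel = bundle$panel)
      acc_rows[[paste(s, m)]] <- data.frame(
        sample = s, method = m, spearman_rho = sp$rho, n_genes = sp$n,
        stringsAsFactors = FALSE)
    }
  }
  accuracy_report <- do.call(rbind, acc_rows)
  rownames(accuracy_report) <- NULL

  diff_rows <- list()
  differential <- list()
  if (length(config$samples) >= 2) {
    sA <- config$samples[1]; sB <- config$samples[2]
    for (m in ARRAY_METHODS) {
      d <- differential_ratio_comparison(
        quants[[sA]][[m]], quants[[sB]][[m]],
        delta_ct_vector(dct, sA), delta_ct_vector(dct, sB),
        min_detection_fraction, reference_gene = bundle$reference_gene)
      differential[[m]] <- d
      diff_rows[[m]] <- data.frame(
        method = m, sample_pair = paste(sA, sB, sep = "_vs_"),
        spearman_rho = d$rho, n_genes = d$n,
        median_abs_array_log2_ratio = stats::median(abs(d$ratios$array_log2_ratio)),
        median_abs_pcr_log2_ratio = stats::median(abs(d$ratios$pcr_log2_ratio)),
        stringsAsFactors = FALSE)
    }
  }
  differential_report <- if (length(diff_rows)) {
    out <- do.call(rbind, diff_rows); rownames(out) <- NULL; out
  } else {
    NULL
  }

  # persist the report tables
  for (s in config$samples) {
    em <- build_expression_matrix(unlist(quants[[s]], recursive = FALSE))
    write_expression_matrix(em, file.path(out_dir,
                                          sprintf("expression_%s.tsv", s)))
  }
  write_tsv_deterministic(qc_report, file.path(out_dir, "qc_report.tsv"))
  venn_df <- data.frame(region = names(venn$counts),
                        count = as.integer(venn$counts),
                        fraction = unname(venn$fractions),
                        stringsAsFactors = FALSE)
  write_tsv_deterministic(venn_df, file.path(out_dir, "venn.tsv"))
  write_tsv_deterministic(accuracy_report,
                          file.path(out_dir, "accuracy_report.tsv"))
  if (!is.null(differential_report)) {
    write_tsv_deterministic(differential_report,
                            file.path(out_dir, "differential_report.tsv"))
  }

  options_used <- list(trim_fraction = trim_fraction, alpha = alpha,
                       ucl_mode = ucl_mode, norm_target = norm_target,
                       fold = fold,
                       min_detection_fraction = min_detection_fraction)
  report <- structure(list(
    out_dir = out_dir, bundle = bundle, options = options_used,
    seed = config$seed,
    version = as.character(utils::packageVersion("arrayprep")),
    quantified = quants,
    qc = qc_report, cv = cv_summaries,
    consensus = consensus, venn = venn, inter_method_pearson = inter_r,
    accuracy = accuracy_report, differential = differential,
    differential_report = differential_report
  ), class = "run_report")
  jsonlite::write_json(list(
    version = report$version, seed = config$seed, options = options_used,
    qc = qc_report, inter_method_pearson = as.list(inter_r),
    venn = as.list(venn$counts), accuracy = accuracy_report,
    differential = differential_report
  ), file.path(out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, dataframe = "rows")
  report
}

#' Replicate-aggregated reference-normalized log2 intensities
#'
#' The per-gene mean of log2 net intensities across the replicates where
#' the gene was detected (genes failing the [detection_threshold()]
#' filter are `NA`), re-expressed
#' relative to the reference gene so the reference maps to exactly 0 —
#' the replicate-set analogue of [reference_normalized_log2()].
#'
#' @param replicate_set list of [quantify_scan()] results.
#' @param reference_gene gene id; must pass the detection filter itself.
#' @param min_detection_fraction detection filter (default 0.6).
#' @return named numeric vector of log2 relative intensities (`NA` where the
#'   filter fails).
#' @export
reference_normalized_mean_log2 <- function(replicate_set, reference_gene,
                                           min_detection_fraction = 0.6) {
  if (inherits(replicate_set, "quantified_array")) {
    replicate_set <- list(replicate_set)
  }
  m <- filtered_mean_log2(replicate_set, min_detection_fraction)
  if (!reference_gene %in% names(m) || is.na(m[reference_gene])) {
    abort_input(sprintf(
      "reference gene '%s' does not pass the detection filter", reference_gene))
  }
  m - m[[reference_gene]]
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Study run report (arrayprep %s, seed %d)\n", x$version, x$seed))
  cat(sprintf("  output: %s\n", x$out_dir))
  cat(sprintf("  options: trim %.2f, alpha %.2f, UCL mode %s, norm target %g\n",
              x$options$trim_fraction, x$options$alpha, x$options$ucl_mode,
              x$options$norm_target))
  cat("\nReplicate QC (first sample):\n")
  print(x$qc, digits = 3)
  cat("\nInter-method Pearson (log10):\n")
  print(round(x$inter_method_pearson, 3))
  cat("\n")
  print(x$venn)
  cat("\nqRT-PCR accuracy (Spearman rho per sample x method):\n")
  print(x$accuracy, digits = 3)
  if (!is.null(x$differential_report)) {
    cat("\nDifferential-ratio comparison:\n")
    print(x$differential_report, digits = 3)
  }
  invisible(x)
}
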