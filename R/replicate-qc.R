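# Intra-method reproducibility statistics: pairwise Pearson correlation on
# log10 intensities, two-fold concordance, undetected fractions, and
# per-gene CV under a replicate-detection filter.

# net intensities restricted to genes detected in both arrays
co_detected_pair <- function(arrayA, arrayB) {
  a <- net_values(arrayA)
  b <- net_values(arrayB)
  if (!setequal(names(a), names(b))) {
    abort_input("arrays must share one gene universe")
  }
  b <- b[names(a)]
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

#' Pairwise Pearson correlation of log10 intensities
#'
#' Pearson's R between `log10(net intensity)` of two quantified arrays over
#' the genes detected in **both** (undetected genes have no defined log
#' intensity and are excluded).
#'
#' @param arrayA,arrayB [quantify_scan()] results over one gene universe.
#' @return Pearson correlation coefficient.
#' @export
pearson_log10 <- function(arrayA, arrayB) {
  p <- co_detected_pair(arrayA, arrayB)
  if (length(p$a) < 3L) {
    abort_insufficient("fewer than 3 genes detected in both arrays")
  }
  stats::cor(log10(p$a), log10(p$b), method = "pearson")
}

#' Fraction of genes within a fold-change band between duplicates
#'
#' Over genes detected in both arrays, the fraction whose intensities agree
#' within `fold` (boundary inclusive: a gene at exactly 2-fold counts as
#' concordant).
#'
#' @param arrayA,arrayB [quantify_scan()] results over one gene universe.
#' @param fold fold-change band (default 2).
#' @return fraction in `[0, 1]`.
#' @export
fold_change_concordance <- function(arrayA, arrayB, fold = 2) {
  stopifnot_scalar_number(fold, "fold", min = 1)
  p <- co_detected_pair(arrayA, arrayB)
  if (length(p$a) < 1L) {
    abort_insufficient("no genes detected in both arrays")
  }
  ratio <- pmax(p$a, p$b) / pmin(p$a, p$b)
  mean(ratio <= fold)
}

#' Fraction of the gene universe not detected
#'
#' For a single quantified array, the per-array undetected fraction. For a
#' list of replicate arrays, the fraction of genes failing the consensus
#' rule (detected in fewer than [detection_threshold()] replicates).
#'
#' @param x a `quantified_array` or a list of them (one replicate set).
#' @param min_detection_fraction consensus rule for a replicate set.
#' @return fraction in `[0, 1]`.
#' @export
undetected_fraction <- function(x, min_detection_fraction = 0.6) {
  if (inherits(x, "quantified_array")) {
    return(mean(!x$genes$detected))
  }
  det <- consensus_detection(x, min_detection_fraction)
  1 - length(det$gene_ids) / length(det$universe)
}

#' Per-gene coefficient of variation across replicates
#'
#' A gene enters the CV calculation iff it is detected in at least
#' [detection_threshold()] replicates — with five
#' replicates the 60% rule gives 3-of-5; with three replicates, 67% gives
#' 2-of-3. The CV of an included gene is the sample (n-1) standard deviation
#' over the replicates where it was detected, divided by their mean, using
#' normalized net intensities.
#'
#' @param replicate_set list of [quantify_scan()] results (same sample and
#'   method, `>= 2` replicates, one gene universe).
#' @param min_detection_fraction detection filter (default 0.6).
#' @return an object of class `cv_summary`: `per_gene_cv` (named vector over
#'   included genes), `median_cv`, `sd_cv`, `n_genes_used`,
#'   `min_detection_fraction`, and the box-plot quantiles (10/25/50/75/90%).
#' @export
replicate_cv <- function(replicate_set, min_detection_fraction = 0.6) {
  if (!is.list(replicate_set) || length(replicate_set) < 2L) {
    abort_input("`replicate_set` must be a list of >= 2 quantified arrays")
  }
  stopifnot_scalar_number(min_detection_fraction, "min_detection_fraction",
                          min = 1e-12, max = 1)
  genes <- replicate_set[[1]]$genes$gene_id
  vals <- vapply(replicate_set, function(q) {
    if (!identical(q$genes$gene_id, genes)) {
      abort_input("replicates must share one gene universe, in order")
    }
    q$genes$net
  }, numeric(length(genes)))
  vals <- matrix(vals, nrow = length(genes))
  n_rep <- length(replicate_set)
  threshold <- detection_threshold(min_detection_fraction, n_rep)
  n_det <- rowSums(!is.na(vals))
  keep <- n_det >= threshold
  if (!any(keep)) abort_insufficient("no genes pass the replicate-detection filter")
  cv <- apply(vals[keep, , drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]
    stats::sd(v) / mean(v)
  })
  names(cv) <- genes[keep]
  qs <- stats::quantile(cv, c(0.10, 0.25, 0.50, 0.75, 0.90), names = TRUE)
  structure(list(
    per_gene_cv = cv,
    median_cv = unname(stats::median(cv)),
    sd_cv = unname(stats::sd(cv)),
    n_genes_used = sum(keep),
    min_detection_fraction = min_detection_fraction,
    detection_threshold = threshold,
    n_replicates = n_rep,
    quantiles = qs
  ), class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf(
    "Replicate CV: median %.3f +/- %.3f over %d genes (detected in >= %d of %d replicates)\n",
    x$median_cv, x$sd_cv, x$n_genes_used, x$detection_threshold, x$n_replicates))
  invisible(x)
}
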