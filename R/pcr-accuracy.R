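# Accuracy of the microarray quantification against qRT-PCR: delta-Ct
# normalization to the reference gene, reference-normalized log2 array
# intensities, Spearman rank concordance per sample, and the two-sample
# differential-ratio comparison under the dual detection filter.

#' Normalize a Ct table to the reference gene (delta-Ct)
#'
#' `delta Ct = mean Ct(gene) - mean Ct(reference)` within each sample, so
#' the reference gene's own delta-Ct is exactly 0 everywhere and lower
#' delta-Ct means higher expression. Not-detected entries propagate.
#'
#' @param ct a [ct_table()].
#' @param reference_gene gene id of the reference (PolR2A analogue); must
#'   have a Ct value in every sample present.
#' @return an object of class `delta_ct_table`: long `data.frame`
#'   (`gene_id`, `sample`, `delta_ct`) with attribute `reference_gene`.
#' @export
compute_delta_ct <- function(ct, reference_gene) {
  if (!inherits(ct, "ct_table")) abort_input("`ct` must be a ct_table")
  samples <- unique(ct$sample)
  ref <- ct[ct$gene_id == reference_gene, , drop = FALSE]
  if (!all(samples %in% ref$sample) || any(is.na(ref$ct))) {
    abort_input(sprintf(
      "reference gene '%s' must have a Ct value in every sample", reference_gene))
  }
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  out <- data.frame(
    gene_id = ct$gene_id,
    sample = ct$sample,
    delta_ct = ct$ct - ref_ct[ct$sample],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, reference_gene = reference_gene,
            class = c("delta_ct_table", "data.frame"))
}

#' Extract one sample's delta-Ct values as a named vector
#'
#' @param dct a [compute_delta_ct()] result.
#' @param sample sample label present in the table.
#' @return named numeric vector of delta-Ct values (`NA` = not detected).
#' @export
delta_ct_vector <- function(dct, sample) {
  rows <- dct[dct$sample == sample, , drop = FALSE]
  if (!nrow(rows)) abort_input(sprintf("no delta-Ct entries for sample '%s'", sample))
  stats::setNames(rows$delta_ct, rows$gene_id)
}

#' Reference-normalized log2 array intensities
#'
#' `log2(net(gene) / net(reference))` for every detected gene on one
#' quantified array; the reference gene itself maps to exactly 0 and
#' undetected genes are absent (`NA`).
#'
#' @param quantified_array a [quantify_scan()] result.
#' @param reference_gene gene id; must be detected on the array.
#' @return named numeric vector of log2 relative intensities.
#' @export
reference_normalized_log2 <- function(quantified_array, reference_gene) {
  net <- net_values(quantified_array)
  if (!reference_gene %in% names(net) || is.na(net[reference_gene])) {
    abort_input(sprintf("reference gene '%s' is not detected on the array",
                        reference_gene))
  }
  log2(net / net[[reference_gene]])
}

#' Spearman rank concordance between array and qRT-PCR values
#'
#' Spearman's rho between reference-normalized log2 array intensities and
#' **negated** delta-Ct over the panel genes with both values present
#' (higher expression means lower delta-Ct, so negating delta-Ct makes an
#' accurate method score positive rho). Average ranks are used for ties.
#'
#' @param array_log2 named vector from [reference_normalized_log2()] (or a
#'   replicate-averaged equivalent).
#' @param delta_ct named delta-Ct vector for the same sample.
#' @param gene_panel genes to compare over; defaults to all shared genes.
#' @return a list with `rho` and `n` (genes used).
#' @export
spearman_accuracy <- function(array_log2, delta_ct,
                              gene_panel = NULL) {
  if (is.null(gene_panel)) {
    gene_panel <- intersect(names(array_log2), names(delta_ct))
  }
  x <- array_log2[gene_panel]
  y <- delta_ct[gene_panel]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) {
    abort_insufficient("fewer than 3 panel genes have both array and qRT-PCR values")
  }
  list(rho = stats::cor(x[keep], -y[keep], method = "spearman"),
       n = sum(keep))
}

# mean log2 net intensity per gene across the replicates where detected,
# for genes passing the detection_threshold(fraction, n) filter
filtered_mean_log2 <- function(replicate_set, min_detection_fraction) {
  genes <- replicate_set[[1]]$genes$gene_id
  vals <- vapply(replicate_set, function(q) {
    if (!identical(q$genes$gene_id, genes)) {
      abort_input("replicates must share one gene universe, in order")
    }
    q$genes$net
  }, numeric(length(genes)))
  vals <- matrix(vals, nrow = length(genes))
  threshold <- detection_threshold(min_detection_fraction, ncol(vals))
  keep <- rowSums(!is.na(vals)) >= threshold
  out <- rep(NA_real_, length(genes))
  out[keep] <- apply(vals[keep, , drop = FALSE], 1, function(v) {
    mean(log2(v[!is.na(v)]))
  })
  stats::setNames(out, genes)
}

#' Two-sample differential expression ratios: array versus qRT-PCR
#'
#' For two samples A and B measured by one method, compares the microarray
#' log2 expression ratio with the qRT-PCR log2 ratio, over genes passing
#' the detection filter (detected in at least [detection_threshold()]
#' replicates) in **both** samples on
#' the array **and** detected in both samples by qRT-PCR. The array ratio
#' per gene is the difference of mean log2 net intensities across the
#' replicates where the gene was detected; the qRT-PCR ratio is
#' `-(delta_ct_A - delta_ct_B)`. Identical underlying abundance ratios put
#' points on the y = x identity line.
#'
#' With `reference_gene` supplied, the array values are re-expressed
#' relative to the reference gene before the A - B difference (see
#' [reference_normalized_mean_log2()]). This mirrors the delta-Ct side,
#' which is reference-normalized by construction, and makes the per-array
#' global-median normalization factors cancel exactly — in the noiseless,
#' bias-free limit the two assays then agree gene for gene. Without it the
#' array ratios carry a constant offset `log2(factor_A / factor_B)` from the
#' two arrays' median-normalization factors; rank statistics are unaffected.
#'
#' @param quantA_set,quantB_set replicate lists of [quantify_scan()] results
#'   for samples A and B under one method.
#' @param delta_ct_A,delta_ct_B named delta-Ct vectors for the two samples
#'   (from [compute_delta_ct()] via [delta_ct_vector()], or any named
#'   vectors).
#' @param min_detection_fraction replicate-detection filter (default 0.6,
#'   i.e. 3-of-5).
#' @param reference_gene optional gene id used to anchor the array ratios,
#'   see above.
#' @return a list with `ratios` (`data.frame`: `gene_id`, `array_log2_ratio`,
#'   `pcr_log2_ratio`), `rho` (Spearman over the two ratio vectors) and `n`.
#' @export
differential_ratio_comparison <- function(quantA_set, quantB_set,
                                          delta_ct_A, delta_ct_B,
                                          min_detection_fraction = 0.6,
                                          reference_gene = NULL) {
  if (inherits(quantA_set, "quantified_array")) quantA_set <- list(quantA_set)
  if (inherits(quantB_set, "quantified_array")) quantB_set <- list(quantB_set)
  if (is.null(reference_gene)) {
    a <- filtered_mean_log2(quantA_set, min_detection_fraction)
    b <- filtered_mean_log2(quantB_set, min_detection_fraction)
  } else {
    a <- reference_normalized_mean_log2(quantA_set, reference_gene,
                                        min_detection_fraction)
    b <- reference_normalized_mean_log2(quantB_set, reference_gene,
                                        min_detection_fraction)
  }
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  shared <- intersect(shared, intersect(names(delta_ct_A)[!is.na(delta_ct_A)],
                                        names(delta_ct_B)[!is.na(delta_ct_B)]))
  if (length(shared) < 3L) {
    abort_insufficient("fewer than 3 genes pass the dual detection filter")
  }
  array_ratio <- a[shared] - b[shared]
  pcr_ratio <- -(delta_ct_A[shared] - delta_ct_B[shared])
  rho <- stats::cor(array_ratio, pcr_ratio, method = "spearman")
  list(
    ratios = data.frame(gene_id = shared,
                        array_log2_ratio = unname(array_ratio),
                        pcr_log2_ratio = unname(pcr_ratio),
                        stringsAsFactors = FALSE),
    rho = rho,
    n = length(shared)
  )
}
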