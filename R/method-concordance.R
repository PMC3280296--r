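# Cross-method qualitative concordance: consensus detection per method,
# three-way Venn partition of the detected sets, and inter-method Pearson.

#' Consensus detection over a replicate set
#'
#' A gene counts as detected by a method iff it was detected in at least
#' [detection_threshold()] replicate arrays (the
#' 60% rule: 3-of-5 with five replicates, 2-of-3 with three).
#'
#' @param replicate_set list of [quantify_scan()] results (`>= 1`).
#' @param min_detection_fraction consensus fraction (default 0.6).
#' @return an object of class `consensus_detection_set` with `gene_ids`
#'   (character vector), the `universe`, the `rule` used, and the method
#'   label of the set.
#' @export
consensus_detection <- function(replicate_set, min_detection_fraction = 0.6) {
  if (inherits(replicate_set, "quantified_array")) {
    replicate_set <- list(replicate_set)
  }
  if (!length(replicate_set)) abort_input("`replicate_set` is empty")
  stopifnot_scalar_number(min_detection_fraction, "min_detection_fraction",
                          min = 1e-12, max = 1)
  genes <- replicate_set[[1]]$genes$gene_id
  det <- vapply(replicate_set, function(q) {
    if (!identical(q$genes$gene_id, genes)) {
      abort_input("replicates must share one gene universe, in order")
    }
    q$genes$detected
  }, logical(length(genes)))
  det <- matrix(det, nrow = length(genes))
  n_rep <- length(replicate_set)
  threshold <- detection_threshold(min_detection_fraction, n_rep)
  structure(list(
    gene_ids = genes[rowSums(det) >= threshold],
    universe = genes,
    rule = c(min_detection_fraction = min_detection_fraction,
             n_replicates = n_rep, threshold = threshold),
    method = replicate_set[[1]]$method
  ), class = "consensus_detection_set")
}

#' @export
print.consensus_detection_set <- function(x, ...) {
  cat(sprintf("Consensus detection [%s]: %d of %d genes (>= %d of %d replicates)\n",
              x$method, length(x$gene_ids), length(x$universe),
              x$rule[["threshold"]], x$rule[["n_replicates"]]))
  invisible(x)
}

as_gene_set <- function(x) {
  if (inherits(x, "consensus_detection_set")) x$gene_ids else as.character(x)
}

#' Three-way Venn partition of detected gene sets
#'
#' Exact set algebra over three detection sets within one gene universe:
#' counts (and universe fractions) for the seven disjoint regions.
#'
#' @param setA,setB,setC character vectors of gene ids or
#'   [consensus_detection()] results.
#' @param universe character vector containing every element of the sets.
#' @return an object of class `venn_partition`: `counts` (named: `A`, `B`,
#'   `C`, `AB`, `AC`, `BC`, `ABC` — each region exclusive), `fractions`,
#'   `universe_size`, `n_union`.
#' @export
#' @examples
#' venn_partition(c("g1", "g2", "g3"), c("g2", "g3", "g4"), c("g3", "g4", "g5"),
#'                universe = sprintf("g%d", 1:6))
venn_partition <- function(setA, setB, setC, universe) {
  A <- unique(as_gene_set(setA))
  B <- unique(as_gene_set(setB))
  C <- unique(as_gene_set(setC))
  universe <- unique(as.character(universe))
  outside <- setdiff(c(A, B, C), universe)
  if (length(outside)) {
    abort_input(sprintf("set element(s) outside the universe: %s",
                        paste(utils::head(outside, 5), collapse = ", ")))
  }
  inA <- universe %in% A
  inB <- universe %in% B
  inC <- universe %in% C
  counts <- c(
    A   = sum(inA & !inB & !inC),
    B   = sum(!inA & inB & !inC),
    C   = sum(!inA & !inB & inC),
    AB  = sum(inA & inB & !inC),
    AC  = sum(inA & !inB & inC),
    BC  = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC)
  )
  structure(list(
    counts = counts,
    fractions = counts / length(universe),
    universe_size = length(universe),
    n_union = sum(inA | inB | inC)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition over %d genes (union %d):\n",
              x$universe_size, x$n_union))
  for (r in names(x$counts)) {
    cat(sprintf("  %-4s %6d  (%.1f%%)\n", r, x$counts[[r]],
                100 * x$fractions[[r]]))
  }
  invisible(x)
}

#' Inter-method Pearson correlation
#'
#' [pearson_log10()] computed across two methods' replicate sets for the
#' same sample. Arrays are paired replicate-index to replicate-index (up to
#' the shorter set) and the mean R over pairs is reported.
#'
#' @param quantA,quantB lists of [quantify_scan()] results (or single
#'   arrays) from two methods on the same sample.
#' @return a list with `mean_r` and the per-pair `r` values.
#' @export
inter_method_pearson <- function(quantA, quantB) {
  if (inherits(quantA, "quantified_array")) quantA <- list(quantA)
  if (inherits(quantB, "quantified_array")) quantB <- list(quantB)
  n <- min(length(quantA), length(quantB))
  if (n < 1L) abort_input("need at least one array per method")
  r <- vapply(seq_len(n), function(i) pearson_log10(quantA[[i]], quantB[[i]]),
              numeric(1))
  list(mean_r = mean(r), r = r)
}
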