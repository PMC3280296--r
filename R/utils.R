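# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that (a) a given (input, seed) pair always reproduces the
#' same output and (b) calling package functions never perturbs the caller's
#' random number stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a base seed and a string key
#'
#' One top-level seed drives a study; every stage (features, abundances,
#' per-round amplification noise, each scan, the Ct table) works from a
#' sub-seed derived deterministically from the base seed and a stage key, so
#' any stage can be re-run in isolation and still reproduce the study output.
#' The derivation is a small multiplicative string hash folded into
#' [1, 2^31 - 2].
#'
#' @param seed integer base seed.
#' @param ... character or numeric key components identifying the stage.
#' @return an integer in [1, 2^31 - 2].
#' @export
#' @examples
#' derive_seed(1, "features")
#' derive_seed(1, "scan", "UHRR", "amp1", 2)
derive_seed <- function(seed, ...) {
  keys <- paste(vapply(list(...), function(x) paste(format(x), collapse = "/"),
                       character(1)), collapse = "|")
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(keys)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# stop() with a classed condition so callers/tests can distinguish error kinds
abort_input <- function(msg) {
  stop(errorCondition(msg, class = c("arrayprep_input_error", "error")))
}
abort_schema <- function(msg) {
  stop(errorCondition(msg, class = c("arrayprep_schema_error", "error")))
}
abort_integrity <- function(msg) {
  stop(errorCondition(msg, class = c("arrayprep_integrity_error", "error")))
}
abort_insufficient <- function(msg) {
  stop(errorCondition(msg, class = c("arrayprep_insufficient_data_error", "error")))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort_input(sprintf("`%s` must be a single number in [%s, %s]",
                        name, format(min), format(max)))
  }
  invisible(x)
}

ARRAY_METHODS <- c("non_amp", "amp1", "amp2")

#' Replicate-detection threshold implied by a consensus fraction
#'
#' The smallest number of replicates k such that k/n reaches `fraction`,
#' where `fraction` is interpreted as a percentage quoted to the nearest
#' whole percent (tolerance half a percent): 0.60 with five replicates gives
#' 3-of-5, and either 0.67 or 2/3 with three replicates gives 2-of-3.
#'
#' @param fraction consensus fraction in (0, 1].
#' @param n_replicates number of replicate arrays.
#' @return integer threshold in [1, n_replicates].
#' @export
#' @examples
#' detection_threshold(0.6, 5)  # 3
#' detection_threshold(0.67, 3) # 2
detection_threshold <- function(fraction, n_replicates) {
  stopifnot_scalar_number(fraction, "fraction", min = 1e-12, max = 1)
  k <- ceiling((fraction - 0.005) * n_replicates - 1e-9)
  as.integer(min(max(k, 1L), n_replicates))
}

match_method <- function(method) {
  if (!is.character(method) || length(method) != 1L || !method %in% ARRAY_METHODS) {
    abort_input(sprintf("`method` must be one of: %s",
                        paste(ARRAY_METHODS, collapse = ", ")))
  }
  method
}
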