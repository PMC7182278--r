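# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

stop_subflux <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

warn_subflux <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

#' Run code under a fixed RNG seed
#'
#' Evaluates `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards. With `seed = NULL` the code runs on the current stream.
#' @noRd
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive independent sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  with_seed_or_not(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name) {
  if (!is_scalar_number(x)) {
    stop_subflux("`%s` must be a single finite number", name)
  }
  invisible(x)
}

# Default standard deviations for enrichment observations: 2% relative with a
# floor, so that fully unlabeled points (value 0 at t = 0) never get zero
# weight.
default_enrichment_sd <- function(value, rel_sd = 0.02, floor_ref = 0.1) {
  rel_sd * pmax(value, floor_ref)
}

fill_sd <- function(series, rel_sd = 0.02, floor_ref = 0.1) {
  if (!"sd" %in% names(series)) {
    series$sd <- NA_real_
  }
  missing <- !is.finite(series$sd)
  series$sd[missing] <- default_enrichment_sd(series$value[missing],
                                              rel_sd, floor_ref)
  if (any(series$sd <= 0)) {
    stop_subflux("standard deviations must be > 0")
  }
  series
}

clip01 <- function(x) pmin(1, pmax(0, x))
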