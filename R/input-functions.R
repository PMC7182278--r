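# Analytical time-functions representing the enrichment curve of a local
# label input. Discrete measurements drive stiff, artifact-prone simulations;
# a smooth fitted curve (logistic or double-logistic) is used instead. The
# functions and their parameters carry no biological meaning — they are a
# continuous representation of the measured labeling dynamics.

LOGISTIC_BOUNDS <- list(
  lower = c(p1 = 1e-6, p2 = -100, p3 = -1000),
  upper = c(p1 = 1 - 1e-6, p2 = 100, p3 = 1000)
)

DOUBLE_LOGISTIC_BOUNDS <- list(
  lower = c(p4 = -1, p5 = -1, p6 = -10, p7 = -1000, p8 = -100, p9 = -1000,
            p10 = -100),
  upper = c(p4 = 1, p5 = 1, p6 = 10, p7 = 1000, p8 = 100, p9 = 1000,
            p10 = 100)
)

#' Evaluate the logistic enrichment curve
#'
#' `p1 / (1 + exp(-p2 * (t - p3)))`: a sigmoid rising (or falling, for
#' negative `p2`) to the plateau `p1`. Evaluation is overflow-safe.
#'
#' @param p Numeric vector `c(p1, p2, p3)` (plateau, steepness, midpoint
#'   time).
#' @param t Time(s), same units as the measurements.
#' @return Enrichment value(s).
#' @export
eval_logistic <- function(p, t) {
  p <- unname(p)
  p[1] * stats::plogis(p[2] * (t - p[3]))
}

#' Evaluate the double-logistic enrichment curve
#'
#' `p4 + (p5 - p6*t) * (1/(1 + exp((p7 - t)/p8)) - 1/(1 + exp((p9 - t)/p10)))`,
#' a flexible rise-then-drift form able to describe non-monotone labeling
#' dynamics.
#'
#' @param p Numeric vector `c(p4, ..., p10)`.
#' @param t Time(s).
#' @return Enrichment value(s).
#' @export
eval_double_logistic <- function(p, t) {
  p <- unname(p)
  if (p[5] == 0 || p[7] == 0) {
    stop_subflux("degenerate double-logistic parameters: p8 and p10 must be non-zero")
  }
  p[1] + (p[2] - p[3] * t) *
    (stats::plogis((t - p[4]) / p[5]) - stats::plogis((t - p[6]) / p[7]))
}

new_input_function <- function(family, par, fun) {
  structure(list(family = family, par = par, fun = fun),
            class = "input_function")
}

#' Constant or step input functions
#'
#' `input_constant()` holds a fixed enrichment; `input_step()` switches from
#' `baseline` to `value` at `t0` (the labeling protocol of a global nutrient
#' switch).
#'
#' @param value Enrichment level in `[0, 1]`.
#' @param t0 Switch time for the step.
#' @param baseline Enrichment before `t0`.
#' @return An `input_function`.
#' @export
input_constant <- function(value) {
  new_input_function("constant", c(value = value),
                     function(t) rep(value, length(t)))
}

#' @rdname input_constant
#' @export
input_step <- function(value = 1, t0 = 0, baseline = 0) {
  new_input_function("step", c(value = value, t0 = t0, baseline = baseline),
                     function(t) ifelse(t >= t0, value, baseline))
}

#' Input function from fitted logistic parameters
#' @param p Parameter vector (see [eval_logistic()], [eval_double_logistic()]).
#' @return An `input_function`.
#' @export
input_logistic <- function(p) {
  p <- stats::setNames(as.numeric(p), names(LOGISTIC_BOUNDS$lower))
  new_input_function("logistic", p, function(t) eval_logistic(p, t))
}

#' @rdname input_logistic
#' @export
input_double_logistic <- function(p) {
  p <- stats::setNames(as.numeric(p), names(DOUBLE_LOGISTIC_BOUNDS$lower))
  new_input_function("double_logistic", p, function(t) eval_double_logistic(p, t))
}

#' Input function interpolating a dense trajectory
#'
#' Monotone Hermite interpolation of a (time, value) trajectory; used to
#' drive a subsystem with the exact labeling of an upstream metabolite taken
#' from a full-network simulation.
#'
#' @param time,value Trajectory samples (time strictly increasing).
#' @return An `input_function`.
#' @export
input_interpolation <- function(time, value) {
  f <- stats::splinefun(time, value, method = "monoH.FC")
  tmin <- min(time)
  tmax <- max(time)
  new_input_function("interpolation", NULL, function(t) {
    f(pmin(pmax(t, tmin), tmax))
  })
}

#' Input function from an arbitrary closure
#'
#' @param fun Function of time returning enrichment values.
#' @return An `input_function`.
#' @export
input_custom <- function(fun) {
  new_input_function("custom", NULL, fun)
}

#' Evaluate an input function
#'
#' Enrichments are clipped to `[0, 1]` (analytical forms may stray slightly
#' outside the physical range between observations).
#'
#' @param f An `input_function` (including fitted ones from [fit_input()]).
#' @param t Time(s).
#' @return Enrichment value(s) in `[0, 1]`.
#' @export
eval_input <- function(f, t) {
  stopifnot(inherits(f, "input_function"))
  clip01(f$fun(t))
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> family: %s\n", x$family))
  if (!is.null(x$par)) {
    cat("  parameters:", paste(sprintf("%s=%.4g", names(x$par), x$par),
                               collapse = ", "), "\n")
  }
  if (!is.null(x$objective)) {
    cat(sprintf("  weighted SSR: %.4g\n", x$objective))
  }
  invisible(x)
}
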