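# Fitting analytical curves to measured enrichment series of local label
# inputs: bounded particle-swarm search of the parameter box followed by an
# L-BFGS-B refinement (capped at 1000 iterations). The objective is the sum
# of squared errors weighted by the measurement standard deviations.

#' Optimizer settings for curve and flux fits
#'
#' @param swarm_particles,swarm_iter Particle count and iteration count of
#'   the particle-swarm stage of [fit_input()].
#' @param local_maxit Iteration cap of the L-BFGS-B refinement of
#'   [fit_input()].
#' @param max_iter Iteration cap of the constrained least-squares flux
#'   estimation ([estimate_fluxes()]).
#' @param ftol Relative objective-change convergence tolerance.
#' @param rtol,atol Relative and absolute ODE solver tolerances.
#' @return A named list of settings.
#' @export
fit_control <- function(swarm_particles = 50, swarm_iter = 500,
                        local_maxit = 1000, max_iter = 50, ftol = 1e-8,
                        rtol = 1e-8, atol = 1e-10) {
  list(
    swarm_particles = as.integer(swarm_particles),
    swarm_iter = as.integer(swarm_iter),
    local_maxit = as.integer(local_maxit),
    max_iter = as.integer(max_iter),
    ftol = ftol,
    rtol = rtol,
    atol = atol
  )
}

# Canonical constriction-coefficient particle swarm over a box. Deterministic
# under a fixed RNG state; returns the best parameter vector, objective, and
# the distinct top candidates (for multi-start local refinement). `init`
# optionally seeds some particles at data-informed starting points.
pso_minimize <- function(fn, lower, upper, particles = 50, iters = 500,
                         init = NULL) {
  d <- length(lower)
  span <- upper - lower
  pos <- matrix(stats::runif(d * particles, lower, upper), nrow = d)
  if (!is.null(init) && ncol(init) > 0L) {
    # seed part of the swarm at the candidate starts (jitter, if any, is the
    # caller's responsibility: its scale is data-dependent, not box-dependent)
    k <- min(ncol(init), particles)
    pos[, seq_len(k)] <- init[, seq_len(k)]
  }
  vel <- matrix(stats::runif(d * particles, -span, span) * 0.1, nrow = d)
  fvals <- apply(pos, 2, fn)
  pbest <- pos
  pbest_f <- fvals
  g <- which.min(fvals)
  gbest <- pos[, g]
  gbest_f <- fvals[[g]]
  chi <- 0.7298
  c1 <- c2 <- 2.05
  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(d * particles), nrow = d)
    r2 <- matrix(stats::runif(d * particles), nrow = d)
    vel <- chi * (vel + c1 * r1 * (pbest - pos) + c2 * r2 * (gbest - pos))
    pos <- pos + vel
    pos <- pmin(pmax(pos, lower), upper)
    fvals <- apply(pos, 2, fn)
    improved <- fvals < pbest_f
    if (any(improved)) {
      pbest[, improved] <- pos[, improved]
      pbest_f[improved] <- fvals[improved]
      g <- which.min(pbest_f)
      if (pbest_f[[g]] < gbest_f) {
        gbest <- pbest[, g]
        gbest_f <- pbest_f[[g]]
      }
    }
  }
  top <- order(pbest_f)[seq_len(min(3L, particles))]
  list(par = gbest, value = gbest_f,
       candidates = lapply(top, function(j) pbest[, j]))
}

# Data-informed starting candidates for the curve families: plateau at the
# late values, amplitude from the observed range, transition at the observed
# half-rise time, transition width a fraction of the sampled window. All
# heuristics are clamped into the parameter box.
input_start_candidates <- function(series, family, bounds) {
  t <- series$time
  x <- series$value
  tr <- max(t) - min(t)
  if (tr <= 0) tr <- 1
  xmin <- min(x)
  xmax <- max(x)
  amp <- xmax - xmin
  level_time <- function(q) {
    if (amp <= 0) {
      return(min(t) + q * tr)
    }
    hit <- which(x >= xmin + q * amp)
    if (length(hit) == 0L) max(t) else t[[hit[[1]]]]
  }
  t10 <- level_time(0.1)
  t50 <- level_time(0.5)
  t90 <- level_time(0.9)
  # observed 10-90% rise interval sets the transition-width scale; near-step
  # inputs need widths far below any fixed fraction of the window
  rise <- max(t90 - t10, min(diff(t)) / 2, tr * 1e-6)
  cand <- if (family == "logistic") {
    list(
      c(min(max(xmax, 1e-3), 1 - 1e-6), min(4 / rise, 99), t50),
      c(min(max(xmax, 1e-3), 1 - 1e-6), 10 / tr, t50),
      c(min(max(xmax, 1e-3), 1 - 1e-6), 40 / tr, t50 / 2),
      c(min(max(mean(x), 1e-3), 1 - 1e-6), 1 / tr, min(t) + tr / 2)
    )
  } else {
    list(
      c(x[[1]], amp, 0, t50, rise / 4, max(t) + 2 * tr, tr / 4),
      c(x[[1]], amp, 0, t50, rise / 10, max(t) + 5 * tr, tr / 2),
      c(x[[1]], amp, 0, t50, tr / 8, max(t) + 2 * tr, tr / 4),
      c(x[[1]], amp, 0, t50, tr / 16, max(t) + 5 * tr, tr / 2),
      c(x[[1]], amp, (x[[length(x)]] - xmax) / tr, t50 / 2,
        rise / 6, max(t) + 3 * tr, tr),
      c(mean(x), amp / 2, 0, min(t) + tr / 3, tr / 6,
        min(t) + 2 * tr / 3, tr / 6)
    )
  }
  # jittered copies of each heuristic, scaled to the candidate itself plus a
  # small data-window term, so the swarm starts with a cloud around each
  mat <- do.call(cbind, cand)
  scale <- pmax(abs(mat), tr / 20)
  jittered <- lapply(seq_len(6), function(j) {
    mat + scale * matrix(stats::rnorm(length(mat), sd = 0.15), nrow(mat))
  })
  out <- cbind(mat, do.call(cbind, jittered))
  pmin(pmax(out, bounds$lower), bounds$upper)
}

input_family_info <- function(family) {
  switch(family,
    logistic = list(
      bounds = LOGISTIC_BOUNDS,
      eval = eval_logistic,
      make = input_logistic
    ),
    double_logistic = list(
      bounds = DOUBLE_LOGISTIC_BOUNDS,
      eval = eval_double_logistic,
      make = input_double_logistic
    ),
    stop_subflux("unknown input-function family '%s'", family)
  )
}

validate_label_series <- function(series) {
  if (!all(c("time", "value") %in% names(series))) {
    stop_subflux("a label series needs columns 'time' and 'value' (optionally 'sd')")
  }
  series <- series[order(series$time), , drop = FALSE]
  if (anyDuplicated(series$time)) {
    stop_subflux("label series times must be strictly increasing")
  }
  if (any(series$value < 0 | series$value > 1 + 1e-6)) {
    if (any(series$value < -1e-6 | series$value > 1.25)) {
      stop_subflux("enrichment values far outside [0, 1]; check units")
    }
    warn_subflux("enrichment values outside [0, 1] clipped")
  }
  series$value <- clip01(series$value)
  fill_sd(tibble::as_tibble(series))
}

series_objective <- function(series, eval_fun) {
  t <- series$time
  x <- series$value
  w <- 1 / series$sd
  function(p) {
    y <- eval_fun(p, t)
    if (any(!is.finite(y))) {
      return(1e12)
    }
    sum(((x - y) * w)^2)
  }
}

#' Fit an analytical time-function to a labeling series
#'
#' Minimizes the weighted sum of squared errors between the measured
#' enrichment series and a logistic or double-logistic curve, subject to the
#' parameter box bounds. The search runs a particle swarm over the box
#' followed by an L-BFGS-B refinement; the refinement never worsens the swarm
#' optimum. Results are reproducible given `seed`.
#'
#' @param series Data frame with columns `time`, `value` and optionally `sd`
#'   (missing standard deviations default to 2% relative with a floor).
#' @param family `"logistic"`, `"double_logistic"`, or `"auto"` (selects via
#'   [select_family()]).
#' @param seed Integer seed for the stochastic swarm stage.
#' @param control Optimizer settings from [fit_control()].
#' @return An `input_fit` (also an `input_function`): fitted parameters,
#'   objective value, residual table, and the series fitted.
#' @examples
#' ser <- data.frame(time = 0:10, value = 0.8 * stats::plogis(1.5 * (0:10 - 3)))
#' fit <- fit_input(ser, family = "logistic", seed = 1,
#'                  control = fit_control(swarm_iter = 50))
#' glance(fit)
#' @export
fit_input <- function(series, family = c("auto", "logistic", "double_logistic"),
                      seed = NULL, control = fit_control()) {
  family <- match.arg(family)
  series <- validate_label_series(series)
  if (family == "auto") {
    family <- select_family(series, seed = seed, control = control)
  }
  info <- input_family_info(family)
  n_par <- length(info$bounds$lower)
  if (nrow(series) < n_par) {
    stop_subflux("need at least %d observations to fit a %s function (got %d)",
                 n_par, family, nrow(series))
  }
  fn <- series_objective(series, info$eval)
  refined <- with_seed_or_not(seed, {
    starts <- input_start_candidates(series, family, info$bounds)
    swarm <- pso_minimize(
      fn, info$bounds$lower, info$bounds$upper,
      particles = control$swarm_particles, iters = control$swarm_iter,
      init = starts
    )
    best <- list(par = swarm$par, value = swarm$value)
    cands <- c(swarm$candidates,
               lapply(seq_len(ncol(starts)), function(j) starts[, j]))
    for (cand in cands) {
      r <- refine_input_par(fn, cand, info$bounds, maxit = control$local_maxit)
      if (r$value < best$value) {
        best <- r
      }
    }
    # basin-hopping polish: local restarts from jittered copies of the
    # incumbent escape the shallow ridges of the double-logistic surface
    for (i in seq_len(10)) {
      start_i <- best$par * (1 + 0.1 * stats::rnorm(length(best$par))) +
        0.01 * stats::rnorm(length(best$par))
      start_i <- pmin(pmax(start_i, info$bounds$lower), info$bounds$upper)
      r <- refine_input_par(fn, start_i, info$bounds,
                            maxit = control$local_maxit)
      if (r$value < best$value) {
        best <- r
      }
    }
    best$swarm_value <- swarm$value
    best
  })
  swarm <- list(value = refined$swarm_value)
  finalize_input_fit(series, family, refined$par, refined$value,
                     swarm_objective = swarm$value, seed = seed)
}

refine_input_par <- function(fn, par, bounds, maxit = 1000) {
  res <- tryCatch(
    stats::optim(par, fn, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = maxit)),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(par = par, value = fn(par)))
  }
  list(par = res$par, value = res$value)
}

finalize_input_fit <- function(series, family, par, objective,
                               swarm_objective = NA_real_, seed = NULL) {
  info <- input_family_info(family)
  par <- stats::setNames(as.numeric(par), names(info$bounds$lower))
  fitted <- info$eval(par, series$time)
  obj <- structure(
    list(
      family = family,
      par = par,
      fun = local({
        p <- par
        ev <- info$eval
        function(t) ev(p, t)
      }),
      objective = objective,
      swarm_objective = swarm_objective,
      residuals = tibble::tibble(
        time = series$time,
        observed = series$value,
        fitted = fitted,
        weighted_residual = (series$value - fitted) / series$sd
      ),
      series = series,
      seed = seed
    ),
    class = c("input_fit", "input_function")
  )
  obj
}

# Fast local re-fit of an existing input fit on a (noised) series: L-BFGS-B
# from the previous optimum, no swarm stage. Used by Monte-Carlo replicates.
refit_input <- function(fit, series) {
  stopifnot(inherits(fit, "input_fit"))
  series <- validate_label_series(series)
  info <- input_family_info(fit$family)
  fn <- series_objective(series, info$eval)
  refined <- refine_input_par(fn, fit$par, info$bounds)
  finalize_input_fit(series, fit$family, refined$par, refined$value,
                     seed = fit$seed)
}

#' Choose between the logistic and double-logistic family
#'
#' Fits both families and returns the one with the lower small-sample
#' corrected information criterion (AICc computed from the weighted sum of
#' squared errors); ties and series too short for the seven-parameter
#' double-logistic fall back to the logistic.
#'
#' @inheritParams fit_input
#' @return `"logistic"` or `"double_logistic"`.
#' @export
select_family <- function(series, seed = NULL, control = fit_control()) {
  series <- validate_label_series(series)
  n <- nrow(series)
  k_dbl <- length(DOUBLE_LOGISTIC_BOUNDS$lower)
  if (n < k_dbl + 2L) {
    return("logistic")
  }
  aicc <- function(h, k) h + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  f_log <- fit_input(series, "logistic", seed = seed, control = control)
  f_dbl <- fit_input(series, "double_logistic", seed = seed, control = control)
  if (aicc(f_dbl$objective, k_dbl) <
      aicc(f_log$objective, length(LOGISTIC_BOUNDS$lower))) {
    "double_logistic"
  } else {
    "logistic"
  }
}

#' @export
tidy.input_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @export
glance.input_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    objective = x$objective,
    n_obs = nrow(x$series),
    n_par = length(x$par)
  )
}

#' @export
autoplot.input_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(
    time = seq(min(object$series$time), max(object$series$time),
               length.out = n_grid)
  )
  grid$value <- eval_input(object, grid$time)
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$value - .data$sd,
      ymax = .data$value + .data$sd
    ), size = 0.3) +
    ggplot2::labs(
      x = "time", y = "mean molecular enrichment",
      title = sprintf("%s input fit (weighted SSR %.3g)", object$family,
                      object$objective)
    )
}
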