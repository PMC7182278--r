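# Uncertainty quantification: Monte-Carlo resampling of the measured data
# (flux confidence intervals) and sensitivity of the estimated fluxes to the
# quality of the local-input representation.

noise_series <- function(series, seed, clip = TRUE) {
  with_seed_or_not(seed, {
    noised <- series
    noised$value <- series$value + stats::rnorm(nrow(series), sd = series$sd)
    if (clip) {
      noised$value <- clip01(noised$value)
    }
    noised
  })
}

#' Monte-Carlo sensitivity analysis of a flux fit
#'
#' Generates `n_rep` noisy replicates of the fitted dataset (Gaussian noise
#' with the experimental standard deviations; enrichments clipped to
#' `[0, 1]`), re-estimates fluxes and pools for each (warm-started at the
#' reference optimum), and summarizes the spread: mean, median, standard
#' deviation and 2.5/97.5 percentiles per quantity. Local label input series
#' carry measurement noise too, so each replicate locally re-fits the input
#' functions before the flux fit (disable with `refit_inputs = FALSE`).
#' Replicate fits that fail are excluded and counted.
#'
#' @param fit A converged `flux_fit`.
#' @param n_rep Number of replicates (default 200).
#' @param seed Master seed; replicate seeds are derived from it, making the
#'   whole analysis reproducible bit-for-bit.
#' @param refit_inputs Re-fit input functions on noised input series
#'   (only inputs fitted with [fit_input()] carry their series).
#' @return A `flux_mc`: `summary` tibble (`id, kind, mean, median, sd,
#'   ci95_low, ci95_high`), raw `samples`, and the failure count.
#' @export
monte_carlo <- function(fit, n_rep = 200, seed = NULL, refit_inputs = TRUE) {
  stopifnot(inherits(fit, "flux_fit"))
  if (n_rep < 2) {
    stop_subflux("n_rep must be >= 2")
  }
  seeds <- derive_seeds(seed, n_rep)
  prep <- fit$measurements
  est_fun <- function(rep_seed) {
    enr <- noise_series(prep$enrichments, rep_seed)
    conc <- prep$concentrations
    if (!is.null(conc)) {
      conc$value <- pmax(conc$value + stats::rnorm(nrow(conc), sd = conc$sd),
                         1e-9)
    }
    inputs <- fit$inputs
    if (refit_inputs) {
      inputs <- lapply(inputs, function(f) {
        if (!inherits(f, "input_fit")) {
          return(f)
        }
        refit_input(f, noise_series(f$series, NULL))
      })
    }
    refit <- estimate_fluxes(
      fit$subsystem, inputs,
      list(enrichments = enr, concentrations = conc),
      constraints = fit$constraints, start = fit$par,
      measured = prep$measured, units = fit$units, control = fit$control,
      warn_fragment = FALSE, system = fit$system
    )
    dplyr::bind_rows(
      dplyr::mutate(refit$fluxes[, c("id", "estimate")], kind = "flux",
                    type = refit$fluxes$type),
      dplyr::mutate(refit$pools[, c("id", "estimate")], kind = "pool",
                    type = "fitted")
    )
  }
  samples <- vector("list", n_rep)
  n_fail <- 0L
  for (i in seq_len(n_rep)) {
    res <- tryCatch(
      with_seed_or_not(seeds[[i]], suppressWarnings(est_fun(NULL))),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_fail <- n_fail + 1L
    } else {
      res$replicate <- i
      samples[[i]] <- res
    }
  }
  samples <- dplyr::bind_rows(samples)
  if (nrow(samples) == 0L) {
    stop_subflux("all %d Monte-Carlo replicates failed", n_rep)
  }
  summary <- samples |>
    dplyr::group_by(.data$id, .data$kind, .data$type) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      median = stats::median(.data$estimate),
      sd = stats::sd(.data$estimate),
      ci95_low = stats::quantile(.data$estimate, 0.025, names = FALSE),
      ci95_high = stats::quantile(.data$estimate, 0.975, names = FALSE),
      n = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(summary = summary, samples = samples, n_rep = n_rep,
         n_fail = n_fail, fit = fit, seed = seed),
    class = "flux_mc"
  )
}

#' @export
print.flux_mc <- function(x, ...) {
  cat(sprintf("<flux_mc> %s: %d replicates (%d failed)\n",
              x$fit$subsystem$name, x$n_rep, x$n_fail))
  fl <- x$summary[x$summary$kind == "flux" & x$summary$type == "fitted", ]
  for (i in seq_len(nrow(fl))) {
    cat(sprintf("  %s: %.4g +/- %.4g [%.4g, %.4g]\n", fl$id[[i]],
                fl$mean[[i]], fl$sd[[i]], fl$ci95_low[[i]], fl$ci95_high[[i]]))
  }
  invisible(x)
}

#' @export
tidy.flux_mc <- function(x, ...) {
  x$summary
}

#' @export
glance.flux_mc <- function(x, ...) {
  tibble::tibble(n_rep = x$n_rep, n_fail = x$n_fail, seed = x$seed %||% NA_integer_)
}

#' @export
autoplot.flux_mc <- function(object, ...) {
  dat <- object$samples
  dat <- dat[dat$kind == "flux" & dat$type == "fitted", ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$id, y = .data$estimate)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = sprintf("flux (%s)", object$fit$units),
                  title = sprintf("Monte-Carlo flux distributions, %s",
                                  object$fit$subsystem$name))
}

#' Sensitivity of fluxes to the local-input representation
#'
#' Degrades the fitted input functions by jittering their parameters
#' uniformly within `±perturb_frac` of the optima, re-estimates the fluxes
#' with each degraded input set, and pairs the resulting flux deviations
#' with the weighted sum of squared residuals of the degraded input fit.
#' Flux errors should be minimal at the optimum and grow as the input fit
#' degrades.
#'
#' @param fit A converged `flux_fit` whose inputs are [fit_input()] results.
#' @param perturb_frac Relative jitter half-width (default 0.05, i.e. ±5%).
#' @param n_samples Number of jittered parameter sets (default 100).
#' @param seed Master seed.
#' @return Tibble `sample, input_ssr, id, estimate, reference, error,
#'   rel_error` (one row per jitter sample and fitted flux).
#' @export
input_sensitivity <- function(fit, perturb_frac = 0.05, n_samples = 100,
                              seed = NULL) {
  stopifnot(inherits(fit, "flux_fit"))
  if (perturb_frac < 0) {
    stop_subflux("perturb_frac must be >= 0")
  }
  fitted_inputs <- Filter(function(f) inherits(f, "input_fit"), fit$inputs)
  if (length(fitted_inputs) == 0L) {
    stop_subflux("input_sensitivity() needs inputs fitted with fit_input()")
  }
  ref <- fit$fluxes[fit$fluxes$type == "fitted", ]
  seeds <- derive_seeds(seed, n_samples)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    res <- tryCatch(with_seed_or_not(seeds[[i]], {
      ssr <- 0
      inputs <- fit$inputs
      for (nm in names(inputs)) {
        f <- inputs[[nm]]
        if (!inherits(f, "input_fit")) next
        jitter <- stats::runif(length(f$par), -perturb_frac, perturb_frac)
        par_j <- f$par * (1 + jitter)
        info <- input_family_info(f$family)
        par_j <- pmin(pmax(par_j, info$bounds$lower), info$bounds$upper)
        inputs[[nm]] <- info$make(par_j)
        ssr <- ssr + series_objective(f$series, info$eval)(par_j)
      }
      refit <- suppressWarnings(estimate_fluxes(
        fit$subsystem, inputs, fit$measurements,
        constraints = fit$constraints, start = fit$par,
        measured = fit$measurements$measured, units = fit$units,
        control = fit$control, warn_fragment = FALSE, system = fit$system
      ))
      est <- refit$fluxes[refit$fluxes$type == "fitted", ]
      tibble::tibble(
        sample = i,
        input_ssr = ssr,
        id = est$id,
        estimate = est$estimate,
        reference = ref$estimate[match(est$id, ref$id)]
      )
    }), error = function(e) NULL)
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    stop_subflux("all sensitivity re-estimations failed")
  }
  out$error <- out$estimate - out$reference
  out$rel_error <- out$error / out$reference
  out
}
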