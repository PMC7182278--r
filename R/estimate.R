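# Flux estimation: bound-constrained weighted least squares on the measured
# labeling dynamics and concentrations of a subsystem's intermediates.
#
# The objective is
#   h(v, m) = sum_i ((x_i - y_i(v, m)) / sigma_i)^2
#           + sum_j ((n_j - m_j) / sigma_j)^2
# where y_i are simulated mean molecular enrichments at the measurement
# times, and the second sum penalizes deviations of the fitted pool sizes
# from the measured concentrations (pools are parameters, not constants).
# Sink fluxes are balanced at every iterate and are never free parameters.

#' Box constraints for flux estimation
#'
#' Defaults: directional fluxes in `[0, 1000]` (reversible reactions are
#' decomposed into forward/reverse pairs, so each direction is non-negative;
#' the magnitude cap matches the conventional `|v| < 10^3` box) and pool
#' sizes in `[10^-6, 1000]`.
#'
#' @param v_lower,v_upper Per-flux bounds (scalars, recycled).
#' @param m_lower,m_upper Per-pool bounds.
#' @param v_fixed Optional named vector of fluxes to hold fixed (equality
#'   constraints to a constant).
#' @param v_equal Optional list of character vectors; the reactions in each
#'   group are constrained to carry the same flux (e.g. a linear pathway
#'   fitted with a single pathway flux).
#' @return A `flux_constraints` list.
#' @export
flux_constraints <- function(v_lower = 0, v_upper = 1000,
                             m_lower = 1e-6, m_upper = 1000,
                             v_fixed = NULL, v_equal = NULL) {
  if (any(v_lower >= v_upper) || any(m_lower >= m_upper)) {
    stop_subflux("constraint lower bounds must be below upper bounds")
  }
  structure(
    list(v_lower = v_lower, v_upper = v_upper,
         m_lower = m_lower, m_upper = m_upper, v_fixed = v_fixed,
         v_equal = v_equal),
    class = "flux_constraints"
  )
}

#' Weighted least-squares objective of a candidate solution
#'
#' Computes h(v, m) for a simulation result against a measurement set:
#' the enrichment sum runs over the measured intermediates at the
#' measurement times, the concentration sum over the measured pools of
#' simulated intermediates.
#'
#' @param measurements List with tibbles `enrichments` (`time, metabolite,
#'   value, sd`) and optionally `concentrations` (`metabolite, value, sd`).
#' @param sim A `flux_sim` whose time grid covers the measurement times.
#' @param pools Named vector of candidate pool sizes (compared against
#'   measured concentrations).
#' @return The scalar objective value.
#' @export
flux_objective <- function(measurements, sim, pools = sim$pools) {
  res <- objective_residuals(measurements, sim, pools)
  sum(res^2)
}

objective_residuals <- function(measurements, sim, pools) {
  enr <- measurements$enrichments
  enr <- enr[enr$metabolite %in% sim$system$measured, , drop = FALSE]
  key_sim <- paste(sim$enrichment$time, sim$enrichment$metabolite)
  idx <- match(paste(enr$time, enr$metabolite), key_sim)
  if (anyNA(idx)) {
    stop_subflux("simulation grid does not cover all measurement times")
  }
  r_enr <- (enr$value - sim$enrichment$enrichment[idx]) / enr$sd
  r_conc <- numeric()
  conc <- measurements$concentrations
  if (!is.null(conc) && nrow(conc) > 0L) {
    keep <- conc$metabolite %in% names(pools)
    conc <- conc[keep, , drop = FALSE]
    r_conc <- (conc$value - as.numeric(pools[conc$metabolite])) / conc$sd
  }
  c(r_enr, r_conc)
}

prepare_measurements <- function(sub, measurements, measured = NULL) {
  enr <- tibble::as_tibble(measurements$enrichments)
  enr <- fill_sd(enr)
  enr_int <- enr[enr$metabolite %in% sub$intermediates, , drop = FALSE]
  if (is.null(measured)) {
    measured <- sort(unique(enr_int$metabolite))
  }
  if (length(measured) == 0L) {
    stop_subflux("no measured intermediate: at least one enrichment series on a subsystem intermediate is required")
  }
  conc <- measurements$concentrations
  if (!is.null(conc)) {
    conc <- fill_sd(tibble::as_tibble(conc), rel_sd = 0.1, floor_ref = 0)
    ignored <- setdiff(conc$metabolite, sub$intermediates)
    if (length(ignored) > 0L) {
      warn_subflux(
        "concentration measurement(s) for non-simulated metabolite(s) ignored: %s",
        paste(ignored, collapse = ", ")
      )
      conc <- conc[conc$metabolite %in% sub$intermediates, , drop = FALSE]
    }
  }
  enr_int <- enr_int[enr_int$metabolite %in% measured, , drop = FALSE]
  list(enrichments = enr_int[order(enr_int$metabolite, enr_int$time), ],
       concentrations = conc, measured = measured)
}

# Deterministic starting point: fluxes at the midpoint of the log-spaced
# feasible range (lower bound floored at 1e-3 for the log scale), pools at
# their measured concentrations where available, otherwise at the log
# midpoint of the pool box.
default_start <- function(flux_ids, pool_ids, cons, conc) {
  v0 <- rep(sqrt(max(cons$v_lower, 1e-3) * cons$v_upper), length(flux_ids))
  names(v0) <- flux_ids
  m0 <- rep(sqrt(max(cons$m_lower, 1e-6) * cons$m_upper), length(pool_ids))
  names(m0) <- pool_ids
  if (!is.null(conc)) {
    hit <- intersect(pool_ids, conc$metabolite)
    m0[hit] <- conc$value[match(hit, conc$metabolite)]
  }
  c(stats::setNames(v0, paste0("v_", flux_ids)),
    stats::setNames(m0, paste0("m_", pool_ids)))
}

#' Estimate fluxes (and pool sizes) of a subsystem
#'
#' Fits the subsystem's flux vector and the pool sizes of its simulated
#' intermediates to measured labeling dynamics and concentrations by
#' bound-constrained nonlinear least squares (Levenberg-Marquardt with box
#' constraints, iteration cap `control$max_iter`, default 50). Sink fluxes
#' are recomputed as balancing outflows at every iterate; candidate flux
#' vectors whose sinks would go negative are penalized. Goodness of fit is
#' evaluated by a chi-square test ([chi2_gof()]).
#'
#' @param sub A `flux_subsystem`.
#' @param inputs Named list of input functions (typically [fit_input()]
#'   results) for the local label inputs.
#' @param measurements List with `enrichments` (tibble `time, metabolite,
#'   value, sd`) and optionally `concentrations` (tibble `metabolite, value,
#'   sd`). Only series on subsystem intermediates are fitted; concentration
#'   measurements of non-simulated metabolites are ignored with a warning.
#' @param constraints A [flux_constraints()] object.
#' @param seed Stored for provenance (the estimator itself is deterministic
#'   given the starting point policy).
#' @param start Optional named starting vector (`v_<reaction>`, `m_<pool>`),
#'   e.g. a previous fit's `$par` for warm starts.
#' @param measured Optional subset of intermediates to fit (defaults to all
#'   measured ones).
#' @param units Flux unit label carried through to outputs.
#' @param control [fit_control()] settings (`max_iter`, `ftol`, solver
#'   tolerances).
#' @param warn_fragment Warn when a fragment input is proxied by a
#'   metabolite-level curve.
#' @return A `flux_fit` with tibbles `fluxes` (including balanced sinks) and
#'   `pools`, the objective value, chi-square statistic/dof/p-value,
#'   residual table, and everything needed to re-run (measurements, inputs,
#'   constraints, seed).
#' @export
estimate_fluxes <- function(sub, inputs, measurements,
                            constraints = flux_constraints(), seed = NULL,
                            start = NULL, measured = NULL,
                            units = "flux units", control = fit_control(),
                            warn_fragment = TRUE, system = NULL) {
  stopifnot(inherits(sub, "flux_subsystem"))
  prep <- prepare_measurements(sub, measurements, measured)
  flux_ids <- names(sub$reactions)
  fixed <- constraints$v_fixed
  # equality groups share one free parameter (their first member)
  flux_param <- stats::setNames(flux_ids, flux_ids)
  for (grp in constraints$v_equal %||% list()) {
    grp <- intersect(grp, flux_ids)
    if (length(grp) > 1L) {
      flux_param[grp] <- grp[[1]]
    }
  }
  free_flux <- setdiff(unique(flux_param), names(fixed))
  if (is.null(system)) {
    # the EMU system determines which intermediates are simulated, hence
    # which pools are parameters
    probe_fluxes <- stats::setNames(rep(1, length(flux_ids)), flux_ids)
    emu <- emu_decompose(sub, prep$measured)
    sim_mets <- unique(emu$states$metabolite)
    probe_pools <- stats::setNames(rep(1, length(sim_mets)), sim_mets)
    sys <- assemble_odes(sub, probe_fluxes, probe_pools, inputs,
                         measured = prep$measured, check_balance = FALSE,
                         warn_fragment = warn_fragment)
  } else {
    # re-use a previously assembled system (the wiring only depends on the
    # subsystem and measurement set), swapping in the given input functions
    sys <- system
    sys$input_funs <- inputs[sys$input_mets]
  }
  pool_ids <- sort(unique(sys$states$metabolite))
  if (!is.null(prep$concentrations)) {
    prep$concentrations <-
      prep$concentrations[prep$concentrations$metabolite %in% pool_ids, ,
                          drop = FALSE]
  }
  par0 <- default_start(free_flux, pool_ids, constraints,
                        prep$concentrations)
  if (!is.null(start)) {
    hit <- intersect(names(par0), names(start))
    par0[hit] <- start[hit]
  }
  n_v <- length(free_flux)
  lower <- c(rep(constraints$v_lower, n_v), rep(constraints$m_lower,
                                                length(pool_ids)))
  upper <- c(rep(constraints$v_upper, n_v), rep(constraints$m_upper,
                                                length(pool_ids)))
  par0 <- pmin(pmax(par0, lower), upper)
  times <- sort(unique(c(0, prep$enrichments$time)))
  # precomputed indices into the simulated mean-enrichment matrix, so the
  # least-squares residual evaluation does no matching work
  enr_obs <- prep$enrichments
  obs_row <- match(enr_obs$time, times)
  obs_col <- match(enr_obs$metabolite, sys$measured)
  obs_w <- 1 / enr_obs$sd
  conc <- prep$concentrations
  conc_idx <- if (is.null(conc)) integer() else match(conc$metabolite, pool_ids)
  n_resid <- nrow(enr_obs) + length(conc_idx) + nrow(sub$sinks)
  unpack <- function(par) {
    vpar <- stats::setNames(par[seq_len(n_v)], free_flux)
    if (length(fixed) > 0L) {
      vpar <- c(vpar, fixed)
    }
    v <- stats::setNames(as.numeric(vpar[flux_param[flux_ids]]), flux_ids)
    m <- stats::setNames(par[n_v + seq_along(pool_ids)], pool_ids)
    list(v = v, m = m)
  }
  resid_fn <- function(par) {
    pp <- unpack(par)
    sinks <- sink_fluxes(sub, pp$v)
    penalty <- 1e4 * pmin(sinks$flux, 0)
    xmat <- tryCatch(
      run_labeling_core(sys, times, pp$v, pp$m, control$rtol, control$atol),
      error = function(e) NULL
    )
    if (is.null(xmat)) {
      return(rep(1e6, n_resid))
    }
    enr_mat <- mean_enrichment_matrix(sys, xmat)
    r_enr <- (enr_obs$value -
                enr_mat[cbind(obs_row, obs_col)]) * obs_w
    r_conc <- if (length(conc_idx) > 0L) {
      (conc$value - pp$m[conc_idx]) / conc$sd
    } else {
      numeric()
    }
    c(r_enr, r_conc, penalty)
  }
  # Optimize on the log scale: fluxes and pools span decades, and the
  # near-flat valleys of the objective (e.g. flux/pool ratios fixed by the
  # labeling data alone) become linear and easy to traverse in log space.
  LOG_FLOOR <- 1e-9
  to_log <- function(p) log(pmax(p, LOG_FLOOR))
  opt <- minpack.lm::nls.lm(
    par = to_log(par0), lower = to_log(lower), upper = to_log(upper),
    fn = function(lp) resid_fn(exp(lp)),
    control = minpack.lm::nls.lm.control(
      maxiter = control$max_iter, ftol = control$ftol, ptol = control$ftol,
      # forward-difference step must dominate the ODE solver noise, or the
      # numerical Jacobian degenerates and the search stalls early
      epsfcn = 1e-6
    )
  )
  opt$par <- stats::setNames(exp(opt$par), names(par0))
  pp <- unpack(opt$par)
  sinks <- sink_fluxes(sub, pp$v)
  sim <- simulate_labeling(sys, times, fluxes = pp$v, pools = pp$m,
                           rtol = control$rtol, atol = control$atol)
  resid <- objective_residuals(prep, sim, pp$m)
  h <- sum(resid^2)
  n_data <- nrow(prep$enrichments) +
    if (is.null(prep$concentrations)) 0L else nrow(prep$concentrations)
  n_free <- length(par0)
  gof <- if (n_data > n_free) chi2_gof(h, n_data, n_free) else
    tibble::tibble(statistic = h, dof = NA_integer_, p_value = NA_real_)
  check_identifiability(opt, names(par0))
  fluxes_tbl <- dplyr::bind_rows(
    tibble::tibble(id = flux_ids, estimate = as.numeric(pp$v[flux_ids]),
                   type = ifelse(flux_ids %in% names(fixed), "fixed", "fitted")),
    tibble::tibble(id = sinks$id, estimate = sinks$flux, type = "sink")
  )
  structure(
    list(
      subsystem = sub,
      fluxes = fluxes_tbl,
      pools = tibble::tibble(id = pool_ids, estimate = as.numeric(pp$m)),
      objective = h,
      chi2 = gof,
      n_data = n_data,
      n_free = n_free,
      residuals = resid,
      par = opt$par,
      lower = lower,
      upper = upper,
      converged = opt$info %in% 1:4,
      n_iter = opt$niter,
      message = opt$message,
      sim = sim,
      system = sys,
      inputs = inputs,
      measurements = prep,
      constraints = constraints,
      control = control,
      units = units,
      seed = seed
    ),
    class = "flux_fit"
  )
}

check_identifiability <- function(opt, par_names) {
  J <- tryCatch(opt$hessian, error = function(e) NULL)
  if (is.null(J)) {
    return(invisible(FALSE))
  }
  r <- qr(J)$rank
  if (r < length(par_names)) {
    warn_subflux(
      "rank-deficient Jacobian at the solution (%d < %d): some parameters are structurally non-identifiable from this measurement set",
      r, length(par_names)
    )
  }
  invisible(r < length(par_names))
}

#' Chi-square goodness-of-fit test
#'
#' With the residuals weighted by the experimental standard deviations, the
#' objective at the optimum is chi-square distributed with `n_data - n_free`
#' degrees of freedom under the model; the upper-tail probability is
#' reported.
#'
#' @param statistic Objective value at the optimum.
#' @param n_data Number of fitted data points (enrichments plus
#'   concentrations).
#' @param n_free Number of free parameters (fluxes plus fitted pools; sinks
#'   are derived, not free).
#' @return Tibble with `statistic`, `dof`, `p_value`.
#' @export
chi2_gof <- function(statistic, n_data, n_free) {
  dof <- n_data - n_free
  if (dof <= 0) {
    stop_subflux("non-positive degrees of freedom (%d data points, %d free parameters)",
                 n_data, n_free)
  }
  tibble::tibble(
    statistic = statistic,
    dof = as.integer(dof),
    p_value = stats::pchisq(statistic, df = dof, lower.tail = FALSE)
  )
}

#' Turnover rate of a metabolite pool
#'
#' Biosynthetic flux divided by pool size (units 1/time): the inverse of the
#' pool's mean residence time.
#'
#' @param flux Biosynthetic flux (>= 0).
#' @param pool Pool size (> 0).
#' @return Turnover rate(s).
#' @export
turnover_rate <- function(flux, pool) {
  if (any(pool <= 0)) {
    stop_subflux("pool size must be > 0")
  }
  flux / pool
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit> %s\n", x$subsystem$name))
  fitted <- x$fluxes[x$fluxes$type == "fitted", ]
  cat(sprintf("  fluxes: %s\n",
              paste(sprintf("%s=%.4g", fitted$id, fitted$estimate),
                    collapse = ", ")))
  cat(sprintf("  pools:  %s\n",
              paste(sprintf("%s=%.4g", x$pools$id, x$pools$estimate),
                    collapse = ", ")))
  cat(sprintf("  objective %.4g | chi2 dof %s p %.3g | %s\n", x$objective,
              as.character(x$chi2$dof), x$chi2$p_value,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.flux_fit <- function(x, ...) {
  fl <- x$fluxes
  fl$term <- fl$id
  fl$kind <- "flux"
  po <- x$pools
  po$term <- po$id
  po$kind <- "pool"
  po$type <- "fitted"
  dplyr::bind_rows(
    fl[, c("term", "kind", "type", "estimate")],
    po[, c("term", "kind", "type", "estimate")]
  ) |>
    tibble::as_tibble() |>
    dplyr::mutate(units = ifelse(.data$kind == "flux", x$units,
                                 paste(x$units, "* time")))
}

#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(
    subsystem = x$subsystem$name,
    objective = x$objective,
    statistic = x$chi2$statistic,
    dof = x$chi2$dof,
    p_value = x$chi2$p_value,
    n_data = x$n_data,
    n_free = x$n_free,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Fitted-versus-measured labeling curves of a flux fit
#'
#' @param fit A `flux_fit`.
#' @param n_grid Number of grid points for the fitted curves.
#' @return Tibble `time, metabolite, enrichment, kind` (`fitted` curves on a
#'   fine grid plus `measured` points with `sd`).
#' @export
fitted_curves <- function(fit, n_grid = 100) {
  enr <- fit$measurements$enrichments
  grid <- seq(min(enr$time), max(enr$time), length.out = n_grid)
  sim <- simulate_labeling(fit$system, grid,
                           fluxes = stats::setNames(
                             fit$fluxes$estimate[fit$fluxes$type != "sink"],
                             fit$fluxes$id[fit$fluxes$type != "sink"]
                           ),
                           pools = stats::setNames(fit$pools$estimate,
                                                   fit$pools$id),
                           rtol = fit$control$rtol, atol = fit$control$atol)
  dplyr::bind_rows(
    dplyr::mutate(sim$enrichment, kind = "fitted", sd = NA_real_),
    tibble::tibble(time = enr$time, metabolite = enr$metabolite,
                   enrichment = enr$value, kind = "measured", sd = enr$sd)
  )
}

#' @export
autoplot.flux_fit <- function(object, ...) {
  curves <- fitted_curves(object)
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$time,
                                         y = .data$enrichment,
                                         colour = .data$metabolite)) +
    ggplot2::geom_line(data = dplyr::filter(curves, .data$kind == "fitted")) +
    ggplot2::geom_pointrange(
      data = dplyr::filter(curves, .data$kind == "measured"),
      ggplot2::aes(ymin = .data$enrichment - .data$sd,
                   ymax = .data$enrichment + .data$sd),
      size = 0.3
    ) +
    ggplot2::labs(x = "time", y = "mean molecular enrichment",
                  title = sprintf("%s: fitted vs measured labeling dynamics",
                                  object$subsystem$name))
}
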