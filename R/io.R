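# Measurement readers, result writer, run configuration.

#' Read a time-course enrichment CSV
#'
#' Expects columns `time, metabolite, value` and optionally `sd`. Values are
#' clipped to `[0, 1]` with a warning; missing standard deviations get the
#' default policy (2% relative with a floor). Duplicate (time, metabolite)
#' pairs and negative standard deviations are errors reported with row
#' numbers.
#'
#' @param path CSV file path.
#' @return Tibble `time, metabolite, value, sd`, sorted by metabolite and
#'   time.
#' @export
read_enrichments <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "metabolite", "value")
  if (!all(need %in% names(raw))) {
    stop_subflux("'%s': expected columns time, metabolite, value[, sd]", path)
  }
  bad <- which(!is.finite(raw$time) | !is.finite(raw$value))
  if (length(bad) > 0L) {
    stop_subflux("'%s': malformed value(s) in row(s) %s", path,
                 paste(bad, collapse = ", "))
  }
  dup <- duplicated(raw[, c("time", "metabolite")])
  if (any(dup)) {
    stop_subflux("'%s': duplicate (time, metabolite) pair(s) in row(s) %s",
                 path, paste(which(dup), collapse = ", "))
  }
  if ("sd" %in% names(raw) && any(raw$sd <= 0, na.rm = TRUE)) {
    stop_subflux("'%s': non-positive sd in row(s) %s", path,
                 paste(which(raw$sd <= 0), collapse = ", "))
  }
  if (any(raw$value > 1 | raw$value < 0)) {
    warn_subflux("'%s': enrichment value(s) outside [0, 1] clipped", path)
    raw$value <- clip01(raw$value)
  }
  out <- fill_sd(tibble::as_tibble(raw[, intersect(
    c("time", "metabolite", "value", "sd"), names(raw)
  )]))
  out[order(out$metabolite, out$time), ]
}

#' Read a steady-state concentration CSV
#'
#' Expects columns `metabolite, value` and optionally `sd` (missing sds
#' default to 10% relative).
#'
#' @param path CSV file path.
#' @return Tibble `metabolite, value, sd`.
#' @export
read_concentrations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "value") %in% names(raw))) {
    stop_subflux("'%s': expected columns metabolite, value[, sd]", path)
  }
  if (any(!is.finite(raw$value) | raw$value <= 0)) {
    stop_subflux("'%s': concentrations must be positive numbers", path)
  }
  if (anyDuplicated(raw$metabolite)) {
    stop_subflux("'%s': duplicate metabolite entries", path)
  }
  if ("sd" %in% names(raw) && any(raw$sd <= 0, na.rm = TRUE)) {
    stop_subflux("'%s': non-positive sd", path)
  }
  fill_sd(tibble::as_tibble(raw[, intersect(c("metabolite", "value", "sd"),
                                            names(raw))]),
          rel_sd = 0.1, floor_ref = 0)
}

#' Run configuration
#'
#' Bundles the workflow's tunable settings with their defaults: ODE solver
#' tolerances, optimizer settings (swarm 50 particles x 500 iterations,
#' L-BFGS-B cap 1000, least-squares cap 50), Monte-Carlo replicate count
#' (200), noise defaults (2% enrichments, 10% concentrations), master seed,
#' and unit labels. Unknown arguments are errors, not warnings.
#'
#' @param ... Named settings overriding the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    rtol = 1e-8, atol = 1e-10,
    swarm_particles = 50L, swarm_iter = 500L, local_maxit = 1000L,
    max_iter = 50L,
    mc_replicates = 200L,
    noise_enrichment = 0.02, noise_concentration = 0.10,
    seed = 1L,
    input_family = "auto",
    flux_units = "flux units", time_units = "time"
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L) {
    stop_subflux("unknown run_config setting(s): %s",
                 paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, override)
  counts <- c("swarm_particles", "swarm_iter", "local_maxit", "max_iter",
              "mc_replicates")
  for (k in counts) {
    if (!is_scalar_number(cfg[[k]]) || cfg[[k]] < 1) {
      stop_subflux("run_config setting '%s' must be a positive count", k)
    }
  }
  structure(cfg, class = "run_config")
}

config_control <- function(cfg) {
  fit_control(
    swarm_particles = cfg$swarm_particles, swarm_iter = cfg$swarm_iter,
    local_maxit = cfg$local_maxit, max_iter = cfg$max_iter,
    rtol = cfg$rtol, atol = cfg$atol
  )
}

#' Write fit results to structured JSON (and fitted curves to CSV)
#'
#' The JSON schema has stable keys: `fluxes` (id, estimate, sd, ci95_low,
#' ci95_high, units), `pools` (same), `fit` (objective, chi2, dof, pvalue),
#' `inputs` (metabolite, family, parameters, ssr) and `provenance` (seed,
#' config_hash, tool_version). Numbers round-trip exactly through
#' [read_results()].
#'
#' @param fit A `flux_fit`.
#' @param path Output JSON path.
#' @param mc Optional `flux_mc` supplying sd and confidence intervals.
#' @param curves_path Optional CSV path for the fitted-vs-measured curve
#'   table ([fitted_curves()]).
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path, mc = NULL, curves_path = NULL) {
  stopifnot(inherits(fit, "flux_fit"))
  mc_row <- function(id, kind) {
    if (is.null(mc)) {
      return(list(sd = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_))
    }
    row <- mc$summary[mc$summary$id == id & mc$summary$kind == kind, ]
    if (nrow(row) == 0L) {
      return(list(sd = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_))
    }
    list(sd = row$sd[[1]], ci95_low = row$ci95_low[[1]],
         ci95_high = row$ci95_high[[1]])
  }
  fluxes <- lapply(seq_len(nrow(fit$fluxes)), function(i) {
    id <- fit$fluxes$id[[i]]
    c(list(id = id, estimate = fit$fluxes$estimate[[i]],
           type = fit$fluxes$type[[i]]),
      mc_row(id, "flux"), list(units = fit$units))
  })
  pools <- lapply(seq_len(nrow(fit$pools)), function(i) {
    id <- fit$pools$id[[i]]
    c(list(id = id, estimate = fit$pools$estimate[[i]]),
      mc_row(id, "pool"))
  })
  inputs <- lapply(names(fit$inputs), function(nm) {
    f <- fit$inputs[[nm]]
    list(
      metabolite = nm,
      family = f$family,
      parameters = if (is.null(f$par)) list() else as.list(f$par),
      ssr = f$objective %||% NA_real_
    )
  })
  payload <- list(
    subsystem = fit$subsystem$name,
    fluxes = fluxes,
    pools = pools,
    fit = list(objective = fit$objective, chi2 = fit$chi2$statistic,
               dof = fit$chi2$dof, pvalue = fit$chi2$p_value),
    inputs = inputs,
    provenance = list(
      seed = fit$seed %||% NA_integer_,
      config_hash = rlang::hash(list(fit$constraints, fit$control)),
      tool_version = as.character(utils::packageVersion("subflux"))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  if (!is.null(curves_path)) {
    utils::write.csv(fitted_curves(fit), curves_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a results JSON
#'
#' @param path JSON path written by [write_results()].
#' @return The parsed result list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
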