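# The end-to-end workflow over one subsystem: check measurability of the
# local label inputs, fit their time-functions, estimate fluxes, test the
# goodness of fit, and quantify uncertainty by Monte-Carlo.

#' Run the full flux-calculation workflow on a subsystem
#'
#' Stages, in order: (1) identify the required local-input measurements and
#' fail fast (naming the missing metabolite and suggesting a subsystem
#' merge) if one is absent from the data; (2) fit analytical time-functions
#' to each local input's enrichment series; (3) estimate fluxes and pools by
#' constrained least squares; (4) chi-square goodness-of-fit (a low p-value
#' sets a warning flag, it does not abort); (5) Monte-Carlo confidence
#' intervals. Every stochastic stage consumes a sub-seed derived from
#' `config$seed`.
#'
#' @param sub A `flux_subsystem` (e.g. from [minimal_subsystem()] or
#'   [merge_subsystems()]).
#' @param enrichments Tibble `time, metabolite, value, sd` covering the
#'   local inputs and at least one intermediate (see [read_enrichments()]).
#' @param concentrations Optional tibble `metabolite, value, sd`.
#' @param config A [run_config()].
#' @param inputs Optional pre-built input functions (named list); inputs not
#'   supplied here are fitted from `enrichments`.
#' @return A `flux_workflow` list: `fit` (`flux_fit`), `mc` (`flux_mc`),
#'   `inputs`, `gof_warning` (TRUE when the chi-square p-value < 0.05), and
#'   `config`.
#' @export
run_workflow <- function(sub, enrichments, concentrations = NULL,
                         config = run_config(), inputs = list()) {
  stopifnot(inherits(sub, "flux_subsystem"))
  enrichments <- fill_sd(tibble::as_tibble(enrichments))
  measured <- intersect(sub$intermediates, unique(enrichments$metabolite))
  if (length(measured) == 0L) {
    stop_subflux("no enrichment series on any intermediate of '%s'", sub$name)
  }
  available <- unique(c(unique(enrichments$metabolite), names(inputs)))
  req <- required_measurements(sub, measured, available = available)
  missing <- req$metabolite[!req$resolvable]
  if (length(missing) > 0L) {
    stop_subflux(paste0(
      "labeling dynamics of local input(s) %s are not available, so label ",
      "propagation through '%s' cannot be simulated; consider merging with ",
      "the upstream subsystem(s) of %s so that a measurable metabolite ",
      "becomes the local input"),
      paste(missing, collapse = ", "), sub$name,
      paste(missing, collapse = ", ")
    )
  }
  seeds <- derive_seeds(config$seed, nrow(req) + 2L)
  control <- config_control(config)
  fitted_inputs <- inputs
  for (i in seq_len(nrow(req))) {
    nm <- req$metabolite[[i]]
    if (!is.null(fitted_inputs[[nm]])) next
    series <- enrichments[enrichments$metabolite == nm, , drop = FALSE]
    fitted_inputs[[nm]] <- fit_input(series, family = config$input_family,
                                     seed = seeds[[i]], control = control)
  }
  fit <- estimate_fluxes(
    sub, fitted_inputs,
    list(enrichments = enrichments, concentrations = concentrations),
    seed = seeds[[nrow(req) + 1L]], measured = measured,
    units = config$flux_units, control = control
  )
  mc <- monte_carlo(fit, n_rep = config$mc_replicates,
                    seed = seeds[[nrow(req) + 2L]])
  structure(
    list(
      fit = fit,
      mc = mc,
      inputs = fitted_inputs,
      gof_warning = isTRUE(fit$chi2$p_value < 0.05),
      config = config
    ),
    class = "flux_workflow"
  )
}

#' @export
print.flux_workflow <- function(x, ...) {
  print(x$fit)
  print(x$mc)
  if (x$gof_warning) {
    cat("  WARNING: chi-square goodness-of-fit p < 0.05 — the model may not explain the data\n")
  }
  invisible(x)
}
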