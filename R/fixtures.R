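# Built-in model systems and synthetic-data generators. Everything the test
# surface needs is generated in code: a didactic example network combining
# the classical topological motifs (linear pathway, branching node, cycle
# with condensation/cleavage), the yeast prenyl pyrophosphate chain, and
# random linear pathways for property tests.

EXAMPLE_NETWORK_TEXT <- "
# Example network: linear pathway, branching node (F), and a cycle through
# G/H/K with condensation (r11) and cleavage (r12). X_out is the global
# label input.
@external X_out
r1\tX_out[ab] -> X_in[ab]\t0
r2\tX_in[ab] -> A[ab]\t0
r3\tA[ab] -> B[ab]\t0
r4\tA[ab] -> F[ab]\t0
r5\tB[ab] -> D[ab]\t0
r6\tB[ab] -> C[ab]\t1
r7\tC[ab] -> E[ab]\t0
r8\tD[ab] -> E[ab]\t0
r9\tE[ab] -> F[ab]\t0
r10\tD[ab] -> G[ab]\t0
r11\tG[ab] + K[cd] -> H[abcd]\t0
r12\tH[abcd] -> I[cd] + J[ab]\t0
r13\tJ[ab] -> K[ab]\t0
r14\tI[ab] -> L[ab]\t0
r15\tL[ab] -> M[ab]\t0
r16\tM[ab] -> N[ab]\t0
r17\tF[ab] -> O[ab]\t0
r18\tN[ab] -> O[ab]\t0
r19\tO[ab] -> P[ab]\t0
r20\tC[ab] -> P[ab]\t0
"

#' The example metabolic network
#'
#' An 18-metabolite, 20-reaction network combining the topological motifs
#' classically found in metabolism: a linear pathway from the global label
#' input `X_out`, a branching node converging on `F` (r4 and r9), a
#' reversible reaction (r6, B <-> C), and a cycle through G/H/K built from a
#' condensation (r11: G + K -> H) and a cleavage (r12: H -> I + J), followed
#' by a chain to `N` and the joint drain through `O`.
#'
#' @return A `flux_network`.
#' @seealso [example_truth()], [decompose_network()]
#' @export
example_network <- function() {
  parse_network(EXAMPLE_NETWORK_TEXT)
}

#' Ground truth for the example network
#'
#' Steady-state-consistent flux and pool values used to simulate reference
#' labeling datasets. Fluxes are in umol/gDW/h with the r10..r16 pathway
#' carrying 1.0; pools (umol/gDW) are chosen so that labeling half-times
#' spread across an 11-point sampling window. The global input `X_out`
#' switches from unlabeled to fully labeled at t = 0.
#'
#' @return A `flux_truth`: `network`, named `fluxes` (over the
#'   irreversible-split reaction set), named `pools`, `inputs` (input
#'   functions for the externals), and unit labels.
#' @export
example_truth <- function() {
  net <- example_network()
  fluxes <- c(
    r1 = 5, r2 = 5, r3 = 3, r4 = 2, r5 = 1.5,
    r6_fwd = 2, r6_rev = 0.5, r7 = 1, r8 = 0.5, r9 = 1.5,
    r10 = 1, r11 = 1, r12 = 1, r13 = 1, r14 = 1, r15 = 1, r16 = 1,
    r17 = 3.5, r18 = 1, r19 = 4.5, r20 = 0.5
  )
  pools <- c(
    X_in = 1.0, A = 1.2, B = 0.8, C = 0.6, D = 0.15, E = 0.35, F = 0.7,
    G = 0.12, H = 0.12, I = 0.08, J = 0.08, K = 0.05, L = 0.1, M = 0.12,
    N = 0.3, O = 0.9, P = 1.0
  )
  new_flux_truth(net, fluxes, pools,
                 inputs = list(X_out = input_step(1)),
                 flux_units = "umol/gDW/h", time_units = "h")
}

new_flux_truth <- function(network, fluxes, pools, inputs,
                           flux_units = "flux units", time_units = "time",
                           times = NULL) {
  truth <- structure(
    list(network = network, fluxes = fluxes, pools = pools, inputs = inputs,
         flux_units = flux_units, time_units = time_units, times = times),
    class = "flux_truth"
  )
  check_steady_state(truth)
  truth
}

# Production minus consumption per intermediate at the true fluxes; the
# balancing sink must be non-negative everywhere (excess production drains
# to unmodeled demand).
check_steady_state <- function(truth) {
  full <- network_subsystem(truth$network)
  missing <- setdiff(names(full$reactions), names(truth$fluxes))
  if (length(missing) > 0L) {
    stop_subflux("truth is missing flux value(s) for: %s",
                 paste(missing, collapse = ", "))
  }
  bal <- sink_fluxes(full, truth$fluxes)
  if (any(bal$flux < -1e-9)) {
    stop_subflux("truth violates steady state: net consumption of %s",
                 paste(bal$substrate[bal$flux < -1e-9], collapse = ", "))
  }
  if (any(truth$pools <= 0)) {
    stop_subflux("truth pools must be > 0")
  }
  invisible(truth)
}

#' @export
print.flux_truth <- function(x, ...) {
  cat(sprintf("<flux_truth> %d reactions, %d pools (%s)\n",
              length(x$fluxes), length(x$pools), x$flux_units))
  invisible(x)
}

PRENYL_NETWORK_TEXT <- "
# Prenyl pyrophosphate biosynthesis: successive C5 condensations of IPP.
# The combined IPP+DMAPP pool is the measured local label input; GGX stands
# for the unmodeled GGPP demand (prenylation, membrane biosynthesis).
@external IPP GGX
iso\tIPP[abcde] -> DMAPP[abcde]\t0
gpps\tDMAPP[abcde] + IPP[fghij] -> GPP[abcdefghij]\t0
fpps\tGPP[abcdefghij] + IPP[klmno] -> FPP[abcdefghijklmno]\t0
ggpps\tFPP[abcdefghijklmno] + IPP[pqrst] -> GGPP[abcdefghijklmnopqrst]\t0
ggdem\tGGPP[abcdefghijklmnopqrst] -> GGX[abcdefghijklmnopqrst]\t0
"

#' The prenyl pyrophosphate pathway
#'
#' Isoprenoid precursor biosynthesis in yeast: IPP is isomerized to DMAPP,
#' and longer prenyl pyrophosphates are built by successive condensation of
#' a C5 unit onto each intermediate (GPP, 10 carbons; FPP, 15; GGPP, 20),
#' with a terminal GGPP demand. The combined IPP/DMAPP pool serves as the
#' measured local label input.
#'
#' @return A `flux_network`.
#' @seealso [prenyl_truth()]
#' @export
prenyl_network <- function() {
  parse_network(PRENYL_NETWORK_TEXT)
}

#' Synthetic ground truth for the prenyl pyrophosphate pathway
#'
#' A stand-in emulating the structure of the published yeast dataset (which
#' is not redistributed here): a constant chain flux in nmol/gDW/min, pool
#' sizes giving a GGPP turnover near 13 per minute, and an IPP labeling
#' curve rising smoothly to a plateau of 0.96 after the switch to labeled
#' glucose.
#'
#' @param flux Chain flux (nmol/gDW/min).
#' @return A `flux_truth`.
#' @export
prenyl_truth <- function(flux = 0.9) {
  net <- prenyl_network()
  fluxes <- c(iso = flux, gpps = flux, fpps = flux, ggpps = flux,
              ggdem = flux)
  pools <- c(DMAPP = 0.02, GPP = 0.03, FPP = 0.12, GGPP = 0.07)
  new_flux_truth(
    net, fluxes, pools,
    # sigmoid rise to a 0.96 plateau with an initial lag, as the long
    # mevalonate cascade upstream of IPP produces after the glucose switch
    inputs = list(IPP = input_custom(function(t) {
      ifelse(t <= 0, 0, 0.96 * (1 - exp(-(pmax(t, 0) / 0.8)^2)))
    })),
    flux_units = "nmol/gDW/min", time_units = "min",
    # 11 sampling times, dense early: the prenyl pools turn over in fractions
    # of a minute, so the short lags that identify them sit in the first
    # minute, while the IPP input rises to plateau over ~3 min
    times = c(0, 0.1, 0.25, 0.45, 0.7, 1.0, 1.35, 1.75, 2.2, 2.6, 3.0)
  )
}

default_sampling_times <- function(truth, n_times = 11) {
  full <- network_subsystem(truth$network)
  production <- vapply(full$intermediates, function(m) {
    tot <- 0
    for (rxn in full$reactions) {
      tot <- tot + truth$fluxes[[rxn$id]] *
        sum(vapply(rxn$products, function(s) (s$met == m) * s$coef, 0))
    }
    tot
  }, 0)
  tau <- truth$pools[full$intermediates] / production
  seq(0, 5 * max(tau), length.out = n_times)
}

#' Simulate a reference labeling dataset from a ground truth
#'
#' Full-network forward simulation from the global-input labeling protocol,
#' sampled at `times` (default: 11 points spanning 0 to five turnover times
#' of the slowest pool). Returns noise-free mean molecular enrichments for
#' every intermediate, with nominal standard deviations attached (2%
#' relative for enrichments with a floor, 10% for concentrations), ready for
#' [make_noisy_dataset()].
#'
#' @param truth A `flux_truth`.
#' @param times Optional numeric vector of sampling times.
#' @param rtol,atol Solver tolerances.
#' @return A list with `enrichments` (tibble `time, metabolite, value, sd`),
#'   `concentrations` (tibble `metabolite, value, sd`), `times`, and the
#'   dense `sim` (`flux_sim`) it was sampled from.
#' @export
simulate_reference_dataset <- function(truth, times = NULL,
                                       rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(truth, "flux_truth"))
  if (is.null(times)) {
    times <- truth$times %||% default_sampling_times(truth)
  }
  full <- network_subsystem(truth$network)
  # dense grid for downstream interpolation: uniform coverage plus
  # log-spaced early points so fast pools (turnover far above the window
  # scale) are resolved too
  tmax <- max(times)
  dense <- sort(unique(c(
    times,
    seq(0, tmax, length.out = 601),
    tmax * 10^seq(-5, 0, length.out = 480)
  )))
  sim <- simulate_subsystem(full, truth$fluxes, truth$pools, truth$inputs,
                            dense, rtol = rtol, atol = atol,
                            warn_fragment = FALSE)
  enr <- sim$enrichment[sim$enrichment$time %in% times, , drop = FALSE]
  enr <- tibble::tibble(
    time = enr$time, metabolite = enr$metabolite,
    value = clip01(enr$enrichment),  # solver-level overshoot of [0, 1]
    sd = default_enrichment_sd(clip01(enr$enrichment))
  )
  conc <- tibble::tibble(
    metabolite = names(truth$pools),
    value = as.numeric(truth$pools),
    sd = 0.10 * as.numeric(truth$pools)
  )
  list(enrichments = enr[order(enr$metabolite, enr$time), ],
       concentrations = conc, times = times, sim = sim, truth = truth)
}

#' Add measurement noise to a dataset
#'
#' Gaussian noise with relative standard deviation `rel_sd_enr` on
#' enrichments (clipped to `[0, 1]`) and `rel_sd_conc` on concentrations;
#' the `sd` columns are set to the applied standard deviations (enrichment
#' sds floored as in [fit_input()]). Reproducible given `seed`.
#'
#' @param dataset A list with `enrichments` and `concentrations` tibbles
#'   (e.g. from [simulate_reference_dataset()]).
#' @param rel_sd_enr,rel_sd_conc Relative standard deviations (defaults 2%
#'   and 10%).
#' @param seed Integer seed.
#' @return The dataset with noised `value` columns and updated `sd` columns.
#' @export
make_noisy_dataset <- function(dataset, rel_sd_enr = 0.02,
                               rel_sd_conc = 0.10, seed = NULL) {
  with_seed_or_not(seed, {
    enr <- dataset$enrichments
    enr$value <- clip01(enr$value +
                          stats::rnorm(nrow(enr), sd = rel_sd_enr * enr$value))
    enr$sd <- default_enrichment_sd(enr$value, rel_sd = max(rel_sd_enr, 1e-12))
    dataset$enrichments <- enr
    conc <- dataset$concentrations
    if (!is.null(conc)) {
      conc$value <- pmax(
        conc$value + stats::rnorm(nrow(conc), sd = rel_sd_conc * conc$value),
        1e-9
      )
      conc$sd <- pmax(rel_sd_conc, 1e-12) * conc$value
      dataset$concentrations <- conc
    }
    dataset
  })
}

#' Random linear pathway ground truth
#'
#' A chain X_out -> M1 -> ... -> Mn with log-uniform random fluxes on
#' `[0.1, 10]` (sorted decreasing so the steady-state slack drains through
#' sinks) and log-uniform pools on `[0.01, 10]`; the global input steps from
#' unlabeled to fully labeled at t = 0. Used for property tests.
#'
#' @param n_steps Number of chain reactions (>= 1).
#' @param seed Integer seed.
#' @return A `flux_truth`.
#' @export
random_linear_pathway <- function(n_steps, seed = NULL) {
  if (n_steps < 1) {
    stop_subflux("n_steps must be >= 1")
  }
  with_seed_or_not(seed, {
    mets <- paste0("M", seq_len(n_steps))
    from <- c("X_out", mets[-n_steps])
    lines <- c("@external X_out",
               sprintf("r%d\t%s[ab] -> %s[ab]\t0", seq_len(n_steps), from,
                       mets))
    net <- parse_network(lines)
    fluxes <- sort(10^stats::runif(n_steps, -1, 1), decreasing = TRUE)
    names(fluxes) <- paste0("r", seq_len(n_steps))
    pools <- 10^stats::runif(n_steps, -2, 1)
    names(pools) <- mets
    # canonical 11-point grid, log-spaced between half the fastest and five
    # times the slowest turnover time: pool turnovers are drawn across
    # decades, and a uniform grid cannot resolve them all
    tau <- pools / fluxes
    times <- c(0, exp(seq(log(min(tau) / 2), log(5 * max(tau)),
                          length.out = 10)))
    new_flux_truth(net, fluxes, pools,
                   inputs = list(X_out = input_step(1)), times = times)
  })
}
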