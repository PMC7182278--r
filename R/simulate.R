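# Label-propagation simulation. The subsystem's EMU decomposition yields a
# linear, time-varying ODE system over positional enrichments x:
#
#   m_Y * dx_{Y,k}/dt = sum_{r in producers(Y)} v_r * x_src(r,Y,k)
#                       - (sum_{r in producers(Y)} v_r) * x_{Y,k}
#
# with local-input positions forced by analytical time-functions. Consuming
# reactions drain a pool at its current enrichment and, under metabolic
# steady state, cancel against the production total, so only producing
# fluxes appear. Condensations contribute one term per atom position, which
# for mean enrichments is exactly the flux-weighted average of the source
# positional enrichments.

#' Assemble the labeling ODE system of a subsystem
#'
#' Builds the minimal positional-enrichment ODE system for the measured
#' metabolites of a subsystem, checks the steady-state feasibility of the
#' flux vector (every sink flux, i.e. production minus in-subsystem
#' consumption of an intermediate, must be non-negative), and attaches the
#' forcing functions of the local label inputs.
#'
#' @param sub A `flux_subsystem`.
#' @param fluxes Named numeric vector of fluxes for the subsystem's (non-sink)
#'   reactions.
#' @param pools Named numeric vector of pool sizes (concentrations) covering
#'   every simulated intermediate; all must be > 0.
#' @param inputs Named list of [input_function][input_constant] objects, one
#'   per required local input metabolite. When only an atom fragment of an
#'   input is required but the function represents the whole molecule's mean
#'   enrichment, it is used as a proxy (with a warning, once, unless
#'   `warn_fragment = FALSE`).
#' @param measured Intermediates whose mean enrichment the system must
#'   reproduce (defaults to all intermediates).
#' @param check_balance Error on negative sink fluxes (infeasible steady
#'   state) when `TRUE`.
#' @param warn_fragment Emit the fragment-proxy warning.
#' @return A `label_ode_system`.
#' @seealso [simulate_labeling()]
#' @export
assemble_odes <- function(sub, fluxes, pools, inputs,
                          measured = sub$intermediates,
                          check_balance = TRUE, warn_fragment = TRUE) {
  stopifnot(inherits(sub, "flux_subsystem"))
  emu <- emu_decompose(sub, measured)
  states <- emu$states
  n <- nrow(states)
  if (n == 0L) {
    stop_subflux("nothing to simulate: no EMU states for subsystem '%s'", sub$name)
  }
  rxn_ids <- names(sub$reactions)
  missing_flux <- setdiff(rxn_ids, names(fluxes))
  if (length(missing_flux) > 0L) {
    stop_subflux("missing flux value(s) for: %s",
                 paste(missing_flux, collapse = ", "))
  }
  sim_mets <- unique(states$metabolite)
  missing_pool <- setdiff(sim_mets, names(pools))
  if (length(missing_pool) > 0L) {
    stop_subflux("missing pool size(s) for simulated metabolite(s): %s",
                 paste(missing_pool, collapse = ", "))
  }
  if (any(pools[sim_mets] <= 0)) {
    stop_subflux("pool sizes must be > 0")
  }
  input_mets <- unique(emu$inputs$metabolite)
  missing_inp <- setdiff(input_mets, names(inputs))
  if (length(missing_inp) > 0L) {
    stop_subflux("missing input function(s) for local label input(s): %s",
                 paste(missing_inp, collapse = ", "))
  }
  if (warn_fragment) {
    req <- required_measurements(sub, measured)
    frag <- req$metabolite[req$fragment]
    if (length(frag) > 0L) {
      warn_subflux(
        "only an atom fragment of input(s) %s is required; using the supplied metabolite-level enrichment curve as a proxy",
        paste(frag, collapse = ", ")
      )
    }
  }
  # Lump dynamically equivalent positional EMUs (identical producer
  # structure implies identical trajectories): partition refinement over the
  # production edges. This collapses, e.g., all atoms inherited from the
  # same C5 unit of a condensation chain into one state.
  lump <- lump_equivalent_states(states, emu$edges)
  states <- lump$states
  n <- nrow(states)
  edges <- lump$edges
  state_key <- states$key
  input_idx <- stats::setNames(seq_along(input_mets), input_mets)
  e_row <- match(edges$key, state_key)
  e_col <- ifelse(
    edges$from_type == "state",
    match(edges$from_key, state_key),
    n + input_idx[edges$from_met]
  )
  sys <- structure(
    list(
      subsystem = sub,
      emu = emu,
      states = states,
      state_key = state_key,
      n_states = n,
      sim_mets = sim_mets,
      input_mets = input_mets,
      input_funs = inputs[input_mets],
      edges = edges,
      e_row = e_row,
      e_col = e_col,
      e_flux = edges$reaction,
      position_map = lump$position_map,
      fluxes = fluxes[rxn_ids],
      pools = pools,
      measured = emu$measured
    ),
    class = "label_ode_system"
  )
  bal <- sink_fluxes(sub, fluxes)
  sys$sinks <- bal
  if (check_balance && any(bal$flux < -1e-9)) {
    bad <- bal$substrate[bal$flux < -1e-9]
    stop_subflux(
      "infeasible steady state: consumption exceeds production for %s (negative sink flux)",
      paste(bad, collapse = ", ")
    )
  }
  sys
}

#' Balancing sink fluxes of a subsystem
#'
#' The sink of each intermediate is not a free parameter: it is the outflow
#' that balances total production against in-subsystem consumption at the
#' given flux vector, enforcing metabolic steady state.
#'
#' @param sub A `flux_subsystem`.
#' @param fluxes Named flux vector over the subsystem reactions.
#' @return Tibble `id`, `substrate`, `flux`.
#' @export
sink_fluxes <- function(sub, fluxes) {
  out <- sub$sinks
  out$flux <- unname(vapply(out$substrate, function(m) {
    prod <- 0
    cons <- 0
    for (rxn in sub$reactions) {
      v <- fluxes[[rxn$id]]
      prod <- prod + v * sum(vapply(rxn$products, function(s) {
        (s$met == m) * s$coef
      }, 0))
      cons <- cons + v * sum(vapply(rxn$substrates, function(s) {
        (s$met == m) * s$coef
      }, 0))
    }
    prod - cons
  }, 0))
  out
}

build_transfer_matrix <- function(sys, fluxes) {
  n <- sys$n_states
  M <- matrix(0, n, n + length(sys$input_mets))
  v <- fluxes[sys$e_flux]
  for (i in seq_along(sys$e_row)) {
    M[sys$e_row[[i]], sys$e_col[[i]]] <-
      M[sys$e_row[[i]], sys$e_col[[i]]] + v[[i]]
  }
  M
}

# Core integration: returns the positional-enrichment matrix (rows = times,
# cols = states). Shared by the user-facing simulate_labeling() and the
# estimator's hot loop (which skips all tibble construction).
run_labeling_core <- function(sys, times, fluxes, pools, rtol, atol,
                              initial = NULL) {
  M <- build_transfer_matrix(sys, fluxes)
  din <- rowSums(M)
  mstate <- as.numeric(pools[sys$states$metabolite])
  if (any(!is.finite(mstate)) || any(mstate <= 0)) {
    stop_subflux("pool sizes must be finite and > 0")
  }
  input_funs <- lapply(sys$input_funs, `[[`, "fun")
  n_inputs <- length(input_funs)
  n <- sys$n_states
  x0 <- rep(0, n)
  if (!is.null(initial)) {
    hit <- sys$states$metabolite %in% names(initial)
    x0[hit] <- as.numeric(initial[sys$states$metabolite[hit]])
  }
  xall <- numeric(n + n_inputs)
  deriv <- function(t, x, parms) {
    xall[seq_len(n)] <- x
    for (j in seq_len(n_inputs)) {
      v <- input_funs[[j]](t)
      xall[n + j] <- if (v < 0) 0 else if (v > 1) 1 else v
    }
    list((M %*% xall - din * x) / mstate)
  }
  sol <- deSolve::lsoda(y = x0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[[1]] < 0) {
    stop_subflux(
      "ODE integration failed for subsystem '%s' (istate %d); the system may be stiff — try tighter tolerances or check flux/pool magnitudes",
      sys$subsystem$name, attr(sol, "istate")[[1]]
    )
  }
  sol[, -1, drop = FALSE]
}

# Mean molecular enrichment matrix (rows = times, cols = measured
# metabolites) from the (lumped) state matrix: average over all original
# atom positions, mapped to their lumped state columns.
mean_enrichment_matrix <- function(sys, xmat) {
  pm <- sys$position_map
  cols <- lapply(sys$measured, function(m) pm$state[pm$metabolite == m])
  out <- vapply(cols, function(idx) rowMeans(xmat[, idx, drop = FALSE]),
                numeric(nrow(xmat)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = nrow(xmat))
  }
  colnames(out) <- sys$measured
  out
}

# Partition refinement over production edges: positional EMUs of the same
# metabolite whose producers are identical (same reaction, and sources that
# are themselves equivalent or the same input metabolite) share one ODE
# state. Returns representative states, their edges, and the map from every
# original position to its lumped state index.
lump_equivalent_states <- function(states, edges) {
  key <- paste0(states$metabolite, "#", states$position)
  edge_key <- paste0(edges$metabolite, "#", edges$position)
  edge_from_key <- paste0(edges$from_met, "#", edges$from_pos)
  cls <- match(states$metabolite, unique(states$metabolite))
  repeat {
    src_tag <- ifelse(edges$from_type == "input",
                      paste0("IN:", edges$from_met),
                      paste0("ST:", cls[match(edge_from_key, key)]))
    tag <- paste(edges$reaction, src_tag)
    sig <- vapply(key, function(k) {
      paste(sort(tag[edge_key == k]), collapse = ";")
    }, "")
    new_cls <- match(paste(states$metabolite, sig),
                     unique(paste(states$metabolite, sig)))
    if (identical(new_cls, cls)) break
    cls <- new_cls
  }
  rep_idx <- match(sort(unique(cls)), cls)
  rep_states <- states[rep_idx, , drop = FALSE]
  rep_states$key <- key[rep_idx]
  rep_key_of_class <- rep_states$key[match(cls, sort(unique(cls)))]
  keep <- edge_key %in% rep_states$key
  rep_edges <- edges[keep, , drop = FALSE]
  rep_edges$key <- edge_key[keep]
  rep_edges$from_key <- ifelse(
    rep_edges$from_type == "input", NA_character_,
    rep_key_of_class[match(edge_from_key[keep], key)]
  )
  position_map <- tibble::tibble(
    metabolite = states$metabolite,
    position = states$position,
    state = match(rep_key_of_class, rep_states$key)
  )
  list(states = rep_states, edges = rep_edges, position_map = position_map)
}

#' Simulate label propagation
#'
#' Integrates the labeling ODE system on a time grid with a stiff-capable
#' solver (`deSolve::lsoda`), starting from a fully unlabeled subsystem
#' (all enrichments 0) unless `initial` overrides it. Mean molecular
#' enrichments are the average of the positional enrichments of each
#' measured metabolite.
#'
#' @param sys A `label_ode_system` from [assemble_odes()].
#' @param times Numeric vector of output times (t = 0 is added if absent).
#' @param fluxes,pools Optional overrides of the assembled values (same
#'   names); this allows one assembled system to be re-simulated cheaply
#'   during fitting.
#' @param rtol,atol Solver tolerances.
#' @param initial Optional named vector of initial positional enrichment per
#'   metabolite.
#' @return A `flux_sim`: tibbles `trajectories` (time, metabolite, position,
#'   enrichment) and `enrichment` (time, metabolite, enrichment — mean
#'   molecular enrichment of the measured metabolites).
#' @export
simulate_labeling <- function(sys, times, fluxes = NULL, pools = NULL,
                              rtol = 1e-8, atol = 1e-10, initial = NULL) {
  stopifnot(inherits(sys, "label_ode_system"))
  fluxes <- if (is.null(fluxes)) sys$fluxes else fluxes[names(sys$fluxes)]
  pools <- if (is.null(pools)) sys$pools else pools
  times <- sort(unique(c(0, times)))
  xmat <- run_labeling_core(sys, times, fluxes, pools, rtol, atol, initial)
  pm <- sys$position_map
  traj <- tibble::tibble(
    time = rep(times, times = nrow(pm)),
    metabolite = rep(pm$metabolite, each = length(times)),
    position = rep(pm$position, each = length(times)),
    enrichment = as.vector(xmat[, pm$state, drop = FALSE])
  )
  enr_mat <- mean_enrichment_matrix(sys, xmat)
  enr <- tibble::tibble(
    time = rep(times, times = length(sys$measured)),
    metabolite = rep(sys$measured, each = length(times)),
    enrichment = as.vector(enr_mat)
  )
  structure(
    list(
      times = times,
      trajectories = traj,
      enrichment = enr,
      system = sys,
      fluxes = fluxes,
      pools = pools
    ),
    class = "flux_sim"
  )
}

#' Simulate a subsystem in one call
#'
#' Convenience wrapper: [assemble_odes()] followed by [simulate_labeling()].
#'
#' @inheritParams assemble_odes
#' @inheritParams simulate_labeling
#' @return A `flux_sim`.
#' @export
simulate_subsystem <- function(sub, fluxes, pools, inputs, times,
                               measured = sub$intermediates,
                               rtol = 1e-8, atol = 1e-10,
                               warn_fragment = TRUE) {
  sys <- assemble_odes(sub, fluxes, pools, inputs, measured = measured,
                       warn_fragment = warn_fragment)
  simulate_labeling(sys, times, rtol = rtol, atol = atol)
}

# A whole network viewed as one subsystem: all intermediates simulated, the
# global inputs (externals feeding reactions) forced. Used to generate
# reference datasets and as the brute-force oracle for the localization
# property.
network_subsystem <- function(net) {
  snet <- split_reversible(net)
  inter <- intermediates_of(net)
  inputs <- setdiff(
    unique(unlist(lapply(snet$reactions, tracer_substrates))),
    inter
  )
  new_flux_subsystem(
    name = "S_full",
    network = net,
    reactions = snet$reactions,
    intermediates = inter,
    local_inputs = inputs
  )
}

#' Fragment mean-enrichment series from a simulation
#'
#' Extracts the mean enrichment of an atom-position subset of a metabolite
#' from simulated positional trajectories — the quantity an MS/MS fragment
#' measurement would deliver. Useful to supply the matching-fragment input
#' data required when a subsystem's product is a cleavage fragment of its
#' local label input.
#'
#' @param sim A `flux_sim` whose states include the requested positions.
#' @param metabolite Metabolite id.
#' @param positions Integer vector of 1-based atom positions.
#' @param times Optional subset of output times.
#' @return Tibble `time, metabolite, value, sd` (sd from the default 2%
#'   relative policy), with the metabolite labeled `met[positions]`.
#' @export
fragment_series <- function(sim, metabolite, positions, times = NULL) {
  stopifnot(inherits(sim, "flux_sim"))
  tr <- sim$trajectories
  tr <- tr[tr$metabolite == metabolite & tr$position %in% positions, ,
           drop = FALSE]
  if (length(unique(tr$position)) != length(unique(positions))) {
    stop_subflux("simulation does not carry position(s) %s of '%s'",
                 paste(setdiff(positions, unique(tr$position)), collapse = ", "),
                 metabolite)
  }
  agg <- tr |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(value = mean(.data$enrichment), .groups = "drop")
  if (!is.null(times)) {
    agg <- agg[agg$time %in% times, , drop = FALSE]
  }
  tibble::tibble(
    time = agg$time,
    metabolite = sprintf("%s[%s]", metabolite,
                         paste(sort(unique(positions)), collapse = ",")),
    value = agg$value,
    sd = default_enrichment_sd(agg$value)
  )
}

#' @export
print.flux_sim <- function(x, ...) {
  cat(sprintf("<flux_sim> %s: %d states, %d times (%.3g to %.3g)\n",
              x$system$subsystem$name, x$system$n_states, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
autoplot.flux_sim <- function(object, ...) {
  ggplot2::ggplot(object$enrichment,
                  ggplot2::aes(x = .data$time, y = .data$enrichment,
                               colour = .data$metabolite)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "mean molecular enrichment",
                  colour = "metabolite")
}
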