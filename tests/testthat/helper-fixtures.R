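# Shared fixtures, built once per test run. The reference dataset of the
# example network is the workhorse of most estimation tests.

example_truth_cached <- example_truth()
example_ref <- simulate_reference_dataset(example_truth_cached)

# a fast optimizer configuration for tests that exercise behaviour rather
# than fit quality
quick_control <- fit_control(swarm_particles = 30, swarm_iter = 60)

# trajectory of one metabolite from the dense reference simulation, as an
# exact interpolated input function
exact_traj_input <- function(dataset, met, positions = NULL) {
  tr <- dataset$sim$trajectories
  tr <- tr[tr$metabolite == met, , drop = FALSE]
  if (!is.null(positions)) {
    tr <- tr[tr$position %in% positions, , drop = FALSE]
  }
  agg <- stats::aggregate(enrichment ~ time, data = tr, FUN = mean)
  input_interpolation(agg$time, agg$enrichment)
}

# measurement list (enrichments + concentrations) restricted to a set of
# metabolites
measurements_for <- function(dataset, mets) {
  list(
    enrichments = dataset$enrichments[
      dataset$enrichments$metabolite %in% mets, , drop = FALSE],
    concentrations = dataset$concentrations[
      dataset$concentrations$metabolite %in% mets, , drop = FALSE]
  )
}

# simple one-reaction ground truth (X_out -> M1), known closed form
single_pool_truth <- function(v = 2, m = 1) {
  net <- parse_network(c("@external X_out", "r1\tX_out[ab] -> M1[ab]\t0"))
  subflux:::new_flux_truth(net, c(r1 = v), c(M1 = m),
                           inputs = list(X_out = input_step(1)))
}
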