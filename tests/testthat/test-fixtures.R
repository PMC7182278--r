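test_that("the example network reproduces the printed counts and motifs", {
  net <- example_network()
  expect_equal(nrow(net$metabolites), 18L)
  expect_equal(length(net$reactions), 20L)
  expect_length(decompose_network(net), 17L)
  expect_equal(producers_of(net, "F"), c("r4", "r9"))
  expect_true(net$reactions$r6$reversible)
  # condensation and cleavage share the cycle through G/H/K
  expect_equal(length(net$reactions$r11$substrates), 2L)
  expect_equal(length(net$reactions$r12$products), 2L)
})

test_that("the prenyl pathway carries C5 arithmetic and a single required input", {
  net <- prenyl_network()
  atoms <- stats::setNames(net$metabolites$n_atoms, net$metabolites$id)
  expect_equal(unname(atoms[c("IPP", "DMAPP", "GPP", "FPP", "GGPP")]),
               c(5L, 5L, 10L, 15L, 20L))
  subs <- decompose_network(net)
  sub <- Reduce(merge_subsystems, subs)
  expect_equal(sort(sub$intermediates), c("DMAPP", "FPP", "GGPP", "GPP"))
  req <- required_measurements(sub)
  expect_equal(req$metabolite, "IPP")
  expect_false(req$fragment)
})

test_that("ground truths satisfy steady state and positive pools", {
  for (truth in list(example_truth_cached, prenyl_truth(),
                     random_linear_pathway(4, seed = 2))) {
    full <- subflux:::network_subsystem(truth$network)
    bal <- sink_fluxes(full, truth$fluxes)
    expect_true(all(bal$flux > -1e-9))
    expect_true(all(truth$pools > 0))
  }
})

test_that("reference datasets rise from zero and lag along a chain", {
  truth <- random_linear_pathway(4, seed = 11)
  ds <- simulate_reference_dataset(truth)
  at0 <- ds$enrichments[ds$enrichments$time == 0, ]
  expect_true(all(at0$value == 0))
  expect_true(all(ds$enrichments$value >= 0 & ds$enrichments$value <= 1))
  # each metabolite lags its precursor: curves are pointwise ordered and
  # strictly separated in the middle of the window
  curve <- function(met) {
    tr <- ds$sim$enrichment[ds$sim$enrichment$metabolite == met, ]
    tr$enrichment[order(tr$time)]
  }
  mid <- length(ds$sim$times) %/% 2
  for (k in 1:3) {
    up <- curve(paste0("M", k))
    down <- curve(paste0("M", k + 1))
    expect_true(all(down <= up + 1e-9))
    expect_lt(down[mid], up[mid])
  }
})

test_that("single-step reference data matches the closed form", {
  truth <- single_pool_truth(v = 1.5, m = 0.5)
  ds <- simulate_reference_dataset(truth, times = seq(0, 2, 0.2))
  k <- 1.5 / 0.5
  expect_equal(ds$enrichments$value, 1 - exp(-k * ds$enrichments$time),
               tolerance = 1e-6)
  expect_equal(ds$concentrations$value, 0.5)
})

test_that("noise generation is calibrated, clipped and reproducible", {
  ds <- list(enrichments = tibble::tibble(time = 1, metabolite = "X",
                                          value = 0.5, sd = NA_real_),
             concentrations = tibble::tibble(metabolite = "X", value = 2,
                                             sd = NA_real_))
  # zero noise is the identity
  same <- make_noisy_dataset(ds, rel_sd_enr = 0, rel_sd_conc = 0, seed = 1)
  expect_equal(same$enrichments$value, 0.5)
  expect_equal(same$concentrations$value, 2)

  # law of large numbers: empirical sd of many noised copies ~ rel_sd * value
  big <- ds
  big$enrichments <- tibble::tibble(time = seq_len(10000), metabolite = "X",
                                    value = 0.5, sd = NA_real_)
  noised <- make_noisy_dataset(big, rel_sd_enr = 0.02, seed = 3)
  expect_equal(stats::sd(noised$enrichments$value), 0.01, tolerance = 0.03)
  expect_true(all(noised$enrichments$value >= 0 &
                    noised$enrichments$value <= 1))

  n1 <- make_noisy_dataset(ds, seed = 42)
  n2 <- make_noisy_dataset(ds, seed = 42)
  expect_identical(n1, n2)
})

test_that("random pathways have the requested size and feasible truths", {
  expect_error(random_linear_pathway(0), "n_steps")
  t1 <- random_linear_pathway(1, seed = 5)
  expect_length(t1$fluxes, 1L)
  t5 <- random_linear_pathway(5, seed = 5)
  expect_length(decompose_network(t5$network), 5L)
  expect_true(all(t5$fluxes >= 0.1 & t5$fluxes <= 10))
  expect_true(all(t5$pools >= 0.01 & t5$pools <= 10))
  # fluxes non-increasing so every sink is feasible
  expect_true(all(diff(unname(t5$fluxes)) <= 0))
  expect_identical(random_linear_pathway(3, seed = 9)$fluxes,
                   random_linear_pathway(3, seed = 9)$fluxes)
})
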