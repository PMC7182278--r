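test_that("the weighted objective matches its definition", {
  truth <- example_truth_cached
  sub <- minimal_subsystem(truth$network, "N")
  sys <- assemble_odes(sub, truth$fluxes[names(sub$reactions)], truth$pools,
                       list(M = exact_traj_input(example_ref, "M")))
  sim <- simulate_labeling(sys, example_ref$times)

  # perfect agreement: build measurements from the simulation itself
  meas <- list(
    enrichments = tibble::tibble(
      time = sim$enrichment$time, metabolite = "N",
      value = sim$enrichment$enrichment, sd = 0.02
    ),
    concentrations = tibble::tibble(metabolite = "N",
                                    value = truth$pools[["N"]], sd = 0.03)
  )
  expect_equal(flux_objective(meas, sim, pools = truth$pools), 0)

  # one residual of exactly two standard deviations -> h = 4
  meas2 <- meas
  meas2$concentrations <- NULL
  meas2$enrichments <- meas2$enrichments[5, ]
  meas2$enrichments$value <- meas2$enrichments$value + 2 * 0.02
  expect_equal(flux_objective(meas2, sim, pools = truth$pools), 4)

  # random case against an independent spreadsheet-style transcription
  set.seed(31)
  meas3 <- meas
  meas3$enrichments$value <- clip01(meas3$enrichments$value +
                                      rnorm(nrow(meas3$enrichments), 0, 0.05))
  meas3$concentrations$value <- 0.35
  direct <- sum(((meas3$enrichments$value - sim$enrichment$enrichment) /
                   meas3$enrichments$sd)^2) +
    ((0.35 - truth$pools[["N"]]) / 0.03)^2
  expect_equal(flux_objective(meas3, sim, pools = truth$pools), direct)
})

test_that("chi-square goodness of fit behaves like the reference tables", {
  expect_equal(chi2_gof(0, 20, 3)$p_value, 1)
  g <- chi2_gof(10, 13, 3)   # statistic equal to its dof
  expect_equal(g$dof, 10L)
  expect_gt(g$p_value, 0.40)
  expect_lt(g$p_value, 0.50)
  expect_lt(chi2_gof(50, 13, 3)$p_value, 0.01)
  expect_error(chi2_gof(1, 3, 3), "degrees of freedom")
})

test_that("a single-reaction subsystem is recovered exactly from clean data", {
  truth <- single_pool_truth(v = 2, m = 1)
  ds <- simulate_reference_dataset(truth, times = seq(0, 2.5, 0.25))
  sub <- minimal_subsystem(truth$network, "M1")
  fit <- estimate_fluxes(sub, list(X_out = input_step(1)),
                         measurements_for(ds, "M1"))
  expect_lt(abs(fit$fluxes$estimate[fit$fluxes$id == "r1"] - 2), 2e-3)
  expect_lt(abs(fit$pools$estimate[fit$pools$id == "M1"] - 1), 2e-3)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-4)
  expect_equal(fit$chi2$dof, fit$n_data - 2L)
  expect_equal(fit$chi2$p_value, 1, tolerance = 1e-6)
  # sink flux equals the single production flux
  expect_equal(fit$fluxes$estimate[fit$fluxes$type == "sink"],
               fit$fluxes$estimate[fit$fluxes$id == "r1"])
})

test_that("estimates respect bounds, fixed values and equality ties", {
  truth <- example_truth_cached
  subs <- decompose_network(truth$network)
  sub <- merge_subsystems(subs$S_M, subs$S_N)
  inputs <- list(L = exact_traj_input(example_ref, "L"))
  meas <- measurements_for(example_ref, c("M", "N"))

  cons <- flux_constraints(v_lower = 0, v_upper = 0.9)
  fit <- suppressWarnings(estimate_fluxes(sub, inputs, meas,
                                          constraints = cons))
  est <- fit$fluxes$estimate[fit$fluxes$type == "fitted"]
  expect_true(all(est <= 0.9 + 1e-9))

  cons2 <- flux_constraints(v_fixed = c(r15 = 1.0))
  fit2 <- suppressWarnings(estimate_fluxes(sub, inputs, meas,
                                           constraints = cons2))
  expect_equal(fit2$fluxes$estimate[fit2$fluxes$id == "r15"], 1.0)
  expect_equal(fit2$fluxes$type[fit2$fluxes$id == "r15"], "fixed")

  cons3 <- flux_constraints(v_equal = list(c("r15", "r16")))
  fit3 <- estimate_fluxes(sub, inputs, meas, constraints = cons3)
  expect_equal(fit3$fluxes$estimate[fit3$fluxes$id == "r15"],
               fit3$fluxes$estimate[fit3$fluxes$id == "r16"])
  expect_lt(abs(fit3$fluxes$estimate[fit3$fluxes$id == "r16"] - 1), 0.05)

  expect_error(flux_constraints(v_lower = 2, v_upper = 1), "bounds")
})

test_that("concentrations of non-simulated metabolites are ignored with a warning", {
  truth <- example_truth_cached
  sub <- minimal_subsystem(truth$network, "N")
  meas <- measurements_for(example_ref, "N")
  meas$concentrations <- rbind(
    meas$concentrations,
    tibble::tibble(metabolite = "M", value = 0.12, sd = 0.012)
  )
  expect_warning(
    fit <- estimate_fluxes(sub, list(M = exact_traj_input(example_ref, "M")),
                           meas),
    "ignored"
  )
  expect_equal(fit$n_data, 12L)  # 11 enrichments + 1 concentration
})

test_that("tidiers and fitted curves expose the fit", {
  truth <- single_pool_truth()
  ds <- simulate_reference_dataset(truth, times = seq(0, 2.5, 0.25))
  sub <- minimal_subsystem(truth$network, "M1")
  fit <- estimate_fluxes(sub, list(X_out = input_step(1)),
                         measurements_for(ds, "M1"), units = "umol/gDW/h")
  td <- tidy(fit)
  expect_true(all(c("term", "kind", "estimate", "units") %in% names(td)))
  expect_true("r1" %in% td$term && "M1" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_free, 2L)
  cv <- fitted_curves(fit, n_grid = 20)
  expect_true(all(c("fitted", "measured") %in% cv$kind))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("turnover rate is flux over pool", {
  expect_equal(turnover_rate(2, 4), 0.5)
  expect_equal(turnover_rate(0, 4), 0)
  expect_equal(turnover_rate(c(1, 2), c(2, 2)), c(0.5, 1))
  expect_error(turnover_rate(1, 0), "> 0")
})
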