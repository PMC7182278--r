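test_that("single-pool step labeling follows the closed form", {
  truth <- single_pool_truth(v = 2, m = 1)
  sub <- minimal_subsystem(truth$network, "M1")
  k <- 2 / 1
  times <- c(0, 1 / k, 5 / k)
  sim <- simulate_subsystem(sub, truth$fluxes, truth$pools,
                            list(X_out = input_step(1)), times)
  got <- sim$enrichment$enrichment[match(times, sim$enrichment$time)]
  expect_lt(max(abs(got - (1 - exp(-k * times)))), 1e-6)
})

test_that("zero flux freezes the state and t = 0 starts unlabeled", {
  truth <- single_pool_truth(v = 2, m = 1)
  sub <- minimal_subsystem(truth$network, "M1")
  sim0 <- simulate_subsystem(sub, c(r1 = 0), c(M1 = 1),
                             list(X_out = input_step(1)), seq(0, 5, 1))
  expect_true(all(sim0$enrichment$enrichment == 0))

  full_sim <- example_ref$sim
  at0 <- full_sim$enrichment[full_sim$enrichment$time == 0, ]
  expect_true(all(at0$enrichment == 0))
})

test_that("a converging node obeys the hand-written two-producer balance", {
  truth <- example_truth_cached
  sub <- minimal_subsystem(truth$network, "F")
  xa <- exact_traj_input(example_ref, "A")
  xe <- exact_traj_input(example_ref, "E")
  times <- example_ref$times
  sim <- simulate_subsystem(sub, truth$fluxes, truth$pools,
                            list(A = xa, E = xe), times)
  v4 <- truth$fluxes[["r4"]]
  v9 <- truth$fluxes[["r9"]]
  mF <- truth$pools[["F"]]
  deriv <- function(t, x, p) {
    list((v4 * eval_input(xa, t) + v9 * eval_input(xe, t) - (v4 + v9) * x) / mF)
  }
  oracle <- deSolve::lsoda(0, times, deriv, NULL, rtol = 1e-10, atol = 1e-12)
  got <- sim$enrichment$enrichment[match(times, sim$enrichment$time)]
  expect_lt(max(abs(got - oracle[, 2])), 1e-6)
})

test_that("subsystem simulation driven by full-network trajectories localizes", {
  truth <- example_truth_cached
  full <- example_ref$sim
  sub <- minimal_subsystem(truth$network, "N")
  sim <- simulate_subsystem(sub, truth$fluxes, truth$pools,
                            list(M = exact_traj_input(example_ref, "M")),
                            example_ref$times)
  ref_N <- full$enrichment[full$enrichment$metabolite == "N" &
                             full$enrichment$time %in% example_ref$times, ]
  got <- sim$enrichment$enrichment[match(ref_N$time, sim$enrichment$time)]
  expect_lt(max(abs(got - ref_N$enrichment)), 1e-5)
})

test_that("enrichments stay in [0, 1] and means average the positions", {
  full <- example_ref$sim
  expect_true(all(full$trajectories$enrichment >= -1e-9 &
                    full$trajectories$enrichment <= 1 + 1e-9))
  hx <- full$trajectories[full$trajectories$metabolite == "H", ]
  hmean <- stats::aggregate(enrichment ~ time, data = hx, FUN = mean)
  got <- full$enrichment[full$enrichment$metabolite == "H", ]
  expect_equal(got$enrichment[match(hmean$time, got$time)], hmean$enrichment,
               tolerance = 1e-12)
})

test_that("halving solver tolerances leaves enrichments stable", {
  truth <- example_truth_cached
  sub <- minimal_subsystem(truth$network, "H")
  inputs <- list(G = exact_traj_input(example_ref, "G"),
                 K = exact_traj_input(example_ref, "K"))
  s1 <- simulate_subsystem(sub, truth$fluxes, truth$pools, inputs,
                           example_ref$times, rtol = 1e-8, atol = 1e-10)
  s2 <- simulate_subsystem(sub, truth$fluxes, truth$pools, inputs,
                           example_ref$times, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(s1$enrichment$enrichment - s2$enrichment$enrichment)),
            1e-5)
})

test_that("assembly validates fluxes, pools, inputs and steady state", {
  truth <- example_truth_cached
  sub <- minimal_subsystem(truth$network, "N")
  expect_error(assemble_odes(sub, c(bogus = 1), c(N = 1),
                             list(M = input_step(1))), "missing flux")
  expect_error(assemble_odes(sub, c(r16 = 1), c(),
                             list(M = input_step(1))), "missing pool")
  expect_error(assemble_odes(sub, c(r16 = 1), c(N = 1), list()),
               "missing input")
  expect_error(assemble_odes(sub, c(r16 = 1), c(N = -1),
                             list(M = input_step(1))), "> 0")
  sGH <- merge_subsystems(minimal_subsystem(truth$network, "G"),
                          minimal_subsystem(truth$network, "H"))
  # consumption of G exceeding its production is an infeasible steady state
  expect_error(
    assemble_odes(sGH, c(r10 = 1, r11 = 2), c(G = 1, H = 1),
                  list(D = input_step(1), K = input_step(1))),
    "infeasible steady state"
  )
})

test_that("fragment series report the fragment mean of simulated positions", {
  fs <- fragment_series(example_ref$sim, "H", 3:4, times = example_ref$times)
  tr <- example_ref$sim$trajectories
  tr <- tr[tr$metabolite == "H" & tr$position %in% 3:4 &
             tr$time %in% example_ref$times, ]
  manual <- stats::aggregate(enrichment ~ time, data = tr, FUN = mean)
  expect_equal(fs$value, manual$enrichment, tolerance = 1e-12)
  expect_match(fs$metabolite[1], "H\\[3,4\\]")
  expect_error(fragment_series(example_ref$sim, "H", 9), "position")
})

test_that("input functions evaluate, clip and print", {
  f <- input_logistic(c(0.8, 2, 1))
  expect_equal(eval_input(f, 1), 0.4)
  g <- input_custom(function(t) 2 * t)   # strays above 1
  expect_equal(eval_input(g, c(0.1, 3)), c(0.2, 1))
  s <- input_step(1, t0 = 1)
  expect_equal(eval_input(s, c(0, 1, 2)), c(0, 1, 1))
  expect_output(print(f), "logistic")
})
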