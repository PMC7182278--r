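test_that("logistic evaluation matches its closed form", {
  expect_equal(eval_logistic(c(1, 3, 5), 5), 0.5)
  expect_equal(eval_logistic(c(0.6, 0, 2), c(-10, 0, 10)), rep(0.3, 3))
  expect_equal(eval_logistic(c(0.8, 2, 5), 1e6), 0.8)
  # overflow-safe far from the midpoint
  expect_equal(eval_logistic(c(0.5, 100, 0), -1e6), 0)
})

test_that("double-logistic evaluation matches an independent transcription", {
  # degenerate cases
  expect_equal(eval_double_logistic(c(0.3, 0, 0, 1, 2, 3, 4), c(0, 5, 50)),
               rep(0.3, 3))
  expect_equal(eval_double_logistic(c(0.25, 0.9, 0, 2, 1.5, 2, 1.5), 7), 0.25)
  # direct formula, written out independently
  direct <- function(p, t) {
    p[1] + (p[2] - p[3] * t) *
      (1 / (1 + exp((p[4] - t) / p[5])) - 1 / (1 + exp((p[6] - t) / p[7])))
  }
  set.seed(99)
  for (i in 1:20) {
    p <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -2, 2),
           runif(1, -5, 5), runif(1, 0.1, 3), runif(1, -5, 5),
           runif(1, 0.1, 3))
    t <- runif(3, -10, 10)
    expect_equal(eval_double_logistic(p, t), direct(p, t), tolerance = 1e-12)
  }
  expect_error(eval_double_logistic(c(0, 1, 0, 1, 0, 2, 1), 1), "non-zero")
})

test_that("fitting recovers a known logistic from noise-free samples", {
  p_true <- c(0.8, 1.5, 3)
  ser <- tibble::tibble(time = seq(0, 10, length.out = 11),
                        value = eval_logistic(p_true, seq(0, 10, length.out = 11)))
  fit <- fit_input(ser, family = "logistic", seed = 1)
  grid <- seq(0, 10, length.out = 101)
  expect_lt(max(abs(eval_input(fit, grid) - eval_logistic(p_true, grid))),
            1e-3)
  expect_equal(fit$family, "logistic")
  # parameters within the printed box bounds
  expect_true(all(fit$par >= c(0, -100, -1000) & fit$par <= c(1, 100, 1000)))
})

test_that("a constant series is fitted flat within measurement sd", {
  ser <- tibble::tibble(time = 0:10, value = rep(0.4, 11), sd = 0.01)
  fit <- fit_input(ser, family = "logistic", seed = 2,
                   control = quick_control)
  expect_true(all(abs(eval_input(fit, 0:10) - 0.4) < 0.01))
})

test_that("fit_input guards, determinism, and refinement contract hold", {
  ser <- tibble::tibble(time = 0:3, value = c(0, 0.3, 0.5, 0.6))
  expect_error(fit_input(ser[1:2, ], family = "logistic"),
               "at least 3 observations")
  expect_error(fit_input(ser, family = "double_logistic"),
               "at least 7 observations")

  ser11 <- tibble::tibble(time = seq(0, 5, 0.5),
                          value = eval_logistic(c(0.7, 2, 2), seq(0, 5, 0.5)))
  f1 <- fit_input(ser11, "double_logistic", seed = 42, control = quick_control)
  f2 <- fit_input(ser11, "double_logistic", seed = 42, control = quick_control)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$objective, f2$objective)
  # local refinement never worsens the swarm optimum
  expect_lte(f1$objective, f1$swarm_objective)
  # bounds respected
  b <- subflux:::DOUBLE_LOGISTIC_BOUNDS
  expect_true(all(f1$par >= b$lower & f1$par <= b$upper))
})

test_that("series validation sorts, clips and floors standard deviations", {
  ser <- tibble::tibble(time = c(2, 0, 1), value = c(1.02, 0, 0.5))
  expect_warning(v <- subflux:::validate_label_series(ser), "clipped")
  expect_equal(v$time, c(0, 1, 2))
  expect_true(all(v$value <= 1))
  expect_equal(v$sd, 0.02 * pmax(v$value, 0.1))
  expect_error(subflux:::validate_label_series(
    tibble::tibble(time = c(0, 0), value = c(0, 0.1))), "increasing")
})

test_that("family selection prefers parsimony and respects data size", {
  t <- seq(0, 10, length.out = 12)
  mono <- tibble::tibble(time = t, value = eval_logistic(c(0.9, 1.2, 4), t))
  expect_equal(select_family(mono, seed = 3, control = quick_control),
               "logistic")

  drift <- tibble::tibble(
    time = t,
    value = clip01(0.05 + (0.8 - 0.03 * t) *
                     (stats::plogis((t - 2) / 0.5) - stats::plogis((t - 30) / 2)))
  )
  expect_equal(select_family(drift, seed = 3, control = quick_control),
               "double_logistic")

  few <- tibble::tibble(time = 0:3, value = c(0, 0.4, 0.7, 0.8))
  expect_equal(select_family(few, seed = 3), "logistic")
})

test_that("local-input curves of the example network are described at the 2% level", {
  # noise-free enrichment curves simulated on the example network, fitted
  # with a double logistic: weighted SSR per curve at or below its
  # observation count means a typical residual within one (2%-relative,
  # floored) standard deviation
  mets <- c("X_in", "A", "B", "D", "F", "G", "M")
  for (m in mets) {
    ser <- example_ref$enrichments[example_ref$enrichments$metabolite == m, ]
    fit <- fit_input(ser, "double_logistic", seed = 7)
    expect_lt(fit$objective, nrow(ser))
  }
})

test_that("tidy, glance and autoplot work on input fits", {
  ser <- tibble::tibble(time = seq(0, 5, 0.5),
                        value = eval_logistic(c(0.7, 2, 2), seq(0, 5, 0.5)))
  fit <- fit_input(ser, "logistic", seed = 1, control = quick_control)
  td <- tidy(fit)
  expect_equal(td$term, c("p1", "p2", "p3"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 11L)
  expect_s3_class(autoplot(fit), "ggplot")
})
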