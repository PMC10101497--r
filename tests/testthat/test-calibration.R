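test_that("hormone datasets validate and carry peak-day weights", {
  data <- synthetic_cycle_data()
  expect_s3_class(data, "hormone_dataset")
  expect_equal(dim(data$obs), c(28, 5))
  ## peak-day z-score weights sit on each hormone's maximum
  for (h in c("E2", "P4", "Inh", "LH", "FSH")) {
    zw <- c(E2 = 1.58, P4 = 1.39, Inh = 1.35, LH = 2.16, FSH = 1.80)
    expect_equal(unname(data$weights[which.max(data$obs[, h]), h]),
                 unname(zw[h]))
  }
  expect_equal(sum(data$weights == 1), 28 * 5 - 5)
  bad <- data.frame(day = 1:3, E2 = c(1, -1, 1), P4 = 1, Inh = 1,
                    LH = 1, FSH = 1)
  expect_error(hormone_dataset(bad), "positive")
})

test_that("the objective is zero for self-generated data", {
  data <- generate_dataset(ref_p, ref_y0, sigma = 0)
  cost <- objective_wls(ref_p, ref_y0, data, repetitions = 1)
  expect_lt(cost, 1e-8)
})

test_that("a uniform offset on one hormone gives the closed-form cost", {
  data <- generate_dataset(ref_p, ref_y0, sigma = 0)
  shifted <- data
  shifted$obs[, "E2"] <- shifted$obs[, "E2"] * 1.1
  res <- objective_wls(ref_p, ref_y0, shifted, repetitions = 1,
                       details = TRUE)
  ## each E2 residual is (H - 1.1 H)/(1.1 H) = -0.1/1.1 with unit weight
  expected_sum <- 28 * (0.1 / 1.1)^2
  expect_equal(res$cost * res$M, expected_sum, tolerance = 1e-6)
})

test_that("the percentage-error construction is scale invariant", {
  set.seed(7)
  model <- matrix(runif(50, 1, 100), 10, 5,
                  dimnames = list(NULL, c("E2", "P4", "Inh", "LH", "FSH")))
  obs <- model * matrix(runif(50, 0.8, 1.2), 10, 5)
  w <- matrix(1, 10, 5)
  s1 <- ovucycle:::wls_sum(model, obs, w)
  ## jointly rescaling one hormone's model output and data leaves the
  ## sum unchanged
  model2 <- model; obs2 <- obs
  model2[, "P4"] <- model2[, "P4"] * 1000
  obs2[, "P4"] <- obs2[, "P4"] * 1000
  expect_equal(ovucycle:::wls_sum(model2, obs2, w), s1, tolerance = 1e-12)
})

test_that("residual sums scale with data repetition as designed", {
  ## formula level: k repetitions of identical residuals scale the
  ## weighted sum by exactly k, and the 1/(M - N) normalisation keeps
  ## the cost flat
  data <- synthetic_cycle_data()
  t2 <- ovucycle:::tile_dataset(data, 2)
  t4 <- ovucycle:::tile_dataset(data, 4)
  model2 <- t2$obs * 1.07
  model4 <- t4$obs * 1.07
  s2 <- ovucycle:::wls_sum(model2, t2$obs, t2$weights)
  s4 <- ovucycle:::wls_sum(model4, t4$obs, t4$weights)
  expect_equal(s4 / s2, 2, tolerance = 1e-12)
  expect_equal(s4 / (length(t4$obs) - 10), s2 / (length(t2$obs) - 5),
               tolerance = 0.02)
  ## model level: the simulated solution is near- but not exactly
  ## 28-day periodic, so the sum grows roughly (not exactly) linearly
  gen <- generate_dataset(ref_p, ref_y0, sigma = 0)
  gen$obs[, "LH"] <- gen$obs[, "LH"] * 1.10
  r2 <- objective_wls(ref_p, ref_y0, gen, repetitions = 2, details = TRUE)
  r4 <- objective_wls(ref_p, ref_y0, gen, repetitions = 4, details = TRUE)
  expect_equal(r4$M, 2 * r2$M)
  expect_gt(r4$cost * r4$M, r2$cost * r2$M)
  expect_lt(r4$cost, 4 * r2$cost)
})

test_that("forcing splines interpolate the data periodically", {
  data <- synthetic_cycle_data()
  f <- forcing_spline(data, "E2")
  d0 <- data$day - data$day[1]
  expect_equal(f(d0), unname(data$obs[, "E2"]), tolerance = 1e-9)
  expect_equal(f(d0 + 28), unname(data$obs[, "E2"]), tolerance = 1e-9)
  expect_equal(f(0), f(28), tolerance = 1e-9)
})

test_that("staged fit recovers perturbed parameters on clean data", {
  ## synthetic truth data; three identifiable parameters are perturbed
  ## by 20 percent and must come back within 10 percent
  data <- generate_dataset(ref_p, ref_y0, sigma = 0)
  free <- c("Km_LH", "V_FSH", "c1")
  start <- cycle_params(base = ref_p)
  start[free] <- start[free] * c(1.2, 0.8, 1.2)
  fit <- fit_staged(data, start, init_state = ref_y0, stages = "c4",
                    free = list(c4 = free), repetitions = 1,
                    maxit = 500, estimate_init = FALSE,
                    prior_penalty = 0)
  rel <- abs(fit$params[free] - ref_p[free]) / ref_p[free]
  expect_true(all(rel < 0.10))
  expect_lt(fit$cost, objective_wls(start, ref_y0, data, 1))
})

test_that("the staged fit attains near-zero cost from the truth", {
  data <- generate_dataset(ref_p, ref_y0, sigma = 0)
  fit <- fit_staged(data, ref_p, init_state = ref_y0, stages = "c4",
                    free = list(c4 = c("Km_LH", "V_FSH")),
                    repetitions = 1, maxit = 50,
                    estimate_init = FALSE, prior_penalty = 0)
  expect_lt(fit$cost, 1e-6)
  expect_s3_class(fit, "cycle_fit")
  expect_identical(names(coef(fit)), names(ref_p))
})
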