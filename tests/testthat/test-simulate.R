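test_that("a sourceless system drains", {
  ## with synthesis and recruitment off, the pituitary states and the
  ## luteal chain drain to zero and the total ovarian mass never grows
  ## (follicular masses can only freeze once LH is gone, since their
  ## outflows are LH-gated)
  p <- cycle_params(V0_LH = 1e-300, V1_LH = 1e-300, V_FSH = 1e-300,
                    b = 1e-300, c1 = 1e-300)
  sim <- simulate_cycle(p, init = ref_y0, horizon = 120)
  last <- sim$states[nrow(sim$states), ]
  pit <- c("RP_LH", "LH", "RP_FSH", "FSH")
  expect_true(all(last[pit] < 1e-3 * pmax(ref_y0[pit], 1)))
  lut <- c("Sc1", "Sc2", "Lut1", "Lut2", "Lut3", "Lut4")
  expect_true(all(last[lut] < 1e-2 * pmax(ref_y0[lut], 1)))
  total <- rowSums(sim$states[, c("RcF", "GrF", "DomF", lut)])
  expect_true(all(diff(total) < 1e-6))
})

test_that("states remain non-negative over ten cycles", {
  sim <- simulate_cycle(ref_p, init = ref_y0, horizon = 280)
  expect_gt(min(sim$states), -1e-8)
  expect_gt(min(sim$hormones), 0)
})

test_that("halving solver tolerances barely changes the solution", {
  s1 <- simulate_cycle(ref_p, init = ref_y0, horizon = 56,
                       rtol = 1e-8, atol = 1e-10)
  s2 <- simulate_cycle(ref_p, init = ref_y0, horizon = 56,
                       rtol = 5e-9, atol = 5e-11)
  rel <- abs(s2$hormones - s1$hormones) /
    rep(apply(abs(s1$hormones), 2, max), each = nrow(s1$hormones))
  expect_lt(max(rel), 1e-4)
})

test_that("the period is invariant to doubling the output grid", {
  s1 <- simulate_cycle(ref_p, init = ref_y0, horizon = 112, dt = 0.1)
  s2 <- simulate_cycle(ref_p, init = ref_y0, horizon = 112, dt = 0.05)
  p1 <- cycle_metrics(s1)$period
  p2 <- cycle_metrics(s2)$period
  expect_lt(abs(p2 - p1) / p1, 0.001)
})

test_that("hormone series are consistent with the auxiliary map", {
  sim <- ref_sim()
  i <- c(10, 200, 700)
  st <- pmax(sim$states[i, ], 0)
  h <- auxiliary_hormones(st, c(0, 0), ref_p)
  expect_equal(unname(sim$hormones[i, c("E2", "P4", "Inh")]), unname(h),
               tolerance = 1e-10)
})

test_that("normal-cycle peak phase ordering holds", {
  ## E2 and LH peak in the late follicular phase before the luteal P4
  ## and Inh maxima, within each settled cycle
  m <- cycle_metrics(ref_sim(), settle_cycles = 1,
                     window = c(28, 56))
  expect_lt(m$peak_times[["E2"]], m$peak_times[["P4"]])
  expect_lt(m$peak_times[["LH"]], m$peak_times[["P4"]])
  expect_lt(m$peak_times[["LH"]], m$peak_times[["Inh"]])
})

test_that("simulation rejects invalid input", {
  expect_error(simulate_cycle(ref_p, init = ref_y0[-1], horizon = 28),
               "13 states")
  expect_error(simulate_cycle(ref_p, init = ref_y0, horizon = 0.1),
               "tau")
})

test_that("the reference cycle is periodic and locally stable", {
  vp <- verify_periodicity(ref_p, ref_y0, n_cycles = 8)
  expect_true(vp$is_periodic)
  ## a 10 percent perturbation of the history returns to the same orbit
  y2 <- ref_y0 * 1.1
  vp2 <- verify_periodicity(ref_p, y2, n_cycles = 8)
  expect_true(vp2$is_periodic)
  expect_equal(vp2$period, vp$period, tolerance = 0.01)
  ## a sourceless system is not periodic
  p0 <- cycle_params(V0_LH = 1e-300, V1_LH = 1e-300, V_FSH = 1e-300,
                     b = 1e-300, c1 = 1e-300)
  vp3 <- verify_periodicity(p0, ref_y0, n_cycles = 4)
  expect_false(vp3$is_periodic)
})
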