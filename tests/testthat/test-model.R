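test_that("auxiliary hormones are the stated linear combinations", {
  p <- ref_p
  z <- const_state(0)
  ## baseline offsets with all masses zero
  h <- auxiliary_hormones(z, c(0, 0), p)
  expect_equal(unname(h), unname(p[c("e0", "p0", "h0")]),
               tolerance = 1e-14)
  ## exogenous input is additive through b1, b2
  h2 <- auxiliary_hormones(z, c(20, 1.4), p)
  expect_equal(h2[["E2"]], p[["e0"]] + p[["b1"]] * 20)
  expect_equal(h2[["P4"]], p[["p0"]] + p[["b2"]] * 1.4)
  expect_equal(h2[["Inh"]], h[["Inh"]])
  ## independent hand evaluation of the three linear combinations at the
  ## reference initial state (explicit sums of products, no shared code)
  y <- ref_y0
  e_hand <- p[["e0"]] + p[["e1"]] * y[["GrF"]] + p[["e2"]] * y[["DomF"]] +
    p[["e3"]] * y[["Lut4"]]
  p_hand <- p[["p0"]] + p[["p1"]] * y[["Lut3"]] + p[["p2"]] * y[["Lut4"]]
  i_hand <- p[["h0"]] + p[["h1"]] * y[["DomF"]] + p[["h2"]] * y[["Lut2"]] +
    p[["h3"]] * y[["Lut3"]]
  h3 <- auxiliary_hormones(y, c(0, 0), p)
  expect_equal(unname(h3), c(e_hand, p_hand, i_hand), tolerance = 1e-12)
  ## negative state is rejected
  bad <- y; bad[["GrF"]] <- -1
  expect_error(auxiliary_hormones(bad, c(0, 0), p), "non-negative")
})

test_that("exogenous partial derivatives equal b1 and b2 exactly", {
  p <- cycle_params(b1 = 0.6, b2 = 2.5)
  y <- ref_y0
  d <- 1e-3
  h0 <- auxiliary_hormones(y, c(10, 1), p)
  h1 <- auxiliary_hormones(y, c(10 + d, 1), p)
  h2 <- auxiliary_hormones(y, c(10, 1 + d), p)
  expect_equal((h1[["E2"]] - h0[["E2"]]) / d, 0.6, tolerance = 1e-9)
  expect_equal((h2[["P4"]] - h0[["P4"]]) / d, 2.5, tolerance = 1e-9)
})

test_that("rhs has no sources when synthesis and recruitment are off", {
  p <- cycle_params(V0_LH = 1e-300, V1_LH = 1e-300, V_FSH = 1e-300,
                    b = 1e-300, c1 = 1e-300, e0 = 0, p0 = 0, h0 = 0)
  d <- cycle_rhs(0, const_state(0), delayed_inh = 0,
                 dose = dose_schedule(), params = p)
  expect_equal(unname(d), rep(0, 13), tolerance = 1e-290)
})

test_that("strong progesterone shuts down FSH synthesis and recruitment", {
  p <- cycle_params(w = 2, q = 2)
  y <- ref_y0
  base <- cycle_rhs(0, y, delayed_inh = 2, dose = dose_schedule(),
                    params = p)
  ## huge exogenous P4 makes P4/w and P4/q dominate
  dP <- dose_schedule(p4exo = 1e9)
  lim <- cycle_rhs(0, y, delayed_inh = 2, dose = dP, params = p)
  ## FSH synthesis term -> 0: RP_FSH derivative becomes pure release
  rel_FSH <- p[["k_FSH"]] * (1 + p[["c_FSH_P"]] *
                               auxiliary_hormones(y, c(0, 1e9), p)[["P4"]]) *
    y[["RP_FSH"]] / (1 + p[["c_FSH_E"]] *
                       auxiliary_hormones(y, c(0, 1e9), p)[["E2"]])^2
  expect_equal(lim[["RP_FSH"]], -rel_FSH, tolerance = 1e-6)
  ## recruitment term -> 0: RcF derivative becomes pure outflow
  out_RcF <- -p[["c2"]] * y[["LH"]]^p[["alpha"]] * y[["RcF"]]
  expect_equal(lim[["RcF"]], out_RcF, tolerance = 1e-6)
  ## while at baseline both terms are positive contributions
  expect_gt(base[["RcF"]], lim[["RcF"]])
})

test_that("ovarian mass chain is conservative between stages", {
  p <- ref_p
  set.seed(42)
  for (i in 1:20) {
    y <- const_state(0)
    y[] <- runif(13, 0, 50)
    d <- cycle_rhs(0, y, delayed_inh = runif(1, 0, 10),
                   dose = dose_schedule(), params = p)
    recr <- (p[["b"]] + p[["c1"]] * y[["RcF"]]) * y[["FSH"]] /
      (1 + auxiliary_hormones(y, c(0, 0), p)[["P4"]] / p[["q"]])
    ovarian <- sum(d[c("RcF", "GrF", "DomF", "Sc1", "Sc2",
                       "Lut1", "Lut2", "Lut3", "Lut4")])
    expect_equal(ovarian, recr - p[["k4"]] * y[["Lut4"]],
                 tolerance = 1e-10)
  }
})

test_that("disabling the w and q terms recovers the unmodified model", {
  ## with w, q -> infinity and zero dose the added inhibition terms
  ## vanish: derivatives match a transcription without those terms
  p_off <- cycle_params(w = 1e15, q = 1e15)
  y <- ref_y0
  d <- cycle_rhs(3, y, delayed_inh = 2.5, dose = dose_schedule(),
                 params = p_off)
  h <- auxiliary_hormones(y, c(0, 0), p_off)
  syn_FSH_unmod <- p_off[["V_FSH"]] / (1 + 2.5 / p_off[["Ki_FSH_Inh"]])
  rel_FSH <- p_off[["k_FSH"]] * (1 + p_off[["c_FSH_P"]] * h[["P4"]]) *
    y[["RP_FSH"]] / (1 + p_off[["c_FSH_E"]] * h[["E2"]])^2
  expect_equal(d[["RP_FSH"]], syn_FSH_unmod - rel_FSH, tolerance = 1e-9)
  recr_unmod <- (p_off[["b"]] + p_off[["c1"]] * y[["RcF"]]) * y[["FSH"]]
  f12 <- p_off[["c2"]] * y[["LH"]]^p_off[["alpha"]] * y[["RcF"]]
  expect_equal(d[["RcF"]], recr_unmod - f12, tolerance = 1e-9)
})

test_that("compiled and reference right-hand sides integrate identically", {
  ## dual-transcription cross-check: the C and R implementations of the
  ## same equations must agree far below solver error
  ds <- dose_schedule(e2exo = 5, p4exo = 0.5)
  sC <- simulate_cycle(ref_p, dose = ds, init = ref_y0, horizon = 20,
                       engine = "C", rtol = 1e-10, atol = 1e-12)
  sR <- simulate_cycle(ref_p, dose = ds, init = ref_y0, horizon = 20,
                       engine = "R", rtol = 1e-10, atol = 1e-12)
  scale <- apply(abs(sC$states), 2, max)
  err <- max(abs(sC$states - sR$states) / rep(scale, each = nrow(sC$states)))
  expect_lt(err, 1e-7)
})

test_that("rhs rejects non-finite input", {
  y <- ref_y0; y[["LH"]] <- NaN
  expect_error(cycle_rhs(0, y, 1, dose_schedule(), ref_p), "non-finite")
  expect_error(cycle_rhs(0, ref_y0, Inf, dose_schedule(), ref_p),
               "non-finite")
})
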