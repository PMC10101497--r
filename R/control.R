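## Optimal time-varying dosing by control parameterization: node values
## of the exogenous controls joined by a shape-preserving piecewise
## cubic, optimised under non-negativity bounds against the dosing
## objective.

#' Define an optimal dosing problem
#'
#' The objective functional minimised over controls
#' \eqn{u_1(t) = E_{2,exo}(t)} and \eqn{u_2(t) = P_{4,exo}(t)} is
#' \deqn{J(u) = \int_{t_0}^{t_f} (P_4(t) - P_0)^2 + a_1 u_1(t)
#'   + a_2 u_2(t)^4 \, dt,}
#' which trades off tracking a sub-anovulation-threshold progesterone
#' target \eqn{P_0} against total administered dose.  The fourth power
#' on \eqn{u_2} adds convexity and smooths the optimised progesterone
#' control.
#'
#' @param case \code{"estrogen"} (u2 = 0), \code{"progesterone"}
#'   (u1 = 0) or \code{"combination"}.
#' @param P0 target P4 level (ng/mL), below the 5 ng/mL anovulation
#'   threshold; default 4.
#' @param a1 weight on the linear u1 term (numerically as conventionally
#'   printed in micrograms/mL; the u1 integrand is evaluated on the
#'   pg/mL scale).  Default 0.4 for the estrogen and combination cases.
#' @param a2 weight on the quartic u2 term (mL^2/ng^2); default 0.07
#'   for progesterone monotherapy, 0.7 in combination.
#' @param t0,tf treatment horizon (days), default one 28-day cycle.
#' @param n_nodes number of equally spaced control nodes (default 29,
#'   daily over the cycle).
#' @param u1_exponent,u2_exponent integrand powers on the controls
#'   (defaults 1 and 4).
#' @return object of class \code{"oc_problem"}.
#' @export
oc_problem <- function(case = c("estrogen", "progesterone", "combination"),
                       P0 = 4, a1 = NULL, a2 = NULL, t0 = 0, tf = 28,
                       n_nodes = 29, u1_exponent = 1, u2_exponent = 4) {
  case <- match.arg(case)
  if (is.null(a1)) a1 <- if (case == "progesterone") 0 else 0.4
  if (is.null(a2)) a2 <- switch(case, estrogen = 0, progesterone = 0.07,
                                combination = 0.7)
  stopifnot(P0 < 5, tf > t0, n_nodes >= 2, a1 >= 0, a2 >= 0)
  structure(list(case = case, P0 = P0, a1 = a1, a2 = a2, t0 = t0,
                 tf = tf, node_times = seq(t0, tf, length.out = n_nodes),
                 u1_exponent = u1_exponent, u2_exponent = u2_exponent),
            class = "oc_problem")
}

#' Dosing objective functional
#'
#' Composite-trapezoid quadrature of the integrand
#' \eqn{(P_4 - P_0)^2 + a_1 u_1^{e_1} + a_2 u_2^{e_2}} on the dense
#' simulation grid.
#'
#' @param sim a [simulate_cycle()] result simulated under the controls.
#' @param u1,u2 control functions of time (pg/mL and ng/mL).
#' @param prob an [oc_problem()].
#' @return the objective value (scalar).
#' @export
objective_J <- function(sim, u1, u2, prob) {
  keep <- sim$times >= prob$t0 & sim$times <= prob$tf
  tt <- sim$times[keep]
  P4 <- sim$hormones[keep, "P4"]
  integrand <- (P4 - prob$P0)^2 +
    prob$a1 * u1(tt)^prob$u1_exponent +
    prob$a2 * u2(tt)^prob$u2_exponent
  pracma::trapz(tt, integrand)
}

## node values -> dose schedule for the case
nodes_to_dose <- function(x, prob) {
  nt <- prob$node_times
  n <- length(nt)
  if (prob$case == "estrogen") {
    dose_schedule(e2exo = cbind(nt, pmax(x, 0)))
  } else if (prob$case == "progesterone") {
    dose_schedule(p4exo = cbind(nt, pmax(x, 0)))
  } else {
    dose_schedule(e2exo = cbind(nt, pmax(x[1:n], 0)),
                  p4exo = cbind(nt, pmax(x[n + 1:n], 0)))
  }
}

## objective as a function of the node vector
oc_cost <- function(x, prob, params, init) {
  ds <- nodes_to_dose(x, prob)
  sim <- tryCatch(
    simulate_cycle(params, dose = ds, init = init, horizon = prob$tf,
                   t0 = prob$t0),
    error = function(e) NULL)
  if (is.null(sim)) return(1e10)
  objective_J(sim, ds$e2, ds$p4, prob)
}

#' Solve the optimal dosing problem
#'
#' Control parameterization: the node values of the piecewise-cubic
#' control(s) are optimised by bound-constrained quasi-Newton search
#' (\code{optim} L-BFGS-B, finite-difference gradients, lower bound 0)
#' from several starting guesses; the best local solution is returned.
#' Default starts are zero controls, a constant profile at the
#' anovulation-threshold level, and half that level.
#'
#' @param prob an [oc_problem()].
#' @param params,init model parameters and initial (cycle-start) state.
#' @param init_nodes optional list of starting node-value vectors
#'   overriding the default multi-start set.
#' @param const_level constant-start level(s); defaults are nominal
#'   mid-scan doses (35 pg/mL for u1, 3.1 ng/mL for u2).  Supplying the
#'   parameter set's own constant anovulation threshold (from
#'   [min_constant_dose()]) usually gives the best start.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param factr L-BFGS-B convergence tolerance (see [stats::optim()]).
#' @return object of class \code{"oc_solution"}: list with \code{nodes},
#'   \code{dose} (the [dose_schedule()]), \code{objective}, \code{sim},
#'   \code{metrics} (over the horizon), \code{auc} (per-control total
#'   dose), \code{feasible} (max P4 < 5 and no surge), \code{prob},
#'   \code{starts} diagnostics.
#' @export
solve_oc <- function(prob, params = ref_params(), init = ref_init(),
                     init_nodes = NULL, const_level = NULL,
                     maxit = 60, factr = 1e10) {
  n <- length(prob$node_times)
  dim <- if (prob$case == "combination") 2L * n else n
  if (is.null(const_level))
    const_level <- switch(prob$case,
                          estrogen = 35, progesterone = 3.1,
                          combination = c(20, 1.4))
  starts <- init_nodes
  if (is.null(starts)) {
    mk <- function(lv) {
      if (prob$case == "combination")
        c(rep(lv[1], n), rep(lv[2], n))
      else rep(lv[1], n)
    }
    starts <- list(rep(0, dim), mk(const_level), mk(const_level / 2))
  }
  runs <- lapply(starts, function(x0) {
    stats::optim(x0, oc_cost, prob = prob, params = params, init = init,
                 method = "L-BFGS-B", lower = rep(0, dim),
                 control = list(maxit = maxit, factr = factr,
                                ndeps = rep(0.05, dim)))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  ds <- nodes_to_dose(best$par, prob)
  sim <- simulate_cycle(params, dose = ds, init = init,
                        horizon = prob$tf, t0 = prob$t0)
  met <- cycle_metrics(sim, window = c(prob$t0, prob$tf))
  structure(list(nodes = best$par, node_times = prob$node_times,
                 dose = ds, objective = best$value, sim = sim,
                 metrics = met,
                 auc = dose_auc(ds, prob$t0, prob$tf),
                 feasible = isTRUE(met$anovulatory),
                 prob = prob,
                 starts = data.frame(value = vals,
                                     convergence = vapply(runs, `[[`,
                                                          numeric(1),
                                                          "convergence"))),
            class = "oc_solution")
}

#' @export
print.oc_solution <- function(x, ...) {
  cat("optimal dosing solution (", x$prob$case, " case)\n", sep = "")
  cat(sprintf("  objective J = %.4g over [%g, %g] days\n",
              x$objective, x$prob$t0, x$prob$tf))
  cat(sprintf("  max P4 = %.3g ng/mL; anovulatory: %s\n",
              x$metrics$peaks[["P4"]], x$feasible))
  cat(sprintf("  total dose (AUC): u1 = %.3g pg/mL, u2 = %.3g ng/mL\n",
              x$auc[["e2exo"]], x$auc[["p4exo"]]))
  invisible(x)
}

#' @export
plot.oc_solution <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  tt <- x$sim$times
  graphics::plot(tt, x$dose$e2(tt), type = "l", ylab = "u1 (pg/mL)",
                 xlab = "", ...)
  graphics::plot(tt, x$dose$p4(tt), type = "l", ylab = "u2 (ng/mL)",
                 xlab = "", ...)
  graphics::plot(tt, x$sim$hormones[, "P4"], type = "l",
                 ylab = "P4 (ng/mL)", xlab = "days", ...)
  graphics::abline(h = 5, lty = 2)
  invisible(x)
}

#' Dose savings of the optimal schedule versus constant dosing
#'
#' For monotherapy, compares the optimised control's total dose (AUC)
#' with the minimum anovulatory constant total over the same horizon:
#' \code{100 (constant_total - AUC) / constant_total} percent saved.
#' For combination therapy, performs the two cross-comparisons: each
#' control's AUC is spread constantly over the horizon, the partner
#' hormone's minimal constant co-dose achieving anovulation is found,
#' and the optimised AUC is compared with that constant requirement.
#'
#' @param oc an [solve_oc()] solution.
#' @param params,init model parameters and initial state.
#' @param resolution bisection resolution for constant-dose thresholds.
#' @return for monotherapy a list with \code{constant_total},
#'   \code{auc}, \code{saved_percent}; for combination a list with the
#'   two cross-comparisons (\code{estrogen}, \code{progesterone}).
#' @export
dose_savings <- function(oc, params = ref_params(), init = ref_init(),
                         resolution = 0.01) {
  horizon <- oc$prob$tf - oc$prob$t0
  if (oc$prob$case != "combination") {
    hormone <- if (oc$prob$case == "estrogen") "estrogen" else "progesterone"
    mc <- min_constant_dose(hormone, params, init, resolution)
    auc <- if (hormone == "estrogen") oc$auc[["e2exo"]] else oc$auc[["p4exo"]]
    return(list(case = oc$prob$case, constant_total = mc$total, auc = auc,
                saved_percent = 100 * (mc$total - auc) / mc$total))
  }
  ## combination: cross-comparisons against the contour of constant
  ## co-doses
  min_partner <- function(fixed, vary) {
    anov <- function(d) {
      ds <- if (vary == "estrogen")
        dose_schedule(e2exo = d, p4exo = fixed)
      else dose_schedule(e2exo = fixed, p4exo = d)
      sim <- simulate_cycle(params, dose = ds, init = init, horizon = 28)
      isTRUE(cycle_metrics(sim, window = c(0, 28))$anovulatory)
    }
    hi <- if (vary == "estrogen") 60 else 4
    if (!anov(hi)) return(NA_real_)
    lo <- 0
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (anov(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  p4_const <- oc$auc[["p4exo"]] / horizon
  e2_need <- min_partner(p4_const, "estrogen")
  e2_const <- oc$auc[["e2exo"]] / horizon
  p4_need <- min_partner(e2_const, "progesterone")
  list(case = "combination",
       estrogen = list(partner_constant = p4_const,
                       constant_total = e2_need * horizon,
                       auc = oc$auc[["e2exo"]],
                       saved_percent =
                         100 * (e2_need * horizon - oc$auc[["e2exo"]]) /
                           (e2_need * horizon)),
       progesterone = list(partner_constant = e2_const,
                           constant_total = p4_need * horizon,
                           auc = oc$auc[["p4exo"]],
                           saved_percent =
                             100 * (p4_need * horizon - oc$auc[["p4exo"]]) /
                               (p4_need * horizon)))
}

#' Multi-cycle re-application of an optimised estrogen dose
#'
#' Identifies the contiguous "large-dose portion" of the optimised u1
#' profile (where u1 exceeds \code{portion_frac} of its peak) and
#' re-applies it over a long horizon, either at fixed equal intervals or
#' triggered whenever the E2 level crosses \code{trigger_E2} from below
#' (a biomarker-triggered regimen).  Returns the long trajectory, the
#' application start times, and per-28-day-period anovulation flags.
#'
#' @param oc an [solve_oc()] solution (estrogen or combination case;
#'   u1 is re-applied).
#' @param params,init model parameters and initial state.
#' @param horizon total days (default 280).
#' @param mode \code{"triggered"} (default) or \code{"fixed"}.
#' @param trigger_E2 E2 trigger level (pg/mL, default 75).
#' @param first_day first application start for \code{mode = "fixed"}
#'   (default 35) -- applications repeat every \code{interval} days.
#' @param interval spacing for \code{mode = "fixed"} (default 28).
#' @param portion_frac fraction of the u1 peak defining the large-dose
#'   portion (default 0.1).
#' @param refractory minimum days between triggered application starts
#'   (default 14).
#' @return object of class \code{"redose_result"}: list with \code{sim},
#'   \code{events} (application start times), \code{portion} (template
#'   support length, days), \code{periods} data.frame (28-day period,
#'   max P4, LH surge, anovulatory).
#' @export
multi_cycle_redose <- function(oc, params = ref_params(), init = ref_init(),
                               horizon = 280,
                               mode = c("triggered", "fixed"),
                               trigger_E2 = 75, first_day = 35,
                               interval = 28, portion_frac = 0.1,
                               refractory = 14) {
  mode <- match.arg(mode)
  tt <- seq(oc$prob$t0, oc$prob$tf, by = 0.05)
  u1 <- oc$dose$e2(tt)
  if (max(u1) <= 0) stop("the solution has no estrogen control to re-apply")
  big <- which(u1 > portion_frac * max(u1))
  i0 <- big[1]; i1 <- big[length(big)]
  t_on <- tt[i0]; t_off <- tt[i1]
  L <- t_off - t_on
  tpl <- function(s) {  # template on [0, L]
    out <- numeric(length(s))
    ok <- s >= 0 & s <= L
    out[ok] <- oc$dose$e2(t_on + s[ok])
    out
  }
  make_dose <- function(events) {
    force(events)
    dose_schedule(e2exo = function(t)
      Reduce(`+`, lapply(events, function(ev) tpl(t - ev)),
             accumulate = FALSE, init = numeric(length(t))))
  }
  simulate_under <- function(events) {
    simulate_cycle(params, dose = make_dose(events), init = init,
                   horizon = horizon)
  }
  if (mode == "fixed") {
    events <- seq(first_day, horizon - L, by = interval)
    ## the first treated cycle keeps the original full optimised profile
    events <- c(t_on, events)
    sim <- simulate_under(events)
  } else {
    ## iterative event construction: re-simulate after each added
    ## application until no further up-crossing of the trigger occurs
    events <- c(t_on)
    repeat {
      sim <- simulate_under(events)
      E2 <- sim$hormones[, "E2"]
      ts <- sim$times
      up <- which(E2[-1] >= trigger_E2 & E2[-length(E2)] < trigger_E2) + 1L
      cand <- ts[up]
      cand <- cand[cand > max(events) + refractory &
                     cand <= horizon - 1]
      if (!length(cand)) break
      events <- c(events, cand[1])
    }
  }
  brk <- seq(0, horizon, by = 28)
  periods <- lapply(seq_len(length(brk) - 1), function(i) {
    m <- cycle_metrics(sim, window = c(brk[i], brk[i + 1]))
    data.frame(period = i, t_start = brk[i], P4_max = m$peaks[["P4"]],
               lh_surge = m$lh_surge, anovulatory = m$anovulatory)
  })
  structure(list(sim = sim, events = events, portion = L,
                 template_start = t_on, mode = mode,
                 trigger_E2 = if (mode == "triggered") trigger_E2 else NA,
                 periods = do.call(rbind, periods)),
            class = "redose_result")
}

#' @export
print.redose_result <- function(x, ...) {
  cat("multi-cycle re-dosing (", x$mode, " mode): ",
      length(x$events), " applications over ",
      max(x$sim$times), " days\n", sep = "")
  cat("  anovulatory periods:", sum(x$periods$anovulatory), "of",
      nrow(x$periods), "\n")
  invisible(x)
}
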