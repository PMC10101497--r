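## Staged weighted least-squares calibration of the cycle model against
## a 28-day daily hormone table.

.hormones <- c("E2", "P4", "Inh", "LH", "FSH")

#' Construct a daily hormone dataset
#'
#' Wraps a 28-day (or longer) daily table of observed E2 (pg/mL), P4
#' (ng/mL), Inh (IU/mL), LH (IU/L) and FSH (IU/L) concentrations for use
#' in calibration.  Per-point weights default to 1; by convention the
#' peak-day observation of each hormone may be up-weighted by its
#' z-score so the fit is pulled toward the hormone maxima.
#'
#' @param df data.frame with columns \code{day}, \code{E2}, \code{P4},
#'   \code{Inh}, \code{LH}, \code{FSH}; all observations positive.
#' @param weights optional matrix/data.frame of the same shape as the
#'   five hormone columns giving per-point weights.
#' @param peak_weights if \code{TRUE} (default) and \code{weights} is
#'   NULL, apply the standard peak-day weights: each hormone's maximum
#'   observation is weighted by \code{c(E2 = 1.58, P4 = 1.39,
#'   Inh = 1.35, LH = 2.16, FSH = 1.80)}.
#' @return object of class \code{"hormone_dataset"}.
#' @export
hormone_dataset <- function(df, weights = NULL, peak_weights = TRUE) {
  need <- c("day", .hormones)
  if (!all(need %in% names(df)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$day), need]
  obs <- as.matrix(df[, .hormones])
  if (any(!is.finite(obs)) || any(obs <= 0))
    stop("all hormone observations must be positive and finite")
  if (is.null(weights)) {
    W <- matrix(1, nrow(obs), 5, dimnames = list(NULL, .hormones))
    if (peak_weights) {
      zw <- c(E2 = 1.58, P4 = 1.39, Inh = 1.35, LH = 2.16, FSH = 1.80)
      for (h in .hormones) W[which.max(obs[, h]), h] <- zw[[h]]
    }
  } else {
    W <- as.matrix(weights)
    if (!all(dim(W) == dim(obs)))
      stop("weights must match the 5 hormone columns row for row")
    colnames(W) <- .hormones
  }
  structure(list(day = df$day, obs = obs, weights = W),
            class = "hormone_dataset")
}

#' Read a hormone dataset from CSV
#'
#' @param path CSV with columns \code{day,E2,P4,Inh,LH,FSH}.
#' @param weights_path optional sidecar CSV of identical layout holding
#'   per-point weights.
#' @param ... passed to [hormone_dataset()].
#' @export
read_hormone_data <- function(path, weights_path = NULL, ...) {
  df <- read.csv(path)
  W <- NULL
  if (!is.null(weights_path)) {
    wdf <- read.csv(weights_path)
    W <- as.matrix(wdf[, .hormones])
  }
  hormone_dataset(df, weights = W, ...)
}

#' The packaged synthetic 28-day hormone table
#'
#' Daily synthetic means over a standardized 28-day cycle, constructed
#' to emulate the published normal-cycle profile shape: E2, LH and FSH
#' peak in the late follicular phase (days 13-14), P4 and inhibin peak
#' in the luteal phase (days 20-21).  This table is a synthetic stand-in
#' for group-mean clinical data and is the dataset against which the
#' reference parameter set was calibrated.
#'
#' @return a [hormone_dataset()].
#' @export
synthetic_cycle_data <- function() {
  f <- system.file("extdata", "hormone_data_synthetic.csv",
                   package = "ovucycle")
  read_hormone_data(f)
}

## Repeat a 28-day dataset k times; model time for data row i of
## repetition r is (day_i - day_1) + 28 (r - 1).
tile_dataset <- function(data, repetitions = 4) {
  d0 <- data$day - data$day[1]
  list(times = rep(d0, repetitions) + 28 * rep(seq_len(repetitions) - 1,
                                               each = length(d0)),
       obs = do.call(rbind, replicate(repetitions, data$obs,
                                      simplify = FALSE)),
       weights = do.call(rbind, replicate(repetitions, data$weights,
                                          simplify = FALSE)))
}

## Weighted percentage-error sum over an observation matrix.
wls_sum <- function(model, obs, weights) {
  sum(weights * ((model - obs) / obs)^2)
}

#' Weighted least-squares calibration objective
#'
#' The dimensionless cost
#' \deqn{\frac{1}{M-N}\sum_i \sum_H w_{H^*}(i)\,
#'   \left(\frac{H(i)-H^*(i)}{H^*(i)}\right)^2}
#' where \eqn{H(i)} is the model output sampled at the data's day grid,
#' the data are repeated \code{repetitions} times (so a periodic
#' solution is favoured), \eqn{M} is the number of residuals and
#' \eqn{N = } \code{n_free} the number of free parameters plus initial
#' conditions.  Division by the observation makes each residual a
#' percentage error, so hormones with different units are commensurate.
#'
#' @param params a [cycle_params()] vector.
#' @param init_state initial 13-state vector.
#' @param data a [hormone_dataset()].
#' @param repetitions number of 28-day repetitions (default 4).
#' @param n_free the \eqn{N} bookkeeping term (default 0).
#' @param details if TRUE, return a list with the cost, per-hormone sums
#'   of squared residuals on the natural scale (the standard diagnostic
#'   table), M and N.
#' @param settle number of 28-day cycles simulated and discarded before
#'   the data grid is aligned, so the comparison probes the settled
#'   (periodic) solution rather than the transient; default 0.
#' @param peak_targets optional named vector of target continuous peak
#'   values (any subset of E2, P4, Inh, LH, FSH).  Daily sampling cannot
#'   see the height of the narrow LH surge, so matching the observed
#'   maxima requires pulling the continuous trajectory peaks toward
#'   targets; this term is the reproducible counterpart of the manual
#'   peak adjustment that typically follows automated fits.
#' @param peak_weight weight of the peak-target penalty (default 20).
#' @param ... passed to [simulate_cycle()].
#' @return the cost (or list if \code{details}).  Simulation failure is
#'   penalised with \code{Inf}.
#' @export
objective_wls <- function(params, init_state, data, repetitions = 4,
                          n_free = 0, details = FALSE, settle = 0,
                          peak_targets = NULL, peak_weight = 20, ...) {
  td <- tile_dataset(data, repetitions)
  M <- length(td$obs)
  if (M <= n_free) stop("M must exceed N = n_free")
  offset <- 28 * settle
  sim <- tryCatch(
    simulate_cycle(params, init = init_state,
                   horizon = offset + max(td$times) + 1e-8, ...),
    error = function(e) e)
  if (inherits(sim, "error")) {
    if (!details) return(Inf)
    return(list(cost = Inf, ssr = setNames(rep(NA_real_, 5), .hormones),
                M = M, N = n_free, error = conditionMessage(sim)))
  }
  H <- sample_hormones(sim, offset + td$times)[, .hormones]
  cost <- wls_sum(H, td$obs, td$weights) / (M - n_free)
  if (!is.null(peak_targets)) {
    keep <- sim$times >= offset
    pk <- apply(sim$hormones[keep, names(peak_targets), drop = FALSE],
                2, max)
    cost <- cost +
      peak_weight * sum(((pk - peak_targets) / peak_targets)^2)
  }
  if (!details) return(cost)
  ssr <- setNames(colSums((H - td$obs)^2), .hormones)
  list(cost = cost, ssr = ssr, M = M, N = n_free)
}

## ---- forcing interpolants -------------------------------------------

#' Periodic cubic-spline forcing of a 28-day hormone series
#'
#' Returns a function of model time t that interpolates one hormone's
#' daily data periodically with period 28 days, used to force the
#' pituitary and ovarian submodels during staged calibration.
#'
#' @param data a [hormone_dataset()].
#' @param hormone one of "E2","P4","Inh","LH","FSH".
#' @export
forcing_spline <- function(data, hormone) {
  d0 <- data$day - data$day[1]
  x <- c(d0, 28)
  y <- c(data$obs[, hormone], data$obs[1, hormone])
  f <- splinefun(x, y, method = "periodic")
  function(t) f(t %% 28)
}

## ---- forced submodels ----------------------------------------------

## Pituitary submodel: (RP_LH, LH, RP_FSH, FSH) with E2, P4, Inh(t)
## forced by data splines.  The inhibin delay becomes a time shift of a
## known forcing, so this is a plain ODE.  `use_w` disables/enables the
## P4/w synthesis-inhibition term.
simulate_pituitary_forced <- function(params, init4, forc, times,
                                      use_w = FALSE,
                                      rtol = 1e-8, atol = 1e-10) {
  p <- params
  rhs <- function(t, y, parms) {
    E2 <- forc$E2(t); P4 <- forc$P4(t)
    InhLag <- forc$Inh(t - p[["tau"]])
    y <- pmax(y, 0)
    hill <- (E2 / p[["Km_LH"]])^8
    hill <- hill / (1 + hill)
    syn_LH <- (p[["V0_LH"]] + p[["V1_LH"]] * hill) / (1 + P4 / p[["Ki_LH_P"]])
    rel_LH <- p[["k_LH"]] * (1 + p[["c_LH_P"]] * P4) * y[1] /
      (1 + p[["c_LH_E"]] * E2)
    wden <- if (use_w) P4 / p[["w"]] else 0
    syn_FSH <- p[["V_FSH"]] / (1 + InhLag / p[["Ki_FSH_Inh"]] + wden)
    rel_FSH <- p[["k_FSH"]] * (1 + p[["c_FSH_P"]] * P4) * y[3] /
      (1 + p[["c_FSH_E"]] * E2)^2
    list(c(syn_LH - rel_LH,
           rel_LH / p[["v"]] - p[["alpha_LH"]] * y[2],
           syn_FSH - rel_FSH,
           rel_FSH / p[["v"]] - p[["alpha_FSH"]] * y[4]))
  }
  deSolve::ode(y = init4, times = times, func = rhs, parms = NULL,
               rtol = rtol, atol = atol)
}

## Ovarian submodel: the nine stage masses with LH(t), FSH(t) forced by
## data splines.  `use_q` enables the P4/q recruitment inhibition (then
## P4 feeds back through the secretion coefficients).
simulate_ovarian_forced <- function(params, init9, forc, times,
                                    use_q = FALSE,
                                    rtol = 1e-8, atol = 1e-10) {
  p <- params
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    LH <- forc$LH(t); FSH <- forc$FSH(t)
    P4 <- p[["p0"]] + p[["p1"]] * y[7] + p[["p2"]] * y[8]
    qden <- if (use_q) 1 + P4 / p[["q"]] else 1
    recr <- (p[["b"]] + p[["c1"]] * y[1]) * FSH / qden
    f12 <- p[["c2"]] * LH^p[["alpha"]] * y[1]
    f23 <- p[["c3"]] * LH * y[2]
    f34 <- p[["c4"]] * LH^p[["gamma"]] * y[3]
    list(c(recr - f12, f12 - f23, f23 - f34,
           f34 - p[["d1"]] * y[4],
           p[["d1"]] * y[4] - p[["d2"]] * y[5],
           p[["d2"]] * y[5] - p[["k1"]] * y[6],
           p[["k1"]] * y[6] - p[["k2"]] * y[7],
           p[["k2"]] * y[7] - p[["k3"]] * y[8],
           p[["k3"]] * y[8] - p[["k4"]] * y[9]))
  }
  deSolve::ode(y = init9, times = times, func = rhs, parms = NULL,
               rtol = rtol, atol = atol)
}

## Weighted non-negative least squares for the secretion coefficients
## given simulated stage masses at the observation times.  Each
## hormone's coefficients solve an independent linear problem on the
## percentage-error scale.
fit_secretion <- function(masses, obs, weights) {
  sw <- sqrt(weights)
  solve1 <- function(basis, h) {
    A <- basis * (sw[, h] / obs[, h])
    y <- sw[, h]
    pracma::lsqnonneg(A, y)$x
  }
  eb <- cbind(1, masses[, "GrF"], masses[, "DomF"], masses[, "Lut4"])
  pb <- cbind(1, masses[, "Lut3"], masses[, "Lut4"])
  hb <- cbind(1, masses[, "DomF"], masses[, "Lut2"], masses[, "Lut3"])
  e <- solve1(eb, "E2"); p <- solve1(pb, "P4"); h <- solve1(hb, "Inh")
  c(e0 = e[1], e1 = e[2], e2 = e[3], e3 = e[4],
    p0 = p[1], p1 = p[2], p2 = p[3],
    h0 = h[1], h1 = h[2], h2 = h[3], h3 = h[4])
}

## ---- staged fitting --------------------------------------------------

.default_free <- list(
  c1 = c("V0_LH", "V1_LH", "Km_LH", "Ki_LH_P", "k_LH", "c_LH_P", "c_LH_E",
         "alpha_LH", "V_FSH", "Ki_FSH_Inh", "tau", "k_FSH", "c_FSH_P",
         "c_FSH_E", "alpha_FSH"),
  c2 = c("b", "c1", "c2", "c3", "c4", "d1", "d2", "k1", "k2", "k3", "k4",
         "alpha", "gamma"),
  c3 = c("V0_LH", "V1_LH", "Km_LH", "V_FSH", "Ki_FSH_Inh", "b", "c1", "c2",
         "c3", "c4", "e1", "e2", "e3", "p1", "p2", "h1", "h2", "h3"),
  c4 = c("V0_LH", "V1_LH", "Km_LH", "V_FSH", "Ki_FSH_Inh", "b", "c1", "c2",
         "c3", "c4", "e1", "e2", "e3", "p1", "p2", "h1", "h2", "h3",
         "w", "q"))

## Nelder-Mead in log space: positivity without constraints.  A mild
## ridge penalty in log space (lambda * ||log p - log p0||^2) keeps
## weakly identified parameter combinations from drifting to degenerate
## compensating magnitudes; it is small enough (default 0.01) to shift
## well-identified parameters negligibly.
nm_log <- function(par0, fn, maxit, reltol = 1e-9, lambda = 0) {
  th0 <- log(par0)
  obj <- function(th) fn(exp(th)) + lambda * sum((th - th0)^2)
  if (length(th0) == 1L) {
    ## one-dimensional simplex search is unreliable; golden-section
    ## within a generous bracket instead
    res <- stats::optimize(obj, th0 + c(-2.3, 2.3), tol = 1e-8)
    best <- if (res$objective <= obj(th0)) res$minimum else th0
    return(list(par = setNames(exp(best), names(par0)),
                value = fn(exp(best)), convergence = 0L,
                counts = NA_integer_))
  }
  res <- optim(th0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  list(par = exp(res$par), value = fn(exp(res$par)),
       convergence = res$convergence, counts = res$counts)
}

#' Staged calibration of the cycle model
#'
#' Implements the four-stage estimation procedure:
#' \describe{
#'   \item{c1}{pituitary submodel (LH/FSH synthesis-release-clearance)
#'     fitted to the LH and FSH series with E2, P4 and Inh forced by
#'     periodic cubic splines through the data; the \code{P4/w} term is
#'     disabled.}
#'   \item{c2}{ovarian staged-mass submodel fitted to the E2, P4 and Inh
#'     series with LH and FSH forced by data splines; the \code{P4/q}
#'     term is disabled.  Stage-transfer constants are optimised by
#'     Nelder-Mead while the secretion coefficients are profiled out by
#'     weighted non-negative least squares at each step.}
#'   \item{c3}{the merged closed-loop model refined against all five
#'     series (without \code{w}, \code{q}).}
#'   \item{c4}{the merged model including the progesterone inhibition
#'     scales \code{w} and \code{q}.}
#' }
#' All searches run in log-parameter space (Nelder-Mead), which keeps
#' every parameter positive without explicit constraints.
#'
#' @param data a [hormone_dataset()].
#' @param init_guess starting [cycle_params()].
#' @param init_state starting 13-state vector.
#' @param stages character subset of \code{c("c1","c2","c3","c4")}, in
#'   order.
#' @param free named list overriding the per-stage free-parameter sets.
#' @param repetitions data repetitions for the merged-stage objective.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @param estimate_init if TRUE (default), submodel stages also estimate
#'   their initial states.
#' @param wq_init starting values for \code{w}, \code{q} entering c4
#'   when they are still at the disabled sentinel.
#' @param submodel_reps data repetitions used in the forced submodel
#'   stages c1/c2 (fewer than the merged stages need, since the forcing
#'   is periodic by construction).
#' @param submodel_rtol,submodel_atol solver tolerances for the forced
#'   submodel stages; looser than the final simulation tolerance because
#'   these stages only steer the search.
#' @param settle settling cycles passed to [objective_wls()] in the
#'   merged stages.
#' @param prior_penalty weight of a log-space ridge penalty toward the
#'   stage starting values, guarding against degenerate compensating
#'   parameter drift in weakly identified directions; 0 disables.
#' @param peak_targets,peak_weight passed to [objective_wls()] in the
#'   merged stages (continuous-peak matching).
#' @param peak_stage if TRUE, run an optional final refinement that
#'   re-weights each hormone's peak-day residual upward (x4) and
#'   re-optimises the c4 free set, pulling the solution toward the
#'   observed maxima.
#' @param verbose print per-stage progress.
#' @return object of class \code{"cycle_fit"} with elements
#'   \code{params}, \code{init}, \code{cost}, \code{ssr}, \code{M},
#'   \code{N}, \code{stages} (per-stage diagnostics), \code{data}.
#' @export
fit_staged <- function(data, init_guess = ref_params(),
                       init_state = ref_init(),
                       stages = c("c1", "c2", "c3", "c4"),
                       free = list(), repetitions = 4, maxit = 3000,
                       estimate_init = TRUE,
                       wq_init = c(w = 0.5, q = 0.5),
                       peak_stage = FALSE, verbose = FALSE,
                       settle = 0, peak_targets = NULL, peak_weight = 20,
                       prior_penalty = 0.01,
                       submodel_reps = 2, submodel_rtol = 1e-6,
                       submodel_atol = 1e-8) {
  stopifnot(inherits(data, "hormone_dataset"))
  stages <- match.arg(stages, c("c1", "c2", "c3", "c4"), several.ok = TRUE)
  fr <- modifyList(.default_free, free)
  p <- cycle_params(base = init_guess)
  y0 <- init_state[.state_names]
  log <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  forc <- list(E2 = forcing_spline(data, "E2"),
               P4 = forcing_spline(data, "P4"),
               Inh = forcing_spline(data, "Inh"),
               LH = forcing_spline(data, "LH"),
               FSH = forcing_spline(data, "FSH"))
  td <- tile_dataset(data, repetitions)
  ts <- tile_dataset(data, submodel_reps)

  if ("c1" %in% stages) {
    ## Given the forced ovarian hormones the LH and FSH blocks are
    ## uncoupled two-state ODEs, so they are fitted separately, halving
    ## the search dimension of the pituitary stage.
    lh_block <- intersect(fr$c1, c("V0_LH", "V1_LH", "Km_LH", "Ki_LH_P",
                                   "k_LH", "c_LH_P", "c_LH_E", "alpha_LH"))
    fsh_block <- intersect(fr$c1, c("V_FSH", "Ki_FSH_Inh", "tau", "k_FSH",
                                    "c_FSH_P", "c_FSH_E", "alpha_FSH"))
    rhs2 <- function(pp, column) {
      if (column == "LH") {
        function(t, y, parms) {
          E2 <- forc$E2(t); P4 <- forc$P4(t)
          hill <- (E2 / pp[["Km_LH"]])^8
          hill <- hill / (1 + hill)
          syn <- (pp[["V0_LH"]] + pp[["V1_LH"]] * hill) /
            (1 + P4 / pp[["Ki_LH_P"]])
          rel <- pp[["k_LH"]] * (1 + pp[["c_LH_P"]] * P4) * max(y[1], 0) /
            (1 + pp[["c_LH_E"]] * E2)
          list(c(syn - rel, rel / pp[["v"]] - pp[["alpha_LH"]] * y[2]))
        }
      } else {
        function(t, y, parms) {
          E2 <- forc$E2(t); P4 <- forc$P4(t)
          syn <- pp[["V_FSH"]] /
            (1 + forc$Inh(t - pp[["tau"]]) / pp[["Ki_FSH_Inh"]])
          rel <- pp[["k_FSH"]] * (1 + pp[["c_FSH_P"]] * P4) * max(y[1], 0) /
            (1 + pp[["c_FSH_E"]] * E2)^2
          list(c(syn - rel, rel / pp[["v"]] - pp[["alpha_FSH"]] * y[2]))
        }
      }
    }
    fit_block <- function(free_names, states, column) {
      fn <- function(x) {
        np <- length(free_names)
        pp <- p; pp[free_names] <- x[seq_len(np)]
        y2 <- y0[states]
        if (estimate_init) y2 <- x[np + 1:2]
        out <- tryCatch(
          deSolve::ode(y = unname(y2), times = ts$times, rhs2(pp, column),
                       parms = NULL, rtol = submodel_rtol,
                       atol = submodel_atol),
          warning = function(w) NULL, error = function(e) NULL)
        if (is.null(out) || nrow(out) < length(ts$times) ||
            any(!is.finite(out[, 3]))) return(1e10)
        wls_sum(out[, 3], ts$obs[, column], ts$weights[, column])
      }
      x0 <- c(p[free_names], if (estimate_init) y0[states])
      r <- nm_log(x0, fn, maxit, lambda = prior_penalty)
      p[free_names] <<- r$par[seq_along(free_names)]
      if (estimate_init) y0[states] <<- r$par[length(free_names) + 1:2]
      r
    }
    r1 <- if (length(lh_block)) fit_block(lh_block, c("RP_LH", "LH"), "LH")
    r2 <- if (length(fsh_block)) fit_block(fsh_block, c("RP_FSH", "FSH"),
                                           "FSH")
    log$c1 <- list(value = sum(c(r1$value, r2$value)),
                   convergence = max(c(r1$convergence, r2$convergence)),
                   counts = c(r1$counts, r2$counts))
    say("c1: cost %.4g (conv %d)", log$c1$value, log$c1$convergence)
  }

  if ("c2" %in% stages) {
    ov_states <- .state_names[5:13]
    secr <- NULL
    fn <- function(x) {
      np <- length(fr$c2)
      pp <- p; pp[fr$c2] <- x[seq_len(np)]
      y9 <- if (estimate_init) x[np + 1:9] else y0[ov_states]
      out <- tryCatch(
        simulate_ovarian_forced(pp, y9, forc, ts$times,
                                rtol = submodel_rtol,
                                atol = submodel_atol),
        warning = function(w) NULL, error = function(e) NULL)
      if (is.null(out) || nrow(out) < length(ts$times)) return(1e10)
      masses <- out[, -1, drop = FALSE]
      colnames(masses) <- ov_states
      sc <- tryCatch(fit_secretion(masses, ts$obs, ts$weights),
                     error = function(e) NULL)
      if (is.null(sc)) return(1e10)
      sc <- pmax(sc, 1e-12)
      secr <<- sc
      H <- cbind(
        E2 = sc[["e0"]] + sc[["e1"]] * masses[, "GrF"] +
          sc[["e2"]] * masses[, "DomF"] + sc[["e3"]] * masses[, "Lut4"],
        P4 = sc[["p0"]] + sc[["p1"]] * masses[, "Lut3"] +
          sc[["p2"]] * masses[, "Lut4"],
        Inh = sc[["h0"]] + sc[["h1"]] * masses[, "DomF"] +
          sc[["h2"]] * masses[, "Lut2"] + sc[["h3"]] * masses[, "Lut3"])
      wls_sum(H, ts$obs[, c("E2", "P4", "Inh")],
              ts$weights[, c("E2", "P4", "Inh")])
    }
    x0 <- c(p[fr$c2], if (estimate_init) pmax(y0[ov_states], 1e-3))
    r <- nm_log(x0, fn, maxit, lambda = prior_penalty)
    val <- fn(r$par)  # refresh secr at the optimum
    p[fr$c2] <- r$par[seq_along(fr$c2)]
    if (estimate_init) y0[ov_states] <- r$par[length(fr$c2) + 1:9]
    if (!is.null(secr)) p[names(secr)] <- secr
    log$c2 <- r[c("value", "convergence", "counts")]
    say("c2: cost %.4g (conv %d)", r$value, r$convergence)
  }

  merged_stage <- function(free_names, label) {
    n_free <- length(free_names)
    fn <- function(x) {
      pp <- p; pp[free_names] <- x
      objective_wls(pp, y0, data, repetitions, n_free = n_free,
                    settle = settle, peak_targets = peak_targets,
                    peak_weight = peak_weight)
    }
    r <- nm_log(p[free_names], fn, maxit, lambda = prior_penalty)
    p[free_names] <<- r$par
    log[[label]] <<- r[c("value", "convergence", "counts")]
    say("%s: cost %.4g (conv %d)", label, r$value, r$convergence)
  }

  if ("c3" %in% stages) {
    ## run with the progesterone-inhibition terms disabled
    wq_keep <- p[c("w", "q")]
    p[c("w", "q")] <- 1e12
    merged_stage(setdiff(fr$c3, c("w", "q")), "c3")
    p[c("w", "q")] <- wq_keep
  }

  if ("c4" %in% stages) {
    if (p[["w"]] >= 1e11) p[["w"]] <- wq_init[["w"]]
    if (p[["q"]] >= 1e11) p[["q"]] <- wq_init[["q"]]
    merged_stage(fr$c4, "c4")
  }

  if (peak_stage) {
    data2 <- data
    for (h in .hormones)
      data2$weights[which.max(data2$obs[, h]), h] <-
        4 * data2$weights[which.max(data2$obs[, h]), h]
    free_names <- fr$c4
    n_free <- length(free_names)
    fn <- function(x) {
      pp <- p; pp[free_names] <- x
      objective_wls(pp, y0, data2, repetitions, n_free = n_free,
                    settle = settle)
    }
    r <- nm_log(p[free_names], fn, maxit, lambda = prior_penalty)
    p[free_names] <- r$par
    log$peak <- r[c("value", "convergence", "counts")]
    say("peak: cost %.4g (conv %d)", r$value, r$convergence)
  }

  n_free <- length(unique(unlist(fr[stages]))) +
    if (estimate_init) 13 else 0
  fin <- objective_wls(p, y0, data, repetitions, n_free = n_free,
                       details = TRUE)
  structure(list(params = cycle_params(base = p), init = y0,
                 cost = fin$cost, ssr = fin$ssr, M = fin$M, N = fin$N,
                 stages = log, data = data, repetitions = repetitions),
            class = "cycle_fit")
}

#' @export
print.cycle_fit <- function(x, ...) {
  cat("staged cycle-model fit\n")
  cat(sprintf("  objective: %.6g  (M = %d, N = %d)\n", x$cost, x$M, x$N))
  cat("  per-hormone SSR (natural scale):\n")
  print(round(x$ssr, 2))
  cat("  stages run:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cycle_fit <- function(object, ...) object$params

#' @export
summary.cycle_fit <- function(object, ...) {
  m <- cycle_metrics(simulate_cycle(object$params, init = object$init,
                                    horizon = 112))
  out <- list(fit = object, metrics = m)
  class(out) <- "summary.cycle_fit"
  out
}

#' @export
print.summary.cycle_fit <- function(x, ...) {
  print(x$fit)
  print(x$metrics)
  invisible(x)
}

#' Simulate from a fitted model
#'
#' @param object a \code{cycle_fit}.
#' @param nsim,seed unused (deterministic model), kept for generic
#'   compatibility.
#' @param horizon days to simulate.
#' @param ... passed to [simulate_cycle()].
#' @export
simulate.cycle_fit <- function(object, nsim = 1, seed = NULL,
                               horizon = 112, ...) {
  simulate_cycle(object$params, init = object$init, horizon = horizon, ...)
}

#' Model-vs-data residuals of a fit
#'
#' @param object a \code{cycle_fit}.
#' @param ... unused.
#' @return matrix of percentage-error residuals (model - data)/data at
#'   the data days of the first repetition.
#' @export
residuals.cycle_fit <- function(object, ...) {
  sim <- simulate_cycle(object$params, init = object$init,
                        horizon = 28 * object$repetitions)
  d0 <- object$data$day - object$data$day[1]
  H <- sample_hormones(sim, d0)[, .hormones]
  (H - object$data$obs) / object$data$obs
}

#' @export
plot.cycle_fit <- function(x, ...) {
  sim <- simulate_cycle(x$params, init = x$init,
                        horizon = 28 * x$repetitions)
  d0 <- x$data$day - x$data$day[1]
  op <- graphics::par(mfrow = c(5, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (h in .hormones) {
    graphics::plot(sim$times, sim$hormones[, h], type = "l", xlab = "",
                   ylab = h, ...)
    graphics::points(rep(d0, x$repetitions) +
                       28 * rep(seq_len(x$repetitions) - 1, each = length(d0)),
                     rep(x$data$obs[, h], x$repetitions), col = 2, pch = 16,
                     cex = 0.5)
  }
  invisible(x)
}
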