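#' Simulate the cycle model
#'
#' Integrates the 13-state delay differential equation system with the
#' method-of-steps machinery of \code{deSolve::dede}, which keeps a
#' continuous (Hermite-interpolated) history for the inhibin lookup at
#' \code{t - tau}.  The history before \code{t0} is the supplied initial
#' state held constant.  By default the compiled right-hand side is
#' used; \code{engine = "R"} integrates the reference R transcription
#' instead (slower, used for cross-checking).
#'
#' @param params a [cycle_params()] vector.
#' @param dose a [dose_schedule()]; default no treatment.
#' @param init named 13-vector of initial state values; default
#'   [ref_init()].
#' @param horizon length of the simulation (days); must be at least
#'   \code{tau}.
#' @param t0 start time (days).
#' @param dt output grid spacing (days); at least 10 points per day are
#'   kept so that peaks and the delayed lookup are well resolved.
#' @param rtol,atol solver tolerances.
#' @param engine \code{"C"} (compiled, default) or \code{"R"}.
#' @return an object of class \code{"cycle_sim"}: list with \code{times},
#'   the \code{states} matrix, the \code{hormones} matrix (columns
#'   \code{E2}, \code{P4}, \code{Inh}, \code{LH}, \code{FSH}), the dose
#'   schedule and solver settings.
#' @export
simulate_cycle <- function(params, dose = dose_schedule(), init = ref_init(),
                           horizon = 112, t0 = 0, dt = 0.1,
                           rtol = 1e-8, atol = 1e-10, engine = c("C", "R")) {
  engine <- match.arg(engine)
  validate_params(params)
  stopifnot(inherits(dose, "dose_schedule"))
  if (horizon < params[["tau"]])
    stop("horizon must be at least the inhibin delay tau")
  init <- init[.state_names]
  if (any(is.na(init)) || any(init < 0))
    stop("init must supply non-negative values for all 13 states")
  dt <- min(dt, 0.1)
  times <- seq(t0, t0 + horizon, by = dt)
  hist_inh <- unname(auxiliary_hormones(init, c(0, 0), params)[["Inh"]])

  if (engine == "C") {
    tf <- seq(t0, t0 + horizon, by = 0.05)
    if (tf[length(tf)] < t0 + horizon) tf <- c(tf, t0 + horizon)
    forc <- list(cbind(tf, dose$e2(tf)), cbind(tf, dose$p4(tf)))
    out <- deSolve::dede(
      y = init, times = times, func = "cycle_derivs",
      parms = c(unname(params[.param_names]), t0, hist_inh),
      dllname = "ovucycle", initfunc = "cycle_initmod",
      initforc = "cycle_initforc", forcings = forc,
      nout = 3, outnames = c("E2c", "P4c", "InhLag"),
      rtol = rtol, atol = atol)
  } else {
    p <- params
    rhs_r <- function(t, y, parms) {
      tlag <- t - p[["tau"]]
      if (p[["tau"]] <= 0) {
        ylag <- y
      } else if (tlag <= t0) {
        ylag <- init
      } else {
        ylag <- deSolve::lagvalue(tlag)
        names(ylag) <- .state_names
      }
      dinh <- unname(auxiliary_hormones(pmax(ylag, 0), c(0, 0), p)[["Inh"]])
      list(cycle_rhs(t, y, dinh, dose, p))
    }
    out <- deSolve::dede(y = init, times = times, func = rhs_r,
                         parms = NULL, rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("DDE solver failed near t = ", max(out[, 1]), " days")
  if (nrow(out) < length(times))
    stop("DDE solver stopped early at t = ", out[nrow(out), 1], " days")

  st <- out[, .state_names, drop = FALSE]
  dv <- cbind(dose$e2(out[, "time"]), dose$p4(out[, "time"]))
  horm <- auxiliary_hormones(pmax(st, 0), dv, params)
  horm <- cbind(horm, LH = st[, "LH"], FSH = st[, "FSH"])
  structure(list(times = out[, "time"], states = st, hormones = horm,
                 dose = dose, params = params, init = init,
                 t0 = t0, rtol = rtol, atol = atol, engine = engine),
            class = "cycle_sim")
}

#' @export
print.cycle_sim <- function(x, ...) {
  cat("cycle model simulation:", length(x$times), "time points over",
      sprintf("[%g, %g] days\n", min(x$times), max(x$times)))
  pk <- apply(x$hormones, 2, max)
  cat("hormone maxima: ",
      paste(sprintf("%s=%.3g", colnames(x$hormones), pk), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Convert a simulation to a data frame
#'
#' @param x a \code{cycle_sim}.
#' @param row.names,optional unused.
#' @param what \code{"hormones"}, \code{"states"} or \code{"all"}.
#' @param long if \code{TRUE}, return tidy (time, variable, value) form.
#' @param ... unused.
#' @export
as.data.frame.cycle_sim <- function(x, row.names = NULL, optional = FALSE,
                                    what = c("hormones", "states", "all"),
                                    long = FALSE, ...) {
  what <- match.arg(what)
  m <- switch(what, hormones = x$hormones, states = x$states,
              all = cbind(x$states, x$hormones[, c("E2", "P4", "Inh")]))
  df <- data.frame(time = x$times, m, check.names = FALSE)
  if (long)
    df <- data.frame(
      time = rep(df$time, ncol(m)),
      variable = rep(colnames(m), each = nrow(df)),
      value = as.vector(m))
  df
}

#' Sample hormone concentrations at arbitrary times
#'
#' Linear interpolation of the dense simulation grid.
#'
#' @param sim a \code{cycle_sim}.
#' @param at numeric vector of days within the simulated span.
#' @return matrix with one row per time, columns E2, P4, Inh, LH, FSH.
#' @export
sample_hormones <- function(sim, at) {
  stopifnot(inherits(sim, "cycle_sim"))
  if (any(at < min(sim$times) - 1e-9) || any(at > max(sim$times) + 1e-9))
    stop("sampling times outside the simulated span")
  out <- sapply(colnames(sim$hormones), function(h)
    approx(sim$times, sim$hormones[, h], xout = at, rule = 2)$y)
  matrix(out, nrow = length(at),
         dimnames = list(NULL, colnames(sim$hormones)))
}

#' Plot hormone trajectories
#'
#' @param x a \code{cycle_sim}.
#' @param hormones which series to draw.
#' @param ... passed to \code{matplot}.
#' @export
plot.cycle_sim <- function(x, hormones = c("E2", "P4", "Inh", "LH", "FSH"),
                           ...) {
  op <- graphics::par(mfrow = c(length(hormones), 1),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (h in hormones)
    graphics::plot(x$times, x$hormones[, h], type = "l", xlab = "",
                   ylab = h, ...)
  invisible(x)
}

#' @importFrom stats approx
NULL
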