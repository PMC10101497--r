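#' Exogenous hormone dose schedules
#'
#' A dose schedule supplies the exogenous estradiol blood-concentration
#' contribution \code{e2exo(t)} (pg/mL) and the exogenous progesterone
#' contribution \code{p4exo(t)} (ng/mL) entering the auxiliary hormone
#' equations.  Each component is either a constant, zero, or a set of
#' node values joined by a shape-preserving piecewise-cubic Hermite
#' interpolant (clipped at zero), so that tabulated time-varying controls
#' never overshoot their node values.
#'
#' @param e2exo either a single non-negative constant (pg/mL) or a
#'   two-column object (\code{time}, \code{value}) of node values.
#' @param p4exo as \code{e2exo}, in ng/mL.
#' @return an object of class \code{"dose_schedule"} with callable
#'   components \code{$e2} and \code{$p4}.
#' @examples
#' d0 <- dose_schedule()                    # no treatment
#' dc <- dose_schedule(e2exo = 20)          # constant estrogen
#' dn <- dose_schedule(p4exo = cbind(time = 0:28, value = rep(1.4, 29)))
#' @export
dose_schedule <- function(e2exo = 0, p4exo = 0) {
  structure(list(e2 = .dose_component(e2exo, "e2exo"),
                 p4 = .dose_component(p4exo, "p4exo"),
                 e2spec = e2exo, p4spec = p4exo),
            class = "dose_schedule")
}

.dose_component <- function(x, what) {
  if (is.function(x)) {
    f <- x
    return(function(t) pmax(f(t), 0))
  }
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x) || x < 0)
      stop(what, " constant must be finite and non-negative")
    force(x)
    return(function(t) rep_len(x, length(t)))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stop(what, " nodes must be a two-column (time, value) object")
  tt <- x[, 1]; vv <- x[, 2]
  if (any(!is.finite(tt)) || any(!is.finite(vv)) || any(vv < 0))
    stop(what, " node values must be finite and non-negative")
  if (is.unsorted(tt, strictly = TRUE))
    stop(what, " node times must be strictly increasing")
  function(t) {
    t <- pmin(pmax(t, tt[1]), tt[length(tt)])
    pmax(pracma::pchip(tt, vv, t), 0)
  }
}

#' Evaluate a dose schedule on a time grid
#'
#' @param dose a \code{dose_schedule}.
#' @param times numeric vector of days.
#' @return data.frame with columns \code{time}, \code{e2exo}, \code{p4exo}.
#' @export
eval_dose <- function(dose, times) {
  stopifnot(inherits(dose, "dose_schedule"))
  data.frame(time = times, e2exo = dose$e2(times), p4exo = dose$p4(times))
}

#' Total administered dose (AUC) of each component
#'
#' Composite-trapezoid area under each dose component over
#' \code{[t0, tf]}.  Units follow the convention of reporting per-day
#' rates integrated over days on the concentration scale (pg/mL for
#' estrogen, ng/mL for progesterone).
#'
#' @param dose a \code{dose_schedule}.
#' @param t0,tf integration limits (days).
#' @param n number of grid points for the quadrature.
#' @return named numeric vector \code{c(e2exo=, p4exo=)}.
#' @export
dose_auc <- function(dose, t0 = 0, tf = 28, n = 2801) {
  tt <- seq(t0, tf, length.out = n)
  c(e2exo = pracma::trapz(tt, dose$e2(tt)),
    p4exo = pracma::trapz(tt, dose$p4(tt)))
}

#' @export
print.dose_schedule <- function(x, ...) {
  desc <- function(spec, unit) {
    if (is.numeric(spec) && length(spec) == 1L) {
      if (spec == 0) "none" else paste0("constant ", spec, " ", unit, "/day")
    } else if (is.function(spec)) "function(t)"
    else paste0("piecewise-cubic, ", nrow(as.matrix(spec)), " nodes")
  }
  cat("dose schedule:\n")
  cat("  E2exo:", desc(x$e2spec, "pg/mL"), "\n")
  cat("  P4exo:", desc(x$p4spec, "ng/mL"), "\n")
  invisible(x)
}
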