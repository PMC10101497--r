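## Synthetic hormone-data generation: model-generated daily tables with
## controllable multiplicative noise, and perturbed-parameter cycle
## variants.

#' Generate a synthetic daily hormone dataset from the model
#'
#' Forward-simulates the cycle model from a known parameter set and
#' samples daily values of the five hormones over one 28-day cycle,
#' optionally applying multiplicative log-normal noise (hormone assays
#' are positive and right-skewed).  With \code{rescale = "none"}
#' (default) days 1..28 are the simulation days 0..27 from the supplied
#' initial state, so a noise-free dataset reproduces the generating
#' trajectory exactly and the calibration objective at the generating
#' parameters is zero.  With \code{rescale = "period"} the trajectory is
#' first settled, its period estimated, and one full cycle is sampled at
#' 28 equally spaced phases (the standardization applied to clinical
#' group data); the generating model must then be periodic.
#'
#' @param params generating [cycle_params()].
#' @param init generating initial state.
#' @param sigma noise standard deviation on the log scale; scalar or
#'   named per-hormone vector (E2, P4, Inh, LH, FSH).  Default 0.
#' @param seed optional RNG seed (fixed and recorded in the result).
#' @param rescale \code{"none"} or \code{"period"} (see above).
#' @param settle_cycles settling cycles before sampling when
#'   \code{rescale = "period"}.
#' @param peak_weights passed to [hormone_dataset()].
#' @return a [hormone_dataset()] with attributes \code{sigma},
#'   \code{seed}, \code{period}.
#' @export
generate_dataset <- function(params = ref_params(), init = ref_init(),
                             sigma = 0, seed = NULL,
                             rescale = c("none", "period"),
                             settle_cycles = 3, peak_weights = FALSE) {
  rescale <- match.arg(rescale)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (length(sigma) == 1L) sigma <- setNames(rep(sigma, 5), .hormones)
  sigma <- sigma[.hormones]

  if (rescale == "none") {
    sim <- simulate_cycle(params, init = init, horizon = 28)
    H <- sample_hormones(sim, 0:27)
    period <- NA_real_
  } else {
    sim <- simulate_cycle(params, init = init,
                          horizon = 28 * (settle_cycles + 2))
    m <- cycle_metrics(sim, settle_cycles = settle_cycles)
    if (is.na(m$period))
      stop("generating model is not periodic; cannot standardize")
    period <- m$period
    t_start <- 28 * settle_cycles
    phases <- t_start + period * (0:27) / 28
    H <- sample_hormones(sim, phases)
  }
  if (!is.null(seed)) set.seed(seed)
  noise <- matrix(stats::rnorm(length(H)), nrow(H), ncol(H))
  H <- H[, .hormones] * exp(sweep(noise[, seq_along(.hormones)], 2,
                                  sigma, `*`))
  out <- hormone_dataset(data.frame(day = 1:28, H),
                         peak_weights = peak_weights)
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- seed
  attr(out, "period") <- period
  out
}

#' Cycle-length variants by perturbing the LH-synthesis E2 threshold
#'
#' The Hill threshold \code{Km_LH} (the E2 level at half-maximal LH
#' synthesis stimulation) is among the parameters the cycle length is
#' most sensitive to: raising it delays the E2 crossing that triggers
#' the LH surge and lengthens the cycle.  For each supplied value the
#' perturbed parameter set and its simulated period are returned.
#'
#' @param base base [cycle_params()].
#' @param km_values numeric vector of \code{Km_LH} values (pg/mL).
#' @param init initial state.
#' @param n_cycles cycles simulated per period estimate.
#' @return data.frame with columns \code{km_LH} and \code{period};
#'   the perturbed parameter sets are attached as attribute
#'   \code{params} (a list).
#' @export
cycle_variants <- function(base = ref_params(), km_values,
                           init = ref_init(), n_cycles = 6) {
  sets <- lapply(km_values, function(km)
    cycle_params(base = base, Km_LH = km))
  periods <- vapply(sets, function(p) {
    m <- tryCatch(
      cycle_metrics(simulate_cycle(p, init = init,
                                   horizon = 28 * n_cycles),
                    settle_cycles = 2),
      error = function(e) list(period = NA_real_))
    m$period
  }, numeric(1))
  out <- data.frame(km_LH = km_values, period = periods)
  attr(out, "params") <- sets
  out
}
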