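## Constant-dose experiments: monotherapy scans, combination contour
## maps, threshold refinement and peak-suppression tables.

#' Constant-dose monotherapy scan
#'
#' Simulates one 28-day treatment window per dose on a grid of constant
#' exogenous doses and records the maximum and minimum LH and P4 and the
#' anovulation classification (P4 maximum below 5 ng/mL with no LH
#' surge) for each dose.
#'
#' @param hormone \code{"estrogen"} (E2exo, pg/mL per day) or
#'   \code{"progesterone"} (P4exo, ng/mL per day).
#' @param grid strictly increasing dose grid; default the standard scan
#'   0 to 60 by 0.1 pg/mL for estrogen, 0 to 4 by 0.1 ng/mL for
#'   progesterone.
#' @param params a [cycle_params()] vector.
#' @param init initial state at treatment start (default [ref_init()]).
#' @param window treatment window (days), default \code{c(0, 28)}.
#' @param ... passed to [cycle_metrics()] (e.g. surge settings).
#' @return object of class \code{"dose_scan"}: data.frame with columns
#'   \code{dose}, \code{LH_max}, \code{LH_min}, \code{P4_max},
#'   \code{P4_min}, \code{anovulatory}, \code{failed} plus attributes.
#' @export
scan_monotherapy <- function(hormone = c("estrogen", "progesterone"),
                             grid = NULL, params = ref_params(),
                             init = ref_init(), window = c(0, 28), ...) {
  hormone <- match.arg(hormone)
  if (is.null(grid))
    grid <- if (hormone == "estrogen") seq(0, 60, by = 0.1)
            else seq(0, 4, by = 0.1)
  if (is.unsorted(grid, strictly = TRUE))
    stop("dose grid must be strictly increasing")
  res <- lapply(grid, function(d) {
    m <- tryCatch(
      dose_metrics(d, hormone, params, init, window, ...),
      error = function(e) NULL)
    if (is.null(m))
      return(data.frame(dose = d, LH_max = NA, LH_min = NA, P4_max = NA,
                        P4_min = NA, anovulatory = NA, failed = TRUE))
    data.frame(dose = d, LH_max = m$peaks[["LH"]],
               LH_min = m$troughs[["LH"]], P4_max = m$peaks[["P4"]],
               P4_min = m$troughs[["P4"]],
               anovulatory = m$anovulatory, failed = FALSE)
  })
  out <- do.call(rbind, res)
  structure(out, hormone = hormone, window = window,
            class = c("dose_scan", "data.frame"))
}

## metrics of one constant-dose 28-day treatment
dose_metrics <- function(dose, hormone, params, init, window = c(0, 28),
                         ...) {
  ds <- if (hormone == "estrogen") dose_schedule(e2exo = dose)
        else dose_schedule(p4exo = dose)
  sim <- simulate_cycle(params, dose = ds, init = init,
                        horizon = window[2], t0 = 0)
  cycle_metrics(sim, window = window, ...)
}

#' Percentage decrease of hormone peaks under a dose
#'
#' Compares the per-hormone maxima over one 28-day treated cycle with
#' the untreated maxima and reports the percentage decrease
#' \code{100 (peak0 - peak_d) / peak0}, rounded to integers by
#' convention for tabulation.
#'
#' @param dose a [dose_schedule()].
#' @param params,init model parameters and initial state.
#' @param window evaluation window (days).
#' @param digits rounding for the reported percentages (default 0).
#' @return named numeric vector over E2, P4, Inh, LH, FSH (percent).
#' @export
percent_peak_decrease <- function(dose, params = ref_params(),
                                  init = ref_init(), window = c(0, 28),
                                  digits = 0) {
  sim0 <- simulate_cycle(params, init = init, horizon = window[2])
  simd <- simulate_cycle(params, dose = dose, init = init,
                         horizon = window[2])
  m0 <- cycle_metrics(sim0, window = window)
  md <- cycle_metrics(simd, window = window)
  round(100 * (m0$peaks - md$peaks) / m0$peaks, digits)
}

#' Maximum-P4 contour grid for combination treatment
#'
#' Simulates a 28-day cycle for every combination of constant E2exo and
#' P4exo doses on the supplied grids, records the P4 maximum, extracts
#' k-level curves and the anovulation-region mask (max P4 < 5 ng/mL),
#' and fits a straight line to the left branch of the k = 5 level curve
#' (the anovulation boundary), whose slope quantifies the estrogen /
#' progesterone trade-off.
#'
#' @param e2_grid E2exo doses (pg/mL per day), default 0..60.
#' @param p4_grid P4exo doses (ng/mL per day), default 0..4.
#' @param params,init model parameters and initial state.
#' @param levels k-levels (ng/mL) for the extracted contour curves.
#' @param slope_e2_max level-curve points with E2exo below this value
#'   are used for the boundary-slope fit (the lower-left branch).
#' @return object of class \code{"contour_grid"}: list with the dose
#'   grids, \code{P4max} matrix, \code{mask} (anovulation region),
#'   \code{contours} (list of k-level curves), \code{boundary_slope}
#'   and the fit range.
#' @export
contour_map <- function(e2_grid = seq(0, 60, by = 2),
                        p4_grid = seq(0, 4, by = 0.2),
                        params = ref_params(), init = ref_init(),
                        levels = c(3, 4, 5), slope_e2_max = 30) {
  P4max <- matrix(NA_real_, length(e2_grid), length(p4_grid))
  LHmax <- P4max
  for (i in seq_along(e2_grid)) {
    for (j in seq_along(p4_grid)) {
      m <- tryCatch({
        ds <- dose_schedule(e2exo = e2_grid[i], p4exo = p4_grid[j])
        sim <- simulate_cycle(params, dose = ds, init = init, horizon = 28)
        cycle_metrics(sim, window = c(0, 28))
      }, error = function(e) NULL)
      if (!is.null(m)) {
        P4max[i, j] <- m$peaks[["P4"]]
        LHmax[i, j] <- m$peaks[["LH"]]
      }
    }
  }
  cl <- grDevices::contourLines(e2_grid, p4_grid, P4max, levels = levels)
  contours <- lapply(cl, function(l)
    data.frame(level = l$level, e2exo = l$x, p4exo = l$y))
  ## boundary slope: straight-line fit to the k = 5 curve's lower-left
  ## branch (E2exo below slope_e2_max)
  b5 <- do.call(rbind, contours[vapply(contours, function(d)
    d$level[1] == 5, logical(1))])
  slope <- NA_real_
  rng <- c(NA_real_, NA_real_)
  if (!is.null(b5)) {
    b5 <- b5[b5$e2exo < slope_e2_max & b5$p4exo > 0, , drop = FALSE]
    if (nrow(b5) >= 2) {
      fit <- stats::lm(p4exo ~ e2exo, data = b5)
      slope <- unname(coef(fit)[2])
      rng <- range(b5$e2exo)
    }
  }
  structure(list(e2_grid = e2_grid, p4_grid = p4_grid, P4max = P4max,
                 LHmax = LHmax, mask = P4max < 5, contours = contours,
                 boundary_slope = slope, slope_fit_range = rng),
            class = "contour_grid")
}

#' @export
print.contour_grid <- function(x, ...) {
  cat("combination-dose contour grid:",
      length(x$e2_grid), "x", length(x$p4_grid), "doses\n")
  cat(sprintf("  anovulatory fraction: %.2f\n", mean(x$mask, na.rm = TRUE)))
  cat(sprintf("  k = 5 boundary slope: %.3f ng/mL per pg/mL (E2exo in [%g, %g])\n",
              x$boundary_slope, x$slope_fit_range[1], x$slope_fit_range[2]))
  invisible(x)
}

#' Minimum anovulatory constant dose
#'
#' Refines the coarse scan threshold by bisection to the smallest
#' constant dose whose 28-day treatment is anovulatory, at the stated
#' resolution.  By construction of the P4 < 5 ng/mL criterion the
#' returned dose lowers the P4 maximum to just below 5 ng/mL (the
#' operational optimum constant dosage).
#'
#' @param hormone \code{"estrogen"} or \code{"progesterone"}.
#' @param params,init model parameters and initial state.
#' @param resolution bisection tolerance on the dose (default 0.01).
#' @param range search range; defaults to the standard scan range.
#' @param coarse_by coarse grid spacing used to bracket the onset.
#' @return list with \code{dose} (per day), \code{total} (dose x 28),
#'   \code{p4_max} at the returned dose, or dose = NA if no anovulatory
#'   dose exists in range.
#' @export
min_constant_dose <- function(hormone = c("estrogen", "progesterone"),
                              params = ref_params(), init = ref_init(),
                              resolution = 0.01, range = NULL,
                              coarse_by = 0.1) {
  hormone <- match.arg(hormone)
  if (is.null(range))
    range <- if (hormone == "estrogen") c(0, 60) else c(0, 4)
  anov <- function(d) {
    m <- dose_metrics(d, hormone, params, init)
    isTRUE(m$anovulatory)
  }
  grid <- seq(range[1], range[2], by = coarse_by)
  flags <- vapply(grid, anov, logical(1))
  if (!any(flags))
    return(list(dose = NA_real_, total = NA_real_, p4_max = NA_real_))
  i1 <- which(flags)[1]
  if (i1 == 1L) {
    d <- grid[1]
  } else {
    lo <- grid[i1 - 1]; hi <- grid[i1]
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (anov(mid)) hi <- mid else lo <- mid
    }
    d <- hi
  }
  m <- dose_metrics(d, hormone, params, init)
  list(dose = d, total = d * 28, p4_max = m$peaks[["P4"]])
}

#' Local sensitivity of the cycle length
#'
#' Central finite-difference sensitivity of the period with respect to
#' log-parameters: \code{d period / d log p}, i.e. the change in days
#' per 100 percent parameter increase, ranked by magnitude.
#'
#' @param params a [cycle_params()] vector.
#' @param perturb_fraction relative perturbation (default 0.01).
#' @param parameters subset of parameter names (default all).
#' @param init initial state.
#' @param n_cycles cycles simulated for each period estimate.
#' @return data.frame with columns \code{parameter}, \code{sensitivity}
#'   (days per log-unit), \code{period_lo}, \code{period_hi}, ranked by
#'   absolute sensitivity; undefined periods yield NA (flagged).
#' @export
sensitivity_cycle_length <- function(params = ref_params(),
                                     perturb_fraction = 0.01,
                                     parameters = NULL,
                                     init = ref_init(), n_cycles = 6) {
  if (is.null(parameters))
    parameters <- setdiff(.param_names, c("b1", "b2"))
  period_of <- function(p) {
    m <- tryCatch(
      cycle_metrics(simulate_cycle(p, init = init,
                                   horizon = 28 * n_cycles),
                    settle_cycles = 2),
      error = function(e) NULL)
    if (is.null(m)) NA_real_ else m$period
  }
  if (perturb_fraction == 0) {
    out <- data.frame(parameter = parameters, sensitivity = 0,
                      period_lo = NA_real_, period_hi = NA_real_)
    return(out)
  }
  rows <- lapply(parameters, function(nm) {
    up <- params; up[nm] <- up[nm] * (1 + perturb_fraction)
    dn <- params; dn[nm] <- dn[nm] * (1 - perturb_fraction)
    Thi <- period_of(cycle_params(base = up))
    Tlo <- period_of(cycle_params(base = dn))
    dlog <- log1p(perturb_fraction) - log1p(-perturb_fraction)
    data.frame(parameter = nm, sensitivity = (Thi - Tlo) / dlog,
               period_lo = Tlo, period_hi = Thi)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$sensitivity)), ]
}
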