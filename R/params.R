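#' @useDynLib ovucycle, .registration = TRUE
#' @importFrom stats approxfun optim setNames splinefun quantile coef
#' @importFrom utils read.csv write.csv modifyList
NULL

## Canonical parameter names for the 13-state cycle model, grouped by
## submodel.  Units are fixed package-wide: E2 pg/mL, P4 ng/mL, Inh IU/mL,
## LH and FSH IU/L, follicular/luteal masses ng, time days.
.param_names <- c(
  ## pituitary: LH synthesis/release/clearance
  "V0_LH", "V1_LH", "Km_LH", "Ki_LH_P", "k_LH", "c_LH_P", "c_LH_E",
  "alpha_LH",
  ## pituitary: FSH synthesis/release/clearance
  "V_FSH", "Ki_FSH_Inh", "tau", "k_FSH", "c_FSH_P", "c_FSH_E", "alpha_FSH",
  ## blood distribution volume
  "v",
  ## contraception-mechanism inhibition scales (P4/w on FSH synthesis,
  ## P4/q on follicular recruitment)
  "w", "q",
  ## ovarian stage-transfer constants
  "b", "c1", "c2", "c3", "c4", "d1", "d2", "k1", "k2", "k3", "k4",
  "alpha", "gamma",
  ## secretion coefficients: E2, P4, Inh as linear combinations of masses
  "e0", "e1", "e2", "e3", "p0", "p1", "p2", "h0", "h1", "h2", "h3",
  ## exogenous-hormone couplings
  "b1", "b2"
)

.state_names <- c("RP_LH", "LH", "RP_FSH", "FSH", "RcF", "GrF", "DomF",
                  "Sc1", "Sc2", "Lut1", "Lut2", "Lut3", "Lut4")

#' Construct a validated cycle-model parameter set
#'
#' Builds the full named parameter vector of the 13-state menstrual cycle
#' model.  Values not supplied default to the package reference set (see
#' [ref_params()]).  All rates and scales must be strictly positive except
#' the delay \code{tau} (non-negative) and the exogenous couplings
#' \code{b1}, \code{b2} (non-negative, default 1).
#'
#' @param ... named parameter values overriding the reference set.
#' @param base optional named numeric vector used as the base instead of
#'   the reference set.
#' @return a named numeric vector of class \code{"cycle_params"}.
#' @export
cycle_params <- function(..., base = NULL) {
  if (is.null(base)) base <- ref_params()
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) &&
      (is.list(over[[1]]) || (is.numeric(over[[1]]) && !is.null(names(over[[1]])))))
    over <- as.list(over[[1]])
  p <- as.list(base)[.param_names]
  names(p) <- .param_names
  if (length(over)) {
    bad <- setdiff(names(over), .param_names)
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p <- unlist(p)
  validate_params(p)
  structure(p, class = "cycle_params")
}

validate_params <- function(p) {
  miss <- setdiff(.param_names, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(p)))
    stop("non-finite parameter value(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  nonneg <- c("tau", "b1", "b2", "e0", "p0", "h0")
  strict <- setdiff(.param_names, nonneg)
  if (any(p[strict] <= 0))
    stop("parameter(s) must be strictly positive: ",
         paste(strict[p[strict] <= 0], collapse = ", "))
  if (any(p[nonneg] < 0))
    stop("parameter(s) must be non-negative: ",
         paste(nonneg[p[nonneg] < 0], collapse = ", "))
  invisible(p)
}

#' Package reference parameter set
#'
#' Returns the calibrated reference parameter set shipped with the
#' package.  The set was obtained with [fit_staged()] against the
#' synthetic 28-day hormone table in
#' \code{inst/extdata/hormone_data_synthetic.csv} and produces a stable
#' periodic solution of roughly 28 days with single late-follicular LH,
#' FSH and E2 peaks and luteal P4 and inhibin peaks.
#'
#' @return a named numeric vector of class \code{"cycle_params"}.
#' @export
ref_params <- function() {
  p <- .ref_param_cache$p
  if (is.null(p)) {
    f <- system.file("extdata", "ref_params.yaml", package = "ovucycle")
    p <- read_params(f)
    .ref_param_cache$p <- p
  }
  p
}
.ref_param_cache <- new.env(parent = emptyenv())

#' Reference initial condition of the cycle model
#'
#' Named 13-vector of state values (amounts in IU for reserve pools,
#' concentrations in IU/L for blood LH/FSH, masses in ng for the nine
#' ovarian stages) from which the reference parameter set settles onto
#' its periodic solution.
#'
#' @return named numeric vector of length 13.
#' @export
ref_init <- function() {
  y <- .ref_param_cache$y0
  if (is.null(y)) {
    f <- system.file("extdata", "ref_init.csv", package = "ovucycle")
    tab <- read.csv(f, stringsAsFactors = FALSE)
    y <- setNames(tab$value, tab$name)[.state_names]
    .ref_param_cache$y0 <- y
  }
  y
}

#' Read a parameter file
#'
#' Reads a flat YAML mapping or a two-column \code{name,value} CSV into a
#' validated parameter set.  Unknown keys are rejected so that files can
#' be audited against the canonical parameter list.
#'
#' @param path file path; format chosen by extension (\code{.yaml},
#'   \code{.yml} or \code{.csv}).
#' @return a \code{cycle_params} vector.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    vals <- yaml::read_yaml(path)
  } else if (ext == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "value") %in% names(tab)))
      stop("parameter CSV needs columns 'name' and 'value'")
    vals <- setNames(as.list(as.numeric(tab$value)), tab$name)
  } else stop("unsupported parameter file format: ", ext)
  bad <- setdiff(names(vals), .param_names)
  if (length(bad))
    stop("unknown parameter name(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  miss <- setdiff(.param_names, names(vals))
  if (length(miss))
    stop("missing parameter(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  p <- unlist(vals)[.param_names]
  validate_params(p)
  structure(p, class = "cycle_params")
}

#' Write a parameter set to YAML or CSV
#'
#' @param p a \code{cycle_params} vector.
#' @param path output path; format chosen by extension.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(as.list(setNames(as.numeric(p), names(p))), path)
  } else if (ext == "csv") {
    write.csv(data.frame(name = names(p), value = as.numeric(p)),
              path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported parameter file format: ", ext)
  invisible(path)
}

#' @export
print.cycle_params <- function(x, ...) {
  cat("13-state menstrual cycle model parameters (", length(x),
      " values)\n", sep = "")
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}
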