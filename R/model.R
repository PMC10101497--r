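#' Auxiliary hormone concentrations
#'
#' Computes the blood concentrations of estradiol, progesterone and
#' inhibin from the ovarian stage masses.  The ovarian hormones are at
#' quasi-steady state, so each is a linear combination of the masses of
#' the stages secreting it plus the exogenous contribution:
#' \deqn{E_2 = e_0 + e_1 GrF + e_2 DomF + e_3 Lut_4 + b_1 E_{2,exo}}
#' \deqn{P_4 = p_0 + p_1 Lut_3 + p_2 Lut_4 + b_2 P_{4,exo}}
#' \deqn{Inh = h_0 + h_1 DomF + h_2 Lut_2 + h_3 Lut_3}
#'
#' @param state named numeric state vector (13 components, non-negative),
#'   or a matrix with one row per time and state names as columns.
#' @param dose_at_t numeric length-2 vector \code{c(e2exo, p4exo)} in
#'   pg/mL and ng/mL, or a two-column matrix matching \code{state} rows.
#' @param params a [cycle_params()] vector.
#' @return named vector \code{c(E2=, P4=, Inh=)} (pg/mL, ng/mL, IU/mL),
#'   or a three-column matrix for matrix input.
#' @export
auxiliary_hormones <- function(state, dose_at_t = c(0, 0), params) {
  p <- params
  if (is.matrix(state)) {
    if (!is.matrix(dose_at_t))
      dose_at_t <- matrix(dose_at_t, nrow(state), 2, byrow = TRUE)
    if (any(!is.finite(state)) || any(state < 0))
      stop("state must be finite and non-negative")
    E2 <- p[["e0"]] + p[["e1"]] * state[, "GrF"] +
      p[["e2"]] * state[, "DomF"] + p[["e3"]] * state[, "Lut4"] +
      p[["b1"]] * dose_at_t[, 1]
    P4 <- p[["p0"]] + p[["p1"]] * state[, "Lut3"] +
      p[["p2"]] * state[, "Lut4"] + p[["b2"]] * dose_at_t[, 2]
    Inh <- p[["h0"]] + p[["h1"]] * state[, "DomF"] +
      p[["h2"]] * state[, "Lut2"] + p[["h3"]] * state[, "Lut3"]
    return(cbind(E2 = E2, P4 = P4, Inh = Inh))
  }
  if (any(!is.finite(state)) || any(state < 0))
    stop("state must be finite and non-negative")
  s <- state
  c(E2 = unname(p[["e0"]] + p[["e1"]] * s[["GrF"]] + p[["e2"]] * s[["DomF"]] +
                  p[["e3"]] * s[["Lut4"]] + p[["b1"]] * dose_at_t[[1]]),
    P4 = unname(p[["p0"]] + p[["p1"]] * s[["Lut3"]] + p[["p2"]] * s[["Lut4"]] +
                  p[["b2"]] * dose_at_t[[2]]),
    Inh = unname(p[["h0"]] + p[["h1"]] * s[["DomF"]] + p[["h2"]] * s[["Lut2"]] +
                   p[["h3"]] * s[["Lut3"]]))
}

#' Right-hand side of the 13-state cycle model
#'
#' Reference (pure R) transcription of the delay differential equations.
#' The pituitary block tracks synthesis, release and clearance of LH and
#' FSH: LH synthesis is switched on by an order-8 Hill function of E2
#' above the threshold \code{Km_LH} and inhibited by P4; release of the
#' reserve pools is stimulated by P4 and inhibited by E2 (quadratically
#' for FSH); clearance is linear.  FSH synthesis is inhibited by inhibin
#' delayed by \code{tau} days and, through the contraceptive mechanism
#' term \code{P4/w}, by progesterone.  The ovarian block moves active
#' follicular/luteal mass through nine stages; recruitment is stimulated
#' by FSH and inhibited by progesterone through \code{P4/q}.
#'
#' @param t time (days).
#' @param state named numeric 13-vector.
#' @param delayed_inh inhibin concentration at \code{t - tau} (IU/mL),
#'   computed via [auxiliary_hormones()] on the delayed state.
#' @param dose a [dose_schedule()].
#' @param params a [cycle_params()] vector.
#' @return named numeric 13-vector of time derivatives.
#' @export
cycle_rhs <- function(t, state, delayed_inh, dose, params) {
  if (any(!is.finite(state)) || !is.finite(delayed_inh))
    stop("non-finite state or delayed inhibin")
  p <- params
  s <- pmax(state, 0)  # guard against tiny solver undershoot
  dval <- c(dose$e2(t), dose$p4(t))
  h <- auxiliary_hormones(s, dval, p)
  E2 <- h[["E2"]]; P4 <- h[["P4"]]

  hill <- E2^8 / (p[["Km_LH"]]^8 + E2^8)
  syn_LH <- (p[["V0_LH"]] + p[["V1_LH"]] * hill) / (1 + P4 / p[["Ki_LH_P"]])
  rel_LH <- p[["k_LH"]] * (1 + p[["c_LH_P"]] * P4) * s[["RP_LH"]] /
    (1 + p[["c_LH_E"]] * E2)

  syn_FSH <- p[["V_FSH"]] /
    (1 + delayed_inh / p[["Ki_FSH_Inh"]] + P4 / p[["w"]])
  rel_FSH <- p[["k_FSH"]] * (1 + p[["c_FSH_P"]] * P4) * s[["RP_FSH"]] /
    (1 + p[["c_FSH_E"]] * E2)^2

  LH <- s[["LH"]]; FSH <- s[["FSH"]]
  recr <- (p[["b"]] + p[["c1"]] * s[["RcF"]]) * FSH / (1 + P4 / p[["q"]])
  f12 <- p[["c2"]] * LH^p[["alpha"]] * s[["RcF"]]
  f23 <- p[["c3"]] * LH * s[["GrF"]]
  f34 <- p[["c4"]] * LH^p[["gamma"]] * s[["DomF"]]

  c(RP_LH = syn_LH - rel_LH,
    LH = rel_LH / p[["v"]] - p[["alpha_LH"]] * LH,
    RP_FSH = syn_FSH - rel_FSH,
    FSH = rel_FSH / p[["v"]] - p[["alpha_FSH"]] * FSH,
    RcF = recr - f12,
    GrF = f12 - f23,
    DomF = f23 - f34,
    Sc1 = f34 - p[["d1"]] * s[["Sc1"]],
    Sc2 = p[["d1"]] * s[["Sc1"]] - p[["d2"]] * s[["Sc2"]],
    Lut1 = p[["d2"]] * s[["Sc2"]] - p[["k1"]] * s[["Lut1"]],
    Lut2 = p[["k1"]] * s[["Lut1"]] - p[["k2"]] * s[["Lut2"]],
    Lut3 = p[["k2"]] * s[["Lut2"]] - p[["k3"]] * s[["Lut3"]],
    Lut4 = p[["k3"]] * s[["Lut3"]] - p[["k4"]] * s[["Lut4"]])
}
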