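# The reduced nine-ODE model of the inversion-excision switch.
#
# State (all a.u.): F (active nuclear FlpO), OHT (4-OHT), Fa (inactive
# cytosolic FlpO), Fb (leak-pathway FlpO), and the five DNA states D_S1,
# D_tS1, D_tS2, D_SX, D_S2. Each recombination event is a single reversible
# reaction: k1, k2 take State 1 to the transient states; k3, k4 take the
# transient states to State 2 plus the excised loop SX; the single rate k_r
# drives every reverse reaction; delta dilutes free SX.

REDUCED_STATE_NAMES <- c("F", "OHT", "Fa", "Fb",
                         "D_S1", "D_tS1", "D_tS2", "D_SX", "D_S2")

#' State names of the reduced model
#' @return Character vector of the nine state variables, in model order.
#' @export
reduced_state_names <- function() REDUCED_STATE_NAMES

#' Right-hand side of the reduced nine-ODE model
#'
#' Evaluates the printed system term for term. Active FlpO `F` is consumed by
#' both forward and reverse inversion fluxes; the excision reverse flux
#' `k_r * D_SX * D_S2` proceeds without `F`; the nuclear-import gains carry
#' the volume quotient `vbar` while the corresponding cytosolic losses do
#' not; the SX balance carries two reverse-excision loss terms and the
#' dilution sink.
#'
#' @param state Named numeric vector over [reduced_state_names()].
#' @param params A [reduced_parameters()] object (or coercible named list).
#' @return Named derivative vector in state order.
#' @export
reduced_rhs <- function(state, params) {
  p <- params
  if (any(unlist(p[reduced_fitted_names()]) < 0)) {
    stop("negative rate constant")
  }
  y <- state[REDUCED_STATE_NAMES]
  if (anyNA(y)) stop("state must be named over the nine reduced variables")
  F <- y[["F"]]; OHT <- y[["OHT"]]; Fa <- y[["Fa"]]; Fb <- y[["Fb"]]
  DS1 <- y[["D_S1"]]; DtS1 <- y[["D_tS1"]]; DtS2 <- y[["D_tS2"]]
  DSX <- y[["D_SX"]]; DS2 <- y[["D_S2"]]

  dF <- p$K_a * p$vbar * OHT * Fa + p$K_b * p$vbar * Fb - p$beta_p * F -
    p$k1 * F * DS1 - p$k_r * F * DtS1 - p$k2 * F * DS1 - p$k_r * F * DtS2 -
    p$k3 * F * DtS1 - p$k4 * F * DtS2
  dOHT <- p$alpha_d - p$beta_d * OHT - p$K_a * OHT * Fa
  dFa <- p$alpha_a - p$beta_p * Fa - p$K_a * OHT * Fa
  dFb <- p$alpha_b - p$beta_p * Fb - p$K_b * Fb
  dDS1 <- p$k_r * F * DtS1 - p$k1 * F * DS1 + p$k_r * F * DtS2 -
    p$k2 * F * DS1
  dDtS1 <- p$k1 * F * DS1 - p$k_r * F * DtS1 - p$k3 * F * DtS1 +
    p$k_r * DSX * DS2
  dDtS2 <- p$k2 * F * DS1 - p$k_r * F * DtS2 - p$k4 * F * DtS2 +
    p$k_r * DSX * DS2
  dDSX <- p$k3 * F * DtS1 - p$k_r * DSX * DS2 + p$k4 * F * DtS2 -
    p$k_r * DSX * DS2 - p$delta * DSX
  dDS2 <- p$k3 * F * DtS1 - p$k_r * DSX * DS2 + p$k4 * F * DtS2 -
    p$k_r * DSX * DS2

  stats::setNames(c(dF, dOHT, dFa, dFb, dDS1, dDtS1, dDtS2, dDSX, dDS2),
                  REDUCED_STATE_NAMES)
}

#' Initial state of the reduced model
#'
#' All genomic DNA starts in State 1; FlpO pools start empty; 4-OHT starts at
#' the dose-mapped initial concentration.
#'
#' @param dose_au Initial 4-OHT concentration (a.u., non-negative).
#' @param total_dna Total genomic DNA (a.u., positive; default 1).
#' @return Named numeric state vector over [reduced_state_names()].
#' @export
reduced_initial_state <- function(dose_au = 0, total_dna = 1) {
  if (!is.finite(dose_au) || dose_au < 0) stop("dose_au must be >= 0")
  if (!is.finite(total_dna) || total_dna <= 0) stop("total_dna must be > 0")
  y <- stats::setNames(numeric(9), REDUCED_STATE_NAMES)
  y["OHT"] <- dose_au
  y["D_S1"] <- total_dna
  y
}

#' @keywords internal
reduced_param_vector <- function(params) {
  c(alpha_a = params$alpha_a, alpha_b = params$alpha_b,
    alpha_d = params$alpha_d, beta_p = params$beta_p, beta_d = params$beta_d,
    K_a = params$K_a, K_b = params$K_b, k1 = params$k1, k2 = params$k2,
    k3 = params$k3, k4 = params$k4, k_r = params$k_r, delta = params$delta,
    vbar = params$vbar)
}
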