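# Parameter containers for the mechanistic and reduced switch models.
#
# Units: concentrations are arbitrary units (a.u.), time is days. Zeroth-order
# rates are a.u./day, first-order rates 1/day, second-order rates 1/(a.u. day).

#' Names of the fitted rate constants of the reduced model
#'
#' The reduced inversion-excision model has exactly twelve fitted rate
#' constants; the 4-OHT input rate `alpha_d` and the cytoplasm-to-nucleus
#' volume quotient `vbar` are inputs, not fitted quantities.
#'
#' @return Character vector of length 12.
#' @export
reduced_fitted_names <- function() {
  c("alpha_a", "alpha_b", "beta_p", "beta_d", "K_a", "K_b",
    "k1", "k2", "k3", "k4", "k_r", "delta")
}

#' Names of the fitted rate constants of the mechanistic model
#'
#' Twenty-seven constants: six protein/drug rates, four cooperative-binding
#' quantities per FRT site pair (two pairs), the Holliday-junction entry/exit
#' pair `k3`/`k3_rev`, the four internal strand-exchange steps with reverses
#' (`k4`..`k7`), the excision resolution/re-association pair `k8`/`k8_rev`,
#' and the dilution rate `delta` of the free excised loop.
#'
#' @return Character vector of length 27.
#' @export
mechanistic_fitted_names <- function() {
  c("alpha_a", "alpha_b", "beta_p", "beta_d", "K_a", "K_b",
    "pairA_k_on", "pairA_k_off", "pairA_m1", "pairA_m2",
    "pairB_k_on", "pairB_k_off", "pairB_m1", "pairB_m2",
    "k3", "k3_rev",
    "k4", "k4_rev", "k5", "k5_rev", "k6", "k6_rev", "k7", "k7_rev",
    "k8", "k8_rev", "delta")
}

#' Reduced-model parameter set
#'
#' Constructs and validates the parameter set of the reduced nine-ODE model.
#' `k1` and `k2` are the forward inversion rates (State 1 to the two transient
#' states), `k3` and `k4` the forward excision rates (transient states to
#' State 2 plus the excised loop), and `k_r` the single shared
#' reverse-recombination rate. `alpha_d` encodes the 4-OHT input (dose
#' derived) and `vbar` the cytoplasm-to-nucleus volume quotient, fixed at 0.3.
#'
#' @param alpha_a,alpha_b Expression rates of cytosolic and leak-pathway FlpO
#'   (a.u./day).
#' @param beta_p,beta_d Degradation rates of FlpO protein and 4-OHT (1/day).
#' @param K_a 4-OHT-dependent FlpO activation/nuclear-import rate
#'   (1/(a.u. day)).
#' @param K_b Leaky FlpO nuclear-import rate (1/day).
#' @param k1,k2,k3,k4 Forward recombination rates (1/(a.u. day)).
#' @param k_r Shared reverse recombination rate (1/(a.u. day)).
#' @param delta Dilution rate of the free excised DNA loop (1/day).
#' @param alpha_d 4-OHT source rate (a.u./day); a dose input, never fitted.
#' @param vbar Cytoplasm-to-nucleus volume quotient (dimensionless).
#' @return An object of class `reduced_parameters` (a named list).
#' @export
reduced_parameters <- function(alpha_a = 0, alpha_b = 0, beta_p = 0,
                               beta_d = 0, K_a = 0, K_b = 0,
                               k1 = 0, k2 = 0, k3 = 0, k4 = 0,
                               k_r = 0, delta = 0,
                               alpha_d = 0, vbar = 0.3) {
  p <- list(alpha_a = alpha_a, alpha_b = alpha_b, beta_p = beta_p,
            beta_d = beta_d, K_a = K_a, K_b = K_b,
            k1 = k1, k2 = k2, k3 = k3, k4 = k4, k_r = k_r, delta = delta,
            alpha_d = alpha_d, vbar = vbar)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("all reduced-model parameters must be finite")
  if (any(vals < 0)) stop("reduced-model rates must be non-negative")
  structure(p, class = "reduced_parameters")
}

#' Build reduced parameters from a named vector of fitted values
#'
#' @param x Named numeric vector containing the twelve fitted rate constants
#'   (see [reduced_fitted_names()]).
#' @param alpha_d,vbar Non-fitted inputs passed through.
#' @return A `reduced_parameters` object.
#' @export
as_reduced_parameters <- function(x, alpha_d = 0, vbar = 0.3) {
  nm <- reduced_fitted_names()
  if (!all(nm %in% names(x))) {
    stop("missing fitted parameters: ", paste(setdiff(nm, names(x)), collapse = ", "))
  }
  do.call(reduced_parameters,
          c(as.list(x[nm]), list(alpha_d = alpha_d, vbar = vbar)))
}

#' @export
print.reduced_parameters <- function(x, ...) {
  cat("<reduced_parameters> 12 fitted rate constants + alpha_d, vbar\n")
  print(round(unlist(x), 5))
  invisible(x)
}

#' Effective cooperative binding rates for one FRT site pair
#'
#' FlpO monomer binding is positively cooperative: a monomer binds an
#' already-occupied attachment site with higher affinity than a free site.
#' With a common base on/off pair and multipliers `0 < m1 < 1`, `0 < m2 < 1`,
#' the free-site rates are (`m1 * k_on`, `k_off`) and the occupied-site rates
#' (`k_on`, `m2 * k_off`), which guarantees the affinity ordering
#' `k1/k-1 < k2/k-2`.
#'
#' @param k_on,k_off Base association/dissociation rates (non-negative).
#' @param m1,m2 Cooperativity multipliers, strictly inside (0, 1).
#' @return Named list with `on_free`, `off_free`, `on_occ`, `off_occ`.
#' @export
effective_binding_rates <- function(k_on, k_off, m1, m2) {
  if (!is.finite(m1) || !is.finite(m2) || m1 <= 0 || m1 >= 1 || m2 <= 0 || m2 >= 1) {
    stop("cooperativity multipliers m1, m2 must lie strictly in (0, 1)")
  }
  if (k_on < 0 || k_off < 0) stop("base binding rates must be non-negative")
  list(on_free = m1 * k_on, off_free = k_off,
       on_occ = k_on, off_occ = m2 * k_off)
}

#' Mechanistic-model parameter set
#'
#' Parameters of the full inversion-excision reaction network. Site-pair A is
#' shared by recombination events i1 and e2, site-pair B by i2 and e1; each
#' pair carries base binding rates and the two cooperativity multipliers.
#'
#' @param alpha_a,alpha_b,beta_p,beta_d,K_a,K_b As in [reduced_parameters()].
#' @param pairA_k_on,pairA_k_off,pairA_m1,pairA_m2 Site-pair A binding
#'   quantities (shared by events i1 and e2).
#' @param pairB_k_on,pairB_k_off,pairB_m1,pairB_m2 Site-pair B binding
#'   quantities (shared by events i2 and e1).
#' @param k3,k3_rev Holliday-junction entry/exit rates.
#' @param k4,k4_rev,k5,k5_rev,k6,k6_rev,k7,k7_rev Internal strand-exchange
#'   steps between the five junction complexes.
#' @param k8,k8_rev Excision resolution (junction to two products) and
#'   bimolecular re-association rates.
#' @param delta Dilution rate of the free excised loop (1/day).
#' @param alpha_d 4-OHT source rate (dose input, not fitted).
#' @param vbar Cytoplasm-to-nucleus volume quotient, fixed 0.3.
#' @return An object of class `mechanistic_parameters`.
#' @export
mechanistic_parameters <- function(alpha_a = 0, alpha_b = 0, beta_p = 0,
                                   beta_d = 0, K_a = 0, K_b = 0,
                                   pairA_k_on = 0, pairA_k_off = 0,
                                   pairA_m1 = 0.5, pairA_m2 = 0.5,
                                   pairB_k_on = 0, pairB_k_off = 0,
                                   pairB_m1 = 0.5, pairB_m2 = 0.5,
                                   k3 = 0, k3_rev = 0,
                                   k4 = 0, k4_rev = 0, k5 = 0, k5_rev = 0,
                                   k6 = 0, k6_rev = 0, k7 = 0, k7_rev = 0,
                                   k8 = 0, k8_rev = 0, delta = 0,
                                   alpha_d = 0, vbar = 0.3) {
  p <- mget(c(mechanistic_fitted_names(), "alpha_d", "vbar"))
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("all mechanistic parameters must be finite")
  neg <- setdiff(names(vals)[vals < 0], character())
  if (length(neg)) stop("negative rate(s): ", paste(neg, collapse = ", "))
  for (m in c("pairA_m1", "pairA_m2", "pairB_m1", "pairB_m2")) {
    if (p[[m]] <= 0 || p[[m]] >= 1) {
      stop("cooperativity multiplier ", m, " must lie strictly in (0, 1)")
    }
  }
  structure(p, class = "mechanistic_parameters")
}

#' Build mechanistic parameters from a named vector of fitted values
#'
#' @param x Named numeric vector covering [mechanistic_fitted_names()].
#' @param alpha_d,vbar Non-fitted inputs passed through.
#' @return A `mechanistic_parameters` object.
#' @export
as_mechanistic_parameters <- function(x, alpha_d = 0, vbar = 0.3) {
  nm <- mechanistic_fitted_names()
  if (!all(nm %in% names(x))) {
    stop("missing fitted parameters: ", paste(setdiff(nm, names(x)), collapse = ", "))
  }
  do.call(mechanistic_parameters,
          c(as.list(x[nm]), list(alpha_d = alpha_d, vbar = vbar)))
}

#' @export
print.mechanistic_parameters <- function(x, ...) {
  cat("<mechanistic_parameters> 27 fitted rate constants + alpha_d, vbar\n")
  print(round(unlist(x), 5))
  invisible(x)
}
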