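# Independent oracles, kept deliberately separate from the package's own
# computation paths.

# Term-by-term transcription of the reduced nine-equation system, written as
# explicit per-equation term lists (independent of reduced_rhs()).
oracle_reduced_rhs <- function(y, p) {
  F <- y[["F"]]; OHT <- y[["OHT"]]; Fa <- y[["Fa"]]; Fb <- y[["Fb"]]
  S1 <- y[["D_S1"]]; tS1 <- y[["D_tS1"]]; tS2 <- y[["D_tS2"]]
  SX <- y[["D_SX"]]; S2 <- y[["D_S2"]]
  terms <- list(
    F = c(p$K_a * p$vbar * OHT * Fa, p$K_b * p$vbar * Fb, -p$beta_p * F,
          -p$k1 * F * S1, -p$k_r * F * tS1, -p$k2 * F * S1,
          -p$k_r * F * tS2, -p$k3 * F * tS1, -p$k4 * F * tS2),
    OHT = c(p$alpha_d, -p$beta_d * OHT, -p$K_a * OHT * Fa),
    Fa = c(p$alpha_a, -p$beta_p * Fa, -p$K_a * OHT * Fa),
    Fb = c(p$alpha_b, -p$beta_p * Fb, -p$K_b * Fb),
    D_S1 = c(p$k_r * F * tS1, -p$k1 * F * S1, p$k_r * F * tS2,
             -p$k2 * F * S1),
    D_tS1 = c(p$k1 * F * S1, -p$k_r * F * tS1, -p$k3 * F * tS1,
              p$k_r * SX * S2),
    D_tS2 = c(p$k2 * F * S1, -p$k_r * F * tS2, -p$k4 * F * tS2,
              p$k_r * SX * S2),
    D_SX = c(p$k3 * F * tS1, -p$k_r * SX * S2, p$k4 * F * tS2,
             -p$k_r * SX * S2, -p$delta * SX),
    D_S2 = c(p$k3 * F * tS1, -p$k_r * SX * S2, p$k4 * F * tS2,
             -p$k_r * SX * S2))
  vapply(terms, sum, numeric(1))
}

# Naive reaction-by-reaction accumulation of the mass-action derivative,
# independent of the stoichiometry-matrix path.
oracle_network_rhs <- function(net, state) {
  names(state) <- net$species$name
  d <- stats::setNames(numeric(length(state)), names(state))
  for (j in seq_len(nrow(net$reactions))) {
    r <- net$reactions[j, ]
    rate <- net$rate_values[[r$rate_ref]]
    flux <- rate
    re <- r$reactants[[1]]
    for (nm in names(re)) flux <- flux * state[[nm]]^re[[nm]]
    for (nm in names(re)) d[nm] <- d[nm] - re[[nm]] * flux
    pd <- r$products[[1]]
    for (nm in names(pd)) d[nm] <- d[nm] + pd[[nm]] * flux
  }
  d
}

# Brute-force distance: explicit sum of the 40 absolute residuals over ten.
oracle_distance <- function(x, y) {
  total <- 0
  for (i in seq_along(x)) total <- total + abs(x[i] - y[i])
  total / 10
}

# Dense-scan response time at fixed resolution (no interpolation).
oracle_response_time <- function(t, v, orientation, step = 1e-4) {
  tt <- seq(min(t), max(t), by = step)
  vv <- stats::approx(t, v, xout = tt)$y
  if (orientation == "ON") {
    hit <- vv >= 0.9 * max(vv)
  } else {
    hit <- (vv[1] - vv) >= 0.9 * (vv[1] - min(vv))
  }
  tt[which(hit)[1]]
}

random_reduced_params <- function(alpha_d = 1) {
  as_reduced_parameters(
    stats::setNames(stats::runif(12), reduced_fitted_names()),
    alpha_d = alpha_d)
}

random_mechanistic_params <- function(alpha_d = 1) {
  x <- stats::setNames(stats::runif(27), mechanistic_fitted_names())
  # keep the cooperativity multipliers strictly interior
  for (m in c("pairA_m1", "pairA_m2", "pairB_m1", "pairB_m2")) {
    x[m] <- 0.05 + 0.9 * x[m]
  }
  as_mechanistic_parameters(x, alpha_d = alpha_d)
}

noiseless_datasets <- function() {
  generate_datasets(synthetic_config(
    noise_sd = 0, apply_global_max_normalization = FALSE))
}
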