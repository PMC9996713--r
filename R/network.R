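# Programmatic construction of the full mechanistic inversion-excision
# reaction network and its mass-action right-hand side.
#
# The switch comprises four recombination sub-networks sharing free genetic
# states: two inversions (i1: S1 <-> tS1, i2: S1 <-> tS2) and two excisions
# (e1: tS1 -> S2 + SX, e2: tS2 -> S2 + SX). FRT site-pair A serves i1/e2 and
# site-pair B serves i2/e1. Each event runs through a cooperative monomer
# binding cascade (free -> F1 -> {F1,1 | F2,0} -> F3 -> F4), five sequential
# Holliday-junction complexes, and a product-side cascade: mirrored
# dissociation for inversions, a resolved product pair (S2-strand and excised
# SX loop, each carrying a doubly-occupied composite site) for excisions.

DNA_STATE_TAGS <- c("S1", "tS1", "tS2", "S2", "SX",
                    paste0("HJ", 1:5))

#' @keywords internal
species_name <- function(state, pathway, occ) {
  if (occ == "free") return(state)
  if (grepl("^HJ", state)) return(paste(state, pathway, sep = "."))
  paste(state, pathway, occ, sep = ".")
}

#' @keywords internal
derived_rate_table <- function(params) {
  rA <- effective_binding_rates(params$pairA_k_on, params$pairA_k_off,
                                params$pairA_m1, params$pairA_m2)
  rB <- effective_binding_rates(params$pairB_k_on, params$pairB_k_off,
                                params$pairB_m1, params$pairB_m2)
  values <- c(
    alpha_a = params$alpha_a, alpha_b = params$alpha_b,
    alpha_d = params$alpha_d,
    beta_p = params$beta_p, beta_d = params$beta_d,
    K_a = params$K_a, K_b = params$K_b,
    pairA_on_free = rA$on_free, pairA_off_free = rA$off_free,
    pairA_on_occ = rA$on_occ, pairA_off_occ = rA$off_occ,
    pairB_on_free = rB$on_free, pairB_off_free = rB$off_free,
    pairB_on_occ = rB$on_occ, pairB_off_occ = rB$off_occ,
    k3 = params$k3, k3_rev = params$k3_rev,
    k4 = params$k4, k4_rev = params$k4_rev,
    k5 = params$k5, k5_rev = params$k5_rev,
    k6 = params$k6, k6_rev = params$k6_rev,
    k7 = params$k7, k7_rev = params$k7_rev,
    k8 = params$k8, k8_rev = params$k8_rev,
    delta = params$delta)
  fitted_map <- list(
    alpha_a = "alpha_a", alpha_b = "alpha_b", alpha_d = character(0),
    beta_p = "beta_p", beta_d = "beta_d", K_a = "K_a", K_b = "K_b",
    pairA_on_free = c("pairA_m1", "pairA_k_on"),
    pairA_off_free = "pairA_k_off",
    pairA_on_occ = "pairA_k_on",
    pairA_off_occ = c("pairA_m2", "pairA_k_off"),
    pairB_on_free = c("pairB_m1", "pairB_k_on"),
    pairB_off_free = "pairB_k_off",
    pairB_on_occ = "pairB_k_on",
    pairB_off_occ = c("pairB_m2", "pairB_k_off"),
    k3 = "k3", k3_rev = "k3_rev", k4 = "k4", k4_rev = "k4_rev",
    k5 = "k5", k5_rev = "k5_rev", k6 = "k6", k6_rev = "k6_rev",
    k7 = "k7", k7_rev = "k7_rev", k8 = "k8", k8_rev = "k8_rev",
    delta = "delta")
  list(values = values, fitted_map = fitted_map)
}

# Reversible edges of the two-site binding cascade. "on_free"/"off_free" are
# the free-site rates (m1*k_on, k_off); "on_occ"/"off_occ" the occupied-site
# rates (k_on, m2*k_off). F1,1 has one monomer at each site; F2,0 two at one.
CASCADE_EDGES <- list(
  list(from = "free", to = "F1",   on = "on_free", off = "off_free"),
  list(from = "F1",   to = "F1_1", on = "on_free", off = "off_free"),
  list(from = "F1",   to = "F2_0", on = "on_occ",  off = "off_occ"),
  list(from = "F1_1", to = "F3",   on = "on_occ",  off = "off_occ"),
  list(from = "F2_0", to = "F3",   on = "on_free", off = "off_free"),
  list(from = "F3",   to = "F4",   on = "on_occ",  off = "off_occ"))

# Composite product sites of an excision carry two monomers at one site.
PRODUCT_EDGES <- list(
  list(from = "free", to = "F1", on = "on_free", off = "off_free"),
  list(from = "F1",   to = "F2", on = "on_occ",  off = "off_occ"))

#' @keywords internal
cascade_reactions <- function(state, pathway, pair, edges = CASCADE_EDGES) {
  out <- list()
  for (e in edges) {
    lo <- species_name(state, pathway, e$from)
    hi <- species_name(state, pathway, e$to)
    out[[length(out) + 1L]] <- list(
      name = paste0("bind:", lo, "->", hi),
      rate_ref = paste0(pair, "_", e$on),
      reactants = c(stats::setNames(1, lo), F = 1),
      products = stats::setNames(1, hi))
    out[[length(out) + 1L]] <- list(
      name = paste0("unbind:", hi, "->", lo),
      rate_ref = paste0(pair, "_", e$off),
      reactants = stats::setNames(1, hi),
      products = c(stats::setNames(1, lo), F = 1))
  }
  out
}

#' @keywords internal
ladder_reactions <- function(pathway) {
  out <- list()
  steps <- c("k4", "k5", "k6", "k7")
  for (i in 1:4) {
    a <- species_name(paste0("HJ", i), pathway, "hj")
    b <- species_name(paste0("HJ", i + 1), pathway, "hj")
    out[[length(out) + 1L]] <- list(
      name = paste0("exchange:", a, "->", b), rate_ref = steps[i],
      reactants = stats::setNames(1, a), products = stats::setNames(1, b))
    out[[length(out) + 1L]] <- list(
      name = paste0("exchange:", b, "->", a), rate_ref = paste0(steps[i], "_rev"),
      reactants = stats::setNames(1, b), products = stats::setNames(1, a))
  }
  out
}

#' Build the full mechanistic reaction network
#'
#' Enumerates every species and reaction of the inversion-excision switch:
#' 63 DNA-containing species (5 free genetic states plus the bound complexes
#' and Holliday junctions of the four recombination events) and the four
#' protein/drug species `F`, `Fa`, `Fb`, `OHT`. FlpO activation converts
#' `Fa + OHT` into `vbar` units of nuclear `F` (the cytoplasm-to-nucleus
#' volume quotient enters as a product stoichiometry), leak import converts
#' `Fb` likewise, and the free excised loop `SX` is diluted at rate `delta`.
#'
#' @param params A [mechanistic_parameters()] object.
#' @return An object of class `recombination_network`: a list with `species`
#'   and `reactions` tibbles, the sparse stoichiometry matrix `stoich`
#'   (species x reactions), derived rate values, and the parameter set.
#' @export
build_mechanistic_network <- function(params) {
  stopifnot(inherits(params, "mechanistic_parameters"))
  rt <- derived_rate_table(params)

  events <- list(
    i1 = list(kind = "inversion", sub = "S1",  prod = "tS1", pair = "pairA"),
    i2 = list(kind = "inversion", sub = "S1",  prod = "tS2", pair = "pairB"),
    e1 = list(kind = "excision",  sub = "tS1", prod = "S2",  pair = "pairB"),
    e2 = list(kind = "excision",  sub = "tS2", prod = "S2",  pair = "pairA"))

  ## ---- species enumeration ------------------------------------------------
  occs <- c("F1", "F1_1", "F2_0", "F3", "F4")
  sp <- list()
  add_sp <- function(name, pathway, state_tag, occupancy) {
    sp[[length(sp) + 1L]] <<- tibble::tibble(
      name = name, pathway = pathway, state_tag = state_tag,
      occupancy = occupancy)
  }
  for (s in c("S1", "tS1", "tS2", "S2", "SX")) add_sp(s, "none", s, "free")
  for (ev in names(events)) {
    e <- events[[ev]]
    for (occ in occs) add_sp(species_name(e$sub, ev, occ), ev, e$sub, occ)
    for (i in 1:5) add_sp(paste0("HJ", i, ".", ev), ev, paste0("HJ", i), "hj")
    if (e$kind == "inversion") {
      for (occ in occs) add_sp(species_name(e$prod, ev, occ), ev, e$prod, occ)
    } else {
      for (occ in c("F2", "F1")) {
        add_sp(species_name("S2", ev, occ), ev, "S2", occ)
        add_sp(species_name("SX", ev, occ), ev, "SX", occ)
      }
    }
  }
  for (s in c("F", "Fa", "Fb", "OHT")) add_sp(s, "none", s, "none")
  species <- dplyr::bind_rows(sp)
  if (anyDuplicated(species$name)) stop("duplicate species in enumeration")

  species <- dplyr::mutate(
    species,
    is_dna = .data$state_tag %in% DNA_STATE_TAGS,
    carries_promoter_strand = .data$is_dna & !(.data$state_tag == "SX"),
    # Excision junctions still hold the whole parental DNA, blank included;
    # only S2-strand species have shed the blank sequence.
    carries_blank_unit = .data$is_dna & !(.data$state_tag == "S2"))
  # Junction complexes of the excisions carry both strands.
  species$carries_promoter_strand[grepl("^HJ", species$state_tag)] <- TRUE
  species$carries_blank_unit[grepl("^HJ", species$state_tag)] <- TRUE

  ## Aggregation groups: State-1 side vs CAR-expressing side (ON convention).
  ## Inversion junctions sit on the State-1 side of the boundary flux of the
  ## aggregated State-1 equation; excision product species (S2 strand, SX
  ## loop) carry weight 1/2 each so one excised parental DNA counts once.
  species$group <- NA_character_
  species$weight <- 0
  is_s1_side <- species$state_tag == "S1" |
    (species$pathway %in% c("i1", "i2") & grepl("^HJ", species$state_tag))
  species$group[species$is_dna] <- ifelse(is_s1_side[species$is_dna],
                                          "state1", "expressing")
  species$weight[species$is_dna] <- ifelse(
    species$state_tag[species$is_dna] %in% c("S2", "SX"), 0.5, 1)

  ## ---- reaction enumeration -----------------------------------------------
  rx <- list()
  add_rx <- function(lst) rx[[length(rx) + 1L]] <<- lst
  one <- function(nm) stats::setNames(1, nm)

  # FlpO expression, activation, import, degradation; 4-OHT source/decay.
  add_rx(list(name = "express:Fa", rate_ref = "alpha_a",
              reactants = numeric(0), products = one("Fa")))
  add_rx(list(name = "express:Fb", rate_ref = "alpha_b",
              reactants = numeric(0), products = one("Fb")))
  add_rx(list(name = "source:OHT", rate_ref = "alpha_d",
              reactants = numeric(0), products = one("OHT")))
  add_rx(list(name = "activate:Fa->F", rate_ref = "K_a",
              reactants = c(Fa = 1, OHT = 1),
              products = stats::setNames(params$vbar, "F")))
  add_rx(list(name = "import:Fb->F", rate_ref = "K_b",
              reactants = one("Fb"),
              products = stats::setNames(params$vbar, "F")))
  for (s in c("F", "Fa", "Fb")) {
    add_rx(list(name = paste0("degrade:", s), rate_ref = "beta_p",
                reactants = one(s), products = numeric(0)))
  }
  add_rx(list(name = "degrade:OHT", rate_ref = "beta_d",
              reactants = one("OHT"), products = numeric(0)))
  add_rx(list(name = "dilute:SX", rate_ref = "delta",
              reactants = one("SX"), products = numeric(0)))

  for (ev in names(events)) {
    e <- events[[ev]]
    for (r in cascade_reactions(e$sub, ev, e$pair)) add_rx(r)
    subF4 <- species_name(e$sub, ev, "F4")
    hj <- paste0("HJ", 1:5, ".", ev)
    add_rx(list(name = paste0("junction:", subF4, "->", hj[1]), rate_ref = "k3",
                reactants = one(subF4), products = one(hj[1])))
    add_rx(list(name = paste0("junction:", hj[1], "->", subF4), rate_ref = "k3_rev",
                reactants = one(hj[1]), products = one(subF4)))
    for (r in ladder_reactions(ev)) add_rx(r)
    if (e$kind == "inversion") {
      prodF4 <- species_name(e$prod, ev, "F4")
      # Mirror of the substrate side: product re-entry at k3, exit at k3_rev.
      add_rx(list(name = paste0("junction:", hj[5], "->", prodF4),
                  rate_ref = "k3_rev",
                  reactants = one(hj[5]), products = one(prodF4)))
      add_rx(list(name = paste0("junction:", prodF4, "->", hj[5]),
                  rate_ref = "k3",
                  reactants = one(prodF4), products = one(hj[5])))
      for (r in cascade_reactions(e$prod, ev, e$pair)) add_rx(r)
    } else {
      s2F2 <- species_name("S2", ev, "F2")
      sxF2 <- species_name("SX", ev, "F2")
      add_rx(list(name = paste0("resolve:", hj[5], "->", s2F2, "+", sxF2),
                  rate_ref = "k8",
                  reactants = one(hj[5]),
                  products = c(one(s2F2), one(sxF2))))
      add_rx(list(name = paste0("reassociate:", s2F2, "+", sxF2, "->", hj[5]),
                  rate_ref = "k8_rev",
                  reactants = c(one(s2F2), one(sxF2)),
                  products = one(hj[5])))
      for (st in c("S2", "SX")) {
        for (r in cascade_reactions(st, ev, e$pair, edges = PRODUCT_EDGES)) add_rx(r)
      }
    }
  }

  reactions <- tibble::tibble(
    name = vapply(rx, `[[`, character(1), "name"),
    rate_ref = vapply(rx, `[[`, character(1), "rate_ref"),
    reactants = lapply(rx, `[[`, "reactants"),
    products = lapply(rx, `[[`, "products"))
  reactions$monomer_delta <- vapply(rx, function(r) {
    sum(r$products[names(r$products) == "F"]) -
      sum(r$reactants[names(r$reactants) == "F"])
  }, numeric(1))

  ## ---- stoichiometry matrix ----------------------------------------------
  idx <- stats::setNames(seq_len(nrow(species)), species$name)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    for (nm in names(r$reactants)) {
      trip_i <- c(trip_i, idx[[nm]]); trip_j <- c(trip_j, j)
      trip_x <- c(trip_x, -r$reactants[[nm]])
    }
    for (nm in names(r$products)) {
      trip_i <- c(trip_i, idx[[nm]]); trip_j <- c(trip_j, j)
      trip_x <- c(trip_x, r$products[[nm]])
    }
  }
  stoich <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                 dims = c(nrow(species), length(rx)),
                                 dimnames = list(species$name, reactions$name))

  # Reactant index vectors for fast mass-action flux evaluation (all reactant
  # stoichiometries are 1 and reactions are at most bimolecular).
  ridx1 <- integer(length(rx)); ridx2 <- integer(length(rx))
  for (j in seq_along(rx)) {
    rn <- names(rx[[j]]$reactants)
    ridx1[j] <- if (length(rn) >= 1) idx[[rn[1]]] else 0L
    ridx2[j] <- if (length(rn) >= 2) idx[[rn[2]]] else 0L
  }

  net <- structure(list(
    species = species, reactions = reactions, stoich = stoich,
    rate_values = rt$values, rate_fitted_map = rt$fitted_map,
    params = params, ridx1 = ridx1, ridx2 = ridx2),
    class = "recombination_network")
  check_network_invariants(net)
  net
}

#' @keywords internal
check_network_invariants <- function(net) {
  sp <- net$species
  pr <- stats::setNames(as.numeric(sp$carries_promoter_strand), sp$name)
  bl <- stats::setNames(as.numeric(sp$carries_blank_unit), sp$name)
  for (j in seq_len(nrow(net$reactions))) {
    r <- net$reactions[j, ]
    re <- r$reactants[[1]]; pd <- r$products[[1]]
    d_prom <- sum(pd * pr[names(pd)]) - sum(re * pr[names(re)])
    if (abs(d_prom) > 1e-12) {
      stop("promoter-strand count not conserved by reaction ", r$name)
    }
    d_blank <- sum(pd * bl[names(pd)]) - sum(re * bl[names(re)])
    is_dilution <- identical(r$rate_ref, "delta")
    if (!is_dilution && abs(d_blank) > 1e-12) {
      stop("blank-unit count not conserved by reaction ", r$name)
    }
    if (length(re) > 2 || length(pd) > 2) stop("reaction beyond bimolecular")
  }
  invisible(net)
}

#' Summary counts of a mechanistic network
#'
#' @param net A `recombination_network`.
#' @return Named list with `n_species`, `n_dna_species`, `n_protein_species`,
#'   `n_reactions`, and `n_fitted_parameters` (distinct fitted rate-constant
#'   names referenced by the reactions; excludes `alpha_d` and `vbar`).
#' @export
network_counts <- function(net) {
  refs <- unique(net$reactions$rate_ref)
  fitted <- unique(unlist(net$rate_fitted_map[refs]))
  list(n_species = nrow(net$species),
       n_dna_species = sum(net$species$is_dna),
       n_protein_species = sum(!net$species$is_dna),
       n_reactions = nrow(net$reactions),
       n_fitted_parameters = length(fitted))
}

#' @export
print.recombination_network <- function(x, ...) {
  ct <- network_counts(x)
  cat("<recombination_network>\n")
  cat("  species:  ", ct$n_species, " (", ct$n_dna_species, " DNA, ",
      ct$n_protein_species, " protein/drug)\n", sep = "")
  cat("  reactions:", ct$n_reactions, "\n")
  cat("  fitted rate constants:", ct$n_fitted_parameters, "\n")
  invisible(x)
}

#' Mass-action right-hand side of a mechanistic network
#'
#' Computes the time derivative of every species concentration as the
#' stoichiometry matrix applied to the mass-action flux vector; every flux is
#' the rate constant times the product of its reactant concentrations.
#'
#' @param net A `recombination_network`.
#' @param state Numeric concentration vector, one entry per species (ordered
#'   as `net$species$name`; names optional).
#' @return Named numeric derivative vector.
#' @export
mass_action_rhs <- function(net, state) {
  if (length(state) != nrow(net$species)) {
    stop("state length ", length(state), " != species count ",
         nrow(net$species))
  }
  rates <- net$rate_values[net$reactions$rate_ref]
  cc <- c(1, as.numeric(state))
  flux <- as.numeric(rates) * cc[net$ridx1 + 1L] * cc[net$ridx2 + 1L]
  stats::setNames(as.numeric(net$stoich %*% flux), net$species$name)
}

#' Aggregate a mechanistic state into genetic-state group totals
#'
#' Sums species concentrations into the State-1 group and the CAR-expressing
#' group. Excision product species (the S2 strand and the excised SX loop,
#' free or bound) carry weight 1/2 each so that one excised parental DNA
#' contributes one unit, preserving concentration bookkeeping.
#'
#' @param net A `recombination_network`.
#' @param state Concentration vector (species order).
#' @param weights Optional numeric vector overriding the per-species group
#'   weights stored in the network.
#' @return Named numeric vector with components `state1` and `expressing`.
#' @export
state_totals <- function(net, state, weights = NULL) {
  sp <- net$species
  if (is.null(weights)) weights <- sp$weight
  if (any(sp$is_dna & is.na(sp$group))) {
    stop("DNA species without group assignment")
  }
  s1 <- sum(state[sp$group %in% "state1"] * weights[sp$group %in% "state1"])
  ex <- sum(state[sp$group %in% "expressing"] *
              weights[sp$group %in% "expressing"])
  c(state1 = s1, expressing = ex)
}

#' Initial state of the mechanistic network
#'
#' All genomic DNA starts as free State 1; proteins start at zero; 4-OHT
#' starts at the dose-mapped initial concentration.
#'
#' @param net A `recombination_network`.
#' @param oht0 Initial 4-OHT concentration (a.u.).
#' @param total_dna Total genomic DNA (a.u.), normalized to 1 by default.
#' @return Named numeric state vector.
#' @export
mechanistic_initial_state <- function(net, oht0 = 0, total_dna = 1) {
  if (oht0 < 0 || total_dna <= 0) stop("invalid initial condition")
  y <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  y["S1"] <- total_dna
  y["OHT"] <- oht0
  y
}

#' Serialize a network description to JSON
#'
#' Writes species (name, pathway, state tag, occupancy, strand flags) and
#' reactions (name, rate-constant reference, reactant/product stoichiometry,
#' monomer delta) for inspection and regression testing.
#'
#' @param net A `recombination_network`.
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
network_to_json <- function(net, path = NULL) {
  obj <- list(
    species = net$species[, c("name", "pathway", "state_tag", "occupancy",
                              "carries_promoter_strand", "carries_blank_unit",
                              "group", "weight")],
    reactions = lapply(seq_len(nrow(net$reactions)), function(j) {
      r <- net$reactions[j, ]
      list(name = r$name, rate_ref = r$rate_ref,
           reactants = as.list(r$reactants[[1]]),
           products = as.list(r$products[[1]]),
           monomer_delta = r$monomer_delta)
    }),
    rate_values = as.list(net$rate_values))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}
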