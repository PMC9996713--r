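# Structural and dynamical checks of the full mechanistic network builder.

make_net <- function(seed = 5) {
  set.seed(seed)
  build_mechanistic_network(random_mechanistic_params(alpha_d = 1))
}

test_that("network has the printed structural counts", {
  net <- make_net()
  ct <- network_counts(net)
  expect_equal(ct$n_dna_species, 63)
  expect_equal(ct$n_protein_species, 4)
  expect_equal(sort(net$species$name[!net$species$is_dna]),
               sort(c("F", "Fa", "Fb", "OHT")))
  expect_equal(ct$n_fitted_parameters, 27)
  # four recombination sub-networks sharing the free genetic states
  expect_setequal(setdiff(unique(net$species$pathway), "none"),
                  c("i1", "i2", "e1", "e2"))
  expect_true(all(net$species$pathway[grepl("^HJ", net$species$state_tag)]
                  %in% c("i1", "i2", "e1", "e2")))
  free <- net$species$occupancy == "free"
  expect_true(all(net$species$pathway[free] == "none"))
})

test_that("every reaction conserves strand counts and is at most bimolecular", {
  net <- make_net()
  sp <- net$species
  prom <- stats::setNames(as.numeric(sp$carries_promoter_strand), sp$name)
  blank <- stats::setNames(as.numeric(sp$carries_blank_unit), sp$name)
  for (j in seq_len(nrow(net$reactions))) {
    r <- net$reactions[j, ]
    re <- r$reactants[[1]]; pd <- r$products[[1]]
    expect_lte(length(re), 2)
    expect_lte(length(pd), 2)
    d_prom <- sum(pd * prom[names(pd)]) - sum(re * prom[names(re)])
    expect_equal(d_prom, 0, tolerance = 1e-12)
    d_blank <- sum(pd * blank[names(pd)]) - sum(re * blank[names(re)])
    if (r$rate_ref == "delta") {
      expect_equal(d_blank, -1)
    } else {
      expect_equal(d_blank, 0, tolerance = 1e-12)
    }
  }
  # monomer bookkeeping: binding consumes one F, unbinding releases one
  binds <- grepl("^bind:", net$reactions$name)
  unbinds <- grepl("^unbind:", net$reactions$name)
  expect_true(all(net$reactions$monomer_delta[binds] == -1))
  expect_true(all(net$reactions$monomer_delta[unbinds] == 1))
})

test_that("mass-action RHS matches naive per-reaction accumulation", {
  net <- make_net(seed = 17)
  set.seed(99)
  for (i in 1:100) {
    state <- runif(nrow(net$species), 0, 2)
    expect_equal(mass_action_rhs(net, state),
                 oracle_network_rhs(net, state), tolerance = 1e-12)
  }
  expect_error(mass_action_rhs(net, numeric(5)), "species count")
})

test_that("zero state leaves only the source terms", {
  net <- make_net(seed = 3)
  d <- mass_action_rhs(net, numeric(nrow(net$species)))
  expect_equal(d[["Fa"]], net$params$alpha_a)
  expect_equal(d[["Fb"]], net$params$alpha_b)
  expect_equal(d[["OHT"]], net$params$alpha_d)
  expect_equal(unname(d[setdiff(names(d), c("Fa", "Fb", "OHT"))]),
               rep(0, length(d) - 3))
})

test_that("promoter-strand derivative sums to zero for any state", {
  net <- make_net(seed = 23)
  set.seed(7)
  for (i in 1:20) {
    state <- runif(nrow(net$species), 0, 3)
    d <- mass_action_rhs(net, state)
    expect_equal(sum(d[net$species$carries_promoter_strand]), 0,
                 tolerance = 1e-10)
  }
})

test_that("state totals aggregate with half-weighted excision products", {
  net <- make_net()
  y <- mechanistic_initial_state(net, total_dna = 2)
  tot <- state_totals(net, y)
  expect_equal(tot[["state1"]], 2)
  expect_equal(tot[["expressing"]], 0)

  # one unit split between the paired excision products counts once, not twice
  y2 <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  y2["S2.e1.F2"] <- 1
  y2["SX.e1.F2"] <- 1
  tot2 <- state_totals(net, y2)
  expect_equal(tot2[["expressing"]], 1)
  expect_equal(tot2[["state1"]], 0)
})

test_that("trajectories conserve strands and reproduce the State-1 boundary flux", {
  net <- make_net(seed = 41)
  h <- 0.01
  traj <- simulate_switch(net, dose = dose_condition(1),
                          t_grid = seq(0, 4, by = h))
  M <- as.matrix(traj[, net$species$name])
  sp <- net$species

  prom <- M %*% as.numeric(sp$carries_promoter_strand)
  expect_lt(max(abs(prom - prom[1])), 1e-6)

  expect_gt(min(M), -1e-8)  # non-negativity up to solver tolerance

  # blank-unit flux: d/dt sum(blank species) = -delta * [free SX]
  blank <- M %*% as.numeric(sp$carries_blank_unit)
  mid <- 2:(nrow(M) - 1)
  fd <- (blank[mid + 1] - blank[mid - 1]) / (2 * h)
  expect_equal(fd, -net$params$delta * M[mid, "SX"], tolerance = 1e-4,
               ignore_attr = TRUE)

  # State-1 group total obeys the aggregated boundary-flux equation:
  # dS1/dt = k3 (tS-side F4 complexes) - k3_rev (inversion HJ5 complexes)
  w <- sp$weight; in_s1 <- sp$group %in% "state1"
  s1tot <- M[, in_s1, drop = FALSE] %*% w[in_s1]
  fd_s1 <- (s1tot[mid + 1] - s1tot[mid - 1]) / (2 * h)
  flux <- net$params$k3 * (M[mid, "tS1.i1.F4"] + M[mid, "tS2.i2.F4"]) -
    net$params$k3_rev * (M[mid, "HJ5.i1"] + M[mid, "HJ5.i2"])
  expect_equal(fd_s1, flux, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("network JSON export round-trips names and stoichiometries", {
  net <- make_net()
  path <- withr::local_tempfile(fileext = ".json")
  network_to_json(net, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(length(parsed$species), nrow(net$species))
  expect_equal(length(parsed$reactions), nrow(net$reactions))
  expect_equal(parsed$reactions[[1]]$rate_ref, net$reactions$rate_ref[1])
  j <- match(TRUE, grepl("^bind:", net$reactions$name))
  expect_equal(unlist(parsed$reactions[[j]]$reactants),
               net$reactions$reactants[[j]])
})
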