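spec <- switching_spec()

test_that("pair energy obeys closed forms, cutoff and continuity", {
  # beyond the cutoff: exactly zero
  expect_identical(pair_energy(13, 1, 1, 0.1, 0.1, 2, 2, spec), 0)
  # pure Coulomb inside the switch-on radius
  expect_equal(pair_energy(5, 1, 1, 0, 0, 2, 2, spec), 332.0636 / 5,
               tolerance = 1e-12)
  # continuity at both switching boundaries
  d <- 1e-6
  for (r0 in c(spec$r_on, spec$r_off)) {
    lhs <- pair_energy(r0 - d, 0.5, -0.3, 0.1, 0.2, 1.9, 2.1, spec)
    rhs <- pair_energy(r0 + d, 0.5, -0.3, 0.1, 0.2, 1.9, 2.1, spec)
    expect_lt(abs(lhs - rhs), 1e-4)
  }
  # switching factor is exactly 1 at r_on and 0 at r_off
  e_on <- pair_energy(spec$r_on, 1, 1, 0, 0, 2, 2, spec)
  expect_equal(e_on, 332.0636 / spec$r_on, tolerance = 1e-12)
  expect_identical(pair_energy(spec$r_off + 1e-12, 1, 1, 0, 0, 2, 2, spec), 0)
  # LJ minimum: at r = rmin1 + rmin2 the LJ term is -sqrt(eps1 eps2)
  expect_equal(pair_energy(4, 0, 0, 0.1, 0.4, 2, 2, spec), -sqrt(0.04),
               tolerance = 1e-12)
  expect_error(pair_energy(0, 1, 1, 0, 0, 2, 2, spec), "distance")
})

test_that("interaction energy equals the all-pairs double-loop oracle", {
  set.seed(5)
  n <- 10
  atoms <- data.frame(atom_index = 1:n, atom_name = "CA", residue_number = 1:n,
                      residue_name = "ALA", chain_id = rep(c("A", "B"), each = 5),
                      stringsAsFactors = FALSE)
  params <- data.frame(atom_index = 1:n, charge_e = runif(n, -0.5, 0.5),
                       epsilon_kcal_mol = runif(n, 0, 0.3),
                       rmin_half_A = runif(n, 1.5, 2.5))
  # jittered lattice: random but physically plausible separations (>= ~2 A),
  # as for real atoms, so LJ terms stay in a sane range
  lattice <- as.matrix(expand.grid(x = c(0, 5), y = c(0, 5, 10), z = c(0, 6)))[1:10, ]
  for (rep in 1:10) {
    xyz <- lattice + matrix(runif(n * 3, -0.9, 0.9), n, 3)
    e <- toy_ensemble(list(xyz), atoms = atoms)
    es <- interaction_energy_series(e, "chain A", "chain B", params, spec)
    expect_lt(abs(es$values - brute_interaction_energy(xyz, 1:5, 6:10, params, spec)),
              1e-10)
    # symmetry
    es_rev <- interaction_energy_series(e, "chain B", "chain A", params, spec)
    expect_equal(es_rev$values, es$values, tolerance = 1e-12)
    # components add up exactly
    expect_equal(es$values, es$coulomb + es$lennard_jones, tolerance = 1e-12)
    # shrinking the cutoff only removes pair contributions (oracle at both)
    spec_small <- switching_spec(r_on = 6, r_off = 8)
    es_small <- interaction_energy_series(e, "chain A", "chain B", params, spec_small)
    expect_lt(abs(es_small$values -
                  brute_interaction_energy(xyz, 1:5, 6:10, params, spec_small)),
              1e-10)
  }
})

test_that("distant atoms contribute nothing and contract errors fire", {
  atoms <- data.frame(atom_index = 1:2, atom_name = "CA", residue_number = 1:2,
                      residue_name = "ALA", chain_id = c("A", "B"),
                      stringsAsFactors = FALSE)
  params <- data.frame(atom_index = 1:2, charge_e = 1, epsilon_kcal_mol = 0.1,
                       rmin_half_A = 2)
  e <- toy_ensemble(list(rbind(c(0, 0, 0), c(20, 0, 0)),
                         rbind(c(0, 0, 0), c(25, 0, 0))), atoms = atoms)
  es <- interaction_energy_series(e, "chain A", "chain B", params, spec)
  expect_equal(es$values, c(0, 0))
  expect_error(interaction_energy_series(e, "chain A", "chain A", params, spec),
               "overlap|disjoint")
  expect_error(interaction_energy_series(e, "chain A", "chain B", params[1, ], spec),
               "missing")
  expect_error(switching_spec(r_on = 12, r_off = 10), "r_on")
})

test_that("interaction calls follow significance and the sign of the median energy", {
  set.seed(8)
  wt <- fake_energy_series(rnorm(2000, 0, 0.5), "WT")
  same <- fake_energy_series(wt$values, "same")
  t0 <- downsample_test(same$values, wt$values, seed = 1)
  expect_equal(interaction_call(same, wt, t0), "n.s.")
  stronger <- fake_energy_series(rnorm(2000, -20, 0.5), "stronger")
  t1 <- downsample_test(stronger$values, wt$values, seed = 1)
  expect_equal(interaction_call(stronger, wt, t1), "+")
  weaker <- fake_energy_series(rnorm(2000, 20, 0.5), "weaker")
  t2 <- downsample_test(weaker$values, wt$values, seed = 1)
  expect_equal(interaction_call(weaker, wt, t2), "-")
})

test_that("distance-dependent dielectric screens as 1/r^2", {
  dd <- switching_spec(dielectric = 1, distance_dependent = TRUE)
  expect_equal(pair_energy(5, 1, 1, 0, 0, 2, 2, dd), 332.0636 / 25,
               tolerance = 1e-12)
})
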