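tpl <- complex_template()
st <- build_template(tpl)

test_that("template is deterministic with exact helical geometry", {
  expect_equal(nrow(st$atoms), 200L)
  expect_equal(sum(st$atoms$chain_id == "A"), 80L)
  expect_equal(sum(st$atoms$chain_id == "B"), 120L)
  st2 <- build_template(tpl)
  expect_identical(st$xyz, st2$xyz)
  # consecutive C-alpha spacing exactly 3.8 A on both chains
  for (ch in c("A", "B")) {
    idx <- which(st$atoms$chain_id == ch)
    d <- sqrt(rowSums(diff(st$xyz[idx, ])^2))
    expect_lt(max(abs(d - 3.8)), 1e-6)
  }
  # degenerate single-residue mobile chain is valid
  st1 <- build_template(complex_template(n_res_mobile = 1L,
                                         domains = list(all = c(1L, 1L))))
  expect_equal(sum(st1$atoms$chain_id == "B"), 1L)
})

test_that("planted modes are orthonormal and validated", {
  md <- planted_modes(tpl)
  expect_lt(max(abs(crossprod(md$vectors) - diag(3))), 1e-12)
  expect_error(planted_modes(tpl, mode_sds = c(1, 2, 3)), "descending")
  expect_error(planted_modes(tpl, vectors = matrix(1, 360, 2),
                             mode_sds = c(2, 1)), "orthonormal")
})

test_that("zero-variance limit reproduces the template after superposition", {
  md <- planted_modes(tpl, mode_sds = c(3e-9, 2e-9, 1e-9), noise_sd = 0)
  sc <- variant_scenario("WT", n_frames = 5L, seed = 2L)
  e <- sample_ensemble(st, md, sc, 1L, 300)
  sup <- superpose_ensemble(e, st, "chain A and name CA")
  for (t in seq_len(5)) expect_lt(max(abs(sup$frames[t, , ] - st$xyz)), 1e-6)
})

test_that("a planted +2 sigma shift moves the mode-1 projection mean as the CLT predicts", {
  md <- planted_modes(tpl)
  sc <- variant_scenario("shifted", mode_shifts = c("1" = 2),
                         n_frames = 500L, seed = 11L)
  e <- sample_ensemble(st, md, sc, 1L, 300)
  sup <- superpose_ensemble(e, st, "chain A and name CA")
  midx <- which(st$atoms$chain_id == "B")
  disp <- t(apply(sup$frames[, midx, ], 1, function(m) as.vector(t(m - st$xyz[midx, ]))))
  proj <- disp %*% md$vectors[, 1]
  # mean within ~3 standard errors of the planted 2 * sd_1
  expect_lt(abs(mean(proj) - 2 * md$sds[1]), 3 * md$sds[1] / sqrt(500))
})

test_that("sampling is reproducible per (seed, replicate) and distinct across seeds", {
  md <- planted_modes(tpl)
  sc <- variant_scenario("WT", n_frames = 10L, seed = 5L)
  e1 <- sample_ensemble(st, md, sc, 1L, 300)
  e2 <- sample_ensemble(st, md, sc, 1L, 300)
  expect_identical(e1$frames, e2$frames)
  e3 <- sample_ensemble(st, md, sc, 2L, 300)
  expect_false(identical(e1$frames, e3$frames))
  sc2 <- variant_scenario("WT", n_frames = 10L, seed = 6L)
  expect_false(identical(e1$frames, sample_ensemble(st, md, sc2, 1L, 300)$frames))
  # unknown mode index is a hard error
  bad <- variant_scenario("x", mode_shifts = c("9" = 1), n_frames = 5L, seed = 1L)
  expect_error(sample_ensemble(st, md, bad, 1L, 300), "mode index")
})

test_that("the fixed chain is exactly static up to the rigid-body jitter", {
  md <- planted_modes(tpl)
  sc <- variant_scenario("WT", n_frames = 8L, seed = 9L)
  sup <- superpose_ensemble(sample_ensemble(st, md, sc, 1L, 300), st,
                            "chain A and name CA")
  aidx <- which(st$atoms$chain_id == "A")
  for (t in 1:8) expect_lt(max(abs(sup$frames[t, aidx, ] - st$xyz[aidx, ])), 1e-6)
})

test_that("temperature widens residual noise by sqrt(T/300) without moving means", {
  md <- planted_modes(tpl, mode_sds = c(3e-9, 2e-9, 1e-9), noise_sd = 0.5)
  sc <- variant_scenario("WT", n_frames = 400L, seed = 4L,
                         temperatures = c(300, 360))
  e300 <- superpose_ensemble(sample_ensemble(st, md, sc, 1L, 300), st,
                             "chain A and name CA")
  e360 <- superpose_ensemble(sample_ensemble(st, md, sc, 1L, 360), st,
                             "chain A and name CA")
  midx <- which(st$atoms$chain_id == "B")
  sd300 <- sd(e300$frames[, midx, 1])
  sd360 <- sd(e360$frames[, midx, 1])
  expect_equal(sd360 / sd300, sqrt(360 / 300), tolerance = 0.1)
})

test_that("charge scaling acts linearly and only on the named domain's Coulomb term", {
  # eps = 0 isolates the Coulomb component
  pt_wt <- make_parameter_table(st, NULL, tpl, epsilon = 0)
  sc2 <- variant_scenario("v", charge_scale = c(iSH2 = 2), seed = 1L)
  pt_2x <- make_parameter_table(st, sc2, tpl, epsilon = 0)
  sc0 <- variant_scenario("v0", charge_scale = c(iSH2 = 0), seed = 1L)
  pt_0 <- make_parameter_table(st, sc0, tpl, epsilon = 0)

  md <- planted_modes(tpl)
  e <- superpose_ensemble(
    sample_ensemble(st, md, variant_scenario("WT", n_frames = 5L, seed = 8L), 1L, 300),
    st, "chain A and name CA")
  sel_i <- "chain B and resid 61-120 and name CA"
  sel_a <- "chain A and name CA"
  e_wt <- interaction_energy_series(e, sel_i, sel_a, pt_wt)
  e_2x <- interaction_energy_series(e, sel_i, sel_a, pt_2x)
  e_0 <- interaction_energy_series(e, sel_i, sel_a, pt_0)
  expect_equal(e_2x$coulomb, 2 * e_wt$coulomb, tolerance = 1e-12)
  expect_equal(e_0$values, rep(0, 5))
  # identity scaling is the WT table
  sc1 <- variant_scenario("v1", charge_scale = c(iSH2 = 1), seed = 1L)
  expect_equal(make_parameter_table(st, sc1, tpl), make_parameter_table(st, NULL, tpl))
})

test_that("fixture sets are written as variant/temperature/replicate trees with a manifest", {
  dir <- file.path(tempdir(), "fixture_set_test")
  on.exit(unlink(dir, recursive = TRUE))
  scens <- default_scenarios(seed = 1L, n_frames = 6L, n_replicates = 2L,
                             temperatures = 300)
  manifest <- write_fixture_set(dir, scens)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "WT", "300", "1.pdb")))
  expect_true(file.exists(file.path(dir, "overgrowth_like", "parameters.tsv")))
  e <- read_ensemble(file.path(dir, "null_variant", "300", "2.pdb"))
  expect_equal(n_frames(e), 6L)
  expect_equal(length(manifest$variants), 3L)
})
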