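make_superposed <- function(scenario_name = "WT", shifts = numeric(0),
                            n_frames = 300L, seed = 10L, sds = c(3, 2, 1),
                            noise = 0.1) {
  tpl <- complex_template()
  st <- build_template(tpl)
  md <- planted_modes(tpl, mode_sds = sds, noise_sd = noise)
  sc <- variant_scenario(scenario_name, mode_shifts = shifts,
                         n_frames = n_frames, seed = seed)
  list(st = st, md = md,
       ens = superpose_ensemble(sample_ensemble(st, md, sc, 1L, 300), st,
                                "chain A and name CA"))
}

test_that("identical frames give an all-zero spectrum", {
  ref <- toy_structure(6)
  e <- toy_ensemble(list(ref$xyz, ref$xyz, ref$xyz))
  b <- fit_modes(e, "name CA", 3)
  expect_equal(b$eigenvalues, rep(0, 3))
  expect_equal(b$total_variance, 0)
})

test_that("the basis conserves total variance and is orthonormal", {
  s <- make_superposed(n_frames = 200L)
  idx <- resolve_selection(s$ens, "chain B and name CA")$indices
  b <- fit_modes(s$ens, "chain B and name CA", 5)
  # trace of the coordinate covariance computed independently
  x <- t(apply(s$ens$frames[, idx, ], 1, function(m) as.vector(t(m))))
  tr <- sum(apply(x, 2, var))
  expect_equal(b$total_variance, tr, tolerance = 1e-6)
  expect_lt(max(abs(crossprod(b$vectors) - diag(5))), 1e-8)
  expect_true(all(diff(b$eigenvalues) <= 1e-12))
  expect_true(all(b$variance_fraction >= 0 & b$variance_fraction <= 1))
  expect_error(fit_modes(toy_ensemble(list(toy_structure(4)$xyz)), "name CA"),
               "2 pooled frames")
})

test_that("planted modes are recovered with matching eigenvalues", {
  s <- make_superposed(n_frames = 1200L, noise = 0.05)
  b <- fit_modes(s$ens, "chain B and name CA", 3)
  for (k in 1:3) {
    expect_gt(abs(sum(b$vectors[, k] * s$md$vectors[, k])), 0.99)
    expect_lt(abs(b$eigenvalues[k] - s$md$sds[k]^2) / s$md$sds[k]^2, 0.15)
  }
})

test_that("projections are exact inner products with deterministic centering", {
  s <- make_superposed(n_frames = 100L)
  b <- fit_modes(s$ens, "chain B and name CA", 3)
  p <- project_ensemble(s$ens, b)
  expect_lt(max(abs(colMeans(p$scores))), 1e-6)
  # frame = mean + 2 v1 scores exactly (2, 0, 0)
  mean_frame <- matrix(b$mean_conformation, ncol = 3, byrow = TRUE)
  shifted <- mean_frame + 2 * matrix(b$vectors[, 1], ncol = 3, byrow = TRUE)
  atoms <- s$ens$atoms[b$indices, ]
  atoms$atom_index <- seq_len(nrow(atoms))
  e1 <- toy_ensemble(list(shifted), atoms = atoms)
  b1 <- b
  b1$indices <- seq_len(nrow(atoms))
  p1 <- project_ensemble(e1, b1)
  expect_equal(as.numeric(p1$scores), c(2, 0, 0), tolerance = 1e-8)
  # basis is invariant under frame-order permutation (sign convention fixed)
  perm <- s$ens
  set.seed(1)
  perm$frames <- perm$frames[sample(n_frames(perm)), , ]
  b_perm <- fit_modes(perm, "chain B and name CA", 3)
  expect_equal(b_perm$vectors, b$vectors, tolerance = 1e-8)
})

test_that("a planted +2 sigma variant projects near +2 sd on PC1", {
  wt <- make_superposed("WT", n_frames = 800L, seed = 21L)
  v <- make_superposed("var", shifts = c("1" = 2), n_frames = 800L, seed = 22L)
  b <- fit_modes(list(wt$ens, v$ens), "chain B and name CA", 3)
  pv <- project_ensemble(v$ens, b)
  pw <- project_ensemble(wt$ens, b)
  delta <- median(pv$scores[, 1]) - median(pw$scores[, 1])
  expect_equal(abs(delta), 2 * 3, tolerance = 0.15)
})

test_that("the one-sigma shift classifier has inclusive, signed semantics", {
  set.seed(3)
  wt_scores <- rnorm(3000)
  # identical data -> none
  c0 <- call_pc_shift(fake_projection(cbind(wt_scores)),
                      fake_projection(cbind(wt_scores)), 1)
  expect_equal(c0$call, "none")
  # clearly separated populations -> signed call
  c1 <- call_pc_shift(fake_projection(cbind(rnorm(3000, 2))),
                      fake_projection(cbind(wt_scores)), 1)
  expect_equal(c1$call, "+PC1")
  expect_equal(sign(c1$variant_median - c1$wt_median), 1)
  # boundary: threshold is >= 1 sigma
  sigma <- sd(wt_scores)
  med_shift <- function(d) call_pc_shift(
    fake_projection(cbind(wt_scores + d)),
    fake_projection(cbind(wt_scores)), 1)$call
  expect_equal(med_shift(0.999 * sigma), "none")
  expect_equal(med_shift(1.001 * sigma), "+PC1")
  expect_equal(med_shift(-1.001 * sigma), "-PC1")
})

test_that("displacement fields reshape and scale eigenvectors", {
  s <- make_superposed(n_frames = 400L)
  b <- fit_modes(s$ens, "chain B and name CA", 3)
  f1 <- displacement_field(b, 1)
  expect_equal(sum(f1^2), b$eigenvalues[1], tolerance = 1e-6)
  planted1 <- matrix(s$md$vectors[, 1], ncol = 3, byrow = TRUE)
  cosang <- sum(f1 * planted1) / sqrt(sum(f1^2) * sum(planted1^2))
  expect_gt(abs(cosang), 0.99)
  # zero-eigenvalue mode -> zero field
  ref <- toy_structure(5)
  bz <- fit_modes(toy_ensemble(list(ref$xyz, ref$xyz)), "name CA", 2)
  expect_equal(displacement_field(bz, 1), matrix(0, 5, 3))
  expect_error(displacement_field(b, 9), "pc_index")
})
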