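test_that("multi-model PDB reading counts models and atoms", {
  f <- write_toy_pdb(tempfile(fileext = ".pdb"), n_atoms = 5, n_models = 3)
  e <- read_ensemble(f)
  expect_equal(n_frames(e), 3L)
  expect_equal(nrow(e$atoms), 5L)
  expect_equal(unique(e$atoms$atom_name), "CA")
})

test_that("mismatched model atom counts and insertion codes are hard errors", {
  f1 <- tempfile(fileext = ".pdb")
  write_toy_pdb(f1, n_atoms = c(5, 4, 5), n_models = 3)
  expect_error(read_ensemble(f1), "model 2")
  f2 <- write_toy_pdb(tempfile(fileext = ".pdb"), n_atoms = 3, n_models = 1,
                      icode = "A")
  expect_error(read_ensemble(f2), "insertion")
})

test_that("write-read round trip preserves metadata exactly and coordinates to PDB precision", {
  tpl <- build_template(complex_template())
  md <- planted_modes(complex_template())
  sc <- variant_scenario("WT", n_frames = 4L, seed = 3L)
  e <- sample_ensemble(tpl, md, sc, 1L, 300)
  f <- tempfile(fileext = ".pdb")
  write_ensemble(e, f)
  e2 <- read_ensemble(f, label = e$label)
  expect_identical(e2$atoms$residue_number, e$atoms$residue_number)
  expect_identical(e2$atoms$chain_id, e$atoms$chain_id)
  expect_identical(e2$atoms$atom_name, e$atoms$atom_name)
  expect_lt(max(abs(e2$frames - e$frames)), 1e-3 + 1e-12)

  fx <- tempfile(fileext = ".xyz")
  write_ensemble(e, fx, format = "xyz")
  e3 <- read_ensemble(fx, format = "xyz")
  expect_equal(dim(e3$frames), dim(e$frames))
  expect_lt(max(abs(e3$frames - e$frames)), 1e-6 + 1e-12)
})

test_that("synthetic fixtures read back with the generator's frame and atom contract", {
  tpl <- build_template(complex_template())
  sc <- variant_scenario("WT", n_frames = 50L, seed = 1L)
  e <- sample_ensemble(tpl, planted_modes(complex_template()), sc, 1L, 300)
  f <- tempfile(fileext = ".pdb")
  write_ensemble(e, f)
  e2 <- read_ensemble(f)
  expect_equal(n_frames(e2), 50L)
  expect_true(all(e2$atoms$atom_name == "CA"))
  expect_equal(sum(e2$atoms$chain_id == "A"), 80L)
  expect_equal(sum(e2$atoms$chain_id == "B"), 120L)
})

test_that("selections resolve inclusive residue ranges per chain", {
  atoms <- data.frame(
    atom_index = 1:291,
    atom_name = "CA",
    residue_number = c(1:100, 420:610),
    residue_name = "ALA",
    chain_id = c(rep("A", 100), rep("B", 191)),
    stringsAsFactors = FALSE)
  st <- structure3d(atoms, matrix(rnorm(291 * 3), ncol = 3))
  sel <- resolve_selection(st, "chain B and resid 440-600 and name CA")
  expect_length(sel$indices, 161L)  # 600 - 440 + 1
  expect_true(all(diff(sel$indices) > 0))
  expect_error(resolve_selection(st, "chain Z and name CA"), "chain 'Z'")

  # order-stable and idempotent
  sel2 <- resolve_selection(st, "name CA and resid 440-600 and chain B")
  expect_identical(sel$indices, sel2$indices)

  tpl <- build_template(complex_template())
  expect_length(resolve_selection(tpl, "chain A and name CA")$indices, 80L)
})

test_that("equilibration discard keeps the ceiling of the retained fraction, from the end", {
  mk <- function(t) toy_ensemble(lapply(seq_len(t), function(i) cbind(i + 1:3, 0, 0)))
  expect_equal(n_frames(drop_equilibration(mk(15), 1 / 3)), 10L)
  expect_equal(n_frames(drop_equilibration(mk(7), 0)), 7L)
  e <- drop_equilibration(mk(100), 0.5)
  expect_equal(n_frames(e), 50L)
  expect_equal(e$frames[1, 1, 1], 51 + 1)  # first retained frame is original frame 51
  expect_error(drop_equilibration(mk(10), 1), "fraction")
  expect_error(drop_equilibration(mk(10), -0.1), "fraction")
  # composing with a zero-fraction drop is a no-op
  e1 <- drop_equilibration(mk(15), 1 / 3)
  expect_identical(drop_equilibration(e1, 0)$frames, e1$frames)
  # original untouched
  orig <- mk(15)
  invisible(drop_equilibration(orig, 1 / 3))
  expect_equal(n_frames(orig), 15L)
})

test_that("structure and ensemble validators reject inconsistent inputs", {
  atoms <- data.frame(atom_index = 1:2, atom_name = "CA", residue_number = 1:2,
                      residue_name = "ALA", chain_id = "A",
                      stringsAsFactors = FALSE)
  expect_error(structure3d(atoms, matrix(0, 3, 3)), "atom count")
  expect_error(structure3d(atoms, matrix(c(0, 0, 0, 0, 0, NA), 2, 3)), "finite")
  bad <- atoms; bad$residue_number <- c(1L, 1L)
  expect_error(structure3d(bad, matrix(0, 2, 3)), "unique")
  expect_error(traj_ensemble(atoms, array(0, c(2, 2, 3)), frame_interval = 0),
               "frame_interval")
})

test_that("parameter tables round-trip through TSV", {
  pt <- make_parameter_table(build_template(complex_template()))
  f <- tempfile(fileext = ".tsv")
  write_parameter_table(pt, f)
  pt2 <- read_parameter_table(f)
  expect_equal(pt2$charge_e, pt$charge_e)
  expect_equal(pt2$rmin_half_A, pt$rmin_half_A)
  bad <- pt; bad$epsilon_kcal_mol[1] <- -1
  expect_error(as_parameter_table <- write_parameter_table(bad, f), "epsilon")
})
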