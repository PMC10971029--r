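# Shared builders for small test fixtures, all constructed in code.

toy_structure <- function(n = 5, chain = "A") {
  atoms <- data.frame(atom_index = seq_len(n), atom_name = "CA",
                      residue_number = seq_len(n), residue_name = "ALA",
                      chain_id = chain, stringsAsFactors = FALSE)
  structure3d(atoms, cbind(seq_len(n) * 3.8, 0, 0))
}

toy_ensemble <- function(frames_list, atoms = NULL, ...) {
  if (is.null(atoms)) {
    n <- nrow(frames_list[[1]])
    atoms <- data.frame(atom_index = seq_len(n), atom_name = "CA",
                        residue_number = seq_len(n), residue_name = "ALA",
                        chain_id = "A", stringsAsFactors = FALSE)
  }
  fr <- array(0, dim = c(length(frames_list), nrow(frames_list[[1]]), 3))
  for (t in seq_along(frames_list)) fr[t, , ] <- frames_list[[t]]
  traj_ensemble(atoms, fr, ...)
}

# fake projection series with given score vectors (one PC per column)
fake_projection <- function(scores, label = "x") {
  structure(list(scores = as.matrix(scores), label = label,
                 replicate = 1L, temperature = 300),
            class = "projection_series")
}

fake_energy_series <- function(values, label = "x") {
  structure(list(values = values, coulomb = values, lennard_jones = 0 * values,
                 selection_a_label = "a", selection_b_label = "b",
                 label = label, replicate = 1L, temperature = 300),
            class = "energy_series")
}

# hand-written multi-model PDB text for parser-contract tests
write_toy_pdb <- function(path, n_atoms = 5, n_models = 3, icode = "",
                          shift = 0) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    na <- if (is.null(dim(n_atoms))) n_atoms else n_atoms[m]
    na <- if (length(n_atoms) > 1) n_atoms[m] else n_atoms
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(na)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, if (nzchar(icode)) icode else " ",
        i * 3.8 + (m - 1) * shift, 0, 0))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
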