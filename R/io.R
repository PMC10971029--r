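#' Read a multi-frame coordinate ensemble
#'
#' Reads a multi-model PDB file (MODEL/ENDMDL records, ATOM records per PDB
#' v3.3 columns; parsed via bio3d) or a minimal XYZ dialect (per frame: an
#' atom-count line, a comment line, then one `name x y z` line per atom).
#' Atom metadata are taken from the first model. Every model must have the
#' same atom ordering and count. Alternate locations: only the first altloc
#' is kept; insertion codes are rejected (they do not occur in modelled
#' structures and would break author-numbering selections).
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model PDB) or `"xyz"`.
#' @param frame_interval time between frames in ps (default 2, the recording
#'   interval used throughout).
#' @param label,replicate,temperature ensemble metadata.
#' @return a [traj_ensemble()].
#' @export
read_ensemble <- function(path, format = c("pdb", "xyz"), frame_interval = 2,
                          label = "WT", replicate = 1L, temperature = 300) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz")
    return(read_ensemble_xyz(path, frame_interval, label, replicate, temperature))
  read_ensemble_pdb(path, frame_interval, label, replicate, temperature)
}

read_ensemble_pdb <- function(path, frame_interval, label, replicate, temperature) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(is_atom)) stop("no ATOM records in ", path)
  # Pre-scan model blocks so mismatches are reported by model index.
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    model_of <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1L) {
      bad <- which(counts > 0 & counts != counts[counts > 0][1])[1]
      stop(sprintf("model %d has %d atoms; model 1 has %d (atom counts must match)",
                   bad, counts[bad], counts[1]))
    }
  }
  icode <- substr(lines[is_atom], 27, 27)
  if (any(icode != " " & icode != ""))
    stop("insertion codes are not supported; renumber residues first")

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (any(!is.na(at$alt))) {
    first_alt <- at$alt[!is.na(at$alt)][1]
    keep <- is.na(at$alt) | at$alt == first_alt
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (any(!keep)) {
    cols <- as.vector(t(outer((which(keep) - 1L) * 3L, 1:3, "+")))
    xyz <- xyz[, cols, drop = FALSE]
    at <- at[keep, , drop = FALSE]
  }
  n <- nrow(at)
  t_frames <- nrow(xyz)
  atoms <- data.frame(
    atom_index = seq_len(n),
    atom_name = at$elety,
    residue_number = at$resno,
    residue_name = at$resid,
    chain_id = at$chain,
    stringsAsFactors = FALSE)
  frames <- aperm(array(t(xyz), dim = c(3L, n, t_frames)), c(3L, 2L, 1L))
  traj_ensemble(atoms, frames, frame_interval, label, replicate, temperature)
}

read_ensemble_xyz <- function(path, frame_interval, label, replicate, temperature) {
  lines <- readLines(path)
  pos <- 1L
  frames_list <- list()
  names_first <- NULL
  model <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) stop("invalid atom-count line at line ", pos)
    model <- model + 1L
    block <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    if (any(lengths(tok) < 4L)) stop("malformed XYZ atom line in frame ", model)
    nm <- vapply(tok, `[[`, "", 1L)
    co <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(names_first)) names_first <- nm
    else if (length(nm) != length(names_first))
      stop(sprintf("model %d has %d atoms; model 1 has %d (atom counts must match)",
                   model, length(nm), length(names_first)))
    frames_list[[model]] <- co
    pos <- pos + 2L + n
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (model == 0L) stop("no frames in ", path)
  n <- length(names_first)
  atoms <- data.frame(
    atom_index = seq_len(n), atom_name = names_first,
    residue_number = seq_len(n), residue_name = "UNK", chain_id = "A",
    stringsAsFactors = FALSE)
  frames <- array(0, dim = c(model, n, 3L))
  for (t in seq_len(model)) frames[t, , ] <- frames_list[[t]]
  traj_ensemble(atoms, frames, frame_interval, label, replicate, temperature)
}

#' Write a coordinate ensemble
#'
#' Writes multi-model PDB (via bio3d; coordinates at the format's 10^-3
#' Angstrom precision) or the minimal XYZ dialect.
#'
#' @param ensemble a [traj_ensemble()] (or [structure3d()], written as one model).
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (inherits(ensemble, "structure3d")) {
    ensemble <- traj_ensemble(ensemble$atoms,
                              array(ensemble$xyz, dim = c(1L, nrow(ensemble$xyz), 3L)))
  }
  at <- ensemble$atoms
  t_frames <- n_frames(ensemble)
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (t in seq_len(t_frames)) {
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf("frame %d", t), con)
      writeLines(sprintf("%s %.6f %.6f %.6f", at$atom_name,
                         ensemble$frames[t, , 1], ensemble$frames[t, , 2],
                         ensemble$frames[t, , 3]), con)
    }
    return(invisible(path))
  }
  xyz <- matrix(aperm(ensemble$frames, c(3L, 2L, 1L)), nrow = t_frames, byrow = TRUE)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(at)),
                   resno = at$residue_number, resid = at$residue_name,
                   eleno = at$atom_index, elety = at$atom_name,
                   chain = at$chain_id)
  invisible(path)
}

#' Resolve an atom selection expression
#'
#' Selection expressions combine clauses with `and`: `chain <id>`,
#' `resid <a>-<b>` (inclusive on both ends) or `resid <a>`, and
#' `name <atom_name>`. Example: `"chain B and resid 440-600 and name CA"`.
#' Matching indices are returned sorted ascending, so the result is
#' independent of clause order. An empty match is allowed but warned about;
#' naming a chain absent from the structure is an error.
#'
#' @param x a [structure3d()] or [traj_ensemble()].
#' @param expression selection string.
#' @return object of class `atom_selection` with fields `expression` and
#'   `indices` (1-based atom indices, strictly increasing).
#' @export
resolve_selection <- function(x, expression) {
  atoms <- atoms_of(x)
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) < 2L) stop("malformed selection clause: '", cl, "'")
    key <- tolower(tok[1])
    val <- paste(tok[-1], collapse = " ")
    if (key == "chain") {
      if (!val %in% atoms$chain_id)
        stop("chain '", val, "' not present in structure (chains: ",
             paste(unique(atoms$chain_id), collapse = ","), ")")
      keep <- keep & atoms$chain_id == val
    } else if (key == "resid") {
      rng <- as.integer(strsplit(val, "-")[[1]])
      if (any(is.na(rng)) || !length(rng) %in% 1:2)
        stop("malformed resid clause: '", cl, "'")
      if (length(rng) == 1L) rng <- c(rng, rng)
      keep <- keep & atoms$residue_number >= rng[1] & atoms$residue_number <= rng[2]
    } else if (key == "name") {
      keep <- keep & atoms$atom_name == val
    } else {
      stop("unknown selection clause '", key, "' in '", cl, "'")
    }
  }
  idx <- sort(atoms$atom_index[keep])
  if (!length(idx)) warning("selection '", expression, "' matches no atoms")
  structure(list(expression = expression, indices = idx), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

as_indices <- function(x, selection) {
  if (inherits(selection, "atom_selection")) sel <- selection
  else if (is.character(selection)) sel <- resolve_selection(x, selection)
  else if (is.numeric(selection))
    return(as.integer(selection))
  else stop("selection must be an atom_selection, expression string, or index vector")
  n <- nrow(atoms_of(x))
  if (length(sel$indices) && max(sel$indices) > n)
    stop("selection indices exceed atom count")
  sel$indices
}

#' Discard the equilibration portion of an ensemble
#'
#' Keeps the last `ceiling(T * (1 - fraction))` frames. The default fraction
#' of 1/3 matches discarding the first 5 ns of a 15 ns trajectory and
#' analysing the final 10 ns.
#'
#' @param ensemble a [traj_ensemble()].
#' @param fraction fraction in `[0, 1)` of initial frames to drop.
#' @return a new [traj_ensemble()]; the input is untouched.
#' @export
drop_equilibration <- function(ensemble, fraction = 1 / 3) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  t_frames <- n_frames(ensemble)
  n_keep <- ceiling(t_frames * (1 - fraction) - 1e-9)  # guard FP noise in T*(1-f)
  if (n_keep < 1L) stop("no frames would remain")
  idx <- seq.int(t_frames - n_keep + 1L, t_frames)
  traj_ensemble(ensemble$atoms, ensemble$frames[idx, , , drop = FALSE],
                ensemble$frame_interval, ensemble$label, ensemble$replicate,
                ensemble$temperature)
}

#' Read / write a nonbonded parameter table
#'
#' Tab-separated with columns `atom_index`, `charge_e`, `epsilon_kcal_mol`
#' (>= 0) and `rmin_half_A` (> 0); one row per atom, 1-based indices.
#'
#' @param path TSV file path.
#' @return `read_parameter_table`: a `parameter_table` data.frame.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  as_parameter_table(df)
}

#' @rdname read_parameter_table
#' @param params a `parameter_table` (or compatible data.frame).
#' @export
write_parameter_table <- function(params, path) {
  params <- as_parameter_table(params)
  utils::write.table(params, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_parameter_table <- function(df) {
  need <- c("atom_index", "charge_e", "epsilon_kcal_mol", "rmin_half_A")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("parameter table missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df[, need], stringsAsFactors = FALSE)
  if (any(df$epsilon_kcal_mol < 0)) stop("epsilon must be >= 0")
  if (any(df$rmin_half_A <= 0)) stop("rmin_half must be > 0")
  if (anyDuplicated(df$atom_index)) stop("duplicate atom_index in parameter table")
  class(df) <- c("parameter_table", "data.frame")
  df
}
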