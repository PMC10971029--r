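#' Construct a static structure
#'
#' A structure is an ordered atom table plus an N x 3 coordinate matrix in
#' Angstrom. Atom indices are 1-based and equal the row position in the
#' atom table (report output also uses 1-based indices, stated in headers).
#'
#' @param atoms data.frame with columns `atom_index` (integer, 1-based,
#'   contiguous), `atom_name`, `residue_number` (author numbering),
#'   `residue_name`, `chain_id` (single character).
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz) {
  atoms <- validate_atoms(atoms)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L)
    stop("coordinates must be an N x 3 matrix")
  if (nrow(xyz) != nrow(atoms))
    stop(sprintf("coordinate rows (%d) != atom count (%d)", nrow(xyz), nrow(atoms)))
  if (!all(is.finite(xyz)))
    stop("all coordinates must be finite")
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "structure3d")
}

validate_atoms <- function(atoms) {
  need <- c("atom_index", "atom_name", "residue_number", "residue_name", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  atoms$atom_index <- as.integer(atoms$atom_index)
  atoms$residue_number <- as.integer(atoms$residue_number)
  if (nrow(atoms) && !identical(atoms$atom_index, seq_len(nrow(atoms))))
    stop("atom_index must equal the 1-based position in the atom list")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("(chain_id, residue_number, atom_name) must be unique within a structure")
  if (any(nchar(atoms$chain_id) != 1L))
    stop("chain_id must be a single character")
  rownames(atoms) <- NULL
  atoms
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d chain(s) [%s]\n",
              nrow(x$atoms), length(unique(x$atoms$chain_id)),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Construct a trajectory ensemble
#'
#' Ordered frames of atom coordinates for one replicate of one variant at
#' one temperature. All frames share a single atom table.
#'
#' @param atoms atom table as in [structure3d()].
#' @param frames numeric T x N x 3 array of coordinates in Angstrom.
#' @param frame_interval time between recorded frames in ps (> 0).
#' @param label variant name.
#' @param replicate replicate index (integer).
#' @param temperature simulation temperature in K.
#' @return An object of class `traj_ensemble`.
#' @export
traj_ensemble <- function(atoms, frames, frame_interval = 2,
                          label = "WT", replicate = 1L, temperature = 300) {
  atoms <- validate_atoms(atoms)
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    stop("frames must be a T x N x 3 array")
  if (dim(frames)[1] < 1L)
    stop("ensemble must contain at least one frame")
  if (dim(frames)[2] != nrow(atoms))
    stop(sprintf("frame atom count (%d) != atom table rows (%d)",
                 dim(frames)[2], nrow(atoms)))
  if (!all(is.finite(frames)))
    stop("all coordinates must be finite")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(atoms = atoms, frames = frames,
                 frame_interval = as.numeric(frame_interval),
                 label = as.character(label), replicate = as.integer(replicate),
                 temperature = as.numeric(temperature)),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf(
    "traj_ensemble '%s' (replicate %d, %g K): %d frames x %d atoms, dt = %g ps\n",
    x$label, x$replicate, x$temperature, n_frames(x), nrow(x$atoms),
    x$frame_interval))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `traj_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$frames)[1]

#' Extract one frame as a structure
#' @param ensemble a `traj_ensemble`.
#' @param i frame index (1-based).
#' @return a `structure3d`.
#' @export
get_frame <- function(ensemble, i = 1L) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(ensemble)) stop("frame index out of range")
  structure3d(ensemble$atoms, ensemble$frames[i, , ])
}

coords_of <- function(x) {
  if (inherits(x, "structure3d")) return(x$xyz)
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("expected a structure3d or an N x 3 coordinate matrix")
}

atoms_of <- function(x) {
  if (inherits(x, c("structure3d", "traj_ensemble"))) return(x$atoms)
  stop("expected a structure3d or traj_ensemble")
}
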