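#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `mobile %*% t(R) + t` and `reference` over a fixed atom
#' correspondence (row i of `mobile` pairs with row i of `reference`).
#' Reflections are excluded. Within one variant's trajectory the
#' correspondence is the identity; for deletion variants it is given by
#' matching author residue numbers, skipping deleted residues.
#'
#' @param mobile,reference numeric N x 3 coordinate matrices, N >= 3,
#'   neither collinear.
#' @return object of class `rigid_transform`: list with `rotation` (3 x 3,
#'   orthonormal, det +1) and `translation` (length 3, Angstrom).
#' @export
kabsch_fit <- function(mobile, reference) {
  p <- coords_of(mobile)
  q <- coords_of(reference)
  if (nrow(p) != nrow(q)) stop("mobile and reference must have matching atom counts")
  if (nrow(p) < 3L) stop("at least 3 paired atoms are required")
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2L, cp)
  qc <- sweep(q, 2L, cq)
  # degenerate (collinear) point sets leave the rotation underdetermined
  sv_p <- svd(pc, nu = 0, nv = 0)$d
  sv_q <- svd(qc, nu = 0, nv = 0)$d
  tol <- 1e-8 * max(sv_p[1], sv_q[1], 1)
  if (sv_p[2] < tol || sv_q[2] < tol)
    stop("degenerate (collinear) point set: rotation is underdetermined")
  h <- crossprod(pc, qc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(list(rotation = rot, translation = as.numeric(cq - rot %*% cp)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, translation |t| = %.3f A\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param coords N x 3 matrix (or `structure3d`).
#' @param transform a `rigid_transform`.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  xyz <- coords_of(coords)
  sweep(xyz %*% t(transform$rotation), 2L, -transform$translation)
}

#' Serialise / restore a rigid transform (JSON, for provenance)
#' @param transform a `rigid_transform`.
#' @return `transform_to_json`: a JSON string.
#' @export
transform_to_json <- function(transform) {
  jsonlite::toJSON(list(rotation = transform$rotation,
                        translation = transform$translation),
                   digits = NA)
}

#' @rdname transform_to_json
#' @param json JSON string from `transform_to_json`.
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(rotation = matrix(obj$rotation, 3L, 3L),
                 translation = as.numeric(obj$translation)),
            class = "rigid_transform")
}

#' Superpose every frame of an ensemble onto a reference
#'
#' Each frame gets its own least-squares fit ([kabsch_fit()]) computed on
#' the fitting selection; the whole frame (all atoms) is then moved
#' rigidly. The conventional split for a complex with a held-fixed partner
#' chain is: fit on the fixed chain's C-alpha atoms, report RMSD/PCA on the
#' mobile chain.
#'
#' @param ensemble a [traj_ensemble()].
#' @param reference a [structure3d()] (or N x 3 matrix with the ensemble's
#'   full atom count).
#' @param fit_selection selection (expression, `atom_selection`, or indices)
#'   resolvable on both ensemble and reference.
#' @return a superposed [traj_ensemble()].
#' @export
superpose_ensemble <- function(ensemble, reference, fit_selection) {
  ref_xyz <- coords_of(reference)
  idx_e <- as_indices(ensemble, fit_selection)
  idx_r <- if (inherits(reference, "structure3d") &&
               (is.character(fit_selection) || inherits(fit_selection, "atom_selection")))
    as_indices(reference, fit_selection) else idx_e
  if (length(idx_e) != length(idx_r))
    stop(sprintf("fit selection resolves to %d atoms on the ensemble but %d on the reference",
                 length(idx_e), length(idx_r)))
  if (!length(idx_e)) stop("empty fit selection")
  ref_sub <- ref_xyz[idx_r, , drop = FALSE]
  out <- ensemble$frames
  for (t in seq_len(n_frames(ensemble))) {
    mob <- ensemble$frames[t, idx_e, , drop = FALSE]
    dim(mob) <- dim(mob)[2:3]
    tf <- kabsch_fit(mob, ref_sub)
    out[t, , ] <- apply_transform(ensemble$frames[t, , ], tf)
  }
  traj_ensemble(ensemble$atoms, out, ensemble$frame_interval, ensemble$label,
                ensemble$replicate, ensemble$temperature)
}

#' RMSD of each frame to a reference
#'
#' `value[t] = sqrt(mean over selected atoms of squared deviation)` in
#' Angstrom. The ensemble is used as-is: superpose first with
#' [superpose_ensemble()]; no re-fitting happens here.
#'
#' @param ensemble a (superposed) [traj_ensemble()].
#' @param reference a [structure3d()] or N x 3 matrix.
#' @param report_selection selection over which deviations are averaged.
#' @param reference_label label recorded in the result for provenance.
#' @return object of class `rmsd_series`: list with `values` (length T, A),
#'   `report_selection`, `reference_label`.
#' @export
rmsd_series <- function(ensemble, reference, report_selection,
                        reference_label = "reference") {
  ref_xyz <- coords_of(reference)
  idx <- as_indices(ensemble, report_selection)
  if (!length(idx)) stop("empty report selection")
  idx_r <- if (inherits(reference, "structure3d") &&
               (is.character(report_selection) || inherits(report_selection, "atom_selection")))
    as_indices(reference, report_selection) else idx
  ref_sub <- ref_xyz[idx_r, , drop = FALSE]
  t_frames <- n_frames(ensemble)
  vals <- numeric(t_frames)
  for (t in seq_len(t_frames)) {
    d <- ensemble$frames[t, idx, , drop = TRUE]
    if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
    vals[t] <- sqrt(mean(rowSums((d - ref_sub)^2)))
  }
  structure(list(values = vals,
                 report_selection = if (is.character(report_selection))
                   report_selection else "custom",
                 reference_label = reference_label,
                 label = ensemble$label, replicate = ensemble$replicate,
                 temperature = ensemble$temperature),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series '%s': %d frames, median %.3f A (min %.3f, max %.3f)\n",
              x$label, length(x$values), stats::median(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
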