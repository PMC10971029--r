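# Flatten selected atoms of all frames into an F x 3M matrix with
# per-atom (x, y, z) coordinate ordering.
frames_matrix <- function(ensemble, idx) {
  sub <- ensemble$frames[, idx, , drop = FALSE]
  m <- length(idx)
  t(matrix(aperm(sub, c(3L, 2L, 1L)), nrow = 3L * m))
}

#' Cartesian principal component analysis of an ensemble pool
#'
#' Eigendecomposition of the covariance of selected (superposed) C-alpha
#' coordinates over all pooled frames. Superpose ensembles first; no
#' fitting happens here. Fitting on the pooled wild type plus variants
#' gives one shared basis so median scores are comparable across variants;
#' a wild-type-only basis is obtained by passing only those ensembles.
#'
#' Eigenvector signs are fixed deterministically: the largest-magnitude
#' component of each mode is made positive (ties broken by lowest atom
#' index), so bases are reproducible across runs. The physical direction
#' of a mode (e.g. whether +PC1 moves a domain towards or away from the
#' partner chain) is a property of this convention and should be read off
#' [displacement_field()], not assumed.
#'
#' @param ensembles a [traj_ensemble()] or list of them, all sharing the
#'   selection's atoms.
#' @param selection atoms to analyse (expression, `atom_selection`, or
#'   indices), typically the mobile chain's C-alpha atoms.
#' @param n_modes number of leading modes to retain (default 3).
#' @return object of class `mode_basis`: `mean_conformation` (length 3M),
#'   `vectors` (3M x K, orthonormal, per-atom x/y/z ordering),
#'   `eigenvalues` (K, descending, A^2), `variance_fraction` (K, fractions
#'   of the total variance over all 3M modes), `total_variance`,
#'   `selection`, `atoms`, `n_frames_fit`.
#' @export
fit_modes <- function(ensembles, selection, n_modes = 3L) {
  if (inherits(ensembles, "traj_ensemble")) ensembles <- list(ensembles)
  if (!length(ensembles)) stop("no ensembles given")
  idx <- as_indices(ensembles[[1]], selection)
  if (!length(idx)) stop("empty selection")
  xs <- lapply(ensembles, function(e) {
    if (!identical(as_indices(e, selection), idx))
      stop("ensembles do not share the selection's atoms")
    frames_matrix(e, idx)
  })
  x <- do.call(rbind, xs)
  if (nrow(x) < 2L) stop("at least 2 pooled frames are required")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  cv <- crossprod(xc) / (nrow(x) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  k <- min(as.integer(n_modes), length(vals))
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))  # ties: which.max takes the lowest index
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(mean_conformation = mu, vectors = vec,
                 eigenvalues = vals[seq_len(k)],
                 variance_fraction = if (sum(vals) > 0) vals[seq_len(k)] / sum(vals)
                                     else rep(0, k),
                 total_variance = sum(vals),
                 selection = if (is.character(selection)) selection else "custom",
                 atoms = atoms_of(ensembles[[1]])[idx, , drop = FALSE],
                 indices = idx,
                 n_frames_fit = nrow(x)),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("mode_basis: %d modes over %d atoms (%d frames)\n",
              ncol(x$vectors), length(x$indices), x$n_frames_fit))
  for (k in seq_along(x$eigenvalues))
    cat(sprintf("  PC%d: eigenvalue %.4g A^2 (%.1f%% of variance)\n",
                k, x$eigenvalues[k], 100 * x$variance_fraction[k]))
  invisible(x)
}

#' Scree plot of a mode basis
#' @param x a `mode_basis`.
#' @param y ignored.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.mode_basis <- function(x, y, ...) {
  graphics::barplot(100 * x$variance_fraction,
                    names.arg = paste0("PC", seq_along(x$eigenvalues)),
                    ylab = "% of total variance", ...)
  invisible(x)
}

#' Project an ensemble onto a mode basis
#'
#' Scores are exact inner products `(frame - mean_conformation) . v_k`; no
#' re-centering beyond the basis mean.
#'
#' @param ensemble a superposed [traj_ensemble()].
#' @param basis a `mode_basis` from [fit_modes()].
#' @param selection selection matching the basis atoms; defaults to the
#'   basis' own stored indices.
#' @return object of class `projection_series`: `scores` (T x K, Angstrom),
#'   plus `label`, `replicate`, `temperature` from the ensemble.
#' @export
project_ensemble <- function(ensemble, basis, selection = NULL) {
  idx <- if (is.null(selection)) basis$indices else as_indices(ensemble, selection)
  if (3L * length(idx) != nrow(basis$vectors))
    stop(sprintf("selection gives %d coordinates but basis expects %d",
                 3L * length(idx), nrow(basis$vectors)))
  x <- frames_matrix(ensemble, idx)
  scores <- sweep(x, 2L, basis$mean_conformation) %*% basis$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, label = ensemble$label,
                 replicate = ensemble$replicate,
                 temperature = ensemble$temperature),
            class = "projection_series")
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("projection_series '%s' (replicate %d): %d frames x %d PCs\n",
              x$label, x$replicate, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

pooled_scores <- function(proj, pc_index) {
  if (inherits(proj, "projection_series")) proj <- list(proj)
  unlist(lapply(proj, function(p) p$scores[, pc_index]))
}

#' Classify a variant's shift along one principal component
#'
#' Implements the one-sigma median-shift rule used in variant summary
#' tables: a PC alteration is called when the variant's median score
#' differs from the wild-type median by at least one standard deviation,
#' where sigma is the standard deviation of the wild-type pooled scores on
#' that PC (the shift is measured "compared to the WT", so the wild-type
#' spread is the reference scale). Replicates are pooled within condition.
#' The threshold is inclusive (>= 1 sigma calls).
#'
#' @param variant_proj,wt_proj a `projection_series` or list of them
#'   (replicates, pooled).
#' @param pc_index which PC (1-based).
#' @return object of class `pc_shift_call`: `pc_index`, `variant_median`,
#'   `wt_median`, `wt_sd` (all Angstrom), and `call` (`"+PCk"`, `"-PCk"`,
#'   or `"none"`).
#' @export
call_pc_shift <- function(variant_proj, wt_proj, pc_index = 1L) {
  sv <- pooled_scores(variant_proj, pc_index)
  sw <- pooled_scores(wt_proj, pc_index)
  if (!length(sv) || !length(sw)) stop("projection sets must be non-empty")
  mv <- stats::median(sv)
  mw <- stats::median(sw)
  sigma <- stats::sd(sw)
  delta <- mv - mw
  call <- if (is.na(sigma) || abs(delta) < sigma) "none"
          else paste0(if (delta > 0) "+" else "-", "PC", pc_index)
  structure(list(pc_index = as.integer(pc_index), variant_median = mv,
                 wt_median = mw, wt_sd = sigma, delta = delta, call = call),
            class = "pc_shift_call")
}

#' @export
print.pc_shift_call <- function(x, ...) {
  cat(sprintf("PC%d shift: variant median %.3f, WT median %.3f (sigma %.3f) -> %s\n",
              x$pc_index, x$variant_median, x$wt_median, x$wt_sd, x$call))
  invisible(x)
}

#' Per-atom displacement field of one mode
#'
#' Reshapes an eigenvector to per-atom 3-vectors scaled by the square root
#' of its eigenvalue (an RMS-amplitude-weighted direction, suitable for
#' cone/arrow visualisation). Squared norms over all atoms sum to the
#' eigenvalue.
#'
#' @param basis a `mode_basis`.
#' @param pc_index which mode (1-based).
#' @return M x 3 matrix of displacement vectors (Angstrom).
#' @export
displacement_field <- function(basis, pc_index = 1L) {
  k <- as.integer(pc_index)
  if (k < 1L || k > ncol(basis$vectors)) stop("invalid pc_index")
  v <- basis$vectors[, k]
  matrix(v, ncol = 3L, byrow = TRUE) * sqrt(basis$eigenvalues[k])
}
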