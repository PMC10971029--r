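#' Nonbonded switching specification
#'
#' Pairwise energies are tapered smoothly to zero between an inner radius
#' `r_on` and an outer cutoff `r_off` by the standard CHARMM energy
#' switching polynomial, applied to both the Coulomb and Lennard-Jones
#' terms. Defaults follow the conventional 12 Angstrom cutoff with
#' switching from 10 Angstrom.
#'
#' @param r_on switch-on radius in Angstrom (default 10).
#' @param r_off cutoff radius in Angstrom (default 12); must exceed `r_on`.
#' @param dielectric relative dielectric constant (default 1). Set
#'   `distance_dependent = TRUE` for an effective `eps * r` screening,
#'   sometimes preferred for coarse C-alpha parameterisations.
#' @param distance_dependent logical; use a distance-dependent dielectric.
#' @param coulomb_constant electrostatic constant in kcal A / (mol e^2).
#' @return a `switching_spec` list.
#' @export
switching_spec <- function(r_on = 10, r_off = 12, dielectric = 1.0,
                           distance_dependent = FALSE,
                           coulomb_constant = 332.0636) {
  if (!(r_on > 0 && r_off > r_on)) stop("need 0 < r_on < r_off")
  structure(list(r_on = r_on, r_off = r_off, dielectric = dielectric,
                 distance_dependent = isTRUE(distance_dependent),
                 coulomb_constant = coulomb_constant),
            class = "switching_spec")
}

# CHARMM energy switching factor S(r): 1 for r <= r_on, 0 for r > r_off,
# and ((roff^2-r^2)^2 (roff^2 + 2r^2 - 3 ron^2)) / (roff^2-ron^2)^3 between.
switch_factor <- function(r, spec) {
  ron2 <- spec$r_on^2
  roff2 <- spec$r_off^2
  r2 <- r^2
  s <- ((roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2)) / (roff2 - ron2)^3
  out <- ifelse(r <= spec$r_on, 1, ifelse(r > spec$r_off, 0, s))
  out
}

#' Switched nonbonded pair energy
#'
#' `E(r) = S(r) * [ k_C q1 q2 / (eps r)  +  eps_ij ((R_ij/r)^12 - 2 (R_ij/r)^6) ]`
#' with Lorentz-Berthelot-style combining: `eps_ij = sqrt(eps1 * eps2)`,
#' `R_ij = rmin1 + rmin2` (each input is the half rmin). Vectorised over `r`.
#'
#' @param r pair distance(s) in Angstrom, all > 0.
#' @param q1,q2 charges in e.
#' @param eps1,eps2 Lennard-Jones well depths in kcal/mol (>= 0).
#' @param rmin1,rmin2 Lennard-Jones rmin/2 in Angstrom.
#' @param spec a [switching_spec()].
#' @return energy (or vector of energies) in kcal/mol.
#' @export
pair_energy <- function(r, q1, q2, eps1, eps2, rmin1, rmin2,
                        spec = switching_spec()) {
  if (any(r <= 0)) stop("pair distance must be > 0")
  denom <- if (spec$distance_dependent) spec$dielectric * r^2 else spec$dielectric * r
  coul <- spec$coulomb_constant * q1 * q2 / denom
  rr <- (rmin1 + rmin2) / r
  lj <- sqrt(eps1 * eps2) * (rr^12 - 2 * rr^6)
  switch_factor(r, spec) * (coul + lj)
}

#' Inter-selection nonbonded interaction energy per frame
#'
#' Sums the switched pair energy over every cross pair (one atom from each
#' selection) within the cutoff, per frame. Selections must be disjoint.
#' The computation is a vectorised cross-distance evaluation per frame and
#' equals the all-pairs double loop exactly.
#'
#' @param ensemble a [traj_ensemble()].
#' @param sel_a,sel_b disjoint selections (expressions, `atom_selection`s,
#'   or index vectors), e.g. a mobile-chain domain vs the partner chain.
#' @param params a `parameter_table` covering every selected atom
#'   (see [read_parameter_table()]).
#' @param spec a [switching_spec()].
#' @param labels length-2 character: names for the two selections.
#' @return object of class `energy_series`: `values` (length T, kcal/mol),
#'   `coulomb`, `lennard_jones` per-frame components (values = coulomb +
#'   lennard_jones), selection labels and ensemble metadata.
#' @export
interaction_energy_series <- function(ensemble, sel_a, sel_b, params,
                                      spec = switching_spec(),
                                      labels = c("A", "B")) {
  params <- as_parameter_table(params)
  ia <- as_indices(ensemble, sel_a)
  ib <- as_indices(ensemble, sel_b)
  if (!length(ia) || !length(ib)) stop("empty selection")
  if (length(intersect(ia, ib)))
    stop("selections overlap: interaction energy needs disjoint atom sets")
  missing <- setdiff(c(ia, ib), params$atom_index)
  if (length(missing))
    stop("atoms missing from parameter table: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  row_of <- match(c(ia, ib), params$atom_index)
  pa <- params[row_of[seq_along(ia)], ]
  pb <- params[row_of[length(ia) + seq_along(ib)], ]

  qq <- spec$coulomb_constant * outer(pa$charge_e, pb$charge_e) / spec$dielectric
  ee <- sqrt(outer(pa$epsilon_kcal_mol, pb$epsilon_kcal_mol))
  rm_ij <- outer(pa$rmin_half_A, pb$rmin_half_A, "+")

  t_frames <- n_frames(ensemble)
  e_coul <- numeric(t_frames)
  e_lj <- numeric(t_frames)
  for (t in seq_len(t_frames)) {
    a <- ensemble$frames[t, ia, , drop = FALSE]; dim(a) <- dim(a)[2:3]
    b <- ensemble$frames[t, ib, , drop = FALSE]; dim(b) <- dim(b)[2:3]
    # explicit coordinate differences: no cancellation error at close range
    r2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
      outer(a[, 3], b[, 3], "-")^2
    within <- which(r2 <= spec$r_off^2)
    if (!length(within)) next
    r <- sqrt(r2[within])
    if (any(r <= 0)) stop("coincident atoms across selections (r = 0)")
    s <- switch_factor(r, spec)
    cdenom <- if (spec$distance_dependent) r^2 else r
    rr <- rm_ij[within] / r
    e_coul[t] <- sum(s * qq[within] / cdenom)
    e_lj[t] <- sum(s * ee[within] * (rr^12 - 2 * rr^6))
  }
  structure(list(values = e_coul + e_lj, coulomb = e_coul,
                 lennard_jones = e_lj,
                 selection_a_label = labels[1], selection_b_label = labels[2],
                 label = ensemble$label, replicate = ensemble$replicate,
                 temperature = ensemble$temperature),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("energy_series %s:%s ('%s'): %d frames, median %.3f kcal/mol\n",
              x$selection_a_label, x$selection_b_label, x$label,
              length(x$values), stats::median(x$values)))
  invisible(x)
}

#' Concatenate energy series (e.g. replicates of one variant)
#' @param series list of `energy_series` with identical selection labels.
#' @return a single pooled `energy_series`.
#' @export
pool_energy_series <- function(series) {
  if (inherits(series, "energy_series")) return(series)
  stopifnot(length(series) >= 1L)
  out <- series[[1]]
  out$values <- unlist(lapply(series, `[[`, "values"))
  out$coulomb <- unlist(lapply(series, `[[`, "coulomb"))
  out$lennard_jones <- unlist(lapply(series, `[[`, "lennard_jones"))
  out$replicate <- NA_integer_
  out
}

#' Direction call for a variant's interaction energy vs wild type
#'
#' `"n.s."` when the resampling test is not significant; otherwise `"+"`
#' (stronger interaction: variant median energy more negative than wild
#' type) or `"-"` (weaker: median energy greater).
#'
#' @param variant,wt `energy_series` (pooled over replicates).
#' @param test the [downsample_test()] result computed on these two series.
#' @return `"+"`, `"-"`, or `"n.s."`.
#' @export
interaction_call <- function(variant, wt, test) {
  if (!isTRUE(test$significant)) return("n.s.")
  if (stats::median(variant$values) < stats::median(wt$values)) "+" else "-"
}
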