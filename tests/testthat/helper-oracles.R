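# Independent oracles used to cross-check the package's own numerics.
# These deliberately take different algorithmic routes from the
# implementations they validate.

# Horn's closed-form quaternion solution to the absolute-orientation
# problem: independent route to the optimal proper rotation.
quaternion_superpose <- function(mobile, reference) {
  cp <- colMeans(mobile)
  cq <- colMeans(reference)
  p <- sweep(mobile, 2, cp)
  q <- sweep(reference, 2, cq)
  m <- crossprod(p, q)  # Sxy matrix
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz),
    4, 4, byrow = TRUE)
  qv <- eigen(n4, symmetric = TRUE)$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(rotation = rot, translation = as.numeric(cq - rot %*% cp))
}

oracle_rmsd_after <- function(mobile, reference, fit) {
  moved <- sweep(mobile %*% t(fit$rotation), 2, -fit$translation)
  sqrt(mean(rowSums((moved - reference)^2)))
}

# All-pairs double loop over cross pairs, calling the scalar pair-energy
# closed form per pair: the aggregation oracle for
# interaction_energy_series().
brute_interaction_energy <- function(xyz, ia, ib, params, spec) {
  total <- 0
  for (i in ia) {
    pi <- params[params$atom_index == i, ]
    for (j in ib) {
      pj <- params[params$atom_index == j, ]
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > spec$r_off) next
      total <- total + pair_energy(r, pi$charge_e, pj$charge_e,
                                   pi$epsilon_kcal_mol, pj$epsilon_kcal_mol,
                                   pi$rmin_half_A, pj$rmin_half_A, spec)
    }
  }
  total
}

random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}
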