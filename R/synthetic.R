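#' Template for a synthetic two-chain complex
#'
#' Describes a C-alpha-only stand-in for a catalytic chain held fixed
#' (chain A, emulating PIK3CA under harmonic constraints) bound to a
#' mobile regulatory chain (chain B, emulating PIK3R1) whose domains move
#' collectively. Each chain is laid out as an ideal alpha-helical arc with
#' exact 3.8 Angstrom consecutive C-alpha spacing.
#'
#' @param n_res_fixed residues in the fixed chain A (default 80).
#' @param n_res_mobile residues in the mobile chain B (default 120).
#' @param domains named list of inclusive residue ranges on the mobile
#'   chain; default `nSH2` = first 40 residues, `iSH2` = last 60. Ranges
#'   must be disjoint and within the chain.
#' @param axis_separation distance in Angstrom between the two helix axes
#'   (default 9, placing many cross-chain pairs inside a 12 A cutoff).
#' @return a `complex_template` list.
#' @export
complex_template <- function(n_res_fixed = 80L, n_res_mobile = 120L,
                             domains = list(nSH2 = c(1L, 40L),
                                            iSH2 = c(61L, 120L)),
                             axis_separation = 9) {
  n_res_fixed <- as.integer(n_res_fixed)
  n_res_mobile <- as.integer(n_res_mobile)
  if (n_res_fixed < 1L || n_res_mobile < 1L) stop("chains need >= 1 residue")
  covered <- integer(0)
  for (nm in names(domains)) {
    rng <- as.integer(domains[[nm]])
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1L || rng[2] > n_res_mobile)
      stop("domain '", nm, "' range invalid for the mobile chain")
    span <- seq.int(rng[1], rng[2])
    if (length(intersect(covered, span))) stop("domain ranges must be disjoint")
    covered <- c(covered, span)
  }
  structure(list(n_res_fixed = n_res_fixed, n_res_mobile = n_res_mobile,
                 domains = lapply(domains, as.integer),
                 axis_separation = axis_separation),
            class = "complex_template")
}

# ideal helix: rise 1.5 A/residue, 100 degrees/turn; radius solved so the
# consecutive C-alpha distance is exactly 3.8 A.
helix_coords <- function(n, origin = c(0, 0, 0), phase = 0) {
  rise <- 1.5
  turn <- 100 * pi / 180
  chord <- sqrt(3.8^2 - rise^2)
  radius <- chord / (2 * sin(turn / 2))
  i <- seq_len(n) - 1L
  cbind(origin[1] + radius * cos(phase + i * turn),
        origin[2] + radius * sin(phase + i * turn),
        origin[3] + i * rise)
}

#' Build the deterministic template structure
#'
#' @param template a [complex_template()].
#' @return a [structure3d()] with chain A (fixed) then chain B (mobile),
#'   one `CA` atom per residue, residues numbered from 1 within each chain.
#' @export
build_template <- function(template = complex_template()) {
  a <- helix_coords(template$n_res_fixed)
  b <- helix_coords(template$n_res_mobile,
                    origin = c(template$axis_separation, 0, 0), phase = pi)
  n <- template$n_res_fixed + template$n_res_mobile
  atoms <- data.frame(
    atom_index = seq_len(n),
    atom_name = "CA",
    residue_number = c(seq_len(template$n_res_fixed), seq_len(template$n_res_mobile)),
    residue_name = "ALA",
    chain_id = c(rep("A", template$n_res_fixed), rep("B", template$n_res_mobile)),
    stringsAsFactors = FALSE)
  structure3d(atoms, rbind(a, b))
}

#' Planted collective modes for the mobile chain
#'
#' Defines K mutually orthonormal mode vectors over the mobile chain's
#' 3N coordinates plus amplitude standard deviations (descending) and an
#' isotropic residual noise SD. Defaults plant three interpretable
#' motions: (1) the nSH2 block translating along x, i.e. towards/away from
#' the fixed chain (a docking-like motion), (2) the iSH2 block translating
#' along x, (3) the nSH2 block translating along z (a sliding motion).
#' Disjoint supports / orthogonal directions make them exactly orthonormal.
#'
#' @param template a [complex_template()].
#' @param mode_sds amplitude SDs in Angstrom, strictly descending
#'   (default `c(3, 2, 1)`).
#' @param noise_sd isotropic per-coordinate residual SD in Angstrom
#'   (default 0.1).
#' @param vectors optional custom 3N x K orthonormal matrix overriding the
#'   default construction (per-atom x,y,z ordering over mobile atoms).
#' @return a `planted_modes` list: `vectors`, `sds`, `noise_sd`.
#' @export
planted_modes <- function(template = complex_template(), mode_sds = c(3, 2, 1),
                          noise_sd = 0.1, vectors = NULL) {
  nm <- template$n_res_mobile
  k <- length(mode_sds)
  if (any(diff(mode_sds) >= 0)) stop("mode_sds must be strictly descending")
  if (any(mode_sds <= 0) || noise_sd < 0) stop("mode_sds > 0 and noise_sd >= 0 required")
  if (is.null(vectors)) {
    if (k > 3L) stop("default construction provides at most 3 modes; pass `vectors`")
    dom <- template$domains
    block <- function(residues, axis) {
      v <- matrix(0, nm, 3L)
      v[residues, axis] <- 1
      as.vector(t(v)) / sqrt(length(residues))
    }
    r1 <- seq.int(dom[[1]][1], dom[[1]][2])
    r2 <- if (length(dom) >= 2L) seq.int(dom[[2]][1], dom[[2]][2]) else
      setdiff(seq_len(nm), r1)
    cand <- cbind(block(r1, 1L), block(r2, 1L), block(r1, 3L))
    vectors <- cand[, seq_len(k), drop = FALSE]
  }
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L * nm) stop("mode vectors must have 3 * n_res_mobile rows")
  gram <- crossprod(vectors)
  if (max(abs(gram - diag(ncol(vectors)))) > 1e-8)
    stop("mode vectors must be orthonormal to 1e-8")
  structure(list(vectors = vectors, sds = as.numeric(mode_sds),
                 noise_sd = as.numeric(noise_sd)),
            class = "planted_modes")
}

#' Variant scenario for the synthetic generator
#'
#' A scenario specifies how one variant's ensembles differ from the
#' template dynamics: mean shifts along planted modes (in units of each
#' mode's SD, emulating the PC shifts disease variants show) and
#' multiplicative rescaling of mobile-chain charges per domain (perturbing
#' the domain's interface interaction energy by a known factor). The
#' replicate/temperature design mirrors the triplicate-at-two-temperatures
#' convention: 3 replicates, 300 K and 360 K, with the higher temperature
#' realised as residual noise widened by sqrt(T/300).
#'
#' @param name variant name (`"WT"` for the reference).
#' @param mode_shifts named numeric: mode index -> shift in SD units
#'   (e.g. `c("1" = 2)` plants a +2 sigma shift on mode 1).
#' @param charge_scale named numeric: mobile-chain domain name -> factor
#'   applied to that domain's charges (1 = wild type).
#' @param n_replicates replicates per temperature (default 3).
#' @param n_frames frames per replicate (default 500, >= 2).
#' @param temperatures simulation temperatures in K (default `c(300, 360)`).
#' @param seed base seed; each (replicate, temperature) stream is derived
#'   from it deterministically.
#' @return a `variant_scenario` list.
#' @export
variant_scenario <- function(name, mode_shifts = numeric(0),
                             charge_scale = numeric(0), n_replicates = 3L,
                             n_frames = 500L, temperatures = c(300, 360),
                             seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  structure(list(name = as.character(name), mode_shifts = mode_shifts,
                 charge_scale = charge_scale,
                 n_replicates = as.integer(n_replicates),
                 n_frames = as.integer(n_frames),
                 temperatures = as.numeric(temperatures),
                 seed = as.integer(seed)),
            class = "variant_scenario")
}

random_rotation_small <- function(sd_deg = 5) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::rnorm(1, 0, sd_deg * pi / 180)
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3L, 3L)
  diag(3L) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

#' Sample one synthetic replicate ensemble
#'
#' Frame t places the mobile chain at `template + sum_k a_kt v_k + eps_t`
#' with `a_kt ~ Normal(shift_k * sd_k, sd_k^2)` and isotropic residual
#' `eps ~ Normal(0, noise_sd^2)` per coordinate; the fixed chain is held
#' exactly static (emulating a harmonically constrained partner). A small
#' random rigid-body transform (1 Angstrom translation SD per axis, 5
#' degree rotation SD) is then applied to every whole frame so that
#' skipping superposition visibly corrupts downstream PCA. Temperatures
#' other than 300 K widen the residual noise by `sqrt(T/300)`; planted
#' means are unchanged. Output is reproducible from
#' `(scenario$seed, replicate, temperature)`.
#'
#' @param structure the [build_template()] result.
#' @param modes a [planted_modes()].
#' @param scenario a [variant_scenario()].
#' @param replicate replicate index (1-based).
#' @param temperature temperature in K (one of the scenario's).
#' @param frame_interval recording interval in ps (default 2).
#' @return a [traj_ensemble()].
#' @export
sample_ensemble <- function(structure, modes, scenario, replicate = 1L,
                            temperature = 300, frame_interval = 2) {
  k <- length(modes$sds)
  shifts <- rep(0, k)
  if (length(scenario$mode_shifts)) {
    ki <- as.integer(names(scenario$mode_shifts))
    if (any(is.na(ki)) || any(ki < 1L) || any(ki > k))
      stop("mode_shifts references a mode index outside 1..", k)
    shifts[ki] <- as.numeric(scenario$mode_shifts)
  }
  midx <- which(structure$atoms$chain_id == "B")
  nm <- length(midx)
  if (nrow(modes$vectors) != 3L * nm)
    stop("modes are not defined on this template's mobile chain")
  t_frames <- scenario$n_frames
  noise_sd <- modes$noise_sd * sqrt(temperature / 300)

  seed <- derive_seed(scenario$seed, scenario$name, replicate, temperature)
  frames <- array(0, dim = c(t_frames, nrow(structure$xyz), 3L))
  with_seed(seed, {
    amp <- matrix(stats::rnorm(t_frames * k, mean = rep(shifts * modes$sds, each = t_frames),
                               sd = rep(modes$sds, each = t_frames)),
                  t_frames, k)
    disp <- amp %*% t(modes$vectors)
    if (noise_sd > 0)
      disp <- disp + matrix(stats::rnorm(t_frames * 3L * nm, 0, noise_sd),
                            t_frames, 3L * nm)
    for (t in seq_len(t_frames)) {
      fr <- structure$xyz
      fr[midx, ] <- fr[midx, ] + matrix(disp[t, ], ncol = 3L, byrow = TRUE)
      rot <- random_rotation_small(5)
      trans <- stats::rnorm(3, 0, 1)
      frames[t, , ] <- sweep(fr %*% t(rot), 2L, -trans)
    }
  })
  traj_ensemble(structure$atoms, frames, frame_interval, scenario$name,
                replicate, temperature)
}

#' Nonbonded parameter table for a synthetic scenario
#'
#' Coarse per-C-alpha parameters: every fixed-chain atom carries
#' `+base_charge`, every mobile-chain atom `-base_charge`, so the
#' cross-chain Coulomb interaction is attractive (negative), as at a
#' binding interface; mobile-chain atoms belonging to a domain named in
#' the scenario's `charge_scale` get their charges multiplied by that
#' factor. Because cross-chain Coulomb energy is bilinear in charges, a
#' factor f scales that domain's Coulomb interaction with the fixed chain
#' by exactly f at fixed geometry (f = 0 removes it entirely; 0 < f < 1
#' weakens the interaction, i.e. raises the energy towards zero).
#'
#' @param structure the [build_template()] result.
#' @param scenario a [variant_scenario()] (use `charge_scale = numeric(0)`
#'   for the wild-type table).
#' @param template the [complex_template()] used (for domain ranges).
#' @param base_charge charge in e given to every atom (default 0.08).
#' @param epsilon LJ well depth in kcal/mol (default 0.05).
#' @param rmin_half LJ rmin/2 in Angstrom (default 2.0).
#' @return a `parameter_table` data.frame.
#' @export
make_parameter_table <- function(structure, scenario = NULL,
                                 template = complex_template(),
                                 base_charge = 0.08, epsilon = 0.05,
                                 rmin_half = 2.0) {
  n <- nrow(structure$atoms)
  charge <- ifelse(structure$atoms$chain_id == "A", base_charge, -base_charge)
  if (!is.null(scenario) && length(scenario$charge_scale)) {
    midx <- which(structure$atoms$chain_id == "B")
    for (dom in names(scenario$charge_scale)) {
      if (!dom %in% names(template$domains))
        stop("charge_scale names unknown domain '", dom, "'")
      rng <- template$domains[[dom]]
      sel <- midx[structure$atoms$residue_number[midx] >= rng[1] &
                  structure$atoms$residue_number[midx] <= rng[2]]
      charge[sel] <- charge[sel] * scenario$charge_scale[[dom]]
    }
  }
  as_parameter_table(data.frame(
    atom_index = seq_len(n), charge_e = charge,
    epsilon_kcal_mol = rep(epsilon, n), rmin_half_A = rep(rmin_half, n)))
}

#' Default scenario set: wild type plus two test variants
#'
#' `WT`: no shifts, unit charges. `overgrowth_like`: +2 sigma on mode 1
#' (the docking-like nSH2 motion) and iSH2 charges halved — planted ground
#' truth for a `+PC1` call and a weaker (`"-"`) iSH2 interaction call.
#' `null_variant`: identical generator settings to WT under a different
#' seed — planted ground truth for all-`"n.s."`/none calls.
#'
#' @param seed base seed (default 1).
#' @param n_frames frames per replicate (default 500).
#' @param n_replicates replicates per temperature (default 3).
#' @param temperatures temperatures in K (default `c(300, 360)`).
#' @return named list of [variant_scenario()] objects.
#' @export
default_scenarios <- function(seed = 1L, n_frames = 500L, n_replicates = 3L,
                              temperatures = c(300, 360)) {
  list(
    WT = variant_scenario("WT", seed = derive_seed(seed, "WT"),
                          n_frames = n_frames, n_replicates = n_replicates,
                          temperatures = temperatures),
    overgrowth_like = variant_scenario(
      "overgrowth_like", mode_shifts = c("1" = 2),
      charge_scale = c(iSH2 = 0.5), seed = derive_seed(seed, "overgrowth_like"),
      n_frames = n_frames, n_replicates = n_replicates,
      temperatures = temperatures),
    null_variant = variant_scenario(
      "null_variant", seed = derive_seed(seed, "null_variant"),
      n_frames = n_frames, n_replicates = n_replicates,
      temperatures = temperatures))
}

#' Write a synthetic fixture set to disk
#'
#' Lays out `dir/{variant}/{temperature}/{replicate}.pdb`, one parameter
#' table per variant (`dir/{variant}/parameters.tsv`) and a
#' `manifest.json` recording seeds, shifts and scale factors.
#'
#' @param dir output directory (created if needed).
#' @param scenarios named list of [variant_scenario()]s
#'   (default [default_scenarios()]).
#' @param template a [complex_template()].
#' @param modes a [planted_modes()] (defaults built from `template`).
#' @return the manifest, invisibly.
#' @export
write_fixture_set <- function(dir, scenarios = default_scenarios(),
                              template = complex_template(),
                              modes = planted_modes(template)) {
  structure <- build_template(template)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(variants = list())
  for (sc in scenarios) {
    vdir <- file.path(dir, sc$name)
    files <- list()
    for (temp in sc$temperatures) {
      tdir <- file.path(vdir, as.character(temp))
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      for (r in seq_len(sc$n_replicates)) {
        ens <- sample_ensemble(structure, modes, sc, r, temp)
        f <- file.path(tdir, sprintf("%d.pdb", r))
        write_ensemble(ens, f)
        files[[length(files) + 1L]] <-
          list(path = f, replicate = r, temperature = temp)
      }
    }
    write_parameter_table(make_parameter_table(structure, sc, template),
                          file.path(vdir, "parameters.tsv"))
    manifest$variants[[sc$name]] <- list(
      seed = sc$seed, mode_shifts = as.list(sc$mode_shifts),
      charge_scale = as.list(sc$charge_scale),
      n_frames = sc$n_frames, files = files)
  }
  manifest$template <- list(n_res_fixed = template$n_res_fixed,
                            n_res_mobile = template$n_res_mobile,
                            domains = template$domains)
  manifest$mode_sds <- modes$sds
  manifest$noise_sd <- modes$noise_sd
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
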