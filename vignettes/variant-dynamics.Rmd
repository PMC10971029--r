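---
title: "Scoring variant effects on complex dynamics with varidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring variant effects on complex dynamics with varidyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varidyn)
```

## The problem

Missense and small in-frame indel variants of a regulatory protein can
change how it moves against its binding partner without changing the
folded structure much. For a two-chain enzyme complex such as PI3K —
the catalytic subunit PIK3CA bound by the regulatory subunit PIK3R1 —
the biologically decisive quantities are *dynamic*: how the regulatory
chain's SH2 domain samples its inhibitory docking pose, and how strongly
each domain interacts with the catalytic chain across a conformational
ensemble. varidyn implements the trajectory-ensemble analysis used to
score such effects: given multi-frame coordinate ensembles for a wild
type and a set of variants, it produces a per-variant table of
principal-component (PC) shift calls, per-domain interaction-energy
direction calls with significance, and RMSD/distance summaries.

The package takes ensembles as input (multi-model PDB or a minimal XYZ
dialect); it does not run molecular dynamics. A synthetic-ensemble
generator with planted ground truth stands in for MD output so that
every stage of the pipeline is testable end to end.

## Pipeline model and assumptions

### Superposition

All frames are superposed onto a single reference conformation (by
default the wild type's first frame) by least-squares rigid-body
fitting (Kabsch's SVD solution, reflections excluded) on a *fitting
selection*, conventionally the Cα atoms of the chain that is held
(nearly) fixed — the catalytic chain. RMSD and PCA are then computed on
a *reporting selection*, conventionally the mobile regulatory chain's
Cα atoms. Each frame is fitted independently, the standard convention
for trajectory analysis. The atom correspondence is fixed and explicit:
within one variant's trajectory it is the identity; for deletion
variants it is given by matching author residue numbers, skipping
deleted residues. No structure-alignment search is performed — with a
known correspondence, least squares is deterministic and checkable
against the closed-form quaternion solution, which the test suite does
on a thousand random instances.

Degenerate fits (fewer than three atoms, or collinear point sets, where
the rotation is underdetermined) are hard errors rather than silently
arbitrary answers.

### Cartesian PCA and the one-sigma shift rule

Collective motions are extracted by eigendecomposition of the
covariance of the superposed, selected Cα coordinates over pooled
frames. By default the covariance pools the wild type *and* all
variants so that every ensemble is projected onto one shared basis and
median scores are directly comparable across variants; fitting on the
wild type alone is available (`pca_pooling = "wt_only"`) and matters
when a variant's motion should not influence the basis. Three modes are
reported by default; the count is configurable.

A variant "activates" a mode when its median projection score differs
from the wild-type median by at least one standard deviation, where
sigma is the standard deviation of the *wild-type* pooled scores on
that PC — shifts are measured against the wild type, so its spread is
the natural scale. The threshold is inclusive (a shift of exactly one
sigma calls), and the call carries the sign of the median difference.

Eigenvector signs are inherently arbitrary, so varidyn fixes them
deterministically: each mode's largest-magnitude component is made
positive, ties broken by the lowest atom index. This makes bases
reproducible across runs, but the *physical* direction of "+PC1"
(towards or away from the partner chain) is a property of this
convention and the data; read it off `displacement_field()` rather than
assuming it. Reports therefore state medians and sigmas alongside the
signed calls.

### Distance monitors

Selected Cα–Cα distances track local unfolding, e.g. at the end of the
long inter-SH2 (iSH2) helices. The three monitors shipped as defaults
for the PIK3R1:PIK3CA complex are K567–E453, R577–Y452 and V445–L584
(regulatory-chain residue first). The source convention qualifies only
the first pair's second residue as belonging to the catalytic chain;
for the other two pairs both readings are plausible, so
`default_monitor_pairs()` exposes `reading = "verbatim"` (second
residue on the catalytic chain) and `reading = "intra_mobile"` (both
residues on the regulatory chain, matching the monitors' inter-helix
purpose). Neither is silently preferred. Distances are invariant under
the superposition (a rigid motion), which the tests assert.

### Switched nonbonded interaction energies

Per-domain interaction strength is summarised by a pairwise nonbonded
energy between two disjoint atom selections, summed over cross pairs
within a cutoff, per frame:

E(r) = S(r) · [ k_C q_i q_j / (ε r) + ε_ij ( (R_ij/r)^12 − 2 (R_ij/r)^6 ) ]

with geometric-mean well depths, summed rmin-halves, and the standard
CHARMM energy-switching polynomial S(r) tapering both terms smoothly
from `r_on = 10` Å to zero at `r_off = 12` Å. The dielectric is
configurable (default 1), with a distance-dependent option for coarse
Cα-level parameterisations.

This is deliberately a *surrogate*: no solvation term, no bonded terms,
coarse per-atom parameters. Its contract is therefore relative — a
variant and the wild type are always compared on identical
parameterisation and geometry conventions, and only the *direction* of
the energy difference is called ("+" stronger interaction, i.e. more
negative median energy; "−" weaker; "n.s." when the resampling test is
not significant). Absolute kcal/mol values are not comparable to
full-force-field energies and are reported only for traceability.

### Free-energy landscapes

The joint distribution of two PC scores over pooled frames is estimated
by a 2-D histogram (default 50×50 bins over the data range padded by 1%
per side) and converted to a relative free energy F = −ln(P/P_max) in
kT units: the most occupied bin has F = 0 and empty bins are undefined
(`NA`), never capped — capping is a rendering choice, not a data one.
The empirical histogram over trajectory frames is the implemented
interpretation of a "time-dependent joint probability"; no lag
structure or smoothing is applied. Temperature enters only through the
kT unit label.

Two closed-form limits anchor the estimator in the tests: standard
bivariate normal scores must reproduce the quadratic well F(r) = r²/2
(checked as a radial profile — annulus-averaged F against r²/2 — since
the per-bin maximum is an extreme statistic whose noise floor at 10⁵
frames is comparable to the tolerance), and uniform scores must give a
flat landscape (checked with `pad = 0` so the grid coincides with the
uniform support; with padded edges the boundary bins genuinely contain
less density and positive F there is the correct answer).

### The down-sampled resampling test

Trajectory frames are densely sampled and strongly autocorrelated, so a
t-test over all frames drastically overstates significance. varidyn
implements the conservative down-sampling procedure: draw `m = 100`
frames from each series (without replacement; with-replacement is a
config option), compute a Welch two-sample t per draw, repeat 1000
times, and take the median t as the test statistic. The two-sided
p-value evaluates the median t against the t distribution at the median
Welch degrees of freedom over the repetitions — converting a median
statistic to a p-value requires *some* convention, so the raw median t
is always reported alongside. Significance uses p < 10⁻⁶. Replicates
are pooled within a condition before drawing. A frame-stride thinning
knob is available as a cruder autocorrelation control; no block
bootstrap is attempted.

Two properties of this procedure are worth stating plainly. First, it
is *conservative by construction*: the median over repetitions averages
out the subsampling noise, leaving approximately the full-data t shrunk
by √(m/n), so with n ≈ 2000 pooled frames the null rejection rate at a
nominal 0.05 is essentially zero (measured: 0 of 200 null runs, minimum
p ≈ 0.5). It is a screen for overwhelming differences, not a calibrated
test — which is the intended behaviour for autocorrelated data, and why
the significance threshold is as extreme as 10⁻⁶. Second, at m = n it
degenerates exactly to the full-data Welch t, which the tests assert.

The Welch (unequal-variance) flavour is used throughout: it is the safe
default when a variant changes the fluctuation amplitude as well as the
mean.

### The pipeline and report

`run_analysis()` composes the stages — load, discard equilibration
(default: first third of each replicate, matching a 5-of-15 ns burn-in
convention at 2 ps recording), superpose, fit the shared basis,
project, classify PC shifts, monitors, energies, tests, landscapes —
and returns a classed report set; `render_report()` writes it as TSV,
JSON or markdown, one row per variant, with "n.s." spelled exactly so.
Temperatures are analysed separately (default 300 K; rerun with
`temperature = 360` for the high-temperature table) since combining
them into one call set has no single obvious convention. Qualitative
level columns (binning RMSD into Low/High and the like) have no
principled built-in thresholds, so the report emits numeric values and
leaves binning to the user. Per-variant test seeds are derived from the
configured seed and the variant's name, so adding or removing one
variant from a manifest never changes another variant's results (PC
calls can move only through the pooled covariance, which is documented
behaviour of the pooling mode).

## The synthetic generator

`build_template()` lays out a Cα-only two-chain complex: a fixed chain
A (80 residues, standing in for the harmonically restrained catalytic
subunit) and a mobile chain B (120 residues, the regulatory subunit),
each an ideal helix with exactly 3.8 Å consecutive Cα spacing, their
axes 9 Å apart so that many cross-chain pairs fall inside the 12 Å
cutoff. Chain B is partitioned into domains (defaults: "nSH2" = first
40 residues, "iSH2" = last 60).

`sample_ensemble()` draws frames as the template plus K planted
orthonormal collective modes with Gaussian amplitudes (SDs 3, 2, 1 Å by
default; a variant scenario shifts the mean of mode k by a stated
number of that mode's SDs) plus isotropic residual noise (0.1 Å), and
then applies a random rigid-body jitter to the whole frame (1 Å
translation SD per axis, 5° rotation SD) — large enough that skipping
superposition visibly corrupts the PCA, which makes the superposition
stage itself testable. The default modes are interpretable block
motions: the nSH2 block translating towards/away from the fixed chain
(a docking-like motion), the iSH2 block doing the same, and the nSH2
block sliding along the helix axis. Replicate structure mirrors the
triplicate-at-two-temperatures design (3 replicates at 300 K and at
360 K; the higher temperature widens the residual noise by √(T/300)
and does not move means — enough to exercise the two-temperature
bookkeeping, with no thermodynamic claim). Frames are recorded at a
nominal 2 ps interval.

`make_parameter_table()` assigns +q to fixed-chain and −q to
mobile-chain atoms (q = 0.08 e) so the cross-chain Coulomb term is
attractive, as at a real binding interface, with uniform LJ parameters
(ε = 0.05 kcal/mol, rmin/2 = 2 Å); a variant scenario rescales a
domain's mobile-chain charges by a stated factor, which by bilinearity
scales that domain's Coulomb interaction with the fixed chain *exactly*
by that factor at fixed geometry. Halving a domain's charges therefore
plants an unambiguous "weaker interaction" ground truth; the sign
matters — with same-sign (repulsive) charges the identical perturbation
would plant the opposite call.

What the generator deliberately does **not** emulate: force-field
energetics, solvent, anharmonic or multi-basin landscapes, and — most
importantly for the statistics — frame-to-frame autocorrelation (frames
are i.i.d. draws). Passing tests on synthetic data therefore
demonstrate the *machinery* (recovery of planted modes, shifts and
energy perturbations; correct calls), not that real MD ensembles are
this well behaved; on real data the i.i.d. assumption fails exactly in
the way the down-sampling test is designed to be robust to.

## Numerical choices

* Kabsch: proper rotation enforced via the determinant correction;
  collinearity detected by the second singular value of the centred
  coordinates (tolerance 10⁻⁸ relative); each frame fitted
  independently.
* Eigenvector sign: largest-magnitude component positive, ties to the
  lowest atom index.
* Equilibration discard keeps the last ⌈T·(1−f)⌉ frames, with a 10⁻⁹
  guard inside the ceiling so that T·(1−f) values such as 15·⅔ are not
  pushed up a frame by floating-point noise.
* Energy kernel: per-frame vectorised cross-distance evaluation using
  explicit coordinate differences (no squared-norm expansion, which
  loses precision at short range); equals the all-pairs double loop to
  10⁻¹⁰ kcal/mol on the test fixtures.
* FEL: empty bins are `NA`; probability normalised over pooled frames;
  the 1% range padding is a display default and is dropped (pad = 0)
  where an estimator limit assumes the grid matches the support.
* The down-sampling p-value uses the median Welch df across
  repetitions; equal constant series give t = 0 by convention, zero
  variance with unequal means is an error.
* All randomness is seed-derived: ensemble generation from
  (scenario seed, variant name, replicate, temperature), test seeds
  from (config seed, variant, domain pair). Re-running a configuration
  reproduces every number bit for bit.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
to keep estimates stable while finishing in about a minute each: 1000
random instances for the superposition oracle; 200 frames for the
energy oracle; 2000 frames for planted-mode recovery (eigenvector
cosines ≥ 0.99); 20 seeds × 3 replicates × 500 frames for the shift
classifier's recovery rate; 200 null runs (n = 2000, m = 100, 1000
repetitions) for the test's conservativeness; 10⁵ points for the
landscape limits; and a full end-to-end analysis of a wild type plus
two planted variants at 3 × 500 frames. The cached-frames
demonstration plants median PC1 shifts of +0.31 and −1.84 Å under mode
SDs of 1.5/1.0/0.5 Å — the smaller shift stays below the one-sigma
threshold and the larger one calls, the configuration of interest for
distinguishing sub-threshold from called shifts — and uses 3 × 2700
frames per variant so the median-difference standard error (≈ 0.05 Å)
resolves the smaller shift.

## Known limitations

* The energy module is a coarse surrogate; only relative,
  identically-parameterised comparisons are meaningful.
* The down-sampling test's p-value is a convention on top of a median
  statistic; treat it as a screen with the raw median t alongside, not
  as a calibrated error rate.
* PC sign conventions are deterministic but not physical; direction
  statements require inspecting the displacement field.
* The PDB reader keeps the first alternate location and rejects
  insertion codes (modelled structures have neither); binary trajectory
  formats (DCD/XTC) and topology files are out of scope.
* Deletion-variant correspondences rely on consistent author residue
  numbering across models.
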