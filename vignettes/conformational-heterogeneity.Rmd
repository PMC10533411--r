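---
title: "Quantifying conformational heterogeneity in tetrameric receptor ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational heterogeneity in tetrameric receptor ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confscape)
```

## The problem

AMPA-type glutamate receptors (AMPARs) are tetrameric ligand-gated cation
channels built from three stacked layers: the N-terminal domains (NTD), the
ligand-binding domains (LBD) and the transmembrane channel. In receptor
assemblies whose NTD layer loses its tetramer interface — GluA1 homomers and
interface mutants of GluA2 — the two NTD dimers detach from one another and
swing through a wide range of configurations, from vertical upright to
splayed past horizontal. The same assemblies also populate *non-swapped*
arrangements, in which an NTD dimer's partners pair with each other again in
the LBD layer instead of crossing over, and they recover slowly from
desensitization. Quantifying this heterogeneity requires several distinct
measurements on ensembles of fitted atomic models, on particle
classifications and on current recordings. `confscape` implements that whole
measurement chain, together with a synthetic-data generator that plants
known ground truth so every stage can be validated quantitatively.

## NTD dimer tilt (splay) angles

Each fitted model contributes two angles (*a*, *b*), one per NTD dimer: the
angle between the dimer's **second** principal axis — which runs along the
dimer's local two-fold axis — and the **first** principal axis of a
reference receptor whose global two-fold axis stands vertical. The angle is
the arccosine of the dot product of unit axes, with the argument clamped to
[−1, 1] so no valid input can produce `NaN`.

Principal axes here are eigenvectors of the *positional* covariance of the
CA atoms (equal weights, population normalization), not of a mass-weighted
inertia tensor: the pipeline operates on CA-only ensembles, where the two
coincide up to the constant atom mass. Eigenvectors carry an arbitrary sign,
so both axes are canonically oriented before the dot product:

* the reference first axis points toward `reference_top`, the NTD end of
  the receptor (by default the mean of the two dimer centres of mass on the
  reference);
* the dimer second axis is oriented so that its dot product with
  (dimer COM − reference COM) is positive, i.e. outward/up, away from the
  receptor core.

When the eigen-solver's deterministically signed axis points the other way
— "down towards the LBD" — the reported angle is the 180° complement of the
naive arccosine and the result is flagged `corrected = TRUE`. The reported
angle therefore covers the full [0°, 180°] range, keeping
splayed-past-horizontal states distinguishable, and planted rigid rotations
about any axis perpendicular to the reference axis are recovered at their
full magnitude. The outward-COM orientation rule presumes the usual
architecture — a dimer hinged above the receptor's centre of mass, with its
own COM displaced along its axis further than the hinge is from the
receptor COM. For bodies rotating about their own COM the rule cannot track
orientation past ~90° and the complement convention decides the branch;
this is a declared convention of this package, chosen because it is
deterministic and recovers planted geometry, not a claim about any
particular upstream implementation.

Which dimer is *a* and which is *b* is not a geometric property; the
assignment follows the order of the two selections supplied to
`splay_landscape()`, so it is configuration-driven and reproducible.

## Ensemble PCA and morphs

`ensemble_pca()` decomposes the mean-centred positional covariance of an
atom-matched CA ensemble. Two conventions needed pinning down:

* **Normalization.** The covariance is divided by the number of frames *M*
  (population form), not *M* − 1. The two-frame identity — frames differing
  by a displacement *d* yield a single mode with eigenvalue |*d*|²/4 — is
  asserted in the tests and fixes the convention observably.
* **No alignment by default.** Ensembles that come from classification
  share one reference frame already; superposing them first would silently
  remove the rigid-body component of the heterogeneity, which for these
  receptors is itself signal (the leading mode of the NTD layer is a
  rotation of the whole layer). `superpose_first = TRUE` is available and
  iteratively Kabsch-fits each frame to the running mean (at most 10
  iterations or a mean shift below 10⁻⁶ Å).

Mode amplitudes support two conventions because both are natural: a
`target_rmsd` *t* displaces along the unit eigenvector by *t*·√*N*, giving a
maximum frame RMSD of exactly *t* (e.g. 20.0 Å for a dominant mode, matched
to the span of the ensemble's own projections); a dimensionless
`scale_factor` *c* displaces by *c*·√λₖ, i.e. it is variance-weighted, so
one factor applied to several modes yields amplitudes proportional to each
mode's spread. The variance-weighted reading is this package's declared
meaning of a bare scale factor.

Morphs sample one closed cycle mean → +max → mean → −max → mean on a
sinusoidal schedule. A uniform phase grid cannot both start/end exactly at
the mean and contain the exact ±max frames for arbitrary frame counts
(e.g. 20), so the grid snaps the three interior key phases (π/2, π, 3π/2)
to their nearest grid points — deterministic, monotone, and exact at the
endpoints and extremes for any *n* ≥ 5. Zero-eigenvalue modes scaled by a
factor produce a zero-motion morph with a warning rather than an error.
Cosine overlaps |v̂ᵢ·ŵⱼ| compare mode sets over identical atom labels; the
self-overlap matrix is the identity to 10⁻⁹.

## LBD rotation angles

The rotation of each subunit's LBD is measured against a reference
structure after all models are placed in a common frame with the global
symmetry axis along *z*. Each chain's linker anchor residue (K501 in GluA1,
K505 in GluA2 numbering) defines a vertical rotation axis; the centre of
mass of helix G is the proxy point that swings about it. Per chain, anchor
and helix-G COMs are pooled across **all** structures (models plus
reference) with equal weight per structure — not per atom — so models whose
selections resolve to different atom counts contribute equally. The vertex
of the measured angle is the chain's reference point: *x*, *y* from the
pooled anchor COM and *z* from the pooled helix-G COM; the two rays run to
the model's helix-G COM and to the reference structure's helix-G COM.

Whether the original angle was taken in 3D or in the *x*–*y* plane is not
recoverable from a three-point construction alone, so both are implemented:
`vertex3d` (default) and `projected_xy`, which zeroes *z* components first
and isolates rotation about the vertical axis. Whenever the three points
share one *z* value the two agree exactly; planted vertical rotations are
recovered exactly by both. The residue range defining helix G is a required
configuration input (it is an annotation of the structure at hand, not a
constant of the method).

## Consensus classification statistics

Discrete particle classification is unstable: repeated runs, and runs with
different class counts, give varying category proportions. The consensus
protocol therefore repeats classification (triplicate in the emulated
design) over a sweep of class counts *k* and asks which runs co-migrate.
`comigration_matched_fraction()` builds the *k*×*k* contingency matrix of
shared particles between two equal-*k* runs, solves the maximum-weight
one-to-one class matching exactly with a Hungarian assignment solver
(implemented here in O(*k*³); verified against brute-force enumeration of
all *k*! matchings for *k* ≤ 6), and reports the fraction of particles in
matched cells — invariant to class relabelling and symmetric in its
arguments.

A run inside the consensus window (default *k* ∈ [6, 20]) counts as
*consistent* when its matched fraction exceeds the threshold (default 0.6)
against at least half of the other in-window runs **with the same k** —
matched fractions are only defined between equal-*k* runs, so a run with no
same-*k* partner cannot be consistent. The summary reports the mean and
standard error (sample SD with the *n* − 1 denominator, divided by √*n*) of
the category fraction over consistent runs, with *n* the number of
consistent runs. Both the threshold and the majority rule are declared
conventions of this package; "most consistent runs" admits several
formalizations and this one is deterministic and monotone in the evidence.
Category annotations (swapped / non-swapped / junk per class) are user
input: in practice they come from visual inspection of class maps, which
cannot be automated here. Fractions are always over non-junk particles.

## Kinetics

All times are ms and currents pA; junction-potential and series-resistance
corrections belong to acquisition, upstream of this package.

* **Desensitization decay.** The fit window runs from the first sample
  after the peak at which the baseline-subtracted current has fallen to 90%
  of the peak, to the end of the agonist pulse; the model is one or two
  exponentials plus a fitted steady-state offset, solved by bounded
  Levenberg–Marquardt least squares from three deterministic starts (the
  bi-exponential likelihood has a well-known identifiability trap).
  Components are ordered τf ≤ τs and the amplitude-weighted
  τw = τf·Af/(Af+As) + τs·As/(Af+As) is reported — a convex combination,
  always inside [τf, τs]. Note that the amplitudes are those at the fit
  window's origin, not at the peak: starting the window at 90% of peak
  slightly re-weights fast versus slow, which is a property of the
  measurement protocol itself, and the tests assert it analytically.
  Peak detection requires |peak| > 5× the baseline SD.
* **Recovery from desensitization.** A two-pulse protocol yields
  second/first peak ratios versus inter-pulse interval, fitted with
  ratio(t) = 1 − (1 − r₀)·exp(−t/τrec). The intercept r₀ is fitted (bounded
  [0, 1)) rather than pinned to a steady-state estimate, since the original
  handling is not recoverable; a data set whose ratios are all ≈ 1 is
  rejected as already recovered. The estimate depends only on ratios, hence
  is invariant to current units.
* **Trains and rectification.** `ppf_normalize()` divides peak amplitudes
  by the first response of a train (e.g. 20 Hz stimulation).
  `rectification_index()` computes −(I₊₄₀ − I₀)/(I₋₆₀ − I₀); an ohmic I–V
  through the origin gives 2/3, complete inward rectification gives 0.

## The synthetic-data generator

The generator is first-class, tested code; it stands in for particle stacks
and recordings that cannot be shipped. Its defaults are the study
conditions the package is validated under:

* **Scaffold.** Four chains with a global two-fold axis along *z*, built by
  constructing the A/B half and rotating it 180° for C/D, so the symmetry
  is exact to machine precision and *z* is an exact principal axis. Each
  chain carries a vertical LBD dummy helix, an 11-residue helix-G segment,
  a single anchor residue (all anchors at equal *z*), and one NTD lobe;
  lobes pair into two dimers whose variances order so that the second
  principal axis is the vertical local two-fold axis. Domains are rigid
  dummy CA traces — sufficient for COM/axis/angle analyses; no side chains,
  no physics.
* **Motions.** Each dimer rotates rigidly about a hinge at its lower tip
  (mimicking the NTD–LBD linker attachment) about the horizontal axis that
  tilts it radially outward; each flagged chain's LBD body rotates about
  the vertical axis through its anchor. Isotropic Gaussian noise is added
  last, and the full ground truth (including the seed) travels with every
  output.
* **Classifications.** Each particle draws its true category once
  (swapped fraction 0.8 by default, i.e. ~20% non-swapped) and keeps a
  stable latent class preference within its category across runs — without
  that stability, independent uniform assignments would co-migrate at only
  ~1/k and no run would ever pass the consistency screen, unlike real
  classifications of a fixed particle stack. Label noise (default 5%)
  reassigns a particle uniformly over *all* classes rather than flipping
  its category: with class counts proportional to category fractions this
  leaves the measured fraction unbiased, whereas category-flip noise would
  bias it toward 0.5 by noise·(1 − 2f).
* **Sweeps.** Conditioning pulses rise instantaneously and decay
  bi-exponentially to a steady state (defaults τf = 4 ms, τs = 40 ms,
  fast-dominant 3:1 amplitudes, 5% steady state — GluA1-like); test-pulse
  peaks follow the planted recovery curve (default τrec = 192 ms; the
  GluA2-like fast alternative 43 ms is exercised in tests); train peaks
  follow a geometric depression factor (0.8).

What the generator does **not** emulate: real fitted models have
non-rigid internal deformations, correlated fitting error and pseudo- rather
than exact symmetry; real classifications have class-size imbalance, junk
classes and k-dependent structure; real currents have filtered rise times,
deactivation tails and drifting baselines. Passing the recovery tests
therefore demonstrates the correctness of the measurement chain on its
stated model class, not robustness to every artefact of experimental data.

## Numerical choices and problem sizes

Kabsch superposition uses SVD with the sign-corrected determinant so a
reflection is never returned, and is deterministic under degenerate
singular values via the SVD's fixed ordering. Eigenvector signs follow a
first-nonzero-positive rule before any geometric canonicalization. All
arccosine arguments are clamped. Random number use is always governed by an
explicit seed, with per-item substreams drawn up front so outputs are
bit-identical across runs — the end-to-end pipeline test hashes its CSV
outputs to assert exactly that.

The validation suite runs at deliberately modest sizes chosen as adequate
for the claims being tested: a 10×10 grid of planted (a, b) splays on a
304-atom scaffold, 50-frame ensembles for planted-mode recovery, 20 000
particles × 45 runs for the consensus recovery, and 50–100 seed replicates
for the noisy kinetics fits. Every tolerance asserted in the tests
(10⁻⁶ ° noiseless recovery, 1° at σ = 0.2 Å, 0.02 on the planted fraction,
5–10% on noisy kinetic constants) was fixed from the study conditions
before the corresponding data were examined, and the same quantities are
recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Chain correspondence between models and reference is by chain label;
  relabelling (when upstream fitting scrambles chains) must happen before
  the analyses, via explicit configuration.
* The consensus consistency rule and threshold are conventions; with very
  few runs per *k* the majority rule is coarse.
* The decay fitter assumes a single dominant pulse per fit window and a
  step-like agonist application; slow perfusion exchange would bias τf.
* mmCIF support covers atom records (via bio3d's reader); exotic altloc or
  insertion-code schemes are resolved by a simple first-by-identifier rule,
  with warnings.
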