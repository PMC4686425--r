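---
title: "Models and methods behind punctakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind punctakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctakit)
```

punctakit quantifies starvation-induced protein-body formation from
four kinds of evidence — gel mobility shifts, scored microscopy time
courses, protein sequences, and fluorescence image stacks — plus exact
contingency inference on clone counts. This vignette explains each
model, its assumptions, the tunable parameters, and the deliberate
numerical choices; it also spells out what the bundled simulators do
and do not emulate, and therefore what a passing test suite does and
does not show about real data.

## Band-shift densitometry

Phosphorylated protein species migrate more slowly on SDS-PAGE, so the
vertical intensity distribution of a lane encodes the phosphorylation
state of the pool. The scoring model is deliberately simple and strictly
linear:

1. `extract_lane_profile()` collapses a lane image to a trace by
   averaging across the lane width at each migration position (index 0
   = top of gel = slowest migration). Lane boundaries are user-supplied;
   automatic lane finding is out of scope.
2. `normalize_total()` rescales each lane so its summed signal equals
   that of a designated reference lane (conventionally the t = 0
   control of the same gel), removing loading differences. The
   reference is per-batch; nothing forces a global reference across
   gels.
3. `position_weighted_score()` computes `Σᵢ wᵢ Iᵢ`, with weights
   interpolating linearly from 100 at the first pixel to 0 at the last
   (both endpoints inclusive, step `100/(n−1)`). The literature
   sometimes calls this a "position weighted mean"; after total
   normalization the weighted sum and the weighted mean differ only by
   the fixed total, and the package reports the sum, in weight units.
4. `fit_anchor_transform()` solves the unique affine map sending a
   high-anchor raw score to 1.0 and a low-anchor raw score to 0.0
   (wild type in 2% glucose and after 60 min in 0% glucose). The same
   constants rescale every lane and any error bars.

Numerical choices: normalized scores are **not** clamped to [0, 1] —
the map is affine, and clamping would hide drift; the transform is
evaluated as `(raw − low)/(high − low)`, which is algebraically the
stored `scale·raw + offset` but floating-point-exact at both anchors;
equal anchors raise a degenerate-anchor error. An optional per-lane
constant background subtraction (the lane minimum) is available but off
by default, since the baseline scoring procedure operates on raw
intensities. Because the score is linear in the profile and the two-band
geometry is fixed, the normalized score of a noiseless lane equals its
true phosphorylated fraction exactly when the anchors are the 1.0/0.0
lanes — the key invariant the tests assert.

## Kinetics of body formation and dissociation

The fraction of cells containing at least one body is modelled as

* formation (starvation): `f(t) = A·(1 − e^(−t/τ)) + c`
* dissociation (repletion): `f(t) = A·e^(−t/τ) + c`
* no change (rich medium): a straight line,

with `A` the responding fraction, `τ` the apparent time constant
(minutes) and `c` the baseline fraction (at the start for formation, at
the end for dissociation). Fitting is unweighted nonlinear least
squares on the replicate-mean fractions — the convention for
figure-level fits of scored time courses; replicate counts enter only
through the mean. Inverse-binomial-variance weighting is available
behind `weights = "binomial"` but is not the default, and means of
fractions (not pooled counts) are fitted.

Optimizer choices, made once: Levenberg–Marquardt with box constraints
`A ∈ [0,1]`, `c ∈ [0,1]`, `τ ∈ (0, 10·t_max]`, and a three-point
multi-start over `τ₀ ∈ {t_max/10, t_max/3, t_max}` with `A` and `c`
seeded from the endpoint fractions; the converged start with the lowest
residual sum of squares wins. This makes convergence reproducible
without hand-tuning. Standard errors are the usual local (curvature)
estimates from the fit. A constant series drives `A` to its lower
bound; the fit is returned with `tau_identifiable = FALSE` rather than
an error, since amplitude zero genuinely means τ carries no
information. Model choice between exponential and line is declared by
the analyst per condition; `compare_to_flat()` provides an F-test as an
aid but is never auto-applied.

## Q/N prion-like motif quantitation

Prion-like motifs (PriLMs) in yeast proteins are glutamine/asparagine
rich. The canonical detectors are HMMs trained on known prion domains;
training one is out of scope here, and the package deliberately
separates two concerns:

* **Quantitation of stated intervals** (`qn_composition()`,
  `composition_table()`): exact Q/N counts and percentages for
  user-supplied coordinates, decoupled from any detector, so table-style
  reporting is reproducible bit for bit. Coordinates are 0-based
  half-open internally and 1-based inclusive at file boundaries
  (`read_interval_manifest()` converts). `X` and other non-Q/N letters
  count toward length, never toward Q/N.
* **Detection** (`scan_qn_windows()`): a transparent compositional
  scanner — flag windows with Q/N fraction ≥ threshold (defaults:
  window 20, threshold 0.4, merge gap 10), merge nearby flags, trim to
  the outermost Q/N residues. It recovers planted or strongly Q/N-biased
  motifs; it is a stand-in and makes no claim of matching HMM
  boundaries.

`mutate_interval_to_alanine()` models motif disruption (Q-stretch →
A-stretch); by construction it drives the interval's Q/N percentage to
zero and removes it from scan output, which the tests assert.

## Foci counting and co-localization

Bodies are scored on maximum projections of short z-stacks (the
projection-then-score workflow; never 3-D detection). The paperless
step here is detection, which in practice is often done by eye;
punctakit automates it so synthetic experiments can be quantified end
to end, and exposes every knob: Gaussian smoothing (σ = 1 px),
threshold at background median + k·MAD (k = 5), 8-connected components,
and an area band (4–200 px) for spot-like signals. When the MAD is zero
or negligible relative to the dynamic range — noiseless renders — the
threshold falls back to halfway between median and maximum, which
segments isolated spots cleanly and returns nothing on a flat image.
Centroids are intensity-weighted on the smoothed image; peak intensity
is read from the raw projection. Connected-component labeling is
written in package code because the available labelers are 4-connected.

Cell segmentation is out of scope: `assign_to_cells()` takes a labeled
cell map (the simulator emits its truth map), assigns each focus to the
label under its centroid, tallies background-landing foci separately,
and reports every cell including zero-body ones. `body_fraction()`
attaches a Wilson score interval. `colocalization_fraction()` declares
a cell co-localized when any same-cell pair of channel-A and channel-B
centroids lies within a caller-chosen pixel distance — no default
distance is claimed, because none is canonical.

## The simulators: what they emulate, and what they do not

Every simulator emits ground truth beside its data and is bitwise
reproducible: one user seed is expanded through a counter-based
substream scheme (per lane, per replicate, per cell), so enlarging a
batch never perturbs earlier draws.

* **Gel lanes**: two Gaussian bands on a 200-pixel migration axis
  (phosphorylated at pixel 60, unphosphorylated at 140, σ = 8), a known
  fraction of the total signal in the top band, additive Gaussian noise
  truncated at zero — the simplest model consistent with non-negative
  intensities. No gel warping, smiling, or multi-band chemistry.
* **Time courses**: binomial sampling of body-positive counts at the
  model fraction `p(t)`, 200 cells per timepoint and 3 replicates by
  default — the typical scored design (real reports state only
  ">200 cells per time-point"). The formation grid spans 0–60 min
  (8 points); the dissociation grid 0–180 min (9 points), chosen once
  so a ~48-minute time constant is identifiable within the sampled
  window. Real scoring noise beyond binomial sampling (observer
  variation, day effects) is not modelled.
* **Sequences**: background residues drawn from a Q/N-free alphabet by
  default, planted motifs with exactly `round(f·L)` Q/N residues at
  stated coordinates. No homology structure, no low-complexity
  background beyond the motif itself.
* **Cell stacks**: cells on a regular grid, a membrane ring per cell,
  3-D Gaussian foci planted in an annulus just outside the ring (the
  perivacuolar zone), optional mirrored foci in a second marker
  channel, additive truncated-Gaussian background noise. Foci of one
  cell are re-drawn until separated by ≥ 7 px in projection — spots
  closer than the detector's resolution would be scored as one by any
  method, manual scoring included. No point-spread-function realism,
  photobleaching, camera noise model, or organelle morphology beyond
  the ring.

Consequently, passing tests demonstrate correctness of the *analysis
operators* and calibration of the *estimators under the stated sampling
models* — not robustness to the full messiness of real micrographs and
gels (out-of-focus light, touching cells, lane distortion). That
boundary is intentional and is why detection parameters, lane windows
and cell maps are all user-controllable rather than inferred.

## Exact viability inference

Clone counts from allele-replacement (loop-in/loop-out) experiments
form 2×2 tables; with cells this small, asymptotic tests are
inappropriate, so `fisher_exact()` enumerates the hypergeometric
distribution of the top-left cell at fixed margins. The kernel
(`hypergeom_pmf()`) multiplies exact integers while every intermediate
stays below 2^53 and falls back to log-space binomials beyond —
overflow-free past N = 10,000. One-sided p-values are tail sums; the
two-sided rule is the minimum-likelihood convention (sum of all tables
no more probable than the observed, with 1e-7 relative slack). The
default alternative is `greater` — directional, retention of the benign
allele exceeding that of the lethal one — and for the tables of
interest, whose extreme cell is 0, the one- and two-sided values
coincide, as the enumeration oracle in the tests confirms.

## Pipeline and reproducibility

`run_pipeline()` executes YAML-declared stages (simulate, bandshift,
kinetics, prilm, foci, fisher) in listed order after full config
validation (unknown stages, missing fields and dangling inputs are
rejected before any work). Stage *i* draws from substream *i* of the
run seed; every output file carries a provenance header (package
version, seed, config hash over seed + stages, so the hash is
independent of the output directory); the run report checksums each
output. Identical config + seed therefore yields byte-identical
outputs, which the test suite asserts across the full simulate → score
→ fit → table chain.

## Problem sizes used in the checks

The test suite works at deliberately desk-scale sizes: Monte-Carlo
calibration of τ recovery uses 1000 simulated experiments per model at
the default design (where the median τ̂ lands within 10% of truth and
±3·se covers truth in ≥95% of runs); foci fidelity uses fields of
100–500 cells over 10 seeds; scanner recovery uses 100 seeded
sequences. These sizes were chosen as the smallest at which the
binomial and least-squares noise floors make the stated tolerances
meaningful.

## Known limitations

* The band-shift score is linear and band-shape-agnostic; strongly
  nonlinear staining response or saturated pixels violate its
  assumptions silently.
* Exponential fits on means ignore replicate-level heteroscedasticity
  unless binomial weighting is requested; standard errors are local
  curvature estimates, not profile or bootstrap intervals.
* The Q/N scanner is compositional only; motifs defined by subtler
  features (charge depletion, hydrophobicity) require a trained model.
* Foci detection assumes spot-like, well-separated signals on a
  reasonably uniform background; it is a stand-in for expert scoring,
  not a general spot detector.
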