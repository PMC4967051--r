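---
title: "Quantifying lesion dispersion: box-counting, multifractal spectra, and a kinetic Monte Carlo spreading model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lesion dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalmet)
```

## The measurement problem

Whole-body tracer imaging of disseminated cancer shows bright voxels
wherever metabolically active tissue — lesions, but also heart, brain,
liver — accumulates the tracer. `fractalmet` quantifies the *spatial
organization* of that uptake. The working hypothesis is mechanistic:
malignant cells travel along the branching circulatory (and lymphatic)
networks and seed colonies adjacent to them, so the set of lesions inherits
the fractal geometry of its transport network (dimension around 2.6–2.7
for human vasculature). Focal, hierarchically clustered uptake then has a
low box-counting dimension; diffuse, body-filling uptake approaches the
embedding dimension 3. Serial changes in these statistics track whether
uptake is concentrating (progression) or dispersing (response).

This vignette documents the models, the conventions and parameter choices,
and what the accompanying tests do and do not demonstrate.

## Fractal analysis

A scan volume is first regridded to an isotropic analysis lattice of cubic
voxels (default edge 4 mm, matching a typical reconstructed slice
thickness; in-plane pixels of ~2 mm aggregate 2×2×1, accepted within a 2 %
commensurability tolerance). Regridding *sums* constituent voxel
intensities, so total activity is conserved; partial blocks at the far
boundary are kept as partial output voxels rather than discarded.

Tracer presence is then thresholded. The default policy marks a voxel
occupied if its intensity exceeds 5 % of the volume maximum; an absolute
threshold is also available. Neither is a clinical standard — the policy
and realized threshold are recorded in the mask provenance, and the choice
matters mainly for reconstruction background. An everywhere-empty mask is
an error rather than a zero: every downstream fit is undefined on it.

The occupied set is covered with cubic boxes of edge `s` anchored at the
volume corner, and `N(s)` — boxes containing at least one occupied voxel —
is recorded for a ladder of sizes. The dimension is the negative slope of
an unweighted least-squares line through `(ln s, ln N(s))`; the intercept
exponentiates to the prefactor `C`, and the `R²` of that regression is
reported as goodness of scaling.

### Numerical conventions that matter

Two conventions dominate the finite-size behaviour of box counting, and we
fixed both by measurement against sets of exactly known dimension:

- **Boundary boxes.** When `s` does not divide the grid, the last box row
  per axis is under-filled. Counting those partial boxes inflates `N(s)`
  preferentially at large `s` (a partial box is almost always hit by a
  dense set) and *flattens* the slope: on the depth-4 vascular generator
  the mixed ladder `s = 1..20` then reads ~2.40 instead of ~2.63. The
  default therefore counts only the `floor(dim/s)` complete boxes per axis
  (`boundary = "complete"` in `box_count()`); the margin voxels are
  ignored for that size. The `"partial"` convention is retained as an
  option (it guarantees `N(s) ≥ 1` for any occupied voxel position).
- **Size ladder.** Even complete-box counting is biased on sizes that do
  not tile the grid (the floor truncation is itself a step function). The
  default scan ladder (`default_box_sizes()`) therefore uses the *divisor
  ladder*: multiples of the analysis edge that divide every axis of the
  regridded grid, within the 4–200 mm whole-body scaling range and capped
  at the body extent. Divisor ladders tile exactly: on self-similar test
  sets the log-log points are collinear and the fitted dimension is exact
  to machine precision. Denser (`"all"`) and doubling (`"pow2"`) ladders
  are available, and explicitly supplied ladders — such as the lattice
  ladder `s = 1..20` used for simulation output — are honoured as given.

Degenerate inputs are defined, not special-cased away: a flat count curve
(all `N(s) = 1`) fits `d_f = 0` with `R² = 1`; any `N(s) = 0` (possible
under the complete-box convention if all occupancy sits in the cropped
margin) is an error; fewer than three distinct sizes is an error.

## Multifractal analysis

Fractal analysis uses only lesion *positions*; the multifractal spectrum
also uses tracer *content*. At the finest analysis scale (4 mm boxes =
voxels of the regridded volume), each occupied box receives mass
`p_i` = box intensity / total intensity, so `Σ p_i = 1` and subjects with
different absolute uptake become comparable. The generalized dimensions
are evaluated at that single scale:

$$D_q = \frac{1}{q-1}\,\frac{\ln \sum_i p_i^q}{\ln \varepsilon},
\qquad
D_1 = \frac{\sum_i p_i \ln p_i}{\ln \varepsilon},$$

with three conventions worth stating explicitly:

- **The scale argument** is the dimensionless `ε = s / (largest body-axis
  extent)`, not `s` in millimetres. With raw millimetres, `ln 4 > 0` would
  flip the sign of every dimension; with the normalized scale, `ln ε < 0`
  and a uniform space-filling measure reads back exactly `D_q ≡ 3`, which
  is the identity we use to pin the convention (tested). This is a
  *single-scale* estimate — no limit `s → 0` is available at a fixed
  reconstruction resolution — and is labelled as such.
- **Empty boxes are excluded** from all sums. A `p_i = 0` term would make
  every negative-`q` sum infinite; restricting to occupied boxes is both
  standard practice and forced by finiteness. Sums for large `|q|` are
  evaluated through log-sum-exp so `p_i^{±10}` cannot under- or overflow.
- **The `q = 1` branch** (information dimension) is used within
  `|q − 1| < 10⁻⁹`, and its continuity against `q = 1 ± 10⁻⁶` is checked
  and recorded on every spectrum.

The spectrum is evaluated on the integer grid `q = −L..L` with `L = 10` by
default — wide enough that the heavy-`|q|` tails have visibly flattened,
and recorded per result so serial comparisons can insist on identical
grids. `D_q` is provably non-increasing in `q` for any fixed-`ε` measure
(a Rényi-entropy monotonicity), and the test suite asserts this on
randomly generated measures.

For two studies on the same grid the averaged index
`D_MF = mean(D_q(I) − D_q(II))` compresses the spectrum shift into one
signed scalar; positive values are read as improvement. It is
antisymmetric, and exactly additive along a study chain (early + late =
final) — both identities are asserted in the tests, and the serial-report
comparator checks the additivity residual of every comparison it emits.

## The kinetic Monte Carlo spreading model

The model world is an `L×L×L` lattice (default `L = 81`) containing a
deterministic fractal stand-in for the circulatory network. The network is
built by recursive 3×3×3 refinement keeping 18 of the 27 subcells at every
level, so depth `k` gives `18^k` sites and dimension `log₃ 18 ≈ 2.6309`.
The specific 18-cell motif is a modelling choice — many 18-subsets exist —
and we use the symmetric, face-connected one that drops the 8 corners and
the body centre; the motif is configurable and recorded in outputs. (Note
`ln 18 / ln 3 = 2.6309`, not 2.69 as sometimes quoted for this
construction; the package follows the arithmetic.)

`n = 10` walkers (malignant cells) start at uniformly drawn network sites
and perform independent *blind-ant* random walks: at each step a walker
picks one of its 6 lattice neighbours uniformly and moves only if that
neighbour is a network site inside the body; otherwise the step is spent
in place. The blind ant is the standard walk on fractal substrates; the
myopic variant (uniform over accessible neighbours only) is a config
switch. Boundaries are closed — no periodic wrap, since the body is
finite. Walkers do not interact.

After each elementary step the walker colonizes, with probability
`p = 0.001`, one uniformly chosen non-network 6-neighbour of its current
site that is not yet infected; if none exists the event lapses without
resampling. Reinfection is impossible, so the infected count `N_m(t)` is
non-decreasing and saturates at the tissue shell adjacent to the network.
A sweep moves every walker once; the default run lasts `T = 100·L³`
sweeps, and times are reported on the rescaled axis `t = sweeps / L³`
(0–100 for the default), on which the growth-rate parameter has
interpretable magnitude.

The inner loop is C++ (via Rcpp) with a xoshiro256++ generator seeded by
splitmix64 from the user's integer seed: runs are bit-reproducible and
independent of R's global RNG state. A default run executes ~5×10⁸
elementary steps in well under a minute.

### Outputs and fits

The final infected set is box-counted with the same machinery as scan
masks (voxel edge = 1 lattice unit, ladder `s = 1..20`), giving the
simulated lesion dimension `d_f(sim)`; snapshots during one run give its
time evolution, with checkpoints before the first infection flagged
undefined rather than fitted. `N_m(t)` is fitted by
`N_m(t) = A·t^α·exp(−βt)` using Levenberg–Marquardt least squares
(`minpack.lm`), with initial `(ln A, α)` from an OLS line through
`(ln t, ln N_m)` and `β₀ = 0`; on non-convergence a deterministic ladder
of `β` starts is tried before failing with diagnostics. `β` is
unconstrained in sign: a positive estimate expresses saturation, and the
sign is reported rather than assumed. A constant series is handled as the
degenerate `N_m ≡ A` (α = β = 0, correlation undefined). Goodness of fit
is the Pearson correlation between observed and fitted counts.

Under the default conditions the acceptance script
(`scripts/acceptance.R`) recomputes, over three seeds: the endpoint
dimension `d_f(sim)`, the growth exponent `α`, and the observed-vs-fitted
correlation. The simulated lesion set lands slightly *above* the network
dimension, as expected — colonies coat the network, covering marginally
more volume than the network itself.

## The phantom generator

No patient volumes ship with the package; the generator
(`phantom_spec()` / `generate_phantom()`) emulates the analysis-relevant
structure of a whole-body study: a metric voxel grid (default 2.03642 ×
2.03642 × 4 mm, so the regridding path is exercised), a few smooth compact
organ-like blobs (parabolic caps with compact support), point lesions at
specified voxel sites — typically sampled from a generated vascular
network, which yields sets of exactly known dimension — and non-negative
uniform background noise. Phantoms are bit-reproducible for a fixed seed.

What the phantom does *not* emulate: reconstruction point-spread and
partial-volume blur, physiological uptake patterns of specific organs,
scanner noise correlations, and patient-to-patient anatomical variability.
Tests passing on phantoms therefore demonstrate the correctness of the
*estimators* (dimensions recovered on sets of known geometry, conservation
and monotonicity properties, pipeline composition) — not clinical
performance on real scans, which additionally suffers the systematic
organ-uptake error discussed below.

## Problem sizes used in the tests

The suite exercises: analytic masks up to 16³ (exact counts, brute-force
oracle equivalence), generator fractals at depths 2–4 (up to 81³
lattices), scaled simulations at `L = 9` and `L = 27` for behavioural
checks, and three full default-condition runs at `L = 81` shared by the
endpoint-dimension and growth-law checks. These sizes keep the whole suite
in the minutes range while covering every code path at full fidelity.

## Known limitations

- **Organ uptake is not masked.** Physiological tracer accumulation
  (heart, brain, liver, urinary tract) is counted as occupancy and biases
  `d_f` towards 3; inflammatory findings can mimic progression. Automatic
  organ masking is an obvious extension; until then results on real scans
  need medical review of non-tumour uptake.
- **DICOM support is deliberately narrow**: uncompressed explicit-VR
  little-endian single-frame series with spacing metadata. Anything else
  (compressed transfer syntaxes, implicit VR, multiframe, missing
  spacing) is rejected with a clear error; NIfTI is the robust input
  path.
- **Single-scale spectrum.** `D_q` is evaluated at the finest box scale
  only; a multi-scale regression of the partition sums (and the Legendre
  `f(α)` transform) is out of scope.
- **The lesion model is geometric.** Colonized sites never grow, merge or
  regress, so simulated `N_m` is not directly the clinical lesion count;
  it is the number of seeded sites.
- **Registration between serial studies is out of scope**; serial
  comparison assumes each study is analyzed in its own frame, which the
  dimensionless statistics tolerate but does not exploit.
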