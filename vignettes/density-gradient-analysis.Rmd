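---
title: "Quantifying dense DNA on caesium sulphate gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dense DNA on caesium sulphate gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densigrad)
```

## The measurement and its model

Equilibrium centrifugation in Cs₂SO₄ separates DNA fragments by buoyant
density. A pumped gradient yields, per fraction, a refractive index (RI, an
optical proxy for local salt concentration measured at 20 °C, for
odd-numbered fractions only in practice) and a blanked spectrophotometric
DNA concentration in ng/µl. Fraction 1 is the densest, because gradients
are pumped bottom-to-top, so RI decreases with fraction index.

`densigrad` models the corrected concentration profile as a superposition
of Gaussian distributions over the RI axis,

$$ c(\mathrm{RI}) = \sum_{j=1}^{k} A_j \exp\!\left(
   -\frac{(\mathrm{RI}-\mu_j)^2}{2\sigma_j^2}\right), \qquad k \in \{1,2\}, $$

where each component is one DNA population: $\mu_j$ locates its buoyant
density, $A_j$ is proportional to its amount, and $\sigma_j$ shrinks with
fragment size (the proportionality constant is unknown here, so fragment
size is never estimated). Density follows from RI by the affine
calibration $D = a\cdot \mathrm{RI} + b$; the reference constants are
$a = 12.46$, $b = -15.62$ g/ml ($n = 38$, $R^2 = 0.9945$). The printed form
of that intercept is a magnitude; its sign must be negative, since bulk DNA
bands at $D \approx 1.43$ g/ml at RI ≈ 1.37.

## Processing chain and its numerical choices

**RI interpolation.** Because only odd fractions carry measured RIs and the
pumped gradient is linear in index, RI is regressed on fraction index and
the fitted line assigns an RI to *every* fraction, including measured ones;
measured values are retained in `ri_measured` for reporting. Using the
fitted line throughout (rather than measured values where available) keeps
the RI axis strictly monotone, which window selection and integration
assume. A constant measured RI series is rejected as degenerate. This
convention is a choice — the alternative, interpolating between measured
neighbours, differs only by refractometer read error.

**Baseline correction.** Raw readings drift linearly across the gradient.
The baseline is an OLS line of concentration against **RI** (not fraction
index: the exclusion windows are specified in RI units, so the abscissa
should live in the same space), fitted over fractions outside the signal
windows RI > 1.3780 (RNA at the dense edge) and RI ∈ [1.365, 1.372] (DNA),
then subtracted from every fraction. Re-fitting the baseline on the
corrected profile returns slope and intercept of zero (machine precision),
making the operation idempotent. Negative corrected concentrations are
**retained**: blanked readings legitimately dip below zero, and clipping
would bias integrals upward.

One consequence worth knowing: a dense DNA population centred near
RI 1.370 with σ ≈ 0.0013 still has a few percent of its peak amplitude at
RI > 1.372, inside the baseline-fit region, so the fitted baseline absorbs
a small part of the dense tail. On noiseless synthetic data this biases the
recovered dense mean by ≈ 1×10⁻⁴ RI units and amplitudes by under 1%. It
is inherent to the stated exclusion windows, not a defect of the fit; the
package reproduces the procedure faithfully rather than re-tuning the
windows per profile.

**Mixture fitting.** Parameters minimise the sum of squared residuals via
bounded Levenberg–Marquardt (σ ∈ [10⁻⁴, 10⁻²] RI, μ within the observed RI
range, A ≥ 0) with multi-start: a moment-based start, a start at the
profile mode, and — for $k=2$ — the $k=1$ solution plus a second component
seeded at the dense-window centre (RI 1.3706), plus the $k=1$ solution with
a vanishing second amplitude. The last start guarantees
$SSE(k{=}2) \le SSE(k{=}1)$ up to optimiser tolerance (nested models).
Components are reported sorted by ascending mean; in a two-component fit
the **larger-mean component is the dense population**, stated explicitly in
`tidy()` output rather than by list position. Non-convergence is flagged
(`converged = FALSE`), never raised.

**Model selection.** $k$ is chosen as 2 when the two-component fit improves
SSE by more than 20% *and* the minor amplitude exceeds 5% of the major one
(both thresholds configurable via `pipeline_config()`). Visual inspection
is the field's usual practice; an explicit rule is needed for an automated
pipeline, and these defaults accept the clearly biphasic secondary profiles
while rejecting single-population (S-phase-like) ones, where the dense
distribution is flagged as absent.

**Quantification.** Percent dense DNA divides the trapezoidal integral of
the corrected secondary profile over the extended dense window
(RI 1.3700–1.3750, closed bounds) by the total integral of the corrected
primary profile. Integration is over RI, not fraction index, with linearly
interpolated samples inserted exactly at the window bounds so the window
edges carry no discretisation error of order the fraction spacing. The
integral-of-data convention (not integral-of-fit) is used. Window bounds
are inclusive on both ends everywhere in the package.

## Interval overlap statistics

Intervals are BED-convention: 0-based, half-open. "Overlap" always means at
least one shared bp, so abutting intervals do not overlap. `intersect_unique()`
reports each query interval at most once; duplicates are counted by row
identity. The null model relocates each interval uniformly within its own
chromosome, preserving lengths, with rejection sampling to keep placements
pairwise disjoint (default budget 10,000 tries per interval; placement in
random order reduces packing bias; failure raises an error naming the
chromosome). The summary reports mutual overlap counts, percentages, and
peaks-per-zone (a-hits divided by b-hits), with the latter undefined when
no b interval is hit. Fold enrichment is observed count over the mean of
the shuffled counts, undefined for an all-zero null.

## Nucleoside composition

Reference monoisotopic neutral masses for dC, 5me-dC, 5hm-dC, 5f-dC and
5ca-dC are summed from atomic masses. Positive-mode adducts add the cation
mass minus the electron: [M+H]⁺ = +1.00728 Da, [M+Na]⁺ = +22.98922 Da — the
nominal "+1"/"+23" are shorthand. A peak is assigned to the nearest
expected m/z within an absolute 0.025 Da tolerance; several peaks landing
in one (nucleoside, adduct) slot are summed, mirroring combined replicate
detections. Peaks from other nucleosides (dG/dA/dT) fall outside every
window and stay unassigned, consistent with reporting percentages of total
deoxycytidines only. `average_compositions()` averages repeats at the
per-percentage level; averaging raw intensities instead would weight
repeats by injection amount, which is rarely wanted, but the choice is
flagged in its documentation.

## Fragment mass accounting

All dC residues count toward modification loading — in the underlying PCR
synthesis the unmodified dCTP pool is replaced entirely, not only CpG-context
cytosines. Per-residue monoisotopic deltas relative to dC: +CH₂ = 14.0157
(5me), +CH₂O = 30.0106 (5hm), +CO = 27.9949 (5f), +CO₂ = 43.9898 Da (5ca);
average-mass variants sit behind `average_mass = TRUE`. Hemi modification
is modelled as exactly one fully modified strand; the real construction
with long unmodified primers switches strand polarity mid-fragment, which
changes *which* residues are modified but, for near-symmetric GC
composition, barely changes the count — the approximation is documented
rather than modelled base-by-base. Ambiguity codes (N) are rejected, not
fractionally counted. The density-shift model is a plain empirical OLS line
of banding RI against Da/bp loading — an interpolation device, not a
physical prediction.

## What the generators emulate — and what they do not

`simulate_gradient()` produces the linear RI ramp (default 60 fractions,
RI 1.3800 → 1.3600, matching the plotted range), Gaussian DNA components, a
linear baseline (default 0.9 + 25·(RI − 1.37) ng/µl: a "slight tilt" of
about 0.5 ng/µl across the span against ~10 ng/µl peaks) and heteroscedastic
Gaussian noise, sd = CV·|signal| + floor (defaults 2% CV, 0.02 ng/µl floor),
chosen to mimic blanked spectrophotometer readings that can go slightly
negative. Odd fractions carry "measured" RI, even ones are blank. Not
emulated: refractometer read error on individual fractions, drop-size
variation in manual fractionation, or any non-Gaussian tailing of real DNA
distributions — so passing tests demonstrate correctness of the analysis
chain, not robustness to every instrumental artefact.

`simulate_peak_sets()` builds construction-exact overlap: exactly
⌊overlap_fraction·n_a⌋ of the a intervals touch b. The default toy genome
(3 chromosomes: 1 Mb, 500 kb, 200 kb) is small enough for brute-force
all-pairs oracles. `simulate_ms_peaks()` emits one H and one Na peak per
nonzero form with Gaussian mass error; real spectra contain isotopologues
and co-eluting contaminants that the matcher simply leaves unassigned.
`simulate_fragment()` draws i.i.d. bases, so it has no CpG clustering or
isochore structure. Every generator is a pure function of parameters and
seed.

## Statistical limits of parameter recovery

Single-component fits recover the generating mean to ~1×10⁻⁵–10⁻⁴ RI under
study-condition noise. The **minor** component of a 3:1 biphasic fit is
harder: with 60 fractions and overlapping components 0.0021 RI apart, the
median absolute error of the dense mean is ≈ 3×10⁻⁴ RI at 2% CV —
truth-initialised fits reach the same SSE as the multi-start optimiser, so
this is the information content of the data, not an optimisation failure.
Tests and the acceptance analysis bound the major component at 2×10⁻⁴ and
the minor one at 1×10⁻³ RI accordingly.

## Problem sizes used in tests

Parameter-recovery checks use 20 seeded replicates of 60-fraction
gradients; closed-form integration checks use 400-fraction noiseless
profiles (trapezoid error ∝ (spacing/σ)²); interval oracles run 50 seeded
instances of up to ~250 × ~180 intervals on the toy genome; CCGG scanning
is cross-checked on 10 kb fragments. These sizes make every oracle
brute-forceable while keeping the full suite under half a minute.

## Known limitations

- Fragment size is never inferred from σ (no constant available).
- At most two mixture components; genuinely triphasic profiles must be
  windowed first.
- The shuffle null is statistically, not bit-wise, equivalent to external
  shuffling tools, whose retry semantics differ between versions.
- MS assignment ignores isotope patterns and chromatographic alignment; it
  assumes the peak table is already consolidated per compound.
- Whether dense-fraction percentages should integrate raw or fitted
  profiles is unstated in the field; the integral-of-data convention here
  slightly weights noise but avoids model dependence.
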