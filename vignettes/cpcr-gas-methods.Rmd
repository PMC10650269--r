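---
title: "Methods: competitive-PCR titration and gas-production kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive-PCR titration and gas-production kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcrquant)
```

This vignette is the package's account of the models it implements, the
choices made where the underlying protocol leaves details open, and what
the synthetic-data checks do and do not demonstrate.

## The competitive-PCR model

A cPCR assay co-amplifies the unknown target with a size-modified
competitor sharing its primer sites (methanogens: 296 bp target vs 196 bp
competitor; protozoa: 360 bp vs 235 bp; see `methanogen_assay()`,
`protozoa_assay()`). The quantification rests on one assumption: **both
templates amplify with the same per-cycle efficiency**, so the molar
product ratio equals the starting template ratio at every cycle — before
and after plateau, provided saturation throttles both species alike.
`simulate_competitive_pcr()` encodes exactly this: shared-efficiency
exponential growth `N' = N (1+e)^c` with a hard total-product ceiling
(`plateau_total_copies`) that rescales both products by a common factor.
This is the simplest model that preserves the ratio property the titration
exploits; sequence-level effects (annealing kinetics, heteroduplexes,
length-dependent efficiency) are deliberately out of scope, and if they
mattered in a real assay they would violate the method's own premise.

Calibration (`build_calibration()`) regresses
`y = log10(I_t / I_c)` on `x = log10(competitor copies)` by ordinary least
squares and reports the equivalence point `10^(-intercept/slope)`. On
ideal ratio-preserving data the slope is exactly −1; a fitted slope that
is positive or has magnitude below 0.1 is rejected as a failed titration
rather than propagated. Points where either band is zero are dropped, not
imputed, and at least three usable points are required. When the fitted
line crosses zero outside the dilution range the estimate is still
returned but flagged `extrapolated`.

### Raw-intensity vs molar-corrected mode

Ethidium staining scales with dsDNA **mass**, so a raw intensity ratio
over-weights the longer target by `L_t/L_c` and biases the equivalence
point upward by exactly that factor (0.179 log10 for 296/196, 0.185 for
360/235 — an identity asserted in the test suite, not an approximation).
Whether bench workflows divide intensities by length before ratioing is
usually unstated, so both conventions are exposed: `mode = "raw"` (what an
image-analysis band table gives directly) and `mode = "molar"`
(length-corrected, unbiased, the default for `enumerate_population()` and
the recommendation). The bias between them is quantified rather than
silently chosen.

### From reaction to culture fluid

`copies_per_ml()` multiplies the per-reaction equivalence by
`1/template_volume_ml` and an explicit chain of fold factors. Extraction
and elution volumes vary between labs and are rarely printed, so the chain
is **mandatory configuration** — a unit chain must be passed explicitly
(`c(extract = 1)`) and every factor is recorded in the estimate's
provenance column. There are no silent volume defaults.

## Densitometry

`detect_bands()` ranks local maxima by topographic prominence (height
above the higher of the two saddles towards taller terrain or the profile
edge) and keeps the expected number of peaks; band identity is then
assigned purely by **migration order** — the earlier peak is the longer
(target) fragment — never by intensity, since fragment sizes are known a
priori.

Background subtraction uses the rubber-band convention: the chord joining
the profile at the two window endpoints. It removes any constant or linear
baseline exactly, which is also why adding a constant to a profile leaves
net intensities unchanged (a property test).

**Integration window: ±4σ, not ±3σ.** The window half-width in estimated
peak sigmas (`k_sigma`) is tunable. A chord baseline under a Gaussian
band systematically removes `2kφ(k)/√(2π)` of the band area — about 2.9%
at k = 3 but only ~0.1% at k = 4 — so the default is `k_sigma = 4`, which
keeps single-band round-trip error around 0.2% and comfortably inside the
2% accuracy the pipeline promises. Peak σ is estimated from the
half-prominence crossings (FWHM/2.355) with linear interpolation between
samples. Overlapping windows are truncated at the inter-peak minimum and
flagged; because both bands of an assay share the same rendered width,
symmetric tail truncation cancels in the intensity *ratio*, which is the
quantity the titration consumes. Negative net areas are clamped to zero
and flagged, and such lanes are treated as unusable by
`enumerate_population()`.

## Gas-production kinetics

The model is the exponential without lag, `y(t) = V(1 − e^(−kt))`,
fitted by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) with no weighting (no variance model is assumed).
Numerical choices:

* start `V₀ = 1.05 max(y)`; `k₀` from the slope of `ln(1 − y/V₀)` vs `t`
  over points with `y < 0.9 V₀` (clipped to [1e−3, 2]);
* bounds `V ∈ (0, 10·max(y)]`, `k ∈ (0, 2]` h⁻¹;
* tolerances `ftol = 1e−10` (relative RSS), `ptol = 1e−8` (parameter
  step), 500 iterations max;
* `t = 0` is not an observation — the model passes through the origin
  implicitly and the first reading is at 2 h;
* blank-corrected volumes that dip slightly negative at early times are
  **retained**; truncating them would bias k upward;
* a solver failure returns the last/initial iterate with
  `converged = FALSE` and the solver message, and data with no increasing
  trend are flagged unconverged rather than reported as a rate.

Derived statistics are exact identities of the fit: `T₀.₅ = ln2/k`,
`G₀.₅ = V/2`, and `y(T₀.₅) = G₀.₅` to machine precision. Rates are
reported in h⁻¹ throughout (published tables sometimes label the rate
column in mixed units; the half-time identity pins the unit down).
`assemble_curve()` subtracts the mean blank volume per time point,
linearly interpolating blank means across grids and carrying the nearest
mean beyond the blank grid's range.

## Fermentation bookkeeping

Degradability is `(in − residue)/in`, serving DM and NDF alike and
scale-invariant by construction. The microbial-protein estimate is the
partitioning difference `degraded − gas × stoich_factor`; the
stoichiometric factor is explicit configuration (default 2.2 mg/mL, a
conventional value) because partitioning constants differ between
substrates. Group summaries stop deliberately at mean ± SEM per factor
level and interaction cell: the mixed-model step of a full analysis
(random run effect, multiple-comparison tests) is routine statistics best
done in `lme4`/`emmeans` on the tidy record table this package emits, and
re-implementing it here would add nothing method-specific. The
methanogen–protozoa association is the Pearson correlation of paired
log10 abundances with the t-transform p-value on n − 2 df
(`stats::cor.test` behind the module surface).

## What the generator emulates — and what it does not

The synthetic module reproduces the *structure* of a batch-culture study:
ten-fold competitor ladders co-amplified against a fixed target, gel
lanes with mass-proportional Gaussian bands, migration linear in
−log10(length), multiplicative lognormal densitometry noise
(scale-dependent, mean-preserving; default CV 0.1), additive white
profile noise on a smooth positive baseline, gas curves on the 11-point
2–120 h recording grid with additive 2 mL reading noise and a saturating
blank drift, and a 2 species × 3 diets × 3 runs factorial with additive
effects, a shared random run effect and a residual correlation of 0.46
between the two log10 populations (so the paired-abundance analysis has a
known truth).

It does **not** emulate: band saturation or comet artifacts, lane
curvature/smile, heteroduplex or primer-dimer bands, length-dependent
amplification efficiency, non-Gaussian transducer error, or
time-by-treatment interactions. Passing recovery tests therefore shows
the *estimators* are correct and well-calibrated under the stated noise
model — not that any real gel meets that model. The demo's default
conditions (competitor stock 10⁶ copies/reaction over 11 ten-fold
dilutions against ~200–250 copies/reaction of target; 1 µL template; unit
extract chain, hence ~5.3–5.4 log10 copies/mL ground truth) were chosen
once to mirror a realistic rumen-fluid titration in which only the 4–6
central lanes show both bands.

## Problem sizes and tolerances used in the checks

Recovery checks run at sizes that keep the whole suite under a minute on
one CPU while leaving no statistical ambiguity: 200 seeded dilution
series (truths 10³–10⁷ copies/reaction, CV 0.1) for equivalence-point
recovery within ±0.1 log10; 100 seeded gas curves (V ∈ [80, 150] mL,
k ∈ [0.04, 0.12] h⁻¹, 2 mL noise) for median parameter errors, each also
compared against a brute-force 200 × 200 grid-search oracle that the NLS
fit must never lose to; 100 random noiseless lanes for 2% band-area
accuracy; 200 replicates of the n = 54 paired-population simulation for
the correlation. Exact identities (ratio preservation, round-trip mass
conversion at relative 1e−12, half-time identities, raw-mode bias factor)
are asserted at numerical precision, not statistically.

## Known limitations

* Image input is reduced to 1-D lane profiles upstream of this package;
  lane auto-detection and smile correction are out of scope.
* The titration assumes exactly two bands; multi-template competition is
  not modelled.
* The gas model has no lag phase or multi-pool variant by design; data
  with a pronounced lag will show structured residuals and an
  under-estimated V at early times.
* Printed population tables from gel-era studies depend on unprinted
  extraction volumes; absolute copies/mL are therefore only comparable
  within a declared dilution chain.
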