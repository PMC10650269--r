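# cpcrquant

Quantification machinery for rumen batch-culture studies that enumerate
methanogens and protozoa by **competitive PCR (cPCR)** and characterise
fermentation by **in vitro gas production**.

## The problem

Absolute microbial abundance in rumen fluid is classically measured without
qPCR hardware: the unknown target (a 16S rRNA fragment for methanogens,
18S for protozoa) is co-amplified with a serially diluted *competitor* — a
size-modified internal standard sharing the same primer sites (296 bp
target vs 196 bp competitor for methanogens; 360 bp vs 235 bp for
protozoa). Both templates amplify with the same efficiency, so the molar
ratio of the two gel bands equals the starting template ratio. Plotting

&nbsp;&nbsp;&nbsp;&nbsp;y = log10(I_target / I_competitor) against
x = log10(competitor copies/reaction)

gives a line of slope ≈ −1; the **equivalence point** x₀ = −b/m, where the
bands are equally intense, is the target's copy number. Copies and band
mass interconvert through

&nbsp;&nbsp;&nbsp;&nbsp;copies = ng × 6.022×10²³ / (length_bp × 10⁹ × 650).

Fermentation extent and rate come from cumulative gas volumes of syringe
incubations, fitted with the exponential model without lag

&nbsp;&nbsp;&nbsp;&nbsp;y(t) = V (1 − e^(−kt)),

with derived half-time T₀.₅ = ln2/k and half-volume G₀.₅ = V/2, plus
blank-syringe correction, substrate degradability from residues,
a Blümmel-style microbial-protein estimate, mean ± SEM factorial
summaries, and the Pearson correlation between the two populations.

`cpcrquant` implements the full path — gel lane densitometry
(peak detection, rubber-band background, band integration), equivalence
point titration, copies/mL bookkeeping with an explicit dilution chain,
gas-curve assembly and nonlinear fitting — **plus a seeded synthetic-data
generator** (competitive amplification with a ratio-preserving plateau,
Gaussian gel bands with lognormal densitometry noise, noisy gas curves,
factorial culture tables) so every stage is testable by parameter
recovery. Everything is data-frame-in / tibble-out with `tidy()`,
`glance()` and `autoplot()` methods on fitted objects.

## Worked example

Titrate a simulated methanogen series (true abundance 250 copies/reaction
= 10^5.4 copies/mL at 1 µL template) through the full gel route:

```r
library(cpcrquant)

cfg <- sim_config(seed = 42, n_dilutions = 11, competitor_stock = 1e6,
                  intensity_noise_cv = 0.1)
ser <- simulate_dilution_series(250, methanogen_assay(), cfg)

en <- enumerate_population(ser$profiles,
                           ser$points[c("lane_id", "competitor_copies")],
                           methanogen_assay(),
                           template_volume_ml = 0.001,
                           dilution_chain = c(extract = 1))
en
#> <cpcr_enumeration> methanogen: 5.478 log10 copies/mL (4/11 lanes usable)
#> <cpcr_calibration> molar mode, 4 points
#>   slope -0.9760, intercept 2.4183, R^2 0.9986
#>   equivalence 300.5 copies/reaction (log10 2.478)
```

Only the 4 lanes where both bands are detectable enter the fit (the
extreme dilutions have one band far below the other — exactly why bench
protocols pick "suitable dilutions"). The slope is close to the ideal −1,
and the equivalence point of 300 copies/reaction (truth: 250) maps to
5.48 log10 copies/mL; `autoplot(en$calibration)` draws the titration line.

Gas kinetics on a noisy synthetic curve (truth V = 105.8 mL,
k = 0.0625 h⁻¹, 2 mL reading noise on the 2–120 h grid):

```r
curve <- simulate_gas_curve(105.8, 0.0625,
                            sim_config(seed = 42, gas_noise_sd = 2))
fit_exponential(curve)
#> <gas_kinetics_fit> V = 107.61 mL, k = 0.0622 /h, T0.5 = 11.14 h,
#>                    G0.5 = 53.81 mL (rss 26.6, converged)
```

`run_demo(seed = 1)` chains everything — both assays, 18 gas syringes with
3 blanks, and the 2 species × 3 diets × 3 runs culture table — and reports
recovered vs injected ground truth.

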