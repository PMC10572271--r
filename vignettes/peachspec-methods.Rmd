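---
title: "Wavelength selection and defect classification for NIR fruit spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection and defect classification for NIR fruit spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ripe peaches bruise internally without visible surface change, so internal
injury cannot be graded by eye or by RGB machine vision. Near-infrared
hyperspectral imaging (900–1700 nm) sees through the skin: water and sugar
absorption (O–H overtone bands near 1190 and 1450 nm) and tissue scattering
differ between intact flesh, internal bruises, scabs and rot. `peachspec`
implements the full chemometric workflow for turning such reflectance
spectra into a four-class defect call: reflectance calibration, spectral
pretreatment, calibration/prediction partitioning, wavelength selection,
support-vector classification, and macro-averaged evaluation.

The four classes, in canonical order, are `intact`, `internal_injury`,
`scab`, `rotten`; their integer codes 1–4 serve as the numeric response
wherever a regression engine (PLS1) drives wavelength selection.

## Reflectance calibration and spectra handling

Raw line-scan counts depend on illumination and dark current. The standard
black/white correction is

    R = (IR - ID) / (IW - ID)

elementwise over pixels and bands, with `IR` the raw frame and `ID`, `IW`
the dark and white references. `correct_reflectance()` guards the
denominator at `1e-12` and reports (but does not clip) corrected values
outside `[-0.5, 1.5]`; clipping would silently hide reference drift. A
sample's spectrum is the mean of a region of interest
(`extract_roi_mean()`); ROI masks are supplied explicitly because defect
regions in this workflow are chosen by the analyst, not segmented
automatically.

Band count is instrument-specific; the working default is 254 evenly
spaced bands over 900–1700 nm, typical of InGaAs line-scan cameras in this
range, and every function accepts an arbitrary strictly increasing grid
within that range.

## Pretreatments

Five pretreatments are provided and compared by `compare_pretreatments()`:

* **SNV** — per-spectrum centering and scaling to unit population standard
  deviation (removes multiplicative scatter and offsets);
* **baseline** — per-spectrum minimum subtraction (a linear detrend is the
  config alternative);
* **SMF** — running median, window 5 (odd, ≥ 3);
* **D-SG** — Savitzky–Golay first derivative, window 7, order 2; filter
  coefficients from the `signal` package;
* **D-GS** — gap–segment (Norris) first derivative, gap 3, segment 3; the
  derivative at band *i* is the difference of the two segment means across
  the gap divided by `gap + segment`.

All filters reflect-pad the edges so band count is preserved; derivatives
are reported per band-index unit (a grid argument converts to per-nm).
Parameter defaults are ordinary choices for ~250-band NIR spectra — the
window must span enough points to suppress noise without flattening the
40 nm-scale absorption features. The comparison harness fits a PLS1 model
per pretreatment on the calibration partition (component count chosen by
5-fold CV RMSE, capped at 10) and tabulates Rc², RMSEC, Rp², RMSEP; the
winner is the highest Rp², ties to lower RMSEP.

## The PLS1 engine

Wavelength selection needs per-band regression coefficients, so the
package carries its own single-response PLS implementation
(`fit_pls1()`): NIPALS deflation on mean-centered data, which for one
response is non-iterative (the weight vector per component is
`X'y / ||X'y||`). Coefficient vectors for every nested component count are
retained, so one fit per cross-validation fold serves all component
counts. At full rank PLS1 equals ordinary least squares; the test suite
checks this equivalence to `1e-8` against a QR oracle, and leave-one-out
CV against an explicit refit loop.

## Wavelength selection

**CARS** (`cars_select()`). At each of N = 50 Monte-Carlo runs, a PLS
model on a random 80% sample subset of the currently retained bands
yields weights `|b_j| / Σ|b_j|`. An exponentially decreasing schedule
`r_i = a·e^(-k·i)` with `a = (p/2)^(1/(N-1))`, `k = ln(p/2)/(N-1)` forces
the retained count from p down to 2; after the forced top-`k_i` cut,
adaptive reweighted sampling (weighted draws with replacement, unique
survivors kept) picks the next working set. Each run's subset is scored
by 5-fold CV RMSE on the full calibration partition (component count by
minimum CV RMSE, capped at 10), and the subset at the global minimum is
returned. Because unique survivors of with-replacement draws number fewer
than the draws, realized retention decays somewhat faster than the
schedule; the trace records both. A deterministic `ars = FALSE` mode
keeps the top-`k_i` only.

**MIV** (`miv_rank()` / `miv_select()`). A black-box model — by default an
RBF support-vector regressor on the class codes, matching the package's
SVM toolchain; any model function is injectable — is probed band by band:
column j is scaled by 1.10 and by 0.90, both matrices are predicted, and
the mean per-sample output difference is that band's mean impact value.
For a linear model `y = Xβ` this reduces exactly to `0.2·β_j·mean(x_j)`,
which the tests assert to `1e-10`. Bands are taken in decreasing `|MIV|`
until the cumulative contribution share first reaches 95%.

**SPA** (`spa_select()`). Successive projections: from each start band a
chain grows by adding the band with maximal column norm after orthogonal
projection onto the complement of the chosen span. Chains are scored by
leave-one-out CV RMSE of an OLS fit (computed from the hat matrix).
Calibration RMSE is available as a switch but is *not* the default: along
a nested chain it is monotone non-increasing, so it always favours the
longest chain and would make a second-stage SPA a no-op.

**UVE** (`uve_select()`). The candidate matrix is augmented with an equal
number of tiny uniform noise columns (amplitude `1e-10` of the data
scale), a PLS model is fitted under leave-one-out resampling, and each
column's reliability is `mean(b)/sd(b)` over the resampled coefficients.
Real bands are kept only if `|c|` exceeds 99% of the largest noise-column
`|c|`. If nothing survives, that is an error, not a silent fallback —
under a pure-noise null the expected survival rate is about
`1/(n_noise + 1)` per band, and the diagnostics record every reliability
and the threshold pair.

**Chaining** (`chain_select()`, `stage_*()`). Second-stage selectors see
only the first stage's columns and results map back to original indices,
so `CARS-MIV ⊆ CARS` holds by construction; composed names and both
stages' diagnostics are retained.

## Classifiers

**GA-SVM** (`ga_svm_train()`). C and the RBF gamma are encoded as 20-bit
binary genes on log2 grids (C in `[2^-5, 2^15]`, gamma in `[2^-15, 2^3]`
— standard SVM tuning ranges); fitness is stratified 5-fold CV accuracy
of an `e1071` C-SVM on min-max-normalized features. Population 20,
100 generations, roulette selection, single-point crossover (0.7),
per-bit mutation (0.01), elitism on — hence best-so-far fitness is
provably non-decreasing, which the tests assert. Fitness ties break
toward smaller C then smaller gamma (simpler models). Identical
chromosomes are evaluated once; the realized evaluation count is
reported, and a random-search baseline at that same realized budget does
not beat the GA on the benchmark (majority over 5 seeds).

**LS-SVM** (`ls_svm_train()`). Each one-vs-one subproblem solves the
equality-constrained dual `[0 1'; 1 K + I/γ][b; α] = [0; y]` directly
(with a `1e-8` jitter retry if singular); four-class prediction is
majority voting with ties broken by aggregate decision margin. `(γ, σ²)`
comes from a log-spaced 7×7 grid by stratified CV accuracy —
misclassification, not RMSE on class codes, because the latter penalizes
confusions between distant codes more than adjacent ones for no physical
reason (the RMSE analog remains a config alternative). The binary solver
is tested against a dense augmented-system oracle.

Feature normalization for both models is per-band min-max scaling fitted
on calibration data only and stored with the model.

## Partitioning and evaluation

`kennard_stone_split()` is the deterministic max-min procedure: the first
two calibration picks are the maximally distant pair, each later pick
maximizes the minimal distance to the chosen set; ties go to the lower
index, so splits are exactly reproducible. A 347-sample set with
`n_cal = 259` yields the 259/88 partition; the ratio is exposed as an
explicit `n_cal` because no single rounding rule maps 3:1 onto those
counts.

The per-class discriminant rate is `100·cm[i,i]/rowsum(i)`; the **total
discriminant rate is the unweighted mean of the four per-class rates**
(macro average), not pooled accuracy — on imbalanced prediction sets the
two differ materially, and the macro form is what the package's reference
checks reproduce. Percentages stay at full precision internally;
presentation rounds half away from zero to 2 decimals
(`round_half_up()`).

## The synthetic generator

`generate_dataset()` exists because no public spectra accompany this
problem; it emulates the documented qualitative structure rather than any
specific instrument: a smooth base curve with reflectance peaks near 1100
and 1290 nm, water-absorption troughs near 1190 and 1450 nm (Gaussian
bumps, width 40 nm), and an overall decreasing trend. Each defect class
perturbs a disjoint pair of planted wavelengths (width 12 nm, effects
0.04–0.055 reflectance units, mixed signs) plus a small global offset.
Per-sample variation: a truncated-normal severity factor (sd 0.45)
scaling the planted bumps — defect severity varies in real fruit, and
this is what keeps the classes genuinely overlapping — multiplicative
scatter (sd 0.035), baseline drift (sd 0.018) and white noise
(sd 0.010 per band). These defaults were fixed once so that a GA-SVM on
the default benchmark lands in the high-80s-to-mid-90s accuracy range
rather than saturating, and were not revisited.

Each sample draws from its own seeded RNG substream, so changing one
class's count never reshuffles another's spectra. A companion
`generate_hypercube()` builds a small scene by pushing planted
reflectance back through the inverse black/white correction, so the
calibration and ROI operations can be tested end to end.

What passing tests on this generator do **not** show: realism of absolute
reflectance values, instrument artifacts (smile, stray light, detector
nonlinearity), within-fruit spatial texture, or biochemical covariance
between bands beyond the planted structure. Results on synthetic data
demonstrate that the algorithms work as specified, not that any accuracy
figure transfers to real fruit.

## Numerical choices and degenerate inputs

* PLS components are capped at `min(10, rank)`; rank exhaustion truncates
  with a warning; a zero-variance response is an error.
* Division guards: `1e-12` on `IW - ID`; SNV rejects constant spectra;
  the LS-SVM solver retries once with `1e-8` jitter.
* MIV cumulative rule: first rank where the cumulative share is ≥ 0.95
  (within `1e-9` to absorb float summation).
* Ties everywhere break toward the lower band/sample index, which is what
  makes reruns byte-identical.
* All stochastic steps take explicit seeds; the pipeline derives stage
  seeds from one master seed, and artifacts (`selection.json`,
  `report.json`, `confusion.csv`) contain no timestamps, so a rerun with
  the same config reproduces them byte for byte.

## Problem sizes used in the shipped checks

The packaged tests run the benchmark at 200 samples × 254 bands (50 per
class) with 50 CARS runs, and smaller 60 × 60 datasets for
pipeline-mechanics tests; the null-model check uses 400 samples. These
sizes exercise every code path at full band resolution while keeping the
whole suite comfortably interactive.

## Known limitations

* PLS1 only (single numeric response); no PLS-DA posteriors — class
  probabilities are out of scope, classification is the SVMs' job.
* The CARS retained count is bounded below by 2 and the trace, not the
  schedule, is authoritative for realized retention.
* `spa_select()` scores candidate subsets by OLS-based criteria and is
  therefore unreliable when the chain length approaches the sample count
  (it caps `k_max` at `n - 2` with a warning).
* Macro total rate requires every class present in the prediction set;
  an absent class is an explicit error rather than an NA.
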