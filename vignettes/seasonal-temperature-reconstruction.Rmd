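---
title: "Reconstructing Holocene seasonal temperatures from pollen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Holocene seasonal temperatures from pollen: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenclim)
```

## The reconstruction problem

Fossil pollen assemblages integrate the response of regional vegetation
to climate. Because plant distributions are limited both by winter cold
(frost tolerance, chilling requirements) and by summer warmth (growing
season heat), an assemblage constrains a *suite* of temperature
variables — here the mean temperature of the coldest month (MTCO), of
the warmest month (MTWA), and the annual mean (ANNT), all in °C. The
package reconstructs these three variables for dated pollen records and
aggregates site series into gridded composites with full uncertainty
propagation.

The core estimator is the modern analogue technique (MAT). Its working
assumption is that compositionally similar assemblages come from similar
climates, so no response model is fitted: the fossil sample is assigned
the dissimilarity-weighted climate of its `k` closest modern surface
samples. Because MAT conditions on the whole composition rather than on a
single calibrated gradient, it can track several covarying climate
variables at once — provided each variable leaves its own imprint on
composition, which the package verifies with redundancy analysis (RDA)
on the calibration data before reconstructing.

## Features: PFT scores

Reconstruction operates on plant-functional-type (PFT) affinity scores
rather than raw taxon percentages. Given a taxa-to-PFT weight matrix and
taxon proportions \(p\),

\[
\mathrm{score}(s,\mathrm{pft}) = \sum_{\text{taxa}} w(\text{taxon},\mathrm{pft})
  \sqrt{\max(0,\, p - \theta)},
\]

the classic biomization affinity. The square root stabilises the
dominance of abundant taxa; the presence threshold \(\theta\) (default
0.5%, configurable per region) suppresses trace occurrences and
long-distance transport. Whether the original procedure used
\(\theta = 0\) or 0.5%, and which pollen sum it used, is not stated in
the source literature for every regional scheme; both are exposed as
configuration (`theta`, `renormalize`) with the biomization-standard
defaults: proportions are recomputed on the taxa present in the regional
matrix (the terrestrial sum), and unmatched fossil taxa are reported,
never silently dropped.

## Dissimilarity and analogue selection

Dissimilarity is the squared chord distance
\(\mathrm{SCD}(p,q) = \sum_i (\sqrt{p_i} - \sqrt{q_i})^2\), computed on
row-normalised feature vectors (taxon proportions or PFT scores alike),
so values live on the familiar 0–2 scale. Defaults: `k = 6` analogues
(the literature's 5–7 range), analogue weights `1/SCD` (the MAT
convention; a zero-distance analogue short-circuits to its climate), and
a no-analogue threshold `scd_max = 0.2` — samples whose closest analogue
is more dissimilar than this are flagged and their estimates withheld.
Ties at the k-th analogue are broken by stable calibration order so runs
are bit-reproducible.

Sample-specific errors bootstrap the calibration rows (100 iterations by
default) and combine the spread with the model RMSEP in quadrature:
\(\sigma_s = \sqrt{\mathrm{sd}_{\mathrm{boot}}^2 + \mathrm{RMSEP}^2}\),
where RMSEP comes from leave-one-out cross-validation.

## Cross-validation and spatial autocorrelation

`cross_validate()` supports leave-one-out and h-block schemes; in the
h-block scheme the training pool excludes every site within `h` km
(great-circle, haversine on a 6371-km sphere) of the test site, so that
spatial autocorrelation cannot inflate skill. `h = 0` reproduces
leave-one-out exactly. The radius is chosen by `select_h()`: the median
nearest-analogue SCD of the h-block search is a non-decreasing function
of `h`, and the selected `h*` is the smallest radius whose median matches
the median SCD actually observed for the fossil samples — i.e. the
cross-validation is made exactly as hard as the fossil prediction
problem.

WA-PLS (weighted-averaging partial least squares) is provided as a
cross-check transfer function: components are extracted iteratively from
species-weighted centred data and the environmental variable is
regressed on them (inverse deshrinking). With one component this reduces
exactly to classic weighted averaging, which the test suite exploits as
an independent oracle. Classical deshrinking is available by flag for
the one-component case only; for deeper models the inverse regression is
part of component extraction itself.

## Significance testing

High calibration R² does not guarantee that an individual record's
reconstruction is meaningful. A reconstruction is therefore retained
only if, used as the sole RDA constraint on the (centred, standardised)
fossil feature matrix, it explains more variance than the empirical
84.2% quantile of 999 reconstructions trained on environmental variables
drawn uniformly over the calibration climate range. The 84.2% threshold
(one standard deviation) is a deliberate compromise: the conventional
95% level is known to reject genuinely informative but low-variability
records.

Two properties of this test are worth separating. Its *calibration*: for
a reconstruction that is itself exchangeable with the random-variable
reconstructions, the pass rate is 1 − 0.842 ≈ 15.8% by construction,
which the acceptance suite verifies by Monte Carlo. Its *behaviour on
noise assemblages*: a MAT reconstruction from the real calibration
climate routes compositional information through the analogue search, so
even a temporally uninformative record can explain substantial fossil
variance and the test is not a pure false-positive filter in that
regime — a known characteristic of random-transfer-function tests with
analogue methods, and the reason the package reports the null
distribution alongside the verdict rather than a bare boolean.

## Chronology

Radiocarbon dates are recalibrated against a three-column calibration
curve (calendar age, ¹⁴C age, curve error). The posterior over calendar
age \(\theta\) is
\(p(\theta) \propto N(a;\, \mu(\theta), \sigma^2 + \sigma_c(\theta)^2)\),
evaluated by interpolating the curve to a 1-yr grid and normalised by
trapezoidal quadrature; the point estimate is the posterior mean with
its posterior standard deviation. The mean (rather than median or
intercept) was chosen because it is stable, standard, and directly
testable against quadrature; the original work does not state which
point estimate its software supplied.

Age–depth models are piecewise-linear interpolations of the calibrated
point ages, extrapolating from the end segments; smoothing alternatives
were deliberately not reimplemented, as interpolation to sample levels
is the reproducible core of the published procedure. Age reversals
between consecutive controls raise an error naming the offending pair —
the original handling of reversals is unstated, so the package refuses
to guess. Core-top, lamination and biostratigraphic controls participate
in interpolation but never count as independent dates.

Screening follows the published rules exactly: more than three
chronological controls with at least two independent dates; record span
above 5 kyr; a sample younger than 1 ka BP (required for the anomaly
baseline); median Holocene inter-sample gap below 400 yr (1000 yr in
northern Asia); and per sample, a date within 1 kyr or a bracketing pair
within 6 kyr, plus at least 200 grains. "More than three" is read
literally as ≥ 4, and resolution is measured as the *median* gap, which
is robust to a single hiatus; both are configurable.

## Isostatic correction

Where former ice sheets depressed or raised the land surface, part of a
site's temperature history is topographic, not climatic. The package
interpolates a time-resolved elevation-anomaly field to each site
(inverse-distance weighting, power 2, 4 nearest nodes; linear in time),
estimates present-day local lapse rates by OLS of each temperature
variable on elevation over grid cells within 300 km, and subtracts
`rate × Δelev(t)` from the estimates. The sign convention is explicit: a
past surface 200 m higher with a −6.5 °C/km lapse rate implies a −1.3 °C
topographic component, whose removal *raises* the corrected estimate.
Sites with fewer than 3 cells or no elevation spread in the radius are
flagged uncorrectable rather than silently skipped, and a `corrected`
attribute guards against double correction.

## Stacking and uncertainty

Site series become anomalies relative to their last-1000-yr mean and are
propagated through two seeded Monte-Carlo stages. Stage one perturbs
each sample by its error, subtracts the draw's own reference mean, and
linearly interpolates each of 1000 draws onto 200-yr bins (centres 100,
300, …, anchored so bins tile 0–11 ka); the bin value is the ensemble
median and `bin_sd` the ensemble spread. Because the published
"standard error" is ambiguous between the ensemble SD and SD/√n, both
are emitted; downstream propagation uses the ensemble SD, and the
composite's percentile route sidesteps the choice entirely. Stage two
averages sites into 2°×2° cells ([lower, upper) membership, unweighted —
an area-weighting flag exists but defaults off to mirror the published
procedure), perturbs cells by their propagated errors, and reports the
per-bin median with 2.5/97.5 percentile bounds.

Seasonality is the summer-minus-winter composite difference with bands
combined in quadrature (an independence assumption, flagged as such).
Trend rates are OLS slopes of the median against age with the
warming-toward-present sign convention.

## Ordination diagnostics

`rda_fit()` is an in-package implementation (centring, least-squares
projection, eigendecomposition of fitted and residual covariances) so
that the permutation scheme is exactly as specified: unrestricted row
permutation of the constraints with the add-one rule. Partial RDA
residualises both sides on the conditioning variable, and all fractions
are reported against the *total* response variance, which makes
`unique₁ + unique₂ + shared = combined` an exact identity in
`variance_partition()`. PFT-score responses are centred and scaled by
default (their columns are on heterogeneous scales); the flag is
exposed because the original scaling is unstated. The test suite checks
the eigenvalues against vegan as an independent oracle.

EOF analysis uses the covariance (not correlation) matrix of the binned
anomaly series — appropriate because the inputs are already anomalies on
a common scale — and reports, exactly as the figure convention of the
source field, the correlation between each unit's series and PC1 rather
than raw loadings. Units missing more than 20% of the window are
dropped, remaining gaps linearly interpolated; mode signs are fixed so
the spatial-mean loading is non-negative. Whether the original analysis
ran on gridded or site-level series is unstated; the pipeline uses
site-level series and both are available through the same function.

## The synthetic study

All tests run against a seeded generator whose defaults encode the study
conditions:

- **Climate field**: smooth latitudinal MTCO/MTWA gradients plus random
  Gaussian bumps on a 55 × 72 grid (about 1° latitude spacing — a
  deliberately scaled-down stand-in for a half-degree climatology),
  elevation with a −6.5 °C/km imprint, and a mixing weight tuned by
  bisection so the per-cell MTCO–MTWA Pearson correlation hits a target
  (default 0.6, inside the 0.35–0.76 range reported for real regional
  calibration sets). ANNT is the mean of a sinusoidal monthly cycle, so
  MTCO ≤ ANNT ≤ MTWA holds by construction.
- **Taxa**: 20 Gaussian-niche taxa whose optima tile the joint
  (MTCO, MTWA) plane with overlapping tolerances (5–8 °C), MTCO spanning
  the wider range so winter is the stronger niche driver. The synthetic
  taxa–PFT matrix clusters taxa in joint-optimum space (8 PFTs, 1–2
  memberships), mirroring how real biomization schemes encode both cold
  and warm limits.
- **Records**: 60 sites, 60 samples each over 0–11 ka, multinomial
  counts of 400 grains, ¹⁴C controls every ~1000 yr with 60-yr errors
  synthesised by inverting a wiggly (monotone sinusoid) calibration
  curve, constant sedimentation; defaults guarantee the screening rules
  pass. The imposed truth is the Holocene-like history: winter warming
  4.1 °C and summer 1.4 °C over 11–7 ka, then cooling 0.7 and 0.5 °C to
  the present, with annual the mean of the two. Each record's
  assemblages additionally feel the glacio-isostatic cooling
  `−6.5 °C/km × Δelev(t)` from a decaying elevation-anomaly bump, while
  the recorded truth stays climate-only — so the isostatic correction is
  tested end-to-end: correcting with the true field and locally
  estimated lapse rates must recover the climate-only history.

What the generator does *not* emulate: moisture limitation and other
non-temperature drivers, taphonomy and pollen-productivity biases,
spatially varying anomaly histories (the truth is spatially uniform by
default; a `truth_scale` hook exists), real coastlines, and reservoir or
hard-water radiocarbon effects. Passing recovery tests therefore shows
the *machinery* is faithful and well-calibrated, not that real-world
reconstructions attain these skill levels — real calibration R² and
retention rates will be lower.

## Problem sizes and runtime choices

The shipped test and acceptance runs use the full 60-record, 300-sample
demo with 100 bootstrap and 1000 Monte-Carlo draws, but scale two purely
statistical checks down, as their design prescribes: the significance
calibration uses 200 records at 99 random reconstructions, and the
band-coverage check 200 repetitions of 20 records at 100 draws. These
sizes put Monte-Carlo error well inside the asserted tolerances while
keeping the whole suite in a few minutes.

## Numerical choices and edge cases

Zero-sum assemblage rows are an error in proportion space and a flagged
no-analogue in prediction; duplicate sample ages are pooled before
binning; bins with no samples are missing, never zero; empty analogue
pools after h-block exclusion drop the sample with a warning and a
count; degenerate bootstrap resamples are redrawn and logged; the
correlation-tuning bisection errors out after 50 attempts rather than
silently missing its target; longitudes are normalised to [−180, 180)
on ingest and region boxes use half-open [lower, upper) bounds so
boundary sites are assigned deterministically. All stochastic stages
draw their seeds from a single master seed via a fixed
`seed + 1009 × stage-index` scheme (`split_seed()`), so any stage can be
rerun in isolation, bit-identically.

## Limitations

MAT inherits the usual analogue caveats: estimates are convex
combinations of analogue climates, so extrapolation beyond the
calibration range is impossible and edge sites are biased toward the
interior; trend amplitudes in weak-signal variables are attenuated
(visible in the synthetic recovery of the late-Holocene summer cooling).
The significance test's behaviour on noise assemblages (above) means
retention fractions should be read as a relative, not absolute, quality
filter. The isostatic correction assumes the present-day spatial lapse
rate applies through time. None of the composites weight cells by area
by default; high-latitude cells are correspondingly over-represented
exactly as in the published procedure.
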