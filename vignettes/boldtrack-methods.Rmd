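---
title: "Methods: personality, foraging strategy and fitness from tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personality, foraging strategy and fitness from tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

boldtrack implements a complete analysis chain for studying consistent
individual differences ("personality") in a colonial seabird: a
novel-object boldness assay scored by principal components, a foraging
personality score from GPS trip metrics, repeatability of both, detection
of area-restricted search (ARS) by first-passage-time (FPT) analysis,
bathymetric habitat classification of foraging zones, spatiotemporal
overlap with longline discarding zones, and mixed models linking
personality, sex and year quality (sea-surface temperature anomaly, SSTa)
to fledging success.  Because raw field data of this kind are rarely
deposited, the package ships a synthetic-data generator with known ground
truth, so that every stage of the chain is verified by recovery tests
rather than by eye.

This vignette records the modelling choices, the tunable parameters and
their defaults, the numerical decisions, and what the synthetic tests do
and do not demonstrate.

## Trips and trip metrics

GPS fixes (2-minute sampling) are segmented into foraging trips as maximal
runs of consecutive fixes further than 2 km from the colony; the buffer
removes time at the nest, where continuous logging would otherwise swamp
the at-sea signal.  Runs shorter than 5 fixes (10 minutes) are discarded as
GPS jitter — the field protocol does not state a minimum, so the cut-off is
configurable and logged.  A trip is *complete* when flanked by
inside-buffer fixes on both sides.  Latitudes are signed decimal degrees
(south negative); the "maximum latitude in a northerly direction" is the
maximum signed latitude, the southerly counterpart the absolute value of
the minimum.  Distances use the haversine formula on a 6371-km sphere;
the sub-0.5% spherical error is immaterial at foraging-trip scales.

Four metrics summarise each complete brooding trip: duration (h), foraging
range (maximum distance from the colony, km), and the two latitude
extents.  Trips recorded on late-incubating birds are excluded before any
personality analysis, because incubation trips are systematically longer
and would inflate between-trip variance.

## First-passage time and ARS zones

Fixes slower than 10 km/h are removed first (birds sitting on the water
drift sinuously without foraging), then each track is interpolated at 1-km
steps of along-path distance, with positions and times linear between
bracketing fixes.  The FPT at a path point for radius $r$ is the time
between the first backward and first forward exits from the circle of
radius $r$ centred there.  Exits are located by a running-maximum scan
(the first point whose distance exceeds $r$), and the crossing time is
refined by solving the chord geometry exactly: along a straight segment
the squared distance to the centre is quadratic in arc length, so the
crossing fraction is a root of that quadratic.  Linear interpolation in
distance instead biases short FPTs by up to ~1.5%; the quadratic
refinement keeps agreement with a 0.01-km brute-force resampling oracle
within 0.5%.  FPT is undefined where the path never leaves the circle in
one direction (notably the path ends); undefined values are excluded, not
imputed.

The ARS scale is the radius maximising the variance of log FPT across
path points (natural log; the base only shifts the curve, never the peak
location).  A radius with fewer than 5 defined FPT values gives no
variance estimate.  Peaks must (i) exceed both neighbouring defined
values, ties broken toward the smaller radius; (ii) reach 10% of the curve
maximum; and (iii) reach an absolute log-FPT variance of 0.05.  The
absolute floor is the package's own decision where the method literature
is silent on what counts as "a peak": on patch-free correlated random
walks the variance curve still wiggles at around 0.001-0.002, while tracks
holding a genuine search patch peak at 0.5-1.6, three orders of magnitude
higher.  The floor sits in the empty middle of that gap, so commuting-only
tracks yield no foraging zones instead of arbitrary splits of noise.

The FPT threshold separating ARS from transit at the peak radius is also
unspecified in the source methods; the package uses the two-class Otsu
criterion on log FPT (the split maximising between-class variance),
computed exactly over all split points.  A quantile threshold is available
as an alternative.  Contiguous runs of above-threshold points form
candidate zones; zones whose centres (arithmetic mean of member
coordinates) lie within 10 km are merged until all pairwise centre
distances exceed 10 km.  "More than 10 km apart" is read as
centre-to-centre distance with merge-until-stable semantics; the
postcondition is asserted in the tests.  When a trip shows several
qualifying peaks the largest-variance peak defines the zones, with all
peaks reported.

## Habitat and fisheries overlap

Habitat at an ARS centre comes from a nearest-cell lookup in the
bathymetry grid — deliberately not bilinear, since interpolating across
the shelf break would manufacture intermediate depths that exist nowhere —
with classes shelf (< 200 m), shelf edge (200-2000 m, both bounds
included: "between" is read as a closed interval) and oceanic (> 2000 m).
Boundary cells tie toward the lower row/column index.

Each longline haul-end point seeds a discarding zone: a 19-km spatial
buffer (the distance a longliner steams in the hour over which discarding
takes place) active from haul end to one hour after it, both ends of the
window included.  A fix overlaps when it falls inside both buffers of any
zone; overlap is monotone in either buffer, which the tests assert.  The
trip-level summary is the overlapping share of fixes and that share times
trip duration.  For the fix-level overlap models the 2-minute fixes are
thinned to 10-minute resolution; consecutive 2-minute fixes are nearly
perfectly dependent for a 19-km/1-h exposure, so the thinning changes the
likelihood-ratio tests negligibly while cutting model rows five-fold.

## Personality scores

Both behavioural assays collapse to the first principal component of the
correlation matrix (variables standardised), because counts, seconds,
kilometres and hours are incommensurate; eigenvalues then sum to the
number of variables and the proportion of variance is eigenvalue / p.
PC1's sign is anchored so that the behavioural-intensity marker loads
positive: pecking for boldness, foraging range for the trip score.  Low
foraging scores therefore mean short trips near the colony.

Per-individual scores are fixed-effect estimates: observation-level PC1
regressed on observation number (first or second test), date (numeric
day-of-season; the coding is the package's choice) and bird identity with
sum-to-zero contrasts, so that test-condition effects stay identifiable;
the bird effects are then mean-centred.  For the foraging score, with no
further covariates, the fixed-effect fit reduces to per-bird means — the
identity is asserted numerically.  The boldness-foraging correlation uses
Spearman ranks (average ranks for ties) with the large-sample t
approximation for the p-value.

## Statistical models

All models are fitted by maximum likelihood so that nested fits are
comparable by likelihood ratio; effects are tested by dropping the term of
interest and referring $2\,\Delta\ell$ to $\chi^2$ on the parameter-count
difference.  Gaussian and binomial random-intercept models are fitted with
lme4 (adaptive Gauss-Hermite quadrature with 15 nodes for a single
random intercept; Laplace for two).  An independent 201-node quadrature
oracle, written from scratch, checks the single-factor binomial marginal
likelihood to 1e-3 in the tests.

Repeatability is the between-individual share of variance,
$r = \sigma^2_{id} / (\sigma^2_{id} + \sigma^2_e)$, from the Gaussian
random-intercept model.  Its uncertainty comes from a parametric bootstrap
(simulate from the fitted model, refit, percentile interval); its p-value
from the boundary likelihood-ratio test against the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture, since the null value lies
on the edge of the parameter space.  Boundary variance estimates are
reported as 0 untransformed.  Repeatability is invariant to affine
transformations of the response, which the tests assert.

No installed package fits mixed cumulative-logit models, so the
proportional-odds machinery is implemented in the package: logit link,
increasing thresholds via a log-difference parameterisation, analytic
gradients for the fixed-effects case (verified against MASS::polr to
1e-6 in log-likelihood), Gauss-Hermite quadrature for a single random
intercept, and a joint Laplace approximation for the nested bird/trip
pair.  The Laplace inner problem is concave, solved by damped Newton with
an exact Hessian.

The long-term fitness model is
$\mathrm{logit}\,P(\text{fledge}) = \beta_0 + \beta_s s + \beta_m m +
\beta_a a + \beta_{sm} sm + \beta_{sa} sa + \beta_{ma} ma +
\beta_{sma} sma + u_{bird} + u_{year}$,
with $s$ the mean-centred personality score, $m$ the male indicator and
$a$ centred SSTa.  Bird and year intercepts are crossed, not nested.  The
"interaction between sex, year quality and personality" test drops the
four interaction terms at once — the unique 4-parameter set consistent
with a 4-df statistic; alternative drop-sets are configurable.  SSTa
enters the models continuously; the low / medium / high bands (boundaries
-0.36 and -0.15 °C) are used only to stratify prediction curves.  In the
single-season analysis year terms are omitted and score, sex and their
product are tested with 1 df each.

## The synthetic generator

The generator's defaults emulate the study design end to end: a colony at
48.4° S, 68.4° E; 69 tracked birds with three trips each at 2-minute
sampling; about 8% of birds in late incubation (longer trips, excluded
downstream, ~17 trips); 154 assayed birds with 16 retested (170 tests); a
radially deepening shelf with the 200-m and 2000-m isobaths at 150 and
250 km; longliners hauling on the shelf edge; 23 breeding seasons with
SSTa drawn uniformly within the three printed band ranges (-0.60 to
0.13 °C); and 59 birds in the long-term breeding record.

Movement is a two-state correlated random walk: commuting at 50 km/h with
15° turning-angle noise and a steady pull toward the target, and patch
search at 15 km/h with 75° noise, reflected at the patch edge.  The
forage speed deliberately stays above the 10-km/h on-water filter — it
represents slow, sinuous search flight, with sitting on the water treated
as already excluded.  Each trip holds one planted 5-km patch whose
distance combines a bird-level preference (between-bird share of variance
= `icc_foraging`, default 0.5), a sex effect (+30 km for females, who also
head more northerly) and trip-level noise; residence time averages 4 h.
These speeds, angles and dwell times are field-plausible round numbers
chosen once; they are not fitted to anything.

A fraction of shelf-edge patches are vessels: with probability 0.4 an
attending fishing event is created at the patch during the bird's
residence, which reproduces the observed situation in which vessels sit on
the shelf edge and birds aggregate during discarding.  With these defaults
roughly a fifth to a quarter of trips overlap a discarding zone.

The boldness assay draws a bird latent with intra-class correlation
`icc_boldness` (default 0.5) on the latent scale, and maps each
observation latent to the five recorded variables through a Gaussian
copula with loadings of 0.95 (pecks, lunges, vocalisations positive;
snaps and sitting negative).  The high loading is deliberate: it keeps
Poisson/rounding noise from attenuating the planted ICC on the PC1 scale,
so the repeatability estimator can be tested against a sharp truth.  The
cost is realism — synthetic assay variables are far more mutually
correlated than real ethogram counts (PC1 explains ~90% of variance here
versus ~32% in the field), so the synthetic PCA exercises the machinery,
not the field eigenstructure.  The bird-level boldness and
foraging-distance latents are correlated at -0.45; after measurement
error on both sides the measured-score Spearman correlation lands near
-0.2, the field-reported order of magnitude.

Fledging success is Bernoulli with the log-odds model above; effect sizes
are per score-SD (female slope +0.5, male -0.5, both shifted by
0.8 × centred SSTa, year-quality main effect 1.2), with bird and year
random effects of SD 0.3.  The generator records every planted quantity —
patch centres and residence windows, latents, coefficients, SSTa — in a
ground-truth JSON.

What the generator does **not** emulate: fix loss and GPS gaps (off by
default; the field rate is unreported), wind and currents, prey-field
structure beyond discrete patches, on-water drift (filtered fixes are
simply absent), device failure, and partial trip recording.  Passing
recovery tests therefore demonstrates that the estimators recover planted
signal under clean sampling, not that they are robust to every field
artefact.

## Test and verification sizes

Verification uses problem sizes chosen to make Monte-Carlo noise small
relative to the tolerances while keeping the suite quick to run: 100
random tracks for the FPT brute-force comparison (< 1% relative error);
50 replicates for ARS recovery (peak scale within [2.5, 15] km and zone
centre within 5 km of the planted patch in >= 80%); 50 replicates at the
field design (73 trips over 36 birds) for ICC recovery within ±0.1; 400
null replicates for the boundary-LRT and 4-df interaction calibrations
(rejection within [2.5%, 7.5%] at nominal 5%); and 50 replicates at
59 birds × 23 years for interaction power (>= 80%).  The 4-df calibration
runs under a null with no bird/year heterogeneity using the fixed-effects
fit, which makes 400 replicates cheap; the power check uses the full
mixed model.

## Known limitations

The FPT scan is quadratic in path length per trip; at brooding-trip
scales (a few hundred 1-km steps) this is fast in vectorised R, but
multi-thousand-kilometre incubation tracks would benefit from a compiled
kernel.  The Laplace approximation for nested ordinal models is known to
bias variance components toward zero with few observations per group —
at one-to-three zones per trip the trip-level variance is weakly
identified, exactly as in the field analysis.  The peak-variance floor of
0.05 is calibrated on this generator's movement regimes; tracks from
loggers with strong positional noise may need a different floor.  Finally,
percentile bootstrap intervals for repeatability are slightly narrow at
very small numbers of repeated individuals; the field design (16 retests)
is near that edge, which the wide reported interval reflects.
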