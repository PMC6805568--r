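---
title: "Methods: movement, diving and habitat analysis for juvenile king penguins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement, diving and habitat analysis for juvenile king penguins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`manchot` is a pipeline for satellite-relay biologging data from juvenile and
non-breeding king penguins (*Aptenodytes patagonicus*) dispersing from the
Crozet Archipelago. It chains five analysis stages — Argos speed filtering,
net-squared-displacement (NSD) segmentation, behavioural-mode clustering of
dive records, binomial habitat models, and orientation analysis against wind
and current — and ships a synthetic study-data generator so that every stage
can be exercised and scored end to end without access to the original field
data. This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions that were genuinely open.

```{r}
library(manchot)
res <- run_pipeline(pipeline_config(seed = 1))
```

## Geometry conventions

All distances are great-circle (haversine) on a sphere of radius 6371.0 km;
the field's tracking packages use spherical formulas and the position error of
Argos fixes (kilometres) dwarfs the spherical-vs-ellipsoidal difference.
Longitudes live in [-180, 180) and are unwrapped before any interpolation or
averaging, so tracks crossing the prime meridian or antimeridian are handled
along the short arc. Bearings are degrees clockwise from true north in
[0, 360). Projected coordinates use Snyder's spherical Lambert azimuthal
equal-area equations centred on the data centroid (the study region spans
tens of degrees of longitude at 45-60 S, where equal-area projection matters
for any spatial smooth).

Austral seasons default to Summer = Dec-Feb, Autumn = Mar-May,
Winter = Jun-Aug, Spring = Sep-Nov; the boundaries are a configurable
argument of `season_of()` because no standard authority fixes them.

## Speed filtering

`speed_filter()` implements the McConnell-style iterative scheme: for every
interior fix compute the root-mean-square of travel speeds to up to two
previous and two following retained fixes; remove the fix with the largest
RMS exceeding `vmax` (ties broken toward the earlier fix, so the procedure is
deterministic); repeat until no interior fix exceeds the limit. `vmax`
defaults to 14 km/h, the established maximum sustained travel speed for king
penguins. Endpoints are never removed — a first or last fix has no two-sided
evidence against it — so a residual speed violation can survive next to an
endpoint; it is counted in the report (`n_residual_violations`) rather than
silently fixed. The filter is idempotent and monotone in `vmax`, and on small
tracks its retained set matches an exhaustive minimum-cardinality removal
oracle whenever that optimum is unique (both properties are tested).

## NSD segmentation

Daily mean locations (arithmetic mean of latitude and unwrapped longitude per
UTC day) give a daily NSD series: squared great-circle distance from the
trip's first daily location. The series is segmented by a 3-state hidden
Markov model with Gaussian emissions on the square-root scale
(`transform = "log1p"` is available). The square root maps km² back to km, so
emission noise is displacement noise and the heavy right tail of NSD is
tamed; a residency phase appears as a plateau and a transit as a ramp.

Estimation is maximum-likelihood EM (Baum-Welch, scaled forward-backward)
with `n_restarts = 10` random initialisations and the best likelihood kept;
the per-iteration log-likelihood is asserted non-decreasing. Decoding is
Viterbi. States are relabelled deterministically: the state with the largest
emission SD is the transit (state 3) — a ramp has by far the widest emission
spread — and the two encamped states are ordered by mean (1 = early/summer
residency, 2 = winter residency). The cited original tool for this analysis
is Bayesian; this package substitutes the ML fit because only the decoded
state path feeds the downstream analysis, not posterior uncertainty. Constant
series trigger a flagged single-state fallback. Individuals with fewer than
`min_duration_days = 120` tracked days are excluded from segmentation: the
study's short deployments (3-4 months) were excluded from the original
three-phase analysis and a 3-state fit on a series that barely spans one
phase transition is not identifiable.

A known limitation, quantified in the package's tests: days at the feet of
the ramp are intrinsically ambiguous. With a realistic transit (~60 km/day
between plateaus ~3000 km apart) and ~100 km of encampment wander on the
displacement scale, roughly 8-10 boundary days per 180-day series are
statistically indistinguishable from plateau noise; decoding with the true
generative parameters mislabels almost exactly the same days as the EM fit.
Planted-state recovery on this geometry is therefore ~94-96%, not higher, and
the package makes no stronger claim.

## Dive modes

Travel speed is computed dive-to-dive: distance between the locations of
consecutive dives of the same individual on the same recording day divided by
the time between dive initiations (so the dive's own duration counts, as the
tag transmits summaries rather than positions). Dive locations come from
linear time-interpolation of the filtered track at the dive start. An
earlier nearest-fix matching design was abandoned after implementation showed
it interacts badly with Argos error: two dives minutes apart snap either to
the same fix (speed 0) or to fixes ~1-3 km apart (speed tens of km/h),
making the hourly speed variable bimodal garbage. Interpolation keeps the
speed continuous; dives more than 90 min from any fix are dropped, and
dive-to-dive speeds above the same 14 km/h physical maximum used by the
filter are censored as residual location-error artefacts.

Hourly records (means of depth, duration, post-dive surface interval and
speed per individual-hour) are standardized to zero mean and unit variance —
the four variables mix metres, seconds and km/h, and an unscaled L1 distance
would be dominated by depth — then clustered with Manhattan distance and
UPGMA (unweighted average) linkage, separately per stage, and the tree cut at
`k = 3`.

Two practical points about this clustering deserve honesty. First, the tool
family this follows (hierarchical clustering with subsequent consolidation)
applies a k-means re-assignment step after cutting the tree, and for good
reason: on noisy mixtures an average-linkage cut at small k reliably isolates
one or two outlying records as their own "cluster" while merging two
substantive ones. `cluster_hourly()` therefore consolidates by default:
candidate seeds are taken as the k largest clusters' centroids at
successively deeper cuts of the same tree, Lloyd k-means is run from each
seeding, and the solution with the lowest within-cluster sum of squares is
kept — deterministic, no extra randomness. `consolidate = FALSE` gives the
raw cut. Second, for datasets beyond `max_n = 4000` records the tree is
built on a seeded subsample (a dense UPGMA distance matrix on the full
~25,000-30,000 hourly records of a study-scale run would need gigabytes);
consolidation then labels all records.

The cluster with the highest mean travel speed is labelled `traveling`, the
rest `foraging`. The label is validated against depth: a "traveling" cluster
that is also the deepest is flagged for review (never silently relabelled),
and speed ties raise a flag.

## Habitat models

The binary mode (traveling = 0, foraging = 1) is modelled with binomial
(logit) penalized-spline GAMMs fitted by `mgcv::gam` with REML smoothing
selection — the same model class and estimation the original analysis used,
so the package wraps the canonical tool rather than re-deriving penalized
IRLS. Each environmental covariate (SST degC, MLD m, CHLA mg/m³, current and
wind speed m/s, optionally SIC %) gets a cubic regression spline with
shrinkage (`bs = "cs"`, k = 10), so penalization can remove a term entirely;
an optional 2-D smooth of the Lambert-projected coordinates (k = 25) absorbs
spatial structure; year, stage and season enter as parametric factors; and
the individual random intercept is the standard `bs = "re"` ridge smooth.
SIC is accepted but excluded from the default term set — it is zero over
most of the study region and months, which makes its smooth nearly
unidentifiable. Covariates are sampled at each hourly record's location and
time by bilinear interpolation at the nearest field time slice; records
outside the field grid are dropped and counted.

`dredge_habitat()` fits every subset of the candidate environmental terms
(factors, spatial smooth and random intercept stay in every model), ranks by
AIC, and flags the selection as ambiguous when the runner-up is within 2 AIC
units — the conventional delta-AIC > 2 retention rule. Predictions
(`predict_foraging()`) are inverse-logit with the random effect at its
population mean, and covariates outside the training range are flagged
rather than refused.

`build_smooth_basis()` exposes the package's reference basis machinery — a
cubic B-spline design on quantile-spaced knots with a second-difference
penalty plus a small ridge — and is verified against an independent
Cox-de Boor recursion in the tests; model fitting itself goes through mgcv.

## Orientation

Tracks are re-interpolated at 12-h steps (linear in latitude and unwrapped
longitude; grid points inside data gaps longer than `max_gap_hours = 48` are
dropped rather than bridged — the original analysis is silent on gap
handling, and interpolating across multi-day gaps fabricates headings).
Heading is the forward azimuth between consecutive 12-h positions; both the
heading and the flow are taken from the interpolated series so the two are
defined at a common time base. Flow direction comes from the (u, v)
components sampled at the segment start — a configurable choice
(`flow_convention`) guards against the meteorological "from" convention,
whose silent mixing is the classic failure mode of this analysis.

The angular difference (heading minus flow direction, mod 360) is classified
with closed bins: [315, 360) plus [0, 45] is `similar` (downstream),
[135, 225] is `against` (upstream), the rest `cross`. The bins span 90, 90
and 180 degrees, so isotropic headings give a 25/25/50 split — the null
every comparison is read against. Proportion tables are computed per
individual first and then averaged within stage-season-medium cells, so the
reported SD is inter-individual spread; cells with one individual are
flagged with the SD omitted.

Upstream-vs-downstream choice (cross excluded, as the response is explicitly
binary) is compared across stage-season cells with a binomial random-
intercept GLMM (`lme4::glmer`, adaptive Gauss-Hermite with 9 nodes) and
all pairwise cell contrasts Bonferroni-adjusted via `emmeans`; the compact
letter display is an insert-and-absorb implementation in the package. The
CHLA model reuses the habitat fitting core: smooths of CHLA at the segment
start (t) and end (t + 1), stage and season factors, individual intercept.

## The synthetic study generator

`simulate_study()` emulates the deployment the package was built around:
17 juveniles departing Crozet (46.43 S, 51.86 E) in early summer over two
cohort years and 6 non-breeding adults departing after their moult, tracked
for ~206 and ~220 days respectively. Its components:

* **Tracks** — a correlated random walk in the Lambert plane with three
  phases: an encampment near the colony (Ornstein-Uhlenbeck wander,
  stationary SD 60 km, hourly step 1.2 km so implied swim speeds stay
  realistic), a 50-day transit at 3.0 km/h with persistent south-westerly
  heading, and a winter encampment (SD 180 km). Argos error is isotropic
  Gaussian jitter (SD 1.5 km); with probability 0.05 a fix is displaced a
  further 100 km and labelled, so filter performance can be scored. Fix
  times are Poisson daily counts (mean 14.5) placed on a jittered regular
  grid within the day, reproducing the ~2-h Argos cadence; the true
  fix-time point process is unknown and this assumption is echoed in the
  bundle manifest.
* **Dives** — only on ON days of the 1-day-ON/2-days-OFF duty cycle, ~55
  per recording day, as sequential non-overlapping events. An hourly
  2-state Markov schedule alternates traveling and foraging regimes, with
  the traveling probability coupled to the movement phase (0.65 in transit,
  0.17 encamped — averaging to the ~0.3/0.7 time split over a deployment)
  so that shallow fast dives co-occur with fast movement, as observed.
  Traveling hours draw dives from cluster 1 of the per-stage parameter
  table, foraging hours from the mixture of clusters 2 and 3; depths are
  truncated below 2 m (the tags' dive threshold).
* **Environment** — regular 1-degree, 7-day fields: SST with a meridional
  gradient and seasonal cycle (strictly decreasing poleward when noise is
  off), MLD deepening in winter, SIC confined to the far south in winter,
  CHLA as fixed Gaussian patches over a background (never negative), a weak
  eastward mean current (0.11 m/s) and prevailing westerlies (8 m/s), all
  with small Gaussian noise.

What the generator deliberately does not emulate: per-quality-class Argos
error ellipses (the analysis filters on speed only), physically consistent
ocean circulation, prey fields, or any feedback of the environment on
behaviour. Passing tests on this generator therefore demonstrate that the
pipeline recovers structure it is pointed at — planted outliers, planted
phases, planted regime mixtures, planted covariate effects — not that the
ecological conclusions would replicate on other data.

## Numerical choices and problem sizes

Emission SDs in the HMM are floored at 1e-4 of the data range to prevent
variance collapse; EM stops at a log-likelihood change below 1e-6 or 200
iterations. Clustering ties (duplicate records) resolve by input order.
`kmeans` consolidation uses Lloyd iterations only, seeded deterministically
from the tree. All randomness flows from explicit integer seeds; derived
sub-seeds stay below 2^31.

The test-suite problem sizes are the package's choices for a thorough but
reasonable run: clustering recovery at n = 5000 hourly records, habitat
recovery at n = 5000 observations across 20 individuals with 50 replicate
dredges, GLMM calibration with 120 null and 40 power replicates, and the
determinism check as two full default-bundle pipeline runs.

## File formats

Tabular data are CSV with ISO-8601 UTC timestamps. Gridded fields use a
long-format CSV (`var, time, lon, lat, value`) validated for complete
regular grids, monotone axes (descending latitude is normalized), and
variable presence, with a name map for renamed inputs. Model fits and
manifests are JSON. These text formats keep every artefact diffable and
portable; a NetCDF reader can be slotted behind `read_env_fields()` without
touching the rest of the pipeline.
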