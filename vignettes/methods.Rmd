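---
title: "Models and design decisions in wolfmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in wolfmove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wolfmove analyses the post-release movement of GPS-collared floating
wolves in human-dominated landscapes. This vignette explains the models
the package implements, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where the methodology left genuine latitude. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Coordinate handling

All distances and areas are Euclidean in a projected metric CRS, one per
run, named in the configuration (`EPSG:326xx`/`EPSG:327xx` UTM codes or
`utm:32N`-style shorthand). The projection is an in-package ellipsoidal
transverse Mercator (Karney–Krüger series on WGS84, sub-millimetre within
a zone); tests check the forward/inverse round trip to 1e-6 degrees and a
1 km meridian arc against an independent geodesic computation
(`geosphere::distGeo`) to within 2 m. Geographic (degree-unit) CRS
identifiers are rejected, because every downstream quantity (step lengths,
UD areas, buffer means) assumes metres. Timestamps are stored in UTC;
day/night labelling uses solar geometry, not clock time, so no timezone
configuration is needed beyond the coordinates themselves.

Rasters are cell-centre registered, stored row-major from the north-west
corner, and serialised as ESRI ASCII grids (a plain-text interchange
format readable by any GIS) with a one-line `.crs` sidecar; vector layers
are GeoJSON in the projected CRS. These text formats were chosen so that
a complete run directory is diffable and portable.

## Trajectory regularisation and steps

Collars record hourly (or denser) fixes; analyses use a regular subsample
on fixed clock-hour anchors (e.g. 00/06/12/18 UTC at 6 h, or every 4 h).
`regularize()` keeps at most one fix per anchor slot — the nearest within
a 10-minute tolerance — and is idempotent. Steps are straight segments
between successive fixes; the turning angle is the signed heading change
in (−π, π]. Steps whose duration exceeds 1.5× the nominal interval are
flagged as gaps rather than interpolated: no continuous-time imputation
is attempted.

A step's period is decided by solar elevation at its temporal midpoint
(symmetric for 4–6 h steps): day above 0°, night below −6° (the civil
twilight bound), twilight between; twilight steps are excluded from all
day/night statistics. Solar positions come from the standard NOAA
low-precision algorithm (geometric elevation, no refraction; accurate to
about 0.01° this century). The daily distance assigns each step to the
calendar day (UTC) of its end fix, which makes the per-day distances sum
exactly to the cumulative line distance. The maximum net displacement is
the exact maximum pairwise distance (blocked brute force, fine at the few
thousand fixes of one deployment).

## Brownian bridge UD

Between fixes `i`, `i+1` separated by `T` seconds, the position at time
fraction `a` is bivariate normal with mean the linear interpolation and
per-coordinate variance `T a(1−a) σ²ₘ + [(1−a)² + a²] δ²`. The UD is the
time-weighted mixture over bridges, integrated per bridge by the midpoint
rule (30 nodes by default; doubling the nodes moves the allocation by
less than 1e-3 total variation, asserted in tests). Per-cell mass uses
exact Gaussian CDF differences rather than density × area, so the grid
resolution (100 m default, 4e6-cell cap) affects only resolution, not
bias. Bridges longer than 7 days (collar outages) are excluded and
logged, otherwise they would smear mass along a straight line.

`σ²ₘ` is estimated by leave-one-out likelihood: every second interior fix
is withheld and evaluated under the bridge spanned by its neighbours.
The predictive variance of a *withheld observed* fix includes its own
location error: `T a(1−a) σ²ₘ + [1 + (1−a)² + a²] δ²`. The last term is
easy to omit, but omitting it inflates `σ̂²ₘ` by `δ²/(T a(1−a))` — a
factor of two under hourly fixes with δ = 30 m — so the package uses the
exact expression; simulation tests recover a known σ²ₘ to within 20%.
δ defaults to 30 m, roughly twice the nominal accuracy claimed for the
collars, and is exposed in the configuration.

The 95% isopleth is the smallest set of cells (by descending density)
holding ≥ 95% of the mass. Over a full deployment that set necessarily
includes low-density ribbons along travel corridors and stopovers
whenever more than 5% of monitoring time is spent outside the settlement
area; the *settlement polygon* is therefore the isopleth's dominant
connected component (8-connectivity, largest enclosed mass), which is
what "main settlement area" denotes throughout.

## Movement-pattern segmentation

Published classifications of post-release, settlement, exploration,
pre-dispersal and dispersal rest on visual inspection of trajectories and
NSD curves; only the duration bounds are quantitative. The package makes
the rules explicit and deterministic, applied to inside/outside runs
against the settlement polygon:

* outside runs spanning ≥ 12 h and < 6 days that return — exploration;
* returning outside runs longer than 6 days — pre-dispersal;
* the terminal outside run that never returns — dispersal;
* the initial span before the first sustained (≥ 2 days) occupancy —
  post-release;
* everything else, including sub-12 h sorties — settlement.

A run's span is measured from its first to its last outside fix. The
2-day sustained-occupancy rule is our determinisation of "non-directional
movements following the release": it must allow the observed 6–15 day
post-release durations to emerge rather than impose them. NSD is computed
and exported for plotting and QC, but the polygon-run rules are
authoritative — they are the only stated quantitative criteria.
Directionality is not tested formally; run length and return/no-return
are the operative criteria.

Wolves that disperse immediately and settle elsewhere (two of the three
collared individuals behaved this way) are handled by a second pass: when
the release site lies outside the polygon and the pre-occupancy span
exceeds the 6-day bound, the transit is relabelled dispersal, leaving a
post-release stub where the NSD had not yet taken off. Consequently
"dispersal" may legitimately precede a settlement segment for immediate
dispersers, while for classic dispersers it is the unique terminal
segment; the tests assert the latter and fix-level agreement ≥ 90% with
planted schedules for both topologies.

## Rank statistics

Step lengths are strongly right-skewed, so all comparisons are
rank-based. `mann_whitney_perm()` computes U with midrank ties and a
two-sided label-permutation p-value `(1 + #{|U′−E[U]| ≥ |U−E[U]|}) /
(n_perm + 1)` with 10,000 permutations by default; when the number of
distinct assignments is below `n_perm` the full set is enumerated and the
p-value is exact. U is reported as `U/(n₁n₂)`, the probability that a
value of the second sample exceeds one of the first — the form in which
such tables are printed (raw U cannot lie in [0, 1] at these sample
sizes). Orientation: P(night > day) within patterns, P(second-listed >
first-listed) between patterns; pre-dispersal and dispersal are pooled
for testing. Between-individual diurnality uses unpaired Wilcoxon
rank-sum tests per pair with Holm adjustment reported alongside the raw
p-values (the adjustment choice is ours; raw values are always emitted).
Empirical type-I error at α = 0.05 under a simulated null is asserted to
lie in [0.03, 0.07].

## Resting sites

A candidate cluster grows from each fix: the span of consecutive
subsequent fixes staying within 250 m of it, with gaps > 1.5× the nominal
interval breaking contiguity. Spans of at least 6 consecutive hours —
strict first-to-last clock time, nothing added for half-intervals, which
is the conservative and unambiguous reading — are candidates; with 6-h
fixes a single inter-fix dwell qualifies, with 4-h fixes two consecutive
dwells are needed. Candidates that share fixes, or are temporally
adjacent with anchors within 500 m, merge by single linkage; the site is
the arithmetic centroid of all member fixes. Diurnality is the fraction
of the occupancy interval in daylight out of the day-plus-night time
(twilight excluded from both sides), integrated on a 2-minute grid; a
bout entirely inside twilight is flagged undefined. Sites are annotated
with the movement pattern at their first fix and the elevation of their
centroid cell (the filter applies to sites, not fixes); the selection
analysis uses sites on the pre-dispersal/dispersal path below 300 m
a.s.l. — the lowland plain.

## Resting-site selection

Each used site is matched with 25 available locations generated from the
fix preceding the site: lengths and turning angles resampled with
replacement from the individual's empirical step distributions, headings
measured from the arrival step at that fix. Points landing off the
landscape or in water are redrawn (cap 100, then clipped with a warning).
Covariates: mean tree and settlement density in buffers of 50/100/250/500
m; patch density (8-connected patches of the full land-cover mosaic per
km²) at 250/500 m; and exponential-decay distances `1 − exp(−d/500 m)` to
the nearest motorway, primary road, river, tree patch and built patch —
0 on the feature, saturating to 1 far away. The decay scale is not
dictated by the method; 500 m was chosen once as the scale at which
linear-feature influence plausibly fades for a resting wolf and is
exposed in the configuration.

The buffer radius per covariate family is chosen by preliminary
univariate CLR (lowest AIC, ties to the smaller radius). Pairwise Pearson
correlations above 0.7 then drop, from each offending pair, the member
with the higher mean absolute correlation against everything else — a
deterministic rule, so a density covariate can legitimately lose its seat
to a correlated distance proxy in a given run. The CLR maximises the
conditional log-likelihood by Newton–Raphson with step halving (gradient
norm < 1e-8); standard errors come from the inverse observed information,
with 90% Wald intervals. Covariates are z-scored across all locations
pooled before fitting so coefficients are comparable under averaging;
raw-scale coefficients are emitted too. Complete separation — which small
stratum counts make entirely possible — is flagged, and separated subsets
are excluded from dredging. Dredging fits all `2^k` subsets (k ≤ 12)
including the null model, retains ΔAIC ≤ 2, and reports Akaike weights,
full-average coefficients (zeros for absent terms) and per-term relative
importance. Tests pin the closed forms (softmax weights, single-model
collapse) and verify the fit against an independent stratified
Cox implementation (`survival::coxph`, exact in the one-case-per-stratum
design) and a brute-force likelihood grid.

## The synthetic-data generator

`make_landscape()` builds a 40 km square at 50 m resolution: an open
matrix with ~150 tree patches (radius 200–700 m, about 6% cover, a share
hugging the river), ~50 built clusters (radius 300–1200 m, about 7%
cover), a sinuous north–south river rasterised as water, six roads
alternating motorway/primary, smoothed density rasters, and a north-south
elevation ramp (500 m to 50 m) crossing the 300 m contour so that a
northern hill zone overlooks a lowland plain. The composition mirrors a
heavily urbanised agricultural plain with small, isolated woods; an
early, much sparser composition (< 1% tree and built cover) left the
density covariates zero almost everywhere and made selection coefficients
unidentifiable, which is a property of the design, not the estimator.

`simulate_wolf()` walks hourly positions through an imposed phase
schedule (default: post-release 8 d, settlement 80 d, exploration 3 d,
settlement 40 d, pre-dispersal 10 d, settlement 40 d, dispersal 35 d —
about seven months, thinned to 4-h fixes ≈ 1300). Movement is a
correlated random walk: gamma step lengths per phase × period and
wrapped-Cauchy turns. Diurnal mean hourly steps are 60 m (post-release),
100 m (settlement), 200–220 m (excursions and dispersal); nocturnal means
are 4× larger — both the ordering (excursions faster than settlement,
settlement faster than post-release) and the night/day factor reflect
what collared wolves in such landscapes show. Settlement is softly
tethered to an anchor (headings steer home beyond 1.5 km) rather than
given true home-range dynamics; exploration and pre-dispersal are biased
out-and-back excursions; dispersal hops between distant southern
waypoints and never returns. A wolf entering settlement after a dispersal
phase re-anchors where it stands, reproducing the
disperse-first-settle-later topology. Once per day (on average) the wolf
rests for 6.5–10 h starting mid-morning: 50 candidate sites within 2 km
are scored by a multinomial logit on covariates extracted with the same
code path the inference uses, with coefficients (on within-set z-scores)
tree density +1.0, distance-from-built decay +2.2, distance-from-river
decay −0.35 — magnitudes of the order reported for real wolves, placed on
covariates with support everywhere so that recovery is a fair test. GPS
error (SD 15 m) is added to emitted fixes.

What the generator does *not* emulate: territorial neighbours, prey
distribution, true home-range attraction (the schedule is imposed, not
emergent), collar failures, habitat-dependent movement outside resting,
and fix loss. Passing recovery tests therefore shows the pipeline
correctly inverts its own generative assumptions at realistic sizes — not
that those assumptions exhaust real wolf behaviour.

## Problem sizes and numerical choices

The bundled configuration analyses one wolf of ~1300 fixes on the 40 km
landscape; the acceptance script repeats the full pipeline on 20 seeds
for the sign-recovery rate, uses 1e5 Monte-Carlo samples for the BBMM
total-variation check, 20 replicates of n = 201 for diffusion recovery,
1000 null replicates for rank-test calibration and 500 for CI coverage.
These sizes keep a complete validation run in minutes on one CPU while
leaving Monte-Carlo noise well inside the asserted tolerances. Scalar
optimisation of σ²ₘ runs on a log bracket [1e-8, 1e4] m²/s with relative
tolerance 1e-6, preferring the lower boundary on flat likelihoods (ties
toward smaller variance). Newton fits cap at 50 iterations with step
halving; a step longer than 50 standardised units is treated as
separation. The isopleth greedy construction breaks density ties by cell
order, which only matters on exactly tied cells.

## Known limitations

* The availability kernel resamples empirical steps independently of
  habitat, so strong movement–habitat interactions would be attributed to
  selection.
* Elevation enters only as the 300 m plain filter; no terrain covariates.
* The two-pass immediate-disperser rule assumes a single major transit;
  serial dispersers with multiple settlements would need per-segment
  polygons.
* Diurnality integrates the whole occupancy interval, not fix-level
  activity within it.
* GeoJSON/ASCII-grid I/O covers the formats the pipeline emits and
  consumes; it is not a general-purpose GIS layer.
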