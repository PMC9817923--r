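# wolfmove

Movement-ecology analysis of GPS-collared floating wolves in
human-dominated landscapes: utilisation distributions, movement-pattern
segmentation, day/night step statistics, resting-site detection, and
matched case-control resting-site selection — with a synthetic-data module
that makes every stage testable against planted ground truth.

## The scientific problem

Wolves recolonising heavily urbanised lowlands (for instance rehabilitated
individuals hard-released into an agricultural plain) must move, rest and
eventually settle amid roads, towns and people. Telemetry studies of such
animals ask a recurring set of questions:

1. **Where did the animal settle?** The utilisation distribution (UD) is
   estimated with a Brownian bridge movement model (BBMM): between
   successive fixes `i` and `i+1` the position at time fraction
   `a` is normal with mean the linear interpolation and per-coordinate
   variance

   `s²(a) = T a(1−a) σ²ₘ + [(1−a)² + a²] δ²`,

   where `T` is the time lag, `σ²ₘ` the Brownian motion variance
   (estimated by leave-one-out likelihood on alternate fixes) and `δ` the
   GPS location error SD (30 m by default). The area within the 95%
   isopleth — and specifically its dominant connected component — is the
   main settlement area.

2. **What movement patterns did it express?** Each fix is classified as
   post-release, settlement, exploration, pre-dispersal or dispersal using
   run-length rules against the settlement polygon: returning
   excursions of ≥ 12 h and < 6 days are exploration; returning excursions
   of > 6 days are pre-dispersal; a terminal excursion that never returns
   is dispersal. Net squared displacement (NSD), minimum daily distance,
   cumulative line distance and net dispersal distances summarise the
   trajectory.

3. **Was the animal more nocturnal than diurnal?** Step lengths between
   successive fixes are compared day vs night (twilight excluded, solar
   elevation at the step midpoint) with a permutation Mann–Whitney test
   (10,000 permutations; U reported in its normalised form
   `U/(n₁n₂) ∈ [0, 1]`), within and between movement patterns.

4. **Where did it rest, and what did it select?** Resting sites are
   spatio-temporal clusters (≥ 6 consecutive hours within a 250 m radius;
   clusters within 500 m merged), each with a diurnality level in [0, 1].
   Sites on the pre-dispersal/dispersal path below 300 m a.s.l. enter a
   matched case-control design: each used site is paired with 25 available
   locations drawn from the individual's empirical step-length and
   turning-angle distributions, and a conditional logistic regression
   (CLR) is fitted by maximising
   `Σ_strata [x_used·β − log Σ_j exp(x_j·β)]`,
   followed by AIC dredging over all covariate subsets and full model
   averaging over the ΔAIC ≤ 2 set.

Because real GPS deployments of this kind are rarely public, the package
ships a generator (`make_landscape()`, `simulate_wolf()`) that produces a
synthetic urbanised landscape and a behaviour-switching trajectory whose
phase labels, resting bouts and selection coefficients are known, so the
whole pipeline is validated by parameter recovery rather than by eye.

## Worked example

```r
library(wolfmove)

cfg <- load_config(system.file("extdata", "demo-config.yaml",
                               package = "wolfmove"))
run <- run_all(cfg, "demo-run")       # simulate -> ud -> segment -> steps
                                      #          -> rest -> select
run$ud$settlement
#> <wm_isopleth> level 0.95: area 53.80 km2 (mass 0.8015)

table(run$phases$labels)
#>     dispersal   exploration pre_dispersal    settlement
#>           205             6            42          1043

run$select$fit
#> Conditional logistic regression (16 strata, loglik -35.041, AIC 82.08)
#>                            beta      se     lo90   hi90      p
#> tree_density_250         1.1704  0.3283   0.6303 1.7105 0.0004
#> settlement_density_250 -11.2957 11.8799 -30.8363 8.2450 0.3417
#> patch_density_500       -0.1289  0.4839  -0.9249 0.6671 0.7900
#> decay_dist_motorway      0.4448  0.4659  -0.3216 1.2112 0.3397
#> decay_dist_primary       1.0481  0.6737  -0.0601 2.1562 0.1198
#> decay_dist_river         0.1135  0.2077  -0.2282 0.4552 0.5848
```

The simulated wolf was generated with positive selection for tree cover,
strong avoidance of built patches and a mild preference for resting near
rivers. The fitted model shows significant tree-cover selection; the
built-patch avoidance is carried here by correlated proxies (the strongly
negative settlement-density coefficient), because the correlation filter
kept settlement density rather than the generating distance-from-built
covariate in this run — refitting on the generating covariates themselves
(as `scripts/acceptance.R` does) recovers both strong coefficients with
the right signs. `demo-run/` holds every artifact: `ud.asc`,
`settlement.geojson`, `phases.csv`, `steps.csv`, `table2.csv`,
`table3.csv`, `resting_sites.geojson`, `choice_sets.csv`, `clr_fit.json`,
`dredge_table.csv`, `averaged_model.json`, plus a manifest per stage with
the seed and config hash. The same pipeline runs from a shell via

```sh
Rscript inst/cli/wolfmove.R all --config inst/extdata/demo-config.yaml \
        --seed 1 --outdir demo-run
```

and on real data by placing `track.csv` and a `landscape/` bundle in the
run directory and calling the stages from `ud` onward.

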