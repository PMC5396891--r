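# camarray

Design tools for camera-trap surveys: how many cameras should be clustered
at a site, and how long should the season run, to reliably detect a target
species?

Camera-trap studies routinely boost low detection probabilities with bait
or non-random camera placement, both of which bias downstream occupancy
and abundance estimates. An alternative is the *camera array*: a cluster
of non-independent, randomly placed cameras within a site. `camarray`
evaluates that design choice by Monte Carlo subsampling of a yearlong
camera-trap record. Each iteration draws a hypothetical design — an array
size *m* (1–10 cameras per site), a season window, and a replicate length
*L* (1–28 days) — rebuilds the detection history that design would have
produced, and computes:

- **survey detection probability** &nbsp; p = ΣP / (N·k), the fraction of
  site-replicates with at least one detection (N sites, k = ⌊S/L⌋
  replicates, P a binary detection indicator), under the assumption that
  the species is present at every site (occupancy = 1);
- **season detection probability** &nbsp; p\* = 1 − (1 − p)^k, the chance of
  at least one detection over the whole season.

Raw trigger events are first merged into independent detections with a
30-minute rule applied across all cameras in a site: a raccoon recorded 10
minutes apart at two cameras is one detection. Season detectability as a
function of season length S is summarised by the saturating curve

&nbsp;&nbsp;&nbsp;&nbsp; p\* = A·(1 − e^(−R·S))

fitted per species × array size by bounded nonlinear least squares (A is
the asymptote, R the daily approach rate), and array sizes are compared
pairwise with familywise error control robust to non-normality and
heteroscedasticity (single-step max-|t| on sandwich variances, or a
max-statistic permutation test), summarised as a compact letter display.
Inverting the fitted curve answers the planning question "how many days do
I need to reach p\* ≥ 0.4 with a 3-camera array?".

Because such field datasets are rarely deposited, the package ships a
synthetic-data generator that emulates the structure of a clustered-array
field study — 4 sites, each with two 1-ha clusters of 5 randomly placed
cameras (~65 m apart within clusters, ~589 m between clusters), a
yearlong deployment, and four species spanning high to low encounter
rates — with known ground truth, so the entire pipeline is testable end to
end.

## Worked example

```r
library(camarray)

cfg <- run_config(out_dir = "demo-run", master_seed = 42,
                  n_iterations = 1500)
run <- run_full(cfg, quiet = TRUE)
run
#> <camarray_run>
#>   seed: 42  config hash: 1d287fe54846a5a0a5a48a58950ececc
#>   cameras: 40  raw events: 27847  detections: 18088
#>   Monte Carlo rows: 6000
#>   outputs in: demo-run
```

40 cameras produced ~28k raw trigger events, merged into ~18k independent
detections; 1,500 Monte Carlo designs × 4 species give 6,000 result rows
(`mc_results.csv`), each with its design and its p and p\*. The compact
letter display shows where adding cameras stops helping (groups sharing a
letter are not significantly different):

```r
run$comparisons$bobcat$groups
#>    1    2    3    4    5    6    7    8    9   10
#>  "a"  "b"  "c" "cd"  "d"  "e"  "e"  "e"  "e"  "e"
run$comparisons$deer$groups
#>    1    2    3    4    5    6    7    8    9   10
#>  "a" "ab"  "b"  "b"  "b"  "b"  "b"  "b"  "b"  "b"
```

For the rarely detected bobcat every camera up to ~5 adds significant
detectability; for deer a second camera already saturates the design. The
mean survey detectability gain from a second camera in this run was +83%
(bobcat), +87% (opossum), +26% (raccoon), +2% (deer) — the rarer the
species, the more an array pays off.

Season planning from the fitted curves:

```r
fit <- run$curve_fits$opossum[["3"]]   # opossum, 3-camera array
round(coef(fit), 5)
#>       A       R
#> 1.00000 0.00409
invert_detcurve(fit, 0.4)              # days of season to reach p* = 0.4
#> [1] 125.0021
report_design_scenario(run$curve_fits$opossum, total_cameras = 40,
                       season_budget_days = 180, target_p_star = 0.4)
```

which tabulates, for every array size, the sites covered per deployment
(⌊40/m⌋), the minimum season length, and whether relocating arrays within
the budget can double spatial coverage. (Numbers vary with the seed; the
curves above come from the `master_seed = 42` run.)

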