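---
title: "Evaluating camera-trap array designs by Monte Carlo subsampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating camera-trap array designs by Monte Carlo subsampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the estimators

Detectability — the probability of recording a species given that it is
present — limits every inference drawn from camera-trap data. Two design
levers control it: how many cameras are clustered at a site (the *array
size* m), and how long the cameras stay out (the *season length* S in
days). `camarray` quantifies both levers by resampling a yearlong record
into hypothetical smaller studies.

The continuous record is cut into k = ⌊S/L⌋ survey replicates of L days
each. For each site and replicate, P = 1 if the species was detected at
least once, else 0. Two quantities follow:

* survey detection probability, p = ΣP / (N·k), with N the number of
  sites — the per-replicate detection chance;
* season detection probability, p\* = 1 − (1 − p)^k — the chance of at
  least one detection across the whole season.

Both rest on two assumptions. First, *presence*: the target species
occupies every site throughout the year (occupancy = 1), so a zero is a
failed detection, not a true absence, and p can be read directly off the
detection/non-detection matrix instead of being estimated jointly with
occupancy. Second, *closure and independence*: p\* treats the k
replicates as independent Bernoulli trials with common p. Long seasons
strain the closure assumption in real data (animals move, vegetation and
behaviour change seasonally); the package computes the estimators as
defined and leaves that judgement to the analyst.

## Independent detections: the 30-minute rule

Cameras clustered within a 1-ha area are deliberately *not* independent:
one animal can trigger several of them in one pass. Raw trigger events
are therefore merged, per site and species, whenever less than 30 minutes
(configurable) separates an event from the latest event of the current
chain — a *sliding* window, so a sequence at minutes 0, 25, 50 is one
continuous visit, not two. The rule operates across all cameras in the
site, and each merged chain becomes one independent detection dated by
its first event.

When the subsampler evaluates a hypothetical m-camera array it re-runs
this deduplication on the selected cameras only (`camera_subset`),
answering the counterfactual "what would this array have seen?". The
alternative — deduplicate once over all cameras and attribute each
detection to its earliest camera — is available as
`attribution = "first_camera"`; the two differ only when cross-camera
merges occur, which are rare at realistic encounter rates. The active
choice is echoed in the run manifest.

One subtlety of sliding-window chaining is worth stating. Adding a camera
adds events, and an added event can *bridge* two chains that were ≥ 30
minutes apart, merging them; the merged detection is dated by its first
event. Consequently "more cameras ⇒ at least as many detections" is not a
strict theorem — what is true, and what the test suite asserts, is that
every detection seen by a subset of cameras lies within the time span of
exactly one full-site detection: information is never lost, only merged.
At the binary replicate level the same corner can in principle move a
detection across a replicate boundary; with a 30-minute window against
replicates of 1–28 days the effect is negligible, and the suite verifies
strict monotonicity whenever site visits are separated by at least the
window.

## The subsampling engine

Each Monte Carlo iteration draws, uniformly and independently:

* an array size m from its configured range (default 1–10), and a
  without-replacement subset of m cameras per site;
* a season start day on 1–365 and a season length S (default 2–365 days);
* a replicate length L on 1–28 days, the range in common use; draws with
  L > S are rejected and redrawn (the count of rejections is logged).

k = ⌊S/L⌋ replicates are laid out from the start day, wrapping modulo 365
so seasons that run past the end of the record loop back to its
beginning, as one does with a single year of data assumed comparable
across years. The trailing S − kL days are discarded rather than forming
a short final replicate, which would be heteroscedastic. Replicate counts
are required to be whole numbers everywhere downstream — flooring happens
here and only here.

Drawing S directly keeps its distribution uniform; drawing start and end
days independently would instead make S triangular. Both readings of
"random season" are defensible; the package controls S directly in
`"random_season"` mode and sweeps an explicit (m, S) grid in
`"fixed_grid"` mode. One design draw is shared by all species within an
iteration, and per-iteration seeds are derived from the master seed by an
up-front `sample.int`, so runs replay bit for bit and iterations are
order-insensitive.

## The season-detectability curve

Season detectability rises with season length toward a plateau. The
package summarises it with the saturating curve

p\* = A · (1 − e^(−R·S)),

where A ∈ [0, 1] is the asymptote — the detectability a design cannot
exceed no matter how long it runs — and R > 0 (per day) the approach
rate. The curve passes through the origin by construction. `fit_detcurve()`
fits (A, R) per species × array size by bounded least squares
(Gauss–Newton with an analytic gradient, A clamped to [0, 1], R positive),
by default to the raw per-iteration (S, p\*) points; `bin = TRUE` fits
per-season-length means instead, which weights season lengths equally but
hides the draw-to-draw spread.

Starting values: A₀ is the largest observed p\* (clipped into (0, 1]);
R₀ comes from log-linearising 1 − p\*/A₀ = e^(−RS) at the two smallest
season lengths, with 1/mean(S) as fallback. Confidence intervals are
profile-likelihood intervals when the profiler succeeds and Wald t-based
intervals otherwise; the object records which (`ci_method`). Plotted
confidence bands are pointwise delta-method bands.

Degenerate inputs are signalled, never papered over: fewer than three
distinct season lengths is an error; an all-zero response (R is then
unidentifiable) or an optimiser failure returns an object with
`converged = FALSE`, `NA` coefficients and the failure message, and every
downstream method refuses unconverged fits. Species that saturate below
the smallest observed season (p\* ≈ 1 everywhere, common for an abundant
species with any array) also fail honestly: a flat-at-1 response carries
no information about R.

Inverting a converged fit answers the planning question: the minimum
season reaching a target t < A is S = −ln(1 − t/A)/R; targets at or above
A are reported as unreachable. `report_design_scenario()` combines the
inversion with camera arithmetic — ⌊total/m⌋ sites per deployment, and
whether relocating the arrays (at most one relocation per season by
default, settable via `max_deployments`) fits the field-season budget.

## Comparing array sizes

Per-iteration p values are bounded, skewed, and their variance shrinks as
arrays grow, so the pairwise comparison of mean p across array sizes uses
familywise error control that tolerates non-normality and
heteroscedasticity. The default is single-step max-|t| inference over all
C(G,2) contrasts of a one-way cell-means model with an HC3 sandwich
covariance (via `multcomp` and `sandwich`); adjusted p-values come from
the joint multivariate-t distribution of the contrasts. A max-statistic
permutation test (Welch statistics, labels permuted, default 2000
permutations, seeded) is provided as a distribution-free alternative and
as an independent cross-check — the two agree on every clear-cut case in
the test suite.

Results are summarised as a compact letter display built by
insert-and-absorb: start from one letter covering all groups; for each
significant pair split every letter containing both members; absorb
subset letters. Two array sizes share a letter exactly when their
adjusted p ≥ α, a property the suite checks against exhaustive search
over small cases rather than assuming.

One caveat is recorded in every comparison object: Monte Carlo iterations
subsample the *same* year of data and are treated as independent
observations. The p-values therefore describe the resampling
distribution, not fresh field seasons; with thousands of iterations the
significance groupings should be read as descriptive structure, not
strict error rates over hypothetical repeated studies.

## What the synthetic generator emulates — and what it does not

`generate_deployment()` reproduces the geometry of a clustered-array
field study: each site holds two 1-ha clusters of five cameras at random
coordinates, cluster layouts rejection-sampled until the mean pairwise
camera spacing lands in a configured band (default 65.2 ± 10 m — uniform
placement in 1 ha alone would centre near 52 m), cluster centres 589.3 m
apart, sites 10 km apart.

`simulate_events()` generates trigger events per camera-day as Poisson
with rate λ · season(t) · camera-effect: passing, unmarked animals are
well approximated by a point process. Camera effects are fixed log-normal
multipliers (mean 1) per camera and species — not all cameras are equal,
which is precisely why arrays pay off. The seasonal term is a sinusoid
with period 365 days and configurable amplitude. Event times are uniform
within the day at minute resolution; with probability
`within_day_cluster_prob` an event spawns a companion 1–29 minutes later
at a random camera of the same cluster, exercising the 30-minute rule.
Cameras are continuously active (the analysis assumes so); the calendar
is a plain 365-day year with no leap days.

The default four-species community is *illustrative, not estimated*:
deer 1.0, raccoon 0.12, opossum 0.0025 and bobcat 0.0015 events per
camera per day. The rare-species rates are deliberately below one event
per camera per year because season detectability saturates roughly as
1 − exp(−E[detections per site-season]): rare species must average well
under one detection per single-camera season for their single-camera
curves to plateau low, which is the qualitative regime of interest —
frequently detected species saturate with one or two cameras while rarely
detected species keep gaining detectability up to large arrays.

The generator does **not** simulate animal movement, home ranges,
territoriality, or spatially explicit capture processes; camera
"heterogeneity" stands in for all micro-site effects, and co-occurrence
across cameras beyond the 30-minute companions is absent. Passing tests
therefore demonstrate that the estimators, the resampling machinery and
the inference are correct *given* a point-process world; they do not
validate the point-process model against real animal behaviour, and
effect sizes on real data will differ.

## Numerical choices and problem sizes

* Deduplication gaps are compared with strict `< window` for joining
  (exactly 30 minutes apart starts a new detection); ties in event time
  are broken by camera id for determinism.
* Timestamps are minute-resolution, timezone-naive (stored as UTC); days
  run from local midnight of the configured year start.
* The curve optimiser runs to the `nls` "port" convergence criteria with
  up to 500 iterations; the suite separately verifies agreement with a
  dense grid search of the residual sum of squares.
* Replicate counts, season lengths and array sizes are validated as
  integers in their documented ranges; estimator inputs outside [0, 1]
  are errors, not clamped.

The test suite and the acceptance script keep simulations at sizes chosen
to make their own Monte Carlo error small relative to what they assert:
5,000 design draws (split over eight independently simulated years, so
the standard error honestly includes year-to-year variation) for the
estimator-consistency check; 200 simulated curves for parameter recovery
and interval coverage; 100 repetitions for the null rejection rate of the
comparison; about a thousand randomised cases for the brute-force oracle
equivalences. The full pipeline default remains 5,000 iterations per
species.

## Known limitations

* The pseudo-replication caveat above: all inference conditions on one
  realised year of data.
* Saturated designs (p\* ≈ 1 at every observed season length) do not
  yield a usable curve fit; the honest `converged = FALSE` is the
  intended behaviour, but it means asymptote estimates are only available
  where the data actually show curvature.
* Wald intervals for A can cross the [0, 1] bounds near saturation;
  they are reported unclipped so that coverage statements stay honest.
* Camera failure, bait effects and non-random placement are out of scope;
  the generator has an explicit continuous-activity assumption.
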