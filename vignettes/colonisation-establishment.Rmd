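---
title: "Simulating and modelling the establishment of small founding populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and modelling the establishment of small founding populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estabsim)
```

## The problem

When a species colonises new territory it usually starts from a handful of
founders. Whether those founders establish a self-sustaining population
depends on propagule pressure -- how many individuals arrive (propagule size,
PS) and in how many separate events (propagule number, PN) -- but below about
twenty founders the outcome becomes highly uncertain, and two widely
overlooked sources of context dependence start to matter: the spatial
arrangement of essential habitat at the point of entry, and the timing of
arrival relative to the environmental cycle that gates breeding.

`estabsim` provides the full computational chain to study this for a model
organism, a semi-aquatic, seasonally breeding invasive amphibian (the cane
toad): a spatially explicit, daily-time-step individual-based simulator on a
hexagonal-grid landscape; a Latin-hypercube incursion-scenario engine with a
population-growth establishment criterion; and a statistical layer of static
and 90-day running-window binomial GLMs with a model-evaluation suite.

## The simulation arena

The arena is a pointy-top, odd-row-offset hexagonal tessellation with 10 m
between cell centres, so each cell covers $\frac{\sqrt 3}{2}\,s^2 = 86.6$ m².
Column and row counts come from `floor(width/s)` and
`floor(height/(s\sqrt3/2))`; a 15 km by 30 km arena therefore holds
1500 x 3464 = 5,196,000 cells. Each cell carries one of eight habitat codes
(ocean, road, human habitation, grassland, woodland, ephemeral flowing water,
non-flowing water, other), from which the simulator derives its functional
layers: freshwater cells are breeding sites; water margins and human
habitation are rehydration sites; grassland and human habitation are foraging
habitat.

Two synthetic entry-point archetypes are generated deterministically from a
seed. The *packed* landscape is a single contiguous ~4 km² cluster of
human-disturbed habitat (housing with an embedded permanent waterbody and one
access road) in a woodland matrix; the *fragmented* landscape scatters
infrastructure patches and pit lakes totalling ~9.7 km². The packed entry
point sits inside the cluster within a few hundred metres of the waterbody --
this matters, because founders that cannot reach standing water cannot breed
and, in the dry season, cannot rehydrate.

The environment is driven by a synthetic tropical wet-dry rainfall series: a
Bernoulli wet-day draw times a Gamma(shape 2) amount, with season-specific
parameters (defaults: wet-season rain probability 0.55 with mean 12 mm on
rain days; dry season 0.05 and 2 mm). Days are labelled wet November-April by
the calendar rule (day 1 = 1 January; 365-day years, no leap days); a
cumulative-rainfall trigger is available as a configuration switch but the
calendar rule is the default because the system's climate is described that
way. The defaults caricature a tropical savannah regime; they are not fitted
to any station record.

## The individual-based model

Each simulated day executes a fixed phase order: environment update, aquatic
development, behaviour choice, movement, breeding and spawning, hydration
update, mortality, then ageing and growth. Reproduction must see
post-movement positions, and mortality runs after spawning so a female can
die the day she spawns without losing the clutch.

**Life cycle.** Clutches of eggs hatch into tadpoles after 3 days and
metamorphose at a clutch-level age drawn uniformly in 34-55 days. Aquatic
cohorts are tracked as counts at their natal waterbody cell (tadpole foraging
along spawning-site coastlines is abstracted to the natal cell, and foraging
is assumed always energetically sufficient). Terrestrial toads are individual
agents. They grow linearly in snout-vent length (SVL) from 10 mm at
metamorphosis at an individual lognormal rate (mean 0.30 mm/day, CV 0.2), and
change stage at SVL thresholds: juvenile at 30 mm, adult at 70 mm. This
calibrates mean age at adulthood to roughly 243 days
(3 + ~44.5 + 60/0.3 ≈ 248 from egg), the field-estimated average, which the
test suite verifies within ±15% on simulated recruits.

**Water.** Terrestrial toads lose a fixed fraction of standard body weight
per dry day (default 0.05, halved when sheltering inactive). At 10% loss a
toad is dehydrated and prioritises rehydrating; at 25% (our quantification of
the "extremely dehydrated" state, which is named but not quantified in the
source literature) it forgoes everything else; at 40% it desiccates and dies.
Wet-season days and rain days rehydrate toads ambiently; otherwise a toad
must stand on a rehydration cell to reset its balance.

**Behaviour and movement.** Each day a toad is active with a season-specific
probability (0.9 wet, 0.5 dry). Dehydration overrides all other choices;
otherwise active wet-season adults breed (males repeatedly; females only
until they spawn, with flags reset at each wet-season onset on day-of-year
305), and all other active toads forage. Displacements are drawn from a
truncated-exponential kernel (means 150 m wet, 30 m dry) capped so realised
centre-to-centre displacement never exceeds 1,000 m/day. Wet-season foragers
keep directional persistence (heading noise SD 0.6 rad); dry-season headings
are uniform. Dry-season rehydrators and breeding toads head for the nearest
rehydration or breeding cell taken from a multi-source BFS distance field
over the hex lattice, never overshooting the target. Foragers choose among
candidate destinations with road cells upweighted 3:1, reflecting the
road-following dispersal of the species.

**Reproduction.** A breeding female at a waterbody (within the 300 m
perception range) that perceives a calling male within the same range spawns
a clutch of `round(linear map of SVL from [70,110] onto [7675,14288])` eggs
into the perceptible water cell holding the fewest tadpoles (ties: nearest,
then lowest index) -- the tadpole-avoidance rule that protects offspring from
cannibalism and chemical suppression by older cohorts. Mate choice among
perceptible males is uniform at random.

**Mortality.** Independent per-stage daily probabilities, eggs highest.
The source text prints the ordering but not the rates, and its placeholder
magnitudes would imply >35% egg-to-metamorph survival -- demographically
explosive for an amphibian that lays ~10⁴ eggs. We instead use
literature-plausible defaults: egg 0.20, tadpole 0.08, metamorph 0.03,
juvenile 0.008, adult 0.002 per day (adult annual survival ≈ 0.48). Under
these rates one clutch yields on the order of 130 metamorphs and a handful of
adult recruits, which both matches field demography in order of magnitude and
keeps 3-year runs tractable. Eggs sharing a cell with tadpoles additionally
lose 50% per day to cannibalism/suppression. All rates are configuration
parameters.

Every day appends a row to a conservation ledger; the identity
stock(t) = stock(t-1) + inflows - outflows is asserted exactly, per
compartment, in the tests.

## Scenarios and the establishment criterion

A scenario is (PS, PN, entry point, introduction days). Designs are sampled
by Latin hypercube over PS 2-20, PN 1-3, the two sites, and first
introduction day 1-730 (two years, so the running windows below are fully
covered); each dimension keeps the Latin stratum property before
discretisation, and a maximin option keeps the best of ≥10 candidate
hypercubes by minimum pairwise distance. PS is read *per event* (the verbatim
reading of the source design); a `split_total` switch provides the
alternative reading. Later events are sampled uniformly after the first, the
spacing being unspecified in the source. Days are 1-based: day 1 is 1 January
of year 1.

Each replicate runs 3 years from first introduction or to extinction,
whichever is first, and scores establishment by the strict ratio rule
`final adults / total introduced > 1.0`. Batches derive per-replicate seeds
by hashing (base seed, combination, replicate), so any row can be replayed
bit-identically.

Each entry point lives on its own landscape (packed = site1,
fragmented = site2) so landscape effects are attributable to composition
rather than position within a shared map; the landscape generator accepts any
grid, so a combined map can be assembled if positional fidelity is wanted.

## The statistical layer

Establishment outcomes are modelled by maximum-likelihood binomial GLMs with
treatment contrasts (reference PN = 1, SE = site1): `EP~PS`, `EP~PS*PN` and
`EP~PS*PN*SE`. The dynamic analysis refits the chosen model on a 90-day
running window of first-introduction days advanced one day at a time: window
k covers days [k, k+89] for k = 1..365, indexed to its centre day of year
((k+44-1) mod 365)+1 -- window 1 is days 1-90, centred on day 45
(14 February). This is the only construction that yields both "365 models"
and "one per day of the year" over a two-year introduction span; windows
beyond day 454 are not wrapped by default (`wrap` pooling is deliberately
absent; the `n_windows` and `window` arguments expose the construction).
Windows with fewer than 30 rows, a single outcome class, complete separation
or non-convergence are carried with a degeneracy flag rather than fitted --
our policy, as the source is silent on degenerate windows.

Predictions use Wald intervals on the link scale back-transformed to
probability (closed-form testable, and the standard ribbon-plot practice;
profile intervals are out of scope). Two predictions can be compared by the
half-arm interval-overlap rule for approximate significance at p = 0.05, with
the exact half-overlap flagged borderline.

Model evaluation covers McFadden's R² (`1 - l/l0`), binned residual
diagnostics (rows sorted by fitted value into ~sqrt(n) near-equal bins with
±2 SE binomial bands), outcome-stratified seeded 10-fold cross-validation
reporting accuracy, precision, recall, F1 and rank-formulation (Mann-Whitney,
ties half) AUC at a 0.5 threshold, nested-model deviance ANOVA (chi-square
primary, an F on the Pearson dispersion of the larger model alongside), and
Tukey HSD on SE-by-PN group means of replicate outcomes. Stratification, the
threshold and the Tukey grouping are our choices where the source does not
state them. Per-window metrics compile into 365-day day-of-year time series.

## Synthetic outcome tables

`generate_outcomes()` draws design-like predictors and Bernoulli outcomes
from a known logistic truth with a seasonal intercept,
$A\cos(2\pi(\text{day}-\phi)/365)$ on the logit scale -- the simplest
structure consistent with smoothly time-varying establishment curves (a
PS-by-season interaction is available by setting the interaction
coefficients). It exists so that every statistical stage is testable without
simulation runs: coefficient recovery and ~95% Wald coverage over 200
replications, recovery of an injected sinusoid by the window-centre intercept
series (r > 0.9), and flatness when the amplitude is zero.

What passing these tests shows -- and does not show. The generator emulates
the *statistical* structure the GLM layer assumes (independent rows, logistic
link, intercept-only seasonality); it does not emulate within-replicate
trajectories, correlated predictors, or the simulator's demographic
stochasticity. Agreement on synthetic tables validates the machinery, not the
biology.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each claim is meaningful: geometry checks use the
full 15 x 30 km arena (cell counts are O(1)); simulation checks use 3-6 km
arenas that still hold the full-sized packed cluster and its waterbody;
the headline packed-landscape check uses 30 replicates of 3 years at PS = 20;
statistical checks use tables of 12,000-18,000 rows, the study-scale batch
size. Establishment-rate comparisons across PS use one-standard-error
tolerances. Replayability is exact: all stochastic stages take explicit
seeds, and omitting a seed at the command line is an error rather than a
silent default.

Known limitations: no energetics or body condition, no toxin or predator
interactions, no management actions, no evolution of dispersal traits
(population-of-origin is carried but inert), no real-GIS ingestion or
hydrological routing, and site-specific published percentages that depend on
the real island's map and rainfall are out of reach of the synthetic
landscapes by design.

## A worked run

```{r example, eval = FALSE}
land <- generate_landscape("packed", build_grid(5000, 5000, 10), seed = 1)
rain <- generate_rainfall(1500, seed = 2)
res <- run_scenario(scenario_params(20, 1, "site1", intro_days = 300),
                    land, rain, seed = 11)
res
#> <scenario_result> PS=20 PN=1 site1 day 300: ESTABLISHED (148 adults / 20 introduced)

tbl <- generate_outcomes(truth_params(), n = 18000, seed = 5)
evaluation_report(tbl)
ws <- evaluate_windows(running_window_fit(tbl, "EP~PS*PN*SE"))
head(compile_series(ws, "mcfadden"))
```
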