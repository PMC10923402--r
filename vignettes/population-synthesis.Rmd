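---
title: "Household co-generation by Gibbs sampling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Household co-generation by Gibbs sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The generative model

`gibbspop` treats a population as a two-level object: households carrying
(size, type, income class, car ownership, income) and ordered members
carrying (role, gender, age class, integer age, activity,
socio-professional category, education, income, overweight status). The
joint distribution is specified as a tree of conditional probability
tables:

* `P(size | zone)` — the household-size distribution of the IRIS;
* `P(type | size)`, restricted to size-compatible types (one person ⇔
  Single; two persons ⇒ couple or single parent; three or more ⇒ family or
  single parent);
* `P(gender | role, type)` for heads and children — the spouse's gender is
  the structural complement of the head's;
* `P(age class | type, role)`, `P(activity | age class)`,
  `P(SPC | age class, activity)`, `P(education | age class, SPC)` per
  member;
* `P(income class | type)` and `P(car | type, income class)` per
  household.

Integer age is uniform within the age class, truncated by the structural
rules. The rules — head at least 21 years old in multi-person households
with an absolute minimum of 18, roles fixed by position, spouse gender
complement, under-18s are schoolchildren with inactive SPC (level 8),
persons 65 and over default to retirement (SPC 7) unless employed, and a
minimum mother–child age difference — are enforced as hard masks on the
conditional supports, never by rejection after the fact. The mother–child
gap is 15 years by default; the constraint is named in the source material
without a printed value, and 15 is the smallest biologically plausible
round figure, kept configurable (`mother_child_gap`).

Activities are drawn *before* integer ages: within the class
`[15–35)` a non-student must be at least 18, so the feasible age interval
depends on the activity. Drawing in this order keeps
`P(activity | age class)` exactly equal to its table while guaranteeing
zero under-18 violations.

## Sampling: why Gibbs, and which Gibbs

A forward (ancestral) pass through the tree yields an exact draw when the
tables are the generative truth. The package nevertheless runs a Gibbs
sampler on each household because estimated tables are used in both
directions of the tree during conditioning-on-evidence scenarios and, more
practically, because the MCMC machinery is what scales to future extensions
where attributes acquire additional parents. Each sweep updates, in tree
order: the `(age class, integer age)` block of every member (the uniform
within-class age density cancels exactly when the pair is drawn jointly),
the `(activity, SPC)` block (single-site updates would deadlock on the
near-deterministic couplings retired ⇔ SPC 7 and student ⇔ SPC 8; blocking
marginalizes SPC out of the activity update), education, and the
household-level `(income class, car)` pair. Fixed attributes — roles,
genders, type, size — are never resampled.

Chains are initialized with an ancestral draw and then run for `burn_in`
sweeps (default 20), retaining the final state — one draw per household.
Starting at the target distribution makes burn-in a robustness margin
rather than a necessity, and reuses the one structural sampling code path
shared with the fixtures module; a deliberately mis-initialized chain is
exercised in the test suite, where 15 sweeps recover an enumerable
two-attribute joint within Monte-Carlo error.

One approximation is documented rather than removed: when the mother's
`(age class, age)` block is resampled, the update masks infeasible values
(she must remain at least `mother_child_gap` older than her eldest child)
but omits the child-interval normalization factor that an exactly detailed
balance would require. The factor differs from 1 only when the gap
constraint binds; the fixture ground truth keeps heads and spouses of
multi-person households in the 35+ classes and children in the two
youngest classes, so the binding region is rare, and the constraint itself
is audited exhaustively (`check_population()`), not sampled.

## Integerizing household counts

A zone of `N` individuals receives counts `h_1..h_6` with
`Σ_s s·h_s = N` whenever such a combination of positively weighted sizes
exists, otherwise the nearest achievable total with undershoot preferred.
Among exact solutions the counts minimize `Σ_s |h_s − E_s|`, where
`E_s = N·p_s / Σ_s' s'·p_s'`, with ties broken to the lexicographically
smallest vector. The optimizer floors the expectation and repairs the
residual with a bounded dynamic program over the supported sizes; a
brute-force enumeration oracle in the test suite confirms exact optimality
and the tie-break on small populations.

## Income, health, housing

Income is `α(SPC) × commune median`, `α = r_SPC / r`, times a
median-preserving lognormal factor `exp(N(0, σ))` with `σ = 0.25` by
default. The weighting scheme alone would give every individual of the
same SPC in the same commune an identical income; the dispersion restores
infra-communal variability while leaving the commune median untouched
(median, not mean, preservation — the income model is median-based
throughout). Setting `dispersion_sigma = 0` restores the deterministic
weighting for exact-reproduction checks. Floors (2010 values): employed
12,672 EUR/year (minimum wage), non-working aged 25+ 5,520 EUR/year
(Active Solidarity Income). Minors and students under 25 receive 0;
non-working 18–24-year-olds are deliberately not floored. Household income
is the plain sum of member incomes; whether minors' transfers should count
is unresolved in the source material, and the sum (with minors at 0) is the
simplest defensible rule.

Overweight/obesity (0 normal / 1 overweight / 2 obese) is drawn
independently per individual from the contingency cell of the (gender, age
class, SPC) subgroup, falling back to the (gender, age class) margin and
then the overall margin for strata absent from the table (e.g. children
when only adult survey data are supplied).

Buildings become housing through three parameterized rules. A 3 m storey
height converts building height to floors (no storey model is given in the
source material; 3 m is the conventional residential figure). A
residential building is a *house* when it has at most 2 floors and a
footprint under 250 m² — these two thresholds stand in for an unpublished
classifier and are configurable. Dwelling counts divide total floor
surface by the zone-class average dwelling size (59 / 69 / 89 m² for
center / inner / outer), rounding half-up with a minimum of one; recorded
counts always pass through untouched. Price classes are per-commune
tertiles of price per m² (department tertiles below three priced
buildings); boundary values go to the lower class, and an all-equal
commune collapses to the intermediate class — both rules are arbitrary but
deterministic, which matters more here than their direction.

Allocation matches per-IRIS income tertiles to the three price classes.
The source material mixes vocabularies (an "upper decile" in its worked
example against three dwelling classes); tertiles align the household and
dwelling partitions so that the balanced case matches perfectly, and the
stratum edges are configurable. Allocation order is high, intermediate,
low; within a stratum households are shuffled by the zone's substream and
draw uniformly among free dwellings of the matching class, spilling to the
nearest class (high→intermediate→low, low→intermediate→high,
intermediate→high then low) on saturation. One household per dwelling.

## Estimation and sparse cells

Conditional tables are empirical frequency tables. The original
methodology chain cites discrete-choice models for constructing
conditionals, but no covariate specification is published; empirical
tables keep the data in charge and make parameter recovery checkable. Each
conditioning cell is estimated at the finest spatial level of the zone's
ancestor chain (IRIS → commune → canton/department → region) with at least
`min_count` observations — 10 by default, small enough to stay
fine-grained at desk scales, large enough to bound cell variance. A cell
below the floor even at region level is a hard estimation error naming the
cell: silent smoothing would mask data problems. Target categories with a
regional relative frequency under 0.5% are merged into the variable's
designated "other" category (activity → "other unemployed", SPC → 8);
variables without a semantically safe sink are never merged.

## What the fixtures emulate — and what they do not

The fixtures module generates all five inputs a real application would
read: individual microdata, a four-level zone tree (1 region, 2
departments, 4 communes, 8 IRIS), a building table (log-uniform footprints
in [50, 2000] m², uniform heights in [3, 30] m, both chosen to exercise the
house and block branches), per-SPC and per-commune median incomes, and an
overweight contingency. The ground-truth conditional tables are Dirichlet
draws with structurally determined cells fixed (students under 15,
retirement at 65+, SPC 7/8 couplings, spouse-gender complement) and two
deliberate support choices: every positive cell is floored at 2%
probability, and adults of multi-person households sit in the 35+ age
classes with children in the two youngest and late-career workers in
mid/upper occupational categories. Both choices serve estimability and
clean recovery: no generative cell is so rare that its empirical estimate
becomes unstable at desk scale, and the structural truncation rules almost
never bind during sampling, which turns conditional-table recovery into a
plain binomial sampling problem.

What passing the fixture suite demonstrates: the estimator recovers known
tables at the expected `n^(−1/2)` rate, the sampler reproduces the joint it
was given, constraints hold exhaustively, conservation is exact, and the
full pipeline is deterministic in its seed. What it does not demonstrate:
robustness to measurement error, spatially heterogeneous conditionals
(fixture tables are spatially homogeneous; only the size distribution
varies by IRIS), real French geography, or the behaviour of the
house/block classifier against actual land registries. Headline statistics
of any real region are inputs, not targets, of this package.

## Numerical conventions

* Probability vectors must sum to 1 within 1e-9 (constructor-enforced).
* Age bins are lower-inclusive, upper-exclusive, with 120 included in the
  last class — the printed interval notation is ambiguous at shared
  endpoints, so the convention is fixed here once.
* Rounding of dwelling counts is half-up (`floor(x + 0.5)`), not banker's.
* All randomness flows from one master seed; per-zone and per-stage
  substreams are derived by hashing tags with a 31-bit polynomial hash, so
  zone processing order cannot change results and adding a stage does not
  perturb the draws of the others.
* Degenerate inputs have defined outcomes: zero-population zones yield
  zero households; empty zones stratify to an empty result; all-equal
  prices or incomes collapse to the intermediate class; an infeasible
  age interval is an error that triggers a class re-draw.

## Problem sizes used by the shipped checks

The test suite runs the full pipeline at 2,500 and 10,000 households and
the parameter-recovery study at 50,000 households (about 130,000
individuals), sizes at which every tracked conditional cell holds well over
100 observations and recovery at 3 binomial standard errors is a sharp
test; the whole suite completes in well under five minutes on one CPU.

## Known limitations

* Conditionals beyond the size distribution are estimated pooled at
  regional level in the default pipeline; per-zone estimation with
  fallback is available (`estimate_conditional(..., given = c("zone", ...))`)
  but multiplies cell counts.
* The mother-update approximation above biases mothers' within-class ages
  upward in the rare configurations where the gap constraint binds.
* Income dispersion is homoskedastic on the log scale across SPCs and
  communes; real income spread varies by category.
* The overweight module transposes a national contingency to the
  population without temporal or regional adjustment, exactly as the
  upstream methodology does; treat small-area prevalence with caution.
* One household per dwelling; vacancy, second homes and multi-household
  dwellings are out of scope.
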