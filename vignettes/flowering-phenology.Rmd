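---
title: "Methods: flowering descriptors, Newstrom classes and the inference stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flowering descriptors, Newstrom classes and the inference stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floracal)
```

## The data model

The unit of analysis is the *floral calendar*: for one population (an
accession at a site in one flowering semester), a dense plants × weeks grid
of flower-bud counts at preanthesis. Two normalization rules are applied
before anything is computed, and both matter for the descriptors:

1. **weeks without buds are zeros**, not missing values — the zero weeks
   carry the temporal structure that the synchrony and CV descriptors
   measure;
2. **individuals that never flowered in the semester are excluded**
   (`drop_nonflowering()`): a flat-zero series has no rank structure and no
   defined CV, and retaining it would contaminate both descriptors. The
   number of removed plants is kept on the calendar and reported.

Weeks are 1-based indices within a semester; calendar dates are not
modelled. A semester defaults to 26 weeks (a six-month November–April or
May–October window); the value is configurable everywhere it appears
because census protocols differ by a week or two at the margins. Semesters
1st/3rd belong to flowering period FP I and 2nd/4th to FP II, and plants
may be present in one semester and absent in another — each calendar is
analyzed with the plants it has, with no imputation across semesters.

## The three descriptors

**Synchrony** `r_i` is the mean of the *absolute values* of all pairwise
Spearman correlations between plants' weekly series. Mid-ranks are used
for ties (the standard convention — ties are pervasive because of the zero
weeks), and no p-value is attached; `r_i` is a descriptor, not a test. Two
choices here were genuinely open:

- *Absolute value per pair, before averaging.* Synchrony is meant to
  measure shared temporal structure; a perfectly anti-phased pair is
  maximally structured. Averaging signed correlations would let opposing
  pairs cancel.
- *Undefined pairs are dropped and counted.* A pair involving a
  constant-count plant has no defined rank correlation. Substituting 0
  (or 1) would bias `r_i` by an arbitrary amount, so such pairs are
  excluded from the mean and reported via `n_pairs_used` /
  `n_pairs_dropped` (which always sum to `n(n-1)/2`). After the exclusion
  of non-flowering plants these pairs are rare — they require a plant with
  identical positive counts every week.

**Temporal variability** `CV_i` averages each plant's coefficient of
variation over the semester's weeks. The sample standard deviation
(denominator `n − 1`) is the default; the population convention is exposed
as a switch (`denominator = "n"`) because the descriptor literature is not
unanimous and the two differ by the constant factor `sqrt((n-1)/n)`.
Under the sample convention a single flowering week among `n` gives
`CV = sqrt(n)` — a useful closed-form anchor (`sqrt(26) ≈ 5.1` for a
26-week semester) for what "very high variability" means.

**Events** counts the weeks in which the population total is positive. It
is monotone under adding buds and deliberately ignores amplitude: it
measures how often the population flowers, not how much.

## Newstrom classes

The Newstrom taxonomy (continual, sub-annual, annual, supra-annual) is
defined qualitatively in the literature; applying it to weekly count
series requires numeric thresholds, which this package makes explicit and
reports alongside every label:

- a *cycle* is a run of flowering weeks in which interior pauses are
  shorter than `cycle_gap = 8` weeks (two months of silence separates
  cycles);
- *continual* requires flowering in ≥ 80% of months with no pause longer
  than `gap_weeks = 4`, and takes precedence over the cycle-count rules;
- one cycle per year on average is *annual*; more is *sub-annual*; a
  single cycle spanning more than a year is *supra-annual*;
- months are consecutive 4-week blocks, since the data model has week
  indices rather than dates; a 52-week year therefore has 13 "months",
  an approximation that is immaterial for the 80% coverage rule.

These defaults are this package's operationalization, not values taken
from the descriptive literature; all are arguments of
`classify_newstrom()`, and the returned evidence (cycles per year, longest
pause, month coverage) lets a user audit any label.

## The inference stage

The descriptor table is analyzed with fixed-effects linear models and
**Type-II sums of squares**: each term's SS is the residual-SS drop when
the term joins the model containing all terms that do not contain it.
Type II is invariant to factor-level ordering, coincides with sequential
SS on balanced data, and does not condition a main effect on an
interaction containing it — the conventional choice for unbalanced
observational factorials like these censuses (plant survival makes cell
sizes unequal). The implementation delegates the linear algebra to
`stats::lm()` + `car::Anova()`; the test suite verifies it against an
explicit full/reduced model-comparison oracle.

The workflow is two-step: a three-factor screen (site, semester,
accession, two-way interactions) to ask whether accession carries any
signal, then the two-factor site × semester model for each descriptor. The
step of dropping accession is left to the analyst — automating model
selection would hide a decision the analysis should surface. A significant
interaction is decomposed by (a) simple effects of site within each
semester, Bonferroni-adjusted over the number of strata, and (b) all
pairwise site comparisons per semester with pooled-variance t tests,
Bonferroni-adjusted over the full family of pairs × strata. The family
definitions are a judgement call (the workflow description in the
literature does not pin down the family size); both are reported as `m` on
every row so the adjustment is auditable. Pooled variance is the default
because Levene's check precedes the comparisons; Welch is a switch.

α = 0.005 is the default significance threshold — deliberately
conservative because several responses are modelled separately — while
assumption checks (Shapiro–Wilk on residuals, Levene across cells) use the
conventional 0.05 and only annotate, never gate: a failed normality check
on descriptor data is information for the reader, not a reason to silently
switch methods. Levene defaults to the median-centred (Brown–Forsythe)
variant for robustness, with the mean-centred classical form available.
`Event`, an integer count with strong floor/ceiling effects, is summarized
by medians only and never modelled.

When a design has empty cells — an annual site simply has no FP II
descriptors — the interaction is inestimable and `fit_aov()` raises an
explicit error naming the aliased coefficients rather than silently
dropping terms; `run_pipeline()` records this per response and continues
with the stages that remain defined.

## The calendar generator

The generator is phenomenological: it reproduces the statistical shape of
censused bud series — a few to many population-level events, partial
participation, slight timing disagreement between plants, heavy-tailed
amplitudes, many zero weeks — without any climate mechanism. For plant `i`
and event `e` at scheduled week `w_e`:

- participation: Bernoulli(π) per plant per event;
- timing: week `w_e` + round(Normal(0, σ_j)), clamped to the semester
  (semesters do not wrap);
- count: `round(s_i · m_e · ε)` with `s_i ~ LogNormal(0, σ_plant)` fixed
  per plant, `m_e ~ LogNormal(μ_amp, σ_amp)` shared across plants, and
  `ε ~ LogNormal(0, 0.1)` noise (settable to 0, which makes every plant an
  exact positive multiple of a shared profile and hence `r_i = 1` — the
  generator's own consistency anchor). Collisions of jittered events on a
  week are summed; rounding is half away from zero.

Lognormal amplitudes with Bernoulli participation were chosen because they
produce the spiky, zero-heavy series that yield empirical `CV_i` well
above 1 at realistic parameter values; a Poisson-type count model would
not. The presets encode the two observed regimes: `annual-north` (two
tightly synchronized, high-amplitude events, active in FP I only),
`continual-central` (fifteen events covering the semester, moderate
jitter) and `continual-south` (seven events, low jitter). Preset
parameters are fixed choices of the package, stated here once: they were
set to the event counts reported for the respective zones and to
participation/jitter/amplitude values that a field census of 5–20 plants
per accession would plausibly produce, and they are not tuned per
analysis.

What the generator does **not** emulate: rainfall- or insolation-driven
event timing (event schedules are fixed, not weather-conditioned),
within-semester trends in amplitude, plant mortality during a semester,
branch-level structure, or between-accession genetic differences (all
accessions share their department's regime unless effects are injected).
Passing tests on simulated data therefore demonstrate that the
*computational pipeline* is correct and well-calibrated, and that the
descriptors separate regimes of this shape — not that any particular field
population follows this generative model.

All randomness flows through explicit seeds (`withr::with_seed`), so the
global RNG state is never consumed or disturbed, and every simulated
object is bit-reproducible from (parameters, seed).

## Numerical choices

- **Rounding** of published-precision climate means is half away from
  zero: several of the built-in fixture's summary values end in `.5` at
  the printed precision and are only consistent with that convention.
  (Base R's `round()` rounds half to even.) A small epsilon guards against
  binary-representation artefacts of the form `28.35 → 28.349999…`.
- **Spearman ties** use mid-ranks; equality checks in tests are at 1e-12
  against explicit-sum oracles.
- **Flowering-period shares** are computed as `p` and `1 − p` so the two
  always sum to exactly 1 in floating point.
- Jittered event weeks are clamped, not wrapped; integer counts are
  enforced at calendar construction.

## Problem sizes

The shipped checks use: a 300-calendar random battery of small grids
(≤ 4 plants, ≤ 6 weeks, counts 0–3) for the descriptor-oracle equivalence;
20,000 Monte-Carlo replicates of a balanced 2 × 2 (n = 3 per cell) null
for the calibration of the interaction test at α = 0.005 (acceptance band
± 3 standard errors); 200 seeded replicates of 15-plant, 26-week calendars
for the annual/continual descriptor ordering; and a 50-seed battery for
Newstrom classification of two-year simulated series. These sizes give
Monte-Carlo standard errors comfortably below the effects being checked.

## Known limitations

- The Newstrom thresholds are operational defaults, not community
  standards; labels near a threshold (e.g. month coverage ≈ 0.8) should be
  read together with the reported evidence columns.
- `r_i` with few plants (5 or fewer) averages over ≤ 10 pairs and is
  noisy; the descriptor table reports `n_plants` and pair counts so users
  can weight or filter.
- The inference stage is fixed-effects only; no variance components,
  blocking terms or effect sizes are fitted.
- Descriptors are bounded (`r_i ∈ [0,1]`, `Event ≤ n_weeks`), so residual
  normality is an approximation that degrades near the bounds — which is
  exactly what the Shapiro–Wilk annotation is for.
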