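---
title: "Kano needs analysis: model, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kano needs analysis: model, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanor)
```

## The model

The Kano model treats each candidate feature of a product or service as a
*need* whose relationship to user satisfaction is asymmetric. Each
respondent answers two five-point Likert questions per item — a functional
form ("if this feature was available, how would you feel?") and a
dysfunctional form ("if it was not available?") — coded
1 = like, 2 = must-be, 3 = neutral, 4 = live-with, 5 = dislike. The pair is
mapped through the standard 5 × 5 evaluation table to one of six categories:

```{r}
kano_evaluation_table()
```

The table's logic: liking the presence while disliking the absence is
**one-dimensional** (O, satisfaction scales with fulfilment); liking the
presence while tolerating the absence is **attractive** (A, a delighter);
tolerating the presence while disliking the absence is **must-be** (M, taken
for granted); the central block is **indifferent** (I); preferring absence
is **reverse** (R); the two self-contradictory diagonal corners are
**questionable** (Q). Over the 25 cells the multiset is I:9, R:7, A:3, M:3,
Q:2, O:1.

An item's final attribute is the *modal* category over its respondents.
From the per-item counts, two coefficients summarise each need:

$$\mathrm{SI} = \frac{A + O}{A + O + M + I}, \qquad
  \mathrm{DSI} = -\,\frac{O + M}{A + O + M + I}.$$

R and Q responses are counted in the item's frequency row (every respondent
with a complete valid pair appears there) but excluded from the index
denominators: they carry no information about the satisfaction/importance
trade-off. SI near 1 means fulfilment raises satisfaction strongly; DSI near
−1 means absence hurts strongly, i.e. the item is important.

Each item is placed at $(|\mathrm{DSI}|, \mathrm{SI})$ and the plane is
split at the origin $(\bar{|\mathrm{DSI}|}, \bar{\mathrm{SI}})$ — the
per-axis mean over the analysed items — into four strategy quadrants:
I predominance, II improving, III secondary improving, IV reserving.

### Assumptions

* The Likert coding direction is fixed (1 = like … 5 = dislike). Data
  collected on a reversed or permuted scale must be remapped through the
  codebook's `likert_mapping`; the core never guesses.
* Respondents are exchangeable and items are analysed marginally; no
  respondent-level latent trait links items.
* The modal rule assumes the mode is meaningful — with very flat category
  distributions the attribute is unstable, which `is_tie` partially flags.

## Conventions and numerical choices

Several points are left open by the usual presentations of the method; the
package fixes them as follows.

**Tie-break precedence M > O > A > I > R > Q.** When two categories share
the maximal count, the one with larger dissatisfaction impact wins — the
conservative convention in the Kano literature (treating a need as must-be
when in doubt costs over-delivery; the reverse error costs user defection).
The precedence is a `kano()` argument, and ties are surfaced via `is_tie`
and an asterisk in `summary()` output.

**Horizontal axis is |DSI|.** DSI is negative by construction, but the
matrix reasons in magnitudes (closer to −1 means more important), so the
origin comparison uses |DSI| against the mean of |DSI|. In the bundled
nurse-demand analysis this convention, with the per-axis mean origin, is the
unique simple rule that reproduces all four originally reported quadrant
memberships. Note that the original report prints the two origin means with
their labels interchanged (satisfaction 0.43, importance 0.49);
recomputation from its own per-item table gives mean SI ≈ 0.489 and mean
|DSI| ≈ 0.429, and only this assignment reproduces the reported memberships.
The package reports the recomputed values.

**Boundary ties go high.** An item exactly on a threshold is assigned to the
higher-importance / higher-satisfaction side (`>=`), so a point at the
origin is in quadrant I. In the bundled data two items sit essentially on
the published boundaries and this convention reproduces both placements.

**Full precision first, display rounding last.** Indices and the origin are
computed at full precision; rounding (half away from zero, 2 decimals — the
convention of typeset survey tables, hence `round_half_up()` rather than
`round()`) happens only in display methods and explicit calls. On the
bundled data the full-precision and 2-dp paths give identical memberships;
both are tested. Report writers emit full precision so a re-read report
reproduces identical downstream results.

**Degenerate inputs** fail loudly: items with zero valid pairs, frequency
rows with `A+O+M+I = 0`, constant-total score matrices (alpha), and two
constant identical coders (kappa) all raise errors rather than returning
NaN. Incomplete pairs are dropped per item, not per respondent, maximising
usable data.

**Screening order.** Logic-error exclusions are applied before the
completion-time filter (default threshold 180 s), so the two reported
tallies are disjoint and `valid = received − logic − time` always holds.
A caveat on the survey behind the bundled table: its reported tallies
(1,723 received, 68 logic, 83 time, 1,571 valid, 91.18%) are mutually
inconsistent by one respondent — 1,723 − 68 − 83 = 1,572, while 91.18% is
exactly 1,571/1,723, so the exclusions must in fact sum to 152. The package
keeps the conservation identity; the test suite documents the discrepancy
rather than silently absorbing it.

**Sample-size planning** follows the 5–10 × variables rule with a
non-response inflation factor (default 1.2, i.e. 20% anticipated
non-response); fractional products round up, since a plan cannot include a
fractional respondent.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `min_seconds` | `screen_respondents()`, `kano()` | 180 s | the common 3-minute floor below which a 52-question instrument cannot be answered attentively |
| `tie_precedence` | `kano()`, `modal_category()` | M, O, A, I, R, Q | conservative dissatisfaction-first convention (above) |
| `origin` | `kano()` | per-axis mean of the fitted items | the standard centroid split; fix it explicitly to compare waves on a common origin |
| `purity` | `kano_profile()` | 1 | fraction of response mass on the target category |
| `time_meanlog`, `time_sdlog` | `simulate_kano_survey()` | log(420), 0.5 | median 7 min, right-skewed, for a 52-question web survey with a 20-min platform limit; puts ~4.5% below the 3-min screen |
| `logic_error_rate` | `simulate_kano_survey()` | 0 | contamination is opt-in |
| `threshold` | `cohens_kappa()` | 0.80 | the customary "substantial agreement" target in instrument development |

## What the synthetic generator does and does not emulate

`simulate_kano_survey()` draws each respondent × item answer pair i.i.d.
from that item's distribution over the 25 answer cells. Profiles come from
three sources: explicit 5 × 5 weight matrices; the `target` + `purity`
shorthand (mass `purity` spread uniformly over the target category's cells,
the remainder uniformly over all other cells — the maximum-entropy default);
or `profile_from_frequencies()`, which converts an observed frequency row
into a profile by spreading each category's observed share uniformly over
its cells. Completion times are lognormal and logic-error flags Bernoulli,
independent of the answers. Given a `seed`, output is byte-for-byte
reproducible and the caller's RNG state is untouched.

This emulates: arbitrary target category mixtures, contamination rates and
sample sizes; screening behaviour; and the sampling noise of frequency
tables, so classification recovery and index convergence can be quantified.

It does **not** emulate: correlation between items within a respondent
(no latent trait), demographic structure, within-category cell skew
(uniform spread is assumed), answer-order or fatigue effects, or any
dependence of completion time and logic errors on the answers. Passing
tests therefore demonstrate correctness of the pipeline and its sampling
behaviour under independence — not robustness to the response styles of
real survey populations.

## Problem sizes used in the test suite

The suite exercises the stochastic guarantees at sizes chosen to make
sampling error negligible relative to the asserted tolerances: empirical
cell frequencies within 0.01 at n = 100,000 draws; SI/DSI convergence
within 0.02 at n = 50,000; modal-category recovery in at least 99% of 500
replicates at n = 200 respondents for purity-0.6 profiles; alpha of
independent noise within 0.05 at 10,000 × 3. The end-to-end checks run on
the bundled 26-item, 1,571-respondent aggregate table, which is exact and
instantaneous.

## Known limitations

* Only the classical discrete evaluation-table method is implemented — no
  3-level dialects, continuous ("analytical") Kano variants, or
  significance tests for category assignment (e.g. Fong's test).
* Cronbach's alpha and unweighted Cohen's kappa only; no McDonald's omega,
  ICC, weighted kappa, factor analysis or IRT.
* The quadrant split is a descriptive centroid partition; items near the
  origin can change quadrant under resampling. Use `simulate()` on a fitted
  object to bootstrap that stability.
* "Obvious logical error" is accepted as a caller-supplied flag; the
  package deliberately does not define one.
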