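---
title: "A Markov cohort model for the cost-effectiveness of whole-breast radiotherapy techniques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-effectiveness of whole-breast radiotherapy techniques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wbrtcea` implements a Markov cohort state-transition model comparing seven
ways of delivering whole-breast radiotherapy (WBRT) after lumpectomy for
early-stage breast cancer: conventional tangential fields (the standard of
care, SOC), field-in-field (FIF), hybrid IMRT, full IMRT, and three
volumetric-modulated arc therapy variants (standard, non-coplanar, and
multiple-arc VMAT). The advanced techniques cost more up front but irradiate
the heart, the contralateral breast and the lungs differently, changing the
long-term risk of radiogenic side effects. The model weighs those risks and
their treatment costs against the upfront price difference, from a payer
perspective, in cost per quality-adjusted life year (QALY).

This vignette documents the model itself: its states and conventions, the
places where the published input tables under-determine the model and the
choices this package makes there, the sensitivity-analysis machinery, and
what the bundled synthetic-model generator does and does not emulate.

## Cohort, states and cycles

The cohort is 65-year-old women starting in the *no evidence of disease*
(NED) state immediately after WBRT (50 Gy in 25 fractions). Time advances in
one-year cycles over a 15-year horizon. The states are:

* **NED** — post-treatment, disease-free;
* **LocalRecurrence** — in-breast recurrence (one-time treatment cost,
  reduced utility);
* **Metastasis** — distant disease (one-time cost, low utility, high
  breast-cancer mortality);
* **Cardiac**, **CLBreast**, **Lung** — radiogenic side-effect states
  (major coronary event, contralateral breast cancer, secondary lung
  cancer), each with a one-time episode treatment cost, its own utility,
  and its own late excess mortality;
* **Death_BC**, **Death_Tox**, **Death_Other** — absorbing death states
  split by cause, so that 15-year overall survival and breast-cancer
  mortality can be read directly off the final occupancy vector.

Printed year brackets `0–5 / 6–10 / 11–15` map onto cycles `[0,5) / [5,10) /
[10,15)`: cycle *t* is treatment year *t*+1. Background (other-cause)
mortality is age-banded; a cycle is classified by the age attained at its
end (65 + *t* + 1), which maps the 65–70 / 71–75 / 76–80 bands exactly onto
the same three cycle blocks with no extrapolation.

Side-effect onset is gated: contralateral-breast events can start in year 6
(`earliest_entry_cycle = 5`), cardiac and lung events in year 11
(`earliest_entry_cycle = 10`). The side-effect states are mutually exclusive
and — apart from their death transitions — absorbing: the model carries no
multi-morbidity transitions because the input tables provide none.

Two structural switches are exposed in `model_config()` because the source
material under-determines them:

* `recurrence_progresses` (default `TRUE`): local-recurrence occupants keep
  facing the distant-metastasis schedule.
* `recurrence_bc_death` (default `TRUE`): local-recurrence occupants also
  face the breast-cancer death schedule directly. Breast-cancer death in
  this population is described as *mainly* — not exclusively — driven by
  distant metastasis, and without this arrow no reading of the probability
  tables comes close to the benchmark 15-year breast-cancer mortality of
  21.7% (the best achievable is roughly 16.5%, against 20–21% with it).

## Annual versus period-cumulative probabilities

The transition-probability table labels its entries "annual", but taking the
NED-to-metastasis row (12.25% per year for five years) literally yields
breast-cancer mortality far above, and survival far below, the published
validation outputs. Each `transition()` therefore carries an explicit
`interpretation` flag; `period_cumulative` values are converted to a
constant annual probability over a piece of length *L* years as

$$p_a = 1 - (1 - P)^{1/L}.$$

Four rows are genuinely ambiguous: local recurrence, metastasis,
recurrence-to-metastasis progression, and the breast-cancer death row.
`calibrate_interpretation()` enumerates all $2^4 = 16$ assignments, runs the
SOC cohort under each, and scores the (cost, QALY, overall survival,
breast-cancer mortality) quadruple against the bundled external benchmarks
by normalized L2 distance. The winner — recurrence *annual*, metastasis
*period-cumulative*, progression *period-cumulative*, breast-cancer death
*annual* — is the shipped default, and the whole score table is returned so
the choice is auditable:

```{r, eval = FALSE}
library(wbrtcea)
cal <- calibrate_interpretation(wbrt_fixture("SOC"))
cal$best
head(cal$table[order(cal$table$score), ])
```

## Rewards, discounting and costs

Cycle-*t* rewards accrue on the post-transition occupancy and are discounted
at 3% per year with factor $(1+r)^{-(t+1)}$; a 15-cycle model with constant
utility $u$ and no exits therefore yields exactly
$u \sum_{t=1}^{15} 1.03^{-t} = 11.938\,u$ QALYs, which the test suite pins
down. `reward_timing = "start"` and `half_cycle_correction = TRUE` implement
the two alternative conventions; the defaults are the simplest convention
consistent with the benchmark totals, and nothing in the source material
indicates a half-cycle correction was applied.

Costs follow these conventions:

* the technique's upfront treatment charge is added undiscounted at cycle 0;
* recurrence, metastasis and side-effect treatment costs are **episode**
  costs, charged once on state entry and discounted with the cycle's factor.
  Charging them per cycle of occupancy instead grossly overshoots the
  benchmark SOC total (every state here is occupied for years);
* death states carry no cost and utility zero.

All costs are nominal USD with no inflation adjustment or currency-year
conversion; the perspective is payer-only.

## Competing risks and degenerate rows

Each row's stay probability is the residual $1 - \sum \text{exits}$. Under
extreme sensitivity draws a row's exits can sum above one; the engine then
rescales that row's exits proportionally and counts the event (reported as
the `rescaled_rows` attribute / trace field). Death rows are identity rows,
occupancy is conserved to $10^{-10}$ per cycle, and death-state occupancy is
non-decreasing — all property-tested on randomly generated models.

## Sensitivity analysis

The varied parameters are exactly the side-effect inputs: the three annual
onset probabilities (technique-specific, with published ranges), the three
side-effect utilities (published ranges), and the three episode costs
(published mean ± SD). Disease progression schedules, baseline utilities and
the treatment charges themselves stay fixed.

**Distributions.** Probabilities and utilities use beta distributions,
matched by method of moments with mean at the base value and, by default,
`sd = (high − low)/3.92` (the range read as a 95% interval;
`beta_range_semantics = "minmax"` divides by 4 instead, and is also the
automatic fallback when the implied shapes are non-positive). Costs use
gamma distributions with `shape = (mean/sd)^2`, `scale = sd^2/mean`, exact
in both moments. Cost parameters printed without an SD get a point mass, and
one-way analysis ranges for costs default to mean ± 1 SD. A degenerate
published range (the IMRT contralateral-breast row prints `0.71–0.71`
around a base of `0.32`) is treated as a misprint: the fixture substitutes
the hybrid-IMRT-like asymmetric spread `(0.12, 0.71)` and records the
substitution in `spec$meta`, because a zero-width range would silently
remove that parameter from every sensitivity analysis.

**Tornado.** `tornado()` sets one parameter at a time to its low and high
bound — in both arms for the shared utilities and costs, in the owning arm
only for the onset probabilities — recomputes the pairwise ICER, and sorts
by the swing $|\mathrm{ICER}_{high} - \mathrm{ICER}_{low}|$. Note a genuine
pathology of ICER-scale tornados on this model: comparisons whose baseline
QALY difference is very small can have the ICER pass through a pole
(ΔE = 0) inside a parameter's range, producing arbitrarily large endpoint
values; the swing ranking is then driven by pole proximity rather than by a
smooth response. The CSV export keeps both endpoint ICERs so such entries
are recognizable.

**PSA.** `run_psa()` draws, per iteration, one shared set of utility and
cost values plus each technique's own onset probabilities, evaluates every
strategy on that joint draw, and returns per-iteration (cost, QALY) pairs.
Sharing the utility/cost draws across arms is essential: independent cost
noise would otherwise swamp the small QALY differences between techniques.
Each (iteration, parameter) pair has its own deterministically derived seed,
so runs are bit-reproducible and adding a strategy or parameter does not
perturb the other draws. `ceac()` then computes, per willingness-to-pay
threshold λ, the fraction of iterations in which the comparator has the
higher net monetary benefit $\mathrm{NMB} = \lambda E - C$ (exact ties count
one half, making pairwise probabilities complementary).

## Synthetic model generator

`generate_model()` emulates the *structure* of the bundled model — a layered
chain of transient states with forward-only transitions plus death sinks,
piecewise-constant schedules, utilities in (0, 1), positive costs with
plausible SDs — so that the engine's invariants (row-stochasticity,
occupancy conservation, cohort/microsimulation agreement, the annuity limit)
can be property-tested on hundreds of models unrelated to the fixture. It
does **not** emulate real epidemiology: no calibration to data, no
covariates, no competing-risk realism beyond the row constraint, and its
transition values are uniform draws, not clinically meaningful rates.
Passing those tests therefore demonstrates numerical correctness of the
engine, not clinical validity of any generated model.

## Verification against the published benchmarks

`wbrt_benchmarks()` bundles the published reference values, and the test
suite recomputes the model's counterparts at fixed problem sizes (the full
baseline takes well under a second; the PSA checks use 10,000 iterations;
the microsimulation cross-checks use 4,000–40,000 patients):

* SOC totals land within the stated tolerances (±5% on cost, ±0.10 QALY),
  and 15-year overall survival / breast-cancer mortality within ±2
  percentage points of 53.3% / 21.7%.
* The per-technique QALY *differences*, and hence the ICERs and most PSA
  acceptability probabilities, are **not** reproducible from the published
  inputs, and the corresponding assertions are expected to fail. The
  benchmark table is internally inconsistent (IMRT has uniformly lower
  side-effect probabilities than hybrid IMRT yet a lower printed QALY), and
  its QALY gains of 0.03–0.05 per technique would require roughly 6 QALYs
  per avoided side-effect event, whereas even instant death at onset caps
  the loss near 2.5 discounted QALYs. This package reports what the printed
  inputs actually imply (QALY differences of 0.0005–0.006) rather than
  forcing agreement.

## Known limitations

* No tunnel states: time-since-event dynamics (for example metastasis
  mortality falling with survivorship) are approximated by calendar-time
  schedules.
* No individual-level heterogeneity except in the microsimulation oracle,
  which exists for verification, not inference.
* PSA correlation structure is the shared-draw rule described above; no
  copulas or rank correlations.
* No expected-value-of-perfect-information analysis, and no plotting beyond
  CSV exports of the tornado, PSA and CEAC data.
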