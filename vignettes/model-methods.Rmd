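---
title: "Model and methods: MRI-based presymptomatic screening for ASD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: MRI-based presymptomatic screening for ASD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdscreen)
```

## The question the model answers

Younger biological siblings of children diagnosed with autism spectrum
disorder (ASD) carry a substantially elevated risk of an ASD diagnosis
themselves, and structural/functional MRI in the first year of life can
predict a later diagnosis with reasonable accuracy — before behavioural
symptoms allow a clinical diagnosis. Early intensive behavioural
intervention (EIBI), when started before age 4, raises IQ and thereby
lowers the risk that ASD is accompanied by intellectual disability (ID),
the comorbidity that dominates lifetime costs, quality of life and
mortality. The economic question is whether buying earlier treatment
assignment with an MRI scan is worth it, and compared to what.

`asdscreen` evaluates four strategies for a birth cohort of high-risk
infant siblings:

* **status quo** — a child with ASD receives EIBI before age 4 with
  probability `p_early_intervention` (0.62), i.e. only when symptoms lead
  to timely identification;
* **test & treat at 6 months** — MRI screen (sensitivity 0.82,
  specificity 1.00); screen-positives receive EIBI, screen-negatives are
  monitored exactly as under the status quo;
* **test & treat at 12 months** — as above with sensitivity 0.88 and
  specificity 0.95;
* **treat all** — every high-risk child receives EIBI, no screening.

## Structure: a decision tree feeding a two-state Markov model

**Decision tree (birth to age 6).** Chance nodes split the cohort by ASD
status (prevalence 0.15), screening result (sensitivity/specificity), and
EIBI receipt. EIBI multiplies the ID risk of a child with ASD by
`rr_id_with_ei` (0.61) relative to the untreated risk `p_id_without_ei`
(0.37). False positives receive treatment and incur its cost but no other
effect; false negatives fall back to the status-quo EIBI probability. The
tree folds into a terminal mixture over three lifetime outcome classes —
ASD with ID, ASD without ID, and no ASD — plus the fractions screened and
treated, which price the upfront costs (MRI $1,814; EIBI $148,367,
covering two years of intervention). Upfront costs enter undiscounted at
model start: they are incurred before the age-6 cohort begins, and a
configuration switch (`discount_upfront_to_birth`) discounts them to birth
for sensitivity exploration.

```{r}
outcome_mixtures(asd_parameters())
```

These mixtures are closed-form products of the inputs, so they are exact;
they reproduce the published cohort ID prevalences (0.0421, 0.0353,
0.0348, 0.0339) and relative risks (1, 0.8397, 0.8280, 0.8045) to four
decimal places.

**Markov model (age 6 to extinction).** Each outcome class runs through a
two-state (alive/dead) cohort model with annual cycles from age 6 to a
terminal age of 110. The class selects a mortality hazard ratio (1, 2.18,
5.78), a quality-of-life weight (1, 0.68, 0.46) and an age-banded annual
cost row (ages 6–17, 18–21, 22+; zero for the non-ASD class, whose members
are identical across strategies and therefore cancel from every
comparison). Rewards accrue at cycle start with no half-cycle correction —
the simplest contract, chosen so results are bit-reproducible and the
geometric-series oracles in the test suite are exact. Both costs and QALYs
are discounted at 3% per year with \(t = 0\) at age 6.

Hazard ratios act on the cumulative-hazard scale,
\(q' = 1 - (1-q)^{\mathrm{hr}}\), never by naive multiplication, which
would exceed 1 at the ASD+ID ratio of 5.78 wherever \(q > 0.17\).

**Assembly.** A strategy's expected cost is its upfront cost plus the
mixture-weighted discounted class costs; expected QALYs are the
mixture-weighted discounted class QALYs. Strategies are then ordered by
effectiveness, strongly and extended-dominated entries are removed, and
incremental cost-effectiveness ratios (ICERs) are computed along the
frontier, with common-baseline ICERs against the status quo reported
alongside. The decision rule at a willingness-to-pay (WTP) threshold picks
the most effective non-dominated strategy whose incremental ICER is at or
below the threshold, which provably maximizes net monetary benefit.

## The synthetic life table

The model needs a schedule of annual death probabilities \(q_x\). The
package bundles a deterministic synthetic table generated from a
Gompertz–Makeham hazard \(\lambda + a e^{bx}\), integrated exactly over
each year of age:

\[ q(x) = 1 - \exp\!\big(-\lambda - \tfrac{a}{b} e^{bx}(e^b - 1)\big), \]

with \(\lambda = 4\times10^{-4}\), \(b = 0.0955\), terminal age 110
(\(q = 1\)), and \(a = 2.4348\times10^{-5}\) fixed by bisection so that
remaining life expectancy at age 6 is 73 years — the midpoint of the
70–75 window typical of a recent U.S. period life table. This captures the
features the Markov engine is sensitive to (near-flat child mortality, an
exponential adult rise, a closed terminal age) without shipping or
downloading any external table. It is an emulation, not a transcription:
users wanting survival-dependent outputs calibrated against a specific
national table can pass one through `read_life_table()` (two columns,
`age` and `qx`, header required, terminal `qx = 1`).

What this means for interpretation: every decision-tree quantity (ID
prevalence, relative risk, upfront costs) is life-table-free and exact,
while lifetime dollar and QALY levels shift with the table. On the bundled
table the base-case societal comparison of 6-month screening against the
status quo gives an ICER of about \$45,400/QALY versus the published
\$49,331 computed on the 2012 U.S. federal table — the same decision at
both WTP thresholds, with the published 12-month and treat-all ICERs
(\$169k and \$2.17M against the common baseline) reproduced at \$160k and
\$2.08M. Passing tests therefore demonstrate exactness of the tree,
correctness of the engine against closed forms, and the published
qualitative structure of the results; they do not certify the federal-table dollar
levels.

## Quality-of-life weights

The two ASD weights derive from one reported overall mean utility via a
two-equation system: with comorbid ID prevalence 0.32 within ASD and an ID
decrement of 0.22, a mean of 0.6096 decomposes into 0.68 (ASD-only) and
0.46 (ASD+ID); `decompose_qol_weights()` performs and validates this
inversion. Weights are held constant through childhood. A decline in
adulthood is plausible and the machinery supports one
(`qol_decline_per_year`, from `qol_decline_start_age`, floored at
`qol_floor`), but the default is zero: no quantified schedule is
established, and silently enabling an uncited default would shift every
output. This is one reason absolute QALY levels here run slightly above
the published ones.

`derive_id_risk_ratio()` documents how an IQ-point gain maps to an ID risk
ratio — the ratio of Gaussian tail masses below the IQ-70 threshold before
and after adding the gain. It is informational; the pipeline uses the
risk ratio 0.61 directly as an input.

## Cost perspectives

Annual cost rows are societal totals. The health-care and educational
perspectives take configurable fractions of them (defaults 0.23 and 0.12,
chosen loosely so status-quo lifetime costs land near the published
per-perspective levels), while both bear 100% of the EIBI cost and the
health-care ledger also bears the MRI. The exact per-category splits
behind the published per-perspective totals are not available, so
per-perspective dollar levels are configuration-dependent; the societal
perspective is the calibrated one, and the ordering societal ≥ health-care
≥ educational is enforced by construction and tested.

## Sensitivity analyses

**One-way (tornado).** `one_way()` replaces a single parameter with its
low/high envelope value and re-runs the entire pipeline; `tornado()` does
this for a default set and sorts by bar width. The target comparison is
6-month screening versus status quo, societal perspective. The default
display set covers the prevalences, the intervention effect and uptake,
the compared test's characteristics, QOL weights, all costs (annual
blocks through ±25% scale parameters) and the discount rate. The
mortality hazard ratios are excluded from the default display: their
envelopes are tight confidence intervals whose effect on an *incremental*
comparison is second-order — an order of magnitude below every displayed
bar — and including them would obscure the headline result that the MRI
price moves the ICER less than any non-cost input. They remain one
`one_way()` call away. At a risk ratio of exactly 1 the comparison has
zero QALY difference and the ICER is reported as `Inf` (pure added cost);
the risk-ratio bar is widest by construction, matching its role as the
model's key mechanism.

**Probabilistic (PSA).** `run_psa()` draws each uncertain parameter from a
beta (probabilities, utilities) or gamma (hazard ratios) distribution
matched to its mean and standard deviation by `beta_from_moments()` /
`gamma_from_moments()`. Test characteristics and costs are held fixed in
the PSA (they carry no distribution) and are explored one-way instead.
Draws are mutually independent — no correlation structure is asserted —
and each parameter draws from its own deterministic substream, derived
from the master seed and the parameter's name, so adding a parameter to
the specification never perturbs the others and identical seeds give
bitwise-identical results. The two QOL weights may cross in a draw
(their uncertainty ranges overlap widely); this is deliberate, is the
mechanism that produces negative incremental QALYs in the cloud, and is
why PSA validation relaxes the base-case ordering check. Threshold
proportions on the cost-effectiveness plane condition on a positive QALY
gain; cost-saving draws count as below any threshold.

At the default 10,000 draws on one CPU a PSA takes a few seconds. On the
bundled table, seed 2018 puts 53% of draws below \$100,000/QALY with a
QALY gain, 43% below \$50,000, and 20% in the superior quadrant
(cost-saving with a gain) — bracketing the published 52%/41%/20% despite
the different life table.

## Numerical choices and degenerate inputs

* Probabilities, weights and rates are validated to their supports on
  construction; beta feasibility (\(\mathrm{sd}^2 < m(1-m)\)) is checked
  before any sampling.
* Moment matching is algebraic and round-trips to 1e−9 relative error.
* Frontier ties break toward lower cost at equal effect and higher effect
  at equal cost; an entry whose incremental ICER equals a successor's is
  removed (weak extended dominance), so surviving ICERs increase strictly.
* `icer()` refuses a zero effect difference (undefined ratio) and flags
  dominance instead of reporting a negative ratio; the internal pairwise
  ICER used by sensitivity analysis returns signed infinity at zero
  effect difference so tornado bars remain well-defined.
* A life table must cover consecutive ages up to a terminal row with
  \(q = 1\); gaps are an error naming the missing age. The cohort trace
  carries an explicit extinction row (survival exactly 0 after the
  terminal age).
* Cost bands must partition ages from the start age upward with an
  open-ended last band.

## Problem sizes used by the test suite

The suite exercises the decision-tree oracle on 1,000 random scenarios,
the frontier oracle on 1,000 random strategy sets, the Markov closed-form
oracle on 100 random (q, w, r) triples, and PSAs of 10,000 draws (run
twice to establish bitwise reproducibility), all on one CPU in a few
minutes. These sizes were chosen to make the statistical bounds sharp
(3-standard-error checks on 10,000 draws) while keeping a full run fast
enough to be part of routine development.

## Known limitations

* Lifetime dollar/QALY *levels* depend on the life table and the
  per-perspective cost fractions; only the societal perspective is
  calibrated, and only structurally.
* Severity is collapsed to the ID/no-ID dichotomy; no symptom-severity
  axis, no negative effects of false-positive labelling beyond cost.
* The adult QOL trajectory defaults to flat (see above).
* Single sex-averaged life table; no repeat or staged screening
  protocols; no budget-impact analysis — cost-effectiveness is not
  affordability.
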