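---
title: "Methods: a Markov model for risk-stratified breast cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov model for risk-stratified breast cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screencea)
```

## The decision problem

`screencea` compares two population screening programmes for breast cancer
over a cohort of women followed from age 35 to 74 (40 annual cycles), from
the perspective of the healthcare system:

* **Current**: biennial mammography from age 50, last screen at 68.
* **Tailored**: polygenic risk stratification at entry (buccal-swab
  genotyping plus a risk-factor questionnaire), then group-specific
  schedules — low risk (51% of women, incidence multiplier 0.5×) screened
  every three years from 37 to 73; intermediate (41%, 1×) every two years
  from 36 to 74; high (8%, 2×) annually from 35 to 74. Modalities follow
  age: self-examination below 40, ultrasound to 49, mammography from 50.

The per-group intervals are a design choice of this package: they are
chosen so the last screens land at ages 73/74/74, high-risk women are
screened more intensively than under the current programme, and low-risk
women less. They are arguments of `build_tailored_strategy()`, so
alternative intensities can be evaluated directly.

## Model structure

The model is a Markov cohort recursion over six states — Healthy, Stage
I–IV, Dead — with one-year cycles and events evaluated at cycle start.
A Healthy woman transitions into stage $s$ during a cycle at age $a$ with
probability

$$p_{\text{dx}}(a, s) = \mathrm{ASIR}(a)\; \pi(s)\; \theta\; m,$$

where $\mathrm{ASIR}$ is the age-specific incidence rate (piecewise
constant over 5-year bands), $\pi$ is the stage-at-diagnosis distribution,
$\theta$ the imaging sensitivity (0.8 for mammogram and ultrasound, absent
for non-screen detection), and $m$ the risk-group multiplier. Diagnosed
women stay in their stage — remission, treatment pathways and stage
progression after diagnosis are deliberately out of scope — and die with
annual probability equal to the stage-specific breast-cancer rate plus the
flat all-cause rate (cause-specific hazards added, capped at 1). Dead is
absorbing. The multiplier applies to incidence only, never to mortality,
utilities or costs.

### Detection timing

The data generating detection events are under-determined by screening
schedules alone: what happens to cancers arising between screens is a
modelling convention. Two conventions are first-class, selected by
`config$detection_mode`:

* `screen_plus_interval` (**default**): in an imaging-screen cycle the
  woman is diagnosed with the *screened* stage distribution and the
  sensitivity factor; in any other cycle she can present symptomatically
  with the *unscreened* (later-stage) distribution and no sensitivity
  factor. Self-examination visits behave like non-screen cycles, since no
  self-exam sensitivity is available.
* `screen_only`: detection happens only at imaging screens; between
  screens nothing is detected.

The default matters. Under `screen_only` a programme that screens *more*
detects *more* cancers, and — because undiagnosed cancers have no health
consequence in a model without a latent disease state — more screening
can only add cost and QALY losses. The tailored programme would then be
dominated, which contradicts both intuition about interval presentation
and the published economics of this comparison. With interval detection
the two arms detect comparable disease totals and differ mainly in stage
composition and timing, which is the mechanism a stage-shift screening
model is meant to capture. Both modes are exercised by the test suite.

### Cost accounting

Stage-specific direct medical costs are charged **annually per year of
stage occupancy** by default (`config$stage_cost_model = "annual"`), not
once at diagnosis (`"once"`, also available). The bundled stage costs
(63,983–110,136 SGD) are of the magnitude of multi-year management costs,
and only annual charging produces per-woman lifetime costs in the
20,000 SGD range that published evaluations of this programme report;
one-time charging yields totals an order of magnitude smaller. Screening
test costs are charged to the Healthy (alive, undiagnosed) occupancy at
each screen; entry costs (swab + questionnaire) once per woman at cycle 0.

### Accumulation and discounting

With discount rate $r$ (default 3%/year), cycle $t$ (0 at age 35)
contributes with factor $(1+r)^{-t}$. Life years count alive occupancy at
cycle start; QALYs weight occupancy by state utilities (Healthy fixed at
1); diagnosed-in-cycle women count as Healthy in the cycle of diagnosis.
Case counts and the lifetime death probability are undiscounted. An
optional half-cycle correction (off by default; the cycle-start convention
is the one the bundled baseline was calibrated under) averages start- and
end-of-cycle occupancy for LY/QALYs.

## Parameters

`baseline_parameters()` bundles the Singaporean inputs: the 11-band
incidence curve (bands above 74 are stored but unused by the default
horizon), screened/unscreened stage distributions (0.53/0.43/0.03/0.01 vs
0.22/0.57/0.12/0.09), stage mortalities (0.020/0.044/0.083/0.268/yr), a
flat all-cause rate (0.002896/yr — a single printed rate, not an
age-specific life table; an age-specific curve can be supplied through the
same band format), utilities (1, 0.731, 0.731, 0.599, 0.352), stage costs,
test costs (mammogram 110, ultrasound 230, buccal swab 210, questionnaire
2 SGD), and the risk stratification. Two published ranges are internally
inconsistent and are handled explicitly: the Stage II utility range prints
minimum = maximum = 0.63, so the bundle mirrors the Stage I range
(0.63–0.83); the Stage III maximum prints equal to its baseline and is
kept verbatim. Parameter files round-trip through
`write_parameters()`/`load_parameters()` (YAML + CSV), with partial
overrides falling back to the baseline with a notice.

## Sensitivity analyses

* **One-way (tornado)**: every parameter with a published range uses it
  (costs ±30%, utilities ±0.1); all others use 80%/120% of baseline
  (sensitivity capped at 1; a perturbed stage proportion is renormalised
  against the remaining stages). Each run re-evaluates the full
  deterministic model at the low and high bound; entries are sorted by
  ICER span with alphabetical tie-breaks, so output order is
  deterministic.
* **Probabilistic**: only cost and utility parameters vary. Published
  ranges are read as 95% intervals, so fitted distributions are
  moment-matched with mean = baseline and sd = half-width/1.96 — Gamma for
  costs, Beta for utilities (with the sd shrunk to the largest feasible
  value if the Beta family cannot attain it). Both arms are evaluated
  under the *same* draw. Since no dynamics parameter varies, outcomes are
  exact linear functionals of the baseline discounted exposures, which
  `run_psa()` exploits; it falls back to per-draw model re-runs if the
  specification ever includes a dynamics parameter. All draws are
  generated up front in specification order from one seed, so results are
  independent of evaluation order and byte-reproducible.
* **CEAC**: the probability of non-negative incremental net monetary
  benefit, $P(\lambda\,\Delta Q - \Delta C \ge 0)$, over a WTP grid.

## Scenario analysis

Four percentile-cutoff scenarios ship: 60L-35I-5H (baseline), 60L-30I-10H,
40L-55I-5H and 40L-50I-10H. Only the baseline cutoffs have an empirical
(Asian-population) proportion mapping, 0.51/0.41/0.08; for the others the
nominal percentile widths serve as proportions. This is an open
approximation — if an empirical mapping for other cutoffs exists, pass it
to `cutoff_scenario()` directly. The ending-age variant truncates the
tailored schedules at 69 (the current programme's ending age) while
keeping the 40-year horizon.

## Synthetic data and the microsimulation oracle

`generate_parameter_set()` draws parameter sets around the baseline with
the structure the analysis assumes: a log-normal common scale and band
jitter for incidence (kept non-decreasing to a plateau), Dirichlet stage
simplexes and risk-group proportions, log-normal cost dispersion
(re-ordered so costs rise with stage), bounded utility jitter (re-ordered
so utilities fall with stage). Every generated set passes full validation
by construction, and an all-zero specification returns the baseline
exactly. These sets emulate the *shape* of real inputs, not their
correlations — real incidence, stage distributions and costs co-vary
through underlying disease biology and care pathways that independent
jitter cannot represent — so passing tests demonstrate correctness of the
computation, not calibration to any real population.

`microsim_oracle()` simulates individual women with the identical
per-cycle probabilities and accounting as the cohort engine (shared code
path for the diagnosis vector), providing a brute-force check that the
expectation-level recursion and the individual-level accounting agree.
The test suite requires agreement within 3 Monte Carlo standard errors at
200,000 women on ten random synthetic sets and both strategies.

## Numerical choices and problem sizes

Simplex and weight sums are validated to 1e-9; transition rows to 1e-12.
Diagnosis probabilities are clamped to [0,1] and a Healthy row whose
off-diagonal mass would exceed 1 raises an infeasible-parameters error
rather than silently renormalising. The deterministic model is exact, so
tests assert equalities at numerical precision; stochastic checks (PSA
mean recovery at 10,000 draws, oracle equivalence at 200,000 women) use
3-standard-error bands under fixed seeds. These sizes keep the full suite
in the order of half a minute while leaving Monte Carlo error well below
the effects being tested.

## Reproduction of previously published figures

The package's conventions were fixed against the arm-level economics of
the published Singapore evaluation of this programme, which the default
configuration reproduces well: per-woman lifetime costs within ~5%, the
incremental cost within ~7%, and lifetime death probabilities within
~1–2%. Other published figures are not mutually consistent under any
single Markov convention this package can express. In particular, a
reported incremental life-year gain close to one discounted year per woman
is incompatible with the accompanying death probabilities (a 0.4
percentage-point death differential bounds the discounted LY difference
near 0.1), and reported case counts match a screen-detected subset under
one convention while the death probabilities match detection totals under
another. The package therefore reports what its model computes; the
acceptance tests mark the irreproducible quantities as failing rather than
bending the model to fit them, and both detection conventions remain
available for readers who want to examine the difference.

## Limitations

No tumour natural history (no latent preclinical state, growth or
dwell-time), hence no overdiagnosis decomposition; no treatment, remission
or post-diagnosis pathway; 100% attendance assumed; a flat all-cause
mortality rate; risk-group membership fixed at entry (no score updating);
costs in nominal SGD with no inflation adjustment; PSA draws are
independent across parameters (no correlation structure); no
value-of-information analysis.
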