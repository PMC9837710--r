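---
title: "Simulating secondary risk-reducing strategies in BRCA1/2 breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating secondary risk-reducing strategies in BRCA1/2 breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcapolicy)
```

## The decision problem

A woman with a BRCA1 or BRCA2 pathogenic variant treated with
breast-conserving therapy (BCT) for a unilateral stage I/II breast cancer
remains at high risk of three further cancer events: an ipsilateral breast
event in the treated breast, a contralateral second primary, and ovarian
cancer. Each can be mitigated — by prophylactic mastectomy of one or both
breasts, salpingo-oophorectomy (RRBSO), or five years of tamoxifen — but
every option trades surgical morbidity or treatment burden against a risk
reduction whose value depends strongly on the patient's stratum: gene, the
exon group of the variant, age at diagnosis, tumour subtype (luminal vs
triple-negative), stage, and whether she received adjuvant chemotherapy.
`brcapolicy` simulates 40-year overall survival for every combination of
144 such cohorts and 9 policies, so the strategies can be ranked per
stratum.

## Model structure

The model is a temporal Bayesian network: seven time-varying binary
variables unrolled into one node per time step, with absorbing semantics
(once an event has happened it stays happened). The canonical DAG,
exportable with `network_edges()` / `export_network_dot()`:

* static covariates parent every hazard they modify;
* `rrso_performed` parents `ovarian_cancer`, `ipsilateral_event` and
  `death_other`;
* `ipsilateral_event` and `contralateral_bc` parent `death_bc`, through the
  stage and subtype sampled for the second tumour at detection;
* `ovarian_cancer` parents `death_oc`;
* every variable at step *k − 1* parents itself at step *k*.

The published description fixes the node semantics and the effect sizes but
only sketches the parent structure ("structured according to expert
knowledge"); the DAG above is this package's canonical reconstruction and
all conditional tables are assembled from it.

Within a step the simulator samples event variables before death variables,
so a cancer detected at step *k* contributes to death hazards from step
*k + 1* onward — detection and its mortality consequence are never
simultaneous. If several death variables fire in the same step, the cause is
attributed by the fixed priority *breast cancer > ovarian cancer > other*;
the tie-break affects cause labels only, never survival times.

## From published evidence to per-step probabilities

All evidence is reduced to per-step conditional probabilities through three
closed forms: `annual_rate(p, o) = -ln(1 - p)/o` for a cumulative risk *p*
over *o* years, `interval_probability(rate, c) = 1 - exp(-rate * c)` for a
step of length *c* years, and `apply_hazard_ratio(ref, hr) = ref^hr` on the
survival scale. Piecewise schedules (e.g. a 5-year and a 10-year cumulative
incidence) are handled by `stepwise_probabilities()`, which assumes a
constant hazard within each segment and extends the final hazard beyond the
last published horizon. Composing the per-step probabilities reproduces the
published cumulative values at every segment boundary to 1e-9, and the
construction is invariant to step refinement — the 2.5-year validation grid
and the annual grid agree at common time points.

Two modelling choices here were genuinely open:

* **The interval length *c*.** We take *c* to be the length of the step
  being converted: 1 for the 40-year annual model, 2.5 for the validation
  model's 2.5-year steps.
* **Effect scale.** Published relative risk reductions ("RRBSO decreased
  the risk of an ipsilateral breast event by 58%") are applied as
  multipliers on the per-step *rate*, not on the per-step probability.
  On the probability scale the composed effect would depend on the step
  length; on the rate scale it is horizon-invariant and equals the
  proportional-hazards interpretation of the published hazard ratios.

## Key parameters

| Parameter | Default | Units / scale | Source tag |
|---|---|---|---|
| Contralateral 10-y cumulative risk | 0.27 (BRCA1) / 0.19 (BRCA2) | probability | paper_body |
| RRBSO effect on ovarian cancer | −80 % / −79 % (BRCA1/2) | rate multiplier | paper_body |
| RRBSO effect on ipsilateral events | −58 % | rate multiplier | paper_body |
| Chemotherapy effect on ipsilateral events | −49 % | rate multiplier | paper_body |
| Tamoxifen effect on contralateral cancer | −56 % / −67 % (BRCA1/2) | rate multiplier | paper_body |
| Tamoxifen effect on 15-y luminal mortality | −30 % | cumulative-mortality reduction | paper_body |
| Mastectomy effect on contralateral cancer | −90 % | rate multiplier | paper_body |
| DCIS lifetime mortality | 0.033 | probability | paper_body |
| Metastatic second-event mortality | 1.0 | probability | paper_body |
| Primary stage distribution | 52.3/43.1/4.0 % | probabilities (as printed) | paper_body |
| Triple-negative prevalence | 69 % / 15 % (BRCA1/2) | probability | paper_body |
| Expected lifetime | 80 | years | paper_body |
| RRSO timing window | 5 | years after diagnosis | paper_body |
| Stage/subtype mortality schedules | see fixture | cumulative probability | placeholder |
| Age-stratified contralateral schedules | see fixture | cumulative probability | placeholder |
| Local-failure schedules (BCT / mastectomy) | see fixture | cumulative probability | placeholder |
| Ovarian lifetime risk by gene × exon | 0.39–0.49 / 0.12–0.22 | probability | placeholder |
| Other-cause mortality by attained age | see fixture | annual probability | placeholder |
| RRSO excess non-cancer mortality | 1.5 | rate multiplier | placeholder |
| Chemotherapy effect on BC mortality | −25 % | rate multiplier | placeholder |

`parameter_table()` flattens the full set with its provenance column;
`save_parameters()` / `load_parameters()` round-trip the YAML schema with
full validation (unknown keys rejected, probabilities bounded, schedules
monotone, categorical distributions summing to 1).

Notes on individual entries:

* **Primary stage distribution.** The printed values sum to 0.994; they are
  stored exactly as printed and renormalised whenever they are sampled.
* **Ovarian risk timing.** The lifetime (to age 80) risk for the cohort's
  gene and exon group is spread uniformly on the hazard scale over the
  years remaining from the representative age at diagnosis (35, 45 or 65).
* **Metastatic second events.** A published mortality of 100 % cannot pass
  through `-ln(1 - p)`; the rate is computed from a cumulative probability
  capped at 1 − 1e−9 over ten years, i.e. death is near-certain within the
  decade.
* **Tamoxifen and mortality.** The −30 % applies to *cumulative 15-year*
  breast-cancer mortality of luminal disease. A constant rate multiplier
  would miss that target because of the nonlinearity of
  1 − exp(−Λ), so the package solves, per stage and chemotherapy status, the
  hazard power `hr = ln(1 − 0.7·M₁₅)/ln(1 − M₁₅)` (an `apply_hazard_ratio`
  on the 15-year survival) and applies it to the first-primary death rate
  during years 1–15 only. The recovered reduction is therefore exactly 30 %
  regardless of the placeholder mortality schedule. It is applied to the
  first primary only, since tamoxifen here is adjuvant therapy for that
  tumour.
* **Chemotherapy and breast-cancer mortality.** The published account makes
  the absence of chemotherapy the strongest determinant of survival but
  folds its mortality effect into unpublished mortality tables; this package
  instead exposes it as an explicit placeholder rate multiplier
  (`effects$chemo_bc_mortality_reduction`), keeping the mortality schedules
  chemotherapy-free.
* **Second-event stage and subtype.** At detection of a contralateral or
  ipsilateral second cancer, its stage is drawn from
  `second_event_stage_distribution` (DCIS/I/II/III/metastatic) and its
  subtype from the gene's triple-negative prevalence; the corresponding
  stage/subtype mortality rate is *added* to the first-primary rate, the
  published "summarised" treatment of multiple primaries. Local failures
  after an ipsilateral mastectomy carry no mortality contribution.
* **RRSO timing.** Under RRBSO policies the `rrso_performed` variable
  activates at a step drawn uniformly from the first five years
  (configurable via `rrso_timing_window_years`; a window of 0 means RRSO at
  diagnosis, which the paired-arm effect recoveries use). The excess
  non-cancer mortality multiplier applies when RRSO happens before age 45
  in a cohort diagnosed before 40.

## Simulation mechanics

`allocate()` spreads a total patient budget uniformly over cohort × policy
cells with a round-robin remainder, so one million patients give ≥ 6,900 per
cohort and ≥ 770 per cell. Sampling is vectorised within each cell;
reproducibility comes from one root seed from which a per-cell substream
seed is derived deterministically — the same root seed yields byte-identical
records. Survivors are censored at the horizon (40 years; 15 in the
validation scenario) with no earlier administrative censoring.

Survival summaries delegate to the `survival` package behind thin wrappers:
`km_curve()` (product-limit, optionally evaluated on a fixed grid),
`logrank_test()` and `cox_hr()` (Efron tie handling — simulated event times
sit on a coarse grid, so ties are heavy). Mirroring the model's intended
use, no P values or confidence intervals accompany simulation output; the
test suite uses standard errors internally only to bound Monte-Carlo error.
Within each cohort cell the Cox model uses policy as its sole covariate.

## The validation scenario

`posh_scenario()` encodes an external-validation population: all patients
triple-negative and under 40 at diagnosis, gene mixture 123/136 BRCA1 and
13/136 BRCA2, chemotherapy probability 117/136, uniform exon distribution,
stage I 61.2 % / II 38.8 %, simulated for 15 years in 2.5-year steps.
`run_validation()` samples the mixture once, simulates all nine policies on
the same covariate sample, and returns per-policy Kaplan–Meier curves on the
2.5-year grid. The published comparison against the external cohort's
confidence bands was done by inspection; this package exports the curves
and leaves that comparison to the user, since the external data are not
redistributable.

## What the tests do and do not show

The test suite verifies structure (144 cohorts, 9/18 policies, 40 nodes per
temporal variable, DAG acyclicity, CPT rows summing to one, absorption),
the conversion layer against closed forms (round-trips to 1e-12,
step-refinement invariance to 1e-9), the statistics layer against
hand-computed product-limit fixtures and null/power simulations, and —
centrally — *parameter recovery*: paired 200,000-patient arms differing only
in one intervention recover each configured effect (58, 49, 56, 67, 80, 79,
30 %) within three Monte-Carlo standard errors. Because paired arms share
all placeholder values, these recoveries validate the simulation machinery
independently of the placeholder evidence. They do **not** validate the
placeholder values themselves: absolute survival levels produced with the
default fixture are illustrative, not clinical estimates, and headline
survival figures from the original study are not reproducible without its
supplementary parameter tables.

Problem sizes used by the packaged checks — 200,000 patients per recovery
arm, 100,000 for mixture-composition checks, 200 replicates for the
log-rank type-I simulation — were chosen so each check's Monte-Carlo error
is far below the effect being measured.

## Known limitations

* Risk modifiers are assumed independent and multiplicative on the hazard
  scale; interactions are not modelled.
* Hormone-replacement therapy after RRSO, neoadjuvant chemotherapy and
  HER2-positive disease are outside the model, as in the source study.
* The evidence base mirrors the study's 2022 literature; the fixture is not
  a living evidence review.
* Exact inference on the network (likelihood evaluation) is out of scope;
  the model is exercised by forward sampling only.
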