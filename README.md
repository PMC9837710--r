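# brcapolicy

Micro-simulation of long-term overall survival for women carrying a
**BRCA1** or **BRCA2** pathogenic variant who were treated with
breast-conserving therapy (BCT) for unilateral stage I/II breast cancer, and
who face a choice among **secondary risk-reducing strategies**: surveillance,
contralateral risk-reducing mastectomy (CRRM), risk-reducing bilateral
mastectomy (RRBM), risk-reducing salpingo-oophorectomy (RRBSO), five-year
tamoxifen, and their combinations — nine policies in all, eighteen when
crossed with adjuvant chemotherapy.

The package is aimed at biostatisticians and decision modellers who need a
reproducible, parameter-transparent engine for comparing these policies
across patient strata, and at methodologists studying discrete-time
competing-risks simulation.

## The model

A **temporal Bayesian network** unrolls seven time-varying variables — an
ipsilateral breast event, contralateral breast cancer, ovarian cancer,
RRSO-performed, and death from breast cancer, ovarian cancer or other causes
— into one node per variable per time step (40 annual steps by default).
Static covariate nodes (gene, exon group, age group at diagnosis, subtype,
stage, chemotherapy, policy) parent the temporal hazards, and every temporal
variable is absorbing: P(Xₖ₊₁ = 1 | Xₖ = 1) = 1.

Published evidence enters through a conversion layer:

- a cumulative risk *p* over *o* years becomes a constant rate
  `rate(p, o) = −ln(1 − p) / o`;
- the event probability over a step of *c* years is `1 − exp(−rate · c)`;
- a hazard ratio *hr* against a reference survival *ref* acts as `ref ^ hr`.

Intervention effects (RRBSO −80 %/−79 % on ovarian cancer and −58 % on
ipsilateral events; chemotherapy −49 % on ipsilateral events; tamoxifen
−56 %/−67 % on contralateral cancer and −30 % on 15-year luminal mortality;
mastectomy −90 % on contralateral cancer) are applied as multipliers on the
per-step hazard rate, so their composition does not depend on the step
length. Patients are sampled forward through the network (ancestral
sampling); 144 cohorts × 9 policies are compared with Kaplan–Meier curves,
log-rank statistics and Cox proportional-hazards ratios.

Values printed in the published study appear verbatim in the default
parameter set (provenance tag `paper_body`); quantities available only from
supplementary appendices or the cited primary literature ship as documented,
clinically plausible placeholders (tag `placeholder`). See
`parameter_table(default_parameters())` for the full audited list.

## Worked example

Compare surveillance against RRBM + RRBSO for BRCA1 carriers (exon 11,
diagnosed at 40–50, luminal stage I, with chemotherapy):

```r
library(brcapolicy)

params <- default_parameters()
net <- build_network(params, horizon = 40, step = 1)
net
#> Temporal network: 40 steps of 1 year(s) (horizon 40 y); 7 temporal variables

cohort <- subset(enumerate_cohorts(),
                 gene == "BRCA1" & exon_group == "exon 11" &
                 age_group == "40-50" & subtype == "luminal" &
                 stage == "I" & chemo)

surv <- simulate_cohort(net, cohort, policy_by_id("surveillance"), 20000, seed = 11)
both <- simulate_cohort(net, cohort, policy_by_id("RRBM+RRBSO"),   20000, seed = 12)

km_curve(surv$survival_time, surv$event, times = c(10, 20, 40))$survival
#> [1] 0.843 0.633 0.206
km_curve(both$survival_time, both$event, times = c(10, 20, 40))$survival
#> [1] 0.907 0.783 0.362

tt <- c(surv$survival_time, both$survival_time)
ev <- c(surv$event, both$event)
gr <- factor(rep(c("surveillance", "RRBM+RRBSO"), each = 20000),
             levels = c("surveillance", "RRBM+RRBSO"))
logrank_test(tt, ev, gr)$statistic
#> [1] 1731.4
cox_hr(tt, ev, gr)$hr[["RRBM+RRBSO"]]
#> [1] 0.612
```

Under this parameterisation, adding RRBM + RRBSO lifts 40-year overall
survival from 20.6 % to 36.2 % in this stratum — an overall-mortality hazard
ratio of 0.61 — by suppressing contralateral and ovarian second cancers
(cause tables are returned per record). Because the data are simulated, the
log-rank statistic is a separation measure, not a significance test.

The full study (all 144 cohorts × 9 policies, one million patients) runs
with `run_full_study(run_config(n_total = 1e6, seed = 1, out_dir = "out"))`,
writing per-patient records, per-cell survival summaries, a per-cohort
policy ranking and a manifest. A thin command-line front-end is installed as
`exec/brcapolicy` (subcommands `simulate`, `validate`, `convert`, `report`).
The 15-year / 2.5-year-step validation scenario for the triple-negative
under-40 population is available via `run_validation()`.

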