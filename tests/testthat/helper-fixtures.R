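# Shared fixtures, built in code.

# Parameter set with every hazard switched off: useful as a blank canvas for
# single-hazard experiments.
zero_risk_parameters <- function() {
  p <- default_parameters()
  zero_sched <- risk_schedule(c(10, 40), c(0, 0))
  for (g in brca_genes()) {
    for (a in brca_age_groups()) p$contralateral_risk[[g]][[a]] <- zero_sched
    p$ovarian_lifetime_risk[[g]][] <- 0
  }
  p$ipsilateral_risk$bct <- zero_sched
  p$ipsilateral_risk$mastectomy <- zero_sched
  for (u in brca_subtypes()) {
    for (s in c("I", "II", "III")) p$bc_mortality[[u]][[s]] <- zero_sched
  }
  p$dcis_mortality <- 0
  p$metastatic_mortality <- 0
  p$other_cause_mortality$annual_prob[] <- 0
  p
}

# Parameter set where only breast-cancer second-event machinery is silent,
# for clean event-specific effect recovery.
test_cohort <- function(gene = "BRCA1", exon = "exon 11", age = "40-50",
                        subtype = "luminal", stage = "I", chemo = FALSE) {
  data.frame(gene = gene, exon_group = exon, age_group = age,
             subtype = subtype, stage = stage, chemo = chemo,
             rep_age = representative_age(age), stringsAsFactors = FALSE)
}

# Time-to-event extraction for a non-fatal event column, censoring at death
# or horizon.
event_surv <- function(records, col) {
  t_ev <- records[[col]]
  data.frame(time = ifelse(is.na(t_ev), records$survival_time, t_ev),
             event = !is.na(t_ev))
}

# Simulate two arms identical except for the policy, and recover the
# percent reduction in the hazard of the event in `col` (Cox HR), together
# with the standard error of the reduction (delta method on the log-HR).
recover_reduction <- function(params, cohort, policy_ref, policy_alt, col,
                              n, seed, horizon = 40, step = 1) {
  net <- build_network(params, horizon = horizon, step = step)
  a <- simulate_cohort(net, cohort, policy_by_id(policy_ref), n, seed)
  b <- simulate_cohort(net, cohort, policy_by_id(policy_alt), n, seed + 1L)
  sa <- event_surv(a, col); sb <- event_surv(b, col)
  fit <- cox_hr(c(sa$time, sb$time), c(sa$event, sb$event),
                factor(rep(c("ref", "alt"), c(n, n)),
                       levels = c("ref", "alt")))
  hr <- unname(fit$hr["alt"])
  se_hr <- unname(fit$se["alt"]) * hr
  list(reduction_pct = 100 * (1 - hr), se_pct = 100 * se_hr, hr = hr)
}
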