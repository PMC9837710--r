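# Temporal Bayesian network builder.
#
# The model unrolls seven temporal variables (ipsilateral breast event,
# contralateral breast cancer, ovarian cancer, RRSO-performed, and three
# cause-specific death variables) over a regular time grid, one node per
# variable per step. Static covariate nodes (gene, exon group, age group,
# subtype, stage, chemotherapy, policy) parent the temporal hazards; every
# temporal variable is absorbing (once true, always true).
#
# The canonical DAG:
#   static covariates -> every temporal hazard they modify;
#   rrso_performed    -> ovarian_cancer, ipsilateral_event, death_other;
#   ipsilateral_event, contralateral_bc -> death_bc (via the sampled
#     stage/subtype of the second event, from the step after detection);
#   ovarian_cancer    -> death_oc;
#   each temporal variable at step k-1 -> itself at step k (absorption).
#
# All published effect sizes are applied as multipliers on the per-step
# hazard rate (not on the per-step probability), so their composition is
# invariant to the step length.

temporal_variables <- function() {
  c("ipsilateral_event", "contralateral_bc", "ovarian_cancer",
    "rrso_performed", "death_bc", "death_oc", "death_other")
}

second_event_stages <- function() c("DCIS", "I", "II", "III", "metastatic")

# Rate of the mortality contribution of a detected second breast event, by
# stage and subtype, indexed by steps since detection. DCIS carries a small
# lifetime-mortality rate; metastatic disease is near-certain death within a
# decade (the published 100% mortality is capped below 1 for the hazard
# conversion).
second_event_rates <- function(params, step, n_steps, horizon) {
  stages <- second_event_stages()
  subs <- brca_subtypes()
  arr <- array(0, dim = c(n_steps, length(stages), length(subs)),
               dimnames = list(NULL, stages, subs))
  dcis_rate <- annual_rate(params$dcis_mortality, horizon)
  met_rate <- annual_rate(min(params$metastatic_mortality, 1 - 1e-9), 10)
  for (ui in seq_along(subs)) {
    arr[, "DCIS", ui] <- dcis_rate
    arr[, "metastatic", ui] <- met_rate
    for (s in c("I", "II", "III")) {
      arr[, s, ui] <- schedule_step_rates(
        params$bc_mortality[[subs[ui]]][[s]], step, n_steps)
    }
  }
  arr
}

#' Build the unrolled temporal network
#'
#' Assembles, for every temporal variable and step, the per-step hazard
#' rates implied by the parameter set: local-failure rates after
#' breast-conserving therapy and after mastectomy, contralateral rates by
#' gene and age group, ovarian rates by gene/exon/age (lifetime risk spread
#' over the remaining years to the expected lifetime), first- and
#' second-primary breast-cancer mortality by stage and subtype, ovarian
#' cancer mortality by stage at detection, and other-cause mortality by
#' attained age. Intervention effects (RRBSO, chemotherapy, tamoxifen,
#' mastectomy) enter as rate multipliers; the tamoxifen mortality effect is
#' converted so that the 15-year cumulative breast-cancer mortality of
#' luminal disease is reduced by exactly the configured fraction.
#'
#' @param params A validated `brca_params` object.
#' @param horizon Follow-up horizon in years (default 40).
#' @param step Step length in years (default 1); must divide `horizon`.
#' @return An object of class `temporal_network`.
#' @examples
#' net <- build_network(default_parameters(), horizon = 40, step = 1)
#' net$n_steps # 40 nodes per temporal variable
#' @export
build_network <- function(params, horizon = 40, step = 1) {
  validate_parameters(params)
  if (step <= 0 || horizon <= 0) stop("`step` and `horizon` must be positive")
  n_steps <- horizon / step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("`horizon` must be a multiple of `step`: ", horizon, " / ", step)
  }
  n_steps <- as.integer(round(n_steps))
  genes <- brca_genes(); exons <- brca_exon_groups()
  ages <- brca_age_groups(); subs <- brca_subtypes(); stages <- brca_stages()

  # ipsilateral local failure: columns bct / mastectomy
  ipsi <- cbind(
    bct = schedule_step_rates(params$ipsilateral_risk$bct, step, n_steps),
    mastectomy = schedule_step_rates(params$ipsilateral_risk$mastectomy,
                                     step, n_steps)
  )

  contra <- array(0, dim = c(n_steps, 2, 3),
                  dimnames = list(NULL, genes, ages))
  for (g in genes) {
    for (a in ages) {
      contra[, g, a] <- schedule_step_rates(
        params$contralateral_risk[[g]][[a]], step, n_steps)
    }
  }

  # ovarian: constant rate from lifetime risk over remaining years to the
  # expected lifetime, per gene x exon x age group
  ov <- array(0, dim = c(2, 3, 3), dimnames = list(genes, exons, ages))
  for (g in genes) {
    for (e in exons) {
      p_life <- params$ovarian_lifetime_risk[[g]][[e]]
      for (a in ages) {
        rem <- params$lifetime_age - representative_age(a)
        ov[g, e, a] <- annual_rate(p_life, rem)
      }
    }
  }

  # first-primary breast-cancer mortality rate by step, stage (I/II), subtype
  fp <- array(0, dim = c(n_steps, 2, 2), dimnames = list(NULL, stages, subs))
  for (s in stages) {
    for (u in subs) {
      fp[, s, u] <- schedule_step_rates(params$bc_mortality[[u]][[s]],
                                        step, n_steps)
    }
  }

  se <- second_event_rates(params, step, n_steps, horizon)

  oc_death <- -log(pmax(params$oc_survival_10y, 1e-12)) / 10

  # other-cause mortality rate by step and age group (attained age at the
  # start of each step)
  ocm <- params$other_cause_mortality
  other <- array(0, dim = c(n_steps, 3), dimnames = list(NULL, ages))
  for (a in ages) {
    attained <- representative_age(a) + (seq_len(n_steps) - 1) * step
    band <- findInterval(attained, ocm$age)
    band[band < 1] <- 1
    other[, a] <- -log1p(-ocm$annual_prob[band])
  }

  # tamoxifen mortality adjustment for luminal disease: a hazard multiplier
  # solved (per stage and chemo status) so that the cumulative first-primary
  # breast-cancer mortality at 15 years shrinks by the configured fraction.
  red <- params$effects$tamoxifen_15y_mortality_reduction
  chemo_mult <- 1 - params$effects$chemo_bc_mortality_reduction
  steps15 <- min(n_steps, as.integer(round(15 / step)))
  tam_hr <- array(1, dim = c(2, 2),
                  dimnames = list(stages, c("nochemo", "chemo")))
  for (s in stages) {
    for (ch in c(FALSE, TRUE)) {
      lam15 <- sum(fp[seq_len(steps15), s, "luminal"]) * step *
        if (ch) chemo_mult else 1
      s15 <- exp(-lam15)
      s15_adj <- 1 - (1 - red) * (1 - s15)
      hr <- if (lam15 > 0) log(s15_adj) / log(s15) else 1
      tam_hr[s, if (ch) "chemo" else "nochemo"] <- hr
    }
  }

  structure(list(
    params = params,
    horizon = horizon,
    step_years = step,
    n_steps = n_steps,
    variables = temporal_variables(),
    rates = list(
      ipsilateral = ipsi,
      contralateral = contra,
      ovarian = ov,
      first_primary_bc = fp,
      second_event = se,
      oc_death = oc_death,
      other = other
    ),
    tamoxifen_mortality_hr = tam_hr,
    steps15 = steps15
  ), class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat("Temporal network:", x$n_steps, "steps of", x$step_years,
      "year(s) (horizon", x$horizon, "y);",
      length(x$variables), "temporal variables\n")
  invisible(x)
}

rrso_window_steps <- function(network) {
  w <- network$params$rrso_timing_window_years
  if (w <= 0) 0L else as.integer(ceiling(w / network$step_years - 1e-9))
}

# Per-step hazard rate of a temporal event variable for one static
# configuration. `config` carries the covariates and policy components the
# variable depends on, plus the states of its temporal parents at the
# previous step.
hazard_rate <- function(network, variable, step, config) {
  if (step < 1 || step > network$n_steps) stop("step out of range: ", step)
  p <- network$params
  eff <- p$effects
  r <- network$rates
  switch(variable,
    ipsilateral_event = {
      base <- r$ipsilateral[step,
        if (isTRUE(config$ipsilateral_mastectomy)) "mastectomy" else "bct"]
      m <- 1
      if (isTRUE(config$chemo)) m <- m * (1 - eff$chemo_ipsilateral_reduction)
      if (isTRUE(config$rrso_active)) {
        m <- m * (1 - eff$rrbso_ipsilateral_reduction)
      }
      base * m
    },
    contralateral_bc = {
      base <- r$contralateral[step, config$gene, config$age_group]
      m <- 1
      if (isTRUE(config$tamoxifen_5y)) {
        m <- m * (1 - eff$tamoxifen_contralateral_reduction[[config$gene]])
      }
      if (isTRUE(config$contralateral_mastectomy)) {
        m <- m * (1 - eff$mastectomy_contralateral_reduction)
      }
      base * m
    },
    ovarian_cancer = {
      base <- r$ovarian[config$gene, config$exon_group, config$age_group]
      if (isTRUE(config$rrso_active)) {
        base <- base * (1 - eff$rrbso_ovarian_rr_reduction[[config$gene]])
      }
      base
    },
    death_other = {
      base <- r$other[step, config$age_group]
      if (isTRUE(config$rrso_active) && isTRUE(config$rrso_excess)) {
        base <- base * p$rrso_excess_noncancer_mortality
      }
      base
    },
    death_oc = {
      if (is.null(config$oc_stage) || is.na(config$oc_stage)) 0
      else r$oc_death[[config$oc_stage]]
    },
    death_bc = {
      rate <- r$first_primary_bc[step, config$stage, config$subtype]
      if (isTRUE(config$chemo)) {
        rate <- rate * (1 - eff$chemo_bc_mortality_reduction)
      }
      if (isTRUE(config$tamoxifen_5y) && config$subtype == "luminal" &&
          step <= network$steps15) {
        rate <- rate * network$tamoxifen_mortality_hr[
          config$stage, if (isTRUE(config$chemo)) "chemo" else "nochemo"]
      }
      for (ev in c("contralateral", "ipsilateral")) {
        j <- config[[paste0(ev, "_steps_since")]]
        if (!is.null(j) && !is.na(j) && j >= 1) {
          st <- config[[paste0(ev, "_stage")]]
          su <- config[[paste0(ev, "_subtype")]]
          rate <- rate + network$rates$second_event[min(j, network$n_steps),
                                                    st, su]
        }
      }
      rate
    },
    stop("unknown hazard variable: ", variable)
  )
}

# Per-step activation probability of rrso_performed: uniform over the steps
# of the timing window. A zero-length window means RRSO at time zero (the
# node is already true before the first step).
rrso_activation_prob <- function(network, step, rrbso_in_policy) {
  if (!rrbso_in_policy) return(0)
  w <- rrso_window_steps(network)
  if (w == 0L) return(if (step == 1L) 1 else 0) # degenerate: certain at entry
  if (step > w) return(0)
  1 / (w - step + 1)
}

#' Conditional probability table of a temporal node
#'
#' Assembles the conditional table of one temporal variable at one step:
#' one row per configuration of its discrete parents (static covariates,
#' policy components, and the states of its temporal parents at the previous
#' step), with columns `p_true` and `p_false` summing to 1. Absorption is
#' explicit: every row with the variable already true at the previous step
#' has `p_true = 1`.
#'
#' For `death_bc`, the table is conditioned on a second-event state passed
#' via `extra` (default: no second event); the full time-dependence on steps
#' since detection is exercised by the simulator.
#'
#' @param network A `temporal_network`.
#' @param variable One of the temporal variable names.
#' @param step Step index in `1:network$n_steps`.
#' @param extra Named list of additional conditioning values (e.g.
#'   `contralateral_steps_since`, `contralateral_stage`,
#'   `contralateral_subtype`, `oc_stage`, `rrso_excess`).
#' @return A data frame, one row per parent configuration.
#' @export
cpt <- function(network, variable, step, extra = list()) {
  if (!inherits(network, "temporal_network")) {
    stop("`network` must be a temporal_network")
  }
  if (!variable %in% network$variables) {
    stop("unknown temporal variable: ", variable)
  }
  if (step < 1 || step > network$n_steps) {
    stop("step out of range: ", step, " (network has ", network$n_steps,
         " steps)")
  }
  dt <- network$step_years
  parents <- switch(variable,
    ipsilateral_event = expand.grid(
      chemo = c(FALSE, TRUE), ipsilateral_mastectomy = c(FALSE, TRUE),
      rrso_active = c(FALSE, TRUE), prev = c(FALSE, TRUE),
      KEEP.OUT.ATTRS = FALSE),
    contralateral_bc = expand.grid(
      gene = brca_genes(), age_group = brca_age_groups(),
      tamoxifen_5y = c(FALSE, TRUE), contralateral_mastectomy = c(FALSE, TRUE),
      prev = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE,
      stringsAsFactors = FALSE),
    ovarian_cancer = expand.grid(
      gene = brca_genes(), exon_group = brca_exon_groups(),
      age_group = brca_age_groups(), rrso_active = c(FALSE, TRUE),
      prev = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE,
      stringsAsFactors = FALSE),
    rrso_performed = expand.grid(
      rrbso = c(FALSE, TRUE), prev = c(FALSE, TRUE),
      KEEP.OUT.ATTRS = FALSE),
    death_bc = expand.grid(
      stage = brca_stages(), subtype = brca_subtypes(),
      chemo = c(FALSE, TRUE), tamoxifen_5y = c(FALSE, TRUE),
      prev = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE,
      stringsAsFactors = FALSE),
    death_oc = expand.grid(
      oc_stage = c(NA_character_, names(network$rates$oc_death)),
      prev = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE,
      stringsAsFactors = FALSE),
    death_other = expand.grid(
      age_group = brca_age_groups(), rrso_active = c(FALSE, TRUE),
      rrso_excess = c(FALSE, TRUE), prev = c(FALSE, TRUE),
      KEEP.OUT.ATTRS = FALSE)
  )
  p_true <- numeric(nrow(parents))
  for (i in seq_len(nrow(parents))) {
    row <- as.list(parents[i, , drop = FALSE])
    if (isTRUE(row$prev)) {
      p_true[i] <- 1 # absorbing
    } else if (variable == "rrso_performed") {
      p_true[i] <- rrso_activation_prob(network, step, isTRUE(row$rrbso))
    } else {
      cfg <- c(row, extra[setdiff(names(extra), names(row))])
      p_true[i] <- -expm1(-hazard_rate(network, variable, step, cfg) * dt)
    }
  }
  parents$p_true <- p_true
  parents$p_false <- 1 - p_true
  parents
}

#' Edge list of the canonical DAG
#'
#' Returns the directed edges of the unrolled network as a data frame of
#' `from`/`to` node labels (`variable@step`, static nodes at step 0),
#' suitable for export and acyclicity checks.
#'
#' @param network A `temporal_network`.
#' @return Data frame with columns `from`, `to`, `from_step`, `to_step`.
#' @export
network_edges <- function(network) {
  n <- network$n_steps
  statics <- c("gene", "exon_group", "age_group", "subtype", "stage",
               "chemo", "policy")
  static_parents <- list(
    ipsilateral_event = c("chemo", "policy"),
    contralateral_bc = c("gene", "age_group", "policy"),
    ovarian_cancer = c("gene", "exon_group", "age_group", "policy"),
    rrso_performed = c("policy", "age_group"),
    death_bc = c("stage", "subtype", "chemo", "policy"),
    death_oc = character(0),
    death_other = c("age_group", "policy")
  )
  temporal_parents <- list(
    ipsilateral_event = "rrso_performed",
    contralateral_bc = character(0),
    ovarian_cancer = "rrso_performed",
    rrso_performed = character(0),
    death_bc = c("ipsilateral_event", "contralateral_bc"),
    death_oc = "ovarian_cancer",
    death_other = "rrso_performed"
  )
  from <- to <- character(0)
  from_step <- to_step <- integer(0)
  add <- function(f, fs, t, ts) {
    from <<- c(from, f); to <<- c(to, t)
    from_step <<- c(from_step, fs); to_step <<- c(to_step, ts)
  }
  for (v in network$variables) {
    for (k in seq_len(n)) {
      node <- paste0(v, "@", k)
      for (s in static_parents[[v]]) add(s, 0L, node, k)
      if (k > 1) {
        add(paste0(v, "@", k - 1), k - 1L, node, k) # absorption link
        for (tp in temporal_parents[[v]]) {
          add(paste0(tp, "@", k - 1), k - 1L, node, k)
        }
      }
    }
  }
  data.frame(from = from, to = to, from_step = from_step, to_step = to_step,
             stringsAsFactors = FALSE)
}

#' Export the DAG in DOT format
#'
#' @param network A `temporal_network`.
#' @param path Output file path (`.dot`).
#' @return `path`, invisibly.
#' @export
export_network_dot <- function(network, path) {
  edges <- network_edges(network)
  lines <- c("digraph temporal_network {",
             "  rankdir=LR;",
             sprintf("  \"%s\" -> \"%s\";", edges$from, edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
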