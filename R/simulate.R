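# Monte-Carlo forward sampling through the unrolled network.
#
# Patients are simulated cell by cell (cohort x policy), vectorised over
# patients within a cell. Within each step, event variables are sampled
# before death variables, so a second cancer detected at step k contributes
# to breast-cancer mortality from step k+1 onward. Ties among death causes
# within a step are resolved by the fixed priority breast cancer > ovarian
# cancer > other; the tie-break affects cause attribution only, never the
# survival time.

#' Allocate simulated patients across cohort x policy cells
#'
#' Uniform allocation with a round-robin remainder rule: every cell receives
#' `floor(n_total / n_cells)` patients and the first `n_total %% n_cells`
#' cells in enumeration order receive one extra.
#'
#' @param n_total Total number of simulated patients; must be at least the
#'   number of cells.
#' @param cohorts Data frame of cohorts, as from [enumerate_cohorts()].
#' @param policies Data frame of policies, as from [enumerate_policies()].
#' @return Data frame with columns `cohort_idx`, `policy_idx`, `n`, one row
#'   per cell in enumeration order (policy varying fastest).
#' @examples
#' a <- allocate(1e6, enumerate_cohorts(), enumerate_policies())
#' range(a$n) # around 770 patients per cell
#' @export
allocate <- function(n_total, cohorts, policies) {
  n_cells <- nrow(cohorts) * nrow(policies)
  if (n_total < n_cells) {
    stop("n_total (", n_total, ") must be at least the number of cells (",
         n_cells, ")")
  }
  base <- n_total %/% n_cells
  rem <- n_total %% n_cells
  n <- rep(base, n_cells)
  if (rem > 0) n[seq_len(rem)] <- n[seq_len(rem)] + 1L
  out <- expand.grid(policy_idx = seq_len(nrow(policies)),
                     cohort_idx = seq_len(nrow(cohorts)),
                     KEEP.OUT.ATTRS = FALSE)[, c("cohort_idx", "policy_idx")]
  out$n <- n
  rownames(out) <- NULL
  out
}

cell_seed <- function(root_seed, cohort_idx, policy_idx) {
  as.integer((as.numeric(root_seed) %% 1e6) * 2011 +
               cohort_idx * 131071 + policy_idx * 8191) %% 2147483629L
}

#' Simulate patients with individual covariates under one policy
#'
#' The workhorse sampler: ancestral sampling of the temporal network, step
#' by step, vectorised over patients. All patients share the policy; each
#' row of `covariates` gives one patient's static covariates. Sampling stops
#' for a patient once any death variable activates; survivors are censored
#' at the horizon.
#'
#' @param network A `temporal_network` from [build_network()].
#' @param covariates Data frame with columns `gene`, `exon_group`,
#'   `age_group`, `subtype`, `stage`, `chemo` (one row per patient).
#' @param policy A one-row policy data frame (see [policy_by_id()]).
#' @param seed Integer seed for this simulation.
#' @return Data frame of patient records: the covariates, `policy`, first
#'   activation times `rrso_time`, `ipsilateral_time`, `contralateral_time`,
#'   `ovarian_time` (NA if never), `survival_time`, `event` (death
#'   indicator) and `cause` (`"breast cancer"`, `"ovarian cancer"`,
#'   `"other"`, or `"censored"`).
#' @export
simulate_patients <- function(network, covariates, policy, seed) {
  stopifnot(inherits(network, "temporal_network"))
  set.seed(as.integer(seed) %% 2147483647L)
  n <- nrow(covariates)
  p <- network$params
  eff <- p$effects
  r <- network$rates
  dt <- network$step_years
  n_steps <- network$n_steps

  gi <- match(covariates$gene, brca_genes())
  ei <- match(covariates$exon_group, brca_exon_groups())
  ai <- match(covariates$age_group, brca_age_groups())
  ui <- match(covariates$subtype, brca_subtypes())
  si <- match(covariates$stage, brca_stages())
  ch <- as.logical(covariates$chemo)
  if (anyNA(gi) || anyNA(ei) || anyNA(ai) || anyNA(ui) || anyNA(si) ||
      anyNA(ch)) {
    stop("covariates contain values outside the documented domains")
  }
  rep_age <- representative_age(covariates$age_group)

  has_cm <- isTRUE(policy$contralateral_mastectomy)
  has_im <- isTRUE(policy$ipsilateral_mastectomy)
  has_bso <- isTRUE(policy$rrbso)
  has_tam <- isTRUE(policy$tamoxifen_5y)

  w_steps <- rrso_window_steps(network)

  # Per-patient constant multipliers
  ipsi_mult <- ifelse(ch, 1 - eff$chemo_ipsilateral_reduction, 1)
  contra_mult <- rep(1, n)
  if (has_tam) {
    contra_mult <- contra_mult *
      (1 - eff$tamoxifen_contralateral_reduction[gi])
  }
  if (has_cm) {
    contra_mult <- contra_mult * (1 - eff$mastectomy_contralateral_reduction)
  }
  ov_base <- r$ovarian[cbind(gi, ei, ai)]
  ov_red <- 1 - eff$rrbso_ovarian_rr_reduction[gi]
  bc_chemo_mult <- ifelse(ch, 1 - eff$chemo_bc_mortality_reduction, 1)
  tam_hr <- if (has_tam) {
    network$tamoxifen_mortality_hr[cbind(si, ifelse(ch, 2L, 1L))]
  } else {
    rep(1, n)
  }
  tam_hr[covariates$subtype != "luminal"] <- 1
  ipsi_col <- if (has_im) 2L else 1L

  # State
  alive <- rep(TRUE, n)
  rrso_step <- rep(NA_integer_, n)
  if (has_bso && w_steps == 0L) rrso_step[] <- 0L # RRSO at time zero
  ipsi_step <- contra_step <- ov_step <- rep(NA_integer_, n)
  ipsi_sev_stage <- contra_sev_stage <- rep(NA_integer_, n)
  ipsi_sev_sub <- contra_sev_sub <- rep(NA_integer_, n)
  oc_stage <- rep(NA_integer_, n)
  death_step <- rep(NA_integer_, n)
  cause <- rep(NA_character_, n)

  sev_dist <- p$second_event_stage_distribution /
    sum(p$second_event_stage_distribution)
  oc_dist <- p$oc_stage_distribution / sum(p$oc_stage_distribution)
  n_sev <- length(sev_dist)
  oc_death_rate <- r$oc_death

  sample_sev <- function(k_idx) {
    # stage from the second-event distribution; subtype by the gene's
    # triple-negative prevalence
    st <- sample.int(n_sev, length(k_idx), replace = TRUE, prob = sev_dist)
    tn <- stats::runif(length(k_idx)) < p$tn_prevalence[gi[k_idx]]
    list(stage = st, subtype = ifelse(tn, 2L, 1L))
  }

  for (k in seq_len(n_steps)) {
    idx <- which(alive)
    if (!length(idx)) break

    # --- RRSO activation (uniform over the timing window)
    if (has_bso && w_steps > 0L && k <= w_steps) {
      cand <- idx[is.na(rrso_step[idx])]
      if (length(cand)) {
        act <- cand[stats::runif(length(cand)) < 1 / (w_steps - k + 1)]
        rrso_step[act] <- k
      }
    }
    rrso_active <- !is.na(rrso_step) & rrso_step < k

    # --- event variables (before death variables)
    at <- idx[is.na(ipsi_step[idx])]
    if (length(at)) {
      rate <- r$ipsilateral[k, ipsi_col] * ipsi_mult[at] *
        ifelse(rrso_active[at], 1 - eff$rrbso_ipsilateral_reduction, 1)
      hit <- at[stats::runif(length(at)) < -expm1(-rate * dt)]
      if (length(hit)) {
        ipsi_step[hit] <- k
        sv <- sample_sev(hit)
        ipsi_sev_stage[hit] <- sv$stage
        ipsi_sev_sub[hit] <- sv$subtype
      }
    }

    at <- idx[is.na(contra_step[idx])]
    if (length(at)) {
      rate <- r$contralateral[cbind(k, gi[at], ai[at])] * contra_mult[at]
      hit <- at[stats::runif(length(at)) < -expm1(-rate * dt)]
      if (length(hit)) {
        contra_step[hit] <- k
        sv <- sample_sev(hit)
        contra_sev_stage[hit] <- sv$stage
        contra_sev_sub[hit] <- sv$subtype
      }
    }

    at <- idx[is.na(ov_step[idx])]
    if (length(at)) {
      rate <- ov_base[at] * ifelse(rrso_active[at], ov_red[at], 1)
      hit <- at[stats::runif(length(at)) < -expm1(-rate * dt)]
      if (length(hit)) {
        ov_step[hit] <- k
        oc_stage[hit] <- sample.int(length(oc_dist), length(hit),
                                    replace = TRUE, prob = oc_dist)
      }
    }

    # --- death variables
    # breast cancer: first primary + detected second events (active from the
    # step after detection)
    rate_bc <- r$first_primary_bc[cbind(k, si[idx], ui[idx])] *
      bc_chemo_mult[idx]
    if (k <= network$steps15) {
      rate_bc <- rate_bc * tam_hr[idx]
    }
    cactive <- !is.na(contra_step[idx]) & contra_step[idx] < k
    if (any(cactive)) {
      ii <- idx[cactive]
      j <- pmin(k - contra_step[ii], n_steps)
      rate_bc[cactive] <- rate_bc[cactive] +
        r$second_event[cbind(j, contra_sev_stage[ii], contra_sev_sub[ii])]
    }
    if (!has_im) { # local failures after mastectomy carry no mortality
      iactive <- !is.na(ipsi_step[idx]) & ipsi_step[idx] < k
      if (any(iactive)) {
        ii <- idx[iactive]
        j <- pmin(k - ipsi_step[ii], n_steps)
        rate_bc[iactive] <- rate_bc[iactive] +
          r$second_event[cbind(j, ipsi_sev_stage[ii], ipsi_sev_sub[ii])]
      }
    }
    d_bc <- stats::runif(length(idx)) < -expm1(-rate_bc * dt)

    oactive <- !is.na(ov_step[idx]) & ov_step[idx] < k
    rate_oc <- ifelse(oactive, oc_death_rate[oc_stage[idx]], 0)
    rate_oc[is.na(rate_oc)] <- 0
    d_oc <- stats::runif(length(idx)) < -expm1(-rate_oc * dt)

    excess <- rrso_active[idx] & rep_age[idx] < 40 &
      (rep_age[idx] + pmax(rrso_step[idx], 0) * dt) < 45
    rate_ot <- r$other[k, ai[idx]] *
      ifelse(excess, p$rrso_excess_noncancer_mortality, 1)
    d_ot <- stats::runif(length(idx)) < -expm1(-rate_ot * dt)

    died <- d_bc | d_oc | d_ot
    if (any(died)) {
      who <- idx[died]
      death_step[who] <- k
      # priority: breast cancer > ovarian cancer > other
      cz <- ifelse(d_bc[died], "breast cancer",
                   ifelse(d_oc[died], "ovarian cancer", "other"))
      cause[who] <- cz
      alive[who] <- FALSE
    }
  }

  event <- !is.na(death_step)
  out <- covariates
  rownames(out) <- NULL
  out$policy <- policy$id
  out$rrso_time <- ifelse(is.na(rrso_step), NA_real_, rrso_step * dt)
  out$ipsilateral_time <- ipsi_step * dt
  out$contralateral_time <- contra_step * dt
  out$ovarian_time <- ov_step * dt
  out$survival_time <- ifelse(event, death_step * dt, network$horizon)
  out$event <- event
  out$cause <- ifelse(event, cause, "censored")
  out
}

#' Simulate one homogeneous cohort under one policy
#'
#' @param network A `temporal_network`.
#' @param cohort One-row data frame with the cohort covariates (a row of
#'   [enumerate_cohorts()]).
#' @param policy One-row policy data frame.
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return Patient records, as for [simulate_patients()].
#' @export
simulate_cohort <- function(network, cohort, policy, n, seed) {
  covs <- cohort[rep(1L, n),
                 c("gene", "exon_group", "age_group", "subtype", "stage",
                   "chemo"), drop = FALSE]
  simulate_patients(network, covs, policy, seed)
}

#' Run the full micro-simulation over an allocation
#'
#' Simulates every cohort x policy cell of `allocation`, deriving one seed
#' substream per cell from the root seed so the run is reproducible and
#' cells are independent.
#'
#' @param network A `temporal_network`.
#' @param allocation Allocation data frame from [allocate()].
#' @param seed Root integer seed.
#' @param cohorts,policies The enumerations the allocation refers to;
#'   default to the full [enumerate_cohorts()] / [enumerate_policies()].
#' @return Data frame of patient records for all cells, in allocation order.
#' @export
simulate_study <- function(network, allocation, seed,
                           cohorts = enumerate_cohorts(),
                           policies = enumerate_policies()) {
  res <- vector("list", nrow(allocation))
  for (i in seq_len(nrow(allocation))) {
    ci <- allocation$cohort_idx[i]
    pi <- allocation$policy_idx[i]
    ni <- allocation$n[i]
    if (ni == 0L) next
    res[[i]] <- simulate_cohort(network, cohorts[ci, , drop = FALSE],
                                policies[pi, , drop = FALSE], ni,
                                cell_seed(seed, ci, pi))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract the survival triple of a patient record
#'
#' @param record A one-row patient record (or a data frame; all rows are
#'   returned).
#' @return Data frame with columns `time`, `event`, `cause`.
#' @export
survival_of <- function(record) {
  data.frame(time = record$survival_time,
             event = record$event,
             cause = record$cause,
             stringsAsFactors = FALSE)
}
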