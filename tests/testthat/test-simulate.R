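test_that("allocation is uniform with a round-robin remainder", {
  co <- enumerate_cohorts(); pol <- enumerate_policies()
  a <- allocate(1296, co, pol)
  expect_true(all(a$n == 1))
  a2 <- allocate(1297, co, pol)
  expect_equal(sort(unique(a2$n)), c(1, 2))
  expect_equal(sum(a2$n == 2), 1)
  expect_equal(sum(a2$n), 1297)
  a3 <- allocate(1e6, co, pol)
  expect_equal(sum(a3$n), 1e6)
  expect_true(max(a3$n) - min(a3$n) <= 1) # cells differ by at most one
  expect_error(allocate(100, co, pol), "at least")
})

test_that("zero hazards censor everyone at the horizon", {
  net <- build_network(zero_risk_parameters(), 40, 1)
  rec <- simulate_cohort(net, test_cohort(), policy_by_id("surveillance"),
                         500, 11)
  expect_true(all(rec$cause == "censored"))
  expect_true(all(!rec$event))
  expect_true(all(rec$survival_time == 40))
})

test_that("a near-certain other-cause hazard kills everyone at step one", {
  p <- zero_risk_parameters()
  p$other_cause_mortality$annual_prob[] <- 1 - 1e-12
  net <- build_network(p, 40, 1)
  rec <- simulate_cohort(net, test_cohort(), policy_by_id("surveillance"),
                         200, 5)
  expect_true(all(rec$survival_time == 1))
  expect_true(all(rec$cause == "other"))
})

test_that("records respect absorption and survival-time construction", {
  net <- build_network(default_parameters(), 40, 1)
  rec <- simulate_cohort(net, test_cohort(chemo = FALSE),
                         policy_by_id("RRBSO"), 3000, 77)
  # survival time equals horizon iff censored
  expect_equal(rec$survival_time == 40 & !rec$event,
               rec$cause == "censored")
  # event times never exceed the survival time
  for (col in c("ipsilateral_time", "contralateral_time", "ovarian_time")) {
    tt <- rec[[col]]
    expect_true(all(is.na(tt) | tt <= rec$survival_time))
  }
  # RRSO occurs within the 5-year window for everyone in an RRBSO policy
  expect_true(all(!is.na(rec$rrso_time) | rec$survival_time < 5))
  expect_true(all(is.na(rec$rrso_time) | rec$rrso_time <= 5))
  # survival_of mirrors the record fields
  sv <- survival_of(rec)
  expect_equal(sv$time, rec$survival_time)
  expect_equal(sv$cause, rec$cause)
})

test_that("identical seeds and inputs reproduce records exactly", {
  net <- build_network(default_parameters(), 40, 1)
  co <- enumerate_cohorts(); pol <- enumerate_policies()
  a <- allocate(2592, co, pol)
  r1 <- simulate_study(net, a, seed = 123)
  r2 <- simulate_study(net, a, seed = 123)
  expect_identical(r1, r2)
  r3 <- simulate_study(net, a, seed = 124)
  expect_false(identical(r1$survival_time, r3$survival_time))
})

test_that("a single constant hazard reproduces its cumulative incidence", {
  p <- zero_risk_parameters()
  h <- 0.03 # annual probability
  p$other_cause_mortality$annual_prob[] <- h
  net <- build_network(p, 40, 1)
  n <- 100000
  rec <- simulate_cohort(net, test_cohort(), policy_by_id("surveillance"),
                         n, 202)
  for (t in c(5, 10, 20)) {
    expected <- 1 - (1 - h)^t
    observed <- mean(rec$survival_time <= t & rec$event)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(observed - expected), 3 * se)
  }
})

test_that("cause priority attributes ties to breast cancer first", {
  p <- zero_risk_parameters()
  # two competing near-certain hazards at step 1
  p$bc_mortality$luminal$I <- risk_schedule(c(10, 40), c(0.99999, 0.999995))
  p$other_cause_mortality$annual_prob[] <- 0.99999
  net <- build_network(p, 40, 1)
  rec <- simulate_cohort(net, test_cohort(), policy_by_id("surveillance"),
                         500, 9)
  died_y1 <- rec$survival_time == 1
  expect_gt(mean(died_y1), 0.95)
  # when both death draws fire, breast cancer wins the attribution
  expect_gt(mean(rec$cause[died_y1] == "breast cancer"), 0.5)
  expect_true(all(rec$cause[died_y1] %in% c("breast cancer", "other")))
})

test_that("RRSO before 45 with onset before 40 raises other-cause mortality", {
  p <- zero_risk_parameters()
  p$other_cause_mortality$annual_prob[] <- 0.01
  p$rrso_excess_noncancer_mortality <- 2.0
  p$rrso_timing_window_years <- 0 # RRSO at diagnosis
  net <- build_network(p, 40, 1)
  young <- test_cohort(age = "<40")
  n <- 60000
  a <- simulate_cohort(net, young, policy_by_id("surveillance"), n, 31)
  b <- simulate_cohort(net, young, policy_by_id("RRBSO"), n, 32)
  fit <- cox_hr(c(a$survival_time, b$survival_time),
                c(a$event, b$event),
                factor(rep(c("ref", "rrso"), c(n, n)),
                       levels = c("ref", "rrso")))
  expect_lt(abs(fit$hr[["rrso"]] - 2.0), 3 * fit$se[["rrso"]] * 2.0)
  # no excess for an older cohort (RRSO after 45)
  old <- test_cohort(age = "40-50")
  a2 <- simulate_cohort(net, old, policy_by_id("surveillance"), n, 33)
  b2 <- simulate_cohort(net, old, policy_by_id("RRBSO"), n, 34)
  fit2 <- cox_hr(c(a2$survival_time, b2$survival_time),
                 c(a2$event, b2$event),
                 factor(rep(c("ref", "rrso"), c(n, n)),
                        levels = c("ref", "rrso")))
  expect_lt(abs(fit2$hr[["rrso"]] - 1.0), 3 * fit2$se[["rrso"]])
})
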