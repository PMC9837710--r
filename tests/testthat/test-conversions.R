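# Frozen expected values below were computed with high-precision evaluation
# of the closed forms (-log(1-p)/o and 1-exp(-rate*c)).

test_that("annual_rate matches the closed form and rejects bad input", {
  expect_equal(annual_rate(0, 10), 0)
  expect_equal(annual_rate(0.27, 10), 0.03147107448397, tolerance = 1e-10)
  expect_equal(annual_rate(0.5, 1), 0.6931471805599, tolerance = 1e-10)
  expect_error(annual_rate(1, 10), "probability")
  expect_error(annual_rate(-0.1, 10), "probability")
  expect_error(annual_rate(0.5, 0), "horizon")
})

test_that("interval_probability matches the closed form and round-trips", {
  expect_equal(interval_probability(0, 1), 0)
  expect_equal(interval_probability(annual_rate(0.19, 10), 10), 0.19,
               tolerance = 1e-12)
  expect_equal(interval_probability(0.0693147, 1), 0.06696699161635,
               tolerance = 1e-9)
  expect_error(interval_probability(-0.1, 1), "non-negative")
  expect_error(interval_probability(0.1, 0), "positive")
})

test_that("round-trip holds to 1e-12 across a parameter grid", {
  for (p in seq(0, 0.99, by = 0.09)) {
    for (o in c(1, 2, 5, 10, 25, 40)) {
      expect_equal(interval_probability(annual_rate(p, o), o), p,
                   tolerance = 1e-12)
    }
  }
})

test_that("annual_rate and interval_probability are monotone", {
  ps <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(annual_rate(ps, 10)) > 0))
  os <- 1:40
  expect_true(all(diff(annual_rate(0.3, os)) < 0))
  rates <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(interval_probability(rates, 2)) > 0))
  cs <- 1:40
  expect_true(all(diff(interval_probability(0.05, cs)) > 0))
})

test_that("apply_hazard_ratio identities hold exactly", {
  expect_identical(apply_hazard_ratio(0.9, 1), 0.9)
  expect_identical(apply_hazard_ratio(1.0, 7.3), 1.0)
  expect_equal(apply_hazard_ratio(0.9, 2), 0.81)
  expect_true(apply_hazard_ratio(0.9, 2) < 0.9) # hr > 1 lowers survival
  expect_error(apply_hazard_ratio(0, 0), "ref_survival")
  expect_error(apply_hazard_ratio(0.9, -1), "hazard ratio")
})

test_that("stepwise probabilities reproduce schedule boundaries", {
  # single segment: equal per-step probabilities composing to 0.27 at 10y
  q <- stepwise_probabilities(risk_schedule(10, 0.27), step = 1, horizon = 10)
  expect_length(q, 10)
  expect_equal(diff(range(q)), 0)
  expect_equal(q[1], interval_probability(annual_rate(0.27, 10), 1))
  expect_equal(1 - prod(1 - q), 0.27, tolerance = 1e-9)

  # zero-risk segment gives all-zero steps
  expect_equal(stepwise_probabilities(risk_schedule(10, 0), 1, 10),
               rep(0, 10))

  # two segments: brute-force cumulative reconstruction at both boundaries
  sch <- risk_schedule(c(5, 10), c(0.1, 0.27))
  q <- stepwise_probabilities(sch, step = 1, horizon = 10)
  expect_equal(1 - prod(1 - q[1:5]), 0.1, tolerance = 1e-9)
  expect_equal(1 - prod(1 - q), 0.27, tolerance = 1e-9)
  # first five steps follow rate(0.1, 5)
  expect_equal(q[1:5], rep(interval_probability(annual_rate(0.1, 5), 1), 5),
               tolerance = 1e-12)

  # schedule shorter than the horizon: last hazard extended
  q <- stepwise_probabilities(risk_schedule(10, 0.27), 1, 20)
  expect_length(q, 20)
  expect_equal(diff(range(q)), 0, tolerance = 1e-15)

  expect_error(stepwise_probabilities(risk_schedule(10, 0.2), 3, 10),
               "divide")
})

test_that("halving the step leaves cumulative incidence invariant", {
  sch <- risk_schedule(c(5, 10, 25), c(0.08, 0.2, 0.4))
  for (s in c(1, 0.5)) {
    q1 <- stepwise_probabilities(sch, s, 40)
    q2 <- stepwise_probabilities(sch, s / 2, 40)
    cum1 <- 1 - cumprod(1 - q1)
    cum2 <- 1 - cumprod(1 - q2)
    # compare at common time points (every step of the coarser grid)
    expect_equal(cum1, cum2[seq(2, length(cum2), by = 2)], tolerance = 1e-9)
  }
})
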