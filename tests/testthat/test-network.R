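test_that("network size follows horizon and step", {
  p <- default_parameters()
  net <- build_network(p, 40, 1)
  expect_equal(net$n_steps, 40)
  net2 <- build_network(p, 15, 2.5)
  expect_equal(net2$n_steps, 6)
  expect_error(build_network(p, 40, 3), "multiple of")
})

test_that("every CPT row is a distribution and absorption holds", {
  net <- build_network(default_parameters(), 20, 1)
  for (v in net$variables) {
    for (k in c(1, 7, 20)) {
      tab <- cpt(net, v, k)
      expect_true(all(tab$p_true >= 0 & tab$p_true <= 1),
                  info = paste(v, k))
      expect_equal(tab$p_true + tab$p_false, rep(1, nrow(tab)),
                   tolerance = 1e-12)
      expect_true(all(tab$p_true[tab$prev] == 1), info = paste(v, k))
    }
  }
  expect_error(cpt(net, "no_such_variable", 1), "unknown")
  expect_error(cpt(net, "death_bc", 99), "out of range")
})

test_that("the unrolled network is a DAG with only forward edges", {
  net <- build_network(default_parameters(), 10, 1)
  edges <- network_edges(net)
  expect_true(all(edges$from_step <= edges$to_step))
  # edges within a step only come from static (step 0) nodes
  same <- edges$from_step == edges$to_step
  expect_true(all(edges$from_step[same] == 0))
  expect_equal(sum(grepl("^ovarian_cancer@", edges$from) &
                     grepl("^death_oc@", edges$to)), net$n_steps - 1)
  dot <- tempfile(fileext = ".dot")
  export_network_dot(net, dot)
  expect_true(any(grepl("->", readLines(dot))))
})

test_that("CPTs encode the published intervention effects on the rate scale", {
  p <- default_parameters()
  net <- build_network(p, 40, 1)

  # chemotherapy multiplies the ipsilateral rate by 1 - 0.49
  tab <- cpt(net, "ipsilateral_event", 5)
  base <- tab$p_true[!tab$chemo & !tab$ipsilateral_mastectomy &
                       !tab$rrso_active & !tab$prev]
  chemo <- tab$p_true[tab$chemo & !tab$ipsilateral_mastectomy &
                        !tab$rrso_active & !tab$prev]
  expect_equal(log1p(-chemo) / log1p(-base), 1 - 0.49, tolerance = 1e-9)
  # RRSO multiplies it by 1 - 0.58
  rrso <- tab$p_true[!tab$chemo & !tab$ipsilateral_mastectomy &
                       tab$rrso_active & !tab$prev]
  expect_equal(log1p(-rrso) / log1p(-base), 1 - 0.58, tolerance = 1e-9)
  # mastectomy switches to the post-mastectomy schedule
  mast <- tab$p_true[!tab$chemo & tab$ipsilateral_mastectomy &
                       !tab$rrso_active & !tab$prev]
  q_mast <- stepwise_probabilities(p$ipsilateral_risk$mastectomy, 1, 40)[5]
  expect_equal(mast, q_mast, tolerance = 1e-12)

  # contralateral: unaffected by RRSO (no such parent), reduced by tamoxifen
  tabc <- cpt(net, "contralateral_bc", 3)
  expect_false("rrso_active" %in% names(tabc))
  pick <- function(g, tam) {
    tabc$p_true[tabc$gene == g & tabc$age_group == "40-50" &
                  tabc$tamoxifen_5y == tam & !tabc$contralateral_mastectomy &
                  !tabc$prev]
  }
  expect_equal(log1p(-pick("BRCA1", TRUE)) / log1p(-pick("BRCA1", FALSE)),
               1 - 0.56, tolerance = 1e-9)
  expect_equal(log1p(-pick("BRCA2", TRUE)) / log1p(-pick("BRCA2", FALSE)),
               1 - 0.67, tolerance = 1e-9)

  # ovarian: RRSO reduces the rate by 80% (BRCA1) / 79% (BRCA2)
  tabo <- cpt(net, "ovarian_cancer", 2)
  picko <- function(g, rrso) {
    tabo$p_true[tabo$gene == g & tabo$exon_group == "exon 11" &
                  tabo$age_group == "40-50" & tabo$rrso_active == rrso &
                  !tabo$prev][1]
  }
  expect_equal(log1p(-picko("BRCA1", TRUE)) / log1p(-picko("BRCA1", FALSE)),
               0.20, tolerance = 1e-9)
  expect_equal(log1p(-picko("BRCA2", TRUE)) / log1p(-picko("BRCA2", FALSE)),
               0.21, tolerance = 1e-9)

  # death_other without RRSO equals the attained-age annual probability
  tabd <- cpt(net, "death_other", 1)
  ocm <- p$other_cause_mortality
  for (a in brca_age_groups()) {
    expected <- ocm$annual_prob[findInterval(representative_age(a), ocm$age)]
    got <- tabd$p_true[tabd$age_group == a & !tabd$rrso_active &
                         !tabd$rrso_excess & !tabd$prev]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("zeroing every intervention effect makes CPTs policy-invariant", {
  p <- default_parameters()
  for (k in names(p$effects)) p$effects[[k]][] <- 0
  p$ipsilateral_risk$mastectomy <- p$ipsilateral_risk$bct
  p$rrso_excess_noncancer_mortality <- 1
  net <- build_network(p, 20, 1)
  for (v in c("ipsilateral_event", "contralateral_bc", "ovarian_cancer",
              "death_other")) {
    tab <- cpt(net, v, 4)
    # collapse over all policy-driven parents: probabilities must not vary
    pol_cols <- intersect(names(tab),
                          c("ipsilateral_mastectomy",
                            "contralateral_mastectomy", "tamoxifen_5y",
                            "rrso_active", "rrso_excess"))
    other_cols <- setdiff(names(tab), c(pol_cols, "p_true", "p_false"))
    split_key <- do.call(interaction, c(tab[other_cols], drop = TRUE))
    for (grp in split(tab$p_true, split_key)) {
      expect_equal(diff(range(grp)), 0, tolerance = 1e-12)
    }
  }
})

test_that("the 15-year tamoxifen mortality adjustment hits 30% exactly", {
  p <- default_parameters()
  net <- build_network(p, 40, 1)
  # closed-form check on the cumulative hazard implied by the adjusted rate
  for (stage in c("I", "II")) {
    lam15 <- sum(net$rates$first_primary_bc[1:15, stage, "luminal"])
    hr <- net$tamoxifen_mortality_hr[stage, "nochemo"]
    m_base <- 1 - exp(-lam15)
    m_tam <- 1 - exp(-lam15 * hr)
    expect_equal(m_tam / m_base, 0.70, tolerance = 1e-12)
  }
})
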