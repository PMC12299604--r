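test_that("annuity factor equals the explicit discount-factor sum", {
  loop_sum <- function(r, n) sum((1 + r)^-(1:n))
  expect_equal(annuity_factor(0, 5), 5)
  expect_equal(annuity_factor(0.03, 5), 4.579707, tolerance = 1e-6)
  expect_equal(annuity_factor(0.05, 5), 4.329477, tolerance = 1e-6)
  for (r in c(0.01, 0.03, 0.05, 0.2)) {
    for (n in c(1, 5, 30)) {
      expect_equal(annuity_factor(r, n), loop_sum(r, n), tolerance = 1e-12)
    }
  }
})

test_that("dose counts follow population x coverage", {
  expect_equal(doses_administered(1367900, 0.1343, rounded = TRUE), 183709)
  expect_equal(doses_administered(1367900, 0.0385, rounded = TRUE), 52664)
  expect_equal(doses_administered(1367900, 0), 0)
  expect_equal(doses_administered(1367900, 0.1343), 1367900 * 0.1343)
  expect_error(doses_administered(100, 1.2))
})

test_that("programme cost decomposition matches the published breakdown", {
  p <- bp()
  cb <- program_cost(183806, p)
  expect_equal(cb$procurement, 183806 * 166) # 30,511,796 CNY
  expect_equal(cb$consumables, 183806 * 32)  #  5,881,792 CNY
  expect_equal(cb$procurement / 7.17 / 1e6, 4.256, tolerance = 1e-3)
  expect_equal(cb$consumables / 7.17 / 1e6, 0.820, tolerance = 1e-3)
  expect_equal(cb$service / 7.17 / 1e6, 0.26, tolerance = 1e-2)
  expect_equal(cb$total,
               cb$procurement + cb$consumables + cb$service +
                 cb$adverse_events, tolerance = 1e-6)

  zero <- program_cost(0, p)
  expect_equal(zero$total, 0)

  # wastage inflates procurement only
  pw <- bp(vaccine.wastage = 0.01)
  expect_equal(program_cost(1000, pw)$procurement, 1000 * 1.01 * 166)
  expect_equal(program_cost(1000, pw)$consumables,
               program_cost(1000, p)$consumables)
})

test_that("averted cases match hand products and the Markov difference", {
  p <- bp()
  expect_equal(averted_annual_cases(p, 183806, "CAP"),
               183806 * 3.8e-4 * 0.773) # 54.0
  expect_equal(round(averted_annual_cases(p, 183806, "CAP")), 54)
  expect_equal(round(averted_annual_cases(p, 183806, "MENINGITIS"), 1), 0.2)
  expect_equal(round(averted_annual_cases(p, 52684, "CAP")), 15)

  # cross-check against first-cycle incidence difference between equal arms
  doses <- 183806
  tru <- run_cohort(build_transition_matrix(p, "UNVACCINATED"), doses, 5)
  trv <- run_cohort(build_transition_matrix(p, "VACCINATED"), doses, 5)
  for (d in c("CAP", "MENINGITIS")) {
    expect_equal(averted_annual_cases(p, doses, d),
                 annual_cases(tru, d)[1] - annual_cases(trv, d)[1],
                 tolerance = 1e-12)
  }
})

test_that("benefit present value follows the closed discounting form", {
  p <- bp()
  expect_equal(benefit_present_value(p, list(cap = 0, meningitis = 0))$total, 0)

  # CAP only, no caregiver: cases x hospitalization x annuity factor
  p0 <- bp(costs.caregiver_days = ranged(0))
  b <- benefit_present_value(p0, list(cap = 54, meningitis = 0))
  expect_equal(b$total / 7.17, 54 * 10250 * annuity_factor(0.03, 5) / 7.17,
               tolerance = 1e-12)
  expect_equal(b$total / 7.17 / 1e3, 353.5, tolerance = 1e-3) # USD 353.5K

  # free arm at base reproduces the published benefit within 0.5%
  free <- evaluate_strategy(p, "free")
  expect_equal(free$benefit$total / 7.17, 399654.855, tolerance = 5e-3)
  expect_equal(free$benefit$total,
               free$benefit$averted_cap_medical +
                 free$benefit$averted_men_medical +
                 free$benefit$averted_caregiver, tolerance = 1e-6)
})

test_that("net benefit and BCR reproduce the published comparison rows", {
  expect_equal(net_benefit(0, 0), 0)
  expect_equal(net_benefit(399654.855, 5332168.48), -4932513.62,
               tolerance = 1e-8)
  expect_equal(net_benefit(22260.042, 1527876.15), -1505616.11,
               tolerance = 1e-8)
  expect_equal(benefit_cost_ratio(5, 5), 1)
  expect_equal(round(benefit_cost_ratio(399654.855, 5332168.48), 4), 0.075)
  expect_equal(round(benefit_cost_ratio(22260.042, 1527876.15), 3), 0.015)
  expect_error(benefit_cost_ratio(1, 0), "undefined")
})

test_that("ICER divides incremental cost by incremental benefit", {
  mk <- function(cost, benefit) {
    structure(list(cost = list(total = cost), benefit = list(total = benefit)),
              class = "ppv_strategy_result")
  }
  expect_equal(icer(mk(2, 1), mk(1, 0)), 1)
  expect_error(icer(mk(2, 1), mk(1, 1)), "undefined")
  # recovered published comparison values give ~10.08
  expect_equal(icer(mk(5332168.48, 399654.855), mk(1527876.15, 22260.042)),
               10.08, tolerance = 1e-3)
})

test_that("NB > 0 if and only if BCR > 1, over random parameter draws", {
  for (p in draw_sets(10, seed = 11)) {
    r <- evaluate_strategy(p, "free")
    expect_equal(r$net_benefit > 0, r$bcr > 1)
    expect_equal(r$net_benefit, r$benefit$total - r$cost$total,
                 tolerance = 1e-12)
  }
  # a synthetic favorable case to cover the NB > 0 branch
  cheap <- bp(costs.vaccine_price = ranged(0.1),
              costs.consumables_per_dose = ranged(0.01),
              costs.service_per_dose = ranged(0.01))
  r <- evaluate_strategy(cheap, "free")
  expect_true(r$net_benefit > 0)
  expect_true(r$bcr > 1)
})

test_that("benefit responds monotonically to efficacy, costs and discounting", {
  base <- evaluate_strategy(bp(), "free")$benefit$total
  expect_gt(evaluate_strategy(bp(vaccine.ve_pneumonia = 0.9),
                              "free")$benefit$total, base)
  expect_gt(evaluate_strategy(bp(epidemiology.cap_incidence = 45),
                              "free")$benefit$total, base)
  expect_gt(evaluate_strategy(bp(costs.cap_hospitalization = 12000),
                              "free")$benefit$total, base)
  expect_lt(evaluate_strategy(bp(settings.discount_rate = 0.05),
                              "free")$benefit$total, base)
})

test_that("currency conversion round-trips and BCR is coverage-invariant", {
  p <- bp()
  r <- evaluate_strategy(p, "free")
  usd <- convert_currency(r$cost, "USD", p$costs$cny_per_usd$base)
  back <- convert_currency(usd, "CNY", p$costs$cny_per_usd$base)
  expect_equal(back$total, r$cost$total, tolerance = 1e-9)
  expect_equal(usd$currency, "USD")

  # identical per-dose assumptions: free and self arms share one BCR
  self <- evaluate_strategy(p, "self")
  expect_equal(r$bcr, self$bcr, tolerance = 1e-12)
})

test_that("strategy comparison table mirrors the evaluation results", {
  p <- bp()
  tab <- compare_strategies(p)
  expect_equal(tab$strategy, c("free", "self", "none"))
  expect_equal(tab$doses[1], 183709)
  expect_equal(round(tab$bcr[1], 3), 0.075)
  expect_true(is.na(tab$bcr[tab$strategy == "none"]))
  expect_equal(tab$cost_usd, tab$cost_cny / 7.17, tolerance = 1e-12)
  expect_false(is.na(tab$icer_vs_self_paid[1]))
  expect_true(all(is.na(tab$icer_vs_self_paid[-1])))
})
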