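test_that("transition probabilities match the published hand products", {
  p <- bp()
  mu <- build_transition_matrix(p, "UNVACCINATED")
  mv <- build_transition_matrix(p, "VACCINATED")

  expect_equal(mu["HEALTHY", "HOSP_CAP"], 3.8e-4)
  expect_equal(mu["HEALTHY", "HOSP_MENINGITIS"], 2.1e-6)
  expect_equal(mu["HEALTHY", "ALL_CAUSE_DEATH"], 0.00625)
  expect_equal(mv["HEALTHY", "HOSP_CAP"], 3.8e-4 * (1 - 0.773)) # 8.626e-5
  # case fatality = mortality rate / incidence rate
  expect_equal(mu["HOSP_CAP", "PNEUMO_DEATH"], 11.22 / 38)
  expect_equal(mu["HOSP_MENINGITIS", "PNEUMO_DEATH"], 0.08 / 0.21)
  # death rows absorb
  expect_equal(mu["PNEUMO_DEATH", ], c(HEALTHY = 0, HOSP_CAP = 0,
    HOSP_MENINGITIS = 0, PNEUMO_DEATH = 1, ALL_CAUSE_DEATH = 0))
  expect_equal(unname(mu["ALL_CAUSE_DEATH", "ALL_CAUSE_DEATH"]), 1)
})

test_that("zero efficacy makes the vaccinated arm identical to unvaccinated", {
  p <- bp(vaccine.ve_pneumonia = ranged(0), vaccine.ve_meningitis = ranged(0))
  expect_equal(unclass(build_transition_matrix(p, "VACCINATED")),
               unclass(build_transition_matrix(p, "UNVACCINATED")),
               ignore_attr = TRUE)
})

test_that("serotype switch scales effective efficacy", {
  p <- bp()
  p$settings$serotype_switch <- TRUE
  m <- build_transition_matrix(p, "VACCINATED")
  expect_equal(m["HEALTHY", "HOSP_CAP"], 3.8e-4 * (1 - 0.773 * 0.966))
  expect_equal(m["HEALTHY", "HOSP_MENINGITIS"], 2.1e-6 * (1 - 0.59 * 0.966))
})

test_that("mortality exceeding incidence is a named domain error", {
  expect_error(
    build_transition_matrix(bp(epidemiology.cap_mortality = ranged(50)),
                            "UNVACCINATED"),
    "pneumonia.*exceeds 1")
  expect_error(
    build_transition_matrix(bp(epidemiology.men_mortality = ranged(0.6)),
                            "UNVACCINATED"),
    "meningitis")
})

test_that("matrices are row-stochastic for any in-range parameter draw", {
  for (p in draw_sets(25)) {
    for (arm in c("VACCINATED", "UNVACCINATED")) {
      m <- build_transition_matrix(p, arm)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
    }
  }
})

test_that("cohort runs conserve persons and death states never shrink", {
  p <- bp()
  for (arm in c("VACCINATED", "UNVACCINATED")) {
    tr <- run_cohort(build_transition_matrix(p, arm), 1e5, 5)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1e5, 6),
                 tolerance = 1e-6)
    for (st in c("PNEUMO_DEATH", "ALL_CAUSE_DEATH")) {
      expect_true(all(diff(tr$occupancy[, st]) >= -1e-12))
    }
  }
})

test_that("degenerate cohorts behave trivially", {
  p <- bp()
  m <- build_transition_matrix(p, "UNVACCINATED")
  tr0 <- run_cohort(m, 0, 5)
  expect_true(all(tr0$occupancy == 0))
  expect_true(all(annual_cases(tr0, "CAP") == 0))

  ident <- diag(5)
  dimnames(ident) <- list(health_states, health_states)
  tri <- run_cohort(ident, 100, 5)
  expect_equal(unname(tri$occupancy[, "HEALTHY"]), rep(100, 6))
  expect_true(all(tri$incident == 0))

  expect_error(run_cohort(m, -1, 5), "non-negative")
  expect_error(run_cohort(m, 10, 0), "cycles")
})

test_that("run_cohort matches the exhaustive path-enumeration oracle", {
  p <- bp()
  for (arm in c("UNVACCINATED", "VACCINATED")) {
    m <- build_transition_matrix(p, arm)
    tr <- run_cohort(m, 1e5, 5)
    expect_equal(tr$occupancy, enum_occupancy(m, 1e5, 5),
                 tolerance = 1e-9)
  }
  # and for an arbitrary in-range draw
  m2 <- build_transition_matrix(draw_sets(1, seed = 7)[[1]], "VACCINATED")
  expect_equal(run_cohort(m2, 1234, 4)$occupancy,
               enum_occupancy(m2, 1234, 4), tolerance = 1e-9)
})

test_that("first-cycle incident cases match the hand products", {
  p <- bp()
  trv <- run_cohort(build_transition_matrix(p, "VACCINATED"), 183806, 5)
  tru <- run_cohort(build_transition_matrix(p, "UNVACCINATED"), 183806, 5)
  expect_equal(annual_cases(trv, "CAP")[1], 183806 * 3.8e-4 * (1 - 0.773),
               tolerance = 1e-12)
  expect_equal(annual_cases(tru, "CAP")[1], 183806 * 3.8e-4,
               tolerance = 1e-12) # 69.85
  expect_equal(round(annual_cases(trv, "CAP")[1], 2), 15.86)
  expect_equal(round(annual_cases(tru, "CAP")[1], 2), 69.85)
})

test_that("higher pneumonia efficacy strictly lowers cumulative CAP cases", {
  prev <- Inf
  for (ve in c(0.2, 0.5, 0.773, 0.95)) {
    p <- bp(vaccine.ve_pneumonia = ve)
    tr <- run_cohort(build_transition_matrix(p, "VACCINATED"), 1e5, 5)
    tot <- sum(annual_cases(tr, "CAP"))
    expect_lt(tot, prev)
    prev <- tot
  }
})

test_that("cohort traces export tidily", {
  p <- bp()
  tr <- run_cohort(build_transition_matrix(p, "UNVACCINATED"), 1000, 3)
  df <- as.data.frame(tr)
  expect_named(df, c("cycle", "state", "count", "incident_cases"))
  expect_equal(nrow(df), 4 * 5)
  expect_true(all(is.na(df$incident_cases[df$cycle == 0])))
  expect_equal(sum(df$count[df$cycle == 3]), 1000, tolerance = 1e-9)
})
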