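econ_draw <- base_case_draw(load_parameters())

# a hand-built trace: constant occupancy in one state for n cycles
flat_trace <- function(state, n, entry_age = 0) {
  occ <- matrix(0, n + 1, 6, dimnames = list(NULL, c("A", "B", "C", "D",
                                                     "E", "F")))
  occ[, state] <- 1
  structure(list(occupancy = occ, entry_state = state,
                 entry_age = entry_age, hazard_set = "manual",
                 ages = entry_age + 0:n),
            class = "sma_trace")
}

manual_pathway <- function(regimen = "none", entry_age = 0) {
  list(arm = "screening", path_id = "manual", probability = 1,
       entry_state = "A", entry_age = entry_age,
       entry_age_exact = entry_age, regimen = regimen,
       hazard_set = "manual", bridge = "none", clinical_type = "manual")
}

test_that("discount factors follow monthly compounding of the annual rate", {
  expect_equal(discount_factor(0), 1)
  expect_equal(discount_factor(12), 1 / 1.015, tolerance = 1e-12)
  expect_equal(discount_factor(24, 0.03), 1 / 1.03^2, tolerance = 1e-12)
  expect_equal(discount_factor(0:100, 0), rep(1, 101))
  expect_error(discount_factor(-1), "nonnegative")
})

test_that("dose schedules implement the dosing rules", {
  prices <- econ_draw$prices
  # nusinersen steady state: 3 doses per year at 118,000 each
  sch <- regimen_schedule("nusinersen", 1, prices, horizon_months = 120)
  yr <- sch[sch$month >= 24 & sch$month < 36, ]
  expect_equal(nrow(yr), 3)
  expect_equal(sum(yr$cost), 354000)
  # loading doses: 4 within the first ~2 months
  expect_equal(sum(sch$month <= 2), 4)
  # single-dose bridge then gene therapy: total drug cost undiscounted
  stream <- smanbs:::regimen_cost_stream
  s1 <- stream("OA_bridge_1", 1, prices, 960)
  expect_equal(sum(s1$alive) + sum(s1$unconditional),
               118000 + 2910500)
  s4 <- stream("OA_bridge_4", 1, prices, 960)
  expect_equal(sum(s4$alive) + sum(s4$unconditional),
               4 * 118000 + 2910500)
  # risdiplam: dose step-up at age 24 months
  sr <- regimen_schedule("risdiplam", 1, prices, horizon_months = 60)
  expect_equal(unique(sr$cost[1 + sr$month < 24]), 93456 / 12)
  expect_equal(unique(sr$cost[1 + sr$month >= 24]), 354000 / 12)
  # untreated: no dose events
  expect_equal(nrow(regimen_schedule("none", 0, prices)), 0)
  expect_error(regimen_schedule("magic", 0, prices), "should be one of")
})

test_that("a full-health year accrues the annual utility as QALYs", {
  d <- econ_draw
  d$econ$discount_annual <- 0
  d$state_costs_monthly[] <- 0
  out <- pathway_outcomes(flat_trace("A", 12), manual_pathway(), d)
  expect_equal(out$qaly, 0.92, tolerance = 1e-12)
  expect_equal(out$cost, 0)
})

test_that("QALY accrual matches the discounted-annuity closed form", {
  d <- econ_draw
  n <- 240
  out <- pathway_outcomes(flat_trace("B", n, entry_age = 30),
                          manual_pathway(entry_age = 30), d)
  q <- (1 + d$econ$discount_annual)^(-1 / 12)
  months <- 30 + 0:(n - 1)
  annuity <- sum(q^months)
  u <- ifelse(months <= 18, d$utilities_monthly[["A_under18"]],
              d$utilities_monthly[["B"]])
  expect_equal(out$qaly, sum(q^months * u), tolerance = 1e-10)
  # and the undiscounted run dominates the discounted one
  d0 <- d
  d0$econ$discount_annual <- 0
  out0 <- pathway_outcomes(flat_trace("B", n, entry_age = 30),
                           manual_pathway(entry_age = 30), d0)
  expect_gt(out0$qaly, out$qaly)
  expect_gt(out0$cost, out$cost)
})

test_that("the public-payer perspective drops non-health-system components", {
  d <- econ_draw
  d$cost_component_shares$B <- c(health_system = 0, out_of_pocket = 0,
                                 indirect = 1)
  tr <- flat_trace("B", 24, entry_age = 30)
  soc <- pathway_outcomes(tr, manual_pathway(entry_age = 30), d,
                          perspective = "societal")
  pub <- pathway_outcomes(tr, manual_pathway(entry_age = 30), d,
                          perspective = "public_payer")
  expect_gt(soc$cost, 0)
  expect_equal(pub$cost, 0)
})

test_that("an extinct cohort accrues nothing", {
  out <- pathway_outcomes(flat_trace("F", 120), manual_pathway(), econ_draw)
  expect_equal(out$qaly, 0)
  expect_equal(out$cost, 0)
})

test_that("societal costs dominate public-payer costs on real pathways", {
  d <- base_case_draw(sma_test_pars)
  pw <- enumerate_pathways(d, "no_screening")
  for (i in seq_len(nrow(pw))) {
    pathway <- as.list(pw[i, ])
    tr <- run_cohort_trace(pathway, sma_test_hz, sma_test_lt, horizon = 960)
    soc <- pathway_outcomes(tr, pathway, d, perspective = "societal")
    pub <- pathway_outcomes(tr, pathway, d, perspective = "public_payer")
    expect_gte(soc$cost + 1e-9, pub$cost)
    expect_equal(soc$qaly, pub$qaly)
  }
})

test_that("arm aggregation is linear in incidence and validates weights", {
  d <- base_case_draw(sma_test_pars)
  pw <- enumerate_pathways(d, "screening")
  outcomes <- lapply(seq_len(nrow(pw)), function(i)
    list(cost = 1e6, qaly = 30))
  sc <- expected_cases(d)
  arm <- aggregate_arm(pw, outcomes, sc, d)
  d2 <- d
  d2$incidence <- 2 * d$incidence
  arm2 <- aggregate_arm(pw, outcomes, expected_cases(d2), d2)
  expect_equal(arm2$qaly, 2 * arm$qaly, tolerance = 1e-12)
  expect_equal(arm2$cost - arm2$screening_cost,
               2 * (arm$cost - arm$screening_cost), tolerance = 1e-9)
  # screening arm always carries the screening-stage costs
  expect_gte(arm$cost, arm$screening_cost)
  # zero incidence: only the first-tier testing cost remains
  d0 <- d
  d0$incidence <- 0
  arm0 <- aggregate_arm(pw, outcomes, expected_cases(d0), d0)
  expect_equal(arm0$cost, d0$prices$screening_dbs * expected_cases(d0)$screened)
  bad <- pw
  bad$probability <- bad$probability * 0.5
  expect_error(aggregate_arm(bad, outcomes, sc, d), "sum to 1")
})

test_that("incremental ratios and dominance labels are correct", {
  mk <- function(cost, qaly) structure(list(cost = cost, qaly = qaly),
                                       class = "sma_arm_result")
  # division of published mean differences
  r <- icer(mk(150.7e6, 1585.219), mk(296.9e6, 712.5025))
  expect_equal(r$icer, (150.7e6 - 296.9e6) / (1585.219 - 712.5025),
               tolerance = 1e-12)
  expect_equal(round(r$icer), -167523)
  expect_equal(r$label, "dominant")
  expect_equal(icer(mk(10, 1), mk(5, 2))$label, "dominated")
  z <- icer(mk(5, 1), mk(5, 0))
  expect_equal(z$icer, 0)
  expect_equal(z$label, "cost-neutral, more effective")
  u <- icer(mk(1, 1), mk(2, 1))
  expect_true(is.na(u$icer))
  expect_equal(u$label, "undefined")
})

test_that("net monetary benefit is affine in willingness to pay", {
  de <- 1585.219 - 712.5025
  dc <- (150.7 - 296.9) * 1e6
  expect_equal(nmb(0, de, dc), -dc)
  v <- vapply(c(1000, 10000, 50000), nmb, numeric(1), delta_e = de,
              delta_c = dc)
  slopes <- diff(v) / diff(c(1000, 10000, 50000))
  expect_equal(slopes, rep(de, 2), tolerance = 1e-9)
})
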