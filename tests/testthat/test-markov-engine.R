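test_that("the assembled generator has the defining properties", {
  # null hazards and null mortality give the zero generator
  Q0 <- assemble_rate_matrix(30, "early_2_3copy", const_library(),
                             zero_life_table())
  expect_true(all(abs(Q0) < 1e-12))
  # real fixture: nonnegative off-diagonals, zero row sums, absorbing death
  for (age in c(1, 8, 15, 60, 400, 900)) {
    Q <- assemble_rate_matrix(age, "late_type1", sma_test_hz, sma_test_lt,
                              clock_time = age - 0.5)
    off <- Q - diag(diag(Q))
    expect_true(all(off >= 0))
    expect_true(all(abs(rowSums(Q)) < 1e-12))
    expect_true(all(Q["F", ] == 0))
  }
  expect_error(assemble_rate_matrix(10, "no_such_set", sma_test_hz,
                                    sma_test_lt), "unknown hazard set")
})

test_that("the milestone window substitutes the life-table death rate", {
  lib <- const_library(d_notsit = 0.05, d_sit = 0.02)
  lt <- sma_test_lt
  # age 6 months, not sitting: still in the normal window -> life-table rate
  Q6 <- assemble_rate_matrix(6, "early_2_3copy", lib, lt)
  expect_equal(Q6["D", "F"], lt$monthly_death_hazard[7])
  # age 10 months: outside the window -> natural-history rate
  Q10 <- assemble_rate_matrix(10, "early_2_3copy", lib, lt)
  expect_equal(Q10["D", "F"], 0.05)
  # sitting: boundary at 18 months
  Q18 <- assemble_rate_matrix(18, "early_2_3copy", lib, lt)
  Q19 <- assemble_rate_matrix(19, "early_2_3copy", lib, lt)
  expect_equal(Q18["C", "F"], lt$monthly_death_hazard[19])
  expect_equal(Q19["C", "F"], 0.02)
})

test_that("the matrix exponential yields stochastic matrices", {
  expect_equal(transition_matrix(matrix(0, 6, 6)), diag(6),
               tolerance = 1e-14, ignore_attr = TRUE)
  # two-state closed form
  h <- 0.3
  Q <- matrix(0, 6, 6, dimnames = list(STATE_NAMES <- c("A", "B", "C", "D",
                                                        "E", "F"),
                                       STATE_NAMES))
  Q["D", "F"] <- h
  diag(Q) <- -rowSums(Q)
  for (s in c(1, 2)) {
    P <- transition_matrix(Q, s)
    expect_equal(P["D", "F"], 1 - exp(-h * s), tolerance = 1e-12)
  }
  # random generators: stochastic and equal to the series oracle
  set.seed(42)
  for (i in 1:100) {
    Qr <- random_generator()
    P <- transition_matrix(Qr)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-10)
    expect_lt(max(abs(P - expm_series(Qr))), 1e-8)
    expect_equal(P[6, 6], 1)
  }
  bad <- matrix(1, 6, 6)
  expect_error(transition_matrix(bad), "generator")
})

test_that("effective-state remapping follows the milestone windows", {
  expect_equal(effective_state("D", 8), "A")
  expect_equal(effective_state("D", 9), "A")
  expect_equal(effective_state("D", 10), "D")
  expect_equal(effective_state("C", 18), "A")
  expect_equal(effective_state("C", 19), "C")
  expect_equal(effective_state("B", 12), "A")
  expect_equal(effective_state("B", 30), "B")
  expect_equal(effective_state("E", 5), "E")
  expect_equal(effective_state("F", 5), "F")
})

test_that("cohort traces conserve occupancy with monotone mortality", {
  pw <- list(entry_state = "D", entry_age = 1, hazard_set = "early_2_3copy")
  tr <- run_cohort_trace(pw, sma_test_hz, sma_test_lt, horizon = 960)
  expect_equal(nrow(tr$occupancy), 960)
  sums <- rowSums(tr$occupancy)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(diff(tr$occupancy[, "F"]) >= -1e-12))
  expect_true(all(tr$occupancy >= 0))
})

test_that("identity dynamics hold under a null generator", {
  pw <- list(entry_state = "D", entry_age = 1, hazard_set = "early_2_3copy")
  tr <- run_cohort_trace(pw, const_library(), zero_life_table(),
                         horizon = 100)
  expect_true(all(abs(tr$occupancy[, "D"] - 1) < 1e-9))
})

test_that("a life-table-only trace equals the cumulative-product survival", {
  pw <- list(entry_state = "A", entry_age = 0, hazard_set = "early_2_3copy")
  tr <- run_cohort_trace(pw, const_library(), sma_test_lt, horizon = 960)
  h <- sma_test_lt$monthly_death_hazard[1:960]
  expect_equal(tr$occupancy[-1, "A"], cumprod(exp(-h)), tolerance = 1e-12)
})

test_that("doubling the not-sitting death hazard dominates mortality", {
  base <- const_library(d_notsit = 0.02)
  doubled <- const_library(d_notsit = 0.04)
  pw <- list(entry_state = "D", entry_age = 20,
             hazard_set = "natural_history")
  tr1 <- run_cohort_trace(pw, base, zero_life_table(), horizon = 200)
  tr2 <- run_cohort_trace(pw, doubled, zero_life_table(), horizon = 200)
  expect_true(all(tr2$occupancy[, "F"] >= tr1$occupancy[, "F"] - 1e-12))
  expect_gt(tr2$occupancy[100, "F"], tr1$occupancy[100, "F"])
})

test_that("the fast trace path equals the public per-cycle operations", {
  pw <- list(entry_state = "D", entry_age = 20, hazard_set = "late_type23")
  horizon <- 60
  tr <- run_cohort_trace(pw, sma_test_hz, sma_test_lt, horizon = horizon)
  state <- c(A = 0, B = 0, C = 0, D = 1, E = 0, F = 0)
  for (cyc in seq_len(horizon - 20)) {
    Q <- assemble_rate_matrix(20 + cyc - 1, "late_type23", sma_test_hz,
                              sma_test_lt, clock_time = cyc - 1 + 0.5)
    state <- as.numeric(state %*% transition_matrix(Q, 1))
  }
  expect_equal(unname(tr$occupancy[horizon - 20 + 1, ]), state,
               tolerance = 1e-12)
})

test_that("trace preconditions are enforced", {
  pw <- list(entry_state = "D", entry_age = 1, hazard_set = "early_2_3copy")
  short_lt <- generate_life_table(max_month = 100)
  expect_error(run_cohort_trace(pw, sma_test_hz, short_lt, horizon = 960),
               "life table")
  late <- list(entry_state = "C", entry_age = 970,
               hazard_set = "late_type23")
  expect_error(run_cohort_trace(late, sma_test_hz, sma_test_lt,
                                horizon = 960), "beyond the model horizon")
  broken <- sma_test_hz
  broken$sets$late_type23$pav <- NULL
  expect_error(run_cohort_trace(pw2 <- list(entry_state = "C",
                                            entry_age = 53,
                                            hazard_set = "late_type23"),
                                broken, sma_test_lt), "missing transition: pav")
})

test_that("traces export the documented CSV dialect", {
  pw <- list(entry_state = "D", entry_age = 1, hazard_set = "early_2_3copy")
  tr <- run_cohort_trace(pw, sma_test_hz, sma_test_lt, horizon = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_named(back, c("cycle", "age_month", "occ_A", "occ_B", "occ_C",
                       "occ_D", "occ_E", "occ_F"))
  expect_equal(nrow(back), 24)
})
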