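# Shared fixtures, built once per test run.

sma_test_pars <- load_parameters()
sma_test_lt <- generate_life_table()
sma_test_suite <- generate_trial_suite("paper_like", seed = 1)
sma_test_hz <- fit_hazard_library(sma_test_suite)
sma_test_model <- build_model(sma_test_pars, sma_test_hz, sma_test_lt)

# A hazard library with constant (exponential) rates everywhere; rates of
# exactly zero are represented by the smallest positive double.
const_fit <- function(rate, label = "const") {
  structure(list(family = "exponential",
                 estimates = c(rate = max(rate, 1e-300)),
                 loglik = NA_real_, k = 1L, n = 0L,
                 covariance = matrix(0, 1, 1), label = label),
            class = "sma_surv_fit")
}

const_library <- function(sit = 0, walk = 0, brnd = 0, pav = 0,
                          d_sit = 0, d_notsit = 0, d_pav = 0,
                          sets = c("early_2_3copy", "early_4copy",
                                   "late_type1", "late_type23",
                                   "natural_history")) {
  one <- list(sit = const_fit(sit), walk = const_fit(walk),
              brnd = const_fit(brnd), pav = const_fit(pav))
  structure(list(sets = stats::setNames(rep(list(one), length(sets)), sets),
                 deaths = list(sitting = const_fit(d_sit),
                               notsitting = const_fit(d_notsit),
                               pav = const_fit(d_pav))),
            class = "sma_hazard_library")
}

zero_life_table <- function(max_month = 960L) {
  data.frame(age_month = 0:max_month, monthly_death_hazard = 0)
}

# Independent matrix-exponential oracle: scaling and squaring with a
# 50-term Taylor series.
expm_series <- function(Q, terms = 50L) {
  j <- max(0L, ceiling(log2(max(1, norm(Q, "I")))))
  A <- Q / 2^j
  S <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    S <- S + term
  }
  for (i in seq_len(j)) S <- S %*% S
  S
}

random_generator <- function(scale = 0.3) {
  Q <- matrix(stats::runif(36) * scale, 6, 6)
  Q[6, ] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}
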