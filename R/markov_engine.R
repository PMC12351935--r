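# Six-state Markov cohort engine.
#
# States, in fixed order: A (broad range of normal development), B
# (walking), C (sitting), D (not sitting), E (permanent assisted
# ventilation), F (death).  Upward milestone transitions are single-step
# (D -> C -> B -> A), ventilation is reachable from D only, death from
# every living state, and no regression to lower-functioning states
# occurs.  Death rates for A and B come from the life table; C, D and E
# use natural-history fits, except that a patient aged at most 9 months in
# D, or at most 18 months in C, is still within the normal
# milestone-achievement window and receives state A's (life-table) death
# rate instead.

STATE_NAMES <- c("A", "B", "C", "D", "E", "F")

# Transition rates entering the generator are capped at 100/month: a
# capped rate already empties a state within one cycle (staying
# probability exp(-100)), while uncapped extrapolation of e.g. a Gompertz
# fit far beyond its data can overflow the matrix exponential.  Tail
# regions where both density and survival underflow (hazard 0/0) get the
# cap as well.
RATE_CAP <- 100

clamp_rate <- function(h) {
  h[!is.finite(h)] <- RATE_CAP
  pmin(pmax(h, 0), RATE_CAP)
}

life_table_rate <- function(life_table, age) {
  idx <- match(floor(age), life_table$age_month)
  if (any(is.na(idx)))
    stop("age ", paste(age[is.na(idx)], collapse = ", "),
         " outside the life table")
  life_table$monthly_death_hazard[idx]
}

#' Assemble the 6x6 transition-rate matrix at a given age
#'
#' Builds the generator over states A-F from a hazard set's fitted
#' milestone and ventilation-onset hazards plus the state-specific death
#' hazards.  Milestone and disease-specific hazards are evaluated on the
#' treatment clock (`clock_time`, months since Markov entry); life-table
#' mortality is evaluated at the absolute `age`.
#'
#' @param age absolute age in months.
#' @param hazard_set one of the sets in the hazard library (e.g.
#'   `"early_2_3copy"`, `"late_type1"`, `"natural_history"`).
#' @param hazards an `sma_hazard_library` from [fit_hazard_library()].
#' @param life_table a life-table data frame (see [generate_life_table()]).
#' @param clock_time months since Markov entry; defaults to `age`.
#' @param milestone_override apply the milestone-window death-rate
#'   override (default `TRUE`).
#' @param include_background add life-table mortality on top of the
#'   natural-history death rates of states C, D, E (default `FALSE`: the
#'   natural-history fits are taken as total mortality).
#' @return a 6x6 generator matrix with zero row sums and a zero death row.
#' @export
assemble_rate_matrix <- function(age, hazard_set, hazards, life_table,
                                 clock_time = age,
                                 milestone_override = TRUE,
                                 include_background = FALSE) {
  hs <- hazards$sets[[hazard_set]]
  if (is.null(hs)) stop("unknown hazard set: ", hazard_set)
  for (tr in c("sit", "walk", "brnd", "pav"))
    if (is.null(hs[[tr]]))
      stop("hazard set '", hazard_set, "' is missing transition: ", tr)
  for (tr in c("sitting", "notsitting", "pav"))
    if (is.null(hazards$deaths[[tr]]))
      stop("hazard library is missing death hazard: ", tr)

  lt <- life_table_rate(life_table, age)
  Q <- matrix(0, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  Q["D", "C"] <- clamp_rate(hazard_at(hs$sit, clock_time))
  Q["C", "B"] <- clamp_rate(hazard_at(hs$walk, clock_time))
  Q["B", "A"] <- clamp_rate(hazard_at(hs$brnd, clock_time))
  Q["D", "E"] <- clamp_rate(hazard_at(hs$pav, clock_time))

  d_sit <- clamp_rate(hazard_at(hazards$deaths$sitting, clock_time))
  d_notsit <- clamp_rate(hazard_at(hazards$deaths$notsitting, clock_time))
  d_pav <- clamp_rate(hazard_at(hazards$deaths$pav, clock_time))
  if (include_background) {
    d_sit <- d_sit + lt; d_notsit <- d_notsit + lt; d_pav <- d_pav + lt
  }
  Q["A", "F"] <- lt
  Q["B", "F"] <- lt
  Q["C", "F"] <- if (milestone_override && age <= 18) lt else d_sit
  Q["D", "F"] <- if (milestone_override && age <= 9) lt else d_notsit
  Q["E", "F"] <- d_pav
  diag(Q) <- -rowSums(Q)
  Q
}

validate_generator <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("Q must be a square matrix")
  off <- Q - diag(diag(Q))
  if (any(off < -tol)) stop("invalid generator: negative off-diagonal rate")
  if (any(abs(rowSums(Q)) > tol * max(1, max(abs(Q)))))
    stop("invalid generator: row sums must be zero")
  invisible(Q)
}

#' One-step transition-probability matrix via the matrix exponential
#'
#' `P(s) = exp(Q s)`.  The result is cleaned of round-off (entries clamped
#' to `[0, 1]`, rows renormalized) so downstream occupancy stays exactly
#' conserved.
#'
#' @param Q a valid generator matrix.
#' @param s step length in months (the model uses `s = 1`).
#' @return a stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(Q, s = 1) {
  validate_generator(Q)
  P <- as.matrix(Matrix::expm(Q * s))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Effective state for cost and utility assignment
#'
#' Children still inside the normal milestone-achievement window are
#' costed and valued as broad-range-of-normal-development: not-sitting at
#' age 9 months or less maps to A, sitting or walking at age 18 months or
#' less maps to A.  Ventilation and death are never remapped.
#'
#' @param state state label in `A`-`F`.
#' @param age absolute age in months.
#' @return the state label whose costs and utilities apply.
#' @export
effective_state <- function(state, age) {
  if (length(age) == 1) age <- rep(age, length(state))
  out <- state
  out[state == "D" & age <= 9] <- "A"
  out[state %in% c("C", "B") & age <= 18] <- "A"
  out
}

#' Propagate cohort occupancy from Markov entry to the model horizon
#'
#' Starts with all mass in the pathway's entry state at its entry age and
#' repeatedly applies the one-month transition matrix, re-assembled each
#' cycle at the current age, until absolute age reaches `horizon` months.
#'
#' @param pathway a pathway allocation row (needs `entry_state`,
#'   `entry_age`, `hazard_set`) from [enumerate_pathways()], or a list with
#'   those elements.
#' @param hazards an `sma_hazard_library`.
#' @param life_table a life-table data frame covering ages up to `horizon`.
#' @param horizon model horizon in months of age (default 960).
#' @param milestone_override,include_background as in
#'   [assemble_rate_matrix()].
#' @return an `sma_trace`: occupancy matrix (cycles x 6 states), entry
#'   metadata, and the absolute age of each cycle.
#' @export
run_cohort_trace <- function(pathway, hazards, life_table, horizon = 960,
                             milestone_override = TRUE,
                             include_background = FALSE) {
  entry_age <- as.integer(round(pathway$entry_age))
  entry_state <- as.character(pathway$entry_state)
  if (!entry_state %in% STATE_NAMES) stop("unknown entry state: ", entry_state)
  if (horizon < 1) stop("horizon must be at least 1 cycle")
  if (entry_age >= horizon)
    stop("entry age ", entry_age, " is beyond the model horizon")
  if (max(life_table$age_month) < horizon - 1)
    stop("life table does not cover the model horizon")

  hs <- hazards$sets[[pathway$hazard_set]]
  if (is.null(hs)) stop("unknown hazard set: ", pathway$hazard_set)
  for (tr in c("sit", "walk", "brnd", "pav"))
    if (is.null(hs[[tr]]))
      stop("hazard set '", pathway$hazard_set,
           "' is missing transition: ", tr)

  n_cycles <- horizon - entry_age
  clock <- 0:(n_cycles - 1)
  ages <- entry_age + clock
  # vectorized pre-evaluation of every rate entering Q over the whole
  # horizon; the per-cycle generator below is entry-identical to
  # assemble_rate_matrix() at clock_time = cycle midpoint
  # (property-tested).  Fitted hazards are evaluated at the midpoint of
  # each cycle on the treatment clock: the cycle-start time is 0 at entry,
  # where decreasing-hazard families have an infinite rate.
  mid <- clock + 0.5
  h_sit <- clamp_rate(hazard_at(hs$sit, mid))
  h_walk <- clamp_rate(hazard_at(hs$walk, mid))
  h_brnd <- clamp_rate(hazard_at(hs$brnd, mid))
  h_pav <- clamp_rate(hazard_at(hs$pav, mid))
  lt <- life_table_rate(life_table, ages)
  d_sit <- clamp_rate(hazard_at(hazards$deaths$sitting, mid))
  d_notsit <- clamp_rate(hazard_at(hazards$deaths$notsitting, mid))
  d_pav <- clamp_rate(hazard_at(hazards$deaths$pav, mid))
  if (include_background) {
    d_sit <- d_sit + lt; d_notsit <- d_notsit + lt; d_pav <- d_pav + lt
  }
  if (milestone_override) {
    d_sit[ages <= 18] <- lt[ages <= 18]
    d_notsit[ages <= 9] <- lt[ages <= 9]
  }

  occ <- matrix(0, n_cycles + 1, 6,
                dimnames = list(NULL, STATE_NAMES))
  occ[1, entry_state] <- 1
  state <- occ[1, ]
  Q <- matrix(0, 6, 6)
  for (cyc in seq_len(n_cycles)) {
    Q[] <- 0
    Q[4, 3] <- h_sit[cyc];  Q[3, 2] <- h_walk[cyc]
    Q[2, 1] <- h_brnd[cyc]; Q[4, 5] <- h_pav[cyc]
    Q[1, 6] <- lt[cyc]; Q[2, 6] <- lt[cyc]
    Q[3, 6] <- d_sit[cyc]; Q[4, 6] <- d_notsit[cyc]; Q[5, 6] <- d_pav[cyc]
    diag(Q) <- -rowSums(Q)
    P <- as.matrix(Matrix::expm(Q))
    P[P < 0] <- 0
    P <- P / rowSums(P)
    state <- as.numeric(state %*% P)
    occ[cyc + 1, ] <- state
  }
  structure(list(occupancy = occ,
                 entry_state = entry_state,
                 entry_age = entry_age,
                 hazard_set = pathway$hazard_set,
                 ages = entry_age + 0:n_cycles),
            class = "sma_trace")
}

#' @export
print.sma_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  cat("<sma_trace> entry ", x$entry_state, " at ", x$entry_age,
      " months; hazard set ", x$hazard_set, "; ", n - 1, " cycles; ",
      "final death occupancy ", round(x$occupancy[n, "F"], 4), "\n",
      sep = "")
  invisible(x)
}

#' Export a cohort trace as CSV
#' @param trace an `sma_trace`.
#' @param path output CSV path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(cycle = seq_len(nrow(trace$occupancy)) - 1L,
                   age_month = trace$ages)
  occ <- as.data.frame(trace$occupancy)
  names(occ) <- paste0("occ_", STATE_NAMES)
  utils::write.csv(cbind(df, occ), path, row.names = FALSE)
  invisible(path)
}
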