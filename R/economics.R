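# Costing and QALY accounting.
#
# All streams are discounted from birth at the annual rate (default
# 1.5%/yr) with monthly compounding of the annual factor:
# (1 + r)^(-month/12).  Disease-modifying-therapy costs follow the dosing
# rules: onasemnogene abeparvovec (OA) is a single dose; nusinersen has 4
# loading doses in the first ~2 months then one dose every 4 months for
# life; risdiplam is costed at the printed annual price with the dose
# step-up at age 2.  Bridge regimens give 1 or 4 nusinersen doses before
# OA.

REGIMENS <- c("OA", "nusinersen", "risdiplam", "OA_bridge_1",
              "OA_bridge_4", "none")

#' Discount factor for a monthly cycle
#' @param cycle months since birth, `>= 0`.
#' @param annual_rate annual discount rate (default 0.015).
#' @return `(1 + annual_rate)^(-cycle/12)`.
#' @export
discount_factor <- function(cycle, annual_rate = 0.015) {
  if (any(cycle < 0)) stop("cycle must be nonnegative")
  (1 + annual_rate)^(-cycle / 12)
}

#' Dose-event schedule of a treatment regimen
#'
#' Expands a regimen into its dose events over the time a patient spends
#' in the model: offsets in months from treatment start, the drug, the
#' cost per event, and whether the charge is gated on being alive
#' (recurring doses) or charged once unconditionally at its scheduled time
#' (the single OA dose; patients are alive at treatment start by
#' construction).
#'
#' @param regimen one of `"OA"`, `"nusinersen"`, `"risdiplam"`,
#'   `"OA_bridge_1"`, `"OA_bridge_4"`, `"none"`.
#' @param entry_age age in months at treatment start (drives the
#'   risdiplam dose step-up at age 24 months).
#' @param prices the `prices` element of an `sma_draw`.
#' @param horizon_months months of follow-up to expand recurring doses
#'   over.
#' @return data frame with columns `month` (offset from start), `drug`,
#'   `cost`, `gated` (`"alive"` or `"unconditional"`).
#' @export
regimen_schedule <- function(regimen, entry_age, prices,
                             horizon_months = 960) {
  regimen <- match.arg(regimen, REGIMENS)
  ev <- function(month, drug, cost, gated = "alive")
    data.frame(month = month, drug = drug, cost = cost, gated = gated,
               stringsAsFactors = FALSE)
  nus_loading <- function(start = 0)
    ev(start + c(0, 0.5, 1, 2), "nusinersen", prices$nusinersen_per_dose)
  nus_maintenance <- function(start) {
    if (start > horizon_months) return(NULL)
    ev(seq(start, horizon_months, by = 4), "nusinersen",
       prices$nusinersen_per_dose)
  }
  risdiplam_stream <- function() {
    m <- seq(0, horizon_months - 1)
    age <- entry_age + m
    monthly <- ifelse(age < 24, prices$risdiplam_annual_under2 / 12,
                      prices$risdiplam_annual_2plus / 12)
    ev(m, "risdiplam", monthly)
  }
  out <- switch(regimen,
    none = ev(numeric(0), character(0), numeric(0), character(0)),
    OA = ev(0, "OA", prices$oa_per_dose, "unconditional"),
    nusinersen = rbind(nus_loading(), nus_maintenance(6)),
    risdiplam = risdiplam_stream(),
    OA_bridge_1 = rbind(ev(0, "nusinersen", prices$nusinersen_per_dose),
                        ev(1, "OA", prices$oa_per_dose, "unconditional")),
    OA_bridge_4 = rbind(nus_loading(),
                        ev(3, "OA", prices$oa_per_dose, "unconditional")))
  out <- out[out$month <= horizon_months, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-cycle drug-cost vectors (length n_cycles, cycle c covers months
# [c, c+1) after entry): `alive` costs are later scaled by the surviving
# fraction, `unconditional` costs are charged as scheduled.
regimen_cost_stream <- function(regimen, entry_age, prices, n_cycles) {
  sched <- regimen_schedule(regimen, entry_age, prices,
                            horizon_months = n_cycles)
  alive <- uncond <- numeric(n_cycles)
  if (nrow(sched)) {
    cyc <- pmin(floor(sched$month), n_cycles - 1) + 1L
    for (i in seq_len(nrow(sched))) {
      if (sched$month[i] >= n_cycles) next
      if (sched$gated[i] == "alive")
        alive[cyc[i]] <- alive[cyc[i]] + sched$cost[i]
      else uncond[cyc[i]] <- uncond[cyc[i]] + sched$cost[i]
    }
  }
  list(alive = alive, unconditional = uncond)
}

# Monthly utility of an effective state at a given age (months).
state_utility_monthly <- function(eff_state, age, utilities) {
  ifelse(eff_state == "F", 0,
    ifelse(eff_state == "A",
           ifelse(age < 216, utilities[["A_under18"]],
                  utilities[["A_18plus"]]),
           utilities[eff_state]))
}

# Monthly cost of an effective state under a perspective.
state_cost_monthly <- function(eff_state, draw, perspective) {
  ifelse(eff_state == "F", 0, {
    base <- draw$state_costs_monthly[eff_state]
    share <- if (perspective == "societal") 1 else
      vapply(eff_state, function(s)
        if (s == "F") 0 else
          draw$cost_component_shares[[s]][["health_system"]], numeric(1))
    base * share
  })
}

# Pre-entry accrual segments for clinical presenters: (state, months)
# pairs covering [0, exact entry age).  NBS-detected children accrue the
# broad-range-of-normal-development month before entry at 1 month.
pre_entry_segments <- function(pathway) {
  switch(pathway$clinical_type,
    nbs = list(c("A", 1)),
    type1 = list(c("A", 3.9)),
    type2 = list(c("A", 18), c("C", 52.8 - 18)),
    type3 = list(c("A", 18), c(pathway$entry_state, 106.8 - 18)),
    list())
}

pre_entry_accrual <- function(pathway, draw, perspective,
                              pre_entry_costs = TRUE) {
  segs <- pre_entry_segments(pathway)
  cost <- qaly <- 0
  t0 <- 0
  r <- draw$econ$discount_annual
  for (sg in segs) {
    st <- sg[1]; dur <- as.numeric(sg[2])
    months <- seq(floor(t0), ceiling(t0 + dur) - 1)
    # fraction of each calendar month covered by this segment
    frac <- pmin(t0 + dur, months + 1) - pmax(t0, months)
    frac <- pmax(frac, 0)
    df <- discount_factor(months, r)
    u <- state_utility_monthly(rep(st, length(months)), months,
                               draw$utilities_monthly)
    qaly <- qaly + sum(frac * df * u)
    if (pre_entry_costs) {
      cm <- state_cost_monthly(rep(st, length(months)), draw, perspective)
      cost <- cost + sum(frac * df * cm)
    }
    t0 <- t0 + dur
  }
  list(cost = cost, qaly = qaly)
}

#' Discounted cost and QALYs of one pathway
#'
#' Accrues, cycle by cycle, the state costs and utilities of the effective
#' state (with the milestone-window remapping to the
#' broad-range-of-normal-development state and the under/over-18-years
#' utility split), plus treatment dose costs scaled by the surviving
#' fraction, all discounted from birth.  Clinical presenters additionally
#' accrue their pre-entry utilities (and, by default, matching state
#' costs) for the months between birth and Markov entry.
#'
#' @param trace an `sma_trace` for the pathway.
#' @param pathway the matching pathway row from [enumerate_pathways()].
#' @param draw an `sma_draw`.
#' @param perspective `"societal"` (all cost components) or
#'   `"public_payer"` (direct health-system costs only).
#' @param pre_entry_costs also accrue state costs (not just utilities)
#'   before Markov entry (default `TRUE`).
#' @return list with `cost` (CAD), `qaly`, and the undiscounted drug cost
#'   `drug_cost_undiscounted`, all per SMA case.
#' @export
pathway_outcomes <- function(trace, pathway, draw,
                             perspective = c("societal", "public_payer"),
                             pre_entry_costs = TRUE) {
  perspective <- match.arg(perspective)
  occ <- trace$occupancy
  n_cycles <- nrow(occ) - 1L
  entry_age <- trace$entry_age
  r <- draw$econ$discount_annual

  ages <- entry_age + seq_len(n_cycles) - 1L  # age during each cycle
  df <- discount_factor(ages, r)
  occ_c <- occ[seq_len(n_cycles), , drop = FALSE]  # start-of-cycle occupancy

  # effective-state cost and utility per (state, age)
  cost_cycle <- numeric(n_cycles)
  qaly_cycle <- numeric(n_cycles)
  for (s in c("A", "B", "C", "D", "E")) {
    w <- occ_c[, s]
    if (all(w == 0)) next
    eff <- effective_state(rep(s, n_cycles), ages)
    u <- state_utility_monthly(eff, ages, draw$utilities_monthly)
    cm <- state_cost_monthly(eff, draw, perspective)
    qaly_cycle <- qaly_cycle + w * u
    cost_cycle <- cost_cycle + w * cm
  }

  stream <- regimen_cost_stream(pathway$regimen, entry_age, draw$prices,
                                n_cycles)
  alive <- 1 - occ_c[, "F"]
  drug_cycle <- stream$alive * alive + stream$unconditional

  pre <- pre_entry_accrual(pathway, draw, perspective, pre_entry_costs)
  # monthly utilities are annual utility / 12, i.e. QALYs accrued per month
  list(cost = sum(df * (cost_cycle + drug_cycle)) + pre$cost,
       qaly = sum(df * qaly_cycle) + pre$qaly,
       drug_cost_undiscounted = sum(stream$alive * alive) +
         sum(stream$unconditional))
}

#' Aggregate pathway outcomes into an arm-level result
#'
#' Weights per-case pathway outcomes by pathway probability and the
#' expected number of SMA cases, and (for the screening arm) adds the
#' cohort-wide screening-stage costs.  Newborns without SMA contribute
#' screening costs only; their health outcomes are identical across arms
#' and excluded by convention.
#'
#' @param pathways pathway data frame (probabilities must sum to 1).
#' @param outcomes list of per-pathway outcome lists, parallel to
#'   `pathways`, from [pathway_outcomes()].
#' @param summary an `sma_screening_summary`.
#' @param draw an `sma_draw`.
#' @return an `sma_arm_result`: total discounted cost and QALYs plus the
#'   per-pathway breakdown.
#' @export
aggregate_arm <- function(pathways, outcomes, summary, draw) {
  if (abs(sum(pathways$probability) - 1) > 1e-9)
    stop("pathway probabilities must sum to 1")
  if (length(outcomes) != nrow(pathways))
    stop("one outcome per pathway required")
  arm <- pathways$arm[1]
  cases <- draw$cohort_size * draw$incidence
  pc <- vapply(outcomes, function(o) o$cost, numeric(1))
  pq <- vapply(outcomes, function(o) o$qaly, numeric(1))
  w <- pathways$probability * cases
  screening_cost <- if (arm == "screening")
    screening_stage_costs(draw, summary) else 0
  res <- list(arm = arm,
              cost = sum(w * pc) + screening_cost,
              qaly = sum(w * pq),
              screening_cost = screening_cost,
              cases = cases,
              per_pathway = data.frame(path_id = pathways$path_id,
                                       probability = pathways$probability,
                                       cost_per_case = pc,
                                       qaly_per_case = pq))
  class(res) <- "sma_arm_result"
  res
}

#' @export
print.sma_arm_result <- function(x, ...) {
  cat("<sma_arm_result> ", x$arm, ": cost ",
      sprintf("%.1f MCAD", x$cost / 1e6), ", QALYs ",
      sprintf("%.1f", x$qaly), " (", sprintf("%.2f", x$cases),
      " SMA cases)\n", sep = "")
  invisible(x)
}

#' Incremental cost-effectiveness ratio between the two arms
#'
#' @param screen,no_screen `sma_arm_result` objects computed under
#'   identical settings.
#' @return list with `delta_cost`, `delta_qaly`, `icer` (NA when the QALY
#'   difference is zero), and a `label`: `"dominant"` (cheaper and more
#'   effective), `"dominated"`, `"cost-neutral, more effective"`,
#'   `"undefined"` (zero QALY difference), or `"icer"`.
#' @export
icer <- function(screen, no_screen) {
  dc <- screen$cost - no_screen$cost
  de <- screen$qaly - no_screen$qaly
  if (de == 0)
    return(list(delta_cost = dc, delta_qaly = de, icer = NA_real_,
                label = "undefined"))
  label <- if (dc < 0 && de > 0) "dominant"
    else if (dc > 0 && de < 0) "dominated"
    else if (dc == 0 && de > 0) "cost-neutral, more effective"
    else "icer"
  list(delta_cost = dc, delta_qaly = de, icer = dc / de, label = label)
}

#' Net monetary benefit
#' @param wtp willingness to pay per QALY (CAD).
#' @param delta_e incremental QALYs.
#' @param delta_c incremental cost (CAD).
#' @return `wtp * delta_e - delta_c`; positive values favour screening.
#' @export
nmb <- function(wtp, delta_e, delta_c) {
  wtp * delta_e - delta_c
}
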