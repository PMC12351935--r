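# Screening and no-screening decision trees.
#
# Pathway probabilities are conditional on being an SMA case within the
# arm.  In the screening arm, cases split into NBS-detected (entering the
# Markov model in the not-sitting state at 1 month) and clinical
# presenters (unscreened newborns plus the 5% false negatives), who are
# routed through the same type-1/2/3 structure as the no-screening arm.

pathway_row <- function(arm, path_id, probability, entry_state, entry_age,
                        entry_age_exact, regimen, hazard_set, bridge,
                        clinical_type) {
  data.frame(arm = arm, path_id = path_id, probability = probability,
             entry_state = entry_state, entry_age = entry_age,
             entry_age_exact = entry_age_exact, regimen = regimen,
             hazard_set = hazard_set, bridge = bridge,
             clinical_type = clinical_type, stringsAsFactors = FALSE)
}

clinical_leaves <- function(draw, arm, weight) {
  ct <- draw$clinical_type_probs
  acc <- draw$p_accept_treatment
  splits <- draw$clinical_treatment_splits
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- pathway_row(...)

  # type 1: not-sitting entry at 3.9 months
  for (rg in names(splits$type1))
    add(arm, paste0("clin_type1_", rg), weight * ct[["type1"]] * acc *
          splits$type1[[rg]], "D", 4L, 3.9, rg, "late_type1", "none",
        "type1")
  add(arm, "clin_type1_decline", weight * ct[["type1"]] * (1 - acc),
      "D", 4L, 3.9, "none", "natural_history", "none", "type1")

  # type 2: sitting entry at 4.4 years
  for (rg in names(splits$type2))
    add(arm, paste0("clin_type2_", rg), weight * ct[["type2"]] * acc *
          splits$type2[[rg]], "C", 53L, 52.8, rg, "late_type23", "none",
        "type2")
  add(arm, "clin_type2_decline", weight * ct[["type2"]] * (1 - acc),
      "C", 53L, 52.8, "none", "natural_history", "none", "type2")

  # type 3: walking (76%) or sitting (24%) entry at 8.9 years
  wfrac <- draw$entry$type3_walking_frac
  for (rg in names(splits$type3)) {
    pr <- weight * ct[["type3"]] * acc * splits$type3[[rg]]
    add(arm, paste0("clin_type3_", rg, "_walk"), pr * wfrac,
        "B", 107L, 106.8, rg, "late_type23", "none", "type3")
    add(arm, paste0("clin_type3_", rg, "_sit"), pr * (1 - wfrac),
        "C", 107L, 106.8, rg, "late_type23", "none", "type3")
  }
  add(arm, "clin_type3_decline_walk",
      weight * ct[["type3"]] * (1 - acc) * wfrac,
      "B", 107L, 106.8, "none", "natural_history", "none", "type3")
  add(arm, "clin_type3_decline_sit",
      weight * ct[["type3"]] * (1 - acc) * (1 - wfrac),
      "C", 107L, 106.8, "none", "natural_history", "none", "type3")
  rows
}

#' Enumerate the decision-tree pathways of one arm
#'
#' Expands the screening (or no-screening) decision tree into its leaves:
#' one row per combination of detection route, SMN2 copy number,
#' symptomatic status, bridge therapy, treatment regimen (including the 1%
#' who decline treatment), and Markov entry state/age.  Probabilities are
#' conditional on being an SMA case and sum to 1 within each arm.
#'
#' @param draw an `sma_draw` (see [base_case_draw()] /
#'   [sample_parameters()]).
#' @param arm `"screening"` or `"no_screening"`.
#' @param prune drop zero-probability leaves (default `TRUE`).
#' @return a data frame of pathway allocations.
#' @examples
#' pw <- enumerate_pathways(base_case_draw(load_parameters()), "screening")
#' sum(pw$probability)
#' @export
enumerate_pathways <- function(draw, arm = c("screening", "no_screening"),
                               prune = TRUE) {
  arm <- match.arg(arm)
  cp <- draw$smn2_copy_probs
  if (abs(sum(cp) - 1) > 1e-9)
    stop("SMN2 copy probabilities must sum to 1")

  if (arm == "no_screening") {
    rows <- clinical_leaves(draw, arm, 1)
  } else {
    p_det <- draw$p_screened * (1 - draw$p_false_negative_given_sma)
    acc <- draw$p_accept_treatment
    rows <- list()
    add <- function(...) rows[[length(rows) + 1L]] <<- pathway_row(...)
    nbs <- function(path_id, prob, regimen, hazard_set, bridge)
      add("screening", path_id, prob, "D", 1L, 1, regimen, hazard_set,
          bridge, "nbs")

    # 2 copies: symptomatic split, bridge therapy
    p2 <- p_det * cp[1]
    psym <- draw$p_symptomatic_2copy
    nbs("nbs_2copy_symp_bridge1",
        p2 * psym * draw$p_bridge_symptomatic * acc,
        "OA_bridge_1", "early_2_3copy", "single_dose")
    nbs("nbs_2copy_symp_oa",
        p2 * psym * (1 - draw$p_bridge_symptomatic) * acc,
        "OA", "early_2_3copy", "none")
    nbs("nbs_2copy_symp_decline", p2 * psym * (1 - acc),
        "none", "natural_history", "none")
    nbs("nbs_2copy_presymp_bridge4",
        p2 * (1 - psym) * draw$p_bridge_preterm_ab * acc,
        "OA_bridge_4", "early_2_3copy", "four_dose")
    nbs("nbs_2copy_presymp_oa",
        p2 * (1 - psym) * (1 - draw$p_bridge_preterm_ab) * acc,
        "OA", "early_2_3copy", "none")
    nbs("nbs_2copy_presymp_decline", p2 * (1 - psym) * (1 - acc),
        "none", "natural_history", "none")

    # 3 copies: all presymptomatic
    p3 <- p_det * cp[2]
    nbs("nbs_3copy_bridge4", p3 * draw$p_bridge_preterm_ab * acc,
        "OA_bridge_4", "early_2_3copy", "four_dose")
    nbs("nbs_3copy_oa", p3 * (1 - draw$p_bridge_preterm_ab) * acc,
        "OA", "early_2_3copy", "none")
    nbs("nbs_3copy_decline", p3 * (1 - acc),
        "none", "natural_history", "none")

    # 4 copies: treatment funded in Quebec only
    p4 <- p_det * cp[3]
    pq <- draw$p_quebec * draw$p_quebec_4copy_treated
    for (rg in names(draw$quebec_4copy_drug_split))
      nbs(paste0("nbs_4copy_quebec_", rg),
          p4 * pq * draw$quebec_4copy_drug_split[[rg]] * acc,
          rg, "early_4copy", "none")
    nbs("nbs_4copy_quebec_decline", p4 * pq * (1 - acc),
        "none", "natural_history", "none")
    nbs("nbs_4copy_untreated",
        p4 * (1 - draw$p_quebec * draw$p_quebec_4copy_treated),
        "none", "natural_history", "none")

    # clinical presenters: unscreened cases plus false negatives
    rows <- c(rows, clinical_leaves(draw, "screening", 1 - p_det))
  }
  out <- do.call(rbind, rows)
  if (prune) out <- out[out$probability > 0, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(abs(sum(out$probability) - 1) < 1e-9)
  out
}

#' Expected screening-stage counts for the birth cohort
#'
#' @param draw an `sma_draw`.
#' @param cohort_size number of live births (defaults to the draw's).
#' @return a list of expected counts: `screened`, `unscreened`,
#'   `sma_cases`, `detected_by_nbs`, `false_negatives`,
#'   `clinical_presenters`, `screen_positive_confirmed`.
#' @examples
#' expected_cases(base_case_draw(load_parameters()))$clinical_presenters
#' @export
expected_cases <- function(draw, cohort_size = draw$cohort_size) {
  if (cohort_size <= 0) stop("cohort_size must be positive")
  screened <- cohort_size * draw$p_screened
  unscreened <- cohort_size - screened
  sma_screened <- screened * draw$incidence
  detected <- sma_screened * (1 - draw$p_false_negative_given_sma)
  fn <- sma_screened * draw$p_false_negative_given_sma
  out <- list(screened = screened,
              unscreened = unscreened,
              sma_cases = cohort_size * draw$incidence,
              detected_by_nbs = detected,
              false_negatives = fn,
              clinical_presenters = unscreened * draw$incidence + fn,
              screen_positive_confirmed = detected)
  class(out) <- "sma_screening_summary"
  out
}

#' @export
print.sma_screening_summary <- function(x, ...) {
  cat("<sma_screening_summary>\n",
      sprintf("  screened: %.1f  unscreened: %.1f\n", x$screened,
              x$unscreened),
      sprintf("  detected by NBS: %.2f  false negatives: %.2f  clinical presenters: %.2f\n",
              x$detected_by_nbs, x$false_negatives, x$clinical_presenters),
      sep = "")
  invisible(x)
}

#' Screening-stage cost of the screening arm
#'
#' First-tier dried-blood-spot testing for every screened newborn plus
#' second-tier ddPCR confirmation for every screen-positive case.
#'
#' @param draw an `sma_draw`.
#' @param summary an `sma_screening_summary` from [expected_cases()].
#' @return total screening cost in CAD.
#' @export
screening_stage_costs <- function(draw, summary) {
  draw$prices$screening_dbs * summary$screened +
    draw$prices$ddpcr * summary$screen_positive_confirmed
}

#' Export a pathway table as CSV
#' @param pathways a pathway data frame from [enumerate_pathways()].
#' @param path output CSV path.
#' @export
write_pathways <- function(pathways, path) {
  cols <- c("arm", "path_id", "probability", "entry_state",
            "entry_age", "regimen", "hazard_set", "bridge")
  df <- pathways[, cols]
  names(df)[names(df) == "entry_age"] <- "entry_age_months"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
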