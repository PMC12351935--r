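# Model assembly: fit the hazard library from event-time data, then
# evaluate both arms of the decision model for a parameter draw.

#' Fit the full hazard library from a trial suite
#'
#' Fits every milestone-achievement, ventilation-onset, and mortality
#' dataset the Markov engine needs.  By default each dataset gets the
#' six-family censored maximum-likelihood treatment with minimum-AICc
#' selection; a fixed family can be forced per dataset label, and the
#' long-term mortality datasets can instead be fitted with the
#' affine-invariant ensemble MCMC Weibull sampler.
#'
#' @param suite named list of event-time data frames (see
#'   [generate_trial_suite()] / [read_trial_suite()]); must contain every
#'   label in [required_hazard_labels()].
#' @param families optional named character vector `label -> family`
#'   forcing a family for specific datasets.
#' @param mcmc_mortality fit the three mortality datasets by ensemble
#'   MCMC (Weibull) instead of maximum likelihood.
#' @param mcmc_walkers,mcmc_steps,seed MCMC settings.
#' @return an `sma_hazard_library`: `$sets` (per treatment group: `sit`,
#'   `walk`, `brnd`, `pav` fits), `$deaths` (`sitting`, `notsitting`,
#'   `pav`), and `$fits` (flat, by label).
#' @export
fit_hazard_library <- function(suite, families = NULL,
                               mcmc_mortality = FALSE,
                               mcmc_walkers = 32L, mcmc_steps = 1000L,
                               seed = 1L) {
  labels <- required_hazard_labels()
  missing <- setdiff(labels, names(suite))
  if (length(missing))
    stop("trial suite is missing dataset(s): ",
         paste(missing, collapse = ", "))
  death_labels <- c("nathist_sitting_death", "nathist_notsitting_death",
                    "nathist_pav_death")
  fits <- list()
  for (lb in labels) {
    fits[[lb]] <- if (!is.null(families) && lb %in% names(families)) {
      fit_parametric(suite[[lb]], families[[lb]])
    } else if (mcmc_mortality && lb %in% death_labels) {
      fit_weibull_ensemble_mcmc(suite[[lb]], walkers = mcmc_walkers,
                                steps = mcmc_steps,
                                seed = seed + match(lb, labels))
    } else {
      suppressWarnings(select_best_fit(suite[[lb]]))
    }
    fits[[lb]]$label <- lb
  }
  sets <- list()
  for (s in c("early_2_3copy", "early_4copy", "late_type1", "late_type23",
              "natural_history")) {
    sets[[s]] <- list(sit = fits[[paste0(s, "_sit")]],
                      walk = fits[[paste0(s, "_walk")]],
                      brnd = fits[[paste0(s, "_brnd")]],
                      pav = fits[[paste0(s, "_pav")]])
  }
  structure(list(sets = sets,
                 deaths = list(sitting = fits$nathist_sitting_death,
                               notsitting = fits$nathist_notsitting_death,
                               pav = fits$nathist_pav_death),
                 fits = fits),
            class = "sma_hazard_library")
}

#' @export
print.sma_hazard_library <- function(x, ...) {
  cat("<sma_hazard_library> ", length(x$fits), " fitted hazards; sets: ",
      paste(names(x$sets), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Replace every fit's estimates by one multivariate-normal draw
#'
#' Used inside the probabilistic sensitivity analysis to propagate hazard
#' parameter uncertainty: each fitted hazard's parameters are redrawn from
#' their asymptotic normal approximation.
#'
#' @param hazards an `sma_hazard_library`.
#' @param seed integer seed.
#' @return a hazard library with perturbed estimates.
#' @export
perturb_hazard_library <- function(hazards, seed = 1L) {
  i <- 0L
  draw_fit <- function(fit) {
    i <<- i + 1L
    sub_seed <- as.integer((as.numeric(seed) * 131 + i) %% 2147483647)
    d <- suppressMessages(sample_hazard_parameters(fit, 1, seed = sub_seed))
    fit$estimates[] <- as.numeric(d[1, ])
    fit
  }
  out <- hazards
  out$fits <- lapply(hazards$fits, draw_fit)
  for (s in names(out$sets))
    for (tr in names(out$sets[[s]]))
      out$sets[[s]][[tr]] <- out$fits[[out$sets[[s]][[tr]]$label]]
  out$deaths <- list(sitting = out$fits$nathist_sitting_death,
                     notsitting = out$fits$nathist_notsitting_death,
                     pav = out$fits$nathist_pav_death)
  out
}

#' Assemble the decision model
#'
#' Bundles parameters, fitted hazards, and the life table into a model
#' object whose `evaluate()` closure runs both arms for one parameter
#' draw.
#'
#' @param params an `sma_parameters` object.
#' @param hazards an `sma_hazard_library`.
#' @param life_table a life table covering the model horizon.
#' @param perspective `"societal"` or `"public_payer"`.
#' @param horizon model horizon in months (defaults to the configured
#'   960).
#' @param pre_entry_costs accrue state costs before Markov entry.
#' @return an `sma_model` list with an `evaluate(draw, hazards)` function.
#' @export
build_model <- function(params, hazards, life_table,
                        perspective = c("societal", "public_payer"),
                        horizon = NULL, pre_entry_costs = TRUE) {
  perspective <- match.arg(perspective)
  horizon <- horizon %||% params$econ$horizon_cycles
  model <- list(params = params, hazards = hazards,
                life_table = life_table, perspective = perspective,
                horizon = horizon, pre_entry_costs = pre_entry_costs)
  model$evaluate <- function(draw, hazards_draw = NULL) {
    evaluate_arms(draw, hazards_draw %||% model$hazards, model$life_table,
                  perspective = model$perspective,
                  horizon = model$horizon,
                  pre_entry_costs = model$pre_entry_costs)
  }
  class(model) <- "sma_model"
  model
}

#' @export
print.sma_model <- function(x, ...) {
  cat("<sma_model> perspective ", x$perspective, "; horizon ", x$horizon,
      " months; cohort ", x$params$cohort_size, "\n", sep = "")
  invisible(x)
}

#' Evaluate both arms of the decision model for one parameter draw
#'
#' Enumerates the pathways of each arm, runs (and caches) the cohort
#' trace for every distinct (hazard set, entry state, entry age)
#' combination, accrues discounted costs and QALYs, and aggregates to
#' arm totals with incremental results.
#'
#' @param draw an `sma_draw`.
#' @param hazards an `sma_hazard_library`.
#' @param life_table a life table covering the horizon.
#' @param perspective `"societal"` or `"public_payer"`.
#' @param horizon model horizon in months.
#' @param pre_entry_costs accrue state costs before Markov entry.
#' @return an `sma_evaluation`: per-arm results, incremental cost and
#'   QALYs, ICER, and NMB over the configured willingness-to-pay grid.
#' @export
evaluate_arms <- function(draw, hazards, life_table,
                          perspective = c("societal", "public_payer"),
                          horizon = 960, pre_entry_costs = TRUE) {
  perspective <- match.arg(perspective)
  summary <- expected_cases(draw)
  trace_cache <- new.env(parent = emptyenv())
  get_trace <- function(pathway) {
    key <- paste(pathway$hazard_set, pathway$entry_state,
                 pathway$entry_age, sep = "|")
    if (is.null(trace_cache[[key]]))
      trace_cache[[key]] <- run_cohort_trace(pathway, hazards, life_table,
                                             horizon = horizon)
    trace_cache[[key]]
  }
  arm_result <- function(arm) {
    pw <- enumerate_pathways(draw, arm)
    outcomes <- lapply(seq_len(nrow(pw)), function(i) {
      pathway <- as.list(pw[i, ])
      pathway_outcomes(get_trace(pathway), pathway, draw,
                       perspective = perspective,
                       pre_entry_costs = pre_entry_costs)
    })
    aggregate_arm(pw, outcomes, summary, draw)
  }
  screening <- arm_result("screening")
  no_screening <- arm_result("no_screening")
  inc <- icer(screening, no_screening)
  wtp <- draw$econ$wtp_grid
  res <- list(screening = screening, no_screening = no_screening,
              delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
              icer = inc$icer, dominance = inc$label,
              nmb = stats::setNames(
                vapply(wtp, nmb, numeric(1),
                       delta_e = inc$delta_qaly, delta_c = inc$delta_cost),
                paste0("wtp_", wtp)),
              summary = summary)
  class(res) <- "sma_evaluation"
  res
}

#' @export
print.sma_evaluation <- function(x, ...) {
  cat("<sma_evaluation>\n",
      sprintf("  screening:    %8.1f MCAD  %9.1f QALYs\n",
              x$screening$cost / 1e6, x$screening$qaly),
      sprintf("  no screening: %8.1f MCAD  %9.1f QALYs\n",
              x$no_screening$cost / 1e6, x$no_screening$qaly),
      sprintf("  incremental:  %8.1f MCAD  %9.1f QALYs  (%s)\n",
              x$delta_cost / 1e6, x$delta_qaly, x$dominance),
      if (is.finite(x$icer))
        sprintf("  ICER: %0.0f CAD/QALY\n", x$icer) else "",
      sep = "")
  invisible(x)
}

#' Run the base-case analysis (all parameters at point values)
#' @param model an `sma_model` from [build_model()].
#' @return an `sma_evaluation`.
#' @export
run_base_case <- function(model) {
  model$evaluate(base_case_draw(model$params))
}
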