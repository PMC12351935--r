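#' Generate right-censored event-time data with known ground truth
#'
#' Draws `n` independent event times from one of the six supported
#' time-to-event families via inverse-CDF sampling and right-censors them
#' at `censor_time`.  Used to emulate milestone-achievement and survival
#' datasets so that the fitting and Markov stages can be exercised against
#' known hazards.
#'
#' @param hazard_family family name; see [surv_families()].
#' @param params parameter vector in the family's conventional order.
#' @param n number of subjects, `n >= 1`.
#' @param censor_time administrative right-censoring time in months
#'   (`Inf` for none).
#' @param seed integer seed.
#' @param label dataset tag stored in the `label` column.
#' @return a data frame with columns `subject_id`, `time`, `event`
#'   (1 = event, 0 = censored), `label`; the generating family and
#'   parameters are attached as attributes `family` and `params`.
#' @examples
#' d <- generate_event_times("exponential", 0.1, n = 200, censor_time = 24,
#'                           seed = 1)
#' mean(d$event)
#' @export
generate_event_times <- function(hazard_family, params, n,
                                 censor_time = Inf, seed = 1L,
                                 label = hazard_family) {
  surv_check_params(hazard_family, params)
  if (n < 1) stop("n must be at least 1")
  if (censor_time < 0) stop("censor_time must be nonnegative")
  set.seed(seed)
  u <- stats::runif(n)
  t_true <- surv_quantile(hazard_family, u, params)
  event <- as.integer(t_true <= censor_time)
  out <- data.frame(subject_id = seq_len(n),
                    time = pmin(t_true, censor_time),
                    event = event,
                    label = label,
                    stringsAsFactors = FALSE)
  attr(out, "family") <- hazard_family
  attr(out, "params") <- params
  out
}

#' Generate a synthetic life table with Gompertz-Makeham mortality
#'
#' Tabulates the monthly death hazard `h(t) = a + b * exp(c * t / 12)`
#' (with `t` in months, so `c` acts on age in years) from age 0 to
#' `max_month`.  The default coefficients give a discrete-time life
#' expectancy of about 82 years, in line with a contemporary Canadian
#' period life table; a real life table can be supplied instead via
#' [read_life_table()].
#'
#' @param makeham coefficients `c(a, b, c)` with `a, b >= 0`, `c > 0`.
#' @param max_month last tabulated age in months.
#' @return data frame with columns `age_month`, `monthly_death_hazard`.
#' @export
generate_life_table <- function(makeham = c(a = 6e-5, b = 1e-6, c = 0.10),
                                max_month = 960L) {
  a <- makeham[[1]]; b <- makeham[[2]]; cc <- makeham[[3]]
  if (a < 0 || b < 0) stop("Makeham coefficients a, b must be nonnegative")
  if (cc <= 0) stop("Makeham coefficient c must be positive")
  age <- 0:max_month
  lt <- data.frame(age_month = age,
                   monthly_death_hazard = a + b * exp(cc * age / 12))
  class(lt) <- c("sma_life_table", "data.frame")
  lt
}

#' Read / write the life-table CSV dialect
#' @param path CSV file with header `age_month,monthly_death_hazard`.
#' @return a life-table data frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age_month", "monthly_death_hazard") %in% names(lt)))
    stop("life table must have columns age_month, monthly_death_hazard")
  if (any(lt$monthly_death_hazard < 0))
    stop("life-table hazards must be nonnegative")
  class(lt) <- c("sma_life_table", "data.frame")
  lt
}

#' @rdname read_life_table
#' @param life_table a life-table data frame.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table)[, c("age_month",
    "monthly_death_hazard")], path, row.names = FALSE)
  invisible(path)
}

# Ground-truth constants of the packaged "paper_like" scenario.  These are
# documented package constants chosen for direction of effect (earlier
# treatment => faster milestone achievement, lower mortality; untreated
# not-sitting median survival under 24 months, consistent with severe SMA
# natural history), not estimates from any published trial.
trial_suite_spec <- function(scenario = "paper_like") {
  if (!identical(scenario, "paper_like"))
    stop("unknown scenario: ", scenario)
  milestone <- function(set, trans, family, params, n, censor) {
    data.frame(label = paste(set, trans, sep = "_"), hazard_set = set,
               transition = trans, family = family,
               params = I(list(params)), n = n, censor_time = censor,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # presymptomatic 2/3-copy, OA in first month of life
    milestone("early_2_3copy", "sit",  "weibull", c(2.0, 6),    500, 24),
    milestone("early_2_3copy", "walk", "weibull", c(2.0, 10),   500, 24),
    milestone("early_2_3copy", "brnd", "weibull", c(1.8, 14),   500, 36),
    milestone("early_2_3copy", "pav",  "exponential", 5e-4,     500, 36),
    # presymptomatic 4-copy, nusinersen-style early treatment
    milestone("early_4copy", "sit",  "weibull", c(2.0, 8),      500, 36),
    milestone("early_4copy", "walk", "weibull", c(2.0, 13),     500, 36),
    milestone("early_4copy", "brnd", "weibull", c(1.8, 20),     500, 48),
    milestone("early_4copy", "pav",  "exponential", 1e-3,       500, 48),
    # clinically presenting type 1, treated late
    milestone("late_type1", "sit",  "weibull", c(1.5, 20),      400, 60),
    milestone("late_type1", "walk", "weibull", c(1.5, 80),      400, 60),
    milestone("late_type1", "brnd", "weibull", c(1.5, 300),     400, 60),
    milestone("late_type1", "pav",  "exponential", 4e-3,        400, 60),
    # clinically presenting type 2/3, treated late
    milestone("late_type23", "sit",  "weibull", c(1.5, 12),     400, 60),
    milestone("late_type23", "walk", "weibull", c(1.5, 60),     400, 60),
    milestone("late_type23", "brnd", "weibull", c(1.5, 200),    400, 60),
    milestone("late_type23", "pav",  "exponential", 1e-3,       400, 60),
    # untreated / declined treatment
    milestone("natural_history", "sit",  "weibull", c(1.0, 60),   400, 60),
    milestone("natural_history", "walk", "weibull", c(1.0, 400),  400, 60),
    milestone("natural_history", "brnd", "weibull", c(1.0, 1000), 400, 60),
    milestone("natural_history", "pav",  "exponential", 8e-3,     400, 60),
    # state-specific mortality (shared across hazard sets)
    milestone("nathist", "sitting_death",    "exponential", 1.2e-3, 400, 360),
    milestone("nathist", "notsitting_death", "weibull", c(1.3, 16), 400, 48),
    milestone("nathist", "pav_death",        "exponential", 1.5e-2, 300, 120))
  do.call(rbind, rows)
}

#' Transition labels the Markov engine requires of a trial suite
#' @return character vector of dataset labels.
#' @export
required_hazard_labels <- function() {
  sets <- c("early_2_3copy", "early_4copy", "late_type1", "late_type23",
            "natural_history")
  c(as.vector(outer(sets, c("sit", "walk", "brnd", "pav"), paste, sep = "_")),
    "nathist_sitting_death", "nathist_notsitting_death", "nathist_pav_death")
}

#' Generate the full suite of synthetic trial and natural-history datasets
#'
#' Produces one right-censored event-time dataset per transition the Markov
#' engine needs: milestone achievement (not-sitting to sitting, sitting to
#' walking, walking to broad-range-of-normal-development) and onset of
#' permanent assisted ventilation for each treatment group, plus
#' natural-history mortality for the sitting, not-sitting, and ventilated
#' states.  Ground-truth parameters are documented package constants
#' (see the methods vignette) in which early treatment dominates late
#' treatment.
#'
#' @param scenario preset name; currently `"paper_like"`.
#' @param seed integer master seed; each dataset uses a deterministic
#'   offset of it.
#' @return named list of event-time data frames (one per label in
#'   [required_hazard_labels()]), with the ground-truth table attached as
#'   attribute `ground_truth`.
#' @export
generate_trial_suite <- function(scenario = "paper_like", seed = 1L) {
  spec <- trial_suite_spec(scenario)
  out <- vector("list", nrow(spec))
  names(out) <- spec$label
  for (i in seq_len(nrow(spec))) {
    out[[i]] <- generate_event_times(spec$family[i], spec$params[[i]],
                                     n = spec$n[i],
                                     censor_time = spec$censor_time[i],
                                     seed = as.integer(
                                       (as.numeric(seed) * 1000 + i) %%
                                         2147483647),
                                     label = spec$label[i])
  }
  attr(out, "ground_truth") <- spec
  attr(out, "scenario") <- scenario
  out
}

#' Write / read the event-time CSV dialect
#' @param suite named list of event-time data frames.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_trial_suite <- function(suite, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(suite)) {
    d <- suite[[nm]]
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(data.frame(subject_id = d$subject_id,
                                time_months = d$time, event = d$event,
                                label = d$label), path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_trial_suite
#' @export
read_trial_suite <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "life_table.csv"]
  out <- list()
  for (f in files) {
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "time_months", "event", "label") %in% names(d)))
      stop("not an event-time CSV: ", f)
    out[[sub("\\.csv$", "", basename(f))]] <-
      data.frame(subject_id = d$subject_id, time = d$time_months,
                 event = d$event, label = d$label)
  }
  out
}
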