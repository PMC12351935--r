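#' Load and validate the full model parameter set
#'
#' Reads a JSON configuration holding every epidemiological, cost, and
#' utility input of the screening model: screening coverage and test
#' performance, SMA incidence, SMN2 copy-number distribution, treatment
#' acceptance and bridge-therapy probabilities, drug prices and dosing
#' costs, monthly health-state costs, annual health-state utilities (stored
#' with their Gamma-disutility sampling distributions), and the economic
#' settings (discount rate, cycle length, horizon, willingness-to-pay
#' grid).  The packaged default configuration is returned when `config` is
#' omitted.
#'
#' @param config path to a JSON configuration file, or a pre-parsed list.
#'   Defaults to the configuration shipped with the package.
#' @return an object of class `sma_parameters`.
#' @examples
#' pars <- load_parameters()
#' pars$incidence$point
#' @export
load_parameters <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "default_config.json", package = "smanbs")
  raw <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else if (is.list(config)) config else
    stop("config must be a file path or a list")

  required <- c("cohort_size", "p_screened", "incidence",
    "p_accept_treatment", "smn2_copy_probs", "p_symptomatic_2copy",
    "p_false_negative_given_sma", "p_bridge_preterm_ab",
    "p_bridge_symptomatic", "p_quebec", "p_quebec_4copy_treated",
    "quebec_4copy_drug_split", "clinical_type_probs",
    "clinical_treatment_splits", "prices", "state_costs_monthly",
    "cost_component_shares", "state_utilities_annual", "econ", "entry")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("configuration error: missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(raw), required)
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  as_spec <- function(node, key) {
    if (is.list(node) && !is.null(node$dist)) {
      do.call(dist_spec, c(list(point = unlist(node$point),
                                family = node$dist$family),
                           node$dist[setdiff(names(node$dist), "family")]))
    } else if (is.numeric(node) && length(node) == 1) {
      dist_spec(node, "point")
    } else stop("configuration error: malformed value for '", key, "'",
                call. = FALSE)
  }

  price_keys <- c("screening_dbs", "ddpcr", "nusinersen_per_dose",
    "oa_per_dose", "risdiplam_per_mg", "risdiplam_annual_under2",
    "risdiplam_annual_2plus")
  pm <- setdiff(price_keys, names(raw$prices))
  if (length(pm))
    stop("configuration error: missing key(s) in prices: ",
         paste(pm, collapse = ", "), call. = FALSE)

  states <- c("E", "D", "C", "B", "A")
  for (blk in c("state_costs_monthly", "cost_component_shares")) {
    sm <- setdiff(states, names(raw[[blk]]))
    if (length(sm))
      stop("configuration error: missing state(s) in ", blk, ": ",
           paste(sm, collapse = ", "), call. = FALSE)
  }
  util_keys <- c("E", "D", "C", "B", "A_under18", "A_18plus")
  um <- setdiff(util_keys, names(raw$state_utilities_annual))
  if (length(um))
    stop("configuration error: missing state(s) in state_utilities_annual: ",
         paste(um, collapse = ", "), call. = FALSE)

  p <- list(
    cohort_size = raw$cohort_size,
    p_screened = raw$p_screened,
    incidence = as_spec(raw$incidence, "incidence"),
    p_accept_treatment = raw$p_accept_treatment,
    smn2_copy_probs = as_spec(raw$smn2_copy_probs, "smn2_copy_probs"),
    p_symptomatic_2copy = as_spec(raw$p_symptomatic_2copy,
                                  "p_symptomatic_2copy"),
    p_false_negative_given_sma = raw$p_false_negative_given_sma,
    p_bridge_preterm_ab = raw$p_bridge_preterm_ab,
    p_bridge_symptomatic = raw$p_bridge_symptomatic,
    p_quebec = raw$p_quebec,
    p_quebec_4copy_treated = raw$p_quebec_4copy_treated,
    quebec_4copy_drug_split = unlist(raw$quebec_4copy_drug_split),
    clinical_type_probs = unlist(raw$clinical_type_probs),
    clinical_treatment_splits = lapply(raw$clinical_treatment_splits, unlist),
    prices = c(list(screening_dbs = as_spec(raw$prices$screening_dbs,
                                            "prices$screening_dbs")),
               raw$prices[setdiff(price_keys, "screening_dbs")]),
    state_costs_monthly = stats::setNames(
      lapply(states, function(s) as_spec(raw$state_costs_monthly[[s]],
                                         paste0("state_costs_monthly$", s))),
      states),
    cost_component_shares = lapply(raw$cost_component_shares, unlist),
    state_utilities_annual = stats::setNames(
      lapply(util_keys, function(s)
        as_spec(raw$state_utilities_annual[[s]],
                paste0("state_utilities_annual$", s))),
      util_keys),
    econ = raw$econ,
    entry = raw$entry)
  class(p) <- "sma_parameters"
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  prob_keys <- c("p_screened", "p_accept_treatment",
    "p_false_negative_given_sma", "p_bridge_preterm_ab",
    "p_bridge_symptomatic", "p_quebec", "p_quebec_4copy_treated")
  for (k in prob_keys) {
    v <- p[[k]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("validation error: '", k, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  sum1 <- function(x, nm) {
    if (abs(sum(x) - 1) > 1e-12)
      stop("validation error: '", nm, "' must sum to 1", call. = FALSE)
  }
  sum1(p$clinical_type_probs, "clinical_type_probs")
  sum1(p$quebec_4copy_drug_split, "quebec_4copy_drug_split")
  for (nm in names(p$clinical_treatment_splits))
    sum1(p$clinical_treatment_splits[[nm]],
         paste0("clinical_treatment_splits$", nm))
  for (nm in names(p$cost_component_shares))
    sum1(p$cost_component_shares[[nm]],
         paste0("cost_component_shares$", nm))
  u <- vapply(p$state_utilities_annual[c("E", "D", "C", "B", "A_under18")],
              function(s) s$point, numeric(1))
  if (any(diff(u) < 0))
    stop("validation error: state utilities must be ordered E <= D <= C <= B <= A",
         call. = FALSE)
  if (p$cohort_size <= 0)
    stop("validation error: 'cohort_size' must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.sma_parameters <- function(x, ...) {
  cat("<sma_parameters>\n",
      " cohort size: ", x$cohort_size,
      "; screened: ", x$p_screened,
      "; incidence (base): ", x$incidence$point, "\n",
      " horizon: ", x$econ$horizon_cycles, " cycles; discount: ",
      x$econ$discount_annual, "/yr\n", sep = "")
  invisible(x)
}

# Registry of named scalar parameters for percentile evaluation and DSA.
# Point-mass entries are included so every named input has a quantile
# (degenerate) and a setter.
param_registry <- function(params) {
  reg <- list(
    incidence = list(spec = params$incidence,
      set = function(d, v) { d$incidence <- v; d }),
    p_symptomatic_2copy = list(spec = params$p_symptomatic_2copy,
      set = function(d, v) { d$p_symptomatic_2copy <- v; d }),
    price_screening_dbs = list(spec = params$prices$screening_dbs,
      set = function(d, v) { d$prices$screening_dbs <- v; d }),
    p_screened = list(spec = dist_spec(params$p_screened),
      set = function(d, v) { d$p_screened <- v; d }))
  for (s in c("E", "D", "C", "B", "A")) {
    local({
      st <- s
      reg[[paste0("state_cost_", st)]] <<- list(
        spec = params$state_costs_monthly[[st]],
        set = function(d, v) { d$state_costs_monthly[[st]] <- v; d })
    })
  }
  for (s in c("E", "D", "C", "B", "A_under18", "A_18plus")) {
    local({
      st <- s
      reg[[paste0("utility_", st)]] <<- list(
        spec = params$state_utilities_annual[[st]],
        set = function(d, v) { d$utilities_monthly[[st]] <- v; d })
    })
  }
  for (i in 1:3) {
    local({
      comp <- i
      reg[[paste0("smn2_copies_", comp + 1)]] <<- list(
        spec = params$smn2_copy_probs, component = comp,
        set = function(d, v) {
          old <- d$smn2_copy_probs
          other <- setdiff(seq_along(old), comp)
          scale <- if (sum(old[other]) > 0) (1 - v) / sum(old[other]) else 0
          old[other] <- old[other] * scale
          old[comp] <- v
          d$smn2_copy_probs <- old
          d
        })
    })
  }
  reg
}

#' Quantile of a named model parameter's distribution
#'
#' Evaluates the q-quantile of the sampling distribution attached to a
#' named parameter, as used by the percentile-sweep deterministic
#' sensitivity analysis.  Point-mass parameters return their point value
#' for any q.  SMN2 copy-number components (`smn2_copies_2/3/4`) use the
#' marginal Beta quantile of the Dirichlet.
#'
#' @param params an `sma_parameters` object.
#' @param name parameter name; see [dsa_parameter_names()].
#' @param q probability strictly in (0, 1).
#' @return the quantile value.
#' @export
parameter_percentile <- function(params, name, q) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  reg <- param_registry(params)
  if (!name %in% names(reg)) stop("unknown parameter name: ", name)
  ent <- reg[[name]]
  dist_quantile(ent$spec, q, component = ent$component %||% 1L)
}

#' Names of parameters available to the deterministic sensitivity analysis
#' @param params an `sma_parameters` object.
#' @param stochastic_only drop point-mass parameters (the default: only
#'   parameters with a listed distribution are swept).
#' @return character vector of parameter names.
#' @export
dsa_parameter_names <- function(params, stochastic_only = TRUE) {
  reg <- param_registry(params)
  nm <- names(reg)
  if (stochastic_only)
    nm <- nm[vapply(reg, function(e) e$spec$family != "point", logical(1))]
  nm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Realize a draw skeleton: point values everywhere.
base_skeleton <- function(params) {
  d <- list(
    cohort_size = params$cohort_size,
    p_screened = params$p_screened,
    incidence = params$incidence$point,
    p_accept_treatment = params$p_accept_treatment,
    smn2_copy_probs = params$smn2_copy_probs$point,
    p_symptomatic_2copy = params$p_symptomatic_2copy$point,
    p_false_negative_given_sma = params$p_false_negative_given_sma,
    p_bridge_preterm_ab = params$p_bridge_preterm_ab,
    p_bridge_symptomatic = params$p_bridge_symptomatic,
    p_quebec = params$p_quebec,
    p_quebec_4copy_treated = params$p_quebec_4copy_treated,
    quebec_4copy_drug_split = params$quebec_4copy_drug_split,
    clinical_type_probs = params$clinical_type_probs,
    clinical_treatment_splits = params$clinical_treatment_splits,
    prices = c(list(screening_dbs = params$prices$screening_dbs$point),
               params$prices[setdiff(names(params$prices), "screening_dbs")]),
    state_costs_monthly = vapply(params$state_costs_monthly,
                                 function(s) s$point, numeric(1)),
    cost_component_shares = params$cost_component_shares,
    utilities_monthly = vapply(params$state_utilities_annual,
                               function(s) s$point / 12, numeric(1)),
    econ = params$econ,
    entry = params$entry)
  class(d) <- "sma_draw"
  d
}

#' Base-case parameter draw (all point values)
#' @param params an `sma_parameters` object.
#' @return an `sma_draw` holding the point value of every parameter;
#'   utilities are on the monthly scale (annual / 12).
#' @export
base_case_draw <- function(params) {
  d <- base_skeleton(params)
  d$draw_index <- 0L
  d$seed <- NA_integer_
  d
}

#' Sample one probabilistic-sensitivity-analysis parameter draw
#'
#' Draws one realization of every parameter that carries a sampling
#' distribution (SMA incidence, SMN2 copy split, symptomatic fraction,
#' first-tier screening cost, monthly state costs, monthly state utilities
#' via 1 - Gamma disutility); parameters without a distribution pass
#' through at their point value.  The same seed always yields the same
#' draw.
#'
#' @param params an `sma_parameters` object.
#' @param seed integer seed for this draw.
#' @param draw_index bookkeeping index stored on the draw.
#' @return an `sma_draw`.
#' @export
sample_parameters <- function(params, seed, draw_index = 1L) {
  d <- base_skeleton(params)
  set.seed(seed)
  d$incidence <- dist_sample(params$incidence)
  d$smn2_copy_probs <- as.numeric(dist_sample(params$smn2_copy_probs))
  d$p_symptomatic_2copy <- dist_sample(params$p_symptomatic_2copy)
  d$prices$screening_dbs <- dist_sample(params$prices$screening_dbs)
  d$state_costs_monthly <- vapply(params$state_costs_monthly, dist_sample,
                                  numeric(1))
  d$utilities_monthly <- vapply(params$state_utilities_annual, function(s) {
    if (s$family == "point") s$point / 12 else dist_sample(s)
  }, numeric(1))
  d$draw_index <- as.integer(draw_index)
  d$seed <- as.integer(seed)
  d
}

#' Base-case draw with one parameter moved to a distribution percentile
#'
#' Used by the deterministic sensitivity analysis: every other parameter is
#' held at its point value.  For a Dirichlet component the remaining
#' components are renormalized to keep the copy-number split summing to 1.
#'
#' @inheritParams parameter_percentile
#' @return an `sma_draw`.
#' @export
draw_at_percentile <- function(params, name, q) {
  reg <- param_registry(params)
  if (!name %in% names(reg)) stop("unknown parameter name: ", name)
  v <- parameter_percentile(params, name, q)
  reg[[name]]$set(base_case_draw(params), v)
}
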