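# Probabilistic and deterministic sensitivity analysis.

# Documented substream rule: iteration i of a run with master seed m uses
# seed (m * 7919 + i * 104729) mod (2^31 - 1), so any subset of
# iterations is reproducible independently of the total count.
psa_iteration_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(i) * 104729) %%
               2147483647)
}

#' Probabilistic sensitivity analysis
#'
#' Repeatedly draws every distributional parameter (and, optionally, the
#' hazard parameters via their multivariate-normal approximation), runs
#' both arms, and stores the per-iteration incremental cost, incremental
#' QALYs, and net monetary benefit at each willingness-to-pay value.
#'
#' @param model an `sma_model` from [build_model()].
#' @param n number of iterations (the full analysis uses 1000; scaled
#'   runs are common for checks).
#' @param master_seed integer master seed; per-iteration substreams are
#'   derived from it.
#' @param sample_hazards propagate hazard-parameter uncertainty (default
#'   `TRUE`).
#' @return an `sma_psa`: `$iterations` data frame (one row per
#'   iteration), `$wtp_grid`, and `$summary` (means and 2.5/97.5
#'   percentiles).
#' @export
run_psa <- function(model, n = 1000L, master_seed = 1L,
                    sample_hazards = TRUE) {
  if (n < 1) stop("n must be at least 1")
  wtp <- model$params$econ$wtp_grid
  rows <- vector("list", n)
  failures <- 0L
  for (i in seq_len(n)) {
    seed_i <- psa_iteration_seed(master_seed, i)
    res <- NULL
    for (attempt in 0:1) {
      s <- seed_i + attempt * 499979L
      res <- tryCatch({
        draw <- sample_parameters(model$params, s, draw_index = i)
        hz <- if (sample_hazards)
          perturb_hazard_library(model$hazards, seed = s) else NULL
        model$evaluate(draw, hz)
      }, error = function(e) {
        warning("PSA iteration ", i, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (!is.null(res)) break
    }
    if (is.null(res)) { failures <- failures + 1L; next }
    rows[[i]] <- data.frame(
      iteration = i, seed = seed_i,
      cost_screening = res$screening$cost,
      qaly_screening = res$screening$qaly,
      cost_no_screening = res$no_screening$cost,
      qaly_no_screening = res$no_screening$qaly,
      delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
      t(stats::setNames(res$nmb, paste0("nmb_", wtp))))
  }
  if (failures > 0.05 * n)
    stop("more than 5% of PSA iterations failed (", failures, "/", n, ")")
  it <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(it) <- NULL
  out <- structure(list(iterations = it, wtp_grid = wtp,
                        master_seed = master_seed, n_requested = n,
                        failures = failures),
                   class = "sma_psa")
  out$summary <- summarize_psa(out)
  out
}

summarize_psa <- function(psa) {
  it <- psa$iterations
  cols <- setdiff(names(it), c("iteration", "seed"))
  do.call(rbind, lapply(cols, function(cn) data.frame(
    quantity = cn,
    mean = mean(it[[cn]]),
    lcl = unname(stats::quantile(it[[cn]], 0.025)),
    ucl = unname(stats::quantile(it[[cn]], 0.975)))))
}

#' @export
print.sma_psa <- function(x, ...) {
  it <- x$iterations
  cat("<sma_psa> ", nrow(it), " iterations (", x$failures, " failed)\n",
      sprintf("  mean delta cost: %.1f MCAD (95%% CI %.1f to %.1f)\n",
              mean(it$delta_cost) / 1e6,
              stats::quantile(it$delta_cost, 0.025) / 1e6,
              stats::quantile(it$delta_cost, 0.975) / 1e6),
      sprintf("  mean delta QALY: %.1f (95%% CI %.1f to %.1f)\n",
              mean(it$delta_qaly),
              stats::quantile(it$delta_qaly, 0.025),
              stats::quantile(it$delta_qaly, 0.975)),
      sprintf("  southeast-quadrant share: %.2f\n",
              mean(it$delta_qaly > 0 & it$delta_cost < 0)),
      sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive net monetary benefit at each
#' willingness-to-pay value.
#'
#' @param psa an `sma_psa`.
#' @param wtp_grid willingness-to-pay values (defaults to the analysis
#'   grid).
#' @return data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = psa$wtp_grid) {
  it <- psa$iterations
  if (is.null(it) || nrow(it) == 0) stop("empty PSA result")
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid, function(l)
               mean(nmb(l, it$delta_qaly, it$delta_cost) > 0), numeric(1)))
}

#' Export PSA scatter and CEAC tables
#' @param psa an `sma_psa`.
#' @param dir output directory.
#' @export
write_psa <- function(psa, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(psa$iterations[, c("iteration", "delta_cost",
                                      "delta_qaly")],
                   file.path(dir, "psa_scatter.csv"), row.names = FALSE)
  utils::write.csv(ceac(psa), file.path(dir, "ceac.csv"),
                   row.names = FALSE)
  utils::write.csv(psa$summary, file.path(dir, "psa_summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# Default percentile sweep of the one-at-a-time analysis.
DSA_PERCENTILES <- c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)

hazard_dsa_entries <- function(hazards, labels = names(hazards$fits)) {
  out <- list()
  for (lb in labels) {
    fit <- hazards$fits[[lb]]
    for (j in seq_along(fit$estimates)) {
      nm <- paste0("hazard_", lb, "_", names(fit$estimates)[j])
      out[[nm]] <- list(label = lb, index = j)
    }
  }
  out
}

#' Deterministic sensitivity analysis (percentile sweep, tornado table)
#'
#' One-at-a-time analysis: each parameter with a sampling distribution is
#' set in turn to each requested percentile of that distribution (all
#' other parameters at base case) and the incremental cost is recorded.
#' Hazard parameters can be swept through their marginal normal quantiles
#' as well; rows carry a `hazard_parameter` flag.  Parameters are ranked
#' by the range of the incremental cost across the sweep.
#'
#' @param model an `sma_model`.
#' @param percentiles percentiles in (0, 1); default the standard 11-point
#'   sweep 1, 10, ..., 90, 99.
#' @param parameters parameter names to sweep (default: every parameter
#'   with a distribution, see [dsa_parameter_names()]).
#' @param include_hazards also sweep fitted hazard parameters (default
#'   `TRUE`; computationally heavier).
#' @param hazard_labels dataset labels whose fitted parameters are swept
#'   (default: all fits in the library).
#' @return an `sma_dsa`: `$table` of per-percentile incremental costs and
#'   `$tornado` with per-parameter ranges ranked descending.
#' @export
run_dsa <- function(model, percentiles = DSA_PERCENTILES,
                    parameters = NULL, include_hazards = TRUE,
                    hazard_labels = NULL) {
  if (!length(percentiles) || any(percentiles <= 0 | percentiles >= 1))
    stop("percentiles must lie strictly in (0, 1)")
  params <- model$params
  parameters <- parameters %||% dsa_parameter_names(params)
  base <- run_base_case(model)
  rows <- list()
  for (nm in parameters) {
    for (q in percentiles) {
      draw <- draw_at_percentile(params, nm, q)
      res <- model$evaluate(draw)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, percentile = q, value = parameter_percentile(
          params, nm, q), delta_cost = res$delta_cost,
        hazard_parameter = FALSE)
    }
  }
  if (include_hazards) {
    hz_entries <- hazard_dsa_entries(model$hazards,
                                     hazard_labels %||%
                                       names(model$hazards$fits))
    base_draw <- base_case_draw(params)
    for (nm in names(hz_entries)) {
      ent <- hz_entries[[nm]]
      fit <- model$hazards$fits[[ent$label]]
      se <- sqrt(max(fit$covariance[ent$index, ent$index], 0))
      for (q in percentiles) {
        hz <- model$hazards
        v <- stats::qnorm(q, fit$estimates[ent$index], se)
        pos <- surv_param_positive(fit$family)[ent$index]
        if (pos) v <- max(v, 1e-10)
        f2 <- fit; f2$estimates[ent$index] <- v
        hz$fits[[ent$label]] <- f2
        for (s in names(hz$sets))
          for (tr in names(hz$sets[[s]]))
            if (identical(hz$sets[[s]][[tr]]$label, ent$label))
              hz$sets[[s]][[tr]] <- f2
        for (dd in names(hz$deaths))
          if (identical(hz$deaths[[dd]]$label, ent$label))
            hz$deaths[[dd]] <- f2
        res <- model$evaluate(base_draw, hz)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = nm, percentile = q, value = v,
          delta_cost = res$delta_cost, hazard_parameter = TRUE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tor <- do.call(rbind, lapply(split(tab, tab$parameter), function(d)
    data.frame(parameter = d$parameter[1],
               hazard_parameter = d$hazard_parameter[1],
               low = min(d$delta_cost), high = max(d$delta_cost),
               range = diff(range(d$delta_cost)))))
  tor <- tor[order(-tor$range), ]
  tor$rank <- seq_len(nrow(tor))
  rownames(tor) <- NULL
  structure(list(table = tab, tornado = tor,
                 base_delta_cost = base$delta_cost,
                 percentiles = percentiles),
            class = "sma_dsa")
}

#' @export
print.sma_dsa <- function(x, ...) {
  cat("<sma_dsa> ", length(unique(x$table$parameter)), " parameters x ",
      length(x$percentiles), " percentiles; top of tornado:\n", sep = "")
  print(utils::head(x$tornado[, c("rank", "parameter", "range")], 5))
  invisible(x)
}

#' Export the tornado table as CSV
#' @param dsa an `sma_dsa`.
#' @param path output CSV path.
#' @export
write_tornado <- function(dsa, path) {
  utils::write.csv(dsa$tornado, path, row.names = FALSE)
  invisible(path)
}
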