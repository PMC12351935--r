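# Parametric fitting of right-censored event-time data.
#
# The log-likelihood is the standard censored form
#   sum_{events} log h(t_i) + sum_{all} log S(t_i),
# maximized over a transformed parameter space (log scale for
# positivity-constrained parameters) with a small deterministic
# multi-start to avoid local optima.

surv_loglik <- function(family, pars, time, event) {
  ok <- tryCatch({ surv_check_params(family, pars); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(-Inf)
  ll <- sum(surv_log_hazard(family, time[event == 1], pars)) +
    sum(surv_log_survival(family, time, pars))
  if (!is.finite(ll)) -Inf else ll
}

surv_transform <- function(family, pars) {
  pos <- surv_param_positive(family)
  ifelse(pos, log(pars), pars)
}

surv_untransform <- function(family, theta) {
  pos <- surv_param_positive(family)
  ifelse(pos, exp(theta), theta)
}

surv_start_values <- function(family, time, event) {
  te <- time[event == 1]
  rate0 <- max(sum(event) / sum(time), 1e-8)
  mlog <- mean(log(pmax(te, 1e-8)))
  slog <- stats::sd(log(pmax(te, 1e-8)))
  if (!is.finite(slog) || slog <= 0) slog <- 1
  switch(family,
    exponential = rate0,
    weibull = c(1, 1 / rate0),
    gompertz = c(1e-3, rate0),
    loglogistic = c(1, stats::median(te)),
    lognormal = c(mlog, slog),
    gengamma = c(mlog, slog, 1))
}

#' Corrected Akaike information criterion
#'
#' `aicc = -2 * loglik + 2k + 2k(k + 1) / (n - k - 1)`, the small-sample
#' correction appropriate when the observation count per fitted parameter
#' is modest.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of fitted parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @examples
#' aicc(0, 1, 41)  # 2 + 4/39
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a parametric survival family to right-censored data
#'
#' Maximizes the right-censored log-likelihood for one of the six
#' supported families.  The parameter covariance is the inverse observed
#' information (numerical Hessian at the maximum).
#'
#' @param data event-time data frame with columns `time` and `event`
#'   (1 = event, 0 = right-censored).
#' @param family family name; see [surv_families()].
#' @param n_starts number of deterministic multi-start points.
#' @return an object of class `sma_surv_fit` with elements `family`,
#'   `estimates`, `loglik`, `k`, `n`, `aicc`, `covariance`.
#' @export
fit_parametric <- function(data, family, n_starts = 3L) {
  family <- match.arg(family, SURV_FAMILIES)
  time <- data$time
  event <- data$event
  if (sum(event) == 0)
    stop("cannot fit '", family, "': dataset has no events")
  k <- surv_n_params(family)
  n <- length(time)
  if (n < k + 2) stop("need at least k + 2 observations")

  negll <- function(theta) {
    -surv_loglik(family, surv_untransform(family, theta), time, event)
  }
  theta0 <- surv_transform(family, surv_start_values(family, time, event))
  starts <- list(theta0, theta0 + 0.5, theta0 - 0.5)
  if (family == "gengamma") {
    # vary the shape-of-shape parameter Q across starts: Weibull-like,
    # lognormal-like, negative-Q branch
    starts[[2]][3] <- 0.05
    starts[[3]][3] <- -0.5
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("fit of family '", family, "' did not converge")

  est <- surv_untransform(family, best$par)
  names(est) <- surv_param_names(family)
  ll <- -best$value

  negll_nat <- function(p) -surv_loglik(family, p, time, event)
  # differentiation steps scaled to each parameter's magnitude (the
  # default absolute step can cross into invalid parameter space for
  # rates near zero)
  H <- tryCatch(stats::optimHess(est, negll_nat,
                                 control = list(ndeps = pmax(abs(est) * 1e-4,
                                                             1e-10))),
                error = function(e) NULL)
  covm <- NULL
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    covm <- tryCatch(solve(H), error = function(e) NULL)
  }
  if (is.null(covm)) covm <- MASS::ginv(if (is.null(H)) diag(k) else H)
  covm <- (covm + t(covm)) / 2
  # a near-singular observed information can leave the inverse indefinite;
  # project onto the nearest positive-semidefinite matrix
  ev <- eigen(covm, symmetric = TRUE)
  if (min(ev$values) < 0)
    covm <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  covm <- (covm + t(covm)) / 2
  dimnames(covm) <- list(names(est), names(est))

  structure(list(family = family, estimates = est, loglik = ll, k = k,
                 n = n, n_events = sum(event), aicc = aicc(ll, k, n),
                 covariance = covm,
                 label = if (!is.null(data$label)) data$label[1] else NA),
            class = "sma_surv_fit")
}

#' @export
print.sma_surv_fit <- function(x, ...) {
  cat("<sma_surv_fit> ", x$family, "; n = ", x$n, " (", x$n_events,
      " events); loglik = ", round(x$loglik, 2),
      "; AICc = ", round(x$aicc, 2), "\n  estimates: ",
      paste(names(x$estimates), signif(x$estimates, 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fit all six families and select the minimum-AICc fit
#'
#' Attempts exponential, Weibull, Gompertz, log-logistic, log-normal and
#' generalized gamma fits; families that fail to converge are skipped with
#' a warning.  The fit with the smallest corrected AIC wins; exact ties go
#' to the family with fewer parameters, then to the fixed family order.
#'
#' @inheritParams fit_parametric
#' @param families candidate families (default: all six).
#' @return the selected `sma_surv_fit`, with the per-family AICc table
#'   attached as attribute `aicc_table`.
#' @export
select_best_fit <- function(data, families = SURV_FAMILIES) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_parametric(data, fam), error = function(e) {
      warning("fit of family '", fam, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("all candidate families failed to fit")
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(aiccs, ks, match(names(fits), SURV_FAMILIES))
  best <- fits[[ord[1]]]
  attr(best, "aicc_table") <- data.frame(family = names(fits),
    k = ks, aicc = aiccs, row.names = NULL)
  best
}

#' Hazard of a fitted survival model at time t
#' @param fit an `sma_surv_fit` (or `sma_mcmc`) object.
#' @param t time in months, `t >= 0`.
#' @return hazard rate per month.
#' @export
hazard_at <- function(fit, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  surv_hazard(fit$family, t, fit$estimates)
}

#' Multivariate-normal draws of fitted hazard parameters
#'
#' Samples parameter vectors from the asymptotic normal approximation
#' around the maximum-likelihood estimates.  Draws that violate the
#' family's parameter constraints (and would give negative or undefined
#' hazards on the model horizon) are rejected and redrawn; the number of
#' rejections is reported via `message()`.
#'
#' @param fit an `sma_surv_fit`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return an `n` x k matrix of parameter draws.
#' @export
sample_hazard_parameters <- function(fit, n, seed = 1L) {
  covm <- (fit$covariance + t(fit$covariance)) / 2
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance matrix is not positive semidefinite")
  covm <- covm + diag(max(0, -min(ev)) + 0, nrow(covm))
  set.seed(seed)
  k <- length(fit$estimates)
  valid <- function(p) tryCatch({
    surv_check_params(fit$family, p)
    all(is.finite(surv_hazard(fit$family, c(0.5, seq(1, 960, by = 24)), p)))
  }, error = function(e) FALSE)
  draws <- matrix(NA_real_, n, k,
                  dimnames = list(NULL, names(fit$estimates)))
  rejected <- 0L
  for (i in seq_len(n)) {
    p <- NULL
    for (try in 1:100) {
      cand <- as.numeric(MASS::mvrnorm(1, fit$estimates, covm))
      if (valid(cand)) { p <- cand; break }
      rejected <- rejected + 1L
    }
    # fall back to the MLE after persistent rejection
    draws[i, ] <- if (is.null(p)) fit$estimates else p
  }
  if (rejected > 0)
    message(rejected, " invalid parameter draw(s) rejected and redrawn")
  draws
}

#' Affine-invariant ensemble MCMC for a censored Weibull fit
#'
#' Runs the stretch-move ensemble sampler over the right-censored Weibull
#' log-likelihood with flat priors on the log-parameters, as used for the
#' long-term survival inputs.  The first 25% of steps are discarded as
#' burn-in.
#'
#' @param data event-time data frame with `time` and `event` columns.
#' @param walkers number of walkers (at least 4, i.e. twice the parameter
#'   dimension).
#' @param steps number of ensemble steps.
#' @param seed integer seed.
#' @param stretch stretch-move scale parameter `a` (default 2).
#' @return an object of class `sma_mcmc` with posterior means and
#'   covariance on the natural (shape, scale) parameter scale, the
#'   per-walker chains, and the acceptance fraction.
#' @export
fit_weibull_ensemble_mcmc <- function(data, walkers = 32L, steps = 2000L,
                                      seed = 1L, stretch = 2) {
  d <- 2L
  if (walkers < 4) stop("need at least 4 walkers (twice the dimension)")
  time <- data$time; event <- data$event
  if (sum(event) == 0) stop("dataset has no events")

  logpost <- function(theta) {
    surv_loglik("weibull", exp(theta), time, event)
  }
  set.seed(seed)
  theta0 <- surv_transform("weibull",
                           surv_start_values("weibull", time, event))
  pos <- matrix(rep(theta0, each = walkers), walkers, d) +
    matrix(stats::rnorm(walkers * d, sd = 0.1), walkers, d)
  lp <- apply(pos, 1, logpost)

  chains <- array(NA_real_, c(walkers, steps, d))
  accept <- 0L
  for (s in seq_len(steps)) {
    for (w in seq_len(walkers)) {
      other <- sample(setdiff(seq_len(walkers), w), 1)
      z <- ((stretch - 1) * stats::runif(1) + 1)^2 / stretch
      prop <- pos[other, ] + z * (pos[w, ] - pos[other, ])
      lp_prop <- logpost(prop)
      if (log(stats::runif(1)) < (d - 1) * log(z) + lp_prop - lp[w]) {
        pos[w, ] <- prop
        lp[w] <- lp_prop
        accept <- accept + 1L
      }
    }
    chains[, s, ] <- pos
  }
  burn <- floor(steps * 0.25)
  post <- exp(matrix(chains[, (burn + 1):steps, ], ncol = d))
  colnames(post) <- c("shape", "scale")
  structure(list(family = "weibull",
                 estimates = colMeans(post),
                 covariance = stats::cov(post),
                 chains = chains,
                 burn_in = burn,
                 acceptance_fraction = accept / (walkers * steps)),
            class = "sma_mcmc")
}

#' @export
print.sma_mcmc <- function(x, ...) {
  cat("<sma_mcmc> weibull posterior; mean shape = ",
      signif(x$estimates[1], 4), ", mean scale = ",
      signif(x$estimates[2], 4), "; acceptance = ",
      round(x$acceptance_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Write a CSV summary of one or more parametric fits
#' @param fits a single `sma_surv_fit` or a list of them.
#' @param path output CSV path.
#' @export
write_fit_summary <- function(fits, path) {
  if (inherits(fits, "sma_surv_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) data.frame(
    label = as.character(f$label %||% NA), family = f$family,
    params = paste(names(f$estimates), signif(f$estimates, 8),
                   sep = "=", collapse = ";"),
    loglik = f$loglik, k = f$k, n = f$n, aicc = f$aicc))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
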