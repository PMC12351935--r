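# Closed-form log-survival, log-hazard and quantile functions for the six
# parametric time-to-event families used throughout the package.
# Parameterizations follow the flexsurv conventions:
#   exponential  rate
#   weibull      shape, scale          S(t) = exp(-(t/scale)^shape)
#   gompertz     shape, rate           h(t) = rate * exp(shape * t)
#   loglogistic  shape, scale          S(t) = 1 / (1 + (t/scale)^shape)
#   lognormal    meanlog, sdlog
#   gengamma     mu, sigma, Q          (Q = 0 reduces to lognormal,
#                                       Q = 1 to Weibull, sigma = Q = 1 to
#                                       exponential)

SURV_FAMILIES <- c("exponential", "weibull", "gompertz", "loglogistic",
                   "lognormal", "gengamma")

surv_n_params <- function(family) {
  switch(family, exponential = 1L, weibull = 2L, gompertz = 2L,
         loglogistic = 2L, lognormal = 2L, gengamma = 3L,
         stop("unknown survival family: ", family))
}

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull = c("shape", "scale"),
    gompertz = c("shape", "rate"),
    loglogistic = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    gengamma = c("mu", "sigma", "Q"))
}

# TRUE where the parameter must be strictly positive; FALSE where any real
# value is admissible (gompertz shape, lognormal meanlog, gengamma mu and Q).
surv_param_positive <- function(family) {
  switch(family,
    exponential = TRUE,
    weibull = c(TRUE, TRUE),
    gompertz = c(FALSE, TRUE),
    loglogistic = c(TRUE, TRUE),
    lognormal = c(FALSE, TRUE),
    gengamma = c(FALSE, TRUE, FALSE))
}

surv_check_params <- function(family, pars) {
  family <- match.arg(family, SURV_FAMILIES)
  k <- surv_n_params(family)
  if (length(pars) != k)
    stop(family, " requires ", k, " parameter(s), got ", length(pars))
  if (any(!is.finite(pars)))
    stop("non-finite ", family, " parameters")
  pos <- surv_param_positive(family)
  if (any(pars[pos] <= 0))
    stop("invalid ", family, " parameters: ",
         paste(surv_param_names(family)[pos & pars <= 0], collapse = ", "),
         " must be strictly positive")
  invisible(family)
}

surv_log_survival <- function(family, t, pars) {
  t <- pmax(t, 0)
  switch(family,
    exponential = -pars[1] * t,
    weibull = -(t / pars[2])^pars[1],
    gompertz = {
      a <- pars[1]; b <- pars[2]
      if (abs(a) < 1e-12) -b * t else -(b / a) * (exp(a * t) - 1)
    },
    loglogistic = -log1p((t / pars[2])^pars[1]),
    lognormal = stats::plnorm(t, pars[1], pars[2], lower.tail = FALSE,
                              log.p = TRUE),
    gengamma = {
      mu <- pars[1]; sigma <- pars[2]; Q <- pars[3]
      if (abs(Q) < 1e-8)
        return(stats::plnorm(t, mu, sigma, lower.tail = FALSE, log.p = TRUE))
      q2 <- Q^-2
      w <- (log(pmax(t, .Machine$double.xmin)) - mu) / sigma
      u <- q2 * exp(Q * w)
      out <- if (Q > 0)
        stats::pgamma(u, q2, lower.tail = FALSE, log.p = TRUE)
      else
        stats::pgamma(u, q2, lower.tail = TRUE, log.p = TRUE)
      out[t <= 0] <- 0
      out
    })
}

surv_log_hazard <- function(family, t, pars) {
  tt <- pmax(t, .Machine$double.xmin)
  switch(family,
    exponential = rep(log(pars[1]), length(t)),
    weibull = log(pars[1]) - log(pars[2]) +
      (pars[1] - 1) * (log(tt) - log(pars[2])),
    gompertz = log(pars[2]) + pars[1] * t,
    loglogistic = {
      z <- (tt / pars[2])^pars[1]
      log(pars[1]) - log(pars[2]) + (pars[1] - 1) * log(tt / pars[2]) -
        log1p(z)
    },
    lognormal = stats::dlnorm(tt, pars[1], pars[2], log = TRUE) -
      surv_log_survival("lognormal", t, pars),
    gengamma = {
      mu <- pars[1]; sigma <- pars[2]; Q <- pars[3]
      if (abs(Q) < 1e-8)
        return(surv_log_hazard("lognormal", t, c(mu, sigma)))
      q2 <- Q^-2
      w <- (log(tt) - mu) / sigma
      logf <- log(abs(Q)) + q2 * log(q2) - lgamma(q2) - log(sigma) -
        log(tt) + q2 * (Q * w - exp(Q * w))
      logf - surv_log_survival("gengamma", t, pars)
    })
}

#' Survival, hazard and density of the supported parametric families
#'
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`, `"gengamma"`.
#' @param t times in months, `t >= 0`.
#' @param pars parameter vector in the family's conventional order (see
#'   [surv_families()]).
#' @return numeric vector.
#' @export
surv_survival <- function(family, t, pars) {
  family <- match.arg(family, SURV_FAMILIES)
  surv_check_params(family, pars)
  exp(surv_log_survival(family, t, pars))
}

#' @rdname surv_survival
#' @export
surv_hazard <- function(family, t, pars) {
  family <- match.arg(family, SURV_FAMILIES)
  surv_check_params(family, pars)
  if (any(t < 0)) stop("t must be nonnegative")
  exp(surv_log_hazard(family, t, pars))
}

#' @rdname surv_survival
#' @export
surv_density <- function(family, t, pars) {
  surv_hazard(family, t, pars) * surv_survival(family, t, pars)
}

#' @rdname surv_survival
#' @param p probabilities in (0, 1).
#' @export
surv_quantile <- function(family, p, pars) {
  family <- match.arg(family, SURV_FAMILIES)
  surv_check_params(family, pars)
  switch(family,
    exponential = stats::qexp(p, pars[1]),
    weibull = stats::qweibull(p, pars[1], pars[2]),
    gompertz = {
      a <- pars[1]; b <- pars[2]
      if (abs(a) < 1e-12) stats::qexp(p, b)
      else {
        arg <- 1 - a * log1p(-p) / b
        out <- ifelse(arg > 0, log(arg) / a, Inf)
        out
      }
    },
    loglogistic = pars[2] * (p / (1 - p))^(1 / pars[1]),
    lognormal = stats::qlnorm(p, pars[1], pars[2]),
    gengamma = {
      mu <- pars[1]; sigma <- pars[2]; Q <- pars[3]
      if (abs(Q) < 1e-8) return(stats::qlnorm(p, mu, sigma))
      q2 <- Q^-2
      u <- if (Q > 0) stats::qgamma(p, q2) else stats::qgamma(1 - p, q2)
      exp(mu + sigma * log(u / q2) / Q)
    })
}

#' List the supported survival families and their parameter names
#' @return named list mapping family to parameter names.
#' @export
surv_families <- function() {
  stats::setNames(lapply(SURV_FAMILIES, surv_param_names), SURV_FAMILIES)
}
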