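#' Distribution specifications for model parameters
#'
#' A `sma_dist` couples a base-case point value with the sampling
#' distribution used in probabilistic sensitivity analysis.  Supported
#' families: `point` (degenerate), `beta`, `gamma` (shape/scale, mean =
#' shape * scale), `dirichlet`, and `one_minus_gamma` (a Gamma disutility
#' subtracted from 1, used for monthly health-state utilities so that draws
#' can fall below zero for states worse than death).
#'
#' @param point base-case value (a probability, cost, or utility; a vector
#'   summing to 1 for `dirichlet`).
#' @param family distribution family name.
#' @param ... family parameters: `a`, `b` (beta); `shape`, `scale` (gamma and
#'   one_minus_gamma); `alpha` (dirichlet concentration vector).
#' @return an object of class `sma_dist`.
#' @examples
#' incidence <- dist_spec(1e-4, "beta", a = 6.57, b = 5.3e4)
#' dist_mean(incidence)
#' @export
dist_spec <- function(point, family = "point", ...) {
  family <- match.arg(family,
    c("point", "beta", "gamma", "dirichlet", "one_minus_gamma"))
  pars <- list(...)
  spec <- structure(list(family = family, params = pars, point = point),
                    class = "sma_dist")
  validate_dist_spec(spec)
  spec
}

validate_dist_spec <- function(spec) {
  fam <- spec$family
  p <- spec$params
  need <- switch(fam,
    point = character(),
    beta = c("a", "b"),
    gamma = c("shape", "scale"),
    one_minus_gamma = c("shape", "scale"),
    dirichlet = "alpha")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("distribution '", fam, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in need)
    if (any(!is.finite(p[[nm]])) || any(p[[nm]] <= 0))
      stop("distribution parameter '", nm, "' must be strictly positive",
           call. = FALSE)
  if (fam == "beta" && (spec$point < 0 || spec$point > 1))
    stop("beta point value must lie in [0, 1]", call. = FALSE)
  if (fam == "dirichlet") {
    if (length(spec$point) != length(p$alpha))
      stop("dirichlet point vector and alpha must have equal length",
           call. = FALSE)
    if (abs(sum(spec$point) - 1) > 1e-9)
      stop("dirichlet point values must sum to 1", call. = FALSE)
  }
  if (fam == "gamma") {
    m <- p$shape * p$scale
    if (spec$point > 0 && abs(m - spec$point) / spec$point > 0.10)
      stop("gamma mean shape*scale = ", signif(m, 4),
           " deviates more than 10% from point value ", spec$point,
           call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.sma_dist <- function(x, ...) {
  cat("<sma_dist> ", x$family, "(",
      paste(names(x$params), unlist(lapply(x$params, function(v)
        paste(signif(v, 4), collapse = ","))), sep = "=", collapse = ", "),
      "), point = ", paste(signif(x$point, 4), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Closed-form mean of a distribution specification
#' @param spec an [dist_spec()] object.
#' @return numeric mean (vector for dirichlet).
#' @export
dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    point = spec$point,
    beta = p$a / (p$a + p$b),
    gamma = p$shape * p$scale,
    one_minus_gamma = 1 - p$shape * p$scale,
    dirichlet = p$alpha / sum(p$alpha))
}

#' Draw from a distribution specification
#'
#' Point-mass specs return the point value unchanged.  Dirichlet draws use
#' the normalized-Gamma construction.
#'
#' @param spec an [dist_spec()] object.
#' @param n number of draws.
#' @return numeric vector of length `n` (an `n` x k matrix for dirichlet).
#' @export
dist_sample <- function(spec, n = 1) {
  p <- spec$params
  switch(spec$family,
    point = rep(spec$point, n),
    beta = stats::rbeta(n, p$a, p$b),
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    one_minus_gamma = 1 - stats::rgamma(n, shape = p$shape, scale = p$scale),
    dirichlet = {
      k <- length(p$alpha)
      g <- matrix(stats::rgamma(n * k, shape = rep(p$alpha, each = n)), n, k)
      g / rowSums(g)
    })
}

#' Quantile of a distribution specification
#'
#' For `one_minus_gamma` the quantile is taken on the utility scale, so the
#' result is increasing in `q`.  For `dirichlet`, `component` selects the
#' marginal Beta(alpha_i, sum(alpha) - alpha_i) quantile.
#'
#' @param spec an [dist_spec()] object.
#' @param q probability in (0, 1).
#' @param component dirichlet component index.
#' @return the q-quantile.
#' @export
dist_quantile <- function(spec, q, component = 1L) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  p <- spec$params
  switch(spec$family,
    point = rep(spec$point, length(q)),
    beta = stats::qbeta(q, p$a, p$b),
    gamma = stats::qgamma(q, shape = p$shape, scale = p$scale),
    one_minus_gamma = 1 - stats::qgamma(1 - q, shape = p$shape,
                                        scale = p$scale),
    dirichlet = {
      a <- p$alpha
      stats::qbeta(q, a[component], sum(a) - a[component])
    })
}
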