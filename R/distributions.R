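## Uncertainty-distribution descriptors.
##
## Every uncertain scalar in the disease and choice tables carries a
## descriptor (family, par1, par2).  The closed family set covers costs
## (gamma, lognormal), probabilities (beta), rates (uniform) and fixed
## values (point); there is deliberately no open-ended descriptor language.

DIST_FAMILIES <- c("point", "gamma", "beta", "lognormal", "uniform")

#' Build an uncertainty-distribution descriptor
#'
#' @param family one of "point", "gamma", "beta", "lognormal", "uniform"
#' @param par1,par2 family parameters: point(value, -), gamma(shape, scale),
#'   beta(alpha, beta), lognormal(meanlog, sdlog), uniform(min, max)
#' @return a list of class "surgecea_dist"
#' @export
dist_spec <- function(family, par1, par2 = NA_real_) {
  family <- match.arg(family, DIST_FAMILIES)
  stopifnot(is.numeric(par1), length(par1) == 1L)
  structure(list(family = family, par1 = as.numeric(par1),
                 par2 = as.numeric(par2)), class = "surgecea_dist")
}

#' Draw from an uncertainty-distribution descriptor
#'
#' Point-mass descriptors return their value for every draw, which is what
#' makes a degenerate parameter table reproduce the base-case run exactly.
#'
#' @param d a `dist_spec()` or an equivalent list
#' @param n number of draws
#' @return numeric vector of length `n`
#' @export
draw_dist <- function(d, n = 1L) {
  switch(d$family,
    point     = rep(d$par1, n),
    gamma     = stats::rgamma(n, shape = d$par1, scale = d$par2),
    beta      = stats::rbeta(n, d$par1, d$par2),
    lognormal = stats::rlnorm(n, meanlog = d$par1, sdlog = d$par2),
    uniform   = stats::runif(n, d$par1, d$par2),
    stop("unknown distribution family: ", d$family)
  )
}

#' Analytic mean of a descriptor (used for validation and calibration)
#' @param d a `dist_spec()`
#' @return numeric scalar
#' @export
dist_mean <- function(d) {
  switch(d$family,
    point     = d$par1,
    gamma     = d$par1 * d$par2,
    beta      = d$par1 / (d$par1 + d$par2),
    lognormal = exp(d$par1 + d$par2^2 / 2),
    uniform   = (d$par1 + d$par2) / 2,
    stop("unknown distribution family: ", d$family)
  )
}
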