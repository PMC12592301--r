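#' Dirichlet-multinomial log probability mass
#'
#' Log pmf of the Dirichlet-multinomial distribution obtained by
#' integrating a Dirichlet(gamma) probability vector out of a multinomial:
#' `log Gamma(n_+ + 1) + log Gamma(g_+) - log Gamma(n_+ + g_+) +
#' sum_j [log Gamma(n_j + g_j) - log Gamma(g_j) - log Gamma(n_j + 1)]`.
#' All terms are computed in log-gamma space.
#'
#' @param n non-negative integer count vector.
#' @param gamma strictly positive concentration vector, same length as `n`.
#' @return log probability (scalar).
#' @examples
#' exp(dm_log_pmf(c(1, 0), c(1, 1)))  # 1/2
#' @export
dm_log_pmf <- function(n, gamma) {
  if (length(n) != length(gamma)) stop("'n' and 'gamma' lengths differ")
  if (anyNA(gamma) || any(gamma <= 0)) stop("all gamma components must be > 0")
  if (anyNA(n) || any(n < 0) || any(n != round(n)))
    stop("'n' must be non-negative integers")
  np <- sum(n); gp <- sum(gamma)
  lgamma(np + 1) + lgamma(gp) - lgamma(np + gp) +
    sum(lgamma(n + gamma) - lgamma(gamma) - lgamma(n + 1))
}

#' Dirichlet-multinomial variance inflation factor
#'
#' Overdispersion of the Dirichlet-multinomial relative to the multinomial:
#' the variance is inflated by `(n_+ + gamma_+) / (1 + gamma_+)`.
#'
#' @param n_plus total count (non-negative).
#' @param gamma_plus total concentration (positive).
#' @return the inflation factor.
#' @export
dm_variance_inflation <- function(n_plus, gamma_plus) {
  if (any(n_plus < 0)) stop("'n_plus' must be non-negative")
  if (any(gamma_plus <= 0)) stop("'gamma_plus' must be positive")
  (n_plus + gamma_plus) / (1 + gamma_plus)
}

## --- internal samplers and densities ------------------------------------

# one draw from Dirichlet(alpha) via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) {  # all-zero underflow for tiny alpha: fall back to argmax
    g <- rep.int(0, length(alpha)); g[which.max(alpha)] <- 1; return(g)
  }
  g / s
}

# truncated-normal draw on [lower, upper] by inverse CDF; degenerate
# intervals collapse to the nearest bound
rtnorm1 <- function(mean, sd, lower, upper) {
  if (!is.finite(lower)) lower <- -Inf
  if (!is.finite(upper)) upper <- Inf
  if (upper <= lower) return(upper)
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (pu - pl < 1e-14) {
    # interval far in a tail: return the bound nearest the mean
    return(if (abs(lower - mean) < abs(upper - mean)) lower else upper)
  }
  x <- stats::qnorm(stats::runif(1, pl, pu), mean, sd)
  min(max(x, lower), upper)
}

# normalized truncated-normal log density (0-width intervals contribute 0,
# treated as a point mass)
dtnorm_log <- function(x, mean, sd, lower, upper) {
  if (upper < lower) return(-Inf)
  if (upper - lower < 1e-12)
    return(if (abs(x - upper) < 1e-9) 0 else -Inf)
  if (x < lower - 1e-12 || x > upper + 1e-12) return(-Inf)
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (z <= 0) return(-Inf)
  stats::dnorm(x, mean, sd, log = TRUE) - log(z)
}

# univariate slice sampler (stepping out + shrinkage); exact for the
# log-concave conditionals it is applied to
slice1 <- function(x0, logf, w = 1, max_steps = 100L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  y <- f0 - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  k <- max_steps
  while (k > 0L && is.finite(fl <- logf(L)) && fl > y) { L <- L - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && is.finite(fr <- logf(R)) && fr > y) { R <- R + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, L, R)
    f1 <- logf(x1)
    if (is.finite(f1) && f1 >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}
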