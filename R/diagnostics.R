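#' Bundle parallel MCMC chains
#'
#' @param chains list of equal-length numeric vectors (one parameter) or
#'   matrices/data frames with identical column names (draws x parameters).
#' @param burnin,thin iteration metadata carried along for reporting.
#' @return an object of class `chain_set`.
#' @export
chain_set <- function(chains, burnin = 0L, thin = 1L) {
  if (!is.list(chains) || !length(chains)) stop("'chains' must be a non-empty list")
  chains <- lapply(chains, function(x) if (is.null(dim(x))) matrix(as.numeric(x)) else as.matrix(x))
  n <- vapply(chains, nrow, integer(1))
  if (length(unique(n)) != 1L) stop("chains must have equal lengths")
  k <- vapply(chains, ncol, integer(1))
  if (length(unique(k)) != 1L) stop("chains must have the same parameters")
  structure(list(chains = chains, burnin = as.integer(burnin),
                 thin = as.integer(thin)), class = "chain_set")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical two-variance form: with m chains of n draws, `W` the mean
#' within-chain variance and `B/n` the variance of chain means, the shrink
#' factor is `sqrt(((n-1)/n W + B/n) / W)`. Values close to 1 indicate
#' convergence. Zero within-chain variance is reported as a degenerate
#' `NA` (attribute `degenerate`), not an error.
#'
#' @param chains a [chain_set()] or list of numeric vectors; at least 2
#'   chains of at least 10 draws.
#' @param parameter column index or name when chains hold several
#'   parameters.
#' @return the shrink factor (scalar).
#' @export
gelman_rubin <- function(chains, parameter = 1L) {
  if (!inherits(chains, "chain_set")) chains <- chain_set(chains)
  xs <- lapply(chains$chains, function(m) m[, parameter])
  m <- length(xs)
  n <- length(xs[[1L]])
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 10L) stop("at least 10 draws per chain are required")
  W <- mean(vapply(xs, stats::var, numeric(1)))
  B_over_n <- stats::var(vapply(xs, mean, numeric(1)))
  if (W <= 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Sample autocorrelation of a chain
#'
#' @param chain numeric draw sequence.
#' @param lag non-negative lag, smaller than the chain length.
#' @return autocorrelation at `lag`; `NA` (flagged `degenerate`) for a
#'   constant chain.
#' @export
autocorrelation <- function(chain, lag) {
  lag <- as.integer(lag)
  if (lag < 0L || lag >= length(chain)) stop("'lag' must be in [0, length)")
  if (stats::var(chain) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric(stats::acf(chain, lag.max = lag, plot = FALSE,
                        demean = TRUE)$acf[lag + 1L])
}

#' Highest posterior density interval
#'
#' Empirical shortest-window HPD: the narrowest contiguous window of the
#' sorted draws containing `ceiling(mass * n)` of them; ties broken by the
#' lowest start.
#'
#' @param draws numeric vector of at least 20 posterior draws.
#' @param mass interval mass in (0, 1).
#' @return length-2 numeric vector `(low, high)`.
#' @export
hpd_interval <- function(draws, mass) {
  if (mass <= 0 || mass >= 1) stop("'mass' must lie in (0, 1)")
  n <- length(draws)
  if (n < 20L) stop("at least 20 draws are required")
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)  # which.min takes the first (lowest-start) tie
  c(x[i], x[i + k - 1L])
}

#' Rolling mean and quantile summaries of a chain
#'
#' Trailing-window statistics used to eyeball stationarity: for each
#' position from `window` to the chain length, the mean and the 2.5th and
#' 97.5th percentiles of the last `window` draws.
#'
#' @param chain numeric draw sequence.
#' @param window window length, at most the chain length.
#' @return data frame with columns `end`, `mean`, `q2.5`, `q97.5`.
#' @export
rolling_summary <- function(chain, window) {
  window <- as.integer(window)
  n <- length(chain)
  if (window < 1L || window > n) stop("'window' must be in [1, length]")
  ends <- window:n
  out <- t(vapply(ends, function(e) {
    w <- chain[(e - window + 1L):e]
    c(mean(w), stats::quantile(w, c(0.025, 0.975), names = FALSE))
  }, numeric(3)))
  data.frame(end = ends, mean = out[, 1L], q2.5 = out[, 2L], q97.5 = out[, 3L])
}
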