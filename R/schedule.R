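#' MCMC sampler schedule
#'
#' Iterations, burn-in, thinning and chain count shared by both samplers.
#' The default mirrors the analysis protocol: 2 chains of 110,000
#' iterations, the first 10,000 discarded, every 10th retained, giving
#' 20,000 posterior draws.
#'
#' @param iters iterations per chain.
#' @param burnin burn-in iterations discarded per chain; must be < `iters`.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param chains number of independent chains.
#' @return an object of class `sampler_schedule`.
#' @export
sampler_schedule <- function(iters = 110000L, burnin = 10000L, thin = 10L,
                             chains = 2L) {
  iters <- as.integer(iters); burnin <- as.integer(burnin)
  thin <- as.integer(thin); chains <- as.integer(chains)
  if (burnin >= iters) stop("burn-in must be smaller than iterations")
  if (burnin < 0L) stop("burn-in must be non-negative")
  if (thin < 1L) stop("thinning must be >= 1")
  if (chains < 1L) stop("at least one chain is required")
  out <- list(iters = iters, burnin = burnin, thin = thin, chains = chains)
  class(out) <- "sampler_schedule"
  out
}

#' Number of retained posterior draws under a schedule
#' @param schedule a [sampler_schedule()].
#' @return total retained draws across chains.
#' @export
retained_draws <- function(schedule) {
  stopifnot(inherits(schedule, "sampler_schedule"))
  schedule$chains * ((schedule$iters - schedule$burnin) %/% schedule$thin)
}

#' @export
print.sampler_schedule <- function(x, ...) {
  cat("Sampler schedule:", x$chains, "chain(s) x", x$iters,
      "iterations, burn-in", x$burnin, ", thin", x$thin, "->",
      retained_draws(x), "retained draws\n")
  invisible(x)
}
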