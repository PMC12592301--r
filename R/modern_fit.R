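#' Poisson linear predictor for one census cell
#'
#' The survivor-count model is `Y_sij ~ Poisson(mu_sij)` with
#' `log mu_sij = eta_i + log PS_ij + beta1 t_j + beta2 Sex_si +
#' beta3 Sex_si t_j`; the log population size enters as an offset with its
#' coefficient fixed at 1, so the model describes survival rates rather
#' than raw counts.
#'
#' @param table a [modern_herd_table()].
#' @param params list with elements `beta1`, `beta2`, `beta3` and `eta`
#'   (one random effect per herd, in `table$herd_ids` order).
#' @param cell length-3 vector `(i, s, j)`: herd index, sex (1 = male,
#'   0 = female), class index.
#' @return the log mean for that cell.
#' @export
linear_predictor <- function(table, params, cell) {
  stopifnot(inherits(table, "modern_herd_table"), length(cell) == 3L)
  i <- as.integer(cell[1L]); s <- as.integer(cell[2L]); j <- as.integer(cell[3L])
  if (i < 1L || i > length(table$herd_ids)) stop("herd index out of range")
  if (!s %in% c(0L, 1L)) stop("sex must be 0 or 1")
  if (j < 1L || j > n_classes(table$schema)) stop("class index out of range")
  df <- table$data
  row <- which(df$herd_id == table$herd_ids[i] & df$sex == s &
                 df$age_class == table$schema$classes$label[j])
  if (length(row) != 1L) stop("cell not found in table")
  tj <- table$schema$midpoints[j]
  params$eta[i] + log(df$population[row]) + params$beta1 * tj +
    params$beta2 * s + params$beta3 * s * tj
}

#' Age-dependent sex ratio
#'
#' Males per female alive at age `t_star` months:
#' `r(t) = exp(beta2 + beta3 t)`.
#'
#' @param beta2 male main effect (log scale).
#' @param beta3 sex-by-age interaction (per month).
#' @param t_star age(s) in months, non-negative.
#' @return sex ratio(s), strictly positive.
#' @export
sex_ratio <- function(beta2, beta3, t_star) {
  if (any(t_star < 0)) stop("'t_star' must be non-negative")
  exp(beta2 + beta3 * t_star)
}

#' Fit the modern sex-ratio model by MCMC
#'
#' Bayesian Poisson regression of survivor counts on age, sex and their
#' interaction, with a log-population offset and herd random effects
#' `eta_i ~ N(0, omega^2)`. Priors: `beta ~ N(0, 10000)` (vague Gaussian),
#' `omega ~ Uniform(0, 100)`. The log-concave conditionals of the betas and
#' etas are updated by univariate slice sampling; omega by random-walk
#' Metropolis on the log scale. Chains are initialised from a Poisson GLM
#' fit for fast convergence.
#'
#' @param table a [modern_herd_table()]; at least two herds are needed for
#'   the random-effect scale to be identifiable (a warning is issued
#'   otherwise).
#' @param schedule a [sampler_schedule()].
#' @param seed integer seed; chain c uses `seed + c - 1`. Runs with the
#'   same seed are identical.
#' @return An object of class `modern_posterior`: list with `draws` (data
#'   frame, one row per retained draw: chain, beta1-3, omega, one eta per
#'   herd), `schedule`, `herd_ids`, `schema`, `fitted_rates` (posterior-mean
#'   mu/PS per training cell) and `accept_omega`.
#' @export
fit_modern <- function(table, schedule = sampler_schedule(), seed = NULL) {
  stopifnot(inherits(table, "modern_herd_table"),
            inherits(schedule, "sampler_schedule"))
  df <- table$data
  labs <- table$schema$classes$label
  tj <- table$schema$midpoints[match(df$age_class, labs)]
  h <- match(df$herd_id, table$herd_ids)
  n_herd <- length(table$herd_ids)
  if (n_herd < 2L)
    warning("only one herd: the random-effect scale omega is not identifiable")
  y <- df$survivors
  sex <- df$sex
  sexT <- sex * tj
  logPS <- log(df$population)
  if (any(!is.finite(logPS))) stop("non-finite offset: population size must be positive")
  rows_by_herd <- split(seq_len(nrow(df)), h)

  # deterministic initial values from a fixed-effect Poisson GLM
  init <- c(0, 0, 0, 0)
  fit0 <- tryCatch(suppressWarnings(
    stats::glm(y ~ tj + sex + sexT, offset = logPS, family = stats::poisson())),
    error = function(e) NULL)
  if (!is.null(fit0) && all(is.finite(stats::coef(fit0))))
    init <- stats::coef(fit0)

  n_keep <- (schedule$iters - schedule$burnin) %/% schedule$thin
  draws <- vector("list", schedule$chains)
  acc_om <- 0; try_om <- 0

  for (ch in seq_len(schedule$chains)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + ch - 1L)
    beta <- c(init[2L], init[3L], init[4L])
    eta <- rep(init[1L], n_herd)
    omega <- max(0.2, stats::sd(eta) %||% 0.2)
    out <- matrix(NA_real_, n_keep, 4L + n_herd)
    k <- 0L
    for (it in seq_len(schedule$iters)) {
      ## beta1 | rest
      fixed <- eta[h] + logPS + beta[2L] * sex + beta[3L] * sexT
      beta[1L] <- slice1(beta[1L], function(b) {
        lp <- fixed + b * tj
        sum(y * lp - exp(lp)) + stats::dnorm(b, 0, 100, log = TRUE)
      }, w = 0.02)
      ## beta2 | rest
      fixed <- eta[h] + logPS + beta[1L] * tj + beta[3L] * sexT
      beta[2L] <- slice1(beta[2L], function(b) {
        lp <- fixed + b * sex
        sum(y * lp - exp(lp)) + stats::dnorm(b, 0, 100, log = TRUE)
      }, w = 0.2)
      ## beta3 | rest
      fixed <- eta[h] + logPS + beta[1L] * tj + beta[2L] * sex
      beta[3L] <- slice1(beta[3L], function(b) {
        lp <- fixed + b * sexT
        sum(y * lp - exp(lp)) + stats::dnorm(b, 0, 100, log = TRUE)
      }, w = 0.02)
      ## herd random effects
      xb <- logPS + beta[1L] * tj + beta[2L] * sex + beta[3L] * sexT
      for (i in seq_len(n_herd)) {
        idx <- rows_by_herd[[i]]
        yi <- y[idx]; xbi <- xb[idx]
        eta[i] <- slice1(eta[i], function(e) {
          lp <- e + xbi
          sum(yi * lp - exp(lp)) + stats::dnorm(e, 0, omega, log = TRUE)
        }, w = 0.3)
      }
      ## omega | eta: Metropolis on log scale, U(0,100) prior
      lw <- log(omega)
      lw_new <- lw + stats::rnorm(1, 0, 0.4)
      try_om <- try_om + 1
      if (exp(lw_new) < 100) {
        lr <- sum(stats::dnorm(eta, 0, exp(lw_new), log = TRUE)) + lw_new -
          (sum(stats::dnorm(eta, 0, omega, log = TRUE)) + lw)
        if (log(stats::runif(1)) < lr) {
          omega <- exp(lw_new)
          acc_om <- acc_om + 1
        }
      }
      if (it > schedule$burnin && (it - schedule$burnin) %% schedule$thin == 0L) {
        k <- k + 1L
        out[k, ] <- c(beta, omega, eta)
      }
    }
    draws[[ch]] <- cbind(chain = ch, out)
  }
  all <- as.data.frame(do.call(rbind, draws))
  names(all) <- c("chain", "beta1", "beta2", "beta3", "omega",
                  paste0("eta_", seq_len(n_herd)))
  pm <- colMeans(all)
  lp_hat <- pm[paste0("eta_", seq_len(n_herd))][h] + logPS + pm["beta1"] * tj +
    pm["beta2"] * sex + pm["beta3"] * sexT
  res <- list(draws = all, schedule = schedule, herd_ids = table$herd_ids,
              schema = table$schema,
              fitted_rates = as.numeric(exp(lp_hat - logPS)),
              accept_omega = acc_om / max(try_om, 1))
  class(res) <- "modern_posterior"
  res
}

#' @export
print.modern_posterior <- function(x, ...) {
  cat("Modern sex-ratio posterior:", nrow(x$draws), "draws,",
      length(x$herd_ids), "herds\n")
  print(round(vapply(x$draws[c("beta1", "beta2", "beta3", "omega")],
                     mean, numeric(1)), 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
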