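# Shared fixtures, memoised so expensive MCMC fits run once per test session.
# Study conditions: the modern census fixture follows the survivor-count
# model with beta = (-0.02, -0.3, -0.01), omega = 0.2, 15 herds, 500 head
# per cell, over a triennial 4-class census schema. The broad bins keep
# survival rates below 1 at the first midpoint so the population-size cap
# essentially never truncates the Poisson counts; with finer bins the cap
# distorts the likelihood and calibration checks become meaningless. The
# ancient fixture is an n = 200 multinomial profile over the nine-class
# cattle schema from an adult-heavy death-probability vector.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, make) {
  if (is.null(.fx[[name]])) .fx[[name]] <- make()
  .fx[[name]]
}

fx_beta_true <- c(-0.02, -0.3, -0.01)
fx_omega_true <- 0.2
fx_theta_true <- c(0.02, 0.04, 0.06, 0.10, 0.08, 0.10, 0.30, 0.20, 0.10)

fx_census_schema <- function() fx_memo("census_schema", function() {
  age_class_schema(lower = seq(0, 108, 36), upper = seq(36, 144, 36))
})

fx_modern_table <- function() fx_memo("modern_table", function() {
  suppressWarnings(generate_modern_synthetic(fx_beta_true, fx_omega_true, 15,
                                             fx_census_schema(), 500, seed = 1))
})

fx_modern_fit <- function() fx_memo("modern_fit", function() {
  fit_modern(fx_modern_table(), sampler_schedule(2000, 400, 4, 2), seed = 1)
})

fx_profile200 <- function() fx_memo("profile200", function() {
  generate_killoff_synthetic(fx_theta_true, 200, legge_schema(), seed = 5)
})

fx_ancient_fit <- function() fx_memo("ancient_fit", function() {
  fit_ancient(fx_profile200(), fx_modern_fit(),
              sampler_schedule(11000, 1000, 10, 1), seed = 3)
})

# brute-force shortest-window HPD, used as the independent oracle
brute_hpd <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1L], x[n]))
  best_w <- Inf; best <- c(NA, NA)
  for (i in 1:(n - k + 1)) {
    w <- x[i + k - 1] - x[i]
    if (w < best_w - 1e-15) {
      best_w <- w
      best <- c(x[i], x[i + k - 1])
    }
  }
  best
}

# enumerate all compositions of n_total into k non-negative parts
compositions <- function(n_total, k) {
  if (k == 1L) return(matrix(n_total, 1L))
  out <- NULL
  for (i in 0:n_total) {
    sub <- compositions(n_total - i, k - 1L)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

# minimal ancient-posterior shell for functions that only need draw matrices
fake_ancient <- function(fmat, mmat = fmat, schema = legge_schema()) {
  Tstar <- n_classes(schema)
  R <- nrow(fmat)
  structure(list(gamma = matrix(1, R, Tstar), beta = matrix(0, R, 2L),
                 chain = rep(1L, R), theta = list(s = matrix(1 / Tstar, R, Tstar)),
                 f = list(s = fmat), m = list(s = mmat),
                 mek = list(s = matrix(0, R, Tstar)), sites = "s",
                 schema = schema, schedule = sampler_schedule(40, 20, 1, 1),
                 control = ancient_control()),
            class = "ancient_posterior")
}
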