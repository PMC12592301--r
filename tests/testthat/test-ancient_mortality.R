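test_that("Dirichlet-multinomial pmf matches closed forms and normalises", {
  expect_equal(dm_log_pmf(c(1, 0), c(1, 1)), log(1 / 2))
  expect_equal(dm_log_pmf(c(0, 0, 0), c(0.5, 1, 2)), 0)
  expect_error(dm_log_pmf(c(1, 0), c(1, 0)), "> 0")
  expect_error(dm_log_pmf(c(1.5, 0), c(1, 1)), "integers")
  # brute-force enumeration oracle: pmf sums to 1 over all compositions
  gam <- c(0.5, 1, 2)
  comps <- compositions(4L, 3L)
  expect_equal(sum(apply(comps, 1, function(n) exp(dm_log_pmf(n, gam)))), 1)
  # beta-binomial special case: n=2 draws, uniform gamma
  expect_equal(exp(dm_log_pmf(c(2, 0), c(1, 1))), 1 / 3)
})

test_that("variance inflation factor is (n+ + g+)/(1 + g+)", {
  expect_equal(dm_variance_inflation(10, 5), 2.5)
  expect_equal(dm_variance_inflation(1, 3.7), 1)
  expect_lt(abs(dm_variance_inflation(50, 1e9) - 1), 1e-6)
  grid <- expand.grid(n = c(0, 1, 5, 20, 100), g = c(0.1, 1, 7, 50))
  expect_equal(dm_variance_inflation(grid$n, grid$g),
               (grid$n + grid$g) / (1 + grid$g))
})

test_that("survival partition follows the sex-ratio identities", {
  out <- survival_from_theta(c(0.5, 0.5), 1)
  expect_equal(out$f, 0.25)
  expect_equal(out$m, 0.25)
  expect_false(any(out$clipped))

  # central values that break monotonicity are clipped and flagged
  out2 <- survival_from_theta(c(0.2, 0.3, 0.5), c(3, 1))
  expect_equal(out2$S, c(0.8, 0.5))
  expect_equal(out2$f, c(0.2, 0.2))  # unclipped centre would be 0.25
  expect_equal(out2$m, c(0.6, 0.3))
  expect_true(out2$clipped[2L])
  expect_true(all(diff(c(0.5, out2$f)) <= 0))

  out3 <- survival_from_theta(c(1, 0, 0), c(1, 1))
  expect_equal(out3$f, c(0, 0))
  expect_equal(out3$m, c(0, 0))
  expect_error(survival_from_theta(c(0.5, 0.5), Inf), "finite")
})

test_that("male excess kill telescopes to total mortality", {
  # f drops 0.5 -> 0.4, m drops 0.5 -> 0.2 across one class
  mek <- male_excess_kill(f = c(0.4, 0), m = c(0.2, 0))
  expect_equal(mek[2L], (0.2 - 0) - (0.4 - 0))
  expect_equal(male_excess_kill(f = c(0.4), m = c(0.4))[1L], 0)
  expect_equal(mek[1L], (0.5 - 0.2) - (0.5 - 0.4))
  # total female + male drops sum to 1 regardless of the curves
  f <- c(0.45, 0.3, 0.12); m <- c(0.31, 0.1, 0.02)
  drops <- -diff(c(0.5, f, 0)) - diff(c(0.5, m, 0))
  expect_equal(sum(drops), 1)
})

test_that("imputation samples candidate classes proportionally to theta", {
  sch <- age_class_schema(c(0, 6, 12), c(6, 12, 24))
  pr <- killoff_profile("a", c(1, 0, 0), sch, ambiguous = list(c(2L, 3L)))
  theta <- c(0.6, 0.3, 0.1)
  set.seed(1)
  picks <- replicate(4000, impute_assignments(pr, theta)$assignment)
  expect_lt(abs(mean(picks == 2L) - 0.75), 0.03)
  # counts include the imputed individual
  one <- impute_assignments(pr, theta)
  expect_equal(sum(one$counts), 2)
  # zero theta on the whole candidate set falls back to uniform
  set.seed(2)
  picks0 <- replicate(2000, impute_assignments(pr, c(1, 0, 0))$assignment)
  expect_lt(abs(mean(picks0 == 2L) - 0.5), 0.05)
  # no ambiguity: counts unchanged
  pr0 <- killoff_profile("a", c(1, 2, 3), sch)
  expect_equal(impute_assignments(pr0, theta)$counts, c(1, 2, 3))
})

test_that("ancient fit is reproducible and validates inputs", {
  sched <- sampler_schedule(600, 200, 4, 1)
  f1 <- fit_ancient(fx_profile200(), fx_modern_fit(), sched, seed = 9)
  f2 <- fit_ancient(fx_profile200(), fx_modern_fit(), sched, seed = 9)
  expect_identical(f1$f, f2$f)
  expect_identical(f1$gamma, f2$gamma)
  f3 <- fit_ancient(fx_profile200(), fx_modern_fit(), sched, seed = 10)
  expect_false(identical(f1$f, f3$f))

  expect_error(fit_ancient(list(), fx_modern_fit(), sched), "no profiles")
  other <- killoff_profile("b", c(1, 1), age_class_schema(c(0, 6), c(6, 12)))
  expect_error(fit_ancient(list(fx_profile200(), other), fx_modern_fit(),
                           sched), "share one")
})

test_that("ancient fit recovers theta and tightens with sample size", {
  post <- fx_ancient_fit()
  th <- post$theta[[1L]]
  pm <- colMeans(th)
  psd <- apply(th, 2, stats::sd)
  expect_true(all(abs(pm - fx_theta_true) <= 3 * psd))

  # an n = 10 profile gives wider credible intervals than n = 200
  prof10 <- generate_killoff_synthetic(fx_theta_true, 10, legge_schema(),
                                       seed = 6)
  post10 <- fit_ancient(prof10, fx_modern_fit(),
                        sampler_schedule(4000, 1000, 3, 1), seed = 4)
  w200 <- mean(apply(th, 2, function(v) diff(hpd_interval(v, 0.9))))
  w10 <- mean(apply(post10$theta[[1L]], 2, function(v)
    diff(hpd_interval(v, 0.9))))
  expect_gt(w10, w200)
})

test_that("every retained draw satisfies the state invariants", {
  post <- fx_ancient_fit()
  th <- post$theta[[1L]]; f <- post$f[[1L]]; m <- post$m[[1L]]
  expect_true(all(abs(rowSums(th) - 1) < 1e-9))
  expect_true(all(th >= 0))
  expect_true(all(f >= 0) && all(m >= 0))
  expect_true(all(f[, 1L] <= 0.5 + 1e-12) && all(m[, 1L] <= 0.5 + 1e-12))
  expect_true(all(t(apply(cbind(0.5, f), 1, diff)) <= 1e-12))
  expect_true(all(t(apply(cbind(0.5, m), 1, diff)) <= 1e-12))
  expect_true(all(f + m <= 1 + 1e-12))
  # per-class female+male drops reproduce theta exactly (accounting identity)
  drops <- -t(apply(cbind(0.5, f, 0), 1, diff)) - t(apply(cbind(0.5, m, 0), 1, diff))
  expect_lt(max(abs(drops - th)), 1e-9)
  # male excess kill consistent with the curves
  expect_true(all(abs(post$mek[[1L]]) <= 1 + 1e-12))
})

test_that("m/f concentrates on r(t) as the link variance vanishes", {
  # the ratio identity holds where the truncation is interior: moderate
  # mortality in every class keeps the central female share strictly
  # inside (0, f_{j-1}) so the bounds never bind
  prof <- generate_killoff_synthetic(c(0.15, 0.10, 0.10, 0.10, 0.08, 0.08,
                                       0.15, 0.12, 0.12), 200,
                                     legge_schema(), seed = 21)
  post <- fit_ancient(prof, fx_modern_fit(),
                      sampler_schedule(2000, 500, 3, 1),
                      control = ancient_control(f_link_sd = 1e-3), seed = 8)
  f <- post$f[[1L]]; m <- post$m[[1L]]
  tstar <- class_midpoints(legge_schema())[1:8]
  dev <- numeric(0)
  for (i in seq_len(nrow(f))) {
    r <- exp(post$beta[i, 1L] + post$beta[i, 2L] * tstar)
    dev <- c(dev, abs(m[i, ] / f[i, ] - r))
  }
  expect_lt(unname(stats::quantile(dev, 0.99)), 0.05)
})

test_that("prior-only run returns Dirichlet(gamma) theta margins", {
  sch <- legge_schema()
  empty <- killoff_profile("prior", rep(0L, 9), sch, .allow_empty = TRUE)
  gam <- c(4, 2, 1, 1, 2, 3, 6, 4, 2)
  post <- fit_ancient(empty, fx_modern_fit(),
                      sampler_schedule(6000, 1000, 5, 1),
                      control = ancient_control(gamma_fix = gam), seed = 12)
  th <- post$theta[[1L]]
  expect_equal(unname(colMeans(th)), gam / sum(gam), tolerance = 0.04)
  # Dirichlet variances, Monte-Carlo tolerance
  a0 <- sum(gam)
  v_exp <- gam * (a0 - gam) / (a0^2 * (a0 + 1))
  expect_equal(unname(apply(th, 2, stats::var)), v_exp, tolerance = 0.25)
})

test_that("ambiguous individuals are imputed inside the fit", {
  prof <- generate_killoff_synthetic(fx_theta_true, 120, legge_schema(),
                                     ambiguity_rate = 0.2, seed = 13)
  expect_gt(length(prof$ambiguous), 0)
  post <- fit_ancient(prof, fx_modern_fit(), sampler_schedule(800, 200, 3, 1),
                      seed = 14)
  expect_equal(nrow(post$theta[[1L]]), 200L)
  expect_true(all(abs(rowSums(post$theta[[1L]]) - 1) < 1e-9))
})

test_that("posterior summary table covers every parameter block", {
  s <- summarize_ancient(fx_ancient_fit(), mass = 0.9)
  expect_setequal(unique(s$param), c("gamma", "theta", "f", "m",
                                     "male_excess_kill"))
  expect_true(all(s$hpd_low <= s$median + 1e-9 & s$median <= s$hpd_high + 1e-9))
})
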