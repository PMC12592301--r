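test_that("growth curve evaluates the stated form", {
  expect_equal(growth_weight(list(tau = 20, a = 0.1, b = 0.1), 0), 20)
  expect_equal(growth_weight(list(tau = 20, a = 0.1, b = 0.1), 12),
               20 * exp(1 - exp(-1.2)))
  # asymptote tau * exp(a/b)
  expect_equal(growth_weight(list(tau = 20, a = 0.1, b = 0.1), 1e6),
               20 * exp(1), tolerance = 1e-9)
  w <- growth_weight(default_growth_params(), 0:144)
  expect_true(all(diff(w) > 0))
  expect_error(growth_weight(default_growth_params(), -1), "non-negative")
})

test_that("growth fit recovers noiseless parameters and flags boundaries", {
  ages <- seq(0, 120, 6)
  truth <- list(tau = 22, a = 0.15, b = 0.08)
  w <- data.frame(age = ages, kg = growth_weight(truth, ages))
  fit <- fit_growth_curve(w)
  expect_lt(abs(fit$tau - truth$tau), 1e-3)
  expect_lt(abs(fit$a - truth$a), 1e-3)
  expect_lt(abs(fit$b - truth$b), 1e-3)
  expect_false(fit$at_boundary)

  # data generated beyond the tau box pin the fit at the constraint
  w50 <- data.frame(age = ages, kg = growth_weight(list(tau = 50, a = 0.15,
                                                        b = 0.08), ages))
  fit50 <- fit_growth_curve(w50)
  expect_equal(fit50$tau, 30)
  expect_true(fit50$at_boundary)

  # noise cannot reduce the residual sum of squares below noiseless
  set.seed(105)
  wn <- w; wn$kg <- wn$kg + stats::rnorm(nrow(w))
  expect_gte(fit_growth_curve(wn)$sse, fit$sse)

  expect_error(fit_growth_curve(data.frame(age = c(1, 1, 1), kg = 1:3)),
               "span")
  expect_error(fit_growth_curve(data.frame(age = c(0, 24), kg = c(20, 80))),
               "3 weight points")
})

test_that("derived constants reproduce the steady-state rates", {
  d <- derive_constants(productivity_constants())
  expect_equal(round(d$birth_prob, 4), 0.0545)
  expect_equal(round(d$milk_available, 2), 6.68)
  expect_equal(round(100 * d$feed_monthly_fraction, 2), 75.33)
  expect_equal(d$milk_per_cow_month, 42.3 * 9.18 / 18.36)
})

test_that("monthly survival interpolates class-boundary knots", {
  sch <- age_class_schema(c(0, 10), c(10, 20))
  s <- monthly_survival(f = 0, m = 0, sch)
  expect_equal(s$s_f[s$age == 5], 0.25)   # halfway from 1/2 to 0
  expect_equal(s$s_f[1L], 0.5)
  expect_equal(s$s_m[1L], 0.5)
  expect_equal(s$s_f[s$age == 20], 0)
  expect_true(all(diff(s$s_f) <= 0) && all(diff(s$s_m) <= 0))

  # survival constant through all classes except the forced terminal fall
  sch3 <- age_class_schema(c(0, 10, 20), c(10, 20, 40))
  s3 <- monthly_survival(f = c(0.5, 0.5), m = c(0.3, 0.3), sch3)
  expect_true(all(s3$s_f[s3$age <= 20] == 0.5))
  expect_true(all(diff(s3$s_f[s3$age >= 20]) < 0))
})

test_that("lifetime yields match direct-summation oracles", {
  cst <- productivity_constants()
  d <- derive_constants(cst)
  g <- default_growth_params()
  sch <- age_class_schema(c(0, 60), c(60, 120))
  s <- monthly_survival(f = 0.5, m = 0.5, sch)
  y <- lifetime_yields(s, g, cst)

  # independent oracle: explicit monthly loops
  sf <- stats::approx(c(0, 60, 120), c(0.5, 0.5, 0), xout = 0:120)$y
  milk_o <- 0; growth_o <- 0
  for (x in 42:119) {
    milk_o <- milk_o + sf[x + 1] * d$milk_available
    growth_o <- growth_o + sf[x + 1] * d$birth_prob
  }
  mow_o <- 0; feed_o <- 0
  nu <- growth_weight(g, 0:120)
  for (x in 0:119) {
    dd <- 2 * (sf[x + 1] - sf[x + 2])  # both sexes symmetric here
    mow_o <- mow_o + dd * nu[x + 2] * cst$mow_fraction_of_liveweight
    feed_o <- feed_o + 2 * sf[x + 1] * nu[x + 1] * d$feed_monthly_fraction
  }
  expect_equal(y$milk_kg, milk_o)
  expect_equal(y$herd_growth, growth_o)
  expect_equal(y$mow_kg, mow_o)
  expect_equal(y$feed_kg, feed_o)
  expect_equal(y$total_kcal, y$milk_kcal + y$mow_kcal)
  expect_equal(y$protein_kg,
               y$milk_kg * cst$milk_protein + y$mow_kg * cst$mow_protein)
  expect_equal(y$fat_kg, y$milk_kg * cst$milk_fat + y$mow_kg * cst$mow_fat)
  expect_equal(y$efficiency, y$total_kcal / y$feed_kg)

  # flat female survival until a 120-month cap: 78 milking months at 1/2
  schf <- age_class_schema(c(0, 119), c(119, 120))
  yf <- lifetime_yields(monthly_survival(0.5, 0.5, schf), g, cst)
  expect_equal(yf$milk_kg, 0.5 * d$milk_available * 78)
  expect_equal(yf$herd_growth, 0.5 * d$birth_prob * 78)
})

test_that("deaths in the first month wipe out milk and births", {
  sch <- age_class_schema(c(0, 1), c(1, 144))
  s <- monthly_survival(f = 0, m = 0, sch)
  y <- lifetime_yields(s, default_growth_params())
  expect_equal(y$milk_kg, 0)
  expect_equal(y$herd_growth, 0)
  expect_gt(y$mow_kg, 0)
})

test_that("yields scale linearly in the per-kg density constants", {
  sch <- legge_schema()
  f <- c(0.48, 0.45, 0.4, 0.35, 0.33, 0.3, 0.2, 0.1)
  m <- c(0.45, 0.35, 0.25, 0.15, 0.1, 0.08, 0.04, 0.01)
  s <- monthly_survival(f, m, sch)
  g <- default_growth_params()
  base <- lifetime_yields(s, g, productivity_constants())
  dbl <- lifetime_yields(s, g, productivity_constants(milk_kcal = 2 * 670))
  expect_equal(dbl$milk_kcal, 2 * base$milk_kcal)
  expect_equal(dbl$mow_kcal, base$mow_kcal)
  half <- lifetime_yields(s, g, productivity_constants(mow_kcal = 990))
  expect_equal(half$mow_kcal, base$mow_kcal / 2)
  expect_equal(half$milk_kg, base$milk_kg)

  # MOW is bounded by the asymptotic carcass: total deaths sum to 1
  cst <- productivity_constants()
  expect_lte(base$mow_kg,
             cst$mow_fraction_of_liveweight * g$tau * exp(g$a / g$b))
})

test_that("herd growth is monotone in female survival", {
  sch <- legge_schema()
  g <- default_growth_params()
  lo <- c(0.4, 0.3, 0.25, 0.2, 0.18, 0.15, 0.1, 0.05)
  hi <- lo + 0.08
  m <- c(0.4, 0.3, 0.2, 0.1, 0.08, 0.05, 0.02, 0.01)
  y_lo <- lifetime_yields(monthly_survival(lo, m, sch), g)
  y_hi <- lifetime_yields(monthly_survival(hi, m, sch), g)
  expect_gt(y_hi$herd_growth, y_lo$herd_growth)
  expect_gt(y_hi$milk_kg, y_lo$milk_kg)
})

test_that("posterior yields are per-draw and summarise correctly", {
  f <- c(0.48, 0.45, 0.4, 0.35, 0.33, 0.3, 0.2, 0.1)
  m <- c(0.45, 0.35, 0.25, 0.15, 0.1, 0.08, 0.04, 0.01)
  post <- fake_ancient(matrix(f, 30, 8, byrow = TRUE),
                       matrix(m, 30, 8, byrow = TRUE))
  g <- default_growth_params()
  y <- yields_over_posterior(post, g)
  expect_equal(nrow(y), 30L)
  # degenerate posterior: zero-width credible intervals
  sm <- summarize_yields(y)
  expect_true(all(sm$hpd_high - sm$hpd_low < 1e-12))
  # doubling the milk energy density doubles milk kcal for every draw
  y2 <- yields_over_posterior(post, g, productivity_constants(milk_kcal = 1340))
  expect_equal(y2$milk_kcal, 2 * y$milk_kcal)
  # matches the single-curve computation
  one <- lifetime_yields(monthly_survival(f, m, legge_schema()), g)
  expect_equal(y$efficiency[1L], one$efficiency)

  # efficiency ranking of two profiles matches the hand-computed oracle
  f2 <- c(0.45, 0.3, 0.2, 0.12, 0.1, 0.08, 0.04, 0.01)
  two <- lifetime_yields(monthly_survival(f2, f2, legge_schema()), g)
  expect_equal(one$efficiency > two$efficiency,
               (one$total_kcal / one$feed_kg) > (two$total_kcal / two$feed_kg))
})

test_that("joint posterior mode finds the density peak", {
  set.seed(106)
  x <- c(stats::rnorm(2000, 0, 0.2), stats::rnorm(200, 4, 0.2))
  y <- c(stats::rnorm(2000, 1, 0.2), stats::rnorm(200, 5, 0.2))
  jm <- joint_posterior_mode(x, y)
  expect_lt(abs(jm[1L] - 0), 0.4)
  expect_lt(abs(jm[2L] - 1), 0.4)
  expect_equal(joint_posterior_mode(rep(2, 30), rep(3, 30)), c(2, 3))
})
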