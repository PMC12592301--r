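#' Monthly survival curves from per-class survival proportions
#'
#' Survival attaches to the upper boundary of each age class: the knots
#' `(0, 1/2)`, `(upper_j, f_j)` for j = 1..T*-1 and `(terminal_cap, 0)` are
#' linearly interpolated at integer months. Non-increasing inputs give
#' non-increasing curves by construction.
#'
#' @param f,m female and male survival proportions, length T*-1.
#' @param schema an [age_class_schema()].
#' @param male_birth_share proportion of males at birth.
#' @return An object of class `monthly_survival`: list with `age`
#'   (0..terminal_cap months), `s_f`, `s_m`.
#' @export
monthly_survival <- function(f, m, schema, male_birth_share = 0.5) {
  stopifnot(inherits(schema, "age_class_schema"))
  p <- n_classes(schema) - 1L
  if (length(f) != p || length(m) != p)
    stop("'f' and 'm' must have length T*-1 = ", p)
  cap <- schema$terminal_cap
  knots <- c(0, schema$classes$upper[seq_len(p)], cap)
  age <- 0:cap
  s_f <- stats::approx(knots, c(1 - male_birth_share, f, 0), xout = age)$y
  s_m <- stats::approx(knots, c(male_birth_share, m, 0), xout = age)$y
  structure(list(age = age, s_f = s_f, s_m = s_m),
            class = "monthly_survival")
}

# core lifetime-yield sums given monthly survival vectors (age 0..cap),
# precomputed weights nu (same grid) and derived constants
yields_core <- function(s_f, s_m, nu, der, constants) {
  cap <- length(s_f) - 1L
  x <- 0:(cap - 1L)                       # month spanning age x -> x+1
  d_f <- s_f[x + 1L] - s_f[x + 2L]        # deaths during month x
  d_m <- s_m[x + 1L] - s_m[x + 2L]
  afc <- ceiling(constants$age_first_calving)
  milk_idx <- if (afc < cap) (afc:(cap - 1L)) + 1L else integer()  # alive at months afc..cap-1
  milk_kg <- sum(s_f[milk_idx]) * der$milk_available
  herd_growth <- sum(s_f[milk_idx]) * der$birth_prob
  mow_kg <- sum((d_f + d_m) * nu[x + 2L]) * constants$mow_fraction_of_liveweight
  feed_kg <- sum((s_f[x + 1L] + s_m[x + 1L]) * nu[x + 1L]) *
    der$feed_monthly_fraction
  milk_kcal <- milk_kg * constants$milk_kcal
  mow_kcal <- mow_kg * constants$mow_kcal
  total_kcal <- milk_kcal + mow_kcal
  c(milk_kg = milk_kg,
    milk_kcal = milk_kcal,
    mow_kg = mow_kg,
    mow_kcal = mow_kcal,
    protein_kg = milk_kg * constants$milk_protein + mow_kg * constants$mow_protein,
    fat_kg = milk_kg * constants$milk_fat + mow_kg * constants$mow_fat,
    total_kcal = total_kcal,
    feed_kg = feed_kg,
    herd_growth = herd_growth,
    efficiency = if (feed_kg > 0) total_kcal / feed_kg else NA_real_,
    milk_efficiency = if (feed_kg > 0) milk_kcal / feed_kg else NA_real_,
    mow_efficiency = if (feed_kg > 0) mow_kcal / feed_kg else NA_real_)
}

#' Lifetime yields per animal from a survival curve
#'
#' Sums monthly contributions over a lifetime, weighted by the probability
#' of being alive (or dying) each month: milk available for humans accrues
#' for every female month past the age at first calving; births accrue at
#' the monthly birth probability over the same months; meat-and-offal
#' weight is the slaughter-month live weight times the MOW fraction,
#' weighted by the monthly survival decrement of both sexes; the feed-cost
#' proxy is live weight times the monthly feed fraction over all
#' animal-months alive. Efficiency is total kcal per kg feed and is a
#' relative measure only. When all animals are dead at birth the feed cost
#' is zero and efficiency is flagged `NA`.
#'
#' @param s a [monthly_survival()].
#' @param growth growth-curve parameters (list with `tau`, `a`, `b`).
#' @param constants a [productivity_constants()].
#' @return one-row data frame of class `yield_summary`: milk_kg, milk_kcal,
#'   mow_kg, mow_kcal, protein_kg, fat_kg, total_kcal, feed_kg,
#'   herd_growth, efficiency, milk_efficiency, mow_efficiency.
#' @export
lifetime_yields <- function(s, growth, constants = productivity_constants()) {
  stopifnot(inherits(s, "monthly_survival"),
            inherits(constants, "productivity_constants"))
  der <- derive_constants(constants)
  nu <- growth_weight(growth, s$age)
  out <- as.data.frame(as.list(yields_core(s$s_f, s$s_m, nu, der, constants)))
  class(out) <- c("yield_summary", "data.frame")
  out
}

#' Lifetime yields for every posterior draw
#'
#' Applies [lifetime_yields()] to the survival curve of each retained draw
#' of an ancient fit, giving the posterior distribution of all yield
#' outputs.
#'
#' @param post an `ancient_posterior` from [fit_ancient()].
#' @param growth growth-curve parameters.
#' @param constants a [productivity_constants()].
#' @param site site id or index (default first site).
#' @return data frame, one row per retained draw, columns as in
#'   [lifetime_yields()].
#' @export
yields_over_posterior <- function(post, growth,
                                  constants = productivity_constants(),
                                  site = 1L) {
  stopifnot(inherits(post, "ancient_posterior"))
  fmat <- post$f[[site]]; mmat <- post$m[[site]]
  if (!nrow(fmat)) stop("posterior is empty")
  schema <- post$schema
  p <- ncol(fmat)
  cap <- schema$terminal_cap
  knots <- c(0, schema$classes$upper[seq_len(p)], cap)
  age <- 0:cap
  der <- derive_constants(constants)
  nu <- growth_weight(growth, age)
  mbs <- post$control$male_birth_share
  out <- matrix(NA_real_, nrow(fmat), 12L)
  for (i in seq_len(nrow(fmat))) {
    s_f <- stats::approx(knots, c(1 - mbs, fmat[i, ], 0), xout = age)$y
    s_m <- stats::approx(knots, c(mbs, mmat[i, ], 0), xout = age)$y
    out[i, ] <- yields_core(s_f, s_m, nu, der, constants)
  }
  out <- as.data.frame(out)
  names(out) <- c("milk_kg", "milk_kcal", "mow_kg", "mow_kcal", "protein_kg",
                  "fat_kg", "total_kcal", "feed_kg", "herd_growth",
                  "efficiency", "milk_efficiency", "mow_efficiency")
  out
}

#' Joint posterior mode of two outputs
#'
#' Peak of a 2-d kernel density estimate (MASS::kde2d) over paired draws;
#' degenerate (zero-variance) inputs return the point itself.
#'
#' @param x,y paired posterior draws.
#' @param n kernel grid resolution per axis.
#' @return length-2 numeric vector (mode of x, mode of y).
#' @export
joint_posterior_mode <- function(x, y, n = 50L) {
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(c(stats::median(x), stats::median(y)))
  kd <- MASS::kde2d(x, y, n = n)
  i <- which(kd$z == max(kd$z), arr.ind = TRUE)[1L, ]
  c(kd$x[i[1L]], kd$y[i[2L]])
}

#' Posterior summaries of yield outputs
#'
#' Mean, median and HPD interval per output column, plus joint posterior
#' modes for the paired outputs of interest (herd growth vs efficiency,
#' MOW vs milk efficiency).
#'
#' @param yields data frame from [yields_over_posterior()].
#' @param mass HPD mass.
#' @return data frame of summaries; joint modes in attribute
#'   `joint_modes`.
#' @export
summarize_yields <- function(yields, mass = 0.95) {
  cols <- names(yields)
  out <- do.call(rbind, lapply(cols, function(cn) {
    v <- yields[[cn]]
    v <- v[is.finite(v)]
    if (length(v) < 20L) {
      return(data.frame(output = cn, mean = mean(v), median = stats::median(v),
                        hpd_low = NA_real_, hpd_high = NA_real_))
    }
    h <- hpd_interval(v, mass)
    data.frame(output = cn, mean = mean(v), median = stats::median(v),
               hpd_low = h[1L], hpd_high = h[2L])
  }))
  jm <- list()
  ok <- stats::complete.cases(yields[c("herd_growth", "efficiency")])
  if (sum(ok) > 2L)
    jm$growth_vs_efficiency <- joint_posterior_mode(yields$herd_growth[ok],
                                                    yields$efficiency[ok])
  ok <- stats::complete.cases(yields[c("mow_efficiency", "milk_efficiency")])
  if (sum(ok) > 2L)
    jm$mow_vs_milk_efficiency <- joint_posterior_mode(yields$mow_efficiency[ok],
                                                      yields$milk_efficiency[ok])
  attr(out, "joint_modes") <- jm
  out
}
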