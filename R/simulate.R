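#' Synthetic modern herd census table
#'
#' Emulates census data from unimproved herds under the survivor-count
#' model: herd effects `eta_i ~ N(0, omega^2)` and
#' `Y_sij ~ Poisson(PS exp(eta_i + beta1 t_j + beta2 s + beta3 s t_j))`,
#' capped at the population size (the number of capped cells is recorded in
#' attribute `n_capped`, with a warning when positive).
#'
#' @param beta length-3 vector (age slope, male effect, sex-age
#'   interaction).
#' @param omega herd random-effect standard deviation (>= 0).
#' @param n_herds number of herds.
#' @param schema an [age_class_schema()].
#' @param ps population size per cell (scalar or per-class vector).
#' @param seed integer seed.
#' @return a [modern_herd_table()].
#' @export
generate_modern_synthetic <- function(beta, omega, n_herds, schema, ps,
                                      seed = NULL) {
  stopifnot(length(beta) == 3L, omega >= 0, n_herds >= 1L,
            inherits(schema, "age_class_schema"))
  if (any(ps <= 0)) stop("'ps' must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  labs <- schema$classes$label
  tj <- schema$midpoints
  ps <- as.integer(rep_len(ps, length(labs)))
  eta <- stats::rnorm(n_herds, 0, omega)
  rows <- expand.grid(class = seq_along(labs), sex = c(0L, 1L),
                      herd = seq_len(n_herds))
  mu <- ps[rows$class] * exp(eta[rows$herd] + beta[1L] * tj[rows$class] +
                               beta[2L] * rows$sex +
                               beta[3L] * rows$sex * tj[rows$class])
  y <- stats::rpois(nrow(rows), mu)
  capped <- y > ps[rows$class]
  y[capped] <- ps[rows$class][capped]
  if (any(capped))
    warning(sum(capped), " cell(s) capped at the population size")
  df <- data.frame(herd_id = paste0("herd", rows$herd), sex = rows$sex,
                   age_class = labs[rows$class], survivors = y,
                   population = ps[rows$class])
  out <- modern_herd_table(df, schema)
  attr(out, "n_capped") <- sum(capped)
  attr(out, "eta") <- eta
  out
}

#' Synthetic kill-off profile from known death probabilities
#'
#' Draws multinomial death counts from a known theta; optionally blurs a
#' fraction of individuals into two-class candidate sets to emulate
#' fragmentary ageing.
#'
#' @param theta death-probability vector over the schema classes.
#' @param n total individuals.
#' @param schema an [age_class_schema()].
#' @param site_id site label.
#' @param ambiguity_rate probability that an individual is recorded as
#'   ambiguous between its class and an adjacent one.
#' @param seed integer seed.
#' @return a [killoff_profile()]; the generating `theta` is kept in
#'   attribute `truth`.
#' @export
generate_killoff_synthetic <- function(theta, n, schema,
                                       site_id = "synthetic",
                                       ambiguity_rate = 0, seed = NULL) {
  stopifnot(inherits(schema, "age_class_schema"),
            length(theta) == n_classes(schema), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- as.integer(stats::rmultinom(1L, n, theta))
  sets <- list()
  if (ambiguity_rate > 0) {
    Tstar <- length(counts)
    for (j in seq_len(Tstar)) {
      n_amb <- stats::rbinom(1L, counts[j], ambiguity_rate)
      if (n_amb > 0L) {
        counts[j] <- counts[j] - n_amb
        set <- if (j < Tstar) c(j, j + 1L) else c(j - 1L, j)
        sets <- c(sets, rep(list(set), n_amb))
      }
    }
  }
  out <- killoff_profile(site_id, counts, schema, ambiguous = sets)
  attr(out, "truth") <- theta
  out
}

# draw one (theta, f, m, r) truth from the generative model given
# (gamma, beta2, beta3)
draw_truth <- function(gamma, beta2, beta3, schema, f_link_sd = 0.1,
                       male_birth_share = 0.5) {
  p <- n_classes(schema) - 1L
  tstar <- class_midpoints(schema)[seq_len(p)]
  theta <- rdirichlet1(gamma)
  r <- sex_ratio(beta2, beta3, tstar)
  fm <- draw_f(theta, r, f_link_sd, 1 - male_birth_share, male_birth_share)
  list(gamma = gamma, beta2 = beta2, beta3 = beta3, theta = theta,
       r = r, f = fm$f, m = fm$m)
}

#' Simulate the validation suite
#'
#' The simulate-and-refit protocol: posterior-predictive truths are drawn
#' jointly (gamma, beta2, beta3) from a reference ancient fit; for each
#' truth a theta is drawn from Dirichlet(gamma), sex-partitioned survival
#' (f, m) is generated through the truncated-normal link, and one
#' multinomial count vector is drawn per sample size. The default design
#' (50 truths x 7 sizes) gives 350 simulated profiles.
#'
#' @param reference an `ancient_posterior` supplying the joint truth draws.
#' @param n_truths number of posterior-predictive truths.
#' @param sizes total individuals per simulated profile.
#' @param seed integer seed; the suite is exactly reproducible from it.
#' @return list of class `validation_suite`; each element has `truth`
#'   (gamma, beta2, beta3, theta, r, f, m), `counts`, `size`, `truth_id`.
#' @export
simulate_validation_suite <- function(reference, n_truths = 50L,
                                      sizes = c(10L, 20L, 50L, 75L, 100L,
                                                150L, 200L),
                                      seed = NULL) {
  stopifnot(inherits(reference, "ancient_posterior"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  schema <- reference$schema
  ctl <- reference$control
  out <- vector("list", n_truths * length(sizes))
  d <- 0L
  for (i in seq_len(n_truths)) {
    idx <- sample.int(nrow(reference$gamma), 1L)
    truth <- draw_truth(reference$gamma[idx, ], reference$beta[idx, 1L],
                        reference$beta[idx, 2L], schema,
                        f_link_sd = ctl$f_link_sd,
                        male_birth_share = ctl$male_birth_share)
    for (n in sizes) {
      d <- d + 1L
      out[[d]] <- structure(
        list(truth = truth, counts = as.integer(
          stats::rmultinom(1L, n, truth$theta)),
          size = as.integer(n), truth_id = i, schema = schema),
        class = "simulated_dataset")
    }
  }
  structure(out, class = c("validation_suite", "list"))
}

#' HPD coverage of the validation refits
#'
#' For each simulated dataset and nominal level, checks whether the HPD
#' interval of the refitted posterior of each f component contains the true
#' simulated value, and tabulates empirical coverage overall, by sample
#' size and by age class.
#'
#' @param suite a `validation_suite`.
#' @param refits list of `ancient_posterior` objects, one per dataset.
#' @param levels nominal HPD levels in percent.
#' @return list of class `coverage_report` with data frames `overall`
#'   (level, coverage), `by_size` and `by_class`.
#' @export
coverage_report <- function(suite, refits,
                            levels = c(95, 90, 80, 70, 60, 50, 40, 30, 20, 10)) {
  stopifnot(inherits(suite, "validation_suite"))
  if (length(suite) != length(refits))
    stop("one refit per dataset is required (", length(suite), " vs ",
         length(refits), ")")
  p <- length(suite[[1L]]$truth$f)
  rec <- list(); ri <- 0L
  for (d in seq_along(suite)) {
    ds <- suite[[d]]
    fmat <- refits[[d]]$f[[1L]]
    for (lv in levels) {
      for (j in seq_len(p)) {
        h <- hpd_interval(fmat[, j], lv / 100)
        ri <- ri + 1L
        rec[[ri]] <- c(level = lv, size = ds$size, class = j,
                       covered = as.numeric(ds$truth$f[j] >= h[1L] &
                                              ds$truth$f[j] <= h[2L]))
      }
    }
  }
  df <- as.data.frame(do.call(rbind, rec))
  agg <- function(by) {
    a <- stats::aggregate(df$covered, by = c(list(level = df$level), by), mean)
    names(a)[ncol(a)] <- "coverage"
    a[order(a$level), , drop = FALSE]
  }
  structure(list(overall = agg(list()),
                 by_size = agg(list(size = df$size)),
                 by_class = agg(list(class = df$class))),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Empirical HPD coverage of f (overall):\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}

# internal: yields for one (f, m) pair without object overhead
strategy_yields <- function(f, m, knots, age, nu, der, constants, mbs) {
  s_f <- stats::approx(knots, c(1 - mbs, f, 0), xout = age)$y
  s_m <- stats::approx(knots, c(mbs, m, 0), xout = age)$y
  yields_core(s_f, s_m, nu, der, constants)
}

#' Simulate one sex-asymmetric kill-off strategy
#'
#' Draws (f, m, r) from the posterior predictive of a reference ancient fit
#' (as in the validation suite) and converts the survival curves into
#' per-sex kill-off proportions and lifetime yields.
#'
#' @param reference an `ancient_posterior`.
#' @param growth growth-curve parameters.
#' @param constants a [productivity_constants()].
#' @param seed integer seed.
#' @return list of class `strategy_point`: `kill_f`, `kill_m` (per-class
#'   death proportions by sex; together they sum to 1), `f`, `m`, and
#'   `yields` (named vector as in [lifetime_yields()]).
#' @export
simulate_strategy_sex_asymmetric <- function(reference, growth,
                                             constants = productivity_constants(),
                                             seed = NULL) {
  stopifnot(inherits(reference, "ancient_posterior"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  schema <- reference$schema
  ctl <- reference$control
  idx <- sample.int(nrow(reference$gamma), 1L)
  truth <- draw_truth(reference$gamma[idx, ], reference$beta[idx, 1L],
                      reference$beta[idx, 2L], schema, ctl$f_link_sd,
                      ctl$male_birth_share)
  p <- length(truth$f)
  knots <- c(0, schema$classes$upper[seq_len(p)], schema$terminal_cap)
  age <- 0:schema$terminal_cap
  y <- strategy_yields(truth$f, truth$m, knots, age,
                       growth_weight(growth, age),
                       derive_constants(constants), constants,
                       ctl$male_birth_share)
  structure(list(kill_f = -diff(c(1 - ctl$male_birth_share, truth$f, 0)),
                 kill_m = -diff(c(ctl$male_birth_share, truth$m, 0)),
                 f = truth$f, m = truth$m, yields = y,
                 scenario = "sex_asymmetric"),
            class = "strategy_point")
}

#' Simulate one sex-symmetric kill-off strategy
#'
#' Draws class death proportions psi from a flat Dirichlet over the T*
#' classes and kills males and females in equal shares (psi/2 each), so
#' f_j = m_j throughout.
#'
#' @param schema an [age_class_schema()].
#' @param growth growth-curve parameters.
#' @param constants a [productivity_constants()].
#' @param seed integer seed.
#' @return a `strategy_point` as in
#'   [simulate_strategy_sex_asymmetric()].
#' @export
simulate_strategy_sex_symmetric <- function(schema, growth,
                                            constants = productivity_constants(),
                                            seed = NULL) {
  stopifnot(inherits(schema, "age_class_schema"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  Tstar <- n_classes(schema)
  psi <- rdirichlet1(rep(1, Tstar))
  p <- Tstar - 1L
  S <- pmax(1 - cumsum(psi)[seq_len(p)], 0)
  f <- S / 2; m <- S / 2
  knots <- c(0, schema$classes$upper[seq_len(p)], schema$terminal_cap)
  age <- 0:schema$terminal_cap
  y <- strategy_yields(f, m, knots, age, growth_weight(growth, age),
                       derive_constants(constants), constants, 0.5)
  structure(list(kill_f = psi / 2, kill_m = psi / 2, f = f, m = m,
                 yields = y, scenario = "sex_symmetric"),
            class = "strategy_point")
}

#' Pareto-optimal subset for joint maximisation
#'
#' @param x,y objective values (both maximised).
#' @return logical vector: `TRUE` for non-dominated points. Invariant to
#'   the order of the points.
#' @export
pareto_front <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  keep <- logical(n)
  ord <- order(x, y, decreasing = TRUE)
  best_y <- -Inf
  for (i in ord) {
    if (y[i] > best_y) {
      keep[i] <- TRUE
      best_y <- y[i]
    }
  }
  keep
}

#' Random search over kill-off strategies
#'
#' Simulates `n_sims` random kill-off strategies under the sex-asymmetric
#' (posterior-predictive) or sex-symmetric (flat Dirichlet) scenario,
#' optionally keeps only sustainable strategies (herd growth > 1), and
#' marks the Pareto-optimal subset on (efficiency, herd growth).
#'
#' @param n_sims number of random strategies (>= 1). The full protocol uses
#'   20,000.
#' @param scenario `"sex_asymmetric"` or `"sex_symmetric"`.
#' @param reference an `ancient_posterior` (required for the
#'   sex-asymmetric scenario).
#' @param schema an [age_class_schema()] (required for the sex-symmetric
#'   scenario; defaults to the reference's schema).
#' @param growth growth-curve parameters.
#' @param constants a [productivity_constants()].
#' @param condition_growth_gt_1 keep only strategies with herd growth > 1.
#' @param seed integer seed.
#' @return list of class `strategy_search`: `points` (data frame of yield
#'   outputs per retained strategy), `kill_f`, `kill_m` (matrices), and
#'   `pareto` (logical, Pareto-optimal on efficiency and herd growth).
#' @export
search_strategies <- function(n_sims, scenario = c("sex_asymmetric",
                                                   "sex_symmetric"),
                              reference = NULL, schema = NULL,
                              growth = default_growth_params(),
                              constants = productivity_constants(),
                              condition_growth_gt_1 = FALSE, seed = NULL) {
  scenario <- match.arg(scenario)
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) stop("'n_sims' must be at least 1")
  if (scenario == "sex_asymmetric") {
    if (!inherits(reference, "ancient_posterior"))
      stop("the sex-asymmetric scenario needs a reference ancient posterior")
    schema <- reference$schema
    mbs <- reference$control$male_birth_share
    sd_f <- reference$control$f_link_sd
  } else {
    if (is.null(schema) && inherits(reference, "ancient_posterior"))
      schema <- reference$schema
    if (!inherits(schema, "age_class_schema"))
      stop("the sex-symmetric scenario needs a schema")
    mbs <- 0.5
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  Tstar <- n_classes(schema)
  p <- Tstar - 1L
  knots <- c(0, schema$classes$upper[seq_len(p)], schema$terminal_cap)
  age <- 0:schema$terminal_cap
  nu <- growth_weight(growth, age)
  der <- derive_constants(constants)
  tstar <- class_midpoints(schema)[seq_len(p)]

  pts <- matrix(NA_real_, n_sims, 12L)
  kf <- matrix(NA_real_, n_sims, Tstar)
  km <- matrix(NA_real_, n_sims, Tstar)
  for (i in seq_len(n_sims)) {
    if (scenario == "sex_asymmetric") {
      idx <- sample.int(nrow(reference$gamma), 1L)
      theta <- rdirichlet1(reference$gamma[idx, ])
      r <- exp(reference$beta[idx, 1L] + reference$beta[idx, 2L] * tstar)
      fm <- draw_f(theta, r, sd_f, 1 - mbs, mbs)
      f <- fm$f; m <- fm$m
    } else {
      psi <- rdirichlet1(rep(1, Tstar))
      S <- pmax(1 - cumsum(psi)[seq_len(p)], 0)
      f <- S / 2; m <- S / 2
    }
    pts[i, ] <- strategy_yields(f, m, knots, age, nu, der, constants, mbs)
    kf[i, ] <- -diff(c(1 - mbs, f, 0))
    km[i, ] <- -diff(c(mbs, m, 0))
  }
  pts <- as.data.frame(pts)
  names(pts) <- c("milk_kg", "milk_kcal", "mow_kg", "mow_kcal", "protein_kg",
                  "fat_kg", "total_kcal", "feed_kg", "herd_growth",
                  "efficiency", "milk_efficiency", "mow_efficiency")
  keep <- rep(TRUE, n_sims)
  if (condition_growth_gt_1) keep <- pts$herd_growth > 1
  pts <- pts[keep, , drop = FALSE]
  kf <- kf[keep, , drop = FALSE]
  km <- km[keep, , drop = FALSE]
  par <- if (nrow(pts)) pareto_front(pts$efficiency, pts$herd_growth) else logical()
  structure(list(points = pts, kill_f = kf, kill_m = km, pareto = par,
                 scenario = scenario,
                 conditioned = isTRUE(condition_growth_gt_1)),
            class = "strategy_search")
}

#' @export
print.strategy_search <- function(x, ...) {
  cat("Strategy search (", x$scenario, "): ", nrow(x$points), " strategies",
      if (x$conditioned) " with herd growth > 1" else "", ", ",
      sum(x$pareto), " Pareto-optimal\n", sep = "")
  invisible(x)
}
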