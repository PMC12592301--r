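#' Sex-partitioned survival from a death-probability vector
#'
#' Given the death probabilities theta over T* age classes and the sex
#' ratio r_j at the midpoints of classes 1..T*-1, total survival past class
#' j is `S_j = 1 - theta_1 - ... - theta_j`, the central female share is
#' `f_j = S_j / (1 + r_j)` and the male share `m_j = S_j - f_j`. Boundary
#' values are `f_0 = 1 - male_birth_share`, `m_0 = male_birth_share` and
#' `f_T* = m_T* = 0`. Central values that would violate the female
#' monotonicity constraint `f_j <= f_{j-1}` (or exceed total survival) are
#' clipped into `[0, min(f_{j-1}, S_j)]` and flagged; male monotonicity is
#' enforced by the sampler's tightened truncation, not by this
#' deterministic map, so extreme sex ratios can leave `m` locally
#' increasing here.
#'
#' @param theta probability vector over T* classes (sums to 1).
#' @param r positive sex ratios, length T*-1.
#' @param male_birth_share proportion of males at birth (default 1/2).
#' @return list with `f`, `m` (length T*-1), `S` (total survival), and
#'   `clipped` (logical, per class).
#' @export
survival_from_theta <- function(theta, r, male_birth_share = 0.5) {
  p <- length(theta) - 1L
  if (length(r) != p) stop("'r' must have length T*-1")
  if (any(!is.finite(r)) || any(r <= 0)) stop("sex ratios must be finite and > 0")
  if (any(theta < -1e-9) || abs(sum(theta) - 1) > 1e-6)
    stop("'theta' must be a probability vector")
  S <- 1 - cumsum(theta)[seq_len(p)]
  S <- pmax(S, 0)
  f <- numeric(p); m <- numeric(p); clipped <- logical(p)
  f_prev <- 1 - male_birth_share; m_prev <- male_birth_share
  for (j in seq_len(p)) {
    centre <- S[j] / (1 + r[j])
    upper <- min(f_prev, S[j])
    fj <- min(max(centre, 0), upper)
    clipped[j] <- abs(fj - centre) > 1e-12
    f[j] <- fj; m[j] <- S[j] - fj
    f_prev <- f[j]; m_prev <- m[j]
  }
  list(f = f, m = m, S = S, clipped = clipped)
}

#' Male kill in excess of female kill, per age class
#'
#' The proportion of males killed as part of the sex-ratio change process
#' in class j: `(m_{j-1} - m_j) - (f_{j-1} - f_j)`, using the boundary
#' values f_0 = m_0 = birth shares and f_T* = m_T* = 0. Female and male
#' class-wise drops telescope to the total mortality of 1.
#'
#' @param f,m survival proportions, length T*-1.
#' @param male_birth_share proportion of males at birth.
#' @return numeric vector of length T*.
#' @export
male_excess_kill <- function(f, m, male_birth_share = 0.5) {
  fb <- c(1 - male_birth_share, f, 0)
  mb <- c(male_birth_share, m, 0)
  (-diff(mb)) - (-diff(fb))
}

#' Impute ambiguous age-class assignments
#'
#' Each ambiguous individual is assigned one class from its candidate set,
#' sampled with probability proportional to the current theta restricted to
#' the set (uniform fallback when theta vanishes on the whole set).
#'
#' @param profile a [killoff_profile()].
#' @param theta current death-probability vector.
#' @return list with `assignment` (one class index per ambiguous
#'   individual) and `counts` (effective per-class counts including the
#'   imputed individuals).
#' @export
impute_assignments <- function(profile, theta) {
  stopifnot(inherits(profile, "killoff_profile"))
  Tstar <- n_classes(profile$schema)
  if (length(theta) != Tstar) stop("'theta' has wrong length")
  counts <- as.numeric(profile$counts)
  assignment <- integer(length(profile$ambiguous))
  for (i in seq_along(profile$ambiguous)) {
    set <- profile$ambiguous[[i]]
    w <- theta[set]
    if (sum(w) <= 0) w <- rep.int(1, length(set))
    cl <- set[sample.int(length(set), 1L, prob = w)]
    assignment[i] <- cl
    counts[cl] <- counts[cl] + 1
  }
  list(assignment = assignment, counts = counts)
}

#' Control parameters for the ancient-mortality sampler
#'
#' @param f_link_sd standard deviation of the truncated-normal link between
#'   the central female survival `S_j/(1+r_j)` and the sampled `f_j`
#'   (default 0.1, i.e. variance 0.01).
#' @param male_birth_share proportion of males at birth (default 1/2;
#'   empirical estimates range 0.51-0.53).
#' @param gamma_step initial random-walk step (log scale) for the gamma
#'   updates; tuned to 20-40% acceptance during burn-in, then frozen.
#' @param tune adapt `gamma_step` during burn-in.
#' @param gamma_fix optional fixed gamma vector; skips the gamma update
#'   (useful for prior-predictive checks).
#' @return a list of class `ancient_control`.
#' @export
ancient_control <- function(f_link_sd = 0.1, male_birth_share = 0.5,
                            gamma_step = 0.5, tune = TRUE, gamma_fix = NULL) {
  stopifnot(f_link_sd > 0, male_birth_share > 0, male_birth_share < 1,
            gamma_step > 0)
  if (!is.null(gamma_fix) && any(gamma_fix <= 0))
    stop("'gamma_fix' must be strictly positive")
  structure(list(f_link_sd = f_link_sd, male_birth_share = male_birth_share,
                 gamma_step = gamma_step, tune = isTRUE(tune),
                 gamma_fix = gamma_fix),
            class = "ancient_control")
}

# log density of the truncated-normal link between f and (theta, r),
# accumulated over classes; -Inf when f is infeasible under theta
link_logdens <- function(f, theta, r, sd, f0, m0) {
  p <- length(f)
  S <- pmax(1 - cumsum(theta)[seq_len(p)], 0)
  f_prev <- f0; m_prev <- m0
  tot <- 0
  for (j in seq_len(p)) {
    lower <- max(0, S[j] - m_prev)
    upper <- min(f_prev, S[j])
    d <- dtnorm_log(f[j], S[j] / (1 + r[j]), sd, lower, upper)
    if (!is.finite(d)) return(-Inf)
    tot <- tot + d
    f_prev <- f[j]; m_prev <- S[j] - f[j]
  }
  tot
}

# draw f given theta and r: sequential truncated-normal sampling honouring
# both monotonicity constraints by construction
draw_f <- function(theta, r, sd, f0, m0) {
  p <- length(theta) - 1L
  S <- pmax(1 - cumsum(theta)[seq_len(p)], 0)
  f <- numeric(p); m <- numeric(p)
  f_prev <- f0; m_prev <- m0
  for (j in seq_len(p)) {
    lower <- max(0, S[j] - m_prev)
    upper <- min(f_prev, S[j])
    f[j] <- rtnorm1(S[j] / (1 + r[j]), sd, lower, upper)
    m[j] <- S[j] - f[j]
    f_prev <- f[j]; m_prev <- m[j]
  }
  list(f = f, m = m, S = S)
}

#' Fit the ancient sex-partitioned mortality model by MCMC
#'
#' Dirichlet-multinomial model of unsexed death counts with a shared
#' concentration vector gamma across sites, combined with the modern
#' posterior over (beta2, beta3) to partition survival by sex. The sampler
#' is a Gibbs scheme: per iteration, (beta2, beta3) is drawn from the
#' stored modern posterior (modular two-stage inference); ambiguous
#' individuals are re-imputed from theta; each gamma_j is updated by
#' random-walk Metropolis on the log scale against the collapsed
#' Dirichlet-multinomial likelihood and its TN(0, 1000; 0, Inf) prior;
#' each site's (theta, f) block is then drawn exactly -- theta from its
#' conjugate Dirichlet(gamma + n_k) conditional and f from the sequential
#' truncated-normal link (truncation tightened so both f and m are
#' non-increasing by construction), with m set to S - f exactly,
#' preserving the accounting identity. The block draw is exact because no
#' other likelihood term involves f, so no Metropolis correction is
#' needed.
#'
#' @param profiles a [killoff_profile()] or list of profiles sharing one
#'   schema.
#' @param modern a [modern_posterior()][fit_modern] (or a matrix/data frame
#'   with columns `beta2`, `beta3`) supplying the sex-ratio draws.
#' @param schedule a [sampler_schedule()].
#' @param control an [ancient_control()].
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return An object of class `ancient_posterior`: matrices `gamma`
#'   (draws x T*), `beta` (draws x 2), `chain`, and per-site lists `theta`,
#'   `f`, `m`, `mek` (male excess kill, draws x T*), plus metadata.
#' @export
fit_ancient <- function(profiles, modern, schedule = sampler_schedule(),
                        control = ancient_control(), seed = NULL) {
  if (inherits(profiles, "killoff_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no profiles supplied")
  if (!all(vapply(profiles, inherits, logical(1), "killoff_profile")))
    stop("'profiles' must be killoff_profile objects")
  schema <- profiles[[1L]]$schema
  for (pr in profiles)
    if (!isTRUE(all.equal(pr$schema$classes, schema$classes)))
      stop("all profiles must share one age-class schema")
  stopifnot(inherits(schedule, "sampler_schedule"),
            inherits(control, "ancient_control"))
  pool <- if (inherits(modern, "modern_posterior")) {
    as.matrix(modern$draws[c("beta2", "beta3")])
  } else {
    mm <- as.matrix(as.data.frame(modern)[c("beta2", "beta3")])
    mm
  }
  if (!nrow(pool)) stop("modern posterior is empty")
  M <- length(profiles)
  Tstar <- n_classes(schema)
  p <- Tstar - 1L
  tstar <- class_midpoints(schema)[seq_len(p)]
  f0 <- 1 - control$male_birth_share
  m0 <- control$male_birth_share
  sd_f <- control$f_link_sd

  n_keep <- (schedule$iters - schedule$burnin) %/% schedule$thin
  R <- n_keep * schedule$chains
  gamma_out <- matrix(NA_real_, R, Tstar)
  beta_out <- matrix(NA_real_, R, 2L)
  chain_out <- integer(R)
  theta_out <- rep(list(matrix(NA_real_, R, Tstar)), M)
  f_out <- rep(list(matrix(NA_real_, R, p)), M)
  m_out <- rep(list(matrix(NA_real_, R, p)), M)
  mek_out <- rep(list(matrix(NA_real_, R, Tstar)), M)
  acc_g <- numeric(Tstar); try_g <- 0
  acc_t <- numeric(M); try_t <- 0
  row0 <- 0L

  for (ch in seq_len(schedule$chains)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + ch - 1L)
    gamma <- if (is.null(control$gamma_fix)) rep(1, Tstar) else control$gamma_fix
    step <- rep(control$gamma_step, Tstar)
    blk_acc <- numeric(Tstar); blk_n <- 0L
    b <- pool[sample.int(nrow(pool), 1L), ]
    r <- exp(b[1L] + b[2L] * tstar)
    counts <- vector("list", M)
    theta <- vector("list", M)
    fst <- vector("list", M)
    for (k in seq_len(M)) {
      counts[[k]] <- impute_assignments(profiles[[k]], rep(1 / Tstar, Tstar))$counts
      theta[[k]] <- (counts[[k]] + 1) / sum(counts[[k]] + 1)
      fst[[k]] <- draw_f(theta[[k]], r, sd_f, f0, m0)
    }
    k_keep <- 0L
    for (it in seq_len(schedule$iters)) {
      ## sex-ratio draw from the modern posterior pool
      b <- pool[sample.int(nrow(pool), 1L), ]
      r <- exp(b[1L] + b[2L] * tstar)
      ## imputation of ambiguous individuals
      for (k in seq_len(M)) {
        if (length(profiles[[k]]$ambiguous))
          counts[[k]] <- impute_assignments(profiles[[k]], theta[[k]])$counts
      }
      ## gamma: per-coordinate RW Metropolis on log scale vs DM likelihood
      if (is.null(control$gamma_fix)) {
        try_g <- try_g + 1
        ll_cur <- sum(vapply(seq_len(M), function(k)
          dm_log_pmf(counts[[k]], gamma), numeric(1)))
        for (j in seq_len(Tstar)) {
          gj_new <- gamma[j] * exp(stats::rnorm(1, 0, step[j]))
          g_new <- gamma; g_new[j] <- gj_new
          ll_new <- sum(vapply(seq_len(M), function(k)
            dm_log_pmf(counts[[k]], g_new), numeric(1)))
          lr <- ll_new - ll_cur +
            (-gj_new^2 + gamma[j]^2) / 2000 +
            log(gj_new) - log(gamma[j])
          if (log(stats::runif(1)) < lr) {
            gamma <- g_new; ll_cur <- ll_new
            acc_g[j] <- acc_g[j] + 1
            blk_acc[j] <- blk_acc[j] + 1
          }
        }
        blk_n <- blk_n + 1L
        if (control$tune && it <= schedule$burnin && blk_n == 100L) {
          rate <- blk_acc / blk_n
          step <- ifelse(rate > 0.4, step * 1.25,
                         ifelse(rate < 0.2, step / 1.25, step))
          blk_acc[] <- 0; blk_n <- 0L
        }
      }
      ## (theta, f) per site: no likelihood term attaches to f beyond its
      ## truncated-normal link, so the joint conditional factorises as
      ## theta ~ Dirichlet(gamma + n) followed by f from its sequential
      ## truncated-normal conditional -- an exact block-Gibbs draw
      try_t <- try_t + 1
      for (k in seq_len(M)) {
        theta[[k]] <- rdirichlet1(gamma + counts[[k]])
        acc_t[k] <- acc_t[k] + 1
        fst[[k]] <- draw_f(theta[[k]], r, sd_f, f0, m0)
      }
      if (it > schedule$burnin && (it - schedule$burnin) %% schedule$thin == 0L) {
        k_keep <- k_keep + 1L
        rr <- row0 + k_keep
        gamma_out[rr, ] <- gamma
        beta_out[rr, ] <- b
        chain_out[rr] <- ch
        for (k in seq_len(M)) {
          theta_out[[k]][rr, ] <- theta[[k]]
          f_out[[k]][rr, ] <- fst[[k]]$f
          m_out[[k]][rr, ] <- fst[[k]]$m
          mek_out[[k]][rr, ] <- male_excess_kill(fst[[k]]$f, fst[[k]]$m,
                                                 control$male_birth_share)
        }
      }
    }
    row0 <- row0 + n_keep
  }
  sites <- vapply(profiles, function(pr) pr$site_id, character(1))
  names(theta_out) <- names(f_out) <- names(m_out) <- names(mek_out) <- sites
  res <- list(gamma = gamma_out, beta = beta_out, chain = chain_out,
              theta = theta_out, f = f_out, m = m_out, mek = mek_out,
              sites = sites, schema = schema, schedule = schedule,
              control = control,
              accept_gamma = acc_g / max(try_g, 1),
              accept_theta = acc_t / max(try_t, 1))
  class(res) <- "ancient_posterior"
  res
}

#' @export
print.ancient_posterior <- function(x, ...) {
  cat("Ancient mortality posterior:", nrow(x$gamma), "draws,",
      length(x$sites), "site(s) [", paste(x$sites, collapse = ", "), "]\n")
  for (s in x$sites) {
    cat("  ", s, " posterior mean f: ",
        paste(sprintf("%.3f", colMeans(x$f[[s]])), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Posterior summary table for an ancient fit
#'
#' Mean, median and HPD interval per parameter (gamma, theta, f, m, male
#' excess kill) and site.
#'
#' @param post an `ancient_posterior`.
#' @param mass HPD mass (default 0.95).
#' @return data frame with columns `site`, `param`, `class`, `mean`,
#'   `median`, `hpd_low`, `hpd_high`.
#' @export
summarize_ancient <- function(post, mass = 0.95) {
  stopifnot(inherits(post, "ancient_posterior"))
  one <- function(mat, param, site) {
    do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
      h <- hpd_interval(mat[, j], mass)
      data.frame(site = site, param = param, class = j,
                 mean = mean(mat[, j]), median = stats::median(mat[, j]),
                 hpd_low = h[1L], hpd_high = h[2L])
    }))
  }
  out <- one(post$gamma, "gamma", NA_character_)
  for (s in post$sites) {
    out <- rbind(out,
                 one(post$theta[[s]], "theta", s),
                 one(post$f[[s]], "f", s),
                 one(post$m[[s]], "m", s),
                 one(post$mek[[s]], "male_excess_kill", s))
  }
  rownames(out) <- NULL
  out
}
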