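#' Cattle weight-by-age growth curve
#'
#' Weight in kg at age `x` months:
#' `nu(x) = tau * exp((a/b) (1 - exp(-b x)))`, a Gompertz-type curve with
#' birth weight `tau` and asymptote `tau * exp(a/b)`.
#'
#' @param params list or named vector with `tau` (birth weight, kg), `a`
#'   (growth rate) and `b` (shape, per month).
#' @param x age(s) in months, non-negative.
#' @return weight(s) in kg.
#' @examples
#' growth_weight(list(tau = 20, a = 0.1, b = 0.1), 12)
#' @export
growth_weight <- function(params, x) {
  if (any(x < 0)) stop("'x' must be non-negative")
  p <- as.list(params)
  p$tau * exp((p$a / p$b) * (1 - exp(-p$b * x)))
}

#' Default growth-curve parameters
#'
#' A reference curve for small unimproved cattle: birth weight 22 kg,
#' `a = 0.15`, `b = 0.08`, asymptotic adult weight about 143 kg. Used when
#' no weight data are supplied for fitting.
#' @return list of class `growth_params` with `tau`, `a`, `b`.
#' @export
default_growth_params <- function() {
  structure(list(tau = 22, a = 0.15, b = 0.08), class = "growth_params")
}

#' Fit the growth curve to weight data by constrained least squares
#'
#' Minimises the sum of squared residuals over a fixed multi-start grid
#' followed by box-constrained quasi-Newton refinement, with parameters
#' constrained to `tau` in [10, 30] and `a`, `b` in (0, 1]. Deterministic:
#' the multi-start grid is fixed.
#'
#' @param weights data frame with columns `age` (months) and `kg`; at least
#'   3 points spanning at least 12 months.
#' @param tau_bounds,ab_lower,ab_upper box constraints.
#' @return list of class `growth_params` with `tau`, `a`, `b`, `sse`, and
#'   `at_boundary` (logical: any parameter pinned at a constraint).
#' @export
fit_growth_curve <- function(weights, tau_bounds = c(10, 30),
                             ab_lower = 1e-4, ab_upper = 1) {
  if (!all(c("age", "kg") %in% names(weights)))
    stop("'weights' must have columns age and kg")
  age <- as.numeric(weights$age); kg <- as.numeric(weights$kg)
  if (length(age) < 3L) stop("at least 3 weight points are required")
  if (diff(range(age)) < 12) stop("weight ages must span at least 12 months")
  if (length(unique(age)) == 1L) stop("all ages are equal")
  sse <- function(p) {
    pred <- p[1L] * exp((p[2L] / p[3L]) * (1 - exp(-p[3L] * age)))
    sum((kg - pred)^2)
  }
  lower <- c(tau_bounds[1L], ab_lower, ab_lower)
  upper <- c(tau_bounds[2L], ab_upper, ab_upper)
  grid <- expand.grid(tau = seq(tau_bounds[1L], tau_bounds[2L], length.out = 3),
                      a = c(0.02, 0.1, 0.3), b = c(0.02, 0.08, 0.3))
  ctl <- list(factr = 1e3, maxit = 1000, parscale = c(10, 0.1, 0.05))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(stats::optim(as.numeric(grid[i, ]), sse,
                                 method = "L-BFGS-B", lower = lower,
                                 upper = upper, control = ctl),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("growth-curve fit failed from every start")
  # polish from the incumbent with a tight tolerance
  polish <- tryCatch(stats::optim(best$par, sse, method = "L-BFGS-B",
                                  lower = lower, upper = upper,
                                  control = utils::modifyList(ctl, list(factr = 1))),
                     error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  p <- best$par
  tol <- 1e-6
  at_b <- any(abs(p - lower) < tol) || any(abs(p - upper) < tol)
  structure(list(tau = p[1L], a = p[2L], b = p[3L], sse = best$value,
                 at_boundary = at_b),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth curve: tau = %.3f kg, a = %.4f, b = %.4f (asymptote %.1f kg)%s\n",
              x$tau, x$a, x$b, x$tau * exp(x$a / x$b),
              if (isTRUE(x$at_boundary)) " [at constraint boundary]" else ""))
  invisible(x)
}
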