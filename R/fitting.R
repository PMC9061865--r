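# Constrained multistart nonlinear least-squares estimation of the BR and
# BRD models from a single-temperature release profile.
#
# The theta simplex constraint of the BRD model is enforced by the
# reparameterisation theta_b = u, theta_r = (1 - u) * v with u, v in [0, 1],
# so the optimiser never visits an infeasible weight combination. D_e spans
# many decades and is searched in log10 space.

#' Adjusted coefficient of determination
#'
#' `R2_adj = 1 - (1 - R2) * (n_dp - 1) / (n_dp - p - 1)`, the penalised
#' goodness-of-fit statistic used to compare models with different numbers
#' of parameters: unlike R^2 it can decrease when a parameter is added.
#'
#' @param r_squared coefficient of determination.
#' @param n_dp number of data points.
#' @param p number of model parameters.
#' @return the adjusted R^2.
#' @examples
#' adjusted_r_squared(0.9929, n_dp = 25, p = 4)  # 0.99148
#' @export
adjusted_r_squared <- function(r_squared, n_dp, p) {
  if (n_dp <= p + 1)
    stop("adjusted R^2 requires n_dp > p + 1", call. = FALSE)
  1 - (1 - r_squared) * (n_dp - 1) / (n_dp - p - 1)
}

#' Goodness of fit of a predicted release curve
#'
#' @param observed observed release fractions.
#' @param predicted model-predicted fractions at the same times.
#' @param p number of fitted parameters (4 for BR, 6 for BRD).
#' @return a list with `r_squared`, `r_squared_adjusted`, `rss`, `n_dp`, `p`.
#' @export
goodness_of_fit <- function(observed, predicted, p) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  n_dp <- length(observed)
  if (n_dp <= p + 1)
    stop("goodness of fit requires n_dp > p + 1", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("zero total variance in 'observed'; R^2 undefined", call. = FALSE)
  rss <- sum((observed - predicted)^2)
  r2 <- 1 - rss / ss_tot
  list(r_squared = r2,
       r_squared_adjusted = adjusted_r_squared(r2, n_dp, p),
       rss = rss, n_dp = n_dp, p = p)
}

# Default deterministic multistart lattice (natural-parameter space).
default_starts_br <- function(t_max_scale) {
  expand.grid(theta_b = c(0.2, 0.5, 0.8),
              k_b = c(0.5, 2, 5),
              k_r = c(0.05, 0.2, 1),
              t_max = c(0.25, 0.5, 0.75) * t_max_scale,
              KEEP.OUT.ATTRS = FALSE)
}

default_starts_brd <- function(t_max_scale) {
  expand.grid(theta_b = c(0.2, 0.5, 0.8),
              theta_r = c(0.1, 0.4),
              k_b = c(0.5, 2, 5),
              k_r = c(0.05, 0.2, 1),
              t_max = c(0.25, 0.5, 0.75) * t_max_scale,
              log10_D_e = c(-19, -17, -15),
              KEEP.OUT.ATTRS = FALSE)
}

# Multiplicative +/-`jitter` perturbation of a start lattice, seeded.
jitter_starts <- function(starts, jitter, seed) {
  if (jitter <= 0) return(starts)
  with_seed(seed, {
    fac <- matrix(stats::runif(nrow(starts) * ncol(starts),
                               1 - jitter, 1 + jitter),
                  nrow = nrow(starts))
    out <- starts * fac
    # weights must stay inside the unit interval
    for (nm in intersect(c("theta_b", "theta_r"), names(out)))
      out[[nm]] <- pmin(0.999, pmax(0.001, out[[nm]]))
    out
  })
}

check_profile_for_fit <- function(profile, min_points) {
  stopifnot(inherits(profile, "release_profile"))
  if (length(profile$times) < min_points)
    stop(sprintf("at least %d data points are required for this model",
                 min_points), call. = FALSE)
  invisible(profile)
}

# Shared multistart LM driver. `residual_fn(par)` returns residuals,
# `lower`/`upper` are box bounds on the optimiser scale.
run_multistart_lm <- function(starts_matrix, residual_fn, lower, upper) {
  coarse <- minpack.lm::nls.lm.control(maxiter = 120)
  fine <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  best <- NULL
  init_obj <- numeric(nrow(starts_matrix))
  for (i in seq_len(nrow(starts_matrix))) {
    par0 <- pmin(upper, pmax(lower, starts_matrix[i, ]))
    init_obj[i] <- sum(residual_fn(par0)^2)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = residual_fn,
                         lower = lower, upper = upper, control = coarse),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all multistart optimisations failed to produce a fit", call. = FALSE)
  polished <- tryCatch(
    minpack.lm::nls.lm(par = best$par, fn = residual_fn,
                       lower = lower, upper = upper, control = fine),
    error = function(e) NULL
  )
  if (!is.null(polished) && polished$deviance <= best$deviance) best <- polished
  list(fit = best, initial_objectives = init_obj)
}

at_bound_flags <- function(par, lower, upper, tol = 1e-6) {
  (par - lower) < tol | (upper - par) < tol
}

make_fit_result <- function(params, profile, predicted, p, converged,
                            at_bound, initial_objectives, geom = NULL) {
  gof <- goodness_of_fit(profile$fractions, predicted, p)
  structure(
    list(params = params,
         residuals = profile$fractions - predicted,
         residual_sum_of_squares = gof$rss,
         r_squared = gof$r_squared,
         r_squared_adjusted = gof$r_squared_adjusted,
         n_dp = gof$n_dp, p = p,
         converged = converged, at_bound = at_bound,
         profile = profile, geom = geom),
    class = "fit_result", initial_objectives = initial_objectives
  )
}

#' Fit the two-stage BR model to a release profile
#'
#' Minimises the unweighted residual sum of squares over
#' `(theta_b, k_b, k_r, t_max)` with box bounds `theta_b` in \[0,1\],
#' rates in (0, 100\] day^-1 and `t_max` in (0, 10 * max(t)\] days, using
#' Levenberg-Marquardt least squares from every point of a deterministic
#' multistart lattice; the best optimum is polished at tight tolerance and
#' returned. Parameters lying within 1e-6 of a bound are flagged.
#'
#' @param profile a [release_profile()] with at least 6 points.
#' @param starts optional data.frame of starting points with columns
#'   `theta_b`, `k_b`, `k_r`, `t_max`; defaults to the built-in lattice.
#' @param jitter optional relative perturbation of the lattice (e.g. 0.1
#'   for +/-10 percent); 0 (default) keeps the lattice deterministic.
#' @param seed RNG seed for the jitter (ignored when `jitter = 0`).
#' @return a `fit_result` with the fitted [mechanism_params()], residuals,
#'   R^2 and adjusted R^2 (`p = 4`), convergence and at-bound flags.
#' @examples
#' p <- mechanism_params(0.5567, 1.8053, 0.1109, 20.1849)
#' prof <- release_profile(0:27, br_model(0:27, p), temperature_K = 310.15)
#' fit <- fit_br(prof)
#' fit$params$theta_b
#' @export
fit_br <- function(profile, starts = NULL, jitter = 0, seed = NULL) {
  check_profile_for_fit(profile, 6L)
  t <- profile$times; y <- profile$fractions
  t_hi <- 10 * max(t)
  if (is.null(starts)) starts <- default_starts_br(max(t))
  starts <- jitter_starts(starts[, c("theta_b", "k_b", "k_r", "t_max")],
                          jitter, seed)
  lower <- c(0, 1e-8, 1e-8, 1e-8)
  upper <- c(1, 100, 100, t_hi)

  residual_fn <- function(par) {
    params <- list(model = "br", theta_b = par[1], theta_r = 1 - par[1],
                   k_b = par[2], k_r = par[3], t_max = par[4], D_e = NA_real_)
    par[1] * (-expm1(-par[2] * t)) +
      (1 - par[1]) * stats::plogis(par[3] * (t - par[4])) - y
  }
  res <- run_multistart_lm(as.matrix(starts), residual_fn, lower, upper)
  par <- res$fit$par
  params <- mechanism_params(theta_b = par[1], k_b = par[2], k_r = par[3],
                             t_max = par[4], model = "br")
  flags <- at_bound_flags(par, lower, upper)
  names(flags) <- c("theta_b", "k_b", "k_r", "t_max")
  make_fit_result(params, profile, br_model(t, params), p = 4L,
                  converged = res$fit$info %in% 1:4, at_bound = flags,
                  initial_objectives = res$initial_objectives)
}

#' Fit the three-stage BRD model to a release profile
#'
#' As [fit_br()], extended with the diffusion mechanism: the weight simplex
#' `theta_b + theta_r <= 1` is enforced through the reparameterisation
#' `theta_b = u`, `theta_r = (1 - u) * v` with `u, v` in \[0,1\], and the
#' effective diffusivity is optimised as `log10(D_e)` over
#' \[1e-22, 1e-12\] cm^2 s^-1.
#'
#' @param profile a [release_profile()] with at least 8 points.
#' @param geom a [particle_geometry()] fixing the particle radius of the
#'   diffusion kernel.
#' @param starts optional data.frame with columns `theta_b`, `theta_r`,
#'   `k_b`, `k_r`, `t_max`, `log10_D_e`; defaults to the built-in lattice.
#' @inheritParams fit_br
#' @return a `fit_result` (`p = 6`); `at_bound` covers the natural
#'   parameters with `D_e` assessed on the log10 scale.
#' @export
fit_brd <- function(profile, geom = particle_geometry(), starts = NULL,
                    jitter = 0, seed = NULL) {
  check_profile_for_fit(profile, 8L)
  geom <- as_particle_geometry(geom)
  t <- profile$times; y <- profile$fractions
  t_hi <- 10 * max(t)
  if (is.null(starts)) starts <- default_starts_brd(max(t))
  starts <- jitter_starts(
    starts[, c("theta_b", "theta_r", "k_b", "k_r", "t_max", "log10_D_e")],
    jitter, seed)
  # optimiser scale: (u, v, k_b, k_r, t_max, log10 D_e)
  u0 <- pmin(1, pmax(0, starts$theta_b))
  v0 <- ifelse(u0 >= 1, 0, pmin(1, pmax(0, starts$theta_r / (1 - u0))))
  starts_opt <- cbind(u = u0, v = v0, k_b = starts$k_b, k_r = starts$k_r,
                      t_max = starts$t_max, log10_D_e = starts$log10_D_e)
  lower <- c(0, 0, 1e-8, 1e-8, 1e-8, -22)
  upper <- c(1, 1, 100, 100, t_hi, -12)

  tau_fac <- geom$seconds_per_day / geom$radius_cm^2
  residual_fn <- function(par) {
    u <- par[1]; v <- par[2]
    tb <- u; tr <- (1 - u) * v; td <- (1 - u) * (1 - v)
    De <- 10^par[6]
    diff_part <- if (td > 0)
      diffusion_series(De * t * tau_fac) else numeric(length(t))
    tb * (-expm1(-par[3] * t)) +
      tr * stats::plogis(par[4] * (t - par[5])) +
      td * diff_part - y
  }
  res <- run_multistart_lm(starts_opt, residual_fn, lower, upper)
  par <- res$fit$par
  theta_b <- par[1]
  theta_r <- (1 - par[1]) * par[2]
  if (theta_b + theta_r > 1 + 1e-12)
    stop("internal error: simplex constraint violated at optimum", call. = FALSE)
  params <- mechanism_params(theta_b = theta_b, theta_r = theta_r,
                             k_b = par[3], k_r = par[4], t_max = par[5],
                             D_e = 10^par[6], model = "brd")
  flags <- at_bound_flags(par, lower, upper)
  names(flags) <- c("theta_b", "theta_r", "k_b", "k_r", "t_max", "log10_D_e")
  make_fit_result(params, profile, brd_model(t, params, geom), p = 6L,
                  converged = res$fit$info %in% 1:4, at_bound = flags,
                  initial_objectives = res$initial_objectives, geom = geom)
}

# Raw Crank series on dimensionless time tau (no input checking; hot path
# inside the BRD residual function).
diffusion_series <- function(tau, tol = 1e-12, max_terms = 10000L) {
  out <- numeric(length(tau))
  active <- tau > 0
  if (any(active)) {
    ta <- tau[active]
    acc <- numeric(length(ta))
    n <- 1
    repeat {
      term <- exp(-n^2 * pi^2 * ta) / n^2
      acc <- acc + term
      if (max(term) * n < tol || n >= max_terms) break
      n <- n + 1
    }
    out[active] <- 1 - (6 / pi^2) * acc
  }
  pmin(1, pmax(0, out))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s model fit: n = %d points, p = %d parameters%s\n",
              toupper(x$params$model), x$n_dp, x$p,
              if (x$converged) "" else "  [did not converge]"))
  print(x$params)
  cat(sprintf("  RSS = %.4g   R^2 = %.4f   adj. R^2 = %.4f\n",
              x$residual_sum_of_squares, x$r_squared, x$r_squared_adjusted))
  if (any(x$at_bound))
    cat("  at bound:", paste(names(x$at_bound)[x$at_bound], collapse = ", "),
        "\n")
  invisible(x)
}
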