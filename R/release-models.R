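# Mechanism kernels and their BR / BRD superpositions.
# All kernels map t >= 0 (days) into [0, 1] and are nondecreasing in t.

# Clamp tiny floating-point overshoot; anything beyond `tol` is a real bug.
clamp_fraction <- function(x, tol = 1e-12) {
  bad <- (x < -tol) | (x > 1 + tol)
  if (any(bad, na.rm = TRUE))
    stop("computed release fraction outside [0, 1] beyond numerical tolerance",
         call. = FALSE)
  pmin(1, pmax(0, x))
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and non-negative (days)", call. = FALSE)
  as.numeric(t)
}

#' First-order initial-burst release kernel
#'
#' Fraction of the burst compartment released by time `t` under first-order
#' interfacial transfer from the particle surface to the medium:
#' `Mt/Minf = 1 - exp(-k_b * t)`.
#'
#' @param t time in days (vectorised), non-negative.
#' @param k_b burst rate constant in day^-1, positive.
#' @return release fraction(s) in `[0, 1)`.
#' @examples
#' burst_fraction(1, k_b = 1.8053)  # ~0.836 after one day at 37 degC rates
#' @export
burst_fraction <- function(t, k_b) {
  t <- check_times(t)
  if (!is.numeric(k_b) || length(k_b) != 1L || !is.finite(k_b) || k_b <= 0)
    stop("'k_b' must be a single positive rate (day^-1)", call. = FALSE)
  -expm1(-k_b * t)
}

#' Prout-Tompkins degradation-relaxation release kernel
#'
#' Sigmoidal release stage attributed to hydrolytic bulk degradation and
#' chain relaxation of the polymer matrix. The linearised Prout-Tompkins
#' law `ln(x / (1 - x)) = k_r * (t - t_max)` gives the logistic
#' `x(t) = 1 / (1 + exp(-k_r * (t - t_max)))`, which passes through 1/2
#' exactly at `t = t_max`, the time of maximum release rate.
#'
#' @param t time in days (vectorised), non-negative.
#' @param k_r degradation-relaxation rate constant in day^-1, positive.
#' @param t_max midpoint time in days, positive.
#' @return release fraction(s) in `(0, 1)`.
#' @examples
#' degradation_fraction(20.1849, k_r = 0.1109, t_max = 20.1849)  # exactly 0.5
#' @export
degradation_fraction <- function(t, k_r, t_max) {
  t <- check_times(t)
  if (!is.numeric(k_r) || length(k_r) != 1L || !is.finite(k_r) || k_r <= 0)
    stop("'k_r' must be a single positive rate (day^-1)", call. = FALSE)
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) || t_max <= 0)
    stop("'t_max' must be a single positive time (days)", call. = FALSE)
  stats::plogis(k_r * (t - t_max))
}

#' Fickian release from a sphere (Crank series solution)
#'
#' Fraction released by radial diffusion out of a sphere of radius r1 with a
#' uniform initial drug distribution, zero surface concentration (sink
#' conditions) and symmetry at the centre:
#' `Mt/Minf = 1 - (6/pi^2) * sum_n n^-2 exp(-n^2 pi^2 D_e t / r1^2)`.
#' Time enters in seconds (`t * 86400`) because `D_e` is in cm^2 s^-1.
#'
#' The series is truncated adaptively: terms are added until the neglected
#' tail is provably below `tol` (the tail of positive decreasing terms is
#' bounded by `n` times the next term, since `sum_{m>n} m^-2 < 1/n`), or
#' until `max_terms` is reached, in which case a warning is raised; that
#' only happens at extremely small dimensionless times. At `t = 0` the
#' untruncated series sums exactly to 1, so 0 is returned by special-casing
#' rather than by truncation.
#'
#' @param t time in days (vectorised), non-negative.
#' @param D_e effective diffusion coefficient in cm^2 s^-1, non-negative.
#' @param geom a [particle_geometry()]; defaults to the 142 nm particle.
#' @param tol truncation tolerance on the next series term.
#' @param max_terms hard cap on the number of series terms.
#' @return release fraction(s) in `[0, 1]`.
#' @examples
#' diffusion_fraction(5, D_e = 3.4908e-18)  # ~0.50 at 37 degC diffusivity
#' @export
diffusion_fraction <- function(t, D_e, geom = particle_geometry(),
                               tol = 1e-12, max_terms = 10000L) {
  t <- check_times(t)
  if (!is.numeric(D_e) || length(D_e) != 1L || !is.finite(D_e) || D_e < 0)
    stop("'D_e' must be a single non-negative diffusivity (cm^2 s^-1)",
         call. = FALSE)
  geom <- as_particle_geometry(geom)
  # dimensionless time tau = D_e * t_sec / r1^2
  tau <- D_e * t * geom$seconds_per_day / geom$radius_cm^2
  out <- numeric(length(t))
  active <- tau > 0
  if (any(active)) {
    ta <- tau[active]
    acc <- numeric(length(ta))
    n <- 1
    repeat {
      term <- exp(-n^2 * pi^2 * ta) / n^2
      acc <- acc + term
      # tail bound: sum_{m>n} exp(-m^2 pi^2 tau)/m^2 <= exp(-n^2 pi^2 tau)/n
      if (max(term) * n < tol) break
      if (n >= max_terms) {
        warning("diffusion series reached 'max_terms' before meeting 'tol'; ",
                "result may be inaccurate at very small times", call. = FALSE)
        break
      }
      n <- n + 1
    }
    out[active] <- 1 - (6 / pi^2) * acc
  }
  clamp_fraction(out)
}

#' Two-stage burst + degradation-relaxation (BR) release model
#'
#' Convex combination of the burst and Prout-Tompkins kernels,
#' `theta_b * burst + (1 - theta_b) * degradation`.
#'
#' @param t time in days (vectorised).
#' @param params a [mechanism_params()] object (BR or BRD; for BRD parameters
#'   only the burst and relaxation weights are meaningful here).
#' @return release fraction(s) in `[0, 1]`.
#' @examples
#' p <- mechanism_params(0.5567, 1.8053, 0.1109, 20.1849)
#' br_model(c(0, 5, 20.1849, 60), p)
#' @export
br_model <- function(t, params) {
  stopifnot(inherits(params, "mechanism_params"))
  clamp_fraction(
    params$theta_b * burst_fraction(t, params$k_b) +
      (1 - params$theta_b) * degradation_fraction(t, params$k_r, params$t_max)
  )
}

#' Three-stage burst + relaxation + diffusion (BRD) release model
#'
#' Convex combination of all three mechanism kernels with weights
#' `theta_b + theta_r + theta_d = 1`:
#' `theta_b * burst + theta_r * degradation + theta_d * diffusion`.
#'
#' @param t time in days (vectorised).
#' @param params a [mechanism_params()] object with `model = "brd"`.
#' @param geom a [particle_geometry()] for the diffusion kernel.
#' @return release fraction(s) in `[0, 1]`.
#' @export
brd_model <- function(t, params, geom = particle_geometry()) {
  stopifnot(inherits(params, "mechanism_params"))
  if (params$model != "brd")
    stop("'params' must be a BRD parameter set (theta_r and D_e present)",
         call. = FALSE)
  td <- 1 - params$theta_b - params$theta_r
  if (td < -1e-12)
    stop("'theta_b' + 'theta_r' exceeds 1", call. = FALSE)
  td <- max(0, td)
  clamp_fraction(
    params$theta_b * burst_fraction(t, params$k_b) +
      params$theta_r * degradation_fraction(t, params$k_r, params$t_max) +
      td * diffusion_fraction(t, params$D_e, geom)
  )
}

#' Evaluate a BR or BRD model curve
#'
#' Thin dispatcher used by the fitting, synthetic-data and sweep layers.
#'
#' @inheritParams brd_model
#' @return release fraction(s) in `[0, 1]`.
#' @export
release_model <- function(t, params, geom = particle_geometry()) {
  if (params$model == "br") br_model(t, params) else brd_model(t, params, geom)
}

#' Per-mechanism decomposition of a release curve
#'
#' Splits the model curve into its theta-weighted mechanism components, the
#' quantity plotted in mechanism-contribution bar charts. The component
#' columns sum to the model curve exactly, by construction.
#'
#' @param t_grid times in days.
#' @param params a [mechanism_params()] object.
#' @param geom a [particle_geometry()] (used for BRD only).
#' @return a data.frame with columns `time_days`, `burst`, `degradation`,
#'   `diffusion` (weighted component curves) and `total`; the mechanism
#'   weights are attached as attribute `"weights"`.
#' @examples
#' p <- mechanism_params(0.5567, 1.8053, 0.1109, 20.1849)
#' attr(mechanism_contributions(0:27, p), "weights")
#' @export
mechanism_contributions <- function(t_grid, params, geom = particle_geometry()) {
  stopifnot(inherits(params, "mechanism_params"))
  t_grid <- check_times(t_grid)
  td <- if (params$model == "brd") max(0, 1 - params$theta_b - params$theta_r) else 0
  burst <- params$theta_b * burst_fraction(t_grid, params$k_b)
  degr <- params$theta_r *
    degradation_fraction(t_grid, params$k_r, params$t_max)
  diff <- if (td > 0) td * diffusion_fraction(t_grid, params$D_e, geom)
          else numeric(length(t_grid))
  out <- data.frame(time_days = t_grid, burst = burst, degradation = degr,
                    diffusion = diff, total = burst + degr + diff)
  weights <- c(burst = params$theta_b, degradation = params$theta_r,
               diffusion = td)
  attr(out, "weights") <- weights
  out
}
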