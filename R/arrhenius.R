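# Arrhenius temperature laws for the release parameters (k_b, k_r, t_max,
# D_e) and their estimation from per-temperature values.

#' Gas constant in cal mol^-1 K^-1
#'
#' Default value of R used throughout the package; activation energies are
#' stored in cal mol^-1 and reported in kcal mol^-1.
#' @export
GAS_CONSTANT_CAL <- 1.9872

#' Arrhenius temperature law for a release parameter
#'
#' Represents `value(T) = A * exp(-Ea / (R * T))` with `T` in kelvin. `A`
#' carries the units of the governed parameter (day^-1 for rate constants,
#' days for `t_max`, cm^2 s^-1 for `D_e`). `Ea` may be negative: a parameter
#' that shrinks with rising temperature (such as `t_max`) has a negative
#' apparent activation energy.
#'
#' @param prefactor pre-exponential constant A, positive.
#' @param ea_cal activation energy in cal mol^-1 (may be negative).
#' @param r_gas gas constant in cal mol^-1 K^-1.
#' @param parameter optional name of the governed parameter (for printing).
#' @return an object of class `arrhenius_law`.
#' @examples
#' law <- arrhenius_law(prefactor = 1703.0412, ea_cal = 4221.1)
#' arrhenius_value(310.15, law)  # ~1.81 /day at 37 degC
#' @export
arrhenius_law <- function(prefactor, ea_cal, r_gas = GAS_CONSTANT_CAL,
                          parameter = NA_character_) {
  if (!is.numeric(prefactor) || length(prefactor) != 1L || prefactor <= 0 ||
      !is.finite(prefactor))
    stop("'prefactor' must be a single positive number", call. = FALSE)
  if (!is.numeric(ea_cal) || length(ea_cal) != 1L || !is.finite(ea_cal))
    stop("'ea_cal' must be a single finite number (cal mol^-1)", call. = FALSE)
  if (!is.numeric(r_gas) || length(r_gas) != 1L || r_gas <= 0)
    stop("'r_gas' must be a single positive number", call. = FALSE)
  structure(
    list(prefactor = prefactor, ea_cal = ea_cal, r_gas = r_gas,
         parameter = parameter),
    class = "arrhenius_law"
  )
}

#' Evaluate an Arrhenius law at absolute temperature
#'
#' @param T_kelvin absolute temperature(s) in kelvin, positive.
#' @param law an [arrhenius_law()] object.
#' @return the governed parameter value(s), always positive.
#' @export
arrhenius_value <- function(T_kelvin, law) {
  stopifnot(inherits(law, "arrhenius_law"))
  if (!is.numeric(T_kelvin) || any(!is.finite(T_kelvin)) || any(T_kelvin <= 0))
    stop("temperature must be positive (kelvin)", call. = FALSE)
  law$prefactor * exp(-law$ea_cal / (law$r_gas * T_kelvin))
}

#' Convert Celsius to kelvin
#'
#' @param temp_c temperature(s) in degrees Celsius.
#' @return temperature(s) in kelvin.
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' Estimate an Arrhenius law from per-temperature parameter values
#'
#' Linearises the law as `ln(value) = ln(A) - (Ea/R) * (1/T)` and regresses
#' `ln(value)` on reciprocal absolute temperature. The slope gives
#' `Ea = -slope * R` and the exponential of the intercept gives `A`, the
#' standard construction of an Arrhenius plot.
#'
#' With `mode = "endpoints"` only the lowest- and highest-temperature points
#' are used (the line through the extremes); with `mode = "ols"` (default)
#' all points enter an ordinary least-squares fit. No bias correction is
#' applied for the log-space fit, matching the conventional linearisation.
#'
#' @param temperatures_K absolute temperatures in kelvin (>= 2 distinct).
#' @param values positive parameter values at those temperatures.
#' @param mode `"ols"` (all points) or `"endpoints"`.
#' @param r_gas gas constant in cal mol^-1 K^-1.
#' @param parameter optional name of the governed parameter.
#' @return an [arrhenius_law()] with attributes `r_squared` (of the line in
#'   ln-value vs 1/T space; `NA` for a two-point fit), `mode` and
#'   `n_points`.
#' @examples
#' # burst-rate constants at 37/47/57 degC
#' fit_arrhenius(celsius_to_kelvin(c(37, 47, 57)),
#'               c(1.8053, 2.2306, 2.7337), mode = "endpoints")
#' @export
fit_arrhenius <- function(temperatures_K, values, mode = c("ols", "endpoints"),
                          r_gas = GAS_CONSTANT_CAL,
                          parameter = NA_character_) {
  mode <- match.arg(mode)
  if (length(temperatures_K) != length(values))
    stop("'temperatures_K' and 'values' must have equal length", call. = FALSE)
  if (length(values) < 2L)
    stop("at least two temperature points are required", call. = FALSE)
  if (any(!is.finite(temperatures_K)) || any(temperatures_K <= 0))
    stop("temperatures must be positive (kelvin)", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("parameter values must be positive for the log-linearisation",
         call. = FALSE)

  if (mode == "endpoints") {
    lo <- which.min(temperatures_K)
    hi <- which.max(temperatures_K)
    if (temperatures_K[lo] == temperatures_K[hi])
      stop("endpoints mode needs two distinct temperatures", call. = FALSE)
    temperatures_K <- temperatures_K[c(lo, hi)]
    values <- values[c(lo, hi)]
  }
  if (length(unique(temperatures_K)) < 2L)
    stop("at least two distinct temperatures are required", call. = FALSE)

  x <- 1 / temperatures_K
  y <- log(values)
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[[2L]]
  intercept <- stats::coef(fit)[[1L]]
  # suppressed: summary.lm warns on an exactly collinear (perfect) fit
  r2 <- if (length(y) > 2L) suppressWarnings(summary(fit)$r.squared)
        else NA_real_

  law <- arrhenius_law(prefactor = exp(intercept), ea_cal = -slope * r_gas,
                       r_gas = r_gas, parameter = parameter)
  attr(law, "r_squared") <- r2
  attr(law, "mode") <- mode
  attr(law, "n_points") <- length(y)
  law
}

#' Activation energy in kcal mol^-1
#'
#' Convenience accessor matching the units activation energies are usually
#' tabulated in.
#'
#' @param law an [arrhenius_law()] object.
#' @return `Ea` in kcal mol^-1.
#' @export
ea_kcal <- function(law) {
  stopifnot(inherits(law, "arrhenius_law"))
  law$ea_cal / 1000
}

#' @export
print.arrhenius_law <- function(x, ...) {
  nm <- if (is.na(x$parameter)) "parameter" else x$parameter
  cat(sprintf("Arrhenius law for %s: A = %.6g, Ea = %.4f kcal/mol (R = %.4f cal/mol/K)\n",
              nm, x$prefactor, ea_kcal(x), x$r_gas))
  if (!is.null(attr(x, "mode")))
    cat(sprintf("  fitted from %d point(s), mode = %s\n",
                attr(x, "n_points"), attr(x, "mode")))
  invisible(x)
}
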