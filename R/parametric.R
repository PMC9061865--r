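# Parametric temperature sweep: release surfaces over a temperature range
# with every rate parameter driven by its Arrhenius law.

#' Release surface over a temperature range
#'
#' Evaluates the BR or BRD model on a time grid at each temperature of a
#' grid, with `k_b`, `k_r`, `t_max` (and `D_e`) computed from their
#' Arrhenius laws. Because the weight fractions have no temperature law of
#' their own, a `weights` policy must be given explicitly: either constants
#' applied at all temperatures, or a per-temperature table
#' (`temperature_K`, `theta_b`\[, `theta_r`\]) that is linearly
#' interpolated (and held constant beyond its range).
#'
#' @param model `"br"` or `"brd"`.
#' @param laws named list of [arrhenius_law()] objects (`k_b`, `k_r`,
#'   `t_max`, plus `D_e` for BRD).
#' @param weights weight policy; see Details above.
#' @param temperatures_K temperature grid in kelvin; defaults to 33-60 degC
#'   in 1 degC steps.
#' @param t_grid time grid in days; defaults to 0-27 days in 0.1-day steps.
#' @param geom a [particle_geometry()].
#' @param validity_K declared validity window of the Arrhenius laws;
#'   temperatures outside it trigger a warning (extrapolation), not an
#'   error. Defaults to the 37-57 degC calibration range.
#' @return an object of class `sweep_surface`: list with `temperatures_K`,
#'   `times`, `fractions` (matrix, temperatures x times) and `model`.
#' @examples
#' laws <- list(k_b = arrhenius_law(1703.0412, 4221.1, parameter = "k_b"),
#'              k_r = arrhenius_law(4321997.7158, 10771.1, parameter = "k_r"),
#'              t_max = arrhenius_law(3.3883e-9, -13870.9, parameter = "t_max"))
#' s <- temperature_sweep("br", laws, weights = list(theta_b = 0.5453),
#'                        temperatures_K = celsius_to_kelvin(c(37, 47, 57)),
#'                        t_grid = seq(0, 27, 1))
#' @export
temperature_sweep <- function(model = c("br", "brd"), laws, weights,
                              temperatures_K = celsius_to_kelvin(seq(33, 60, 1)),
                              t_grid = seq(0, 27, 0.1),
                              geom = particle_geometry(),
                              validity_K = celsius_to_kelvin(c(37, 57))) {
  model <- match.arg(model)
  need <- if (model == "br") c("k_b", "k_r", "t_max")
          else c("k_b", "k_r", "t_max", "D_e")
  if (!all(need %in% names(laws)))
    stop("'laws' must contain Arrhenius laws named: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (missing(weights) || is.null(weights))
    stop("a 'weights' policy is required: constants or a per-temperature table",
         call. = FALSE)
  if (any(temperatures_K < min(validity_K)) ||
      any(temperatures_K > max(validity_K)))
    warning("sweep extrapolates the Arrhenius laws outside their ",
            sprintf("%.2f-%.2f K validity window", min(validity_K),
                    max(validity_K)), call. = FALSE)

  weight_fun <- make_weight_policy(weights, model)
  surf <- matrix(NA_real_, nrow = length(temperatures_K),
                 ncol = length(t_grid))
  for (i in seq_along(temperatures_K)) {
    T_K <- temperatures_K[i]
    w <- weight_fun(T_K)
    params <- if (model == "br") {
      mechanism_params(theta_b = w$theta_b,
                       k_b = arrhenius_value(T_K, laws$k_b),
                       k_r = arrhenius_value(T_K, laws$k_r),
                       t_max = arrhenius_value(T_K, laws$t_max),
                       model = "br")
    } else {
      mechanism_params(theta_b = w$theta_b, theta_r = w$theta_r,
                       k_b = arrhenius_value(T_K, laws$k_b),
                       k_r = arrhenius_value(T_K, laws$k_r),
                       t_max = arrhenius_value(T_K, laws$t_max),
                       D_e = arrhenius_value(T_K, laws$D_e),
                       model = "brd")
    }
    surf[i, ] <- release_model(t_grid, params, geom)
  }
  structure(
    list(temperatures_K = temperatures_K, times = t_grid,
         fractions = surf, model = model),
    class = "sweep_surface"
  )
}

# Resolve a weight policy into a function of temperature.
make_weight_policy <- function(weights, model) {
  need <- if (model == "br") "theta_b" else c("theta_b", "theta_r")
  if (is.data.frame(weights)) {
    if (!all(c("temperature_K", need) %in% names(weights)))
      stop("weight table must have columns temperature_K, ",
           paste(need, collapse = ", "), call. = FALSE)
    if (nrow(weights) < 2L)
      stop("weight table needs >= 2 rows for interpolation; ",
           "use a constant list for a single value", call. = FALSE)
    ord <- order(weights$temperature_K)
    weights <- weights[ord, ]
    function(T_K) {
      out <- lapply(need, function(nm)
        stats::approx(weights$temperature_K, weights[[nm]], xout = T_K,
                      rule = 2)$y)
      names(out) <- need
      out
    }
  } else {
    if (!all(need %in% names(weights)))
      stop("constant weights must be named: ", paste(need, collapse = ", "),
           call. = FALSE)
    force(weights)
    function(T_K) weights[need]
  }
}

#' Long-format table of a sweep surface
#'
#' @param x a `sweep_surface`.
#' @param ... unused.
#' @return data.frame with columns `temperature_C`, `time_days`, `fraction`.
#' @export
as.data.frame.sweep_surface <- function(x, ...) {
  data.frame(
    temperature_C = rep(x$temperatures_K - 273.15, times = length(x$times)),
    time_days = rep(x$times, each = length(x$temperatures_K)),
    fraction = as.vector(x$fractions)
  )
}

#' @export
print.sweep_surface <- function(x, ...) {
  cat(sprintf("%s release surface: %d temperatures (%.1f-%.1f degC) x %d times (0-%.3g days)\n",
              toupper(x$model), length(x$temperatures_K),
              min(x$temperatures_K) - 273.15, max(x$temperatures_K) - 273.15,
              length(x$times), max(x$times)))
  invisible(x)
}
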