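#' Release profile: one temperature's cumulative-release time series
#'
#' @param times sampling times in days, strictly increasing, non-negative.
#' @param fractions cumulative fractional release Mt/Minf. Values up to 1.05
#'   are accepted (small experimental overshoot) but flagged via the
#'   `overshoot` attribute; anything larger is rejected.
#' @param temperature_K incubation temperature in kelvin (scalar, optional).
#' @param label free-text label.
#' @return an object of class `release_profile`.
#' @examples
#' release_profile(times = c(0, 1, 3, 7, 14, 27),
#'                 fractions = c(0, 0.3, 0.5, 0.7, 0.85, 0.95),
#'                 temperature_K = 310.15)
#' @export
release_profile <- function(times, fractions, temperature_K = NA_real_,
                            label = "") {
  times <- as.numeric(times)
  fractions <- as.numeric(fractions)
  if (length(times) != length(fractions))
    stop("'times' and 'fractions' must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative (days)", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(fractions)))
    stop("'fractions' must be finite", call. = FALSE)
  if (any(fractions < 0) || any(fractions > 1.05))
    stop("'fractions' must lie in [0, 1.05]", call. = FALSE)
  overshoot <- any(fractions > 1)
  if (overshoot)
    warning("release fractions above 1 present (experimental overshoot); ",
            "flagged but retained", call. = FALSE)
  structure(
    list(times = times, fractions = fractions,
         temperature_K = temperature_K, label = as.character(label)),
    class = "release_profile", overshoot = overshoot
  )
}

#' @export
print.release_profile <- function(x, ...) {
  temp <- if (is.na(x$temperature_K)) "unknown temperature"
          else sprintf("%.2f K (%.1f degC)", x$temperature_K,
                       x$temperature_K - 273.15)
  cat(sprintf("Release profile%s: %d points over %.3g days at %s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), max(x$times), temp))
  invisible(x)
}

#' @export
as.data.frame.release_profile <- function(x, ...) {
  data.frame(time_days = x$times, fraction_released = x$fractions,
             temperature_C = x$temperature_K - 273.15)
}
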