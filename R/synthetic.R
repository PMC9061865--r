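# Synthetic release-profile generation: forward model evaluation plus an
# additive Gaussian measurement-noise layer, and the sampling-withdrawal
# mass-balance bookkeeping of a replenished dialysis release experiment.

#' Sampling schedule of a release experiment
#'
#' Describes when aliquots are taken from the incubation medium and the
#' volumes involved. The defaults mimic a dialysis release study in 30 mL
#' of buffer with 1 mL aliquots withdrawn and replenished at sampling times
#' spanning 0-27 days.
#'
#' @param sample_times sampling times in days, strictly increasing.
#' @param medium_volume_ml incubation-medium volume V (mL).
#' @param aliquot_volume_ml withdrawn (and replenished) volume v (mL);
#'   must satisfy `0 < v <= V`.
#' @param replenished whether each aliquot is replaced by fresh buffer.
#' @return an object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(sample_times = c(0.25, 0.5, 1:14, seq(16, 26, 2), 27),
                              medium_volume_ml = 30,
                              aliquot_volume_ml = 1,
                              replenished = TRUE) {
  sample_times <- as.numeric(sample_times)
  if (any(!is.finite(sample_times)) || any(sample_times < 0) ||
      any(diff(sample_times) <= 0))
    stop("'sample_times' must be non-negative and strictly increasing",
         call. = FALSE)
  if (aliquot_volume_ml <= 0 || aliquot_volume_ml > medium_volume_ml)
    stop("need 0 < aliquot_volume_ml <= medium_volume_ml", call. = FALSE)
  structure(
    list(sample_times = sample_times,
         medium_volume_ml = medium_volume_ml,
         aliquot_volume_ml = aliquot_volume_ml,
         replenished = isTRUE(replenished)),
    class = "sampling_schedule"
  )
}

#' Measurement-noise specification
#'
#' Additive iid Gaussian noise on the fraction scale. By default generated
#' fractions are truncated back into \[0, 1\] to keep profiles physically
#' valid; the number of clipped points is recorded on the output.
#'
#' @param sd noise standard deviation in fraction units, >= 0.
#' @param seed RNG seed; identical seeds give identical profiles.
#' @param truncate clip noisy fractions into \[0, 1\].
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0.01, seed = NULL, truncate = TRUE) {
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
    stop("'sd' must be a single non-negative number", call. = FALSE)
  structure(list(sd = sd, seed = seed, truncate = isTRUE(truncate)),
            class = "noise_spec")
}

#' Generate a synthetic release profile
#'
#' Evaluates the BR or BRD model on the sampling schedule and adds iid
#' Gaussian measurement noise: `fraction = model(t) + N(0, sd^2)`. With
#' `sd = 0` the output equals the model curve exactly. The generating
#' parameters are attached as attribute `"generating_params"`.
#'
#' @param params a [mechanism_params()] object.
#' @param model `"br"` or `"brd"`; defaults to the model of `params`.
#' @param schedule a [sampling_schedule()].
#' @param noise a [noise_spec()].
#' @param geom a [particle_geometry()] (BRD only).
#' @param temperature_K incubation temperature recorded on the profile.
#' @return a [release_profile()]; attribute `"n_truncated"` counts points
#'   clipped into \[0, 1\].
#' @examples
#' p <- mechanism_params(0.5567, 1.8053, 0.1109, 20.1849)
#' prof <- generate_profile(p, noise = noise_spec(sd = 0.01, seed = 1),
#'                          temperature_K = 310.15)
#' @export
generate_profile <- function(params, model = params$model,
                             schedule = sampling_schedule(),
                             noise = noise_spec(sd = 0),
                             geom = particle_geometry(),
                             temperature_K = NA_real_) {
  stopifnot(inherits(params, "mechanism_params"),
            inherits(schedule, "sampling_schedule"),
            inherits(noise, "noise_spec"))
  model <- match.arg(model, c("br", "brd"))
  if (model != params$model)
    stop("'model' does not match the model of 'params'", call. = FALSE)
  t <- schedule$sample_times
  clean <- release_model(t, params, geom)
  y <- if (noise$sd > 0) {
    with_seed(noise$seed, clean + stats::rnorm(length(t), 0, noise$sd))
  } else clean
  n_trunc <- 0L
  if (noise$truncate) {
    n_trunc <- sum(y < 0 | y > 1)
    y <- pmin(1, pmax(0, y))
  }
  prof <- release_profile(t, y, temperature_K = temperature_K,
                          label = sprintf("synthetic %s", model))
  attr(prof, "generating_params") <- params
  attr(prof, "n_truncated") <- n_trunc
  prof
}

#' Cumulative released mass from withdrawn-sample concentrations
#'
#' In a replenished sampling design each aliquot removes drug from the
#' medium, so the cumulative mass released by the k-th sampling time is
#' `M_k = V * C_k + v * sum_{i<k} C_i`: the mass currently in the medium
#' plus the mass carried away by the earlier aliquots.
#'
#' @param concentrations measured concentrations at the schedule's sampling
#'   times (mass per mL), non-negative.
#' @param schedule a replenished [sampling_schedule()].
#' @return cumulative released mass at each sampling time (same mass units).
#' @examples
#' sched <- sampling_schedule(sample_times = c(1, 2), medium_volume_ml = 30,
#'                            aliquot_volume_ml = 1)
#' withdrawal_mass_balance(c(1, 2), sched)  # c(30, 61)
#' @export
withdrawal_mass_balance <- function(concentrations, schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  if (!schedule$replenished)
    stop("mass balance implemented for replenished sampling only",
         call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("'concentrations' must be finite and non-negative", call. = FALSE)
  if (length(concentrations) != length(schedule$sample_times))
    stop("'concentrations' must match the schedule's sampling times",
         call. = FALSE)
  V <- schedule$medium_volume_ml
  v <- schedule$aliquot_volume_ml
  prior <- c(0, cumsum(concentrations))[seq_along(concentrations)]
  V * concentrations + v * prior
}

#' Invert the withdrawal mass balance
#'
#' Recovers the concentrations an experimenter would measure in successive
#' aliquots given the true cumulative released masses; the inverse of
#' [withdrawal_mass_balance()], used by the synthetic-data generator.
#'
#' @param cumulative_mass cumulative released mass at each sampling time.
#' @param schedule a replenished [sampling_schedule()].
#' @return measured concentrations (mass per mL).
#' @export
concentrations_from_mass <- function(cumulative_mass, schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  if (!schedule$replenished)
    stop("mass balance implemented for replenished sampling only",
         call. = FALSE)
  V <- schedule$medium_volume_ml
  v <- schedule$aliquot_volume_ml
  conc <- numeric(length(cumulative_mass))
  acc <- 0
  for (k in seq_along(cumulative_mass)) {
    conc[k] <- (cumulative_mass[k] - v * acc) / V
    acc <- acc + conc[k]
  }
  conc
}

#' Generate release profiles across several temperatures
#'
#' Composes the Arrhenius layer with the forward model: at each requested
#' temperature the rate parameters are evaluated from their Arrhenius laws,
#' combined with the supplied mechanism weights, and a profile is generated.
#' Per-temperature noise seeds are derived as `seed + index - 1` so the set
#' is reproducible from a single seed.
#'
#' @param laws named list of [arrhenius_law()] objects: `k_b`, `k_r`,
#'   `t_max`, and `D_e` for the BRD model.
#' @param weights either a named list of constants (`theta_b`, and `theta_r`
#'   for BRD) applied at every temperature, or a data.frame with column
#'   `temperature_K` plus the weight columns, matched row-wise to
#'   `temperatures_K`.
#' @param temperatures_K absolute temperatures (kelvin).
#' @param model `"br"` or `"brd"`.
#' @param schedule a [sampling_schedule()].
#' @param noise a [noise_spec()].
#' @param geom a [particle_geometry()].
#' @return a list of [release_profile()] objects, one per temperature, each
#'   carrying its generating [mechanism_params()] as an attribute.
#' @export
generate_multitemperature_set <- function(laws, weights, temperatures_K,
                                          model = c("br", "brd"),
                                          schedule = sampling_schedule(),
                                          noise = noise_spec(sd = 0),
                                          geom = particle_geometry()) {
  model <- match.arg(model)
  need <- if (model == "br") c("k_b", "k_r", "t_max")
          else c("k_b", "k_r", "t_max", "D_e")
  if (!all(need %in% names(laws)))
    stop("'laws' must contain Arrhenius laws named: ",
         paste(need, collapse = ", "), call. = FALSE)
  weight_at <- function(i, T_K) {
    if (is.data.frame(weights)) {
      j <- match(T_K, weights$temperature_K)
      if (is.na(j))
        stop("no weight row for temperature ", T_K, " K", call. = FALSE)
      as.list(weights[j, setdiff(names(weights), "temperature_K"), drop = FALSE])
    } else as.list(weights)
  }
  out <- vector("list", length(temperatures_K))
  for (i in seq_along(temperatures_K)) {
    T_K <- temperatures_K[i]
    w <- weight_at(i, T_K)
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
    noise_i <- if (is.null(noise$seed)) noise
               else noise_spec(noise$sd, noise$seed + i - 1L, noise$truncate)
    out[[i]] <- generate_profile(params, model, schedule, noise_i, geom,
                                 temperature_K = T_K)
  }
  names(out) <- sprintf("%.2fK", temperatures_K)
  out
}
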