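#' Nanoparticle geometry for the diffusion kernel
#'
#' Bundles the particle radius and the day-to-second conversion used by the
#' spherical diffusion series. The default radius is half the mean
#' hydrodynamic diameter of the PEGylated PLGA particles the models were
#' developed for (142 nm), i.e. 7.1e-6 cm.
#'
#' @param radius_cm particle radius r1 in cm; must be positive.
#' @param seconds_per_day unit conversion applied to times (given in days)
#'   before they meet the diffusivity (given in cm^2 s^-1).
#' @return an object of class `particle_geometry`.
#' @examples
#' particle_geometry()                 # default 142 nm particle
#' particle_geometry(radius_cm = 1e-5) # a 200 nm particle
#' @export
particle_geometry <- function(radius_cm = 7.1e-6, seconds_per_day = 86400) {
  if (!is.numeric(radius_cm) || length(radius_cm) != 1L || !is.finite(radius_cm) ||
      radius_cm <= 0) {
    stop("'radius_cm' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(seconds_per_day) || length(seconds_per_day) != 1L ||
      seconds_per_day <= 0) {
    stop("'seconds_per_day' must be a single positive number", call. = FALSE)
  }
  structure(
    list(radius_cm = radius_cm, seconds_per_day = seconds_per_day),
    class = "particle_geometry"
  )
}

#' @export
print.particle_geometry <- function(x, ...) {
  cat("Particle geometry: radius r1 =", format(x$radius_cm, digits = 4),
      "cm (", format(x$radius_cm * 2e7, digits = 4), "nm diameter )\n")
  invisible(x)
}

as_particle_geometry <- function(geom) {
  if (is.null(geom)) return(particle_geometry())
  if (inherits(geom, "particle_geometry")) return(geom)
  stop("'geom' must be a particle_geometry object", call. = FALSE)
}
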