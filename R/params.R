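#' Mechanism parameter set for the BR / BRD release models
#'
#' Collects the kinetic parameters of one release profile at one temperature.
#' For the two-stage BR model the burst weight `theta_b` fixes the
#' degradation-relaxation weight at `1 - theta_b`. For the three-stage BRD
#' model `theta_b` and `theta_r` are free on the simplex and the diffusion
#' weight is `theta_d = 1 - theta_b - theta_r`.
#'
#' @param theta_b fraction of release carried by the initial burst, in \[0,1\].
#' @param k_b first-order burst rate constant (day^-1), positive.
#' @param k_r degradation-relaxation rate constant (day^-1), positive.
#' @param t_max time at which the relaxation stage reaches half of its
#'   release (days), positive.
#' @param theta_r fraction carried by degradation-relaxation. Required for
#'   `model = "brd"`; for `"br"` it is forced to `1 - theta_b`.
#' @param D_e effective diffusion coefficient (cm^2 s^-1), non-negative.
#'   Required for `model = "brd"`.
#' @param model `"br"` or `"brd"`.
#' @return an object of class `mechanism_params`.
#' @examples
#' # BR parameters of the 37 degC reference fit
#' mechanism_params(theta_b = 0.5567, k_b = 1.8053, k_r = 0.1109,
#'                  t_max = 20.1849)
#' @export
mechanism_params <- function(theta_b, k_b, k_r, t_max,
                             theta_r = NULL, D_e = NULL,
                             model = if (is.null(D_e)) "br" else "brd") {
  model <- match.arg(model, c("br", "brd"))
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    x
  }
  theta_b <- num1(theta_b, "theta_b")
  k_b <- num1(k_b, "k_b"); k_r <- num1(k_r, "k_r"); t_max <- num1(t_max, "t_max")
  if (theta_b < 0 || theta_b > 1)
    stop("'theta_b' must lie in [0, 1]", call. = FALSE)
  if (k_b <= 0) stop("'k_b' must be positive", call. = FALSE)
  if (k_r <= 0) stop("'k_r' must be positive", call. = FALSE)
  if (t_max <= 0) stop("'t_max' must be positive", call. = FALSE)

  if (model == "br") {
    if (!is.null(theta_r) && abs(num1(theta_r, "theta_r") - (1 - theta_b)) > 1e-10)
      stop("for the BR model 'theta_r' is defined as 1 - theta_b", call. = FALSE)
    theta_r <- 1 - theta_b
    D_e <- NA_real_
  } else {
    if (is.null(theta_r) || is.null(D_e))
      stop("the BRD model requires both 'theta_r' and 'D_e'", call. = FALSE)
    theta_r <- num1(theta_r, "theta_r")
    D_e <- num1(D_e, "D_e")
    if (theta_r < 0 || theta_r > 1)
      stop("'theta_r' must lie in [0, 1]", call. = FALSE)
    if (theta_b + theta_r > 1 + 1e-12)
      stop("'theta_b' + 'theta_r' must not exceed 1", call. = FALSE)
    if (D_e < 0) stop("'D_e' must be non-negative", call. = FALSE)
  }
  structure(
    list(model = model, theta_b = theta_b, theta_r = theta_r,
         k_b = k_b, k_r = k_r, t_max = t_max, D_e = D_e),
    class = "mechanism_params"
  )
}

#' Diffusion weight implied by a parameter set
#'
#' @param params a [mechanism_params()] object.
#' @return `1 - theta_b - theta_r` (zero, up to rounding, for BR parameters).
#' @export
theta_d <- function(params) {
  stopifnot(inherits(params, "mechanism_params"))
  max(0, 1 - params$theta_b - params$theta_r)
}

#' @export
print.mechanism_params <- function(x, ...) {
  cat(sprintf("%s release parameters\n", toupper(x$model)))
  cat(sprintf("  theta_b = %.4f  k_b = %.4f /day\n", x$theta_b, x$k_b))
  cat(sprintf("  theta_r = %.4g  k_r = %.4f /day  t_max = %.4f day\n",
              x$theta_r, x$k_r, x$t_max))
  if (x$model == "brd")
    cat(sprintf("  theta_d = %.4g  D_e = %.4g cm^2/s\n", theta_d(x), x$D_e))
  invisible(x)
}
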