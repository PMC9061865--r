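# Independent brute-force oracle for the spherical diffusion kernel:
# method-of-lines finite-difference solution of the radial diffusion PDE
#   dC/dt = D (1/r^2) d/dr (r^2 dC/dr)
# with symmetry at the centre, C = 0 at the surface (sink) and a uniform
# initial concentration. Uses the substitution u = C * r, which turns the
# problem into the 1-D heat equation u_t = D u_rr on [0, r1] with
# u(0) = u(r1) = 0 and u(r, 0) = r, discretised on `n_shells` interior
# nodes and integrated with deSolve's stiff solver. The released fraction
# is 1 - integral(C r^2 dr) / integral(C0 r^2 dr).
fd_sphere_release <- function(times_days, D_e, radius_cm = 7.1e-6,
                              n_shells = 240L, seconds_per_day = 86400) {
  # dimensionless: rho in [0,1], tau = D t / r1^2
  tau <- D_e * times_days * seconds_per_day / radius_cm^2
  h <- 1 / (n_shells + 1)
  rho <- seq(h, 1 - h, length.out = n_shells)
  u0 <- rho  # C0 = 1
  rhs <- function(t, u, parms) {
    up <- c(u[-1], 0)        # u(1) = 0 (sink surface)
    um <- c(0, u[-n_shells]) # u(0) = 0 (symmetry via u = C r)
    list((up - 2 * u + um) / h^2)
  }
  # include tau = 0 for the initial state; deSolve needs increasing times
  sol <- deSolve::ode(y = u0, times = c(0, tau[tau > 0]), func = rhs,
                      parms = NULL, method = "lsoda",
                      jactype = "bandint", bandup = 1, banddown = 1,
                      rtol = 1e-10, atol = 1e-12)
  # mass remaining: integral of C rho^2 = integral of u rho over [0,1];
  # trapezoid including the u = 0 end points
  remaining <- apply(sol[, -1, drop = FALSE], 1L, function(u) {
    integrand <- c(0, u * rho, 0)
    grid <- c(0, rho, 1)
    sum(diff(grid) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  })
  m0 <- 1 / 3  # integral of rho^2 over [0,1]
  frac <- 1 - remaining / m0
  out <- numeric(length(tau))
  out[tau > 0] <- frac[-1]
  out[tau == 0] <- 0
  out
}
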