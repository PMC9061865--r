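# Shared test utilities.

rel_err <- function(est, true) abs(est - true) / abs(true)

# Reference per-temperature parameter values (duplicated from the packaged
# CSV tables so tests do not depend on the loader they also test).
REF_T_KELVIN <- c(310.15, 320.15, 330.15)

REF_BR <- list(
  k_b = c(1.8053, 2.2306, 2.7337),
  theta_b = c(0.5567, 0.5453, 0.6139),
  k_r = c(0.1109, 0.1924, 0.3198),
  t_max = c(20.1849, 9.5761, 5.1626)
)

REF_BRD <- list(
  k_b = c(2.5244, 3.9805, 4.9721),
  theta_b = c(0.4636, 0.3988, 0.3945),
  k_r = c(0.1274, 5.2914, 10.6848),
  t_max = c(27.2835, 13.1061, 8.5548),
  theta_r = c(0.2372, 0.0688, 2.6144e-9),
  D_e = c(3.4908e-18, 4.7670e-18, 9.2404e-18)
)

# Published Arrhenius constants (prefactor, Ea in kcal/mol).
REF_ARRHENIUS <- list(
  br = list(
    k_b = c(A = 1703.0412, ea = 4.2211),
    k_r = c(A = 4321997.7158, ea = 10.7711),
    t_max = c(A = 3.3883e-9, ea = -13.8709)
  ),
  brd = list(
    k_b = c(A = 182668.5606, ea = 6.8957),
    k_r = c(A = 7.22680605824739e30, ea = 45.0589),
    t_max = c(A = 1.3220e-7, ea = -11.7986),
    D_e = c(A = 3.3345e-11, ea = 9.9030)
  )
)

ref_br_params <- function(i) {
  mechanism_params(theta_b = REF_BR$theta_b[i], k_b = REF_BR$k_b[i],
                   k_r = REF_BR$k_r[i], t_max = REF_BR$t_max[i], model = "br")
}

ref_brd_params <- function(i) {
  mechanism_params(theta_b = REF_BRD$theta_b[i], theta_r = REF_BRD$theta_r[i],
                   k_b = REF_BRD$k_b[i], k_r = REF_BRD$k_r[i],
                   t_max = REF_BRD$t_max[i], D_e = REF_BRD$D_e[i],
                   model = "brd")
}
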