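test_that("adjusted R^2 follows the penalised formula", {
  expect_equal(adjusted_r_squared(0.95, n_dp = 10, p = 0), 0.95)
  expect_equal(adjusted_r_squared(1, n_dp = 12, p = 4), 1)
  expect_equal(adjusted_r_squared(0.9929, n_dp = 25, p = 4), 0.99148)
  expect_error(adjusted_r_squared(0.9, n_dp = 5, p = 4), "n_dp")
})

test_that("goodness_of_fit computes R^2 about the observed mean", {
  obs <- c(0.1, 0.3, 0.5, 0.6, 0.7, 0.8, 0.9)
  gof <- goodness_of_fit(obs, obs, p = 2)
  expect_equal(gof$r_squared, 1)
  expect_equal(gof$r_squared_adjusted, 1)
  pred <- obs + 0.05
  gof2 <- goodness_of_fit(obs, pred, p = 2)
  expect_equal(gof2$rss, 7 * 0.05^2, tolerance = 1e-12)
  expect_lt(gof2$r_squared_adjusted, gof2$r_squared)
  expect_error(goodness_of_fit(rep(0.5, 7), rep(0.4, 7), p = 2), "variance")
})

test_that("fit_br recovers noiseless generating parameters", {
  for (i in 1:3) {
    p <- ref_br_params(i)
    prof <- generate_profile(p, noise = noise_spec(sd = 0),
                             temperature_K = REF_T_KELVIN[i])
    fit <- fit_br(prof)
    expect_true(fit$converged)
    expect_lt(rel_err(fit$params$theta_b, p$theta_b), 1e-4)
    expect_lt(rel_err(fit$params$k_b, p$k_b), 1e-4)
    expect_lt(rel_err(fit$params$k_r, p$k_r), 1e-4)
    expect_lt(rel_err(fit$params$t_max, p$t_max), 1e-4)
    # best optimum beats every multistart initial point
    expect_true(all(fit$residual_sum_of_squares <=
                      attr(fit, "initial_objectives") + 1e-15))
  }
})

test_that("a pure-burst profile drives theta_b to its upper bound, flagged", {
  p <- mechanism_params(theta_b = 1, k_b = 2, k_r = 0.2, t_max = 10,
                        model = "br")
  prof <- generate_profile(p, noise = noise_spec(sd = 0))
  fit <- fit_br(prof)
  expect_gt(fit$params$theta_b, 1 - 1e-5)
  expect_true(fit$at_bound[["theta_b"]])
})

test_that("custom start lattices and seeded jitter behave deterministically", {
  p <- ref_br_params(2)
  prof <- generate_profile(p, noise = noise_spec(sd = 0.01, seed = 7),
                           temperature_K = REF_T_KELVIN[2])
  starts <- expand.grid(theta_b = c(0.3, 0.6), k_b = c(1, 3),
                        k_r = c(0.1, 0.5), t_max = c(5, 15))
  fit_a <- fit_br(prof, starts = starts)
  expect_true(all(fit_a$residual_sum_of_squares <=
                    attr(fit_a, "initial_objectives") + 1e-15))
  # the same jitter seed reproduces the same optimum; jitter leaves the
  # recovered parameters essentially unchanged on well-posed data
  fit_j1 <- fit_br(prof, jitter = 0.1, seed = 42)
  fit_j2 <- fit_br(prof, jitter = 0.1, seed = 42)
  expect_identical(fit_j1$params, fit_j2$params)
  expect_lt(rel_err(fit_j1$params$theta_b, fit_a$params$theta_b), 1e-4)
})

test_that("fit_brd recovers noiseless generating parameters (D_e in log space)", {
  p <- ref_brd_params(1)  # 37 degC: all parameters interior
  prof <- generate_profile(p, noise = noise_spec(sd = 0),
                           temperature_K = REF_T_KELVIN[1])
  fit <- fit_brd(prof)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$theta_b, p$theta_b), 1e-3)
  expect_lt(rel_err(fit$params$theta_r, p$theta_r), 1e-3)
  expect_lt(rel_err(fit$params$k_b, p$k_b), 1e-3)
  expect_lt(rel_err(fit$params$k_r, p$k_r), 1e-3)
  expect_lt(rel_err(fit$params$t_max, p$t_max), 1e-3)
  expect_lt(abs(log10(fit$params$D_e) - log10(p$D_e)), 1e-3)
  expect_false(any(fit$at_bound))
})

test_that("model nesting: theta_d = 0 makes fit_brd agree with fit_br", {
  pbr <- ref_br_params(1)
  pbrd <- mechanism_params(theta_b = pbr$theta_b, theta_r = 1 - pbr$theta_b,
                           k_b = pbr$k_b, k_r = pbr$k_r, t_max = pbr$t_max,
                           D_e = 1e-20, model = "brd")
  prof <- generate_profile(pbrd, noise = noise_spec(sd = 0))
  fbr <- fit_br(release_profile(prof$times, prof$fractions))
  fbrd <- fit_brd(prof)
  for (nm in c("theta_b", "k_b", "k_r", "t_max"))
    expect_lt(rel_err(fbrd$params[[nm]], fbr$params[[nm]]), 0.01)
  # the richer model can never fit worse
  expect_lte(fbrd$residual_sum_of_squares,
             fbr$residual_sum_of_squares + 1e-12)
})

test_that("adding the diffusion mechanism never lowers R^2 on the same data", {
  p <- ref_brd_params(2)
  prof <- generate_profile(p, noise = noise_spec(sd = 0.01, seed = 11),
                           temperature_K = REF_T_KELVIN[2])
  fbr <- fit_br(prof)
  fbrd <- fit_brd(prof)
  expect_gte(fbrd$r_squared, fbr$r_squared - 1e-12)
  expect_lte(fbrd$r_squared_adjusted, fbrd$r_squared)
  expect_lte(fbr$r_squared_adjusted, fbr$r_squared)
})

test_that("fits fail informatively on degenerate input", {
  expect_error(fit_br(release_profile(c(0, 1, 2), c(0, 0.2, 0.4))),
               "at least 6")
  expect_error(
    fit_brd(release_profile(c(0, 1, 2, 3, 4, 5, 6),
                            c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6))),
    "at least 8")
})
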