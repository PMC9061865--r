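test_that("burst kernel matches the first-order law and its limits", {
  expect_identical(burst_fraction(0, 1.8053), 0)
  expect_equal(burst_fraction(1, 1.8053), 1 - exp(-1.8053), tolerance = 1e-12)
  expect_equal(burst_fraction(1, 1.8053), 0.8355749, tolerance = 1e-6)
  expect_equal(burst_fraction(1e4, 0.5), 1, tolerance = 1e-12)
  # nondecreasing everywhere, strictly increasing until double-precision
  # saturation at 1
  t <- seq(0, 50, 0.1)
  f <- burst_fraction(t, 1.8053)
  expect_true(all(diff(f) >= 0))
  unsat <- f[-1] < 1 - 1e-12
  expect_true(all(diff(f)[unsat] > 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(burst_fraction(-1, 1), "non-negative")
  expect_error(burst_fraction(1, 0), "positive")
})

test_that("degradation kernel is the Prout-Tompkins logistic with midpoint t_max", {
  expect_identical(degradation_fraction(20.1849, 0.1109, 20.1849), 0.5)
  expect_equal(degradation_fraction(0, 0.1109, 20.1849),
               1 / (1 + exp(0.1109 * 20.1849)), tolerance = 1e-12)
  expect_equal(degradation_fraction(0, 0.1109, 20.1849), 0.0963456,
               tolerance = 1e-6)
  expect_equal(degradation_fraction(1e4, 0.3, 5), 1, tolerance = 1e-12)
  # linearised form: ln(x/(1-x)) linear in t with slope k_r
  t <- c(2, 7, 19)
  x <- degradation_fraction(t, 0.25, 9)
  expect_equal(diff(log(x / (1 - x))) / diff(t), c(0.25, 0.25),
               tolerance = 1e-12)
  expect_error(degradation_fraction(1, -1, 5), "positive")
  expect_error(degradation_fraction(1, 1, 0), "positive")
})

test_that("diffusion kernel matches the sphere series solution", {
  expect_identical(diffusion_fraction(0, 3.4908e-18), 0)
  expect_equal(diffusion_fraction(5, 3.4908e-18), 0.4957482,
               tolerance = 1e-6)
  expect_equal(diffusion_fraction(1e5, 3.4908e-18), 1, tolerance = 1e-12)
  # D_e = 0: nothing ever diffuses out
  expect_identical(diffusion_fraction(c(0, 5, 27), 0), c(0, 0, 0))
  # monotone nondecreasing on a dense grid for all reference diffusivities
  t <- seq(0, 27, 0.05)
  for (De in REF_BRD$D_e) {
    f <- diffusion_fraction(t, De)
    expect_true(all(diff(f) >= -1e-15))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("diffusion truncation is adaptive and convergent", {
  t <- c(0.01, 0.1, 1, 5)
  for (tol in c(1e-6, 1e-8, 1e-10)) {
    a <- diffusion_fraction(t, 3.4908e-18, tol = tol)
    b <- diffusion_fraction(t, 3.4908e-18, tol = tol / 2)
    expect_true(all(abs(a - b) < tol))
  }
  # cap reached at extremely small dimensionless time -> warning
  expect_warning(diffusion_fraction(1e-7, 3.4908e-18, max_terms = 100L),
                 "max_terms")
})

test_that("diffusion kernel follows the early-time square-root law", {
  geom <- particle_geometry()
  # tau < 1e-3: Mt/Minf ~ 6 sqrt(tau/pi) - 3 tau to < 1% relative
  taus <- 10^seq(-5, -3, 0.25)
  De <- 3.4908e-18
  t_days <- taus * geom$radius_cm^2 / (De * geom$seconds_per_day)
  series <- diffusion_fraction(t_days, De, geom)
  early <- 6 * sqrt(taus / pi) - 3 * taus
  expect_true(all(rel_err(series, early) < 0.01))
})

test_that("BR model is the convex combination of burst and relaxation", {
  p <- ref_br_params(1)  # 37 degC
  expect_equal(br_model(0, p), 0.4433 * degradation_fraction(0, p$k_r, p$t_max),
               tolerance = 1e-12)
  expect_equal(br_model(0, p), 0.0427, tolerance = 1e-3)
  # at t = t_max the burst is saturated (k_b * t ~ 36): theta_b + (1-theta_b)/2
  expect_equal(br_model(20.1849, p), 0.7784, tolerance = 1e-4)
  expect_equal(br_model(1e4, p), 1, tolerance = 1e-12)
})

test_that("BRD model respects the weight simplex and its degenerate cases", {
  p57 <- ref_brd_params(3)  # theta_r ~ 2.6e-9, theta_d ~ 0.6055
  t <- seq(0, 27, 0.25)
  expect_equal(theta_d(p57), 1 - 0.3945 - 2.6144e-9, tolerance = 1e-12)
  manual <- p57$theta_b * burst_fraction(t, p57$k_b) +
    p57$theta_r * degradation_fraction(t, p57$k_r, p57$t_max) +
    theta_d(p57) * diffusion_fraction(t, p57$D_e)
  expect_equal(brd_model(t, p57), manual, tolerance = 1e-12)
  # theta_b = 1: reduces to the pure burst kernel
  pure <- mechanism_params(theta_b = 1, theta_r = 0, k_b = 2, k_r = 0.2,
                           t_max = 5, D_e = 1e-18, model = "brd")
  expect_equal(brd_model(t, pure), burst_fraction(t, 2), tolerance = 1e-12)
  # at t = 0 only the relaxation term contributes
  p37 <- ref_brd_params(1)
  expect_equal(brd_model(0, p37),
               p37$theta_r * degradation_fraction(0, p37$k_r, p37$t_max),
               tolerance = 1e-12)
  expect_error(mechanism_params(theta_b = 0.7, theta_r = 0.5, k_b = 1,
                                k_r = 1, t_max = 1, D_e = 1e-18,
                                model = "brd"),
               "exceed")
})

test_that("BRD with theta_d = 0 reduces exactly to BR", {
  for (i in 1:3) {
    pbr <- ref_br_params(i)
    pbrd <- mechanism_params(theta_b = pbr$theta_b, theta_r = 1 - pbr$theta_b,
                             k_b = pbr$k_b, k_r = pbr$k_r, t_max = pbr$t_max,
                             D_e = 1e-18, model = "brd")
    t <- seq(0, 27, 0.5)
    expect_equal(brd_model(t, pbrd), br_model(t, pbr), tolerance = 1e-14)
  }
})

test_that("all model curves stay in [0,1] and are nondecreasing in time", {
  t <- seq(0, 60, 0.1)
  cases <- c(lapply(1:3, ref_br_params), lapply(1:3, ref_brd_params))
  for (p in cases) {
    f <- release_model(t, p)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("mechanism decomposition sums exactly to the model curve", {
  t <- seq(0, 27, 0.5)
  p <- ref_br_params(1)
  dec <- mechanism_contributions(t, p)
  expect_identical(unname(attr(dec, "weights")[c("burst", "degradation")]),
                   c(0.5567, 0.4433))
  expect_identical(dec$total, br_model(t, p))
  p2 <- ref_brd_params(2)  # 47 degC: weights (0.3988, 0.0688, 0.5324)
  dec2 <- mechanism_contributions(t, p2)
  expect_equal(unname(attr(dec2, "weights")),
               c(0.3988, 0.0688, 0.5324), tolerance = 1e-10)
  expect_identical(dec2$total, brd_model(t, p2))
})
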