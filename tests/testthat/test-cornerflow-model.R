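test_that("Concus-Finn predictions match the observed corner pattern", {
  p30 <- concus_finn_flow(30, 60)
  expect_identical(p30$flows, "yes")
  expect_equal(p30$margin, 15)
  p90 <- concus_finn_flow(90, 60)
  expect_identical(p90$flows, "no")
  expect_equal(p90$margin, -15)
  expect_identical(concus_finn_flow(60, 60, tolerance = 1)$flows, "marginal")
  expect_identical(concus_finn_flow(50, 60)$flows, "yes")
  expect_identical(concus_finn_flow(120, 60)$flows, "no")
  expect_error(concus_finn_flow(200, 60), class = "cf_invalid_parameter")
  expect_error(concus_finn_flow(30, -5), class = "cf_invalid_parameter")
})

test_that("critical corner angle follows 2 * (90 - theta_min), floored at 0", {
  expect_equal(critical_corner_angle(60), 60)
  expect_equal(critical_corner_angle(90), 0)
  expect_equal(critical_corner_angle(0), 180)
  expect_equal(critical_corner_angle(120), 0)
  expect_error(critical_corner_angle(-1), class = "cf_invalid_parameter")
})

test_that("flow prediction and critical angle are mutually consistent", {
  # flows == yes  <=>  alpha < alpha_th(theta), exactly at tolerance 0
  for (theta in seq(0, 85, by = 5)) {
    ath <- critical_corner_angle(theta)
    for (alpha in seq(5, 175, by = 10)) {
      flows <- concus_finn_flow(alpha, theta, tolerance = 0)$flows
      expect_identical(flows == "yes", alpha < ath,
                       label = sprintf("alpha=%g theta=%g", alpha, theta))
    }
  }
})

test_that("maximum rise height reproduces the capillary balance", {
  f <- fluid_properties(1000, 0.030, 60, 9.81)
  h <- max_rise_height(f, corner_spec(30, 225e-6))
  expect_equal(h, 2 * 0.030 * cos(pi / 3) / (1000 * 9.81 * 225e-6),
               tolerance = 1e-12)
  # non-wetting liquid does not rise
  expect_identical(max_rise_height(fluid_properties(1000, 0.030, 90),
                                   corner_spec(30, 225e-6)), 0)
  expect_identical(max_rise_height(fluid_properties(1000, 0.030, 135),
                                   corner_spec(30, 225e-6)), 0)
  # h ~ 1/d
  h2 <- max_rise_height(f, corner_spec(30, 450e-6))
  expect_equal(h / h2, 2, tolerance = 1e-12)
  expect_error(corner_spec(30, -1e-6), class = "cf_invalid_parameter")
})

test_that("h_max is decreasing in theta and d, linear in gamma", {
  d <- 225e-6
  hs <- vapply(seq(0, 85, by = 5), function(th)
    max_rise_height(fluid_properties(1000, 0.030, th), corner_spec(30, d)),
    numeric(1))
  expect_true(all(diff(hs) < 0))
  gaps <- seq(100e-6, 500e-6, by = 50e-6)
  hd <- vapply(gaps, function(dd)
    max_rise_height(fluid_properties(1000, 0.030, 60), corner_spec(30, dd)),
    numeric(1))
  expect_true(all(diff(hd) < 0))
  h1 <- max_rise_height(fluid_properties(1000, 0.020, 60), corner_spec(30, d))
  h3 <- max_rise_height(fluid_properties(1000, 0.060, 60), corner_spec(30, d))
  expect_equal(h3 / h1, 3, tolerance = 1e-12)
})

test_that("critical concentration brackets the wetting transition", {
  g <- gen_concentration_series() # theta crosses 75 deg between 1e-4 and 3e-4 M
  cstar <- crossing_concentration(g$truth, 75)
  expect_true(cstar > 1e-4 && cstar < 3e-4)
  br <- critical_concentration(g$series, alpha = 30)
  expect_false(br$none)
  expect_equal(br$c_low, 1e-4)
  expect_equal(br$c_high, 3e-4)

  never <- surfactant_series(c(1e-5, 1e-4, 1e-3), rep(0.05, 3), rep(120, 3))
  expect_true(critical_concentration(never, 30)$none)

  always <- surfactant_series(c(1e-5, 1e-4, 1e-3), rep(0.03, 3), rep(40, 3))
  ba <- critical_concentration(always, 30)
  expect_true(ba$below_range)
  expect_equal(ba$c_high, 1e-5)
})

test_that("bracket is invariant to grid refinement preserving its endpoints", {
  coarse <- gen_concentration_series(
    concentrations = c(1e-5, 1e-4, 3e-4, 1e-3))
  fine <- gen_concentration_series(
    concentrations = c(1e-5, 2e-5, 5e-5, 1e-4, 3e-4, 5e-4, 1e-3))
  b1 <- critical_concentration(coarse$series, 30)
  b2 <- critical_concentration(fine$series, 30)
  expect_equal(b1$c_low, b2$c_low)
  expect_equal(b1$c_high, b2$c_high)
})

test_that("surfactant series validate and round-trip through CSV", {
  expect_error(surfactant_series(c(1e-4, 1e-5), c(0.07, 0.03), c(100, 60)),
               class = "cf_invalid_input")
  expect_error(surfactant_series(c(1e-5, 1e-4), c(0.07, -0.03), c(100, 60)),
               class = "cf_invalid_input")
  s <- gen_concentration_series(noise_theta_deg = 1, noise_gamma = 1e-3,
                                seed = 8)$series
  path <- withr::local_tempfile(fileext = ".csv")
  write_surfactant_series(s, path)
  back <- read_surfactant_series(path)
  expect_equal(back$theta_deg, s$theta_deg, tolerance = 1e-9)
  expect_equal(back$concentration_M, s$concentration_M, tolerance = 1e-12)
})
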