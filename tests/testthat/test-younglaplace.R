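test_that("zero-Bond profile is the analytic sphere", {
  b <- 1e-3
  p <- integrate_drop_profile(bond = 0, apex_radius = b, arc_length_max = 3e-3)
  expect_identical(c(p$x[1], p$z[1]), c(0, 0))
  expect_true(all(p$x >= 0))
  # circle of radius b centred one apex radius up the axis
  dev <- abs(sqrt(p$x^2 + (p$z - b)^2) - b)
  expect_lt(max(dev), 1e-6)
})

test_that("integration agrees with a 10x finer-step oracle", {
  b <- 1e-3
  coarse <- integrate_drop_profile(0.3, b, 3e-3, step = b / 200)
  fine <- integrate_drop_profile(0.3, b, 3e-3, step = b / 2000)
  # every coarse node coincides with every 10th fine node
  idx <- seq(1, length(coarse$x)) * 10L - 9L
  expect_lt(max(abs(coarse$x - fine$x[idx])), 1e-7)
  expect_lt(max(abs(coarse$z - fine$z[idx])), 1e-7)
})

test_that("pendant gravity widens the profile relative to the sphere", {
  b <- 1e-3
  sph <- integrate_drop_profile(0, b, 2.2e-3)
  pen <- integrate_drop_profile(0.3, b, 2.2e-3, orientation = "pendant")
  zq <- seq(0.2e-3, 0.9e-3, by = 0.1e-3)
  xs <- approx(sph$z, sph$x, zq)$y
  xp <- approx(pen$z, pen$x, zq)$y
  expect_true(all(xp > xs))
})

test_that("integrator rejects bad geometry and flags closed profiles", {
  expect_error(integrate_drop_profile(-0.1, 1e-3, 3e-3),
               class = "cf_invalid_parameter")
  expect_error(integrate_drop_profile(0.3, 0, 3e-3),
               class = "cf_invalid_parameter")
  expect_error(integrate_drop_profile(0.3, 1e-3, 1e-6),
               class = "cf_invalid_parameter")
  # a long enough sessile arc closes: phi reaches pi and truncation is flagged
  closed <- integrate_drop_profile(0.5, 1e-3, 8e-3, orientation = "sessile")
  expect_true(closed$truncated)
  # a heavy pendant drop stops at the neck instead of curling back
  neck <- integrate_drop_profile(1.4, 1.5e-3, 8e-3, orientation = "pendant")
  expect_true(neck$truncated)
  expect_true(all(diff(neck$z) >= -1e-12))
})

test_that("drop_profile enforces its invariants", {
  expect_error(drop_profile(c(0.1, 0.2), c(0, 1e-3)),
               class = "cf_invalid_input")
  expect_error(drop_profile(c(0, -0.2e-3), c(0, 1e-3)),
               class = "cf_invalid_input")
  expect_error(drop_profile(c(0, 1e-4, 2e-4), c(0, 2e-3, 1e-3),
                            orientation = "pendant"),
               class = "cf_invalid_input")
})

test_that("noiseless round trip recovers surface tension within 0.5%", {
  # acceptance covers the full 9-point grid; spot-check the corners here
  for (b in c(0.8e-3, 1.6e-3)) {
    for (gamma in c(0.025, 0.072)) {
      tr <- make_pendant_truth(gamma, b)
      fit <- fit_pendant_profile(tr, water$drho, water$g)
      expect_true(fit$converged)
      expect_lt(abs(fit$surface_tension - gamma) / gamma, 0.005)
      expect_lt(abs(fit$apex_radius - b) / b, 0.005)
    }
  }
})

test_that("seeded 2-um edge noise keeps recovery within 3%", {
  gamma <- 0.030; b <- 1.5e-3
  tr <- make_pendant_truth(gamma, b)
  noisy <- jitter_profile_x(tr, 2e-6, seed = 11)
  fit <- fit_pendant_profile(noisy, water$drho, water$g)
  expect_lt(abs(fit$surface_tension - gamma) / gamma, 0.03)
})

test_that("fit is scale-equivariant: b ~ k, gamma ~ k^2, Bond invariant", {
  gamma <- 0.045; b <- 1.2e-3; k <- 1.5
  tr <- make_pendant_truth(gamma, b)
  fit1 <- fit_pendant_profile(tr, water$drho, water$g)
  scaled <- drop_profile(tr$x * k, tr$z * k)
  fit2 <- fit_pendant_profile(scaled, water$drho, water$g)
  expect_equal(fit2$apex_radius / fit1$apex_radius, k, tolerance = 0.005)
  expect_equal(fit2$surface_tension / fit1$surface_tension, k^2,
               tolerance = 0.01)
  expect_equal(fit2$bond, fit1$bond, tolerance = 0.01)
})

test_that("returned optimum never exceeds the initialisation residual", {
  gamma <- 0.030; b <- 1.5e-3
  noisy <- jitter_profile_x(make_pendant_truth(gamma, b), 2e-6, seed = 3)
  # deliberately poor starting point
  bad_init <- pendant_fit(0.05, b * 1.3, 0.4, rmse = 0, converged = FALSE)
  fit <- fit_pendant_profile(noisy, water$drho, water$g, init = bad_init)
  obs <- cbind(noisy$x, noisy$z)
  s_max <- sum(sqrt(diff(noisy$x)^2 + diff(noisy$z)^2)) * 1.02
  resid_at <- function(b, bond) {
    m <- integrate_drop_profile(bond, b, s_max, step = b / 200)
    mean(cornerflow:::min_dist_to_polyline(obs[, 1], obs[, 2], m$x, m$z))
  }
  expect_lte(resid_at(fit$apex_radius, fit$bond),
             resid_at(bad_init$apex_radius, bad_init$bond))
})

test_that("degenerate profiles are rejected", {
  tr <- make_pendant_truth(0.072, 1.5e-3)
  short <- drop_profile(tr$x[1:10], tr$z[1:10])
  expect_error(fit_pendant_profile(short, 1000),
               class = "cf_insufficient_profile")
  line <- drop_profile(rep(0, 30), seq(0, 3e-3, length.out = 30))
  expect_error(fit_pendant_profile(line, 1000),
               class = "cf_insufficient_profile")
  expect_error(fit_pendant_profile(tr, -5), class = "cf_invalid_parameter")
})

test_that("profiles round-trip through CSV", {
  tr <- make_pendant_truth(0.045, 1.2e-3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_drop_profile(tr, path)
  back <- read_drop_profile(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_equal(back$z, tr$z, tolerance = 1e-12)
})
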