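#' Ground-truth record for a synthetic artifact
#'
#' Every generator returns, alongside its artifact, a `synthetic_truth`
#' carrying the generator parameters, the seed, and the ground-truth
#' quantity the artifact encodes. Identical seed and parameters produce
#' bit-identical artifacts.
#'
#' @param kind Generator name.
#' @param params Named list of generator parameters.
#' @param seed Integer seed used.
#' @param truth Named list of ground-truth quantities.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(kind, params, seed, truth) {
  structure(list(kind = kind, params = params, seed = as.integer(seed),
                 truth = truth),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s (seed %d): %s\n", x$kind, x$seed,
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

#' Write / read a synthetic truth record as JSON
#'
#' @param truth A [synthetic_truth()].
#' @param path File path.
#' @return `read_synthetic_truth` returns a [synthetic_truth()].
#' @export
write_synthetic_truth <- function(truth, path) {
  cf_assert(inherits(truth, "synthetic_truth"), "cf_invalid_input",
            "truth must be a synthetic_truth")
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_truth
#' @export
read_synthetic_truth <- function(path) {
  cf_assert(file.exists(path), "cf_invalid_input",
            paste("no such truth file:", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(x$kind, x$params, x$seed, x$truth)
}

# Fill one raster row with a dark span [el, er] (fractional column units,
# pixel c spans [c - 0.5, c + 0.5]) using exact area coverage, so that
# linear-interpolation edge extraction recovers el and er to sub-pixel
# precision.
fill_row_coverage <- function(ncol, el, er, bg, fg) {
  cols <- seq_len(ncol)
  f <- pmin(cols + 0.5, er) - pmax(cols - 0.5, el)
  f <- pmin(pmax(f, 0), 1)
  bg + (fg - bg) * f
}

#' Render a synthetic pendant-drop image
#'
#' Integrates the axisymmetric Young-Laplace pendant shape for the requested
#' surface tension and apex radius, rasterises it as a filled dark-on-light
#' silhouette (apex down) with exact-coverage anti-aliasing, and optionally
#' jitters the edge position of every row by seeded Gaussian noise.
#'
#' @param gamma Surface tension (N/m).
#' @param density_difference Delta-rho (kg/m^3), default 1000.
#' @param apex_radius Apex radius b (m), default 1.5 mm.
#' @param calibration Length per pixel (m/px), default 5 um/px.
#' @param noise_sigma_px Gaussian edge jitter, standard deviation in pixels.
#' @param seed Integer seed.
#' @param gravity g (m/s^2).
#' @param arc_factor Arc length integrated, in units of `apex_radius`
#'   (default 3).
#' @param margin_px Background margin around the silhouette.
#' @return `list(image = drop_image, truth = synthetic_truth)`.
#' @export
gen_pendant_image <- function(gamma, density_difference = 1000,
                              apex_radius = 1.5e-3, calibration = 5e-6,
                              noise_sigma_px = 0, seed = 1, gravity = 9.81,
                              arc_factor = 3, margin_px = 20L) {
  cf_assert(is_number(gamma) && gamma > 0 && is_number(density_difference) &&
              density_difference > 0 && is_number(apex_radius) &&
              apex_radius > 0 && is_number(calibration) && calibration > 0,
            "cf_invalid_parameter",
            "physical generator parameters must be positive")
  bond <- density_difference * gravity * apex_radius^2 / gamma
  if (bond >= 1.5)
    cf_error("cf_infeasible_drop", sprintf(
      "implied Bond number %.3g >= 1.5: drop would detach from the needle",
      bond))
  prof <- integrate_drop_profile(bond, apex_radius,
                                 arc_length_max = arc_factor * apex_radius,
                                 step = apex_radius / 400,
                                 orientation = "pendant")
  if (prof$truncated)
    cf_error("cf_infeasible_drop", "profile closed before the needle plane")
  zmax <- max(prof$z); xmax <- max(prof$x)
  nrow_img <- ceiling(zmax / calibration) + 2L * margin_px
  ncol_img <- 2L * ceiling(xmax / calibration) + 2L * margin_px
  axis_col <- (ncol_img + 1) / 2
  apex_row <- nrow_img - margin_px
  bg <- 0.9; fg <- 0.1
  img <- matrix(bg, nrow_img, ncol_img)
  rows <- seq.int(apex_row - floor(zmax / calibration), apex_row)
  zr <- (apex_row - rows) * calibration
  w_px <- approx(prof$z, prof$x, xout = zr, rule = 2)$y / calibration
  withr::with_seed(seed, {
    jl <- rnorm(length(rows), 0, noise_sigma_px)
    jr <- rnorm(length(rows), 0, noise_sigma_px)
  })
  for (i in seq_along(rows)) {
    if (w_px[i] <= 0) next
    img[rows[i], ] <- fill_row_coverage(ncol_img,
                                        axis_col - w_px[i] + jl[i],
                                        axis_col + w_px[i] + jr[i], bg, fg)
  }
  truth <- synthetic_truth(
    "pendant_image",
    params = list(gamma = gamma, density_difference = density_difference,
                  apex_radius = apex_radius, calibration = calibration,
                  noise_sigma_px = noise_sigma_px, gravity = gravity,
                  arc_factor = arc_factor),
    seed = seed,
    truth = list(gamma = gamma, bond = bond, apex_row = apex_row,
                 axis_col = axis_col))
  list(image = drop_image(img, calibration), truth = truth)
}

#' Render a synthetic sessile-drop (spherical cap) image
#'
#' Rasterises a spherical cap meeting a rendered substrate at exactly the
#' requested contact angle, dark-on-light, with exact-coverage edges and
#' optional seeded Gaussian edge jitter. The substrate appears as a dark
#' band whose top row is the baseline.
#'
#' @param theta Contact angle (degrees, in `[5, 175]`).
#' @param cap_base_radius Contact-line radius a (m), default 1 mm.
#' @param calibration Length per pixel (m/px), default 4 um/px.
#' @param noise_sigma_px Gaussian edge jitter (pixels).
#' @param seed Integer seed.
#' @param substrate_rows Thickness of the rendered substrate (rows).
#' @param margin_px Background margin.
#' @return `list(image = drop_image, truth = synthetic_truth)`; the truth
#'   records `theta` and `baseline_row`.
#' @export
gen_sessile_image <- function(theta, cap_base_radius = 1e-3,
                              calibration = 4e-6, noise_sigma_px = 0,
                              seed = 1, substrate_rows = 12L,
                              margin_px = 20L) {
  cf_assert(is_number(theta) && theta >= 5 && theta <= 175,
            "cf_invalid_parameter", "theta must lie in [5, 175] degrees")
  cf_assert(is_number(cap_base_radius) && cap_base_radius > 0 &&
              is_number(calibration) && calibration > 0,
            "cf_invalid_parameter", "geometry parameters must be positive")
  th <- deg2rad(theta)
  r_sph <- cap_base_radius / sin(th)
  centre <- -r_sph * cos(th)       # sphere centre height above the baseline
  h_top <- centre + r_sph          # cap apex height
  wmax <- if (theta <= 90) cap_base_radius else r_sph
  ncol_img <- 2L * ceiling(wmax / calibration) + 2L * margin_px
  axis_col <- (ncol_img + 1) / 2
  baseline_row <- ceiling(h_top / calibration) + margin_px + 1L
  nrow_img <- baseline_row + substrate_rows - 1L
  bg <- 0.9; fg <- 0.1
  img <- matrix(bg, nrow_img, ncol_img)
  img[baseline_row:nrow_img, ] <- fg
  rows <- seq_len(baseline_row - 1L)
  h <- (baseline_row - 0.5 - rows) * calibration
  inside <- h <= h_top & r_sph^2 - (h - centre)^2 > 0
  w_px <- sqrt(pmax(r_sph^2 - (h - centre)^2, 0)) / calibration
  withr::with_seed(seed, {
    jl <- rnorm(length(rows), 0, noise_sigma_px)
    jr <- rnorm(length(rows), 0, noise_sigma_px)
  })
  for (i in which(inside)) {
    img[rows[i], ] <- fill_row_coverage(ncol_img,
                                        axis_col - w_px[i] + jl[i],
                                        axis_col + w_px[i] + jr[i], bg, fg)
  }
  truth <- synthetic_truth(
    "sessile_image",
    params = list(theta = theta, cap_base_radius = cap_base_radius,
                  calibration = calibration, noise_sigma_px = noise_sigma_px),
    seed = seed,
    truth = list(theta = theta, baseline_row = baseline_row,
                 axis_col = axis_col, sphere_radius = r_sph))
  list(image = drop_image(img, calibration, baseline_row = baseline_row),
       truth = truth)
}

# Ramp-plateau trajectory: zero before t_start, linear rise to h_max at
# t_end, flat after. The smooth variant is a logistic centred mid-rise.
truth_trajectory <- function(times, h_max, t_start, t_end,
                             shape = c("ramp", "logistic")) {
  shape <- match.arg(shape)
  if (shape == "ramp") {
    pmin(pmax(times - t_start, 0) * h_max / (t_end - t_start), h_max)
  } else {
    k <- 8 / (t_end - t_start)
    h_max * stats::plogis(k * (times - (t_start + t_end) / 2))
  }
}

#' Generate a synthetic corner-flow time-lapse stack
#'
#' Emulates a fluorescence time-lapse of a corner chamber: a bright liquid
#' reservoir below the initial level and a bright corner-flow wedge whose
#' tip follows a ramp-plateau trajectory (zero until `t_start`, monotone
#' rise, plateau at `h_max` by `t_end`), plus seeded Gaussian intensity
#' noise. `h_max = 0` emulates a surfactant-deficient mutant that never
#' flows.
#'
#' @param h_max Plateau height (m, >= 0).
#' @param t_start,t_end Flow onset and plateau times (hours,
#'   `t_start < t_end <= total_hours`).
#' @param total_hours Total duration (hours), default 24.
#' @param frame_interval_min Frame interval (minutes), default 2.
#' @param corner_alpha Corner opening angle label (degrees); metadata only.
#' @param calibration Length per pixel (m/px), default 30 um/px.
#' @param noise_sigma Intensity noise standard deviation (fraction of full
#'   scale), default 0.02.
#' @param seed Integer seed.
#' @param shape `"ramp"` (default) or `"logistic"` trajectory.
#' @param ncol_px Frame width (columns), default 40.
#' @param reservoir_rows Rows of liquid below the initial level, default 20.
#' @param wedge_halfwidth_px Half-width of the bright wedge (columns).
#' @return `list(frames, times_h, corner_roi, baseline_row, calibration,
#'   truth)`; `truth$truth` records the full trajectory.
#' @export
gen_corner_timelapse <- function(h_max = 9e-3, t_start = 8, t_end = 15,
                                 total_hours = 24, frame_interval_min = 2,
                                 corner_alpha = 30, calibration = 3e-5,
                                 noise_sigma = 0.02, seed = 1,
                                 shape = c("ramp", "logistic"),
                                 ncol_px = 40L, reservoir_rows = 20L,
                                 wedge_halfwidth_px = 2L) {
  shape <- match.arg(shape)
  cf_assert(is_number(h_max) && h_max >= 0, "cf_invalid_parameter",
            "h_max must be >= 0")
  cf_assert(is_number(t_start) && is_number(t_end) && is_number(total_hours) &&
              t_start < t_end && t_end <= total_hours && t_start >= 0,
            "cf_invalid_parameter",
            "need 0 <= t_start < t_end <= total_hours")
  cf_assert(is_number(frame_interval_min) && frame_interval_min > 0,
            "cf_invalid_parameter", "frame_interval_min must be > 0")
  cf_assert(is_number(calibration) && calibration > 0, "cf_invalid_parameter",
            "calibration must be > 0")
  times <- seq(0, total_hours, by = frame_interval_min / 60)
  traj <- truth_trajectory(times, h_max, t_start, t_end, shape)
  headroom <- ceiling(max(h_max, 1e-3) * 1.15 / calibration)
  nrow_img <- headroom + reservoir_rows + 5L
  baseline_row <- nrow_img - reservoir_rows + 1L
  centre <- ceiling(ncol_px / 2)
  wedge_cols <- seq.int(max(1L, centre - wedge_halfwidth_px),
                        min(ncol_px, centre + wedge_halfwidth_px))
  bg <- 0.05; fluo <- 0.85
  frames <- vector("list", length(times))
  withr::with_seed(seed, {
    for (i in seq_along(times)) {
      fr <- matrix(bg, nrow_img, ncol_px)
      fr[baseline_row:nrow_img, ] <- fluo
      tip_rows <- ceiling(baseline_row - traj[i] / calibration)
      if (tip_rows < baseline_row)
        fr[tip_rows:(baseline_row - 1L), wedge_cols] <- fluo
      if (noise_sigma > 0) {
        fr <- fr + matrix(rnorm(length(fr), 0, noise_sigma),
                          nrow_img, ncol_px)
        fr <- pmin(pmax(fr, 0), 1)
      }
      frames[[i]] <- fr
    }
  })
  truth <- synthetic_truth(
    "corner_timelapse",
    params = list(h_max = h_max, t_start = t_start, t_end = t_end,
                  total_hours = total_hours,
                  frame_interval_min = frame_interval_min,
                  corner_alpha = corner_alpha, calibration = calibration,
                  noise_sigma = noise_sigma, shape = shape),
    seed = seed,
    truth = list(times_h = times, heights_m = traj,
                 baseline_row = baseline_row))
  list(frames = frames, times_h = times,
       corner_roi = c(wedge_cols[1], wedge_cols[length(wedge_cols)]),
       baseline_row = baseline_row, calibration = calibration, truth = truth)
}

#' Generate a synthetic surfactant concentration series
#'
#' Both the surface tension and the contact angle decrease with
#' concentration following a logistic step in log10 concentration between a
#' water-like high plateau and a saturated low plateau, emulating measured
#' surfactant curves. The analytic crossing concentration for any contact
#' angle threshold is available from the truth via
#' [crossing_concentration()].
#'
#' @param theta_high,theta_low Contact-angle plateaus (degrees,
#'   `theta_high > theta_low`). Defaults 120 and 60.
#' @param gamma_high,gamma_low Surface-tension plateaus (N/m,
#'   `gamma_high > gamma_low`). Defaults 0.072 and 0.030.
#' @param logC_mid Midpoint of the logistic step (log10 mol/L), default -4.
#' @param slope Logistic steepness per decade of concentration, default 2.
#' @param concentrations Strictly increasing concentration grid (mol/L);
#'   default half-decade steps over 1e-5 to 1e-2 M.
#' @param noise_theta_deg,noise_gamma Seeded Gaussian measurement noise.
#' @param seed Integer seed.
#' @param label Series label.
#' @return `list(series = surfactant_series, truth = synthetic_truth)`.
#' @export
gen_concentration_series <- function(theta_high = 120, theta_low = 60,
                                     gamma_high = 0.072, gamma_low = 0.030,
                                     logC_mid = -4, slope = 2,
                                     concentrations = c(1e-5, 3e-5, 1e-4,
                                                        3e-4, 1e-3, 3e-3,
                                                        1e-2),
                                     noise_theta_deg = 0, noise_gamma = 0,
                                     seed = 1, label = "synthetic") {
  cf_assert(theta_high > theta_low, "cf_invalid_parameter",
            "theta_high must exceed theta_low")
  cf_assert(gamma_high > gamma_low, "cf_invalid_parameter",
            "gamma_high must exceed gamma_low")
  cf_assert(length(concentrations) >= 1L && all(diff(concentrations) > 0),
            "cf_invalid_input",
            "concentration grid must be strictly increasing")
  f <- 1 / (1 + 10^(slope * (log10(concentrations) - logC_mid)))
  theta <- theta_low + (theta_high - theta_low) * f
  gamma <- gamma_low + (gamma_high - gamma_low) * f
  withr::with_seed(seed, {
    theta <- theta + rnorm(length(theta), 0, noise_theta_deg)
    gamma <- gamma + rnorm(length(gamma), 0, noise_gamma)
  })
  theta <- pmin(pmax(theta, 0), 180)
  gamma <- pmax(gamma, 1e-4)
  truth <- synthetic_truth(
    "concentration_series",
    params = list(theta_high = theta_high, theta_low = theta_low,
                  gamma_high = gamma_high, gamma_low = gamma_low,
                  logC_mid = logC_mid, slope = slope,
                  concentrations = concentrations,
                  noise_theta_deg = noise_theta_deg,
                  noise_gamma = noise_gamma),
    seed = seed,
    truth = list(theta_high = theta_high, theta_low = theta_low,
                 logC_mid = logC_mid, slope = slope))
  list(series = surfactant_series(concentrations, gamma, theta, label),
       truth = truth)
}

#' Analytic contact-angle crossing concentration of a synthetic series
#'
#' For a truth produced by [gen_concentration_series()], the concentration
#' at which the noiseless contact-angle curve crosses `theta_threshold`.
#' Returns 0 if the threshold is at or above the high plateau (always
#' below), and `Inf` if at or below the low plateau (never reached).
#'
#' @param truth A [synthetic_truth()] of kind `"concentration_series"`.
#' @param theta_threshold Contact-angle threshold (degrees).
#' @return Concentration in mol/L (possibly 0 or `Inf`).
#' @export
crossing_concentration <- function(truth, theta_threshold) {
  cf_assert(inherits(truth, "synthetic_truth") &&
              truth$kind == "concentration_series", "cf_invalid_input",
            "truth must come from gen_concentration_series")
  tt <- truth$truth
  if (theta_threshold >= tt$theta_high) return(0)
  if (theta_threshold <= tt$theta_low) return(Inf)
  r <- (tt$theta_high - tt$theta_low) / (theta_threshold - tt$theta_low) - 1
  10^(tt$logC_mid + log10(r) / tt$slope)
}
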