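#' Ordered drop silhouette in physical units
#'
#' A `drop_profile` is the ordered right half-silhouette of an axisymmetric
#' drop: horizontal distance `x` from the symmetry axis and axial distance `z`
#' from the apex, both in metres. The first point is the apex `(0, 0)` and all
#' `x >= 0`. For a pendant drop imaged apex-down, `z` increases from the apex
#' towards the needle; for a sessile drop, from the apex towards the substrate.
#'
#' @param x,z Numeric vectors of equal length, metres. `x[1]` must be 0.
#' @param orientation `"pendant"` or `"sessile"`.
#' @param calibration Optional length-per-pixel (m/px) when the profile came
#'   from an image; `NULL` for purely synthetic profiles.
#' @param truncated Logical flag set when forward integration stopped early
#'   because the profile closed (turning angle reached pi).
#' @return An object of class `drop_profile`.
#' @export
drop_profile <- function(x, z, orientation = c("pendant", "sessile"),
                         calibration = NULL, truncated = FALSE) {
  orientation <- match.arg(orientation)
  cf_assert(is.numeric(x) && is.numeric(z) && length(x) == length(z) &&
              length(x) >= 1L, "cf_invalid_input",
            "x and z must be numeric vectors of equal positive length")
  cf_assert(abs(x[1]) < 1e-12, "cf_invalid_input",
            "first profile point must be the apex with x = 0")
  cf_assert(all(x >= -1e-12), "cf_invalid_input",
            "profile x must be non-negative (right half-profile)")
  if (orientation == "pendant") {
    cf_assert(all(diff(z) >= -1e-12), "cf_invalid_input",
              "pendant profile z must be monotone nondecreasing from the apex")
  }
  if (!is.null(calibration)) {
    cf_assert(is_number(calibration) && calibration > 0, "cf_invalid_parameter",
              "calibration must be a positive number")
  }
  structure(
    list(x = pmax(x, 0), z = z, orientation = orientation,
         calibration = calibration, truncated = isTRUE(truncated)),
    class = "drop_profile"
  )
}

#' @export
print.drop_profile <- function(x, ...) {
  cat(sprintf("<drop_profile> %s, %d points, extent x: %.3g mm, z: %.3g mm%s\n",
              x$orientation, length(x$x), max(x$x) * 1e3, max(x$z) * 1e3,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Fluid properties bundle
#'
#' @param density Liquid density rho (kg/m^3).
#' @param surface_tension Surface tension gamma (N/m).
#' @param contact_angle Contact angle theta_c (degrees, in `[0, 180]`).
#' @param gravity Gravitational acceleration g (m/s^2), default 9.81.
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(density, surface_tension, contact_angle,
                             gravity = 9.81) {
  cf_assert(is_number(density) && density > 0, "cf_invalid_parameter",
            "density must be > 0")
  cf_assert(is_number(surface_tension) && surface_tension > 0,
            "cf_invalid_parameter", "surface_tension must be > 0")
  cf_assert(is_number(contact_angle) && contact_angle >= 0 &&
              contact_angle <= 180, "cf_invalid_parameter",
            "contact_angle must lie in [0, 180] degrees")
  cf_assert(is_number(gravity) && gravity > 0, "cf_invalid_parameter",
            "gravity must be > 0")
  structure(list(density = density, surface_tension = surface_tension,
                 contact_angle = contact_angle, gravity = gravity),
            class = "fluid_properties")
}

# Right-hand side of the axisymmetric Young-Laplace system in arc length.
# State (x, z, phi); curvature at the apex handled by the analytic limit
# sin(phi)/x -> 1/b. `sgn` is -1 for pendant (hydrostatic pressure decreases
# with height above the apex of a hanging drop), +1 for sessile.
yl_rhs <- function(x, z, phi, b, bond, sgn) {
  ratio <- if (x < b * 1e-9) 1 / b else sin(phi) / x
  c(cos(phi), sin(phi), 2 / b + sgn * bond * z / b^2 - ratio)
}

#' Integrate an axisymmetric Young-Laplace drop shape
#'
#' Integrates the drop silhouette in arc length s from the apex:
#' dx/ds = cos(phi), dz/ds = sin(phi),
#' dphi/ds = 2/b -/+ beta z / b^2 - sin(phi)/x,
#' where b is the apex radius of curvature and beta the Bond number
#' (Delta-rho g b^2 / gamma). The minus sign applies to a pendant drop with z
#' measured from the apex towards the needle, the plus sign to a sessile drop.
#' A classical fixed-step fourth-order Runge-Kutta scheme is used; the apex
#' singularity is removed by the limit sin(phi)/x -> 1/b.
#'
#' Integration stops early, with the `truncated` flag set, if the turning
#' angle phi reaches pi (the profile closes back on itself).
#'
#' @param bond Bond number (dimensionless, >= 0).
#' @param apex_radius Apex radius of curvature b (m, > 0).
#' @param arc_length_max Total arc length to integrate (m, > step).
#' @param step Integration step (m); default `apex_radius / 200`.
#' @param orientation `"pendant"` or `"sessile"`.
#' @return A [drop_profile()].
#' @examples
#' p <- integrate_drop_profile(bond = 0.3, apex_radius = 1e-3,
#'                             arc_length_max = 3e-3)
#' head(cbind(p$x, p$z))
#' @export
integrate_drop_profile <- function(bond, apex_radius, arc_length_max,
                                   step = apex_radius / 200,
                                   orientation = c("pendant", "sessile")) {
  orientation <- match.arg(orientation)
  cf_assert(is_number(bond) && bond >= 0, "cf_invalid_parameter",
            "bond must be a non-negative number")
  cf_assert(is_number(apex_radius) && apex_radius > 0, "cf_invalid_parameter",
            "apex_radius must be > 0")
  cf_assert(is_number(step) && step > 0, "cf_invalid_parameter",
            "step must be > 0")
  cf_assert(is_number(arc_length_max) && arc_length_max > step,
            "cf_invalid_parameter", "arc_length_max must exceed step")
  sgn <- if (orientation == "pendant") -1 else 1
  b <- apex_radius
  n <- as.integer(ceiling(arc_length_max / step))
  xs <- numeric(n + 1L); zs <- numeric(n + 1L)
  x <- 0; z <- 0; phi <- 0
  truncated <- FALSE
  h <- step
  m <- n
  for (i in seq_len(n)) {
    k1 <- yl_rhs(x, z, phi, b, bond, sgn)
    k2 <- yl_rhs(x + h / 2 * k1[1], z + h / 2 * k1[2], phi + h / 2 * k1[3],
                 b, bond, sgn)
    k3 <- yl_rhs(x + h / 2 * k2[1], z + h / 2 * k2[2], phi + h / 2 * k2[3],
                 b, bond, sgn)
    k4 <- yl_rhs(x + h * k3[1], z + h * k3[2], phi + h * k3[3], b, bond, sgn)
    x <- x + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    z <- z + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    phi <- phi + h / 6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3])
    if (phi >= pi || phi < 0) {
      # phi = pi: the profile closes; phi < 0 (pendant beyond the neck):
      # the silhouette stops being single-valued in z
      truncated <- TRUE
      m <- i - 1L
      break
    }
    xs[i + 1L] <- x; zs[i + 1L] <- z
  }
  drop_profile(xs[seq_len(m + 1L)], zs[seq_len(m + 1L)],
               orientation = orientation, truncated = truncated)
}

#' Pendant-drop fit result
#'
#' Holds the surface tension and shape parameters recovered from a pendant
#' profile: gamma = Delta-rho g b^2 / beta.
#'
#' @param surface_tension Fitted gamma (N/m).
#' @param apex_radius Fitted apex radius b (m).
#' @param bond Fitted Bond number beta.
#' @param rmse Mean orthogonal distance between data and fitted shape (m).
#' @param converged Logical.
#' @return Object of class `pendant_fit`.
#' @export
pendant_fit <- function(surface_tension, apex_radius, bond, rmse, converged) {
  cf_assert(surface_tension > 0 && apex_radius > 0 && bond >= 0 && rmse >= 0,
            "cf_invalid_parameter", "invalid pendant_fit fields")
  structure(list(surface_tension = surface_tension, apex_radius = apex_radius,
                 bond = bond, rmse = rmse, converged = isTRUE(converged)),
            class = "pendant_fit")
}

#' @export
print.pendant_fit <- function(x, ...) {
  cat(sprintf(
    "<pendant_fit> gamma = %.4g mN/m, b = %.4g mm, Bond = %.4g, rmse = %.3g um%s\n",
    x$surface_tension * 1e3, x$apex_radius * 1e3, x$bond, x$rmse * 1e6,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Apex radius estimate: least-squares circle with centre on the symmetry axis,
# fitted to the fraction of points nearest the apex.
estimate_apex_radius <- function(x, z, fraction = 0.2) {
  ord <- order(z)
  k <- max(5L, ceiling(fraction * length(x)))
  idx <- ord[seq_len(min(k, length(x)))]
  xi <- x[idx]; zi <- z[idx]
  # x^2 + z^2 = 2 c z + (R^2 - c^2), linear in (c, q)
  a <- cbind(2 * zi, 1)
  y <- xi^2 + zi^2
  sol <- tryCatch(qr.solve(a, y), error = function(e) NULL)
  if (is.null(sol)) return(NA_real_)
  r2 <- sol[2] + sol[1]^2
  if (!is.finite(r2) || r2 <= 0) return(NA_real_)
  sqrt(r2)
}

yl_fit_objective <- function(b, bond, obs, s_max, n_model = 200L) {
  mod <- tryCatch(
    integrate_drop_profile(bond, b, arc_length_max = s_max, step = b / 200),
    error = function(e) NULL)
  if (is.null(mod)) return(1)
  mp <- resample_polyline(mod$x, mod$z, n_model)
  mean(min_dist_to_polyline(obs[, 1], obs[, 2], mp[, 1], mp[, 2]))
}

#' Fit a pendant-drop profile for surface tension
#'
#' Recovers surface tension from an observed pendant silhouette by fitting
#' the forward-integrated axisymmetric Young-Laplace shape over the apex
#' radius b and Bond number beta, minimising the mean orthogonal distance
#' between the observed points and the model curve. The surface tension is
#' then gamma = Delta-rho g b^2 / beta.
#'
#' The optimiser is a derivative-free Nelder-Mead search in (log b, log beta),
#' which enforces positivity without hard box constraints. The apex radius is
#' initialised from a circle fit to the 20% of points nearest the apex, and
#' beta from 0.2, unless `init` supplies both.
#'
#' @param profile A [drop_profile()] with at least 20 points.
#' @param density_difference Density difference Delta-rho (kg/m^3, > 0).
#' @param gravity g (m/s^2), default 9.81.
#' @param init Optional [pendant_fit()] used as the starting point.
#' @param rmse_tol Convergence threshold on the mean orthogonal residual (m);
#'   the `converged` flag requires the optimiser to stop normally *and* the
#'   residual to fall below this value. Default 1e-5 m.
#' @param maxit Nelder-Mead iteration cap.
#' @return A [pendant_fit()].
#' @examples
#' tr <- integrate_drop_profile(0.5, 1.2e-3, 3.2e-3)
#' fit <- fit_pendant_profile(tr, density_difference = 1000)
#' fit$surface_tension  # ~ 1000 * 9.81 * 1.2e-3^2 / 0.5
#' @importFrom stats optim
#' @export
fit_pendant_profile <- function(profile, density_difference, gravity = 9.81,
                                init = NULL, rmse_tol = 1e-5, maxit = 400L) {
  cf_assert(inherits(profile, "drop_profile"), "cf_invalid_input",
            "profile must be a drop_profile")
  cf_assert(is_number(density_difference) && density_difference > 0,
            "cf_invalid_parameter", "density_difference must be > 0")
  cf_assert(is_number(gravity) && gravity > 0, "cf_invalid_parameter",
            "gravity must be > 0")
  x <- profile$x; z <- profile$z
  if (length(x) < 20L)
    cf_error("cf_insufficient_profile",
             "pendant fit requires at least 20 profile points")
  # collinearity guard: orthogonal scatter about the principal axis
  v <- principal_direction(x, z)
  perp <- -(x - mean(x)) * v[2] + (z - mean(z)) * v[1]
  if (stats::sd(perp) < 1e-12)
    cf_error("cf_insufficient_profile",
             "profile points are collinear; not a drop silhouette")

  if (!is.null(init)) {
    cf_assert(inherits(init, "pendant_fit"), "cf_invalid_input",
              "init must be a pendant_fit")
    b0 <- init$apex_radius
    beta0 <- max(init$bond, 1e-4)
  } else {
    b0 <- estimate_apex_radius(x, z)
    if (!is.finite(b0) || b0 <= 0) b0 <- max(x) # fallback: equatorial radius
    beta0 <- 0.2
  }

  obs <- resample_polyline(x, z, 200L)
  s_data <- sum(sqrt(diff(x)^2 + diff(z)^2))
  s_max <- s_data * 1.02

  obj <- function(par) {
    b <- exp(par[1]); bond <- exp(par[2])
    if (!is.finite(b) || !is.finite(bond) || bond > 20) return(1)
    yl_fit_objective(b, bond, obs, s_max)
  }
  par0 <- c(log(b0), log(beta0))
  f0 <- obj(par0)
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  # Nelder-Mead never returns a worse point than it evaluated, but keep the
  # initialisation if the search somehow did not improve on it.
  if (opt$value > f0) {
    opt$par <- par0
    opt$value <- f0
  }
  b <- exp(opt$par[1]); bond <- exp(opt$par[2])
  gamma <- density_difference * gravity * b^2 / bond
  pendant_fit(gamma, b, bond, rmse = opt$value,
              converged = opt$convergence == 0 && opt$value < rmse_tol)
}

#' Read / write drop profiles as two-column CSV
#'
#' The on-disk format is a CSV with header `x_m,z_m` (metres).
#'
#' @param profile A [drop_profile()].
#' @param path File path.
#' @param orientation Orientation to assign on read.
#' @return `read_drop_profile` returns a [drop_profile()];
#'   `write_drop_profile` returns `path` invisibly.
#' @export
write_drop_profile <- function(profile, path) {
  cf_assert(inherits(profile, "drop_profile"), "cf_invalid_input",
            "profile must be a drop_profile")
  utils::write.csv(data.frame(x_m = profile$x, z_m = profile$z), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_drop_profile
#' @export
read_drop_profile <- function(path, orientation = c("pendant", "sessile")) {
  orientation <- match.arg(orientation)
  cf_assert(file.exists(path), "cf_invalid_input",
            paste("no such profile file:", path))
  d <- utils::read.csv(path)
  cf_assert(all(c("x_m", "z_m") %in% names(d)), "cf_invalid_input",
            "profile CSV must have columns x_m,z_m")
  drop_profile(d$x_m, d$z_m, orientation = orientation)
}
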