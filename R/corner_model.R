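#' Corner geometry
#'
#' Describes an interior corner of a chamber: its opening angle and the
#' minimum wall separation at the (rounded) corner tip. Real corners are
#' never perfectly sharp; the finite tip gap is what caps the capillary rise
#' height.
#'
#' @param alpha Corner opening angle (degrees, in (0, 180)).
#' @param min_gap Minimum wall separation d at the tip (m, > 0).
#' @return Object of class `corner_spec`.
#' @export
corner_spec <- function(alpha, min_gap) {
  cf_assert(is_number(alpha) && alpha > 0 && alpha < 180,
            "cf_invalid_parameter", "alpha must lie in (0, 180) degrees")
  cf_assert(is_number(min_gap) && min_gap > 0, "cf_invalid_parameter",
            "min_gap must be > 0")
  structure(list(alpha = alpha, min_gap = min_gap), class = "corner_spec")
}

#' Concus-Finn corner-wetting prediction
#'
#' A liquid spreads spontaneously along an interior corner of opening angle
#' alpha when `alpha/2 + theta_c < 90` degrees. The returned margin is
#' `90 - (alpha/2 + theta_c)` in degrees: positive means flow. Because an
#' observation exactly at the boundary (e.g. a 60-degree corner with a
#' 60-degree contact angle) shows only a slight rise, predictions within
#' `tolerance` of the boundary are reported as `"marginal"`.
#'
#' @param alpha Corner opening angle (degrees, in (0, 180)).
#' @param theta_c Contact angle (degrees, in `[0, 180]`).
#' @param tolerance Marginal band half-width (degrees, default 1).
#' @return Object of class `flow_prediction` with fields `flows`
#'   (`"yes"`/`"no"`/`"marginal"`) and `margin` (degrees).
#' @examples
#' concus_finn_flow(30, 60)  # flows, margin 15 deg
#' concus_finn_flow(90, 60)  # no flow, margin -15 deg
#' @export
concus_finn_flow <- function(alpha, theta_c, tolerance = 1) {
  cf_assert(is_number(alpha) && alpha > 0 && alpha < 180,
            "cf_invalid_parameter", "alpha must lie in (0, 180) degrees")
  cf_assert(is_number(theta_c) && theta_c >= 0 && theta_c <= 180,
            "cf_invalid_parameter", "theta_c must lie in [0, 180] degrees")
  cf_assert(is_number(tolerance) && tolerance >= 0, "cf_invalid_parameter",
            "tolerance must be >= 0")
  margin <- 90 - (alpha / 2 + theta_c)
  flows <- if (abs(margin) <= tolerance) "marginal"
  else if (margin > 0) "yes" else "no"
  structure(list(flows = flows, margin = margin, alpha = alpha,
                 theta_c = theta_c, tolerance = tolerance, h_max = NULL),
            class = "flow_prediction")
}

#' @export
print.flow_prediction <- function(x, ...) {
  cat(sprintf("<flow_prediction> alpha = %g deg, theta_c = %g deg: %s (margin %+.2f deg)%s\n",
              x$alpha, x$theta_c, x$flows, x$margin,
              if (!is.null(x$h_max))
                sprintf(", h_max = %.3g mm", x$h_max * 1e3) else ""))
  invisible(x)
}

#' Critical corner angle for corner flow
#'
#' The largest corner opening angle that still admits corner flow for a
#' liquid whose (minimum attained) contact angle is `theta_min`:
#' `alpha_th = 2 * (90 - theta_min)` degrees, floored at 0 for non-wetting
#' liquids.
#'
#' @param theta_min Minimum contact angle attained by the liquid (degrees,
#'   in `[0, 180]`).
#' @return Threshold angle alpha_th in degrees.
#' @examples
#' critical_corner_angle(60)  # 60
#' @export
critical_corner_angle <- function(theta_min) {
  cf_assert(is_number(theta_min) && theta_min >= 0 && theta_min <= 180,
            "cf_invalid_parameter", "theta_min must lie in [0, 180] degrees")
  max(0, 2 * (90 - theta_min))
}

#' Maximum capillary rise height in a rounded corner
#'
#' Balancing the weight of the liquid column against the capillary force
#' between two parallel walls a distance d apart gives the maximum rise
#' height `h = 2 gamma cos(theta_c) / (rho g d)`. The rounded corner tip is
#' modelled as a stack of parallel-plate segments, so the minimum tip gap d
#' sets the height and the corner opening angle drops out. Non-wetting
#' liquids (`theta_c >= 90` degrees) do not rise: the function returns 0.
#'
#' @param fluid A [fluid_properties()] (density, surface tension, contact
#'   angle, gravity).
#' @param corner A [corner_spec()]; only `min_gap` enters the height.
#' @return Maximum rise height in metres.
#' @examples
#' f <- fluid_properties(1000, 0.030, 60)
#' max_rise_height(f, corner_spec(30, 225e-6)) * 1e3  # 13.6 mm
#' @export
max_rise_height <- function(fluid, corner) {
  cf_assert(inherits(fluid, "fluid_properties"), "cf_invalid_input",
            "fluid must be a fluid_properties object")
  cf_assert(inherits(corner, "corner_spec"), "cf_invalid_input",
            "corner must be a corner_spec object")
  if (fluid$contact_angle >= 90) return(0)
  2 * fluid$surface_tension * cos(deg2rad(fluid$contact_angle)) /
    (fluid$density * fluid$gravity * corner$min_gap)
}

#' Corner-flow prediction with rise height
#'
#' Combines [concus_finn_flow()] with [max_rise_height()]: when flow is
#' predicted (or marginal), the maximum rise height for the rounded corner
#' is attached.
#'
#' @inheritParams concus_finn_flow
#' @param fluid A [fluid_properties()]; its `contact_angle` is used as
#'   `theta_c`.
#' @param corner A [corner_spec()]; its `alpha` is used as the corner angle.
#' @return A `flow_prediction` with `h_max` set when `flows != "no"`.
#' @export
predict_corner_flow <- function(fluid, corner, tolerance = 1) {
  pred <- concus_finn_flow(corner$alpha, fluid$contact_angle, tolerance)
  if (pred$flows != "no") pred$h_max <- max_rise_height(fluid, corner)
  pred
}

#' Per-concentration surfactant measurements
#'
#' A table of surface tension and contact angle versus surfactant
#' concentration, as measured from pendant and advancing drops. Both
#' quantities typically decrease monotonically with concentration between a
#' water-like high plateau and a saturated low plateau.
#'
#' @param concentration_M Strictly increasing concentrations (mol/L).
#' @param gamma_N_per_m Surface tensions (N/m, > 0).
#' @param theta_deg Contact angles (degrees, in `[0, 180]`).
#' @param label Optional surfactant label.
#' @return A data frame of class `surfactant_series`.
#' @export
surfactant_series <- function(concentration_M, gamma_N_per_m, theta_deg,
                              label = NULL) {
  cf_assert(length(concentration_M) >= 1L &&
              length(concentration_M) == length(gamma_N_per_m) &&
              length(concentration_M) == length(theta_deg),
            "cf_invalid_input", "series columns must have equal length >= 1")
  cf_assert(all(diff(concentration_M) > 0), "cf_invalid_input",
            "concentrations must be strictly increasing")
  cf_assert(all(gamma_N_per_m > 0), "cf_invalid_input",
            "all surface tensions must be > 0")
  cf_assert(all(theta_deg >= 0 & theta_deg <= 180), "cf_invalid_input",
            "contact angles must lie in [0, 180] degrees")
  d <- data.frame(concentration_M = concentration_M,
                  gamma_N_per_m = gamma_N_per_m, theta_deg = theta_deg)
  attr(d, "label") <- label
  class(d) <- c("surfactant_series", "data.frame")
  d
}

#' Read / write a surfactant concentration series as CSV
#'
#' Columns: `concentration_M, gamma_N_per_m, theta_deg`.
#'
#' @param series A [surfactant_series()].
#' @param path File path.
#' @return `read_surfactant_series` returns a [surfactant_series()].
#' @export
write_surfactant_series <- function(series, path) {
  cf_assert(inherits(series, "surfactant_series"), "cf_invalid_input",
            "series must be a surfactant_series")
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_surfactant_series
#' @param label Optional label to attach on read.
#' @export
read_surfactant_series <- function(path, label = NULL) {
  cf_assert(file.exists(path), "cf_invalid_input",
            paste("no such series file:", path))
  d <- utils::read.csv(path)
  cf_assert(all(c("concentration_M", "gamma_N_per_m", "theta_deg") %in%
                  names(d)), "cf_invalid_input",
            "series CSV must have columns concentration_M,gamma_N_per_m,theta_deg")
  surfactant_series(d$concentration_M, d$gamma_N_per_m, d$theta_deg, label)
}

#' Critical surfactant concentration bracket for corner flow
#'
#' Scans a measured concentration series in increasing concentration and
#' returns the bracket around the first concentration at which the
#' Concus-Finn criterion turns to flow: `(largest C without flow, smallest C
#' with flow)`. Measured (possibly non-monotone) series are scanned as-is;
#' the first crossing wins. Returns a `"none"` bracket when no concentration
#' admits flow, and a below-range bracket when the first concentration
#' already flows.
#'
#' @param series A [surfactant_series()].
#' @param alpha Corner opening angle (degrees).
#' @param tolerance Marginal band passed to [concus_finn_flow()]; default 0
#'   so that any strict inequality counts as flow.
#' @return Object of class `concentration_bracket` with fields `c_low`,
#'   `c_high` (mol/L or `NA`), `none`, `below_range`.
#' @export
critical_concentration <- function(series, alpha, tolerance = 0) {
  cf_assert(inherits(series, "surfactant_series") && nrow(series) >= 1L,
            "cf_invalid_input", "series must be a non-empty surfactant_series")
  flows <- vapply(series$theta_deg, function(th)
    concus_finn_flow(alpha, th, tolerance)$flows == "yes", logical(1))
  first <- which(flows)[1]
  if (is.na(first)) {
    out <- list(c_low = NA_real_, c_high = NA_real_, none = TRUE,
                below_range = FALSE)
  } else if (first == 1L) {
    out <- list(c_low = NA_real_, c_high = series$concentration_M[1],
                none = FALSE, below_range = TRUE)
  } else {
    out <- list(c_low = series$concentration_M[first - 1L],
                c_high = series$concentration_M[first],
                none = FALSE, below_range = FALSE)
  }
  out$alpha <- alpha
  structure(out, class = "concentration_bracket")
}

#' @export
print.concentration_bracket <- function(x, ...) {
  if (x$none) {
    cat("<concentration_bracket> no concentration admits corner flow\n")
  } else if (x$below_range) {
    cat(sprintf("<concentration_bracket> flow already at the lowest tested concentration (%.3g M)\n",
                x$c_high))
  } else {
    cat(sprintf("<concentration_bracket> corner flow onset between %.3g and %.3g M (alpha = %g deg)\n",
                x$c_low, x$c_high, x$alpha))
  }
  invisible(x)
}
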