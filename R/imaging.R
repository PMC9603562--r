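#' Grayscale drop image with calibration
#'
#' Wraps a 2-D intensity matrix (row 1 at the top, as stored in image files)
#' with its pixel-to-length calibration and an optional known substrate row.
#' Intensities may be on any scale; thresholds are taken as fractions of the
#' observed dynamic range.
#'
#' @param pixels Numeric matrix of intensities.
#' @param calibration Length per pixel (m/px, > 0).
#' @param baseline_row Optional row index of the substrate surface (the first
#'   substrate row); must lie within the image.
#' @return Object of class `drop_image`.
#' @export
drop_image <- function(pixels, calibration, baseline_row = NULL) {
  cf_assert(is.matrix(pixels) && is.numeric(pixels) && all(is.finite(pixels)),
            "cf_invalid_input", "pixels must be a finite numeric matrix")
  cf_assert(is_number(calibration) && calibration > 0, "cf_invalid_parameter",
            "calibration must be > 0")
  if (!is.null(baseline_row)) {
    cf_assert(is_number(baseline_row) && baseline_row >= 1 &&
                baseline_row <= nrow(pixels), "cf_invalid_parameter",
              "baseline_row outside image bounds")
    baseline_row <- as.integer(round(baseline_row))
  }
  structure(list(pixels = pixels, calibration = calibration,
                 baseline_row = baseline_row),
            class = "drop_image")
}

#' @export
print.drop_image <- function(x, ...) {
  cat(sprintf("<drop_image> %d x %d px, %.3g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$calibration * 1e6,
              if (is.null(x$baseline_row)) ""
              else sprintf(", baseline row %d", x$baseline_row)))
  invisible(x)
}

# Connected components of a logical matrix (4-connectivity) via row runs and
# union-find. Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nextlab <- 0L
  prev_runs <- NULL # matrix: from, to, label
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    runs <- cbind(from = starts[rl$values], to = ends[rl$values], label = 0L)
    for (k in seq_len(nrow(runs))) {
      lab <- 0L
      if (!is.null(prev_runs)) {
        for (j in seq_len(nrow(prev_runs))) {
          if (prev_runs[j, "from"] <= runs[k, "to"] &&
              prev_runs[j, "to"] >= runs[k, "from"]) {
            pl <- find(prev_runs[j, "label"])
            if (lab == 0L) lab <- pl
            else if (pl != lab) parent[pl] <- lab
          }
        }
      }
      if (lab == 0L) {
        nextlab <- nextlab + 1L
        parent[nextlab] <- nextlab
        lab <- nextlab
      }
      runs[k, "label"] <- lab
      labels[r, runs[k, "from"]:runs[k, "to"]] <- lab
    }
    prev_runs <- runs
  }
  if (nextlab == 0L) return(labels)
  root <- vapply(seq_len(nextlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  labels
}

# Intensity level for a threshold expressed as a fraction of the robust
# dynamic range (1%/99% quantiles).
threshold_level <- function(pixels, threshold) {
  q <- stats::quantile(pixels, c(0.01, 0.99), names = FALSE)
  q[1] + threshold * (q[2] - q[1])
}

#' Extract a sub-pixel drop silhouette from an image
#'
#' Segments the single drop silhouette (dark-on-light by default), then for
#' each image row locates the drop boundary at sub-pixel precision by linear
#' interpolation of the threshold crossing between neighbouring pixel
#' centres. The silhouette is returned as an apex-anchored [drop_profile()]
#' in physical units; the drop symmetry axis is the median of per-row edge
#' midpoints.
#'
#' The apex axial position is refined to sub-pixel precision by a linear fit
#' of squared half-width against axial distance over the rows nearest the
#' apex (for a smooth apex, x^2 ~ 2 b z).
#'
#' @param image A [drop_image()].
#' @param threshold Fraction of the robust dynamic range, default 0.5.
#' @param side `"left"` or `"right"` half-silhouette.
#' @param orientation `"sessile"` (apex at top) or `"pendant"` (apex at
#'   bottom, hanging drop).
#' @param polarity `"dark"` (drop darker than background) or `"light"`.
#' @param min_size Minimum silhouette area in pixels (default 400).
#' @return A [drop_profile()] with attributes `apex_row` and `axis_col`
#'   (fractional image coordinates of the apex and symmetry axis).
#' @export
extract_drop_edge <- function(image, threshold = 0.5,
                              side = c("left", "right"),
                              orientation = c("sessile", "pendant"),
                              polarity = c("dark", "light"),
                              min_size = 400L) {
  side <- match.arg(side)
  orientation <- match.arg(orientation)
  polarity <- match.arg(polarity)
  cf_assert(inherits(image, "drop_image"), "cf_invalid_input",
            "image must be a drop_image")
  px <- image$pixels
  if (polarity == "light") px <- max(px) + min(px) - px
  level <- threshold_level(px, threshold)
  mask <- px < level
  if (!any(mask))
    cf_error("cf_segmentation_error", "no silhouette found in image")
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  big <- which(sizes >= min_size)
  if (length(big) == 0L)
    cf_error("cf_segmentation_error",
             sprintf("no connected silhouette of at least %d px", min_size))
  if (length(big) > 1L)
    cf_error("cf_segmentation_error",
             "multiple silhouettes above the size cutoff")
  mask <- labels == big

  rows <- which(rowSums(mask) > 0L)
  nc <- ncol(px)
  el <- er <- rep(NA_real_, length(rows))
  for (i in seq_along(rows)) {
    r <- rows[i]
    cols <- which(mask[r, ])
    cl <- cols[1]; cr <- cols[length(cols)]
    el[i] <- if (cl > 1L && px[r, cl - 1L] > level)
      (cl - 1L) + (level - px[r, cl - 1L]) / (px[r, cl] - px[r, cl - 1L])
    else cl - 0.5
    er[i] <- if (cr < nc && px[r, cr + 1L] > level)
      cr + (level - px[r, cr]) / (px[r, cr + 1L] - px[r, cr])
    else cr + 0.5
  }
  axis_col <- stats::median((el + er) / 2)
  cal <- image$calibration
  xw <- if (side == "left") axis_col - el else er - axis_col

  if (orientation == "sessile") {
    apex_row <- rows[1]
    zr <- (rows - apex_row) # rows below apex
  } else {
    apex_row <- rows[length(rows)]
    zr <- (apex_row - rows) # rows above apex (towards needle)
  }
  ord <- order(zr)
  zr <- zr[ord]; xw <- pmax(xw[ord], 0)

  # sub-pixel apex refinement: x^2 is locally linear in z near a smooth apex
  k <- min(6L, length(zr))
  fit <- tryCatch(stats::lm.fit(cbind(1, zr[seq_len(k)]),
                                xw[seq_len(k)]^2)$coefficients,
                  error = function(e) c(0, NA))
  z0 <- if (is.finite(fit[2]) && fit[2] > 0) -fit[1] / fit[2] else 0
  if (!is.finite(z0) || abs(z0) > 1.5) z0 <- 0
  z <- (zr - z0) * cal
  keep <- z > 0
  apex_row_frac <- apex_row + if (orientation == "sessile") z0 else -z0

  prof <- drop_profile(c(0, xw[keep] * cal), c(0, z[keep]),
                       orientation = orientation, calibration = cal)
  attr(prof, "apex_row") <- apex_row_frac
  attr(prof, "axis_col") <- axis_col
  prof
}

#' Detect the substrate baseline row
#'
#' Finds the row with the strongest horizontal-edge response in the lower
#' half of the image. The response of a row boundary is the jump in the
#' per-row 98th-percentile intensity, which ignores the (dark) drop columns
#' straddling the baseline while responding strongly to the full-width
#' substrate edge. When the image carries a `baseline_row` it is returned
#' verbatim as an override.
#'
#' @param image A [drop_image()].
#' @param min_response Minimum edge response required, as a fraction of the
#'   image dynamic range (default 0.25).
#' @return Integer row index of the first substrate row.
#' @export
detect_baseline <- function(image, min_response = 0.25) {
  cf_assert(inherits(image, "drop_image"), "cf_invalid_input",
            "image must be a drop_image")
  if (!is.null(image$baseline_row)) return(image$baseline_row)
  px <- image$pixels
  nr <- nrow(px)
  cf_assert(nr >= 4L, "cf_invalid_input", "image too small")
  rowq <- apply(px, 1L, stats::quantile, probs = 0.98, names = FALSE)
  resp <- abs(diff(rowq))
  lower <- seq.int(floor(nr / 2), nr - 1L)
  rng <- diff(range(px))
  best <- lower[which.max(resp[lower])]
  if (rng <= 0 || resp[best] < min_response * rng)
    cf_error("cf_baseline_not_found",
             "no horizontal substrate edge found; supply baseline_row")
  best + 1L
}

#' Contact-angle measurement record
#'
#' @param theta_c Advancing contact angle (degrees).
#' @param side `"left"`, `"right"` or `"mean"`.
#' @param tangent_window Number of edge points used for the tangent.
#' @param uncertainty Half-spread between the two sides (degrees), `NA` for a
#'   single-sided measurement.
#' @param left,right Per-side angles (degrees) when available.
#' @return Object of class `contact_angle_measurement`.
#' @export
contact_angle_measurement <- function(theta_c, side, tangent_window,
                                      uncertainty = NA_real_,
                                      left = NA_real_, right = NA_real_) {
  cf_assert(theta_c >= 0 && theta_c <= 180, "cf_invalid_parameter",
            "theta_c must lie in [0, 180]")
  cf_assert(tangent_window >= 5, "cf_invalid_parameter",
            "tangent_window must be >= 5")
  structure(list(theta_c = theta_c, side = side,
                 tangent_window = as.integer(tangent_window),
                 uncertainty = uncertainty, left = left, right = right),
            class = "contact_angle_measurement")
}

#' @export
print.contact_angle_measurement <- function(x, ...) {
  cat(sprintf("<contact_angle> theta_c = %.2f deg (%s%s)\n", x$theta_c, x$side,
              if (is.finite(x$uncertainty))
                sprintf(", +/- %.2f", x$uncertainty) else ""))
  invisible(x)
}

# Tangent angle (degrees) of a half-profile at the baseline. `x` is distance
# from the symmetry axis, `h` height above the baseline; both in metres.
side_contact_angle <- function(x, h, tangent_window, method) {
  ord <- order(h)
  k <- min(tangent_window, length(h))
  idx <- ord[seq_len(k)]
  xi <- x[idx]; hi <- h[idx]
  if (method == "quadratic" && k >= 6L) {
    # local quadratic x(h); tangent slope extrapolated to the contact plane
    # h = 0 removes the chord bias of a straight-line fit on a curved edge
    cf <- stats::lm.fit(cbind(1, hi, hi^2), xi)$coefficients
    m <- cf[2]
    theta <- atan2(1, -m)
  } else {
    v <- principal_direction(xi, hi)
    if (v[2] < 0) v <- -v
    theta <- atan2(v[2], -v[1])
  }
  rad2deg(theta)
}

#' Measure the advancing contact angle at the substrate baseline
#'
#' Computes the interior angle, measured through the liquid, between the
#' substrate plane and the tangent of the drop edge at the contact line. The
#' tangent is estimated from the `tangent_window` edge points nearest the
#' contact point: by default the slope at the contact plane of a local
#' quadratic fit (which removes the chord bias a straight line incurs on a
#' curved edge); `method = "linear"` uses the principal axis of the window
#' points instead.
#'
#' @param edges A single [drop_profile()] (one side) or a list of one or two
#'   profiles, e.g. `list(left = ..., right = ...)`, each apex-anchored with
#'   `z` increasing from apex towards the substrate.
#' @param baseline_pos Axial distance (m) from the apex to the substrate
#'   plane, on the same axis as the profiles' `z`.
#' @param tangent_window Number of edge points nearest the contact line used
#'   for the tangent (>= 5, default 15).
#' @param method `"quadratic"` (default) or `"linear"`.
#' @return A [contact_angle_measurement()]; with two sides, `theta_c` is the
#'   mean and `uncertainty` the half-spread.
#' @export
measure_contact_angle <- function(edges, baseline_pos, tangent_window = 15L,
                                  method = c("quadratic", "linear")) {
  method <- match.arg(method)
  cf_assert(is_number(baseline_pos) && baseline_pos > 0, "cf_invalid_parameter",
            "baseline_pos must be a positive length")
  cf_assert(is_number(tangent_window) && tangent_window >= 5,
            "cf_invalid_parameter", "tangent_window must be >= 5")
  if (inherits(edges, "drop_profile")) edges <- list(edges)
  cf_assert(length(edges) >= 1L && all(vapply(edges, inherits, logical(1),
                                              "drop_profile")),
            "cf_invalid_input", "edges must be drop_profile objects")
  angles <- vapply(edges, function(e) {
    px_tol <- if (is.null(e$calibration)) 0 else 3 * e$calibration
    if (max(e$z) < baseline_pos - px_tol)
      cf_error("cf_no_contact", "drop edge does not reach the baseline")
    h <- pmax(baseline_pos - e$z, 0)
    side_contact_angle(e$x, h, tangent_window, method)
  }, numeric(1))
  angles <- pmin(pmax(angles, 0), 180)
  if (length(angles) == 1L) {
    nm <- names(edges)
    side <- if (!is.null(nm) && nzchar(nm[1])) nm[1] else "left"
    contact_angle_measurement(angles[1], side, tangent_window)
  } else {
    contact_angle_measurement(mean(angles[1:2]), "mean", tangent_window,
                              uncertainty = abs(diff(angles[1:2])) / 2,
                              left = angles[1], right = angles[2])
  }
}

#' Contact angle straight from a goniometry image
#'
#' Convenience wrapper: detects (or accepts) the substrate baseline, crops
#' the reflection below it, extracts both half-silhouettes and measures the
#' advancing contact angle on each side.
#'
#' @inheritParams extract_drop_edge
#' @inheritParams measure_contact_angle
#' @param baseline_row Optional substrate row override; otherwise taken from
#'   the image or detected with [detect_baseline()].
#' @return A [contact_angle_measurement()].
#' @export
contact_angle_from_image <- function(image, threshold = 0.5,
                                     tangent_window = 15L,
                                     baseline_row = NULL,
                                     polarity = c("dark", "light"),
                                     min_size = 400L,
                                     method = c("quadratic", "linear")) {
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  cf_assert(inherits(image, "drop_image"), "cf_invalid_input",
            "image must be a drop_image")
  if (is.null(baseline_row)) baseline_row <- detect_baseline(image)
  cf_assert(baseline_row > 2 && baseline_row <= nrow(image$pixels),
            "cf_invalid_parameter", "baseline_row outside image bounds")
  # crop the substrate and any reflection below the baseline
  cropped <- drop_image(image$pixels[seq_len(baseline_row - 1L), , drop = FALSE],
                        image$calibration)
  left <- extract_drop_edge(cropped, threshold, side = "left",
                            orientation = "sessile", polarity = polarity,
                            min_size = min_size)
  right <- extract_drop_edge(cropped, threshold, side = "right",
                             orientation = "sessile", polarity = polarity,
                             min_size = min_size)
  # substrate plane sits half a pixel above the first substrate row
  baseline_pos <- (baseline_row - 0.5 - attr(left, "apex_row")) *
    image$calibration
  measure_contact_angle(list(left = left, right = right), baseline_pos,
                        tangent_window = tangent_window, method = method)
}
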