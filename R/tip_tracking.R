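#' Corner-flow tip trajectory
#'
#' Time series of the corner-flow tip height H_c above the initial liquid
#' level. Negative detections (tip below the initial level) are clipped to 0
#' and counted in `n_clipped`.
#'
#' @param times_h Strictly increasing times (hours).
#' @param heights_m Tip heights H_c (m).
#' @param frame_interval_min Acquisition interval (minutes), if known.
#' @param corner_label Optional label (e.g. `"30deg"`).
#' @return Object of class `tip_trajectory`.
#' @export
tip_trajectory <- function(times_h, heights_m, frame_interval_min = NA_real_,
                           corner_label = NULL) {
  cf_assert(is.numeric(times_h) && is.numeric(heights_m) &&
              length(times_h) == length(heights_m) && length(times_h) >= 1L,
            "cf_invalid_input",
            "times and heights must be numeric vectors of equal length >= 1")
  cf_assert(all(diff(times_h) > 0) || length(times_h) == 1L,
            "cf_invalid_input", "times must be strictly increasing")
  n_clipped <- sum(heights_m < 0)
  structure(list(times_h = times_h, heights_m = pmax(heights_m, 0),
                 frame_interval_min = frame_interval_min,
                 corner_label = corner_label, n_clipped = n_clipped),
            class = "tip_trajectory")
}

#' @export
print.tip_trajectory <- function(x, ...) {
  cat(sprintf("<tip_trajectory> %d frames over %.2f h, max H_c = %.3g mm%s\n",
              length(x$times_h), diff(range(x$times_h)),
              max(x$heights_m) * 1e3,
              if (x$n_clipped > 0)
                sprintf(" (%d negative detections clipped)", x$n_clipped)
              else ""))
  invisible(x)
}

#' Track the corner-flow tip through a time-lapse stack
#'
#' For each frame, the tip is the topmost row inside the corner region of
#' interest whose maximum intensity exceeds
#' `intensity_threshold x (frame dynamic range)` above the frame minimum
#' (the corner flow is the bright fluorescent wedge). The tip height is
#' `H_c = (baseline_row - tip_row) x calibration`, measured from the initial
#' liquid level and clipped at 0.
#'
#' @param stack A list of numeric matrices (frames of equal dimension), or a
#'   3-D array with frames along the third dimension.
#' @param corner_roi Integer column range `c(first, last)` containing the
#'   corner.
#' @param baseline_row Row index of the initial liquid level.
#' @param calibration Length per pixel (m/px).
#' @param intensity_threshold Fraction of the per-frame dynamic range
#'   (default 0.5).
#' @param frame_interval_min Time between frames (minutes, default 2).
#' @param times_h Optional explicit frame times (hours); overrides
#'   `frame_interval_min`.
#' @param corner_label Optional label stored on the trajectory.
#' @return A [tip_trajectory()].
#' @export
track_tip_heights <- function(stack, corner_roi, baseline_row, calibration,
                              intensity_threshold = 0.5,
                              frame_interval_min = 2,
                              times_h = NULL, corner_label = NULL) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  cf_assert(is.list(stack) && length(stack) >= 1L &&
              all(vapply(stack, is.matrix, logical(1))),
            "cf_invalid_input", "stack must be a non-empty list of matrices")
  dims <- vapply(stack, dim, integer(2))
  cf_assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
            "cf_invalid_input", "all frames must share dimensions")
  nr <- dims[1, 1]; nc <- dims[2, 1]
  cf_assert(length(corner_roi) == 2L && corner_roi[1] >= 1 &&
              corner_roi[2] <= nc && corner_roi[1] <= corner_roi[2],
            "cf_invalid_input", "corner_roi outside image columns")
  cf_assert(is_number(baseline_row) && baseline_row >= 1 && baseline_row <= nr,
            "cf_invalid_parameter", "baseline_row outside image rows")
  cf_assert(is_number(calibration) && calibration > 0, "cf_invalid_parameter",
            "calibration must be > 0")
  cols <- seq.int(corner_roi[1], corner_roi[2])
  heights <- vapply(stack, function(fr) {
    rng <- range(fr)
    level <- rng[1] + intensity_threshold * (rng[2] - rng[1])
    prof <- apply(fr[, cols, drop = FALSE], 1L, max)
    lit <- which(prof > level)
    if (length(lit) == 0L) return(0)
    (baseline_row - lit[1]) * calibration
  }, numeric(1))
  if (is.null(times_h))
    times_h <- (seq_along(stack) - 1) * frame_interval_min / 60
  tip_trajectory(times_h, heights, frame_interval_min = frame_interval_min,
                 corner_label = corner_label)
}

#' Corner-flow kinetics summary
#'
#' @param t_start,t_end Onset and plateau-attainment times (hours).
#' @param h_max Maximum tip height (m).
#' @param mean_speed Average climbing speed (m/h, >= 0).
#' @param flow Logical; `FALSE` for a no-flow trajectory.
#' @return Object of class `flow_kinetics`.
#' @export
flow_kinetics <- function(t_start, t_end, h_max, mean_speed, flow = TRUE) {
  if (flow) {
    cf_assert(t_start <= t_end, "cf_invalid_parameter", "t_start must be <= t_end")
  }
  cf_assert(mean_speed >= 0 && h_max >= 0, "cf_invalid_parameter",
            "h_max and mean_speed must be >= 0")
  structure(list(t_start = t_start, t_end = t_end, h_max = h_max,
                 mean_speed = mean_speed, flow = isTRUE(flow)),
            class = "flow_kinetics")
}

#' @export
print.flow_kinetics <- function(x, ...) {
  if (!x$flow) {
    cat("<flow_kinetics> no flow detected\n")
  } else {
    cat(sprintf("<flow_kinetics> onset %.2f h, plateau %.2f h, h_max = %.3g mm, mean speed = %.2g mm/h\n",
                x$t_start, x$t_end, x$h_max * 1e3, x$mean_speed * 1e3))
  }
  invisible(x)
}

#' Onset, plateau and climbing speed of a corner flow
#'
#' Detects when a corner flow started and ended from its tip trajectory:
#' `t_start` is the first time H_c exceeds `movement_threshold`, `t_end` the
#' first time H_c reaches 95% of the maximum height, and the average
#' climbing speed is `(H_c(t_end) - H_c(t_start)) / (t_end - t_start)`. A
#' 3-frame temporal median filter suppresses single-frame flicker before
#' detection (the raw trajectory is untouched). If H_c never exceeds the
#' threshold the trajectory is flagged no-flow with zero speed.
#'
#' @param traj A [tip_trajectory()].
#' @param movement_threshold Minimum height counted as movement (m, default
#'   0.2 mm).
#' @param plateau_fraction Fraction of `h_max` defining `t_end` (default
#'   0.95).
#' @param median_filter Apply the 3-frame median filter (default `TRUE`).
#' @return A [flow_kinetics()].
#' @examples
#' t <- seq(0, 24, by = 1 / 30)
#' h <- pmin(pmax(t - 8, 0) * 9e-3 / 7, 9e-3)
#' flow_onset_end(tip_trajectory(t, h))$mean_speed * 1e3  # ~1.3 mm/h
#' @importFrom stats runmed
#' @export
flow_onset_end <- function(traj, movement_threshold = 2e-4,
                           plateau_fraction = 0.95, median_filter = TRUE) {
  cf_assert(inherits(traj, "tip_trajectory"), "cf_invalid_input",
            "traj must be a tip_trajectory")
  cf_assert(is_number(movement_threshold) && movement_threshold >= 0,
            "cf_invalid_parameter", "movement_threshold must be >= 0")
  h <- traj$heights_m
  t <- traj$times_h
  if (median_filter && length(h) >= 3L) h <- as.numeric(runmed(h, 3L))
  hmax <- max(h)
  i_start <- which(h > movement_threshold)[1]
  if (is.na(i_start)) {
    return(flow_kinetics(NA_real_, NA_real_, hmax, 0, flow = FALSE))
  }
  i_end <- which(h >= plateau_fraction * hmax)[1]
  if (i_end < i_start) i_end <- i_start
  dt <- t[i_end] - t[i_start]
  speed <- if (dt > 0) (h[i_end] - h[i_start]) / dt else 0
  flow_kinetics(t[i_start], t[i_end], hmax, max(speed, 0))
}

#' Write a tip trajectory as CSV
#'
#' Columns `t_h` (hours) and `Hc_mm` (millimetres).
#'
#' @param traj A [tip_trajectory()].
#' @param path File path.
#' @return `read_tip_trajectory` returns a [tip_trajectory()].
#' @export
write_tip_trajectory <- function(traj, path) {
  cf_assert(inherits(traj, "tip_trajectory"), "cf_invalid_input",
            "traj must be a tip_trajectory")
  utils::write.csv(data.frame(t_h = traj$times_h,
                              Hc_mm = traj$heights_m * 1e3),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tip_trajectory
#' @export
read_tip_trajectory <- function(path) {
  cf_assert(file.exists(path), "cf_invalid_input",
            paste("no such trajectory file:", path))
  d <- utils::read.csv(path)
  cf_assert(all(c("t_h", "Hc_mm") %in% names(d)), "cf_invalid_input",
            "trajectory CSV must have columns t_h,Hc_mm")
  tip_trajectory(d$t_h, d$Hc_mm * 1e-3)
}
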