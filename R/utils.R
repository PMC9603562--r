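# Internal helpers: condition constructors, angle conversion, polyline tools.

cf_error <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "cornerflow_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

cf_assert <- function(cond, subclass, message) {
  if (!isTRUE(cond)) cf_error(subclass, message, call = sys.call(-1))
  invisible(TRUE)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @importFrom stats approx
resample_polyline <- function(x, z, n) {
  # Resample an ordered planar polyline to n points equally spaced in arc length.
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(z)^2)))
  if (s[length(s)] <= 0) {
    return(cbind(x = rep(x[1], n), z = rep(z[1], n)))
  }
  # collapse duplicated arc positions (zero-length segments)
  keep <- !duplicated(s)
  si <- seq(0, s[length(s)], length.out = n)
  cbind(
    x = approx(s[keep], x[keep], xout = si)$y,
    z = approx(s[keep], z[keep], xout = si)$y
  )
}

min_dist_to_polyline <- function(px, pz, vx, vz) {
  # For each point (px, pz), minimum Euclidean distance to the polyline with
  # vertices (vx, vz). Projects onto every segment; fully vectorised.
  ax <- vx[-length(vx)]; az <- vz[-length(vz)]
  dx <- diff(vx); dz <- diff(vz)
  len2 <- dx^2 + dz^2
  len2[len2 == 0] <- .Machine$double.eps
  # t (n_points x n_segments): projection parameter clamped to [0, 1]
  tnum <- outer(px, dx) + outer(pz, dz) -
    matrix(ax * dx + az * dz, nrow = length(px), ncol = length(ax), byrow = TRUE)
  tt <- tnum / matrix(len2, nrow = length(px), ncol = length(ax), byrow = TRUE)
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  qx <- matrix(ax, nrow = length(px), ncol = length(ax), byrow = TRUE) +
    tt * matrix(dx, nrow = length(px), ncol = length(ax), byrow = TRUE)
  qz <- matrix(az, nrow = length(px), ncol = length(ax), byrow = TRUE) +
    tt * matrix(dz, nrow = length(px), ncol = length(ax), byrow = TRUE)
  d2 <- (qx - px)^2 + (qz - pz)^2
  sqrt(apply(d2, 1L, min))
}

# Principal direction of a 2-D point cloud (orthogonal least squares).
principal_direction <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  m <- cbind(xc, yc)
  sv <- svd(m, nu = 0, nv = 2)
  sv$v[, 1]
}
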