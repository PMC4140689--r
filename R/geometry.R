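#' Angle wrapping to (-180, 180]
#'
#' Folds any angle in degrees into the half-open interval `(-180, 180]`;
#' the boundary value maps to `+180` so the negative x-axis has a unique
#' representation.
#'
#' @param a Numeric vector of angles, degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Circular distance between two undirected axis angles, in [0, 90].
axis_error <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Object centroid as the component-wise median of keypoints
#'
#' For even counts each component is the mean of the two middle order
#' statistics (`stats::median`). Note this estimator is not
#' rotation-equivariant; the detection pipeline therefore defaults to the
#' geometric median ([centroid_geometric()]), which is. See the methods
#' vignette.
#'
#' @param points Keypoint `data.frame` with `x`, `y` columns.
#' @return List with `x`, `y`, `n_points` (class `symaxis_centroid`).
#' @export
centroid_median <- function(points) {
  assert_nonempty(points)
  new_centroid(stats::median(points$x), stats::median(points$y), nrow(points))
}

#' Object centroid as the arithmetic mean of keypoints
#' @inheritParams centroid_median
#' @return List with `x`, `y`, `n_points` (class `symaxis_centroid`).
#' @export
centroid_mean <- function(points) {
  assert_nonempty(points)
  new_centroid(mean(points$x), mean(points$y), nrow(points))
}

#' Object centroid as the geometric (spatial) median of keypoints
#'
#' Weiszfeld iteration started at the component-wise median. The geometric
#' median is equivariant under rotations and reflections, so for a point set
#' that is exactly mirror-symmetric it lies exactly on the symmetry axis —
#' the property the axis sweep relies on. It keeps the median's robustness
#' to outlying (e.g. clutter) keypoints.
#'
#' @inheritParams centroid_median
#' @param tol Convergence tolerance in pixels.
#' @param max_iter Iteration cap.
#' @return List with `x`, `y`, `n_points` (class `symaxis_centroid`).
#' @export
centroid_geometric <- function(points, tol = 1e-9, max_iter = 500L) {
  assert_nonempty(points)
  x <- points$x; y <- points$y
  cx <- stats::median(x); cy <- stats::median(y)
  eps <- 1e-9
  for (it in seq_len(max_iter)) {
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    at_pt <- d < eps
    # Vardi-Zhang step: plain Weiszfeld stalls when the iterate coincides
    # with a data point (its 1/d weight blows up and pins the iterate).
    w <- 1 / pmax(d, eps)
    w[at_pt] <- 0
    sw <- sum(w)
    if (sw == 0) break                       # all points coincide here
    tx <- sum(w * x) / sw; ty <- sum(w * y) / sw
    if (any(at_pt)) {
      rx <- sum(w * (x - cx)); ry <- sum(w * (y - cy))
      r <- sqrt(rx^2 + ry^2)
      eta <- sum(at_pt)
      if (r <= eta) break                    # the data point is the median
      lam <- min(1, eta / r)
      tx <- (1 - lam) * tx + lam * cx
      ty <- (1 - lam) * ty + lam * cy
    }
    done <- max(abs(tx - cx), abs(ty - cy)) < tol
    cx <- tx; cy <- ty
    if (done) break
  }
  new_centroid(cx, cy, length(x))
}

#' Centroid dispatcher used by the detection pipeline
#'
#' @inheritParams centroid_median
#' @param method `"geometric"` (default), `"median"` (component-wise), or
#'   `"mean"`.
#' @return `symaxis_centroid`.
#' @export
object_centroid <- function(points, method = c("geometric", "median", "mean")) {
  switch(match.arg(method),
         geometric = centroid_geometric(points),
         median = centroid_median(points),
         mean = centroid_mean(points))
}

new_centroid <- function(x, y, n) {
  structure(list(x = x, y = y, n_points = n), class = "symaxis_centroid")
}

assert_nonempty <- function(points) {
  if (is.null(points) || nrow(points) == 0L) {
    stop("insufficient features: no keypoints to take a centroid of",
         call. = FALSE)
  }
}

#' @export
print.symaxis_centroid <- function(x, ...) {
  cat(sprintf("centroid (%.3f, %.3f) from %d keypoint(s)\n",
              x$x, x$y, x$n_points))
  invisible(x)
}

#' Convert keypoints to polar coordinates about a centroid
#'
#' The image y-axis (which points down in raster convention) is flipped
#' before taking `atan2`, so angles are counter-clockwise positive in
#' conventional math orientation. `theta` lies in `(-180, 180]` with the
#' negative x-direction mapping to `+180`; a point coincident with the
#' centroid gets `r = 0, theta = 0`.
#'
#' @param points Keypoint `data.frame` with `x`, `y` columns.
#' @param center `symaxis_centroid` or list with `x`, `y`.
#' @return The input `data.frame` with `r` (pixels) and `theta` (degrees)
#'   columns appended.
#' @export
to_polar <- function(points, center) {
  dx <- points$x - center$x
  dy <- center$y - points$y            # flip raster y so CCW is positive
  r <- sqrt(dx^2 + dy^2)
  theta <- ifelse(r == 0, 0, wrap_angle(atan2(dy, dx) * 180 / pi))
  points$r <- r
  points$theta <- theta
  points
}

# Centered math-frame Cartesian coordinates from polar columns.
polar_to_cartesian <- function(r, theta) {
  t <- theta * pi / 180
  list(u = r * cos(t), v = r * sin(t))
}
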