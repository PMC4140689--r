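#' Pairing tolerances
#'
#' The four thresholds that decide whether two keypoints mirror each other
#' across a candidate axis:
#' \describe{
#'   \item{theta_r}{maximum `|r1 - r2|`, pixels. `NULL` resolves to 2% of
#'     the constellation's radial range at pairing time.}
#'   \item{theta_theta}{maximum angular mirror residual, degrees. `NULL`
#'     resolves to one axis-sweep increment (`delta_alpha`).}
#'   \item{grad_mag_tol}{gradient-magnitude difference band (the `+/-5`
#'     band), applied after magnitudes are normalised so the constellation
#'     maximum is `magnitude_scale`.}
#'   \item{grad_ori_tol}{gradient-orientation band in histogram bins (the
#'     `+/-2` band), circular distance after mirror reflection.}
#' }
#'
#' @param theta_r Pixels, or `NULL` for the scale-free default.
#' @param theta_theta Degrees, or `NULL` for one sweep increment.
#' @param grad_mag_tol Magnitude band half-width (default 5).
#' @param grad_ori_tol Orientation band half-width in bins (default 2).
#' @param r_range Radial range used to resolve `theta_r = NULL`.
#' @param delta_alpha Sweep increment used to resolve `theta_theta = NULL`.
#' @return List of four nonnegative tolerances (class `symaxis_tolerances`).
#' @export
pair_tolerances <- function(theta_r = NULL, theta_theta = NULL,
                            grad_mag_tol = 5, grad_ori_tol = 2,
                            r_range = NULL, delta_alpha = 1) {
  if (is.null(theta_r)) {
    if (is.null(r_range)) {
      stop("theta_r is NULL and no r_range given to resolve it", call. = FALSE)
    }
    theta_r <- 0.02 * r_range
  }
  if (is.null(theta_theta)) theta_theta <- delta_alpha
  tol <- list(theta_r = theta_r, theta_theta = theta_theta,
              grad_mag_tol = grad_mag_tol, grad_ori_tol = grad_ori_tol)
  if (any(unlist(tol) < 0)) stop("tolerances must be >= 0", call. = FALSE)
  structure(tol, class = "symaxis_tolerances")
}

#' Geometric mirror test for a candidate axis
#'
#' Two polar points mirror each other across the line through the origin at
#' angle `alpha` when their radii agree within `theta_r` and the angular
#' residual `wrap(theta1 + theta2 - 2 alpha)` lies within `theta_theta`.
#' At `alpha = 0` this is exactly the polar-axis rule `r1 = r2`,
#' `theta1 = -theta2` (within tolerances). Comparisons are inclusive.
#'
#' @param r1,theta1,r2,theta2 Polar coordinates (pixels / degrees);
#'   vectorised.
#' @param alpha Candidate axis angle, degrees in `[0, 180)`.
#' @param tol `symaxis_tolerances`.
#' @return Logical vector.
#' @export
geometric_pair_test <- function(r1, theta1, r2, theta2, alpha, tol) {
  abs(r1 - r2) <= tol$theta_r &
    abs(wrap_angle(theta1 + theta2 - 2 * alpha)) <= tol$theta_theta
}

#' Reflect a gradient orientation across an axis
#'
#' Reflection across a line at angle `alpha` maps direction `q` to
#' `2 alpha - q` (mod 360).
#'
#' @param q Orientation(s), degrees.
#' @param alpha Axis angle, degrees.
#' @return Reflected orientation(s) in `[0, 360)`.
#' @export
reflect_orientation <- function(q, alpha) {
  (2 * alpha - q) %% 360
}

#' Gradient-consistency mirror test
#'
#' Magnitudes must agree within `grad_mag_tol` (callers are expected to
#' normalise; [find_symmetric_pairs()] rescales the constellation maximum to
#' the configured scale first) and the circular distance between `q1` and
#' the mirror reflection of `q2` about the axis must not exceed
#' `grad_ori_tol` histogram bins.
#'
#' @param m1,q1,m2,q2 Gradient magnitudes and orientations (degrees);
#'   vectorised. `NA` orientation (unoriented keypoint) fails the test.
#' @param alpha Candidate axis angle, degrees.
#' @param tol `symaxis_tolerances`.
#' @param bin_width Histogram bin width in degrees (default 10).
#' @return Logical vector (`FALSE`, never `NA`, for unoriented input).
#' @export
gradient_pair_test <- function(m1, q1, m2, q2, alpha, tol, bin_width = 10) {
  ok_mag <- abs(m1 - m2) <= tol$grad_mag_tol
  d <- abs(wrap_angle(q1 - reflect_orientation(q2, alpha)))
  ok_ori <- d / bin_width <= tol$grad_ori_tol
  out <- ok_mag & ok_ori
  out[is.na(out)] <- FALSE
  out
}

# Precompute everything alpha-independent for a constellation so the axis
# sweep only re-evaluates the two angular terms. `points` must carry
# r, theta, grad_magnitude, grad_orientation, unoriented.
pair_precompute <- function(points, magnitude_scale = 100,
                            normalize_magnitude = TRUE) {
  usable <- which(!points$unoriented & points$r >= 1)
  n <- length(usable)
  if (n < 2L) {
    return(list(usable = usable, i = integer(), j = integer()))
  }
  idx <- usable
  m <- points$grad_magnitude[idx]
  if (normalize_magnitude && max(m) > 0) m <- m / max(m) * magnitude_scale
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  list(usable = idx,
       i = idx[ii], j = idx[jj],
       rdiff = abs(points$r[idx[ii]] - points$r[idx[jj]]),
       thsum = points$theta[idx[ii]] + points$theta[idx[jj]],
       mdiff = abs(m[ii] - m[jj]),
       qsum = (points$grad_orientation[idx[ii]] +
               points$grad_orientation[idx[jj]]) %% 360)
}

# Evaluate one candidate axis on a precomputed constellation and apply the
# greedy one-to-one assignment. Returns a pair table (possibly 0 rows).
pairs_at_alpha <- function(pre, points, alpha, tol, bin_width = 10) {
  empty <- data.frame(i = integer(), j = integer(),
                      axis_angle = numeric(),
                      residual_r = numeric(), residual_theta = numeric(),
                      residual = numeric(),
                      mid_u = numeric(), mid_v = numeric())
  if (length(pre$i) == 0L) return(empty)
  res_theta <- wrap_angle(pre$thsum - 2 * alpha)
  geo <- pre$rdiff <= tol$theta_r & abs(res_theta) <= tol$theta_theta
  # orientation mirror: |wrap(q1 - (2a - q2))| = |wrap(q1 + q2 - 2a)|
  ori <- abs(wrap_angle(pre$qsum - 2 * alpha)) / bin_width <= tol$grad_ori_tol
  ok <- which(geo & pre$mdiff <= tol$grad_mag_tol & ori)
  if (length(ok) == 0L) return(empty)
  rel <- function(x, t) if (t > 0) x / t else ifelse(x == 0, 0, Inf)
  resid <- rel(pre$rdiff[ok], tol$theta_r) +
    rel(abs(res_theta[ok]), tol$theta_theta)
  perm <- order(resid, pre$i[ok], pre$j[ok])
  ord <- ok[perm]
  resid <- resid[perm]
  used <- logical(nrow(points))
  keep <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- pre$i[ord[k]]; j <- pre$j[ord[k]]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  sel <- ord[keep]
  uv_i <- polar_to_cartesian(points$r[pre$i[sel]], points$theta[pre$i[sel]])
  uv_j <- polar_to_cartesian(points$r[pre$j[sel]], points$theta[pre$j[sel]])
  data.frame(i = pre$i[sel], j = pre$j[sel],
             axis_angle = alpha,
             residual_r = pre$rdiff[sel],
             residual_theta = abs(wrap_angle(pre$thsum[sel] - 2 * alpha)),
             residual = resid[keep],
             mid_u = (uv_i$u + uv_j$u) / 2,
             mid_v = (uv_i$v + uv_j$v) / 2)
}

#' Find symmetric keypoint pairs for one candidate axis
#'
#' Enumerates all point pairs, keeps those passing both the geometric
#' ([geometric_pair_test()]) and gradient ([gradient_pair_test()]) mirror
#' tests, and greedily assigns them one-to-one: candidates are sorted by
#' ascending combined residual (`|dr|/theta_r + |dtheta|/theta_theta`, ties
#' broken lexicographically on the point indices) and taken while both
#' endpoints are unused. Unoriented keypoints and points closer than 1 px to
#' the centroid (which lie on every axis) are excluded. Gradient magnitudes
#' are normalised so the constellation maximum equals `magnitude_scale`
#' before the `grad_mag_tol` band is applied.
#'
#' @param points Keypoint `data.frame` carrying polar columns (`r`, `theta`
#'   from [to_polar()]) and gradient columns.
#' @param alpha Candidate axis angle, degrees in `[0, 180)`.
#' @param tol `symaxis_tolerances`; `NULL` resolves defaults from the
#'   constellation (`theta_r` = 2% of radial range, `theta_theta` =
#'   `delta_alpha`).
#' @param bin_width Orientation histogram bin width, degrees.
#' @param delta_alpha Sweep increment used only to resolve a `NULL`
#'   `theta_theta`.
#' @param magnitude_scale Normalised constellation maximum magnitude.
#' @param normalize_magnitude Set `FALSE` to compare raw magnitudes.
#' @return `data.frame` with one row per accepted pair: point indices `i`,
#'   `j` (rows of `points`), `axis_angle`, residuals, and the pair midpoint
#'   (`mid_u`, `mid_v`) in centred math-frame coordinates.
#' @export
find_symmetric_pairs <- function(points, alpha, tol = NULL, bin_width = 10,
                                 delta_alpha = 1, magnitude_scale = 100,
                                 normalize_magnitude = TRUE) {
  if (nrow(points) < 2L) {
    stop("need at least 2 points to pair", call. = FALSE)
  }
  if (is.null(tol)) {
    tol <- pair_tolerances(r_range = diff(range(points$r)),
                           delta_alpha = delta_alpha)
  }
  pre <- pair_precompute(points, magnitude_scale = magnitude_scale,
                         normalize_magnitude = normalize_magnitude)
  pairs_at_alpha(pre, points, alpha, tol, bin_width = bin_width)
}
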