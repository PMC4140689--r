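# Independent oracles used by the property and acceptance tests. These are
# deliberately written from the definitions, without reusing the package's
# pairing internals.

# Fold an angle into (-180, 180].
oracle_wrap <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

# Exhaustive O(N^2) mirror-pair enumeration plus the greedy one-to-one
# assignment (sort by combined residual, tie-break on the point indices).
# Returns a two-column matrix of row indices into `points`.
oracle_pairs <- function(points, alpha, tol, bin_width = 10,
                         magnitude_scale = 100) {
  use <- which(!points$unoriented & points$r >= 1)
  n <- length(use)
  if (n < 2) return(matrix(integer(), ncol = 2))
  m <- points$grad_magnitude[use]
  if (max(m) > 0) m <- m / max(m) * magnitude_scale
  r <- points$r[use]; th <- points$theta[use]; q <- points$grad_orientation[use]
  dr <- abs(outer(r, r, "-"))
  dth <- abs(oracle_wrap(outer(th, th, "+") - 2 * alpha))
  dm <- abs(outer(m, m, "-"))
  # |Q_i - reflect(Q_j)| = |wrap(Q_i + Q_j - 2 alpha)|
  dq <- abs(oracle_wrap(outer(q, q, "+") - 2 * alpha))
  pass <- dr <= tol$theta_r & dth <= tol$theta_theta &
    dm <= tol$grad_mag_tol & dq / bin_width <= tol$grad_ori_tol
  idx <- which(upper.tri(pass) & pass, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(), ncol = 2))
  rel <- function(x, t) if (t > 0) x / t else ifelse(x == 0, 0, Inf)
  resid <- rel(dr[idx], tol$theta_r) + rel(dth[idx], tol$theta_theta)
  ord <- order(resid, use[idx[, 1]], use[idx[, 2]])
  taken <- logical(nrow(points))
  out <- matrix(integer(), ncol = 2)
  for (k in ord) {
    i <- use[idx[k, 1]]; j <- use[idx[k, 2]]
    if (!taken[i] && !taken[j]) {
      taken[i] <- taken[j] <- TRUE
      out <- rbind(out, c(i, j))
    }
  }
  out
}

# Circular distance between undirected axis angles, degrees in [0, 90].
oracle_axis_err <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# A small high-contrast blob on a flat background, for detector tests.
blob_image <- function(size = 48, cx = 20, cy = 28, sigma = 3, amp = 0.8) {
  x <- matrix(0:(size - 1), size, size, byrow = TRUE)
  y <- matrix(0:(size - 1), size, size)
  0.1 + amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
}

# Keypoint table builder for hand-made pairing cases.
mk_points <- function(r, theta, M = 50, Q = 0, unoriented = FALSE) {
  n <- length(r)
  data.frame(x = r * cos(theta * pi / 180), y = -r * sin(theta * pi / 180),
             scale = rep(2, n),
             grad_magnitude = rep_len(M, n),
             grad_orientation = rep_len(Q, n),
             unoriented = rep_len(unoriented, n),
             r = r, theta = theta)
}
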