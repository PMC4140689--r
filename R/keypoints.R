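#' Keypoint tables
#'
#' Keypoints are rows of a plain `data.frame` with columns:
#' \describe{
#'   \item{x, y}{0-based pixel coordinates (x = column, y = row, y down).}
#'   \item{scale}{detection scale in pixels (sigma of the scale-space level).}
#'   \item{grad_magnitude}{weighted gradient-histogram peak mass, `M`; `NA`
#'     until [gradient_features()] has run.}
#'   \item{grad_orientation}{peak-bin centre in degrees, `[0, 360)`, `Q`.}
#'   \item{unoriented}{`TRUE` when the histogram peak fell below the
#'     assignment floor; such points are excluded from pairing.}
#' }
#' @name symaxis-keypoints
NULL

new_keypoints <- function(x = numeric(), y = numeric(), scale = numeric()) {
  data.frame(x = x, y = y, scale = scale,
             grad_magnitude = rep(NA_real_, length(x)),
             grad_orientation = rep(NA_real_, length(x)),
             unoriented = rep(TRUE, length(x)))
}

#' Extract scale-invariant keypoints from an intensity image
#'
#' Deterministic difference-of-Gaussians (DoG) scale-space extremum detector:
#' a Gaussian pyramid is built per octave, adjacent levels are subtracted,
#' and local extrema over a 3x3x3 neighbourhood that pass a contrast
#' threshold and an edge-response (principal-curvature ratio) test become
#' keypoints. Locations are refined to subpixel accuracy by a quadratic fit.
#' The result is identical across runs for fixed inputs and parameters.
#'
#' @param image Single-channel numeric matrix; values above 1 are assumed
#'   8-bit and divided by 255. Minimum dimension 16 px.
#' @param contrast_thresh Minimum |DoG| response (image scaled to `[0,1]`).
#' @param edge_ratio Maximum ratio of principal curvatures (Lowe-style
#'   `tr^2/det < (r+1)^2/r` test).
#' @param intervals Scale samples per octave.
#' @param sigma0 Base scale of the first pyramid level, pixels.
#' @param n_octaves Number of octaves; default chosen from the image size.
#' @return Keypoint `data.frame` (see [symaxis-keypoints]) sorted by
#'   `(x, y, scale)`; gradient columns are `NA` until [gradient_features()].
#' @export
extract_keypoints <- function(image, contrast_thresh = 0.015,
                              edge_ratio = 10, intervals = 3,
                              sigma0 = 1.6, n_octaves = NULL) {
  if (!is.matrix(image)) stop("expected a single-channel matrix", call. = FALSE)
  if (min(dim(image)) < 16L) {
    stop("image too small: minimum dimension is 16 px", call. = FALSE)
  }
  img <- image
  if (max(img) > 1.5) img <- img / 255
  if (is.null(n_octaves)) {
    n_octaves <- max(1L, floor(log2(min(dim(img)) / 16)) + 1L)
  }
  s <- intervals
  # assumed capture blur 0.5 px; lift the base image to sigma0
  base <- blur_gaussian(img, sqrt(max(sigma0^2 - 0.25, 1e-8)))
  kp_x <- kp_y <- kp_s <- numeric()
  edge_lim <- (edge_ratio + 1)^2 / edge_ratio
  for (oct in seq_len(n_octaves) - 1L) {
    gauss <- vector("list", s + 3L)
    gauss[[1L]] <- base
    for (i in 2L:(s + 3L)) {
      sp <- sigma0 * 2^((i - 2) / s)
      sn <- sigma0 * 2^((i - 1) / s)
      gauss[[i]] <- blur_gaussian(gauss[[i - 1L]], sqrt(sn^2 - sp^2))
    }
    dog <- lapply(seq_len(s + 2L), function(i) gauss[[i + 1L]] - gauss[[i]])
    h <- nrow(base); w <- ncol(base)
    if (h >= 3L && w >= 3L) {
      ri <- 2L:(h - 1L); ci <- 2L:(w - 1L)
      for (j in 2L:(s + 1L)) {
        d <- dog[[j]]
        v <- d[ri, ci, drop = FALSE]
        nmax <- matrix(-Inf, length(ri), length(ci))
        nmin <- matrix(Inf, length(ri), length(ci))
        for (lay in (j - 1L):(j + 1L)) {
          dd <- dog[[lay]]
          for (dr in -1L:1L) for (dc in -1L:1L) {
            if (lay == j && dr == 0L && dc == 0L) next
            nb <- dd[ri + dr, ci + dc, drop = FALSE]
            nmax <- pmax(nmax, nb)
            nmin <- pmin(nmin, nb)
          }
        }
        cand <- which((v > nmax | v < nmin) & abs(v) > contrast_thresh,
                      arr.ind = TRUE)
        if (nrow(cand) == 0L) next
        for (k in seq_len(nrow(cand))) {
          r <- cand[k, 1L] + 1L; c <- cand[k, 2L] + 1L   # absolute indices
          dxx <- d[r, c + 1L] + d[r, c - 1L] - 2 * d[r, c]
          dyy <- d[r + 1L, c] + d[r - 1L, c] - 2 * d[r, c]
          dxy <- (d[r + 1L, c + 1L] - d[r + 1L, c - 1L] -
                  d[r - 1L, c + 1L] + d[r - 1L, c - 1L]) / 4
          det <- dxx * dyy - dxy^2
          if (det <= 0 || (dxx + dyy)^2 / det >= edge_lim) next
          gx <- (d[r, c + 1L] - d[r, c - 1L]) / 2
          gy <- (d[r + 1L, c] - d[r - 1L, c]) / 2
          off <- c(0, 0)
          if (abs(det) > 1e-12) {
            off <- -solve(matrix(c(dxx, dxy, dxy, dyy), 2L), c(gx, gy))
            off <- pmin(pmax(off, -0.6), 0.6)
          }
          kp_x <- c(kp_x, (c - 1L + off[1]) * 2^oct)
          kp_y <- c(kp_y, (r - 1L + off[2]) * 2^oct)
          kp_s <- c(kp_s, sigma0 * 2^((j - 1) / s) * 2^oct)
        }
      }
    }
    base <- downsample2(gauss[[s + 1L]])
    if (min(dim(base)) < 8L) break
  }
  kp <- new_keypoints(kp_x, kp_y, kp_s)
  kp <- kp[kp$x >= 0 & kp$x < ncol(image) & kp$y >= 0 & kp$y < nrow(image), ]
  kp <- kp[order(kp$x, kp$y, kp$scale), ]
  rownames(kp) <- NULL
  kp
}

# Bilinear lookup at fractional 0-based coordinates, clamped (replicate)
# to the image, preserving the shape of the coordinate matrices.
sample_clamped <- function(image, px, py) {
  h <- nrow(image); w <- ncol(image)
  px <- pmin(pmax(px, 0), w - 1); py <- pmin(pmax(py, 0), h - 1)
  x0 <- pmin(floor(px), w - 2); y0 <- pmin(floor(py), h - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- px - x0; fy <- py - y0
  at <- function(yy, xx) image[cbind(as.vector(yy) + 1L, as.vector(xx) + 1L)]
  v <- (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x0 + 1) +
       (1 - fx) * fy * at(y0 + 1, x0) + fx * fy * at(y0 + 1, x0 + 1)
  if (is.matrix(px)) matrix(v, nrow(px), ncol(px)) else v
}

#' Gaussian-weighted gradient orientation histogram around a point
#'
#' The window is sampled at unit spacing centred exactly on the (subpixel)
#' point via bilinear interpolation, so two keypoints that mirror each other
#' see mirrored windows regardless of where they fall on the pixel grid.
#' Per-sample gradients are taken by central differences; at the image
#' border the stencil is clamped to the image (one-sided, divided by the
#' actual sample span). Gradient magnitudes are weighted by a Gaussian
#' centred on the point and accumulated into an orientation histogram.
#'
#' @param image Single-channel matrix.
#' @param x,y Point location, 0-based pixel coordinates.
#' @param window Window side length in pixels (default 16).
#' @param sigma Gaussian weighting sigma, pixels.
#' @param n_bins Number of orientation bins (>= 4); bin width is
#'   `360 / n_bins` degrees.
#' @param smooth_passes Circular box-smoothing passes applied to the
#'   finished histogram (kernel `c(1,1,1)/3`, default 2). Smoothing keeps
#'   the total mass but makes the peak bin — and hence the assigned `M`
#'   and `Q` — insensitive to how a narrow orientation ridge happens to
#'   straddle a bin boundary.
#' @return List with `weights` (length `n_bins`), `n_bins`, `bin_width`, and
#'   `clipped` (`TRUE` when the window (plus its 1-px gradient margin) ran
#'   over the image border and was clamped).
#' @export
orientation_histogram <- function(image, x, y, window = 16, sigma = 2.4,
                                  n_bins = 36, smooth_passes = 2) {
  if (n_bins < 4L) stop("n_bins must be >= 4", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (window > min(h, w)) {
    stop("invalid parameter: window larger than image", call. = FALSE)
  }
  half <- window %/% 2L
  offs <- if (window %% 2L == 0L) (-half):(half - 1L) else (-half):half
  px <- x + matrix(offs, length(offs), length(offs), byrow = TRUE)
  py <- y + matrix(offs, length(offs), length(offs))
  clipped <- any(px < 1 | px > w - 2 | py < 1 | py > h - 2)
  cx <- function(v) pmin(pmax(v, 0), w - 1)
  cy <- function(v) pmin(pmax(v, 0), h - 1)
  sx <- cx(px + 1) - cx(px - 1)
  sy <- cy(py + 1) - cy(py - 1)
  gx <- (sample_clamped(image, cx(px + 1), cy(py)) -
         sample_clamped(image, cx(px - 1), cy(py)))
  gx <- ifelse(sx > 0, gx / sx, 0)   # zero span: window fully past the border
  # flip raster y so the gradient lives in math orientation (y up)
  gy_math <- (sample_clamped(image, cx(px), cy(py - 1)) -
              sample_clamped(image, cx(px), cy(py + 1)))
  gy_math <- ifelse(sy > 0, gy_math / sy, 0)
  mag <- sqrt(gx^2 + gy_math^2)
  ori <- (atan2(gy_math, gx) * 180 / pi) %% 360
  wgt <- exp(-((px - x)^2 + (py - y)^2) / (2 * sigma^2))
  bw <- 360 / n_bins
  bin <- pmin(floor(ori / bw), n_bins - 1L) + 1L
  weights <- vapply(seq_len(n_bins),
                    function(b) sum(mag[bin == b] * wgt[bin == b]), 0)
  for (k in seq_len(smooth_passes)) {
    weights <- (weights + c(weights[-1], weights[1]) +
                c(weights[n_bins], weights[-n_bins])) / 3
  }
  list(weights = weights, n_bins = n_bins, bin_width = bw, clipped = clipped)
}

#' Assign gradient magnitude and orientation to keypoints
#'
#' For each keypoint an orientation histogram ([orientation_histogram()]) is
#' built; the keypoint's orientation `Q` is the centre of the peak bin and
#' its magnitude `M` is the peak-bin mass. When the peak holds less than
#' `floor_frac` of the total histogram mass (or the window is flat) the
#' keypoint is flagged `unoriented` and later excluded from pairing. Windows
#' running over the image border are clipped; a single summary warning is
#' emitted when that happens.
#'
#' @param image Single-channel matrix.
#' @param keypoints Keypoint `data.frame` from [extract_keypoints()].
#' @param window Window side length, pixels (default 16).
#' @param sigma Gaussian weighting sigma; default `sigma_factor * scale`
#'   per keypoint.
#' @param sigma_factor Multiplier on the keypoint scale when `sigma` is
#'   `NULL` (default 1.5).
#' @param n_bins Orientation bins (default 36, 10 degrees per bin).
#' @param floor_frac Peak-mass assignment floor as a fraction of total
#'   histogram mass (default 0.05).
#' @return The keypoint `data.frame` with `grad_magnitude`,
#'   `grad_orientation` and `unoriented` filled in.
#' @export
gradient_features <- function(image, keypoints, window = 16, sigma = NULL,
                              sigma_factor = 1.5, n_bins = 36,
                              floor_frac = 0.05) {
  if (nrow(keypoints) == 0L) return(keypoints)
  n_clipped <- 0L
  for (i in seq_len(nrow(keypoints))) {
    sg <- if (is.null(sigma)) sigma_factor * keypoints$scale[i] else sigma
    hist <- orientation_histogram(image, keypoints$x[i], keypoints$y[i],
                                  window = window, sigma = sg,
                                  n_bins = n_bins)
    if (hist$clipped) n_clipped <- n_clipped + 1L
    total <- sum(hist$weights)
    peak <- which.max(hist$weights)
    peak_mass <- if (length(peak)) hist$weights[peak] else 0
    keypoints$grad_magnitude[i] <- peak_mass
    if (!length(peak) || total <= 0 || peak_mass < floor_frac * total) {
      keypoints$grad_orientation[i] <- NA_real_
      keypoints$unoriented[i] <- TRUE
    } else {
      keypoints$grad_orientation[i] <- (peak - 1) * hist$bin_width +
        hist$bin_width / 2
      keypoints$unoriented[i] <- FALSE
    }
  }
  if (n_clipped > 0L) {
    warning(sprintf("%d keypoint window(s) clipped at the image border",
                    n_clipped), call. = FALSE)
  }
  keypoints
}

#' Write / read keypoint tables
#'
#' CSV or JSON with columns `x, y, scale, grad_magnitude, grad_orientation,
#' unoriented` (plus any extra columns present, e.g. `r`, `theta`).
#'
#' @param keypoints Keypoint `data.frame`.
#' @param path Output file; format inferred from the `.csv` / `.json`
#'   extension unless `format` is given.
#' @param format `"csv"`, `"json"`, or `NULL` to infer.
#' @return `path` invisibly (writer); keypoint `data.frame` (reader).
#' @export
write_keypoints <- function(keypoints, path, format = NULL) {
  format <- format %||% infer_format(path)
  if (format == "csv") {
    utils::write.csv(keypoints, path, row.names = FALSE)
  } else {
    jsonlite::write_json(keypoints, path, dataframe = "columns",
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_keypoints
#' @export
read_keypoints <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  df <- if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  need <- c("x", "y", "scale", "grad_magnitude", "grad_orientation",
            "unoriented")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("keypoint table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$unoriented <- as.logical(df$unoriented)
  df
}

infer_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
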