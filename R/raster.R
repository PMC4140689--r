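#' Raster images in symaxis
#'
#' Grayscale images are plain numeric matrices (rows = image rows, columns =
#' image columns); RGB images are numeric arrays of dimension
#' `height x width x 3`. Pixel coordinates are 0-based: pixel `(x, y)` lives
#' at `m[y + 1, x + 1]`, with `y` increasing downwards (raster convention).
#' Intensities are arbitrary nonnegative numbers; functions that need a
#' normalised range rescale internally.
#'
#' @name symaxis-raster
NULL

#' Convert an image to a single-channel intensity raster
#'
#' RGB channels are combined with luminance weights; an already-gray image is
#' returned unchanged. Optional Gaussian smoothing is available but off by
#' default.
#'
#' @param image Numeric matrix (gray) or `h x w x 3` array (RGB).
#' @param weights Length-3 channel weights, normalised to sum to 1.
#'   Default Rec. 601 luma: (0.299, 0.587, 0.114).
#' @param smooth_sigma Gaussian smoothing sigma in pixels; 0 (default)
#'   disables smoothing.
#' @return Numeric matrix with the same width and height as the input.
#' @export
to_intensity <- function(image, weights = c(0.299, 0.587, 0.114),
                         smooth_sigma = 0) {
  if (is.null(image) || length(image) == 0L) {
    stop("invalid input: empty image", call. = FALSE)
  }
  if (is.matrix(image)) {
    out <- image
  } else if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] == 1L) {
      out <- image[, , 1L]
    } else {
      if (dim(image)[3] != 3L) {
        stop("invalid input: expected 1 or 3 channels", call. = FALSE)
      }
      w <- weights / sum(weights)
      out <- w[1] * image[, , 1L] + w[2] * image[, , 2L] + w[3] * image[, , 3L]
    }
  } else {
    stop("invalid input: image must be a matrix or h x w x 3 array",
         call. = FALSE)
  }
  if (nrow(out) == 0L || ncol(out) == 0L) {
    stop("invalid input: empty image", call. = FALSE)
  }
  if (smooth_sigma > 0) out <- blur_gaussian(out, smooth_sigma)
  out
}

#' One-dimensional Gaussian kernel
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Half-width; defaults to `ceiling(3 * sigma)`.
#' @return Normalised numeric vector of length `2 * radius + 1`.
#' @keywords internal
gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix with replicate boundary handling: row i holds the
# kernel centred at i with out-of-range taps folded onto the border samples.
conv_matrix <- function(n, kernel) {
  radius <- (length(kernel) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (off in seq_along(kernel)) {
    j <- pmin(pmax(seq_len(n) + (off - 1L - radius), 1L), n)
    m[cbind(seq_len(n), j)] <- m[cbind(seq_len(n), j)] + kernel[off]
  }
  m
}

#' Separable Gaussian blur
#'
#' Replicate (clamp) boundary handling, exact separable convolution.
#'
#' @param image Numeric matrix.
#' @param sigma Standard deviation in pixels; values below 1e-6 return the
#'   input unchanged.
#' @return Blurred matrix of identical dimensions.
#' @export
blur_gaussian <- function(image, sigma) {
  if (sigma < 1e-6) return(image)
  k <- gaussian_kernel1d(sigma)
  conv_matrix(nrow(image), k) %*% image %*% t(conv_matrix(ncol(image), k))
}

# Keep every other sample starting at the first row/column.
downsample2 <- function(image) {
  image[seq(1L, nrow(image), by = 2L), seq(1L, ncol(image), by = 2L),
        drop = FALSE]
}

#' Rotate an image about a point
#'
#' Rotation is counter-clockwise in conventional math orientation (y up),
#' i.e. a feature at axis angle `alpha` moves to `alpha + angle`.
#' Catmull-Rom bicubic interpolation (bilinear would blur anisotropically
#' and measurably shift blob extrema); samples falling outside the source
#' are filled with `fill`.
#'
#' @param image Numeric matrix.
#' @param angle Rotation angle in degrees, counter-clockwise positive.
#' @param center Length-2 vector `c(x, y)` in 0-based pixel coordinates;
#'   defaults to the image centre.
#' @param fill Fill value for out-of-image samples.
#' @return Rotated matrix, same dimensions.
#' @export
rotate_image <- function(image, angle, center = NULL, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  a <- angle * pi / 180
  x <- matrix(0:(w - 1), h, w, byrow = TRUE) - center[1]
  y <- center[2] - matrix(0:(h - 1), h, w)        # math orientation, y up
  # inverse map: rotate output coords by -angle to find the source sample
  xs <- cos(a) * x + sin(a) * y
  ys <- -sin(a) * x + cos(a) * y
  px <- center[1] + xs
  py <- center[2] - ys
  bicubic_sample(image, px, py, fill)
}

# Catmull-Rom weight for offsets in [-2, 2].
catmull_rom <- function(t) {
  at <- abs(t)
  ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

# Bicubic lookup at fractional 0-based coordinates (matrices px, py);
# taps are clamped to the image, fully-outside samples get `fill`.
bicubic_sample <- function(image, px, py, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  inside <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  acc <- matrix(0, nrow(px), ncol(px))
  for (dy in -1:2) {
    wy <- catmull_rom(dy - fy)
    ry <- pmin(pmax(y0 + dy, 0), h - 1)
    for (dx in -1:2) {
      wx <- catmull_rom(dx - fx)
      rx <- pmin(pmax(x0 + dx, 0), w - 1)
      vals <- matrix(image[cbind(as.vector(ry) + 1L, as.vector(rx) + 1L)],
                     nrow(px), ncol(px))
      acc <- acc + wy * wx * vals
    }
  }
  acc[!inside] <- fill
  acc
}

# Bilinear lookup at fractional 0-based pixel coordinates (matrices px, py).
bilinear_sample <- function(image, px, py, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  inside <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
  cx0 <- pmin(pmax(x0, 0), w - 1); cy0 <- pmin(pmax(y0, 0), h - 1)
  cx1 <- pmin(cx0 + 1, w - 1);     cy1 <- pmin(cy0 + 1, h - 1)
  idx <- function(yy, xx) image[cbind(as.vector(yy) + 1L, as.vector(xx) + 1L)]
  v <- (1 - fx) * (1 - fy) * idx(cy0, cx0) +
       fx * (1 - fy) * idx(cy0, cx1) +
       (1 - fx) * fy * idx(cy1, cx0) +
       fx * fy * idx(cy1, cx1)
  out <- matrix(v, h, w)
  out[!inside] <- fill
  out
}

#' Read a plain-text PGM (P2) image
#'
#' The offline toolchain has no PNG/JPEG/TIFF reader, so file-based raster
#' exchange uses the ASCII portable graymap format. Values are returned
#' rescaled to `[0, 1]`.
#'
#' @param path File path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  tokens <- unlist(strsplit(paste(raw, collapse = " "), "[ \t]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 4L || tokens[1] != "P2") {
    stop("not a plain PGM (P2) file: ", path, call. = FALSE)
  }
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.numeric(tokens[4])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != w * h) {
    stop("corrupt PGM: expected ", w * h, " samples, got ", length(vals),
         call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a plain-text PGM (P2) image
#'
#' @param image Numeric matrix; values are clipped to `[0, 1]` after dividing
#'   by `max(image)` when the maximum exceeds 1.
#' @param path Output file path.
#' @param maxval Integer maximum sample value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  m <- image
  if (length(m) && max(m) > 1) m <- m / max(m)
  q <- round(pmin(pmax(m, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  apply_rows <- apply(q, 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}
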