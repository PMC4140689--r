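#' Synthetic ground-truthed fixtures
#'
#' Generators for mirror-symmetric phantom images, asymmetric control
#' constellations and cluttered variants, each with a recorded ground-truth
#' axis, so every pipeline stage is testable without any external data.
#' All generators are bit-reproducible from `(spec, seed)`.
#'
#' Mirrored images are built analytically: smooth primitives (an elongated
#' body Gaussian plus paired anisotropic blobs) are evaluated as functions of
#' the axis-frame coordinates `(|u|, v)` (`u` perpendicular to the axis,
#' `v` along it), so the underlying continuous intensity is exactly
#' mirror-symmetric for any axis angle. For axis-aligned angles the sampled
#' pixel grid maps onto itself under the reflection and the pixel-level
#' identity `I(p) = I(reflect(p))` holds exactly.
#'
#' @name symaxis-fixtures
NULL

#' Specify a synthetic fixture
#'
#' @param kind One of `"mirrored_image"`, `"mirrored_points"`,
#'   `"asymmetric_points"`, `"cluttered_image"`.
#' @param true_alpha Ground-truth axis angle in degrees `[0, 180)`;
#'   required for mirrored kinds, disallowed for asymmetric ones.
#' @param n_points Number of features: blob-pair endpoints for images,
#'   points for constellations (must be even for mirrored points).
#' @param jitter_r,jitter_theta Half-widths of uniform jitter applied to
#'   constellation points, pixels / degrees.
#' @param clutter_density Clutter blobs per 10^4 px^2 (cluttered images).
#' @param seed Integer RNG seed; fixed seed implies bit-identical output.
#' @param size Canvas side length in pixels (images).
#' @return List (class `symaxis_fixture_spec`).
#' @export
fixture_spec <- function(kind = c("mirrored_image", "mirrored_points",
                                  "asymmetric_points", "cluttered_image"),
                         true_alpha = NULL, n_points = 24,
                         jitter_r = 0, jitter_theta = 0,
                         clutter_density = 0, seed = 1, size = 160) {
  kind <- match.arg(kind)
  mirrored <- kind != "asymmetric_points"
  if (mirrored) {
    if (is.null(true_alpha) || true_alpha < 0 || true_alpha >= 180) {
      stop("mirrored fixtures need true_alpha in [0, 180)", call. = FALSE)
    }
  } else if (!is.null(true_alpha)) {
    stop("asymmetric fixtures carry no true_alpha", call. = FALSE)
  }
  if (kind == "mirrored_points" && n_points %% 2 != 0) {
    stop("invalid parameter: mirrored constellations need an even n_points",
         call. = FALSE)
  }
  if (jitter_r < 0 || jitter_theta < 0 || clutter_density < 0) {
    stop("jitters and clutter_density must be >= 0", call. = FALSE)
  }
  structure(list(kind = kind, true_alpha = true_alpha, n_points = n_points,
                 jitter_r = jitter_r, jitter_theta = jitter_theta,
                 clutter_density = clutter_density, seed = as.integer(seed),
                 size = as.integer(size)),
            class = "symaxis_fixture_spec")
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# Axis-frame coordinate grids for an image of side S and axis angle alpha
# through the canvas centre: u perpendicular to the axis, v along it
# (math orientation, y up).
axis_frame <- function(size, alpha) {
  c0 <- (size - 1) / 2
  # sinpi/cospi give exact 0/1 at axis-aligned angles, which makes the
  # sampled image a bit-exact mirror there
  sa <- sinpi(alpha / 180); ca <- cospi(alpha / 180)
  x <- matrix(0:(size - 1), size, size, byrow = TRUE) - c0
  y <- c0 - matrix(0:(size - 1), size, size)
  list(u = -x * sa + y * ca,
       v = x * ca + y * sa,
       center = c(c0, c0))
}

# Draw npair mirrored blob pairs: positions in the axis half-plane with a
# minimum mutual separation, amplitudes of both signs. Blobs are
# anisotropic (random elongation and in-plane angle) so each carries a
# well-defined dominant gradient orientation — isotropic blobs have a
# near-uniform orientation histogram whose peak is decided by sampling
# noise and does not mirror reliably.
sample_blobs <- function(npair, size, min_sep = 0.085 * size) {
  u <- v <- numeric(npair)
  placed <- 0L
  tries <- 0L
  while (placed < npair && tries < 4000L) {
    tries <- tries + 1L
    uu <- stats::runif(1, 0.08 * size, 0.28 * size)
    vv <- stats::runif(1, -0.28 * size, 0.28 * size)
    if (placed == 0L ||
        min(sqrt((u[seq_len(placed)] - uu)^2 +
                 (v[seq_len(placed)] - vv)^2)) >= min_sep) {
      placed <- placed + 1L
      u[placed] <- uu; v[placed] <- vv
    }
  }
  n <- placed
  data.frame(u = u[seq_len(n)], v = v[seq_len(n)],
             sigma = stats::runif(n, 0.014 * size, 0.022 * size),
             aspect = stats::runif(n, 1.8, 3.0),
             phi = stats::runif(n, 0, 180),
             amp = sample(c(-1, 1), n, replace = TRUE) *
               stats::runif(n, 0.30, 0.60))
}

# Anisotropic Gaussian in axis-frame coordinates: centre (u0, v0), major
# axis at angle phi from the v (along-axis) direction.
aniso_blob <- function(u, v, u0, v0, sigma, aspect, phi) {
  sa <- sigma * sqrt(aspect); sb <- sigma / sqrt(aspect)
  p <- phi * pi / 180
  du <- u - u0; dv <- v - v0
  along <- dv * cos(p) + du * sin(p)
  across <- -dv * sin(p) + du * cos(p)
  exp(-(along^2 / (2 * sa^2) + across^2 / (2 * sb^2)))
}

render_mirrored <- function(spec) {
  S <- spec$size
  fr <- axis_frame(S, spec$true_alpha)
  body_su <- stats::runif(1, 0.09, 0.12) * S
  body_sv <- stats::runif(1, 0.20, 0.26) * S
  blobs <- sample_blobs(spec$n_points / 2, S)
  img <- 0.12 + 0.45 * exp(-(fr$u^2 / (2 * body_su^2) +
                             fr$v^2 / (2 * body_sv^2)))
  for (k in seq_len(nrow(blobs))) {
    # the mirror copy sits at -u with its in-plane angle reflected
    g <- aniso_blob(fr$u, fr$v, blobs$u[k], blobs$v[k],
                    blobs$sigma[k], blobs$aspect[k], blobs$phi[k]) +
         aniso_blob(fr$u, fr$v, -blobs$u[k], blobs$v[k],
                    blobs$sigma[k], blobs$aspect[k], -blobs$phi[k])
    img <- img + blobs$amp[k] * g
  }
  list(image = pmin(pmax(img, 0), 1), frame = fr, blobs = blobs)
}

#' Generate a mirror-symmetric phantom image
#'
#' A random smooth half-object (elongated body plus blobs) is mirrored
#' analytically across the line through the canvas centre at
#' `spec$true_alpha`; see [symaxis-fixtures] for the exactness guarantee.
#'
#' @param spec `symaxis_fixture_spec` with kind `"mirrored_image"` (or
#'   `"cluttered_image"`, for internal reuse).
#' @return List (class `symaxis_fixture`) with `image` (matrix in
#'   `[0, 1]`), `truth` (list: `symmetric`, `true_alpha`, `center`, `kind`,
#'   `seed`), and `spec`.
#' @export
make_mirrored_image <- function(spec) {
  stopifnot(inherits(spec, "symaxis_fixture_spec"))
  out <- with_seed(spec$seed, render_mirrored(spec))
  structure(list(image = out$image,
                 truth = list(symmetric = TRUE,
                              true_alpha = spec$true_alpha,
                              center = out$frame$center,
                              kind = spec$kind, seed = spec$seed),
                 spec = spec),
            class = "symaxis_fixture")
}

#' Generate a mirrored phantom over a cluttered background
#'
#' The mirrored object of [make_mirrored_image()] composited with random
#' off-object blobs that generate background keypoints; the ground truth is
#' unchanged. With `clutter_density = 0` the output is identical to the
#' clean mirrored image.
#'
#' @param spec `symaxis_fixture_spec` with kind `"cluttered_image"`.
#' @return `symaxis_fixture` (as [make_mirrored_image()]).
#' @export
make_cluttered_image <- function(spec) {
  stopifnot(inherits(spec, "symaxis_fixture_spec"))
  S <- spec$size
  out <- with_seed(spec$seed, {
    base <- render_mirrored(spec)
    n_clutter <- round(spec$clutter_density * S^2 / 1e4)
    img <- base$image
    if (n_clutter > 0) {
      c0 <- (S - 1) / 2
      x <- matrix(0:(S - 1), S, S, byrow = TRUE)
      y <- matrix(0:(S - 1), S, S)
      placed <- 0L
      while (placed < n_clutter) {
        bx <- stats::runif(1, 0, S - 1); by <- stats::runif(1, 0, S - 1)
        if (sqrt((bx - c0)^2 + (by - c0)^2) < 0.20 * S) next
        sg <- stats::runif(1, 1.5, 3)
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.25, 0.50)
        img <- img + amp * exp(-((x - bx)^2 + (y - by)^2) / (2 * sg^2))
        placed <- placed + 1L
      }
      img <- pmin(pmax(img, 0), 1)
    }
    list(image = img, frame = base$frame)
  })
  structure(list(image = out$image,
                 truth = list(symmetric = TRUE,
                              true_alpha = spec$true_alpha,
                              center = out$frame$center,
                              kind = spec$kind, seed = spec$seed),
                 spec = spec),
            class = "symaxis_fixture")
}

#' Generate a ground-truthed keypoint constellation
#'
#' Mirrored kind: `n_points / 2` random points (polar about the canvas
#' centre) with random gradient attributes, each reflected across the line
#' at `true_alpha` with orientation reflected and magnitude copied; uniform
#' jitter of half-width `jitter_r` / `jitter_theta` is then added to every
#' point. Asymmetric kind: `n_points` uniform random points and attributes,
#' ground truth "no axis".
#'
#' @param spec `symaxis_fixture_spec` with kind `"mirrored_points"` or
#'   `"asymmetric_points"`.
#' @return List (class `symaxis_fixture`) with `points` (keypoint
#'   `data.frame`), `truth`, and `spec`.
#' @export
make_point_constellation <- function(spec) {
  stopifnot(inherits(spec, "symaxis_fixture_spec"))
  S <- spec$size
  c0 <- (S - 1) / 2
  pts <- with_seed(spec$seed, {
    if (spec$kind == "mirrored_points") {
      npair <- spec$n_points / 2
      r <- stats::runif(npair, 10, 0.31 * S)
      th <- stats::runif(npair, -180, 180)
      M <- stats::runif(npair, 20, 100)
      Q <- stats::runif(npair, 0, 360)
      a <- spec$true_alpha
      r_all <- c(r, r)
      th_all <- c(th, wrap_angle(2 * a - th))
      M_all <- c(M, M)
      Q_all <- c(Q, (2 * a - Q) %% 360)
    } else {
      n <- spec$n_points
      r_all <- stats::runif(n, 5, 0.31 * S)
      th_all <- stats::runif(n, -180, 180)
      M_all <- stats::runif(n, 20, 100)
      Q_all <- stats::runif(n, 0, 360)
    }
    n <- length(r_all)
    r_all <- pmax(r_all + stats::runif(n, -spec$jitter_r, spec$jitter_r), 0)
    th_all <- wrap_angle(th_all +
                         stats::runif(n, -spec$jitter_theta,
                                      spec$jitter_theta))
    t <- th_all * pi / 180
    df <- new_keypoints(x = c0 + r_all * cos(t),
                        y = c0 - r_all * sin(t),
                        scale = rep(2, n))
    df$grad_magnitude <- M_all
    df$grad_orientation <- Q_all
    df$unoriented <- FALSE
    df
  })
  truth <- if (spec$kind == "mirrored_points") {
    list(symmetric = TRUE, true_alpha = spec$true_alpha,
         center = c(c0, c0), kind = spec$kind, seed = spec$seed)
  } else {
    list(symmetric = FALSE, true_alpha = NA_real_,
         center = c(c0, c0), kind = spec$kind, seed = spec$seed)
  }
  structure(list(points = pts, truth = truth, spec = spec),
            class = "symaxis_fixture")
}

#' Build the default fixture suite specification
#'
#' Mirrors the cohort structure of the evaluation: clean mirrored images,
#' cluttered mirrored images, and asymmetric control constellations, with
#' declared counts (default 100 / 50 / 50). Ground-truth angles are drawn
#' uniformly on `[0, 180)` and per-fixture seeds derive deterministically
#' from `base_seed`.
#'
#' @param n_clean,n_clutter,n_asym Cohort sizes.
#' @param base_seed Master seed.
#' @param clutter_density Clutter level for the cluttered cohort (default 5
#'   blobs per 10^4 px^2).
#' @param n_points Features per fixture.
#' @param size Canvas side, pixels.
#' @return List of `symaxis_fixture_spec`.
#' @export
fixture_suite_specs <- function(n_clean = 100, n_clutter = 50, n_asym = 50,
                                base_seed = 1, clutter_density = 5,
                                n_points = 24, size = 160) {
  with_seed(base_seed, {
    total <- n_clean + n_clutter + n_asym
    alphas <- stats::runif(n_clean + n_clutter, 0, 180)
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    specs <- vector("list", total)
    for (i in seq_len(n_clean)) {
      specs[[i]] <- fixture_spec("mirrored_image", true_alpha = alphas[i],
                                 n_points = n_points, seed = seeds[i],
                                 size = size)
    }
    for (i in seq_len(n_clutter)) {
      k <- n_clean + i
      specs[[k]] <- fixture_spec("cluttered_image",
                                 true_alpha = alphas[k],
                                 n_points = n_points,
                                 clutter_density = clutter_density,
                                 seed = seeds[k], size = size)
    }
    for (i in seq_len(n_asym)) {
      k <- n_clean + n_clutter + i
      specs[[k]] <- fixture_spec("asymmetric_points", n_points = 60,
                                 seed = seeds[k], size = size)
    }
    specs
  })
}

#' Materialise a fixture from its spec
#'
#' @param spec `symaxis_fixture_spec`.
#' @return `symaxis_fixture`.
#' @export
make_fixture <- function(spec) {
  switch(spec$kind,
         mirrored_image = make_mirrored_image(spec),
         cluttered_image = make_cluttered_image(spec),
         mirrored_points = ,
         asymmetric_points = make_point_constellation(spec))
}

#' Write a fixture suite to disk
#'
#' Images as plain-text PGM, constellations as CSV, plus a JSON manifest
#' recording every spec and ground truth.
#'
#' @param dir Output directory (created if missing).
#' @param specs List of specs, default [fixture_suite_specs()].
#' @return The manifest path, invisibly.
#' @export
write_fixture_suite <- function(dir, specs = fixture_suite_specs()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fx <- make_fixture(specs[[i]])
    file <- if (!is.null(fx$image)) {
      f <- sprintf("fixture_%03d.pgm", i)
      write_pgm(fx$image, file.path(dir, f))
      f
    } else {
      f <- sprintf("fixture_%03d.csv", i)
      write_keypoints(fx$points, file.path(dir, f))
      f
    }
    manifest[[i]] <- c(unclass(specs[[i]]),
                       list(file = file, truth = fx$truth))
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
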