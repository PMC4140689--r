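#' Detector configuration
#'
#' Every tunable of the pipeline in one list. Defaults:
#' \describe{
#'   \item{delta_alpha}{axis sweep increment, degrees (1); must divide 180.}
#'   \item{min_votes}{absolute verdict threshold, or `NULL` to use
#'     `max(3, ceiling(vote_fraction * N / 2))` with `N` the number of
#'     usable keypoints.}
#'   \item{vote_fraction}{relative verdict floor (0.2).}
#'   \item{theta_r, theta_theta}{geometric tolerances; `NULL` = scale-free
#'     defaults (2% of radial range; one increment).}
#'   \item{grad_mag_tol, grad_ori_tol}{gradient bands (+/-5 on magnitudes
#'     normalised to max `magnitude_scale`; +/-2 histogram bins).}
#'   \item{window, n_bins, sigma_factor, orientation_floor}{gradient
#'     histogram parameters (16 px, 36 bins x 10 degrees, 1.5 x scale, 5%).}
#'   \item{contrast_thresh, edge_ratio, intervals, sigma0}{DoG detector
#'     parameters.}
#'   \item{centroid}{`"geometric"` (default), `"median"`, or `"mean"`.}
#'   \item{smooth_sigma}{pre-smoothing during intensity conversion (0 =
#'     off).}
#' }
#'
#' @param ... Overrides of the defaults above.
#' @return Config list (class `symaxis_config`).
#' @export
symaxis_config <- function(...) {
  cfg <- list(delta_alpha = 1, min_votes = NULL, vote_fraction = 0.2,
              theta_r = NULL, theta_theta = NULL,
              grad_mag_tol = 5, grad_ori_tol = 2, magnitude_scale = 100,
              window = 16, n_bins = 36, sigma_factor = 1.5,
              orientation_floor = 0.05,
              contrast_thresh = 0.015, edge_ratio = 10, intervals = 3,
              sigma0 = 1.6,
              centroid = "geometric", smooth_sigma = 0,
              refine_centroid = TRUE, refine_iters = 2,
              coarse_theta_theta = c(20, 8),
              coarse_theta_r_frac = c(0.20, 0.08))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "symaxis_config")
}

#' @export
print.symaxis_config <- function(x, ...) {
  cat("symaxis configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(v)) "(auto)" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a configuration as JSON
#'
#' @param path File path.
#' @param config `symaxis_config`.
#' @return `symaxis_config` (reader); `path` invisibly (writer).
#' @export
read_config <- function(path) {
  do.call(symaxis_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Sweep candidate symmetry axes and collect votes
#'
#' Candidate axes sit at `alpha = 0, delta_alpha, ..., 180 - delta_alpha`
#' (axes are undirected so 180 degrees covers every line). Each candidate's
#' vote count is the number of symmetric pairs found by
#' [find_symmetric_pairs()] at that angle.
#'
#' @param points Keypoint `data.frame` with polar and gradient columns.
#' @param delta_alpha Increment in degrees; must divide 180 evenly.
#' @param tol `symaxis_tolerances`, or `NULL` for defaults resolved from the
#'   constellation.
#' @param bin_width Orientation histogram bin width, degrees.
#' @param magnitude_scale Normalised maximum gradient magnitude.
#' @return List (class `symaxis_candidates`) with `alpha` (vector), `votes`
#'   (vector), `pairs` (list of pair tables), and `tol`.
#' @export
sweep_axes <- function(points, delta_alpha = 1, tol = NULL, bin_width = 10,
                       magnitude_scale = 100) {
  n_cand <- 180 / delta_alpha
  if (abs(n_cand - round(n_cand)) > 1e-9) {
    stop("invalid parameter: delta_alpha must divide 180 evenly",
         call. = FALSE)
  }
  if (nrow(points) < 2L) stop("need at least 2 points", call. = FALSE)
  if (is.null(tol)) {
    tol <- pair_tolerances(r_range = diff(range(points$r)),
                           delta_alpha = delta_alpha)
  }
  alphas <- seq(0, 180 - delta_alpha, by = delta_alpha)
  pre <- pair_precompute(points, magnitude_scale = magnitude_scale)
  pairs <- lapply(alphas, function(a) {
    pairs_at_alpha(pre, points, a, tol, bin_width = bin_width)
  })
  structure(list(alpha = alphas,
                 votes = vapply(pairs, nrow, 0L),
                 pairs = pairs,
                 n_usable = length(pre$usable),
                 tol = tol),
            class = "symaxis_candidates")
}

#' Select the winning axis and issue a verdict
#'
#' The winner is the candidate with the most votes; ties break toward the
#' smallest angle. The verdict is `"symmetric"` when the winner reaches
#' `min_votes`, else `"asymmetric"` (with no best axis reported).
#'
#' @param candidates `symaxis_candidates` from [sweep_axes()].
#' @param min_votes Minimum winning vote count for a symmetric verdict.
#' @return List with `verdict` and `best_axis` (list with `alpha`, `votes`,
#'   `pairs`, or `NULL`).
#' @export
select_axis <- function(candidates, min_votes) {
  if (length(candidates$votes) == 0L) {
    stop("empty candidate list", call. = FALSE)
  }
  best <- which.max(candidates$votes)   # first maximum = smallest alpha
  if (candidates$votes[best] >= min_votes) {
    list(verdict = "symmetric",
         best_axis = list(alpha = candidates$alpha[best],
                          votes = candidates$votes[best],
                          pairs = candidates$pairs[[best]]))
  } else {
    list(verdict = "asymmetric", best_axis = NULL)
  }
}

# Assemble the final report shared by the image and constellation entry
# points.
build_report <- function(verdict, best_axis, centroid, candidates, points,
                         config, counts, log = character(), reason = NULL) {
  min_votes <- counts$min_votes
  rep <- list(verdict = verdict,
              best_axis = best_axis,
              centroid = centroid,
              vote_table = if (!is.null(candidates)) {
                data.frame(alpha = candidates$alpha, votes = candidates$votes)
              },
              keypoints = points,
              parameters = list(config = unclass(config),
                                tol = if (!is.null(candidates))
                                  unclass(candidates$tol),
                                min_votes = min_votes),
              counts = counts,
              reason = reason,
              log = log,
              schema_version = "1.0")
  if (!is.null(best_axis) && !is.null(centroid)) {
    p <- best_axis$pairs
    rep$best_axis$pairs$mid_x <- centroid$x + p$mid_u
    rep$best_axis$pairs$mid_y <- centroid$y - p$mid_v
  }
  structure(rep, class = "symaxis_report")
}

#' Detect the symmetry axis of a keypoint constellation
#'
#' Runs the geometric part of the pipeline on an already-extracted keypoint
#' table: centroid, polar conversion, axis sweep, verdict. Used directly for
#' synthetic constellations and imported keypoint tables; [detect_symmetry()]
#' feeds it after feature extraction.
#'
#' @param points Keypoint `data.frame` (gradient columns required).
#' @param config `symaxis_config`.
#' @return `symaxis_report`.
#' @export
detect_constellation <- function(points, config = symaxis_config()) {
  n_oriented <- sum(!points$unoriented)
  if (nrow(points) < 2L || n_oriented < 2L) {
    return(build_report("undetermined", NULL, NULL, NULL, points, config,
                        counts = list(n_keypoints = nrow(points),
                                      n_oriented = n_oriented,
                                      n_usable = 0L, min_votes = NA_integer_),
                        reason = "fewer than 2 usable keypoints"))
  }
  centroid <- object_centroid(points, config$centroid)
  points <- to_polar(points, centroid)
  usable <- !points$unoriented & points$r >= 1
  n_usable <- sum(usable)
  if (n_usable < 2L) {
    return(build_report("undetermined", NULL, centroid, NULL, points, config,
                        counts = list(n_keypoints = nrow(points),
                                      n_oriented = n_oriented,
                                      n_usable = n_usable,
                                      min_votes = NA_integer_),
                        reason = "fewer than 2 usable keypoints"))
  }
  tight_sweep <- function(pts) {
    ok <- !pts$unoriented & pts$r >= 1
    tol <- pair_tolerances(theta_r = config$theta_r,
                           theta_theta = config$theta_theta,
                           grad_mag_tol = config$grad_mag_tol,
                           grad_ori_tol = config$grad_ori_tol,
                           r_range = diff(range(pts$r[ok])),
                           delta_alpha = config$delta_alpha)
    sweep_axes(pts, delta_alpha = config$delta_alpha, tol = tol,
               bin_width = 360 / config$n_bins,
               magnitude_scale = config$magnitude_scale)
  }
  cand <- tight_sweep(points)
  refined <- FALSE
  if (isTRUE(config$refine_centroid)) {
    # The keypoint centroid can sit several pixels off the true axis
    # (detector stragglers, resampling jitter), which starves the tight
    # angular tolerance. Mirror-pair midpoints lie on the axis regardless
    # of that offset, so anneal: sweep under wide-then-narrow geometric
    # bands and re-anchor the centroid at the midpoints' median each pass.
    # The refined centroid is kept only if it wins more final votes than
    # the original ("propose and verify").
    th_sched <- rep_len(config$coarse_theta_theta, config$refine_iters)
    rf_sched <- rep_len(config$coarse_theta_r_frac, config$refine_iters)
    ct_work <- centroid
    pts_work <- points
    anchored <- FALSE
    for (pass in seq_len(config$refine_iters)) {
      ok <- !pts_work$unoriented & pts_work$r >= 1
      r_range <- diff(range(pts_work$r[ok]))
      coarse <- pair_tolerances(theta_r = rf_sched[pass] * r_range,
                                theta_theta = th_sched[pass],
                                grad_mag_tol = config$grad_mag_tol,
                                grad_ori_tol = config$grad_ori_tol)
      cand1 <- sweep_axes(pts_work, delta_alpha = config$delta_alpha,
                          tol = coarse, bin_width = 360 / config$n_bins,
                          magnitude_scale = config$magnitude_scale)
      b1 <- which.max(cand1$votes)
      p1 <- cand1$pairs[[b1]]
      # an anchor from fewer than 3 midpoints is as likely to teleport the
      # centroid onto a spurious constellation as to help
      if (nrow(p1) < 3L) next
      # The coarse argmax can sit at the edge of a vote plateau several
      # degrees off the true axis; in a tilted frame the along-axis spread
      # of the midpoints leaks into their perpendicular coordinate. Each
      # pair carries its own axis-angle estimate (half its signed angular
      # residual off the candidate), so re-centre the frame on their
      # median first, then take scalar medians of the midpoints' along-
      # and cross-axis components (robust to mispaired outliers).
      signed_res <- wrap_angle(pts_work$theta[p1$i] + pts_work$theta[p1$j] -
                               2 * cand1$alpha[b1])
      a1 <- (cand1$alpha[b1] + stats::median(signed_res) / 2) * pi / 180
      along <- p1$mid_u * cos(a1) + p1$mid_v * sin(a1)
      perp <- -p1$mid_u * sin(a1) + p1$mid_v * cos(a1)
      mu <- stats::median(along) * cos(a1) - stats::median(perp) * sin(a1)
      mv <- stats::median(along) * sin(a1) + stats::median(perp) * cos(a1)
      ct_work <- new_centroid(ct_work$x + mu, ct_work$y - mv, nrow(p1))
      pts_work <- to_polar(points, ct_work)
      anchored <- TRUE
    }
    if (anchored) {
      cand_ref <- tight_sweep(pts_work)
      if (max(cand_ref$votes) > max(cand$votes)) {
        centroid <- ct_work
        points <- pts_work
        cand <- cand_ref
        refined <- TRUE
      }
    }
  }
  usable <- !points$unoriented & points$r >= 1
  n_usable <- sum(usable)
  min_votes <- config$min_votes %||%
    max(3L, ceiling(config$vote_fraction * n_usable / 2))
  sel <- select_axis(cand, min_votes)
  build_report(sel$verdict, sel$best_axis, centroid, cand, points, config,
               counts = list(n_keypoints = nrow(points),
                             n_oriented = n_oriented,
                             n_usable = n_usable,
                             min_votes = min_votes,
                             centroid_refined = refined))
}

#' Detect the bilateral symmetry axis of an image
#'
#' Full pipeline: intensity conversion, DoG keypoint extraction, gradient
#' magnitude/orientation assignment, centroid, polar conversion, candidate
#' axis sweep, vote-based selection.
#'
#' @param image Gray matrix or RGB array (see [symaxis-raster]).
#' @param config `symaxis_config`.
#' @return `symaxis_report` with verdict `"symmetric"`, `"asymmetric"`, or
#'   `"undetermined"` (too few usable keypoints), the winning axis and its
#'   pairs, the full vote table, centroid, keypoints and parameters.
#' @export
detect_symmetry <- function(image, config = symaxis_config()) {
  log <- character()
  gray <- to_intensity(image, smooth_sigma = config$smooth_sigma)
  kp <- extract_keypoints(gray, contrast_thresh = config$contrast_thresh,
                          edge_ratio = config$edge_ratio,
                          intervals = config$intervals,
                          sigma0 = config$sigma0)
  if (nrow(kp) >= 1L) {
    kp <- withCallingHandlers(
      gradient_features(gray, kp, window = config$window,
                        sigma_factor = config$sigma_factor,
                        n_bins = config$n_bins,
                        floor_frac = config$orientation_floor),
      warning = function(w) {
        log <<- c(log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  rep <- detect_constellation(kp, config)
  rep$log <- c(rep$log, log)
  rep
}

#' @export
print.symaxis_report <- function(x, ...) {
  cat("symaxis detection report\n")
  cat(sprintf("  verdict : %s%s\n", x$verdict,
              if (!is.null(x$reason)) paste0(" (", x$reason, ")") else ""))
  if (!is.null(x$best_axis)) {
    cat(sprintf("  axis    : alpha = %g deg, %d vote(s)\n",
                x$best_axis$alpha, x$best_axis$votes))
  }
  if (!is.null(x$centroid)) {
    cat(sprintf("  centroid: (%.2f, %.2f)\n", x$centroid$x, x$centroid$y))
  }
  cat(sprintf("  points  : %d keypoint(s), %d oriented, %d usable\n",
              x$counts$n_keypoints, x$counts$n_oriented, x$counts$n_usable))
  if (!is.na(x$counts$min_votes)) {
    cat(sprintf("  verdict threshold: %d vote(s)\n", x$counts$min_votes))
  }
  invisible(x)
}

#' Render the detected symmetry line onto an image
#'
#' Draws (a) each pair midpoint as a small square mark, (b) the polyline
#' joining midpoints ordered by their projection onto the axis direction,
#' and (c) the straight axis through the centroid at the winning angle.
#' Returns an annotated copy; the input is never mutated.
#'
#' @param report `symaxis_report` with verdict `"symmetric"`.
#' @param image Gray matrix the report was computed from.
#' @param line_value Pixel value for the axis and polyline (default: image
#'   maximum).
#' @param mark_value Pixel value for midpoint marks (default: image
#'   minimum).
#' @return Annotated matrix with identical dimensions.
#' @export
render_symmetry_line <- function(report, image, line_value = NULL,
                                 mark_value = NULL) {
  if (report$verdict != "symmetric") {
    stop("no symmetry axis: verdict is ", report$verdict, call. = FALSE)
  }
  out <- image
  line_value <- line_value %||% max(image)
  mark_value <- mark_value %||% min(image)
  h <- nrow(out); w <- ncol(out)
  cx <- report$centroid$x; cy <- report$centroid$y
  a <- report$best_axis$alpha * pi / 180
  dx <- cos(a); dy <- -sin(a)                  # raster frame: y down
  span <- sqrt(h^2 + w^2)
  p <- report$best_axis$pairs
  if (nrow(p) > 0L) {
    # order midpoints by projection onto the axis direction (math frame)
    proj <- p$mid_u * cos(a) + p$mid_v * sin(a)
    ord <- order(proj)
    mx <- p$mid_x[ord]; my <- p$mid_y[ord]
    for (k in seq_along(mx)) {
      rr <- round(my[k]) + (-1L:1L); cc <- round(mx[k]) + (-1L:1L)
      rr <- rr[rr >= 0 & rr < h]; cc <- cc[cc >= 0 & cc < w]
      out[rr + 1L, cc + 1L] <- mark_value
    }
    if (length(mx) > 1L) {
      for (k in seq_len(length(mx) - 1L)) {
        out <- draw_segment(out, mx[k], my[k], mx[k + 1L], my[k + 1L],
                            line_value)
      }
    }
  }
  # the straight selected axis goes on top of the midpoint drawing
  out <- draw_segment(out, cx - span * dx, cy - span * dy,
                      cx + span * dx, cy + span * dy, line_value)
  out
}

# Dense-sampled segment rasterisation (0-based endpoint coordinates).
draw_segment <- function(image, x0, y0, x1, y1, value) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  xs <- round(x0 + t * (x1 - x0)); ys <- round(y0 + t * (y1 - y0))
  keep <- xs >= 0 & xs < ncol(image) & ys >= 0 & ys < nrow(image)
  image[unique(cbind(ys[keep] + 1L, xs[keep] + 1L))] <- value
  image
}

#' Serialize / restore a detection report as JSON
#'
#' The JSON schema is versioned (`schema_version` field) and carries the
#' verdict, best axis with its pair table, centroid, full vote table,
#' keypoints, counts and parameters — enough to re-threshold verdicts (ROC)
#' without re-running detection.
#'
#' @param report `symaxis_report`.
#' @param path Output / input file path.
#' @return `path` invisibly (writer); `symaxis_report` (reader).
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$centroid <- if (!is.null(x$centroid)) unclass(x$centroid)
  jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$vote_table)) x$vote_table <- as.data.frame(x$vote_table)
  if (!is.null(x$keypoints)) x$keypoints <- as.data.frame(x$keypoints)
  if (!is.null(x$best_axis)) {
    x$best_axis$pairs <- as.data.frame(x$best_axis$pairs)
  }
  if (!is.null(x$centroid)) class(x$centroid) <- "symaxis_centroid"
  structure(x, class = "symaxis_report")
}
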