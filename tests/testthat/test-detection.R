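test_that("sweep_axes enumerates 180/delta_alpha undirected candidates", {
  pts <- mk_points(r = c(10, 10), theta = c(30, 30), M = 50, Q = c(0, 0))
  sw <- sweep_axes(pts, delta_alpha = 1)
  expect_identical(length(sw$alpha), 180L)
  expect_identical(sw$alpha[1], 0)
  expect_identical(sw$alpha[180], 179)
  expect_error(sweep_axes(pts, delta_alpha = 7), "divide 180")
})

test_that("a mirrored pair votes exactly at its axis", {
  pts <- mk_points(r = c(12, 12), theta = c(75, -15), M = 50,
                   Q = c(10, 50))            # mirrors about alpha = 30
  tol <- pair_tolerances(theta_r = 0.5, theta_theta = 0.9)
  sw <- sweep_axes(pts, delta_alpha = 1, tol = tol)
  expect_identical(sw$votes[sw$alpha == 30], 1L)
  expect_identical(sum(sw$votes), 1L)
})

test_that("a 40-point mirrored constellation concentrates votes at truth", {
  fx <- make_point_constellation(
    fixture_spec("mirrored_points", true_alpha = 73, n_points = 40,
                 jitter_r = 0.05, jitter_theta = 0.1, seed = 21))
  pts <- to_polar(fx$points, centroid_geometric(fx$points))
  sw <- sweep_axes(pts, delta_alpha = 1)
  expect_identical(sw$alpha[which.max(sw$votes)], 73)
  expect_identical(max(sw$votes), 20L)
})

test_that("select_axis applies the vote floor and the smallest-alpha tie", {
  cand <- structure(list(alpha = c(0, 45, 90), votes = c(0L, 0L, 0L),
                         pairs = list(NULL, NULL, NULL)),
                    class = "symaxis_candidates")
  sel <- select_axis(cand, min_votes = 3)
  expect_identical(sel$verdict, "asymmetric")
  expect_null(sel$best_axis)
  cand$votes <- c(5L, 2L, 5L)
  sel <- select_axis(cand, min_votes = 3)
  expect_identical(sel$verdict, "symmetric")
  expect_identical(sel$best_axis$alpha, 0)
  expect_error(select_axis(list(votes = integer()), 3), "empty")
})

test_that("detect_symmetry finds the axis of a vertical-mirror phantom", {
  fx <- make_mirrored_image(fixture_spec("mirrored_image", true_alpha = 90,
                                         seed = 31))
  rep <- detect_symmetry(fx$image)
  expect_identical(rep$verdict, "symmetric")
  expect_lte(axis_error(rep$best_axis$alpha, 90), 1)
  expect_identical(nrow(rep$vote_table), 180L)
  # determinism: identical reports on identical input
  expect_identical(rep, detect_symmetry(fx$image))
  # no candidate can out-vote the pairing capacity
  expect_true(all(rep$vote_table$votes <= floor(rep$counts$n_usable / 2)))
})

test_that("degenerate images yield an undetermined verdict, not an error", {
  rep <- detect_symmetry(matrix(0.5, 48, 48))
  expect_identical(rep$verdict, "undetermined")
  expect_match(rep$reason, "usable keypoints")
})

test_that("vote counts are monotone when all tolerances are enlarged", {
  for (seed in c(2, 5, 11, 17)) {
    fx <- make_point_constellation(
      fixture_spec("mirrored_points", true_alpha = 40, n_points = 20,
                   jitter_r = 1, jitter_theta = 2, seed = seed))
    pts <- to_polar(fx$points, centroid_geometric(fx$points))
    rr <- diff(range(pts$r))
    narrow <- pair_tolerances(theta_r = 0.02 * rr, theta_theta = 2,
                              grad_mag_tol = 5, grad_ori_tol = 2)
    wide <- pair_tolerances(theta_r = 0.04 * rr, theta_theta = 4,
                            grad_mag_tol = 10, grad_ori_tol = 4)
    v1 <- sweep_axes(pts, 5, narrow)$votes
    v2 <- sweep_axes(pts, 5, wide)$votes
    expect_true(all(v2 >= v1))
  }
})

test_that("render_symmetry_line annotates a copy of the image", {
  fx <- make_mirrored_image(fixture_spec("mirrored_image", true_alpha = 90,
                                         seed = 31))
  rep <- detect_symmetry(fx$image)
  before <- fx$image
  out <- render_symmetry_line(rep, fx$image)
  expect_identical(dim(out), dim(fx$image))
  expect_identical(fx$image, before)            # input untouched
  expect_gt(sum(out != fx$image), 0)
  # the straight axis passes through the centroid at the winning angle
  expect_identical(out[round(rep$centroid$y) + 1, round(rep$centroid$x) + 1],
                   max(fx$image))
  # every midpoint mark leaves mark-valued pixels in its 3x3 block (the
  # axis line drawn on top may cross the block's centre)
  p <- rep$best_axis$pairs
  for (k in seq_len(nrow(p))) {
    blk <- out[round(p$mid_y[k]) + 1 + (-1:1), round(p$mid_x[k]) + 1 + (-1:1)]
    expect_true(any(blk == min(fx$image)))
  }
  # no axis, no rendering
  asym <- detect_constellation(make_point_constellation(
    fixture_spec("asymmetric_points", n_points = 60, seed = 3))$points)
  expect_error(render_symmetry_line(asym, fx$image), "no symmetry axis")
})

test_that("reports and configs serialise to JSON and back", {
  fx <- make_mirrored_image(fixture_spec("mirrored_image", true_alpha = 90,
                                         seed = 31))
  rep <- detect_symmetry(fx$image)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_identical(back$verdict, rep$verdict)
  expect_equal(back$best_axis$alpha, rep$best_axis$alpha)
  expect_equal(back$vote_table$votes, rep$vote_table$votes)
  expect_equal(back$centroid$x, rep$centroid$x, tolerance = 1e-12)

  cfgp <- withr::local_tempfile(fileext = ".json")
  write_config(symaxis_config(delta_alpha = 2, min_votes = 7), cfgp)
  cfg <- read_config(cfgp)
  expect_identical(cfg$delta_alpha, 2L)
  expect_identical(cfg$min_votes, 7L)
  expect_error(symaxis_config(bogus = 1), "unknown config field")
})
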