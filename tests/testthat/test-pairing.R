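test_that("geometric_pair_test implements the mirror rule about alpha", {
  tol <- pair_tolerances(theta_r = 1, theta_theta = 2)
  # the literal polar-axis rule at alpha = 0
  expect_true(geometric_pair_test(5, 30, 5, -30, 0, tol))
  # rotated line, boundary inclusive: residual 70 + 22 - 90 = 2
  expect_true(geometric_pair_test(5, 70, 5, 22, 45, tol))
  expect_false(geometric_pair_test(5, 70, 5, 22.1, 45, tol))
  # radial mismatch
  expect_false(geometric_pair_test(5, 30, 8, -30, 0, tol))
  # symmetry in the two points
  set.seed(1)
  for (k in 1:50) {
    r1 <- runif(1, 0, 50); r2 <- runif(1, 0, 50)
    t1 <- runif(1, -180, 180); t2 <- runif(1, -180, 180)
    al <- runif(1, 0, 180)
    expect_identical(geometric_pair_test(r1, t1, r2, t2, al, tol),
                     geometric_pair_test(r2, t2, r1, t1, al, tol))
  }
})

test_that("gradient_pair_test compares magnitudes and mirrored orientations", {
  tol <- pair_tolerances(theta_r = 1, theta_theta = 2,
                         grad_mag_tol = 5, grad_ori_tol = 2)
  # exact mirror: Q_b = 330 reflects about alpha = 0 to 30 = Q_a
  expect_true(gradient_pair_test(10, 30, 12, 330, 0, tol, bin_width = 10))
  # magnitude band violated
  expect_false(gradient_pair_test(0, 30, 10, 330, 0, tol, bin_width = 10))
  # reflected Q_b = 310, circular bin distance |0 - 310| -> 50 deg = 5 bins
  expect_false(gradient_pair_test(10, 0, 10, 50, 0, tol, bin_width = 10))
  # unoriented input is rejected, not an error
  expect_false(gradient_pair_test(10, NA, 10, 30, 0, tol, bin_width = 10))
  expect_identical(gradient_pair_test(10, 30, 12, 330, 0, tol, 10),
                   gradient_pair_test(12, 330, 10, 30, 0, tol, 10))
})

test_that("reflect_orientation maps Q to 2*alpha - Q in [0, 360)", {
  expect_equal(reflect_orientation(30, 0), 330)
  expect_equal(reflect_orientation(30, 45), 60)
  expect_equal(reflect_orientation(0, 0), 0)
})

test_that("find_symmetric_pairs recovers exact mirror constructions", {
  set.seed(9)
  alpha <- 30
  th <- runif(5, -170, 170)
  q <- runif(5, 0, 360)
  pts <- mk_points(r = rep(c(5, 9, 14, 20, 27), 2),
                   theta = c(th, wrap_angle(2 * alpha - th)),
                   M = rep(runif(5, 10, 90), 2),
                   Q = c(q, (2 * alpha - q) %% 360))
  tol <- pair_tolerances(theta_r = 0.5, theta_theta = 2)
  got <- find_symmetric_pairs(pts, alpha, tol)
  expect_identical(nrow(got), 5L)
  expect_identical(sort(c(got$i, got$j)), 1:10)
  # at the orthogonal axis no pair survives (verified by the oracle too)
  got120 <- find_symmetric_pairs(pts, 120, tol)
  expect_identical(nrow(got120), 0L)
  expect_identical(nrow(oracle_pairs(pts, 120, tol)), 0L)
})

test_that("greedy assignment is one-to-one and residual-ordered", {
  # point 1 could pair with 2 (residual 0) or 3 (residual 0.25); only the
  # better pair must be returned
  pts <- mk_points(r = c(5, 5, 5), theta = c(10, -10, -10.5),
                   M = 50, Q = c(40, 320, 320))
  tol <- pair_tolerances(theta_r = 1, theta_theta = 2, grad_ori_tol = 3)
  got <- find_symmetric_pairs(pts, 0, tol)
  expect_identical(nrow(got), 1L)
  expect_identical(c(got$i, got$j), c(1L, 2L))
})

test_that("points at the centroid and unoriented points never pair", {
  pts <- mk_points(r = c(0.5, 0.5, 10, 10), theta = c(20, -20, 45, -45),
                   M = 50, Q = c(10, 350, 30, 330))
  tol <- pair_tolerances(theta_r = 5, theta_theta = 5)
  got <- find_symmetric_pairs(pts, 0, tol)
  expect_identical(nrow(got), 1L)        # only the r = 10 pair
  expect_identical(c(got$i, got$j), c(3L, 4L))
  pts$unoriented[3] <- TRUE
  expect_identical(nrow(find_symmetric_pairs(pts, 0, tol)), 0L)
})

test_that("perfect mirrors yield N/2 pairs at the true axis for any alpha", {
  for (seed in 1:10) {
    set.seed(seed)
    alpha <- runif(1, 0, 180)
    n <- 2 * sample(3:10, 1)
    fx <- make_point_constellation(
      fixture_spec("mirrored_points", true_alpha = alpha, n_points = n,
                   seed = seed))
    ctr <- list(x = fx$truth$center[1], y = fx$truth$center[2])
    pts <- to_polar(fx$points, ctr)
    tol <- pair_tolerances(theta_r = 1e-6, theta_theta = 1e-6)
    got <- find_symmetric_pairs(pts, alpha, tol)
    expect_identical(nrow(got), as.integer(n / 2))
  }
})

test_that("midpoints are the centred means of the paired endpoints", {
  pts <- mk_points(r = c(10, 10), theta = c(50, 10), M = 50, Q = c(20, 40))
  tol <- pair_tolerances(theta_r = 1, theta_theta = 1)
  got <- find_symmetric_pairs(pts, 30, tol)
  expect_identical(nrow(got), 1L)
  u <- 10 * cos(c(50, 10) * pi / 180)
  v <- 10 * sin(c(50, 10) * pi / 180)
  expect_equal(got$mid_u, mean(u), tolerance = 1e-9)
  expect_equal(got$mid_v, mean(v), tolerance = 1e-9)
})

test_that("find_symmetric_pairs matches the exhaustive oracle", {
  for (seed in 1:8) {
    set.seed(100 + seed)
    n <- sample(10:40, 1)
    pts <- mk_points(r = runif(n, 0, 40), theta = runif(n, -180, 180),
                     M = runif(n, 0, 100), Q = runif(n, 0, 360))
    tol <- pair_tolerances(theta_r = 2, theta_theta = 6, grad_mag_tol = 30,
                           grad_ori_tol = 4)
    for (alpha in c(0, 17, 90, 133)) {
      got <- find_symmetric_pairs(pts, alpha, tol)
      ref <- oracle_pairs(pts, alpha, tol)
      expect_identical(list(got$i, got$j), list(ref[, 1], ref[, 2]))
    }
  }
})
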