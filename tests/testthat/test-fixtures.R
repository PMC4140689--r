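test_that("axis-aligned mirrored images are pixel-exact mirrors", {
  # vertical axis: reflection maps the pixel grid onto itself
  fx <- make_mirrored_image(fixture_spec("mirrored_image", true_alpha = 90,
                                         seed = 7))
  img <- fx$image
  expect_identical(img, img[, ncol(img):1])
  # horizontal axis
  fx0 <- make_mirrored_image(fixture_spec("mirrored_image", true_alpha = 0,
                                          seed = 7))
  expect_identical(fx0$image, fx0$image[nrow(fx0$image):1, ])
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(fx$truth$true_alpha, 90)
  expect_identical(fx$truth$center, c(79.5, 79.5))
})

test_that("oblique mirrored images are symmetric under interpolation", {
  fx <- make_mirrored_image(fixture_spec("mirrored_image", true_alpha = 37.3,
                                         seed = 9))
  img <- fx$image
  a <- 37.3 * pi / 180
  c0 <- 79.5
  # sample the reflection of a grid block bicubically; the underlying
  # continuous field is exactly symmetric, so values must match closely
  x <- matrix(30:129, 100, 100, byrow = TRUE) - c0
  y <- c0 - matrix(30:129, 100, 100)
  u <- -x * sin(a) + y * cos(a); v <- x * cos(a) + y * sin(a)
  xr <- (v * cos(a) + u * sin(a)) + c0
  yr <- c0 - (v * sin(a) - u * cos(a))
  refl <- symaxis:::bicubic_sample(img, xr, yr)
  # the bound is interpolation error: bicubic on ~2 px blobs is good to a
  # few percent of the intensity range
  expect_lt(max(abs(refl - img[31:130, 31:130])), 0.03)
})

test_that("fixtures are bit-reproducible from (spec, seed)", {
  sp <- fixture_spec("mirrored_image", true_alpha = 123.4, seed = 99)
  expect_identical(make_mirrored_image(sp)$image, make_mirrored_image(sp)$image)
  spc <- fixture_spec("cluttered_image", true_alpha = 123.4, seed = 99,
                      clutter_density = 5)
  expect_identical(make_cluttered_image(spc)$image,
                   make_cluttered_image(spc)$image)
  spp <- fixture_spec("mirrored_points", true_alpha = 10, n_points = 12,
                      seed = 4)
  expect_identical(make_point_constellation(spp)$points,
                   make_point_constellation(spp)$points)
  # the generator must not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(make_mirrored_image(sp)); b <- runif(1)
  expect_identical(a, b)
})

test_that("mirrored constellations pair perfectly at zero jitter", {
  fx <- make_point_constellation(
    fixture_spec("mirrored_points", true_alpha = 30, n_points = 10, seed = 2))
  ctr <- list(x = fx$truth$center[1], y = fx$truth$center[2])
  pts <- to_polar(fx$points, ctr)
  got <- find_symmetric_pairs(pts, 30, pair_tolerances(theta_r = 1e-6,
                                                       theta_theta = 1e-6))
  expect_identical(nrow(got), 5L)
})

test_that("angular jitter beyond tolerance breaks pairs", {
  theta_theta <- 1
  broken <- vapply(1:100, function(s) {
    fx <- make_point_constellation(
      fixture_spec("mirrored_points", true_alpha = 30, n_points = 10,
                   jitter_theta = 3 * theta_theta, seed = s))
    pts <- to_polar(fx$points, list(x = fx$truth$center[1],
                                    y = fx$truth$center[2]))
    tol <- pair_tolerances(theta_r = 1, theta_theta = theta_theta)
    nrow(find_symmetric_pairs(pts, 30, tol)) < 5
  }, TRUE)
  expect_gte(mean(broken), 0.9)
})

test_that("fixture_spec validates its arguments", {
  expect_error(fixture_spec("mirrored_points", true_alpha = 10,
                            n_points = 9), "even")
  expect_error(fixture_spec("mirrored_image"), "true_alpha")
  expect_error(fixture_spec("mirrored_image", true_alpha = 180), "true_alpha")
  expect_error(fixture_spec("asymmetric_points", true_alpha = 10),
               "no true_alpha")
  asym <- make_point_constellation(fixture_spec("asymmetric_points",
                                                n_points = 60, seed = 1))
  expect_false(asym$truth$symmetric)
  expect_true(is.na(asym$truth$true_alpha))
})

test_that("clutter reduces to the clean image at density zero and adds
           off-object keypoints as density grows", {
  sp0 <- fixture_spec("cluttered_image", true_alpha = 45, seed = 13,
                      clutter_density = 0)
  clean <- make_mirrored_image(fixture_spec("mirrored_image", true_alpha = 45,
                                            seed = 13))
  expect_identical(make_cluttered_image(sp0)$image, clean$image)
  counts <- vapply(c(2, 8), function(dens) {
    mean(vapply(1:8, function(s) {
      sp <- fixture_spec("cluttered_image", true_alpha = 45, seed = s,
                         clutter_density = dens)
      nrow(extract_keypoints(make_cluttered_image(sp)$image))
    }, 0))
  }, 0)
  expect_gt(counts[2], counts[1])
})

test_that("the fixture suite writes images, tables and a manifest", {
  dir <- withr::local_tempdir()
  specs <- fixture_suite_specs(n_clean = 2, n_clutter = 1, n_asym = 1,
                               base_seed = 5)
  expect_identical(length(specs), 4L)
  # deterministic spec generation
  specs2 <- fixture_suite_specs(n_clean = 2, n_clutter = 1, n_asym = 1,
                                base_seed = 5)
  expect_identical(specs, specs2)
  manifest <- write_fixture_suite(dir, specs)
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  expect_identical(length(m), 4L)
  expect_true(all(vapply(m, function(e)
    file.exists(file.path(dir, e$file)), TRUE)))
  img <- read_pgm(file.path(dir, m[[1]]$file))
  expect_identical(dim(img), c(160L, 160L))
  pts <- read_keypoints(file.path(dir, m[[4]]$file))
  expect_identical(nrow(pts), 60L)
})
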