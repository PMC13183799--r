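test_that("gray world recovers the gain of an achromatic-mean scene", {
  # scene whose mean reflectance is achromatic by construction
  refl <- c(0.3, 0.5, 0.4)
  img <- step_image(refl, 0.8 - refl, gain = c(1, 1, 1))
  e0 <- gray_world(img)
  expect_equal(e0$rgb, rep(1, 3) / sqrt(3), tolerance = 1e-9)
  gain <- c(1.3, 0.9, 0.7)
  e <- gray_world(step_image(refl, 0.8 - refl, gain = gain))
  expect_equal(e$rgb, gain / sqrt(sum(gain^2)), tolerance = 1e-9)
  # duplicating the image leaves the mean unchanged
  img2 <- array(c(img, img), dim = c(dim(img)[1], 2 * dim(img)[2], 3))
  img2[, seq_len(dim(img)[2]), ] <- img
  img2[, dim(img)[2] + seq_len(dim(img)[2]), ] <- img
  expect_equal(gray_world(img2)$rgb, e0$rgb)
})

test_that("white patch keys on the brightest surface", {
  gain <- c(1.2, 1.0, 0.8)
  img <- step_image(c(0.8, 0.8, 0.8), c(0.3, 0.4, 0.2), gain = gain)
  expect_equal(white_patch(img)$rgb, gain / sqrt(sum(gain^2)),
               tolerance = 1e-9)
  one <- array(c(0.2, 0.5, 0.1), dim = c(1, 1, 3))
  expect_equal(white_patch(one)$rgb,
               c(0.2, 0.5, 0.1) / sqrt(sum(c(0.2, 0.5, 0.1)^2)))
})

test_that("shades of gray interpolates gray world to white patch", {
  set.seed(21)
  img <- array(runif(32 * 32 * 3, 0.05, 0.9), dim = c(32, 32, 3))
  expect_equal(shades_of_gray(img, p = 1)$rgb, gray_world(img)$rgb,
               tolerance = 1e-12)
  expect_lt(max(abs(shades_of_gray(img, p = 100)$rgb - white_patch(img)$rgb)),
            1e-3)
  # convergence to the white-patch direction at large p
  errs <- vapply(c(8, 16, 32, 64, 100), function(p)
    angular_error(shades_of_gray(img, p)$rgb, white_patch(img)$rgb),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[length(errs)], 0.1)
  expect_error(shades_of_gray(img, p = 0.5), "p must be")
})

test_that("constant images give neutral mean estimates and degenerate edge estimates", {
  img <- flat_image(c(0.4, 0.4, 0.4), size = 32)
  expect_equal(shades_of_gray(img, p = 6)$rgb, rep(1, 3) / sqrt(3))
  expect_true(gray_edge(img)$degenerate)
  expect_true(weighted_gray_edge(img)$degenerate)
  expect_error(white_balance(img, gray_edge(img)), "degenerate")
})

test_that("gray edge recovers the gain from an achromatic step edge", {
  gain <- c(1.25, 0.95, 0.8)
  # edge between two achromatic surfaces: the color difference at the edge
  # is proportional to the gain
  img <- step_image(rep(0.25, 3), rep(0.65, 3), gain = gain, size = 32)
  e <- gray_edge(img, p = 1, sigma = 1)
  expect_lt(angular_error(e$rgb, gain), 1e-6)
  e2 <- gray_edge(img, p = 1, sigma = 1, order = 2)
  expect_lt(angular_error(e2$rgb, gain), 1e-6)
})

test_that("gray edge ignores edge-free regions", {
  gain <- c(1.25, 0.95, 0.8)
  img <- step_image(rep(0.25, 3), rep(0.65, 3), gain = gain, size = 32)
  # grow the flat right side; derivatives there are zero so the estimate
  # direction is unchanged
  wide <- array(0, dim = c(32, 48, 3))
  wide[, 1:32, ] <- img
  for (k in 1:3) wide[, 33:48, k] <- 0.65 * gain[k]
  expect_lt(angular_error(gray_edge(wide)$rgb, gray_edge(img)$rgb), 1e-6)
})

test_that("weighted gray edge reduces to gray edge at exponent 0 and favors strong edges", {
  set.seed(5)
  img <- array(runif(32 * 32 * 3, 0.1, 0.8), dim = c(32, 32, 3))
  expect_equal(weighted_gray_edge(img, weight_exponent = 0)$rgb,
               gray_edge(img)$rgb, tolerance = 1e-12)
  # one strong achromatic edge under the true gain + many weak chromatic
  # edges: weighting should move the estimate toward the true gain
  gain <- c(1.3, 1.0, 0.75)
  base <- step_image(rep(0.1, 3), rep(0.85, 3), gain = gain, size = 32)
  set.seed(6)
  weak <- base
  for (k in 1:3) {
    weak[, , k] <- weak[, , k] +
      matrix(runif(32 * 32, 0, 0.03 * k), 32, 32)  # chromatic texture
  }
  err_u <- angular_error(gray_edge(weak)$rgb, gain)
  err_w <- angular_error(weighted_gray_edge(weak, weight_exponent = 4)$rgb,
                         gain)
  expect_lt(err_w, err_u)
})

test_that("all estimators are invariant to global intensity scaling", {
  set.seed(31)
  img <- array(runif(32 * 32 * 3, 0.05, 0.45), dim = c(32, 32, 3))
  for (f in list(gray_world, white_patch,
                 function(x) shades_of_gray(x, 6),
                 gray_edge,
                 function(x) weighted_gray_edge(x, weight_exponent = 2))) {
    expect_equal(f(img * 2)$rgb, f(img)$rgb, tolerance = 1e-9)
  }
})

test_that("white balance inverts the diagonal model and is idempotent", {
  set.seed(13)
  refl <- array(runif(16 * 16 * 3, 0.1, 0.7), dim = c(16, 16, 3))
  # achromatic mean so gray world's own assumption holds
  m <- vapply(1:3, function(k) mean(refl[, , k]), numeric(1))
  for (k in 1:3) refl[, , k] <- refl[, , k] * mean(m) / m[k]
  gain <- c(1.35, 1.0, 0.7)
  img <- refl
  for (k in 1:3) img[, , k] <- img[, , k] * gain[k]
  est <- gray_world(img)
  expect_lt(angular_error(est$rgb, gain), 0.1)
  corrected <- white_balance(img, est)
  ratio <- corrected / refl
  expect_lt(diff(range(ratio)), 1e-6)  # proportional to reflectance
  # neutral estimate changes the image only by a global scale
  neut <- illuminant_estimate(c(1, 1, 1), "manual")
  wb <- white_balance(img, neut)
  expect_lt(diff(range(wb / img)), 1e-9)
  # re-estimating after correction yields a neutral direction
  est2 <- gray_world(corrected)
  expect_lt(angular_error(est2$rgb, c(1, 1, 1)), 1e-6)
  # and mean luminance is preserved
  expect_equal(mean(corrected), mean(img), tolerance = 1e-12)
})

test_that("estimators recover the illuminant on scenes satisfying their assumptions", {
  ils <- test_illuminants(20)
  for (il in c("blue", "yellow", "red", "green")) {
    gain <- ils[[il]]$gain
    refl <- grayworld_reflectance(seed = 17)
    img <- refl
    for (k in 1:3) img[, , k] <- img[, , k] * gain[k]
    expect_lt(angular_error(gray_world(img)$rgb, gain), 0.1)
    expect_lt(angular_error(white_patch(img)$rgb, gain), 0.1)
    achro_step <- step_image(rep(0.2, 3), rep(0.6, 3), gain = gain)
    expect_lt(angular_error(gray_edge(achro_step)$rgb, gain), 0.1)
  }
})
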