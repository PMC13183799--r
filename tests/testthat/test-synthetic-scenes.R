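test_that("illuminant set is symmetric about neutral in gain space", {
  ils <- test_illuminants(20)
  g <- sapply(ils[-1], function(i) i$gain)
  expect_equal(rowMeans(g), ils$neutral$gain)
  expect_equal((ils$blue$gain + ils$yellow$gain) / 2, ils$neutral$gain)
  expect_equal((ils$red$gain + ils$green$gain) / 2, ils$neutral$gain)
  expect_equal(ils$blue$axis, "daylight")
  expect_equal(ils$red$axis, "orthogonal")
})

test_that("zero offset degenerates to five copies of neutral", {
  ils <- make_illuminant_set(0)
  for (il in ils) expect_equal(il$gain, ils$neutral$gain)
})

test_that("the chromatic step lands where requested in a*b*", {
  ils <- test_illuminants(20)
  lab_of <- function(g) linear_rgb_to_lab(0.4 * g)
  ref <- lab_of(ils$neutral$gain)
  expect_equal(lab_of(ils$blue$gain) - ref, c(0, 0, -20), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(lab_of(ils$red$gain) - ref, c(0, 20, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("excessive offsets and bad gains are rejected", {
  expect_error(make_illuminant_set(80), "non-positive gain")
  expect_error(illuminant_spec("x", c(1, -1, 1)), "positive")
  expect_error(illuminant_spec("x", c(1, 1, 1), axis = "bogus"), "axis")
})

test_that("rendering is the diagonal model: identity under unit gains, linear in gain", {
  spec <- scene_spec(seed = 7)
  unit <- illuminant_spec("neutral", c(1, 1, 1))
  sc <- render_scene(spec, unit)
  expect_identical(sc$rgb, sc$reflectance)
  half <- render_scene(spec, illuminant_spec("dim", c(0.5, 0.5, 0.5)))
  expect_equal(half$rgb, sc$rgb * 0.5)
})

test_that("scene mean matches a brute-force pixel sum", {
  ils <- test_illuminants(20)
  spec <- scene_spec(seed = 3)
  sc <- render_scene(spec, ils$blue, ils$neutral)
  brute <- vapply(1:3, function(k)
    sum(sc$reflectance[, , k] * ils$blue$gain[k]) / (64 * 64), numeric(1))
  expect_equal(vapply(1:3, function(k) mean(sc$rgb[, , k]), numeric(1)),
               brute, tolerance = 1e-12)
})

test_that("competitor sets have the designed collinear uniform geometry", {
  for (il in c("blue", "yellow", "red", "green")) {
    cs <- test_competitors(il)
    labs <- cs$labs
    step <- labs["T", ] - labs["S2", ]
    expect_equal(labs["S2", ] - labs["S1", ], step, tolerance = 1e-9)
    expect_equal(labs["S1", ] - labs["R", ], step, tolerance = 1e-9)
    expect_equal(labs["R", ] - labs["O", ], step, tolerance = 1e-9)
    expect_false(cs$degenerate)
  }
})

test_that("the tristimulus match reflects the target's neutral light under the test illuminant", {
  ils <- test_illuminants(20)
  cs <- test_competitors("red")
  light_T_under_red <- cs$reflectances["T", ] * ils$red$gain
  light_target_under_neutral <- rep(0.4, 3) * ils$neutral$gain
  expect_equal(light_T_under_red, light_target_under_neutral,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the neutral-illuminant competitor set is flagged degenerate", {
  ils <- test_illuminants(20)
  cs <- make_competitor_set(rep(0.4, 3), ils$neutral, ils$neutral)
  expect_true(cs$degenerate)
  expect_equal(cs$labs["R", ], cs$labs["T", ])
  expect_error(make_competitor_set(c(0.3, 0.4, 0.4), ils$blue, ils$neutral),
               "achromatic")
})

test_that("baseline manipulation is a bit-identical no-op", {
  ils <- test_illuminants(20)
  sc <- render_scene(scene_spec(seed = 5), ils$blue, ils$neutral)
  expect_identical(apply_manipulation(sc, "baseline", ils$blue), sc)
  expect_error(apply_manipulation(sc, "warp", ils$blue), "unknown mechanism")
})

test_that("local surround silencing fixes the surround pixels across illuminants", {
  ils <- test_illuminants(20)
  leaf <- make_surround_color_set()$rose
  mk <- function(il) {
    spec <- scene_spec(seed = 5, surround = leaf$reflectance,
                       surround_name = "rose", mechanism = "local_surround")
    render_scene(spec, il, ils$neutral)
  }
  a <- mk(ils$blue)
  b <- mk(ils$yellow)
  sel <- a$role == 4L
  for (k in 1:3) {
    expect_equal(a$rgb[, , k][sel], b$rgb[, , k][sel])
  }
  # without silencing the leaf renders differently under the two illuminants
  spec0 <- scene_spec(seed = 5, surround = leaf$reflectance)
  a0 <- render_scene(spec0, ils$blue, ils$neutral)
  b0 <- render_scene(spec0, ils$yellow, ils$neutral)
  expect_gt(max(abs(a0$rgb[, , 3][sel] - b0$rgb[, , 3][sel])), 0.05)
})

test_that("maximum flux silencing fixes the bright patch", {
  ils <- test_illuminants(20)
  spec <- scene_spec(seed = 5, mechanism = "maximum_flux")
  a <- render_scene(spec, ils$blue, ils$neutral)
  b <- render_scene(spec, ils$red, ils$neutral)
  sel <- a$role == 2L
  for (k in 1:3) expect_equal(a$rgb[, , k][sel], b$rgb[, , k][sel])
})

test_that("spatial mean manipulations push the scene mean opposite the illuminant", {
  ils <- test_illuminants(20)
  neutral_mean_ab <- function(sc) {
    m <- vapply(1:3, function(k) mean(sc$rgb[, , k]), numeric(1))
    linear_rgb_to_lab(m)[2:3]
  }
  base <- render_scene(scene_spec(seed = 5), ils$blue, ils$neutral)
  neutral_sc <- render_scene(scene_spec(seed = 5), ils$neutral, ils$neutral)
  ref_ab <- neutral_mean_ab(neutral_sc)
  # baseline scene mean shifts with the blue illuminant (negative b*)
  expect_lt((neutral_mean_ab(base) - ref_ab)[2], 0)
  for (mech in c("spatial_mean_add", "spatial_mean_change")) {
    man <- render_scene(scene_spec(seed = 5, mechanism = mech),
                        ils$blue, ils$neutral)
    # manipulated mean lies on the yellow side of neutral instead
    expect_gt((neutral_mean_ab(man) - ref_ab)[2], 0)
  }
})

test_that("surround colors sit on the diagonals, symmetric about neutral", {
  ss <- make_surround_color_set()
  expect_setequal(names(ss), c("khaki", "rose", "purple", "teal"))
  expect_equal((ss$khaki$lab + ss$purple$lab) / 2, c(55, 0, 0))
  expect_equal((ss$rose$lab + ss$teal$lab) / 2, c(55, 0, 0))
  for (s in ss) {
    # 45 degrees off every illuminant axis (axes at 0, 90, 180, 270)
    expect_equal(s$hue %% 90, 45)
  }
})

test_that("direction classification matches the designed geometry", {
  ils <- test_illuminants(20)
  ss <- make_surround_color_set()
  expect_equal(classify_direction(ils$blue, ss$purple$hue), "Neighboring")
  expect_equal(classify_direction(ils$red, ss$purple$hue), "Neighboring")
  expect_equal(classify_direction(ils$green, ss$purple$hue), "Opposing")
  expect_equal(classify_direction(ils$yellow, ss$purple$hue), "Opposing")
  expect_error(classify_direction(ils$neutral, 45), "neutral")
})

test_that("experiment datasets are complete, labeled and deterministic", {
  ils <- test_illuminants(20)
  ds <- generate_experiment_dataset(ils, mechanisms = "baseline",
                                    n_locations = 2, size = 32, seed = 42)
  expect_equal(nrow(ds$manifest), 5 * 5 * 2)
  counts <- table(ds$manifest$illuminant, ds$manifest$competitor)
  expect_true(all(counts == 2))
  for (rec in ds$records[1:10]) {
    sel <- rec$scene$mask > 0
    expect_gt(sum(sel), 0)
    ci <- match(rec$competitor, rownames(ds$competitor_sets[[1]]$labs))
    expect_true(all(rec$scene$mask[sel] == ci))
    want <- ds$competitor_sets[[rec$illuminant]]$reflectances[rec$competitor, ]
    for (k in 1:3) {
      expect_equal(unique(rec$scene$reflectance[, , k][sel]), want[[k]],
                   tolerance = 1e-12)
    }
  }
  ds2 <- generate_experiment_dataset(ils, mechanisms = "baseline",
                                     n_locations = 2, size = 32, seed = 42)
  expect_identical(ds$records[[7]]$scene$rgb, ds2$records[[7]]$scene$rgb)
})
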