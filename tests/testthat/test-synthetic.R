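test_that("a vertical centred field is symmetric in x and y", {
  b <- beam_spec("6MV", 10, gantry_angle = 0)
  p <- true_dose_plane(b)
  v <- p$values
  expect_equal(v, v[, rev(seq_len(ncol(v)))], tolerance = 1e-12)
  expect_equal(v, v[rev(seq_len(nrow(v))), ], tolerance = 1e-12)
  expect_true(all(v >= 0))
})

test_that("opposed vertical beams double the single-beam plane", {
  # phantom entry is symmetric about the mid-height detector plane, so the
  # 0 and 180 deg contributions coincide there
  b0 <- true_dose_plane(beam_spec("6MV", 10, gantry_angle = 0))
  b180 <- true_dose_plane(beam_spec("6MV", 10, gantry_angle = 180))
  expect_equal(b0$values, b180$values, tolerance = 1e-12)
  comp <- composite_true_dose(plan_spec(list(
    beam_spec("6MV", 10, gantry_angle = 0),
    beam_spec("6MV", 10, gantry_angle = 180))))
  expect_equal(comp$values, 2 * b0$values, tolerance = 1e-12)
})

test_that("the central-axis dose matches the closed-form product", {
  # fluence x attenuation x inverse-square, evaluated by hand at the centre
  p <- true_dose_plane(beam_spec("6MV", 10, gantry_angle = 0))
  centre <- central_detector_dose(p$values)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  hand <- function(x, y) {
    flu <- (0.5 * (erf((50 - x) / (sqrt(2) * 3)) + erf((50 + x) / (sqrt(2) * 3)))) *
           (0.5 * (erf((50 - y) / (sqrt(2) * 3)) + erf((50 + y) / (sqrt(2) * 3))))
    src <- c(0, 0, 1000)
    L <- sqrt(x^2 + y^2 + 1000^2)
    depth <- (1 - (110 - 1000) / (0 - 1000)) * L
    100 * flu * exp(-0.0049 * depth) * (1000 / L)^2
  }
  four <- c(hand(-3.81, -3.81), hand(3.81, -3.81),
            hand(-3.81, 3.81), hand(3.81, 3.81))
  expect_equal(centre, mean(four), tolerance = 1e-12)
  # lateral beam: depth grows away from the entry side
  p90 <- true_dose_plane(beam_spec("6MV", c(30, 10), gantry_angle = 90))
  expect_true(all(diff(p90$values[16, ]) > 0))  # dose rises toward +x entry
})

test_that("the packaged response models anchor at the characterised extrema", {
  for (spec in list(list("6MV", 1.06, 0.85, 0.92),
                    list("10MV", 1.04, 0.89, 0.95))) {
    m <- default_response_model(spec[[1]])
    cen <- (m$column_response[16, ] + m$column_response[17, ]) / 2
    a <- m$anchor_angles
    expect_equal(unname(cen[a == 0]), 1.0)
    expect_equal(m$column_response[, a == 0], rep(1, 32))
    expect_equal(unname(cen[a == 90]), spec[[2]])
    expect_equal(unname(cen[a == 92]), spec[[3]])
    expect_equal(unname(cen[a == 180]), spec[[4]])
    # off-axis curves lie between the two outermost columns
    for (k in seq_along(a)) {
      rng <- range(m$column_response[c(1, 32), k])
      expect_true(all(m$column_response[, k] >= rng[1] - 1e-12))
      expect_true(all(m$column_response[, k] <= rng[2] + 1e-12))
    }
  }
  expect_error(default_response_model("4MV"))
})

test_that("column offsets span the characterised difference ranges", {
  m <- default_response_model("6MV")
  a <- m$anchor_angles
  cen <- (m$column_response[16, ] + m$column_response[17, ]) / 2
  diffs <- 100 * sweep(sweep(m$column_response, 2, cen, `-`), 2, cen, `/`)
  in_band <- function(lo, hi) a >= lo & a <= hi
  expect_equal(max(diffs[, in_band(80, 110)]), 7.0, tolerance = 1e-9)
  expect_equal(min(diffs[, in_band(80, 110)]), -6.1, tolerance = 1e-9)
  expect_lte(max(abs(diffs[, in_band(0, 70)])), 2.2 + 1e-9)
  expect_lte(max(abs(diffs[, in_band(120, 180)])), 2.1 + 1e-9)
})

test_that("the calibration grid has 37 distinct angles", {
  a <- calibration_angles()
  expect_equal(length(a), 37)
  expect_equal(length(unique(c(seq(0, 180, 10), 90:110))), 37)
  expect_true(all(diff(a) > 0))
  expect_true(0 %in% a && 180 %in% a && all(90:110 %in% a))
})

test_that("angular response mirrors about the 0-180 axis", {
  m <- default_response_model("6MV")
  expect_equal(arrayqa:::response_at(m, 270), arrayqa:::response_at(m, 90))
  expect_equal(arrayqa:::response_at(m, 185), arrayqa:::response_at(m, 175))
})

test_that("an ideal detector with no noise reproduces the true composite", {
  plan <- simple_plans("6MV")$plan3
  movie <- simulate_measurement(plan, model = NULL, noise_sigma = 0)
  truth <- composite_true_dose(plan)
  expect_equal(accumulate(movie)$dose, truth$values, tolerance = 1e-12)
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  plan <- simple_plans("6MV")$plan2
  model <- default_response_model("6MV")
  m1 <- simulate_measurement(plan, model, seed = 123)
  m2 <- simulate_measurement(plan, model, seed = 123)
  expect_identical(lapply(m1$frames, `[[`, "dose"),
                   lapply(m2$frames, `[[`, "dose"))
  m3 <- simulate_measurement(plan, model, seed = 124)
  expect_false(identical(m1$frames[[1]]$dose, m3$frames[[1]]$dose))
})

test_that("frame noise has the configured relative spread", {
  plan <- plan_spec(beam_spec("6MV", 10, gantry_angle = 0))
  model <- default_response_model("6MV")
  movie <- simulate_measurement(plan, model, seed = 55,
                                frames_per_beam = 10000L)
  centre <- vapply(movie$frames, function(f) f$dose[16, 16], numeric(1))
  rel_sd <- sd(centre) / mean(centre)
  expect_lt(abs(rel_sd / 0.003 - 1), 0.05)
})

test_that("uncorrected lateral measurements are biased with the response sign", {
  model <- default_response_model("6MV")
  truth90 <- true_dose_plane(beam_spec("6MV", 10, gantry_angle = 90))
  mk <- function(th) accumulate(simulate_measurement(
    plan_spec(beam_spec("6MV", 10, gantry_angle = th)), model,
    noise_sigma = 0))
  # over-response at 90 deg, under-response at 100 deg
  expect_gt(roi_mean(frame_to_plane(mk(90))) /
              roi_mean(true_dose_plane(beam_spec("6MV", 10, gantry_angle = 90))), 1.01)
  expect_lt(roi_mean(frame_to_plane(mk(100))) /
              roi_mean(true_dose_plane(beam_spec("6MV", 10, gantry_angle = 100))), 0.99)
})

test_that("reference_at_detectors wraps the analytic dose model", {
  refs <- reference_at_detectors("6MV", angles = c(0, 40, 90))
  expect_equal(length(refs), 3)
  expect_equal(refs[[1]]$gantry_angle, 0)
  direct <- true_dose_plane(beam_spec("6MV", c(30, 10), gantry_angle = 40))
  expect_equal(refs[[2]]$dose, direct$values)
})

test_that("beam and plan validation catches bad geometry", {
  expect_error(beam_spec("6MV", 0, gantry_angle = 0))
  expect_error(beam_spec("6MV", 10, gantry_angle = 0, weight = -1))
  expect_error(beam_spec("6MV", 10), "gantry_angle or arc")
  expect_error(plan_spec(list()), "length")
  expect_error(true_dose_plane(plan_spec(beam_spec("6MV", 10,
    arc_start = 185, arc_stop = 175))$beams[[1]]), "no single gantry angle")
})
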