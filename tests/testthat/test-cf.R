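angles_small <- c(0, 45, 90, 135, 180)

test_that("identical measured and reference doses give unit CFs", {
  ref <- lapply(angles_small, function(th)
    dose_frame(matrix(50, 32, 32), gantry_angle = th))
  tab <- derive_cf(ref, ref, energy = "6MV")
  expect_equal(tab$central_cf, rep(1, 5))
  expect_equal(tab$column_cf, matrix(1, 32, 5))
})

test_that("CF arithmetic follows the measured/reference ratio", {
  # central measured 53 vs reference 50 at 90 deg, ratio 1 at 0 deg
  ref <- lapply(c(0, 90), function(th)
    dose_frame(matrix(50, 32, 32), gantry_angle = th))
  m90 <- matrix(50, 32, 32); m90[16:17, 16:17] <- 53
  meas <- list(dose_frame(matrix(50, 32, 32), gantry_angle = 0),
               dose_frame(m90, gantry_angle = 90))
  tab <- derive_cf(meas, ref)
  expect_equal(predict(tab, 90), 1.06)
  expect_equal(predict(tab, 0), 1)
})

test_that("noiseless synthetic calibration reproduces the response model", {
  for (en in c("6MV", "10MV")) {
    model <- default_response_model(en)
    tab <- derive_cf(simulate_calibration(model),
                     reference_at_detectors(en), energy = en)
    expect_equal(tab$angles, model$anchor_angles)
    norm <- model$column_response / model$column_response[, 1]
    expect_equal(tab$column_cf, norm, tolerance = 1e-12)
    central_norm <- (norm[16, ] + norm[17, ]) / 2
    expect_equal(tab$central_cf, central_norm, tolerance = 1e-12)
  }
})

test_that("derive_cf validates its inputs", {
  ref <- lapply(c(10, 90), function(th)
    dose_frame(matrix(50, 32, 32), gantry_angle = th))
  expect_error(derive_cf(ref, ref), "0 deg")
  ref0 <- lapply(c(0, 90), function(th)
    dose_frame(matrix(50, 32, 32), gantry_angle = th))
  bad <- list(matrix(50, 32, 32), matrix(0, 32, 32))
  expect_error(derive_cf(ref0, bad), "positive")
})

test_that("CF interpolation is exact at grid angles and linear between", {
  tab <- make_cf_table(c(0, 90, 100, 110, 180), c(1, 1.06, 0.95, 0.97, 0.92))
  expect_equal(predict(tab, 0), 1)
  expect_equal(predict(tab, 100), 0.95)
  expect_equal(predict(tab, 105), 0.96)  # linear midpoint
  expect_equal(predict(tab, 270), predict(tab, 90))  # mirror assumption
  expect_equal(predict(tab, 350), predict(tab, 10))
  expect_warning(v <- predict(tab, -10), "normalised")
  expect_equal(v, predict(tab, 350))
})

test_that("central vs off-axis CF differences follow the definition", {
  col <- matrix(1, 32, 2)
  col[5, 2] <- 1.070; col[28, 2] <- 0.939
  tab <- make_cf_table(c(0, 92), c(1, 1), col)
  expect_equal(cf_difference(tab, 5, 92), 7.0)
  expect_equal(cf_difference(tab, 28, 92), -6.1)
  expect_equal(cf_difference(tab, 16, 92), 0)
})

test_that("apply_correction divides by the scheme's CF", {
  f <- uniform_frame(106, angle = 90)
  tab <- make_cf_table(c(0, 90, 180), c(1, 1.06, 0.92))
  expect_identical(apply_correction(f, tab, "none"), f)
  corr <- apply_correction(f, tab, "central")
  expect_equal(corr$dose, matrix(100, 32, 32))
  expect_equal(corr$gantry_angle, 90)
  expect_equal(corr$duration, f$duration)
  expect_error(apply_correction(uniform_frame(1), tab, "central"),
               "no gantry angle")
})

test_that("correction round-trips: multiplying back restores the frame", {
  model <- default_response_model("6MV")
  tab <- derive_cf(simulate_calibration(model),
                   reference_at_detectors("6MV"), energy = "6MV")
  set.seed(5)
  f <- dose_frame(matrix(runif(1024, 10, 60), 32, 32), gantry_angle = 137.3)
  corr <- apply_correction(f, tab, "entire")
  cfs <- vapply(1:32, function(j) predict(tab, 137.3, column = j), numeric(1))
  back <- sweep(corr$dose, 2, cfs, `*`)
  expect_equal(back, f$dose, tolerance = 1e-12)
  corrc <- apply_correction(f, tab, "central")
  expect_equal(corrc$dose * predict(tab, 137.3), f$dose, tolerance = 1e-12)
})

test_that("central and entire schemes coincide for column-constant CFs", {
  tab <- make_cf_table(c(0, 90, 180), c(1, 1.05, 0.93))
  f <- uniform_frame(80, angle = 72)
  expect_equal(apply_correction(f, tab, "central")$dose,
               apply_correction(f, tab, "entire")$dose)
})

test_that("movie correction equals per-frame correction then accumulation", {
  model <- default_response_model("6MV")
  tab <- derive_cf(simulate_calibration(model),
                   reference_at_detectors("6MV"), energy = "6MV")
  plan <- plan_spec(beam_spec("6MV", 10, arc_start = 185, arc_stop = 175),
                    name = "arc")
  movie <- simulate_measurement(plan, model, seed = 9, noise_sigma = 0)
  got <- correct_movie(movie, tab, "entire")
  manual <- accumulate(dose_movie(lapply(movie$frames, apply_correction,
                                         table = tab, scheme = "entire")))
  expect_equal(got$dose, manual$dose)
  # single-frame movie reduces to apply_correction
  one <- dose_movie(movie$frames[1])
  expect_equal(correct_movie(one, tab, "central")$dose,
               apply_correction(movie$frames[[1]], tab, "central")$dose)
  # unit CF table leaves the accumulation unchanged
  unit <- make_cf_table(c(0, 90, 180), c(1, 1, 1))
  expect_equal(correct_movie(movie, unit, "entire")$dose,
               accumulate(movie)$dose)
  noang <- dose_movie(list(uniform_frame(1)))
  expect_error(correct_movie(noang, tab, "entire"), "gantry angle")
})

test_that("arc correction recovers the ground truth (noiseless round trip)", {
  model <- default_response_model("10MV")
  tab <- derive_cf(simulate_calibration(model),
                   reference_at_detectors("10MV"), energy = "10MV")
  plan <- plan_spec(beam_spec("10MV", 10, arc_start = 185, arc_stop = 175),
                    name = "arc")
  movie <- simulate_measurement(plan, model, noise_sigma = 0)
  truth <- composite_true_dose(plan)
  corr <- correct_movie(movie, tab, "entire")
  expect_equal(corr$dose, truth$values, tolerance = 1e-10)
  # uncorrected accumulation is visibly biased
  unc <- accumulate(movie)
  expect_gt(max(abs(unc$dose - truth$values)) / max(truth$values), 0.01)
})

test_that("with 0.3% frame noise the per-angle CF error stays below 1%", {
  model <- default_response_model("6MV")
  tab <- derive_cf(simulate_calibration(model, noise_sigma = 0.003,
                                        seed = 2026),
                   reference_at_detectors("6MV"), energy = "6MV")
  truth <- model$column_response / model$column_response[, 1]
  err <- abs(tab$column_cf / truth - 1)
  expect_lt(max(err), 0.01)
})

test_that("CF tables round-trip through the file format bit-exactly", {
  model <- default_response_model("6MV")
  tab <- derive_cf(simulate_calibration(model),
                   reference_at_detectors("6MV"), energy = "6MV")
  path <- withr::local_tempfile(fileext = ".json")
  write_cf_table(tab, path)
  back <- read_cf_table(path)
  expect_identical(back$angles, tab$angles)
  expect_identical(back$central_cf, tab$central_cf)
  expect_identical(unname(back$column_cf), unname(tab$column_cf))
  expect_identical(back$energy, tab$energy)
  expect_identical(back$normalization$column, tab$normalization$column)
})
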