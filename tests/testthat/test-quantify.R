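test_that("calibration inverts a noise-free linear camera exactly", {
  cam <- camera_config("low", gain = 50, offset = 80, saturation_level = 1e5,
                       noise_sd = 0)
  levels <- c(0, 2, 5, 10, 20, 50)
  map <- fit_calibration(calibration_stacks(cam, levels, seed = 1))
  for (cc in c(0, 1.3, 7.7, 20, 49)) {
    expect_equal(predict(map, 80 + 50 * cc), cc, tolerance = 1e-9)
  }
})

test_that("saturated calibration levels are excluded and noise handled", {
  cam <- high_exposure_camera() # saturates near 20 uM, default noise
  levels <- c(0, 1, 2, 5, 10, 15, 20, 30, 40, 50)
  map <- fit_calibration(calibration_stacks(cam, levels, seed = 5))
  expect_lte(max(map$concentration), 15)
  # unsaturated levels recovered within 2% of the span under default noise
  for (cc in c(1, 5, 10, 15)) {
    expect_equal(predict(map, cam$offset + cam$gain * cc), cc,
                 tolerance = 0.02 * 15 / cc)
  }
})

test_that("degenerate calibrations raise errors", {
  cam <- camera_config("low", gain = 50, offset = 80, saturation_level = 1e5,
                       noise_sd = 0)
  one <- calibration_stacks(cam, levels = c(5), seed = 1)
  expect_error(fit_calibration(one), "at least two")
  # non-monotone means: decreasing gain trick via manual stacks
  s1 <- calibration_stacks(cam, c(0, 10), seed = 1)
  s1$stacks <- rev(s1$stacks)
  expect_error(fit_calibration(s1), "strictly increasing")
})

test_that("axial concentration averages before mapping", {
  cam <- camera_config("low", gain = 10, offset = 0, saturation_level = 1e5,
                       noise_sd = 0)
  map <- fit_calibration(calibration_stacks(cam, c(0, 10, 20, 100), seed = 1))
  uni <- matrix(50, 3, 8)
  expect_equal(axial_concentration(uni, map), rep(5, 3), tolerance = 1e-12)
  # half the columns at I1, half at I2: profile = map((I1 + I2)/2)
  half <- cbind(matrix(40, 2, 4), matrix(80, 2, 4))
  expect_equal(axial_concentration(half, map), rep(6, 2), tolerance = 1e-12)
})

test_that("rendered frames round-trip through the pipeline to 1e-9", {
  C <- matrix(c(0, 3, 17, 42), 4, 1)
  f <- make_field(C)
  cam <- camera_config("low", gain = 76, offset = 100, saturation_level = 1e5,
                       noise_sd = 0)
  st <- render_frames(f, cam, seed = 1, width = 6)
  map <- fit_calibration(calibration_stacks(cam, c(0, 5, 10, 20, 30, 50), seed = 1))
  expect_equal(axial_concentration(st$frames[[1]], map), C[, 1], tolerance = 1e-9)
})

test_that("exposure merge follows the strict-threshold rule", {
  low <- c(15, 9.9, 10.0)
  high <- c(14.8, 9.7, 10.3)
  expect_equal(merge_exposures(low, high, 10), c(15, 9.7, 10.0))
  expect_equal(merge_exposures(c(11, 12), c(99, 99), 10), c(11, 12))
  expect_equal(merge_exposures(c(1, 2), c(0.9, 2.1), 10), c(0.9, 2.1))
  expect_error(merge_exposures(1:3, 1:4), "equal length")
  # idempotence: merging a profile with itself returns itself
  x <- c(0, 5, 10, 15)
  expect_equal(merge_exposures(x, x, 10), x)
})

test_that("spatiotemporal assembly recovers a simulated field", {
  g <- uniform_geometry(60)
  p <- single_protocol(site_z = -10, bolus_vol = 0.3, bolus_rate = 1)
  tp <- transport_params(molecular_diffusivity = 0.2, dispersion_factor = 0,
                         production_rate = 0, absorption_rate = 0,
                         production_site_z = 10, absorption_site_z = 5)
  f <- simulate_transport(g, still_waveform(), p, tp, duration = 900,
                          injection_start = 0, frame_interval = 30)
  cams <- list(low = low_exposure_camera(noise_sd = 0),
               high = high_exposure_camera(noise_sd = 0))
  levels <- c(0, 1, 2, 5, 10, 15, 20, 30, 40, 50)
  maps <- lapply(cams, function(cm) fit_calibration(calibration_stacks(cm, levels, seed = 1)))
  lo <- render_frames(f, cams$low, seed = 1, width = 8)
  hi <- render_frames(f, cams$high, seed = 2, width = 8)
  st <- build_spatiotemporal(lo, hi, maps, quant_config(duration = 0.25,
                                                        auc_windows = list(c(0, 0.25))))
  sat_thresh <- 50
  below <- f$C < sat_thresh
  expect_lt(max(abs(st$C[below] - f$C[below])), 0.01 * sat_thresh)

  # zero-field stacks give an all-zero map
  z0 <- make_field(matrix(0, 60, 3), z_mm = g$z_mm)
  st0 <- build_spatiotemporal(render_frames(z0, cams$low, 1, width = 8),
                              render_frames(z0, cams$high, 1, width = 8), maps)
  expect_true(all(st0$C == 0))

  # frame-count mismatch errors
  z1 <- make_field(matrix(0, 60, 2), z_mm = g$z_mm)
  expect_error(build_spatiotemporal(render_frames(z0, cams$low, 1, width = 8),
                                    render_frames(z1, cams$high, 1, width = 8),
                                    maps),
               "frame counts differ")
})

test_that("AUC profiles integrate exactly for simple shapes", {
  nz <- 5
  t_s <- seq(0, 3 * 3600, by = 30)
  const <- make_field(matrix(4, nz, length(t_s)), t_s = t_s)
  auc <- auc_profile(const, c(0, 3))
  expect_equal(auc$auc_uM_hr, rep(12, nz), tolerance = 1e-12)

  ramp <- make_field(matrix(rep(seq(0, 6, length.out = length(t_s)), each = nz),
                            nz, length(t_s)), t_s = t_s)
  expect_equal(auc_profile(ramp, c(0, 3))$auc_uM_hr, rep(9, nz), tolerance = 1e-12)
  expect_error(auc_profile(const, c(2, 1)), "exceed")
})

test_that("AUC matches a refined-grid oracle within the trapezoid bound", {
  t_coarse <- seq(0, 3600 * 3, by = 30)
  t_fine <- seq(0, 3600 * 3, by = 1)
  fun <- function(t) 10 * (1 - exp(-t / 2500)) * (1 + 0.2 * sin(t / 800))
  coarse <- make_field(matrix(fun(t_coarse), 1, byrow = TRUE), z_mm = 0.5,
                       t_s = t_coarse)
  a <- auc_profile(coarse, c(0, 3))$auc_uM_hr
  oracle <- pracma::trapz(t_fine / 3600, fun(t_fine))
  # trapezoid error bound ~ (b-a) h^2 max|f''| / 12; generous envelope
  expect_equal(a, oracle, tolerance = 1e-4)
})

test_that("AUC is additive across adjoining windows", {
  set.seed(9)
  t_s <- seq(0, 3 * 3600, by = 30)
  f <- make_field(matrix(runif(20 * length(t_s), 0, 30), 20), t_s = t_s)
  a03 <- auc_profile(f, c(0, 3))$auc_uM_hr
  a01 <- auc_profile(f, c(0, 1))$auc_uM_hr
  a13 <- auc_profile(f, c(1, 3))$auc_uM_hr
  expect_equal(a03, a01 + a13, tolerance = 1e-12)
})

test_that("percent injected dose follows the volume-weighted sum", {
  # toy hand evaluation: V = [0.1, 0.2, 0.3] ml, C = [10, 5, 2] uM
  vp <- volume_profile(c(0.5, 1.5, 2.5), c(0.1, 0.2, 0.3))
  f <- make_field(matrix(c(10, 5, 2), 3, 1), z_mm = vp$z_mm, t_s = 10800)
  rm <- region_map(eaCSF = c(0, 3))
  pid <- percent_id_eacsf(f, 3, vp, rm, injected_mass = 165.5)
  expect_equal(pid, 2.6 / 165.5 * 100, tolerance = 1e-12)
  expect_equal(round(pid, 3), 1.571)

  # closure: the full dose spread over the eaCSF slices gives 100%
  mass <- 165.5
  conc <- mass / sum(vp$volume_ml) # uniform concentration carrying all mass
  f100 <- make_field(matrix(conc, 3, 1), z_mm = vp$z_mm, t_s = 10800)
  expect_equal(percent_id_eacsf(f100, 3, vp, rm, mass), 100, tolerance = 1e-12)

  f0 <- make_field(matrix(0, 3, 1), z_mm = vp$z_mm, t_s = 10800)
  expect_equal(percent_id_eacsf(f0, 3, vp, rm, mass), 0)
  expect_error(percent_id_eacsf(f0, 3, vp, rm, 0), "positive")

  # monotonicity: adding concentration inside the region never decreases %ID
  fplus <- make_field(matrix(c(10, 5.5, 2), 3, 1), z_mm = vp$z_mm, t_s = 10800)
  expect_gte(percent_id_eacsf(fplus, 3, vp, rm, mass), pid)
})

test_that("region mean AUC averages slices as specified", {
  rm <- region_map(eaCSF = c(0, 2))
  auc <- tibble::tibble(z_mm = c(0.5, 1.5, 2.5), auc_uM_hr = c(2, 4, 99))
  expect_equal(region_mean_auc(auc, rm, "eaCSF"), 3)
  const <- tibble::tibble(z_mm = c(0.5, 1.5), auc_uM_hr = c(7, 7))
  expect_equal(region_mean_auc(const, rm, "eaCSF"), 7)
  set.seed(2)
  rnd <- tibble::tibble(z_mm = seq(0.5, 9.5), auc_uM_hr = runif(10))
  rm10 <- region_map(eaCSF = c(0, 10))
  expect_equal(region_mean_auc(rnd, rm10, "eaCSF"), mean(rnd$auc_uM_hr))
  # volume-weighted option
  vp <- volume_profile(c(0.5, 1.5), c(1, 3))
  w <- region_mean_auc(const, rm, "eaCSF", geometry = vp, volume_weighted = TRUE)
  expect_equal(w, 7)
  expect_error(region_mean_auc(rnd, region_map(eaCSF = c(100, 160)), "eaCSF"),
               "no slices")
})
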