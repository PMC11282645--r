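test_that("injected dose is concentration times bolus volume", {
  prot <- nhp_protocols()
  expect_equal(injected_mass(prot[prot$name == "3G2", ]), 165.5)
  expect_equal(injected_mass(prot[prot$name == "2NHP2", ]), 165.5)
  expect_equal(injected_mass(single_protocol(bolus_vol = 0)), 0)
})

test_that("protocol table enforces rate/volume consistency", {
  bad <- single_protocol(flush_vol = 1, flush_rate = 0)
  expect_error(csfdispersion:::validate_protocols(bad), "rates must be positive")
  path <- withr::local_tempfile(fileext = ".csv")
  write_protocols(nhp_protocols(), path)
  p2 <- read_protocols(path)
  expect_equal(p2$tracer_concentration_uM, nhp_protocols()$tracer_concentration_uM)
})

test_that("no source gives an identically zero field", {
  g <- uniform_geometry(60)
  w <- quick_waveform(duration = 2)
  p <- single_protocol(site_z = 0, bolus_vol = 0, flush_vol = 0)
  f <- simulate_transport(g, w, p, transport_params(production_rate = 0, absorption_rate = 0,
                                                    production_site_z = 10, absorption_site_z = 5),
                          duration = 300, frame_interval = 30)
  expect_true(all(f$C == 0))
})

test_that("closed ends conserve injected tracer mass", {
  g <- uniform_geometry(80)
  w <- quick_waveform(duration = 2)
  p <- single_protocol(site_z = 0, bolus_vol = 0.5, bolus_rate = 1)
  tp <- transport_params(production_rate = 0, absorption_rate = 0,
                         production_site_z = 10, absorption_site_z = 5)
  f <- simulate_transport(g, w, p, tp, duration = 600, frame_interval = 30,
                          injection_start = 0, end_outflow = FALSE)
  domain_mass <- colSums(f$C * g$volume_ml)
  after <- f$t_s > 40 # bolus lasts 30 s
  expect_true(all(abs(domain_mass[after] - 165.5 * 0.5) / (165.5 * 0.5) < 0.005))
})

test_that("pure diffusion matches the Gaussian heat kernel", {
  n <- 101
  g <- uniform_geometry(n, area_ml_per_mm = 0.05, z0 = -50.5)
  w <- still_waveform()
  D <- 0.5
  tp <- transport_params(molecular_diffusivity = D, dispersion_factor = 0,
                         production_rate = 0, absorption_rate = 0,
                         production_site_z = 10, absorption_site_z = 5)
  M <- 10 # uM*ml impulse at the center cell
  init <- numeric(n); init[(n + 1) / 2] <- M / g$volume_ml[(n + 1) / 2]
  p <- single_protocol(site_z = 0, bolus_vol = 0, flush_vol = 0)
  f <- simulate_transport(g, w, p, tp, duration = 240, dt_coast = 0.25,
                          frame_interval = 30, end_outflow = FALSE,
                          initial = init)
  A <- 0.05 # ml/mm
  for (tt in c(120, 240)) {
    k <- which(f$t_s == tt)
    exact <- M / A / sqrt(4 * pi * D * tt) * exp(-(f$z_mm - 0)^2 / (4 * D * tt))
    num <- f$C[, k]
    expect_lt(sqrt(sum((num - exact)^2) / sum(exact^2)), 0.02)
  }
})

test_that("mass budget closes within 0.5% at every frame for default protocols", {
  g <- build_synthetic_geometry()
  w <- quick_waveform(duration = 2)
  prot <- nhp_protocols()
  for (nm in c("2G2", "1NHP3")) {
    f <- simulate_transport(g, w, prot[prot$name == nm, ], transport_params(),
                            duration = 3600, frame_interval = 60)
    mb <- mass_budget_check(f)
    expect_true(all(mb$relative_error < 0.005))
    expect_true(all(f$C >= 0))
  }
})

test_that("tracer is zero before the injection starts", {
  g <- uniform_geometry(60)
  f <- simulate_transport(g, quick_waveform(duration = 2),
                          single_protocol(site_z = 0),
                          transport_params(production_rate = 0, absorption_rate = 0,
                                           production_site_z = 10, absorption_site_z = 5),
                          duration = 600, frame_interval = 30, injection_start = 120)
  expect_true(all(f$C[, f$t_s < 120] == 0))
  expect_gt(max(f$C[, f$t_s > 150]), 0)
})

test_that("unstable dt and out-of-domain sites raise informative errors", {
  g <- uniform_geometry(40, area_ml_per_mm = 0.002)
  w <- quick_waveform(duration = 2)
  p <- single_protocol(site_z = 0, bolus_rate = 10)
  tp <- transport_params(production_rate = 0, absorption_rate = 0,
                         production_site_z = 5, absorption_site_z = 2)
  expect_error(
    simulate_transport(g, w, p, tp, duration = 120, dt = 60, injection_start = 0),
    "CFL bound")
  expect_error(
    simulate_transport(g, w, single_protocol(site_z = 500), tp, duration = 120),
    "outside domain")
})

test_that("rendering is linear, clipped, and seed-deterministic", {
  C <- matrix(c(0, 5, 30, 1000), 4, 2)
  f <- make_field(C)
  cam <- camera_config("low", gain = 10, offset = 100, saturation_level = 1000,
                       noise_sd = 0)
  st <- render_frames(f, cam, seed = 3, width = 4)
  expect_true(all(st$frames[[1]][1, ] == 100))       # zero field -> offset
  expect_true(all(st$frames[[1]][2, ] == 150))
  expect_true(all(st$frames[[1]][4, ] == 1000))      # clipped at saturation

  noisy <- camera_config("low", gain = 10, offset = 100, saturation_level = 1000,
                         noise_sd = 5)
  a <- render_frames(f, noisy, seed = 7)
  b <- render_frames(f, noisy, seed = 7)
  expect_identical(a$frames, b$frames)
  c2 <- render_frames(f, noisy, seed = 8)
  expect_false(identical(a$frames, c2$frames))
})

test_that("calibration stacks behave per the camera configuration", {
  expect_error(calibration_stacks(low_exposure_camera(), levels = c(0, 5, 5)),
               "strictly increasing")
  cam <- camera_config("low", gain = 50, offset = 80, saturation_level = 4000,
                       noise_sd = 0)
  cs <- calibration_stacks(cam, levels = c(0, 10, 20), seed = 1)
  means <- vapply(cs$stacks, function(s) mean(s$frames[[1]]), numeric(1))
  expect_equal(means, 80 + 50 * c(0, 10, 20))

  # default pair: high exposure saturates at the top level, low does not
  levels <- c(0, 1, 2, 5, 10, 15, 20, 30, 40, 50)
  hi <- calibration_stacks(high_exposure_camera(noise_sd = 0), levels, seed = 1)
  lo <- calibration_stacks(low_exposure_camera(noise_sd = 0), levels, seed = 1)
  hi_top <- mean(hi$stacks[[10]]$frames[[1]])
  lo_top <- mean(lo$stacks[[10]]$frames[[1]])
  expect_equal(hi_top, high_exposure_camera()$saturation_level)
  expect_lt(lo_top, low_exposure_camera()$saturation_level)
})

test_that("image stacks round-trip through multi-page TIFF", {
  C <- matrix(runif(12, 0, 40), 4, 3)
  f <- make_field(C)
  cam <- low_exposure_camera(noise_sd = 0)
  st <- render_frames(f, cam, seed = 1, width = 4)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_image_stack(st, path)
  st2 <- read_image_stack(path, cam, frame_interval = 30)
  expect_equal(length(st2$frames), 3)
  # 16-bit quantization: intensities agree to sat/2^16
  err <- max(abs(st2$frames[[1]] - st$frames[[1]]))
  expect_lt(err, cam$saturation_level / 2^15)
})
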