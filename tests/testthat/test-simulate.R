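test_that("restitution function reproduces its closed form and monotonicity", {
  w <- waveform_params(380, 140, 120)
  expect_equal(restitution_function(Inf, w), 380)
  expect_equal(restitution_function(0, w), 240)
  expect_equal(restitution_function(120, w), 380 - 140 * exp(-1),
               tolerance = 1e-12)
  di <- seq(0, 2000, by = 25)
  d <- restitution_function(di, w)
  expect_true(all(diff(d) > 0))
  expect_true(all(d <= 380))
  expect_error(restitution_function(-1, w), "must be >= 0")
})

test_that("waveform and region invariants are enforced", {
  expect_error(waveform_params(apd_max_ms = 100, restitution_amplitude_ms = 100),
               "positive at DI = 0")
  expect_error(waveform_params(apd_max_ms = 100, restitution_amplitude_ms = 50,
                               upstroke_ms = 150),
               "upstroke_ms")
  expect_error(region_spec("x", "rect", rows = c(1, 5), cols = c(1, 5),
                           erp_ms = 300, intrinsic_cycle_ms = 200),
               "exceed")
  g <- sim_grid(10, 10, 1)
  bad <- region_spec("x", "rect", rows = c(1, 20), cols = c(1, 5), erp_ms = 300)
  expect_error(region_mask(bad, g), "exceeds the image grid")
  expect_error(
    build_activation_schedule(
      sim_protocol("point", point_site = c(50, 50), cycle_lengths_ms = 500,
                   total_duration_ms = 1000),
      list(region_spec("x", "rect", rows = c(1, 10), cols = c(1, 10),
                       erp_ms = 200)),
      g, cv = 0.5),
    "point_site outside")
})

test_that("schedule-level capture ratio matches the refractory-period rule", {
  # brute-force sweep on a 1-pixel grid: with strict-inequality capture the
  # steady-state period is the smallest k with k * PCL > ERP,
  # i.e. ratio = floor(ERP / PCL) + 1
  grid <- sim_grid(1, 1, 1)
  for (erp in seq(200, 1200, by = 200)) {
    for (pcl in seq(200, 2000, by = 300)) {
      expected <- floor(erp / pcl) + 1
      pulses <- 4 * expected + 4
      reg <- region_spec("r", "rect", rows = c(1, 1), cols = c(1, 1),
                         erp_ms = erp)
      pro <- sim_protocol("point", point_site = c(1, 1),
                          cycle_lengths_ms = pcl, pulses_per_step = pulses,
                          total_duration_ms = 20 + pulses * pcl)
      truth <- build_activation_schedule(pro, list(reg), grid, cv = 0.5)
      acts <- truth_activation_times(truth, c(1, 1))
      steady <- acts[acts >= 20 + 2 * pcl]
      expect_gte(length(steady), 2)
      expect_equal(unique(diff(steady)) / pcl, expected,
                   info = sprintf("erp=%d pcl=%d", erp, pcl))
    }
  }
})

test_that("SAN-like region shows 1:1, 2:1 and 3:1 capture at 1000/600/400 ms pacing", {
  grid <- sim_grid(1, 1, 1)
  reg <- region_spec("san", "rect", rows = c(1, 1), cols = c(1, 1),
                     erp_ms = 900)
  for (case in list(c(1000, 1), c(600, 2), c(400, 3))) {
    pro <- sim_protocol("point", point_site = c(1, 1),
                        cycle_lengths_ms = case[1], pulses_per_step = 10,
                        total_duration_ms = 20 + 10 * case[1])
    truth <- build_activation_schedule(pro, list(reg), grid, cv = 0.5)
    acts <- truth_activation_times(truth, c(1, 1))
    expect_equal(unique(diff(acts)) / case[1], case[2])
  }
})

test_that("automatic regions fire at their intrinsic cycle when unpaced", {
  grid <- sim_grid(3, 3, 1)
  reg <- region_spec("san", "rect", rows = c(1, 3), cols = c(1, 3),
                     erp_ms = 400, intrinsic_cycle_ms = 1000)
  pro <- sim_protocol("none", total_duration_ms = 10500)
  truth <- build_activation_schedule(pro, list(reg), grid, cv = 0.5)
  acts <- truth_activation_times(truth, c(2, 2))
  expect_length(acts, 10)
  expect_equal(diff(acts), rep(1000, 9))
})

test_that("paced capture resets the spontaneous clock (phase reset)", {
  grid <- sim_grid(1, 1, 1)
  reg <- region_spec("san", "rect", rows = c(1, 1), cols = c(1, 1),
                     erp_ms = 300, intrinsic_cycle_ms = 1000)
  # stimulus at 520 ms captures (interval > ERP); next spontaneous beat
  # comes 1000 ms after the paced one, not after the previous spontaneous
  pro <- sim_protocol("point", point_site = c(1, 1),
                      cycle_lengths_ms = 5000, pulses_per_step = 1,
                      start_ms = 1520, total_duration_ms = 3000)
  truth <- build_activation_schedule(pro, list(reg), grid, cv = 0.5)
  acts <- truth_activation_times(truth, c(1, 1))
  expect_equal(acts, c(1000, 1520, 2520))
})

test_that("plane-wave schedules are affine and point sources radial", {
  grid <- sim_grid(15, 15, 0.5)
  reg <- region_spec("t", "rect", rows = c(1, 15), cols = c(1, 15),
                     erp_ms = 250)
  pro <- sim_protocol("field", cycle_lengths_ms = 1000, pulses_per_step = 1,
                      total_duration_ms = 1500)
  truth <- build_activation_schedule(pro, list(reg), grid, cv = 0.5)
  act <- truth$beats[[1]]$act
  # affine in the propagation coordinate: rows identical, columns linear
  expect_equal(act[1, ], act[15, ])
  expect_equal(diff(act[8, ]), rep(0.5 / 0.5, 14))

  pro2 <- sim_protocol("point", point_site = c(8, 8),
                       cycle_lengths_ms = 1000, pulses_per_step = 1,
                       total_duration_ms = 1500)
  truth2 <- build_activation_schedule(pro2, list(reg), grid, cv = 0.4)
  act2 <- truth2$beats[[1]]$act
  rr <- matrix(seq_len(15), 15, 15); cc <- t(rr)
  dist_mm <- sqrt((rr - 8)^2 + (cc - 8)^2) * 0.5
  expect_equal(act2 - act2[8, 8], dist_mm / 0.4, tolerance = 1e-10)
})

test_that("per-pixel scheduled activation times are strictly increasing", {
  sim <- sim_san_atrial(n = 12, pcl = 600, pulses = 8,
                        san_intrinsic = 1400)
  for (px in list(c(2, 2), c(6, 8), c(11, 11))) {
    acts <- truth_activation_times(sim$truth, px)
    expect_true(all(diff(acts) > 0))
  }
})

test_that("rendered upstrokes cross 50% within one frame of the schedule", {
  sim <- sim_plane_wave(n = 10, cv = 0.5, pulses = 2)
  st <- sim$stack
  for (px in list(c(1, 1), c(5, 5), c(10, 10))) {
    tr <- pixel_trace(st, px)
    wins <- segment_beats(tr, st$stim_times_ms)
    measured <- vapply(seq_len(nrow(wins)), function(b)
      activation_time(tr, wins[b, ]), 0)
    truth_t <- truth_activation_times(sim$truth, px)
    expect_equal(length(measured), length(truth_t))
    expect_true(all(abs(measured - truth_t) < 1000 / st$fps_hz))
  }
})

test_that("polarity -1 renders the negation of polarity +1 about the baseline", {
  sim <- sim_plane_wave(n = 6, pulses = 1)
  neg <- render_movie(sim$truth, artifact_params(polarity = -1), fps = 1000)
  dia <- 0.1  # configured diastolic level
  expect_equal(neg$frames, 2 * dia - sim$stack$frames,
               tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rendering with noise is reproducible under a fixed seed", {
  sim <- sim_plane_wave(n = 6, pulses = 1)
  a <- render_movie(sim$truth, artifact_params(noise_sd = 0.1, seed = 42),
                    fps = 500)
  b <- render_movie(sim$truth, artifact_params(noise_sd = 0.1, seed = 42),
                    fps = 500)
  c_ <- render_movie(sim$truth, artifact_params(noise_sd = 0.1, seed = 43),
                     fps = 500)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c_$frames))
})

test_that("rendering refuses movies that truncate the last beat", {
  sim <- sim_plane_wave(n = 6, pulses = 2, pcl = 800)
  expect_error(render_movie(sim$truth, artifact_params(), fps = 500,
                            duration_ms = 900),
               "truncate")
})
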