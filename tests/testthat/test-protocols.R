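test_that("capture ratio identifies 1:1, 2:1 and irregular rhythms", {
  stims <- seq(0, by = 600, length.out = 10)

  all_cap <- capture_ratio(stims + 5, stims)
  expect_equal(all_cap$ratio, 1L)
  expect_equal(all_cap$pcl_ms, 600)
  expect_equal(all_cap$responses, all_cap$stimuli)

  half <- capture_ratio(stims[seq(1, 9, by = 2)] + 5, stims)
  expect_equal(half$ratio, 2L)

  none <- capture_ratio(numeric(), stims)
  expect_true(is.na(none$ratio))
  expect_equal(none$responses, 0)

  # responses at irregular multiples of the cycle length do not lock
  irregular <- capture_ratio(stims[c(3, 4, 6, 9)] + 5, stims, discard = 0)
  expect_true(is.na(irregular$ratio))

  expect_error(capture_ratio(1, numeric()), "stimuli")
  expect_error(capture_ratio(1, c(0, 600), discard = 2), "post-transient")
})

test_that("SAN shows 2:1 and atrium 1:1 through the rendered pipeline", {
  sim <- sim_san_atrial(n = 16, pcl = 600, pulses = 8)
  st <- sim$stack
  for (case in list(list(mask = sim$san_mask, ratio = 2L),
                    list(mask = sim$atrial_mask & !sim$san_mask, ratio = 1L))) {
    tr <- conditioned_regional_trace(st, case$mask)
    wins <- segment_beats(tr, st$stim_times_ms)
    cr <- capture_ratio(wins$upstroke_ms, st$stim_times_ms)
    expect_equal(cr$ratio, case$ratio)
  }
})

test_that("ERP is the midpoint of the capture-loss bracket", {
  mk <- function(pcl, ratio) structure(
    list(pcl_ms = pcl, stimuli = 8, responses = 8, ratio = ratio),
    class = "capture_result")
  est <- estimate_erp(list(mk(400, 1L), mk(350, 1L), mk(300, 2L)), step_ms = 50)
  expect_equal(est$erp_ms, 325)
  expect_equal(est$last_captured_pcl_ms, 350)
  expect_equal(est$first_lost_pcl_ms, 300)

  expect_error(estimate_erp(list(mk(400, 1L), mk(350, 1L)), 50),
               "never lost")
  expect_error(estimate_erp(list(mk(400, 2L), mk(350, NA_integer_)), 50),
               "never achieved")
})

test_that("a scheduled S1-S1 ramp recovers a 275 ms ERP within half a step", {
  erp_true <- 275
  grid <- sim_grid(1, 1, 1)
  reg <- region_spec("t", "rect", rows = c(1, 1), cols = c(1, 1),
                     erp_ms = erp_true)
  step <- 50
  results <- lapply(seq(450, 200, by = -step), function(pcl) {
    pro <- sim_protocol("point", point_site = c(1, 1),
                        cycle_lengths_ms = pcl, pulses_per_step = 10,
                        total_duration_ms = 20 + 10 * pcl)
    truth <- build_activation_schedule(pro, list(reg), grid, cv = 0.5)
    capture_ratio(truth_activation_times(truth, c(1, 1)),
                  truth$stim_times_ms)
  })
  est <- estimate_erp(results, step_ms = step)
  expect_lte(abs(est$erp_ms - erp_true), step / 2)
})

test_that("restitution curves recover the steady-state duration at each PCL", {
  w <- waveform_params()
  pcls <- c(1000, 700, 500)
  entries <- lapply(pcls, function(pcl) {
    sim <- sim_plane_wave(n = 6, pcl = pcl, pulses = 8)
    list(pcl_ms = pcl, stack = sim$stack)
  })
  mask <- full_mask(entries[[1]]$stack)
  curve <- build_restitution(entries, mask, n_discard = 5)
  pts <- curve$points
  expect_equal(pts$pcl_ms, pcls)                      # descending order
  expect_true(all(diff(pts$mean_duration_ms) < 0))    # shorter PCL, shorter APD
  for (i in seq_along(pcls)) {
    expect_lt(abs(pts$mean_duration_ms[i] - steady_duration(pcls[i], w)), 1)
    expect_gt(pts$n_beats[i], 0)
  }
})

test_that("cycle lengths that lose 1:1 capture are excluded with a warning", {
  sim_ok <- sim_plane_wave(n = 4, pcl = 800, pulses = 8)
  sim_block <- sim_plane_wave(n = 4, pcl = 200, pulses = 16, erp = 250)
  mask <- full_mask(sim_ok$stack)
  expect_warning(
    curve <- build_restitution(
      list(list(pcl_ms = 800, stack = sim_ok$stack),
           list(pcl_ms = 200, stack = sim_block$stack)),
      mask, n_discard = 5),
    "capture lost")
  expect_equal(curve$points$pcl_ms, 800)
})

test_that("automaticity detection separates paced from spontaneous beats", {
  acts <- seq(1000, 9000, by = 1000)
  free <- detect_automaticity(acts, numeric(), record_ms = 10000)
  expect_true(free$spontaneous)
  expect_equal(free$rate_hz, 1)

  paced <- detect_automaticity(acts, acts - 10, record_ms = 10000)
  expect_false(paced$spontaneous)
  expect_true(is.na(paced$rate_hz))

  few <- detect_automaticity(c(500, 1500), numeric(), record_ms = 10000)
  expect_true(few$spontaneous)
  expect_true(is.na(few$rate_hz))

  expect_warning(detect_automaticity(acts[1:4], numeric(), record_ms = 3000),
                 "5 s")
  none <- detect_automaticity(numeric(), numeric())
  expect_false(none$spontaneous)
})

test_that("classification separates Gaussian feature clusters at >= 95%", {
  set.seed(31)
  n <- 24
  mask <- matrix(TRUE, n, n)
  truth_nodal <- matrix(FALSE, n, n)
  truth_nodal[9:16, 9:16] <- TRUE
  dur <- matrix(stats::rnorm(n * n, 200, 5), n, n)
  rise <- matrix(stats::rnorm(n * n, 5, 1), n, n)
  dur[truth_nodal] <- stats::rnorm(sum(truth_nodal), 400, 5)
  rise[truth_nodal] <- stats::rnorm(sum(truth_nodal), 50, 2)
  labels <- classify_regions(dur, rise, mask)
  agree <- (labels == "nodal-like") == truth_nodal
  expect_gte(mean(agree), 0.95)
})

test_that("homogeneous tissue yields a single working label with a warning", {
  set.seed(32)
  n <- 15
  dur <- matrix(stats::rnorm(n * n, 220, 4), n, n)
  rise <- matrix(stats::rnorm(n * n, 6, 0.5), n, n)
  expect_warning(labels <- classify_regions(dur, rise, matrix(TRUE, n, n)),
                 "unimodal")
  expect_true(all(labels == "working"))

  expect_error(classify_regions(dur, rise, matrix(TRUE, n, n),
                                min_pixels = 500), "need >= 500")
})
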