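# shared builders for small simulated slices

atrial_wave <- function(...) {
  waveform_params(apd_max_ms = 235, restitution_amplitude_ms = 90,
                  restitution_tau_ms = 150, upstroke_ms = 5, ...)
}

san_wave <- function(...) {
  waveform_params(apd_max_ms = 420, restitution_amplitude_ms = 120,
                  restitution_tau_ms = 200, upstroke_ms = 80,
                  ca_delay_ms = 20, ...)
}

# homogeneous slice paced from the left edge
sim_plane_wave <- function(n = 20, cv = 0.5, pcl = 1000, pulses = 3,
                           erp = 250, wave = waveform_params(),
                           fps = 1000, artifacts = artifact_params(),
                           pixel_mm = 10 / n) {
  grid <- sim_grid(n, n, pixel_mm)
  reg <- region_spec("tissue", "rect", rows = c(1, n), cols = c(1, n),
                     erp_ms = erp, waveform = wave)
  pro <- sim_protocol("field", cycle_lengths_ms = pcl,
                      pulses_per_step = pulses,
                      total_duration_ms = 20 + pcl * pulses + 400)
  truth <- build_activation_schedule(pro, list(reg), grid, cv = cv)
  stack <- render_movie(truth, artifacts, fps = fps)
  list(truth = truth, stack = stack, grid = grid, region = reg)
}

# atrial slice with an embedded SAN ellipse, field-paced from the left
sim_san_atrial <- function(n = 30, pcl = 600, pulses = 10, cv = 0.5,
                           erp_san = 900, erp_atrial = 250,
                           san_intrinsic = NA_real_, fps = 1000,
                           artifacts = artifact_params()) {
  grid <- sim_grid(n, n, 10 / n)
  atrial <- region_spec("atrial", "rect", rows = c(1, n), cols = c(1, n),
                        erp_ms = erp_atrial, waveform = atrial_wave())
  san <- region_spec("SAN", "ellipse",
                     center = round(c(n / 2, 0.7 * n)),
                     radii = round(c(n / 4, n / 5)),
                     erp_ms = erp_san, intrinsic_cycle_ms = san_intrinsic,
                     waveform = san_wave())
  pro <- sim_protocol("field", cycle_lengths_ms = pcl,
                      pulses_per_step = pulses,
                      total_duration_ms = 20 + pcl * pulses + 600)
  truth <- build_activation_schedule(pro, list(atrial, san), grid, cv = cv)
  stack <- render_movie(truth, artifacts, fps = fps)
  list(truth = truth, stack = stack, grid = grid,
       san_mask = truth$region_labels == "SAN",
       atrial_mask = truth$region_labels == "atrial")
}

# steady-state duration oracle: the fixed point D = f(PCL - D) of the
# restitution relation, solved numerically (independent of the renderer
# and of the mapping code)
steady_duration <- function(pcl, w) {
  g <- function(D) restitution_function(max(pcl - D, 0), w) - D
  lo <- w$apd_max_ms - w$restitution_amplitude_ms
  stats::uniroot(g, c(lo - 1e-9, w$apd_max_ms + 1e-9), tol = 1e-10)$root
}

# regional mean trace, conditioned at trace level (no spatial binning)
conditioned_regional_trace <- function(stack, mask, cutoff_hz = NA) {
  tr <- regional_trace(stack, mask)
  if (!is.na(cutoff_hz)) tr <- lowpass(tr, cutoff_hz)
  tr <- remove_drift(tr, diastolic_only = TRUE)
  tr <- normalize01(tr)
  suppressWarnings(orient_polarity(tr, stim_times_ms = stack$stim_times_ms))
}
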