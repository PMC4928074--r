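#' Action-potential / calcium-transient waveform parameters
#'
#' Describes one region's beat shape and its rate dependence. Duration
#' restitution is mono-exponential in the diastolic interval (DI):
#' `D(DI) = apd_max_ms - restitution_amplitude_ms * exp(-DI / restitution_tau_ms)`,
#' so the duration rises monotonically with DI and saturates at `apd_max_ms`.
#'
#' @param apd_max_ms asymptotic duration at long diastolic interval (ms).
#' @param restitution_amplitude_ms depth of rate-dependent shortening (ms);
#'   must be below `apd_max_ms` so the duration stays positive at DI = 0.
#' @param restitution_tau_ms restitution time constant (ms).
#' @param upstroke_ms 10-90% rise time of the voltage upstroke (ms); must be
#'   shorter than `apd_max_ms`.
#' @param ca_delay_ms latency of the calcium transient behind the action
#'   potential (ms); used only when rendering the `"Ca"` modality.
#' @param amplitude peak fluorescence excursion above the diastolic level.
#' @param diastolic_level resting fluorescence value.
#' @return a `waveform_params` object.
#' @export
waveform_params <- function(apd_max_ms = 380, restitution_amplitude_ms = 140,
                            restitution_tau_ms = 120, upstroke_ms = 5,
                            ca_delay_ms = 0, amplitude = 1,
                            diastolic_level = 0.1) {
  stopifnot(apd_max_ms > 0, restitution_amplitude_ms >= 0,
            restitution_tau_ms > 0, upstroke_ms > 0,
            ca_delay_ms >= 0, amplitude > 0)
  if (restitution_amplitude_ms >= apd_max_ms)
    stop("restitution_amplitude_ms must be < apd_max_ms (duration must stay positive at DI = 0)",
         call. = FALSE)
  if (upstroke_ms >= apd_max_ms)
    stop("upstroke_ms must be < apd_max_ms", call. = FALSE)
  structure(list(apd_max_ms = apd_max_ms,
                 restitution_amplitude_ms = restitution_amplitude_ms,
                 restitution_tau_ms = restitution_tau_ms,
                 upstroke_ms = upstroke_ms, ca_delay_ms = ca_delay_ms,
                 amplitude = amplitude, diastolic_level = diastolic_level),
            class = "waveform_params")
}

#' Duration restitution (mono-exponential in diastolic interval)
#'
#' @param di_ms diastolic interval(s) in ms, non-negative (Inf allowed).
#' @param w a [waveform_params()] object.
#' @return duration(s) in ms, strictly increasing in `di_ms` and bounded
#'   above by `w$apd_max_ms`.
#' @export
restitution_function <- function(di_ms, w) {
  if (any(di_ms < 0)) stop("diastolic interval must be >= 0", call. = FALSE)
  w$apd_max_ms - w$restitution_amplitude_ms * exp(-di_ms / w$restitution_tau_ms)
}

#' Simulation grid geometry
#'
#' @param nrow,ncol image dimensions in pixels.
#' @param pixel_size_mm pixel side length (mm). The defaults reproduce a
#'   1 cm field of view on a 100 x 100 sensor.
#' @return a `sim_grid` object.
#' @export
sim_grid <- function(nrow = 100, ncol = 100, pixel_size_mm = 0.1) {
  stopifnot(nrow >= 1, ncol >= 1, pixel_size_mm > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size_mm = pixel_size_mm),
            class = "sim_grid")
}

#' Tissue region with its own refractoriness and waveform
#'
#' @param label region name, e.g. `"SAN"` or `"atrial"`.
#' @param shape `"rect"` or `"ellipse"`.
#' @param rows,cols for `"rect"`: inclusive pixel ranges `c(first, last)`.
#' @param center,radii for `"ellipse"`: pixel center `c(row, col)` and
#'   semi-axes `c(row_radius, col_radius)` in pixels.
#' @param erp_ms effective refractory period (ms, > 0): an incoming wavefront
#'   captures the region only if it arrives strictly more than `erp_ms` after
#'   the region's previous local activation.
#' @param intrinsic_cycle_ms spontaneous firing cycle length (ms) for
#'   automatic (pacemaker-like) regions, or `NA` for quiescent tissue. Must
#'   exceed `erp_ms`. Any activation of the region resets the spontaneous
#'   clock (phase reset).
#' @param waveform a [waveform_params()] object.
#' @return a `region_spec` object.
#' @export
region_spec <- function(label, shape = c("rect", "ellipse"),
                        rows = NULL, cols = NULL,
                        center = NULL, radii = NULL,
                        erp_ms, intrinsic_cycle_ms = NA_real_,
                        waveform = waveform_params()) {
  shape <- match.arg(shape)
  stopifnot(is.character(label), length(label) == 1L, erp_ms > 0)
  if (!is.na(intrinsic_cycle_ms) && intrinsic_cycle_ms <= erp_ms)
    stop("intrinsic_cycle_ms must exceed erp_ms", call. = FALSE)
  if (shape == "rect") {
    stopifnot(length(rows) == 2L, length(cols) == 2L,
              rows[1] <= rows[2], cols[1] <= cols[2])
  } else {
    stopifnot(length(center) == 2L, length(radii) == 2L, all(radii > 0))
  }
  structure(list(label = label, shape = shape, rows = rows, cols = cols,
                 center = center, radii = radii, erp_ms = erp_ms,
                 intrinsic_cycle_ms = intrinsic_cycle_ms,
                 waveform = waveform),
            class = "region_spec")
}

#' Pixel membership mask of a region
#' @param region a [region_spec()].
#' @param grid a [sim_grid()].
#' @return logical `nrow x ncol` matrix.
#' @export
region_mask <- function(region, grid) {
  r <- matrix(seq_len(grid$nrow), grid$nrow, grid$ncol)
  c_ <- matrix(rep(seq_len(grid$ncol), each = grid$nrow), grid$nrow, grid$ncol)
  if (region$shape == "rect") {
    if (region$rows[1] < 1 || region$rows[2] > grid$nrow ||
        region$cols[1] < 1 || region$cols[2] > grid$ncol)
      stop("region geometry exceeds the image grid", call. = FALSE)
    r >= region$rows[1] & r <= region$rows[2] &
      c_ >= region$cols[1] & c_ <= region$cols[2]
  } else {
    if (region$center[1] - region$radii[1] < 1 ||
        region$center[1] + region$radii[1] > grid$nrow ||
        region$center[2] - region$radii[2] < 1 ||
        region$center[2] + region$radii[2] > grid$ncol)
      stop("region geometry exceeds the image grid", call. = FALSE)
    ((r - region$center[1]) / region$radii[1])^2 +
      ((c_ - region$center[2]) / region$radii[2])^2 <= 1
  }
}

#' Pacing protocol for the simulator
#'
#' @param mode `"field"` (whole-edge stimulation), `"point"` (single-site
#'   electrode) or `"none"` (record intrinsic activity only).
#' @param point_site pixel `c(row, col)` of the pacing electrode
#'   (required for `"point"`).
#' @param field_edge which image edge carries the field stimulus:
#'   `"left"`, `"right"`, `"top"` or `"bottom"`.
#' @param cycle_lengths_ms pacing cycle lengths in ms, one pacing train per
#'   entry, delivered in the order given (S1-S1 restitution protocols run
#'   them strictly decreasing, e.g. 2000 down to 200 ms).
#' @param pulses_per_step number of stimuli per cycle length.
#' @param start_ms time of the first stimulus (ms).
#' @param total_duration_ms length of the simulated record (ms).
#' @return a `sim_protocol` object with a `stim_times_ms` component.
#' @export
sim_protocol <- function(mode = c("field", "point", "none"),
                         point_site = NULL, field_edge = "left",
                         cycle_lengths_ms = numeric(),
                         pulses_per_step = 1L, start_ms = 20,
                         total_duration_ms) {
  mode <- match.arg(mode)
  stopifnot(total_duration_ms > 0, pulses_per_step >= 1)
  if (mode == "point" && (is.null(point_site) || length(point_site) != 2L))
    stop("point pacing needs `point_site = c(row, col)`", call. = FALSE)
  if (mode != "none" && length(cycle_lengths_ms) == 0L)
    stop("pacing requires at least one cycle length", call. = FALSE)
  stopifnot(all(cycle_lengths_ms > 0))
  stim <- numeric()
  t0 <- start_ms
  for (cl in cycle_lengths_ms) {
    stim <- c(stim, t0 + (seq_len(pulses_per_step) - 1) * cl)
    t0 <- stim[length(stim)] + cl
  }
  if (mode == "none") stim <- numeric()
  stim <- stim[stim < total_duration_ms]
  structure(list(mode = mode, point_site = point_site,
                 field_edge = field_edge,
                 cycle_lengths_ms = cycle_lengths_ms,
                 pulses_per_step = as.integer(pulses_per_step),
                 start_ms = start_ms,
                 total_duration_ms = total_duration_ms,
                 stim_times_ms = stim),
            class = "sim_protocol")
}

#' Recording-artifact parameters for the renderer
#'
#' @param noise_sd additive Gaussian noise SD as a fraction of the waveform
#'   amplitude.
#' @param drift_slope linear baseline drift, in fractions of the waveform
#'   amplitude per second.
#' @param polarity `+1` (depolarization-positive) or `-1` (voltage-dye style
#'   inversion: fluorescence falls on depolarization).
#' @param seed integer RNG seed for the noise.
#' @return an `artifact_params` object.
#' @export
artifact_params <- function(noise_sd = 0, drift_slope = 0, polarity = 1L,
                            seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (!polarity %in% c(-1, 1))
    stop("polarity must be +1 or -1", call. = FALSE)
  structure(list(noise_sd = noise_sd, drift_slope = drift_slope,
                 polarity = as.integer(polarity), seed = as.integer(seed)),
            class = "artifact_params")
}

# travel time (ms) from each of a set of source pixels to every grid pixel;
# returns the per-pixel minimum. `cv` is either a single isotropic speed in
# m/s (= mm/ms) or list(long = , trans = , fiber_angle_rad = ) for an
# anisotropic velocity ellipse.
.travel_time_ms <- function(sources_rc, grid, cv) {
  r <- matrix(seq_len(grid$nrow), grid$nrow, grid$ncol)
  c_ <- matrix(rep(seq_len(grid$ncol), each = grid$nrow), grid$nrow, grid$ncol)
  px <- grid$pixel_size_mm
  best <- matrix(Inf, grid$nrow, grid$ncol)
  for (i in seq_len(nrow(sources_rc))) {
    dy <- (r - sources_rc[i, 1]) * px      # mm, down rows
    dx <- (c_ - sources_rc[i, 2]) * px     # mm, across cols
    if (is.list(cv)) {
      a <- cv$fiber_angle_rad
      dl <- dx * cos(a) + dy * sin(a)
      dt <- -dx * sin(a) + dy * cos(a)
      tt <- sqrt((dl / cv$long)^2 + (dt / cv$trans)^2)
    } else {
      tt <- sqrt(dx^2 + dy^2) / cv
    }
    best <- pmin(best, tt)
  }
  best
}

.source_pixels <- function(protocol, grid) {
  switch(protocol$mode,
    point = {
      ps <- protocol$point_site
      if (ps[1] < 1 || ps[1] > grid$nrow || ps[2] < 1 || ps[2] > grid$ncol)
        stop("point_site outside the image grid", call. = FALSE)
      matrix(ps, 1, 2)
    },
    field = switch(protocol$field_edge,
      left   = cbind(seq_len(grid$nrow), 1),
      right  = cbind(seq_len(grid$nrow), grid$ncol),
      top    = cbind(1, seq_len(grid$ncol)),
      bottom = cbind(grid$nrow, seq_len(grid$ncol)),
      stop("unknown field_edge", call. = FALSE)),
    none = NULL)
}

#' Build the ground-truth activation schedule
#'
#' Runs an event-driven kinematic simulation: stimuli (field or point) and
#' spontaneous firings of automatic regions are processed in time order. A
#' wavefront starting at time `t0` from a source reaches pixel `p` at
#' `t0 + travel_time(p)`; a region responds to it only if the wavefront
#' arrives at the region strictly more than `erp_ms` after the region's last
#' local activation (so `erp_ms` is the longest failing interval). Captured
#' responses activate every pixel of the region at its kinematic arrival
#' time. Automatic regions fire from their centroid whenever the time since
#' their last local activation reaches `intrinsic_cycle_ms`; any activation
#' (paced or spontaneous) resets that clock.
#'
#' @param protocol a [sim_protocol()].
#' @param regions list of [region_spec()] objects; later regions take
#'   precedence where geometries overlap.
#' @param grid a [sim_grid()].
#' @param cv conduction speed in m/s, or
#'   `list(long =, trans =, fiber_angle_rad =)` for an anisotropic ellipse.
#' @return a `ground_truth` object: `beats` (list of
#'   `list(time, source, act)` with `act` an H x W matrix of activation
#'   times, `NA` where a region blocked), `region_labels` (character H x W),
#'   `region_index` (integer H x W), plus the full configuration.
#' @export
build_activation_schedule <- function(protocol, regions, grid, cv) {
  if (length(regions) == 0L) stop("at least one region required", call. = FALSE)
  if (is.list(cv)) stopifnot(cv$long > 0, cv$trans > 0)
  else stopifnot(cv > 0)

  n_reg <- length(regions)
  masks <- lapply(regions, region_mask, grid = grid)
  region_index <- matrix(NA_integer_, grid$nrow, grid$ncol)
  for (i in seq_len(n_reg)) region_index[masks[[i]]] <- i
  # re-derive exclusive masks after overlap resolution
  masks <- lapply(seq_len(n_reg), function(i) {
    m <- region_index == i
    m[is.na(m)] <- FALSE
    m
  })
  if (any(vapply(masks, sum, 0L) == 0L))
    stop("a region is fully hidden by later regions", call. = FALSE)
  labels <- matrix(NA_character_, grid$nrow, grid$ncol)
  for (i in seq_len(n_reg)) labels[masks[[i]]] <- regions[[i]]$label

  centroids <- t(vapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(round(mean(idx[, 1])), round(mean(idx[, 2])))
  }, numeric(2)))

  stim_sources <- .source_pixels(protocol, grid)
  stim_queue <- protocol$stim_times_ms
  last_act <- rep(-Inf, n_reg)
  intrinsic <- vapply(regions, function(r) r$intrinsic_cycle_ms, 0)
  # automatic regions start their clock at t = 0
  last_act[!is.na(intrinsic)] <- 0

  beats <- list()
  repeat {
    next_stim <- if (length(stim_queue)) stim_queue[1] else Inf
    auto_times <- ifelse(is.na(intrinsic), Inf, last_act + intrinsic)
    next_auto <- min(auto_times)
    t0 <- min(next_stim, next_auto)
    if (!is.finite(t0) || t0 >= protocol$total_duration_ms) break

    if (next_stim <= next_auto) {
      src <- stim_sources
      origin <- "stimulus"
      stim_queue <- stim_queue[-1]
    } else {
      i_auto <- which.min(auto_times)
      src <- matrix(centroids[i_auto, ], 1, 2)
      origin <- paste0("auto:", regions[[i_auto]]$label)
    }
    tt <- .travel_time_ms(src, grid, cv)
    act <- matrix(NA_real_, grid$nrow, grid$ncol)
    any_captured <- FALSE
    for (i in seq_len(n_reg)) {
      arr <- t0 + min(tt[masks[[i]]])
      if (arr - last_act[i] > regions[[i]]$erp_ms) {
        act[masks[[i]]] <- t0 + tt[masks[[i]]]
        last_act[i] <- arr
        any_captured <- TRUE
      }
    }
    if (any_captured)
      beats[[length(beats) + 1L]] <- list(time = t0, source = origin, act = act)
  }

  structure(list(beats = beats, region_labels = labels,
                 region_index = region_index, cv_true = cv, grid = grid,
                 regions = regions, protocol = protocol,
                 stim_times_ms = protocol$stim_times_ms),
            class = "ground_truth")
}

#' Per-pixel activation times from a ground truth
#' @param truth a `ground_truth`.
#' @param pixel `c(row, col)`.
#' @return sorted numeric vector of activation times (ms).
#' @export
truth_activation_times <- function(truth, pixel) {
  out <- vapply(truth$beats, function(b) b$act[pixel[1], pixel[2]], 0)
  sort(out[!is.na(out)])
}

# beat shape on a time axis t (ms) for activation time ta and duration d:
# logistic upstroke crossing 0.5 exactly at ta (10-90% width upstroke_ms),
# a plateau, and a sigmoidal phase-3 downstroke of width w = repol_frac * d
# positioned so the 80%-repolarization level (0.2) is crossed exactly at
# ta + d. The steep downstroke ensures repolarization is essentially
# complete shortly after the crossing, as in real action potentials.
.beat_template <- function(t, ta, d, upstroke_ms, repol_frac = 0.03) {
  k <- upstroke_ms / (2 * log(9))
  u <- stats::plogis((t - ta) / k)
  w <- repol_frac * d
  tc <- ta + d - w * log(4)        # plogis(-(ta + d - tc)/w) = 0.2
  r <- stats::plogis(-(t - tc) / w)
  u * r
}

#' Render a fluorescence movie from a ground-truth schedule
#'
#' Each pixel's trace is `diastolic_level + polarity * amplitude * s(t)` plus
#' linear drift and Gaussian noise, where `s(t)` is the superposition
#' (pointwise maximum) of beat templates at the scheduled activation times.
#' Beat durations follow the region's restitution function of the preceding
#' diastolic interval. For the `"Ca"` modality the upstroke is rendered
#' `ca_upstroke_factor` times slower and delayed by the region's
#' `ca_delay_ms`.
#'
#' @param truth a `ground_truth` from [build_activation_schedule()].
#' @param artifacts an [artifact_params()].
#' @param fps frame rate in Hz (>= 100 so activation timing is meaningful).
#' @param modality `"Vm"` or `"Ca"`.
#' @param duration_ms movie length; default covers the last beat plus its
#'   full repolarization. Must not truncate any beat.
#' @param ca_upstroke_factor upstroke slowdown applied for `"Ca"` rendering.
#' @param repol_width_frac width of the sigmoidal phase-3 downstroke as a
#'   fraction of the beat duration (0.03 gives a 10-90% fall time of about
#'   13% of the duration).
#' @return a [frame_stack()].
#' @export
render_movie <- function(truth, artifacts = artifact_params(), fps = 1000,
                         modality = c("Vm", "Ca"), duration_ms = NULL,
                         ca_upstroke_factor = 3, repol_width_frac = 0.03) {
  modality <- match.arg(modality)
  if (fps < 100) stop("fps must be >= 100 Hz", call. = FALSE)
  grid <- truth$grid
  n_reg <- length(truth$regions)
  H <- grid$nrow; W <- grid$ncol; P <- H * W
  reg_idx <- as.vector(truth$region_index)

  par_of <- function(f) {
    v <- vapply(truth$regions, function(r) r$waveform[[f]], 0)
    out <- rep(NA_real_, P)
    ok <- !is.na(reg_idx)
    out[ok] <- v[reg_idx[ok]]
    out
  }
  apd_max <- par_of("apd_max_ms"); ramp <- par_of("restitution_amplitude_ms")
  rtau <- par_of("restitution_tau_ms"); upk <- par_of("upstroke_ms")
  cadel <- par_of("ca_delay_ms"); amp <- par_of("amplitude")
  dia <- par_of("diastolic_level")
  if (modality == "Ca") upk <- upk * ca_upstroke_factor

  # per-beat per-pixel durations from the restitution relation
  n_beats <- length(truth$beats)
  acts <- lapply(truth$beats, function(b) {
    a <- as.vector(b$act)
    if (modality == "Ca") a <- a + cadel
    a
  })
  durs <- vector("list", n_beats)
  last_end <- rep(-Inf, P)
  for (b in seq_len(n_beats)) {
    a <- acts[[b]]
    di <- pmax(a - last_end, 0)                 # Inf - -Inf handled below
    di[!is.finite(last_end)] <- Inf
    d <- apd_max - ramp * exp(-di / rtau)
    d[is.na(a)] <- NA_real_
    durs[[b]] <- d
    upd <- !is.na(a)
    last_end[upd] <- a[upd] + d[upd]
  }

  needed_ms <- if (n_beats)
    max(vapply(seq_len(n_beats), function(b) {
      ok <- !is.na(acts[[b]])
      if (!any(ok)) return(0)
      max(acts[[b]][ok] + durs[[b]][ok])
    }, 0)) else 0
  if (is.null(duration_ms))
    duration_ms <- max(needed_ms + 200, truth$protocol$total_duration_ms)
  if (duration_ms < needed_ms)
    stop(sprintf(
      "movie duration %.0f ms would truncate the last beat (needs %.0f ms)",
      duration_ms, needed_ms), call. = FALSE)

  nT <- ceiling(duration_ms * fps / 1000)
  t_ms <- (seq_len(nT) - 1) / fps * 1000
  sig <- matrix(0, nT, P)                       # template superposition
  in_tissue <- which(!is.na(reg_idx))
  for (b in seq_len(n_beats)) {
    a <- acts[[b]]; d <- durs[[b]]
    px <- in_tissue[!is.na(a[in_tissue])]
    if (!length(px)) next
    t_lo <- min(a[px]) - 4 * max(upk[px])
    t_hi <- max(a[px] + d[px] * (1 + 7 * repol_width_frac))
    fr <- which(t_ms >= t_lo & t_ms <= t_hi)
    for (f in fr) {
      v <- .beat_template(t_ms[f], a[px], d[px], upk[px], repol_width_frac)
      sig[f, px] <- pmax(sig[f, px], v)
    }
  }

  # physiology -> fluorescence with artifacts
  base <- matrix(dia, nT, P, byrow = TRUE)
  base[, is.na(reg_idx)] <- 0
  gain <- artifacts$polarity * ifelse(is.na(reg_idx), 0, amp)
  out <- base + sweep(sig, 2, gain, `*`)
  if (artifacts$drift_slope != 0) {
    drift_amp <- ifelse(is.na(reg_idx), 1, amp)
    out <- out + outer(t_ms / 1000 * artifacts$drift_slope, drift_amp)
  }
  if (artifacts$noise_sd > 0) {
    rng_state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv())
    }, add = TRUE)
    set.seed(artifacts$seed)
    noise_amp <- ifelse(is.na(reg_idx), 1, amp)
    out <- out + matrix(stats::rnorm(nT * P), nT, P) *
      matrix(noise_amp * artifacts$noise_sd, nT, P, byrow = TRUE)
  }

  frame_stack(array(out, c(nT, H, W)), fps_hz = fps,
              pixel_size_mm = grid$pixel_size_mm, modality = modality,
              stim_times_ms = truth$stim_times_ms[
                truth$stim_times_ms < duration_ms],
              provenance = "simulated")
}
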