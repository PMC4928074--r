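#' Segment a trace into beat windows
#'
#' Upstrokes are located as groups of samples whose first derivative exceeds
#' half the maximum derivative, separated by at least `min_separation_ms`;
#' each group's derivative peak marks the upstroke. A candidate is kept only
#' if the signal rises by at least `min_prominence` of the record amplitude
#' around it. Each window runs from the diastolic minimum preceding its
#' upstroke to just before the next window (or the record end), so it
#' contains the baseline, the upstroke and the repolarization of one beat.
#' A window is
#' tagged with a stimulus when its upstroke falls within
#' `capture_tolerance_ms` after that stimulus; otherwise the beat is
#' spontaneous.
#'
#' @param trace a conditioned, depolarization-positive [om_trace()].
#' @param stim_times_ms stimulus times (ms) used for tagging.
#' @param capture_tolerance_ms maximum capture latency for tagging.
#' @param min_separation_ms minimum distance between distinct upstrokes.
#' @param min_prominence minimum beat amplitude as a fraction of the record
#'   amplitude.
#' @return data.frame with columns `start_ms`, `end_ms`, `upstroke_ms`
#'   (time of peak derivative) and `stim_time_ms` (`NA` when spontaneous);
#'   zero rows (with a warning) when no beat is found.
#' @export
segment_beats <- function(trace, stim_times_ms = numeric(),
                          capture_tolerance_ms = 50,
                          min_separation_ms = 100,
                          min_prominence = 0.3) {
  s <- trace$samples
  fps <- trace$fps_hz
  dt_ms <- 1000 / fps
  empty <- data.frame(start_ms = numeric(), end_ms = numeric(),
                      upstroke_ms = numeric(), stim_time_ms = numeric())
  amp_rec <- max(s) - min(s)
  d <- diff(s)
  if (amp_rec <= 0 || max(d) <= 0) {
    warning("no beats detected", call. = FALSE)
    return(empty)
  }
  thr <- 0.5 * max(d)
  cand <- which(d >= thr)
  # group candidates separated by < min_separation
  gap <- floor(min_separation_ms / dt_ms)
  grp <- cumsum(c(1, diff(cand) > gap))
  ups <- vapply(split(cand, grp), function(ix) ix[which.max(d[ix])], 0)
  ups <- sort(unname(ups))
  # prominence: rise from local pre-upstroke minimum to post-upstroke maximum
  keep <- vapply(ups, function(u) {
    lo <- max(1, u - gap); hi <- min(length(s), u + gap)
    (max(s[u:hi]) - min(s[lo:u])) >= min_prominence * amp_rec
  }, TRUE)
  ups <- ups[keep]
  if (!length(ups)) {
    warning("no beats detected", call. = FALSE)
    return(empty)
  }
  up_ms <- (ups - 1) * dt_ms   # derivative between frames u and u+1; use frame u time
  n <- length(ups)
  # each window starts at the diastolic minimum preceding its upstroke and
  # ends just before the next window, so it holds one full beat
  start_idx <- vapply(seq_len(n), function(i) {
    lo <- max(1L, ups[i] - gap, if (i > 1) ups[i - 1] + 1L else 1L)
    seg <- lo:ups[i]
    seg[which.min(s[seg])]
  }, 0L)
  start_ms <- (start_idx - 1) * dt_ms
  end_ms <- c(start_ms[-1] - dt_ms, (length(s) - 1) * dt_ms)
  stim_tag <- rep(NA_real_, n)
  if (length(stim_times_ms)) {
    for (i in seq_len(n)) {
      lat <- up_ms[i] - stim_times_ms
      ok <- which(lat >= -dt_ms & lat <= capture_tolerance_ms)
      if (length(ok)) stim_tag[i] <- stim_times_ms[ok[length(ok)]]
    }
  }
  data.frame(start_ms = start_ms, end_ms = end_ms, upstroke_ms = up_ms,
             stim_time_ms = stim_tag)
}

.window_frames <- function(trace, window) {
  dt_ms <- 1000 / trace$fps_hz
  i0 <- max(1L, floor(window$start_ms / dt_ms) + 1L)
  i1 <- min(length(trace$samples), floor(window$end_ms / dt_ms) + 1L)
  if (i1 - i0 < 2L) stop("beat window too short", call. = FALSE)
  i0:i1
}

# first crossing of `level`, linearly interpolated; dir = +1 upward,
# -1 downward; returns time in ms or NA
.first_crossing_ms <- function(s, idx, level, dt_ms, dir = 1) {
  v <- s[idx]
  if (dir > 0) hit <- which(v[-length(v)] < level & v[-1] >= level)
  else hit <- which(v[-length(v)] > level & v[-1] <= level)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  frac <- (level - v[i]) / (v[i + 1] - v[i])
  ((idx[i] - 1) + frac) * dt_ms
}

#' Activation time at 50% of upstroke amplitude
#'
#' The activation time of a beat is the first upward crossing of the level
#' halfway between the window minimum and maximum, linearly interpolated
#' between samples for sub-frame resolution.
#'
#' @param trace an [om_trace()].
#' @param window one row of [segment_beats()] output (or any list with
#'   `start_ms`/`end_ms`).
#' @return activation time in ms from the record start, or `NA` with a
#'   warning when the window contains no upstroke.
#' @export
activation_time <- function(trace, window) {
  dt_ms <- 1000 / trace$fps_hz
  idx <- .window_frames(trace, window)
  v <- trace$samples[idx]
  amp <- max(v) - min(v)
  if (amp <= 0) {
    warning("zero amplitude in beat window", call. = FALSE)
    return(NA_real_)
  }
  at <- .first_crossing_ms(trace$samples, idx, min(v) + 0.5 * amp, dt_ms, 1)
  if (is.na(at)) warning("no 50% upstroke crossing in window", call. = FALSE)
  at
}

#' Duration at 80% repolarization (APD80 / CaTD80)
#'
#' Time from the 50%-upstroke activation time to the first downward crossing
#' of 20% amplitude after the beat's peak, linearly interpolated.
#'
#' @inheritParams activation_time
#' @return duration in ms, or `NA` with a warning when the beat does not
#'   repolarize to 80% inside the window (truncated beat).
#' @export
duration80 <- function(trace, window) {
  dt_ms <- 1000 / trace$fps_hz
  at <- activation_time(trace, window)
  if (is.na(at)) return(NA_real_)
  idx <- .window_frames(trace, window)
  v <- trace$samples[idx]
  amp <- max(v) - min(v)
  pk <- idx[which.max(v)]
  tail_idx <- idx[idx >= pk]
  rt <- .first_crossing_ms(trace$samples, tail_idx, min(v) + 0.2 * amp,
                           dt_ms, -1)
  if (is.na(rt)) {
    warning("no 80% repolarization crossing in window (truncated beat?)",
            call. = FALSE)
    return(NA_real_)
  }
  rt - at
}

#' Upstroke kinetics of one beat
#'
#' @inheritParams activation_time
#' @return list with `rise_time_10_90_ms` (interpolated 10-to-90% amplitude
#'   rise time) and `max_derivative_per_ms` (maximum first difference scaled
#'   to per-ms units of normalized amplitude).
#' @export
upstroke_metrics <- function(trace, window) {
  dt_ms <- 1000 / trace$fps_hz
  idx <- .window_frames(trace, window)
  v <- trace$samples[idx]
  amp <- max(v) - min(v)
  if (amp <= 0) {
    warning("zero amplitude in beat window", call. = FALSE)
    return(list(rise_time_10_90_ms = NA_real_,
                max_derivative_per_ms = NA_real_))
  }
  t10 <- .first_crossing_ms(trace$samples, idx, min(v) + 0.1 * amp, dt_ms, 1)
  t90 <- .first_crossing_ms(trace$samples, idx, min(v) + 0.9 * amp, dt_ms, 1)
  list(rise_time_10_90_ms = if (is.na(t10) || is.na(t90)) NA_real_
       else t90 - t10,
       max_derivative_per_ms = max(diff(v)) / dt_ms)
}

#' Per-pixel activation and duration maps for one beat
#'
#' Runs beat segmentation on every in-mask pixel trace and applies
#' [activation_time()] and [duration80()] to the `beat_index`-th detected
#' beat.
#'
#' @param stack a conditioned [frame_stack()].
#' @param mask a `tissue_mask`.
#' @param beat_index which beat to map (1-based).
#' @param stim_times_ms stimulus times; defaults to the stack metadata.
#' @param ... further arguments passed to [segment_beats()].
#' @return list with `activation` (an `activation_map`: `times_ms` H x W,
#'   `reference_ms` the tagged stimulus time or `NA`) and `duration`
#'   (a `duration_map`: `durations_ms` H x W, `modality`, `level = 0.8`),
#'   plus `n_undefined`, the number of in-mask pixels without a usable beat.
#' @export
build_maps <- function(stack, mask, beat_index = 1,
                       stim_times_ms = stack$stim_times_ms, ...) {
  m <- .check_mask(stack, mask)
  d <- dim(stack$frames)
  times <- matrix(NA_real_, d[2], d[3])
  durs <- matrix(NA_real_, d[2], d[3])
  rise <- matrix(NA_real_, d[2], d[3])
  refs <- numeric()
  pix <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(pix))) {
    tr <- pixel_trace(stack, pix[k, ])
    wins <- suppressWarnings(segment_beats(tr, stim_times_ms, ...))
    if (nrow(wins) < beat_index) next
    w <- wins[beat_index, ]
    at <- suppressWarnings(activation_time(tr, w))
    du <- suppressWarnings(duration80(tr, w))
    um <- suppressWarnings(upstroke_metrics(tr, w))
    times[pix[k, 1], pix[k, 2]] <- at
    durs[pix[k, 1], pix[k, 2]] <- du
    rise[pix[k, 1], pix[k, 2]] <- um$rise_time_10_90_ms
    if (!is.na(w$stim_time_ms)) refs <- c(refs, w$stim_time_ms)
  }
  n_undef <- sum(m) - sum(!is.na(times[m]))
  if (n_undef > 0.5 * sum(m))
    stop(sprintf("beat %d undefined in %d of %d in-mask pixels",
                 beat_index, n_undef, sum(m)), call. = FALSE)
  reference <- if (length(refs)) stats::median(refs) else NA_real_
  act <- structure(list(times_ms = times, reference_ms = reference,
                        pixel_size_mm = stack$pixel_size_mm),
                   class = "activation_map")
  dur <- structure(list(durations_ms = durs, modality = stack$modality,
                        level = 0.8), class = "duration_map")
  list(activation = act, duration = dur, rise_time_ms = rise,
       n_undefined = n_undef)
}
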