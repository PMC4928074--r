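#' Tissue mask from per-pixel signal-to-noise ratio
#'
#' A pixel is kept when its beat amplitude (2nd-98th intensity percentile
#' range) divided by its noise floor is at least `snr_threshold`. The noise
#' floor is the robust SD of the first differences divided by `sqrt(2)`,
#' which estimates sample noise while ignoring the slow physiological
#' excursions. Pixels with zero amplitude get SNR 0; noise-free pixels with
#' signal get SNR `Inf`, so clean simulations reduce to the tissue
#' footprint.
#'
#' @param stack a [frame_stack()], raw or conditioned.
#' @param snr_threshold non-negative SNR cutoff; 0 keeps every pixel.
#' @return a `tissue_mask`: list with logical `mask` (H x W) and the
#'   threshold used.
#' @export
make_mask <- function(stack, snr_threshold = 3) {
  stopifnot(snr_threshold >= 0)
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, nrow = d[1])
  # amplitude on the linearly detrended trace so drift never counts as signal
  X <- cbind(1, seq_len(d[1]))
  detr <- flat - X %*% qr.coef(qr(X), flat)
  amp <- apply(detr, 2, function(s) diff(stats::quantile(s, c(0.02, 0.98),
                                                         names = FALSE)))
  noise <- apply(flat, 2, function(s) stats::mad(diff(s))) / sqrt(2)
  snr <- ifelse(amp <= 0, 0, ifelse(noise <= 0, Inf, amp / noise))
  keep <- snr >= snr_threshold
  if (!any(keep))
    stop("no pixel reaches the SNR threshold; lower `snr_threshold`",
         call. = FALSE)
  structure(list(mask = matrix(keep, d[2], d[3]),
                 snr_threshold = snr_threshold),
            class = "tissue_mask")
}

#' All-inclusive mask for a stack
#' @param stack a [frame_stack()].
#' @return a `tissue_mask` covering every pixel.
#' @export
full_mask <- function(stack) {
  d <- dim(stack$frames)
  structure(list(mask = matrix(TRUE, d[2], d[3]), snr_threshold = 0),
            class = "tissue_mask")
}

.check_mask <- function(stack, mask) {
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  if (!identical(dim(m), dim(stack$frames)[2:3]))
    stop("mask dimensions must match the stack", call. = FALSE)
  m
}

#' 3 x 3 spatial averaging restricted to the tissue mask
#'
#' Every in-mask pixel is replaced by the mean of the in-mask pixels in its
#' 3 x 3 neighbourhood; neighbours outside the image or outside the mask
#' simply drop out of the mean (no zero padding, so edges are not dimmed).
#' Out-of-mask pixels pass through unchanged.
#'
#' @param stack a [frame_stack()].
#' @param mask a `tissue_mask` (default: all pixels).
#' @return a [frame_stack()] of the same geometry.
#' @export
spatial_bin <- function(stack, mask = full_mask(stack)) {
  m <- .check_mask(stack, mask)
  d <- dim(stack$frames)
  H <- d[2]; W <- d[3]
  shift <- function(x, dr, dc) {
    # shift a H x W matrix by (dr, dc), zero-filling
    out <- matrix(0, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
    out
  }
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  mnum <- m * 1
  counts <- Reduce(`+`, Map(function(dr, dc) shift(mnum, dr, dc),
                            offsets$dr, offsets$dc))
  out <- stack$frames
  for (i in seq_len(d[1])) {
    fr <- stack$frames[i, , ]
    masked <- fr * mnum
    sums <- Reduce(`+`, Map(function(dr, dc) shift(masked, dr, dc),
                            offsets$dr, offsets$dc))
    binned <- fr
    binned[m] <- sums[m] / counts[m]
    out[i, , ] <- binned
  }
  stack$frames <- out
  stack
}

#' Zero-phase low-pass filter
#'
#' A 4th-order Butterworth filter applied forward and backward
#' (`signal::filtfilt`), so activation times are not delayed by filter
#' phase. The cutoff defaults to 100 Hz, the lower end of the 100-150 Hz
#' range appropriate for optical action potentials.
#'
#' @param x an [om_trace()] or [frame_stack()].
#' @param cutoff_hz cutoff frequency; must be below the Nyquist rate.
#' @param order Butterworth order.
#' @return the same type as `x`, filtered per pixel.
#' @export
lowpass <- function(x, cutoff_hz = 100, order = 4) UseMethod("lowpass")

.butter_lp <- function(fps_hz, cutoff_hz, order) {
  if (cutoff_hz >= fps_hz / 2)
    stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)",
                 cutoff_hz, fps_hz / 2), call. = FALSE)
  if (cutoff_hz <= 0) stop("cutoff must be positive", call. = FALSE)
  signal::butter(order, cutoff_hz / (fps_hz / 2), type = "low")
}

# forward-backward filtering with odd (point-reflected) end padding and a
# linear baseline anchored at the padded endpoints removed before filtering,
# so records that start or end away from zero have no edge transients and a
# constant (pure DC) trace passes through unchanged
.filtfilt_pad <- function(bf, s) {
  n <- length(s)
  L <- min(n - 1L, 3L * (length(bf$b) + length(bf$a)))
  head_pad <- 2 * s[1] - s[(L + 1):2]
  tail_pad <- 2 * s[n] - s[(n - 1):(n - L)]
  padded <- c(head_pad, s, tail_pad)
  base <- seq(padded[1], padded[length(padded)], length.out = length(padded))
  out <- signal::filtfilt(bf, padded - base) + base
  out[(L + 1):(L + n)]
}

#' @export
lowpass.om_trace <- function(x, cutoff_hz = 100, order = 4) {
  bf <- .butter_lp(x$fps_hz, cutoff_hz, order)
  x$samples <- .filtfilt_pad(bf, x$samples)
  x
}

#' @export
lowpass.frame_stack <- function(x, cutoff_hz = 100, order = 4) {
  bf <- .butter_lp(x$fps_hz, cutoff_hz, order)
  d <- dim(x$frames)
  flat <- matrix(x$frames, nrow = d[1])
  for (j in seq_len(ncol(flat)))
    flat[, j] <- .filtfilt_pad(bf, flat[, j])
  x$frames <- array(flat, d)
  x
}

#' Remove first-order (linear) fluorescence drift
#'
#' Fits a straight line to the trace by least squares and subtracts it, so
#' the output has zero linear trend. With `diastolic_only = TRUE` the line
#' is fitted only on the lowest 20% of sample values (an approximation of
#' the diastolic baseline), then evaluated and subtracted everywhere.
#'
#' @param x an [om_trace()] or [frame_stack()].
#' @param diastolic_only fit on diastolic samples only.
#' @return the same type as `x`, detrended.
#' @export
remove_drift <- function(x, diastolic_only = FALSE) UseMethod("remove_drift")

#' @export
remove_drift.om_trace <- function(x, diastolic_only = FALSE) {
  s <- x$samples
  t <- seq_along(s)
  use <- if (diastolic_only)
    s <= stats::quantile(s, 0.2, names = FALSE) else rep(TRUE, length(s))
  if (sum(use) < 2L) use <- rep(TRUE, length(s))
  fit <- stats::lm.fit(cbind(1, t[use]), s[use])
  x$samples <- s - (fit$coefficients[1] + fit$coefficients[2] * t)
  x
}

#' @export
remove_drift.frame_stack <- function(x, diastolic_only = FALSE) {
  d <- dim(x$frames)
  flat <- matrix(x$frames, nrow = d[1])
  t <- seq_len(d[1])
  if (diastolic_only) {
    for (j in seq_len(ncol(flat))) {
      s <- flat[, j]
      use <- s <= stats::quantile(s, 0.2, names = FALSE)
      if (sum(use) < 2L) use <- rep(TRUE, length(s))
      fit <- stats::lm.fit(cbind(1, t[use]), s[use])
      flat[, j] <- s - (fit$coefficients[1] + fit$coefficients[2] * t)
    }
  } else {
    X <- cbind(1, t)
    coefs <- qr.coef(qr(X), flat)          # 2 x P in one pass
    flat <- flat - X %*% coefs
  }
  x$frames <- array(flat, d)
  x
}

#' Normalize a trace to the 0-1 range
#'
#' Affine rescale so the minimum maps to 0 and the maximum to 1 within the
#' chosen window (default: the whole record).
#'
#' @param x an [om_trace()] or [frame_stack()].
#' @param window integer frame range `c(first, last)` used to take the
#'   extrema, or `NULL` for the full record.
#' @param mask for stacks: restrict normalization to in-mask pixels
#'   (out-of-mask pixels pass through).
#' @return the same type as `x`, rescaled.
#' @export
normalize01 <- function(x, window = NULL, mask = NULL) UseMethod("normalize01")

.norm_window <- function(n, window) {
  if (is.null(window)) return(seq_len(n))
  stopifnot(length(window) == 2L, window[1] >= 1, window[2] <= n,
            window[1] <= window[2])
  window[1]:window[2]
}

#' @export
normalize01.om_trace <- function(x, window = NULL, mask = NULL) {
  idx <- .norm_window(length(x$samples), window)
  lo <- min(x$samples[idx]); hi <- max(x$samples[idx])
  if (hi <= lo)
    stop("trace has zero dynamic range in the normalization window",
         call. = FALSE)
  x$samples <- (x$samples - lo) / (hi - lo)
  x
}

#' @export
normalize01.frame_stack <- function(x, window = NULL, mask = NULL) {
  d <- dim(x$frames)
  m <- if (is.null(mask)) matrix(TRUE, d[2], d[3]) else .check_mask(x, mask)
  flat <- matrix(x$frames, nrow = d[1])
  idx <- .norm_window(d[1], window)
  sel <- which(as.vector(m))
  lo <- apply(flat[idx, sel, drop = FALSE], 2, min)
  hi <- apply(flat[idx, sel, drop = FALSE], 2, max)
  if (any(hi <= lo))
    stop("some in-mask pixels have zero dynamic range; mask them out first",
         call. = FALSE)
  flat[, sel] <- sweep(sweep(flat[, sel, drop = FALSE], 2, lo), 2,
                       hi - lo, `/`)
  x$frames <- array(flat, d)
  x
}

.skewness <- function(s) {
  s <- s - mean(s)
  v <- mean(s^2)
  if (v <= 0) return(0)
  mean(s^3) / v^1.5
}

#' Orient signals depolarization-positive
#'
#' Voltage dyes emit less light on depolarization, so raw voltage traces
#' have downward transients. When stimulus times are supplied the polarity
#' is read from the mean post-stimulus deflection (a captured stimulus
#' always drives the signal away from diastole), which stays reliable even
#' when fast pacing makes the depolarized state occupy more than half the
#' cycle. Without stimuli (or when too few stimuli capture) the decision
#' falls back to the trace skewness: transient-dominated traces are
#' strongly skewed in the transient direction. When the skewness magnitude
#' is below `ambiguity` the polarity is ambiguous; a warning is raised and
#' `override` (+1/-1, if supplied) decides. Flipping negates the trace
#' about its median baseline and is idempotent.
#'
#' @param x an [om_trace()] or [frame_stack()].
#' @param override explicit polarity (+1 leave, -1 flip) used when detection
#'   is ambiguous; `NULL` leaves ambiguous traces untouched.
#' @param ambiguity skewness magnitude below which polarity is ambiguous.
#' @param mask for stacks: pixels whose mean trace decides the flip.
#' @param stim_times_ms optional stimulus times (ms) for the post-stimulus
#'   deflection criterion; for stacks this defaults to the stack metadata.
#' @return the same type as `x`, depolarization-positive.
#' @export
orient_polarity <- function(x, override = NULL, ambiguity = 0.1,
                            mask = NULL,
                            stim_times_ms = NULL) UseMethod("orient_polarity")

.flip_about_baseline <- function(s) {
  b <- stats::median(s)
  2 * b - s
}

# +1 depolarization-positive, -1 inverted, 0 ambiguous
.polarity_sign <- function(s, fps_hz, stim_times_ms, ambiguity) {
  if (!is.null(stim_times_ms) && length(stim_times_ms)) {
    dt <- 1000 / fps_hz
    amp <- max(s) - min(s)
    n <- length(s)
    defl <- vapply(stim_times_ms, function(st) {
      i0 <- floor(st / dt) + 1L
      i1 <- min(n, i0 + ceiling(50 / dt))
      if (i0 < 1L || i0 + 1L > n) return(NA_real_)
      mean(s[(i0 + 1L):i1]) - s[i0]
    }, 0)
    defl <- defl[!is.na(defl)]
    if (length(defl) && amp > 0) {
      rel <- mean(defl) / amp
      if (rel > 0.05) return(1L)
      if (rel < -0.05) return(-1L)
    }
  }
  sk <- .skewness(s)
  if (abs(sk) < ambiguity) 0L else if (sk > 0) 1L else -1L
}

#' @export
orient_polarity.om_trace <- function(x, override = NULL, ambiguity = 0.1,
                                     mask = NULL, stim_times_ms = NULL) {
  sgn <- .polarity_sign(x$samples, x$fps_hz, stim_times_ms, ambiguity)
  if (sgn == 0L) {
    warning("polarity ambiguous (|skewness| < ", ambiguity,
            "); using override" , call. = FALSE)
    if (!is.null(override) && override == -1)
      x$samples <- .flip_about_baseline(x$samples)
    return(x)
  }
  if (sgn < 0L) x$samples <- .flip_about_baseline(x$samples)
  x
}

#' @export
orient_polarity.frame_stack <- function(x, override = NULL, ambiguity = 0.1,
                                        mask = NULL,
                                        stim_times_ms = x$stim_times_ms) {
  d <- dim(x$frames)
  m <- if (is.null(mask)) matrix(TRUE, d[2], d[3]) else .check_mask(x, mask)
  mean_trace <- regional_trace(x, m)
  sgn <- .polarity_sign(mean_trace$samples, x$fps_hz, stim_times_ms,
                        ambiguity)
  flip <- if (sgn == 0L) {
    warning("polarity ambiguous (|skewness| < ", ambiguity,
            "); using override", call. = FALSE)
    !is.null(override) && override == -1
  } else sgn < 0L
  if (flip) {
    flat <- matrix(x$frames, nrow = d[1])
    sel <- which(as.vector(m))
    base <- apply(flat[, sel, drop = FALSE], 2, stats::median)
    flat[, sel] <- sweep(-flat[, sel, drop = FALSE], 2, -2 * base)
    x$frames <- array(flat, d)
  }
  x
}

#' Full signal-conditioning chain
#'
#' Applies, in order: 3 x 3 masked spatial averaging, zero-phase low-pass
#' filtering, first-order drift removal, 0-1 normalization and polarity
#' orientation — the standard preprocessing for optical action potentials
#' and calcium transients.
#'
#' @param stack a raw [frame_stack()].
#' @param mask a `tissue_mask`; defaults to [make_mask()] at `snr`.
#' @param cutoff_hz low-pass cutoff (Hz); `NA` skips filtering (e.g. for
#'   noise-free simulations).
#' @param snr SNR threshold used when `mask` is not supplied.
#' @param diastolic_only_drift fit the drift line on diastolic samples only
#'   (the default: a full-trace fit is tilted by the action potentials
#'   themselves when the record does not hold a whole number of beats).
#' @param polarity_override passed to [orient_polarity()].
#' @return list with the conditioned `stack` and the `mask` used.
#' @export
condition_stack <- function(stack, mask = NULL, cutoff_hz = 100, snr = 3,
                            diastolic_only_drift = TRUE,
                            polarity_override = NULL) {
  if (is.null(mask)) mask <- make_mask(stack, snr)
  out <- spatial_bin(stack, mask)
  if (!is.na(cutoff_hz)) out <- lowpass(out, cutoff_hz)
  out <- remove_drift(out, diastolic_only = diastolic_only_drift)
  out <- normalize01(out, mask = mask)
  out <- orient_polarity(out, override = polarity_override, mask = mask)
  list(stack = out, mask = mask)
}
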