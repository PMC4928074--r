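#' Steady-state capture ratio under S1-S1 pacing
#'
#' A response is an activation occurring within `tolerance_ms` after a
#' stimulus. After discarding the first `discard` stimuli (pacing
#' transient), the ratio is the number of pacing intervals between
#' consecutive responses: 1 for 1:1 capture, 2 for 2:1 block, and so on.
#' When the response intervals do not lock onto an integer multiple of the
#' pacing cycle length the rhythm is irregular and the ratio is `NA`.
#'
#' @param activation_times_ms detected activation times of the region (ms).
#' @param stim_times_ms stimulus times (ms); at least `discard + 2`.
#' @param tolerance_ms capture-latency tolerance (default 50 ms).
#' @param discard stimuli dropped from the start of the train (default 2).
#' @return a `capture_result`: `pcl_ms`, `stimuli`, `responses`, `ratio`
#'   (integer stimuli per captured beat, or `NA` for none/irregular).
#' @export
capture_ratio <- function(activation_times_ms, stim_times_ms,
                          tolerance_ms = 50, discard = 2) {
  if (length(stim_times_ms) == 0L)
    stop("capture analysis needs stimuli", call. = FALSE)
  stim_times_ms <- sort(stim_times_ms)
  if (length(stim_times_ms) < discard + 2L)
    stop(sprintf("need at least %d stimuli (2 post-transient)", discard + 2L),
         call. = FALSE)
  pcl <- stats::median(diff(stim_times_ms))
  stim <- if (discard > 0) stim_times_ms[-seq_len(discard)]
          else stim_times_ms
  resp <- vapply(stim, function(s0)
    any(activation_times_ms >= s0 &
          activation_times_ms <= s0 + tolerance_ms), TRUE)
  resp_t <- stim[resp]
  ratio <- NA_integer_
  if (length(resp_t) >= 2L) {
    k <- diff(resp_t) / pcl
    k0 <- round(stats::median(k))
    if (k0 >= 1 && all(abs(k - k0) < 0.2)) ratio <- as.integer(k0)
  } else if (length(resp_t) == length(stim) && length(stim) >= 1L) {
    ratio <- 1L
  }
  structure(list(pcl_ms = pcl, stimuli = length(stim),
                 responses = length(resp_t), ratio = ratio),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  lab <- if (is.na(x$ratio)) "no regular capture" else
    sprintf("%d:1 capture", x$ratio)
  cat(sprintf("PCL %g ms: %d/%d stimuli captured, %s\n",
              x$pcl_ms, x$responses, x$stimuli, lab))
  invisible(x)
}

#' Effective refractory period from a set of capture results
#'
#' The ERP is bracketed between the longest pacing cycle length at which
#' 1:1 capture was lost and the shortest at which it was maintained; the
#' estimate is the bracket midpoint. The protocol step size bounds the
#' recovery error at half a step.
#'
#' @param results list of `capture_result` objects spanning at least one
#'   captured and one lost cycle length.
#' @param step_ms the protocol's cycle-length decrement (ms).
#' @return an `erp_estimate`: `erp_ms`, `last_captured_pcl_ms`,
#'   `first_lost_pcl_ms`, `step_ms`.
#' @export
estimate_erp <- function(results, step_ms) {
  pcl <- vapply(results, function(r) r$pcl_ms, 0)
  ratio <- vapply(results, function(r) as.numeric(r$ratio), 0)
  captured <- !is.na(ratio) & ratio == 1
  lost <- is.na(ratio) | ratio > 1
  if (!any(captured))
    stop("1:1 capture never achieved: ERP outside tested range",
         call. = FALSE)
  if (!any(lost))
    stop("1:1 capture never lost: ERP outside tested range", call. = FALSE)
  last_captured <- min(pcl[captured])
  first_lost <- max(pcl[lost])
  if (first_lost >= last_captured)
    stop("capture results are not monotone in cycle length", call. = FALSE)
  structure(list(erp_ms = (first_lost + last_captured) / 2,
                 last_captured_pcl_ms = last_captured,
                 first_lost_pcl_ms = first_lost, step_ms = step_ms),
            class = "erp_estimate")
}

#' @export
print.erp_estimate <- function(x, ...) {
  cat(sprintf("ERP %.1f ms (bracket [%g, %g] ms, step %g ms)\n",
              x$erp_ms, x$first_lost_pcl_ms, x$last_captured_pcl_ms,
              x$step_ms))
  invisible(x)
}

#' Restitution curve from one conditioned movie per pacing cycle length
#'
#' For each cycle length, beats are segmented per in-mask pixel, the first
#' `n_discard` are dropped as the pacing transient, and the remaining
#' durations at 80% repolarization are pooled into mean, SD and n. Cycle
#' lengths whose mask-average trace has lost regular 1:1 capture are
#' excluded with a warning.
#'
#' @param per_pcl_stacks list of `list(pcl_ms =, stack =)` entries with
#'   conditioned stacks.
#' @param mask a `tissue_mask`.
#' @param modality curve label, `"Vm"` or `"Ca"`.
#' @param n_discard beats dropped per cycle length (default 5).
#' @param condition_label free-text label for the curve.
#' @param ... passed to [segment_beats()].
#' @return a `restitution_curve`: data.frame `points` with `pcl_ms`,
#'   `mean_duration_ms`, `sd_ms`, `n_beats`, ordered by descending cycle
#'   length.
#' @export
build_restitution <- function(per_pcl_stacks, mask, modality = "Vm",
                              n_discard = 5, condition_label = "", ...) {
  rows <- list()
  for (entry in per_pcl_stacks) {
    pcl <- entry$pcl_ms
    stack <- entry$stack
    m <- .check_mask(stack, mask)
    mean_tr <- regional_trace(stack, m)
    cr <- tryCatch(
      capture_ratio(
        suppressWarnings(segment_beats(mean_tr, stack$stim_times_ms,
                                       ...))$upstroke_ms,
        stack$stim_times_ms, discard = min(2, n_discard)),
      error = function(e) NULL)
    if (is.null(cr) || is.na(cr$ratio) || cr$ratio != 1L) {
      warning(sprintf("PCL %g ms excluded: 1:1 capture lost", pcl),
              call. = FALSE)
      next
    }
    durs <- c()
    pix <- which(m, arr.ind = TRUE)
    for (k in seq_len(nrow(pix))) {
      tr <- pixel_trace(stack, pix[k, ])
      wins <- suppressWarnings(segment_beats(tr, stack$stim_times_ms, ...))
      if (nrow(wins) <= n_discard) next
      use <- wins[-seq_len(n_discard), , drop = FALSE]
      # drop the final window: its repolarization may be cut by record end
      if (nrow(use) > 1) use <- use[-nrow(use), , drop = FALSE]
      for (b in seq_len(nrow(use)))
        durs <- c(durs, suppressWarnings(duration80(tr, use[b, ])))
    }
    durs <- durs[!is.na(durs)]
    if (!length(durs)) {
      warning(sprintf("PCL %g ms excluded: no measurable beats", pcl),
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pcl_ms = pcl, mean_duration_ms = mean(durs),
      sd_ms = if (length(durs) > 1) stats::sd(durs) else 0,
      n_beats = length(durs))
  }
  pts <- do.call(rbind, rows)
  if (!is.null(pts)) pts <- pts[order(-pts$pcl_ms), , drop = FALSE]
  structure(list(points = pts, modality = modality,
                 condition_label = condition_label),
            class = "restitution_curve")
}

#' @export
print.restitution_curve <- function(x, ...) {
  cat(sprintf("<restitution_curve> %s %s\n", x$modality, x$condition_label))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Detect spontaneous (pacemaker) activity
#'
#' An activation is spontaneous when it does not fall within `tolerance_ms`
#' after any stimulus. When at least three spontaneous beats are present
#' their rate is `1000 / median inter-beat interval` in Hz.
#'
#' @param activation_times_ms detected activation times (ms).
#' @param stim_times_ms stimulus times (ms); may be empty.
#' @param tolerance_ms capture-latency tolerance.
#' @param record_ms record length; rates are only reported for records of
#'   at least 5 s (`NA` otherwise, with a warning).
#' @return list with `spontaneous` (logical) and `rate_hz` (`NA` when fewer
#'   than three spontaneous beats).
#' @export
detect_automaticity <- function(activation_times_ms, stim_times_ms = numeric(),
                                tolerance_ms = 50, record_ms = Inf) {
  if (length(activation_times_ms) == 0L)
    return(list(spontaneous = FALSE, rate_hz = NA_real_))
  paced <- vapply(activation_times_ms, function(a)
    any(a - stim_times_ms >= 0 & a - stim_times_ms <= tolerance_ms), TRUE)
  spont <- activation_times_ms[!paced]
  rate <- NA_real_
  if (length(spont) >= 3L) {
    if (record_ms < 5000)
      warning("record shorter than 5 s; rate estimate unreliable",
              call. = FALSE)
    rate <- 1000 / stats::median(diff(sort(spont)))
  }
  list(spontaneous = length(spont) > 0L, rate_hz = rate)
}

#' Classify pixels into nodal-like and working myocardium
#'
#' Standardizes per-pixel duration and upstroke rise time, then partitions
#' them with 2-means clustering seeded deterministically at the 25th and
#' 75th percentiles of both features. The cluster with the larger summed
#' centroid (longer duration and slower upstroke) is labelled
#' `"nodal-like"`, the other `"working"`. When the two centroids are closer
#' than `min_separation` standardized units the feature distribution is
#' considered unimodal: everything is labelled `"working"` with a warning.
#'
#' @param duration_map a `duration_map` from [build_maps()], or a numeric
#'   matrix (ms).
#' @param risetime_map numeric H x W matrix of 10-90% rise times (ms).
#' @param mask a `tissue_mask` or logical matrix.
#' @param min_pixels minimum number of jointly defined pixels.
#' @param min_separation centroid distance (standardized units) below which
#'   a single label is returned. 2-means forced onto unimodal Gaussian
#'   noise produces separations around 1.6, while genuinely bimodal
#'   features give well over 2, hence the default of 2.
#' @return character H x W matrix with `"nodal-like"` / `"working"` on
#'   defined in-mask pixels and `NA` elsewhere.
#' @export
classify_regions <- function(duration_map, risetime_map, mask,
                             min_pixels = 100, min_separation = 2) {
  dm <- if (inherits(duration_map, "duration_map"))
    duration_map$durations_ms else duration_map
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  ok <- m & !is.na(dm) & !is.na(risetime_map)
  if (sum(ok) < min_pixels)
    stop(sprintf("only %d pixels with both features (need >= %d)",
                 sum(ok), min_pixels), call. = FALSE)
  z <- scale(cbind(dur = dm[ok], rise = risetime_map[ok]))
  centers <- rbind(apply(z, 2, stats::quantile, 0.25, names = FALSE),
                   apply(z, 2, stats::quantile, 0.75, names = FALSE))
  labels <- matrix(NA_character_, nrow(dm), ncol(dm))
  if (sqrt(sum((centers[1, ] - centers[2, ])^2)) < 1e-8) {
    warning("features are unimodal; returning a single label", call. = FALSE)
    labels[ok] <- "working"
    return(labels)
  }
  km <- stats::kmeans(z, centers = centers)
  sep <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
  if (sep < min_separation) {
    warning("features are unimodal; returning a single label", call. = FALSE)
    labels[ok] <- "working"
    return(labels)
  }
  nodal <- which.max(rowSums(km$centers))
  labels[ok] <- ifelse(km$cluster == nodal, "nodal-like", "working")
  labels
}
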