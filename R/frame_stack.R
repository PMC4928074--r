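#' Construct a fluorescence movie container
#'
#' A `frame_stack` holds a T x H x W array of fluorescence values together
#' with the acquisition metadata every downstream operation needs: frame
#' rate, pixel size, imaging modality (transmembrane voltage or intracellular
#' calcium) and the stimulus schedule. Frame `i` (1-based in R) is stamped at
#' `(i - 1) / fps_hz` seconds, i.e. the first frame is at time zero.
#'
#' @param frames numeric array with dimensions `c(T, H, W)`, `T >= 2`.
#' @param fps_hz sampling rate in frames per second (> 0).
#' @param pixel_size_mm side length of one pixel in millimetres (> 0).
#' @param modality `"Vm"` for voltage dye or `"Ca"` for calcium dye.
#' @param stim_times_ms ascending stimulus times in milliseconds, all within
#'   the record.
#' @param provenance free-text origin tag (file path, simulator config, ...).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps_hz, pixel_size_mm,
                        modality = c("Vm", "Ca"),
                        stim_times_ms = numeric(),
                        provenance = "") {
  modality <- match.arg(modality)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array", call. = FALSE)
  if (dim(frames)[1] < 2L)
    stop("a movie needs at least 2 frames", call. = FALSE)
  if (!is.numeric(fps_hz) || length(fps_hz) != 1L || fps_hz <= 0)
    stop("`fps_hz` must be a single positive number", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a single positive number", call. = FALSE)
  stim_times_ms <- as.numeric(stim_times_ms)
  if (is.unsorted(stim_times_ms))
    stop("`stim_times_ms` must be sorted ascending", call. = FALSE)
  dur_ms <- dim(frames)[1] / fps_hz * 1000
  if (length(stim_times_ms) && any(stim_times_ms < 0 | stim_times_ms >= dur_ms))
    stop("all `stim_times_ms` must lie within the record", call. = FALSE)
  structure(
    list(frames = frames, fps_hz = fps_hz, pixel_size_mm = pixel_size_mm,
         modality = modality, stim_times_ms = stim_times_ms,
         provenance = provenance),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, %g fps, %g mm/px, modality %s\n",
    d[1], d[2], d[3], x$fps_hz, x$pixel_size_mm, x$modality))
  cat(sprintf("  duration %.1f ms, %d stimuli\n",
              d[1] / x$fps_hz * 1000, length(x$stim_times_ms)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `frame_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' Frame timestamps in milliseconds
#' @param stack a `frame_stack`.
#' @return numeric vector of length T, starting at 0.
#' @export
frame_times_ms <- function(stack) {
  (seq_len(n_frames(stack)) - 1) / stack$fps_hz * 1000
}

#' Construct a single-pixel (or regional mean) time trace
#'
#' @param samples numeric vector of fluorescence values.
#' @param fps_hz sampling rate in Hz.
#' @param pixel `c(row, col)` of the source pixel, or the string
#'   `"regional mean"`.
#' @return an object of class `om_trace`.
#' @export
om_trace <- function(samples, fps_hz, pixel = "regional mean") {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("`samples` must be a numeric vector of length >= 2", call. = FALSE)
  if (fps_hz <= 0) stop("`fps_hz` must be positive", call. = FALSE)
  structure(list(samples = as.numeric(samples), fps_hz = fps_hz,
                 pixel = pixel),
            class = "om_trace")
}

#' @export
print.om_trace <- function(x, ...) {
  cat(sprintf("<om_trace> %d samples at %g fps (%s)\n",
              length(x$samples), x$fps_hz,
              paste(x$pixel, collapse = ",")))
  invisible(x)
}

#' Extract the trace of one pixel
#' @param stack a `frame_stack`.
#' @param pixel integer `c(row, col)`.
#' @return an `om_trace`.
#' @export
pixel_trace <- function(stack, pixel) {
  d <- dim(stack$frames)
  if (pixel[1] < 1 || pixel[1] > d[2] || pixel[2] < 1 || pixel[2] > d[3])
    stop("pixel outside the image grid", call. = FALSE)
  om_trace(stack$frames[, pixel[1], pixel[2]], stack$fps_hz, pixel)
}

#' Mean trace over a pixel set
#' @param stack a `frame_stack`.
#' @param mask logical H x W matrix selecting the pixels to average.
#' @return an `om_trace` labelled "regional mean".
#' @export
regional_trace <- function(stack, mask) {
  d <- dim(stack$frames)
  if (!identical(dim(mask), d[2:3]))
    stop("mask dimensions must match the stack", call. = FALSE)
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  flat <- matrix(stack$frames, nrow = d[1])   # T x (H*W), column-major over (row, col)
  om_trace(rowMeans(flat[, as.vector(mask), drop = FALSE]), stack$fps_hz)
}
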