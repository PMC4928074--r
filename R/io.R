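#' Write a simulated movie and its ground truth to disk
#'
#' The movie goes to a multi-frame 16-bit grayscale TIFF, acquisition
#' metadata to a JSON sidecar, and the activation schedule to a ground-truth
#' JSON. Intensities are stored as
#' `round((value - intensity_offset) / intensity_span * 65535)` counts; the
#' affine mapping is recorded in the sidecar so [read_stack()] can invert
#' it. Values falling outside `[intensity_offset, intensity_offset +
#' intensity_span]` would overflow the 16-bit range and are rejected.
#'
#' @param stack a [frame_stack()].
#' @param truth the matching `ground_truth`, or `NULL` to write the movie
#'   only.
#' @param dir output directory (created if missing).
#' @param intensity_offset,intensity_span affine intensity mapping into the
#'   16-bit range; defaults span the data with a small margin.
#' @return invisibly, the paths written
#'   (`movie.tif`, `sidecar.json`, `truth.json`).
#' @export
write_fixture <- function(stack, truth = NULL, dir,
                          intensity_offset = NULL, intensity_span = NULL) {
  if (!is.null(truth)) {
    d <- dim(stack$frames)
    if (truth$grid$nrow != d[2] || truth$grid$ncol != d[3])
      stop("stack and ground truth use different grids", call. = FALSE)
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  rng <- range(stack$frames)
  if (is.null(intensity_offset)) intensity_offset <- floor(rng[1] * 100) / 100
  if (is.null(intensity_span))
    intensity_span <- max(ceiling((rng[2] - intensity_offset) * 100) / 100,
                          1e-6)
  scaled <- (stack$frames - intensity_offset) / intensity_span
  if (any(scaled < 0 | scaled > 1))
    stop(sprintf(
      "intensities outside [%.4g, %.4g] overflow the 16-bit range",
      intensity_offset, intensity_offset + intensity_span), call. = FALSE)

  tif <- file.path(dir, "movie.tif")
  frames <- lapply(seq_len(dim(scaled)[1]), function(i) scaled[i, , ])
  tiff::writeTIFF(frames, tif, bits.per.sample = 16, compression = "none")

  sidecar <- list(
    fps_hz = stack$fps_hz, pixel_size_mm = stack$pixel_size_mm,
    modality = stack$modality, stim_times_ms = I(stack$stim_times_ms),
    n_frames = dim(stack$frames)[1],
    height_px = dim(stack$frames)[2], width_px = dim(stack$frames)[3],
    intensity_offset = intensity_offset, intensity_span = intensity_span,
    provenance = stack$provenance)
  side <- file.path(dir, "sidecar.json")
  jsonlite::write_json(sidecar, side, auto_unbox = TRUE, digits = NA)

  truth_path <- NULL
  if (!is.null(truth)) {
    truth_path <- file.path(dir, "truth.json")
    tr <- list(
      grid = unclass(truth$grid),
      cv_true = if (is.list(truth$cv_true)) truth$cv_true else
        list(isotropic = truth$cv_true),
      stim_times_ms = I(truth$stim_times_ms),
      region_labels = truth$region_labels,
      beats = lapply(truth$beats, function(b)
        list(time = b$time, source = b$source, act = b$act)))
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor", na = "null")
  }
  invisible(list(movie = tif, sidecar = side, truth = truth_path))
}

#' Read a movie TIFF with its JSON sidecar
#'
#' @param tiff_path multi-frame grayscale TIFF.
#' @param sidecar_path JSON sidecar; must provide `fps_hz` and
#'   `pixel_size_mm` (and usually `modality`, `stim_times_ms`, and the
#'   intensity mapping written by [write_fixture()]).
#' @return a [frame_stack()] with intensities mapped back to the original
#'   scale when the sidecar records an affine intensity mapping.
#' @export
read_stack <- function(tiff_path, sidecar_path) {
  if (!file.exists(sidecar_path))
    stop("sidecar file not found: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("fps_hz", "pixel_size_mm"))
    if (is.null(meta[[f]]))
      stop("sidecar is missing required field `", f, "`", call. = FALSE)
  frames <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) < 2L)
    stop("a movie needs at least 2 frames", call. = FALSE)
  d <- dim(frames[[1]])
  if (!is.null(meta$n_frames) && meta$n_frames != length(frames))
    stop(sprintf("sidecar declares %d frames but TIFF holds %d",
                 meta$n_frames, length(frames)), call. = FALSE)
  if ((!is.null(meta$height_px) && meta$height_px != d[1]) ||
      (!is.null(meta$width_px) && meta$width_px != d[2]))
    stop("sidecar image dimensions do not match the TIFF", call. = FALSE)
  arr <- array(0, c(length(frames), d[1], d[2]))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  if (!is.null(meta$intensity_span))
    arr <- arr * meta$intensity_span +
      (meta$intensity_offset %||% 0)
  frame_stack(arr, fps_hz = meta$fps_hz, pixel_size_mm = meta$pixel_size_mm,
              modality = meta$modality %||% "Vm",
              stim_times_ms = meta$stim_times_ms %||% numeric(),
              provenance = tiff_path)
}

#' Reload a ground-truth JSON written by [write_fixture()]
#' @param path `truth.json` path.
#' @return a `ground_truth` object (geometry/config fields limited to what
#'   the file stores).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- sim_grid(tr$grid$nrow, tr$grid$ncol, tr$grid$pixel_size_mm)
  beats <- lapply(seq_len(nrow_or_len(tr$beats)), function(i) {
    b <- if (is.data.frame(tr$beats)) tr$beats[i, ] else tr$beats[[i]]
    act <- if (is.data.frame(tr$beats)) b$act[[1]] else b$act
    if (!is.matrix(act))  # row-major nested lists
      act <- matrix(as.numeric(unlist(act)), grid$nrow, grid$ncol,
                    byrow = TRUE)
    storage.mode(act) <- "double"
    list(time = b$time, source = b$source, act = act)
  })
  cv <- tr$cv_true
  if (!is.null(cv$isotropic)) cv <- cv$isotropic
  structure(list(beats = beats,
                 region_labels = if (is.matrix(tr$region_labels))
                   tr$region_labels else
                   matrix(as.character(unlist(tr$region_labels)),
                          grid$nrow, grid$ncol, byrow = TRUE),
                 region_index = NULL, cv_true = cv, grid = grid,
                 regions = NULL, protocol = NULL,
                 stim_times_ms = as.numeric(tr$stim_times_ms)),
            class = "ground_truth")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
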