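#' Local conduction-velocity field from an activation map
#'
#' At every defined pixel a plane `t(x, y) = a + gx * x + gy * y` is fitted
#' by least squares to the activation times in the surrounding
#' `(2r + 1) x (2r + 1)` window (coordinates in mm). The local speed is the
#' inverse gradient magnitude `1 / |g|` in mm/ms = m/s and the propagation
#' direction is `g / |g|` (the wave moves toward later activation).
#' Pixels are left undefined when fewer than half the window is defined,
#' when the fit quality (R squared) falls below `min_quality`, or when the
#' speed exceeds `max_speed` (near-flat activation gradients produce
#' arbitrarily large apparent speeds).
#'
#' @param act an `activation_map` from [build_maps()], or a plain numeric
#'   matrix of activation times in ms.
#' @param pixel_size_mm pixel size; taken from the map when available.
#' @param window_radius_px plane-fit window radius `r` (default 2, a 5 x 5
#'   window).
#' @param max_speed outlier gate in m/s (default 2; slice conduction runs
#'   roughly 0.25-0.9 m/s).
#' @param min_quality minimum R squared of the local fit.
#' @return a `velocity_field`: `speed_m_per_s`, `direction_rad`,
#'   `fit_quality` (H x W each), and the settings used.
#' @export
local_velocity_field <- function(act, pixel_size_mm = NULL,
                                 window_radius_px = 2, max_speed = 2,
                                 min_quality = 0.8) {
  tm <- if (inherits(act, "activation_map")) act$times_ms else act
  if (is.null(pixel_size_mm)) pixel_size_mm <- act$pixel_size_mm
  stopifnot(is.numeric(pixel_size_mm), pixel_size_mm > 0,
            window_radius_px >= 1, max_speed > 0)
  H <- nrow(tm); W <- ncol(tm)
  r <- as.integer(window_radius_px)
  need <- ceiling(((2 * r + 1)^2) / 2)
  speed <- matrix(NA_real_, H, W)
  ang <- matrix(NA_real_, H, W)
  qual <- matrix(NA_real_, H, W)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  # local mm coordinates: x across columns, y down rows
  xs <- off$dc * pixel_size_mm
  ys <- off$dr * pixel_size_mm
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (is.na(tm[i, j])) next
      rr <- i + off$dr; cc <- j + off$dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      t_ij <- rep(NA_real_, nrow(off))
      t_ij[ok] <- tm[cbind(rr[ok], cc[ok])]
      ok <- ok & !is.na(t_ij)
      if (sum(ok) < need) next
      X <- cbind(1, xs[ok], ys[ok])
      y <- t_ij[ok]
      fit <- stats::lm.fit(X, y)
      g <- fit$coefficients[2:3]
      ss_tot <- sum((y - mean(y))^2)
      if (!all(is.finite(g)) || ss_tot <= 0) next   # degenerate neighborhood
      r2 <- 1 - sum(fit$residuals^2) / ss_tot
      gn <- sqrt(sum(g^2))
      if (gn <= 0) next
      sp <- 1 / gn
      if (sp > max_speed || r2 < min_quality) next
      speed[i, j] <- sp
      ang[i, j] <- atan2(g[2], g[1])   # direction of propagation (y down)
      qual[i, j] <- r2
    }
  }
  structure(list(speed_m_per_s = speed, direction_rad = ang,
                 fit_quality = qual, window_radius_px = r,
                 max_speed_m_per_s = max_speed,
                 pixel_size_mm = pixel_size_mm),
            class = "velocity_field")
}

#' Summary conduction velocity of a field
#'
#' @param field a `velocity_field`.
#' @param mask optional `tissue_mask` (or logical matrix) restricting the
#'   summary.
#' @param method `"median"` (with IQR dispersion, the default — robust to
#'   plane-fit outliers) or `"mean"` (with SD).
#' @param min_pixels minimum number of defined speeds required.
#' @param labels optional character H x W matrix; when given, one summary
#'   per label is returned as a named list.
#' @return a `cv_summary` (`central_value_m_per_s`, `dispersion`,
#'   `n_pixels`, `method`), or a named list of them when `labels` is given.
#' @export
summary_cv <- function(field, mask = NULL, method = c("median", "mean"),
                       min_pixels = 25, labels = NULL) {
  method <- match.arg(method)
  sp <- field$speed_m_per_s
  keep <- !is.na(sp)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
    if (!identical(dim(m), dim(sp)))
      stop("mask dimensions must match the field", call. = FALSE)
    keep <- keep & m
  }
  if (!is.null(labels)) {
    labs <- unique(labels[keep & !is.na(labels)])
    out <- lapply(labs, function(L) {
      f2 <- field
      f2$speed_m_per_s[!(keep & !is.na(labels) & labels == L)] <- NA_real_
      summary_cv(f2, method = method, min_pixels = min_pixels)
    })
    names(out) <- labs
    return(out)
  }
  v <- sp[keep]
  if (length(v) < min_pixels)
    stop(sprintf("only %d defined velocity pixels (need >= %d)",
                 length(v), min_pixels), call. = FALSE)
  if (method == "median") {
    ctr <- stats::median(v); disp <- stats::IQR(v)
  } else {
    ctr <- mean(v); disp <- stats::sd(v)
  }
  structure(list(central_value_m_per_s = ctr, dispersion = disp,
                 n_pixels = length(v), method = method),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("CV %s = %.3f m/s (dispersion %.3f, n = %d pixels)\n",
              x$method, x$central_value_m_per_s, x$dispersion, x$n_pixels))
  invisible(x)
}

#' Conduction velocity along a ray from a point-stimulation site
#'
#' Samples activation times at one-pixel steps along a ray leaving
#' `source_px` at `ray_angle_rad` and regresses distance from the source on
#' activation time; the slope is the conduction speed along the ray in
#' m/s. With the ray set perpendicular to the fiber direction this measures
#' transverse conduction velocity.
#'
#' @param act an `activation_map` or numeric matrix (times in ms).
#' @param source_px pacing site `c(row, col)`.
#' @param ray_angle_rad ray direction in radians (0 = +x across columns,
#'   pi/2 = +y down rows).
#' @param pixel_size_mm pixel size; taken from the map when available.
#' @param min_samples minimum defined samples along the ray.
#' @return a `cv_summary` whose dispersion is the standard error of the
#'   fitted slope.
#' @export
transverse_cv <- function(act, source_px, ray_angle_rad,
                          pixel_size_mm = NULL, min_samples = 10) {
  tm <- if (inherits(act, "activation_map")) act$times_ms else act
  if (is.null(pixel_size_mm)) pixel_size_mm <- act$pixel_size_mm
  H <- nrow(tm); W <- ncol(tm)
  if (source_px[1] < 1 || source_px[1] > H ||
      source_px[2] < 1 || source_px[2] > W)
    stop("source_px outside the grid", call. = FALSE)
  dr <- sin(ray_angle_rad); dc <- cos(ray_angle_rad)
  dist_mm <- numeric(); t_ms <- numeric()
  step <- 0
  repeat {
    step <- step + 1
    rr <- round(source_px[1] + step * dr)
    cc <- round(source_px[2] + step * dc)
    if (rr < 1 || rr > H || cc < 1 || cc > W) break
    v <- tm[rr, cc]
    if (!is.na(v)) {
      dist_mm <- c(dist_mm, step * pixel_size_mm)
      t_ms <- c(t_ms, v)
    }
  }
  if (length(dist_mm) < min_samples)
    stop(sprintf("only %d defined samples along the ray (need >= %d)",
                 length(dist_mm), min_samples), call. = FALSE)
  fit <- stats::lm(dist_mm ~ t_ms)
  # slope standard error computed directly so that exact (zero-residual)
  # synthetic maps do not trip summary.lm's perfect-fit warning
  rdf <- fit$df.residual
  sigma2 <- sum(fit$residuals^2) / rdf
  se <- sqrt(sigma2 / sum((t_ms - mean(t_ms))^2))
  structure(list(central_value_m_per_s = unname(stats::coef(fit)["t_ms"]),
                 dispersion = se,
                 n_pixels = length(dist_mm), method = "ray regression"),
            class = "cv_summary")
}
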