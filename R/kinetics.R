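#' Rectangular region of interest
#'
#' @param id ROI identifier (character or number).
#' @param rows,cols inclusive `c(first, last)` pixel ranges.
#' @return an object of class `lyo_roi`.
#' @export
roi <- function(id, rows, cols) {
  if (length(rows) != 2 || length(cols) != 2 ||
      rows[1] > rows[2] || cols[1] > cols[2] || rows[1] < 1 || cols[1] < 1)
    stop("'rows' and 'cols' must be increasing 1-based ranges")
  structure(list(id = as.character(id), rows = as.integer(rows),
                 cols = as.integer(cols)), class = "lyo_roi")
}

#' Front detection configuration
#'
#' The sublimation front separates the dried porous region from the
#' still-frozen region. Each profile perpendicular to the front is reduced
#' to a feature and the front position in a column is the farthest
#' dried/frozen boundary from the entry border, found as the majority
#' change point of the thresholded feature.
#'
#' @param feature `"contrast"` (default): absolute deviation of the gray
#'   level from the frozen reference level; the composite boundary is sharp,
#'   so positions are pixel-accurate. `"texture"`: rolling local standard
#'   deviation, usable when the frozen phase's mean gray level overlaps the
#'   dried phases.
#' @param texture_window odd window width (px) of the local-sd filter
#'   (texture feature only).
#' @param perp_window odd box width (px) for averaging the feature across
#'   the coordinate perpendicular to travel: pore interiors are locally
#'   smooth and can match the frozen level, so each column profile borrows
#'   wall signal from its neighbours without smearing the front itself.
#' @param smooth_sigma optional isotropic Gaussian sd (px) for very noisy
#'   data; 0 (default) preserves single-pixel front resolution.
#' @param bimodal_min_separation without a frozen reference, the frame's
#'   feature histogram must split (Otsu) into two classes whose means are
#'   at least this many pooled within-class standard deviations apart;
#'   otherwise the frame has no detectable dried/frozen transition.
#' @return an object of class `detect_config`.
#' @export
detect_config <- function(feature = c("contrast", "texture"),
                          texture_window = 7,
                          perp_window = 15,
                          smooth_sigma = 0,
                          bimodal_min_separation = 5) {
  feature <- match.arg(feature)
  if (texture_window %% 2 != 1) stop("'texture_window' must be odd")
  if (perp_window %% 2 != 1) stop("'perp_window' must be odd")
  structure(list(feature = feature,
                 texture_window = as.integer(texture_window),
                 perp_window = as.integer(perp_window),
                 smooth_sigma = smooth_sigma,
                 bimodal_min_separation = bimodal_min_separation),
            class = "detect_config")
}

# Map the frame so the front travels along increasing columns (+x) and the
# entry border is column 1; perpendicular coordinate = rows.
canonicalize_travel <- function(m, travel_direction) {
  switch(travel_direction,
    "+x" = m,
    "-x" = m[, rev(seq_len(ncol(m))), drop = FALSE],
    "+y" = t(m),
    "-y" = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
    stop("invalid travel_direction: ", travel_direction))
}

# Feature image in canonical (+x travel) orientation.
front_feature <- function(m, cfg, level = NULL) {
  f <- if (cfg$feature == "contrast") {
    if (is.null(level)) stop("contrast feature needs a frozen level")
    abs(m - level)
  } else {
    w <- cfg$texture_window
    k <- matrix(1 / w^2, w, w)
    mu <- as_mat(EBImage::filter2(m, k, boundary = "replicate"))
    mu2 <- as_mat(EBImage::filter2(m^2, k, boundary = "replicate"))
    sqrt(pmax(mu2 - mu^2, 0))
  }
  if (cfg$perp_window > 1 && nrow(f) >= cfg$perp_window) {
    kp <- matrix(1 / cfg$perp_window, cfg$perp_window, 1)
    f <- as_mat(EBImage::filter2(f, kp, boundary = "replicate"))
  }
  if (cfg$smooth_sigma > 0) f <- as_mat(EBImage::gblur(f, cfg$smooth_sigma))
  f
}

far_strip <- function(m) {
  m[, max(1, ncol(m) - ceiling(0.1 * ncol(m))):ncol(m), drop = FALSE]
}

#' Frozen-texture reference
#'
#' Gray-level statistics of the frozen phase, taken from the far-border
#' strip (last 10 percent of the travel extent) of a frame on which the
#' front has not arrived there - typically the first frame of a sequence.
#' Used to threshold the dried/frozen contrast feature and to classify
#' frames without a transition as fully frozen or fully dried.
#'
#' @param frame numeric matrix or [micrograph].
#' @param travel_direction front travel direction.
#' @return list with `level` (median gray) and `spread` (MAD, floored so
#'   noiseless frames still yield a usable threshold).
#' @export
estimate_frozen_ref <- function(frame, travel_direction) {
  m <- if (inherits(frame, "micrograph")) frame$pixels else frame
  strip <- far_strip(canonicalize_travel(m, travel_direction))
  list(level = median(strip), spread = max(mad(strip), 1e-3))
}

# Majority change point of a logical indicator row: the split c maximizing
# (#above in 1..c) - (#above in (c+1)..W), i.e. argmax of cumsum(I - 1/2).
# 0 when no prefix beats the empty split (fully frozen column). Robust to
# isolated misclassified pixels on either side.
indicator_changepoint <- function(above) {
  cs <- t(apply(above - 0.5, 1, cumsum))
  pos <- max.col(cs, ties.method = "first")
  best <- cs[cbind(seq_len(nrow(cs)), pos)]
  pos[best < 0] <- 0L
  pos
}

#' Per-column sublimation-front positions in one frame
#'
#' For each coordinate perpendicular to the travel direction, the front
#' position is the farthest dried-frozen boundary from the entry border,
#' the majority change point of the thresholded feature profile. With a
#' `frozen_ref` the threshold is the frozen level plus five spreads and
#' uniform frames are classified as fully frozen (positions 0) or fully
#' dried (positions = extent, `complete = TRUE`). Without a reference the
#' frozen level is self-estimated from the far-border strip and the frame
#' must be detectably bimodal, otherwise the front is not found (error).
#'
#' @param frame numeric matrix or [micrograph].
#' @param travel_direction `"+x"`, `"-x"`, `"+y"` or `"-y"`.
#' @param pixel_scale micrometres per pixel (taken from the micrograph if
#'   omitted).
#' @param cfg a [detect_config()].
#' @param frozen_ref optional reference from [estimate_frozen_ref()].
#' @return list with `positions_um` (length = perpendicular extent),
#'   `boundary` (logical: column has its own dried/frozen boundary, i.e.
#'   the front is inside it), `uniform` (frame classified without a
#'   detected transition), `complete` (front has traversed the whole
#'   extent) and `extent_um`.
#' @export
front_profile <- function(frame, travel_direction, pixel_scale = NULL,
                          cfg = detect_config(), frozen_ref = NULL) {
  if (inherits(frame, "micrograph")) {
    if (is.null(pixel_scale)) pixel_scale <- frame$pixel_scale
    frame <- frame$pixels
  }
  if (is.null(pixel_scale)) stop("'pixel_scale' is required")
  m <- canonicalize_travel(frame, travel_direction)
  H <- nrow(m); W <- ncol(m)
  extent_um <- W * pixel_scale
  self_ref <- is.null(frozen_ref)
  if (self_ref)
    frozen_ref <- list(level = median(far_strip(m)),
                       spread = max(mad(far_strip(m)), 1e-3))
  f <- front_feature(m, cfg, level = frozen_ref$level)

  if (cfg$feature == "contrast" && !self_ref) {
    thr <- 5 * frozen_ref$spread
  } else {
    # threshold from the frame's own feature histogram; gate on bimodality
    rng <- range(f)
    fail <- diff(rng) < 1e-9
    thr <- NA_real_
    if (!fail) {
      t_norm <- EBImage::otsu((f - rng[1]) / diff(rng), range = c(0, 1),
                              levels = 256)
      thr <- t_norm * diff(rng) + rng[1]
      lo <- f[f < thr]; hi <- f[f >= thr]
      within <- sqrt((var(lo) * length(lo) + var(hi) * length(hi)) /
                       length(f))
      sep <- (mean(hi) - mean(lo)) / max(within, 1e-12)
      fail <- !is.finite(sep) || sep < cfg$bimodal_min_separation
    }
    if (fail)
      stop("front not found: no detectable dried/frozen transition",
           if (self_ref) " (uniform frame and no frozen reference)")
  }

  dried_frac <- mean(f > thr)
  if (dried_frac < 0.005 || dried_frac > 0.995) {
    if (self_ref)
      stop("front not found: frame is uniform and no frozen reference ",
           "was given")
    dried <- dried_frac > 0.99
    return(list(positions_um = rep(if (dried) extent_um else 0, H),
                boundary = rep(FALSE, H), uniform = TRUE,
                complete = dried, extent_um = extent_um))
  }

  pos_px <- indicator_changepoint(f >= thr)
  pos <- pmin(pos_px * pixel_scale, extent_um)
  boundary <- pos_px > 0L & pos_px < W
  list(positions_um = pos, boundary = boundary, uniform = FALSE,
       complete = all(pos >= extent_um - pixel_scale),
       extent_um = extent_um)
}

roi_bounds_canonical <- function(r, travel_direction, dims, pixel_scale) {
  H <- dims[1]; W <- dims[2]
  if (r$rows[2] > H || r$cols[2] > W)
    stop("ROI '", r$id, "' exceeds the frame")
  # perpendicular range and travel far edge (um from entry border)
  switch(travel_direction,
    "+x" = list(perp = r$rows, far_um = r$cols[2] * pixel_scale),
    "-x" = list(perp = r$rows, far_um = (W - r$cols[1] + 1) * pixel_scale),
    "+y" = list(perp = r$cols, far_um = r$rows[2] * pixel_scale),
    "-y" = list(perp = r$cols, far_um = (H - r$rows[1] + 1) * pixel_scale))
}

#' Track the sublimation front and estimate its velocity
#'
#' Detects per-column front positions in every frame, averages them over the
#' ROI's perpendicular extent (or the whole field of view), and converts
#' per-interval displacements into velocities in um/min. Only frames with a
#' detected boundary enter the velocity fit: uniform frames (before the
#' front entered or after it traversed) have classified, not measured,
#' positions, and frames after the front exits the ROI are dropped. The
#' mean velocity is the arithmetic mean of the interval velocities with a
#' Student-t confidence interval.
#'
#' @param frames a [frame_sequence].
#' @param travel_direction front travel direction.
#' @param roi optional [roi()]; `NULL` uses the whole field of view.
#' @param cfg a [detect_config()].
#' @param confidence confidence level for the CI (default 0.95).
#' @param image_id optional source-image identifier, carried to
#'   [roi_compare()].
#' @return an object of class `velocity_trace`: list with `times_s`,
#'   `positions_um` (all frames x ROI columns), `mean_positions_um`,
#'   `fit_frames` (frame indices used for the velocity), `interval_velocities`
#'   (um/min), `mean_velocity`, `ci_halfwidth`, `n_intervals`, `extent_um`,
#'   `complete` (per frame), `roi_id`, `image_id`.
#' @export
velocity_trace <- function(frames, travel_direction, roi = NULL,
                           cfg = detect_config(), confidence = 0.95,
                           image_id = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  if (n < 2) stop("need at least 2 frames")
  dt <- diff(frames$times_s)
  if (max(abs(dt - mean(dt))) > 0.01 * mean(dt))
    stop("frame interval must be constant within 1%")
  scale <- frames$pixel_scale
  dims <- dim(frames$frames[[1]])

  ref <- estimate_frozen_ref(frames$frames[[1]], travel_direction)
  profs <- lapply(frames$frames, front_profile,
                  travel_direction = travel_direction, pixel_scale = scale,
                  cfg = cfg, frozen_ref = ref)
  pos <- do.call(rbind, lapply(profs, `[[`, "positions_um"))
  extent_um <- profs[[1]]$extent_um

  if (!is.null(roi)) {
    b <- roi_bounds_canonical(roi, travel_direction, dims, scale)
    pos <- pos[, b$perp[1]:b$perp[2], drop = FALSE]
    far_um <- b$far_um
  } else far_um <- extent_um

  mean_pos <- rowMeans(pos)
  measured <- !vapply(profs, `[[`, logical(1), "uniform")
  inside <- mean_pos <= far_um
  fit <- which(measured & inside)
  # a detected boundary beyond the ROI ends the usable window
  if (any(!inside)) fit <- fit[fit < min(which(!inside))]
  if (length(fit) < 2)
    stop("fewer than 2 usable frames with a measured front inside the ROI")
  v <- diff(mean_pos[fit]) / diff(frames$times_s[fit]) * 60
  structure(
    list(times_s = frames$times_s, positions_um = pos,
         mean_positions_um = mean_pos, fit_frames = fit,
         interval_velocities = v, mean_velocity = mean(v),
         ci_halfwidth = t_ci_halfwidth(v, confidence),
         n_intervals = length(v), extent_um = extent_um,
         complete = vapply(profs, `[[`, logical(1), "complete"),
         roi_id = if (is.null(roi)) NA_character_ else roi$id,
         image_id = image_id),
    class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf(
    "velocity_trace: %d intervals, mean %.3g +/- %.2g um/min (roi: %s)\n",
    x$n_intervals, x$mean_velocity,
    ifelse(is.na(x$ci_halfwidth), NA, x$ci_halfwidth), x$roi_id))
  invisible(x)
}

#' Primary drying time from a front trace
#'
#' Primary drying ends when the slowest column of the front (its minimum
#' position) has traversed the full extent. If the trace does not cover the
#' traversal, the time is extrapolated as `extent / mean velocity` and
#' flagged.
#'
#' @param trace a `velocity_trace` from [velocity_trace()].
#' @param extent_um extent to traverse in um (default: the trace's field of
#'   view).
#' @return list with `minutes` and `extrapolated`.
#' @export
primary_drying_time <- function(trace, extent_um = NULL) {
  stopifnot(inherits(trace, "velocity_trace"))
  if (is.null(extent_um)) extent_um <- trace$extent_um
  min_pos <- apply(trace$positions_um, 1, min)
  hit <- which(min_pos >= extent_um)
  if (length(hit))
    return(list(minutes = trace$times_s[min(hit)] / 60,
                extrapolated = FALSE))
  if (trace$mean_velocity <= 0)
    stop("zero mean velocity: drying time cannot be extrapolated")
  list(minutes = extent_um / trace$mean_velocity, extrapolated = TRUE)
}
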