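#' Synthetic microstructure specification
#'
#' Describes a synthetic freeze-dried microstructure: an amorphous wall phase
#' enclosing elliptical pores with configurable size, shape and orientation
#' statistics. Two morphology presets mirror what different freezing
#' protocols produce: `"cellular"` (near-isotropic, aspect ratio about
#' 1.2-2) and `"dendritic"` (lamellar, aspect ratio >= 2.5, orientations
#' concentrated about a preferred axis).
#'
#' Distributions are given as named lists:
#' * diameter (equivalent diameter, um): `list(family = "lognormal",
#'   meanlog=, sdlog=)`, `list(family = "normal", mean=, sd=)` or
#'   `list(family = "constant", value=)`.
#' * aspect ratio (>= 1): `"uniform"` (`min`, `max`), `"constant"`.
#' * orientation (degrees in `[0, 180)`): `"uniform"`, `"constant"`, or
#'   `"wrapped_normal"` (`mean`, `sd`) - a normal wrapped onto the 180-degree
#'   axis circle, emulating ice-crystal growth along a preferred direction.
#'
#' @param canvas integer `c(H, W)` canvas size in pixels.
#' @param pixel_scale micrometres per pixel (> 0).
#' @param n_pores number of pores to place (exclusive with
#'   `target_porosity`).
#' @param target_porosity pore area fraction in `(0, 1)` to reach instead of
#'   a fixed count.
#' @param morphology `"cellular"` or `"dendritic"`; sets the default shape
#'   and orientation distributions.
#' @param diameter_dist,aspect_ratio_dist,orientation_dist distribution
#'   lists as above; `NULL` uses the morphology preset.
#' @param wall_min_thickness minimum wall (gap) between pores, px (>= 1).
#' @param min_semi_axis_px smallest admissible minor semi-axis, px; draws
#'   below it are resampled so every pore is resolvable.
#' @param pore_polarity `"dark_pores"` (bright walls, the default) or
#'   `"bright_pores"`.
#' @param wall_level,pore_level gray levels of the two phases in `[0, 1]`;
#'   `NULL` picks 0.75/0.25 consistent with `pore_polarity`.
#' @param noise_sigma additive Gaussian noise sd, gray levels.
#' @param blur_sigma Gaussian optical blur sd, px (0 = none).
#' @param allow_cut_pores place pores overlapping the canvas border
#'   (default `FALSE`: fully interior placement).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `microstructure_spec`.
#' @export
microstructure_spec <- function(canvas = c(384L, 384L),
                                pixel_scale = 0.5,
                                n_pores = NULL,
                                target_porosity = NULL,
                                morphology = c("cellular", "dendritic"),
                                diameter_dist = NULL,
                                aspect_ratio_dist = NULL,
                                orientation_dist = NULL,
                                wall_min_thickness = 3,
                                min_semi_axis_px = 2,
                                pore_polarity = c("dark_pores",
                                                  "bright_pores"),
                                wall_level = NULL, pore_level = NULL,
                                noise_sigma = 0.03,
                                blur_sigma = 0.8,
                                allow_cut_pores = FALSE,
                                seed = 1L) {
  morphology <- match.arg(morphology)
  pore_polarity <- match.arg(pore_polarity)
  stopifnot_scalar(pixel_scale, "pixel_scale")
  if (pixel_scale <= 0) stop("'pixel_scale' must be > 0")
  if (wall_min_thickness < 1) stop("'wall_min_thickness' must be >= 1 px")
  if (is.null(n_pores) == is.null(target_porosity))
    stop("give exactly one of 'n_pores' or 'target_porosity'")
  if (!is.null(target_porosity) &&
      (target_porosity <= 0 || target_porosity >= 1))
    stop("'target_porosity' must be in (0, 1)")

  if (is.null(diameter_dist))
    diameter_dist <- list(family = "lognormal",
                          meanlog = log(7) - 0.25^2 / 2, sdlog = 0.25)
  if (is.null(aspect_ratio_dist))
    aspect_ratio_dist <- switch(morphology,
      cellular  = list(family = "uniform", min = 1.2, max = 2.0),
      dendritic = list(family = "uniform", min = 2.5, max = 4.0))
  if (is.null(orientation_dist))
    orientation_dist <- switch(morphology,
      cellular  = list(family = "uniform"),
      dendritic = list(family = "wrapped_normal", mean = 90, sd = 10))
  if (is.null(wall_level))
    wall_level <- if (pore_polarity == "dark_pores") 0.75 else 0.25
  if (is.null(pore_level))
    pore_level <- if (pore_polarity == "dark_pores") 0.25 else 0.75
  structure(
    list(canvas = as.integer(canvas), pixel_scale = pixel_scale,
         n_pores = n_pores, target_porosity = target_porosity,
         morphology = morphology, diameter_dist = diameter_dist,
         aspect_ratio_dist = aspect_ratio_dist,
         orientation_dist = orientation_dist,
         wall_min_thickness = wall_min_thickness,
         min_semi_axis_px = min_semi_axis_px,
         pore_polarity = pore_polarity,
         wall_level = wall_level, pore_level = pore_level,
         noise_sigma = noise_sigma, blur_sigma = blur_sigma,
         allow_cut_pores = allow_cut_pores, seed = as.integer(seed)),
    class = "microstructure_spec"
  )
}

draw_dist <- function(dist, n) {
  switch(dist$family,
    constant  = rep(dist$value, n),
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
    normal    = rnorm(n, dist$mean, dist$sd),
    uniform   = if (is.null(dist$min)) runif(n, 0, 180)
                else runif(n, dist$min, dist$max),
    wrapped_normal = (rnorm(n, dist$mean, dist$sd)) %% 180,
    stop("unknown distribution family: ", dist$family)
  )
}

# Pixel set of an ellipse, bbox-local evaluation at pixel centers.
# Returns a two-column (row, col) integer matrix, possibly empty.
ellipse_pixels <- function(center, semi_axes, angle_deg, canvas) {
  a <- semi_axes[1]; b <- semi_axes[2]
  # cospi/sinpi are exact at multiples of 90 deg, keeping rotations of the
  # same ellipse pixel-for-pixel symmetric
  cth <- cospi(angle_deg / 180); sth <- sinpi(angle_deg / 180)
  rmax <- max(a, b)
  r0 <- max(1L, floor(center[1] - rmax)); r1 <- min(canvas[1], ceiling(center[1] + rmax))
  c0 <- max(1L, floor(center[2] - rmax)); c1 <- min(canvas[2], ceiling(center[2] + rmax))
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), ncol = 2))
  rows <- r0:r1; cols <- c0:c1
  dx <- rep(cols - center[2], each = length(rows))
  dy <- rep(-(rows - center[1]), times = length(cols))   # y = -row
  u <- dx * cth + dy * sth
  v <- -dx * sth + dy * cth
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(matrix(integer(0), ncol = 2))
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

#' Rasterize an ellipse onto a canvas
#'
#' A pixel belongs to the ellipse when the ellipse inequality holds at its
#' center. The axis angle is measured counter-clockwise from the +x (column)
#' axis in display orientation (y pointing up).
#'
#' @param center `c(row, col)` of the ellipse center, px (1-based).
#' @param semi_axes `c(a, b)` semi-axes in px, both >= 1.
#' @param angle_deg major-axis angle in degrees.
#' @param canvas `c(H, W)` canvas size.
#' @return an H x W logical mask.
#' @export
rasterize_ellipse <- function(center, semi_axes, angle_deg, canvas) {
  if (any(semi_axes < 1)) stop("semi-axes must be >= 1 px")
  px <- ellipse_pixels(center, semi_axes, angle_deg, canvas)
  if (nrow(px) == 0) stop("ellipse lies fully outside the canvas")
  m <- matrix(FALSE, canvas[1], canvas[2])
  m[px] <- TRUE
  m
}

#' Generate a synthetic pore field with ground truth
#'
#' Places non-overlapping elliptical pores by rejection sampling with a
#' wall-thickness exclusion zone, renders the two-phase image at the
#' configured polarity, applies Gaussian blur then additive Gaussian noise,
#' and returns the exact per-pore ground truth.
#'
#' @param spec a [microstructure_spec()].
#' @return a list of class `pore_field` with elements `image` (a
#'   [micrograph]), `truth` (data frame: `id`, `center_row`, `center_col`,
#'   `semi_major_px`, `semi_minor_px`, `axis_angle_deg`, `area_px`,
#'   `eq_diameter_um`, `aspect_ratio`), `mask` (true pore mask) and `spec`.
#' @export
generate_pore_field <- function(spec) {
  stopifnot(inherits(spec, "microstructure_spec"))
  H <- spec$canvas[1]; W <- spec$canvas[2]
  with_seed(spec$seed, {
    occupied <- matrix(FALSE, H, W)
    mask <- matrix(FALSE, H, W)
    t_wall <- spec$wall_min_thickness
    rows <- list()
    n_target <- spec$n_pores
    budget <- 200L * if (is.null(n_target)) 500L else n_target
    attempts <- 0L
    placed <- 0L
    done <- function() {
      if (!is.null(n_target)) placed >= n_target
      else sum(mask) / (H * W) >= spec$target_porosity
    }
    while (!done()) {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop("packing infeasible: attempt budget exhausted after placing ",
             placed, " pores; reduce n_pores/target_porosity or ",
             "wall_min_thickness")
      d_um <- draw_dist(spec$diameter_dist, 1)
      ar <- draw_dist(spec$aspect_ratio_dist, 1)
      if (!is.finite(d_um) || d_um <= 0 || ar < 1) next
      a <- (d_um / 2) * sqrt(ar) / spec$pixel_scale
      b <- (d_um / 2) / sqrt(ar) / spec$pixel_scale
      if (b < spec$min_semi_axis_px) next
      ang <- draw_dist(spec$orientation_dist, 1) %% 180
      margin <- if (spec$allow_cut_pores) 0 else max(a, t_wall, 2)
      if (2 * margin >= min(H, W) - 2) next
      ctr <- c(runif(1, 1 + margin, H - margin),
               runif(1, 1 + margin, W - margin))
      # conservative separation test: the dilation of an ellipse by a disc
      # of radius t is contained in the ellipse grown by t on both axes
      exp_px <- ellipse_pixels(ctr, c(a + t_wall, b + t_wall), ang,
                               c(H, W))
      if (nrow(exp_px) == 0 || any(occupied[exp_px])) next
      px <- ellipse_pixels(ctr, c(a, b), ang, c(H, W))
      if (nrow(px) == 0) next
      occupied[px] <- TRUE
      mask[px] <- TRUE
      placed <- placed + 1L
      rows[[placed]] <- data.frame(
        id = placed, center_row = ctr[1], center_col = ctr[2],
        semi_major_px = a, semi_minor_px = b, axis_angle_deg = ang,
        area_px = nrow(px),
        eq_diameter_um = 2 * sqrt(a * b) * spec$pixel_scale,
        aspect_ratio = a / b)
    }
    truth <- if (placed > 0) do.call(rbind, rows) else
      data.frame(id = integer(0), center_row = numeric(0),
                 center_col = numeric(0), semi_major_px = numeric(0),
                 semi_minor_px = numeric(0), axis_angle_deg = numeric(0),
                 area_px = numeric(0), eq_diameter_um = numeric(0),
                 aspect_ratio = numeric(0))

    img <- matrix(spec$wall_level, H, W)
    img[mask] <- spec$pore_level
    if (spec$blur_sigma > 0)
      img <- as_mat(EBImage::gblur(img, sigma = spec$blur_sigma))
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    img <- pmin(pmax(img, 0), 1)

    structure(
      list(image = micrograph(img, spec$pixel_scale,
                              meta = list(morphology = spec$morphology)),
           truth = truth, mask = mask, spec = spec),
      class = "pore_field")
  })
}

#' Front kinetics specification for synthetic time-lapses
#'
#' Describes how a sublimation front advances across the field of view
#' during a simulated primary drying: entry border, base velocity, frame
#' cadence, and an optional "fissured front" where per-column velocities
#' differ with the local microstructure (columns whose pores are oriented
#' perpendicular to the front dry faster).
#'
#' @param travel_direction `"+x"`, `"-x"`, `"+y"` or `"-y"`; the front
#'   enters at the opposite border and advances in this direction.
#' @param base_velocity front velocity in um/min (> 0).
#' @param frame_interval frame spacing in seconds (default 60).
#' @param n_frames number of frames (>= 2); frame 1 is at t = 0 with the
#'   front at the entry border.
#' @param fissure_amplitude approximate position spread (um) between the
#'   fastest and average columns at the final frame; 0 = straight front.
#' @param fissure_model `"orientation"` (default; derives per-column
#'   multipliers from local pore orientation) or `"none"`.
#' @param velocity_multipliers optional explicit per-column multiplier
#'   vector (length = FOV extent perpendicular to travel); overrides the
#'   fissure model.
#' @param frozen_level,frozen_noise gray level and noise sd of the frozen
#'   phase texture.
#' @param frame_noise per-frame additive noise sd, gray levels.
#' @param seed integer seed.
#' @return an object of class `front_kinetics_spec`.
#' @export
front_kinetics_spec <- function(travel_direction = "+x",
                                base_velocity = 10,
                                frame_interval = 60,
                                n_frames = 10,
                                fissure_amplitude = 0,
                                fissure_model = c("orientation", "none"),
                                velocity_multipliers = NULL,
                                frozen_level = 0.45, frozen_noise = 0.01,
                                frame_noise = 0.005,
                                seed = 1L) {
  fissure_model <- match.arg(fissure_model)
  travel_direction <- match.arg(travel_direction,
                                c("+x", "-x", "+y", "-y"))
  if (base_velocity <= 0) stop("'base_velocity' must be > 0")
  if (frame_interval <= 0) stop("'frame_interval' must be > 0")
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  structure(
    list(travel_direction = travel_direction,
         base_velocity = base_velocity, frame_interval = frame_interval,
         n_frames = as.integer(n_frames),
         fissure_amplitude = fissure_amplitude,
         fissure_model = fissure_model,
         velocity_multipliers = velocity_multipliers,
         frozen_level = frozen_level, frozen_noise = frozen_noise,
         frame_noise = frame_noise, seed = as.integer(seed)),
    class = "front_kinetics_spec"
  )
}

# Per-column velocity multipliers from local pore orientation: columns
# whose pores sit perpendicular to the front ((theta-45)/45 > 0) are
# boosted, parallel ones slowed. Nadaraya-Watson smoothing over the
# perpendicular coordinate, amplitude scaled so the position spread at the
# final frame approximates fissure_amplitude.
fissure_multipliers <- function(field, kin, n_perp) {
  if (!is.null(kin$velocity_multipliers)) {
    m <- kin$velocity_multipliers
    if (length(m) != n_perp)
      stop("'velocity_multipliers' must have length ", n_perp)
    return(m)
  }
  if (kin$fissure_model == "none" || kin$fissure_amplitude == 0 ||
      nrow(field$truth) == 0)
    return(rep(1, n_perp))
  along_rows <- kin$travel_direction %in% c("+x", "-x")
  p <- if (along_rows) field$truth$center_row else field$truth$center_col
  theta <- orientation_to_front(field$truth$axis_angle_deg,
                                kin$travel_direction)
  s <- (theta - 45) / 45
  j <- seq_len(n_perp)
  bw <- 10
  k <- exp(-outer(j, p, "-")^2 / (2 * bw^2))
  denom <- rowSums(k)
  w <- ifelse(denom > 1e-8, rowSums(k * rep(s, each = n_perp)) / denom, 0)
  if (max(abs(w)) > 0) w <- w / max(abs(w))
  duration_min <- (kin$n_frames - 1) * kin$frame_interval / 60
  rel <- min(0.9, kin$fissure_amplitude /
               (kin$base_velocity * duration_min))
  1 + rel * w
}

#' Generate a synthetic drying time-lapse with front ground truth
#'
#' Composites the dried pore field behind the advancing front and a smooth
#' frozen texture ahead of it, frame by frame. Per-column true front
#' positions are `base_velocity * multiplier * t`.
#'
#' @param field a `pore_field` from [generate_pore_field()]; its image is
#'   the dried texture.
#' @param kin a [front_kinetics_spec()].
#' @return a list of class `drying_timelapse`: `frames` (a
#'   [frame_sequence]), `truth` (list with `positions_um`, an
#'   n_frames x n_columns matrix of true front positions in um from the
#'   entry border; `velocity_um_min`, the per-column true mean velocity;
#'   `times_s`), and `kin`.
#' @export
generate_timelapse <- function(field, kin) {
  stopifnot(inherits(field, "pore_field"),
            inherits(kin, "front_kinetics_spec"))
  dried <- field$image$pixels
  H <- nrow(dried); W <- ncol(dried)
  scale <- field$image$pixel_scale
  along_rows <- kin$travel_direction %in% c("+x", "-x")
  n_perp <- if (along_rows) H else W
  extent_px <- if (along_rows) W else H

  mult <- fissure_multipliers(field, kin, n_perp)
  times <- (seq_len(kin$n_frames) - 1) * kin$frame_interval
  v_col <- kin$base_velocity * mult                     # um/min per column
  pos_um <- outer(times / 60, v_col)                    # frames x columns

  with_seed(kin$seed, {
    frozen <- kin$frozen_level +
      matrix(rnorm(H * W, 0, kin$frozen_noise), H, W)
    frozen <- pmin(pmax(as_mat(EBImage::gblur(frozen, sigma = 1)), 0), 1)
    frames <- vector("list", kin$n_frames)
    for (k in seq_len(kin$n_frames)) {
      pos_px <- pmin(pos_um[k, ] / scale, extent_px)
      dried_sel <- switch(kin$travel_direction,
        "+x" = outer(pos_px, seq_len(W), ">="),
        "-x" = outer(pos_px, rev(seq_len(W)), ">="),
        "+y" = t(outer(pos_px, seq_len(H), ">=")),
        "-y" = t(outer(pos_px, rev(seq_len(H)), ">=")))
      f <- frozen
      f[dried_sel] <- dried[dried_sel]
      if (kin$frame_noise > 0)
        f <- f + matrix(rnorm(H * W, 0, kin$frame_noise), H, W)
      frames[[k]] <- pmin(pmax(f, 0), 1)
    }
    structure(
      list(frames = frame_sequence(frames, times, scale,
                                   meta = list(
                                     travel_direction = kin$travel_direction,
                                     base_velocity = kin$base_velocity)),
           truth = list(positions_um = pos_um, velocity_um_min = v_col,
                        times_s = times),
           kin = kin),
      class = "drying_timelapse")
  })
}
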