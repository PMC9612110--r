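#' Equivalent pore diameter
#'
#' Diameter of the circle with the same area as the pore,
#' `2 * sqrt(area / pi)`, converted to micrometres with the pixel scale.
#'
#' @param area_px pore area in px^2 (>= 1), vectorized.
#' @param pixel_scale micrometres per pixel (> 0).
#' @return equivalent diameter(s) in um.
#' @export
equivalent_diameter <- function(area_px, pixel_scale) {
  if (any(area_px < 1)) stop("'area_px' must be >= 1")
  stopifnot_scalar(pixel_scale, "pixel_scale")
  if (pixel_scale <= 0) stop("'pixel_scale' must be > 0")
  2 * sqrt(area_px / pi) * pixel_scale
}

#' Moment-equivalent ellipse of a pixel region
#'
#' Fits the ellipse with the same normalized second central moments as the
#' region (the regionprops convention): the 1/12 variance of a unit pixel is
#' added to the diagonal, axis lengths are `2*sqrt(2)` times the square
#' roots of the moment-matrix eigenvalues, and the major-axis angle is
#' measured counter-clockwise from the +x (column) axis, in `[0, 180)`.
#'
#' @param rows,cols pixel coordinates of the region (equal length, >= 1).
#' @return list with `major_px`, `minor_px` (full axis lengths),
#'   `angle_deg` in `[0, 180)`, and `degenerate` (`TRUE` when the minor
#'   axis had to be floored at 1 px).
#' @export
fit_ellipse <- function(rows, cols) {
  n <- length(rows)
  if (n < 1 || length(cols) != n) stop("need matching 'rows' and 'cols'")
  x <- cols; y <- -rows                       # y axis pointing up
  mx <- mean(x); my <- mean(y)
  uxx <- sum((x - mx)^2) / n + 1 / 12
  uyy <- sum((y - my)^2) / n + 1 / 12
  uxy <- sum((x - mx) * (y - my)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor2 <- uxx + uyy - common
  minor <- 2 * sqrt(2) * sqrt(max(minor2, 0))
  degenerate <- FALSE
  if (!is.finite(minor) || minor < 1) {
    minor <- 1
    degenerate <- TRUE
  }
  angle <- if (common < 1e-12) 0
           else (atan2(2 * uxy, uxx - uyy) / 2) * 180 / pi
  list(major_px = major, minor_px = minor,
       angle_deg = angle %% 180, degenerate = degenerate)
}

#' Pore orientation relative to the sublimation front
#'
#' Angle between a pore's major axis and the front line (the line
#' perpendicular to the travel direction), folded to `[0, 90]`: 0 degrees =
#' pore parallel to the front, 90 degrees = perpendicular (aligned with the
#' vapor escape path). Only absolute values are used, so the axis angle's
#' 180-degree ambiguity does not matter.
#'
#' @param axis_angle major-axis angle(s) in degrees (any real; interpreted
#'   mod 180).
#' @param travel_direction `"+x"`, `"-x"`, `"+y"` or `"-y"`.
#' @return orientation(s) in degrees in `[0, 90]`.
#' @export
orientation_to_front <- function(axis_angle, travel_direction) {
  travel_direction <- match.arg(travel_direction,
                                c("+x", "-x", "+y", "-y"))
  front_line <- if (travel_direction %in% c("+x", "-x")) 90 else 0
  d <- (axis_angle - front_line) %% 180
  pmin(d, 180 - d)
}

#' Per-pore morphometric records
#'
#' One record per label: area, equivalent diameter, moment-ellipse axes,
#' aspect ratio (shape factor), axis angle and orientation to the front.
#' Pores with aspect ratio < 1.1 are effectively circular, so their axis
#' direction is dominated by raster noise; they are flagged (`low_ar`) but
#' included by default, and [summarize_pores()] can exclude them.
#'
#' @param labels integer label matrix from [segment_pores()] /
#'   [label_pores_watershed()].
#' @param pixel_scale micrometres per pixel.
#' @param travel_direction front travel direction (for orientation).
#' @param image_id optional identifier of the source image; stored as an
#'   attribute and enforced by [roi_compare()].
#' @return data frame with one row per pore: `pore_id`, `area_px`,
#'   `eq_diameter_um`, `major_um`, `minor_um`, `aspect_ratio`,
#'   `axis_angle_deg`, `orientation_deg`, `centroid_row`, `centroid_col`,
#'   `low_ar`, `degenerate`.
#' @export
pore_records <- function(labels, pixel_scale, travel_direction = "+x",
                         image_id = NULL) {
  empty <- data.frame(pore_id = integer(0), area_px = numeric(0),
                      eq_diameter_um = numeric(0), major_um = numeric(0),
                      minor_um = numeric(0), aspect_ratio = numeric(0),
                      axis_angle_deg = numeric(0),
                      orientation_deg = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      low_ar = logical(0), degenerate = logical(0))
  idx <- which(labels > 0)
  if (!length(idx)) {
    attr(empty, "image_id") <- image_id
    return(empty)
  }
  rc <- arrayInd(idx, dim(labels))
  labs <- labels[idx]
  recs <- lapply(split(seq_along(labs), labs), function(i) {
    r <- rc[i, 1]; c <- rc[i, 2]
    area <- length(i)
    e <- fit_ellipse(r, c)
    ar <- e$major_px / e$minor_px
    data.frame(
      pore_id = labs[i[1]], area_px = area,
      eq_diameter_um = equivalent_diameter(area, pixel_scale),
      major_um = e$major_px * pixel_scale,
      minor_um = e$minor_px * pixel_scale,
      aspect_ratio = ar,
      axis_angle_deg = e$angle_deg,
      orientation_deg = orientation_to_front(e$angle_deg, travel_direction),
      centroid_row = mean(r), centroid_col = mean(c),
      low_ar = ar < 1.1, degenerate = e$degenerate)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out <- out[order(out$pore_id), , drop = FALSE]
  attr(out, "image_id") <- image_id
  attr(out, "pixel_scale") <- pixel_scale
  attr(out, "travel_direction") <- travel_direction
  out
}

#' Condition-level structure summary
#'
#' Arithmetic means of pore size, shape factor and orientation with
#' Student-t confidence intervals (default confidence level 0.95). With a
#' single pore the half-widths are undefined (`NA`).
#'
#' @param records data frame from [pore_records()].
#' @param confidence confidence level (default 0.95).
#' @param exclude_low_ar drop near-circular pores (aspect ratio < 1.1) from
#'   the orientation mean (default `FALSE`).
#' @return an object of class `structure_summary`: a one-row data frame
#'   with `n_pores`, `mean_pore_size_um`, `pore_size_ci`,
#'   `mean_shape_factor`, `shape_factor_ci`, `mean_orientation_deg`,
#'   `orientation_ci`, `confidence`.
#' @export
summarize_pores <- function(records, confidence = 0.95,
                            exclude_low_ar = FALSE) {
  if (nrow(records) == 0) stop("cannot summarize zero pore records")
  ori <- if (exclude_low_ar) records$orientation_deg[!records$low_ar]
         else records$orientation_deg
  if (!length(ori)) ori <- NA_real_
  out <- data.frame(
    n_pores = nrow(records),
    mean_pore_size_um = mean(records$eq_diameter_um),
    pore_size_ci = t_ci_halfwidth(records$eq_diameter_um, confidence),
    mean_shape_factor = mean(records$aspect_ratio),
    shape_factor_ci = t_ci_halfwidth(records$aspect_ratio, confidence),
    mean_orientation_deg = mean(ori),
    orientation_ci = t_ci_halfwidth(ori, confidence),
    confidence = confidence)
  class(out) <- c("structure_summary", "data.frame")
  out
}

#' @export
format.structure_summary <- function(x, ...) {
  fmt <- function(m, hw, md = 1, hd = 2)
    paste0(round(m, md), " ± ",
           if (is.na(hw)) "NA" else format(round(hw, hd), nsmall = hd))
  c(pore_size = fmt(x$mean_pore_size_um, x$pore_size_ci),
    shape_factor = fmt(x$mean_shape_factor, x$shape_factor_ci),
    orientation = fmt(x$mean_orientation_deg, x$orientation_ci, 0, 1))
}

#' @export
print.structure_summary <- function(x, ...) {
  f <- format(x)
  cat(sprintf("structure summary (n = %d pores, %.2f confidence):\n",
              x$n_pores, x$confidence))
  cat(sprintf("  pore size    %s um\n", f["pore_size"]))
  cat(sprintf("  shape factor %s\n", f["shape_factor"]))
  cat(sprintf("  orientation  %s deg\n", f["orientation"]))
  invisible(x)
}

#' Pore size distribution
#'
#' Histogram of equivalent diameters over the given bin edges, with relative
#' frequencies and the cumulative fraction. Records outside the bin range
#' are counted in open-ended outer bins and flagged.
#'
#' @param records data frame from [pore_records()].
#' @param bin_edges strictly increasing bin edges in um.
#' @return data frame with `bin_lo`, `bin_hi` (`-Inf`/`Inf` for open end
#'   bins), `count`, `freq`, `cum_freq`; attribute `out_of_range` = number
#'   of records outside the edges.
#' @export
size_distribution <- function(records, bin_edges) {
  if (any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be strictly increasing")
  d <- records$eq_diameter_um
  edges <- c(-Inf, bin_edges, Inf)
  cuts <- cut(d, edges, right = FALSE)
  count <- as.integer(table(cuts))
  k <- length(bin_edges)
  out <- data.frame(
    bin_lo = edges[seq_len(k + 1)],
    bin_hi = edges[seq_len(k + 1) + 1],
    count = count)
  oor <- out$count[1] + out$count[k + 1]
  if (oor == 0) out <- out[-c(1, k + 1), , drop = FALSE]
  total <- sum(out$count)
  out$freq <- if (total > 0) out$count / total else 0
  out$cum_freq <- cumsum(out$freq)
  rownames(out) <- NULL
  attr(out, "out_of_range") <- oor
  out
}
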