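#' Segmentation configuration
#'
#' Parameters for the binarize -> clear borders -> distance map -> watershed
#' pipeline. The threshold defaults to Otsu's method, which is deterministic;
#' an adaptive local threshold and a manual gray-level threshold are
#' available for micrographs with uneven illumination.
#'
#' @param threshold_method `"otsu"`, `"adaptive"` or `"manual"`.
#' @param manual_threshold gray level; required iff `method = "manual"`.
#' @param pore_polarity `"dark_pores"` (default) or `"bright_pores"`.
#' @param connectivity pixel connectivity for components and border contact,
#'   4 or 8 (default 8).
#' @param marker_smoothing_sigma Gaussian sd (px) applied to the distance
#'   map before marker extraction; suppresses raster noise in the maxima.
#' @param marker_min_separation minimum distance (px) between watershed
#'   markers; local maxima closer than this are merged.
#' @param marker_tolerance depth tolerance (distance-map units, px): pixels
#'   within this of the local maximum join the marker plateau, so a flat
#'   ridge along an elongated pore yields a single marker instead of an
#'   oversegmented chain.
#' @param min_pore_area smallest retained pore, px^2 (default 4, suppresses
#'   noise specks).
#' @param adaptive_window,adaptive_offset window half-width (px) and offset
#'   (gray levels) for the adaptive threshold.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(threshold_method = c("otsu", "adaptive", "manual"),
                       manual_threshold = NULL,
                       pore_polarity = c("dark_pores", "bright_pores"),
                       connectivity = 8,
                       marker_smoothing_sigma = 1,
                       marker_min_separation = 5,
                       marker_tolerance = 1,
                       min_pore_area = 4,
                       adaptive_window = 15,
                       adaptive_offset = 0.01) {
  threshold_method <- match.arg(threshold_method)
  pore_polarity <- match.arg(pore_polarity)
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  if (threshold_method == "manual" && is.null(manual_threshold))
    stop("'manual_threshold' is required for threshold_method = 'manual'")
  if (min_pore_area < 1) stop("'min_pore_area' must be >= 1")
  structure(
    list(threshold_method = threshold_method,
         manual_threshold = manual_threshold,
         pore_polarity = pore_polarity,
         connectivity = as.integer(connectivity),
         marker_smoothing_sigma = marker_smoothing_sigma,
         marker_min_separation = marker_min_separation,
         marker_tolerance = marker_tolerance,
         min_pore_area = min_pore_area,
         adaptive_window = as.integer(adaptive_window),
         adaptive_offset = adaptive_offset),
    class = "seg_config"
  )
}

#' Binarize a micrograph into a pore mask
#'
#' @param img a [micrograph] or numeric matrix.
#' @param cfg a [seg_config()].
#' @return logical H x W mask, `TRUE` = pore phase.
#' @export
binarize <- function(img, cfg = seg_config()) {
  m <- if (inherits(img, "micrograph")) img$pixels else img
  rng <- range(m)
  mask <- switch(cfg$threshold_method,
    manual = {
      if (cfg$pore_polarity == "bright_pores") m > cfg$manual_threshold
      else m < cfg$manual_threshold
    },
    otsu = {
      if (rng[1] == rng[2])
        stop("degenerate histogram: constant image has no Otsu threshold")
      norm <- (m - rng[1]) / (rng[2] - rng[1])
      t_norm <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
      t_val <- t_norm * (rng[2] - rng[1]) + rng[1]
      if (cfg$pore_polarity == "bright_pores") m > t_val else m < t_val
    },
    adaptive = {
      x <- if (cfg$pore_polarity == "bright_pores") m else rng[2] - m
      w <- cfg$adaptive_window
      as_mat(EBImage::thresh(x, w = w, h = w,
                             offset = cfg$adaptive_offset)) > 0.5
    }
  )
  mask <- matrix(as.logical(mask), nrow(m), ncol(m))
  mask
}

#' Remove pore components touching the image border
#'
#' Pores cut by the field-of-view edge have truncated areas and would
#' distort the size distribution, so every connected component touching any
#' border is deleted. Idempotent.
#'
#' @param mask logical pore mask.
#' @param connectivity 4 or 8.
#' @return logical mask with border components removed.
#' @export
clear_border_pores <- function(mask, connectivity = 8) {
  if (!any(mask)) return(mask)
  lab <- .cc_label(mask, as.integer(connectivity))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) mask[lab %in% border] <- FALSE
  mask
}

#' Extract watershed markers from the distance map
#'
#' Computes the Euclidean distance transform of the pore phase, smooths it,
#' and takes local maxima (within `marker_tolerance` of the neighbourhood
#' maximum over a disc of radius `marker_min_separation`) as marker
#' plateaus. Plateau components whose centroids are closer than the minimum
#' separation are merged, highest peak first.
#'
#' @inheritParams clear_border_pores
#' @param cfg a [seg_config()].
#' @return list with `markers` (integer matrix, 0 = none) and `dist`
#'   (smoothed distance map used for flooding).
#' @export
pore_markers <- function(mask, cfg = seg_config()) {
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask))
    return(list(markers = matrix(0L, H, W), dist = matrix(0, H, W)))
  d <- as_mat(EBImage::distmap(mask, metric = "euclidean"))
  ds <- if (cfg$marker_smoothing_sigma > 0)
    as_mat(EBImage::gblur(d, sigma = cfg$marker_smoothing_sigma)) else d
  ds[!mask] <- 0
  sep <- cfg$marker_min_separation
  size <- 2L * as.integer(ceiling(sep)) + 1L
  localmax <- as_mat(EBImage::dilate(ds, EBImage::makeBrush(size, "disc")))
  cand <- mask & ds > 0 & ds >= localmax - cfg$marker_tolerance
  comp <- .cc_label(cand, 8L)
  n <- max(comp)
  if (n == 0) return(list(markers = matrix(0L, H, W), dist = ds))
  idx <- which(comp > 0)
  rc <- arrayInd(idx, dim(comp))
  labs <- comp[idx]
  peak <- vapply(split(ds[idx], labs), max, numeric(1))
  cen_r <- vapply(split(rc[, 1], labs), mean, numeric(1))
  cen_c <- vapply(split(rc[, 2], labs), mean, numeric(1))
  ord <- order(-peak, as.integer(names(peak)))
  keep <- integer(0)           # component ids kept as distinct markers
  remap <- integer(n)          # component id -> component id it merges into
  for (i in ord) {
    if (length(keep)) {
      dd <- sqrt((cen_r[keep] - cen_r[i])^2 + (cen_c[keep] - cen_c[i])^2)
      j <- which(dd < sep)
      if (length(j)) { remap[i] <- keep[j[which.min(dd[j])]]; next }
    }
    keep <- c(keep, i)
    remap[i] <- i
  }
  markers <- matrix(0L, H, W)
  markers[idx] <- remap[labs]
  list(markers = markers, dist = ds)
}

# Relabel regions 1..N canonically: by raster order (row-major) of each
# region's first pixel. Makes the labeling deterministic for testing.
canonical_relabel <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(lab)
  rc <- arrayInd(idx, dim(lab))
  raster <- (rc[, 1] - 1) * ncol(lab) + rc[, 2]
  first <- vapply(split(raster, lab[idx]), min, numeric(1))
  old <- as.integer(names(first))
  new <- integer(max(old))
  new[old[order(first)]] <- seq_along(old)
  out <- lab
  out[idx] <- new[lab[idx]]
  out
}

#' Label pores by marker-based watershed on the distance map
#'
#' Floods the smoothed Euclidean distance map from the extracted markers,
#' restricted to the pore phase, so fused pores separated by a distance-map
#' waist are split while elongated single pores stay whole. Regions smaller
#' than `min_pore_area` are discarded; labels are canonical (raster order).
#'
#' @param mask logical pore mask, border-cleared.
#' @param cfg a [seg_config()].
#' @return integer H x W label matrix, 0 = wall, 1..N = pores, with
#'   attribute `n` = N.
#' @export
label_pores_watershed <- function(mask, cfg = seg_config()) {
  mk <- pore_markers(mask, cfg)
  if (max(mk$markers) == 0) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "n") <- 0L
    return(out)
  }
  lab <- .ws_flood(mk$dist, mk$markers, mask, cfg$connectivity)
  if (cfg$min_pore_area > 1) {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes > 0 & sizes < cfg$min_pore_area)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  lab <- canonical_relabel(lab)
  attr(lab, "n") <- max(lab)
  lab
}

#' Full pore segmentation: binarize, clear borders, watershed
#'
#' @param img a [micrograph] or numeric matrix.
#' @param cfg a [seg_config()].
#' @return integer label matrix as in [label_pores_watershed()], with an
#'   additional attribute `stage_counts` logging pixel/pore counts after
#'   each stage.
#' @export
segment_pores <- function(img, cfg = seg_config()) {
  mask <- binarize(img, cfg)
  cleared <- clear_border_pores(mask, cfg$connectivity)
  lab <- label_pores_watershed(cleared, cfg)
  attr(lab, "stage_counts") <- list(
    mask_px = sum(mask),
    cleared_px = sum(cleared),
    n_pores = attr(lab, "n"))
  lab
}
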