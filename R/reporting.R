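#' Join per-ROI structure and kinetics into one comparison table
#'
#' One row per ROI with its pore-structure means and local front velocity.
#' ROIs measured in different fields of view are not comparable (their mass
#' transfer path lengths differ), so mixing image identifiers is an error.
#'
#' @param records_by_roi named list of [pore_records()] data frames, one per
#'   ROI.
#' @param velocity_by_roi named list of [velocity_trace()] results with
#'   matching names.
#' @param min_n rows with fewer pores than this are flagged
#'   (`low_sample = TRUE`); default 30.
#' @return data frame of class `roi_comparison`: `roi`, `n_pores`,
#'   `mean_pore_size_um`, `mean_shape_factor`, `mean_orientation_deg`,
#'   `mean_velocity_um_min`, `low_sample`.
#' @export
roi_compare <- function(records_by_roi, velocity_by_roi, min_n = 30) {
  ids <- union(names(records_by_roi), names(velocity_by_roi))
  if (is.null(names(records_by_roi)) || is.null(names(velocity_by_roi)))
    stop("both inputs must be named lists keyed by ROI id")
  for (id in ids) {
    if (is.null(records_by_roi[[id]]))
      stop("ROI '", id, "' has no pore records")
    if (is.null(velocity_by_roi[[id]]))
      stop("ROI '", id, "' has no velocity estimate")
    if (nrow(records_by_roi[[id]]) < 1)
      stop("ROI '", id, "' has zero pore records")
  }
  imgs <- c(
    lapply(records_by_roi, attr, "image_id"),
    lapply(velocity_by_roi, function(v) v$image_id))
  imgs <- unique(unlist(imgs[!vapply(imgs, is.null, logical(1))]))
  if (length(imgs) > 1)
    stop("ROIs come from different images (", paste(imgs, collapse = ", "),
         "); only ROIs within one field of view are comparable")
  rows <- lapply(ids, function(id) {
    r <- records_by_roi[[id]]
    data.frame(roi = id, n_pores = nrow(r),
               mean_pore_size_um = mean(r$eq_diameter_um),
               mean_shape_factor = mean(r$aspect_ratio),
               mean_orientation_deg = mean(r$orientation_deg),
               mean_velocity_um_min = velocity_by_roi[[id]]$mean_velocity,
               low_sample = nrow(r) < min_n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!is.finite(as.matrix(out[, 3:6]))))
    stop("non-finite ROI means")
  attr(out, "image_id") <- if (length(imgs)) imgs else NULL
  attr(out, "single_roi") <- length(ids) == 1
  class(out) <- c("roi_comparison", "data.frame")
  out
}

#' Spiderweb (radar) diagram data
#'
#' Min-max normalizes each metric across the compared ROIs to `[0, 1]` for
#' a joint radar display of pore size, shape, orientation and front
#' velocity. Metrics constant across ROIs carry no contrast; they map to
#' 0.5 and are flagged. Idempotent: normalizing an already-normalized table
#' reproduces it.
#'
#' @param cmp a `roi_comparison` from [roi_compare()].
#' @return data frame with the same metric columns, values normalized to
#'   `[0, 1]`; attributes `degenerate` (names of constant metrics) and
#'   `normalized = TRUE`.
#' @export
spiderweb_data <- function(cmp) {
  metrics <- c("mean_pore_size_um", "mean_shape_factor",
               "mean_orientation_deg", "mean_velocity_um_min")
  out <- cmp[, c("roi", metrics), drop = FALSE]
  degen <- character(0)
  for (mcol in metrics) {
    v <- out[[mcol]]
    rng <- range(v)
    if (diff(rng) < .Machine$double.eps^0.5) {
      out[[mcol]] <- rep(0.5, length(v))
      degen <- c(degen, mcol)
    } else out[[mcol]] <- (v - rng[1]) / diff(rng)
  }
  out <- as.data.frame(out)
  rownames(out) <- NULL
  attr(out, "degenerate") <- degen
  attr(out, "normalized") <- TRUE
  out
}

#' Condition-level report across replicate runs
#'
#' Aggregates run-level structure summaries and primary drying times per
#' freezing condition (sugar type, solid concentration, cooling rate):
#' unweighted means across the replicate runs with Student-t confidence
#' intervals over run means (half-width `NA` for a single run).
#'
#' @param runs list of runs; each run is a list with elements `condition`
#'   (list with `sugar`, `concentration_ww`, `cooling_rate_K_min`),
#'   `summary` (a [summarize_pores()] result) and `drying_time_min`.
#' @param confidence confidence level (default 0.95).
#' @return data frame with one row per condition: `sugar`,
#'   `concentration_ww`, `cooling_rate_K_min`, `pore_size_um`,
#'   `pore_size_ci`, `shape_factor`, `shape_factor_ci`, `drying_time_min`,
#'   `n_runs`.
#' @export
condition_report <- function(runs, confidence = 0.95) {
  if (length(runs) < 1) stop("need at least one run")
  key <- vapply(runs, function(r)
    paste(r$condition$sugar, r$condition$concentration_ww,
          r$condition$cooling_rate_K_min, sep = "|"), character(1))
  rows <- lapply(split(seq_along(runs), key), function(i) {
    cond <- runs[[i[1]]]$condition
    ps <- vapply(runs[i], function(r) r$summary$mean_pore_size_um,
                 numeric(1))
    sf <- vapply(runs[i], function(r) r$summary$mean_shape_factor,
                 numeric(1))
    dt <- vapply(runs[i], function(r) r$drying_time_min, numeric(1))
    data.frame(sugar = cond$sugar,
               concentration_ww = cond$concentration_ww,
               cooling_rate_K_min = cond$cooling_rate_K_min,
               pore_size_um = mean(ps),
               pore_size_ci = t_ci_halfwidth(ps, confidence),
               shape_factor = mean(sf),
               shape_factor_ci = t_ci_halfwidth(sf, confidence),
               drying_time_min = mean(dt),
               n_runs = length(i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sugar, out$concentration_ww, out$cooling_rate_K_min), ,
      drop = FALSE]
}
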