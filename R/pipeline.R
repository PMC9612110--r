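#' Load and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent named list) with top-level
#' keys: `pixel_scale` (um/px, required), `travel_direction` (required),
#' `frame_interval` (s, default 60), `seed` (default 1), optional
#' `segmentation` and `detection` parameter blocks (arguments of
#' [seg_config()] / [detect_config()]), an optional `rois` list (each with
#' `id`, `rows`, `cols`), and either a `synth` block (`field` =
#' [microstructure_spec()] arguments, `kinetics` = [front_kinetics_spec()]
#' arguments) or an `inputs` block (`image`, optionally `frames_dir`).
#' Validation happens before any stage runs; all offending keys are listed
#' in one error.
#'
#' @param x path to a YAML file or a named list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a YAML file or a named list")
  problems <- character(0)
  if (is.null(cfg$pixel_scale) || !is.numeric(cfg$pixel_scale) ||
      cfg$pixel_scale <= 0)
    problems <- c(problems, "pixel_scale: required positive number (um/px)")
  if (is.null(cfg$travel_direction) ||
      !cfg$travel_direction %in% c("+x", "-x", "+y", "-y"))
    problems <- c(problems,
                  "travel_direction: required, one of +x,-x,+y,-y")
  if (is.null(cfg$frame_interval)) cfg$frame_interval <- 60
  if (cfg$frame_interval <= 0)
    problems <- c(problems, "frame_interval: must be > 0 s")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$synth) && is.null(cfg$inputs))
    problems <- c(problems, "synth or inputs: one block is required")
  if (!is.null(cfg$rois)) {
    for (i in seq_along(cfg$rois)) {
      r <- cfg$rois[[i]]
      if (is.null(r$id) || is.null(r$rows) || is.null(r$cols))
        problems <- c(problems,
                      sprintf("rois[%d]: needs id, rows, cols", i))
    }
  }
  if (length(problems))
    stop("invalid pipeline config:\n  ",
         paste(problems, collapse = "\n  "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Every output table carries the config hash and package version.
write_table <- function(df, path, config_hash) {
  df$config_hash <- config_hash
  df$package_version <- as.character(utils::packageVersion("lyomorph"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

roi_from_cfg <- function(r) roi(r$id, unlist(r$rows), unlist(r$cols))

# Segment within an ROI the way the reference workflow does: crop the image
# to the ROI rectangle so that border clearing removes pores cut by the ROI
# edge, then measure inside the crop.
segment_roi <- function(pixels, r, scfg) {
  crop <- pixels[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2], drop = FALSE]
  segment_pores(crop, scfg)
}

#' Run the full pipeline from one configuration
#'
#' Executes synth (optional) -> segment -> pores -> front -> report, writes
#' every stage's outputs under `out_dir`, and logs an md5 hash of each
#' written file together with the config echo. All randomness derives from
#' the config seed via [derive_seed()], so a rerun with the same config is
#' byte-identical.
#'
#' @param config a [pipeline_config()], a named list, or a YAML path.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list with the key result objects and `files`, the
#'   hash log of written outputs.
#' @export
run_all <- function(config, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(cfg)
  write_json_file(c(unclass(cfg), list(config_hash = chash)),
                  file.path(out_dir, "config_echo.json"))

  scfg <- do.call(seg_config, as.list(cfg$segmentation))
  dcfg <- do.call(detect_config, as.list(cfg$detection))
  rois <- lapply(cfg$rois, roi_from_cfg)
  names(rois) <- vapply(rois, `[[`, character(1), "id")

  # --- synth ---------------------------------------------------------
  frames <- NULL
  if (!is.null(cfg$synth)) {
    sargs <- as.list(cfg$synth$field)
    sargs$pixel_scale <- cfg$pixel_scale
    sargs$seed <- derive_seed(cfg$seed, "synth")
    if (!is.null(sargs$canvas)) sargs$canvas <- unlist(sargs$canvas)
    spec <- do.call(microstructure_spec, sargs)
    field <- generate_pore_field(spec)
    kargs <- as.list(cfg$synth$kinetics)
    kargs$travel_direction <- cfg$travel_direction
    kargs$frame_interval <- cfg$frame_interval
    kargs$seed <- derive_seed(cfg$seed, "synth")
    kin <- do.call(front_kinetics_spec, kargs)
    tl <- generate_timelapse(field, kin)
    frames <- tl$frames
    write_image(field$image$pixels, file.path(out_dir, "dried.tif"))
    write_table(field$truth, file.path(out_dir, "ground_truth_pores.csv"),
                chash)
    write_table(
      data.frame(column = seq_along(tl$truth$velocity_um_min),
                 velocity_um_min = tl$truth$velocity_um_min),
      file.path(out_dir, "ground_truth_front.csv"), chash)
    write_frame_sequence(frames, file.path(out_dir, "frames"))
    image <- field$image
    image_id <- "synthetic"
  } else {
    image <- read_micrograph(cfg$inputs$image, cfg$pixel_scale)
    image_id <- basename(cfg$inputs$image)
    if (!is.null(cfg$inputs$frames_dir))
      frames <- read_frame_sequence(cfg$inputs$frames_dir)
  }

  # --- segment -------------------------------------------------------
  labels <- segment_pores(image, scfg)
  write_labels(labels, file.path(out_dir, "labels.tif"))
  write_json_file(attr(labels, "stage_counts"),
                  file.path(out_dir, "segment_log.json"))

  # --- pores ---------------------------------------------------------
  records <- pore_records(labels, cfg$pixel_scale, cfg$travel_direction,
                          image_id = image_id)
  write_table(records, file.path(out_dir, "pores.csv"), chash)
  if (nrow(records) > 0) {
    summ <- summarize_pores(records)
    write_json_file(as.list(summ), file.path(out_dir, "summary.json"))
  } else summ <- NULL
  records_by_roi <- lapply(rois, function(r) {
    lab <- segment_roi(image$pixels, r, scfg)
    pore_records(lab, cfg$pixel_scale, cfg$travel_direction,
                 image_id = image_id)
  })

  # --- front ---------------------------------------------------------
  velocity <- NULL
  velocity_by_roi <- list()
  if (!is.null(frames)) {
    velocity <- velocity_trace(frames, cfg$travel_direction, roi = NULL,
                               cfg = dcfg, image_id = image_id)
    velocity_by_roi <- lapply(rois, function(r)
      velocity_trace(frames, cfg$travel_direction, roi = r, cfg = dcfg,
                     image_id = image_id))
    write_table(
      data.frame(time_s = velocity$times_s,
                 mean_position_um = velocity$mean_positions_um),
      file.path(out_dir, "front_trace.csv"), chash)
    write_json_file(
      list(mean_velocity_um_min = velocity$mean_velocity,
           ci_halfwidth = velocity$ci_halfwidth,
           n_intervals = velocity$n_intervals,
           interval_velocities = velocity$interval_velocities),
      file.path(out_dir, "velocity.json"))
  }

  # --- report --------------------------------------------------------
  cmp <- NULL; web <- NULL
  if (length(rois) && length(velocity_by_roi)) {
    cmp <- roi_compare(records_by_roi, velocity_by_roi)
    write_table(as.data.frame(cmp), file.path(out_dir, "roi_comparison.csv"),
                chash)
    web <- spiderweb_data(cmp)
    write_table(web, file.path(out_dir, "spiderweb.csv"), chash)
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "hashes.json"]
  hashes <- as.list(tools::md5sum(sort(files)))
  names(hashes) <- substring(names(hashes), nchar(out_dir) + 2)
  write_json_file(hashes, file.path(out_dir, "hashes.json"))

  invisible(list(labels = labels, records = records, summary = summ,
                 velocity = velocity, records_by_roi = records_by_roi,
                 velocity_by_roi = velocity_by_roi, comparison = cmp,
                 spiderweb = web, config_hash = chash, files = hashes))
}
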