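# End-to-end orchestration: configuration, per-plant extraction, cohort
# statistics, decay curves, superposition, and a reproducibility manifest.

config_defaults <- function() {
  list(input_dir = NULL, output_dir = "roottrack_out",
       px_mm = NULL, frame_interval_min = 15,
       groups = NULL,                 # named list/vector plant_id -> group
       control_group = NULL,
       distance_mm = 2,               # emergence-angle traversal
       prune_len_mm = 0.3, min_lr_len_mm = 0.5,
       seed_attach_radius_px = 20, smooth_window = 5,
       radius_px = 10, min_track_frames = 4,
       alpha = 0.05, min_n = 3, fdr = FALSE,
       hull_hour = 0,                 # daily evaluation hour (lights-on)
       seed = 1L, verbose = FALSE)
}

#' Pipeline configuration
#'
#' Builds a validated configuration from a YAML file and/or explicit
#' overrides. Unknown keys are rejected; every effective value is echoed to
#' the run manifest.
#'
#' @param file Optional YAML file of key-value settings.
#' @param ... Explicit overrides (take precedence over the file).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- config_defaults()
  from_file <- if (!is.null(file)) yaml::read_yaml(file) else list()
  overrides <- list(...)
  for (src in list(from_file, overrides)) {
    bad <- setdiff(names(src), names(cfg))
    if (length(bad) > 0)
      stop("pipeline_config: unknown key(s): ", paste(bad, collapse = ", "))
    cfg[names(src)] <- src
  }
  num_pos <- c("px_mm", "distance_mm", "prune_len_mm", "min_lr_len_mm",
               "seed_attach_radius_px", "radius_px", "frame_interval_min")
  for (k in num_pos) {
    v <- cfg[[k]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop("pipeline_config: ", k, " must be a positive number")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("pipeline_config: alpha must be in (0, 1)")
  if (60 %% cfg$frame_interval_min != 0)
    stop("pipeline_config: frame_interval_min must divide 60")
  structure(cfg, class = "pipeline_config")
}

#' Extract all per-plant results from a mask series
#'
#' Decomposes every frame, builds LR tracks, evaluates angles and assembles
#' the hourly feature table for one plant.
#'
#' @param frames List of `mask_frame` objects (one plant, time-sorted).
#' @param config A [pipeline_config()] (defaults used when omitted).
#' @return List: `frames_rsf` (decompositions), `tracks`, `angles`
#'   (angle records), `features` (hourly feature table).
#' @export
extract_plant <- function(frames, config = pipeline_config()) {
  rsfs <- lapply(frames, function(f)
    tryCatch(root_system_frame(f,
                               prune_len_mm = config$prune_len_mm,
                               seed_attach_radius_px =
                                 config$seed_attach_radius_px,
                               min_lr_len_mm = config$min_lr_len_mm,
                               smooth_window = config$smooth_window),
             error = function(e) NULL))
  dropped <- sum(vapply(rsfs, is.null, logical(1)))
  if (dropped > 0)
    warning("extract_plant: ", dropped,
            " frame(s) without a measurable root skipped")
  rsfs <- Filter(Negate(is.null), rsfs)
  if (length(rsfs) == 0) stop("extract_plant: no measurable frames")
  tracks <- build_tracks(rsfs, radius_px = config$radius_px,
                         min_track_frames = config$min_track_frames)
  pid <- frames[[1]]$plant_id
  ang <- angle_records(tracks, plant_id = pid,
                       distance_mm = config$distance_mm)
  feat <- feature_table(rsfs)
  list(frames_rsf = rsfs, tracks = tracks, angles = ang, features = feat)
}

#' Run the full pipeline
#'
#' Per plant: skeletonize, decompose, track, measure angles, aggregate
#' hourly metrics and daily hull metrics; then cohort statistics, first-LR
#' decay curves and the superposition map. All outputs are written as CSV
#' (and the superposition as PNG) under `config$output_dir`, together with
#' a manifest (config echo, package version, seed, warnings) that fully
#' determines the outputs. A plant that fails is reported and excluded;
#' the pipeline fails only if every plant fails.
#'
#' @param plants Named list: plant_id -> list of `mask_frame` objects.
#'   Alternatively `NULL`, in which case `config$input_dir` is scanned for
#'   per-plant subdirectories readable by [load_mask_series()].
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `features`, `angles`, `stats`, `decay`,
#'   `hulls`, `superposition`, `manifest`.
#' @export
run_pipeline <- function(plants = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (is.null(plants)) {
    if (is.null(config$input_dir))
      stop("run_pipeline: no plants and no input_dir configured")
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    plants <- lapply(dirs, load_mask_series, px_mm = config$px_mm,
                     frame_interval_min = config$frame_interval_min)
    names(plants) <- basename(dirs)
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)

  results <- list()
  for (pid in names(plants)) {
    res <- withCallingHandlers(
      tryCatch(extract_plant(plants[[pid]], config),
               error = function(e) e),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(pid, ": ",
                                                conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      warnings_log <- c(warnings_log,
                        paste0(pid, ": FAILED: ", conditionMessage(res)))
      next
    }
    results[[pid]] <- res
  }
  if (length(results) == 0) stop("run_pipeline: all plants failed")

  group_of <- function(pid) {
    if (is.null(config$groups)) "all" else
      as.character(config$groups[[pid]])
  }
  features <- do.call(rbind, lapply(names(results), function(pid) {
    f <- results[[pid]]$features
    f$group <- group_of(pid)
    f
  }))
  angles <- do.call(rbind, lapply(results, `[[`, "angles"))

  # daily hull metrics at the configured evaluation hour
  hulls <- do.call(rbind, lapply(names(results), function(pid) {
    fr <- plants[[pid]]
    ts <- vapply(fr, `[[`, numeric(1), "timestamp_h")
    sel <- which(ts %% 24 == config$hull_hour %% 24)
    if (length(sel) == 0) return(NULL)
    do.call(rbind, lapply(sel, function(i) {
      feat <- results[[pid]]$features
      hr <- floor(ts[i])
      row <- feat[feat$hour == hr, , drop = FALSE]
      hm <- frame_hull_metrics(fr[[i]],
                               mr_len_mm = if (nrow(row)) row$mr_len_mm
                                           else NA_real_,
                               lr_len_mm = if (nrow(row)) row$lr_len_mm
                                           else NA_real_,
                               tr_len_mm = if (nrow(row)) row$tr_len_mm
                                           else NA_real_)
      hm$plant_id <- pid
      hm$day <- floor(ts[i] / 24)
      hm
    }))
  }))

  stats <- NULL
  if (!is.null(config$groups) && !is.null(config$control_group)) {
    stats <- timeseries_compare(features, control = config$control_group,
                                alpha = config$alpha, min_n = config$min_n,
                                fdr = config$fdr)
  }
  decay <- first_lr_decay_curve(angles)

  sup <- NULL
  sup_in <- lapply(names(results), function(pid) {
    fr <- plants[[pid]]
    rsf <- results[[pid]]$frames_rsf
    if (length(rsf) == 0) return(NULL)
    last_rsf <- rsf[[length(rsf)]]
    ch <- last_rsf$mr$chain
    if (is.null(ch)) return(NULL)
    # mask frame matching the last measurable decomposition
    ts <- vapply(fr, `[[`, numeric(1), "timestamp_h")
    k <- which.min(abs(ts - last_rsf$timestamp_h))
    list(mask = fr[[k]]$mask, mr_start = ch[1, ], mr_end = ch[nrow(ch), ])
  })
  sup_in <- Filter(Negate(is.null), sup_in)
  if (length(sup_in) > 0) sup <- superposition_map(sup_in)

  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(angles, file.path(out_dir, "angles.csv"), row.names = FALSE)
  if (!is.null(hulls))
    write.csv(hulls, file.path(out_dir, "hulls.csv"), row.names = FALSE)
  if (!is.null(stats))
    write.csv(stats, file.path(out_dir, "stats.csv"), row.names = FALSE)
  write.csv(decay$cohort, file.path(out_dir, "first_lr_decay.csv"),
            row.names = FALSE)
  if (!is.null(sup))
    write_superposition_png(sup, file.path(out_dir, "superposition.png"))

  manifest <- list(
    package = "roottrack",
    version = as.character(utils::packageVersion("roottrack")),
    config = unclass(config),
    n_plants = length(results),
    plants = names(results),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = features, angles = angles, stats = stats,
                 decay = decay, hulls = hulls, superposition = sup,
                 manifest = manifest))
}
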