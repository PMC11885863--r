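# Mask frames: one timestamped binary segmentation image plus calibration.

#' Construct a mask frame
#'
#' @param mask Integer/logical matrix; values must be 0/1 (or FALSE/TRUE).
#' @param timestamp_h Hours since sowing (or since imaging start).
#' @param px_mm Image scale, mm per pixel (> 0).
#' @param plant_id Plant identifier.
#' @param seed_point Pixel (row, col) at or near the seed / MR start.
#' @return Object of class `mask_frame`.
#' @export
mask_frame <- function(mask, timestamp_h, px_mm, plant_id = "plant",
                       seed_point) {
  if (is.logical(mask)) mask <- mask + 0L
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L)))
    stop("mask_frame: mask must be binary (0/1)")
  if (!is.numeric(px_mm) || px_mm <= 0) stop("mask_frame: px_mm must be > 0")
  if (length(seed_point) != 2) stop("mask_frame: seed_point must be (row, col)")
  structure(list(mask = mask, timestamp_h = as.numeric(timestamp_h),
                 px_mm = px_mm, plant_id = plant_id,
                 seed_point = as.numeric(seed_point)),
            class = "mask_frame")
}

#' @export
print.mask_frame <- function(x, ...) {
  cat(sprintf("mask_frame %s t=%.2fh %dx%d px (%.3f mm/px), %d foreground\n",
              x$plant_id, x$timestamp_h, nrow(x$mask), ncol(x$mask),
              x$px_mm, sum(x$mask)))
  invisible(x)
}

# read one image file as a binary matrix (values > 0.5 are foreground)
read_mask_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  (img > 0.5) + 0L
}

#' Load a time series of mask frames
#'
#' Reads a directory of numbered PNG/TIFF masks (or a single multi-page
#' TIFF). Frames are ordered by the number embedded in the filename, and
#' timestamps are `index * frame_interval_min / 60` hours. Unreadable frames
#' are skipped with a warning.
#'
#' @param path Directory of numbered images, or one multi-page TIFF file.
#' @param px_mm Image scale, mm per pixel.
#' @param frame_interval_min Capture interval in minutes.
#' @param plant_id Plant identifier attached to every frame.
#' @param seed_point Pixel (row, col) of the seed; if `NULL` and the
#'   directory contains `plant.json`, it is read from there.
#' @return List of `mask_frame` objects, time-sorted.
#' @export
load_mask_series <- function(path, px_mm = NULL, frame_interval_min = 15,
                             plant_id = NULL, seed_point = NULL) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "plant.json")
    if (file.exists(meta_path)) {
      meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
      if (is.null(px_mm)) px_mm <- meta$px_mm
      if (is.null(seed_point)) seed_point <- meta$seed_point
      if (is.null(plant_id)) plant_id <- meta$plant_id
      if (!is.null(meta$frame_interval_min))
        frame_interval_min <- meta$frame_interval_min
    }
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stop("load_mask_series: no mask images in ", path)
    num <- as.numeric(gsub("\\D", "", basename(files)))
    files <- files[order(num)]
    imgs <- vector("list", length(files))
    keep <- logical(length(files))
    for (i in seq_along(files)) {
      img <- tryCatch(read_mask_image(files[i]), error = function(e) NULL)
      if (is.null(img)) {
        warning("load_mask_series: skipping unreadable frame ",
                basename(files[i]))
      } else {
        imgs[[i]] <- img
        keep[i] <- TRUE
      }
    }
    idx <- which(keep)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    imgs <- lapply(pages, function(img) {
      if (length(dim(img)) == 3) img <- img[, , 1]
      (img > 0.5) + 0L
    })
    idx <- seq_along(imgs)
    keep <- rep(TRUE, length(imgs))
  } else stop("load_mask_series: path not found: ", path)
  if (!any(keep)) stop("load_mask_series: zero readable frames")
  if (is.null(px_mm)) stop("load_mask_series: px_mm not given and no sidecar")
  if (is.null(plant_id)) plant_id <- basename(path)
  frames <- lapply(idx, function(i) {
    sp <- seed_point
    if (is.null(sp)) {
      # default: topmost foreground pixel of the first frame
      fg <- which(imgs[[i]] == 1L, arr.ind = TRUE)
      sp <- fg[which.min(fg[, 1]), ]
    }
    mask_frame(imgs[[i]], timestamp_h = (i - 1) * frame_interval_min / 60,
               px_mm = px_mm, plant_id = plant_id, seed_point = sp)
  })
  frames
}
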