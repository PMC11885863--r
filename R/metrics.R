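# Scalar feature catalogue per plant per hour: lengths, counts, densities,
# growth speeds, spectral features of the speeds, and convex-hull geometry.

#' Per-frame scalar metrics
#'
#' Applies the standard formulas to one frame decomposition:
#' TR = MR + sum(LR); LR density = LR length / MR length (mm/mm); discrete
#' LR density = 10 x n_LR / MR length (LRs/cm); MR over TR = MR / TR.
#' When the MR length is zero the lengths are still reported but densities
#' and the ratio are `NA`.
#'
#' @param rsf A `root_system_frame`.
#' @return One-row tibble: plant_id, timestamp_h, mr_len_mm, lr_len_mm,
#'   tr_len_mm, n_lr, lr_density, discrete_lr_density, mr_over_tr.
#' @export
frame_metrics <- function(rsf) {
  stopifnot(inherits(rsf, "root_system_frame"))
  mr <- rsf$mr$length_mm
  lr <- sum(vapply(rsf$lrs, `[[`, numeric(1), "length_mm"))
  n <- length(rsf$lrs)
  tr <- mr + lr
  dens <- if (mr > 0) lr / mr else NA_real_
  disc <- if (mr > 0) 10 * n / mr else NA_real_
  ratio <- if (mr > 0) mr / tr else NA_real_
  tibble::tibble(plant_id = rsf$plant_id, timestamp_h = rsf$timestamp_h,
                 mr_len_mm = mr, lr_len_mm = lr, tr_len_mm = tr,
                 n_lr = n, lr_density = dens, discrete_lr_density = disc,
                 mr_over_tr = ratio)
}

#' Average a 15-minute-cadence series to one value per hour
#'
#' Each clock hour's value is the mean of the frames falling in
#' `[h, h + 1)`; hours with no frames are absent from the output (missing
#' is propagated, never interpolated).
#'
#' @param df Data frame with a `timestamp_h` column.
#' @param cols Columns to average (default: all numeric except
#'   `timestamp_h`).
#' @return Tibble with `hour` plus the hourly means (grouped by `plant_id`
#'   when present).
#' @export
hourly_aggregate <- function(df, cols = NULL) {
  stopifnot(is.data.frame(df), "timestamp_h" %in% names(df))
  if (is.null(cols))
    cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                    c("timestamp_h", "hour"))
  hour <- floor(df$timestamp_h)
  by <- list(hour = hour)
  if ("plant_id" %in% names(df)) by <- c(list(plant_id = df$plant_id), by)
  agg <- aggregate(df[cols], by = by, FUN = mean, na.rm = TRUE)
  agg[is.na(agg)] <- NA            # normalize NaN from all-NA cells
  out <- tibble::as_tibble(agg)
  ord <- if ("plant_id" %in% names(out)) order(out$plant_id, out$hour)
         else order(out$hour)
  out[ord, , drop = FALSE]
}

#' Growth speeds from an hourly length series
#'
#' Finite differences of length against time: central differences on
#' interior points, forward/backward at the ends. Negative speeds (length
#' can only grow; dips are segmentation noise) are clipped to zero; the raw
#' differences are kept in `raw_speed`.
#'
#' @param hour Hour stamps (numeric, increasing).
#' @param length_mm Hourly lengths.
#' @return Tibble: hour, speed_mm_h (clipped), raw_speed_mm_h, with the
#'   number of clipped points as attribute `n_clipped`.
#' @export
growth_speeds <- function(hour, length_mm) {
  n <- length(hour)
  stopifnot(n == length(length_mm), n >= 2)
  sp <- numeric(n)
  sp[1] <- (length_mm[2] - length_mm[1]) / (hour[2] - hour[1])
  sp[n] <- (length_mm[n] - length_mm[n - 1]) / (hour[n] - hour[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    sp[i] <- (length_mm[i + 1] - length_mm[i - 1]) / (hour[i + 1] - hour[i - 1])
  }
  clipped <- sum(sp < 0, na.rm = TRUE)
  out <- tibble::tibble(hour = hour, speed_mm_h = pmax(sp, 0),
                        raw_speed_mm_h = sp)
  attr(out, "n_clipped") <- clipped
  out
}

#' Amplitude spectrum of a detrended, normalized speed series
#'
#' Detrends by subtracting a centred 24-h moving average (window shrinks
#' near the edges), normalizes to unit variance, linearly interpolates
#' missing points (count kept as attribute `n_interpolated`), and returns
#' the discrete-Fourier-transform amplitude spectrum on the one-sided
#' frequency grid `k / (N * dt)`.
#'
#' @param speed Hourly speed series (mm/h), possibly with `NA`s.
#' @param dt_h Sampling interval in hours (default 1).
#' @param detrend_window_h Moving-average window (default 24).
#' @return Tibble: freq_per_h, amplitude.
#' @export
spectral_features <- function(speed, dt_h = 1, detrend_window_h = 24) {
  n <- length(speed)
  stopifnot(n >= 2)
  x <- speed
  n_int <- sum(!is.finite(x))
  if (n_int > 0) {
    idx <- seq_len(n)
    ok <- is.finite(x)
    if (sum(ok) < 2) stop("spectral_features: too few finite points")
    x <- stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
  }
  w <- max(3, round(detrend_window_h / dt_h))
  trend <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - w %/% 2); hi <- min(n, i + w %/% 2)
    mean(x[lo:hi])
  }, numeric(1))
  x <- x - trend
  s <- sd(x)
  if (s > 0) x <- x / s       # all-constant series stays a zero vector
  sp <- abs(fft(x)) / n
  k <- 0:(n %/% 2)
  out <- tibble::tibble(freq_per_h = k / (n * dt_h), amplitude = sp[k + 1])
  attr(out, "n_interpolated") <- n_int
  out
}

# shoelace area of an ordered polygon (matrix x, y)
shoelace_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

#' Convex-hull geometry of a root system
#'
#' Convex hull of the foreground coordinates (mm): area by the shoelace
#' formula over the hull vertices, width/height as the bounding-box extents
#' of the hull, aspect ratio = height / width, and MR/LR/TR length per hull
#' area. Degenerate inputs (fewer than 3 points, or collinear) give area 0
#' and `NA` densities; zero width gives `NA` aspect ratio.
#'
#' @param points_mm Matrix (x, y) of root coordinates in mm.
#' @param mr_len_mm,lr_len_mm,tr_len_mm Lengths used for the area densities
#'   (optional; `NA` densities when missing).
#' @return One-row tibble: hull_area_mm2, hull_width_mm, hull_height_mm,
#'   aspect_ratio, mr_area_density, lr_area_density, tr_area_density.
#' @export
hull_metrics <- function(points_mm, mr_len_mm = NA_real_,
                         lr_len_mm = NA_real_, tr_len_mm = NA_real_) {
  points_mm <- as.matrix(points_mm)
  if (nrow(points_mm) == 0)
    stop("hull_metrics: no points")
  w <- diff(range(points_mm[, 1]))
  h <- diff(range(points_mm[, 2]))
  area <- 0
  if (nrow(points_mm) >= 3) {
    hull <- grDevices::chull(points_mm[, 1], points_mm[, 2])
    area <- shoelace_area(points_mm[hull, , drop = FALSE])
  }
  dens <- function(len) if (area > 0 && is.finite(len)) len / area
                        else NA_real_
  tibble::tibble(hull_area_mm2 = area, hull_width_mm = w, hull_height_mm = h,
                 aspect_ratio = if (w > 0) h / w else NA_real_,
                 mr_area_density = dens(mr_len_mm),
                 lr_area_density = dens(lr_len_mm),
                 tr_area_density = dens(tr_len_mm))
}

#' Hull metrics of a mask frame
#'
#' @param frame A `mask_frame`.
#' @param mr_len_mm,lr_len_mm,tr_len_mm Passed to [hull_metrics()].
#' @return One-row tibble as [hull_metrics()], plus `timestamp_h`.
#' @export
frame_hull_metrics <- function(frame, mr_len_mm = NA_real_,
                               lr_len_mm = NA_real_, tr_len_mm = NA_real_) {
  stopifnot(inherits(frame, "mask_frame"))
  fg <- which(frame$mask == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("frame_hull_metrics: empty mask")
  pts <- cbind((fg[, 2] - 1) * frame$px_mm, (fg[, 1] - 1) * frame$px_mm)
  out <- hull_metrics(pts, mr_len_mm, lr_len_mm, tr_len_mm)
  out$timestamp_h <- frame$timestamp_h
  out
}

#' Per-plant feature table
#'
#' Runs [frame_metrics()] over a series of frame decompositions and
#' averages to the hourly grid, appending growth speeds for the MR, LR and
#' TR lengths.
#'
#' @param rsfs List of `root_system_frame` objects (one plant,
#'   time-sorted).
#' @return Tibble, one row per hour: plant_id, hour, the frame metrics, and
#'   mr/lr/tr speeds.
#' @export
feature_table <- function(rsfs) {
  per_frame <- do.call(rbind, lapply(rsfs, frame_metrics))
  hourly <- hourly_aggregate(per_frame)
  if (nrow(hourly) >= 2) {
    for (ch in c("mr", "lr", "tr")) {
      gs <- growth_speeds(hourly$hour, hourly[[paste0(ch, "_len_mm")]])
      hourly[[paste0(ch, "_speed_mm_h")]] <- gs$speed_mm_h
    }
  } else {
    hourly$mr_speed_mm_h <- hourly$lr_speed_mm_h <-
      hourly$tr_speed_mm_h <- NA_real_
  }
  hourly
}
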