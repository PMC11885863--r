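# Lateral-root tracking: match per-frame LR observations across consecutive
# frames by the pixel position of their initiation point on the MR, and
# assemble stable, emergence-ordered tracks.

#' Match lateral roots between two consecutive frames
#'
#' Greedy nearest-neighbour assignment on base-pixel distance: candidate
#' pairs are considered in order of increasing distance; pairs farther apart
#' than `radius_px` stay unmatched and every unmatched current observation
#' is flagged as new. Each previous observation is used at most once.
#'
#' @param prev,curr Lists of LR observations (each with a `base_px` field);
#'   may be empty.
#' @param radius_px Maximum base displacement in pixels (default 10).
#' @return Integer vector, one entry per `curr` observation: the index of
#'   the matched `prev` observation, or `NA` for a new root.
#' @export
match_frames <- function(prev, curr, radius_px = 10) {
  np <- length(prev); nc <- length(curr)
  map <- rep(NA_integer_, nc)
  if (np == 0 || nc == 0) return(map)
  pb <- do.call(rbind, lapply(prev, `[[`, "base_px"))
  cb <- do.call(rbind, lapply(curr, `[[`, "base_px"))
  d <- sqrt(outer(cb[, 1], pb[, 1], "-")^2 + outer(cb[, 2], pb[, 2], "-")^2)
  cand <- which(d <= radius_px, arr.ind = TRUE)
  if (nrow(cand) == 0) return(map)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_p <- logical(np); used_c <- logical(nc)
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, 1]; pi <- cand[i, 2]
    if (used_c[ci] || used_p[pi]) next
    map[ci] <- pi
    used_c[ci] <- TRUE; used_p[pi] <- TRUE
  }
  map
}

#' Assemble lateral-root tracks across a frame series
#'
#' Chains [match_frames()] over the time-sorted series. Stable labels are
#' assigned in order of emergence (label 1 = first LR to appear; ties within
#' a frame broken by base arc position, apical last), and tracks observed in
#' fewer than `min_track_frames` frames are dropped.
#'
#' @param frames List of `root_system_frame` objects, time-sorted.
#' @param radius_px Passed to [match_frames()].
#' @param min_track_frames Minimum number of observations for a track to be
#'   kept (default 4).
#' @return List of `lr_track` objects: `label`, `emergence_time_h`,
#'   `times_h`, `base_px` (matrix), `base_arc_on_mr_mm`, `lengths_mm`,
#'   `polylines` (list of mm polylines), and `frame_idx`.
#' @export
build_tracks <- function(frames, radius_px = 10, min_track_frames = 4) {
  ts <- vapply(frames, `[[`, numeric(1), "timestamp_h")
  if (is.unsorted(ts, strictly = FALSE))
    stop("build_tracks: frames must be sorted by timestamp")
  tracks <- list()          # each: list of (frame index, obs index)
  active <- integer(0)      # track index per previous-frame observation
  prev_obs <- list()
  for (k in seq_along(frames)) {
    curr_obs <- frames[[k]]$lrs
    map <- match_frames(prev_obs, curr_obs, radius_px)
    new_active <- integer(length(curr_obs))
    for (ci in seq_along(curr_obs)) {
      if (!is.na(map[ci])) {
        ti <- active[map[ci]]
      } else {
        tracks[[length(tracks) + 1]] <- list()
        ti <- length(tracks)
      }
      tracks[[ti]][[length(tracks[[ti]]) + 1]] <- c(k, ci)
      new_active[ci] <- ti
    }
    active <- new_active
    prev_obs <- curr_obs
  }
  if (length(tracks) == 0) return(list())
  keep <- vapply(tracks, length, integer(1)) >= min_track_frames
  tracks <- tracks[keep]
  if (length(tracks) == 0) return(list())
  built <- lapply(tracks, function(tr) {
    ks <- vapply(tr, `[`, numeric(1), 1)
    cs <- vapply(tr, `[`, numeric(1), 2)
    obs <- Map(function(k, c) frames[[k]]$lrs[[c]], ks, cs)
    list(emergence_time_h = frames[[ks[1]]]$timestamp_h,
         times_h = vapply(ks, function(k) frames[[k]]$timestamp_h,
                          numeric(1)),
         frame_idx = as.integer(ks),
         base_px = do.call(rbind, lapply(obs, `[[`, "base_px")),
         base_arc_on_mr_mm = vapply(obs, `[[`, numeric(1),
                                    "base_arc_on_mr_mm"),
         lengths_mm = vapply(obs, `[[`, numeric(1), "length_mm"),
         polylines = lapply(obs, `[[`, "poly_mm"),
         gt_id = if (!is.null(obs[[1]]$gt_id)) obs[[1]]$gt_id else NA)
  })
  ord <- order(vapply(built, `[[`, numeric(1), "emergence_time_h"),
               vapply(built, function(t) t$base_arc_on_mr_mm[1], numeric(1)))
  built <- built[ord]
  for (i in seq_along(built)) {
    built[[i]]$label <- i
    class(built[[i]]) <- "lr_track"
  }
  built
}

#' @export
print.lr_track <- function(x, ...) {
  cat(sprintf("lr_track %d: emerged %.2fh, %d frames, final %.2f mm\n",
              x$label, x$emergence_time_h, length(x$times_h),
              x$lengths_mm[length(x$lengths_mm)]))
  invisible(x)
}

#' Track table
#'
#' @param tracks List of `lr_track` (from [build_tracks()]).
#' @param plant_id Identifier column value.
#' @return Tibble: plant_id, label, emergence_time_h, time_h, length_mm,
#'   base_row, base_col, base_arc_on_mr_mm.
#' @export
track_table <- function(tracks, plant_id = "plant") {
  if (length(tracks) == 0)
    return(tibble::tibble(plant_id = character(0), label = integer(0),
                          emergence_time_h = numeric(0), time_h = numeric(0),
                          length_mm = numeric(0), base_row = numeric(0),
                          base_col = numeric(0),
                          base_arc_on_mr_mm = numeric(0)))
  do.call(rbind, lapply(tracks, function(t)
    tibble::tibble(plant_id = plant_id, label = t$label,
                   emergence_time_h = t$emergence_time_h,
                   time_h = t$times_h, length_mm = t$lengths_mm,
                   base_row = t$base_px[, 1], base_col = t$base_px[, 2],
                   base_arc_on_mr_mm = t$base_arc_on_mr_mm)))
}
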