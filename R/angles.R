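# Gravity-referenced lateral-root angles: the base-tip angle, the
# fixed-arc-length emergence angle, the first-LR decay curve, and the MR
# tip angle used in plate-rotation (gravitropic bending) assays.

#' Unsigned angle between a base-to-point vector and gravity
#'
#' Gravity points along +y (downward in the image). The angle is
#' `acos(dy / |v|)` in degrees, which reduces to the right-triangle
#' `atan(|dx| / dy)` construction when the point lies below the base, and
#' extends it to upward-pointing vectors (angle > 90).
#'
#' @param base,p Length-2 numeric vectors (x, y) in mm.
#' @param signed If `TRUE`, return the signed angle in (-180, 180]
#'   (`atan2(dx, dy)`, positive toward +x) instead of the unsigned default.
#' @return Angle in degrees; unsigned result lies in \[0, 180\].
#' @export
gravity_angle <- function(base, p, signed = FALSE) {
  v <- c(p[1] - base[1], p[2] - base[2])
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n == 0)
    stop("gravity_angle: zero-length vector")
  if (signed) unname(rad2deg(atan2(v[1], v[2])))
  else unname(rad2deg(acos(clip(v[2] / n, -1, 1))))
}

#' Base-tip angle of a lateral root
#'
#' Unsigned gravity-referenced angle of the vector from the first to the
#' last polyline vertex; interior vertices are ignored. Declines over time
#' as gravitropism bends the root downward.
#'
#' @param lr Polyline matrix (x, y) in mm, base first.
#' @param signed Passed to [gravity_angle()].
#' @return Degrees, or `NA` for a degenerate (tip = base) polyline.
#' @export
base_tip_angle <- function(lr, signed = FALSE) {
  lr <- as.matrix(lr)
  if (nrow(lr) < 2) stop("base_tip_angle: polyline needs >= 2 points")
  base <- lr[1, ]; tip <- lr[nrow(lr), ]
  if (sum((tip - base)^2) == 0) return(NA_real_)
  gravity_angle(base, tip, signed)
}

#' Emergence angle of a lateral root
#'
#' Gravity-referenced angle of the vector from the base to the point a
#' fixed arc length along the skeleton (2 mm by default, adjustable). The
#' point is located by linear interpolation within the containing segment.
#' Roots shorter than the traversal distance yield `NA`: the angle is not
#' yet defined for them.
#'
#' @param lr Polyline matrix (x, y) in mm, base first.
#' @param distance_mm Traversal arc length (default 2).
#' @param reference Either `"gravity"` (default) or a length-2 unit vector
#'   to measure against (e.g. the local MR direction).
#' @param signed Passed to [gravity_angle()] (gravity reference only).
#' @return Degrees, or `NA` if the root is shorter than `distance_mm`.
#' @export
emergence_angle <- function(lr, distance_mm = 2, reference = "gravity",
                            signed = FALSE) {
  if (!is.numeric(distance_mm) || distance_mm <= 0)
    stop("emergence_angle: distance_mm must be > 0")
  lr <- as.matrix(lr)
  if (nrow(lr) < 2 || arc_length(lr) < distance_mm) return(NA_real_)
  pt <- point_at_arc(lr, distance_mm)
  if (identical(reference, "gravity"))
    return(gravity_angle(lr[1, ], pt, signed))
  ref <- reference / sqrt(sum(reference^2))
  v <- pt - lr[1, ]
  rad2deg(acos(clip(sum(v * ref) / sqrt(sum(v^2)), -1, 1)))
}

#' Main-root tip angle
#'
#' Gravity-referenced angle of the last `window_mm` of the MR, i.e. of the
#' vector from the point at arc length `L - window_mm` to the tip.
#' Quantifies MR reorientation after a 90-degree plate rotation.
#'
#' @param mr Polyline matrix (x, y) in mm, seed first.
#' @param window_mm Tip window (default 1 mm).
#' @return Degrees, or `NA` if the MR is shorter than the window.
#' @export
mr_tip_angle <- function(mr, window_mm = 1) {
  mr <- as.matrix(mr)
  L <- arc_length(mr)
  if (nrow(mr) < 2 || L < window_mm) return(NA_real_)
  p0 <- point_at_arc(mr, L - window_mm)
  tip <- mr[nrow(mr), ]
  if (sum((tip - p0)^2) == 0) return(NA_real_)
  gravity_angle(p0, tip)
}

#' Angle records for a set of tracks
#'
#' Evaluates base-tip and emergence angles for every observation of every
#' track of one plant.
#'
#' @param tracks List of `lr_track` objects.
#' @param plant_id Identifier column value.
#' @param distance_mm Emergence-angle traversal distance.
#' @return Tibble: plant_id, lr_label, timestamp_h, hours_since_emergence,
#'   lr_length_mm, base_tip_deg, emergence_deg (`NA` while the root is
#'   shorter than `distance_mm`).
#' @export
angle_records <- function(tracks, plant_id = "plant", distance_mm = 2) {
  if (length(tracks) == 0)
    return(tibble::tibble(plant_id = character(0), lr_label = integer(0),
                          timestamp_h = numeric(0),
                          hours_since_emergence = numeric(0),
                          lr_length_mm = numeric(0),
                          base_tip_deg = numeric(0),
                          emergence_deg = numeric(0)))
  do.call(rbind, lapply(tracks, function(t) {
    bt <- vapply(t$polylines, function(p)
      if (nrow(p) >= 2) base_tip_angle(p) else NA_real_, numeric(1))
    em <- vapply(t$polylines, emergence_angle, numeric(1),
                 distance_mm = distance_mm)
    tibble::tibble(plant_id = plant_id, lr_label = t$label,
                   timestamp_h = t$times_h,
                   hours_since_emergence = t$times_h - t$emergence_time_h,
                   lr_length_mm = t$lengths_mm,
                   base_tip_deg = bt, emergence_deg = em)
  }))
}

#' First-lateral-root decay curve
#'
#' Selects the first-emerged LR (label 1) of each plant and returns its
#' base-tip angle against hours since emergence, plus the cohort mean and
#' sd per whole hour. Plants without any LR are excluded with a warning.
#'
#' @param records Angle records ([angle_records()] rows, possibly several
#'   plants bound together).
#' @return List with `per_plant` (tibble: plant_id, hours_since_emergence,
#'   base_tip_deg) and `cohort` (tibble: hour, mean_deg, sd_deg, n).
#' @export
first_lr_decay_curve <- function(records) {
  stopifnot(is.data.frame(records))
  plants <- unique(records$plant_id)
  first <- records[records$lr_label == 1, , drop = FALSE]
  missing <- setdiff(plants, unique(first$plant_id))
  if (length(missing) > 0)
    warning("first_lr_decay_curve: no LR for plant(s) ",
            paste(missing, collapse = ", "))
  per_plant <- tibble::tibble(plant_id = first$plant_id,
                              hours_since_emergence =
                                first$hours_since_emergence,
                              base_tip_deg = first$base_tip_deg)
  per_plant <- per_plant[!is.na(per_plant$base_tip_deg), , drop = FALSE]
  if (nrow(per_plant) == 0)
    return(list(per_plant = per_plant,
                cohort = tibble::tibble(hour = numeric(0),
                                        mean_deg = numeric(0),
                                        sd_deg = numeric(0),
                                        n = integer(0))))
  hr <- floor(per_plant$hours_since_emergence)
  agg <- aggregate(per_plant$base_tip_deg, by = list(hour = hr),
                   FUN = function(x) c(mean = mean(x), sd = sd(x),
                                       n = length(x)))
  cohort <- tibble::tibble(hour = agg$hour,
                           mean_deg = agg$x[, "mean"],
                           sd_deg = agg$x[, "sd"],
                           n = as.integer(agg$x[, "n"]))
  list(per_plant = per_plant, cohort = cohort)
}

# predicted base-tip chord angle under the exponential-heading law:
# the tip heading decays as theta(t) = final + (theta_e - final) exp(-k t)
# while the tip advances at constant speed, so the chord from base to tip
# is the direction of the time-integral of the heading unit vector.
chord_angle_model <- function(tau_h, theta_e, final_angle, kappa,
                              grid_n = 400) {
  tmax <- max(tau_h)
  if (tmax <= 0) return(rep(theta_e, length(tau_h)))
  tg <- seq(0, tmax, length.out = grid_n)
  th <- deg2rad(lr_heading_law(tg, theta_e, final_angle, kappa))
  dtg <- tg[2] - tg[1]
  X <- cumsum(sin(th)) * dtg
  Y <- cumsum(cos(th)) * dtg
  ang <- rad2deg(atan2(X, Y))
  ifelse(tau_h <= 0, theta_e,
         stats::approx(tg, ang, xout = pmin(tau_h, tmax), rule = 2)$y)
}

#' Fit the gravitropic decay law to a base-tip angle series
#'
#' Least-squares fit of the exponential tip-heading relaxation
#' `theta(t) = final + (theta_e - final) exp(-kappa t)` to measured
#' base-tip angles. Because the base-tip angle is a chord statistic (the
#' direction of the integrated tip path), the default forward model is the
#' integral of the heading law (`model = "chord"`); `model = "heading"`
#' fits the bare exponential instead.
#'
#' @param tau_h Hours since emergence.
#' @param angle_deg Measured base-tip angles (degrees); `NA` dropped.
#' @param model `"chord"` (default) or `"heading"`.
#' @return Named vector: theta_e, final_angle, kappa.
#' @export
fit_decay_curve <- function(tau_h, angle_deg, model = c("chord", "heading")) {
  model <- match.arg(model)
  ok <- is.finite(tau_h) & is.finite(angle_deg)
  tau_h <- tau_h[ok]; angle_deg <- angle_deg[ok]
  if (length(tau_h) < 4) stop("fit_decay_curve: need >= 4 points")
  pred <- function(p) {
    if (model == "chord")
      chord_angle_model(tau_h, p[1], p[2], max(p[3], 0))
    else lr_heading_law(tau_h, p[1], p[2], max(p[3], 0))
  }
  obj <- function(p) sum((pred(p) - angle_deg)^2)
  start <- c(theta_e = angle_deg[which.min(tau_h)],
             final_angle = angle_deg[which.max(tau_h)],
             kappa = 0.05)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  out <- fit$par
  out["kappa"] <- max(out["kappa"], 0)
  out
}
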