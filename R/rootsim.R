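# Parametric synthetic root-growth simulator and mask renderer.
#
# The simulator emulates a vertically grown Arabidopsis-like seedling: one
# main root (MR) elongating downward with a small heading wobble, and lateral
# roots (LRs) emerging as a Poisson process along the mature part of the MR.
# Each LR starts at a stochastic emergence angle and its tip heading relative
# to gravity then relaxes exponentially toward an asymptotic angle,
#   theta(t) = final_angle + (theta_e - final_angle) * exp(-kappa * (t - t_i)),
# a controllable stand-in for gravitropic bending. Ground truth (polylines,
# emergence times/angles, per-frame base-tip angles) is retained so every
# downstream estimator can be validated against known values.

#' Simulation parameters
#'
#' Constructs and validates the parameter set of the synthetic root-growth
#' model. Defaults describe a plausible Arabidopsis seedling time course:
#' MR elongation 0.25 mm/h, LR elongation 0.15 mm/h, LR emergence 0.1 per
#' hour along MR tissue older than 24 h, emergence angles around 75 deg from
#' gravity (sd 10 deg) relaxing toward 40 deg with rate 0.0385 per hour
#' (18 h half-life).
#'
#' @param duration_h Simulated duration in hours.
#' @param frame_interval_min Capture interval in minutes; must divide 60.
#' @param mr_speed Main-root elongation speed, mm/h.
#' @param mr_wobble_sd Per-step sd of the MR heading increment, degrees.
#' @param lr_emergence_rate Poisson rate of LR emergence, LRs/h, applied
#'   while the mature MR zone is non-empty.
#' @param emergence_angle_mean,emergence_angle_sd Mean/sd (degrees from the
#'   gravity vector) of the LR emergence angle; draws are clipped to
#'   \[0, 180\].
#' @param final_angle Asymptotic LR tip angle from gravity, degrees
#'   (gravitropic setpoint).
#' @param decay_rate_kappa Exponential relaxation rate of the LR tip heading,
#'   1/h.
#' @param lr_speed LR elongation speed, mm/h.
#' @param maturation_lag_h LRs emerge only from MR tissue older than this lag
#'   (hours); models the delay between MR tip passage and LR emergence.
#' @param min_lr_spacing_mm Minimum arc distance between emergence sites:
#'   candidate positions closer than this to an existing LR base are
#'   rejected (lateral-root primordia are spaced along the pericycle, and
#'   coincident emergence sites would be unresolvable in a segmentation).
#' @param seed Integer RNG seed; fixes the whole series.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(duration_h = 96,
                       frame_interval_min = 15,
                       mr_speed = 0.25,
                       mr_wobble_sd = 2,
                       lr_emergence_rate = 0.1,
                       emergence_angle_mean = 75,
                       emergence_angle_sd = 10,
                       final_angle = 40,
                       decay_rate_kappa = 0.0385,
                       lr_speed = 0.15,
                       maturation_lag_h = 24,
                       min_lr_spacing_mm = 0.5,
                       seed = 1L) {
  p <- list(duration_h = duration_h, frame_interval_min = frame_interval_min,
            mr_speed = mr_speed, mr_wobble_sd = mr_wobble_sd,
            lr_emergence_rate = lr_emergence_rate,
            emergence_angle_mean = emergence_angle_mean,
            emergence_angle_sd = emergence_angle_sd,
            final_angle = final_angle, decay_rate_kappa = decay_rate_kappa,
            lr_speed = lr_speed, maturation_lag_h = maturation_lag_h,
            min_lr_spacing_mm = min_lr_spacing_mm,
            seed = as.integer(seed))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))
  if (!all(num)) stop("sim_params: all parameters must be finite scalars")
  if (duration_h <= 0) stop("sim_params: duration_h must be > 0")
  if (frame_interval_min <= 0 || 60 %% frame_interval_min != 0)
    stop("sim_params: frame_interval_min must be positive and divide 60")
  rates <- c(mr_speed, mr_wobble_sd, lr_emergence_rate, emergence_angle_sd,
             decay_rate_kappa, lr_speed, maturation_lag_h,
             min_lr_spacing_mm)
  if (any(rates < 0)) stop("sim_params: rates, speeds and sds must be >= 0")
  angs <- c(emergence_angle_mean, final_angle)
  if (any(angs < 0 | angs > 180))
    stop("sim_params: angles must lie in [0, 180]")
  structure(p, class = "sim_params")
}

# evaluate the bending law
lr_heading_law <- function(tau_h, theta_e, final_angle, kappa) {
  final_angle + (theta_e - final_angle) * exp(-kappa * tau_h)
}

#' Simulate a ground-truthed root system
#'
#' Runs the generative growth model at the capture cadence and returns exact
#' (pre-rasterization) geometry plus per-frame true angles. The returned
#' series is bit-identical for identical parameters (seeded RNG; the global
#' RNG state is restored on exit).
#'
#' @param params A [sim_params()] object.
#' @return Object of class `ground_truth_series` with elements `times`
#'   (hours), `mr` (full MR vertex matrix; frame k uses the first k
#'   vertices), and `lrs`, a list with one record per LR: emergence time and
#'   frame, base point and arc position on the MR, bending side, true
#'   emergence angle `theta_e_deg`, vertex matrix (base to final tip; frame
#'   j uses the first `j - frame_emerge + 1` vertices), per-frame true tip
#'   heading and true base-tip chord angle.
#' @export
simulate_root_system <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(p$seed)

  dt <- p$frame_interval_min / 60
  times <- seq(0, p$duration_h, by = dt)
  nf <- length(times)

  # MR: heading increments; first step straight down
  dphi <- c(0, rnorm(nf - 2, 0, p$mr_wobble_sd))
  phi <- cumsum(dphi)                        # heading (deg) for steps 1..nf-1
  step <- p$mr_speed * dt * dir_from_gravity(phi)
  mr <- rbind(c(0, 0), cbind(cumsum(step[, 1]), cumsum(step[, 2])))
  colnames(mr) <- c("x", "y")

  # LR emergence: Poisson per step along the mature MR zone
  lrs <- list()
  for (k in 2:nf) {
    t_k <- times[k]
    mature_len <- p$mr_speed * max(0, t_k - p$maturation_lag_h)
    if (mature_len <= 0 || p$lr_emergence_rate <= 0) next
    m <- rpois(1, p$lr_emergence_rate * dt)
    if (m == 0) next
    for (dummy in seq_len(m)) {
      taken <- vapply(lrs, `[[`, numeric(1), "base_arc_mm")
      base_arc <- NA_real_
      for (try in 1:10) {
        cand <- runif(1, 0, mature_len)
        if (length(taken) == 0 ||
            min(abs(taken - cand)) >= p$min_lr_spacing_mm) {
          base_arc <- cand
          break
        }
      }
      if (!is.finite(base_arc)) next   # zone saturated; thin the process
      theta_e <- clip(rnorm(1, p$emergence_angle_mean, p$emergence_angle_sd),
                      0, 180)
      side <- sample(c(-1, 1), 1)
      lrs[[length(lrs) + 1]] <- list(frame_emerge = k, t_emerge_h = t_k,
                                     base_arc_mm = base_arc,
                                     theta_e_deg = theta_e, side = side)
    }
  }

  # grow each LR deterministically from its emergence record
  lrs <- lapply(seq_along(lrs), function(i) {
    lr <- lrs[[i]]
    k0 <- lr$frame_emerge
    base <- point_at_arc(mr, lr$base_arc_mm)
    taus <- times[k0:nf] - lr$t_emerge_h          # 0, dt, 2*dt, ...
    headings <- lr_heading_law(taus, lr$theta_e_deg, p$final_angle,
                               p$decay_rate_kappa)
    nsteg <- length(taus) - 1
    pts <- matrix(rep(base, each = nsteg + 1), ncol = 2)
    if (nsteg > 0) {
      d <- p$lr_speed * dt * dir_from_gravity(headings[seq_len(nsteg)],
                                              lr$side)
      pts[-1, 1] <- base[1] + cumsum(d[, 1])
      pts[-1, 2] <- base[2] + cumsum(d[, 2])
    }
    colnames(pts) <- c("x", "y")
    v <- pts[-1, , drop = FALSE] - matrix(rep(base, each = max(nsteg, 0)),
                                          ncol = 2)
    chord <- if (nsteg > 0)
      rad2deg(acos(clip(v[, 2] / sqrt(rowSums(v^2)), -1, 1))) else numeric(0)
    c(lr, list(id = i, base_mm = base, points = pts,
               tip_heading_deg = headings,
               base_tip_deg = c(NA_real_, chord),
               length_mm_final = p$lr_speed * dt * nsteg))
  })

  structure(list(params = p, times = times, dt_h = dt, mr = mr, lrs = lrs),
            class = "ground_truth_series")
}

# MR polyline visible at frame k (first k vertices)
gt_mr_at <- function(gt, k) gt$mr[seq_len(min(k, nrow(gt$mr))), ,
                                  drop = FALSE]

# LR polyline visible at frame k (NULL if not yet emerged)
gt_lr_at <- function(lr, k) {
  if (k < lr$frame_emerge) return(NULL)
  lr$points[seq_len(k - lr$frame_emerge + 1), , drop = FALSE]
}

# true LR length at frame k
gt_lr_len_at <- function(gt, lr, k) {
  if (k < lr$frame_emerge) return(0)
  gt$params$lr_speed * gt$dt_h * (k - lr$frame_emerge)
}

#' @export
print.ground_truth_series <- function(x, ...) {
  cat("ground_truth_series:", length(x$times), "frames over",
      x$params$duration_h, "h;", length(x$lrs), "lateral roots\n")
  invisible(x)
}

#' Ground truth as a tidy table
#'
#' One row per lateral root per frame from its emergence on, with the true
#' base position, base-tip angle and emergence angle.
#'
#' @param x A `ground_truth_series`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data.frame with columns label, time_h, base_x_mm, base_y_mm,
#'   length_mm, true_base_tip_deg, true_tip_heading_deg, true_emergence_deg.
#' @export
as.data.frame.ground_truth_series <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  if (length(x$lrs) == 0)
    return(data.frame(label = integer(0), time_h = numeric(0),
                      base_x_mm = numeric(0), base_y_mm = numeric(0),
                      length_mm = numeric(0), true_base_tip_deg = numeric(0),
                      true_tip_heading_deg = numeric(0),
                      true_emergence_deg = numeric(0)))
  rows <- lapply(x$lrs, function(lr) {
    ks <- lr$frame_emerge:length(x$times)
    data.frame(label = lr$id, time_h = x$times[ks],
               base_x_mm = lr$base_mm[1], base_y_mm = lr$base_mm[2],
               length_mm = vapply(ks, function(k) gt_lr_len_at(x, lr, k),
                                  numeric(1)),
               true_base_tip_deg = lr$base_tip_deg,
               true_tip_heading_deg = lr$tip_heading_deg,
               true_emergence_deg = lr$theta_e_deg)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rendering parameters
#'
#' @param px_mm Image scale, mm per pixel.
#' @param stroke_width_px Root stroke width in pixels (>= 1).
#' @param width_px,height_px Canvas size; `NULL` auto-fits the full series
#'   with a margin.
#' @param origin_px Pixel (row, col) where the MR start (seed point) is
#'   placed; `NULL` auto-places it.
#' @param margin_px Margin used when auto-fitting.
#' @return Object of class `render_params`.
#' @export
render_params <- function(px_mm = 0.04, stroke_width_px = 3,
                          width_px = NULL, height_px = NULL,
                          origin_px = NULL, margin_px = 10) {
  if (!is.numeric(px_mm) || px_mm <= 0) stop("px_mm must be > 0")
  if (!is.numeric(stroke_width_px) || stroke_width_px < 1)
    stop("stroke_width_px must be >= 1")
  structure(list(px_mm = px_mm, stroke_width_px = stroke_width_px,
                 width_px = width_px, height_px = height_px,
                 origin_px = origin_px, margin_px = margin_px),
            class = "render_params")
}

# disc offsets (row, col) for a given stroke width
stroke_offsets <- function(stroke_width_px) {
  r <- stroke_width_px / 2
  h <- ceiling(r)
  g <- expand.grid(dr = -h:h, dc = -h:h)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  if (nrow(g) == 0) g <- data.frame(dr = 0, dc = 0)
  g
}

# rasterize one mm polyline into (row, col) pixel indices (no stroke)
raster_polyline_px <- function(poly_mm, px_mm, origin_px) {
  n <- nrow(poly_mm)
  if (n == 0) return(matrix(integer(0), ncol = 2))
  if (n == 1) {
    return(cbind(round(poly_mm[1, 2] / px_mm) + origin_px[1],
                 round(poly_mm[1, 1] / px_mm) + origin_px[2]))
  }
  pts <- lapply(seq_len(n - 1), function(i) {
    a <- poly_mm[i, ]; b <- poly_mm[i + 1, ]
    len_px <- sqrt(sum((b - a)^2)) / px_mm
    m <- max(2, ceiling(len_px / 0.3))
    f <- seq(0, 1, length.out = m)
    cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2]))
  })
  pts <- do.call(rbind, pts)
  px <- cbind(round(pts[, 2] / px_mm) + origin_px[1],
              round(pts[, 1] / px_mm) + origin_px[2])
  px[!duplicated(px), , drop = FALSE]
}

#' Render a ground-truth series to binary mask frames
#'
#' Rasterizes every frame's polylines with an anti-alias-free thick stroke;
#' output masks are strictly binary. Geometry that falls outside the canvas
#' raises an error naming the offending frame.
#'
#' @param gt A `ground_truth_series`.
#' @param rp A [render_params()] object.
#' @param frames Integer indices of frames to render (default all).
#' @param plant_id Identifier stored on each frame.
#' @return List of [mask_frame()] objects.
#' @export
render_frames <- function(gt, rp = render_params(), frames = NULL,
                          plant_id = "sim") {
  stopifnot(inherits(gt, "ground_truth_series"),
            inherits(rp, "render_params"))
  if (is.null(frames)) frames <- seq_along(gt$times)
  allx <- c(gt$mr[, 1], unlist(lapply(gt$lrs, function(l) l$points[, 1])))
  ally <- c(gt$mr[, 2], unlist(lapply(gt$lrs, function(l) l$points[, 2])))
  pad <- rp$margin_px + ceiling(rp$stroke_width_px / 2)
  origin <- rp$origin_px
  if (is.null(origin))
    origin <- c(pad + 1 - floor(min(ally) / rp$px_mm),
                pad + 1 - floor(min(allx) / rp$px_mm))
  h <- rp$height_px
  w <- rp$width_px
  if (is.null(h)) h <- ceiling(max(ally) / rp$px_mm) + origin[1] + pad
  if (is.null(w)) w <- ceiling(max(allx) / rp$px_mm) + origin[2] + pad
  off <- stroke_offsets(rp$stroke_width_px)

  lapply(frames, function(k) {
    polys <- c(list(gt_mr_at(gt, k)),
               Filter(Negate(is.null),
                      lapply(gt$lrs, gt_lr_at, k = k)))
    m <- matrix(0L, nrow = h, ncol = w)
    for (pl in polys) {
      px <- raster_polyline_px(pl, rp$px_mm, origin)
      if (nrow(px) == 0) next
      rr <- rep(px[, 1], each = nrow(off)) + off$dr
      cc <- rep(px[, 2], each = nrow(off)) + off$dc
      if (any(rr < 1 | rr > h | cc < 1 | cc > w))
        stop("render_frames: geometry out of bounds at frame ", k)
      m[cbind(rr, cc)] <- 1L
    }
    mask_frame(m, timestamp_h = gt$times[k], px_mm = rp$px_mm,
               plant_id = plant_id, seed_point = origin)
  })
}

#' Write a simulated series to disk
#'
#' Masks go to zero-padded numbered PNGs, ground truth to a CSV (one LR per
#' frame per row) and the simulation parameters to a JSON sidecar.
#'
#' @param gt A `ground_truth_series`.
#' @param frames List of `mask_frame` objects (from [render_frames()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_sim_series <- function(gt, frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    f <- file.path(dir, sprintf("frame_%05d.png", i))
    png::writePNG(frames[[i]]$mask + 0.0, f)
  }
  write.csv(as.data.frame(gt), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  jsonlite::write_json(unclass(gt$params), file.path(dir, "sim_params.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(px_mm = frames[[1]]$px_mm,
               seed_point = frames[[1]]$seed_point,
               plant_id = frames[[1]]$plant_id,
               frame_interval_min = gt$params$frame_interval_min)
  jsonlite::write_json(meta, file.path(dir, "plant.json"), auto_unbox = TRUE)
  invisible(dir)
}
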