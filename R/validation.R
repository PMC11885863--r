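# Ground-truth validation harnesses: run the simulator, render masks, push
# them through the full measurement pipeline, and pair every estimate with
# its generative truth. Used by the test suite and the acceptance script.

# benchmark cohorts use a compressed observation window (shorter maturation
# lag, brisker emergence) so a desk-scale run yields >= 20 measurable LRs;
# estimator validity depends on the measurement geometry, not the absolute
# time axis
bench_params <- function(seed, duration_h = 48, theta_e = 60, sd_e = 0,
                         kappa = 0, final_angle = 40,
                         frame_interval_min = 60) {
  sim_params(duration_h = duration_h, frame_interval_min = frame_interval_min,
             mr_speed = 0.35, mr_wobble_sd = 2, lr_emergence_rate = 0.25,
             emergence_angle_mean = theta_e, emergence_angle_sd = sd_e,
             final_angle = final_angle, decay_rate_kappa = kappa,
             lr_speed = 0.2, maturation_lag_h = 12, seed = seed)
}

#' Length, count and emergence-angle recovery benchmark
#'
#' Simulates a cohort of non-bending plants (`kappa = 0`, zero
#' emergence-angle spread, so that every lateral is a straight line at the
#' stated angle and roots cannot cross), renders the final frame of each at
#' the given scale, runs the skeleton pipeline, and matches every
#' measurement to its ground truth by base position.
#'
#' @param n_plants Number of plants (default 20).
#' @param seed Base RNG seed; plant i uses `seed + i`.
#' @param theta_e True emergence angle, degrees from gravity (default 60).
#' @param px_mm,stroke_width_px Rendering scale and stroke.
#' @param duration_h Simulated hours per plant (default 48).
#' @return List: `per_plant` (tibble: plant, mr_len_gt, mr_len_meas, n_lr_gt
#'   (true laterals >= 1 mm), n_lr_meas, n_matched), `per_lr` (tibble:
#'   plant, len_gt, len_meas, emergence_meas; one row per matched true
#'   lateral >= 1 mm).
#' @export
recovery_benchmark <- function(n_plants = 20, seed = 1, theta_e = 60,
                               px_mm = 0.04, stroke_width_px = 3,
                               duration_h = 48) {
  rp <- render_params(px_mm = px_mm, stroke_width_px = stroke_width_px)
  pp <- list(); pl <- list()
  for (i in seq_len(n_plants)) {
    p <- bench_params(seed + i, duration_h = duration_h, theta_e = theta_e)
    gt <- simulate_root_system(p)
    k <- length(gt$times)
    fr <- render_frames(gt, rp, frames = k, plant_id = paste0("p", i))
    rsf <- suppressWarnings(root_system_frame(fr[[1]]))
    gl <- vapply(gt$lrs, function(l) gt_lr_len_at(gt, l, k), numeric(1))
    ga <- vapply(gt$lrs, `[[`, numeric(1), "base_arc_mm")
    ra <- vapply(rsf$lrs, `[[`, numeric(1), "base_arc_on_mr_mm")
    keep <- which(gl >= 1)
    matched <- 0
    for (j in keep) {
      if (length(ra) == 0) break
      m <- which.min(abs(ra - ga[j]))
      if (abs(ra[m] - ga[j]) > 0.5) next
      matched <- matched + 1
      lr <- rsf$lrs[[m]]
      pl[[length(pl) + 1]] <- tibble::tibble(
        plant = i, len_gt = gl[j], len_meas = lr$length_mm,
        emergence_meas = emergence_angle(lr$poly_mm, 2))
    }
    pp[[i]] <- tibble::tibble(
      plant = i, mr_len_gt = arc_length(gt$mr),
      mr_len_meas = rsf$mr$length_mm,
      n_lr_gt = length(keep), n_lr_meas = length(rsf$lrs),
      n_matched = matched)
  }
  list(per_plant = do.call(rbind, pp), per_lr = do.call(rbind, pl))
}

#' Gravitropic decay-curve recovery benchmark
#'
#' Simulates a bending cohort (tip heading relaxing from `theta_e` toward
#' `final_angle` at rate `kappa`), renders every frame, tracks the
#' laterals, and pairs the measured base-tip angle of each plant's first
#' lateral with the true base-tip chord angle at the same frame. Also fits
#' the relaxation rate to the cohort-mean curve with [fit_decay_curve()].
#'
#' @param n_plants Number of plants (default 20).
#' @param seed Base RNG seed.
#' @param theta_e,final_angle,kappa True bending-law parameters (defaults
#'   90 deg, 30 deg, 0.0385 per hour: an 18-h half-life).
#' @param px_mm,stroke_width_px Rendering scale and stroke.
#' @param duration_h Simulated hours (default 72).
#' @return List: `curve` (tibble: plant, tau_h, base_tip_meas,
#'   base_tip_gt), `fit` (named vector theta_e/final_angle/kappa),
#'   `kappa_true`.
#' @export
decay_benchmark <- function(n_plants = 20, seed = 1, theta_e = 90,
                            final_angle = 30, kappa = 0.0385,
                            px_mm = 0.04, stroke_width_px = 3,
                            duration_h = 72) {
  rp <- render_params(px_mm = px_mm, stroke_width_px = stroke_width_px)
  rows <- list()
  for (i in seq_len(n_plants)) {
    p <- bench_params(seed + i, duration_h = duration_h, theta_e = theta_e,
                      kappa = kappa, final_angle = final_angle)
    p$lr_emergence_rate <- 0.1
    gt <- simulate_root_system(p)
    if (length(gt$lrs) == 0) next
    fr <- render_frames(gt, rp, plant_id = paste0("p", i))
    rsfs <- lapply(fr, function(f)
      tryCatch(suppressWarnings(root_system_frame(f)),
               error = function(e) NULL))
    rsfs <- Filter(Negate(is.null), rsfs)
    tracks <- build_tracks(rsfs)
    if (length(tracks) == 0) next
    tr <- tracks[[1]]
    # first ground-truth lateral (earliest emergence)
    emg <- vapply(gt$lrs, `[[`, numeric(1), "t_emerge_h")
    lr_gt <- gt$lrs[[which.min(emg)]]
    for (j in seq_along(tr$frame_idx)) {
      k <- tr$frame_idx[j]
      gi <- k - lr_gt$frame_emerge + 1
      if (gi < 2 || gi > length(lr_gt$base_tip_deg)) next
      bt <- base_tip_angle(tr$polylines[[j]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        plant = i, tau_h = gt$times[k] - lr_gt$t_emerge_h,
        base_tip_meas = bt, base_tip_gt = lr_gt$base_tip_deg[gi])
    }
  }
  curve <- do.call(rbind, rows)
  agg <- aggregate(curve$base_tip_meas, by = list(tau = curve$tau_h), mean)
  fit <- fit_decay_curve(agg$tau, agg$x, model = "chord")
  list(curve = curve, fit = fit, kappa_true = kappa)
}
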