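test_that("noise-free simulation gives the closed-form vertical MR", {
  p <- sim_params(duration_h = 10, frame_interval_min = 15, mr_speed = 1,
                  mr_wobble_sd = 0, lr_emergence_rate = 0, seed = 5)
  gt <- simulate_root_system(p)
  expect_equal(arc_length(gt$mr), 10, tolerance = 1e-12)
  expect_true(all(abs(gt$mr[, 1]) < 1e-12))       # straight down
  expect_length(gt$lrs, 0)
})

test_that("the bending law has the stated exponential form", {
  # half-life check: kappa * dt = ln 2 halves the angle above the asymptote
  kappa <- log(2) / 18
  th <- roottrack:::lr_heading_law(18, theta_e = 60, final_angle = 0,
                                   kappa = kappa)
  expect_equal(th, 30, tolerance = 1e-12)
  # simulated tip headings follow the law exactly
  p <- sim_params(duration_h = 60, frame_interval_min = 30,
                  lr_emergence_rate = 0.3, maturation_lag_h = 6,
                  decay_rate_kappa = 0.05, emergence_angle_sd = 5,
                  final_angle = 35, seed = 9)
  gt <- simulate_root_system(p)
  expect_gt(length(gt$lrs), 0)
  for (lr in gt$lrs) {
    taus <- gt$times[lr$frame_emerge:length(gt$times)] - lr$t_emerge_h
    expect_equal(lr$tip_heading_deg,
                 35 + (lr$theta_e_deg - 35) * exp(-0.05 * taus),
                 tolerance = 1e-12)
  }
})

test_that("identical parameters give bit-identical series", {
  p <- sim_params(duration_h = 48, seed = 77, maturation_lag_h = 12,
                  lr_emergence_rate = 0.3)
  expect_identical(simulate_root_system(p), simulate_root_system(p))
})

test_that("growth is monotone: arc lengths never decrease across frames", {
  for (s in c(2, 13)) {
    p <- sim_params(duration_h = 48, frame_interval_min = 60,
                    maturation_lag_h = 12, lr_emergence_rate = 0.3,
                    emergence_angle_sd = 15, seed = s)
    gt <- simulate_root_system(p)
    mr_lens <- vapply(seq_along(gt$times), function(k)
      arc_length(roottrack:::gt_mr_at(gt, k)), numeric(1))
    expect_true(all(diff(mr_lens) >= -1e-12))
    for (lr in gt$lrs) {
      lens <- vapply(lr$frame_emerge:length(gt$times), function(k)
        arc_length(roottrack:::gt_lr_at(lr, k)), numeric(1))
      expect_true(all(diff(lens) >= -1e-12))
    }
    # every LR base lies on the MR polyline
    for (lr in gt$lrs) {
      d <- sqrt(rowSums((gt$mr - matrix(lr$base_mm, nrow(gt$mr), 2,
                                        byrow = TRUE))^2))
      seg <- min(d)   # base interpolated within a segment: near some vertex
      expect_lt(seg, p$mr_speed * gt$dt_h + 1e-9)
    }
  }
})

test_that("invalid parameters are rejected", {
  expect_error(sim_params(duration_h = -1), "duration")
  expect_error(sim_params(frame_interval_min = 7), "divide 60")
  expect_error(sim_params(mr_speed = -0.1), ">= 0")
  expect_error(sim_params(emergence_angle_mean = 200), "\\[0, 180\\]")
  expect_error(sim_params(mr_speed = Inf), "finite")
})

test_that("rendering a vertical MR gives one component of expected height", {
  p <- sim_params(duration_h = 10, frame_interval_min = 15, mr_speed = 1,
                  mr_wobble_sd = 0, lr_emergence_rate = 0, seed = 5)
  gt <- simulate_root_system(p)
  fr <- render_frames(gt, render_params(px_mm = 0.1, stroke_width_px = 3))
  m <- fr[[length(fr)]]$mask
  expect_true(all(m %in% c(0L, 1L)))
  rows <- range(which(rowSums(m) > 0))
  expect_equal(diff(rows) + 1, 101, tolerance = 0.03)
  lab <- roottrack:::label_components(m)
  expect_equal(max(lab), 1)
  # empty geometry renders an all-zero mask
  gt0 <- gt
  gt0$mr <- gt$mr[integer(0), , drop = FALSE]
  fr0 <- render_frames(gt0, render_params(px_mm = 0.1, width_px = 40,
                                          height_px = 40,
                                          origin_px = c(5, 5)),
                       frames = 1)
  expect_equal(sum(fr0[[1]]$mask), 0)
})

test_that("out-of-bounds geometry raises an error naming the frame", {
  p <- sim_params(duration_h = 10, frame_interval_min = 15, mr_speed = 1,
                  mr_wobble_sd = 0, lr_emergence_rate = 0, seed = 5)
  gt <- simulate_root_system(p)
  rp <- render_params(px_mm = 0.1, height_px = 50, width_px = 50,
                      origin_px = c(5, 25))
  expect_error(render_frames(gt, rp), "frame")
})

test_that("render-skeletonize round trip recovers arc length within 2%", {
  p <- sim_params(duration_h = 20, frame_interval_min = 60, mr_speed = 0.5,
                  mr_wobble_sd = 3, lr_emergence_rate = 0, seed = 21)
  gt <- simulate_root_system(p)
  for (stroke in c(3, 5)) {
    fr <- render_frames(gt, render_params(px_mm = 0.04,
                                          stroke_width_px = stroke),
                        frames = length(gt$times))
    rsf <- root_system_frame(fr[[1]])
    expect_equal(rsf$mr$length_mm, arc_length(gt$mr), tolerance = 0.02)
  }
})

test_that("a simulated series round-trips through disk", {
  p <- sim_params(duration_h = 6, frame_interval_min = 60, mr_speed = 1,
                  mr_wobble_sd = 0, lr_emergence_rate = 0, seed = 5)
  gt <- simulate_root_system(p)
  fr <- render_frames(gt, render_params(px_mm = 0.1, stroke_width_px = 3))
  dir <- file.path(tempdir(), "simseries")
  write_sim_series(gt, fr, dir)
  back <- load_mask_series(dir)
  expect_length(back, length(fr))
  expect_identical(back[[3]]$mask, fr[[3]]$mask)
  expect_equal(back[[3]]$timestamp_h, fr[[3]]$timestamp_h)
  unlink(dir, recursive = TRUE)
})
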