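rsf_with <- function(mr_len, lr_lens) {
  structure(list(timestamp_h = 0, plant_id = "t", px_mm = 0.1,
                 mr = list(chain = NULL, poly_mm = NULL, length_mm = mr_len),
                 lrs = lapply(lr_lens, function(l)
                   list(base_px = c(1, 1), base_arc_on_mr_mm = 0,
                        poly_mm = NULL, length_mm = l))),
            class = "root_system_frame")
}

test_that("frame metrics apply the published formulas", {
  m <- frame_metrics(rsf_with(50, c(10, 10)))
  expect_equal(m$tr_len_mm, 70)
  expect_equal(m$n_lr, 2L)
  expect_equal(m$lr_density, 0.4)             # LR length / MR length
  expect_equal(m$discrete_lr_density, 0.4)    # 10 * n / MR = LRs per cm
  expect_equal(m$mr_over_tr, 50 / 70)
  m0 <- frame_metrics(rsf_with(30, numeric(0)))
  expect_equal(m0$lr_density, 0)
  expect_equal(m0$discrete_lr_density, 0)
  expect_equal(m0$mr_over_tr, 1)
  mz <- frame_metrics(rsf_with(0, c(1)))
  expect_true(is.na(mz$lr_density) && is.na(mz$mr_over_tr))
  expect_equal(mz$lr_len_mm, 1)               # lengths still reported
})

test_that("TR additivity holds exactly on simulated frames", {
  p <- sim_params(duration_h = 48, frame_interval_min = 60,
                  lr_emergence_rate = 0.3, maturation_lag_h = 10,
                  emergence_angle_sd = 10, seed = 12)
  gt <- simulate_root_system(p)
  for (rsf in gt_frames(gt)[seq(10, 48, by = 10)]) {
    m <- frame_metrics(rsf)
    expect_identical(m$tr_len_mm, m$mr_len_mm + m$lr_len_mm)
  }
})

test_that("hourly aggregation averages frames within each clock hour", {
  df <- data.frame(timestamp_h = c(0, 0.25, 0.5, 0.75, 2.25),
                   v = c(1, 2, 3, 4, 9))
  out <- hourly_aggregate(df)
  expect_equal(out$hour, c(0, 2))              # empty hour 1 absent
  expect_equal(out$v, c(2.5, 9))
})

test_that("growth speeds use central differences and clip negatives", {
  gs <- growth_speeds(0:3, c(0, 1, 3, 6))
  expect_equal(gs$speed_mm_h, c(1, 1.5, 2.5, 3))
  gs0 <- growth_speeds(0:5, rep(4, 6))
  expect_equal(gs0$speed_mm_h, rep(0, 6))
  gsn <- growth_speeds(0:2, c(2, 1.5, 2))
  expect_equal(gsn$speed_mm_h[1], 0)           # clipped
  expect_equal(gsn$raw_speed_mm_h[1], -0.5)    # raw retained
  expect_equal(attr(gsn, "n_clipped"), 1)
})

test_that("the spectrum finds an injected daily rhythm on a trend", {
  t <- 0:95
  speed <- 0.02 * t + 0.5 * sin(2 * pi * t / 24)
  sp <- spectral_features(speed)
  peak <- sp$freq_per_h[which.max(sp$amplitude[-1]) + 1]  # skip DC
  expect_equal(peak, 1 / 24, tolerance = 1e-9)
  zero <- spectral_features(rep(3, 50))
  expect_true(all(zero$amplitude < 1e-12))
})

test_that("the spectral pipeline agrees with an independent recomputation", {
  # independent route: centred moving-average detrend, unit variance, DFT
  oracle <- function(x, w = 24) {
    n <- length(x)
    tr <- vapply(seq_len(n), function(i)
      mean(x[max(1, i - w %/% 2):min(n, i + w %/% 2)]), numeric(1))
    y <- x - tr
    if (sd(y) > 0) y <- y / sd(y)
    a <- Mod(fft(y)) / n
    a[1:(n %/% 2 + 1)]
  }
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(72)
    expect_equal(spectral_features(x)$amplitude, oracle(x),
                 tolerance = 1e-12)
  }
  # under the white-noise null, no frequency is systematically preferred
  set.seed(1)
  peaks <- replicate(60, {
    sp <- spectral_features(rnorm(72))
    which.max(sp$amplitude[-1])
  })
  expect_gt(length(unique(peaks)), 10)
})

test_that("missing speed points are interpolated and counted", {
  x <- sin(2 * pi * (0:71) / 24)
  x[c(10, 30)] <- NA
  sp <- spectral_features(x)
  expect_equal(attr(sp, "n_interpolated"), 2)
  expect_false(any(is.na(sp$amplitude)))
})

test_that("hull metrics match closed forms and a brute-force oracle", {
  # filled rectangle 10 x 20 mm
  g <- as.matrix(expand.grid(x = seq(0, 10, by = 0.5),
                             y = seq(0, 20, by = 0.5)))
  h <- hull_metrics(g, mr_len_mm = 40, lr_len_mm = 10, tr_len_mm = 50)
  expect_equal(h$hull_area_mm2, 200)
  expect_equal(h$hull_width_mm, 10)
  expect_equal(h$hull_height_mm, 20)
  expect_equal(h$aspect_ratio, 2)
  expect_equal(h$tr_area_density, 50 / 200)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(hull_metrics(tri)$hull_area_mm2, 6)
  # random point clouds against the O(n^3) oracle
  set.seed(99)
  for (i in 1:25) {
    pts <- cbind(runif(30, 0, 12), runif(30, 0, 9))
    got <- hull_metrics(pts)
    expect_equal(got$hull_area_mm2, shoelace(brute_hull(pts)),
                 tolerance = 1e-9)
    expect_equal(got$hull_width_mm, diff(range(pts[, 1])))
    expect_equal(got$hull_height_mm, diff(range(pts[, 2])))
  }
  # degenerate: collinear points
  col3 <- cbind(1:5, 2 * (1:5))
  hc <- hull_metrics(col3, mr_len_mm = 1)
  expect_equal(hc$hull_area_mm2, 0)
  expect_true(is.na(hc$mr_area_density))
})

test_that("hull area never decreases when points are added", {
  set.seed(4)
  pts <- cbind(runif(10), runif(10))
  a_prev <- hull_metrics(pts)$hull_area_mm2
  for (i in 1:15) {
    pts <- rbind(pts, runif(2))
    a <- hull_metrics(pts)$hull_area_mm2
    expect_gte(a, a_prev - 1e-12)
    a_prev <- a
  }
})

test_that("lengths scale with calibration while densities stay invariant", {
  chain <- px_chain(c(1, 1), c(81, 1))
  for (px in c(0.05, 0.1)) {
    mm <- roottrack:::chain_to_mm(chain, px, smooth_window = 0)
    expect_equal(arc_length(mm), 80 * px)
  }
  # density formulas are ratios of lengths, hence scale-free
  m1 <- frame_metrics(rsf_with(50, c(10, 10)))
  m2 <- frame_metrics(rsf_with(100, c(20, 20)))
  expect_equal(m1$lr_density, m2$lr_density)
  expect_equal(m1$mr_over_tr, m2$mr_over_tr)
})
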