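test_that("a wide vertical bar skeletonizes to a single chain of known length", {
  m <- bar_mask(120, 60, 10:109, 28:32)      # 100 px tall, 5 px wide
  f <- mask_frame(m, 0, 0.1, seed_point = c(10, 30))
  sg <- skeletonize_mask(f)
  expect_true(roottrack:::skeleton_is_thin(sg$skel))
  expect_length(sg$edges, 1)
  expect_equal(sg$edges[[1]]$length_mm, 10, tolerance = 0.02)
  expect_setequal(sg$nodes$kind, "endpoint")
})

test_that("a T-shaped mask yields one junction and three endpoint chains", {
  m <- bar_mask(120, 100, 10:109, 48:52)
  m[58:62, 52:90] <- 1L
  f <- mask_frame(m, 0, 0.1, seed_point = c(10, 50))
  sg <- skeletonize_mask(f)
  expect_equal(sum(sg$nodes$kind == "junction"), 1)
  expect_equal(sum(sg$nodes$kind == "endpoint"), 3)
  expect_length(sg$edges, 3)
})

test_that("spurs below the pruning threshold are removed", {
  m <- bar_mask(120, 60, 10:109, 28:32)
  m[60:61, 33:34] <- 1L                       # 0.2 mm stub at px_mm = 0.1
  f <- mask_frame(m, 0, 0.1, seed_point = c(10, 30))
  sg <- skeletonize_mask(f)                   # default prune_len_mm = 0.3
  expect_length(sg$edges, 1)
  expect_equal(sum(sg$nodes$kind == "junction"), 0)
})

test_that("degenerate masks raise informative errors", {
  f0 <- mask_frame(matrix(0L, 10, 10), 0, 0.1, seed_point = c(5, 5))
  expect_error(skeletonize_mask(f0), "no foreground")
  m <- bar_mask(100, 100, 60:90, 60:62)
  f <- mask_frame(m, 0, 0.1, seed_point = c(2, 2))
  expect_error(skeletonize_mask(f), "farther than")
})

test_that("components away from the seed are ignored with a warning", {
  m <- bar_mask(120, 100, 10:80, 28:32)
  m[100:110, 70:72] <- 1L                     # debris far from the seed
  f <- mask_frame(m, 0, 0.1, seed_point = c(10, 30))
  expect_warning(sg <- skeletonize_mask(f), "ignoring")
  expect_length(sg$edges, 1)
})

test_that("skeletonizing a skeleton is idempotent up to one pixel step", {
  p <- sim_params(duration_h = 30, frame_interval_min = 60, mr_speed = 0.4,
                  mr_wobble_sd = 2, lr_emergence_rate = 0.3,
                  emergence_angle_mean = 60, emergence_angle_sd = 0,
                  maturation_lag_h = 8, seed = 4)
  gt <- simulate_root_system(p)
  fr <- render_frames(gt, render_params(px_mm = 0.05, stroke_width_px = 3),
                      frames = length(gt$times))
  sg <- suppressWarnings(skeletonize_mask(fr[[1]]))
  again <- skeletonize_mask(mask_frame(sg$skel, 0, fr[[1]]$px_mm,
                                       seed_point = fr[[1]]$seed_point -
                                         sg$crop_offset),
                            prune_len_mm = 0)
  len1 <- vapply(sg$edges, `[[`, numeric(1), "length_mm")
  len2 <- vapply(again$edges, `[[`, numeric(1), "length_mm")
  # topology is stable up to sub-pixel churn inside junction clusters,
  # and the total measured length moves by less than one pixel step per
  # chain (in practice well under 1%)
  expect_lte(abs(length(len2) - length(len1)), 2)
  expect_equal(sum(len2), sum(len1), tolerance = 0.01)
  # and the measured decomposition is unchanged: same MR within a step
  mr1 <- extract_main_root(sg)
  mr2 <- extract_main_root(again)
  expect_equal(mr2$length_mm, mr1$length_mm,
               tolerance = 2 * sqrt(2) * fr[[1]]$px_mm / mr1$length_mm)
})

test_that("MR plus laterals never exceeds the total skeleton length", {
  for (s in c(3, 8)) {
    p <- sim_params(duration_h = 48, frame_interval_min = 60, mr_speed = 0.35,
                    mr_wobble_sd = 2, lr_emergence_rate = 0.25,
                    emergence_angle_sd = 0, emergence_angle_mean = 60,
                    maturation_lag_h = 12, seed = s)
    gt <- simulate_root_system(p)
    fr <- render_frames(gt, render_params(px_mm = 0.04, stroke_width_px = 3),
                        frames = length(gt$times))
    sg <- suppressWarnings(skeletonize_mask(fr[[1]]))
    mr <- extract_main_root(sg)
    lrs <- extract_lateral_roots(sg, mr)
    total <- sum(vapply(sg$edges, `[[`, numeric(1), "length_mm"))
    parts <- mr$length_mm + sum(vapply(lrs, `[[`, numeric(1), "length_mm"))
    expect_lte(parts, total + 1e-9)
  }
})

test_that("the MR is the longest root-to-tip path", {
  # Y: stem 10 mm, branches 8 mm and 3 mm at px_mm = 0.1
  stem <- px_chain(c(10, 50), c(110, 50))
  long_branch <- px_chain(c(110, 50), c(190, 130))    # 80 diagonal steps
  short_branch <- px_chain(c(110, 50), c(140, 20))    # 30 diagonal steps
  sg <- make_sg(list(stem, long_branch, short_branch), root_px = c(10, 50))
  mr <- extract_main_root(sg)
  expect_equal(mr$length_mm, 10 + 8 * sqrt(2), tolerance = 1e-9)
  expect_equal(mr$chain[nrow(mr$chain), ], c(190, 130))
})

test_that("equal-length MR candidates break ties toward gravity", {
  stem <- px_chain(c(10, 50), c(60, 50))
  down <- px_chain(c(60, 50), c(100, 50))             # 40 steps, vertical
  side <- px_chain(c(60, 50), c(60, 90))              # 40 steps, horizontal
  sg <- make_sg(list(stem, down, side), root_px = c(10, 50))
  mr <- extract_main_root(sg)
  expect_equal(mr$chain[nrow(mr$chain), ], c(100, 50))
})

test_that("laterals hang off the MR with correct bases and length filter", {
  # T with one long and one sub-threshold arm
  stem <- px_chain(c(10, 50), c(110, 50))
  arm <- px_chain(c(60, 50), c(60, 80))               # 3 mm
  stub <- px_chain(c(90, 50), c(90, 54))              # 0.4 mm < 0.5 default
  sg <- make_sg(list(px_chain(c(10, 50), c(60, 50)),
                     px_chain(c(60, 50), c(90, 50)),
                     px_chain(c(90, 50), c(110, 50)), arm, stub),
                root_px = c(10, 50))
  mr <- extract_main_root(sg)
  lrs <- extract_lateral_roots(sg, mr)
  expect_length(lrs, 1)
  expect_equal(lrs[[1]]$base_px, c(60, 50))
  expect_equal(lrs[[1]]$base_arc_on_mr_mm, 5, tolerance = 1e-9)
  expect_equal(lrs[[1]]$length_mm, 3, tolerance = 1e-9)
  # lowering the filter keeps the stub too
  expect_length(extract_lateral_roots(sg, mr, min_lr_len_mm = 0.3), 2)
})
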