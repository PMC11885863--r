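test_that("gravity angles match closed forms", {
  expect_equal(gravity_angle(c(0, 0), c(0, 10)), 0)
  expect_equal(gravity_angle(c(0, 0), c(10, 0)), 90)
  expect_equal(gravity_angle(c(0, 0), c(3, 4)), 180 / pi * acos(4 / 5),
               tolerance = 1e-12)
  expect_equal(gravity_angle(c(0, 0), c(3, -4)), 180 / pi * acos(-4 / 5),
               tolerance = 1e-12)
  expect_error(gravity_angle(c(1, 1), c(1, 1)), "zero-length")
  # signed variant distinguishes sides
  expect_equal(gravity_angle(c(0, 0), c(1, 1), signed = TRUE), 45)
  expect_equal(gravity_angle(c(0, 0), c(-1, 1), signed = TRUE), -45)
})

test_that("base-tip angle uses endpoints only", {
  straight <- rbind(c(0, 0), c(3, 3))
  expect_equal(base_tip_angle(straight), 45)
  elbow <- rbind(c(0, 0), c(4, 0), c(4, 4))
  expect_equal(base_tip_angle(elbow), 45)
  expect_true(is.na(base_tip_angle(rbind(c(1, 2), c(1, 2)))))
  expect_error(base_tip_angle(rbind(c(0, 0))), ">= 2 points")
})

test_that("emergence angle traverses a fixed arc length", {
  th <- 30 * pi / 180
  line5 <- cbind(seq(0, 5 * sin(th), length.out = 60),
                 seq(0, 5 * cos(th), length.out = 60))
  for (d in c(0.5, 2, 5)) expect_equal(emergence_angle(line5, d), 30,
                                       tolerance = 1e-9)
  # a root shorter than the traversal distance has no emergence angle yet
  short <- line5 * 0.3                        # length 1.5 mm
  expect_true(is.na(emergence_angle(short, 2)))
  expect_error(emergence_angle(line5, -1), "> 0")
  # equals the base-tip angle exactly when length equals the distance
  curved <- cbind(cumsum(rep(0.05, 40)) * 0.9, cumsum(rep(0.05, 40)))
  L <- arc_length(curved)
  expect_equal(emergence_angle(curved, L), base_tip_angle(curved),
               tolerance = 1e-9)
})

test_that("emergence angle on a circular arc matches its chord angle", {
  # radius 2 mm, starting horizontal (+x) and curving downward; after a
  # 2-mm traversal the chord makes 90 - s/(2R) rad with gravity
  R <- 2
  phi <- seq(0, 1.2, length.out = 4000)       # arc length = R * phi
  arc <- cbind(R * sin(phi), R * (1 - cos(phi)))
  got <- emergence_angle(arc, 2)
  expect_equal(got, 90 - (2 / (2 * R)) * 180 / pi, tolerance = 1e-3)
  # and agrees with an independent computation on the same polyline
  ca <- cumsum(c(0, sqrt(rowSums(diff(arc)^2))))
  i <- which(ca >= 2)[1]
  f <- (2 - ca[i - 1]) / (ca[i] - ca[i - 1])
  pt <- arc[i - 1, ] + f * (arc[i, ] - arc[i - 1, ])
  expect_equal(got, 180 / pi * acos(pt[2] / sqrt(sum(pt^2))),
               tolerance = 1e-9)
})

test_that("an MR-referenced emergence angle is available", {
  line <- rbind(c(0, 0), c(3, 3 * sqrt(3)))   # 30 deg from +y
  expect_equal(emergence_angle(line, 2, reference = c(0, 1)), 30,
               tolerance = 1e-9)
  expect_equal(emergence_angle(line, 2, reference = c(1, 0)), 60,
               tolerance = 1e-9)
})

test_that("gravity-referenced angles are rotation-equivariant and scale-free", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    poly <- cbind(cumsum(runif(n, 0.1, 1)), cumsum(runif(n, 0.1, 1)))
    poly <- rbind(c(0, 0), poly)
    a0 <- base_tip_angle(poly)
    phi <- runif(1, -30, 30)
    rot <- phi * pi / 180
    Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    rotated <- t(Rm %*% t(poly))     # rotates the unsigned angle by -phi
    if (a0 - phi >= 0 && a0 - phi <= 180)
      expect_equal(base_tip_angle(rotated), a0 - phi, tolerance = 1e-9)
    expect_equal(base_tip_angle(poly * 3.7), a0, tolerance = 1e-12)
  }
})

test_that("MR tip angle measures the final window", {
  vert <- cbind(rep(0, 50), seq(0, 10, length.out = 50))
  expect_equal(mr_tip_angle(vert), 0)
  hook <- rbind(cbind(rep(0, 50), seq(0, 5, length.out = 50)),
                cbind(seq(0.02, 1, length.out = 49), rep(5, 49)))
  expect_equal(mr_tip_angle(hook, 1), 90, tolerance = 1e-6)
  bent <- rbind(cbind(rep(0, 40), seq(0, 4, length.out = 40)),
                cbind(seq(0.025, 1, length.out = 40) * sin(25 * pi / 180),
                      4 + seq(0.025, 1, length.out = 40) * cos(25 * pi / 180)))
  expect_equal(mr_tip_angle(bent, 0.8), 25, tolerance = 2)
  expect_true(is.na(mr_tip_angle(vert[1:2, ] * 0.005, 1)))
})

test_that("measured base-tip series declines monotonically under bending", {
  p <- sim_params(duration_h = 72, frame_interval_min = 60,
                  lr_emergence_rate = 0.2, maturation_lag_h = 10,
                  emergence_angle_mean = 80, emergence_angle_sd = 0,
                  final_angle = 30, decay_rate_kappa = 0.05, seed = 3)
  gt <- simulate_root_system(p)
  for (lr in gt$lrs) {
    bt <- lr$base_tip_deg[-1]
    if (length(bt) > 1) expect_true(all(diff(bt) <= 1e-9))
  }
})

test_that("first-LR decay curves aggregate per plant and hour", {
  p1 <- tibble::tibble(plant_id = "a", lr_label = c(1, 1, 2),
                       timestamp_h = c(10, 11, 12),
                       hours_since_emergence = c(0, 1, 0),
                       lr_length_mm = 1:3, base_tip_deg = c(80, 70, 60),
                       emergence_deg = NA_real_)
  p2 <- p1; p2$plant_id <- "b"; p2$base_tip_deg <- c(90, 80, 70)
  out <- first_lr_decay_curve(rbind(p1, p2))
  expect_equal(nrow(out$per_plant), 4)        # label 1 rows only
  expect_equal(out$cohort$mean_deg, c(85, 75))
  expect_equal(out$cohort$n, c(2L, 2L))
  p3 <- tibble::tibble(plant_id = "c", lr_label = integer(0),
                       timestamp_h = numeric(0),
                       hours_since_emergence = numeric(0),
                       lr_length_mm = numeric(0),
                       base_tip_deg = numeric(0),
                       emergence_deg = numeric(0))
  expect_warning(first_lr_decay_curve(rbind(p1, p3)), NA)
})

test_that("decay fitting recovers the relaxation rate", {
  tau <- seq(0, 60, by = 1)
  true <- c(theta_e = 90, final_angle = 30, kappa = 0.0385)
  chord <- roottrack:::chord_angle_model(tau, 90, 30, 0.0385)
  fit <- fit_decay_curve(tau, chord + rnorm(length(tau), 0, 0.2),
                         model = "chord")
  expect_equal(unname(fit["kappa"]), 0.0385, tolerance = 0.1)
  # kappa = 0 gives a flat curve at theta_e
  flat <- roottrack:::chord_angle_model(tau, 70, 30, 0)
  expect_equal(flat, rep(70, length(tau)), tolerance = 1e-9)
})
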