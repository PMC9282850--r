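test_that("a plate of +z-oriented pairs gives the exact frame", {
  rec <- static_plate_recording(20)
  fr <- estimate_frame(rec, 1)
  expect_equal(abs(fr$axis[3]), 1, tolerance = 1e-12)
  expect_equal(fr$centroid, apply(rec$pos[1, , ], 1, mean))
  expect_equal(fr$centroid[3], 0)
  expect_length(fr$included, 20)
})

test_that("frame estimation is equivariant under rigid rotation", {
  rec <- static_plate_recording(12, icd = 1.2)
  set.seed(21)
  rot <- rotation_about(rnorm(3), 0.9)
  rec2 <- rigid_transform_recording(rec, rot, c(4, 5, -6))
  f1 <- estimate_frame(rec, 1)
  f2 <- estimate_frame(rec2, 1)
  expect_equal(abs(sum(f2$axis * (rot %*% f1$axis))), 1, tolerance = 1e-9)
  expect_equal(f2$centroid, as.numeric(rot %*% f1$centroid + c(4, 5, -6)),
               tolerance = 1e-9)
})

test_that("estimated axis matches a brute-force hemisphere grid search", {
  # 20 pairs perturbed ~10 deg about a known axis; oracle maximizes the
  # mean squared dot product over a 1-degree hemisphere grid.
  set.seed(7)
  true_axis <- unit(c(0.3, -0.2, 0.93))
  n <- 20
  base <- rotation_about(c(0, 0, 1), 0)   # identity
  U <- sapply(seq_len(n), function(i) {
    tilt <- rotation_about(unit(rnorm(3)), abs(rnorm(1, 0, 10)) * pi / 180)
    as.numeric(tilt %*% true_axis)
  })
  nt <- 5
  pos <- array(NA_real_, c(nt, 3, 2 * n))
  ang <- 2 * pi * seq_len(n) / n
  for (i in seq_len(n)) {
    mid <- c(2.5 * cos(ang[i]), 2.5 * sin(ang[i]), 0)
    mid <- mid - sum(mid * true_axis) * true_axis   # put plate on equator
    for (tt in seq_len(nt)) {
      pos[tt, , 2 * i - 1] <- mid - 0.8 * U[, i]
      pos[tt, , 2 * i] <- mid + 0.8 * U[, i]
    }
  }
  rec <- oocyte_recording(
    "grid", "test", 2, seq(0, 8, 2),
    data.frame(chromosome_id = rep(seq_len(n), each = 2),
               sister_index = rep(0:1, n)), pos)
  fr <- estimate_frame(rec, 1)

  # brute-force oracle on a 1-degree grid
  th <- seq(0, 90, by = 1) * pi / 180
  ph <- seq(0, 359, by = 1) * pi / 180
  grid <- cbind(rep(sin(th), each = length(ph)) * cos(ph),
                rep(sin(th), each = length(ph)) * sin(ph),
                rep(cos(th), each = length(ph)))
  score <- rowMeans((grid %*% U)^2)
  oracle_axis <- grid[which.max(score), ]

  ang_to <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi
  expect_lt(ang_to(fr$axis, true_axis), 3)
  expect_lt(ang_to(fr$axis, oracle_axis), 0.5)
})

test_that("degenerate and underpopulated inputs raise estimation errors", {
  rec <- static_plate_recording(2)
  expect_error(estimate_frame(rec, 1), ">= 3 chromosomes")
  # all connection vectors exactly in the plate plane, equally spaced:
  # no dominant direction
  n <- 8
  nt <- 3
  pos <- array(NA_real_, c(nt, 3, 2 * n))
  for (i in seq_len(n)) {
    u <- c(cos(pi * i / n), sin(pi * i / n), 0)
    mid <- c(2 * cos(2 * pi * i / n), 2 * sin(2 * pi * i / n), 0)
    for (tt in seq_len(nt)) {
      pos[tt, , 2 * i - 1] <- mid - 0.8 * u
      pos[tt, , 2 * i] <- mid + 0.8 * u
    }
  }
  rec <- oocyte_recording(
    "degen", "test", 2, c(0, 2, 4),
    data.frame(chromosome_id = rep(seq_len(n), each = 2),
               sister_index = rep(0:1, n)), pos)
  expect_error(estimate_frame(rec, 1), "degenerate")
})

test_that("hand-geometry metric examples are exact", {
  # chromosome 1: sisters straddling the equator along z -> icd 1.6,
  # angle 0, zero distances; chromosome 2: sisters (0,0,0)/(1,0,1) plus
  # two plate-filling pairs so the axis stays estimable.
  nt <- 12
  times <- seq(0, by = 2, length.out = nt)
  pos <- array(0, c(nt, 3, 8))
  for (tt in seq_len(nt)) {
    pos[tt, , 1] <- c(0, 0, -0.8); pos[tt, , 2] <- c(0, 0, 0.8)
    pos[tt, , 3] <- c(0, 0, 0);    pos[tt, , 4] <- c(1, 0, 1)
    pos[tt, , 5] <- c(2, 0, -0.6); pos[tt, , 6] <- c(2, 0, 0.6)
    pos[tt, , 7] <- c(-2, 1, -0.6); pos[tt, , 8] <- c(-2, 1, 0.6)
  }
  rec <- oocyte_recording(
    "hand", "test", 2, times,
    data.frame(chromosome_id = rep(1:4, each = 2),
               sister_index = rep(0:1, 4)), pos)
  sm <- smooth_recording(rec, 0.35)
  idx <- seq_len(nt - 1)
  frames <- estimate_frames(sm, idx)
  # force the exact frame the example states (centroid at origin, axis z):
  frames <- lapply(frames, function(f) {
    f$axis <- c(0, 0, 1); f$centroid <- c(0, 0, 0); f
  })
  met <- compute_metrics(sm, frames, onset_min = times[nt],
                         window_min = 40)
  m1 <- met[met$chromosome_id == 1, ]
  expect_equal(m1$mean_icd_um, 1.6, tolerance = 1e-9)
  expect_equal(m1$mean_angle_deg, 0, tolerance = 1e-9)
  expect_equal(m1$max_dist_to_equator_um, 0, tolerance = 1e-9)
  expect_equal(m1$max_dist_to_axis_um, 0, tolerance = 1e-9)
  expect_equal(m1$mean_speed_um_per_min, 0, tolerance = 1e-9)
  m2 <- met[met$chromosome_id == 2, ]
  expect_equal(m2$mean_angle_deg, 45, tolerance = 1e-9)
  expect_equal(m2$max_dist_to_equator_um, 0.5, tolerance = 1e-9)
  expect_equal(m2$max_dist_to_axis_um, 0.5, tolerance = 1e-9)
  expect_equal(m2$mean_icd_um, sqrt(2), tolerance = 1e-9)
})

test_that("angle folding makes sister relabeling irrelevant", {
  cfg <- generator_config("aged")
  sim <- simulate_oocyte(cfg, seed = 14)
  a1 <- analyze_oocyte(sim$recording)
  a2 <- analyze_oocyte(relabel_sisters(sim$recording))
  expect_equal(a1$metrics$mean_angle_deg, a2$metrics$mean_angle_deg,
               tolerance = 1e-9)
  expect_equal(a1$metrics$mean_icd_um, a2$metrics$mean_icd_um,
               tolerance = 1e-9)
})

test_that("noise-free generator output recovers icd and angle exactly", {
  cfg <- clean_config(p_oocyte_aberrant = 0)
  sim <- simulate_oocyte(cfg, seed = 5)
  a <- analyze_oocyte(sim$recording)
  expect_equal(a$metrics$mean_icd_um, rep(1.6, 20), tolerance = 1e-6)
  expect_equal(a$metrics$mean_angle_deg, rep(7.5, 20), tolerance = 1e-6)
  # raw generated frame-to-frame speed is exactly the configured speed
  meta <- sim$recording$times <= cfg$metaphase_duration_min
  ss <- sister_slices(sim$recording)
  mid <- (sim$recording$pos[meta, , ss$s0[1]] +
            sim$recording$pos[meta, , ss$s1[1]]) / 2
  sp <- speeds_from_positions(sim$recording$times[meta], mid)
  expect_equal(sp[-1], rep(0.18, sum(meta) - 1), tolerance = 1e-9)
})

test_that("metrics are invariant under rigid transforms of the recording", {
  cfg <- generator_config("aged")
  sim <- simulate_oocyte(cfg, seed = 31)
  set.seed(32)
  rot <- rotation_about(rnorm(3), 2.2)
  rec2 <- rigid_transform_recording(sim$recording, rot, c(-8, 3, 12))
  a1 <- analyze_oocyte(sim$recording)
  a2 <- analyze_oocyte(rec2)
  for (col in c("max_dist_to_equator_um", "max_dist_to_axis_um",
                "mean_angle_deg", "mean_speed_um_per_min", "mean_icd_um")) {
    expect_equal(a1$metrics[[col]], a2$metrics[[col]], tolerance = 1e-6)
  }
  expect_equal(as.character(a1$calls$pattern), as.character(a2$calls$pattern))
})

test_that("window with fewer than 2 frames raises a metrics error", {
  rec <- static_plate_recording(5, n_time = 8)
  sm <- smooth_recording(rec, 0.35)
  frames <- estimate_frames(sm, 1:8)
  expect_error(compute_metrics(sm, frames, onset_min = 2, window_min = 40),
               "fewer than 2 frames")
})
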