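test_that("the keypoint schema has the canonical 14 names in order", {
  nms <- keypoint_names()
  expect_length(nms, 14)
  expect_identical(nms, c("nose", "neck",
                          "shoulder_r", "elbow_r", "wrist_r",
                          "shoulder_l", "elbow_l", "wrist_l",
                          "hip_r", "knee_r", "ankle_r",
                          "hip_l", "knee_l", "ankle_l"))
})

test_that("keypoint sequences round-trip through CSV and JSON", {
  s <- test_walk(20, noise_sd = 1, seed = 2)
  s$x[3, 5] <- NA  # a missing slot survives the round trip
  s$y[3, 5] <- NA
  s$missing <- is.na(s$x) | is.na(s$y)
  td <- withr::local_tempdir()
  write_keypoints_csv(s, file.path(td, "kp.csv"))
  s2 <- read_keypoints_csv(file.path(td, "kp.csv"), dt = s$dt)
  expect_equal(s2$x, s$x)
  expect_equal(s2$missing, s$missing)
  write_keypoints_json(s, file.path(td, "kp.json"))
  s3 <- read_keypoints_json(file.path(td, "kp.json"))
  expect_equal(s3$y, s$y)
})

test_that("subject tracking follows the nearest-assignment oracle", {
  set.seed(11)
  n <- 30
  walkerA <- test_walk(n, seed = 3)
  walkerB <- test_walk(n, seed = 4)
  # separate the walkers by far more than their per-frame step
  walkerB$x <- walkerB$x + 2000
  frames <- lapply(seq_len(n), function(i) {
    cands <- list(
      list(coords = cbind(walkerB$x[i, ], walkerB$y[i, ])),
      list(coords = cbind(walkerA$x[i, ], walkerA$y[i, ])))
    cands[sample(2)]  # shuffle candidate order
  })
  tr <- track_subject(frames, cbind(walkerA$x[1, ], walkerA$y[1, ]))
  expect_equal(tr$x, walkerA$x, ignore_attr = TRUE)
  # brute-force oracle frame by frame
  for (i in 2:n) {
    dA <- sum(sqrt((walkerA$x[i, ] - tr$x[i - 1, ])^2 +
                   (walkerA$y[i, ] - tr$y[i - 1, ])^2))
    dB <- sum(sqrt((walkerB$x[i, ] - tr$x[i - 1, ])^2 +
                   (walkerB$y[i, ] - tr$y[i - 1, ])^2))
    expect_lt(dA, dB)
  }
})

test_that("tracking marks empty frames missing and resumes", {
  s <- test_walk(10, seed = 5)
  frames <- lapply(seq_len(10), function(i) {
    if (i == 4) list() else list(list(coords = cbind(s$x[i, ], s$y[i, ])))
  })
  tr <- track_subject(frames, cbind(s$x[1, ], s$y[1, ]))
  expect_true(all(tr$missing[4, ]))
  expect_false(any(tr$missing[5, ]))
})

test_that("kalman filtering tracks a constant-velocity target", {
  s <- linear_track(60)
  sm <- kalman_smooth(s)
  burn <- 10:60
  expect_lt(max(abs(sm$x[burn, ] - s$x[burn, ]) / pmax(abs(s$x[burn, ]), 1)),
            0.01)
})

test_that("kalman filtering reduces noise against ground truth", {
  truth <- test_walk(100, seed = 6)
  for (sd_i in 1:20) {
    noisy <- truth
    set.seed(sd_i)
    noisy$x <- truth$x + matrix(rnorm(length(truth$x), 0, 5), nrow(truth$x))
    noisy$y <- truth$y + matrix(rnorm(length(truth$y), 0, 5), nrow(truth$y))
    sm <- kalman_smooth(noisy, meas_var = 25)
    rmse_raw <- sqrt(mean((noisy$x - truth$x)^2 + (noisy$y - truth$y)^2))
    rmse_sm <- sqrt(mean((sm$x - truth$x)^2 + (sm$y - truth$y)^2))
    expect_lt(rmse_sm, rmse_raw)
  }
})

test_that("kalman prediction bridges gaps with finite values", {
  s <- linear_track(30)
  s$x[10:12, ] <- NA
  s$y[10:12, ] <- NA
  sm <- kalman_smooth(s)
  expect_true(all(is.finite(sm$x)))
  expect_true(all(is.finite(sm$y)))
})

test_that("interpolation fills missing points on the connecting line", {
  s <- linear_track(10, vx = 1, vy = 1)
  # make one keypoint trace (0,0) -> missing -> (2,2)
  s$x[, 1] <- 0:9; s$y[, 1] <- 0:9
  s$x[2, 1] <- NA; s$y[2, 1] <- NA
  out <- remove_peaks_interpolate(s)
  expect_equal(out$x[2, 1], 1, ignore_attr = TRUE)
  expect_equal(out$y[2, 1], 1, ignore_attr = TRUE)
})

test_that("an isolated huge spike is removed and refilled", {
  s <- linear_track(50, vx = 2, vy = 0)
  clean <- s
  s$x[25, 3] <- s$x[25, 3] + 100 * 2   # 100x the median step
  out <- remove_peaks_interpolate(s)
  expect_lt(abs(out$x[25, 3] - clean$x[25, 3]), 1)
})

test_that("cleaning is the identity on already-clean tracks", {
  s <- linear_track(40)
  out <- remove_peaks_interpolate(s)
  expect_equal(out$x, s$x)
  expect_equal(out$y, s$y)
  # idempotence of the full cleaning stage (within filter steady state)
  c1 <- clean_sequence(s)
  c2 <- clean_sequence(c1)
  expect_lt(max(abs(c2$x[10:40, ] - c1$x[10:40, ])), 0.5)
})

test_that("an all-missing keypoint channel is unrecoverable", {
  s <- linear_track(10)
  s$x[, 2] <- NA
  expect_error(remove_peaks_interpolate(s), "unrecoverable-channel")
})

test_that("kinematics of a 3-4-5 step and the printed acceleration rule", {
  x <- matrix(rep(c(0, 3), each = 14), nrow = 2, byrow = TRUE)
  y <- matrix(rep(c(0, 4), each = 14), nrow = 2, byrow = TRUE)
  s <- keypoint_sequence(x, y, dt = 1)
  kin <- compute_kinematics(s)
  expect_equal(kin$d, 5)
  expect_equal(kin$v, 5)
  expect_equal(kin$a, 5)      # printed rule a = v / dt with dt = 1
  kin2 <- compute_kinematics(s, acceleration = "difference")
  expect_equal(kin2$a, 5)     # first step: (v - 0) / dt
  expect_error(compute_kinematics(keypoint_sequence(x[1, , drop = FALSE],
                                                    y[1, , drop = FALSE])),
               "2 frames")
})

test_that("tangent angle is quadrant-aware", {
  mk <- function(dx, dy) {
    x <- matrix(rep(c(0, dx), each = 14), nrow = 2, byrow = TRUE)
    y <- matrix(rep(c(0, dy), each = 14), nrow = 2, byrow = TRUE)
    compute_kinematics(keypoint_sequence(x, y, dt = 1))$rho
  }
  expect_equal(mk(1, 0), 0)
  expect_equal(mk(-1, 0), pi)
  expect_equal(mk(0, 1), pi / 2)
  expect_equal(mk(0, -1), -pi / 2)
})

test_that("temporal channels match a brute-force oracle on random sequences", {
  set.seed(12)
  for (rep_i in 1:100) {
    n <- sample(3:8, 1)
    dt <- runif(1, 0.01, 0.2)
    x <- matrix(rnorm(n * 14), n, 14)
    y <- matrix(rnorm(n * 14), n, 14)
    s <- keypoint_sequence(x, y, dt = dt)
    kin <- compute_kinematics(s)
    px <- rowMeans(x); py <- rowMeans(y)
    for (i in seq_len(n - 1)) {
      dxi <- px[i + 1] - px[i]
      dyi <- py[i + 1] - py[i]
      di <- sqrt(dxi^2 + dyi^2)
      expect_equal(kin$dx[i], dxi, tolerance = 1e-12)
      expect_equal(kin$dy[i], dyi, tolerance = 1e-12)
      expect_equal(kin$d[i], di, tolerance = 1e-12)
      expect_equal(kin$v[i], di / dt, tolerance = 1e-12)
      expect_equal(kin$vx[i], dxi / dt, tolerance = 1e-12)
      expect_equal(kin$vy[i], dyi / dt, tolerance = 1e-12)
      expect_equal(kin$a[i], di / dt / dt, tolerance = 1e-12)
      expect_equal(kin$ax[i], dxi / dt / dt, tolerance = 1e-12)
      expect_equal(kin$ay[i], dyi / dt / dt, tolerance = 1e-12)
      expect_equal(kin$rho[i], atan2(dyi, dxi), tolerance = 1e-12)
    }
  }
})

test_that("corner angles handle collinear, right-angle and random cases", {
  x <- y <- rep(0, 14)
  # collinear nose-neck-hip along the y axis
  x[1] <- 0; y[1] <- 0        # nose
  x[2] <- 0; y[2] <- 1        # neck
  x[9] <- 0; y[9] <- 2        # hip_r
  x[12] <- 0; y[12] <- 2      # hip_l
  a <- compute_angles(x, y)
  expect_equal(unname(a["nose_neck_hip"]), pi)
  # right angle at the elbow: shoulder (0,0), elbow (0,1), wrist (1,1)
  x2 <- y2 <- rep(NA_real_, 14)
  x2[3] <- 0; y2[3] <- 0
  x2[4] <- 0; y2[4] <- 1
  x2[5] <- 1; y2[5] <- 1
  a2 <- compute_angles(x2, y2)
  expect_equal(unname(a2["shoulder_elbow_wrist"]), pi / 2)
  expect_true(is.na(a2["hip_knee_ankle"]))
  # random triples against an explicit vector-math oracle
  set.seed(13)
  for (i in 1:50) {
    x3 <- rnorm(14); y3 <- rnorm(14)
    a3 <- compute_angles(x3, y3)
    u <- c(x3[9] - x3[10], y3[9] - y3[10])      # hip_r - knee_r
    w <- c(x3[11] - x3[10], y3[11] - y3[10])    # ankle_r - knee_r
    oracle <- acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2)))
    expect_equal(unname(a3["hip_knee_ankle"]), oracle, tolerance = 1e-12)
  }
  # degenerate zero-length limb
  x4 <- rnorm(14); y4 <- rnorm(14)
  x4[4] <- x4[5]; y4[4] <- y4[5]   # wrist on top of elbow
  expect_true(is.na(compute_angles(x4, y4)["shoulder_elbow_wrist"]))
})

test_that("the default feature vector has 30 documented slots", {
  s <- test_walk(60, seed = 7)
  f <- extract_gait_features(s, clean = FALSE)
  expect_length(f$summary, 30)
  expect_identical(names(f$summary), default_feature_layout())
  expect_identical(ncol(f$channels), 15L)
  # permuting the layout permutes the values identically
  perm <- sample(default_feature_layout())
  f2 <- assemble_feature_vector(f$channels, f$slog, layout = perm)
  expect_identical(unname(f2), unname(f$summary[perm]))
  expect_error(assemble_feature_vector(f$channels, f$slog,
                                       layout = c("nope")),
               "layout/feature mismatch")
})

test_that("constant channels summarize to the constant with zero spread", {
  ch <- matrix(3, nrow = 10, ncol = 15,
               dimnames = list(NULL, c(gaitshield:::TEMPORAL_CHANNELS,
                                       gaitshield:::ANGLE_CHANNELS)))
  v <- assemble_feature_vector(ch, NULL)
  expect_true(all(v[paste0("mean_", colnames(ch))] == 3))
  # the default layout carries spreads for the temporal channels
  expect_true(all(v[paste0("sd_", gaitshield:::TEMPORAL_CHANNELS)] == 0))
})
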