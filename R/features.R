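#' Gait kinematic channels and joint angles
#'
#' From a cleaned keypoint sequence the per-frame channels extracted are:
#' step displacement `d`, its components `dx`, `dy`, velocity `v`, `vx`,
#' `vy`, acceleration `a`, `ax`, `ay`, the tangent angle `rho`, and five
#' corner (joint) angles: nose-neck-hip, neck-hip-knee,
#' shoulder-elbow-wrist, hip-knee-ankle and right knee-hip-left knee.
#'
#' The temporal channels follow the stepwise definitions
#' \eqn{\Delta x_i = x_{i+1} - x_i}, \eqn{d_i = \sqrt{\Delta x_i^2 +
#' \Delta y_i^2}}, \eqn{v_i = d_i / \Delta t}, and — in the default
#' `"ratio"` convention — \eqn{a_i = v_i / \Delta t} (the ratio of speed to
#' the frame interval; the conventional finite-difference
#' \eqn{a_i = \Delta v_i / \Delta t} is available via
#' `acceleration = "difference"`). The tangent angle uses the quadrant-aware
#' two-argument arctangent `atan2(dy, dx)` so direction reversals (the
#' subject walks the track both ways) are not aliased onto the same angle.
#'
#' @name gait-features
NULL

TEMPORAL_CHANNELS <- c("d", "dx", "dy", "v", "vx", "vy", "a", "ax", "ay", "rho")
ANGLE_CHANNELS <- c("nose_neck_hip", "neck_hip_knee", "shoulder_elbow_wrist",
                    "hip_knee_ankle", "knee_hip_knee")

#' Compute per-step kinematic channels
#'
#' The reference trajectory is the body centroid of each frame (mean of all
#' 14 keypoints), the standard whole-body reduction for sagittal gait;
#' `point` selects a single named keypoint instead.
#'
#' @param seq a cleaned `keypoint_sequence` with at least 2 frames.
#' @param acceleration `"ratio"` for `a = v / dt` (default) or
#'   `"difference"` for `a = diff(v) / dt`.
#' @param point optional keypoint name to track instead of the centroid.
#' @return a `gait_feature_sequence`: data frame with `n_frames - 1` rows
#'   and the ten temporal channels.
#' @export
compute_kinematics <- function(seq, acceleration = c("ratio", "difference"),
                               point = NULL) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  acceleration <- match.arg(acceleration)
  if (nrow(seq$x) < 2) stop("at least 2 frames are required")
  if (is.null(point)) {
    px <- rowMeans(seq$x, na.rm = TRUE)
    py <- rowMeans(seq$y, na.rm = TRUE)
  } else {
    k <- match(point, keypoint_names())
    if (is.na(k)) stop("unknown keypoint: ", point)
    px <- seq$x[, k]
    py <- seq$y[, k]
  }
  dt <- seq$dt
  dx <- diff(px)
  dy <- diff(py)
  d <- sqrt(dx^2 + dy^2)
  v <- d / dt
  vx <- dx / dt
  vy <- dy / dt
  if (acceleration == "ratio") {
    a <- v / dt
    ax <- vx / dt
    ay <- vy / dt
  } else {
    # finite difference from rest: a_1 = v_1 / dt, a_i = (v_i - v_{i-1}) / dt
    a <- diff(c(0, v)) / dt
    ax <- diff(c(0, vx)) / dt
    ay <- diff(c(0, vy)) / dt
  }
  rho <- atan2(dy, dx)
  out <- data.frame(d = d, dx = dx, dy = dy, v = v, vx = vx, vy = vy,
                    a = a, ax = ax, ay = ay, rho = rho)
  class(out) <- c("gait_feature_sequence", class(out))
  attr(out, "dt") <- dt
  out
}

# Interior angle at b formed by segments b->a and b->c, in [0, pi].
angle_at <- function(a, b, c) {
  u <- a - b
  w <- c - b
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (!is.finite(nu) || !is.finite(nw) || nu == 0 || nw == 0) return(NA_real_)
  cosang <- sum(u * w) / (nu * nw)
  acos(pmin(1, pmax(-1, cosang)))
}

#' Compute the five corner angles of one frame
#'
#' Each angle is the interior angle at the middle joint, `acos` of the
#' normalized dot product of the two limb vectors, in `[0, pi]` radians.
#' The nose-neck-hip angle uses the hip midpoint; the single-sided angles
#' (neck-hip-knee, shoulder-elbow-wrist, hip-knee-ankle) are computed on
#' the chosen `side`; knee-hip-knee uses the hip midpoint as vertex between
#' the two knees. Degenerate (zero-length) limb vectors or missing
#' keypoints give `NA` for that angle.
#'
#' @param frame_x,frame_y length-14 coordinate vectors for one frame (in
#'   [keypoint_names()] order).
#' @param side `"right"` (default) or `"left"` for the single-sided angles.
#' @return named numeric vector of the 5 angles in radians.
#' @export
compute_angles <- function(frame_x, frame_y, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(length(frame_x) == N_KEYPOINTS, length(frame_y) == N_KEYPOINTS)
  kp <- function(name) {
    k <- match(name, keypoint_names())
    c(frame_x[k], frame_y[k])
  }
  sfx <- if (side == "right") "_r" else "_l"
  hip_mid <- (kp("hip_r") + kp("hip_l")) / 2
  out <- c(
    nose_neck_hip = angle_at(kp("nose"), kp("neck"), hip_mid),
    neck_hip_knee = angle_at(kp("neck"), kp(paste0("hip", sfx)),
                             kp(paste0("knee", sfx))),
    shoulder_elbow_wrist = angle_at(kp(paste0("shoulder", sfx)),
                                    kp(paste0("elbow", sfx)),
                                    kp(paste0("wrist", sfx))),
    hip_knee_ankle = angle_at(kp(paste0("hip", sfx)), kp(paste0("knee", sfx)),
                              kp(paste0("ankle", sfx))),
    knee_hip_knee = angle_at(kp("knee_r"), hip_mid, kp("knee_l")))
  out
}

#' Per-frame channel matrix for sequence models
#'
#' Stacks the ten temporal channels and the five corner angles into a
#' `(n_frames - 1) x 15` matrix (angles taken at the step's starting frame),
#' the multivariate time series consumed by the classifier and, framewise,
#' by the protection scheme.
#'
#' @inheritParams compute_kinematics
#' @param side side for single-sided angles.
#' @return numeric matrix with named columns.
#' @export
gait_channel_matrix <- function(seq, acceleration = "ratio", side = "right") {
  kin <- compute_kinematics(seq, acceleration = acceleration)
  tf <- nrow(seq$x)
  ang <- t(vapply(seq_len(tf - 1), function(i) {
    compute_angles(seq$x[i, ], seq$y[i, ], side = side)
  }, numeric(5)))
  out <- cbind(as.matrix(kin), ang)
  colnames(out) <- c(TEMPORAL_CHANNELS, ANGLE_CHANNELS)
  out
}

#' Assemble the length-j protected feature vector
#'
#' For the protection stage a recording is summarized into a fixed-length
#' vector. The default 30-slot layout is: mean of each of the 10 temporal
#' channels, standard deviation of each of the 10 temporal channels, mean
#' of each of the 5 corner angles, then 5 sigma-lognormal globals
#' (stroke count and the per-stroke means of D, mu, sigma and theta).
#'
#' @param channels matrix from [gait_channel_matrix()].
#' @param slog a `sigma_lognormal_params` object (see
#'   [sigma_lognormal_decompose()]), or `NULL` for zeros.
#' @param layout character vector naming the slots; permuting it permutes
#'   the output identically. Default [default_feature_layout()].
#' @return named numeric vector of length `length(layout)`.
#' @export
assemble_feature_vector <- function(channels, slog = NULL,
                                    layout = default_feature_layout()) {
  mu <- colMeans(channels, na.rm = TRUE)
  sdv <- apply(channels, 2, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv)] <- 0
  if (is.null(slog)) {
    sl <- c(slog_n = 0, slog_D = 0, slog_mu = 0, slog_sigma = 0, slog_theta = 0)
  } else {
    stopifnot(inherits(slog, "sigma_lognormal_params"))
    s <- slog$strokes
    sl <- c(slog_n = nrow(s),
            slog_D = if (nrow(s)) mean(s$D) else 0,
            slog_mu = if (nrow(s)) mean(s$mu) else 0,
            slog_sigma = if (nrow(s)) mean(s$sigma) else 0,
            slog_theta = if (nrow(s)) mean((s$theta_start + s$theta_end) / 2) else 0)
  }
  pool <- c(stats::setNames(mu, paste0("mean_", names(mu))),
            stats::setNames(sdv, paste0("sd_", names(sdv))),
            sl)
  bad <- setdiff(layout, names(pool))
  if (length(bad)) {
    stop("layout/feature mismatch: unknown slots ", paste(bad, collapse = ", "))
  }
  out <- pool[layout]
  out[!is.finite(out)] <- 0
  out
}

#' @rdname assemble_feature_vector
#' @export
default_feature_layout <- function() {
  c(paste0("mean_", TEMPORAL_CHANNELS),
    paste0("sd_", TEMPORAL_CHANNELS),
    paste0("mean_", ANGLE_CHANNELS),
    "slog_n", "slog_D", "slog_mu", "slog_sigma", "slog_theta")
}

#' Extract features for one recording
#'
#' Runs the full per-recording path: cleaning (unless `clean = FALSE`),
#' channel matrix, sigma-lognormal decomposition of the speed profile, and
#' the pooled length-30 summary vector.
#'
#' @param seq a `keypoint_sequence`.
#' @param clean apply [clean_sequence()] first (default `TRUE`).
#' @param acceleration,side passed to [gait_channel_matrix()].
#' @param ... passed to [clean_sequence()].
#' @return list with `channels` (matrix), `slog`
#'   (`sigma_lognormal_params`), `summary` (named length-30 vector).
#' @export
extract_gait_features <- function(seq, clean = TRUE, acceleration = "ratio",
                                  side = "right", ...) {
  if (clean) seq <- clean_sequence(seq, ...)
  ch <- gait_channel_matrix(seq, acceleration = acceleration, side = side)
  tgrid <- seq$dt * (seq_len(nrow(ch)) - 1)
  slog <- sigma_lognormal_decompose(ch[, "v"], tgrid, tangent = ch[, "rho"])
  list(channels = ch, slog = slog,
       summary = assemble_feature_vector(ch, slog))
}
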