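#' Keypoint preprocessing: tracking, smoothing, cleaning
#'
#' Pose estimators emit per-frame detections for every visible person, with
#' missing keypoints and occasional coordinate spikes. The pipeline applied
#' before feature extraction is, in order: subject isolation by Euclidean
#' distance to the previous frame's selection, per-keypoint constant-velocity
#' Kalman filtering, then spike removal with linear interpolation of missing
#' samples.
#'
#' @name preprocessing
NULL

#' Isolate one subject from multi-person detections
#'
#' Starting from the target's coordinates in the first frame, each following
#' frame selects the candidate whose keypoints have the smallest summed
#' Euclidean distance (over jointly available keypoints) to the previously
#' selected coordinates. Frames with no candidate are marked missing and
#' tracking resumes from the last good selection.
#'
#' @param frames a list; element `i` is itself a list of candidate persons
#'   for frame `i`, each candidate a list with `coords` (14 x 2 matrix, NA
#'   rows for undetected keypoints) and optional `conf` (length-14).
#' @param initial_coords 14 x 2 matrix identifying the target in frame 1.
#' @param dt,subject_id,direction metadata for the output sequence.
#' @return a `keypoint_sequence` for the tracked subject.
#' @export
track_subject <- function(frames, initial_coords, dt = 1 / 30,
                          subject_id = NA_character_,
                          direction = "left_to_right") {
  if (!length(frames)) stop("empty sequence")
  tf <- length(frames)
  x <- y <- matrix(NA_real_, tf, N_KEYPOINTS)
  conf <- matrix(0, tf, N_KEYPOINTS)
  ref <- as.matrix(initial_coords)
  stopifnot(nrow(ref) == N_KEYPOINTS, ncol(ref) == 2)
  for (i in seq_len(tf)) {
    cands <- frames[[i]]
    if (!length(cands)) next  # no detection: missing frame
    d <- vapply(cands, function(p) {
      cc <- as.matrix(p$coords)
      ok <- stats::complete.cases(cc) & stats::complete.cases(ref)
      if (!any(ok)) return(Inf)
      sum(sqrt(rowSums((cc[ok, , drop = FALSE] - ref[ok, , drop = FALSE])^2)))
    }, 0)
    if (all(!is.finite(d))) next
    sel <- cands[[which.min(d)]]
    cc <- as.matrix(sel$coords)
    x[i, ] <- cc[, 1]
    y[i, ] <- cc[, 2]
    conf[i, ] <- if (!is.null(sel$conf)) sel$conf else as.numeric(stats::complete.cases(cc))
    upd <- stats::complete.cases(cc)
    ref[upd, ] <- cc[upd, , drop = FALSE]
  }
  keypoint_sequence(x, y, conf, dt = dt, subject_id = subject_id,
                    direction = direction)
}

# One-dimensional constant-velocity Kalman filter. State (position,
# velocity); process noise is the continuous white-noise-acceleration model
# scaled by process_var; missing observations trigger predict-only steps.
# Measurements whose innovation exceeds `gate` predicted standard deviations
# are rejected as outliers (chi-square gating), so isolated coordinate
# spikes do not drag the state.
kalman_cv_1d <- function(z, dt, process_var, meas_var, gate = 6) {
  tf <- length(z)
  FF <- matrix(c(1, 0, dt, 1), 2, 2)
  Q <- process_var * matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2, 2)
  H <- matrix(c(1, 0), 1, 2)
  first <- which(!is.na(z))[1]
  if (is.na(first)) return(rep(NA_real_, tf))
  s <- c(z[first], 0)
  P <- diag(c(meas_var, meas_var / dt^2))
  out <- rep(NA_real_, tf)
  out[seq_len(first)] <- z[first]
  if (first < tf) {
    for (i in (first + 1):tf) {
      s <- FF %*% s
      P <- FF %*% P %*% t(FF) + Q
      if (!is.na(z[i])) {
        innov <- z[i] - (H %*% s)[1]
        S <- (H %*% P %*% t(H))[1] + meas_var
        if (abs(innov) <= gate * sqrt(S)) {
          K <- (P %*% t(H)) / S
          s <- s + K * innov
          P <- (diag(2) - K %*% H) %*% P
        }
      }
      out[i] <- s[1]
    }
  }
  out
}

#' Kalman-smooth a keypoint sequence
#'
#' Runs an independent constant-velocity Kalman filter on each keypoint and
#' axis, estimating position and velocity while attenuating measurement
#' noise. Missing measurements are bridged by predict-only steps, so the
#' output is finite across gaps (downstream interpolation still treats the
#' original missing mask as missing when asked to).
#'
#' @param seq a `keypoint_sequence`.
#' @param process_var process-noise intensity (white-noise acceleration,
#'   px^2/s^4 scale). The default 4e6 corresponds to peak limb
#'   accelerations of order 2000 px/s^2, what a swinging ankle reaches at
#'   ~1 Hz stride frequency and ~50 px amplitude at typical image scales; a
#'   much smaller value makes the constant-velocity filter lag the limbs.
#' @param meas_var measurement noise variance in px^2. Default 4 (2 px sd,
#'   a typical pose-estimator jitter).
#' @return a `keypoint_sequence` of identical shape.
#' @export
kalman_smooth <- function(seq, process_var = 4e6, meas_var = 4) {
  stopifnot(inherits(seq, "keypoint_sequence"), seq$dt > 0)
  if (any(is.infinite(seq$x), is.infinite(seq$y))) stop("non-finite inputs")
  out <- seq
  for (k in seq_len(N_KEYPOINTS)) {
    out$x[, k] <- kalman_cv_1d(seq$x[, k], seq$dt, process_var, meas_var)
    out$y[, k] <- kalman_cv_1d(seq$y[, k], seq$dt, process_var, meas_var)
  }
  out$missing <- is.na(out$x) | is.na(out$y)
  out
}

#' Remove coordinate spikes and interpolate missing samples
#'
#' Per keypoint, frames whose step displacement from the previous frame
#' exceeds `spike_factor` times the median step displacement are marked
#' missing; every missing interior sample is then replaced by linear
#' interpolation between its nearest valid neighbours, and leading/trailing
#' gaps take the nearest valid value.
#'
#' @param seq a `keypoint_sequence`.
#' @param spike_factor spike threshold as a multiple of the median step
#'   (must be > 1; default 5).
#' @return a `keypoint_sequence` with no missing values.
#' @export
remove_peaks_interpolate <- function(seq, spike_factor = 5) {
  stopifnot(inherits(seq, "keypoint_sequence"), spike_factor > 1)
  out <- seq
  tf <- nrow(seq$x)
  for (k in seq_len(N_KEYPOINTS)) {
    xs <- seq$x[, k]
    ys <- seq$y[, k]
    if (all(is.na(xs))) {
      stop("unrecoverable-channel error: keypoint '", keypoint_names()[k],
           "' has no valid sample")
    }
    if (tf >= 3) {
      step <- sqrt(diff(xs)^2 + diff(ys)^2)
      med <- stats::median(step, na.rm = TRUE)
      if (is.finite(med) && med > 0) {
        spikes <- which(!is.na(step) & step > spike_factor * med) + 1L
        xs[spikes] <- NA_real_
        ys[spikes] <- NA_real_
      }
    }
    if (anyNA(xs)) {
      idx <- seq_len(tf)
      ok <- !is.na(xs)
      xs <- stats::approx(idx[ok], xs[ok], xout = idx, rule = 2)$y
      ys <- stats::approx(idx[ok], ys[ok], xout = idx, rule = 2)$y
    }
    out$x[, k] <- xs
    out$y[, k] <- ys
  }
  out$missing <- matrix(FALSE, tf, N_KEYPOINTS,
                        dimnames = dimnames(seq$missing))
  out
}

#' Full cleaning pipeline
#'
#' Kalman smoothing followed by spike removal and interpolation, the order
#' applied before any feature is computed.
#'
#' @inheritParams kalman_smooth
#' @inheritParams remove_peaks_interpolate
#' @return a cleaned `keypoint_sequence`.
#' @export
clean_sequence <- function(seq, process_var = 4e6, meas_var = 4,
                           spike_factor = 5) {
  remove_peaks_interpolate(
    kalman_smooth(seq, process_var = process_var, meas_var = meas_var),
    spike_factor = spike_factor)
}
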