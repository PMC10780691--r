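#' Synthetic sagittal walking cohorts
#'
#' The reference study population — hospital videos of subjects walking a
#' 4 m track filmed laterally, with healthy controls and patients whose
#' dementia-related gait shows reduced speed, raised stride-time
#' variability and reduced arm swing — is private, so the package ships a
#' generator that emulates its statistical structure: an articulated
#' sagittal stick body driven by phase-locked sinusoidal joint angles,
#' forward-kinematically rendered to the 14 keypoints, with pixel noise,
#' missing detections and coordinate spikes, 2-3 recordings per subject in
#' both walking directions, and two classes with a learnable kinematic
#' separation. The profile magnitudes are documented defaults, not claims
#' about real dementia effect sizes.
#'
#' @name synthetic-gait
NULL

#' Gait profile for one synthetic subject class
#'
#' @param class_label `"healthy"` or `"dementia"`.
#' @param walking_speed forward speed in m/s.
#' @param stride_frequency strides per second (Hz).
#' @param stride_time_cv coefficient of variation of stride timing.
#' @param arm_swing_amplitude shoulder swing amplitude in radians.
#' @param trunk_sway vertical hip bob amplitude in px.
#' @param leg_length,thigh_frac,arm_length,torso,head segment lengths in px.
#' @param px_per_m image scale (px per metre).
#' @param noise_sd additive Gaussian keypoint noise, px.
#' @return a `gait_profile` object.
#' @export
gait_profile <- function(class_label = c("healthy", "dementia"),
                         walking_speed = NULL,
                         stride_frequency = NULL,
                         stride_time_cv = NULL,
                         arm_swing_amplitude = NULL,
                         trunk_sway = 6,
                         leg_length = 90, thigh_frac = 0.5,
                         arm_length = 65, torso = 55, head = 25,
                         px_per_m = 100, noise_sd = 1.5) {
  class_label <- match.arg(class_label)
  defaults <- if (class_label == "healthy") {
    list(speed = 1.2, freq = 0.95, cv = 0.03, arm = 0.45)
  } else {
    # slower, more variable, diminished arm swing
    list(speed = 0.65, freq = 0.75, cv = 0.10, arm = 0.15)
  }
  p <- list(class_label = class_label,
            walking_speed = walking_speed %||% defaults$speed,
            stride_frequency = stride_frequency %||% defaults$freq,
            stride_time_cv = stride_time_cv %||% defaults$cv,
            arm_swing_amplitude = arm_swing_amplitude %||% defaults$arm,
            trunk_sway = trunk_sway,
            leg_length = leg_length, thigh_frac = thigh_frac,
            arm_length = arm_length, torso = torso, head = head,
            px_per_m = px_per_m, noise_sd = noise_sd)
  stopifnot(p$walking_speed > 0, p$stride_time_cv >= 0,
            p$stride_frequency > 0)
  structure(p, class = "gait_profile")
}

#' Generate one synthetic walking recording
#'
#' Sagittal articulated model: the hip centre translates horizontally at
#' `walking_speed` with a sinusoidal vertical bob at twice the stride
#' frequency; thigh, shank and arm angles are antiphase sinusoids at the
#' stride frequency whose phase accumulates with per-stride timing jitter
#' of coefficient of variation `stride_time_cv`; the 14 keypoints follow by
#' forward kinematics, plus additive Gaussian pixel noise. Deterministic
#' for a given seed.
#'
#' @param profile a `gait_profile`.
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval in seconds (default 1/30).
#' @param direction `"left_to_right"` or `"right_to_left"`.
#' @param seed integer seed.
#' @param subject_id recorded id.
#' @return a `keypoint_sequence`.
#' @export
generate_walker <- function(profile, n_frames = 120, dt = 1 / 30,
                            direction = c("left_to_right", "right_to_left"),
                            seed = 1, subject_id = NA_character_) {
  stopifnot(inherits(profile, "gait_profile"), n_frames >= 2)
  direction <- match.arg(direction)
  p <- profile
  with_local_seed(seed, {
    tt <- (seq_len(n_frames) - 1) * dt
    sgn <- if (direction == "left_to_right") 1 else -1
    # stride phase with per-stride timing jitter: instantaneous frequency is
    # resampled once per stride around stride_frequency with sd = cv * f
    n_strides <- ceiling(p$stride_frequency * tt[n_frames]) + 2L
    f_str <- stats::rnorm(n_strides, p$stride_frequency,
                          p$stride_time_cv * p$stride_frequency)
    f_str <- pmax(f_str, 0.2 * p$stride_frequency)
    phase <- numeric(n_frames)
    ph <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(n_frames)) {
      phase[i] <- ph
      idx <- min(floor(ph / (2 * pi)) + 1L, n_strides)
      ph <- ph + 2 * pi * f_str[idx] * dt
    }
    hip_x <- 400 + sgn * p$walking_speed * p$px_per_m * tt
    hip_y <- 300 - p$trunk_sway * cos(2 * phase)   # double bob per stride
    thigh <- p$leg_length * p$thigh_frac
    shank <- p$leg_length - thigh
    upper_arm <- p$arm_length * 0.55
    fore_arm <- p$arm_length * 0.45
    A_thigh <- 0.42            # rad, thigh swing amplitude
    A_knee <- 0.55             # rad, knee flexion amplitude
    kpx <- matrix(0, n_frames, N_KEYPOINTS,
                  dimnames = list(NULL, keypoint_names()))
    kpy <- kpx
    limb <- function(phi) list(c = cos(phi), s = sin(phi))
    # y grows downward (image coordinates)
    for (legside in c("r", "l")) {
      ph_leg <- phase + if (legside == "r") 0 else pi
      th <- sgn * A_thigh * sin(ph_leg)              # thigh angle from vertical
      kn <- pmax(A_knee * (1 - cos(ph_leg)) / 2, 0)  # knee flexion >= 0
      sh <- th - sgn * kn                            # shank angle
      hipx <- hip_x; hipy <- hip_y
      kneex <- hipx + thigh * sin(th)
      kneey <- hipy + thigh * cos(th)
      ankx <- kneex + shank * sin(sh)
      anky <- kneey + shank * cos(sh)
      kpx[, paste0("hip_", legside)] <- hipx
      kpy[, paste0("hip_", legside)] <- hipy
      kpx[, paste0("knee_", legside)] <- kneex
      kpy[, paste0("knee_", legside)] <- kneey
      kpx[, paste0("ankle_", legside)] <- ankx
      kpy[, paste0("ankle_", legside)] <- anky
    }
    neck_x <- hip_x
    neck_y <- hip_y - p$torso
    kpx[, "neck"] <- neck_x; kpy[, "neck"] <- neck_y
    kpx[, "nose"] <- neck_x + sgn * 0.3 * p$head
    kpy[, "nose"] <- neck_y - p$head
    for (armside in c("r", "l")) {
      # arms swing in antiphase with the ipsilateral leg
      ph_arm <- phase + if (armside == "r") pi else 0
      aa <- sgn * p$arm_swing_amplitude * sin(ph_arm)
      elb <- aa + sgn * 0.25                          # slight elbow flexion
      shx <- neck_x; shy <- neck_y + 4
      elx <- shx + upper_arm * sin(aa)
      ely <- shy + upper_arm * cos(aa)
      wrx <- elx + fore_arm * sin(elb)
      wry <- ely + fore_arm * cos(elb)
      kpx[, paste0("shoulder_", armside)] <- shx
      kpy[, paste0("shoulder_", armside)] <- shy
      kpx[, paste0("elbow_", armside)] <- elx
      kpy[, paste0("elbow_", armside)] <- ely
      kpx[, paste0("wrist_", armside)] <- wrx
      kpy[, paste0("wrist_", armside)] <- wry
    }
    kpx <- kpx + stats::rnorm(length(kpx), 0, p$noise_sd)
    kpy <- kpy + stats::rnorm(length(kpy), 0, p$noise_sd)
    keypoint_sequence(kpx, kpy, dt = dt, subject_id = subject_id,
                      direction = direction)
  })
}

#' Corrupt a keypoint sequence with missing points and spikes
#'
#' Emulates pose-estimator defects: a Bernoulli missing mask per
#' keypoint-frame slot and spike injection displacing a slot by at least
#' `spike_mag` times the median per-frame step, in a random direction.
#'
#' @param seq a `keypoint_sequence`.
#' @param missing_rate,spike_rate Bernoulli rates in `[0, 1)`.
#' @param spike_mag spike magnitude as a multiple of the median step
#'   displacement (default 20).
#' @param seed integer seed.
#' @return a corrupted `keypoint_sequence`.
#' @export
corrupt_sequence <- function(seq, missing_rate = 0.05, spike_rate = 0.02,
                             spike_mag = 20, seed = 1) {
  stopifnot(inherits(seq, "keypoint_sequence"),
            missing_rate >= 0, missing_rate < 1,
            spike_rate >= 0, spike_rate < 1)
  with_local_seed(seed, {
    out <- seq
    tf <- nrow(seq$x)
    nslots <- tf * N_KEYPOINTS
    med_step <- stats::median(sqrt(diff(seq$x[, 1])^2 + diff(seq$y[, 1])^2),
                              na.rm = TRUE)
    if (!is.finite(med_step) || med_step == 0) med_step <- 1
    spikes <- which(stats::runif(nslots) < spike_rate)
    if (length(spikes)) {
      ang <- stats::runif(length(spikes), 0, 2 * pi)
      mag <- spike_mag * med_step * stats::runif(length(spikes), 1, 2)
      out$x[spikes] <- out$x[spikes] + mag * cos(ang)
      out$y[spikes] <- out$y[spikes] + mag * sin(ang)
    }
    miss <- which(stats::runif(nslots) < missing_rate)
    if (length(miss)) {
      out$x[miss] <- NA_real_
      out$y[miss] <- NA_real_
      out$conf[miss] <- 0
    }
    out$missing <- is.na(out$x) | is.na(out$y)
    out
  })
}

#' Generate a labeled synthetic cohort
#'
#' Per subject, a profile is drawn around the class defaults (between-
#' subject variability of about 8% on speed and stride frequency), then
#' `recordings_per_subject` recordings alternating walking directions are
#' generated and corrupted. All randomness flows from `seed` through
#' per-subject derived seeds, so any recording is reproducible in
#' isolation.
#'
#' @param n_healthy,n_patient subjects per class (the emulated study has
#'   23 and 20).
#' @param recordings_per_subject recordings per subject (2-3 in the
#'   emulated study; default 3).
#' @param n_frames,dt recording length and frame interval.
#' @param seed cohort seed.
#' @param missing_rate,spike_rate,spike_mag corruption settings (see
#'   [corrupt_sequence()]); set both rates to 0 for clean recordings.
#' @return a `synthetic_cohort`: list with `recordings` (each a list of
#'   `seq`, `class_label`, `subject_id`, `direction`), `manifest` (data
#'   frame), and `seed`.
#' @export
generate_cohort <- function(n_healthy = 23, n_patient = 20,
                            recordings_per_subject = 3, n_frames = 120,
                            dt = 1 / 30, seed = 1,
                            missing_rate = 0.03, spike_rate = 0.01,
                            spike_mag = 20) {
  stopifnot(n_healthy >= 1, n_patient >= 1, recordings_per_subject >= 1)
  subjects <- data.frame(
    subject_id = c(sprintf("H%02d", seq_len(n_healthy)),
                   sprintf("P%02d", seq_len(n_patient))),
    class_label = c(rep("healthy", n_healthy), rep("dementia", n_patient)),
    stringsAsFactors = FALSE)
  sub_seeds <- with_local_seed(seed, {
    sample.int(.Machine$integer.max %/% 4L, nrow(subjects))
  })
  recordings <- list()
  manifest <- NULL
  for (si in seq_len(nrow(subjects))) {
    cls <- subjects$class_label[si]
    sid <- subjects$subject_id[si]
    base <- gait_profile(cls)
    prof <- with_local_seed(sub_seeds[si], {
      gait_profile(cls,
                   walking_speed = base$walking_speed * exp(stats::rnorm(1, 0, 0.08)),
                   stride_frequency = base$stride_frequency * exp(stats::rnorm(1, 0, 0.08)),
                   stride_time_cv = base$stride_time_cv * exp(stats::rnorm(1, 0, 0.2)),
                   arm_swing_amplitude = base$arm_swing_amplitude * exp(stats::rnorm(1, 0, 0.15)))
    })
    for (ri in seq_len(recordings_per_subject)) {
      dir <- if (ri %% 2 == 1) "left_to_right" else "right_to_left"
      rseed <- (sub_seeds[si] + 7919L * ri) %% (.Machine$integer.max %/% 2L)
      s <- generate_walker(prof, n_frames = n_frames, dt = dt,
                           direction = dir, seed = rseed, subject_id = sid)
      if (missing_rate > 0 || spike_rate > 0) {
        s <- corrupt_sequence(s, missing_rate, spike_rate, spike_mag,
                              seed = rseed + 1L)
      }
      recordings[[length(recordings) + 1L]] <-
        list(seq = s, class_label = cls, subject_id = sid, direction = dir)
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, class_label = cls,
                                   recording = length(recordings),
                                   direction = dir,
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(recordings = recordings, manifest = manifest,
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic gait cohort: %d subjects (%d recordings), seed %d\n",
              length(unique(x$manifest$subject_id)), nrow(x$manifest), x$seed))
  print(table(x$manifest$class_label[!duplicated(x$manifest$subject_id)]))
  invisible(x)
}

#' Write a cohort to keypoint CSV files plus a manifest
#'
#' Emits one long-form keypoint CSV per recording (the dialect
#' [read_keypoints_csv()] consumes) and a `manifest.csv` with columns
#' `subject_id, class_label, path, direction`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$path <- sprintf("rec_%03d.csv", man$recording)
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    write_keypoints_csv(rec$seq, file.path(dir, man$path[i]),
                        recording_id = sprintf("rec_%03d", i))
  }
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `manifest.csv` and recording CSVs.
#' @param dt frame interval for the reconstructed sequences.
#' @return a `synthetic_cohort`.
#' @export
read_cohort <- function(dir, dt = 1 / 30) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(man)), function(i) {
    s <- read_keypoints_csv(file.path(dir, man$path[i]), dt = dt,
                            subject_id = man$subject_id[i],
                            direction = man$direction[i])
    list(seq = s, class_label = man$class_label[i],
         subject_id = man$subject_id[i], direction = man$direction[i])
  })
  structure(list(recordings = recordings, manifest = man, seed = NA_integer_),
            class = "synthetic_cohort")
}
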