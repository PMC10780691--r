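#' The 14-keypoint body schema
#'
#' Every frame carries 14 named 2D keypoints in image coordinates, in this
#' fixed order: nose, neck, then right and left shoulder / elbow / wrist,
#' then right and left hip / knee / ankle. Missing detections are flagged,
#' never silently zeroed; detections with confidence below a floor are
#' treated as missing.
#'
#' @return character vector of the 14 keypoint names, in canonical order.
#' @export
keypoint_names <- function() {
  c("nose", "neck",
    "shoulder_r", "elbow_r", "wrist_r",
    "shoulder_l", "elbow_l", "wrist_l",
    "hip_r", "knee_r", "ankle_r",
    "hip_l", "knee_l", "ankle_l")
}

N_KEYPOINTS <- 14L

#' Construct a keypoint sequence
#'
#' The in-memory container for one recording: `T x 14` matrices of x, y and
#' confidence, a logical missing mask, the frame interval and recording
#' metadata.
#'
#' @param x,y numeric `T x 14` matrices of image coordinates (NA allowed
#'   where missing).
#' @param conf confidence matrix in `[0, 1]`; defaults to 1 where observed.
#' @param dt frame interval in seconds (> 0), default 1/30.
#' @param subject_id,direction recording metadata; direction is one of
#'   `"left_to_right"`, `"right_to_left"`, `"both"`.
#' @param conf_floor confidences below this are treated as missing
#'   (default 0.1).
#' @return an object of class `keypoint_sequence`.
#' @export
keypoint_sequence <- function(x, y, conf = NULL, dt = 1 / 30,
                              subject_id = NA_character_,
                              direction = c("left_to_right", "right_to_left", "both"),
                              conf_floor = 0.1) {
  direction <- match.arg(direction)
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == N_KEYPOINTS, ncol(y) == N_KEYPOINTS,
            nrow(x) == nrow(y), nrow(x) >= 1, dt > 0)
  if (is.null(conf)) conf <- matrix(1, nrow(x), N_KEYPOINTS)
  conf <- as.matrix(conf)
  missing <- is.na(x) | is.na(y) | conf < conf_floor
  x[missing] <- NA_real_
  y[missing] <- NA_real_
  colnames(x) <- colnames(y) <- colnames(conf) <- colnames(missing) <- keypoint_names()
  structure(list(x = x, y = y, conf = conf, missing = missing,
                 dt = dt, subject_id = subject_id, direction = direction),
            class = "keypoint_sequence")
}

#' @export
print.keypoint_sequence <- function(x, ...) {
  cat(sprintf(
    "Keypoint sequence: %d frames x %d keypoints, dt = %.4g s, subject %s, %s (%.1f%% missing)\n",
    nrow(x$x), ncol(x$x), x$dt, x$subject_id, x$direction,
    100 * mean(x$missing)))
  invisible(x)
}

n_frames <- function(seq) nrow(seq$x)

#' Read / write keypoint sequences as long-form CSV
#'
#' The on-disk dialect is one row per (frame, keypoint):
#' `recording_id, frame, keypoint_name, x, y, confidence`, using the
#' 14-name vocabulary of [keypoint_names()]. Missing detections are empty
#' x/y cells (or confidence 0).
#'
#' @param seq a `keypoint_sequence`.
#' @param path CSV path.
#' @param recording_id identifier written in the first column.
#' @param dt,subject_id,direction metadata applied on read.
#' @return `write_keypoints_csv` returns `path` invisibly;
#'   `read_keypoints_csv` returns a `keypoint_sequence`.
#' @export
write_keypoints_csv <- function(seq, path, recording_id = "rec1") {
  stopifnot(inherits(seq, "keypoint_sequence"))
  tf <- nrow(seq$x)
  df <- data.frame(
    recording_id = recording_id,
    frame = rep(seq_len(tf), each = N_KEYPOINTS),
    keypoint_name = rep(keypoint_names(), times = tf),
    x = as.vector(t(seq$x)),
    y = as.vector(t(seq$y)),
    confidence = as.vector(t(seq$conf)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_keypoints_csv
#' @export
read_keypoints_csv <- function(path, dt = 1 / 30, subject_id = NA_character_,
                               direction = "left_to_right") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "keypoint_name", "x", "y", "confidence")
  if (!all(need %in% names(df))) {
    stop("keypoint CSV must contain columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$keypoint_name), keypoint_names())
  if (length(bad)) stop("unknown keypoint names: ", paste(bad, collapse = ", "))
  frames <- sort(unique(df$frame))
  tf <- length(frames)
  x <- y <- conf <- matrix(NA_real_, tf, N_KEYPOINTS,
                           dimnames = list(NULL, keypoint_names()))
  fi <- match(df$frame, frames)
  ki <- match(df$keypoint_name, keypoint_names())
  x[cbind(fi, ki)] <- df$x
  y[cbind(fi, ki)] <- df$y
  conf[cbind(fi, ki)] <- ifelse(is.na(df$confidence), 0, df$confidence)
  conf[is.na(conf)] <- 0
  keypoint_sequence(x, y, conf, dt = dt, subject_id = subject_id,
                    direction = direction)
}

#' Read / write keypoint sequences as per-frame JSON
#'
#' Equivalent JSON dialect: an object with `dt`, `subject_id`, `direction`
#' and a `frames` array, each frame an array of 14 `{name, x, y, confidence}`
#' records.
#'
#' @inheritParams write_keypoints_csv
#' @export
write_keypoints_json <- function(seq, path) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  frames <- lapply(seq_len(nrow(seq$x)), function(i) {
    lapply(seq_len(N_KEYPOINTS), function(k) {
      list(name = keypoint_names()[k],
           x = if (is.na(seq$x[i, k])) NULL else seq$x[i, k],
           y = if (is.na(seq$y[i, k])) NULL else seq$y[i, k],
           confidence = seq$conf[i, k])
    })
  })
  jsonlite::write_json(
    list(dt = seq$dt, subject_id = seq$subject_id, direction = seq$direction,
         frames = frames),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_keypoints_json
#' @export
read_keypoints_json <- function(path) {
  obj <- jsonlite::read_json(path)
  tf <- length(obj$frames)
  x <- y <- conf <- matrix(NA_real_, tf, N_KEYPOINTS,
                           dimnames = list(NULL, keypoint_names()))
  for (i in seq_len(tf)) {
    for (rec in obj$frames[[i]]) {
      k <- match(rec$name, keypoint_names())
      if (is.na(k)) stop("unknown keypoint name: ", rec$name)
      x[i, k] <- rec$x %||% NA_real_
      y[i, k] <- rec$y %||% NA_real_
      conf[i, k] <- rec$confidence %||% 0
    }
  }
  keypoint_sequence(x, y, conf, dt = obj$dt,
                    subject_id = obj$subject_id %||% NA_character_,
                    direction = obj$direction %||% "left_to_right")
}
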