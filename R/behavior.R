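#' Nose position of a tracked mouse
#'
#' The nose is half a major axis ahead of the centroid along the heading:
#' centroid + (major_axis / 2) * (cos(heading), sin(heading)). This single
#' definition is shared by the audio simulator, the localization density
#' evaluation and the behavior classifier.
#'
#' @param track a [mouse_track()].
#' @param frame 0-based frame index.
#' @return `c(x, y)` in metres.
#' @export
nose_position <- function(track, frame) {
  i <- as.integer(frame) + 1L
  if (i < 1L || i > n_frames(track)) {
    stop_usv("frame %d outside track (0..%d)", frame, n_frames(track) - 1L,
             class = "usvdyad_validation_error")
  }
  c(track$x[i] + track$major_axis[i] / 2 * cos(track$heading[i]),
    track$y[i] + track$major_axis[i] / 2 * sin(track$heading[i]))
}

#' Per-frame speed and movement direction
#'
#' Central-difference velocity of the centroid (one-sided at the track
#' ends), smoothed with a centered moving average of `smooth_window` frames;
#' speed is the velocity norm in cm/s, movement direction its angle.
#' Direction is undefined (NA) below 1 cm/s.
#'
#' @param track a [mouse_track()].
#' @param smooth_window moving-average width in frames (default 5).
#' @return data frame: `speed_cms`, `direction_rad` per frame.
#' @export
kinematics <- function(track, smooth_window = 5) {
  n <- n_frames(track)
  if (n < 2L) {
    stop_usv("kinematics needs at least 2 frames",
             class = "usvdyad_validation_error")
  }
  fps <- track$frame_rate
  cdiff <- function(p) {
    v <- numeric(n)
    v[1] <- (p[2] - p[1]) * fps
    v[n] <- (p[n] - p[n - 1]) * fps
    if (n > 2L) v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) * fps / 2
    v
  }
  smooth <- function(v) {
    if (smooth_window <= 1L) return(v)
    half <- smooth_window %/% 2L
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  vx <- smooth(cdiff(track$x))
  vy <- smooth(cdiff(track$y))
  speed <- sqrt(vx^2 + vy^2) * 100
  dir <- atan2(vy, vx)
  dir[speed < 1] <- NA_real_
  data.frame(speed_cms = speed, direction_rad = dir)
}

#' Frame-level social-context criteria for a dyad
#'
#' Evaluates, per frame, the four pursuit criteria and the separation
#' criterion:
#' * `follows_ab` (mouse B follows mouse A): movement directions within
#'   `angle_deg`; centroid distance under `dist_cm`; both speeds above
#'   `speed_cms`; and B behind A (the vector from B to A projects positively
#'   on A's movement direction, and the reverse test for A behind B fails).
#' * `follows_ba`: the mirror image.
#' * `not_close`: centroid distance at least `notclose_cm`.
#' Frames with undefined movement direction fail the pursuit criteria.
#'
#' @param track_a,track_b [mouse_track()]s of equal length and frame rate.
#' @param angle_deg,dist_cm,speed_cms,notclose_cm criterion thresholds.
#' @param smooth_window passed to [kinematics()].
#' @return data frame: `frame` (0-based), `distance_cm`, `follows_ab`,
#'   `follows_ba`, `not_close`.
#' @export
classify_frames <- function(track_a, track_b, angle_deg = 25, dist_cm = 5,
                            speed_cms = 20, notclose_cm = 15,
                            smooth_window = 5) {
  n <- n_frames(track_a)
  if (n_frames(track_b) != n || track_a$frame_rate != track_b$frame_rate) {
    stop_usv("tracks must share length and frame rate",
             class = "usvdyad_validation_error")
  }
  ka <- kinematics(track_a, smooth_window)
  kb <- kinematics(track_b, smooth_window)
  dx <- track_a$x - track_b$x
  dy <- track_a$y - track_b$y
  dist_cm_v <- sqrt(dx^2 + dy^2) * 100

  angle_ok <- abs(wrap_angle(ka$direction_rad - kb$direction_rad)) <
    angle_deg * pi / 180
  angle_ok[is.na(angle_ok)] <- FALSE
  speed_ok <- ka$speed_cms > speed_cms & kb$speed_cms > speed_cms
  close_ok <- dist_cm_v < dist_cm

  # projection of (A - B) on A's direction: positive when A is in front of B
  proj_on <- function(ddx, ddy, dir) cos(dir) * ddx + sin(dir) * ddy
  a_ahead <- proj_on(dx, dy, ka$direction_rad) > 0
  b_ahead <- proj_on(-dx, -dy, kb$direction_rad) > 0
  a_ahead[is.na(a_ahead)] <- FALSE
  b_ahead[is.na(b_ahead)] <- FALSE

  base <- angle_ok & speed_ok & close_ok
  data.frame(frame = seq_len(n) - 1L,
             distance_cm = dist_cm_v,
             follows_ab = base & a_ahead & !b_ahead,  # B pursues A
             follows_ba = base & b_ahead & !a_ahead,
             not_close = dist_cm_v >= notclose_cm)
}

#' Runs of true frames as behavior intervals
#'
#' @param flags logical vector, one element per frame.
#' @param min_frames minimum run length (default 10 consecutive frames).
#' @return data frame: `start_frame`, `end_frame` (0-based, inclusive), one
#'   row per qualifying run.
#' @export
extract_bouts <- function(flags, min_frames = 10) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start_frame = starts[keep] - 1L, end_frame = ends[keep] - 1L)
}

#' Classify a dyad's behavioral bouts
#'
#' Applies [classify_frames()] + [extract_bouts()] and expands each pursuit
#' run into a `following` interval for the pursuer and an identically-framed
#' `followed` interval for the leader; `not_close` runs yield one interval
#' per mouse.
#'
#' @inheritParams classify_frames
#' @param min_frames minimum bout length in frames.
#' @return data frame: `mouse_id`, `kind`, `start_frame`, `end_frame`,
#'   `partner_id`.
#' @export
classify_bouts <- function(track_a, track_b, min_frames = 10, angle_deg = 25,
                           dist_cm = 5, speed_cms = 20, notclose_cm = 15,
                           smooth_window = 5) {
  fl <- classify_frames(track_a, track_b, angle_deg, dist_cm, speed_cms,
                        notclose_cm, smooth_window)
  ida <- track_a$mouse_id; idb <- track_b$mouse_id
  out <- list()
  add <- function(b, mouse, kind, partner) {
    if (!nrow(b)) return(NULL)
    data.frame(mouse_id = mouse, kind = kind, start_frame = b$start_frame,
               end_frame = b$end_frame, partner_id = partner,
               stringsAsFactors = FALSE)
  }
  ab <- extract_bouts(fl$follows_ab, min_frames)   # B pursues A
  ba <- extract_bouts(fl$follows_ba, min_frames)
  nc <- extract_bouts(fl$not_close, min_frames)
  out <- rbind(add(ab, idb, "following", ida), add(ab, ida, "followed", idb),
               add(ba, ida, "following", idb), add(ba, idb, "followed", ida),
               add(nc, ida, "not_close", idb), add(nc, idb, "not_close", ida))
  if (is.null(out)) {
    out <- data.frame(mouse_id = character(), kind = character(),
                      start_frame = integer(), end_frame = integer(),
                      partner_id = character(), stringsAsFactors = FALSE)
  }
  out[order(out$mouse_id, out$start_frame), , drop = FALSE]
}

#' Label vocalizations with their emitter's behavioral context
#'
#' A vocalization's context is the kind of the emitter's interval containing
#' its onset frame, with precedence following > followed > not_close should
#' intervals ever overlap; onset outside every interval gives "other";
#' unassigned signals keep `NA` and are excluded from context tables.
#'
#' @param features a [feature_table] (one row per signal, `emitter` set).
#' @param intervals data frame from [classify_bouts()].
#' @param onset_s per-row onset times in seconds.
#' @param frame_rate frames per second.
#' @return the feature table with `context` filled.
#' @export
label_vocalizations <- function(features, intervals, onset_s, frame_rate = 30) {
  stopifnot(length(onset_s) == nrow(features))
  precedence <- c(following = 1, followed = 2, not_close = 3)
  onset_frame <- floor(onset_s * frame_rate)
  ctx <- rep(NA_character_, nrow(features))
  for (i in seq_len(nrow(features))) {
    em <- features$emitter[i]
    if (is.na(em) || em == "unassigned") next
    hits <- intervals[intervals$mouse_id == em &
                        intervals$start_frame <= onset_frame[i] &
                        intervals$end_frame >= onset_frame[i], ]
    ctx[i] <- if (nrow(hits)) {
      hits$kind[order(precedence[hits$kind])][1]
    } else "other"
  }
  features$context <- ctx
  features
}

#' Context occupancy table (behavioral instances and vocalization counts)
#'
#' For each sex and context: how many behavioral intervals contained at
#' least one vocalization by that mouse, and how many vocalizations were
#' emitted in that context in total.
#'
#' @param features a labelled [feature_table].
#' @param intervals optional data frame from [classify_bouts()] together
#'   with `onset_s`; needed for the instance counts, otherwise only
#'   vocalization counts are filled.
#' @param onset_s per-row onset seconds (parallel to `features`).
#' @param frame_rate frames per second.
#' @return data frame: `sex`, `context`, `n_instances` (NA without
#'   intervals), `n_vocalizations`.
#' @export
context_table <- function(features, intervals = NULL, onset_s = NULL,
                          frame_rate = 30) {
  sex <- emitter_sex(features$emitter)
  contexts <- c("not_close", "followed", "following")
  out <- expand.grid(sex = c("male", "female"), context = contexts,
                     stringsAsFactors = FALSE)
  out$n_instances <- NA_integer_
  out$n_vocalizations <- vapply(seq_len(nrow(out)), function(i) {
    sum(sex == out$sex[i] & features$context == out$context[i], na.rm = TRUE)
  }, 1L)
  if (!is.null(intervals) && !is.null(onset_s)) {
    onset_frame <- floor(onset_s * frame_rate)
    out$n_instances <- vapply(seq_len(nrow(out)), function(i) {
      iv <- intervals[intervals$kind == out$context[i] &
                        emitter_sex(intervals$mouse_id) == out$sex[i], ,
                      drop = FALSE]
      if (!nrow(iv)) return(0L)
      sum(vapply(seq_len(nrow(iv)), function(j) {
        any(features$emitter == iv$mouse_id[j] &
              onset_frame >= iv$start_frame[j] &
              onset_frame <= iv$end_frame[j], na.rm = TRUE)
      }, TRUE))
    }, 1L)
  }
  out
}
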