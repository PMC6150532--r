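#' Behavior script for the trajectory simulator
#'
#' An ordered set of non-overlapping bouts. During a `following`/`followed`
#' bout the mouse named by `leader_id` runs in front and its partner pursues;
#' during `not_close` the two mice stay at least `not_close` distance apart;
#' frames outside any bout are neutral ("other": intermediate distance, no
#' criterion satisfied).
#'
#' @param kind character vector in `{"following", "followed", "not_close",
#'   "other"}`.
#' @param start_frame 0-based first frame of each bout.
#' @param n_frames bout lengths in frames (>= 1).
#' @param leader_id mouse id leading each bout (ignored for `not_close` /
#'   `other`).
#' @return a `behavior_script` data frame.
#' @export
behavior_script <- function(kind, start_frame, n_frames, leader_id = NA) {
  df <- data.frame(kind = as.character(kind),
                   start_frame = as.integer(start_frame),
                   n_frames = as.integer(n_frames),
                   leader_id = as.character(leader_id),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% c("following", "followed", "not_close", "other")
  if (any(bad)) {
    stop_usv("unknown bout kind: %s", paste(df$kind[bad], collapse = ", "),
             class = "usvdyad_validation_error")
  }
  if (any(df$n_frames < 1L)) {
    stop_usv("bouts must span at least one frame",
             class = "usvdyad_validation_error")
  }
  if (any(df$start_frame < 0L)) {
    stop_usv("start_frame must be >= 0", class = "usvdyad_validation_error")
  }
  df <- df[order(df$start_frame), ]
  ends <- df$start_frame + df$n_frames - 1L
  if (nrow(df) > 1L && any(df$start_frame[-1L] <= ends[-nrow(df)])) {
    stop_usv("bouts overlap", class = "usvdyad_validation_error")
  }
  class(df) <- c("behavior_script", "data.frame")
  df
}

#' Simulate a dyad's trajectories from a behavior script
#'
#' Both mice run along a circular path (radius `path_radius` around the
#' arena centre) at `speed_ms`; the inter-animal arc gap is switched per
#' frame so that each scripted bout satisfies its defining criteria exactly
#' on the scripted frames and on no others:
#' * `following`/`followed`: centroid gap `follow_gap_m` (< 5 cm), directions
#'   aligned within the arc angle, both speeds equal to `speed_ms` (> 20
#'   cm/s), pursuer behind the leader;
#' * `not_close`: centroid gap `not_close_gap_m` (>= 15 cm);
#' * neutral frames: centroid gap `neutral_gap_m`, between the following and
#'   not-close thresholds, so neither criterion can fire.
#'
#' Gap changes are realized by forward jumps along the path, so speeds never
#' drop and movement direction never reverses; frame-level classification
#' criteria therefore switch exactly at bout boundaries.
#'
#' @param script a [behavior_script()].
#' @param n_frames total frames to generate (must cover the script).
#' @param mouse_ids ids of the two mice, default `c("M", "F")`.
#' @param frame_rate frames per second.
#' @param arena arena (width, height) in metres.
#' @param speed_ms running speed, m/s (default 0.25 = 25 cm/s).
#' @param follow_gap_m,neutral_gap_m,not_close_gap_m centroid distances (m)
#'   during follow bouts, neutral frames and not-close bouts.
#' @param path_radius circle radius, metres.
#' @param seed RNG seed (the construction is deterministic; the seed only
#'   fixes the random starting phase).
#' @return list with `tracks` (named list of two [mouse_track()]), `labels`
#'   (named list of per-frame character labels per mouse) and `script`.
#' @export
simulate_trajectories <- function(script, n_frames,
                                  mouse_ids = c("M", "F"),
                                  frame_rate = 30,
                                  arena = c(0.762, 0.762),
                                  speed_ms = 0.25,
                                  follow_gap_m = 0.04,
                                  neutral_gap_m = 0.09,
                                  not_close_gap_m = 0.20,
                                  path_radius = 0.25,
                                  seed = NULL) {
  stopifnot(length(mouse_ids) == 2L)
  ends <- script$start_frame + script$n_frames - 1L
  if (nrow(script) && max(ends) > n_frames - 3L) {
    stop_usv("script does not fit in %d frames (keep >= 2 trailing frames)",
             n_frames, class = "usvdyad_validation_error")
  }
  if (nrow(script) && min(script$start_frame) < 2L) {
    stop_usv("bouts must start at frame >= 2 (kinematic edge frames)",
             class = "usvdyad_validation_error")
  }
  if (2 * path_radius >= min(arena)) {
    stop_usv("path does not fit inside the arena",
             class = "usvdyad_validation_error")
  }
  known <- script$leader_id[script$kind %in% c("following", "followed")]
  if (length(known) && !all(known %in% mouse_ids)) {
    stop_usv("leader_id must be one of the mouse ids",
             class = "usvdyad_validation_error")
  }

  centre <- arena / 2
  r <- path_radius
  chord_to_arc <- function(d) 2 * r * asin(pmin(d / (2 * r), 1))
  gap_of <- c(following = chord_to_arc(follow_gap_m),
              followed  = chord_to_arc(follow_gap_m),
              not_close = chord_to_arc(not_close_gap_m),
              other     = chord_to_arc(neutral_gap_m))
  step <- speed_ms / frame_rate  # arc length per frame

  # per-frame bout kind and leader
  kind <- rep("other", n_frames)
  leader <- rep(mouse_ids[1], n_frames)
  if (nrow(script)) {
    for (i in seq_len(nrow(script))) {
      idx <- script$start_frame[i]:ends[i] + 1L
      kind[idx] <- script$kind[i]
      if (script$kind[i] %in% c("following", "followed") &&
          !is.na(script$leader_id[i])) {
        leader[idx] <- script$leader_id[i]
      }
    }
    # carry the last leader through neutral frames for continuity
    for (t in 2:n_frames) {
      if (kind[t] == "other" || kind[t] == "not_close") leader[t] <- leader[t - 1L]
    }
  }

  phase0 <- with_seed(seed, runif(1, 0, 2 * pi))
  ang <- matrix(0, n_frames, 2, dimnames = list(NULL, mouse_ids))
  ang[1, leader[1]] <- phase0
  ang[1, setdiff(mouse_ids, leader[1])] <- phase0 - gap_of[kind[1]] / r
  for (t in 2:n_frames) {
    ld <- leader[t]; fo <- setdiff(mouse_ids, ld)
    g <- gap_of[kind[t]] / r
    # leader keeps moving forward; jumps ahead if the gap must widen
    ang[t, ld] <- max(ang[t - 1L, ld] + step / r,
                      ang[t - 1L, fo] + step / r + g)
    ang[t, fo] <- ang[t, ld] - g
  }

  tracks <- lapply(mouse_ids, function(id) {
    a <- ang[, id]
    x <- centre[1] + r * cos(a)
    y <- centre[2] + r * sin(a)
    # headings = local direction of travel (tangent, counterclockwise)
    heading <- wrap_angle(a + pi / 2)
    mouse_track(id, x, y, major_axis = 0.08, minor_axis = 0.03,
                heading = heading, frame_rate = frame_rate)
  })
  names(tracks) <- mouse_ids

  labels <- lapply(mouse_ids, function(id) {
    lab <- rep("other", n_frames)
    lab[kind == "not_close"] <- "not_close"
    fol <- kind %in% c("following", "followed")
    lab[fol & leader != id] <- "following"
    lab[fol & leader == id] <- "followed"
    lab
  })
  names(labels) <- mouse_ids

  list(tracks = tracks, labels = labels, script = script)
}
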