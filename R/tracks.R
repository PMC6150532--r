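#' Per-mouse trajectory
#'
#' One tracked mouse: a per-frame fitted ellipse (centroid, axes, heading),
#' the standard output of video trackers for this assay.
#'
#' @param mouse_id identifier (e.g. "M" / "F").
#' @param x,y centroid coordinates per frame, metres.
#' @param major_axis,minor_axis ellipse axes per frame, metres.
#' @param heading heading direction per frame, radians in (-pi, pi].
#' @param frame_rate frames per second (default 30, the camera trigger rate).
#' @return object of class `mouse_track`.
#' @export
mouse_track <- function(mouse_id, x, y, major_axis, minor_axis, heading,
                        frame_rate = 30) {
  n <- length(x)
  stopifnot(length(y) == n, length(heading) == n)
  major_axis <- rep_len(major_axis, n)
  minor_axis <- rep_len(minor_axis, n)
  if (any(major_axis <= 0) || any(minor_axis <= 0)) {
    stop_usv("ellipse axes must be positive", class = "usvdyad_schema_error")
  }
  if (anyNA(c(x, y, heading))) {
    stop_usv("track has missing frames; interpolate before constructing",
             class = "usvdyad_schema_error")
  }
  heading <- wrap_angle(heading)
  structure(list(mouse_id = mouse_id, x = x, y = y,
                 major_axis = major_axis, minor_axis = minor_axis,
                 heading = heading, frame_rate = frame_rate),
            class = "mouse_track")
}

n_frames <- function(track) length(track$x)

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' @export
print.mouse_track <- function(x, ...) {
  cat(sprintf("<mouse_track '%s': %d frames @ %g fps>\n",
              x$mouse_id, n_frames(x), x$frame_rate))
  invisible(x)
}

#' Read a two-mouse trajectory table
#'
#' Long-format CSV with columns `frame, mouse_id, x_m, y_m, major_axis_m,
#' minor_axis_m, heading_rad`; frames are 0-based.
#'
#' @param path CSV path.
#' @param frame_rate frames per second.
#' @return named list of `mouse_track` objects.
#' @export
read_tracks <- function(path, frame_rate = 30) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "mouse_id", "x_m", "y_m", "major_axis_m",
            "minor_axis_m", "heading_rad")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_usv("trajectory table missing columns: %s",
             paste(missing, collapse = ", "), class = "usvdyad_schema_error")
  }
  ids <- unique(df$mouse_id)
  out <- lapply(ids, function(id) {
    d <- df[df$mouse_id == id, ]
    d <- d[order(d$frame), ]
    if (!all(diff(d$frame) == 1L)) {
      stop_usv("track '%s' has missing frames", id,
               class = "usvdyad_schema_error")
    }
    mouse_track(id, d$x_m, d$y_m, d$major_axis_m, d$minor_axis_m,
                d$heading_rad, frame_rate)
  })
  names(out) <- ids
  out
}

#' Write trajectory tracks to CSV
#'
#' @param tracks named list of `mouse_track`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(frame = seq_len(n_frames(tr)) - 1L,
               mouse_id = tr$mouse_id,
               x_m = tr$x, y_m = tr$y,
               major_axis_m = tr$major_axis, minor_axis_m = tr$minor_axis,
               heading_rad = tr$heading)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
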