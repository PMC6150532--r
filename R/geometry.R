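#' Microphone-array geometry
#'
#' Positions of the microphones and the arena bounds, the common spatial
#' frame for localization. Coordinates are metres with the origin at the
#' arena's lower-left corner.
#'
#' @param mic_positions numeric matrix (n x 2) of microphone (x, y) in
#'   metres, or a list of length-2 vectors.
#' @param arena arena (width, height) in metres; default 0.762 x 0.762,
#'   the recording cage.
#' @return an object of class `mic_array_geometry`.
#' @export
mic_array_geometry <- function(mic_positions, arena = c(0.762, 0.762)) {
  if (is.list(mic_positions)) {
    mic_positions <- do.call(rbind, lapply(mic_positions, as.numeric))
  }
  mic_positions <- as.matrix(mic_positions)
  if (ncol(mic_positions) != 2L) {
    stop_usv("mic_positions must be n x 2", class = "usvdyad_schema_error")
  }
  if (nrow(mic_positions) < 4L) {
    stop_usv("need at least 4 microphones, got %d", nrow(mic_positions),
             class = "usvdyad_schema_error")
  }
  if (!all(is.finite(mic_positions))) {
    stop_usv("non-finite microphone position", class = "usvdyad_schema_error")
  }
  arena <- as.numeric(arena)
  if (length(arena) != 2L || any(!is.finite(arena)) || any(arena <= 0)) {
    stop_usv("arena dimensions must be two positive numbers",
             class = "usvdyad_schema_error")
  }
  structure(list(mic_positions = unname(mic_positions), arena = arena),
            class = "mic_array_geometry")
}

#' Default 8-microphone arrangement
#'
#' Microphones at the four corners and four edge midpoints of the arena
#' perimeter, mirroring an array that surrounds the cage.
#'
#' @param arena arena (width, height) in metres.
#' @return a `mic_array_geometry` with 8 microphones.
#' @export
default_array_geometry <- function(arena = c(0.762, 0.762)) {
  w <- arena[1]; h <- arena[2]
  pos <- rbind(
    c(0, 0), c(w / 2, 0), c(w, 0), c(w, h / 2),
    c(w, h), c(w / 2, h), c(0, h), c(0, h / 2)
  )
  mic_array_geometry(pos, arena)
}

#' @export
print.mic_array_geometry <- function(x, ...) {
  cat(sprintf("<mic_array_geometry: %d microphones, arena %.3f x %.3f m>\n",
              nrow(x$mic_positions), x$arena[1], x$arena[2]))
  invisible(x)
}
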