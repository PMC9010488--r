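#' CrCEST acquisition protocol
#'
#' Describes the exercise-recovery CrCEST acquisition: the saturation offsets
#' sampled around the creatine amine resonance, the frame timing of the
#' baseline / post-exercise series, saturation settings and image geometry.
#' Defaults reproduce a 3 T calf protocol: offsets at +/-1.5, +/-1.8 and
#' +/-2.1 ppm relative to water, 24 s temporal resolution, five baseline
#' frames, two minutes of in-magnet plantar-flexion exercise (not imaged) and
#' eight minutes of post-exercise imaging.
#'
#' @param offsets_ppm Signed saturation offsets in ppm; must come in +/- pairs.
#' @param frame_interval_s Time between consecutive frames, seconds.
#' @param n_baseline_frames Number of pre-exercise frames.
#' @param exercise_duration_s Duration of the (un-imaged) exercise bout, s.
#' @param post_duration_s Post-exercise imaging window, seconds; must be a
#'   positive integer multiple of `frame_interval_s`.
#' @param sat_b1_uT Saturation pulse amplitude, microtesla.
#' @param sat_duration_ms Saturation duration, milliseconds.
#' @param matrix In-plane matrix size (single integer, square matrix).
#' @param fov_mm Field of view, millimetres (square).
#'
#' @return A `crcest_protocol` object (a validated list).
#' @examples
#' p <- cest_protocol()
#' frame_times(p)
#' @export
cest_protocol <- function(offsets_ppm = c(-2.1, -1.8, -1.5, 1.5, 1.8, 2.1),
                          frame_interval_s = 24,
                          n_baseline_frames = 5,
                          exercise_duration_s = 120,
                          post_duration_s = 480,
                          sat_b1_uT = 3,
                          sat_duration_ms = 500,
                          matrix = 128L,
                          fov_mm = 160) {
  offsets_ppm <- sort(as.numeric(offsets_ppm))
  if (length(offsets_ppm) < 2 || any(offsets_ppm == 0)) {
    abort("`offsets_ppm` must be nonzero saturation offsets.",
          class = "crcest_schema_error")
  }
  pos <- sort(offsets_ppm[offsets_ppm > 0])
  neg <- sort(-offsets_ppm[offsets_ppm < 0])
  if (length(pos) != length(neg) || any(abs(pos - neg) > 1e-9)) {
    abort("Saturation offsets must come in symmetric +/- pairs.",
          class = "crcest_schema_error")
  }
  if (frame_interval_s <= 0) {
    abort("`frame_interval_s` must be positive.", class = "crcest_schema_error")
  }
  if (n_baseline_frames < 1) {
    abort("At least one baseline frame is required.",
          class = "crcest_schema_error")
  }
  n_post <- post_duration_s / frame_interval_s
  if (n_post <= 0 || abs(n_post - round(n_post)) > 1e-9) {
    abort("`post_duration_s` must be a positive integer multiple of `frame_interval_s`.",
          class = "crcest_schema_error")
  }
  if (matrix < 32) {
    abort("`matrix` must be at least 32 pixels.", class = "crcest_schema_error")
  }
  structure(
    list(
      offsets_ppm = offsets_ppm,
      frame_interval_s = frame_interval_s,
      n_baseline_frames = as.integer(n_baseline_frames),
      exercise_duration_s = exercise_duration_s,
      post_duration_s = post_duration_s,
      n_post_frames = as.integer(round(n_post)),
      sat_b1_uT = sat_b1_uT,
      sat_duration_ms = sat_duration_ms,
      matrix = as.integer(matrix),
      fov_mm = fov_mm
    ),
    class = "crcest_protocol"
  )
}

#' Frame times of a protocol
#'
#' Times are relative to the end of exercise: baseline frames are negative
#' (`-n_baseline..-1` times the frame interval), the first post-exercise frame
#' is at t = 0 s, and the exercise interval itself is not imaged.
#'
#' @param protocol A [cest_protocol()].
#' @return Numeric vector of frame times in seconds, strictly increasing.
#' @export
frame_times <- function(protocol) {
  stopifnot(inherits(protocol, "crcest_protocol"))
  dt <- protocol$frame_interval_s
  c(-rev(seq_len(protocol$n_baseline_frames)) * dt,
    (seq_len(protocol$n_post_frames) - 1) * dt)
}

n_frames <- function(protocol) {
  protocol$n_baseline_frames + protocol$n_post_frames
}

#' @export
print.crcest_protocol <- function(x, ...) {
  cat("<crcest_protocol>\n")
  cat("  offsets (ppm):", paste(x$offsets_ppm, collapse = ", "), "\n")
  cat(sprintf("  frames: %d baseline + %d post @ %g s\n",
              x$n_baseline_frames, x$n_post_frames, x$frame_interval_s))
  cat(sprintf("  saturation: %g uT, %g ms; matrix %dx%d, FOV %g mm\n",
              x$sat_b1_uT, x$sat_duration_ms, x$matrix, x$matrix, x$fov_mm))
  invisible(x)
}
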