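# Endpoint detection: trim leading/trailing non-voice from an utterance by
# the classic double-threshold short-time energy rule with zero-crossing
# refinement at the edges.

.frame_stats <- function(x, frame_len, hop) {
  n <- length(x)
  starts <- seq(1L, max(1L, n - frame_len + 1L), by = hop)
  energy <- vapply(starts, function(s) {
    seg <- x[s:(s + frame_len - 1L)]
    mean(seg^2)
  }, numeric(1))
  zcr <- vapply(starts, function(s) {
    seg <- x[s:(s + frame_len - 1L)]
    mean(diff(sign(seg)) != 0)
  }, numeric(1))
  list(starts = starts, energy = energy, zcr = zcr, frame_len = frame_len)
}

#' Trim non-voice leading and trailing portions of an utterance
#'
#' Double-threshold short-time energy endpoint detection: frames whose
#' energy exceeds `energy_hi` (a fraction of the peak frame energy) seed
#' the voiced region, which is grown outward through frames above
#' `energy_lo`, then further through edge frames whose zero-crossing rate
#' exceeds `zcr_thresh` while retaining non-negligible energy (to keep
#' breathy onsets). The result is a contiguous slice of the input —
#' interior samples are never altered.
#'
#' An absolute energy floor guards against all-silence input: the method
#' assumes roughly unit-scale audio (the synthesiser peak-normalises to
#' 0.9), and a recording whose loudest frame stays below the floor raises
#' a no-voice error.
#'
#' @param signal An `audio_signal` (or numeric vector; then `fs` required).
#' @param fs Sampling rate, used when `signal` is a bare vector.
#' @param frame_ms,hop_ms Analysis frame length and hop in milliseconds.
#' @param energy_hi,energy_lo Upper/lower energy thresholds as fractions of
#'   the peak frame energy.
#' @param zcr_thresh Zero-crossing rate (crossings per sample) above which
#'   an edge frame is kept.
#' @param floor_energy Absolute frame-energy floor defining silence.
#' @return The trimmed `audio_signal`, with attributes `start_sample` and
#'   `end_sample` giving the retained slice of the input.
#' @export
endpoint_detect <- function(signal, fs = NULL, frame_ms = 20, hop_ms = 10,
                            energy_hi = 0.10, energy_lo = 0.02,
                            zcr_thresh = 0.25, floor_energy = 1e-6) {
  if (inherits(signal, "audio_signal")) {
    x <- signal$samples
    fs <- signal$fs
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric signal", call. = FALSE)
    x <- as.numeric(signal)
    signal <- structure(list(samples = x, fs = fs, group = NA_character_),
                        class = "audio_signal")
  }
  frame_len <- max(2L, round(frame_ms / 1000 * fs))
  hop <- max(1L, round(hop_ms / 1000 * fs))
  if (length(x) < 3L * frame_len) {
    stop("signal shorter than 3 frames", call. = FALSE)
  }
  fr <- .frame_stats(x, frame_len, hop)
  peak <- max(fr$energy)
  hi <- energy_hi * peak
  lo <- energy_lo * peak
  core <- which(fr$energy > hi & fr$energy > floor_energy)
  if (length(core) == 0L) {
    stop("no voice detected: no frame exceeds the energy threshold",
         call. = FALSE)
  }
  # longest run of frames above lo that contains a core frame
  above <- fr$energy > pmax(lo, floor_energy)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values &
                  vapply(seq_along(runs$values),
                         function(i) any(core >= starts[i] & core <= ends[i]),
                         logical(1)))
  best <- cand[which.max(runs$lengths[cand])]
  f1 <- starts[best]
  f2 <- ends[best]
  # ZCR refinement: extend edges over active but low-energy frames
  while (f1 > 1L && fr$zcr[f1 - 1L] > zcr_thresh &&
         fr$energy[f1 - 1L] > max(0.25 * lo, floor_energy)) f1 <- f1 - 1L
  while (f2 < length(fr$energy) && fr$zcr[f2 + 1L] > zcr_thresh &&
         fr$energy[f2 + 1L] > max(0.25 * lo, floor_energy)) f2 <- f2 + 1L
  s1 <- fr$starts[f1]
  s2 <- min(length(x), fr$starts[f2] + frame_len - 1L)
  out <- signal
  out$samples <- x[s1:s2]
  attr(out, "start_sample") <- s1
  attr(out, "end_sample") <- s2
  out
}
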