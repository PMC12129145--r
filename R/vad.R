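#' Construct an audio track
#'
#' A single-speaker audio channel. Dyadic recordings are assumed to be
#' pre-separated (one channel per interlocutor, no crosstalk), so no
#' diarization is ever attempted.
#'
#' @param samples numeric amplitude vector in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param speaker_id speaker label, conventionally `"A"` or `"B"`.
#' @return an object of class `audio_track`.
#' @export
audio_track <- function(samples, sample_rate, speaker_id = "A") {
  if (!is.numeric(samples) || length(samples) < 1)
    stop("samples must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop("samples must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 speaker_id = as.character(speaker_id)),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track %s: %.3f s @ %g Hz>\n", x$speaker_id,
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Voice activity detection parameters
#'
#' The detector marks a short analysis window as speech when more than
#' `exceed_fraction` of its sample-level log-energies exceed the
#' recording-wide median sample log-energy plus `offset_db`. Defaults are
#' 5 ms windows, a 15% exceedance fraction and a 5 dB offset. Because the
#' threshold is relative to the median, the rule is invariant to a global
#' gain change of the recording.
#'
#' Sample log-energies of exact zeros are floored at `energy_floor_db`
#' so all-silent input is well defined. After windowing, speech runs
#' shorter than `min_speech_ms` and silent gaps shorter than
#' `min_silence_ms` are smoothed away; both default to 25 ms, short enough
#' that smoothing can neither create nor destroy pauses near the 300 ms
#' pause-compression rule.
#'
#' @param window_ms analysis window duration in ms (> 0).
#' @param exceed_fraction required fraction of supra-threshold samples,
#'   in (0, 1).
#' @param offset_db level offset above the median log-energy, in dB.
#' @param min_speech_ms drop speech runs shorter than this (ms).
#' @param min_silence_ms bridge silent gaps shorter than this (ms).
#' @param energy_floor_db log-energy assigned to zero samples (dB).
#' @return an object of class `vad_params`.
#' @export
vad_params <- function(window_ms = 5, exceed_fraction = 0.15, offset_db = 5,
                       min_speech_ms = 25, min_silence_ms = 25,
                       energy_floor_db = -120) {
  if (window_ms <= 0) stop("window_ms must be > 0")
  if (exceed_fraction <= 0 || exceed_fraction >= 1)
    stop("exceed_fraction must lie strictly between 0 and 1")
  structure(list(window_ms = window_ms, exceed_fraction = exceed_fraction,
                 offset_db = offset_db, min_speech_ms = min_speech_ms,
                 min_silence_ms = min_silence_ms,
                 energy_floor_db = energy_floor_db),
            class = "vad_params")
}

#' Energy-threshold voice activity detection
#'
#' Computes per-sample log-energies (dB of the squared amplitude, floored
#' at `params$energy_floor_db`), then flags each `window_ms` window as
#' speech iff more than `exceed_fraction` of its samples exceed the global
#' median sample log-energy plus `offset_db`. The final partial window is
#' evaluated over its available samples. The mask is then smoothed
#' (short gaps bridged, then short speech runs dropped).
#'
#' @param track an [audio_track()].
#' @param params a [vad_params()].
#' @return an object of class `activity_mask`: logical `flags` (one per
#'   window), `window_s`, `speaker_id`, `sample_rate`, `n_samples`.
#' @export
detect_voice_activity <- function(track, params = vad_params()) {
  stopifnot(inherits(track, "audio_track"), inherits(params, "vad_params"))
  x <- track$samples
  w <- max(1L, as.integer(round(track$sample_rate * params$window_ms / 1000)))
  n <- length(x)
  n_win <- as.integer(ceiling(n / w))

  log_e <- 10 * log10(pmax(x^2, 10^(params$energy_floor_db / 10)))
  thr <- stats::median(log_e) + params$offset_db
  exceed <- log_e > thr

  idx <- rep(seq_len(n_win), each = w)[seq_len(n)]
  hits <- tabulate(idx[exceed], nbins = n_win)
  sizes <- tabulate(idx, nbins = n_win)
  flags <- hits / sizes > params$exceed_fraction

  win_s <- params$window_ms / 1000
  flags <- smooth_flags(flags,
                        min_speech = ceiling(params$min_speech_ms / 1000 / win_s),
                        min_silence = ceiling(params$min_silence_ms / 1000 / win_s))

  structure(list(flags = flags, window_s = win_s,
                 speaker_id = track$speaker_id,
                 sample_rate = track$sample_rate, n_samples = n),
            class = "activity_mask")
}

# three-stage smoothing: drop single-window flicker, bridge interior
# silent gaps shorter than min_silence windows, then drop speech runs
# still shorter than min_speech windows. Dropping isolated windows first
# keeps sporadic supra-threshold noise windows from being bridged into
# spurious speech runs.
smooth_flags <- function(flags, min_speech, min_silence) {
  if (!length(flags)) return(flags)
  if (min_speech > 1) {
    r <- rle(flags)
    r$values[r$values & r$lengths == 1] <- FALSE
    flags <- inverse.rle(r)
  }
  r <- rle(flags)
  if (length(r$lengths) > 2) {
    interior <- 2:(length(r$lengths) - 1)
    bridge <- interior[!r$values[interior] & r$lengths[interior] < min_silence]
    r$values[bridge] <- TRUE
  }
  flags <- inverse.rle(r)
  r <- rle(flags)
  r$values[r$values & r$lengths < min_speech] <- FALSE
  inverse.rle(r)
}

#' Convert an activity mask to speech intervals
#'
#' @param mask an `activity_mask` from [detect_voice_activity()].
#' @return data frame with columns `speaker`, `start`, `end` (seconds);
#'   the final interval is capped at the track duration.
#' @export
mask_to_intervals <- function(mask) {
  stopifnot(inherits(mask, "activity_mask"))
  r <- rle(mask$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  dur <- mask$n_samples / mask$sample_rate
  out <- data.frame(speaker = mask$speaker_id,
                    start = starts[keep] * mask$window_s,
                    end = pmin(ends[keep] * mask$window_s, dur))
  rownames(out) <- NULL
  out
}

#' Write a VAD result as a Praat TextGrid
#'
#' One interval tier named after the speaker, speech intervals labelled
#' `"speech"`, gaps empty.
#'
#' @param mask an `activity_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vad_textgrid <- function(mask, path) {
  iv <- mask_to_intervals(mask)
  iv$label <- "speech"
  tiers <- stats::setNames(list(iv[, c("start", "end", "label")]),
                           mask$speaker_id)
  write_textgrid(tiers, path, xmax = mask$n_samples / mask$sample_rate)
}
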