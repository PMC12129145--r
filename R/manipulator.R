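# Re-timing and re-rendering of classified conversation segments under
# the four FTO manipulation schemes: per-turn loudness equalization,
# pause compression, FTO scheduling and mono rendering.

#' Define an FTO manipulation scheme
#'
#' Four schemes are supported: `conLow` and `conNHQ` impose a constant
#' FTO at every floor transfer (50 ms and 190 ms by default); `NHQ` draws
#' FTOs i.i.d. from a source logistic distribution (the normal-hearing-
#' in-quiet fit by default); `HIN` draws from the source distribution and
#' maps the draws onto a target distribution (the hearing-impaired-in-
#' noise fit) with the affine scale-and-shift transform of
#' [transform_to_distribution()].
#'
#' @param name one of `"conLow"`, `"conNHQ"`, `"NHQ"`, `"HIN"`.
#' @param constant_fto_ms constant FTO in ms (constant schemes only;
#'   defaults 50 / 190).
#' @param source_dist [logistic_params()] the draws come from (NHQ and
#'   HIN schemes).
#' @param target_dist [logistic_params()] the draws are transformed to
#'   (HIN scheme only).
#' @return an object of class `manipulation_scheme`.
#' @export
manipulation_scheme <- function(name = c("conLow", "conNHQ", "NHQ", "HIN"),
                                constant_fto_ms = NULL, source_dist = NULL,
                                target_dist = NULL) {
  name <- match.arg(name)
  constant <- name %in% c("conLow", "conNHQ")
  if (constant) {
    if (!is.null(source_dist) || !is.null(target_dist))
      stop("constant schemes carry no distributions")
    if (is.null(constant_fto_ms))
      constant_fto_ms <- if (name == "conLow") con_low_ms() else con_nhq_ms()
  } else {
    if (!is.null(constant_fto_ms))
      stop("distribution schemes carry no constant FTO")
    if (is.null(source_dist)) source_dist <- nhq_logistic()
    if (name == "HIN" && is.null(target_dist)) target_dist <- hin_logistic()
    if (name == "NHQ" && !is.null(target_dist))
      stop("NHQ scheme carries no target distribution")
  }
  structure(list(name = name, constant_fto_ms = constant_fto_ms,
                 source_dist = source_dist, target_dist = target_dist),
            class = "manipulation_scheme")
}

#' @export
print.manipulation_scheme <- function(x, ...) {
  if (!is.null(x$constant_fto_ms))
    cat(sprintf("<manipulation_scheme %s: constant FTO %g ms>\n",
                x$name, x$constant_fto_ms))
  else
    cat(sprintf("<manipulation_scheme %s: draws from logistic(%.1f, %.1f)%s>\n",
                x$name, x$source_dist$mu, x$source_dist$sigma,
                if (is.null(x$target_dist)) "" else
                  sprintf(", mapped to logistic(%.1f, %.1f)",
                          x$target_dist$mu, x$target_dist$sigma)))
  invisible(x)
}

#' Rendering configuration
#'
#' @param leading_silence_ms silence prepended to each stimulus (200 ms).
#' @param max_internal_pause_ms pause-compression threshold: within-turn
#'   pauses longer than this are repeatedly halved until shorter (300 ms).
#' @param target_rms per-turn RMS target over IPU samples (linear
#'   amplitude; default 0.05, about -26 dB FS).
#' @param sample_rate output sampling rate in Hz (48000).
#' @param seed master seed for FTO draws (`NULL` = use current RNG).
#' @param overlap_clamp_fraction a drawn FTO may not place an incoming
#'   turn earlier than this fraction of the preceding turn before its end
#'   (redraw up to 10 times, then clamp).
#' @param ramp_ms linear fade applied at audio cut points to avoid
#'   clicks.
#' @return an object of class `render_config`.
#' @export
render_config <- function(leading_silence_ms = 200,
                          max_internal_pause_ms = 300, target_rms = 0.05,
                          sample_rate = 48000, seed = NULL,
                          overlap_clamp_fraction = 0.9, ramp_ms = 5) {
  stopifnot(leading_silence_ms >= 0, max_internal_pause_ms >= 0,
            target_rms > 0, target_rms < 1, sample_rate > 0)
  structure(list(leading_silence_ms = leading_silence_ms,
                 max_internal_pause_ms = max_internal_pause_ms,
                 target_rms = target_rms, sample_rate = sample_rate,
                 seed = seed,
                 overlap_clamp_fraction = overlap_clamp_fraction,
                 ramp_ms = ramp_ms),
            class = "render_config")
}

#' Scale audio so its IPU samples hit a target RMS
#'
#' The gain is computed over the IPU (speech) samples only -- pause
#' samples are excluded from the RMS but are scaled by the same gain, so
#' one uniform gain applies per turn.
#'
#' @param audio numeric sample vector for one turn.
#' @param target_rms target root-mean-square amplitude.
#' @param ipu_mask logical vector marking IPU samples (default: all).
#' @return scaled audio, with the applied gain as attribute `"gain"`.
#' @export
equalize_loudness <- function(audio, target_rms, ipu_mask = NULL) {
  if (is.null(ipu_mask)) ipu_mask <- rep(TRUE, length(audio))
  r <- sqrt(mean(audio[ipu_mask]^2))
  if (!is.finite(r) || r == 0) stop("silent turn: cannot equalize loudness")
  out <- audio * (target_rms / r)
  attr(out, "gain") <- target_rms / r
  out
}

#' Compressed duration of a within-turn pause
#'
#' Pauses longer than `max_ms` are repeatedly halved until shorter than
#' `max_ms`; pauses of at most `max_ms` are untouched. Forced values:
#' 1000 -> 250, 600 -> 150 (600 halves to 300, which is not *shorter*
#' than 300, so it halves again), 300 -> 300.
#'
#' @param pause_ms pause duration in ms.
#' @param max_ms threshold (default 300).
#' @return compressed duration in ms, vectorized over `pause_ms`.
#' @export
compressed_pause_ms <- function(pause_ms, max_ms = 300) {
  vapply(pause_ms, function(p) {
    if (p > max_ms) while (p >= max_ms) p <- p / 2
    p
  }, numeric(1))
}

#' Compress the internal pauses of a turn
#'
#' Applies [compressed_pause_ms()] to every within-turn pause, shifting
#' later IPUs left; IPU audio (and their source references) is unchanged
#' and the turn end moves left by the total removed time.
#'
#' @param turn a turn object (as in a `conversation_timeline`).
#' @param max_pause_ms compression threshold in ms.
#' @return the compressed turn object.
#' @export
compress_pauses <- function(turn, max_pause_ms = 300) {
  ip <- turn$ipus
  if (is.null(ip$src_start)) {
    ip$src_start <- ip$start
    ip$src_end <- ip$end
  }
  n <- nrow(ip)
  if (n >= 2) {
    dur <- ip$end - ip$start
    gaps <- ip$start[-1] - ip$end[-n]
    new_gaps <- compressed_pause_ms(gaps * 1000, max_pause_ms) / 1000
    pos <- ip$start[1]
    for (j in seq_len(n)) {
      ip$start[j] <- pos
      ip$end[j] <- pos + dur[j]
      if (j < n) pos <- ip$end[j] + new_gaps[j]
    }
  }
  turn$ipus <- ip
  turn$start <- ip$start[1]
  turn$end <- ip$end[n]
  gaps <- which(ip$start[-1] - ip$end[-n] > 1e-9)
  turn$internal_pauses <- data.frame(start = ip$end[gaps],
                                     end = ip$start[gaps + 1])
  turn
}

# draw one realized FTO (ms) under the scheme, redrawing values that
# would start the incoming turn before 90% of the outgoing turn has
# elapsed (bound_ms is negative)
draw_fto <- function(scheme, bound_ms) {
  draw_raw <- function() {
    u <- stats::runif(1)
    x <- scheme$source_dist$mu +
      scheme$source_dist$sigma * log(u / (1 - u))
    if (!is.null(scheme$target_dist))
      x <- transform_to_distribution(x, scheme$source_dist,
                                     scheme$target_dist)
    x
  }
  for (i in 1:10) {
    x <- draw_raw()
    if (x >= bound_ms) return(x)
  }
  bound_ms
}

#' Schedule turn onsets under a manipulation scheme
#'
#' Assigns one FTO per floor transfer (constant value, or draws from the
#' scheme's distribution) and shifts each turn rigidly so that turn
#' *k + 1* starts at the offset of turn *k* plus its FTO. The first turn
#' is rebased to time 0. Overlaps-within are re-attached at their
#' original offset relative to the (compressed) host turn start; if an
#' overlap reaches past its host turn end and collides with the next
#' scheduled onset it is truncated 1 ms before that onset.
#'
#' @param timeline a `conversation_timeline` whose turns are already
#'   pause-compressed (see [compress_pauses()]).
#' @param scheme a [manipulation_scheme()].
#' @param config a [render_config()]; `config$seed` drives the draws via
#'   a scheme-specific child seed.
#' @param ftos optional numeric vector of pre-drawn FTOs in ms (length =
#'   number of transfers); values below the overlap clamp are clamped,
#'   never redrawn.
#' @return list with `timeline` (scheduled `conversation_timeline`) and
#'   `assigned_ftos` (ms).
#' @export
schedule_turns <- function(timeline, scheme, config = render_config(),
                           ftos = NULL) {
  stopifnot(inherits(timeline, "conversation_timeline"),
            inherits(scheme, "manipulation_scheme"))
  turns <- timeline$turns
  n_tr <- length(turns) - 1
  if (n_tr < 1) stop("scheduling needs at least 2 turns")
  durs <- vapply(turns, function(t) t$end - t$start, numeric(1))
  bounds <- -config$overlap_clamp_fraction * durs[seq_len(n_tr)] * 1000

  if (is.null(ftos)) {
    if (!is.null(scheme$constant_fto_ms)) {
      ftos <- rep(scheme$constant_fto_ms, n_tr)
    } else {
      child <- if (!is.null(config$seed))
        derive_seed(config$seed, "ftos", scheme$name) else NULL
      ftos <- with_seed(child,
                        vapply(seq_len(n_tr),
                               function(k) draw_fto(scheme, bounds[k]),
                               numeric(1)))
    }
  } else {
    if (length(ftos) != n_tr)
      stop("need one FTO per floor transfer (", n_tr, ")")
    ftos <- pmax(ftos, bounds)
  }

  shift_turn <- function(t, delta) {
    t$start <- t$start + delta
    t$end <- t$end + delta
    t$ipus$start <- t$ipus$start + delta
    t$ipus$end <- t$ipus$end + delta
    if (nrow(t$internal_pauses)) {
      t$internal_pauses$start <- t$internal_pauses$start + delta
      t$internal_pauses$end <- t$internal_pauses$end + delta
    }
    t
  }
  new_starts <- numeric(length(turns))
  new_starts[1] <- 0
  sched <- vector("list", length(turns))
  sched[[1]] <- shift_turn(turns[[1]], -turns[[1]]$start)
  for (k in seq_len(n_tr)) {
    new_starts[k + 1] <- sched[[k]]$end + ftos[k] / 1000
    sched[[k + 1]] <- shift_turn(turns[[k + 1]],
                                 new_starts[k + 1] - turns[[k + 1]]$start)
  }

  ov <- timeline$overlaps_within
  if (nrow(ov)) {
    dur_ov <- ov$end - ov$start
    host_start <- vapply(ov$host_index, function(i) sched[[i]]$start,
                         numeric(1))
    host_end <- vapply(ov$host_index, function(i) sched[[i]]$end,
                       numeric(1))
    ov$start <- host_start + ov$rel_offset
    ov$end <- ov$start + dur_ov
    ov$truncated <- FALSE
    for (j in seq_len(nrow(ov))) {
      hi <- ov$host_index[j]
      if (ov$end[j] > host_end[j] + 1e-9 && hi < length(sched)) {
        next_onset <- sched[[hi + 1]]$start
        if (ov$end[j] > next_onset - 0.001) {
          ov$end[j] <- max(next_onset - 0.001, ov$start[j] + 0.001)
          ov$truncated[j] <- TRUE
        }
      }
    }
  }
  out <- conversation_timeline(sched, ov, segment_id = timeline$segment_id,
                               total_duration = NULL)
  list(timeline = out, assigned_ftos = ftos)
}

#' Render a scheduled timeline to a mono waveform
#'
#' Prepends the leading silence, places every IPU's source audio (scaled
#' by its turn gain, with short linear ramps at cut points) at its
#' scheduled position, sums overlapping regions, and applies one global
#' gain normalizing the peak to 0.99 only if the summed peak exceeds 1.
#' The realized timeline and FTOs are recomputed from the final
#' sample-grid placements.
#'
#' @param scheduled a scheduled `conversation_timeline` whose turns carry
#'   `gain` and whose IPUs carry `src_start`/`src_end` source references
#'   (as produced by [manipulate_segment()]; both default to 1 /
#'   scheduled times when absent).
#' @param tracks named list of [audio_track()] objects, one per speaker.
#' @param config a [render_config()].
#' @param scheme optional [manipulation_scheme()] recorded as provenance.
#' @param assigned_ftos optional assigned FTO vector recorded as
#'   provenance.
#' @param segment_id optional identifier.
#' @param split_by_speaker if `TRUE`, additionally return the two
#'   per-speaker render buffers (element `channels`, a named list of
#'   numeric vectors summing to `waveform`), e.g. to re-run voice
#'   activity detection per interlocutor on the rendered stimulus.
#' @return an object of class `rendered_conversation`: `waveform`,
#'   `sample_rate`, `realized_timeline`, `realized_ftos` (ms), `scheme`,
#'   `segment_id`, `seed` (and `channels` if requested).
#' @export
render_audio <- function(scheduled, tracks, config = render_config(),
                         scheme = NULL, assigned_ftos = NULL,
                         segment_id = NULL, split_by_speaker = FALSE) {
  stopifnot(inherits(scheduled, "conversation_timeline"))
  sr <- config$sample_rate
  names(tracks) <- vapply(tracks, `[[`, character(1), "speaker_id")
  for (tr in tracks)
    if (abs(tr$sample_rate - sr) > 1e-9)
      stop("track sample rate ", tr$sample_rate,
           " differs from configured rate ", sr, " (no resampling)")

  lead_n <- round(config$leading_silence_ms / 1000 * sr)
  ends <- vapply(scheduled$turns, `[[`, numeric(1), "end")
  ov <- scheduled$overlaps_within
  max_end <- max(ends, if (nrow(ov)) max(ov$end) else -Inf)
  n_total <- lead_n + round(max_end * sr)
  spk_ids <- unique(vapply(scheduled$turns, `[[`, character(1), "speaker"))
  chans <- stats::setNames(
    lapply(spk_ids, function(s) numeric(n_total)), spk_ids)
  ramp_n <- round(config$ramp_ms / 1000 * sr)

  cut_src <- function(track, s0, s1) {
    i0 <- round(s0 * sr) + 1
    i1 <- round(s1 * sr)
    if (i1 > length(track$samples) || i0 < 1)
      stop("missing source audio for an IPU of speaker ", track$speaker_id)
    track$samples[seq.int(i0, i1)]
  }
  apply_ramp <- function(x) {
    k <- min(ramp_n, floor(length(x) / 2))
    if (k > 1) {
      r <- seq(0, 1, length.out = k)
      x[1:k] <- x[1:k] * r
      x[(length(x) - k + 1):length(x)] <-
        x[(length(x) - k + 1):length(x)] * rev(r)
    }
    x
  }
  place <- function(seg, start_s, spk) {
    pos <- lead_n + round(start_s * sr)
    idx <- pos + seq_along(seg)
    keep <- idx >= 1 & idx <= n_total
    chans[[spk]][idx[keep]] <<- chans[[spk]][idx[keep]] + seg[keep]
  }

  for (t in scheduled$turns) {
    track <- tracks[[t$speaker]]
    if (is.null(track)) stop("no track for speaker ", t$speaker)
    gain <- if (is.null(t$gain)) 1 else t$gain
    ip <- t$ipus
    if (is.null(ip$src_start)) {
      ip$src_start <- ip$start
      ip$src_end <- ip$end
    }
    for (j in seq_len(nrow(ip))) {
      seg <- cut_src(track, ip$src_start[j], ip$src_end[j]) * gain
      place(apply_ramp(seg), ip$start[j], t$speaker)
    }
  }
  if (nrow(ov)) {
    if (is.null(ov$src_start)) {
      ov$src_start <- ov$start
      ov$src_end <- ov$end
    }
    if (is.null(ov$gain)) ov$gain <- 1
    for (j in seq_len(nrow(ov))) {
      dur <- ov$end[j] - ov$start[j]  # may be truncated
      seg <- cut_src(tracks[[ov$speaker[j]]], ov$src_start[j],
                     ov$src_start[j] + dur) * ov$gain[j]
      place(apply_ramp(seg), ov$start[j], ov$speaker[j])
    }
  }

  buf <- Reduce(`+`, chans)
  peak <- max(abs(buf))
  if (peak > 1) {
    g <- 0.99 / peak
    buf <- buf * g
    chans <- lapply(chans, `*`, g)
  }

  q <- function(x) round(x * sr) / sr
  rq <- lapply(scheduled$turns, function(t) {
    t$start <- q(t$start); t$end <- q(t$end)
    t$ipus$start <- q(t$ipus$start); t$ipus$end <- q(t$ipus$end)
    if (nrow(t$internal_pauses)) {
      t$internal_pauses$start <- q(t$internal_pauses$start)
      t$internal_pauses$end <- q(t$internal_pauses$end)
    }
    t
  })
  ovq <- ov
  if (nrow(ovq)) {
    ovq$start <- q(ovq$start)
    ovq$end <- q(ovq$end)
  }
  realized <- conversation_timeline(rq, ovq,
                                    segment_id = scheduled$segment_id)
  structure(list(waveform = buf, sample_rate = sr,
                 realized_timeline = realized,
                 realized_ftos = realized$ftos$value_ms,
                 scheme = scheme, assigned_ftos = assigned_ftos,
                 segment_id = if (is.null(segment_id))
                   scheduled$segment_id else segment_id,
                 seed = config$seed,
                 channels = if (split_by_speaker) chans else NULL),
            class = "rendered_conversation")
}

#' @export
print.rendered_conversation <- function(x, ...) {
  cat(sprintf(
    "<rendered_conversation %s [%s]: %.2f s @ %g Hz, %d floor transfers>\n",
    x$segment_id, if (is.null(x$scheme)) "raw" else x$scheme$name,
    length(x$waveform) / x$sample_rate, x$sample_rate,
    length(x$realized_ftos)))
  invisible(x)
}

#' Manipulate one conversation segment end to end
#'
#' Composition of the four per-turn steps, in timeline order: loudness
#' equalization over IPU samples, pause compression, FTO scheduling under
#' the scheme, and mono rendering with a 200 ms leading silence.
#'
#' @param tracks named list of [audio_track()] objects (one per speaker,
#'   at the configured sample rate).
#' @param timeline the segment's `conversation_timeline` (detected or
#'   ground truth), in source-track coordinates.
#' @param scheme a [manipulation_scheme()].
#' @param config a [render_config()].
#' @param ftos optional pre-drawn FTO vector in ms (see
#'   [schedule_turns()]).
#' @param split_by_speaker passed to [render_audio()].
#' @return a `rendered_conversation`.
#' @export
manipulate_segment <- function(tracks, timeline, scheme,
                               config = render_config(), ftos = NULL,
                               split_by_speaker = FALSE) {
  stopifnot(inherits(timeline, "conversation_timeline"))
  sr <- config$sample_rate
  names(tracks) <- vapply(tracks, `[[`, character(1), "speaker_id")

  turn_gain <- function(t) {
    track <- tracks[[t$speaker]]
    if (is.null(track)) stop("no track for speaker ", t$speaker)
    ip <- t$ipus
    src0 <- if (is.null(ip$src_start)) ip$start else ip$src_start
    src1 <- if (is.null(ip$src_end)) ip$end else ip$src_end
    samp <- unlist(lapply(seq_len(nrow(ip)), function(j) {
      track$samples[seq.int(round(src0[j] * sr) + 1, round(src1[j] * sr))]
    }))
    r <- sqrt(mean(samp^2))
    if (!is.finite(r) || r == 0)
      stop("silent turn: cannot equalize loudness")
    config$target_rms / r
  }

  turns <- lapply(timeline$turns, function(t) {
    t$gain <- turn_gain(t)
    compress_pauses(t, config$max_internal_pause_ms)
  })
  ov <- timeline$overlaps_within
  if (nrow(ov)) {
    ov$src_start <- ov$start
    ov$src_end <- ov$end
    ov$gain <- vapply(seq_len(nrow(ov)), function(j) {
      track <- tracks[[ov$speaker[j]]]
      samp <- track$samples[seq.int(round(ov$start[j] * sr) + 1,
                                    round(ov$end[j] * sr))]
      r <- sqrt(mean(samp^2))
      if (!is.finite(r) || r == 0)
        stop("silent overlap-within: cannot equalize loudness")
      config$target_rms / r
    }, numeric(1))
  }
  compressed <- conversation_timeline(turns, ov,
                                      segment_id = timeline$segment_id)

  if (length(turns) >= 2) {
    sch <- schedule_turns(compressed, scheme, config, ftos = ftos)
    scheduled <- sch$timeline
    assigned <- sch$assigned_ftos
  } else {
    sch0 <- compressed
    delta <- -turns[[1]]$start
    sch0$turns[[1]]$start <- sch0$turns[[1]]$start + delta
    sch0$turns[[1]]$end <- sch0$turns[[1]]$end + delta
    sch0$turns[[1]]$ipus$start <- sch0$turns[[1]]$ipus$start + delta
    sch0$turns[[1]]$ipus$end <- sch0$turns[[1]]$ipus$end + delta
    if (nrow(sch0$overlaps_within)) {
      d_ov <- sch0$overlaps_within$end - sch0$overlaps_within$start
      sch0$overlaps_within$start <- sch0$turns[[1]]$start +
        sch0$overlaps_within$rel_offset
      sch0$overlaps_within$end <- sch0$overlaps_within$start + d_ov
    }
    scheduled <- conversation_timeline(sch0$turns, sch0$overlaps_within,
                                       segment_id = timeline$segment_id)
    assigned <- numeric(0)
  }
  render_audio(scheduled, tracks, config, scheme = scheme,
               assigned_ftos = assigned, segment_id = timeline$segment_id,
               split_by_speaker = split_by_speaker)
}

#' Manipulate an NHQ/HIN segment pair with shared draws
#'
#' Because the two reference FTO distributions overlap substantially
#' (overlapping index about 0.69), independently drawn NHQ and HIN values
#' would often be similar. Segment pairs are therefore manipulated
#' jointly: the first segment receives raw draws from the NHQ
#' distribution, and the second receives draws from the same seeded
#' sequence (sized to its own transfer count) pushed through the affine
#' NHQ-to-HIN transform, guaranteeing that the applied values differ
#' between conditions while remaining random.
#'
#' @param segment_nhq,segment_hin lists with elements `tracks` (named
#'   list of [audio_track()]) and `timeline` (`conversation_timeline`).
#' @param nhq_params,hin_params [logistic_params()] for the source and
#'   target distributions.
#' @param config a [render_config()].
#' @param seed integer seed for the shared draw sequence (defaults to
#'   `config$seed`).
#' @return list with elements `nhq` and `hin`, both
#'   `rendered_conversation` objects, plus `draws` (the raw NHQ draw
#'   sequence for the first segment).
#' @export
make_paired_nhq_hin <- function(segment_nhq, segment_hin,
                                nhq_params = nhq_logistic(),
                                hin_params = hin_logistic(),
                                config = render_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  n1 <- length(segment_nhq$timeline$turns) - 1
  n2 <- length(segment_hin$timeline$turns) - 1
  if (n1 < 1 || n2 < 1) stop("both segments need at least 2 turns")
  child <- if (!is.null(seed)) derive_seed(seed, "paired-draw") else NULL
  draws1 <- sample_ftos(nhq_params, n1, seed = child)
  draws2 <- sample_ftos(nhq_params, n2, seed = child)
  ftos2 <- transform_to_distribution(draws2, nhq_params, hin_params)

  r1 <- manipulate_segment(segment_nhq$tracks, segment_nhq$timeline,
                           manipulation_scheme("NHQ",
                                               source_dist = nhq_params),
                           config, ftos = draws1)
  r2 <- manipulate_segment(segment_hin$tracks, segment_hin$timeline,
                           manipulation_scheme("HIN",
                                               source_dist = nhq_params,
                                               target_dist = hin_params),
                           config, ftos = ftos2)
  list(nhq = r1, hin = r2, draws = draws1)
}

#' Write a rendered conversation as WAV plus JSON sidecar
#'
#' @param rendered a `rendered_conversation`.
#' @param wav_path output WAV path (16-bit PCM mono).
#' @param json_path optional sidecar path (default: `wav_path` with a
#'   `.json` extension) holding scheme, seed, realized FTOs and the
#'   flattened realized timeline.
#' @return `wav_path`, invisibly.
#' @export
write_rendered <- function(rendered, wav_path, json_path = NULL) {
  stopifnot(inherits(rendered, "rendered_conversation"))
  write_wav(rendered$waveform, rendered$sample_rate, wav_path)
  if (is.null(json_path)) json_path <- sub("\\.wav$", ".json", wav_path)
  meta <- list(segment_id = rendered$segment_id,
               scheme = if (is.null(rendered$scheme)) NULL
                 else rendered$scheme$name,
               seed = rendered$seed,
               sample_rate = rendered$sample_rate,
               realized_ftos_ms = rendered$realized_ftos,
               timeline = timeline_to_df(rendered$realized_timeline))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(wav_path)
}
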