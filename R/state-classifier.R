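# Communicative-state classification: inter-pausal units -> turns,
# overlaps-within and floor-transfer offsets.
#
# Coordinate convention: all intervals are half-open [start, end) in
# seconds (float); FTOs are reported in milliseconds.

#' Build inter-pausal units from an activity mask or interval table
#'
#' Maximal speech runs separated by at most `max_gap_ms` of silence are
#' merged into a single inter-pausal unit (IPU). Silences at or below the
#' merge threshold disappear inside an IPU; longer silences separate IPUs
#' and later become within-turn pauses or between-turn gaps.
#'
#' @param x an `activity_mask` (from [detect_voice_activity()]) or a data
#'   frame with columns `speaker`, `start`, `end` in seconds.
#' @param max_gap_ms silences up to this duration are merged (default
#'   180 ms; the 300 ms pause-compression rule then operates on surviving
#'   within-turn silences).
#' @return data frame of IPUs (`speaker`, `start`, `end`), sorted by start.
#' @export
build_ipus <- function(x, max_gap_ms = 180) {
  iv <- if (inherits(x, "activity_mask")) mask_to_intervals(x) else x
  stopifnot(is.data.frame(iv), all(c("speaker", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0)
    return(data.frame(speaker = character(0), start = numeric(0),
                      end = numeric(0)))
  iv <- iv[order(iv$start), , drop = FALSE]
  gap_s <- max_gap_ms / 1000
  starts <- iv$start[1]
  ends <- iv$end[1]
  spk <- iv$speaker[1]
  for (j in seq_len(nrow(iv))[-1]) {
    k <- length(starts)
    if (iv$speaker[j] == spk[k] && iv$start[j] - ends[k] <= gap_s + 1e-9) {
      ends[k] <- max(ends[k], iv$end[j])
    } else {
      starts <- c(starts, iv$start[j])
      ends <- c(ends, iv$end[j])
      spk <- c(spk, iv$speaker[j])
    }
  }
  out <- data.frame(speaker = spk, start = starts, end = ends)
  rownames(out) <- NULL
  out
}

#' Classify IPUs into turns and overlaps-within
#'
#' Implements the communicative-state rules: a turn is a sequence of
#' connected IPUs from one interlocutor, including its internal pauses,
#' bounded by floor transfers; an overlap-within is speech uttered
#' completely within the other interlocutor's turn and produces no floor
#' transfer.
#'
#' Operational rules (documented choices where the definitions are
#' circular): an IPU of the non-holding speaker that starts at or after
#' the current turn's speech end always takes the floor (positive or zero
#' FTO). An IPU starting inside the current turn is an overlap-within iff
#' it ends no later than the holder's speech extended through any holder
#' IPUs that start before the intruder ends (the holder "talks through");
#' otherwise the intruder outlasts the holder and takes the floor with a
#' negative FTO. Simultaneous onsets (< 1 ms apart) are resolved in favour
#' of the speaker who continues longer.
#'
#' @param ipus_a,ipus_b per-speaker IPU data frames (`speaker`, `start`,
#'   `end`), each internally disjoint.
#' @param segment_id optional identifier stored on the timeline.
#' @param total_duration optional total duration in seconds (defaults to
#'   the last speech offset).
#' @return a `conversation_timeline`: list with `turns` (list of turn
#'   objects), `overlaps_within` (data frame), `ftos` (data frame),
#'   `segment_id`, `total_duration`.
#' @export
classify_states <- function(ipus_a, ipus_b, segment_id = NA_character_,
                            total_duration = NULL) {
  check_disjoint <- function(d, who) {
    if (nrow(d) < 2) return(invisible())
    d <- d[order(d$start), ]
    if (any(d$start[-1] < d$end[-nrow(d)] - 1e-9))
      stop("IPUs of speaker ", who, " must be disjoint")
  }
  check_disjoint(ipus_a, "A")
  check_disjoint(ipus_b, "B")
  all_ipus <- rbind(ipus_a, ipus_b)
  if (nrow(all_ipus) == 0) stop("no speech in either channel")
  if (any(all_ipus$end <= all_ipus$start)) stop("IPU with end <= start")
  all_ipus <- all_ipus[order(all_ipus$start, -all_ipus$end,
                             all_ipus$speaker), , drop = FALSE]
  rownames(all_ipus) <- NULL

  n <- nrow(all_ipus)
  turns <- list()
  overlaps <- list()
  cur <- NULL # list(speaker, ipus = row indices, end, overlaps = list)

  finish <- function(cur) {
    ip <- all_ipus[cur$ipus, c("start", "end"), drop = FALSE]
    rownames(ip) <- NULL
    gaps <- which(ip$start[-1] - ip$end[-nrow(ip)] > 1e-9)
    pauses <- data.frame(start = ip$end[gaps], end = ip$start[gaps + 1])
    turn <- list(speaker = cur$speaker, start = ip$start[1],
                 end = max(ip$end), ipus = ip, internal_pauses = pauses)
    class(turn) <- "conv_turn"
    turn
  }

  for (k in seq_len(n)) {
    q <- all_ipus[k, ]
    if (is.null(cur)) {
      cur <- list(speaker = q$speaker, ipus = k, end = q$end,
                  overlaps = list())
      next
    }
    if (q$speaker == cur$speaker) {
      cur$ipus <- c(cur$ipus, k)
      cur$end <- max(cur$end, q$end)
      next
    }
    if (q$start >= cur$end - 1e-3) {
      # floor transfer across a gap (or a near-simultaneous boundary)
      turns[[length(turns) + 1]] <- finish(cur)
      host_idx <- length(turns)
      for (ov in cur$overlaps) {
        ov$host_index <- host_idx
        overlaps[[length(overlaps) + 1]] <- ov
      }
      cur <- list(speaker = q$speaker, ipus = k, end = q$end,
                  overlaps = list())
    } else {
      # q intrudes inside the current turn: extend the holder's speech
      # through any of its IPUs that start before q ends
      ext <- cur$end
      if (k < n) for (j in (k + 1):n) {
        r <- all_ipus[j, ]
        if (r$start >= q$end - 1e-9) break
        if (r$speaker == cur$speaker) ext <- max(ext, r$end)
      }
      if (q$end <= ext + 1e-9) {
        cur$overlaps[[length(cur$overlaps) + 1]] <-
          list(speaker = q$speaker, start = q$start, end = q$end)
      } else {
        turns[[length(turns) + 1]] <- finish(cur)
        host_idx <- length(turns)
        for (ov in cur$overlaps) {
          ov$host_index <- host_idx
          overlaps[[length(overlaps) + 1]] <- ov
        }
        cur <- list(speaker = q$speaker, ipus = k, end = q$end,
                    overlaps = list())
      }
    }
  }
  turns[[length(turns) + 1]] <- finish(cur)
  host_idx <- length(turns)
  for (ov in cur$overlaps) {
    ov$host_index <- host_idx
    overlaps[[length(overlaps) + 1]] <- ov
  }

  ov_df <- if (length(overlaps)) {
    data.frame(
      speaker = vapply(overlaps, `[[`, character(1), "speaker"),
      start = vapply(overlaps, `[[`, numeric(1), "start"),
      end = vapply(overlaps, `[[`, numeric(1), "end"),
      host_index = vapply(overlaps, `[[`, numeric(1), "host_index"))
  } else {
    data.frame(speaker = character(0), start = numeric(0), end = numeric(0),
               host_index = numeric(0))
  }
  ov_df$rel_offset <- if (nrow(ov_df))
    ov_df$start - vapply(ov_df$host_index,
                         function(i) turns[[i]]$start, numeric(1))
  else numeric(0)

  conversation_timeline(turns, ov_df, segment_id = segment_id,
                        total_duration = total_duration)
}

#' Construct a conversation timeline
#'
#' Validates the timeline invariants (consecutive turns alternate
#' speakers, overlaps lie inside their host turn and belong to the other
#' speaker) and derives the floor-transfer-offset table.
#'
#' @param turns list of turn objects (`speaker`, `start`, `end`, `ipus`,
#'   `internal_pauses`).
#' @param overlaps_within data frame (`speaker`, `start`, `end`,
#'   `host_index`, `rel_offset`), possibly empty.
#' @param segment_id identifier.
#' @param total_duration duration in seconds; defaults to the last offset.
#' @return a `conversation_timeline` object.
#' @export
conversation_timeline <- function(turns, overlaps_within = NULL,
                                  segment_id = NA_character_,
                                  total_duration = NULL) {
  stopifnot(length(turns) >= 1)
  if (is.null(overlaps_within))
    overlaps_within <- data.frame(speaker = character(0), start = numeric(0),
                                  end = numeric(0), host_index = numeric(0),
                                  rel_offset = numeric(0))
  spk <- vapply(turns, `[[`, character(1), "speaker")
  if (length(spk) > 1 && any(spk[-1] == spk[-length(spk)]))
    stop("consecutive turns must alternate speakers")
  for (t in turns) {
    if (t$end <= t$start) stop("turn with end <= start")
    if (nrow(t$internal_pauses) &&
        (any(t$internal_pauses$start < t$start - 1e-9) ||
         any(t$internal_pauses$end > t$end + 1e-9)))
      stop("internal pause outside its turn")
  }
  if (nrow(overlaps_within)) {
    for (j in seq_len(nrow(overlaps_within))) {
      h <- turns[[overlaps_within$host_index[j]]]
      if (overlaps_within$speaker[j] == h$speaker)
        stop("overlap-within must belong to the other speaker")
    }
  }
  ftos <- if (length(turns) >= 2) {
    starts <- vapply(turns, `[[`, numeric(1), "start")
    ends <- vapply(turns, `[[`, numeric(1), "end")
    m <- length(turns) - 1
    data.frame(value_ms = (starts[-1] - ends[-length(ends)]) * 1000,
               from_speaker = spk[-length(spk)], to_speaker = spk[-1],
               transfer_index = seq_len(m))
  } else {
    data.frame(value_ms = numeric(0), from_speaker = character(0),
               to_speaker = character(0), transfer_index = integer(0))
  }
  if (is.null(total_duration))
    total_duration <- max(vapply(turns, `[[`, numeric(1), "end"),
                          if (nrow(overlaps_within)) max(overlaps_within$end)
                          else -Inf)
  structure(list(turns = turns, overlaps_within = overlaps_within,
                 ftos = ftos, segment_id = segment_id,
                 total_duration = total_duration),
            class = "conversation_timeline")
}

#' @export
print.conversation_timeline <- function(x, ...) {
  s <- summarize_timeline(x)
  cat(sprintf(
    "<conversation_timeline %s: %d turns, %d floor transfers, %d overlaps-within, %.1f s>\n",
    x$segment_id, s$n_turns, s$turn_change_count, s$n_overlaps_within,
    s$duration_s))
  invisible(x)
}

#' Extract floor-transfer offsets from a timeline
#'
#' The FTO at transfer *i* is the onset of turn *i + 1* minus the offset of
#' turn *i*, in milliseconds: positive values are between-turn gaps,
#' negative values are turns started in overlap.
#'
#' @param timeline a `conversation_timeline`.
#' @return data frame with `value_ms`, `from_speaker`, `to_speaker`,
#'   `transfer_index` (empty if fewer than two turns).
#' @export
extract_ftos <- function(timeline) {
  stopifnot(inherits(timeline, "conversation_timeline"))
  timeline$ftos
}

#' Summary counts of a conversation timeline
#'
#' @param timeline a `conversation_timeline`.
#' @return list with `n_turns`, `n_overlaps_within`, `duration_s` and
#'   `turn_change_count` (= number of FTOs).
#' @export
summarize_timeline <- function(timeline) {
  stopifnot(inherits(timeline, "conversation_timeline"))
  list(n_turns = length(timeline$turns),
       n_overlaps_within = nrow(timeline$overlaps_within),
       duration_s = timeline$total_duration,
       turn_change_count = nrow(timeline$ftos))
}

#' All IPUs of one speaker in a timeline
#'
#' Collects turn IPUs and overlaps-within belonging to `speaker`, e.g. to
#' feed ground-truth timelines back through [classify_states()].
#'
#' @param timeline a `conversation_timeline`.
#' @param speaker speaker label.
#' @return data frame (`speaker`, `start`, `end`) sorted by start.
#' @export
timeline_ipus <- function(timeline, speaker) {
  rows <- list()
  for (t in timeline$turns) {
    if (t$speaker == speaker && nrow(t$ipus))
      rows[[length(rows) + 1]] <- data.frame(speaker = speaker,
                                             start = t$ipus$start,
                                             end = t$ipus$end)
  }
  ov <- timeline$overlaps_within
  ov <- ov[ov$speaker == speaker, , drop = FALSE]
  if (nrow(ov))
    rows[[length(rows) + 1]] <- data.frame(speaker = speaker,
                                           start = ov$start, end = ov$end)
  if (!length(rows))
    return(data.frame(speaker = character(0), start = numeric(0),
                      end = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Flatten a timeline to a tabular event dump
#'
#' One row per turn, overlap-within and floor transfer; convenient for CSV
#' export and inspection.
#'
#' @param timeline a `conversation_timeline`.
#' @return data frame with columns `segment_id`, `kind`, `speaker`,
#'   `start_s`, `end_s`, `host_index`, `value_ms`.
#' @export
timeline_to_df <- function(timeline) {
  tn <- data.frame(
    segment_id = timeline$segment_id, kind = "turn",
    speaker = vapply(timeline$turns, `[[`, character(1), "speaker"),
    start_s = vapply(timeline$turns, `[[`, numeric(1), "start"),
    end_s = vapply(timeline$turns, `[[`, numeric(1), "end"),
    host_index = NA_real_, value_ms = NA_real_)
  ov <- timeline$overlaps_within
  ovd <- if (nrow(ov)) data.frame(
    segment_id = timeline$segment_id, kind = "overlap_within",
    speaker = ov$speaker, start_s = ov$start, end_s = ov$end,
    host_index = ov$host_index, value_ms = NA_real_) else NULL
  ft <- timeline$ftos
  ftd <- if (nrow(ft)) data.frame(
    segment_id = timeline$segment_id, kind = "fto",
    speaker = ft$to_speaker, start_s = NA_real_, end_s = NA_real_,
    host_index = NA_real_, value_ms = ft$value_ms) else NULL
  out <- rbind(tn, ovd, ftd)
  rownames(out) <- NULL
  out
}
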