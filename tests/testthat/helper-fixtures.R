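# Shared fixture builders and independent oracles. Everything is built in
# code at test time; no binary fixtures.

# track with constant-amplitude tone bursts in the given intervals over a
# low noise floor (defaults give a 40 dB contrast)
tone_track <- function(intervals, duration_s, sr = 8000, speaker = "A",
                       speech_amp = 0.1, floor_rms = 1e-3, f0 = 200,
                       seed = 99) {
  with_seed(seed, {
    n <- round(duration_s * sr)
    x <- rnorm(n) * floor_rms
    tt <- seq_len(n) / sr
    for (j in seq_len(nrow(intervals))) {
      i0 <- round(intervals$start[j] * sr) + 1
      i1 <- min(round(intervals$end[j] * sr), n)
      x[i0:i1] <- x[i0:i1] +
        speech_amp * sqrt(2) * sin(2 * pi * f0 * tt[i0:i1])
    }
    audio_track(x, sr, speaker)
  })
}

# timeline with single-IPU turns at the given (start, end) rows,
# alternating speakers starting with A
simple_timeline <- function(bounds, speakers = NULL, id = "fixture") {
  n <- nrow(bounds)
  if (is.null(speakers)) speakers <- rep(c("A", "B"), length.out = n)
  turns <- lapply(seq_len(n), function(k) {
    structure(list(speaker = speakers[k], start = bounds$start[k],
                   end = bounds$end[k],
                   ipus = data.frame(start = bounds$start[k],
                                     end = bounds$end[k]),
                   internal_pauses = data.frame(start = numeric(0),
                                                end = numeric(0))),
              class = "conv_turn")
  })
  conversation_timeline(turns, segment_id = id)
}

# independent windowed-energy oracle for the VAD rule: straightforward
# per-window loop, no smoothing
vad_oracle_flags <- function(samples, sr, window_ms = 5,
                             exceed_fraction = 0.15, offset_db = 5,
                             floor_db = -120) {
  log_e <- 10 * log10(pmax(samples^2, 10^(floor_db / 10)))
  thr <- median(log_e) + offset_db
  w <- round(sr * window_ms / 1000)
  n_win <- ceiling(length(samples) / w)
  sapply(seq_len(n_win), function(k) {
    idx <- ((k - 1) * w + 1):min(k * w, length(samples))
    mean(log_e[idx] > thr) > exceed_fraction
  })
}

# brute-force run-length IPU oracle over window flags: collect speech
# runs, then iteratively merge any pair separated by <= max_gap
ipu_oracle <- function(flags, window_s, max_gap_s, speaker = "A") {
  runs <- list()
  j <- 1
  while (j <= length(flags)) {
    if (flags[j]) {
      k <- j
      while (k < length(flags) && flags[k + 1]) k <- k + 1
      runs[[length(runs) + 1]] <- c((j - 1) * window_s, k * window_s)
      j <- k + 1
    } else j <- j + 1
  }
  if (!length(runs))
    return(data.frame(speaker = character(0), start = numeric(0),
                      end = numeric(0)))
  repeat {
    merged <- FALSE
    for (i in seq_len(length(runs) - 1)) {
      if (runs[[i + 1]][1] - runs[[i]][2] <= max_gap_s + 1e-9) {
        runs[[i]] <- c(runs[[i]][1], runs[[i + 1]][2])
        runs[[i + 1]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  data.frame(speaker = speaker,
             start = sapply(runs, `[`, 1), end = sapply(runs, `[`, 2))
}

# exhaustive matched-subset oracle: test every window start on the step
# grid, apply the criteria directly, return the best (max count, ties to
# the lower edge)
matched_subset_oracle <- function(records, match_on, width = 80, step = 5,
                                  alpha = 0.05, max_diff = 20) {
  d <- records[records$scheme %in% c("NHQ", "HIN") &
               records$attribute == "flow", ]
  x <- if (match_on == "median") d$realized_fto_median_ms
       else d$realized_fto_iqr_ms
  best <- list(n = 0, interval = c(NA, NA))
  for (s in seq(min(x), max(max(x) - width, min(x)), by = step)) {
    in_w <- x >= s & x <= s + width
    xa <- x[in_w & d$scheme == "NHQ"]
    xb <- x[in_w & d$scheme == "HIN"]
    if (length(xa) < 3 || length(xb) < 3) next
    if (abs(length(xa) - length(xb)) > max_diff) next
    p <- compare_groups_ranksum(xa, xb)$p
    if (p <= alpha) next
    if (length(xa) + length(xb) > best$n) {
      best <- list(n = length(xa) + length(xb), interval = c(s, s + width),
                   n_nhq = length(xa), n_hin = length(xb))
    }
  }
  best
}

# fixture rating table whose flow depends only on the FTO median, with
# overlapping median and IQR supports between the NHQ and HIN schemes
median_driven_records <- function(n = 400, seed = 2, flow_sd = 0.3) {
  with_seed(seed, {
    sch <- rep(c("NHQ", "HIN"), each = n / 2)
    med <- ifelse(sch == "NHQ", rnorm(n, 320, 80), rnorm(n, 430, 80))
    iqr <- ifelse(sch == "NHQ", rnorm(n, 450, 120), rnorm(n, 610, 120))
    data.frame(scheme = sch, attribute = "flow",
               value = 5 - 0.004 * med + rnorm(n, 0, flow_sd),
               realized_fto_median_ms = med, realized_fto_iqr_ms = iqr)
  })
}

# small end-to-end simulation backbone reused by analysis tests
sim_backbone <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      segs <- segment_inventory(seed = 3)
      lists <- build_lists(segs, n_lists = 10, master_seed = 42)
      meta <- simulate_stimulus_metadata(lists, segs)
      cache <<- list(segments = segs, lists = lists, meta = meta)
    }
    cache
  }
})
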