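# Synthetic two-speaker conversations with exact ground-truth timelines,
# and synthetic listener ratings with the covariance structure the
# analysis layer assumes. These generators stand in for corpus audio and
# human raters so every pipeline stage is testable offline.

#' Parameters of the synthetic conversation generator
#'
#' Defaults emulate the segment statistics of the study conditions:
#' 12-25 floor transfers per segment, roughly 30 s of dialogue,
#' within-turn pauses of 100-1200 ms (some beyond the 300 ms compression
#' threshold), occasional overlaps-within, and original between-turn
#' timing drawn from the normal-hearing-in-quiet logistic fit.
#'
#' @param n_transfers number of floor transfers; `NULL` draws uniformly
#'   from 12-25.
#' @param turn_meanlog,turn_sdlog log-normal parameters of turn speech
#'   duration in seconds (median `exp(turn_meanlog)` = 1.5 s).
#' @param internal_pause_prob probability that a turn contains an
#'   internal pause.
#' @param internal_pause_range_ms within-turn pause duration range (ms).
#' @param overlap_within_prob probability that a turn hosts an
#'   overlap-within.
#' @param gap_dist [logistic_params()] for the original between-turn
#'   FTOs.
#' @param speech_surrogate `"noise_burst"` (amplitude-modulated noise) or
#'   `"harmonic_vowel"` (amplitude-modulated harmonic complex).
#' @param sample_rate sampling rate in Hz.
#' @param speech_rms RMS of surrogate speech (linear amplitude).
#' @param noise_floor_rms RMS of the channel noise floor; the default
#'   gives a 40 dB speech-to-floor contrast.
#' @return an object of class `conv_gen_params`.
#' @export
conv_gen_params <- function(n_transfers = NULL, turn_meanlog = log(1.5),
                            turn_sdlog = 0.4, internal_pause_prob = 0.3,
                            internal_pause_range_ms = c(100, 1200),
                            overlap_within_prob = 0.15,
                            gap_dist = nhq_logistic(),
                            speech_surrogate = c("noise_burst",
                                                 "harmonic_vowel"),
                            sample_rate = 48000, speech_rms = 0.1,
                            noise_floor_rms = 1e-3) {
  speech_surrogate <- match.arg(speech_surrogate)
  stopifnot(internal_pause_prob >= 0, internal_pause_prob <= 1,
            overlap_within_prob >= 0, overlap_within_prob <= 1,
            all(internal_pause_range_ms > 0), sample_rate > 0,
            inherits(gap_dist, "logistic_params"))
  structure(list(n_transfers = n_transfers, turn_meanlog = turn_meanlog,
                 turn_sdlog = turn_sdlog,
                 internal_pause_prob = internal_pause_prob,
                 internal_pause_range_ms = internal_pause_range_ms,
                 overlap_within_prob = overlap_within_prob,
                 gap_dist = gap_dist, speech_surrogate = speech_surrogate,
                 sample_rate = sample_rate, speech_rms = speech_rms,
                 noise_floor_rms = noise_floor_rms),
            class = "conv_gen_params")
}

#' Generate a synthetic dyadic conversation
#'
#' Plants alternating turns with known FTOs, within-turn pauses and
#' nested overlaps-within, then renders one surrogate-speech track per
#' speaker. The emitted ground-truth timeline is exact; the planted
#' structure is constrained so that the communicative-state rules recover
#' it (incoming turns outlast outgoing ones; overlaps-within sit strictly
#' inside a single host IPU with margins; same-speaker turns are
#' separated by more than the IPU merge gap on their channel).
#'
#' @param params a [conv_gen_params()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `track_a`, `track_b` ([audio_track()] objects) and
#'   `timeline` (the ground-truth `conversation_timeline`).
#' @export
generate_synthetic_conversation <- function(params = conv_gen_params(),
                                            seed = NULL) {
  stopifnot(inherits(params, "conv_gen_params"))
  with_seed(seed, {
    n_tr <- if (is.null(params$n_transfers)) sample(12:25, 1)
            else params$n_transfers
    n_turns <- n_tr + 1
    speakers <- rep(c("A", "B"), length.out = n_turns)

    turns <- vector("list", n_turns)
    cur_end <- numeric(n_turns)   # absolute turn end
    t0 <- 0.2                     # small lead-in on the source tracks
    planted_ftos <- numeric(0)
    for (k in seq_len(n_turns)) {
      speech <- min(5, max(0.6, stats::rlnorm(1, params$turn_meanlog,
                                              params$turn_sdlog)))
      has_pause <- stats::runif(1) < params$internal_pause_prob &&
        speech >= 0.6
      if (k == 1) {
        start <- t0
      } else {
        prev <- turns[[k - 1]]
        # redraw FTOs that would break the planted-turn structure:
        # the incoming turn must end after the outgoing one (+0.1 s), not
        # start before 90% of it has elapsed, and leave >= 0.25 s to the
        # same speaker's previous turn end on this channel
        prev_dur <- prev$end - prev$start
        lo1 <- -0.9 * prev_dur * 1000
        # a turn started in overlap must begin during the outgoing turn's
        # final IPU, or the state rules would split the outgoing turn
        prev_last_ipu <- prev$ipus$start[nrow(prev$ipus)]
        same_prev_end <- if (k >= 3) turns[[k - 2]]$end else -Inf
        # consecutive overlapped starts (two negative FTOs in a row) make
        # the middle turn indistinguishable from an overlap-within under
        # the state rules, so a transfer after an overlapped one must
        # leave a gap
        prev_fto_neg <- length(planted_ftos) > 0 &&
          planted_ftos[length(planted_ftos)] < 0
        ok <- FALSE
        for (i in 1:20) {
          fto <- sample_ftos(params$gap_dist, 1)
          start_try <- prev$end + fto / 1000
          if (fto >= lo1 &&
              (!prev_fto_neg || fto >= 30) &&
              start_try >= prev_last_ipu + 0.05 &&
              start_try + speech > prev$end + 0.1 &&
              start_try >= same_prev_end + 0.25) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          fto <- max(lo1, (same_prev_end + 0.25 - prev$end) * 1000, 100)
          start_try <- prev$end + fto / 1000
        }
        planted_ftos <- c(planted_ftos, fto)
        start <- start_try
      }
      if (has_pause) {
        p_ms <- stats::runif(1, params$internal_pause_range_ms[1],
                             params$internal_pause_range_ms[2])
        frac <- stats::runif(1, 0.3, 0.7)
        d1 <- max(0.25, speech * frac)
        d2 <- max(0.25, speech - d1)
        ipus <- data.frame(start = c(start, start + d1 + p_ms / 1000),
                           end = c(start + d1,
                                   start + d1 + p_ms / 1000 + d2))
      } else {
        ipus <- data.frame(start = start, end = start + speech)
      }
      n_ip <- nrow(ipus)
      gaps <- which(ipus$start[-1] - ipus$end[-n_ip] > 1e-9)
      turn <- list(speaker = speakers[k], start = ipus$start[1],
                   end = ipus$end[n_ip], ipus = ipus,
                   internal_pauses = data.frame(start = ipus$end[gaps],
                                                end = ipus$start[gaps + 1]))
      class(turn) <- "conv_turn"
      turns[[k]] <- turn
      cur_end[k] <- turn$end
    }

    # plant overlaps-within strictly inside a host IPU, clear of the
    # overlapping speaker's own turns on their channel
    ov_rows <- list()
    for (k in seq_len(n_turns)) {
      if (stats::runif(1) >= params$overlap_within_prob) next
      host <- turns[[k]]
      ip <- host$ipus
      j <- which.max(ip$end - ip$start)
      ip_dur <- ip$end[j] - ip$start[j]
      if (ip_dur < 0.8) next
      ov_dur <- stats::runif(1, 0.2, min(0.6, ip_dur - 0.15))
      ov_start <- ip$start[j] + 0.06 +
        stats::runif(1) * (ip_dur - ov_dur - 0.12)
      ov_end <- ov_start + ov_dur
      other <- setdiff(c("A", "B"), host$speaker)
      prev_other <- if (k >= 2) turns[[k - 1]]$end else -Inf
      next_other <- if (k + 1 <= n_turns) turns[[k + 1]]$start else Inf
      if (ov_start < prev_other + 0.25 || ov_end > next_other - 0.25) next
      ov_rows[[length(ov_rows) + 1]] <-
        data.frame(speaker = other, start = ov_start, end = ov_end,
                   host_index = k, rel_offset = ov_start - host$start)
    }
    ov <- if (length(ov_rows)) do.call(rbind, ov_rows) else NULL

    timeline <- conversation_timeline(turns, ov, segment_id = "synthetic",
                                      total_duration = max(cur_end) + 0.3)

    sr <- params$sample_rate
    n_samp <- round(timeline$total_duration * sr)
    make_track <- function(spk) {
      buf <- stats::rnorm(n_samp) * params$noise_floor_rms
      f0 <- if (spk == "A") 120 else 210
      iv <- timeline_ipus(timeline, spk)
      for (r in seq_len(nrow(iv))) {
        i0 <- round(iv$start[r] * sr) + 1
        i1 <- min(round(iv$end[r] * sr), n_samp)
        n <- i1 - i0 + 1
        if (n < 2) next
        tt <- seq_len(n) / sr
        env <- 0.7 + 0.3 * sin(2 * pi * 3.7 * tt + stats::runif(1, 0, 2 * pi))
        core <- if (params$speech_surrogate == "noise_burst") {
          stats::rnorm(n)
        } else {
          rowSums(vapply(1:6, function(h)
            sin(2 * pi * f0 * h * tt + stats::runif(1, 0, 2 * pi)) / h,
            numeric(n)))
        }
        core <- core / sqrt(mean(core^2)) * params$speech_rms * env
        k_r <- min(round(0.005 * sr), floor(n / 2))
        if (k_r > 1) {
          ramp <- seq(0, 1, length.out = k_r)
          core[1:k_r] <- core[1:k_r] * ramp
          core[(n - k_r + 1):n] <- core[(n - k_r + 1):n] * rev(ramp)
        }
        buf[i0:i1] <- buf[i0:i1] + core
      }
      audio_track(pmin(1, pmax(-1, buf)), sr, spk)
    }
    list(track_a = make_track("A"), track_b = make_track("B"),
         timeline = timeline)
  })
}

#' Parameters of the synthetic rating generator
#'
#' Encodes the generative model the analysis layer assumes: a grand mean
#' plus per-scheme shifts, a linear effect of the stimulus's realized FTO
#' median, a participant random intercept, an optional gender-by-scheme
#' interaction, and residual noise, truncated to the rating scale.
#' Default effect sizes qualitatively place the hearing-impaired-in-noise
#' scheme worst; they are synthetic choices, not estimates from any human
#' data.
#'
#' @param n_participants number of listeners (default 44).
#' @param prop_female proportion of female participants.
#' @param grand_mean scale units.
#' @param condition_effects named per-scheme shifts (scale units).
#' @param fto_median_slope scale units per ms of realized FTO median.
#' @param participant_sd random-intercept SD.
#' @param residual_sd residual SD.
#' @param interaction_effects optional named list
#'   `list(female = c(...), male = c(...))` of per-scheme shifts.
#' @param scale_range VAS coding range (continuous 1-5 by default).
#' @return an object of class `rating_gen_params`.
#' @export
rating_gen_params <- function(n_participants = 44, prop_female = 0.455,
                              grand_mean = 3.6,
                              condition_effects = c(conLow = 0, conNHQ = 0,
                                                    NHQ = -0.3, HIN = -0.8),
                              fto_median_slope = -0.001,
                              participant_sd = 0.5, residual_sd = 0.6,
                              interaction_effects = NULL,
                              scale_range = c(1, 5)) {
  stopifnot(participant_sd >= 0, residual_sd >= 0, n_participants >= 1,
            length(scale_range) == 2, scale_range[1] < scale_range[2])
  structure(list(n_participants = n_participants, prop_female = prop_female,
                 grand_mean = grand_mean,
                 condition_effects = condition_effects,
                 fto_median_slope = fto_median_slope,
                 participant_sd = participant_sd, residual_sd = residual_sd,
                 interaction_effects = interaction_effects,
                 scale_range = scale_range),
            class = "rating_gen_params")
}

#' Simulate realized FTO metadata for every stimulus of a list set
#'
#' Computes, without audio rendering, the FTO values each stimulus would
#' realize: the constant schemes give degenerate values (all 190 ms or
#' all 50 ms), the NHQ scheme draws from `nhq` with the stimulus seed,
#' and the HIN scheme pushes an NHQ draw sequence through the affine
#' transform to `hin`. Used to drive rating simulations at scale.
#'
#' @param lists output of [build_lists()].
#' @param segments the segment inventory data frame (needs `pair_id`,
#'   `segment_idx`, `n_transfers`).
#' @param nhq,hin [logistic_params()] source and target distributions.
#' @return data frame with one row per (list, trial): ids, scheme, seed,
#'   `fto_median_ms`, `fto_iqr_ms`.
#' @export
simulate_stimulus_metadata <- function(lists, segments,
                                       nhq = nhq_logistic(),
                                       hin = hin_logistic()) {
  rows <- lapply(lists, function(pl) {
    a <- pl$assignments
    a$fto_median_ms <- NA_real_
    a$fto_iqr_ms <- NA_real_
    for (i in seq_len(nrow(a))) {
      n_tr <- segments$n_transfers[segments$pair_id == a$pair_id[i] &
                                   segments$segment_idx == a$segment_idx[i]]
      vals <- switch(a$scheme[i],
        conLow = rep(con_low_ms(), n_tr),
        conNHQ = rep(con_nhq_ms(), n_tr),
        NHQ = sample_ftos(nhq, n_tr, seed = a$seed[i]),
        HIN = transform_to_distribution(
          sample_ftos(nhq, n_tr, seed = a$seed[i]), nhq, hin))
      s <- summarize_ftos(vals)
      a$fto_median_ms[i] <- s$median
      a$fto_iqr_ms[i] <- s$iqr
    }
    a$list_id <- pl$list_id
    a
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic listener ratings
#'
#' Each participant is assigned one presentation list (round robin over
#' participants) and rates every stimulus of that list on the three
#' attributes. Ratings follow the model in [rating_gen_params()] and are
#' truncated to the scale range.
#'
#' @param lists output of [build_lists()].
#' @param stimuli metadata from [simulate_stimulus_metadata()] (or real
#'   rendering metadata with the same columns).
#' @param params a [rating_gen_params()].
#' @param seed integer seed.
#' @return data frame with columns `participant`, `gender`, `list_id`,
#'   `trial`, `scheme`, `segment`, `attribute`, `value`,
#'   `realized_fto_median_ms`, `realized_fto_iqr_ms`.
#' @export
generate_synthetic_ratings <- function(lists, stimuli,
                                       params = rating_gen_params(),
                                       seed = NULL) {
  stopifnot(inherits(params, "rating_gen_params"))
  attributes_ <- c("naturalness", "flow", "ease_of_following")
  with_seed(seed, {
    np <- params$n_participants
    n_female <- round(np * params$prop_female)
    gender <- sample(c(rep("female", n_female),
                       rep("male", np - n_female)))
    intercepts <- stats::rnorm(np, 0, params$participant_sd)
    list_ids <- vapply(lists, `[[`, numeric(1), "list_id")
    rows <- vector("list", np)
    for (p in seq_len(np)) {
      lid <- list_ids[(p - 1) %% length(list_ids) + 1]
      st <- stimuli[stimuli$list_id == lid, , drop = FALSE]
      st <- st[order(st$trial), , drop = FALSE]
      n_st <- nrow(st)
      ce <- params$condition_effects[st$scheme]
      ie <- if (!is.null(params$interaction_effects))
        params$interaction_effects[[gender[p]]][st$scheme] else 0
      base <- params$grand_mean + ce + ie +
        params$fto_median_slope * st$fto_median_ms + intercepts[p]
      per_attr <- lapply(attributes_, function(att) {
        v <- base + stats::rnorm(n_st, 0, params$residual_sd)
        v <- pmin(params$scale_range[2], pmax(params$scale_range[1], v))
        data.frame(participant = p, gender = gender[p], list_id = lid,
                   trial = st$trial, scheme = st$scheme,
                   segment = paste0(st$pair_id, "_", st$segment_idx),
                   attribute = att, value = v,
                   realized_fto_median_ms = st$fto_median_ms,
                   realized_fto_iqr_ms = st$fto_iqr_ms)
      })
      rows[[p]] <- do.call(rbind, per_attr)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
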