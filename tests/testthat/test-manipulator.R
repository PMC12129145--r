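test_that("pause compression follows the halving rule", {
  expect_equal(compressed_pause_ms(1000), 250) # 1000 -> 500 -> 250
  expect_equal(compressed_pause_ms(600), 150)  # 600 -> 300 -> 150
  expect_equal(compressed_pause_ms(300), 300)  # trigger is strictly > 300
  expect_equal(compressed_pause_ms(299), 299)
  expect_equal(compressed_pause_ms(c(350, 2000)), c(175, 250))
})

test_that("turn-level pause compression shifts the end and keeps IPU audio refs", {
  turn <- structure(list(
    speaker = "A", start = 1, end = 4.5,
    ipus = data.frame(start = c(1, 3.5), end = c(2.5, 4.5)),
    internal_pauses = data.frame(start = 2.5, end = 3.5)),
    class = "conv_turn")
  out <- compress_pauses(turn) # 1000 ms pause -> 250 ms
  expect_equal(out$end, 4.5 - 0.75)
  expect_equal(out$ipus$src_start, c(1, 3.5))
  expect_equal(out$ipus$src_end, c(2.5, 4.5))
  expect_equal(out$internal_pauses$end - out$internal_pauses$start, 0.25)
  # a 300 ms pause is untouched
  turn$ipus <- data.frame(start = c(1, 2.8), end = c(2.5, 4))
  turn$internal_pauses <- data.frame(start = 2.5, end = 2.8)
  turn$end <- 4
  expect_equal(compress_pauses(turn)$end, 4)
})

test_that("loudness equalization targets RMS over IPU samples only", {
  x <- sqrt(2) * sin(2 * pi * 100 * seq_len(8000) / 8000) * 0.3
  y <- equalize_loudness(x, 0.05)
  expect_equal(sqrt(mean(y^2)), 0.05, tolerance = 1e-6)

  at_target <- x * 0.05 / sqrt(mean(x^2))
  expect_equal(attr(equalize_loudness(at_target, 0.05), "gain"), 1,
               tolerance = 1e-9)

  # two-IPU turn with a silent pause: hand-computed gain over IPU samples
  n1 <- 400; np <- 200; n2 <- 400
  audio <- c(rep(0.2, n1), rep(0, np), rep(0.4, n2))
  mask <- c(rep(TRUE, n1), rep(FALSE, np), rep(TRUE, n2))
  rms_ipu <- sqrt((n1 * 0.04 + n2 * 0.16) / (n1 + n2))
  y2 <- equalize_loudness(audio, 0.05, mask)
  expect_equal(attr(y2, "gain"), 0.05 / rms_ipu, tolerance = 1e-12)
  expect_equal(sqrt(mean(y2[mask]^2)), 0.05, tolerance = 1e-9)
  expect_equal(y2[n1 + 1], 0) # pause scaled by the same (finite) gain
  expect_error(equalize_loudness(rep(0, 100), 0.05), "silent")
})

test_that("constant schemes realize exactly their constant FTO", {
  g <- generate_synthetic_conversation(
    conv_gen_params(n_transfers = 8), seed = 13)
  tracks <- list(g$track_a, g$track_b)
  for (nm in c("conNHQ", "conLow")) {
    r <- manipulate_segment(tracks, g$timeline, manipulation_scheme(nm),
                            render_config())
    want <- if (nm == "conNHQ") 190 else 50
    expect_equal(r$realized_ftos, rep(want, 8), tolerance = 1e-9)
    expect_equal(sd(r$realized_ftos), 0)
  }
})

test_that("NHQ draws match the pre-drawn child-seed sample and are reproducible", {
  g <- generate_synthetic_conversation(conv_gen_params(n_transfers = 8),
                                       seed = 13)
  cfg <- render_config(seed = 5)
  r <- manipulate_segment(list(g$track_a, g$track_b), g$timeline,
                          manipulation_scheme("NHQ"), cfg)
  pre <- sample_ftos(nhq_logistic(), 8,
                     seed = derive_seed(5, "ftos", "NHQ"))
  expect_equal(r$assigned_ftos, pre, tolerance = 1e-12)
  # realized values differ from assigned only by sample-grid rounding
  expect_lt(max(abs(r$realized_ftos - r$assigned_ftos)), 1000 / 48000 + 1e-9)
  r2 <- manipulate_segment(list(g$track_a, g$track_b), g$timeline,
                           manipulation_scheme("NHQ"), cfg)
  expect_identical(r$waveform, r2$waveform)
})

test_that("rendering adds exactly the 200 ms leading silence", {
  sr <- 48000
  tl <- simple_timeline(data.frame(start = 0.5, end = 1.7),
                        speakers = "A")
  tr <- tone_track(data.frame(start = 0.5, end = 1.7), 2, sr = sr)
  r <- manipulate_segment(list(tr), tl, manipulation_scheme("conNHQ"),
                          render_config())
  lead_n <- round(0.2 * sr)
  expect_length(r$waveform, lead_n + round(1.2 * sr))
  expect_true(all(r$waveform[seq_len(lead_n)] == 0))
  first_sound <- which(r$waveform != 0)[1]
  expect_lte(abs((first_sound - 1) - lead_n), 2) # edge ramp starts at zero
})

test_that("between-turn gaps in the rendered waveform are digital silence", {
  sr <- 48000
  tl <- simple_timeline(data.frame(start = c(0.3, 1.6), end = c(1.3, 2.6)))
  trA <- tone_track(data.frame(start = 0.3, end = 1.3), 3, sr, "A")
  trB <- tone_track(data.frame(start = 1.6, end = 2.6), 3, sr, "B", f0 = 350)
  r <- manipulate_segment(list(trA, trB), tl, manipulation_scheme("conNHQ"),
                          render_config())
  t1 <- r$realized_timeline$turns[[1]]
  t2 <- r$realized_timeline$turns[[2]]
  gap_idx <- seq.int(round((0.2 + t1$end) * sr) + 2,
                     round((0.2 + t2$start) * sr) - 1)
  expect_true(all(r$waveform[gap_idx] == 0))
})

test_that("manipulation conserves total speech (IPU) time", {
  g <- generate_synthetic_conversation(
    conv_gen_params(n_transfers = 10, internal_pause_prob = 0.6,
                    internal_pause_range_ms = c(350, 2000)), seed = 17)
  r <- manipulate_segment(list(g$track_a, g$track_b), g$timeline,
                          manipulation_scheme("conLow"), render_config())
  speech_in <- sum(vapply(g$timeline$turns, function(t)
    sum(t$ipus$end - t$ipus$start), numeric(1)))
  speech_out <- sum(vapply(r$realized_timeline$turns, function(t)
    sum(t$ipus$end - t$ipus$start), numeric(1)))
  expect_equal(speech_out, speech_in, tolerance = 1e-3)
})

test_that("no internal pause of 300 ms or more survives manipulation", {
  g <- generate_synthetic_conversation(
    conv_gen_params(n_transfers = 12, internal_pause_prob = 1,
                    internal_pause_range_ms = c(350, 2000)), seed = 19)
  planted <- unlist(lapply(g$timeline$turns, function(t)
    1000 * (t$internal_pauses$end - t$internal_pauses$start)))
  expect_gt(max(planted), 300) # the fixture does seed long pauses
  r <- manipulate_segment(list(g$track_a, g$track_b), g$timeline,
                          manipulation_scheme("NHQ"),
                          render_config(seed = 2))
  survived <- unlist(lapply(r$realized_timeline$turns, function(t)
    1000 * (t$internal_pauses$end - t$internal_pauses$start)))
  expect_gt(length(survived), 0)
  expect_true(all(survived < 300))
})

test_that("rendered stimuli survive the full VAD + classification loop", {
  g <- generate_synthetic_conversation(conv_gen_params(n_transfers = 10),
                                       seed = 11)
  r <- manipulate_segment(list(g$track_a, g$track_b), g$timeline,
                          manipulation_scheme("conNHQ"), render_config(),
                          split_by_speaker = TRUE)
  expect_equal(Reduce(`+`, r$channels), r$waveform, tolerance = 1e-12)
  tl <- classify_states(
    build_ipus(detect_voice_activity(
      audio_track(r$channels$A, 48000, "A"))),
    build_ipus(detect_voice_activity(
      audio_track(r$channels$B, 48000, "B"))))
  expect_length(tl$ftos$value_ms, 10)
  expect_true(all(abs(tl$ftos$value_ms - 190) <= 10))
})

test_that("scheme constructor enforces its parameter contract", {
  expect_equal(manipulation_scheme("conLow")$constant_fto_ms, 50)
  expect_equal(manipulation_scheme("conNHQ")$constant_fto_ms, 190)
  expect_error(manipulation_scheme("conLow", source_dist = nhq_logistic()),
               "no distributions")
  expect_error(manipulation_scheme("NHQ", constant_fto_ms = 100),
               "no constant")
  hin <- manipulation_scheme("HIN")
  expect_equal(hin$source_dist$mu, 139.8)
  expect_equal(hin$target_dist$mu, 454.7)
})

test_that("paired manipulation applies the affine image of the shared draws", {
  g1 <- generate_synthetic_conversation(conv_gen_params(n_transfers = 7),
                                        seed = 23)
  g2 <- generate_synthetic_conversation(conv_gen_params(n_transfers = 7),
                                        seed = 24)
  pair <- make_paired_nhq_hin(list(tracks = list(g1$track_a, g1$track_b),
                                   timeline = g1$timeline),
                              list(tracks = list(g2$track_a, g2$track_b),
                                   timeline = g2$timeline),
                              config = render_config(), seed = 77)
  want <- transform_to_distribution(pair$nhq$assigned_ftos,
                                    nhq_logistic(), hin_logistic())
  expect_equal(pair$hin$assigned_ftos, want, tolerance = 1e-9)
  # identity transform when source and target coincide
  pair0 <- make_paired_nhq_hin(list(tracks = list(g1$track_a, g1$track_b),
                                    timeline = g1$timeline),
                               list(tracks = list(g2$track_a, g2$track_b),
                                    timeline = g2$timeline),
                               nhq_params = nhq_logistic(),
                               hin_params = nhq_logistic(),
                               config = render_config(), seed = 77)
  expect_equal(pair0$hin$assigned_ftos, pair0$nhq$assigned_ftos,
               tolerance = 1e-9)
})

test_that("pooled distribution-scheme draws refit to the scheme's distribution", {
  pooled <- numeric(0)
  for (seed in 1:12) {
    g <- generate_synthetic_conversation(
      conv_gen_params(n_transfers = 20, turn_meanlog = log(2.5),
                      internal_pause_prob = 0), seed)
    sch <- schedule_turns(g$timeline, manipulation_scheme("HIN"),
                          render_config(seed = seed))
    pooled <- c(pooled, sch$assigned_ftos)
  }
  expect_gte(length(pooled), 200)
  s <- summarize_ftos(pooled)
  # logistic(454.7, 382.5) has median 454.7; MC error of the median at
  # n = 240 is about 2 * 382.5 / sqrt(240) = 49 ms
  expect_lt(abs(s$median - 454.7), 100)
})

test_that("rendered output writes and reads back as WAV plus sidecar", {
  g <- generate_synthetic_conversation(conv_gen_params(n_transfers = 6),
                                       seed = 4)
  r <- manipulate_segment(list(g$track_a, g$track_b), g$timeline,
                          manipulation_scheme("conLow"), render_config())
  wav <- file.path(tempdir(), "stim.wav")
  write_rendered(r, wav)
  back <- read_wav(wav, expected_channels = 1)
  expect_equal(back$sample_rate, 48000)
  expect_equal(nrow(back$samples), length(r$waveform))
  expect_lt(max(abs(back$samples[, 1] - r$waveform)), 1 / 32767)
  meta <- jsonlite::read_json(sub("\\.wav$", ".json", wav),
                              simplifyVector = TRUE)
  expect_equal(meta$scheme, "conLow")
  expect_equal(meta$realized_ftos_ms, r$realized_ftos, tolerance = 1e-9)
})
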