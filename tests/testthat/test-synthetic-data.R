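test_that("transfer counts force the turn inventory", {
  g <- generate_synthetic_conversation(
    conv_gen_params(n_transfers = 12, overlap_within_prob = 0), seed = 1)
  expect_length(g$timeline$turns, 13)
  expect_equal(nrow(g$timeline$ftos), 12)
  expect_equal(nrow(g$timeline$overlaps_within), 0)
  s <- summarize_timeline(g$timeline)
  expect_equal(s$turn_change_count, 12)
})

test_that("generation is bit-identical per seed and varies across seeds", {
  g1 <- generate_synthetic_conversation(seed = 5)
  g2 <- generate_synthetic_conversation(seed = 5)
  expect_identical(g1$track_a$samples, g2$track_a$samples)
  expect_identical(g1$timeline$ftos$value_ms, g2$timeline$ftos$value_ms)
  g3 <- generate_synthetic_conversation(seed = 6)
  expect_false(identical(g1$track_a$samples, g3$track_a$samples))
})

test_that("planted timelines satisfy the timeline invariants", {
  for (seed in c(2, 8, 15)) {
    g <- generate_synthetic_conversation(
      conv_gen_params(overlap_within_prob = 0.5), seed)
    tl <- g$timeline
    spk <- vapply(tl$turns, `[[`, character(1), "speaker")
    expect_true(all(spk[-1] != spk[-length(spk)]))
    expect_equal(nrow(tl$ftos), length(tl$turns) - 1)
    starts <- vapply(tl$turns, `[[`, numeric(1), "start")
    ends <- vapply(tl$turns, `[[`, numeric(1), "end")
    expect_equal(tl$ftos$value_ms, (starts[-1] - ends[-length(ends)]) * 1000)
    if (nrow(tl$overlaps_within)) {
      for (j in seq_len(nrow(tl$overlaps_within))) {
        host <- tl$turns[[tl$overlaps_within$host_index[j]]]
        expect_true(tl$overlaps_within$start[j] >= host$start)
        expect_true(tl$overlaps_within$end[j] <= host$end)
        expect_false(tl$overlaps_within$speaker[j] == host$speaker)
      }
    }
  }
})

test_that("surrogate speech has at least 30 dB contrast over the floor", {
  g <- generate_synthetic_conversation(conv_gen_params(n_transfers = 12),
                                       seed = 3)
  iv <- timeline_ipus(g$timeline, "A")
  sr <- g$track_a$sample_rate
  sp_idx <- unlist(lapply(seq_len(nrow(iv)), function(j)
    seq.int(round(iv$start[j] * sr) + 1, round(iv$end[j] * sr))))
  speech_rms <- sqrt(mean(g$track_a$samples[sp_idx]^2))
  floor_rms <- sqrt(mean(g$track_a$samples[-sp_idx]^2))
  expect_gt(20 * log10(speech_rms / floor_rms), 30)
})

test_that("zero-effect, zero-noise ratings collapse to the grand mean", {
  bb <- sim_backbone()
  rp <- rating_gen_params(n_participants = 4, grand_mean = 3,
                          condition_effects = c(conLow = 0, conNHQ = 0,
                                                NHQ = 0, HIN = 0),
                          fto_median_slope = 0, participant_sd = 0,
                          residual_sd = 0)
  rt <- generate_synthetic_ratings(bb$lists, bb$meta, rp, seed = 1)
  expect_true(all(rt$value == 3))
  expect_equal(nrow(rt), 4 * 32 * 3)
})

test_that("a pure negative FTO-median slope drives Spearman rho to -1", {
  bb <- sim_backbone()
  rp <- rating_gen_params(n_participants = 8, grand_mean = 3,
                          condition_effects = c(conLow = 0, conNHQ = 0,
                                                NHQ = 0, HIN = 0),
                          fto_median_slope = -0.002, participant_sd = 0,
                          residual_sd = 0)
  rt <- generate_synthetic_ratings(bb$lists, bb$meta, rp, seed = 2)
  ct <- correlate_flow_vs_fto(rt, "median")
  expect_equal(ct$rho, -1, tolerance = 1e-9)
  # and weakens away from -1 once residual noise enters
  rp$residual_sd <- 0.5
  rtn <- generate_synthetic_ratings(bb$lists, bb$meta, rp, seed = 2)
  ctn <- correlate_flow_vs_fto(rtn, "median")
  expect_lt(ctn$rho, -0.3)
  expect_gt(ctn$rho, -1)
})

test_that("planted condition ordering is recovered by the analysis stage", {
  bb <- sim_backbone()
  rp <- rating_gen_params() # defaults: HIN worst, NHQ below the constants
  rt <- generate_synthetic_ratings(bb$lists, bb$meta, rp, seed = 7)
  cm <- average_per_condition(rt)
  flow <- cm[cm$attribute == "flow", ]
  means <- tapply(flow$value, flow$scheme, mean)
  expect_lt(means[["HIN"]], means[["NHQ"]])
  expect_lt(means[["NHQ"]], means[["conNHQ"]])
})

test_that("participant random-intercept variance is distribution faithful", {
  bb <- sim_backbone()
  rp <- rating_gen_params(n_participants = 400, grand_mean = 3,
                          condition_effects = c(conLow = 0, conNHQ = 0,
                                                NHQ = 0, HIN = 0),
                          fto_median_slope = 0, participant_sd = 0.5,
                          residual_sd = 0.05, scale_range = c(-10, 10))
  rt <- generate_synthetic_ratings(bb$lists, bb$meta, rp, seed = 4)
  pm <- tapply(rt$value, rt$participant, mean)
  expect_equal(sd(pm), 0.5, tolerance = 0.08)
})

test_that("stimulus metadata reflects the scheme contracts", {
  bb <- sim_backbone()
  m <- bb$meta
  expect_true(all(m$fto_median_ms[m$scheme == "conNHQ"] == 190))
  expect_true(all(m$fto_iqr_ms[m$scheme == "conLow"] == 0))
  # HIN medians sit clearly above NHQ medians on average
  expect_gt(mean(m$fto_median_ms[m$scheme == "HIN"]),
            mean(m$fto_median_ms[m$scheme == "NHQ"]) + 100)
})
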