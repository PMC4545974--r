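test_that("opening peaks of a pure sinusoidal velocity land at the minima", {
  fs <- 250
  t <- (0:(fs - 1)) / fs
  vel <- trajectory(-sin(2 * pi * 5 * t), fs, units = "mm/s")
  pk <- find_opening_peaks(vel)
  # minima of -sin(2 pi 5 t) at t = 0.05, 0.25, ..., 0.85
  expect_length(pk, 5L)
  expect_lt(max(abs((pk - 1) / fs - c(0.05, 0.25, 0.45, 0.65, 0.85))),
            1 / fs + 1e-12)
  expect_length(find_opening_peaks(trajectory(rep(0, 100), fs)), 0L)
  expect_error(find_opening_peaks(vel, prominence_frac = 1.5),
               "prominence_frac")
})

test_that("segmentation hits the simulator's annotated peaks exactly", {
  sc <- gesture_score()
  cfg <- default_config()
  for (seed in 1:5) {
    tr <- generate_trial(sc, variability_model(0.1, 0.015, 0.04, 0), seed)
    gt <- attr(tr, "ground_truth")
    seg <- pipe_segment(tr, cfg)
    found_t <- (seg$opening_peak_indices + seg$start_index - 2) /
      tr$sample_rate
    expect_length(seg$opening_peak_indices, 5L)
    expect_lt(max(abs(found_t - gt$opening_peak_s)), 1 / tr$sample_rate + 1e-9)
    # velocity at each found peak is a negative local minimum
    v <- seg$velocity$samples
    expect_true(all(v[seg$opening_peak_indices] < 0))
    # both lips cut at identical indices
    expect_equal(length(seg$displacement$upper_lip$samples),
                 length(seg$displacement$lower_lip$samples))
  }
})

test_that("too few gestures is a loud segmentation error", {
  fs <- 250
  t <- (0:499) / fs
  d <- trajectory(sin(2 * pi * 4 * t), fs)
  v <- differentiate(d)  # 4-cycle input: only 4 opening peaks in window?
  # construct exactly 4 negative peaks
  v4 <- trajectory(-sin(2 * pi * 4 * t[1:250]) - 0.0, fs, units = "mm/s")
  expect_error(
    segment_utterance(trajectory(t[1:250], fs), v4, first = 1, last = 5),
    "segmentation error")
})

test_that("segmentation is idempotent and shift-equivariant", {
  sc <- gesture_score()
  tr <- generate_trial(sc, variability_model(0, 0, 0, 0), 3)
  cfg <- default_config()
  seg <- pipe_segment(tr, cfg)
  # idempotent: re-segmenting the cut traces returns the full span
  seg2 <- segment_utterance(seg$displacement, seg$velocity)
  expect_equal(seg2$start_index, 1L)
  expect_equal(seg2$end_index, length(seg$velocity$samples))
  expect_equal(seg2$opening_peak_indices, seg$opening_peak_indices)
  # shifting the input by k frames shifts every index by k
  k <- 25L
  fs <- tr$sample_rate
  d <- seg$displacement$lower_lip$samples
  v <- seg$velocity$samples
  pad_d <- trajectory(c(rep(d[1], k), d), fs)
  pad_v <- trajectory(c(rep(0, k), v), fs, units = "mm/s")
  s0 <- segment_utterance(trajectory(d, fs), trajectory(v, fs, units = "mm/s"))
  s1 <- segment_utterance(pad_d, pad_v)
  expect_equal(s1$start_index, s0$start_index + k)
  expect_equal(s1$end_index, s0$end_index + k)
  expect_equal(s1$opening_peak_indices, s0$opening_peak_indices)
})

test_that("movement cycles for Bob/pup match programmed gesture boundaries", {
  # run on unsmoothed traces: boundary landmarks are then free of the
  # low-pass filter's pulse broadening and comparable to ground truth
  # at frame resolution
  sc <- gesture_score()
  tr <- generate_trial(sc, variability_model(0, 0, 0, 0), 4)
  gt <- attr(tr, "ground_truth")
  z <- tr$markers$lower_lip[, 3]
  lo <- trajectory(z - z[1], tr$sample_rate, "lower_lip")
  up <- trajectory(-(tr$markers$upper_lip[, 3] -
                       tr$markers$upper_lip[1, 3]), tr$sample_rate,
                   "upper_lip")
  seg <- segment_utterance(list(upper_lip = up, lower_lip = lo),
                           differentiate(lo))
  cyc <- extract_movement_cycles(seg, c(Bob = 2L, pup = 4L))
  expect_equal(nrow(cyc), 4L)
  expect_setequal(cyc$direction, c("opening", "closing"))
  fs <- tr$sample_rate
  to_time <- function(i) (i + seg$start_index - 2) / fs
  for (i in seq_len(nrow(cyc))) {
    row <- cyc[i, ]
    k <- c(Bob = 2L, pup = 4L)[[row$syllable]]
    if (row$direction == "opening") {
      expect_lt(abs(to_time(row$onset) - gt$opening_onset_s[k]),
                1.5 / fs)
      open_end <- gt$opening_onset_s[k] +
        (gt$opening_peak_s[k] - gt$opening_onset_s[k]) * 2
      expect_lt(abs(to_time(row$offset) - open_end), 1.5 / fs)
    } else {
      expect_lt(abs(to_time(row$offset) - gt$closing_offset_s[k]),
                1.5 / fs)
    }
    expect_true(row$onset < row$peak_velocity_index)
    expect_true(row$peak_velocity_index < row$offset)
  }
  # opening and closing peak signs
  v <- seg$velocity$samples
  expect_true(all(v[cyc$peak_velocity_index[cyc$direction == "opening"]] < 0))
  expect_true(all(v[cyc$peak_velocity_index[cyc$direction == "closing"]] > 0))
  expect_error(extract_movement_cycles(seg, c(extra = 6L)),
               "extraction error")
})

test_that("peak recovery stays near-exact under full trial variability", {
  # with timing jitter and tempo scatter the 10 Hz zero-phase filter
  # can shift a velocity minimum by about one frame when adjacent
  # gesture pulses overlap; counts stay exact and timing within 1.5
  # frames for at least 95% of trials
  sc <- gesture_score()
  cfg <- default_config()
  v <- variability_model(0.15, 0.02, 0.05, 0)
  errs <- vapply(1:60, function(i) {
    tr <- generate_trial(sc, v, 7000 + i)
    gt <- attr(tr, "ground_truth")
    seg <- pipe_segment(tr, cfg)
    if (length(seg$opening_peak_indices) != 5L) return(Inf)
    ft <- (seg$opening_peak_indices + seg$start_index - 2) /
      tr$sample_rate
    max(abs(ft - gt$opening_peak_s)) * tr$sample_rate
  }, numeric(1))
  expect_true(all(is.finite(errs)))        # 5/5 count in every trial
  expect_gte(mean(errs <= 1.5), 0.95)
})

test_that("symmetric gestures give equal opening/closing durations", {
  sym <- gesture_score(
    opening_extent = rep(7, 5), closing_extent = rep(7, 5),
    opening_duration = rep(0.14, 5), closing_duration = rep(0.14, 5))
  tr <- generate_trial(sym, variability_model(0, 0, 0, 0), 1)
  seg <- pipe_segment(tr, default_config())
  cyc <- extract_movement_cycles(seg, c(Bob = 2L, pup = 4L))
  for (syl in c("Bob", "pup")) {
    dur <- with(cyc[cyc$syllable == syl, ], offset - onset)
    expect_lte(abs(diff(dur)), 1)
  }
})
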