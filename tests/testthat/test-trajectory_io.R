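test_that("marker tables parse with inferred rate and round-trip", {
  set.seed(11)
  p <- write_traj_fixture(n = 4, rate = 250)
  rec <- read_marker_file(p, declared_rate = 250)
  expect_s3_class(rec, "marker_recording")
  expect_equal(rec$n_frames, 4L)
  expect_equal(rec$sample_rate, 250)
  expect_setequal(
    names(rec$markers),
    c("upper_lip", "lower_lip", "head_1", "head_2", "head_3"))

  # comma dialect parses identically
  p2 <- write_traj_fixture(n = 6, sep = ",")
  expect_s3_class(read_marker_file(p2), "marker_recording")

  # write -> read is identity on positions
  out <- tempfile(fileext = ".tsv")
  write_marker_file(rec, out)
  rec2 <- read_marker_file(out, declared_rate = 250)
  expect_equal(rec2$markers, rec$markers, tolerance = 1e-8)
})

test_that("malformed marker tables are rejected with the right errors", {
  set.seed(12)
  expect_error(read_marker_file(write_traj_fixture(drop_col = "lower_lip_z")),
               "format error")
  # non-uniform steps beyond 0.1% tolerance
  p <- write_traj_fixture(time = c(0, 0.004, 0.008, 0.016))
  expect_error(read_marker_file(p), "sampling error")
  # declared-vs-inferred rate mismatch
  p <- write_traj_fixture(n = 8, rate = 200)
  expect_error(read_marker_file(p, declared_rate = 250), "sampling error")
  # fewer than 2 frames
  p <- write_traj_fixture(n = 1)
  expect_error(read_marker_file(p), "fewer than 2 frames|input error")
})

test_that("deleting any mandatory coordinate column breaks the parse", {
  set.seed(13)
  cols <- as.vector(outer(c("upper_lip", "lower_lip", "head_1"),
                          c("_x", "_y", "_z"), paste0))
  for (cl in cols) {
    p <- write_traj_fixture(n = 5, drop_col = cl)
    expect_error(read_marker_file(p), "format error", info = cl)
  }
})

test_that("short dropouts are interpolated, long ones invalidate the trial", {
  set.seed(14)
  n <- 40
  z <- sin(seq(0, 2 * pi, length.out = n)) * 5 + 20
  df <- data.frame(time_s = (seq_len(n) - 1) / 250)
  for (m in c("upper_lip", "lower_lip", "head_1", "head_2", "head_3"))
    for (ax in c("x", "y", "z"))
      df[[paste0(m, "_", ax)]] <- z
  df$lower_lip_z[10:12] <- NA  # 3-frame gap: interpolatable
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_marker_file(p)
  expect_equal(attr(rec, "n_interpolated"), 3L)
  # interpolation is linear across the gap
  expect_equal(rec$markers$lower_lip[10:12, 3],
               approx(c(9, 13), z[c(9, 13)], xout = 10:12)$y)

  df$lower_lip_z[20:26] <- NA  # 7-frame gap: invalid
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_marker_file(p), "dropout")
})

test_that("metadata parses codes, counts groups, rejects bad rows", {
  meta_file <- function(df) {
    p <- tempfile(fileext = ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  m <- read_metadata(meta_file(data.frame(
    participant_id = c("a", "b"), group = c("CWS", "control"),
    sex = c("M", "female"))))
  expect_equal(as.character(m$group), c("stutter", "control"))
  expect_equal(as.character(m$sex), c("male", "female"))

  expect_error(read_metadata(meta_file(data.frame(
    participant_id = "a", group = "CWS?", sex = "M"))),
    "validation error")
  expect_error(read_metadata(meta_file(data.frame(
    participant_id = c("a", "a"), group = c("CWS", "CWS"),
    sex = c("M", "M")))), "duplicate")

  # cohort-sized table: 58 stutter (44 male), 43 control (29 male)
  coh <- data.frame(
    participant_id = sprintf("c%03d", 1:101),
    group = rep(c("CWS", "CWNS"), c(58, 43)),
    sex = c(rep(c("M", "F"), c(44, 14)), rep(c("M", "F"), c(29, 14))))
  m <- read_metadata(meta_file(coh))
  expect_equal(nrow(m), 101L)
  expect_equal(as.vector(table(m$group)), c(58L, 43L))
  expect_equal(as.vector(table(m$group, m$sex)),
               c(44L, 29L, 14L, 14L))
})

test_that("results tables round-trip at 6 significant digits incl. NA", {
  rec <- data.frame(
    participant_id = c("a", "b"), sentence_id = "s",
    displacement_dynamic_range = c(8.3456789, 10.0123456),
    la_index = c(25.31234, NA), n_trials = c(8L, 6L),
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_results_table(rec, p)
  back <- read_results_table(p)
  expect_equal(back$displacement_dynamic_range,
               signif(rec$displacement_dynamic_range, 6))
  expect_true(is.na(back$la_index[2]))
  expect_equal(back$la_index[1], signif(rec$la_index[1], 6))
  expect_equal(back$participant_id, rec$participant_id)
  expect_error(write_results_table(rec[0, ], p), "non-empty")
})
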