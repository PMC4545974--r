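#' Single-movement kinematic parameters
#'
#' Amplitude, peak velocity and duration of one opening or closing
#' movement: amplitude is the absolute displacement change from onset
#' to offset (cycles are monotone between velocity zero-crossings, so
#' this equals the peak-to-trough extent up to noise), peak velocity
#' is the maximum absolute velocity within the cycle, duration is the
#' onset-to-offset span in seconds.
#'
#' @param cycle One row of an [extract_movement_cycles()] result (or a
#'   list with \code{onset}, \code{offset}, \code{direction},
#'   \code{syllable}).
#' @param displ Displacement [trajectory()] the cycle indexes into
#'   (within-segment).
#' @param vel Matching velocity trace.
#' @return A one-row data.frame with \code{syllable},
#'   \code{direction}, \code{amplitude} (mm), \code{peak_velocity}
#'   (mm/s), \code{duration} (s).
#' @export
movement_parameters <- function(cycle, displ, vel) {
  on <- cycle$onset; off <- cycle$offset
  if (is.null(on) || is.null(off) || on >= off)
    stop("computation error: degenerate movement cycle", call. = FALSE)
  d <- displ$samples; v <- vel$samples
  if (off > length(d))
    stop("cycle indices exceed trace length", call. = FALSE)
  data.frame(
    syllable = as.character(cycle$syllable),
    direction = as.character(cycle$direction),
    amplitude = abs(d[off] - d[on]),
    peak_velocity = max(abs(v[on:off])),
    duration = (off - on) / displ$sample_rate,
    stringsAsFactors = FALSE)
}

#' Central-coverage dynamic range
#'
#' The span of sample values containing the central \code{coverage}
#' fraction of the value distribution of a trajectory (or its
#' velocity) over a whole utterance: the difference between the
#' \code{50 + 50 * coverage} and \code{50 - 50 * coverage} percentiles
#' (linear-interpolation percentiles, R type 7). With the default 0.8
#' this is the 10th-90th percentile span -- the articulator's primary
#' operating range, robust to the extreme 20\% of samples.
#'
#' @param samples Numeric vector (mm or mm/s) or a [trajectory()];
#'   at least 10 samples.
#' @param coverage Central fraction covered, in (0, 1).
#' @return Scalar range in the units of the input.
#' @export
dynamic_range <- function(samples, coverage = 0.8) {
  if (inherits(samples, "trajectory")) samples <- samples$samples
  x <- as.numeric(samples)
  if (length(x) < 10L)
    stop("computation error: dynamic_range needs at least 10 samples",
         call. = FALSE)
  if (coverage <= 0 || coverage >= 1)
    stop("coverage must be in (0, 1)", call. = FALSE)
  q <- quantile(x, c(0.5 - coverage / 2, 0.5 + coverage / 2),
                type = 7, names = FALSE)
  q[2] - q[1]
}

#' Sentence duration of a segmented repetition
#'
#' The time in seconds of the original, non-normalised repetition
#' after segmentation: the span between the bounding opening peaks,
#' \code{(end_index - start_index) / sample_rate} (first-to-last-frame
#' convention, i.e. \code{(n_frames - 1) / sample_rate}).
#'
#' @param seg An [segment_utterance()] result.
#' @return Duration in seconds.
#' @export
sentence_duration <- function(seg) {
  stopifnot(inherits(seg, "utterance_segment"))
  (seg$end_index - seg$start_index) / seg$sample_rate
}

#' Per-participant summary of one trial set
#'
#' Computes, for every segmented repetition, the phrase-level measures
#' (displacement and velocity dynamic ranges of the lower lip,
#' sentence duration) and the single-movement parameters for the
#' mapped syllable cycles, averages them arithmetically across trials,
#' and attaches the LA variability index ([la_index()]). A participant
#' whose averaged dynamic range lies more than \code{k_sd} normative
#' SDs above the normative mean is flagged excluded (measurement
#' artifact screen); normative values are configuration, not computed
#' here.
#'
#' @param trials A [trial_set()] with at least
#'   \code{config$analysis$min_trials} segments (at most the first
#'   \code{max_trials} are used).
#' @param config See [default_config()].
#' @return A one-row data.frame (class \code{"kinematic_record"}) of
#'   averaged dependent variables, with columns
#'   \code{displacement_dynamic_range}, \code{velocity_dynamic_range},
#'   \code{sentence_duration}, \code{la_index},
#'   \code{<syllable>_<direction>_<parameter>} means, \code{n_trials},
#'   \code{excluded}, \code{exclude_reason}.
#' @export
summarize_participant <- function(trials, config = default_config()) {
  stopifnot(inherits(trials, "trial_set"))
  segs <- trials$segments
  min_tr <- config$analysis$min_trials
  max_tr <- config$analysis$max_trials
  if (length(segs) < min_tr)
    stop(sprintf(
      "participant %s: only %d valid trials (< %d); skipped",
      trials$participant_id, length(segs), min_tr), call. = FALSE)
  segs <- segs[seq_len(min(length(segs), max_tr))]

  per_trial <- lapply(segs, function(seg) {
    ll <- seg$displacement$lower_lip
    if (is.null(ll)) ll <- seg$displacement[[1]]
    vel <- seg$velocity
    vsamp <- if (isTRUE(config$dynamic_range$velocity_signed))
      vel$samples else abs(vel$samples)
    cyc <- extract_movement_cycles(seg, config$segmentation$cycles)
    mp <- do.call(rbind, lapply(seq_len(nrow(cyc)), function(i)
      movement_parameters(cyc[i, ], ll, vel)))
    list(ddr = dynamic_range(ll$samples, config$dynamic_range$coverage),
         vdr = dynamic_range(vsamp, config$dynamic_range$coverage),
         dur = sentence_duration(seg),
         mp = mp)
  })

  rec <- data.frame(
    participant_id = trials$participant_id,
    sentence_id = trials$sentence_id,
    displacement_dynamic_range =
      mean(vapply(per_trial, `[[`, numeric(1), "ddr")),
    velocity_dynamic_range =
      mean(vapply(per_trial, `[[`, numeric(1), "vdr")),
    sentence_duration =
      mean(vapply(per_trial, `[[`, numeric(1), "dur")),
    stringsAsFactors = FALSE)

  mp_all <- do.call(rbind, lapply(per_trial, `[[`, "mp"))
  for (syl in unique(mp_all$syllable)) {
    for (dir in c("opening", "closing")) {
      sub <- mp_all[mp_all$syllable == syl & mp_all$direction == dir, ]
      for (p in c("amplitude", "peak_velocity", "duration"))
        rec[[paste(syl, dir, p, sep = "_")]] <- mean(sub[[p]])
    }
  }

  la <- la_index(trials, n_points = config$sti$n_points,
                 include_zero = config$sti$include_zero,
                 sd_denominator = config$sti$sd_denominator)
  rec$la_index <- la$la_index
  rec$n_trials <- length(segs)

  rec$excluded <- FALSE
  rec$exclude_reason <- NA_character_
  norm <- config$exclusion$normative
  if (!is.null(norm)) {
    k <- config$exclusion$k_sd
    for (m in names(norm)) {
      if (!is.null(rec[[m]]) &&
          rec[[m]] > norm[[m]]$mean + k * norm[[m]]$sd) {
        rec$excluded <- TRUE
        rec$exclude_reason <- sprintf(
          "%s exceeds normative mean by > %g SD", m, k)
      }
    }
  }
  class(rec) <- c("kinematic_record", "data.frame")
  rec
}
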