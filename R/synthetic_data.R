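#' Minimum-jerk displacement segment
#'
#' The smooth point-to-point displacement profile
#' \code{x(tau) = extent * (10 tau^3 - 15 tau^4 + 6 tau^5)},
#' \code{tau = t / duration}, sampled uniformly. Velocity is zero at
#' both ends and peaks at \code{15 * extent / (8 * duration)} at the
#' midpoint -- the analytic handle the simulator's ground-truth
#' annotations are built on. Used here as the gesture primitive for
#' synthetic opening/closing lip movements.
#'
#' @param extent Movement extent in mm (> 0).
#' @param duration Movement duration in s (> 0).
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric vector of displacements from 0 to \code{extent},
#'   sampled at \code{0, 1/sample_rate, ...} up to \code{duration}.
#' @export
min_jerk_segment <- function(extent, duration, sample_rate = 250) {
  stopifnot(extent > 0, duration > 0, sample_rate > 0)
  tau <- seq(0, duration, by = 1 / sample_rate) / duration
  extent * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

min_jerk_profile <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Gesture score for a five-cycle sentence production
#'
#' Specification of the deterministic movement template: per-cycle
#' opening/closing extents and durations plus inter-cycle gaps,
#' emulating the five oral opening/closing cycles of a sentence like
#' "Buy Bobby a puppy". Defaults follow typical preschool lower-lip
#' kinematics (openings of 6-8.5 mm over 0.14-0.16 s, slightly smaller
#' and faster closings, ~1.2 s from first to fifth opening peak), with
#' cycle 2 the largest ("Bob") and cycle 4 the smallest ("pup").
#'
#' @param opening_extent,closing_extent Numeric length-5 vectors, mm.
#' @param opening_duration,closing_duration Numeric length-5 vectors, s.
#' @param inter_cycle_gap Length-5 vector of holds after each closing, s
#'   (the 5th is the trailing hold).
#' @param upper_lip_gain Upper-lip counter-movement as a fraction of
#'   the lower-lip deviation (opposite sign); lip aperture is then
#'   dominated by the lower lip.
#' @param baseline Resting lower-lip z in head frame, mm.
#' @param lead_in Pre-utterance hold, s.
#' @return Object of class \code{"gesture_score"}.
#' @export
gesture_score <- function(
    opening_extent = c(7.5, 8.4, 7.0, 6.2, 6.6),
    closing_extent = c(7.1, 7.4, 6.7, 6.3, 6.4),
    opening_duration = c(0.15, 0.16, 0.14, 0.14, 0.14),
    closing_duration = c(0.12, 0.12, 0.12, 0.12, 0.12),
    inter_cycle_gap = rep(0.04, 5),
    upper_lip_gain = 0.3,
    baseline = 0,
    lead_in = 0.15) {
  stopifnot(length(opening_extent) == 5L, length(closing_extent) == 5L,
            length(opening_duration) == 5L,
            length(closing_duration) == 5L,
            length(inter_cycle_gap) == 5L,
            all(opening_extent > 0), all(closing_extent > 0),
            all(opening_duration > 0), all(closing_duration > 0),
            all(inter_cycle_gap >= 0), upper_lip_gain >= 0)
  structure(
    list(opening_extent = opening_extent,
         closing_extent = closing_extent,
         opening_duration = opening_duration,
         closing_duration = closing_duration,
         inter_cycle_gap = inter_cycle_gap,
         upper_lip_gain = upper_lip_gain,
         baseline = baseline, lead_in = lead_in),
    class = "gesture_score")
}

#' Trial-to-trial variability model for the simulator
#'
#' Operationalises the sources of repetition-to-repetition variability
#' the analysis is sensitive to, each switchable to zero:
#' \code{amplitude_cv}, a single per-trial multiplicative factor on all
#' gesture extents (pure amplitude scatter, removed by amplitude
#' normalisation); \code{timing_jitter_sd}, independent per-gesture
#' onset jitter in seconds with durations intact (phase variability,
#' the main driver of the LA index); \code{tempo_cv}, a per-trial
#' global time-scale factor (rate variability, removed by time
#' normalisation); and \code{noise_sd}, additive measurement noise in
#' mm, low-passed at \code{noise_bandwidth} Hz.
#'
#' @param amplitude_cv,timing_jitter_sd,tempo_cv,noise_sd Non-negative
#'   scalars (defaults 0.15, 0.02 s, 0.05, 0.1 mm: moderate preschool
#'   trial-to-trial variability).
#' @param noise_bandwidth Noise low-pass cutoff, Hz.
#' @return Object of class \code{"variability_model"}.
#' @export
variability_model <- function(amplitude_cv = 0.15,
                              timing_jitter_sd = 0.02,
                              tempo_cv = 0.05, noise_sd = 0.1,
                              noise_bandwidth = 30) {
  stopifnot(amplitude_cv >= 0, timing_jitter_sd >= 0, tempo_cv >= 0,
            noise_sd >= 0, noise_bandwidth > 0)
  structure(
    list(amplitude_cv = amplitude_cv,
         timing_jitter_sd = timing_jitter_sd,
         tempo_cv = tempo_cv, noise_sd = noise_sd,
         noise_bandwidth = noise_bandwidth),
    class = "variability_model")
}

#' Sinusoidal rigid head-motion generator
#'
#' Returns a function of time giving a rigid transform (rotation about
#' \code{rot_axis} plus translation) to composite onto all markers of
#' a simulated trial, for validating head-motion cancellation.
#'
#' @param trans_amp Length-3 translation amplitudes, mm.
#' @param trans_freq Translation frequency, Hz.
#' @param rot_amp_deg Rotation amplitude, degrees.
#' @param rot_freq Rotation frequency, Hz.
#' @param rot_axis Unit-normalised rotation axis.
#' @return \code{function(t)} returning \code{list(R = 3x3, t = length-3)}.
#' @export
head_motion_sinusoid <- function(trans_amp = c(2, 1, 3),
                                 trans_freq = 0.7,
                                 rot_amp_deg = 5, rot_freq = 0.9,
                                 rot_axis = c(0, 0, 1)) {
  rot_axis <- rot_axis / sqrt(sum(rot_axis^2))
  function(t) {
    theta <- rot_amp_deg * pi / 180 * sin(2 * pi * rot_freq * t)
    K <- matrix(c(0, -rot_axis[3], rot_axis[2],
                  rot_axis[3], 0, -rot_axis[1],
                  -rot_axis[2], rot_axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    list(R = R, t = trans_amp * sin(2 * pi * trans_freq * t))
  }
}

# Fixed body-frame marker layout (mm): 4 non-coplanar head markers,
# lips below them at midline.
simulator_layout <- function() {
  list(head = list(head_1 = c(0, 0, 50), head_2 = c(60, 5, 55),
                   head_3 = c(30, 40, 62), head_4 = c(25, -35, 48)),
       lower_lip_base = c(30, -20, 20),
       upper_lip_base = c(30, -20, 33))
}

# Evaluate the piecewise min-jerk lower-lip deviation (mm, <= 0 during
# opening) at times tt, given per-cycle onsets/durations/extents.
eval_gesture_train <- function(tt, onset, od, oe, cd, ce) {
  x <- numeric(length(tt))
  level <- 0
  for (c in seq_along(onset)) {
    o0 <- onset[c]; o1 <- o0 + od[c]
    c0 <- o1; c1 <- c0 + cd[c]
    x[tt >= o0 & tt < o1] <- level -
      oe[c] * min_jerk_profile((tt[tt >= o0 & tt < o1] - o0) / od[c])
    lev2 <- level - oe[c]
    x[tt >= c0 & tt < c1] <- lev2 +
      ce[c] * min_jerk_profile((tt[tt >= c0 & tt < c1] - c0) / cd[c])
    level <- lev2 + ce[c]
    x[tt >= c1] <- level
  }
  x
}

#' Simulate one marker-tracked sentence repetition
#'
#' Builds a lower-lip superior-inferior trajectory as a train of five
#' jittered minimum-jerk opening/closing gestures (opening =
#' downward), a counter-moving upper lip, and static head markers
#' (optionally composited with programmed rigid head motion applied to
#' all markers), and packages it as a [marker_recording()]. Ground
#' truth (per-cycle opening peak time, peak velocity
#' \code{-15 extent / (8 duration)}, and extents) is attached as
#' attribute \code{"ground_truth"}; the trial's realised amplitude and
#' tempo factors as \code{"factors"}.
#'
#' @param score A [gesture_score()].
#' @param var A [variability_model()].
#' @param trial_seed Integer seed for this trial's randomness.
#' @param sample_rate Hz.
#' @param head_motion Optional \code{function(t)} as returned by
#'   [head_motion_sinusoid()].
#' @param participant_id,trial_id Identifiers.
#' @return A [marker_recording()]; attribute \code{"ground_truth"} is
#'   a data.frame with columns \code{cycle}, \code{opening_onset_s},
#'   \code{opening_peak_s}, \code{opening_peak_velocity},
#'   \code{opening_extent}, \code{closing_extent},
#'   \code{closing_peak_velocity}, \code{closing_offset_s}.
#' @export
generate_trial <- function(score, var = variability_model(),
                           trial_seed = 1L, sample_rate = 250,
                           head_motion = NULL,
                           participant_id = "sim",
                           trial_id = paste0("trial_", trial_seed)) {
  stopifnot(inherits(score, "gesture_score"),
            inherits(var, "variability_model"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(as.integer(trial_seed))

  amp <- if (var$amplitude_cv > 0)
    max(0.1, rnorm(1, 1, var$amplitude_cv)) else 1
  tempo <- if (var$tempo_cv > 0)
    max(0.5, rnorm(1, 1, var$tempo_cv)) else 1

  oe <- score$opening_extent * amp
  ce <- score$closing_extent * amp
  od <- score$opening_duration * tempo
  cd <- score$closing_duration * tempo
  gap <- score$inter_cycle_gap * tempo

  # nominal onsets, then per-gesture jitter with durations intact
  base_onset <- numeric(5)
  t0 <- score$lead_in
  for (c in 1:5) {
    base_onset[c] <- t0
    t0 <- t0 + od[c] + cd[c] + gap[c]
  }
  for (try in 1:50) {
    jit <- if (var$timing_jitter_sd > 0)
      rnorm(5, 0, var$timing_jitter_sd) else numeric(5)
    onset <- base_onset + jit
    ends <- onset + od + cd
    ok <- onset[1] > 0 && all(diff(onset) > 0) &&
      all(onset[-1] > ends[-5])
    if (ok) break
    if (try == 50L)
      stop("generation error: timing jitter produced overlapping gestures",
           call. = FALSE)
  }

  total <- ends[5] + score$lead_in
  n <- floor(total * sample_rate) + 1L
  tt <- (seq_len(n) - 1) / sample_rate
  dev <- eval_gesture_train(tt, onset, od, oe, cd, ce)

  lay <- simulator_layout()
  noise <- function() {
    if (var$noise_sd == 0) return(numeric(n))
    w <- rnorm(n, 0, var$noise_sd)
    lowpass(trajectory(w, sample_rate, "noise"),
            cutoff = var$noise_bandwidth)$samples
  }
  lower <- matrix(rep(lay$lower_lip_base, each = n), n, 3)
  lower[, 3] <- lower[, 3] + score$baseline + dev + noise()
  upper <- matrix(rep(lay$upper_lip_base, each = n), n, 3)
  upper[, 3] <- upper[, 3] - score$upper_lip_gain * dev + noise()
  markers <- c(
    list(upper_lip = upper, lower_lip = lower),
    lapply(lay$head, function(p) matrix(rep(p, each = n), n, 3)))

  if (!is.null(head_motion)) {
    markers <- lapply(markers, function(m) {
      out <- m
      for (i in seq_len(n)) {
        hm <- head_motion(tt[i])
        out[i, ] <- as.numeric(hm$R %*% m[i, ]) + hm$t
      }
      out
    })
  }

  rec <- marker_recording(participant_id, trial_id, sample_rate, markers)
  attr(rec, "ground_truth") <- data.frame(
    cycle = 1:5,
    opening_onset_s = onset,
    opening_peak_s = onset + od / 2,
    opening_peak_velocity = -15 * oe / (8 * od),
    opening_extent = oe,
    closing_extent = ce,
    closing_peak_velocity = 15 * ce / (8 * cd),
    closing_offset_s = onset + od + cd)
  attr(rec, "factors") <- c(amplitude = amp, tempo = tempo)
  attr(rec, "seed") <- as.integer(trial_seed)
  rec
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Cohort design for the simulator
#'
#' Cell-level specification of a 2 (stutter/control) x 2 (male/female)
#' between-subject design: per-cell sample size, mean gesture scale
#' (a multiplicative factor on all template extents, the knob that
#' shifts a cell's displacement and velocity dynamic ranges), the
#' between-participant SD of that scale, and per-cell variability
#' parameters. Defaults emulate the observed sentence-task cohort:
#' cell sizes 43/14/27/13 (male-stutter, female-stutter, male-control,
#' female-control), a male-stutter gesture scale of 0.83 relative to
#' male controls, and between-participant scatter giving
#' displacement-dynamic-range SDs of roughly a quarter of the mean.
#'
#' @param cells Data.frame with columns \code{group}, \code{sex},
#'   \code{n}, \code{extent_scale}, \code{extent_scale_sd}.
#' @param n_trials Repetitions per participant.
#' @param score Base [gesture_score()].
#' @param var Within-participant [variability_model()].
#' @return Object of class \code{"cohort_design"}.
#' @export
cohort_design <- function(
    cells = data.frame(
      group = c("stutter", "stutter", "control", "control"),
      sex = c("male", "female", "male", "female"),
      n = c(43L, 14L, 27L, 13L),
      extent_scale = c(0.83, 0.94, 1.00, 0.86),
      extent_scale_sd = rep(0.245, 4)),
    n_trials = 10L,
    score = gesture_score(),
    var = variability_model()) {
  stopifnot(is.data.frame(cells),
            all(c("group", "sex", "n", "extent_scale",
                  "extent_scale_sd") %in% names(cells)),
            all(cells$n >= 2L))
  structure(list(cells = cells, n_trials = as.integer(n_trials),
                 score = score, var = var),
            class = "cohort_design")
}

#' Simulate a whole cohort with known ground truth
#'
#' Draws each participant's gesture scale from their cell's
#' distribution, simulates \code{n_trials} repetitions per participant
#' with the within-participant variability model, and returns the
#' recordings plus metadata and a ground-truth table for
#' parameter-recovery tests. All randomness flows from \code{seed}
#' through per-participant and per-trial derived seeds, so the output
#' is reproducible.
#'
#' @param design A [cohort_design()].
#' @param seed Integer root seed.
#' @return List with \code{recordings} (named list: participant ->
#'   list of [marker_recording()]s), \code{meta} (data.frame
#'   \code{participant_id}, \code{group}, \code{sex}), \code{truth}
#'   (data.frame with each participant's drawn \code{extent_scale} and
#'   cell parameters), and \code{design}.
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(as.integer(seed))
  cells <- design$cells
  n_total <- sum(cells$n)
  pseeds <- sample.int(.Machine$integer.max - 1L, n_total)

  recordings <- list(); meta <- list(); truth <- list()
  pid_i <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (j in seq_len(cells$n[ci])) {
      pid_i <- pid_i + 1L
      pid <- sprintf("P%03d", pid_i)
      set.seed(pseeds[pid_i])
      scale_i <- max(0.15, rnorm(1, cells$extent_scale[ci],
                                 cells$extent_scale_sd[ci]))
      tseeds <- sample.int(.Machine$integer.max - 1L, design$n_trials)
      sc <- design$score
      sc$opening_extent <- sc$opening_extent * scale_i
      sc$closing_extent <- sc$closing_extent * scale_i
      recordings[[pid]] <- lapply(seq_len(design$n_trials), function(tr)
        generate_trial(sc, design$var, trial_seed = tseeds[tr],
                       participant_id = pid,
                       trial_id = sprintf("%s_t%02d", pid, tr)))
      meta[[pid_i]] <- data.frame(
        participant_id = pid, group = cells$group[ci],
        sex = cells$sex[ci], stringsAsFactors = FALSE)
      truth[[pid_i]] <- data.frame(
        participant_id = pid, group = cells$group[ci],
        sex = cells$sex[ci], extent_scale = scale_i,
        cell_mean_scale = cells$extent_scale[ci],
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  meta$group <- factor(meta$group, levels = c("stutter", "control"))
  meta$sex <- factor(meta$sex, levels = c("male", "female"))
  list(recordings = recordings, meta = meta,
       truth = do.call(rbind, truth), design = design)
}
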