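#' Locate negative (opening) velocity peaks
#'
#' Finds local minima of the lower-lip velocity that are negative and
#' whose depth below zero exceeds \code{prominence_frac} times the
#' maximum absolute velocity of the trial. With +z superior, each oral
#' opening movement produces one such negative velocity peak; a
#' five-opening sentence such as "Buy Bobby a puppy" yields five.
#'
#' @param vel A velocity trace ([differentiate()]) or numeric vector
#'   wrapped via \code{sample_rate}.
#' @param prominence_frac Depth threshold as a fraction of
#'   \code{max(abs(velocity))}; must be in (0, 1).
#' @return Integer vector of peak frame indices in temporal order
#'   (empty for flat or all-positive signals).
#' @export
find_opening_peaks <- function(vel, prominence_frac = 0.10) {
  v <- if (inherits(vel, "trajectory")) vel$samples else as.numeric(vel)
  if (prominence_frac <= 0 || prominence_frac >= 1)
    stop("prominence_frac must be in (0, 1)", call. = FALSE)
  n <- length(v)
  if (n < 3L || all(v == 0)) return(integer(0))
  vmax <- max(abs(v))
  i <- 2:(n - 1L)
  is_min <- v[i] < v[i - 1L] & v[i] <= v[i + 1L]
  cand <- i[is_min & v[i] < 0 & (-v[i]) > prominence_frac * vmax]
  # boundary samples count when they undercut their single neighbour,
  # so an already-cut segment keeps its bounding peaks
  if (v[1] < v[2] && v[1] < 0 && -v[1] > prominence_frac * vmax)
    cand <- c(1L, cand)
  if (v[n] < v[n - 1L] && v[n] < 0 && -v[n] > prominence_frac * vmax)
    cand <- c(cand, n)
  as.integer(cand)
}

#' Segment one utterance between opening velocity peaks
#'
#' Cuts all articulator displacement traces and the lower-lip velocity
#' trace of one sentence repetition to the span from the
#' \code{first}-th to the \code{last}-th negative opening velocity
#' peak (inclusive). The lower-lip velocity defines the cut; upper and
#' lower lip are cut at identical indices. If more than \code{last}
#' qualifying peaks are present, the \code{last} most prominent are
#' taken in temporal order; fewer is a segmentation error.
#'
#' @param displ A [trajectory()] or named list of trajectories (e.g.
#'   \code{upper_lip}, \code{lower_lip}) to cut.
#' @param vel Lower-lip velocity trace.
#' @param first,last Ordinal positions of the bounding opening peaks
#'   (defaults 1 and 5, the five-opening sentence tasks).
#' @param prominence_frac Passed to [find_opening_peaks()].
#' @return An object of class \code{"utterance_segment"}: list with
#'   \code{displacement} (named list of cut trajectories),
#'   \code{velocity}, \code{start_index}, \code{end_index} (into the
#'   source trial), \code{opening_peak_indices} (within-segment, length
#'   \code{last - first + 1}), \code{sample_rate}.
#' @export
segment_utterance <- function(displ, vel, first = 1L, last = 5L,
                              prominence_frac = 0.10) {
  if (inherits(displ, "trajectory"))
    displ <- setNames(list(displ), displ$label)
  stopifnot(is.list(displ), length(displ) >= 1L)
  vv <- if (inherits(vel, "trajectory")) vel$samples else as.numeric(vel)
  peaks <- find_opening_peaks(vel, prominence_frac)
  want <- last
  if (length(peaks) < want)
    stop(sprintf(
      "segmentation error: found %d opening peak(s), need %d",
      length(peaks), want), call. = FALSE)
  if (length(peaks) > want) {
    depth <- -vv[peaks]
    peaks <- sort(peaks[order(depth, decreasing = TRUE)[seq_len(want)]])
  }
  s <- peaks[first]; e <- peaks[last]
  cut_traj <- function(tr) {
    tr$samples <- tr$samples[s:e]
    tr
  }
  out_d <- lapply(displ, cut_traj)
  out_v <- if (inherits(vel, "trajectory")) cut_traj(vel) else
    trajectory(vv[s:e], out_d[[1]]$sample_rate, "lower_lip", "mm/s")
  structure(
    list(displacement = out_d, velocity = out_v,
         start_index = s, end_index = e,
         opening_peak_indices = peaks[first:last] - s + 1L,
         sample_rate = out_v$sample_rate),
    class = "utterance_segment")
}

#' @export
print.utterance_segment <- function(x, ...) {
  cat(sprintf(
    "<utterance_segment> frames %d-%d (%.3f s), %d opening peaks, articulators: %s\n",
    x$start_index, x$end_index,
    (x$end_index - x$start_index) / x$sample_rate,
    length(x$opening_peak_indices),
    paste(names(x$displacement), collapse = ", ")))
  invisible(x)
}

# Movement boundaries at velocity zero-crossings. A small epsilon
# (fraction of the trial's peak speed) absorbs the near-zero ripple a
# zero-phase filter leaves around rest phases, which would otherwise
# stretch cycles into the preceding/following holds.
zero_cross_before <- function(v, i, eps = 0) {
  j <- i
  while (j >= 1L && v[j] < -eps) j <- j - 1L
  if (j < 1L) NA_integer_ else j
}
zero_cross_after <- function(v, i, sign_neg = TRUE, eps = 0) {
  n <- length(v)
  j <- i
  if (sign_neg) { # leaving a negative (opening) phase
    while (j <= n && v[j] < -eps) j <- j + 1L
  } else {        # leaving a positive (closing) phase
    while (j <= n && v[j] > eps) j <- j + 1L
  }
  if (j > n) NA_integer_ else j
}

#' Extract opening/closing movement cycles for target syllables
#'
#' For each requested cycle the opening movement spans the velocity
#' zero-crossing preceding that opening peak to the zero-crossing
#' following it, and the subsequent closing movement runs to the next
#' zero-crossing. Defaults map the syllable "Bob" to cycle 2 and "pup"
#' to cycle 4 of "Buy Bobby a puppy"; the mapping is configuration.
#'
#' @param seg An [segment_utterance()] result.
#' @param cycle_map Named integer vector syllable -> cycle ordinal
#'   (within \code{seg$opening_peak_indices}).
#' @param eps_frac Zero-crossing tolerance as a fraction of the
#'   segment's peak speed (absorbs filter ripple around rest phases).
#' @return Data.frame of class \code{"movement_cycles"}: one row per
#'   movement with \code{syllable}, \code{direction}
#'   (\code{opening}/\code{closing}), \code{onset}, \code{offset},
#'   \code{peak_velocity_index} (within-segment frame indices).
#' @export
extract_movement_cycles <- function(seg,
                                    cycle_map = c(Bob = 2L, pup = 4L),
                                    eps_frac = 0.02) {
  stopifnot(inherits(seg, "utterance_segment"))
  v <- seg$velocity$samples
  eps <- eps_frac * max(abs(v))
  npk <- length(seg$opening_peak_indices)
  rows <- list()
  for (syl in names(cycle_map)) {
    k <- cycle_map[[syl]]
    if (k < 1L || k > npk)
      stop(sprintf(
        "extraction error: cycle %d requested for '%s' but only %d available",
        k, syl, npk), call. = FALSE)
    p <- seg$opening_peak_indices[k]
    on_o <- zero_cross_before(v, p, eps = eps)
    off_o <- zero_cross_after(v, p, sign_neg = TRUE, eps = eps)
    if (is.na(on_o) || is.na(off_o))
      stop(sprintf(
        "extraction error: opening cycle %d ('%s') hits segment edge",
        k, syl), call. = FALSE)
    # closing: the positive-velocity phase after the opening; locate
    # its peak inside the window up to the next opening peak, then walk
    # forward to the following zero-crossing
    win_end <- if (k < npk) seg$opening_peak_indices[k + 1L] else
      length(v)
    pk_c <- off_o + which.max(v[off_o:win_end]) - 1L
    if (v[pk_c] <= eps)
      stop(sprintf(
        "extraction error: no closing movement after cycle %d ('%s')",
        k, syl), call. = FALSE)
    off_c <- zero_cross_after(v, pk_c, sign_neg = FALSE, eps = eps)
    if (is.na(off_c))
      stop(sprintf(
        "extraction error: closing cycle %d ('%s') hits segment edge",
        k, syl), call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      syllable = syl,
      direction = c("opening", "closing"),
      onset = c(on_o, off_o),
      offset = c(off_o, off_c),
      peak_velocity_index = c(p, pk_c),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("movement_cycles", "data.frame")
  out
}

#' Trial set: the segmented repetitions of one participant x sentence
#'
#' @param participant_id,sentence_id Identifiers.
#' @param segments List of [segment_utterance()] results (one fluent
#'   repetition each). Downstream analysis requires at least 7 and
#'   uses at most the first 10 (see [default_config()]).
#' @return Object of class \code{"trial_set"}.
#' @export
trial_set <- function(participant_id, sentence_id, segments) {
  stopifnot(is.list(segments),
            all(vapply(segments, inherits, logical(1),
                       "utterance_segment")))
  structure(
    list(participant_id = as.character(participant_id),
         sentence_id = as.character(sentence_id),
         segments = segments),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %s / %s: %d segmented repetitions\n",
              x$participant_id, x$sentence_id, length(x$segments)))
  invisible(x)
}
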