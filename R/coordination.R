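#' Lip-aperture signal
#'
#' Sample-by-sample difference of the segmented upper- and lower-lip
#' displacement signals, \code{LA(t) = upper(t) - lower(t)}. With +z
#' superior and the lower lip carrying the jaw, LA grows as the mouth
#' opens; it is the functional vocal-tract variable whose
#' trial-to-trial consistency the LA index quantifies. Common-mode
#' (head-residual) displacement cancels.
#'
#' @param upper,lower [trajectory()] objects of equal length and
#'   sample rate.
#' @return A [trajectory()] labelled \code{"lip_aperture"}.
#' @export
lip_aperture <- function(upper, lower) {
  upper <- as_trajectory(upper); lower <- as_trajectory(lower)
  if (length(upper$samples) != length(lower$samples))
    stop("input error: upper and lower traces differ in length",
         call. = FALSE)
  if (abs(upper$sample_rate - lower$sample_rate) > 1e-9)
    stop("input error: sample rates differ", call. = FALSE)
  trajectory(upper$samples - lower$samples, upper$sample_rate,
             label = "lip_aperture", units = "mm")
}

#' Time-normalise a trajectory onto a fixed relative-time axis
#'
#' Cubic-spline interpolation of the signal onto \code{n_points}
#' equally spaced points spanning relative time [0, 1], so repetitions
#' of different durations become comparable point-by-point. Endpoints
#' are preserved exactly (they are spline knots).
#'
#' @param traj A [trajectory()] or numeric vector of length >= 4.
#' @param n_points Length of the output axis (default 1000).
#' @return Numeric vector of length \code{n_points}.
#' @export
time_normalize <- function(traj, n_points = 1000L) {
  x <- if (inherits(traj, "trajectory")) traj$samples else
    as.numeric(traj)
  n <- length(x)
  if (n < 4L)
    stop("input error: time_normalize needs at least 4 samples",
         call. = FALSE)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  spline(x = seq(0, 1, length.out = n), y = x,
         xout = seq(0, 1, length.out = n_points), method = "fmm")$y
}

#' Amplitude-normalise a signal to mean 0, SD 1
#'
#' Subtracts the mean and divides by the (population, i.e. 1/n
#' denominator) standard deviation, removing per-trial offset and
#' scale so only the shape of the trajectory contributes to
#' across-trial variability.
#'
#' @param series Numeric vector with positive variance.
#' @return Numeric vector with mean 0 and population SD 1.
#' @export
amplitude_normalize <- function(series) {
  x <- as.numeric(series)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s <= 0)
    stop("normalization error: zero-variance signal", call. = FALSE)
  (x - m) / s
}

#' Lip-aperture variability index
#'
#' The coordination-consistency measure for a set of repeated
#' productions: each repetition's lip-aperture trajectory is
#' time-normalised onto 1000 points ([time_normalize()]) and
#' amplitude-normalised to mean 0, SD 1 ([amplitude_normalize()]);
#' the standard deviation across repetitions is then computed at fixed
#' 2\% intervals of relative time (50 points, realised as every 20th
#' sample of the 1000-point axis) and summed. Higher values reflect
#' greater trial-to-trial variability of articulatory coordination.
#' Identical repetitions -- or repetitions differing only by positive
#' affine amplitude transforms or uniform time dilation -- score 0.
#'
#' @param trials A [trial_set()] whose segments carry \code{upper_lip}
#'   and \code{lower_lip} displacement, or a list of lip-aperture
#'   [trajectory()] objects / numeric vectors (one per repetition).
#'   At least 2 repetitions (the analysis floor of 7 is enforced by
#'   the pipeline, not here).
#' @param n_points Time-normalised axis length (default 1000).
#' @param include_zero Also include relative time 0 in the SD grid
#'   (51 points instead of 50).
#' @param sd_denominator \code{"sample"} (n - 1, default) or
#'   \code{"population"} (n) for the across-trial SD.
#' @return Object of class \code{"la_result"}: list with
#'   \code{normalized_trajectories} (n_trials x n_points matrix),
#'   \code{sd_profile}, \code{grid} (relative times of the SD grid),
#'   \code{la_index} (sum of \code{sd_profile}), \code{n_trials}.
#' @export
la_index <- function(trials, n_points = 1000L, include_zero = FALSE,
                     sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  apertures <- la_trial_signals(trials)
  n_tr <- length(apertures)
  if (n_tr < 2L)
    stop("la_index requires at least 2 trials", call. = FALSE)
  norm <- t(vapply(apertures, function(x)
    amplitude_normalize(time_normalize(x, n_points)),
    numeric(n_points)))
  idx <- as.integer(round(seq_len(50L) * (n_points / 50)))
  if (include_zero) idx <- c(1L, idx)
  sds <- apply(norm[, idx, drop = FALSE], 2, sd)
  if (sd_denominator == "population")
    sds <- sds * sqrt((n_tr - 1) / n_tr)
  structure(
    list(normalized_trajectories = norm,
         sd_profile = unname(sds),
         grid = (idx - 1) / (n_points - 1),
         la_index = sum(sds),
         n_trials = n_tr),
    class = "la_result")
}

# Pull one lip-aperture numeric vector per repetition out of whatever
# the caller supplied.
la_trial_signals <- function(trials) {
  if (inherits(trials, "trial_set")) {
    lapply(trials$segments, function(seg) {
      up <- seg$displacement$upper_lip
      lo <- seg$displacement$lower_lip
      if (is.null(up) || is.null(lo))
        stop("trial_set segments must carry upper_lip and lower_lip",
             call. = FALSE)
      lip_aperture(up, lo)$samples
    })
  } else if (is.list(trials)) {
    lapply(trials, function(x)
      if (inherits(x, "trajectory")) x$samples else as.numeric(x))
  } else stop("unsupported input to la_index", call. = FALSE)
}

#' @export
print.la_result <- function(x, ...) {
  cat(sprintf(
    "<la_result> LA variability index = %.3f (%d trials, %d-point SD grid)\n",
    x$la_index, x$n_trials, length(x$sd_profile)))
  cat(sprintf("  sd profile: min %.3f, median %.3f, max %.3f\n",
              min(x$sd_profile), median(x$sd_profile),
              max(x$sd_profile)))
  invisible(x)
}

#' @export
summary.la_result <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot an LA variability result
#'
#' Top panel: the time- and amplitude-normalised lip-aperture
#' trajectories overlaid. Bottom panel: the across-trial SD profile at
#' the 2\% grid, whose sum is the LA index.
#'
#' @param x An [la_index()] result.
#' @param ... Unused.
#' @export
plot.la_result <- function(x, ...) {
  old <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  rel <- seq(0, 1, length.out = ncol(x$normalized_trajectories))
  matplot(rel, t(x$normalized_trajectories), type = "l", lty = 1,
          col = grDevices::grey(0.4, alpha = 0.6),
          xlab = "relative time", ylab = "normalised LA",
          main = sprintf("%d normalised repetitions", x$n_trials))
  plot(x$grid, x$sd_profile, type = "h", xlab = "relative time",
       ylab = "SD across trials",
       main = sprintf("LA index = %.2f", x$la_index))
  invisible(x)
}
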