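#' Zero-phase low-pass filtering of a displacement trajectory
#'
#' Smooths a displacement trace with a Butterworth low-pass filter
#' applied forward and backward, giving zero phase distortion and a
#' squared magnitude response. Oral movement during sentence production
#' lives below roughly 10 Hz at normal speaking rates; the default
#' cutoff follows the convention of the orofacial-kinematics
#' literature. The signal is extended by odd-symmetric reflection at
#' both ends before filtering so the startup transient falls on the
#' extension, not the data.
#'
#' @param traj A [trajectory()].
#' @param cutoff Cutoff frequency in Hz; must lie in
#'   \code{(0, sample_rate / 2)}.
#' @param order Butterworth order of the one-pass filter (default 4;
#'   the effective two-pass order is double).
#' @return A [trajectory()] of identical length and units.
#' @examples
#' tr <- trajectory(sin(2 * pi * 2 * (0:499) / 250), 250)
#' sm <- lowpass(tr, cutoff = 10)
#' @export
lowpass <- function(traj, cutoff = 10, order = 4) {
  traj <- as_trajectory(traj)
  fs <- traj$sample_rate
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= fs / 2)
    stop(sprintf("cutoff must be in (0, %g) Hz", fs / 2), call. = FALSE)
  x <- traj$samples
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection pad keeps value and slope continuous at the ends;
  # constant lead-in/out blocks long enough for the slowest pole to
  # decay let each pass start from (numerical) steady state.
  pad <- min(n - 1L, ceiling(3 * fs / cutoff))
  rmax <- max(Mod(polyroot(rev(bf$a))))
  K <- ceiling(log(1e-13) / log(min(rmax, 1 - 1e-6)))
  pre  <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xx <- c(rep(pre[1], K), pre, x, post, rep(post[pad], K))
  y <- as.numeric(signal::filter(bf, xx))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  traj$samples <- y[(K + pad + 1L):(K + pad + n)]
  traj
}

#' Differentiate a displacement trajectory to velocity
#'
#' Central-difference differentiation, with one-sided differences at
#' the two endpoints. Exact for linear signals; at 250 Hz the
#' second-order truncation error is negligible for the sub-10-Hz
#' content that survives [lowpass()].
#'
#' @param traj A [trajectory()] in mm, length at least 3.
#' @return A velocity trace: an object of class
#'   \code{c("velocity_trace", "trajectory")} in mm/s, same length and
#'   sample rate as the input.
#' @export
differentiate <- function(traj) {
  traj <- as_trajectory(traj)
  x <- traj$samples
  n <- length(x)
  if (n < 3L)
    stop("differentiate requires at least 3 samples", call. = FALSE)
  fs <- traj$sample_rate
  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  out <- trajectory(v, fs, label = traj$label, units = "mm/s")
  class(out) <- c("velocity_trace", "trajectory")
  out
}
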