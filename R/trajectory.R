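#' One-dimensional articulatory trajectory
#'
#' Container for a uniformly sampled 1-D displacement (or velocity)
#' series. Frame \code{i} occurs at time \code{(i - 1) / sample_rate}
#' seconds; no explicit time axis is stored.
#'
#' @param samples Numeric vector of finite values (mm, or mm/s for a
#'   velocity trace), length at least 2.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param label Articulator label, e.g. \code{"upper_lip"},
#'   \code{"lower_lip"} or \code{"lip_aperture"}.
#' @param units Measurement units, \code{"mm"} or \code{"mm/s"}.
#' @return An object of class \code{"trajectory"}: a list with elements
#'   \code{samples}, \code{sample_rate}, \code{label}, \code{units}.
#' @export
trajectory <- function(samples, sample_rate, label = "lower_lip",
                       units = "mm") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("trajectory requires at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("trajectory samples must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 0)
    stop("sample_rate must be a positive scalar", call. = FALSE)
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         label = label, units = units),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d frames @ %g Hz (%.3f s), range [%.3g, %.3g] %s\n",
              x$label, length(x$samples), x$sample_rate,
              (length(x$samples) - 1) / x$sample_rate,
              min(x$samples), max(x$samples), x$units))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$samples)

#' @export
plot.trajectory <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$sample_rate
  plot(t, x$samples, type = "l", xlab = "time (s)",
       ylab = sprintf("%s (%s)", x$label, x$units), ...)
  invisible(x)
}

as_trajectory <- function(x, sample_rate = NULL, label = "signal",
                          units = "mm") {
  if (inherits(x, "trajectory")) return(x)
  if (is.null(sample_rate))
    stop("sample_rate required when input is a bare numeric vector",
         call. = FALSE)
  trajectory(x, sample_rate, label = label, units = units)
}
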