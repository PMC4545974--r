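#' Estimate per-frame rigid head transforms
#'
#' Expresses each frame's head-marker configuration relative to a
#' reference frame by a least-squares rigid transform (rotation +
#' translation, no scaling), solved per frame by SVD (the
#' Kabsch/Umeyama solution without the scale term). Applying the
#' frame-\code{t} transform to any lab-frame point moves it into the
#' head coordinate system defined at the reference frame, so lip
#' markers can be measured relative to the skull rather than the room.
#' The head-frame axes inherit the lab axes at the reference frame;
#' superior-inferior is lab +z there.
#'
#' @param rec A [marker_recording()] with at least three non-collinear
#'   head markers (\code{head_1, head_2, ...}).
#' @param reference_frame Index of the frame defining the head
#'   coordinate system (default 1, the first frame of the trial).
#' @param rms_warn Residual RMS (mm) above which a frame is flagged
#'   with a warning -- residuals measure departure from rigidity.
#' @return An object of class \code{"rigid_transform_series"}: list
#'   with \code{rotation} (3 x 3 x n_frames array; applied on the right
#'   of a row vector), \code{centroid_lab} (n_frames x 3),
#'   \code{centroid_ref} (length 3), \code{rms} (per-frame residual
#'   RMS, mm), \code{reference_frame}, \code{n_frames}.
#' @export
estimate_head_transforms <- function(rec, reference_frame = 1L,
                                     rms_warn = 1.0) {
  stopifnot(inherits(rec, "marker_recording"))
  heads <- head_marker_names(rec)
  n <- rec$n_frames
  if (reference_frame < 1L || reference_frame > n)
    stop("reference_frame out of range", call. = FALSE)
  k <- length(heads)
  # ref configuration: k x 3 matrix of head markers at the reference frame
  ref <- t(vapply(heads, function(m) rec$markers[[m]][reference_frame, ],
                  numeric(3)))
  c_ref <- colMeans(ref)
  refc <- sweep(ref, 2, c_ref)
  sv <- svd(refc)$d
  if (sv[2] < 1e-6 * max(sv[1], 1e-12))
    stop("geometry error: head markers are collinear or degenerate",
         call. = FALSE)

  rot <- array(NA_real_, c(3, 3, n))
  rms <- numeric(n)
  # H[t, i, a]: frame t, head marker i, axis a; centred per frame
  H <- array(NA_real_, c(n, k, 3))
  for (i in seq_len(k)) H[, i, ] <- rec$markers[[heads[i]]]
  cents <- apply(H, 3, rowMeans)                 # n x 3 centroids
  for (a in 1:3) H[, , a] <- H[, , a] - cents[, a]
  # cross-covariances S_t = t(Xc_t) %*% refc, all frames at once
  S_all <- lapply(1:3, function(a) H[, , a, drop = TRUE] %*% refc)
  ss_x <- rowSums(H[, , 1]^2 + H[, , 2]^2 + H[, , 3]^2)
  ss_ref <- sum(refc^2)
  S <- matrix(0, 3, 3)
  for (t in seq_len(n)) {
    for (a in 1:3) S[a, ] <- S_all[[a]][t, ]
    dec <- svd(S)
    d <- sign(det(dec$u) * det(dec$v))
    A <- dec$u %*% (c(1, 1, d) * t(dec$v))
    rot[, , t] <- A
    # ||Xc A - refc||^2 = ||Xc||^2 + ||refc||^2 - 2 tr(A' S)
    rms[t] <- sqrt(max(0, ss_x[t] + ss_ref - 2 * sum(A * S)) / k)
  }
  if (any(rms > rms_warn))
    warning(sprintf(
      "%d frame(s) with rigid-fit residual RMS above %g mm (max %.3g mm)",
      sum(rms > rms_warn), rms_warn, max(rms)), call. = FALSE)
  structure(
    list(rotation = rot, centroid_lab = cents, centroid_ref = c_ref,
         rms = rms, reference_frame = reference_frame, n_frames = n),
    class = "rigid_transform_series")
}

#' @export
print.rigid_transform_series <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform_series> %d frames, reference frame %d, residual RMS %.3g-%.3g mm\n",
    x$n_frames, x$reference_frame, min(x$rms), max(x$rms)))
  invisible(x)
}

# Apply the frame-wise transforms to an n x 3 lab-frame point series.
apply_transforms <- function(transforms, pts) {
  n <- transforms$n_frames
  stopifnot(nrow(pts) == n)
  out <- matrix(NA_real_, n, 3)
  for (t in seq_len(n)) {
    out[t, ] <- (pts[t, ] - transforms$centroid_lab[t, ]) %*%
      transforms$rotation[, , t] + transforms$centroid_ref
  }
  out
}

#' Project a lip marker into the head frame
#'
#' Applies the per-frame head transforms to a lip marker and returns
#' its superior-inferior (z) displacement relative to the reference
#' frame. With +z superior, oral opening moves the lower lip to
#' negative displacement and negative velocity. Any rigid motion
#' common to all markers (the head moving in the room) cancels
#' exactly.
#'
#' @param rec A [marker_recording()].
#' @param transforms Result of [estimate_head_transforms()] for the
#'   same recording.
#' @param marker Marker name, e.g. \code{"lower_lip"}.
#' @return A [trajectory()] in mm: head-frame z minus its value at the
#'   reference frame.
#' @export
project_lip_trajectory <- function(rec, transforms, marker = "lower_lip") {
  stopifnot(inherits(rec, "marker_recording"),
            inherits(transforms, "rigid_transform_series"))
  if (!marker %in% names(rec$markers))
    stop(sprintf("input error: unknown marker '%s'", marker),
         call. = FALSE)
  if (transforms$n_frames != rec$n_frames)
    stop("transform series length does not match recording", call. = FALSE)
  z <- apply_transforms(transforms, rec$markers[[marker]])[, 3]
  z <- z - z[transforms$reference_frame]
  trajectory(z, rec$sample_rate, label = marker, units = "mm")
}
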