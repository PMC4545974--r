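#' Marker recording container
#'
#' Per-frame 3D positions (mm) of the named markers tracked in one
#' trial: the two lip markers plus at least three head-reference
#' markers used to build the head coordinate system. Frames are
#' uniformly spaced; frame \code{i} is at \code{(i - 1) / sample_rate}
#' seconds.
#'
#' @param participant_id,trial_id Opaque identifier strings.
#' @param sample_rate Sampling rate in Hz.
#' @param markers Named list of \code{n_frames x 3} numeric matrices
#'   (columns x, y, z in mm). Must contain \code{upper_lip},
#'   \code{lower_lip} and at least three markers named
#'   \code{head_1, head_2, ...}.
#' @return An object of class \code{"marker_recording"}.
#' @export
marker_recording <- function(participant_id, trial_id, sample_rate,
                             markers) {
  if (!is.list(markers) || is.null(names(markers)))
    stop("markers must be a named list of n x 3 matrices", call. = FALSE)
  nm <- names(markers)
  need <- c("upper_lip", "lower_lip")
  if (!all(need %in% nm))
    stop("markers must include upper_lip and lower_lip", call. = FALSE)
  heads <- grep("^head_[0-9]+$", nm, value = TRUE)
  if (length(heads) < 3L)
    stop("at least 3 head markers (head_1, head_2, ...) required",
         call. = FALSE)
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker needs 3 columns (x, y, z)",
                            call. = FALSE)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  nf <- vapply(markers, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    stop("all marker series must have identical length", call. = FALSE)
  if (nf[1] < 2L)
    stop("recording must have at least 2 frames", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive", call. = FALSE)
  if (any(!vapply(markers, function(m) all(is.finite(m)), logical(1))))
    stop("marker positions contain non-finite values", call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id),
         trial_id = as.character(trial_id),
         sample_rate = as.numeric(sample_rate),
         markers = markers,
         n_frames = unname(nf[1])),
    class = "marker_recording")
}

#' @export
print.marker_recording <- function(x, ...) {
  cat(sprintf("<marker_recording> %s / %s: %d frames @ %g Hz, markers: %s\n",
              x$participant_id, x$trial_id, x$n_frames, x$sample_rate,
              paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

head_marker_names <- function(rec) {
  sort(grep("^head_[0-9]+$", names(rec$markers), value = TRUE))
}

detect_sep <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (grepl("\t", line1)) "\t" else ","
}

# Linear interpolation across short NaN runs; returns list(x, n_interp)
# or signals an error when a gap exceeds max_gap frames or touches an
# endpoint (no extrapolation).
fill_gaps <- function(x, max_gap, what) {
  bad <- !is.finite(x)
  if (!any(bad)) return(list(x = x, n_interp = 0L))
  r <- rle(bad)
  if (any(r$values & r$lengths > max_gap))
    stop(sprintf("%s: dropout run longer than %d frames; trial invalid",
                 what, max_gap), call. = FALSE)
  if (bad[1] || bad[length(x)])
    stop(sprintf("%s: dropout at trial boundary cannot be interpolated",
                 what), call. = FALSE)
  idx <- seq_along(x)
  x[bad] <- approx(idx[!bad], x[!bad], xout = idx[bad])$y
  list(x = x, n_interp = sum(bad))
}

#' Read a marker trajectory table
#'
#' Parses a delimited text table (tab default, comma accepted) with a
#' header row naming columns \code{time_s} and
#' \code{<marker>_x, <marker>_y, <marker>_z} in mm for each marker.
#' The sampling rate is inferred from the median time step; every step
#' must agree with the median within 0.1\%, and when \code{declared_rate}
#' is given the inferred rate must match it within 0.1\%. Runs of up to
#' \code{max_gap} consecutive missing frames (blank or NaN cells) are
#' linearly interpolated -- 5 frames is 20 ms at 250 Hz, well under one
#' movement cycle -- and counted in the returned object; longer runs
#' invalidate the trial.
#'
#' @param path Path to the delimited text file.
#' @param participant_id,trial_id Identifiers stored in the result;
#'   default to the file name.
#' @param declared_rate Optional nominal sampling rate in Hz to
#'   validate against.
#' @param max_gap Longest interpolatable dropout, in frames.
#' @return A [marker_recording()] with attribute \code{"n_interpolated"}
#'   (frames filled per marker coordinate, summed).
#' @export
read_marker_file <- function(path, participant_id = basename(path),
                             trial_id = basename(path),
                             declared_rate = NULL, max_gap = 5L) {
  sep <- detect_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", "NaN", ""))
  if (!"time_s" %in% names(tab))
    stop("format error: missing time_s column", call. = FALSE)
  if (nrow(tab) < 2L)
    stop("input error: fewer than 2 frames", call. = FALSE)
  coord_cols <- grep("_[xyz]$", names(tab), value = TRUE)
  marker_names <- unique(sub("_[xyz]$", "", coord_cols))
  for (m in c("upper_lip", "lower_lip")) {
    if (!m %in% marker_names)
      stop(sprintf("format error: missing marker columns for '%s'", m),
           call. = FALSE)
  }
  tt <- tab$time_s
  dt <- diff(tt)
  med <- median(dt)
  if (med <= 0)
    stop("sampling error: non-increasing time column", call. = FALSE)
  if (any(abs(dt - med) > 1e-3 * med))
    stop("sampling error: non-uniform time steps beyond 0.1% tolerance",
         call. = FALSE)
  rate <- 1 / med
  if (!is.null(declared_rate) &&
      abs(rate - declared_rate) > 1e-3 * declared_rate)
    stop(sprintf(
      "sampling error: inferred rate %.4g Hz differs from declared %g Hz",
      rate, declared_rate), call. = FALSE)

  n_interp <- 0L
  markers <- lapply(marker_names, function(m) {
    cols <- paste0(m, "_", c("x", "y", "z"))
    if (!all(cols %in% names(tab)))
      stop(sprintf("format error: incomplete coordinates for marker '%s'",
                   m), call. = FALSE)
    mat <- vapply(cols, function(cl) {
      fg <- fill_gaps(as.numeric(tab[[cl]]), max_gap,
                      sprintf("%s (%s)", basename(path), cl))
      n_interp <<- n_interp + fg$n_interp
      fg$x
    }, numeric(nrow(tab)))
    unname(mat)
  })
  names(markers) <- marker_names
  rec <- marker_recording(participant_id, trial_id,
                          if (is.null(declared_rate)) rate else declared_rate,
                          markers)
  attr(rec, "n_interpolated") <- n_interp
  rec
}

#' Write a marker recording to a delimited text table
#'
#' Inverse of [read_marker_file()]: emits \code{time_s} plus
#' \code{<marker>_x/_y/_z} columns in mm, tab-separated.
#'
#' @param rec A [marker_recording()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_marker_file <- function(rec, path) {
  stopifnot(inherits(rec, "marker_recording"))
  out <- data.frame(time_s = (seq_len(rec$n_frames) - 1) / rec$sample_rate)
  for (m in names(rec$markers)) {
    for (j in 1:3)
      out[[paste0(m, "_", c("x", "y", "z")[j])]] <- rec$markers[[m]][, j]
  }
  write.table(format(out, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a participant metadata table
#'
#' Delimited table with header columns \code{participant_id},
#' \code{group}, \code{sex} and optionally \code{age_months},
#' \code{therapy_history}, \code{severity_score}. Group codes
#' \code{stutter}/\code{CWS} and \code{control}/\code{CWNS} are
#' accepted (case-insensitive), sex codes \code{male}/\code{M} and
#' \code{female}/\code{F}.
#'
#' @param path Path to the delimited text file (tab or comma).
#' @return A data.frame, one row per participant, with \code{group}
#'   normalised to \code{stutter}/\code{control} and \code{sex} to
#'   \code{male}/\code{female} (both factors).
#' @export
read_metadata <- function(path) {
  sep <- detect_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "sex")
  if (!all(need %in% names(tab)))
    stop("format error: metadata requires participant_id, group, sex",
         call. = FALSE)
  if (anyDuplicated(tab$participant_id))
    stop("validation error: duplicate participant_id", call. = FALSE)
  gmap <- c(stutter = "stutter", cws = "stutter",
            control = "control", cwns = "control")
  smap <- c(male = "male", m = "male", boy = "male",
            female = "female", f = "female", girl = "female")
  g <- gmap[tolower(trimws(tab$group))]
  s <- smap[tolower(trimws(tab$sex))]
  if (any(is.na(g)))
    stop(sprintf("validation error: unknown group code '%s'",
                 tab$group[which(is.na(g))[1]]), call. = FALSE)
  if (any(is.na(s)))
    stop(sprintf("validation error: unknown sex code '%s'",
                 tab$sex[which(is.na(s))[1]]), call. = FALSE)
  tab$group <- factor(unname(g), levels = c("stutter", "control"))
  tab$sex <- factor(unname(s), levels = c("male", "female"))
  tab$participant_id <- as.character(tab$participant_id)
  tab
}

#' Write and read back a per-participant results table
#'
#' One row per participant x sentence with the dependent variables
#' produced by the pipeline. Values are written at 6 significant
#' digits, so a write/read cycle round-trips to that precision; missing
#' measures (for example an LA index unavailable below the trial floor)
#' are emitted as the explicit token \code{NA}.
#'
#' @param records Data.frame of kinematic records (see
#'   [run_participant()]).
#' @param path Output path (tab-separated).
#' @return \code{path} invisibly for the writer; the data.frame for the
#'   reader.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame", call. = FALSE)
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), NA_character_, sprintf("%.6g", x)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}
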