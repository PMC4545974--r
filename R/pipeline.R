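#' Default analysis configuration
#'
#' Nested list of every tunable parameter of the pipeline, validated
#' by [validate_config()]. Keys: \code{filter} (Butterworth
#' \code{cutoff_hz} 10, \code{order} 4), \code{segmentation}
#' (\code{prominence_frac} 0.10, bounding peaks \code{first} 1 /
#' \code{last} 5, syllable \code{cycles} map Bob = 2, pup = 4),
#' \code{analysis} (\code{min_trials} 7, \code{max_trials} 10),
#' \code{dynamic_range} (\code{coverage} 0.8, \code{velocity_signed}
#' TRUE), \code{sti} (\code{n_points} 1000, \code{include_zero} FALSE,
#' \code{sd_denominator} "sample"), \code{exclusion} (\code{normative}
#' NULL or a named list of \code{list(mean, sd)} per measure,
#' \code{k_sd} 3), \code{stats} (\code{alpha} 0.05).
#'
#' @param ... Named overrides merged into the defaults, e.g.
#'   \code{default_config(filter = list(cutoff_hz = 8))}.
#' @return Config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    filter = list(cutoff_hz = 10, order = 4),
    segmentation = list(prominence_frac = 0.10, first = 1L, last = 5L,
                        cycles = c(Bob = 2L, pup = 4L)),
    analysis = list(min_trials = 7L, max_trials = 10L),
    dynamic_range = list(coverage = 0.8, velocity_signed = TRUE),
    sti = list(n_points = 1000L, include_zero = FALSE,
               sd_denominator = "sample"),
    exclusion = list(normative = NULL, k_sd = 3),
    stats = list(alpha = 0.05))
  over <- list(...)
  for (top in names(over)) {
    if (!top %in% names(cfg))
      stop(sprintf("unknown config section '%s'", top), call. = FALSE)
    for (key in names(over[[top]])) {
      if (!key %in% names(cfg[[top]]))
        stop(sprintf("unknown config key '%s.%s'", top, key),
             call. = FALSE)
      cfg[[top]][[key]] <- over[[top]][[key]]
    }
  }
  validate_config(cfg)
}

#' @rdname default_config
#' @param config A config list to validate.
#' @export
validate_config <- function(config) {
  with(config, {
    stopifnot(
      filter$cutoff_hz > 0, filter$order >= 1,
      segmentation$prominence_frac > 0,
      segmentation$prominence_frac < 1,
      segmentation$first >= 1,
      segmentation$last > segmentation$first,
      all(segmentation$cycles >= 1),
      analysis$min_trials >= 2,
      analysis$max_trials >= analysis$min_trials,
      dynamic_range$coverage > 0, dynamic_range$coverage < 1,
      sti$n_points >= 100,
      sti$sd_denominator %in% c("sample", "population"),
      exclusion$k_sd > 0,
      stats$alpha > 0, stats$alpha < 1)
  })
  config
}

# One trial through head frame -> filter -> differentiate -> segment.
# Returns an utterance_segment or signals an error naming the stage.
process_trial <- function(rec, config) {
  transforms <- estimate_head_transforms(rec)
  upper <- lowpass(project_lip_trajectory(rec, transforms, "upper_lip"),
                   cutoff = config$filter$cutoff_hz,
                   order = config$filter$order)
  lower <- lowpass(project_lip_trajectory(rec, transforms, "lower_lip"),
                   cutoff = config$filter$cutoff_hz,
                   order = config$filter$order)
  vel <- differentiate(lower)
  segment_utterance(list(upper_lip = upper, lower_lip = lower), vel,
                    first = config$segmentation$first,
                    last = config$segmentation$last,
                    prominence_frac = config$segmentation$prominence_frac)
}

#' Analyse one participant's recordings
#'
#' Runs every trial through head-motion correction, smoothing,
#' differentiation and segmentation, drops trials that fail any stage
#' (recording the reason), and summarises the surviving trials into a
#' kinematic record ([summarize_participant()]). Participants with
#' fewer than \code{analysis$min_trials} valid trials yield a dropped
#' record with reason \code{"insufficient trials"}; at most the first
#' \code{analysis$max_trials} valid trials are used.
#'
#' @param recordings List of [marker_recording()] objects (the
#'   candidate repetitions, in recording order).
#' @param participant_id,sentence_id Identifiers for the output.
#' @param config See [default_config()].
#' @return List with \code{record} (one-row kinematic record, or NULL
#'   when dropped), \code{qc} (data.frame, one row per input trial:
#'   \code{trial_id}, \code{status}, \code{reason}), \code{dropped}
#'   (logical), \code{drop_reason}.
#' @export
run_participant <- function(recordings, participant_id,
                            sentence_id = "sentence",
                            config = default_config()) {
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  segs <- list(); qc <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    tid <- if (inherits(rec, "marker_recording")) rec$trial_id else
      as.character(i)
    res <- tryCatch(process_trial(rec, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      qc[[i]] <- data.frame(trial_id = tid, status = "dropped",
                            reason = conditionMessage(res),
                            stringsAsFactors = FALSE)
    } else {
      keep <- length(segs) < config$analysis$max_trials
      segs[[length(segs) + 1L]] <- res
      qc[[i]] <- data.frame(
        trial_id = tid,
        status = if (keep) "used" else "valid_unused",
        reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  qc <- do.call(rbind, qc)
  n_valid <- sum(qc$status == "used")
  if (n_valid < config$analysis$min_trials) {
    return(list(record = NULL, qc = qc, dropped = TRUE,
                drop_reason = sprintf(
                  "insufficient trials (%d < %d)", n_valid,
                  config$analysis$min_trials)))
  }
  ts <- trial_set(participant_id, sentence_id,
                  segs[seq_len(min(length(segs),
                                   config$analysis$max_trials))])
  rec <- summarize_participant(ts, config)
  list(record = rec, qc = qc, dropped = FALSE, drop_reason = NA)
}

#' Analyse a cohort and run the group statistics
#'
#' Applies [run_participant()] to every participant in the metadata,
#' assembles the per-participant results table, screens it with the
#' normative exclusion rule (if configured), summarises each dependent
#' variable by group x sex, and runs the statistical workflow per
#' measure: Levene's variance-homogeneity test across the four cells,
#' a 2 x 2 between-subject ANOVA (stuttering group x sex, Type III),
#' and Tukey-Kramer post hocs across the cells. Every participant in
#' \code{meta} appears either in \code{records} or in \code{dropped}.
#' The analysis contains no randomness: identical inputs and config
#' give identical results.
#'
#' @param recordings Named list (participant_id -> list of
#'   [marker_recording()]s).
#' @param meta Metadata data.frame as from [read_metadata()].
#' @param sentence_id Sentence label for the output records.
#' @param config See [default_config()].
#' @param measures Dependent variables to test (default the three
#'   phrase-level measures plus the LA index).
#' @return Object of class \code{"cohort_result"}: list with
#'   \code{records} (data.frame), \code{dropped} (data.frame
#'   \code{participant_id}, \code{reason}), \code{group_summary}
#'   (mean/SD per group x sex x measure), \code{levene},
#'   \code{anova}, \code{posthoc} (named lists per measure),
#'   \code{qc}, \code{config}.
#' @export
run_cohort <- function(recordings, meta, sentence_id = "sentence",
                       config = default_config(),
                       measures = c("displacement_dynamic_range",
                                    "velocity_dynamic_range",
                                    "sentence_duration", "la_index")) {
  stopifnot(is.data.frame(meta),
            all(c("participant_id", "group", "sex") %in% names(meta)))
  missing_rec <- setdiff(meta$participant_id, names(recordings))
  records <- list(); dropped <- list(); qc <- list()
  for (pid in meta$participant_id) {
    if (pid %in% missing_rec) {
      dropped[[pid]] <- data.frame(participant_id = pid,
                                   reason = "no recordings",
                                   stringsAsFactors = FALSE)
      next
    }
    out <- run_participant(recordings[[pid]], pid, sentence_id, config)
    qc[[pid]] <- cbind(participant_id = pid, out$qc)
    if (out$dropped) {
      dropped[[pid]] <- data.frame(participant_id = pid,
                                   reason = out$drop_reason,
                                   stringsAsFactors = FALSE)
    } else records[[pid]] <- out$record
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  if (!is.null(records)) {
    rownames(records) <- NULL
    # normative screen applied by summarize_participant; move excluded
    excl <- records$excluded
    if (any(excl)) {
      for (pid in records$participant_id[excl])
        dropped[[pid]] <- data.frame(
          participant_id = pid,
          reason = records$exclude_reason[records$participant_id == pid],
          stringsAsFactors = FALSE)
      records <- records[!excl, ]
    }
    records <- merge(records, meta[, c("participant_id", "group", "sex")],
                     by = "participant_id", sort = TRUE)
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(participant_id = character(), reason = character())
  rownames(dropped) <- NULL

  group_summary <- NULL; lev <- an <- ph <- list()
  cells_ok <- !is.null(records) &&
    all(table(records$group, records$sex) >= 2L)
  if (cells_ok) {
    cell <- interaction(records$group, records$sex, sep = "-")
    measures <- intersect(measures, names(records))
    group_summary <- do.call(rbind, lapply(measures, function(m)
      data.frame(measure = m,
                 cell = levels(cell),
                 mean = as.numeric(tapply(records[[m]], cell, mean)),
                 sd = as.numeric(tapply(records[[m]], cell, sd)),
                 n = as.numeric(table(cell)),
                 stringsAsFactors = FALSE)))
    for (m in measures) {
      lev[[m]] <- levene_test(records[[m]], cell)
      an[[m]] <- mixed_anova(records, dv = m,
                             between = c("group", "sex"),
                             subject = "participant_id")
      ph[[m]] <- tukey_kramer(records[[m]], cell)
    }
  } else if (!is.null(records)) {
    message("run_cohort: empty or size-1 design cell; group statistics skipped")
  }
  structure(
    list(records = records, dropped = dropped,
         group_summary = group_summary,
         levene = lev, anova = an, posthoc = ph,
         qc = if (length(qc)) do.call(rbind, c(qc, make.row.names = FALSE))
              else NULL,
         config = config),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d analysed participant(s), %d dropped\n",
              if (is.null(x$records)) 0L else nrow(x$records),
              nrow(x$dropped)))
  if (!is.null(x$group_summary)) {
    cat("\nGroup means (SD):\n")
    gs <- x$group_summary
    for (m in unique(gs$measure)) {
      sub <- gs[gs$measure == m, ]
      cat(sprintf("  %s: %s\n", m,
                  paste(sprintf("%s %.3g (%.2g)", sub$cell, sub$mean,
                                sub$sd), collapse = ", ")))
    }
    alpha <- x$config$stats$alpha
    cat("\nGroup x sex ANOVA interactions:\n")
    for (m in names(x$anova)) {
      a <- x$anova[[m]]
      row <- a[a$effect == "group:sex", ]
      cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.3f%s\n", m,
                  row$df_num, row$df_den, row$F, row$p,
                  if (row$p < alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' @export
summary.cohort_result <- function(object, ...) {
  print(object)
  if (length(object$posthoc)) {
    cat("\nPost hoc (Tukey-Kramer) tables:\n")
    for (m in names(object$posthoc)) {
      cat(sprintf("\n-- %s --\n", m))
      print(object$posthoc[[m]])
    }
  }
  invisible(object)
}

#' JSON group summary of a cohort result
#'
#' Writes the per-cell means/SDs and the ANOVA tables to a JSON file
#' (machine-readable companion to the results TSV).
#'
#' @param result A [run_cohort()] result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_group_summary <- function(result, path) {
  stopifnot(inherits(result, "cohort_result"))
  payload <- list(
    group_summary = result$group_summary,
    anova = lapply(result$anova, as.data.frame),
    levene = result$levene,
    dropped = result$dropped)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
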