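# Trial segmentation, quality control and the two dependent measures:
# latency to orient to the eyes ROI after array onset, and first-pass dwell
# (total fixation time in the eyes ROI from first entry to first exit).

#' Trial quality-control parameters
#'
#' The four inclusion rules: a trial is excluded when (a) the first fixation
#' at target starts sooner than `anticipatory_ms` after onset (anticipatory
#' look, initiated before the stimulus could drive it), (b) fewer than
#' `validity_min` of its raw samples have both-eyes validity codes 0-1,
#' (c) gaze was at the screen-center rectangle for less than `baseline_min`
#' of the baseline interval, or (d) no fixation ever lands in the target ROI.
#' `contrast_eligibility` is the per-condition valid-trial fraction a
#' participant needs to enter the cued/silent contrast.
#'
#' @param anticipatory_ms Anticipation cutoff in ms (default 100).
#' @param validity_min Minimum both-eyes valid-sample fraction (default 0.33).
#' @param baseline_min Minimum baseline center-gaze fraction (default 0.5).
#' @param contrast_eligibility Minimum per-condition valid-trial fraction for
#'   the cued/silent contrast (default 0.5).
#' @param roi_membership `"centroid"` (default): a fixation belongs to an ROI
#'   iff its centroid does; `"samples"`: iff a majority of its member samples
#'   do (sensitivity variant).
#' @return A `qc_params` list.
#' @export
qc_params <- function(anticipatory_ms = 100,
                      validity_min = 0.33,
                      baseline_min = 0.5,
                      contrast_eligibility = 0.5,
                      roi_membership = c("centroid", "samples")) {
  roi_membership <- match.arg(roi_membership)
  stopifnot(
    anticipatory_ms > 0,
    validity_min >= 0, validity_min <= 1,
    baseline_min >= 0, baseline_min <= 1,
    contrast_eligibility >= 0, contrast_eligibility <= 1
  )
  structure(
    list(
      anticipatory_ms = anticipatory_ms,
      validity_min = validity_min,
      baseline_min = baseline_min,
      contrast_eligibility = contrast_eligibility,
      roi_membership = roi_membership
    ),
    class = "qc_params"
  )
}

#' Segment a recording into trial records
#'
#' Each trial record holds the raw samples with `onset <= t < offset`, the
#' baseline-interval samples (`baseline_start <= t < baseline_end`), and the
#' recording-level fixations that overlap the stimulus window, with start and
#' end clipped to the window for within-trial duration accounting (the
#' unclipped interval is retained).
#'
#' @param samples A gaze-sample tibble for one recording.
#' @param trial_log A trial-log tibble (see [read_trial_log()]).
#' @param points Optional cyclopean points for the same recording.
#' @param fixations Optional fixation tibble from [detect_fixations()].
#' @return A list of `trial_record` objects, ordered by onset.
#' @export
segment_trials <- function(samples, trial_log, points = NULL,
                           fixations = NULL) {
  trial_log <- dplyr::arrange(trial_log, .data$onset_ms)
  lapply(seq_len(nrow(trial_log)), function(i) {
    info <- as.list(trial_log[i, ])
    # timestamps are strictly increasing, so window membership is an index
    # range (half-open intervals on both windows)
    in_trial <- interval_indices(samples$t_ms, info$onset_ms, info$offset_ms)
    in_base <- interval_indices(samples$t_ms, info$baseline_start_ms,
                                info$baseline_end_ms)
    fx <- NULL
    if (!is.null(fixations)) {
      keep <- which(fixations$start_ms < info$offset_ms &
                      fixations$end_ms > info$onset_ms)
      fx <- subset_rows(fixations, keep)
      fx$start_clipped_ms <- pmax(fx$start_ms, info$onset_ms)
      fx$end_clipped_ms <- pmin(fx$end_ms, info$offset_ms)
      fx$duration_in_trial_ms <- fx$end_clipped_ms - fx$start_clipped_ms
    }
    structure(
      list(
        info = info,
        samples = subset_rows(samples, in_trial),
        baseline_samples = subset_rows(samples, in_base),
        points = if (!is.null(points)) {
          subset_rows(points, interval_indices(points$t_ms, info$onset_ms,
                                               info$offset_ms))
        },
        fixations = fx
      ),
      class = "trial_record"
    )
  })
}

# fast positional row subset of a tibble (no tibble dispatch)
subset_rows <- function(df, idx) {
  tibble::new_tibble(lapply(unclass(df), `[`, idx), nrow = length(idx))
}

# indices i with lo <= t[i] < hi, for strictly increasing t
interval_indices <- function(t, lo, hi) {
  i0 <- findInterval(lo - 1e-9, t) + 1L
  i1 <- findInterval(hi - 1e-9, t)
  if (i0 > i1) integer() else i0:i1
}

#' Both-eyes sample validity fraction of a trial
#'
#' Fraction of the trial's raw samples whose left and right validity codes are
#' both 0 or 1 (reliably tracked). A trial with no samples at all has
#' fraction 0.
#'
#' @param trial A `trial_record`.
#' @return A fraction in `[0, 1]`.
#' @export
validity_fraction <- function(trial) {
  s <- trial$samples
  if (nrow(s) == 0L) return(0)
  mean(s$left_validity <= 1L & s$right_validity <= 1L)
}

#' Baseline center-gaze fraction of a trial
#'
#' Fraction of baseline-interval samples whose cyclopean point lies in the
#' center rectangle. Missing samples count against the fraction (a
#' conservative reading of the attention check). An empty baseline interval
#' yields `NA`, which the QC step treats as a failure.
#'
#' @param trial A `trial_record`.
#' @param center_rect The center ROI rectangle for the trial's array.
#' @return A fraction in `[0, 1]`, or `NA` if there are no baseline samples.
#' @export
baseline_center_fraction <- function(trial, center_rect) {
  s <- trial$baseline_samples
  if (nrow(s) == 0L) return(NA_real_)
  p <- combine_eyes(s)
  mean(point_in_roi(p$x, p$y, center_rect))
}

# ROI membership of fixations: by centroid (default) or by per-sample
# majority over the fixation's member samples.
fixation_in_rect <- function(fx, rect, trial = NULL,
                             roi_membership = "centroid") {
  if (roi_membership == "centroid" || is.null(trial$points)) {
    return(point_in_roi(fx$centroid_x, fx$centroid_y, rect))
  }
  vapply(seq_len(nrow(fx)), function(i) {
    p <- trial$points
    m <- p$t_ms >= fx$start_ms[i] & p$t_ms <= fx$end_ms[i]
    if (!any(m)) return(FALSE)
    mean(point_in_roi(p$x[m], p$y[m], rect)) > 0.5
  }, logical(1))
}

#' Latency to the first fixation on the target (eyes) ROI
#'
#' Scans the trial's fixations in time order for the first whose centroid
#' falls in the eyes ROI; latency is that fixation's (clipped) start minus
#' array onset. Latencies below the anticipation cutoff flag the trial
#' `anticipatory`; absence of any target fixation flags `no_target_fixation`.
#'
#' @param trial A `trial_record` with fixations attached.
#' @param roi_set The ROI set (the eyes rectangle of the trial's array is
#'   used).
#' @param qc A [qc_params()] list.
#' @return A list: `latency_ms` (or `NA`), `anticipatory`,
#'   `no_target_fixation`, and `first_index` (row of the first target
#'   fixation in the trial's fixation table, or `NA`).
#' @export
latency_to_target <- function(trial, roi_set, qc = qc_params()) {
  eyes <- roi_rect(roi_set, trial$info$array_id, "eyes")
  fx <- trial$fixations
  if (is.null(fx) || nrow(fx) == 0L) {
    return(list(latency_ms = NA_real_, anticipatory = FALSE,
                no_target_fixation = TRUE, first_index = NA_integer_))
  }
  fx <- subset_rows(fx, order(fx$start_clipped_ms))
  in_eyes <- fixation_in_rect(fx, eyes, trial, qc$roi_membership)
  hit <- which(in_eyes)
  if (!length(hit)) {
    return(list(latency_ms = NA_real_, anticipatory = FALSE,
                no_target_fixation = TRUE, first_index = NA_integer_))
  }
  first <- hit[1L]
  latency <- fx$start_clipped_ms[first] - trial$info$onset_ms
  list(
    latency_ms = latency,
    anticipatory = latency < qc$anticipatory_ms,
    no_target_fixation = FALSE,
    first_index = first
  )
}

#' First-pass dwell time in the target ROI
#'
#' Starting at the first target fixation, sums the within-trial durations of
#' the maximal run of consecutive fixations whose centroids stay in the eyes
#' ROI; the run ends at the first fixation outside the ROI or at trial offset
#' (durations are clipped there). Gaps between fixations (saccade time) are
#' not counted.
#'
#' @inheritParams latency_to_target
#' @return Dwell in ms, or `NA` when the trial has no target fixation.
#' @export
first_pass_dwell <- function(trial, roi_set, qc = qc_params()) {
  eyes <- roi_rect(roi_set, trial$info$array_id, "eyes")
  fx <- trial$fixations
  if (is.null(fx) || nrow(fx) == 0L) return(NA_real_)
  fx <- subset_rows(fx, order(fx$start_clipped_ms))
  in_eyes <- fixation_in_rect(fx, eyes, trial, qc$roi_membership)
  hit <- which(in_eyes)
  if (!length(hit)) return(NA_real_)
  first <- hit[1L]
  run_end <- first
  while (run_end + 1L <= nrow(fx) && in_eyes[run_end + 1L]) {
    run_end <- run_end + 1L
  }
  sum(fx$duration_in_trial_ms[first:run_end])
}

#' Apply quality control and compute the dependent measures for one trial
#'
#' Applies the inclusion rules of [qc_params()] and, for included trials,
#' reports latency to the eyes and first-pass dwell. Excluded trials carry at
#' least one reason code (`anticipatory`, `low_validity`, `baseline_fail`,
#' `no_target_fixation`) and `NA` measures. `valid_for_contrast` records
#' whether the trial passes the three data-quality rules (a trial whose only
#' defect is never fixating the target still counts as a valid recording for
#' the contrast-eligibility accounting).
#'
#' @param trial A `trial_record`.
#' @param roi_set The ROI set.
#' @param qc A [qc_params()] list.
#' @return A one-row tibble of per-trial metrics.
#' @export
compute_trial_metrics <- function(trial, roi_set, qc = qc_params()) {
  info <- trial$info
  center <- roi_rect(roi_set, info$array_id, "center")
  vfrac <- validity_fraction(trial)
  bfrac <- baseline_center_fraction(trial, center)
  lat <- latency_to_target(trial, roi_set, qc)

  reasons <- character()
  if (nrow(trial$samples) == 0L || vfrac < qc$validity_min) {
    reasons <- c(reasons, "low_validity")
  }
  if (is.na(bfrac) || bfrac < qc$baseline_min) {
    reasons <- c(reasons, "baseline_fail")
  }
  if (lat$anticipatory) reasons <- c(reasons, "anticipatory")
  if (lat$no_target_fixation) reasons <- c(reasons, "no_target_fixation")

  included <- length(reasons) == 0L
  latency <- if (included) lat$latency_ms else NA_real_
  dwell <- if (included && !is.na(lat$latency_ms)) {
    first_pass_dwell(trial, roi_set, qc)
  } else {
    NA_real_
  }

  tibble::new_tibble(list(
    trial_id = info$trial_id,
    array_id = info$array_id,
    condition = info$condition,
    condition_class = if (info$condition == "silent") "silent" else "cued",
    n_samples = nrow(trial$samples),
    validity_fraction = vfrac,
    baseline_fraction = bfrac,
    qc_status = if (included) "included" else "excluded",
    qc_reasons = paste(reasons, collapse = ";"),
    valid_for_contrast =
      !any(reasons %in% c("anticipatory", "low_validity", "baseline_fail")),
    latency_to_eyes_ms = latency,
    first_pass_dwell_ms = dwell
  ), nrow = 1L)
}

#' Score one participant's recording
#'
#' The full per-recording pipeline: cyclopean combination, gap interpolation,
#' fixation detection over the whole recording, trial segmentation, QC and
#' the two dependent measures per trial.
#'
#' @param samples A gaze-sample tibble for one recording.
#' @param trial_log A trial-log tibble.
#' @param roi_set The ROI set.
#' @param participant_id Identifier copied into the output.
#' @param filter A [filter_params()] list.
#' @param qc A [qc_params()] list.
#' @return A tibble of per-trial metrics, one row per trial.
#' @export
score_recording <- function(samples, trial_log, roi_set,
                            participant_id = NA_character_,
                            filter = filter_params(), qc = qc_params()) {
  points <- interpolate_gaps(combine_eyes(samples), filter$max_gap_interp_ms)
  fixations <- detect_fixations(points, filter)
  records <- segment_trials(samples, trial_log, points, fixations)
  metrics <- dplyr::bind_rows(
    lapply(records, compute_trial_metrics, roi_set = roi_set, qc = qc)
  )
  dplyr::bind_cols(
    tibble::new_tibble(
      list(participant_id = rep(participant_id, nrow(metrics))),
      nrow = nrow(metrics)
    ),
    metrics
  )
}

#' Summarise a participant's trial metrics
#'
#' Means of both measures over included trials, overall and split by cue
#' condition (silent vs cued), with valid-trial fractions and eligibility for
#' the cued/silent contrast (at least `contrast_eligibility` valid trials in
#' each condition). Means use only included trials on which the measure is
#' present.
#'
#' @param trial_metrics Per-trial metrics from [score_recording()].
#' @param qc A [qc_params()] list.
#' @return A one-row tibble.
#' @export
summarize_participant <- function(trial_metrics, qc = qc_params()) {
  m <- trial_metrics
  inc <- m[m$qc_status == "included", , drop = FALSE]
  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  cond_mean <- function(data, cls, col) {
    mean_or_na(data[[col]][data$condition_class == cls])
  }
  frac_valid <- function(cls) {
    sel <- m$condition_class == cls
    if (!any(sel)) return(NA_real_)
    mean(m$valid_for_contrast[sel])
  }
  vs <- frac_valid("silent")
  vc <- frac_valid("cued")
  tibble::tibble(
    participant_id = m$participant_id[1L],
    n_trials = nrow(m),
    n_included = nrow(inc),
    mean_latency_ms = mean_or_na(inc$latency_to_eyes_ms),
    mean_dwell_ms = mean_or_na(inc$first_pass_dwell_ms),
    mean_latency_silent_ms = cond_mean(inc, "silent", "latency_to_eyes_ms"),
    mean_latency_cued_ms = cond_mean(inc, "cued", "latency_to_eyes_ms"),
    mean_dwell_silent_ms = cond_mean(inc, "silent", "first_pass_dwell_ms"),
    mean_dwell_cued_ms = cond_mean(inc, "cued", "first_pass_dwell_ms"),
    valid_fraction_silent = vs,
    valid_fraction_cued = vc,
    contrast_eligible = !is.na(vs) && !is.na(vc) &&
      vs >= qc$contrast_eligibility && vc >= qc$contrast_eligibility
  )
}

#' Summarise every participant of a cohort
#' @param trial_metrics Row-bound per-trial metrics for several participants.
#' @param qc A [qc_params()] list.
#' @return A tibble, one row per participant. Participants with no included
#'   trials are retained with `NA` means and noted in a message.
#' @export
summarize_cohort <- function(trial_metrics, qc = qc_params()) {
  parts <- split(trial_metrics, trial_metrics$participant_id)
  out <- purrr::map_dfr(parts, summarize_participant, qc = qc)
  dropped <- out$participant_id[out$n_included == 0L]
  if (length(dropped)) {
    message("participant(s) with no included trials: ",
            paste(dropped, collapse = ", "))
  }
  out
}

#' Write per-trial metrics and participant summaries
#' @param trial_metrics Per-trial metrics tibble.
#' @param path Output CSV path.
#' @export
write_trial_metrics <- function(trial_metrics, path) {
  readr::write_csv(trial_metrics, path, progress = FALSE)
  invisible(path)
}
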