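# Fixture builders shared across tests. All fixtures are generated in code;
# gaze streams are built on the exact 120 Hz sample grid used by the package.

PERIOD <- 1000 / 120

# A cyclopean point tibble from x/y vectors on the 120 Hz grid.
make_points <- function(x, y = x, t0 = 0) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  tibble::tibble(
    t_ms = t0 + (seq_len(n) - 1) * PERIOD,
    x = x, y = y,
    interpolated = rep(FALSE, n)
  )
}

# A binocular sample tibble with both eyes at the cyclopean position and
# validity 0; positions NA + validity 4 where `missing` is TRUE.
make_samples <- function(x, y = x, missing = FALSE, t0 = 0) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  missing <- rep_len(missing, n)
  x[missing] <- NA; y[missing] <- NA
  v <- ifelse(missing, 4L, 0L)
  tibble::tibble(
    t_ms = t0 + (seq_len(n) - 1) * PERIOD,
    left_x = x - 10, left_y = y, left_validity = v,
    right_x = x + 10, right_y = y, right_validity = v
  )
}

# A step stream: n1 samples at (x1, y1), then n2 at (x2, y2).
make_step_points <- function(n1, n2, x1, y1, x2, y2) {
  make_points(c(rep(x1, n1), rep(x2, n2)), c(rep(y1, n1), rep(y2, n2)))
}

# Random plateau stream: k plateaus of random length and position; returns
# the points plus the planted change-point indices.
make_random_plateaus <- function(k = 4, len_range = c(20, 60),
                                 pos_range = c(100, 900)) {
  lens <- sample(seq(len_range[1], len_range[2]), k, replace = TRUE)
  xs <- runif(k, pos_range[1], pos_range[2])
  ys <- runif(k, pos_range[1], pos_range[2])
  pts <- make_points(rep(xs, lens), rep(ys, lens))
  list(points = pts, change_points = cumsum(lens)[-k] + 1L, lens = lens)
}

# A hand-made trial_record (only the fields the op under test uses).
make_trial_record <- function(info = NULL, samples = NULL,
                              baseline_samples = NULL, fixations = NULL,
                              points = NULL) {
  structure(
    list(info = info, samples = samples,
         baseline_samples = baseline_samples,
         points = points, fixations = fixations),
    class = "trial_record"
  )
}

# Fixation rows for direct metric tests.
make_fixations <- function(start, end, cx, cy, onset = 0, offset = Inf) {
  tibble::tibble(
    start_ms = start, end_ms = end, duration_ms = end - start,
    centroid_x = cx, centroid_y = cy,
    n_samples = as.integer(round((end - start) / PERIOD)),
    mean_validity_fraction = 1,
    start_clipped_ms = pmax(start, onset),
    end_clipped_ms = pmin(end, offset),
    duration_in_trial_ms = pmin(end, offset) - pmax(start, onset)
  )
}

# ---------------------------------------------------------------------------
# The 12-trial QC fixture: three trials of each kind, each violating exactly
# one inclusion rule (or none):
#   clean          included, latency ~400 ms, dwell ~500 ms
#   anticipatory   first target fixation planted 80 ms after onset
#   low_validity   only 30% of stimulus samples tracked
#   baseline_fail  gaze at center for only 40% of the baseline interval
# Gaze steps are instantaneous (no saccade ramps) so planted times are sharp.
build_qc_fixture <- function() {
  roi_set <- default_roi_set()
  trial_len <- 6500
  onset_rel <- 1500
  array_ms <- 5000
  types <- rep(c("clean", "anticipatory", "low_validity", "baseline_fail"), 3)
  k <- seq_along(types)
  onset <- (k - 1) * trial_len + onset_rel
  trial_log <- tibble::tibble(
    trial_id = as.integer(k),
    array_id = as.integer(((k - 1) %% 12) + 1),
    onset_ms = onset,
    offset_ms = onset + array_ms,
    condition = rep(c("silent", "phoneme", "beep"), 4),
    baseline_start_ms = onset - 500,
    baseline_end_ms = onset
  )

  centers <- function(a, label) {
    r <- roi_rect(roi_set, a, label)
    c(r$x0 + r$width / 2, r$y0 + r$height / 2)
  }

  n_total <- round(12 * trial_len / PERIOD)
  t <- (seq_len(n_total) - 1) * PERIOD
  x <- numeric(n_total); y <- numeric(n_total)
  miss <- logical(n_total)

  for (i in k) {
    a <- trial_log$array_id[i]
    eyes <- centers(a, "eyes")
    d1 <- centers(a, "distractor_1")
    ctr <- centers(a, "center")
    u <- t - trial_log$onset_ms[i]          # trial-relative time
    in_tr <- u >= -onset_rel & u < array_ms
    seg <- function(lo, hi) in_tr & u >= lo & u < hi

    at <- function(sel, pos) {
      x[sel] <<- pos[1]; y[sel] <<- pos[2]
    }
    at(seg(-onset_rel, 0), ctr)             # animation + baseline at center
    switch(types[i],
      clean = {
        at(seg(0, 400), ctr)
        at(seg(400, 900), eyes)
        at(seg(900, array_ms), d1)
      },
      anticipatory = {
        at(seg(0, 80), ctr)
        at(seg(80, 580), eyes)
        at(seg(580, array_ms), d1)
      },
      low_validity = {
        at(seg(0, 400), ctr)
        at(seg(400, 1400), eyes)
        at(seg(1400, 1500), d1)
        miss[seg(1500, array_ms)] <- TRUE   # 70% of stimulus samples lost
      },
      baseline_fail = {
        at(seg(-500, -300), ctr)            # only 40% of baseline at center
        at(seg(-300, 0), d1)
        at(seg(0, 400), ctr)
        at(seg(400, 900), eyes)
        at(seg(900, array_ms), d1)
      }
    )
  }

  samples <- make_samples(x, y, missing = miss)
  expected <- tibble::tibble(
    trial_id = trial_log$trial_id,
    type = types,
    qc_status = ifelse(types == "clean", "included", "excluded"),
    qc_reasons = dplyr::case_match(types,
      "clean" ~ "", "anticipatory" ~ "anticipatory",
      "low_validity" ~ "low_validity", "baseline_fail" ~ "baseline_fail"
    )
  )
  list(samples = samples, trial_log = trial_log, roi_set = roi_set,
       expected = expected)
}
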