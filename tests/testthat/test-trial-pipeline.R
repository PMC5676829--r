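test_that("segmentation assigns the scheduled sample counts, half-open", {
  p <- cohort_params(n_participants = 2, missingness_rate = 0, seed = 8)
  co <- simulate_cohort(p)
  recs <- segment_trials(co$streams[[1]], co$trial_log)
  expect_length(recs, 12)
  for (r in recs) {
    # 5000 ms stimulus window at 120 Hz = 600 samples; 500 ms baseline = 60
    expect_equal(nrow(r$samples), 600)
    expect_equal(nrow(r$baseline_samples), 60)
    expect_true(all(r$samples$t_ms >= r$info$onset_ms))
    expect_true(all(r$samples$t_ms < r$info$offset_ms))   # offset excluded
  }
  # a sample exactly at offset belongs to no trial window, although the
  # stream contains one at that time
  off <- co$trial_log$offset_ms[1]
  expect_false(any(abs(recs[[1]]$samples$t_ms - off) < 1e-6))
  expect_true(any(abs(co$streams[[1]]$t_ms - off) < 1e-6))
})

test_that("a trial absent from the stream is excluded as low_validity", {
  p <- cohort_params(n_participants = 2, seed = 8)
  co <- simulate_cohort(p)
  log2 <- co$trial_log
  shift <- max(co$streams[[1]]$t_ms) + 10000
  log2$onset_ms[12] <- shift + 1500
  log2$offset_ms[12] <- shift + 6500
  log2$baseline_start_ms[12] <- shift + 1000
  log2$baseline_end_ms[12] <- shift + 1500
  m <- score_recording(co$streams[[1]], log2, co$roi_set, "P001")
  expect_equal(m$qc_status[12], "excluded")
  expect_match(m$qc_reasons[12], "low_validity")
  expect_equal(m$n_samples[12], 0)
})

test_that("validity fraction counts both-eyes-tracked samples; 33% is retained", {
  s <- make_samples(x = rep(500, 120), missing = c(rep(TRUE, 80), rep(FALSE, 40)))
  rec <- make_trial_record(samples = s)
  expect_equal(validity_fraction(rec), 40 / 120)
  # exactly 1/3 is not below the 33% rule under the default threshold
  expect_false(40 / 120 < qc_params()$validity_min)
  s2 <- make_samples(x = rep(500, 120))
  expect_equal(validity_fraction(make_trial_record(samples = s2)), 1)
  # one bad eye disqualifies the sample
  s3 <- s2
  s3$left_validity[1:30] <- 2L
  expect_equal(validity_fraction(make_trial_record(samples = s3)), 0.75)
})

test_that("baseline center fraction counts missing samples against the check", {
  roi <- default_roi_set()
  ctr <- roi_rect(roi, 1, "center")
  at_center <- make_samples(x = rep(640, 60), y = rep(512, 60))
  rec <- make_trial_record(baseline_samples = at_center)
  expect_equal(baseline_center_fraction(rec, ctr), 1)

  half <- make_samples(
    x = c(rep(640, 30), rep(320, 30)),
    y = c(rep(512, 30), rep(256, 30))
  )
  expect_equal(baseline_center_fraction(make_trial_record(baseline_samples = half), ctr), 0.5)
  expect_false(0.5 < qc_params()$baseline_min)  # boundary: retained

  gone <- make_samples(x = rep(640, 60), y = rep(512, 60),
                       missing = c(rep(TRUE, 40), rep(FALSE, 20)))
  expect_equal(baseline_center_fraction(make_trial_record(baseline_samples = gone), ctr), 1 / 3)
  empty <- make_trial_record(baseline_samples = make_samples(numeric(0)))
  expect_true(is.na(baseline_center_fraction(empty, ctr)))
})

test_that("latency to target flags anticipation and absent target fixations", {
  roi <- default_roi_set()
  eyes <- roi_rect(roi, 1, "eyes")
  ec <- c(eyes$x0 + eyes$width / 2, eyes$y0 + eyes$height / 2)
  info <- list(trial_id = 1L, array_id = 1L, onset_ms = 1500,
               offset_ms = 6500)

  fx <- make_fixations(
    start = c(0, 1900, 2400), end = c(1880, 2300, 3000),
    cx = c(640, ec[1], 960), cy = c(512, ec[2], 768),
    onset = 1500, offset = 6500
  )
  lat <- latency_to_target(make_trial_record(info = info, fixations = fx), roi)
  expect_equal(lat$latency_ms, 400)
  expect_false(lat$anticipatory)
  expect_false(lat$no_target_fixation)

  fx80 <- make_fixations(
    start = c(0, 1580), end = c(1560, 2100),
    cx = c(640, ec[1]), cy = c(512, ec[2]), onset = 1500, offset = 6500
  )
  lat80 <- latency_to_target(make_trial_record(info = info, fixations = fx80), roi)
  expect_equal(lat80$latency_ms, 80)
  expect_true(lat80$anticipatory)

  fxd <- make_fixations(
    start = c(1600, 2100), end = c(2000, 2600),
    cx = c(960, 320), cy = c(768, 768), onset = 1500, offset = 6500
  )
  latd <- latency_to_target(make_trial_record(info = info, fixations = fxd), roi)
  expect_true(is.na(latd$latency_ms))
  expect_true(latd$no_target_fixation)
})

test_that("first-pass dwell sums the run of in-ROI fixations, gaps excluded", {
  roi <- default_roi_set()
  eyes <- roi_rect(roi, 1, "eyes")
  ec <- c(eyes$x0 + eyes$width / 2, eyes$y0 + eyes$height / 2)
  info <- list(trial_id = 1L, array_id = 1L, onset_ms = 1500,
               offset_ms = 6500)
  rec <- function(fx) make_trial_record(info = info, fixations = fx)

  # one 350 ms target fixation, then a distractor
  fx1 <- make_fixations(
    start = c(1900, 2300), end = c(2250, 2800),
    cx = c(ec[1], 960), cy = c(ec[2], 768), onset = 1500, offset = 6500
  )
  expect_equal(first_pass_dwell(rec(fx1), roi), 350)

  # two consecutive target fixations 200 + 150 ms with a 30 ms gap, then exit:
  # dwell is the sum of fixation time, not the elapsed span
  fx2 <- make_fixations(
    start = c(1900, 2130, 2400), end = c(2100, 2280, 2900),
    cx = c(ec[1], ec[1] + 5, 960), cy = c(ec[2], ec[2], 768),
    onset = 1500, offset = 6500
  )
  expect_equal(first_pass_dwell(rec(fx2), roi), 350)

  # target fixation running past trial offset is clipped there
  fx3 <- make_fixations(
    start = 6200, end = 7000, cx = ec[1], cy = ec[2],
    onset = 1500, offset = 6500
  )
  expect_equal(first_pass_dwell(rec(fx3), roi), 300)

  # a return to the eyes after leaving does not extend the first pass
  fx4 <- make_fixations(
    start = c(1900, 2300, 2900), end = c(2250, 2800, 3400),
    cx = c(ec[1], 960, ec[1]), cy = c(ec[2], 768, ec[2]),
    onset = 1500, offset = 6500
  )
  expect_equal(first_pass_dwell(rec(fx4), roi), 350)
})

test_that("participant summaries average included trials and apply eligibility", {
  base <- tibble::tibble(
    participant_id = "P001",
    trial_id = 1:12,
    array_id = 1:12,
    condition = c(rep("silent", 4), rep("phoneme", 4), rep("beep", 4)),
    condition_class = c(rep("silent", 4), rep("cued", 8)),
    n_samples = 600L,
    validity_fraction = 1,
    baseline_fraction = 1,
    qc_status = "included",
    qc_reasons = "",
    valid_for_contrast = TRUE,
    latency_to_eyes_ms = NA_real_,
    first_pass_dwell_ms = NA_real_
  )
  m <- base
  m$latency_to_eyes_ms[1:3] <- c(400, 500, 600)
  m$first_pass_dwell_ms[1:3] <- c(300, 400, 500)
  s <- summarize_participant(m)
  expect_equal(s$mean_latency_ms, 500)
  expect_equal(s$mean_dwell_ms, 400)
  expect_equal(s$n_included, 12)
  expect_true(s$contrast_eligible)

  # 3/4 silent valid but only 2/8 cued valid: not eligible for the contrast
  m2 <- base
  m2$valid_for_contrast <- c(TRUE, TRUE, TRUE, FALSE,
                             TRUE, TRUE, rep(FALSE, 6))
  m2$qc_status[!m2$valid_for_contrast] <- "excluded"
  m2$qc_reasons[!m2$valid_for_contrast] <- "low_validity"
  s2 <- summarize_participant(m2)
  expect_equal(s2$valid_fraction_silent, 0.75)
  expect_equal(s2$valid_fraction_cued, 0.25)
  expect_false(s2$contrast_eligible)

  # filter/summarize commute: dropping excluded rows leaves the means alone
  s3 <- summarize_participant(m2[m2$qc_status == "included", ])
  expect_equal(s3$mean_latency_ms, s2$mean_latency_ms)
  expect_equal(s3$mean_dwell_ms, s2$mean_dwell_ms)
  expect_equal(s3$n_included, s2$n_included)
})

test_that("QC is exhaustive and exclusive on a simulated cohort", {
  p <- cohort_params(n_participants = 4, missingness_rate = 0.3, seed = 19)
  co <- simulate_cohort(p)
  sc <- run_cohort_pipeline(co, run_config())
  m <- sc$trial_metrics
  included <- m$qc_status == "included"
  expect_true(all(included == (m$qc_reasons == "")))
  expect_true(all(nchar(m$qc_reasons[!included]) > 0))
  known <- c("anticipatory", "low_validity", "baseline_fail",
             "no_target_fixation")
  reasons <- unlist(strsplit(m$qc_reasons[!included], ";"))
  expect_true(all(reasons %in% known))
  # included trials always carry a latency >= the anticipation cutoff
  expect_true(all(is.na(m$latency_to_eyes_ms[!included])))
  expect_true(all(m$latency_to_eyes_ms[included] >= 100, na.rm = TRUE))
  # dwell present whenever latency is, and bounded by the trial window
  has_lat <- included & !is.na(m$latency_to_eyes_ms)
  expect_true(all(!is.na(m$first_pass_dwell_ms[has_lat])))
  expect_true(all(m$first_pass_dwell_ms[has_lat] > 0))
  expect_true(all(m$first_pass_dwell_ms[has_lat] <= 5000))
})
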