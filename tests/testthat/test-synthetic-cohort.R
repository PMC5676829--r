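test_that("generated traits reproduce the configured moments", {
  set.seed(1)
  p <- cohort_params()
  tr <- generate_traits(p, n = 10000)
  expect_equal(mean(tr$srs_total), 49, tolerance = 1 / 49)
  expect_equal(mean(tr$spaic_total), 35, tolerance = 1 / 35)
  expect_equal(sd(tr$srs_total), 19, tolerance = 0.05)
  expect_equal(cor(tr$srs_total, tr$spaic_total), 0.36, tolerance = 0.1)
  expect_true(all(tr$srs_total >= 0))
  expect_true(all(tr$srs_total == round(tr$srs_total)))

  set.seed(2)
  tr0 <- generate_traits(cohort_params(trait_correlation = 0), n = 10000)
  expect_lt(abs(cor(tr0$srs_total, tr0$spaic_total)), 0.03)

  expect_error(cohort_params(trait_correlation = 1.2))
  bad <- cohort_params()
  bad$trait_correlation <- 1.2
  expect_error(generate_traits(bad), "trait_correlation")
})

test_that("trait generation is deterministic under a fixed seed", {
  set.seed(77); a <- generate_traits(cohort_params(), n = 50)
  set.seed(77); b <- generate_traits(cohort_params(), n = 50)
  expect_identical(a, b)
})

test_that("planted latency follows the configured trait coupling", {
  p <- cohort_params(beta_latency = 60, anticipatory_rate = 0)
  set.seed(5)
  # z_A = +2: mean silent latency should be 711 + 2 * 60 = 831 ms
  lat <- replicate(1000, plan_trial(2, 0, "silent", p)$planted_latency_ms)
  expect_equal(mean(lat), 831, tolerance = 30 / 831)
  set.seed(6)
  lat_cued <- replicate(1000, plan_trial(0, 0, "beep", p)$planted_latency_ms)
  expect_equal(mean(lat_cued), 611, tolerance = 25 / 611)

  # beta = 0: planted latencies carry no trait information
  p0 <- cohort_params(beta_latency = 0, beta_dwell = 0, anticipatory_rate = 0)
  set.seed(7)
  z <- rnorm(2000)
  lat0 <- vapply(z, function(zi) plan_trial(zi, zi, "silent", p0)$planted_latency_ms, 0)
  expect_lt(abs(cor(z, lat0)), 0.05)
})

test_that("anticipatory_rate = 1 plants every first look before 100 ms", {
  p <- cohort_params(anticipatory_rate = 1)
  set.seed(8)
  plans <- replicate(50, plan_trial(0, 0, "silent", p), simplify = FALSE)
  expect_true(all(vapply(plans, function(x) x$anticipatory, TRUE)))
  expect_true(all(vapply(plans, function(x) x$planted_latency_ms, 0) < 100))
})

test_that("trial schedules are internally consistent", {
  p <- cohort_params()
  set.seed(11)
  for (i in 1:50) {
    pl <- plan_trial(rnorm(1), rnorm(1), sample(c("silent", "beep"), 1), p)
    s <- pl$segments
    expect_equal(s$t0_ms[1], 0)
    expect_equal(s$t0_ms[-1], s$t1_ms[-length(s$t1_ms)])  # contiguous
    expect_equal(max(s$t1_ms), 6500)                       # covers the trial
    expect_gte(pl$planted_latency_ms, 0)
    expect_lte(pl$planted_dwell_ms, 5000 - pl$planted_latency_ms + 1e-9)
    i_eyes <- which(s$label == "eyes")[1]
    expect_equal(s$t0_ms[i_eyes] - 1500, pl$planted_latency_ms)
    expect_equal(s$t1_ms[i_eyes] - s$t0_ms[i_eyes], pl$planted_dwell_ms)
  }
})

test_that("rendered streams are reproducible and carry the planted structure", {
  p <- cohort_params(n_participants = 2, seed = 42)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$streams, b$streams)
  expect_identical(a$ledger, b$ledger)
  # 12 trials x 6500 ms at 120 Hz
  expect_equal(nrow(a$streams[[1]]), 9360)
  expect_equal(diff(a$streams[[1]]$t_ms)[1], 1000 / 120, tolerance = 1e-9)
  # constant binocular disparity around the cyclopean point
  ok <- a$streams[[1]]$left_validity == 0
  expect_equal(a$streams[[1]]$right_x[ok] - a$streams[[1]]$left_x[ok],
               rep(20, sum(ok)))
})

test_that("injected missingness matches the validity codes and the QC rule", {
  p <- cohort_params(n_participants = 3, missingness_rate = 0.6, seed = 13)
  co <- simulate_cohort(p)
  s <- co$streams[[1]]
  expect_equal(mean(s$left_validity == 4), 0.6, tolerance = 0.1)
  expect_true(all(is.na(s$left_x[s$left_validity == 4])))
  expect_true(all(!is.na(s$left_x[s$left_validity == 0])))

  sc <- run_cohort_pipeline(co, run_config())
  m <- sc$trial_metrics
  # brute-force recount of the 33% rule from the rendered codes, all
  # participants
  brute_all <- unlist(lapply(co$traits$participant_id, function(id) {
    recs <- segment_trials(co$streams[[id]], co$trial_log)
    vapply(recs, function(r) {
      mean(r$samples$left_validity <= 1 & r$samples$right_validity <= 1)
    }, 0)
  }))
  expect_equal(m$validity_fraction, brute_all)
  expect_identical(grepl("low_validity", m$qc_reasons), brute_all < 0.33)
  expect_gt(sum(brute_all < 0.33), 0)  # heavy dropout must sink some trials
})

test_that("noise-free rendering lets the detector recover the planted itinerary", {
  p <- cohort_params(n_participants = 2, noise_sd_px = 0,
                     missingness_rate = 0, anticipatory_rate = 0, seed = 3)
  co <- simulate_cohort(p)
  cfg <- run_config()
  points <- interpolate_gaps(combine_eyes(co$streams[[1]]),
                             cfg$filter$max_gap_interp_ms)
  fx <- detect_fixations(points, cfg$filter)
  # re-plan the same participant to count planted segments
  set.seed(gazedissect:::participant_seed(p$seed, 1))
  z_A <- (co$traits$srs_total[1] - p$trait_mean_A) / p$trait_sd_A
  z_B <- (co$traits$spaic_total[1] - p$trait_mean_B) / p$trait_sd_B
  plans <- lapply(seq_len(12), function(k) {
    plan_trial(z_A, z_B, co$trial_log$condition[k], p)
  })
  # planted segments shorter than ~100 ms (the truncated final wander hop of
  # a trial) lose their two transition samples plus the boundary sample and
  # fall under the 60 ms duration floor; all longer segments must be found
  spans <- unlist(lapply(plans, function(pl) {
    pl$segments$t1_ms - pl$segments$t0_ms
  }))
  expect_equal(nrow(fx), sum(spans >= 100))
})

test_that("cohort directories hold the full file census and reproduce", {
  p <- cohort_params(n_participants = 5, seed = 99)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  co <- generate_cohort(p, out)
  files <- list.files(out)
  expect_length(grep("^gaze_P[0-9]+\\.tsv$", files), 5)
  expect_true(all(c("traits.csv", "trial_log.csv", "roi_config.json",
                    "ground_truth_ledger.csv", "cohort_manifest.json")
                  %in% files))
  expect_equal(nrow(co$ledger), 5 * 12)

  expect_error(generate_cohort(p, out), "not empty")

  # regeneration from the manifest's seed reproduces the ledger exactly
  man <- jsonlite::read_json(file.path(out, "cohort_manifest.json"),
                             simplifyVector = TRUE)
  p2 <- do.call(cohort_params, man$params)
  out2 <- file.path(dir, "cohort2")
  co2 <- generate_cohort(p2, out2)
  expect_identical(co$ledger, co2$ledger)
  expect_identical(readLines(file.path(out, "gaze_P001.tsv")),
                   readLines(file.path(out2, "gaze_P001.tsv")))

  # reading back gives the simulated cohort
  rd <- read_cohort(out)
  expect_equal(length(rd$streams), 5)
  expect_equal(as.data.frame(rd$trial_log), as.data.frame(co$trial_log))
  expect_equal(rd$streams[["P003"]]$t_ms, co$streams[["P003"]]$t_ms,
               tolerance = 1e-4)
})
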