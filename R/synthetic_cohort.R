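# Synthetic-cohort generator: trait tables, ROI geometry, trial logs and
# 120 Hz binocular gaze streams with planted trait-attention couplings, so
# that every downstream stage can be validated against a ground-truth ledger.

SAMPLE_PERIOD_MS <- 1000 / 120

#' Cohort-generator parameters
#'
#' Defaults encode the emulated study conditions: trait A is an SRS-like
#' autistic-traits raw score (mean 49, SD 19), trait B a SPAI-C-like social
#' anxiety score (mean 35.0, SD 7.3), correlated 0.36; per-trial latency to
#' orient to the eyes is lognormal with mean 711 ms (SD 268) on silent trials
#' and 611 ms (SD 173) on cued trials; the paradigm has 12 trials (4 silent,
#' 8 cued) at 120 Hz. `beta_latency` shifts a participant's mean latency per
#' SD of trait A (default +60 ms/SD); `beta_dwell` shifts mean first-pass
#' dwell per SD of trait B (default -80 ms/SD). Standardisation uses the
#' configured population moments, not sample moments, so the betas have a
#' fixed meaning.
#'
#' @param n_participants Number of participants.
#' @param trait_mean_A,trait_sd_A Moments of trait A (autistic traits).
#' @param trait_mean_B,trait_sd_B Moments of trait B (social anxiety).
#' @param trait_correlation Population correlation of the two traits.
#' @param base_latency_silent_ms,latency_sd_silent_ms Per-trial latency
#'   distribution on silent trials (lognormal, given as mean/SD in ms).
#' @param base_latency_cued_ms,latency_sd_cued_ms Same for cued trials.
#' @param beta_latency Latency shift in ms per SD of trait A.
#' @param base_dwell_ms,dwell_sd_ms Per-trial first-pass dwell distribution
#'   (lognormal mean/SD in ms).
#' @param beta_dwell Dwell shift in ms per SD of trait B.
#' @param p_first_look_target Probability that the first look after onset goes
#'   straight to the eyes ROI (otherwise one distractor look precedes it).
#' @param missingness_rate Expected fraction of samples lost to tracking
#'   dropout (injected as runs with validity code 4 and empty positions).
#' @param anticipatory_rate Probability a trial's first target look is planted
#'   before the 100 ms anticipation cutoff.
#' @param noise_sd_px Isotropic Gaussian position noise during fixations.
#' @param trials_per_participant Trials per run (4 silent + 8 cued when 12).
#' @param animation_ms,blank_ms Center animation and blank durations before
#'   each array (the last `baseline_window_ms` of this period is the baseline
#'   interval).
#' @param array_ms Stimulus-array presentation time.
#' @param baseline_window_ms Length of the baseline interval before onset.
#' @param seed Master seed; per-participant substreams are derived from it.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_participants = 25,
                          trait_mean_A = 49, trait_sd_A = 19,
                          trait_mean_B = 35.0, trait_sd_B = 7.3,
                          trait_correlation = 0.36,
                          base_latency_silent_ms = 711,
                          latency_sd_silent_ms = 268,
                          base_latency_cued_ms = 611,
                          latency_sd_cued_ms = 173,
                          beta_latency = 60,
                          base_dwell_ms = 500,
                          dwell_sd_ms = 270,
                          beta_dwell = -80,
                          p_first_look_target = 0.6,
                          missingness_rate = 0.10,
                          anticipatory_rate = 0.05,
                          noise_sd_px = 5,
                          trials_per_participant = 12,
                          animation_ms = 1000,
                          blank_ms = 500,
                          array_ms = 5000,
                          baseline_window_ms = 500,
                          seed = 1L) {
  p <- list(
    n_participants = as.integer(n_participants),
    trait_mean_A = trait_mean_A, trait_sd_A = trait_sd_A,
    trait_mean_B = trait_mean_B, trait_sd_B = trait_sd_B,
    trait_correlation = trait_correlation,
    base_latency_silent_ms = base_latency_silent_ms,
    latency_sd_silent_ms = latency_sd_silent_ms,
    base_latency_cued_ms = base_latency_cued_ms,
    latency_sd_cued_ms = latency_sd_cued_ms,
    beta_latency = beta_latency,
    base_dwell_ms = base_dwell_ms,
    dwell_sd_ms = dwell_sd_ms,
    beta_dwell = beta_dwell,
    p_first_look_target = p_first_look_target,
    missingness_rate = missingness_rate,
    anticipatory_rate = anticipatory_rate,
    noise_sd_px = noise_sd_px,
    trials_per_participant = as.integer(trials_per_participant),
    animation_ms = animation_ms,
    blank_ms = blank_ms,
    array_ms = array_ms,
    baseline_window_ms = baseline_window_ms,
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_participants >= 2L,
    p$trait_sd_A > 0, p$trait_sd_B > 0,
    abs(p$trait_correlation) < 1,
    p$latency_sd_silent_ms > 0, p$latency_sd_cued_ms > 0, p$dwell_sd_ms > 0,
    p$p_first_look_target >= 0, p$p_first_look_target <= 1,
    p$missingness_rate >= 0, p$missingness_rate <= 1,
    p$anticipatory_rate >= 0, p$anticipatory_rate <= 1,
    p$noise_sd_px >= 0
  )
  structure(p, class = "cohort_params")
}

#' Default ROI geometry
#'
#' A 1280 x 1024 px screen (17-inch 5:4 monitor) with the four equal 300 x
#' 224 px stimulus rectangles centred in the screen quadrants and a same-size
#' center rectangle for the baseline check. The eyes rectangle rotates
#' through the four quadrant positions across the 12 arrays
#' (counterbalanced), the three distractors fill the remaining positions.
#'
#' @param n_arrays Number of stimulus arrays (default 12).
#' @return A validated ROI-set tibble.
#' @export
default_roi_set <- function(n_arrays = 12L) {
  w <- 300; h <- 224
  centers <- list(c(320, 256), c(960, 256), c(320, 768), c(960, 768))
  rows <- list()
  for (a in seq_len(n_arrays)) {
    eyes_pos <- ((a - 1L) %% 4L) + 1L
    dis <- setdiff(1:4, eyes_pos)
    labels <- character(4L)
    labels[eyes_pos] <- "eyes"
    labels[dis] <- paste0("distractor_", 1:3)
    for (p in 1:4) {
      cc <- centers[[p]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        array_id = a, label = labels[p],
        x0 = cc[1] - w / 2, y0 = cc[2] - h / 2, width = w, height = h
      )
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      array_id = a, label = "center",
      x0 = 640 - w / 2, y0 = 512 - h / 2, width = w, height = h
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "screen") <- list(width_px = 1280, height_px = 1024,
                              monitor_inches = 17)
  validate_roi_set(out)
  out
}

#' Generate a trait table
#'
#' Bivariate-normal draws with the configured means, SDs and correlation,
#' truncated at zero and rounded to integers (questionnaire raw scores).
#' Subscale scores are noisy proportional splits of the total, with split
#' proportions matching typical SRS subscale shares.
#'
#' @param params A [cohort_params()] list.
#' @param n Number of participants (defaults to `params$n_participants`).
#' @param subscales Also generate the five SRS subscale columns.
#' @return A trait tibble (draws from the current RNG state).
#' @export
generate_traits <- function(params = cohort_params(),
                            n = params$n_participants, subscales = TRUE) {
  if (abs(params$trait_correlation) >= 1) {
    stop("trait_correlation must lie in (-1, 1)", call. = FALSE)
  }
  sigma <- matrix(c(
    params$trait_sd_A^2,
    params$trait_correlation * params$trait_sd_A * params$trait_sd_B,
    params$trait_correlation * params$trait_sd_A * params$trait_sd_B,
    params$trait_sd_B^2
  ), 2L, 2L)
  draws <- MASS::mvrnorm(n, c(params$trait_mean_A, params$trait_mean_B),
                         sigma)
  srs <- pmax(0, round(draws[, 1L]))
  spaic <- pmax(0, round(draws[, 2L]))
  out <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    srs_total = srs,
    spaic_total = spaic
  )
  if (subscales) {
    shares <- c(srs_awareness = 0.100, srs_communication = 0.306,
                srs_cognition = 0.127, srs_motivation = 0.353,
                srs_rirb = 0.106)
    for (nm in names(shares)) {
      out[[nm]] <- pmax(0, round(srs * shares[[nm]] + stats::rnorm(n, 0, 1.5)))
    }
  }
  out
}

#' Trait-coupling betas that induce a target population correlation
#'
#' Under the generator model, a participant's mean measure over the paradigm's
#' trials is `base + beta * z + e`, where `e` has standard deviation
#' `sigma_m`, the configured per-trial SD scaled down by the trial count
#' (for latency, pooling the silent and cued per-trial SDs). The population
#' correlation between trait and participant mean is then
#' `r = beta / sqrt(beta^2 + sigma_m^2)`, so the beta inducing a target `r`
#' is `beta = sigma_m * r / sqrt(1 - r^2)`. Trial exclusions and detector
#' error shrink the realised correlation somewhat below the target.
#'
#' @param params A [cohort_params()] list.
#' @param target_r Target population correlation for the latency coupling
#'   (trait A) and, with its sign, for the dwell coupling (trait B).
#' @param target_r_dwell Target for the dwell coupling (default `-target_r`).
#' @return A list `beta_latency, beta_dwell` (ms per trait SD).
#' @export
beta_for_target_r <- function(params = cohort_params(), target_r = 0.5,
                              target_r_dwell = -target_r) {
  n_tot <- params$trials_per_participant
  n_sil <- round(n_tot / 3)
  n_cue <- n_tot - n_sil
  sigma_lat <- sqrt((n_sil * params$latency_sd_silent_ms^2 +
                       n_cue * params$latency_sd_cued_ms^2) / n_tot^2)
  sigma_dwell <- params$dwell_sd_ms / sqrt(n_tot)
  list(
    beta_latency = sigma_lat * target_r / sqrt(1 - target_r^2),
    beta_dwell = sigma_dwell * target_r_dwell / sqrt(1 - target_r_dwell^2)
  )
}

lognormal_ms <- function(n, mean_ms, sd_ms) {
  sigma2 <- log(1 + (sd_ms / mean_ms)^2)
  stats::rlnorm(n, log(mean_ms) - sigma2 / 2, sqrt(sigma2))
}

#' Plan one trial's gaze itinerary
#'
#' Draws the trial's planted latency (lognormal with mean
#' `base_latency(condition) + beta_latency * z_A`), planted first-pass dwell
#' (lognormal with mean `base_dwell + beta_dwell * z_B`), the first-look ROI
#' (eyes with probability `p_first_look_target`, else one distractor look
#' first), an optional anticipatory first target look, and a
#' distractor-wander itinerary after the dwell until array offset. Times in
#' the schedule are relative to trial start; the stimulus onset falls at
#' `animation_ms + blank_ms`.
#'
#' @param z_A,z_B The participant's traits standardised against the
#'   configured population moments.
#' @param condition `"silent"`, `"phoneme"` or `"beep"`.
#' @param params A [cohort_params()] list.
#' @return A list: `segments` (parallel vectors `label, t0_ms, t1_ms`,
#'   trial-relative),
#'   `planted_latency_ms`, `planted_dwell_ms` (clipped at array offset),
#'   `first_look_roi`, `anticipatory`.
#' @export
plan_trial <- function(z_A, z_B, condition, params = cohort_params()) {
  onset <- params$animation_ms + params$blank_ms
  offset <- onset + params$array_ms
  silent <- condition == "silent"
  base_lat <- if (silent) params$base_latency_silent_ms else
    params$base_latency_cued_ms
  sd_lat <- if (silent) params$latency_sd_silent_ms else
    params$latency_sd_cued_ms

  anticipatory <- stats::runif(1) < params$anticipatory_rate
  if (anticipatory) {
    latency <- stats::runif(1, 0, 70)
  } else {
    mean_lat <- max(150, base_lat + params$beta_latency * z_A)
    latency <- lognormal_ms(1, mean_lat, sd_lat)
    latency <- min(max(latency, 120), params$array_ms - 400)
  }
  mean_dwell <- max(100, params$base_dwell_ms + params$beta_dwell * z_B)
  dwell <- lognormal_ms(1, mean_dwell, params$dwell_sd_ms)
  dwell <- max(dwell, 80)
  planted_dwell <- min(dwell, params$array_ms - latency)

  distractor_first <- !anticipatory && latency >= 500 &&
    stats::runif(1) >= params$p_first_look_target
  first_look <- if (distractor_first) {
    sample(paste0("distractor_", 1:3), 1L)
  } else {
    "eyes"
  }

  labels <- "center"
  t0 <- 0
  t1 <- onset + if (distractor_first) 0.3 * latency else latency
  if (distractor_first) {
    labels <- c(labels, first_look)
    t0 <- c(t0, onset + 0.3 * latency)
    t1 <- c(t1, onset + latency)
  }
  eyes_end <- onset + latency + planted_dwell
  labels <- c(labels, "eyes")
  t0 <- c(t0, onset + latency)
  t1 <- c(t1, eyes_end)
  # distractor wander until offset: durations drawn in one batch, each hop
  # avoids repeating the previous ROI
  remaining <- offset - eyes_end
  if (remaining > 1e-9) {
    n_max <- ceiling(remaining / 200) + 1L
    durs <- stats::runif(n_max, 200, 400)
    n_w <- which(cumsum(durs) >= remaining - 1e-9)[1L]
    durs <- durs[seq_len(n_w)]
    dlabs <- paste0("distractor_", 1:3)
    picks <- sample.int(2L, n_w, replace = TRUE)
    prev <- 0L  # eyes; any distractor allowed first
    wl <- character(n_w)
    first_pick <- sample.int(3L, 1L)
    for (j in seq_len(n_w)) {
      avail <- if (prev == 0L) 1:3 else (1:3)[-prev]
      nxt <- if (prev == 0L) first_pick else avail[picks[j]]
      wl[j] <- dlabs[nxt]
      prev <- nxt
    }
    w_t0 <- eyes_end + c(0, cumsum(durs))[seq_len(n_w)]
    labels <- c(labels, wl)
    t0 <- c(t0, w_t0)
    t1 <- c(t1, pmin(w_t0 + durs, offset))
  }
  list(
    segments = list(label = labels, t0_ms = t0, t1_ms = t1),
    planted_latency_ms = latency,
    planted_dwell_ms = planted_dwell,
    first_look_roi = first_look,
    anticipatory = anticipatory
  )
}

#' Render a gaze-sample stream from trial schedules
#'
#' Renders 120 Hz binocular samples over the whole recording: during a
#' fixation segment, positions are the ROI center plus isotropic Gaussian
#' noise; the first two samples of each new segment are in-flight saccade
#' transitions; the two eyes carry a small constant horizontal disparity
#' around the cyclopean point; tracking dropout is injected as runs of
#' samples with validity code 4 and empty positions.
#'
#' @param schedules A list of trial plans from [plan_trial()], one per trial
#'   in presentation order.
#' @param trial_log The trial log giving each trial's array and absolute
#'   times (trial k occupies `[onset - animation - blank, offset)`).
#' @param roi_set ROI geometry.
#' @param params A [cohort_params()] list.
#' @return A gaze-sample tibble in the canonical seven columns.
#' @export
render_stream <- function(schedules, trial_log, roi_set,
                          params = cohort_params()) {
  trial_len <- params$animation_ms + params$blank_ms + params$array_ms
  n_trials <- length(schedules)
  t0_list <- vector("list", n_trials)
  cx_list <- vector("list", n_trials)
  cy_list <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    s <- schedules[[k]]$segments
    base <- (k - 1) * trial_len
    a <- trial_log$array_id[k]
    r <- roi_set[roi_set$array_id == a, ]
    cx <- r$x0 + r$width / 2
    cy <- r$y0 + r$height / 2
    names(cx) <- r$label
    names(cy) <- r$label
    t0_list[[k]] <- base + s$t0_ms
    cx_list[[k]] <- unname(cx[s$label])
    cy_list[[k]] <- unname(cy[s$label])
  }
  segs <- list(t0 = unlist(t0_list), cx = unlist(cx_list),
               cy = unlist(cy_list))
  total_ms <- n_trials * trial_len
  n <- floor(total_ms / SAMPLE_PERIOD_MS + 1e-9)
  t <- (seq_len(n) - 1) * SAMPLE_PERIOD_MS

  si <- findInterval(t, segs$t0)
  x <- segs$cx[si]
  y <- segs$cy[si]
  # 2-sample saccade transitions into each new segment
  first_of_seg <- c(TRUE, diff(si) > 0)
  idx1 <- which(first_of_seg & si > 1L)
  idx2 <- idx1[idx1 < n] + 1L
  idx2 <- idx2[si[idx2] == si[idx2 - 1L]]  # still in the same segment
  px <- segs$cx[pmax(si - 1L, 1L)]
  py <- segs$cy[pmax(si - 1L, 1L)]
  x[idx1] <- px[idx1] + (segs$cx[si[idx1]] - px[idx1]) / 3
  y[idx1] <- py[idx1] + (segs$cy[si[idx1]] - py[idx1]) / 3
  x[idx2] <- px[idx2] + 2 * (segs$cx[si[idx2]] - px[idx2]) / 3
  y[idx2] <- py[idx2] + 2 * (segs$cy[si[idx2]] - py[idx2]) / 3

  if (params$noise_sd_px > 0) {
    x <- x + stats::rnorm(n, 0, params$noise_sd_px)
    y <- y + stats::rnorm(n, 0, params$noise_sd_px)
  }

  miss <- rep(FALSE, n)
  if (params$missingness_rate > 0) {
    # dropout runs of ~12 samples (~100 ms); the start rate compensates for
    # run overlap so the expected missing fraction equals the configured rate
    mean_run <- 12
    p_start <- if (params$missingness_rate >= 1) 1 else
      -log(1 - params$missingness_rate) / mean_run
    starts <- which(stats::runif(n) < p_start)
    if (length(starts)) {
      lens <- stats::rgeom(length(starts), 1 / mean_run) + 1L
      hit <- unlist(mapply(function(s, l) s:min(s + l - 1L, n), starts, lens,
                           SIMPLIFY = FALSE))
      miss[hit] <- TRUE
    }
  }

  disparity <- 10
  lx <- x - disparity; rx <- x + disparity
  ly <- y; ry <- y
  lv <- rep(0L, n); rv <- rep(0L, n)
  lx[miss] <- NA; ly[miss] <- NA; rx[miss] <- NA; ry[miss] <- NA
  lv[miss] <- 4L; rv[miss] <- 4L

  tibble::new_tibble(
    list(t_ms = t,
         left_x = lx, left_y = ly, left_validity = lv,
         right_x = rx, right_y = ry, right_validity = rv),
    nrow = n
  )
}

build_trial_log <- function(params, conditions) {
  trial_len <- params$animation_ms + params$blank_ms + params$array_ms
  k <- seq_len(params$trials_per_participant)
  onset <- (k - 1) * trial_len + params$animation_ms + params$blank_ms
  tibble::tibble(
    trial_id = as.integer(k),
    array_id = as.integer(((k - 1L) %% 12L) + 1L),
    onset_ms = onset,
    offset_ms = onset + params$array_ms,
    condition = conditions,
    baseline_start_ms = onset - params$baseline_window_ms,
    baseline_end_ms = onset
  )
}

participant_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 10007 + i * 7919) %% 2147483647)
}

#' Simulate a cohort in memory
#'
#' Generates the trait table, a shared trial log and ROI set, one rendered
#' gaze stream per participant (each from a substream seeded from the master
#' seed, so cohorts are reproducible piecewise), and the ground-truth ledger
#' of every planted latency and dwell.
#'
#' @param params A [cohort_params()] list.
#' @return A list: `params, traits, trial_log, roi_set, streams` (named list
#'   of gaze-sample tibbles), `ledger` (tibble of planted values), and
#'   `manifest`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  set.seed(params$seed)
  traits <- generate_traits(params)
  n_silent <- round(params$trials_per_participant / 3)
  n_cued <- params$trials_per_participant - n_silent
  conditions <- sample(c(
    rep("silent", n_silent),
    rep("phoneme", ceiling(n_cued / 2)),
    rep("beep", floor(n_cued / 2))
  ))
  trial_log <- build_trial_log(params, conditions)
  roi_set <- default_roi_set()

  streams <- vector("list", params$n_participants)
  ledger <- vector("list", params$n_participants)
  for (i in seq_len(params$n_participants)) {
    set.seed(participant_seed(params$seed, i))
    z_A <- (traits$srs_total[i] - params$trait_mean_A) / params$trait_sd_A
    z_B <- (traits$spaic_total[i] - params$trait_mean_B) / params$trait_sd_B
    plans <- lapply(seq_len(params$trials_per_participant), function(k) {
      plan_trial(z_A, z_B, trial_log$condition[k], params)
    })
    streams[[i]] <- render_stream(plans, trial_log, roi_set, params)
    ledger[[i]] <- tibble::tibble(
      participant_id = traits$participant_id[i],
      trial_id = trial_log$trial_id,
      condition = trial_log$condition,
      planted_latency_ms =
        vapply(plans, function(p) p$planted_latency_ms, 0),
      planted_dwell_ms = vapply(plans, function(p) p$planted_dwell_ms, 0),
      first_look_roi = vapply(plans, function(p) p$first_look_roi, ""),
      anticipatory = vapply(plans, function(p) p$anticipatory, TRUE)
    )
  }
  names(streams) <- traits$participant_id
  list(
    params = params,
    traits = traits,
    trial_log = trial_log,
    roi_set = roi_set,
    streams = streams,
    ledger = dplyr::bind_rows(ledger),
    manifest = list(params = unclass(params), seed = params$seed)
  )
}

#' Generate a cohort on disk
#'
#' Writes one gaze log per participant plus the shared artifacts: trial log,
#' ROI config, trait table, ground-truth ledger and a manifest recording all
#' parameters and the seed (regenerating with the manifest's seed reproduces
#' the ledger exactly).
#'
#' @param params A [cohort_params()] list.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The cohort list from [simulate_cohort()], invisibly.
#' @export
generate_cohort <- function(params = cohort_params(), dir,
                            overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
    stop("output directory exists and is not empty: ", dir, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(params)
  write_trait_table(cohort$traits, file.path(dir, "traits.csv"))
  write_trial_log(cohort$trial_log, file.path(dir, "trial_log.csv"))
  write_roi_config(cohort$roi_set, file.path(dir, "roi_config.json"))
  readr::write_csv(cohort$ledger, file.path(dir, "ground_truth_ledger.csv"),
                   progress = FALSE)
  for (id in names(cohort$streams)) {
    write_gaze_log(cohort$streams[[id]],
                   file.path(dir, sprintf("gaze_%s.tsv", id)))
  }
  jsonlite::write_json(cohort$manifest,
                       file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Read a cohort directory written by [generate_cohort()]
#' @param dir Cohort directory.
#' @return A cohort list in the layout of [simulate_cohort()] (without
#'   `params`; the manifest carries them).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                                  simplifyVector = TRUE)
  traits <- read_trait_table(file.path(dir, "traits.csv"))
  streams <- lapply(traits$participant_id, function(id) {
    read_gaze_log(file.path(dir, sprintf("gaze_%s.tsv", id)))
  })
  names(streams) <- traits$participant_id
  list(
    traits = traits,
    trial_log = read_trial_log(file.path(dir, "trial_log.csv")),
    roi_set = read_roi_config(file.path(dir, "roi_config.json")),
    streams = streams,
    ledger = readr::read_csv(file.path(dir, "ground_truth_ledger.csv"),
                             show_col_types = FALSE, progress = FALSE),
    manifest = manifest
  )
}
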