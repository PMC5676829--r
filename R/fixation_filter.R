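# Fixation detection from binocular gaze samples: cyclopean combination,
# short-gap interpolation, and a sliding-window mean-difference filter of the
# distance/velocity family, with centroid-distance merging of adjacent
# candidates. Both thresholds are in pixels; the "velocity" threshold applies
# to the window-mean displacement, not a px/s rate.

#' Fixation filter parameters
#'
#' @param velocity_threshold_px Displacement threshold (pixels) on the
#'   sliding-window mean-difference signal above which a local maximum marks a
#'   saccade boundary. Default 35.
#' @param distance_threshold_px Maximum centroid distance (pixels) at which
#'   adjacent candidate fixations are merged. Default 35.
#' @param window_halfwidth_samples Number of samples averaged on each side of
#'   a sample when computing its displacement signal. Default 5 (~42 ms at
#'   120 Hz).
#' @param max_gap_interp_ms Longest run of missing samples (ms) bridged by
#'   linear interpolation; longer gaps always terminate a fixation. Default 75.
#' @param min_fixation_ms Fixations shorter than this (after merging) are
#'   discarded from analysis. Default 60.
#' @return A `filter_params` list.
#' @export
filter_params <- function(velocity_threshold_px = 35,
                          distance_threshold_px = 35,
                          window_halfwidth_samples = 5,
                          max_gap_interp_ms = 75,
                          min_fixation_ms = 60) {
  p <- list(
    velocity_threshold_px = velocity_threshold_px,
    distance_threshold_px = distance_threshold_px,
    window_halfwidth_samples = as.integer(window_halfwidth_samples),
    max_gap_interp_ms = max_gap_interp_ms,
    min_fixation_ms = min_fixation_ms
  )
  if (any(unlist(p) <= 0)) {
    stop("all filter parameters must be strictly positive", call. = FALSE)
  }
  structure(p, class = "filter_params")
}

#' Combine the two eyes into a cyclopean gaze point
#'
#' An eye contributes when its validity code is 0 or 1 and its position is
#' present. Both eyes valid: the midpoint; one eye valid: that eye; neither:
#' missing. Returns one point per input sample.
#'
#' @param samples A gaze-sample tibble (see [read_gaze_log()]).
#' @return A tibble `t_ms, x, y, interpolated` (all `interpolated = FALSE`;
#'   the flag is set by [interpolate_gaps()]).
#' @export
combine_eyes <- function(samples) {
  l_ok <- samples$left_validity <= 1L &
    is.finite(samples$left_x) & is.finite(samples$left_y)
  r_ok <- samples$right_validity <= 1L &
    is.finite(samples$right_x) & is.finite(samples$right_y)
  x <- rep(NA_real_, nrow(samples))
  y <- rep(NA_real_, nrow(samples))
  both <- l_ok & r_ok
  x[both] <- (samples$left_x[both] + samples$right_x[both]) / 2
  y[both] <- (samples$left_y[both] + samples$right_y[both]) / 2
  lo <- l_ok & !r_ok
  x[lo] <- samples$left_x[lo]; y[lo] <- samples$left_y[lo]
  ro <- r_ok & !l_ok
  x[ro] <- samples$right_x[ro]; y[ro] <- samples$right_y[ro]
  tibble::new_tibble(
    list(t_ms = samples$t_ms, x = x, y = y,
         interpolated = rep(FALSE, nrow(samples))),
    nrow = nrow(samples)
  )
}

#' Interpolate short gaps in a cyclopean gaze stream
#'
#' Runs of missing points whose span does not exceed `max_gap_interp_ms` and
#' that are flanked by valid points on both sides are filled by linear
#' interpolation in time and flagged `interpolated = TRUE`. Longer runs, and
#' runs touching either end of the stream, are left missing.
#'
#' @param points A cyclopean point tibble from [combine_eyes()].
#' @param max_gap_interp_ms Gap cap in ms.
#' @return The points tibble with gaps filled and the `interpolated` flag set.
#' @export
interpolate_gaps <- function(points, max_gap_interp_ms = 75) {
  n <- nrow(points)
  if (n < 3L) return(points)
  t <- points$t_ms
  miss <- !is.finite(points$x) | !is.finite(points$y)
  if (!any(miss)) return(points)
  period <- stats::median(diff(t))
  x <- points$x; y <- points$y; interp <- points$interpolated
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n) next
    span <- (t[e + 1L] - t[s - 1L]) - period
    if (span > max_gap_interp_ms) next
    frac <- (t[s:e] - t[s - 1L]) / (t[e + 1L] - t[s - 1L])
    x[s:e] <- x[s - 1L] + frac * (x[e + 1L] - x[s - 1L])
    y[s:e] <- y[s - 1L] + frac * (y[e + 1L] - y[s - 1L])
    interp[s:e] <- TRUE
  }
  points$x <- x
  points$y <- y
  points$interpolated <- interp
  points
}

# Sliding-window mean-difference displacement signal: for sample i, the
# Euclidean distance between the mean position of the `w` samples before i
# and the mean of the `w` samples after i. NA at the edges and wherever a
# window contains a missing sample.
displacement_signal <- function(x, y, w) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n < 2L * w + 1L) return(d)
  miss <- !is.finite(x) | !is.finite(y)
  xz <- ifelse(miss, 0, x); yz <- ifelse(miss, 0, y)
  Cx <- c(0, cumsum(xz)); Cy <- c(0, cumsum(yz))
  Ck <- c(0, cumsum(as.numeric(!miss)))
  i <- (w + 1L):(n - w)
  bk <- Ck[i] - Ck[i - w]
  ak <- Ck[i + w + 1L] - Ck[i + 1L]
  full <- bk == w & ak == w
  dx <- (Cx[i] - Cx[i - w]) / w - (Cx[i + w + 1L] - Cx[i + 1L]) / w
  dy <- (Cy[i] - Cy[i - w]) / w - (Cy[i + w + 1L] - Cy[i + 1L]) / w
  d[i] <- ifelse(full, sqrt(dx^2 + dy^2), NA_real_)
  d
}

#' Locate saccade boundaries
#'
#' A sample is a boundary when its displacement signal exceeds the velocity
#' threshold and is a local maximum; on a tied plateau the earliest sample is
#' the boundary.
#'
#' @param points A cyclopean point tibble.
#' @param params A [filter_params()] list.
#' @return Integer sample indices of the boundaries.
#' @export
saccade_boundaries <- function(points, params = filter_params()) {
  d <- displacement_signal(points$x, points$y, params$window_halfwidth_samples)
  n <- length(d)
  if (n == 0L) return(integer())
  dprev <- c(NA_real_, d[-n])
  dnext <- c(d[-1L], NA_real_)
  rises <- !is.na(d) & !is.na(dprev) & d > dprev
  not_below_next <- !is.na(d) & (is.na(dnext) | d >= dnext)
  which(!is.na(d) & d > params$velocity_threshold_px & rises & not_below_next)
}

#' Detect fixations in a cyclopean gaze stream
#'
#' Implements the sliding-window mean-difference variant of the
#' distance/velocity fixation-filter family: saccade boundaries are local
#' maxima of the window-mean displacement signal above
#' `velocity_threshold_px`; maximal runs of samples between boundaries that
#' contain no missing span become candidate fixations (centroid = mean member
#' position); adjacent candidates not separated by missing data whose
#' centroids lie closer than `distance_threshold_px` are merged, recomputing
#' the pooled centroid until the pass is stable; candidates shorter than
#' `min_fixation_ms` are then dropped.
#'
#' @param points A time-ordered cyclopean point tibble (after gap
#'   interpolation).
#' @param params A [filter_params()] list.
#' @return A tibble of fixations: `start_ms, end_ms, duration_ms, centroid_x,
#'   centroid_y, n_samples, mean_validity_fraction` (fraction of member
#'   samples that were measured rather than interpolated), time-ordered and
#'   non-overlapping.
#' @export
detect_fixations <- function(points, params = filter_params()) {
  empty <- tibble::tibble(
    start_ms = double(), end_ms = double(), duration_ms = double(),
    centroid_x = double(), centroid_y = double(),
    n_samples = integer(), mean_validity_fraction = double()
  )
  n <- nrow(points)
  w <- params$window_halfwidth_samples
  if (n < 2L * w + 1L) {
    warning("too few samples for fixation detection (need at least ",
            2L * w + 1L, ")", call. = FALSE)
    return(empty)
  }
  t <- points$t_ms; x <- points$x; y <- points$y
  interp <- if ("interpolated" %in% names(points)) points$interpolated else
    rep(FALSE, n)
  miss <- !is.finite(x) | !is.finite(y)
  bnd <- saccade_boundaries(points, params)

  cls <- integer(n)          # 0 = fixation candidate member
  cls[bnd] <- 1L             # 1 = saccade boundary
  cls[miss] <- 2L            # 2 = missing
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_runs <- which(r$values == 0L)
  if (!length(cand_runs)) return(empty)
  segs <- lapply(cand_runs, function(k) starts[k]:ends[k])

  segs <- merge_candidates(segs, x, y, miss, params$distance_threshold_px)

  first <- vapply(segs, function(i) i[1L], 0L)
  last <- vapply(segs, function(i) i[length(i)], 0L)
  ns <- lengths(segs)
  fix <- tibble::new_tibble(list(
    start_ms = t[first],
    end_ms = t[last],
    duration_ms = t[last] - t[first],
    centroid_x = vapply(segs, function(i) sum(x[i]), 0) / ns,
    centroid_y = vapply(segs, function(i) sum(y[i]), 0) / ns,
    n_samples = ns,
    mean_validity_fraction = vapply(segs, function(i) sum(!interp[i]), 0) / ns
  ), nrow = length(segs))
  fix[fix$duration_ms >= params$min_fixation_ms, , drop = FALSE]
}

# One-or-more merge passes over candidate segments (lists of member sample
# indices), until stable. Candidates separated by a missing sample are never
# merged: long gaps always terminate a fixation.
merge_candidates <- function(segs, x, y, miss, distance_threshold_px) {
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < length(segs)) {
      a <- segs[[i]]; b <- segs[[i + 1L]]
      gap <- seq2(max(a) + 1L, min(b) - 1L)
      gap_missing <- length(gap) > 0L && any(miss[gap])
      d <- sqrt((mean(x[a]) - mean(x[b]))^2 + (mean(y[a]) - mean(y[b]))^2)
      if (!gap_missing && d < distance_threshold_px) {
        segs[[i]] <- c(a, b)
        segs[[i + 1L]] <- NULL
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!changed) break
  }
  segs
}

seq2 <- function(from, to) {
  if (from > to) integer() else from:to
}

#' Export a fixation list as CSV
#' @param fixations A fixation tibble from [detect_fixations()].
#' @param path Output path.
#' @param participant_id Optional id recorded in the first column.
#' @export
write_fixation_csv <- function(fixations, path, participant_id = NA) {
  out <- dplyr::mutate(
    fixations[, c("start_ms", "end_ms", "centroid_x", "centroid_y",
                  "duration_ms")],
    participant_id = participant_id, .before = 1L
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
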