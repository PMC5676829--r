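# On-disk artifacts: gaze-sample logs (TSV), trial logs (CSV), ROI configs
# (JSON), trait tables (CSV). All readers validate; all writers emit the
# canonical dialect so that write(read(f)) is byte-identical.

gaze_log_columns <- c(
  "t_ms", "left_x", "left_y", "left_validity",
  "right_x", "right_y", "right_validity"
)

trial_log_columns <- c(
  "trial_id", "array_id", "onset_ms", "offset_ms", "condition",
  "baseline_start_ms", "baseline_end_ms"
)

trial_conditions <- c("silent", "phoneme", "beep")

stimulus_roi_labels <- c("eyes", "distractor_1", "distractor_2", "distractor_3")

#' Read a binocular gaze log
#'
#' Parses the tab-separated gaze-log dialect: one header line naming the seven
#' columns `t_ms, left_x, left_y, left_validity, right_x, right_y,
#' right_validity`; positions in screen pixels (origin top-left, y down);
#' per-eye Tobii-style validity codes 0-4 (0-1 = reliably tracked); missing
#' positions encoded as empty fields, never as (0,0).
#'
#' Malformed rows (wrong field count, unparseable numbers) are rejected, not
#' silently dropped: their file line numbers are attached as
#' `attr(, "rejected_rows")` and reported in a warning, so
#' `rows in = rows parsed + rows rejected` always holds. Two defects are hard
#' errors because they indicate a corrupt recording rather than a bad row:
#' non-monotone timestamps and validity codes outside 0-4.
#'
#' @param path Path to a gaze-log TSV file.
#' @return A tibble with the seven gaze-log columns, time-ordered, with
#'   attribute `rejected_rows` (integer file line numbers, possibly empty).
#' @export
read_gaze_log <- function(path) {
  if (!file.exists(path)) {
    stop("gaze log not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("gaze log is empty: ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, gaze_log_columns)) {
    stop(
      "gaze log header must name the columns ",
      paste(gaze_log_columns, collapse = ", "),
      call. = FALSE
    )
  }
  body <- lines[-1L]
  if (length(body) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(double(), double(), double(), integer()),
        list(double(), double(), integer())),
      gaze_log_columns
    ))
    attr(out, "rejected_rows") <- integer()
    return(out)
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # strsplit drops a trailing empty field; pad rows that are short by one
  fields[nf == 6L] <- lapply(fields[nf == 6L], function(f) c(f, ""))
  nf <- lengths(fields)
  bad_shape <- nf != 7L
  mat <- matrix("", nrow = length(fields), ncol = 7L)
  okr <- which(!bad_shape)
  if (length(okr)) {
    mat[okr, ] <- matrix(unlist(fields[!bad_shape]), ncol = 7L, byrow = TRUE)
  }

  num_or_na <- function(s) suppressWarnings(as.numeric(ifelse(s == "", NA, s)))
  t_ms <- num_or_na(mat[, 1L])
  lx <- num_or_na(mat[, 2L]); ly <- num_or_na(mat[, 3L])
  rx <- num_or_na(mat[, 5L]); ry <- num_or_na(mat[, 6L])
  lv_chr <- mat[, 4L]; rv_chr <- mat[, 7L]
  lv_num <- num_or_na(lv_chr); rv_num <- num_or_na(rv_chr)

  # malformed: bad shape, missing/unparseable time, non-empty but unparseable
  # position, or unparseable validity field
  pos_bad <- (mat[, 2L] != "" & is.na(lx)) | (mat[, 3L] != "" & is.na(ly)) |
    (mat[, 5L] != "" & is.na(rx)) | (mat[, 6L] != "" & is.na(ry))
  val_unparseable <- is.na(lv_num) | is.na(rv_num)
  malformed <- bad_shape | is.na(t_ms) | pos_bad | val_unparseable

  file_row <- seq_along(body) + 1L  # header is line 1
  rejected <- file_row[malformed]
  if (length(rejected)) {
    warning(
      sprintf(
        "rejected %d malformed gaze-log row(s) at line(s): %s",
        length(rejected), paste(utils::head(rejected, 10L), collapse = ", ")
      ),
      call. = FALSE
    )
  }

  keep <- !malformed
  t_ms <- t_ms[keep]; lx <- lx[keep]; ly <- ly[keep]
  rx <- rx[keep]; ry <- ry[keep]
  lv <- as.integer(lv_num[keep]); rv <- as.integer(rv_num[keep])
  rows_kept <- file_row[keep]

  bad_code <- which(!(lv %in% 0:4) | !(rv %in% 0:4) |
                      lv != lv_num[keep] | rv != rv_num[keep])
  if (length(bad_code)) {
    stop(
      sprintf(
        "unknown validity code at line %d (codes must be integers 0-4)",
        rows_kept[bad_code[1L]]
      ),
      call. = FALSE
    )
  }

  if (length(t_ms) > 1L) {
    non_mono <- which(diff(t_ms) <= 0)
    if (length(non_mono)) {
      stop(
        sprintf(
          "timestamps not strictly increasing: first offending row at line %d",
          rows_kept[non_mono[1L] + 1L]
        ),
        call. = FALSE
      )
    }
  }

  out <- tibble::tibble(
    t_ms = t_ms,
    left_x = lx, left_y = ly, left_validity = lv,
    right_x = rx, right_y = ry, right_validity = rv
  )
  attr(out, "rejected_rows") <- rejected
  out
}

#' Write a gaze log in the canonical dialect
#'
#' Times are written with four decimals (sufficient for a 120 Hz sample grid),
#' positions with two, validity codes as integers; missing positions become
#' empty fields. Reading a file produced by this writer and writing it again
#' reproduces the file byte for byte.
#'
#' @param samples A tibble with the seven gaze-log columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_log <- function(samples, path) {
  stopifnot(all(gaze_log_columns %in% names(samples)))
  fmt <- function(x, f) ifelse(is.na(x), "", sprintf(f, x))
  lines <- c(
    paste(gaze_log_columns, collapse = "\t"),
    paste(
      sprintf("%.4f", samples$t_ms),
      fmt(samples$left_x, "%.2f"), fmt(samples$left_y, "%.2f"),
      sprintf("%d", samples$left_validity),
      fmt(samples$right_x, "%.2f"), fmt(samples$right_y, "%.2f"),
      sprintf("%d", samples$right_validity),
      sep = "\t"
    )
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a trial log
#'
#' CSV with columns `trial_id, array_id, onset_ms, offset_ms, condition,
#' baseline_start_ms, baseline_end_ms`. Conditions are `silent`, `phoneme` or
#' `beep` (the latter two are the auditory-cue conditions). Validates that each
#' baseline interval precedes its stimulus interval and that trials do not
#' overlap.
#'
#' @param path Path to the trial-log CSV.
#' @param check_paradigm If `TRUE`, additionally require the canonical
#'   12-trial paradigm (4 silent, 8 cued).
#' @return A tibble, one row per trial, ordered by onset.
#' @export
read_trial_log <- function(path, check_paradigm = FALSE) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  log <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial_id = readr::col_integer(),
      array_id = readr::col_integer(),
      onset_ms = readr::col_double(),
      offset_ms = readr::col_double(),
      condition = readr::col_character(),
      baseline_start_ms = readr::col_double(),
      baseline_end_ms = readr::col_double()
    ),
    progress = FALSE
  )
  validate_trial_log(log, check_paradigm = check_paradigm)
  dplyr::arrange(log, .data$onset_ms)
}

#' @rdname read_trial_log
#' @param log A trial-log tibble.
#' @export
validate_trial_log <- function(log, check_paradigm = FALSE) {
  missing_cols <- setdiff(trial_log_columns, names(log))
  if (length(missing_cols)) {
    stop("trial log lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(log$condition %in% trial_conditions)) {
    stop("unknown condition label(s): ",
         paste(setdiff(unique(log$condition), trial_conditions), collapse = ", "),
         call. = FALSE)
  }
  bad <- log$onset_ms >= log$offset_ms
  if (any(bad)) {
    stop("trial(s) with onset >= offset: ",
         paste(log$trial_id[bad], collapse = ", "), call. = FALSE)
  }
  bad_bl <- log$baseline_start_ms >= log$baseline_end_ms |
    log$baseline_end_ms > log$onset_ms
  if (any(bad_bl)) {
    stop("baseline interval must precede the stimulus interval; trial(s): ",
         paste(log$trial_id[bad_bl], collapse = ", "), call. = FALSE)
  }
  ord <- order(log$onset_ms)
  if (nrow(log) > 1L) {
    s <- log[ord, ]
    if (any(s$onset_ms[-1L] < s$offset_ms[-nrow(s)])) {
      stop("trial intervals overlap", call. = FALSE)
    }
  }
  if (check_paradigm) {
    n_silent <- sum(log$condition == "silent")
    n_cued <- sum(log$condition != "silent")
    if (nrow(log) != 12L || n_silent != 4L || n_cued != 8L) {
      stop("paradigm run must have 12 trials: 4 silent and 8 cued",
           call. = FALSE)
    }
  }
  invisible(log)
}

#' Write a trial log
#' @param log A trial-log tibble.
#' @param path Output path.
#' @export
write_trial_log <- function(log, path) {
  validate_trial_log(log)
  readr::write_csv(log[, trial_log_columns], path, progress = FALSE)
  invisible(path)
}

#' Read an ROI configuration
#'
#' JSON config describing, per stimulus array, the four equal-sized stimulus
#' rectangles (`eyes`, `distractor_1..3`) and one `center` rectangle used for
#' the baseline attention check. Rectangles are `x0, y0, width, height` in
#' pixels, origin top-left. The set is validated on load: equal stimulus
#' sizes, pairwise non-overlap, exactly one `eyes` label per array.
#'
#' @param path Path to the JSON config.
#' @return An ROI-set tibble (`array_id, label, x0, y0, width, height`) with a
#'   `screen` attribute carrying monitor geometry.
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) stop("ROI config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$arrays)) stop("ROI config lacks 'arrays'", call. = FALSE)
  arrays <- cfg$arrays
  rois <- purrr::map_dfr(seq_len(nrow(arrays)), function(i) {
    r <- arrays$rois[[i]]
    tibble::tibble(
      array_id = as.integer(arrays$array_id[[i]]),
      label = r$label,
      x0 = as.numeric(r$x0), y0 = as.numeric(r$y0),
      width = as.numeric(r$width), height = as.numeric(r$height)
    )
  })
  attr(rois, "screen") <- cfg$screen
  validate_roi_set(rois)
  rois
}

#' Write an ROI configuration
#' @param roi_set An ROI-set tibble as returned by [read_roi_config()].
#' @param path Output path.
#' @export
write_roi_config <- function(roi_set, path) {
  validate_roi_set(roi_set)
  ids <- unique(roi_set$array_id)
  cfg <- list(
    screen = attr(roi_set, "screen"),
    arrays = lapply(ids, function(a) {
      r <- roi_set[roi_set$array_id == a, ]
      list(
        array_id = a,
        rois = data.frame(
          label = r$label, x0 = r$x0, y0 = r$y0,
          width = r$width, height = r$height
        )
      )
    })
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate an ROI set
#'
#' Checks, per array: exactly one `eyes` and one `center` rectangle plus three
#' distractors; the four stimulus rectangles share one size; no two rectangles
#' overlap (rectangles are half-open, so rectangles sharing an edge do not
#' overlap). Errors name the offending array.
#'
#' @param roi_set An ROI-set tibble.
#' @export
validate_roi_set <- function(roi_set) {
  needed <- c("array_id", "label", "x0", "y0", "width", "height")
  missing_cols <- setdiff(needed, names(roi_set))
  if (length(missing_cols)) {
    stop("ROI set lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (a in unique(roi_set$array_id)) {
    r <- roi_set[roi_set$array_id == a, ]
    if (sum(r$label == "eyes") != 1L) {
      stop("array ", a, ": must contain exactly one 'eyes' ROI", call. = FALSE)
    }
    if (sum(r$label == "center") != 1L) {
      stop("array ", a, ": must contain exactly one 'center' ROI",
           call. = FALSE)
    }
    if (!setequal(r$label, c(stimulus_roi_labels, "center"))) {
      stop("array ", a, ": labels must be eyes, distractor_1..3, center",
           call. = FALSE)
    }
    stim <- r[r$label %in% stimulus_roi_labels, ]
    if (length(unique(stim$width)) != 1L || length(unique(stim$height)) != 1L) {
      stop("array ", a, ": stimulus ROIs must be of equal size", call. = FALSE)
    }
    n <- nrow(r)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (rects_overlap(r[i, ], r[j, ])) {
          stop("array ", a, ": ROIs '", r$label[i], "' and '", r$label[j],
               "' overlap", call. = FALSE)
        }
      }
    }
  }
  invisible(roi_set)
}

rects_overlap <- function(a, b) {
  a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width &&
    a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height
}

#' Test whether points fall inside an ROI rectangle
#'
#' Membership is half-open on both axes: a point is inside iff
#' `x0 <= x < x0 + width` and `y0 <= y < y0 + height`, so a point on a shared
#' edge belongs to exactly one of two adjacent rectangles. Missing coordinates
#' are never inside.
#'
#' @param x,y Point coordinates in pixels (vectorised).
#' @param rect A single ROI row or list with `x0, y0, width, height`.
#' @return Logical vector.
#' @export
point_in_roi <- function(x, y, rect) {
  inside <- x >= rect$x0 & x < rect$x0 + rect$width &
    y >= rect$y0 & y < rect$y0 + rect$height
  inside & !is.na(inside)
}

#' Look up one rectangle of an ROI set
#' @param roi_set An ROI-set tibble.
#' @param array_id Array number.
#' @param label ROI label, e.g. `"eyes"` or `"center"`.
#' @return A one-row tibble.
#' @export
roi_rect <- function(roi_set, array_id, label) {
  r <- roi_set[roi_set$array_id == array_id & roi_set$label == label, ]
  if (nrow(r) != 1L) {
    stop("no unique ROI '", label, "' in array ", array_id, call. = FALSE)
  }
  r
}

#' Read a participant trait table
#'
#' CSV with `participant_id`, `srs_total` (Social Responsiveness Scale raw
#' total, parent report, indexing autistic traits) and `spaic_total` (Social
#' Phobia and Anxiety Inventory for Children raw total, self report). Optional
#' columns: the five SRS subscales (`srs_awareness, srs_communication,
#' srs_cognition, srs_motivation, srs_rirb`), `sex`, `age`. Scores must be
#' non-negative; a missing SPAI-C score is permitted.
#'
#' @param path Path to the trait CSV.
#' @return A tibble, one row per participant.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  traits <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("participant_id", "srs_total", "spaic_total")
  missing_cols <- setdiff(required, names(traits))
  if (length(missing_cols)) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  score_cols <- intersect(
    c("srs_total", "spaic_total", "srs_awareness", "srs_communication",
      "srs_cognition", "srs_motivation", "srs_rirb"),
    names(traits)
  )
  for (col in score_cols) {
    if (any(traits[[col]] < 0, na.rm = TRUE)) {
      stop("negative score(s) in column ", col, call. = FALSE)
    }
  }
  if (anyNA(traits$srs_total)) {
    stop("srs_total must not be missing", call. = FALSE)
  }
  traits
}

#' Write a participant trait table
#' @param traits A trait tibble.
#' @param path Output path.
#' @export
write_trait_table <- function(traits, path) {
  readr::write_csv(traits, path, progress = FALSE)
  invisible(path)
}
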