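# Statistics layer: Pearson and partial correlations with exact t tests,
# Steiger's Z for comparing dependent correlations, Cook's-distance outlier
# screening, Shapiro-Wilk normality screening, the paired cued/silent
# contrast, and the orchestrating association analysis.

complete_pairs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Pearson correlation with exact t test
#'
#' Product-moment correlation on pairwise-complete observations, with
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom and a
#' two-tailed p value.
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped
#'   and the complete-case `n` reported.
#' @return A one-row tibble: `r, n, t_stat, df, p_value, controlled_for`
#'   (`NA` for a zero-order correlation).
#' @export
pearson_corr <- function(x, y) {
  cc <- complete_pairs(x, y)
  if (cc$n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(cc$x) == 0 || stats::sd(cc$y) == 0) {
    stop("correlation undefined: a variable has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(cc$x, cc$y, method = "pearson",
                        alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate),
    n = cc$n,
    t_stat = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    controlled_for = NA_character_
  )
}

#' Partial correlation controlling one covariate
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, tested with
#' `t = r * sqrt((n - 3) / (1 - r^2))` on `n - 3` degrees of freedom
#' (two-tailed). Equivalent to the Pearson correlation of the least-squares
#' residuals of `x` and `y` on `z`.
#'
#' @param x,y Variables to correlate.
#' @param z Covariate partialled out of both.
#' @param label Name recorded in `controlled_for`.
#' @return A one-row tibble as in [pearson_corr()], with `df = n - 3`.
#' @export
partial_corr <- function(x, y, z, label = "z") {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  n <- sum(ok)
  if (n < 5L) stop("need at least 5 complete triples", call. = FALSE)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  out <- partial_corr_from_r(stats::cor(x, y), stats::cor(x, z),
                             stats::cor(y, z), n)
  out$controlled_for <- label
  out
}

#' @rdname partial_corr
#'
#' @param r_xy,r_xz,r_yz Zero-order correlations among the two variables and
#'   the covariate.
#' @param n Sample size the correlations were computed on.
#' @export
partial_corr_from_r <- function(r_xy, r_xz, r_yz, n) {
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("degenerate control: covariate collinear with a variable",
         call. = FALSE)
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  df <- n - 3L
  t_stat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    r = r,
    n = n,
    t_stat = t_stat,
    df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    controlled_for = "r-input"
  )
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Compares `r12` and `r13` (two correlations sharing variable 1) given the
#' correlation `r23` between the non-shared variables, using the
#' Fisher-transform form with a pooled coefficient:
#' `rbar = (r12 + r13)/2`;
#' `psi_bar = r23 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r23^2)/2`;
#' `s_bar = psi_bar / (1 - rbar^2)^2`;
#' `Z = (z(r12) - z(r13)) sqrt((n - 3) / (2 (1 - s_bar)))`
#' with `z()` the Fisher transform, referred to the standard normal
#' (two-tailed). `Z` is exactly antisymmetric in `r12, r13` and zero when
#' they are equal.
#'
#' @param r12,r13 The two correlations being compared.
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (>= 10).
#' @return A one-row tibble: `r12, r13, r23, n, rbar, psi_bar, s_bar, z,
#'   p_value`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (n < 10L) stop("need n >= 10", call. = FALSE)
  rbar <- (r12 + r13) / 2
  psi_bar <- r23 * (1 - 2 * rbar^2) -
    0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  s_bar <- psi_bar / (1 - rbar^2)^2
  if (s_bar >= 1) {
    stop("degenerate configuration: pooled covariance term s_bar >= 1",
         call. = FALSE)
  }
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 * (1 - s_bar)))
  tibble::tibble(
    r12 = r12, r13 = r13, r23 = r23, n = n,
    rbar = rbar, psi_bar = psi_bar, s_bar = s_bar,
    z = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Cook's-distance influence diagnostics for a simple regression
#'
#' Fits `y ~ x` by least squares and reports, per complete-case observation,
#' the residual, the leverage `h_ii`, Cook's distance, and a flag for
#' `D_i > threshold` (default rule `4/n`; the sum of leverages is 2 for a
#' simple regression).
#'
#' @param x Predictor.
#' @param y Response.
#' @param threshold Flagging cutoff; either a number or the default rule
#'   `4 / n`.
#' @return A tibble with one row per complete-case observation: `index`
#'   (position in the input vectors), `x, y, residual, leverage, cooks_d,
#'   flagged`; the cutoff used is attached as `attr(, "threshold")`.
#' @export
cooks_distance_screen <- function(x, y, threshold = NULL) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0) {
    stop("degenerate design: predictor is constant", call. = FALSE)
  }
  if (is.null(threshold)) threshold <- 4 / n
  fit <- stats::lm(ys ~ xs)
  out <- tibble::tibble(
    index = which(ok),
    x = xs,
    y = ys,
    residual = unname(stats::residuals(fit)),
    leverage = unname(stats::hatvalues(fit)),
    cooks_d = unname(stats::cooks.distance(fit)),
    flagged = unname(stats::cooks.distance(fit)) > threshold
  )
  attr(out, "threshold") <- threshold
  out
}

#' Paired t test for the cued/silent contrast
#'
#' Two-tailed paired t on complete pairs: `t = mean(d) / (sd(d)/sqrt(n))` with
#' `n - 1` degrees of freedom. A degenerate difference vector (identical
#' non-zero differences) is an error; identical vectors give `t = 0, p = 1`.
#'
#' @param a,b Paired numeric vectors (e.g. per-participant silent and cued
#'   mean latencies).
#' @return A one-row tibble: `mean_diff, t_stat, df, p_value, n`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length",
                                   call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- a[ok] - b[ok]
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(mean_diff = 0, t_stat = 0, df = n - 1L,
                            p_value = 1, n = n))
    }
    stop("undefined test: differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
  tibble::tibble(
    mean_diff = unname(tt$estimate),
    t_stat = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n = n
  )
}

#' Shapiro-Wilk normality screen
#'
#' Reported as a screening statistic only; no downstream step switches on its
#' outcome.
#'
#' @param x Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return A one-row tibble: `W, p_value, n`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("undefined for a constant vector", call. = FALSE)
  sw <- stats::shapiro.test(x)
  tibble::tibble(W = unname(sw$statistic), p_value = sw$p.value, n = n)
}

#' Association-analysis configuration
#'
#' @param apply_cooks Screen each measure-trait pair for bivariate outliers by
#'   Cook's distance before correlating (default `TRUE`).
#' @param cooks_threshold `NULL` for the `4/n` rule, or a fixed numeric
#'   cutoff.
#' @param subscales Also correlate the SRS subscales with latency (default
#'   `TRUE` when subscale columns are present).
#' @param min_n Minimum number of participants with both measures and both
#'   trait scores (default 10).
#' @return An `assoc_config` list.
#' @export
assoc_config <- function(apply_cooks = TRUE, cooks_threshold = NULL,
                         subscales = TRUE, min_n = 10L) {
  if (length(cooks_threshold) == 0L) cooks_threshold <- NULL
  if (!is.null(cooks_threshold)) {
    stopifnot(is.numeric(cooks_threshold), length(cooks_threshold) == 1L,
              cooks_threshold > 0)
  }
  structure(
    list(apply_cooks = apply_cooks, cooks_threshold = cooks_threshold,
         subscales = subscales, min_n = as.integer(min_n)),
    class = "assoc_config"
  )
}

srs_subscale_cols <- c("srs_awareness", "srs_communication", "srs_cognition",
                       "srs_motivation", "srs_rirb")

# One measure-trait pair: optional Cook's screening on the pair, zero-order
# Pearson on the screened cases, partial correlation controlling the other
# trait on the screened complete triples.
pair_analysis <- function(data, measure, trait, other_trait, config) {
  x <- data[[trait]]
  y <- data[[measure]]
  z <- data[[other_trait]]
  removed <- integer()
  if (config$apply_cooks) {
    diag <- cooks_distance_screen(x, y, threshold = config$cooks_threshold)
    removed <- diag$index[diag$flagged]
    if (length(removed)) {
      x[removed] <- NA; y[removed] <- NA; z[removed] <- NA
    }
  }
  zero <- pearson_corr(x, y)
  part <- partial_corr(x, y, z, label = other_trait)
  list(zero = zero, partial = part, n_removed = length(removed),
       removed = removed)
}

result_row <- function(analysis, measure, predictor, covariate, n, estimate,
                       statistic, df, p_value, n_removed = 0L) {
  tibble::tibble(
    analysis = analysis, measure = measure, predictor = predictor,
    covariate = covariate, n = n, estimate = estimate,
    statistic = statistic, df = df, p_value = p_value,
    n_removed_outliers = n_removed
  )
}

#' Run the full association analysis
#'
#' For each attention measure (mean latency to the eyes; mean first-pass
#' dwell) and each trait (SRS autistic traits; SPAI-C social anxiety):
#' zero-order Pearson correlation and partial correlation controlling the
#' other trait, each after per-pair Cook's-distance screening; Steiger's Z
#' comparing the two traits' correlations with each measure (on unscreened
#' complete cases); the trait intercorrelation; the paired cued/silent
#' latency contrast over contrast-eligible participants; a Shapiro-Wilk
#' screen of every analysis variable; and, when subscale columns are present,
#' SRS-subscale correlations with latency (zero-order and SPAI-C-partialled).
#'
#' @param summaries Participant summaries from [summarize_cohort()].
#' @param traits Trait table (see [read_trait_table()]).
#' @param config An [assoc_config()] list.
#' @return A tibble with one row per test: `analysis, measure, predictor,
#'   covariate, n, estimate, statistic, df, p_value, n_removed_outliers`.
#' @export
run_association_analysis <- function(summaries, traits,
                                     config = assoc_config()) {
  data <- dplyr::inner_join(summaries, traits, by = "participant_id")
  complete <- is.finite(data$mean_latency_ms) &
    is.finite(data$mean_dwell_ms) & is.finite(data$srs_total) &
    is.finite(data$spaic_total)
  if (sum(complete) < config$min_n) {
    stop("insufficient sample: ", sum(complete),
         " participants with both measures and both traits (need ",
         config$min_n, ")", call. = FALSE)
  }

  measures <- c(latency = "mean_latency_ms", dwell = "mean_dwell_ms")
  trait_cols <- c(SRS = "srs_total", `SPAI-C` = "spaic_total")
  rows <- list()

  for (mi in seq_along(measures)) {
    mname <- names(measures)[mi]; mcol <- measures[[mi]]
    for (ti in seq_along(trait_cols)) {
      tname <- names(trait_cols)[ti]; tcol <- trait_cols[[ti]]
      oname <- names(trait_cols)[-ti]; ocol <- trait_cols[[-ti]]
      pa <- pair_analysis(data, mcol, tcol, ocol, config)
      rows[[length(rows) + 1L]] <- result_row(
        "pearson", mname, tname, NA_character_, pa$zero$n, pa$zero$r,
        pa$zero$t_stat, pa$zero$df, pa$zero$p_value, pa$n_removed
      )
      rows[[length(rows) + 1L]] <- result_row(
        "partial", mname, tname, oname, pa$partial$n, pa$partial$r,
        pa$partial$t_stat, pa$partial$df, pa$partial$p_value, pa$n_removed
      )
    }
    # Steiger comparison of the two traits' correlations with this measure
    cc <- data[is.finite(data[[mcol]]) & is.finite(data$srs_total) &
                 is.finite(data$spaic_total), ]
    st <- steiger_z(
      stats::cor(cc[[mcol]], cc$srs_total),
      stats::cor(cc[[mcol]], cc$spaic_total),
      stats::cor(cc$srs_total, cc$spaic_total),
      nrow(cc)
    )
    rows[[length(rows) + 1L]] <- result_row(
      "steiger", mname, "SRS", "SPAI-C", st$n, st$z, st$z, NA_real_,
      st$p_value
    )
  }

  tc <- pearson_corr(data$srs_total, data$spaic_total)
  rows[[length(rows) + 1L]] <- result_row(
    "pearson", "traits", "SRS", NA_character_, tc$n, tc$r, tc$t_stat, tc$df,
    tc$p_value
  )

  eligible <- data[data$contrast_eligible, ]
  if (nrow(eligible) >= 2L &&
      sum(is.finite(eligible$mean_latency_silent_ms) &
            is.finite(eligible$mean_latency_cued_ms)) >= 2L) {
    pt <- tryCatch(
      paired_t(eligible$mean_latency_silent_ms,
               eligible$mean_latency_cued_ms),
      error = function(e) NULL
    )
    if (!is.null(pt)) {
      rows[[length(rows) + 1L]] <- result_row(
        "paired_t", "latency", "silent_vs_cued", NA_character_, pt$n,
        pt$mean_diff, pt$t_stat, pt$df, pt$p_value
      )
    }
  }

  screen_vars <- c(measures, trait_cols)
  screen_names <- c(names(measures), names(trait_cols))
  for (i in seq_along(screen_vars)) {
    sw <- shapiro_wilk(data[[screen_vars[[i]]]])
    rows[[length(rows) + 1L]] <- result_row(
      "shapiro_wilk", screen_names[i], NA_character_, NA_character_, sw$n,
      sw$W, sw$W, NA_real_, sw$p_value
    )
  }

  if (config$subscales && all(srs_subscale_cols %in% names(data))) {
    for (sub in srs_subscale_cols) {
      if (sum(is.finite(data[[sub]])) < config$min_n) next
      zc <- pearson_corr(data[[sub]], data$mean_latency_ms)
      pc <- partial_corr(data[[sub]], data$mean_latency_ms,
                         data$spaic_total, label = "SPAI-C")
      rows[[length(rows) + 1L]] <- result_row(
        "pearson", "latency", sub, NA_character_, zc$n, zc$r, zc$t_stat,
        zc$df, zc$p_value
      )
      rows[[length(rows) + 1L]] <- result_row(
        "partial", "latency", sub, "SPAI-C", pc$n, pc$r, pc$t_stat, pc$df,
        pc$p_value
      )
    }
  }

  dplyr::bind_rows(rows)
}

#' Render a human-readable report of the association results
#' @param results The tibble from [run_association_analysis()].
#' @return A character vector of report lines.
#' @export
format_association_report <- function(results) {
  fmt_p <- function(p) ifelse(p < .001, "< .001", sprintf("= %.3f", p))
  lines <- c("Association analysis", "====================", "")
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    lines <- c(lines, switch(
      r$analysis,
      pearson = sprintf(
        "r(%s, %s) = %.3f, n = %d, t(%d) = %.2f, p %s%s",
        r$measure, r$predictor, r$estimate, r$n, as.integer(r$df),
        r$statistic, fmt_p(r$p_value),
        ifelse(r$n_removed_outliers > 0,
               sprintf("  [%d outlier(s) removed]", r$n_removed_outliers), "")
      ),
      partial = sprintf(
        "r(%s, %s | %s) = %.3f, n = %d, t(%d) = %.2f, p %s",
        r$measure, r$predictor, r$covariate, r$estimate, r$n,
        as.integer(r$df), r$statistic, fmt_p(r$p_value)
      ),
      steiger = sprintf(
        "Steiger Z (%s: %s vs %s) = %.3f, n = %d, p %s",
        r$measure, r$predictor, r$covariate, r$estimate, r$n,
        fmt_p(r$p_value)
      ),
      paired_t = sprintf(
        "paired t (%s, silent - cued): diff = %.1f ms, t(%d) = %.2f, p %s",
        r$measure, r$estimate, as.integer(r$df), r$statistic,
        fmt_p(r$p_value)
      ),
      shapiro_wilk = sprintf(
        "Shapiro-Wilk (%s): W = %.3f, n = %d, p %s",
        r$measure, r$estimate, r$n, fmt_p(r$p_value)
      ),
      sprintf("%s: estimate = %.3f, p %s", r$analysis, r$estimate,
              fmt_p(r$p_value))
    ))
  }
  lines
}
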