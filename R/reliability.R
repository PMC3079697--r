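#' One-way variance components for paired test-retest scores
#'
#' Decomposes paired (T0, T1) scores with a one-way random-effects ANOVA,
#' subjects as the random factor and k = 2 replicates per subject:
#' `MSW = sum_ij (x_ij - xbar_i)^2 / (n (k - 1))`,
#' `MSB = k * sum_i (xbar_i - xbar)^2 / (n - 1)`. The error variance is MSW;
#' the between-subject variance is `(MSB - MSW) / k`, truncated at zero.
#' Incomplete pairs are dropped with a warning.
#'
#' @param t0,t1 Numeric vectors of scores at the two administrations.
#' @return An object of class `variance_components`: list with `n`, `k`,
#'   `msb`, `msw`, `between_var`, `error_var`.
#' @export
variance_components <- function(t0, t1) {
  if (length(t0) != length(t1)) {
    stop("`t0` and `t1` must have the same length", call. = FALSE)
  }
  complete <- !is.na(t0) & !is.na(t1)
  if (any(!complete)) {
    warning(sum(!complete), " incomplete pair(s) excluded", call. = FALSE)
    t0 <- t0[complete]
    t1 <- t1[complete]
  }
  n <- length(t0)
  if (n < 2) {
    stop("at least 2 complete pairs are required", call. = FALSE)
  }
  k <- 2
  m <- (t0 + t1) / 2
  g <- mean(m)
  msb <- k * sum((m - g)^2) / (n - 1)
  msw <- sum((t0 - m)^2 + (t1 - m)^2) / (n * (k - 1))
  structure(list(n = n, k = k, msb = msb, msw = msw,
                 between_var = max(0, (msb - msw) / k), error_var = msw),
            class = "variance_components")
}

#' One-way intraclass correlation with exact F confidence interval
#'
#' ICC(1,1): the between-subject variance divided by total variance,
#' computed as `(MSB - MSW) / (MSB + (k - 1) MSW)`. Negative values are
#' reported as computed (no truncation), since genuinely unreliable scores
#' can produce small negative estimates. The confidence interval is the
#' exact one-way F interval: with `F = MSB/MSW` on (n - 1, n(k - 1))
#' degrees of freedom, the bounds are `(F/Fu - 1)/(F/Fu + k - 1)` and
#' `(F*Fl - 1)/(F*Fl + k - 1)` where `Fu = qf(1 - a/2, n - 1, n(k - 1))`
#' and `Fl = qf(1 - a/2, n(k - 1), n - 1)`.
#'
#' @param vc A [variance_components()] object.
#' @param conf Confidence level (default 0.95).
#' @return A list with `icc`, `lower`, `upper`, `n`, `k`, `conf`.
#' @export
icc_oneway <- function(vc, conf = 0.95) {
  stopifnot(inherits(vc, "variance_components"))
  n <- vc$n
  k <- vc$k
  if (vc$msw == 0) {
    icc <- if (vc$msb > 0) 1 else NA_real_
    return(list(icc = icc, lower = icc, upper = icc, n = n, k = k,
                conf = conf))
  }
  icc <- (vc$msb - vc$msw) / (vc$msb + (k - 1) * vc$msw)
  alpha <- 1 - conf
  f <- vc$msb / vc$msw
  fl <- f / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  list(icc = icc,
       lower = (fl - 1) / (fl + k - 1),
       upper = (fu - 1) / (fu + k - 1),
       n = n, k = k, conf = conf)
}

#' Standard error of measurement and smallest detectable difference
#'
#' The SEM is the square root of the error variance; the smallest detectable
#' difference at 95% confidence is `SDD95 = 1.96 * sqrt(2) * SEM`, the
#' change a single subject must exceed before it can be attributed to real
#' change rather than measurement error.
#'
#' @param x Either a [variance_components()] object or a numeric error
#'   variance (score units squared).
#' @return A list with `sem` and `sdd95`.
#' @export
#' @examples
#' sem_sdd(663^2)
sem_sdd <- function(x) {
  error_var <- if (inherits(x, "variance_components")) x$error_var else x
  if (!is.numeric(error_var) || length(error_var) != 1 || error_var < 0) {
    stop("`x` must be a variance_components object or a single ",
         "non-negative error variance", call. = FALSE)
  }
  sem <- sqrt(error_var)
  list(sem = sem, sdd95 = 1.96 * sqrt(2) * sem)
}

#' Measurement range, SDD/range ratio and distinguishable steps
#'
#' The observed measurement range `range95` is the difference between the
#' 97.5th and 2.5th percentiles of the pooled T0 and T1 values (linear
#' interpolation between order statistics, `quantile(type = 7)`), which
#' excludes outliers from the range. The ratio `sdd95 / range95` expresses
#' measurement error relative to the scale's usable range; its reciprocal,
#' rounded half away from zero, is the number of SDD-sized steps the
#' instrument can distinguish across the range. A ratio of at most 0.20
#' (at least ~5 steps) is considered small enough for clinical use.
#'
#' @param values Numeric vector of pooled observed scores (typically
#'   `c(t0, t1)`).
#' @param sdd95 Smallest detectable difference from [sem_sdd()].
#' @return A list with `range95`, `ratio`, `steps`,
#'   `clinically_useful` (`ratio <= 0.20`).
#' @export
range95_ratio_steps <- function(values, sdd95) {
  if (sdd95 < 0) stop("`sdd95` must be non-negative", call. = FALSE)
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("at least 2 observed values are required", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  range95 <- q[2] - q[1]
  if (range95 == 0) {
    warning("range95 is zero; ratio and steps undefined", call. = FALSE)
    return(list(range95 = 0, ratio = NA_real_, steps = NA_real_,
                clinically_useful = NA))
  }
  ratio <- sdd95 / range95
  steps <- if (sdd95 == 0) NA_real_ else round_half_away(range95 / sdd95)
  list(range95 = range95, ratio = ratio, steps = steps,
       clinically_useful = ratio <= 0.20)
}

#' Qualitative rating of an ICC
#'
#' Below 0.40 is poor, 0.40 up to 0.60 fair, 0.60 up to 0.75 good, and 0.75
#' and above excellent. The published scheme leaves the intervals
#' (0.59, 0.60) and (0.74, 0.75) unassigned; they are closed downward
#' (fair and good respectively).
#'
#' @param icc Numeric vector of ICC values.
#' @return Character vector: `"poor"`, `"fair"`, `"good"` or `"excellent"`.
#' @export
#' @examples
#' rate_icc(c(-0.001, 0.45, 0.70, 0.90))
rate_icc <- function(icc) {
  if (any(!is.finite(icc))) stop("`icc` must be finite", call. = FALSE)
  as.character(cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
                   right = FALSE,
                   labels = c("poor", "fair", "good", "excellent")))
}

#' Test-retest reliability table for a set of scores
#'
#' Produces one row per score with the layout of a reliability results
#' table: medians and quartiles at each administration, one-way ICC with
#' exact 95% CI, SEM, SDD95, SDD95/range95 ratio, distinguishable steps,
#' the qualitative ICC rating, and a clinical-usefulness flag
#' (ratio <= 0.20). Only subjects with both administrations enter each
#' row's analysis.
#'
#' @param scores A long tibble with columns `subject_id`, `visit`
#'   (values `"T0"`/`"T1"`), `score` (score name) and `value`.
#' @param conf Confidence level for the ICC interval.
#' @return A tibble with one row per score.
#' @export
reliability_table <- function(scores, conf = 0.95) {
  req <- c("subject_id", "visit", "score", "value")
  miss <- setdiff(req, names(scores))
  if (length(miss)) {
    stop("`scores` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(unique(scores$score), function(s) {
    wide <- scores |>
      dplyr::filter(.data$score == s) |>
      tidyr::pivot_wider(id_cols = "subject_id", names_from = "visit",
                         values_from = "value")
    vc <- variance_components(wide$T0, wide$T1)
    ic <- icc_oneway(vc, conf)
    ss <- sem_sdd(vc)
    complete <- !is.na(wide$T0) & !is.na(wide$T1)
    rr <- range95_ratio_steps(c(wide$T0[complete], wide$T1[complete]),
                              ss$sdd95)
    q0 <- stats::quantile(wide$T0, c(0.5, 0.25, 0.75), na.rm = TRUE,
                          names = FALSE, type = 7)
    q1 <- stats::quantile(wide$T1, c(0.5, 0.25, 0.75), na.rm = TRUE,
                          names = FALSE, type = 7)
    tibble::tibble(
      score = s, n = vc$n,
      t0_median = q0[1], t0_p25 = q0[2], t0_p75 = q0[3],
      t1_median = q1[1], t1_p25 = q1[2], t1_p75 = q1[3],
      icc = ic$icc, icc_lower = ic$lower, icc_upper = ic$upper,
      sem = ss$sem, sdd95 = ss$sdd95,
      range95 = rr$range95, ratio = rr$ratio, steps = rr$steps,
      rating = rate_icc(ic$icc),
      clinically_useful = rr$clinically_useful
    )
  })
}
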