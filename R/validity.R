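#' Spearman rank correlation with t or permutation p-value
#'
#' Computes the Spearman coefficient with average ranks for ties. The
#' default p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`
#' on n - 2 degrees of freedom (two-sided), the mainstream choice at the
#' sample sizes of validation studies. For small samples a permutation
#' p-value is available: exact enumeration of all n! orderings when
#' n <= 8, otherwise Monte-Carlo with `n_perm` random permutations.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @param p_method `"t"` (default), `"permutation"` or `"exact"`.
#' @param n_perm Number of random permutations for `"permutation"`.
#' @param seed Seed for the Monte-Carlo permutation draw.
#' @return A list with `rho`, `p_value`, `n`, `adequate`
#'   (`rho >= 0.50`, the conventional adequacy bound for construct
#'   validity of activity questionnaires).
#' @export
#' @examples
#' spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
spearman_cor <- function(x, y, p_method = c("t", "permutation", "exact"),
                         n_perm = 10000, seed = 1) {
  p_method <- match.arg(p_method)
  complete <- !is.na(x) & !is.na(y)
  x <- x[complete]
  y <- y[complete]
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input; Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, adequate = NA))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- switch(
    p_method,
    t = {
      tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
      2 * stats::pt(-abs(tt), df = n - 2)
    },
    exact = {
      if (n > 8) stop("exact enumeration supported for n <= 8", call. = FALSE)
      perms <- all_permutations(n)
      rho_perm <- apply(perms, 1, function(p_) stats::cor(rx, ry[p_]))
      mean(abs(rho_perm) >= abs(rho) - 1e-12)
    },
    permutation = {
      set.seed(seed)
      rho_perm <- replicate(n_perm, stats::cor(rx, sample(ry)))
      (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    }
  )
  list(rho = rho, p_value = p, n = n, adequate = rho >= 0.50)
}

# All permutations of 1..n, one per row (n at every insertion position of
# each (n-1)-permutation).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1)
      row <- row + 1L
    }
  }
  out
}

#' Agreement ICC between two measurement methods
#'
#' Intraclass correlation treating the two methods (for example a
#' questionnaire and an accelerometer, both in min/week) as the two
#' "replicates" per subject. The default is the two-way consistency form
#' ICC(C,1), `(MSR - MSE) / (MSR + (k - 1) MSE)` from a two-way model that
#' removes the systematic method difference: self-report instruments and
#' accelerometers differ in level by construction, and the consistency form
#' measures whether they rank and space subjects the same way despite that
#' offset. The one-way absolute form of [icc_oneway()] (which charges the
#' method offset to error) is available with `type = "oneway"`. Confidence
#' intervals use the corresponding exact F interval.
#'
#' @param a,b Paired numeric vectors, one value per subject per method.
#' @param type `"consistency"` (default) or `"oneway"`.
#' @param conf Confidence level.
#' @return A list with `icc`, `lower`, `upper`, `n`, `type`.
#' @export
agreement_icc <- function(a, b, type = c("consistency", "oneway"),
                          conf = 0.95) {
  type <- match.arg(type)
  complete <- !is.na(a) & !is.na(b)
  a <- a[complete]
  b <- b[complete]
  n <- length(a)
  if (n < 2) stop("at least 2 complete pairs are required", call. = FALSE)
  if (type == "oneway") {
    vc <- variance_components(a, b)
    ic <- icc_oneway(vc, conf)
    return(list(icc = ic$icc, lower = ic$lower, upper = ic$upper, n = n,
                type = type))
  }
  k <- 2
  m <- (a + b) / 2
  g <- mean(m)
  col_eff <- c(mean(a) - g, mean(b) - g)
  msr <- k * sum((m - g)^2) / (n - 1)
  sse <- sum((a - m - col_eff[1])^2 + (b - m - col_eff[2])^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (mse == 0) {
    icc <- if (msr > 0) 1 else NA_real_
    return(list(icc = icc, lower = icc, upper = icc, n = n, type = type))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  alpha <- 1 - conf
  f <- msr / mse
  df2 <- (n - 1) * (k - 1)
  fl <- f / stats::qf(1 - alpha / 2, n - 1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, n - 1)
  list(icc = icc,
       lower = (fl - 1) / (fl + k - 1),
       upper = (fu - 1) / (fu + k - 1),
       n = n, type = type)
}

#' Fraction of subjects below an activity guideline
#'
#' The American College of Sports Medicine recommends at least 150 minutes
#' of moderate-intensity activity per week; this returns the fraction of
#' subjects not meeting the threshold (strictly below it).
#'
#' @param moderate_min_per_wk Numeric vector of weekly moderate-intensity
#'   minutes, one per subject.
#' @param threshold Guideline threshold in min/week (default 150).
#' @return Fraction non-compliant in `[0, 1]`, or `NA` for empty input.
#' @export
#' @examples
#' acsm_noncompliance(c(0, 149, 150, 300))
acsm_noncompliance <- function(moderate_min_per_wk, threshold = 150) {
  x <- moderate_min_per_wk[!is.na(moderate_min_per_wk)]
  if (any(x < 0)) stop("min/week values must be non-negative", call. = FALSE)
  if (length(x) == 0) {
    warning("no values; non-compliance undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(x < threshold)
}

#' Median and quartiles
#'
#' Descriptive summary used in results tables: median, 25th and 75th
#' percentile, with the same linear-interpolation convention
#' (`quantile(type = 7)`) as the range95 computation.
#'
#' @param values Numeric vector (missing values dropped).
#' @return A tibble with columns `median`, `p25`, `p75`, `n`.
#' @export
quartile_summary <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 1) stop("at least one value is required", call. = FALSE)
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  tibble::tibble(median = q[1], p25 = q[2], p75 = q[3], n = length(x))
}

#' Study response rate as a whole percentage
#'
#' @param n_participating Number of subjects who agreed to participate.
#' @param n_eligible Number of eligible subjects approached.
#' @return Response rate as a percentage rounded to the nearest whole
#'   number (half away from zero).
#' @export
#' @examples
#' response_rate(53, 105)
response_rate <- function(n_participating, n_eligible) {
  if (n_eligible <= 0 || n_participating < 0 ||
      n_participating > n_eligible) {
    stop("need 0 <= n_participating <= n_eligible, n_eligible > 0",
         call. = FALSE)
  }
  round_half_away(100 * n_participating / n_eligible)
}

#' Construct-validity table: questionnaires versus accelerometer
#'
#' Builds a results table comparing questionnaire scores at one
#' administration with accelerometer summaries on the subjects the
#' accelerometer inclusion rule retains (>= 5 valid days). Total scores are
#' correlated (Spearman) with overall counts/min; min/week scores get
#' agreement ICCs against the matching accelerometer band. Excluded
#' subjects are dropped with a message and `n_included` records the
#' analysed sample size.
#'
#' @param scores Long tibble (`subject_id`, `visit`, `score`, `value`);
#'   the `visit` given by `use_visit` is analysed.
#' @param accel_summaries Tibble from [summarize_cohort()].
#' @param use_visit Which administration to compare (default `"T0"`).
#' @param conf Confidence level for agreement ICCs.
#' @return A tibble with one row per comparison: instrument, score, median
#'   and quartiles, `rho`, `p_value`, `adequate`, `icc`, `icc_lower`,
#'   `icc_upper`, `n_included`.
#' @export
validity_table <- function(scores, accel_summaries, use_visit = "T0",
                           conf = 0.95) {
  included <- accel_summaries[accel_summaries$included, ]
  excluded <- setdiff(accel_summaries$subject_id, included$subject_id)
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " subject(s) with < 5 valid wearing days: ",
            paste(excluded, collapse = ", "))
  }
  if (nrow(included) == 0) {
    warning("no accelerometer-included subjects; validity table is empty",
            call. = FALSE)
    return(tibble::tibble(instrument = character(), score = character(),
                          median = double(), p25 = double(), p75 = double(),
                          rho = double(), p_value = double(),
                          adequate = logical(), icc = double(),
                          icc_lower = double(), icc_upper = double(),
                          n_included = integer()))
  }
  wide <- scores |>
    dplyr::filter(.data$visit == use_visit,
                  .data$subject_id %in% included$subject_id) |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "score",
                       values_from = "value") |>
    dplyr::inner_join(included, by = "subject_id")

  acc_rows <- purrr::map_dfr(
    c(counts_per_min = "counts_per_min", total_pa = "total_pa_min_wk",
      light = "light_min_wk", mvpa = "mvpa_min_wk",
      sedentary = "sedentary_min_wk"),
    function(col) quartile_summary(wide[[col]]),
    .id = "score") |>
    dplyr::mutate(instrument = "actigraph")

  spearman_row <- function(instrument, score_col) {
    sp <- spearman_cor(wide[[score_col]], wide$counts_per_min)
    dplyr::bind_cols(
      tibble::tibble(instrument = instrument, score = score_col),
      quartile_summary(wide[[score_col]]),
      tibble::tibble(rho = sp$rho, p_value = sp$p_value,
                     adequate = sp$adequate))
  }
  icc_row <- function(instrument, score_col, accel_col) {
    ai <- agreement_icc(wide[[score_col]], wide[[accel_col]], conf = conf)
    dplyr::bind_cols(
      tibble::tibble(instrument = instrument, score = score_col),
      quartile_summary(wide[[score_col]]),
      tibble::tibble(icc = ai$icc, icc_lower = ai$lower,
                     icc_upper = ai$upper))
  }
  quest_rows <- dplyr::bind_rows(
    spearman_row("aquaa", "aquaa_score"),
    icc_row("aquaa", "aquaa_total_pa", "total_pa_min_wk"),
    icc_row("aquaa", "aquaa_light", "light_min_wk"),
    icc_row("aquaa", "aquaa_mvpa", "mvpa_min_wk"),
    icc_row("aquaa", "aquaa_sedentary", "sedentary_min_wk"),
    spearman_row("pase", "pase_score"),
    icc_row("pase", "pase_total_pa", "total_pa_min_wk"),
    icc_row("pase", "pase_sedentary", "sedentary_min_wk")
  )
  dplyr::bind_rows(acc_rows, quest_rows) |>
    dplyr::mutate(n_included = nrow(wide)) |>
    dplyr::relocate("instrument", "score")
}
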