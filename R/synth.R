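#' Simulate paired test-retest scores with known variance components
#'
#' The variance-components workhorse behind reliability validation: each
#' subject gets a latent score `mu_i ~ Normal(mean, between_sd^2)` and two
#' observations `T0 = mu_i + e_i0`, `T1 = mu_i + e_i1` with independent
#' errors of standard deviation `error_sd`. The population one-way ICC is
#' `between_sd^2 / (between_sd^2 + error_sd^2)`. Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param between_sd Between-subject standard deviation (score units, >= 0).
#' @param error_sd Within-subject error standard deviation (>= 0).
#' @param mean Population mean of the latent score.
#' @param seed RNG seed.
#' @return A tibble with columns `subject_id`, `latent`, `t0`, `t1`.
#' @export
#' @examples
#' simulate_paired_scores(5, between_sd = 2, error_sd = 1, seed = 42)
simulate_paired_scores <- function(n_subjects, between_sd, error_sd,
                                   mean = 0, seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop_config("n_subjects", "must be at least 2")
  }
  if (!is.numeric(between_sd) || between_sd < 0) {
    stop_config("between_sd", "must be non-negative")
  }
  if (!is.numeric(error_sd) || error_sd < 0) {
    stop_config("error_sd", "must be non-negative")
  }
  set.seed(seed)
  n <- as.integer(n_subjects)
  latent <- mean + between_sd * stats::rnorm(n)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    latent = latent,
    t0 = latent + error_sd * stats::rnorm(n),
    t1 = latent + error_sd * stats::rnorm(n)
  )
}

# ---- calibration targets (study conditions for the default cohort) --------

# Questionnaire scores: published medians, test-retest ICCs and SEMs of the
# cohort the generator emulates. These are the generator's defaults, not
# re-estimated quantities.
default_quest_targets <- function() {
  tibble::tribble(
    ~score,            ~median, ~icc, ~sem, ~band,   ~factor,
    "aquaa_sedentary",    3090, 0.78,  637, "sedentary", "sedentary",
    "aquaa_light",        1063, 0.57,  596, "light",     "activity",
    "aquaa_mvpa",          230, 0.70,  275, "mvpa",      "activity",
    "pase_total_pa",      1518, 0.90,  498, "light",     "activity",
    "pase_sedentary",     1079, 0.67,  335, "sedentary", "sedentary"
  )
}

# Accelerometer weekly band minutes: median and quartiles per band.
default_accel_targets <- function() {
  tibble::tribble(
    ~band,       ~median, ~p25, ~p75,
    "sedentary",    4329, 3551, 4584,
    "light",        1120,  935, 1448,
    "mvpa",          223,  132,  316
  )
}

# Questionnaire-vs-accelerometer consistency-ICC targets. `against` names
# the accelerometer quantity the printed ICC compares with; the copula edge
# is attached to the band in `band` of default_quest_targets().
default_agreement_targets <- function() {
  tibble::tribble(
    ~score,            ~against,    ~icc,
    "aquaa_sedentary", "sedentary",  0.44,
    "aquaa_light",     "light",     -0.001,
    "aquaa_mvpa",      "mvpa",       0.32,
    "pase_total_pa",   "total",      0.12,
    "pase_sedentary",  "sedentary",  0.39
  )
}

# Counts-per-minute levels of wear minutes by intensity band: mean of the
# minute-count distribution and the band's admissible range. With the
# default weekly band minutes these imply an overall intensity near
# 289 counts/min.
default_count_levels <- function() {
  list(
    sedentary = list(mean = 50, range = c(0, 99)),
    light = list(mean = 800, shape = 9, range = c(100, 1951)),
    mvpa = list(mean = 2500, shape = 25, range = c(1952, 5724))
  )
}

# Lognormal with a given median and between-subject variance:
# meanlog = log(median); solve (e^{s2}-1) e^{s2} = var / median^2.
lognormal_from_median_var <- function(median, between_var) {
  a <- between_var / median^2
  s2 <- log((1 + sqrt(1 + 4 * a)) / 2)
  list(meanlog = log(median), sdlog = sqrt(s2))
}

lognormal_from_quartiles <- function(median, p25, p75) {
  list(meanlog = log(median),
       sdlog = log(p75 / p25) / (stats::qnorm(0.75) - stats::qnorm(0.25)))
}

lognormal_mean <- function(p) exp(p$meanlog + p$sdlog^2 / 2)
lognormal_var <- function(p) {
  (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)
}

# Normal-copula correlation giving covariance `cov` between two lognormals:
# cov = m1 m2 (e^{r s1 s2} - 1)  =>  r = log(1 + cov/(m1 m2)) / (s1 s2).
copula_r_for_cov <- function(cov, p1, p2) {
  ratio <- cov / (lognormal_mean(p1) * lognormal_mean(p2))
  if (ratio <= -1) {
    stop("requested covariance is infeasible for these marginals",
         call. = FALSE)
  }
  log(1 + ratio) / (p1$sdlog * p2$sdlog)
}

#' Configuration for the synthetic cohort generator
#'
#' Builds the full parametrisation of [simulate_cohort()] from interpretable
#' targets: per-questionnaire-score medians, test-retest ICCs and SEMs;
#' accelerometer band medians and quartiles; and
#' questionnaire-vs-accelerometer consistency-ICC targets. Latent scores
#' are lognormal (matching the right-skew of activity data) with median
#' equal to the target median and between-subject variance
#' `SEM^2 * ICC / (1 - ICC)`; test-retest error is multiplicative lognormal
#' calibrated so the error variance equals `SEM^2`. Cross-instrument
#' coupling uses a Gaussian copula whose correlations are solved in closed
#' form from the agreement-ICC targets; a shared "activity" factor (and a
#' "sedentariness" factor) correlates scores of the same construct across
#' instruments, giving derived sum scores realistic reliability.
#'
#' @param n_subjects Number of subjects (default 50, the planning size of
#'   instrument-validation studies).
#' @param days Accelerometer days per subject (default 7).
#' @param epoch_seconds Accelerometer epoch length (default 15).
#' @param quest_targets,accel_targets,agreement_targets Target tables; see
#'   the defaults in the source for the expected columns.
#' @param activity_loading,sedentary_loading Loadings of the shared factors
#'   on the activity-type and sedentary-type latent scores.
#' @param sdlog_cap Upper bound on the lognormal shape (log-scale SD) of
#'   the most dispersed latent score. All between-subject variances are
#'   deflated by the common factor that brings the largest shape down to
#'   this bound (variance ratios across scores are preserved, and error
#'   variances are rescaled so every population ICC stays exact).
#'   Right-skew is kept while the extreme kurtosis that would destabilise
#'   ANOVA-based ICC estimation at the default cohort size is avoided.
#' @param count_levels Wear-minute count distributions per band.
#' @param p_missing_visit Probability a whole questionnaire visit is
#'   missing (default 0).
#' @param nonwear_blocks Optional tibble of planted off-body blocks with
#'   columns `day`, `start_minute`, `duration_minutes`, applied to every
#'   subject's stream.
#' @param max_wear_minutes_per_day Upper bound on simulated daily wear
#'   (default 1370, leaving at least a 70-minute sleep gap so the non-wear
#'   detector always sees the night).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50, days = 7, epoch_seconds = 15,
                          quest_targets = default_quest_targets(),
                          accel_targets = default_accel_targets(),
                          agreement_targets = default_agreement_targets(),
                          activity_loading = sqrt(0.15),
                          sedentary_loading = 0.5,
                          sdlog_cap = 0.35,
                          count_levels = default_count_levels(),
                          p_missing_visit = 0,
                          nonwear_blocks = NULL,
                          max_wear_minutes_per_day = 1370) {
  if (n_subjects < 2) stop_config("n_subjects", "must be at least 2")
  if (days < 1) stop_config("days", "must be at least 1")
  if (60 %% epoch_seconds != 0) stop_config("epoch_seconds", "must divide 60")
  if (p_missing_visit < 0 || p_missing_visit > 1) {
    stop_config("p_missing_visit", "must lie in [0, 1]")
  }
  validate_nonwear_blocks(nonwear_blocks, days)

  accel <- accel_targets
  acc_par <- lapply(seq_len(nrow(accel)), function(i) {
    lognormal_from_quartiles(accel$median[i], accel$p25[i], accel$p75[i])
  })
  names(acc_par) <- accel$band
  acc_var <- vapply(acc_par, lognormal_var, numeric(1))

  q <- quest_targets
  # Between-subject variances implied by the published SEM and ICC of each
  # score. The variance RATIOS across scores (which drive the reliability
  # of derived composite scores) are preserved, but the common scale is
  # deflated so that the most dispersed score's lognormal shape does not
  # exceed `sdlog_cap`: distributions stay right-skewed while the extreme
  # kurtosis that would destabilise ANOVA-based ICC estimates at the
  # default cohort size is avoided. Medians and population ICCs are exact.
  sem_between <- q$sem^2 * q$icc / (1 - q$icc)
  a <- sem_between / q$median^2
  f_cap <- (exp(sdlog_cap^2) - 1) * exp(sdlog_cap^2)
  alpha <- min(1, f_cap / max(a))
  q$between_var <- alpha * sem_between
  q$error_var <- q$between_var * (1 - q$icc) / q$icc
  par <- lapply(seq_len(nrow(q)), function(i) {
    lognormal_from_median_var(q$median[i], q$between_var[i])
  })
  q$meanlog <- vapply(par, `[[`, numeric(1), "meanlog")
  q$sdlog <- vapply(par, `[[`, numeric(1), "sdlog")
  # multiplicative error: E[L^2] (e^{tau^2} - 1) = error_var
  e_l2 <- exp(2 * q$meanlog + 2 * q$sdlog^2)
  q$tau <- sqrt(log(1 + q$error_var / e_l2))
  q$loading <- ifelse(q$factor == "activity", activity_loading,
                      sedentary_loading)

  # copula correlation between each questionnaire latent and its
  # accelerometer band, solved from the consistency-ICC target:
  # icc_C = 2 cov / (var_x + var_y)  =>  cov = icc_C (var_x + var_y) / 2
  q$copula_r <- 0
  for (i in seq_len(nrow(agreement_targets))) {
    tgt <- agreement_targets[i, ]
    j <- match(tgt$score, q$score)
    var_x <- q$between_var[j] + q$error_var[j]
    var_y <- if (tgt$against == "total") {
      acc_var[["light"]] + acc_var[["mvpa"]]
    } else {
      acc_var[[tgt$against]]
    }
    cov_needed <- tgt$icc * (var_x + var_y) / 2
    qp <- list(meanlog = q$meanlog[j], sdlog = q$sdlog[j])
    r <- copula_r_for_cov(cov_needed, qp, acc_par[[q$band[j]]])
    r_max <- sqrt(1 - q$loading[j]^2) - 1e-6
    if (abs(r) > r_max) {
      max_icc <- 2 * sqrt(var_x * var_y) / (var_x + var_y)
      warning("agreement-ICC target for ", tgt$score, " (", tgt$icc,
              ") is not fully achievable with these marginal variances ",
              "(maximum ", signif(max_icc, 2),
              " at perfect correlation); copula correlation capped at ",
              signif(r_max, 3), call. = FALSE)
      r <- sign(r) * r_max
    }
    q$copula_r[j] <- r
  }
  q$residual <- sqrt(1 - q$copula_r^2 - q$loading^2)

  structure(list(
    n_subjects = as.integer(n_subjects),
    days = as.integer(days),
    epoch_seconds = as.integer(epoch_seconds),
    scores = q,
    accel = tibble::tibble(
      band = accel$band,
      meanlog = vapply(acc_par, `[[`, numeric(1), "meanlog"),
      sdlog = vapply(acc_par, `[[`, numeric(1), "sdlog")
    ),
    count_levels = count_levels,
    p_missing_visit = p_missing_visit,
    nonwear_blocks = nonwear_blocks,
    max_wear_minutes_per_day = max_wear_minutes_per_day
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d subjects, %d accelerometer days (%ds epochs)\n",
              x$n_subjects, x$days, x$epoch_seconds))
  cat("questionnaire score models:\n")
  print(x$scores[, c("score", "median", "icc", "sem", "copula_r")])
  invisible(x)
}

validate_nonwear_blocks <- function(blocks, days) {
  if (is.null(blocks)) return(invisible(NULL))
  req <- c("day", "start_minute", "duration_minutes")
  if (!all(req %in% names(blocks))) {
    stop_config("nonwear_blocks",
                "needs columns day, start_minute, duration_minutes")
  }
  if (any(blocks$duration_minutes < 0)) {
    stop_config("nonwear_blocks", "durations must be non-negative")
  }
  if (any(blocks$day < 1 | blocks$day > days)) {
    stop_config("nonwear_blocks", "day out of range")
  }
  if (any(blocks$start_minute < 0 |
          blocks$start_minute + blocks$duration_minutes > 1440)) {
    stop_config("nonwear_blocks", "blocks must fit inside a day")
  }
  for (d in unique(blocks$day)) {
    b <- blocks[blocks$day == d, ]
    b <- b[order(b$start_minute), ]
    if (nrow(b) > 1 &&
        any(b$start_minute[-1] <
            (b$start_minute + b$duration_minutes)[-nrow(b)])) {
      stop_config("nonwear_blocks", "blocks overlap within a day")
    }
  }
  invisible(NULL)
}

# Draw one wear minute's counts per band; values stay inside the band's
# counts/min range so planned band minutes survive classification.
draw_minute_counts <- function(n, level) {
  if (n == 0) return(integer(0))
  x <- if (is.null(level$shape)) {
    stats::rpois(n, level$mean)
  } else {
    round(stats::rgamma(n, shape = level$shape,
                        scale = level$mean / level$shape))
  }
  as.integer(pmin(pmax(x, level$range[1]), level$range[2]))
}

# Assemble a week of minute counts from weekly band-minute targets. Uses the
# current RNG state. Sleep (all minutes not allocated to a band) sits at the
# start of each day as a zero block; wear minutes follow in contiguous
# sedentary, light, mvpa segments (order is irrelevant to the summaries).
build_minute_week <- function(band_weekly, days, count_levels,
                              nonwear_blocks, max_wear) {
  daily <- sapply(band_weekly, function(w) {
    wk <- max(0, round(w))
    q <- wk %/% days
    r <- wk %% days
    q + as.integer(seq_len(days) <= r)
  })
  if (days == 1) daily <- matrix(daily, nrow = 1)
  minutes <- integer(0)
  wear_plan <- logical(0)
  for (d in seq_len(days)) {
    bands <- daily[d, ]
    wear_d <- sum(bands)
    if (wear_d > max_wear) {
      bands <- floor(bands * max_wear / wear_d)
      wear_d <- sum(bands)
    }
    day_counts <- c(
      rep(0L, 1440 - wear_d),
      draw_minute_counts(bands[["sedentary"]], count_levels$sedentary),
      draw_minute_counts(bands[["light"]], count_levels$light),
      draw_minute_counts(bands[["mvpa"]], count_levels$mvpa)
    )
    minutes <- c(minutes, day_counts)
    wear_plan <- c(wear_plan, rep(c(FALSE, TRUE), c(1440 - wear_d, wear_d)))
  }
  if (!is.null(nonwear_blocks)) {
    for (i in seq_len(nrow(nonwear_blocks))) {
      b <- nonwear_blocks[i, ]
      if (b$duration_minutes == 0) next
      idx <- (b$day - 1) * 1440 + b$start_minute + seq_len(b$duration_minutes)
      minutes[idx] <- 0L
      wear_plan[idx] <- FALSE
      # guard minutes: keep planted blocks maximal zero runs of exactly the
      # planted length inside wear time
      for (g in c(min(idx) - 1, max(idx) + 1)) {
        if (g >= 1 && g <= length(minutes) && wear_plan[g]) {
          minutes[g] <- max(minutes[g], 1L)
        }
      }
    }
  }
  minutes
}

minutes_to_epochs <- function(minutes, epoch_seconds) {
  per_min <- 60L %/% epoch_seconds
  q <- minutes %/% per_min
  r <- minutes %% per_min
  eq <- rep(q, each = per_min)
  pos <- rep(seq_len(per_min) - 1L, times = length(minutes))
  as.integer(eq + (pos < rep(r, each = per_min)))
}

#' Simulate a 7-day accelerometer epoch stream
#'
#' Generates an epoch count stream either from explicit weekly band-minute
#' targets or from a latent physical-activity score. In the latter mode the
#' subject's overall intensity (counts/min) is coupled to the latent score
#' through a Gaussian copula with target Spearman correlation
#' `rho_construct` (`r = 2 sin(pi rho / 6)` on the normal scale), and the
#' moderate-to-vigorous minutes are set so the stream realises that
#' intensity. Sleep appears as a nightly zero block; planted non-wear
#' blocks are exact zero runs of the requested length.
#'
#' @param latent_pa Latent activity score (used when `band_minutes_per_week`
#'   is `NULL`).
#' @param rho_construct Target Spearman correlation between the latent score
#'   and realised counts/min, in `[-1, 1]`.
#' @param band_minutes_per_week Optional named vector
#'   (`sedentary`, `light`, `mvpa`) of weekly wear minutes per band.
#' @param days,epoch_seconds Stream geometry.
#' @param nonwear_blocks Optional planted off-body blocks (tibble with
#'   `day`, `start_minute`, `duration_minutes`; must not overlap).
#' @param count_levels Per-band minute-count distributions.
#' @param latent_meanlog,latent_sdlog Lognormal parameters of the latent
#'   score population (defaults match the AQuAA total-score scale).
#' @param cpm_median,cpm_sdlog Lognormal parameters of the counts/min
#'   population.
#' @param wear_min_wk,light_min_wk Weekly wear and light-band minutes used
#'   in latent mode.
#' @param subject_id Subject identifier.
#' @param seed RNG seed.
#' @return An [epoch_series()].
#' @export
simulate_epoch_stream <- function(latent_pa = NULL, rho_construct = 0.15,
                                  band_minutes_per_week = NULL,
                                  days = 7, epoch_seconds = 15,
                                  nonwear_blocks = NULL,
                                  count_levels = default_count_levels(),
                                  latent_meanlog = log(5316),
                                  latent_sdlog = 0.6,
                                  cpm_median = 289, cpm_sdlog = 0.3,
                                  wear_min_wk = 5670, light_min_wk = 1120,
                                  subject_id = "S1", seed = 1) {
  if (abs(rho_construct) > 1) {
    stop_config("rho_construct", "must lie in [-1, 1]")
  }
  validate_nonwear_blocks(nonwear_blocks, days)
  set.seed(seed)
  if (is.null(band_minutes_per_week)) {
    if (is.null(latent_pa)) {
      stop_config("latent_pa",
                  "is required when band_minutes_per_week is not given")
    }
    u <- stats::plnorm(latent_pa, latent_meanlog, latent_sdlog)
    z_pa <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
    r <- 2 * sin(pi * rho_construct / 6)
    z_cpm <- r * z_pa + sqrt(1 - r^2) * stats::rnorm(1)
    cpm <- stats::qlnorm(stats::pnorm(z_cpm), log(cpm_median), cpm_sdlog)
    sed_m <- count_levels$sedentary$mean
    light_m <- count_levels$light$mean
    mvpa_m <- count_levels$mvpa$mean
    mvpa_w <- (cpm * wear_min_wk - sed_m * wear_min_wk -
                 (light_m - sed_m) * light_min_wk) / (mvpa_m - sed_m)
    mvpa_w <- min(max(mvpa_w, 0), wear_min_wk - light_min_wk)
    band_minutes_per_week <- c(
      sedentary = wear_min_wk - light_min_wk - mvpa_w,
      light = light_min_wk, mvpa = mvpa_w)
  } else {
    need <- c("sedentary", "light", "mvpa")
    if (!all(need %in% names(band_minutes_per_week))) {
      stop_config("band_minutes_per_week",
                  "must name sedentary, light and mvpa")
    }
  }
  minutes <- build_minute_week(
    band_minutes_per_week[c("sedentary", "light", "mvpa")],
    days, count_levels, nonwear_blocks, max_wear = 1370)
  epoch_series(minutes_to_epochs(minutes, epoch_seconds),
               subject_id = subject_id, epoch_seconds = epoch_seconds)
}

# AQuAA entries realising target weekly band minutes. One entry per band
# with a known MET (sitting 1.0, walking 3.0, running 11.5); minutes/day
# are rounded to whole minutes so scoring recovers the target within
# 3.5 min/wk.
build_aquaa_entries <- function(sedentary_wk, light_wk, mvpa_wk) {
  entries <- tibble::tibble(
    category = c("leisure", "leisure", "sports"),
    activity = c("sitting", "walking", "running"),
    days_per_week = 7,
    minutes_per_day = round(c(sedentary_wk, light_wk, mvpa_wk) / 7),
    intensity = c("low", "medium", "high")
  )
  entries[entries$minutes_per_day > 0, ]
}

pase_activity_items <- c("walk", "light_sport", "moderate_sport",
                         "strenuous_sport", "muscle_strength",
                         "light_housework", "heavy_housework", "home_repair",
                         "lawn_work", "gardening", "caring_for_others")

pase_combo_table <- function(weights) {
  grid <- expand.grid(frequency = setdiff(pase_frequencies, "never"),
                      duration = pase_durations, stringsAsFactors = FALSE)
  grid$hours <- pase_hours_per_week(grid$frequency, grid$duration, weights)
  grid[order(-grid$hours), ]
}

# Greedy inversion of the PASE activity hours: walk first, then the other
# items, each taking the largest achievable category combination not
# exceeding the remaining target. Ties break toward fewer entries.
build_pase_activity <- function(target_hours, weights) {
  combos <- pase_combo_table(weights)
  rows <- list()
  remaining <- target_hours
  for (item in pase_activity_items) {
    fit <- combos[combos$hours <= remaining + 1e-9, ]
    if (nrow(fit) == 0) next
    pick <- fit[1, ]
    rows[[item]] <- tibble::tibble(item = item, frequency = pick$frequency,
                                   duration = pick$duration,
                                   hours = pick$hours)
    remaining <- remaining - pick$hours
  }
  if (remaining >= 0.375) {
    unused <- setdiff(pase_activity_items, names(rows))
    if (length(unused)) {
      rows[[unused[1]]] <- tibble::tibble(item = unused[1],
                                          frequency = "seldom",
                                          duration = "lt1h", hours = 0.75)
    }
  }
  dplyr::bind_rows(rows)
}

# Sitting hours split over the leisure sitting item and (if it helps) a
# mostly-sitting work item; exhaustive search over the small grid.
build_pase_sitting <- function(target_hours, weights) {
  combos <- pase_combo_table(weights)
  sit_opts <- rbind(data.frame(frequency = NA, duration = NA, hours = 0),
                    combos[, c("frequency", "duration", "hours")])
  work_opts <- data.frame(work_hours = c(NA, names(weights$work_hours_week)),
                          hours = c(0, unname(weights$work_hours_week)))
  best <- NULL
  for (i in seq_len(nrow(sit_opts))) {
    for (j in seq_len(nrow(work_opts))) {
      total <- sit_opts$hours[i] + work_opts$hours[j]
      err <- abs(total - target_hours)
      n_parts <- (sit_opts$hours[i] > 0) + (work_opts$hours[j] > 0)
      if (is.null(best) || err < best$err - 1e-9 ||
          (err < best$err + 1e-9 && n_parts < best$n_parts)) {
        best <- list(i = i, j = j, err = err, n_parts = n_parts)
      }
    }
  }
  sit <- sit_opts[best$i, ]
  work <- work_opts[best$j, ]
  rows <- list()
  if (sit$hours > 0) {
    rows$sit <- tibble::tibble(item = "sitting", frequency = sit$frequency,
                               duration = sit$duration, hours = sit$hours)
  }
  work_row <- NULL
  if (work$hours > 0) {
    work_row <- tibble::tibble(item = "work", frequency = NA_character_,
                               duration = NA_character_, worked = TRUE,
                               sitting_only = TRUE,
                               work_hours = work$work_hours,
                               hours = work$hours)
  }
  list(items = dplyr::bind_rows(rows), work = work_row)
}

#' Simulate a complete synthetic cohort
#'
#' Generates, for each subject, AQuAA and PASE questionnaire responses at
#' two administrations (T0, T1) and a multi-day accelerometer epoch stream,
#' with known ground truth. Latent scores follow the lognormal models in
#' the [cohort_config()]; observed visit targets apply multiplicative
#' test-retest error; questionnaire responses are constructed by inverting
#' the scoring maps (activity minutes and PASE categories chosen to score
#' back to the target, ties toward the fewest entries); epoch streams
#' realise the subject's accelerometer band-minute targets. Each subject
#' draws from its own seed substream, so cohorts are reproducible
#' subject-by-subject.
#'
#' @param cfg A [cohort_config()].
#' @param seed Master RNG seed.
#' @param pase_weights PASE weights used for the response inversion.
#' @return An object of class `synthetic_cohort`: a list with `config`,
#'   `seed`, `subjects`, `aquaa` (long entry tibble), `pase` (long item
#'   tibble), `epochs` (list of [epoch_series()]) and `ground_truth` (one
#'   row per subject with latent scores, per-visit targets and
#'   accelerometer band targets, recorded exactly as simulated).
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1,
                            pase_weights = default_pase_weights()) {
  stopifnot(inherits(cfg, "cohort_config"))
  sc <- cfg$scores
  acc <- cfg$accel
  aquaa_rows <- list()
  pase_rows <- list()
  epochs <- list()
  truth_rows <- list()

  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%03d", i)
    set.seed(substream_seed(seed, i))
    z_acc <- stats::setNames(stats::rnorm(nrow(acc)), acc$band)
    eta <- c(activity = stats::rnorm(1), sedentary = stats::rnorm(1))
    z_q <- sc$copula_r * z_acc[sc$band] + sc$loading * eta[sc$factor] +
      sc$residual * stats::rnorm(nrow(sc))
    latent <- stats::setNames(exp(sc$meanlog + sc$sdlog * z_q), sc$score)
    acc_target <- stats::setNames(exp(acc$meanlog + acc$sdlog * z_acc),
                                  acc$band)

    visit_targets <- list()
    for (visit in c("T0", "T1")) {
      if (stats::runif(1) < cfg$p_missing_visit) next
      obs <- latent * exp(stats::rnorm(nrow(sc), -sc$tau^2 / 2, sc$tau))
      visit_targets[[visit]] <- obs
      aq <- build_aquaa_entries(obs[["aquaa_sedentary"]],
                                obs[["aquaa_light"]], obs[["aquaa_mvpa"]])
      if (nrow(aq)) {
        aquaa_rows[[paste(sid, visit)]] <-
          dplyr::bind_cols(tibble::tibble(subject_id = sid, visit = visit),
                           aq)
      }
      act <- build_pase_activity(obs[["pase_total_pa"]] / 60, pase_weights)
      sit <- build_pase_sitting(obs[["pase_sedentary"]] / 60, pase_weights)
      items <- dplyr::bind_rows(act, sit$items)
      items$worked <- FALSE
      items$sitting_only <- FALSE
      items$work_hours <- NA_character_
      items <- dplyr::bind_rows(items, sit$work)
      items$hours <- NULL
      if (nrow(items) == 0) {
        # all targets below the smallest category: an all-"never" form
        items <- tibble::tibble(item = "sitting", frequency = "never",
                                duration = NA_character_, worked = FALSE,
                                sitting_only = FALSE,
                                work_hours = NA_character_)
      }
      pase_rows[[paste(sid, visit)]] <-
        dplyr::bind_cols(tibble::tibble(subject_id = sid, visit = visit),
                         items)
    }

    es <- epoch_series(
      minutes_to_epochs(
        build_minute_week(acc_target[c("sedentary", "light", "mvpa")],
                          cfg$days, cfg$count_levels, cfg$nonwear_blocks,
                          cfg$max_wear_minutes_per_day),
        cfg$epoch_seconds),
      subject_id = sid, epoch_seconds = cfg$epoch_seconds)
    epochs[[sid]] <- es

    truth <- tibble::tibble(subject_id = sid)
    for (s in sc$score) truth[[paste0("latent_", s)]] <- latent[[s]]
    for (visit in names(visit_targets)) {
      for (s in sc$score) {
        truth[[paste0(tolower(visit), "_", s)]] <-
          visit_targets[[visit]][[s]]
      }
    }
    for (b in acc$band) truth[[paste0("acc_", b, "_wk")]] <- acc_target[[b]]
    truth_rows[[sid]] <- truth
  }

  structure(list(
    config = cfg, seed = seed,
    subjects = tibble::tibble(subject_id = sprintf("S%03d",
                                                   seq_len(cfg$n_subjects))),
    aquaa = dplyr::bind_rows(aquaa_rows),
    pase = dplyr::bind_rows(pase_rows),
    epochs = epochs,
    ground_truth = dplyr::bind_rows(truth_rows)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, seed %s\n",
              nrow(x$subjects), format(x$seed)))
  cat(sprintf("  questionnaire entries: %d AQuAA, %d PASE rows\n",
              nrow(x$aquaa), nrow(x$pase)))
  cat(sprintf("  epoch streams: %d x %d epochs\n", length(x$epochs),
              length(x$epochs[[1]]$counts)))
  invisible(x)
}

#' Score a synthetic cohort's questionnaires into the long score format
#'
#' Runs [score_aquaa()] and [score_pase()] over a cohort (or over raw
#' response tibbles) and reshapes the outcomes into the long
#' (`subject_id`, `visit`, `score`, `value`) layout the reliability and
#' validity tables consume. AQuAA outcomes are the total score, total PA
#' minutes (light + moderate + vigorous), light, moderate-to-vigorous and
#' sedentary minutes; PASE outcomes are the sum score, total PA minutes and
#' sedentary minutes.
#'
#' @param aquaa AQuAA entry tibble (or a `synthetic_cohort`).
#' @param pase PASE item tibble (ignored when `aquaa` is a cohort).
#' @param met_table MET lookup table for AQuAA.
#' @param pase_weights PASE weights object.
#' @return A long tibble with columns `subject_id`, `visit`, `score`,
#'   `value`.
#' @export
score_questionnaires <- function(aquaa, pase = NULL,
                                 met_table = default_met_table(),
                                 pase_weights = default_pase_weights()) {
  if (inherits(aquaa, "synthetic_cohort")) {
    pase <- aquaa$pase
    aquaa <- aquaa$aquaa
  }
  aq <- score_aquaa(aquaa, met_table) |>
    dplyr::mutate(
      aquaa_score = .data$total_score,
      aquaa_total_pa = .data$light_min + .data$moderate_min +
        .data$vigorous_min,
      aquaa_light = .data$light_min,
      aquaa_mvpa = .data$moderate_min + .data$vigorous_min,
      aquaa_sedentary = .data$sedentary_min,
      .keep = "unused"
    ) |>
    tidyr::pivot_longer(dplyr::starts_with("aquaa_"), names_to = "score",
                        values_to = "value")
  ps <- score_pase(pase, pase_weights) |>
    dplyr::rename(pase_score = "sum_score", pase_total_pa = "total_pa_min",
                  pase_sedentary = "sedentary_min") |>
    tidyr::pivot_longer(dplyr::starts_with("pase_"), names_to = "score",
                        values_to = "value")
  dplyr::bind_rows(aq, ps) |>
    dplyr::arrange(.data$subject_id, .data$visit, .data$score)
}

#' Write a synthetic cohort to plain-text files
#'
#' Lays the cohort out as portable files: one epoch CSV per subject
#' (`epochs/<id>.csv`, columns `timestamp`, `axis1`), questionnaire JSON
#' (`aquaa.json`, `pase.json`; arrays of subject-visit objects) and
#' `ground_truth.csv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  to_records <- function(df) {
    keys <- dplyr::distinct(df, .data$subject_id, .data$visit)
    lapply(seq_len(nrow(keys)), function(i) {
      sub <- df[df$subject_id == keys$subject_id[i] &
                  df$visit == keys$visit[i], ]
      list(subject_id = keys$subject_id[i], visit = keys$visit[i],
           entries = sub[setdiff(names(sub), c("subject_id", "visit"))])
    })
  }
  jsonlite::write_json(to_records(cohort$aquaa),
                       file.path(dir, "aquaa.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(to_records(cohort$pase),
                       file.path(dir, "pase.json"), auto_unbox = TRUE,
                       digits = NA)
  readr::write_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  for (es in cohort$epochs) {
    write_epoch_csv(es, file.path(dir, "epochs",
                                  paste0(es$subject_id, ".csv")))
  }
  invisible(dir)
}

read_questionnaire_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    entries <- recs$entries[[i]]
    dplyr::bind_cols(
      tibble::tibble(subject_id = recs$subject_id[i], visit = recs$visit[i]),
      tibble::as_tibble(entries))
  })
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `aquaa.json`, `pase.json` and `epochs/`.
#' @return A list with `aquaa`, `pase`, `epochs` and (when present)
#'   `ground_truth`.
#' @export
read_cohort <- function(dir) {
  epoch_files <- list.files(file.path(dir, "epochs"), full.names = TRUE,
                            pattern = "\\.csv$")
  epochs <- lapply(epoch_files, read_epoch_csv)
  names(epochs) <- vapply(epochs, `[[`, character(1), "subject_id")
  gt_path <- file.path(dir, "ground_truth.csv")
  list(
    aquaa = read_questionnaire_json(file.path(dir, "aquaa.json")),
    pase = read_questionnaire_json(file.path(dir, "pase.json")),
    epochs = epochs,
    ground_truth = if (file.exists(gt_path)) {
      readr::read_csv(gt_path, show_col_types = FALSE)
    }
  )
}
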