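test_that("paired-score simulation honours its variance components", {
  # zero error: the two administrations are identical
  p0 <- simulate_paired_scores(20, between_sd = 3, error_sd = 0, seed = 1)
  expect_identical(p0$t0, p0$t1)
  expect_identical(p0$t0, p0$latent)

  # no between-subject variance: population ICC 0
  pf <- simulate_paired_scores(2000, between_sd = 0, error_sd = 1, seed = 2)
  expect_lt(abs(icc_oneway(variance_components(pf$t0, pf$t1))$icc), 0.05)

  # between 7, error 3: sample ICC near 0.70 by direct ANOVA
  p <- simulate_paired_scores(2000, between_sd = sqrt(7),
                              error_sd = sqrt(3), seed = 3)
  o <- oracle_anova(p$t0, p$t1)
  expect_equal(o$icc, 0.70, tolerance = 0.03)

  expect_error(simulate_paired_scores(1, 1, 1), "n_subjects")
  expect_error(simulate_paired_scores(10, -1, 1), "between_sd")
  expect_error(simulate_paired_scores(10, 1, -1), "error_sd")

  # determinism
  expect_identical(simulate_paired_scores(50, 2, 1, seed = 7),
                   simulate_paired_scores(50, 2, 1, seed = 7))
})

test_that("mean ICC over replicate cohorts recovers the configured value", {
  ests <- vapply(1:300, function(r) {
    p <- simulate_paired_scores(50, between_sd = sqrt(0.6),
                                error_sd = sqrt(0.4), seed = r)
    icc_oneway(variance_components(p$t0, p$t1))$icc
  }, numeric(1))
  expect_equal(mean(ests), 0.6, tolerance = 0.05)
})

test_that("epoch streams realise planted non-wear exactly", {
  # blocks covering all days: an all-zero stream
  all_off <- tibble::tibble(day = 1:2, start_minute = 0,
                            duration_minutes = 1440)
  es <- simulate_epoch_stream(band_minutes_per_week = c(sedentary = 2000,
                                                        light = 800,
                                                        mvpa = 100),
                              days = 2, nonwear_blocks = all_off, seed = 5)
  expect_true(all(es$counts == 0))

  # wear sits at the end of each day; plant blocks inside it
  bands <- c(sedentary = 4200, light = 1400, mvpa = 700)  # 900 min/day wear
  plant <- function(dur) {
    simulate_epoch_stream(
      band_minutes_per_week = bands, days = 7,
      nonwear_blocks = tibble::tibble(day = 2, start_minute = 700,
                                      duration_minutes = dur),
      seed = 5)
  }
  m90 <- detect_nonwear(to_minutes(plant(90)))
  day2 <- m90[1441:2880, ]
  expect_equal(sum(!day2$wear[701:790]), 90)  # the planted block
  expect_true(all(!day2$wear[1:540]))         # the sleep gap

  # blocks under 60 minutes stay wear
  m45 <- detect_nonwear(to_minutes(plant(45)))
  expect_true(all(m45$wear[1440 + 701:745]))

  # geometry and configuration errors
  expect_equal(length(es$counts), 2 * 5760)
  overlap <- tibble::tibble(day = c(1, 1), start_minute = c(100, 150),
                            duration_minutes = c(100, 30))
  expect_error(simulate_epoch_stream(band_minutes_per_week = bands,
                                     nonwear_blocks = overlap),
               "overlap")
  toolong <- tibble::tibble(day = 1, start_minute = 1400,
                            duration_minutes = 100)
  expect_error(simulate_epoch_stream(band_minutes_per_week = bands,
                                     nonwear_blocks = toolong),
               "inside a day")
  expect_error(simulate_epoch_stream(latent_pa = 100, rho_construct = 1.5),
               "rho_construct")
})

test_that("planted zero runs and only they are flagged, across geometries", {
  bands <- c(sedentary = 4900, light = 1400, mvpa = 700)  # 1000 min/day
  set.seed(37)
  for (i in 1:8) {
    dur <- sample(c(30, 59, 60, 61, 120, 200), 1)
    day <- sample(1:7, 1)
    start <- sample(500:1100, 1)  # inside the wear window (440..1439)
    es <- simulate_epoch_stream(
      band_minutes_per_week = bands, days = 7,
      nonwear_blocks = tibble::tibble(day = day, start_minute = start,
                                      duration_minutes = dur),
      seed = i)
    m <- detect_nonwear(to_minutes(es))
    idx <- (day - 1) * 1440 + start + seq_len(dur)
    if (dur >= 60) {
      expect_true(all(!m$wear[idx]))
    } else {
      expect_true(all(m$wear[idx]))
    }
  }
})

test_that("rho_construct couples latent activity to realised counts/min", {
  n <- 400
  set.seed(41)
  latent <- rlnorm(n, log(5316), 0.6)
  cpm <- vapply(seq_len(n), function(i) {
    es <- simulate_epoch_stream(latent_pa = latent[i], rho_construct = 0.15,
                                days = 7, seed = 1000 + i)
    m <- detect_nonwear(to_minutes(es))
    sum(m$counts[m$wear]) / sum(m$wear)
  }, numeric(1))
  rho <- cor(latent, cpm, method = "spearman")
  expect_gte(rho, 0.05)
  expect_lte(rho, 0.25)
})

test_that("cohorts are reproducible and subject-stable", {
  cfg <- quiet_cfg(n_subjects = 6, days = 2)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$aquaa, b$aquaa)
  expect_identical(a$pase, b$pase)
  expect_identical(lapply(a$epochs, `[[`, "counts"),
                   lapply(b$epochs, `[[`, "counts"))
  # different seed, different cohort
  c2 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$ground_truth, c2$ground_truth))
  # per-subject substreams: a smaller cohort shares its subjects' draws
  small <- simulate_cohort(quiet_cfg(n_subjects = 3, days = 2), seed = 11)
  expect_identical(small$ground_truth,
                   a$ground_truth[1:3, names(small$ground_truth)])
})

test_that("questionnaire inversion scores back to the simulated targets", {
  cfg <- quiet_cfg(n_subjects = 25, days = 2)
  cohort <- simulate_cohort(cfg, seed = 13)
  scores <- score_questionnaires(cohort)
  gt <- cohort$ground_truth
  wide <- tidyr::pivot_wider(scores, id_cols = "subject_id",
                             names_from = c("visit", "score"),
                             values_from = "value")
  wide <- wide[match(gt$subject_id, wide$subject_id), ]
  # AQuAA: whole-minute rounding per day, at most 3.5 min/wk per band
  for (s in c("aquaa_sedentary", "aquaa_light", "aquaa_mvpa")) {
    expect_lt(max(abs(wide[[paste0("T0_", s)]] - gt[[paste0("t0_", s)]])),
              3.5 + 1e-9)
    expect_lt(max(abs(wide[[paste0("T1_", s)]] - gt[[paste0("t1_", s)]])),
              3.5 + 1e-9)
  }
  # PASE categories are coarse; the inversion promises the nearest grid
  # point (greedy residual under 22.5 min/wk for activity; the sparse top
  # of the sitting+work grid can sit up to ~105 min/wk from the target)
  expect_lt(max(abs(wide$T0_pase_total_pa - gt$t0_pase_total_pa)), 45)
  expect_lt(max(abs(wide$T0_pase_sedentary - gt$t0_pase_sedentary)), 120)
})

test_that("accelerometer summaries recover the simulated band targets", {
  cfg <- quiet_cfg(n_subjects = 10)
  cohort <- simulate_cohort(cfg, seed = 17)
  su <- summarize_cohort(cohort$epochs)
  gt <- cohort$ground_truth
  ok <- su$included
  # weekly band minutes within rounding of the lognormal targets
  expect_lt(max(abs(su$sedentary_min_wk[ok] - gt$acc_sedentary_wk[ok])), 8)
  expect_lt(max(abs(su$light_min_wk[ok] - gt$acc_light_wk[ok])), 8)
  expect_lt(max(abs(su$mvpa_min_wk[ok] - gt$acc_mvpa_wk[ok])), 8)
})

test_that("cohorts survive a write/read round trip", {
  cfg <- quiet_cfg(n_subjects = 4, days = 2)
  cohort <- simulate_cohort(cfg, seed = 19)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(sort(names(back$epochs)),
                   sort(cohort$subjects$subject_id))
  expect_equal(back$epochs[["S002"]]$counts,
               cohort$epochs[["S002"]]$counts)
  expect_equal(
    score_questionnaires(back$aquaa, back$pase),
    score_questionnaires(cohort))
  expect_equal(nrow(back$ground_truth), 4)
})

test_that("cohort configuration validates its fields", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(p_missing_visit = 2), "p_missing_visit")
  expect_error(cohort_config(epoch_seconds = 7), "epoch_seconds")
  bad_blocks <- tibble::tibble(day = 9, start_minute = 0,
                               duration_minutes = 30)
  expect_error(cohort_config(nonwear_blocks = bad_blocks), "day out of")
  neg <- tibble::tibble(day = 1, start_minute = 0, duration_minutes = -5)
  expect_error(cohort_config(nonwear_blocks = neg), "non-negative")
})
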