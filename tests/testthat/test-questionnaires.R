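test_that("MET bands use half-open, lower-inclusive boundaries", {
  expect_equal(met_intensity_band(1.5), "sedentary")
  expect_equal(met_intensity_band(2.0), "light")
  expect_equal(met_intensity_band(6.5), "vigorous")
  # exhaustive scan around every band edge
  grid <- sort(c(seq(0.1, 12, by = 0.05), 2, 4, 6.5,
                 2 - 1e-9, 4 - 1e-9, 6.5 - 1e-9))
  oracle <- ifelse(grid < 2, "sedentary",
                   ifelse(grid < 4, "light",
                          ifelse(grid < 6.5, "moderate", "vigorous")))
  expect_equal(met_intensity_band(grid), oracle)
  expect_error(met_intensity_band(0), "> 0")
  expect_error(met_intensity_band(-1), "> 0")
})

test_that("AQuAA scoring matches hand arithmetic", {
  expect_equal(
    score_aquaa(tibble::tibble(category = character(),
                               activity = character(),
                               days_per_week = numeric(),
                               minutes_per_day = numeric(),
                               intensity = character())),
    tibble::tibble(total_score = 0, sedentary_min = 0, light_min = 0,
                   moderate_min = 0, vigorous_min = 0))

  # 3 days x 60 min of a 3.0-MET activity
  one <- tibble::tibble(category = "leisure", activity = "walking",
                        days_per_week = 3, minutes_per_day = 60,
                        intensity = "medium")
  s <- score_aquaa(one)
  expect_equal(s$light_min, 180)
  expect_equal(s$total_score, 540)
  expect_equal(s$sedentary_min + s$moderate_min + s$vigorous_min, 0)

  # 7 days x 120 min at 1.5 MET: sedentary, excluded from the total score
  sed <- tibble::tibble(category = "work_school", activity = "sitting_work",
                        days_per_week = 7, minutes_per_day = 120,
                        intensity = "medium")
  s2 <- score_aquaa(sed)
  expect_equal(s2$sedentary_min, 840)
  expect_equal(s2$total_score, 0)
})

test_that("AQuAA MET lookup falls back per category and errors otherwise", {
  unknown <- tibble::tibble(category = "sports", activity = "korfball",
                            days_per_week = 2, minutes_per_day = 30,
                            intensity = "medium")
  s <- score_aquaa(unknown)  # sports fallback is 6.0 MET -> moderate
  expect_equal(s$moderate_min, 60)
  expect_equal(s$total_score, 6 * 60)

  met <- default_met_table()
  no_fallback <- met[met$activity != "*", ]
  expect_error(score_aquaa(unknown, no_fallback), "korfball")
  bad <- unknown
  bad$category <- "gymnastics"
  expect_error(score_aquaa(bad), "category")
  bad2 <- unknown
  bad2$days_per_week <- 9
  expect_error(score_aquaa(bad2), "days_per_week")
})

test_that("AQuAA scoring is monotone and additive over entries", {
  set.seed(7)
  met <- default_met_table()
  pool <- met[met$activity != "*" & met$met >= 2, ]
  random_entries <- function(n) {
    idx <- sample(nrow(pool), n, replace = TRUE)
    tibble::tibble(category = pool$category[idx],
                   activity = pool$activity[idx],
                   days_per_week = sample(0:7, n, replace = TRUE),
                   minutes_per_day = sample(0:120, n, replace = TRUE),
                   intensity = pool$intensity[idx])
  }
  for (rep in 1:20) {
    a <- random_entries(sample(1:6, 1))
    b <- random_entries(sample(1:6, 1))
    sa <- score_aquaa(a)
    sb <- score_aquaa(b)
    sab <- score_aquaa(dplyr::bind_rows(a, b))
    # additivity
    expect_equal(sab$total_score, sa$total_score + sb$total_score)
    expect_equal(sab$light_min + sab$moderate_min + sab$vigorous_min,
                 sa$light_min + sa$moderate_min + sa$vigorous_min +
                   sb$light_min + sb$moderate_min + sb$vigorous_min)
    # monotonicity: adding entries with MET >= 2 never lowers the total
    expect_gte(sab$total_score, sa$total_score)
  }
})

test_that("PASE hours/week follow the category midpoints", {
  expect_equal(pase_hours_per_week("never", "gt4h"), 0)
  expect_equal(pase_hours_per_week("never", NA), 0)
  expect_equal(pase_hours_per_week("sometimes", "h1to2"), 3.5 * 1.5)
  expect_equal(pase_hours_per_week("often", "gt4h"), 30)
  expect_equal(pase_hours_per_week("seldom", "h2to4"), 4.5)
  expect_error(pase_hours_per_week("always", "gt4h"), "frequency")
  expect_error(pase_hours_per_week("often", "h9to12"), "duration")
})

test_that("PASE scoring is a weighted sum with sitting handled separately", {
  w <- default_pase_weights()
  all_never <- tibble::tibble(item = names(w$weights), frequency = "never",
                              duration = NA_character_)
  s0 <- score_pase(all_never, w)
  expect_equal(s0$sum_score, 0)
  expect_equal(s0$total_pa_min, 0)

  # single item, weight 20, 1.5 days x 3 h = 4.5 h/wk -> 90
  w20 <- w
  w20$weights[["walk"]] <- 20
  s <- score_pase(tibble::tibble(item = "walk", frequency = "seldom",
                                 duration = "h2to4"), w20)
  expect_equal(s$sum_score, 90)
  expect_equal(s$total_pa_min, 4.5 * 60)

  # two identical items double the score (linearity of the weighted sum)
  two <- tibble::tibble(item = c("walk", "gardening"),
                        frequency = "sometimes", duration = "h1to2")
  one <- lapply(seq_len(2), function(i) score_pase(two[i, ], w))
  both <- score_pase(two, w)
  expect_equal(both$sum_score, one[[1]]$sum_score + one[[2]]$sum_score)
  expect_equal(both$total_pa_min,
               one[[1]]$total_pa_min + one[[2]]$total_pa_min)

  # sitting item goes to sedentary minutes, not the weighted sum
  sit <- score_pase(tibble::tibble(item = "sitting", frequency = "often",
                                   duration = "h2to4"), w)
  expect_equal(sit$sum_score, 0)
  expect_equal(sit$sedentary_min, 18 * 60)

  expect_error(score_pase(tibble::tibble(item = "jogging",
                                         frequency = "often",
                                         duration = "h2to4"), w), "jogging")
})

test_that("PASE work item splits by sitting_only", {
  w <- default_pase_weights()
  work <- tibble::tibble(item = "work", frequency = NA, duration = NA,
                         worked = TRUE, sitting_only = FALSE,
                         work_hours = "h5to8")
  s <- score_pase(work, w)
  expect_equal(s$sum_score, w$work_weight * 6.5)
  expect_equal(s$total_pa_min, 6.5 * 60)
  expect_equal(s$sedentary_min, 0)

  desk <- work
  desk$sitting_only <- TRUE
  s2 <- score_pase(desk, w)
  expect_equal(s2$sum_score, 0)
  expect_equal(s2$total_pa_min, 0)
  expect_equal(s2$sedentary_min, 6.5 * 60)
})

test_that("raising a PASE frequency or duration never lowers the score", {
  w <- default_pase_weights()
  freqs <- c("never", "seldom", "sometimes", "often")
  durs <- c("lt1h", "h1to2", "h2to4", "gt4h")
  scores <- outer(freqs, durs, Vectorize(function(f, d) {
    score_pase(tibble::tibble(item = "walk", frequency = f,
                              duration = d), w)$sum_score
  }))
  expect_true(all(apply(scores, 2, diff) >= 0))  # frequency monotone
  expect_true(all(apply(scores, 1, diff) >= 0))  # duration monotone
})
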