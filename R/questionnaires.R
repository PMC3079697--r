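#' MET intensity band of an activity
#'
#' Assigns a metabolic-equivalent (MET) value to one of the four AQuAA
#' intensity bands: sedentary (< 2 MET), light (2-4 MET), moderate
#' (4-6.5 MET) and vigorous (>= 6.5 MET). Bands are half-open and
#' lower-inclusive, so 2 is light, 4 is moderate and 6.5 is vigorous;
#' this keeps "< 2 MET" sedentary exact while resolving the overlapping
#' printed interval labels.
#'
#' @param met Numeric vector of MET values; must be strictly positive.
#' @return Character vector with values `"sedentary"`, `"light"`,
#'   `"moderate"` or `"vigorous"`.
#' @export
#' @examples
#' met_intensity_band(c(1.5, 2, 3.9, 4, 6.5, 8))
met_intensity_band <- function(met) {
  if (!is.numeric(met) || any(!is.finite(met)) || any(met <= 0)) {
    stop("`met` must be a finite numeric vector with all values > 0",
         call. = FALSE)
  }
  as.character(cut(met, breaks = c(0, 2, 4, 6.5, Inf), right = FALSE,
                   labels = c("sedentary", "light", "moderate", "vigorous")))
}

aquaa_categories <- c("commuting", "work_school", "household", "leisure",
                      "sports")
aquaa_intensities <- c("low", "medium", "high")

#' Default MET lookup table for AQuAA scoring
#'
#' A compendium-style table mapping (activity token, perceived intensity) to a
#' MET value, with one fallback MET per AQuAA category (rows with
#' `activity = "*"`). The AQuAA instrument itself does not prescribe MET
#' values; these defaults are editable and a study can supply its own table
#' with the same columns. Perceived intensity (low/medium/high) selects
#' between the low/typical/high compendium values for the same activity;
#' the instrument does not define this interaction, so the keying is a
#' documented package convention.
#'
#' @return A tibble with columns `category`, `activity`, `intensity`, `met`.
#' @export
#' @examples
#' default_met_table()
default_met_table <- function() {
  tribble_row <- function(category, activity, low, medium, high) {
    tibble::tibble(category = category, activity = activity,
                   intensity = aquaa_intensities, met = c(low, medium, high))
  }
  dplyr::bind_rows(
    tribble_row("commuting", "walking", 2.5, 3.0, 3.5),
    tribble_row("commuting", "cycling", 4.0, 5.0, 6.0),
    tribble_row("work_school", "sitting_work", 1.3, 1.5, 1.8),
    tribble_row("work_school", "standing_work", 2.0, 2.3, 3.0),
    tribble_row("work_school", "manual_labor", 3.5, 4.5, 6.0),
    tribble_row("household", "chores", 2.0, 3.0, 3.5),
    tribble_row("household", "gardening", 3.8, 4.5, 5.5),
    tribble_row("leisure", "sitting", 1.0, 1.3, 1.8),
    tribble_row("leisure", "walking", 2.5, 3.0, 3.5),
    tribble_row("leisure", "odd_jobs", 2.5, 3.0, 4.5),
    tribble_row("sports", "fitness", 3.5, 5.0, 6.5),
    tribble_row("sports", "swimming", 6.0, 7.0, 8.0),
    tribble_row("sports", "running", 8.0, 9.8, 11.5),
    tribble_row("sports", "cycling_sport", 5.0, 6.8, 8.5),
    # per-category fallbacks, used when an activity token is unknown
    tibble::tibble(category = aquaa_categories, activity = "*",
                   intensity = "*", met = c(3.0, 2.5, 3.0, 2.5, 6.0))
  )
}

# Resolve MET values for entries; exact (activity, intensity) key first,
# then the category fallback. Errors listing unresolvable tokens.
lookup_met <- function(category, activity, intensity, met_table) {
  key <- data.frame(category = category, activity = activity,
                    intensity = intensity, stringsAsFactors = FALSE)
  exact <- met_table[met_table$activity != "*", ]
  idx <- match(paste(key$category, key$activity, key$intensity),
               paste(exact$category, exact$activity, exact$intensity))
  met <- exact$met[idx]
  fb <- met_table[met_table$activity == "*", ]
  fb_idx <- match(key$category, fb$category)
  missing_fb <- is.na(met) & is.na(fb_idx)
  if (any(missing_fb)) {
    stop("no MET value or category fallback for activity token(s): ",
         paste(unique(activity[missing_fb]), collapse = ", "), call. = FALSE)
  }
  met[is.na(met)] <- fb$met[fb_idx[is.na(met)]]
  met
}

validate_aquaa <- function(resp) {
  req <- c("category", "activity", "days_per_week", "minutes_per_day",
           "intensity")
  miss <- setdiff(req, names(resp))
  if (length(miss)) {
    stop("AQuAA response is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(resp) == 0) return(invisible(resp))
  bad_cat <- setdiff(unique(resp$category), aquaa_categories)
  if (length(bad_cat)) {
    stop("unknown AQuAA category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  if (any(resp$days_per_week < 0 | resp$days_per_week > 7)) {
    stop("`days_per_week` must lie in [0, 7]", call. = FALSE)
  }
  if (any(resp$minutes_per_day < 0)) {
    stop("`minutes_per_day` must be non-negative", call. = FALSE)
  }
  bad_int <- setdiff(unique(resp$intensity), aquaa_intensities)
  if (length(bad_int)) {
    stop("unknown perceived intensity: ", paste(bad_int, collapse = ", "),
         call. = FALSE)
  }
  invisible(resp)
}

#' Score AQuAA questionnaire responses
#'
#' Computes the five AQuAA outcomes from activity entries: the total PA score
#' in MET*min/week (summing MET x weekly minutes over all activities with
#' MET >= 2) and weekly minutes spent in the sedentary, light, moderate and
#' vigorous intensity bands. Weekly minutes per entry are
#' `days_per_week * minutes_per_day`.
#'
#' @param resp A tibble of activity entries with columns `category`
#'   (one of commuting, work_school, household, leisure, sports), `activity`
#'   (token resolved against `met_table`), `days_per_week` (0-7),
#'   `minutes_per_day` (>= 0) and `intensity` (low/medium/high). Optional
#'   `subject_id` and `visit` columns produce one score row per
#'   subject-visit.
#' @param met_table MET lookup table, see [default_met_table()].
#' @return A tibble with columns `total_score`, `sedentary_min`, `light_min`,
#'   `moderate_min`, `vigorous_min` (plus any grouping columns).
#' @export
#' @examples
#' resp <- tibble::tibble(category = "leisure", activity = "walking",
#'                        days_per_week = 3, minutes_per_day = 60,
#'                        intensity = "medium")
#' score_aquaa(resp)
score_aquaa <- function(resp, met_table = default_met_table()) {
  validate_aquaa(resp)
  group_cols <- intersect(c("subject_id", "visit"), names(resp))
  if (nrow(resp) == 0) {
    return(tibble::tibble(total_score = 0, sedentary_min = 0, light_min = 0,
                          moderate_min = 0, vigorous_min = 0))
  }
  scored <- resp |>
    dplyr::mutate(
      met = lookup_met(.data$category, .data$activity, .data$intensity,
                       met_table),
      weekly_min = .data$days_per_week * .data$minutes_per_day,
      band = met_intensity_band(.data$met)
    )
  scored |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      total_score = sum(.data$met * .data$weekly_min * (.data$met >= 2)),
      sedentary_min = sum(.data$weekly_min[.data$band == "sedentary"]),
      light_min = sum(.data$weekly_min[.data$band == "light"]),
      moderate_min = sum(.data$weekly_min[.data$band == "moderate"]),
      vigorous_min = sum(.data$weekly_min[.data$band == "vigorous"]),
      .groups = "drop"
    )
}

pase_frequencies <- c("never", "seldom", "sometimes", "often")
pase_durations <- c("lt1h", "h1to2", "h2to4", "gt4h")
pase_work_hours <- c("lt1h", "h1to4", "h5to8", "gt8h")

#' Default PASE item weights and category midpoints
#'
#' The PASE sum score multiplies hours/week per item by an empirically derived
#' item weight. The weights shipped here are external to this package: they
#' are the published PASE instrument weights (Washburn et al. 1993, J Clin
#' Epidemiol), which are defined on an hours/day scale, divided by 7 so they
#' apply to the hours/week convention used by [score_pase()]. Category
#' midpoints convert the ordered frequency and duration categories to
#' days/week and hours/day: frequencies seldom = 1.5, sometimes = 3.5,
#' often = 6 days/week; durations lt1h = 0.5, h1to2 = 1.5, h2to4 = 3,
#' gt4h = 5 hours/day (midpoints of the printed ranges, open-ended
#' categories set just above the bound). Work hours map directly to
#' hours/week: lt1h = 0.5, h1to4 = 2.5, h5to8 = 6.5, gt8h = 10.
#'
#' The leisure "sitting" item carries weight 0: it contributes to sedentary
#' minutes, not to the weighted sum score, matching the instrument.
#'
#' @return An object of class `pase_weights`: a list with elements `weights`
#'   (named vector, per item), `item_type` (`"activity"` or `"sedentary"`),
#'   `freq_days`, `dur_hours`, `work_hours_week` and `work_weight`.
#' @export
default_pase_weights <- function() {
  published <- c(sitting = 0, walk = 20, light_sport = 21,
                 moderate_sport = 23, strenuous_sport = 23,
                 muscle_strength = 30, light_housework = 25,
                 heavy_housework = 25, home_repair = 30, lawn_work = 36,
                 gardening = 20, caring_for_others = 35)
  structure(list(
    weights = published / 7,
    item_type = c(sitting = "sedentary",
                  stats::setNames(rep("activity", length(published) - 1),
                                  setdiff(names(published), "sitting"))),
    freq_days = c(never = 0, seldom = 1.5, sometimes = 3.5, often = 6),
    dur_hours = c(lt1h = 0.5, h1to2 = 1.5, h2to4 = 3, gt4h = 5),
    work_hours_week = c(lt1h = 0.5, h1to4 = 2.5, h5to8 = 6.5, gt8h = 10),
    work_weight = 21 / 7
  ), class = "pase_weights")
}

#' Hours per week implied by PASE frequency and duration categories
#'
#' Multiplies the frequency midpoint (days/week) by the duration midpoint
#' (hours/day). A frequency of `"never"` yields 0 regardless of duration.
#'
#' @param frequency Character vector: never, seldom, sometimes or often.
#' @param duration Character vector: lt1h, h1to2, h2to4 or gt4h. Ignored
#'   (may be `NA`) where `frequency == "never"`.
#' @param weights A [default_pase_weights()]-style object supplying the
#'   midpoint maps.
#' @return Numeric vector of hours/week.
#' @export
#' @examples
#' pase_hours_per_week("sometimes", "h1to2")
pase_hours_per_week <- function(frequency, duration,
                                weights = default_pase_weights()) {
  frequency <- as.character(frequency)
  duration <- as.character(duration)
  bad_f <- setdiff(unique(frequency), pase_frequencies)
  if (length(bad_f)) {
    stop("unknown PASE frequency: ", paste(bad_f, collapse = ", "),
         call. = FALSE)
  }
  never <- frequency == "never"
  bad_d <- setdiff(unique(duration[!never]), pase_durations)
  if (length(bad_d) && !all(is.na(bad_d))) {
    stop("unknown PASE duration: ", paste(stats::na.omit(bad_d),
                                          collapse = ", "), call. = FALSE)
  }
  h <- unname(weights$freq_days[frequency] * weights$dur_hours[duration])
  h[never] <- 0
  h
}

validate_pase <- function(resp, weights) {
  if (!inherits(weights, "pase_weights")) {
    stop("`weights` must be a `pase_weights` object; the PASE scorer does ",
         "not run without explicit item weights (see default_pase_weights())",
         call. = FALSE)
  }
  req <- c("item", "frequency", "duration")
  miss <- setdiff(req, names(resp))
  if (length(miss)) {
    stop("PASE response is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  items <- setdiff(unique(resp$item), "work")
  unknown <- setdiff(items, names(weights$weights))
  if (length(unknown)) {
    stop("unknown PASE item id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(resp)
}

score_pase_one <- function(resp, weights) {
  is_work <- resp$item == "work"
  items <- resp[!is_work, ]
  sum_score <- 0
  act_hours <- 0
  sed_hours <- 0
  if (nrow(items)) {
    h <- pase_hours_per_week(items$frequency, items$duration, weights)
    w <- weights$weights[items$item]
    type <- weights$item_type[items$item]
    sum_score <- sum(w * h)
    act_hours <- sum(h[type == "activity"])
    sed_hours <- sum(h[type == "sedentary"])
  }
  work <- resp[is_work, ]
  if (nrow(work)) {
    if (nrow(work) > 1) stop("more than one work item", call. = FALSE)
    worked <- isTRUE(work$worked)
    if (worked) {
      wh <- unname(weights$work_hours_week[work$work_hours])
      if (is.na(wh)) {
        stop("unknown PASE work-hours category: ", work$work_hours,
             call. = FALSE)
      }
      if (isTRUE(work$sitting_only)) {
        # mostly-sitting work counts as sedentary time, not weighted work
        sed_hours <- sed_hours + wh
      } else {
        sum_score <- sum_score + weights$work_weight * wh
        act_hours <- act_hours + wh
      }
    }
  }
  tibble::tibble(sum_score = sum_score, total_pa_min = 60 * act_hours,
                 sedentary_min = 60 * sed_hours)
}

#' Score PASE questionnaire responses
#'
#' Computes the PASE sum score (sum over items of item weight x hours/week),
#' total physical-activity minutes per week and sedentary minutes per week.
#' Work that involves mostly sitting contributes to sedentary minutes and is
#' excluded from the weighted sum, matching the instrument's handling of
#' office-type work.
#'
#' @param resp A tibble with one row per answered item: columns `item`
#'   (token present in `weights`, or `"work"`), `frequency`, `duration`
#'   (categories, `NA` for the work row), and for the work row logical
#'   columns `worked`, `sitting_only` and category `work_hours`
#'   (lt1h/h1to4/h5to8/gt8h). Optional `subject_id`/`visit` columns give one
#'   output row per subject-visit.
#' @param weights A `pase_weights` object; see [default_pase_weights()].
#' @return A tibble with columns `sum_score`, `total_pa_min`,
#'   `sedentary_min` (plus grouping columns).
#' @export
#' @examples
#' resp <- tibble::tibble(item = "walk", frequency = "sometimes",
#'                        duration = "h1to2")
#' score_pase(resp)
score_pase <- function(resp, weights = default_pase_weights()) {
  validate_pase(resp, weights)
  group_cols <- intersect(c("subject_id", "visit"), names(resp))
  if (nrow(resp) == 0) {
    return(tibble::tibble(sum_score = 0, total_pa_min = 0, sedentary_min = 0))
  }
  for (col in c("worked", "sitting_only")) {
    if (!col %in% names(resp)) resp[[col]] <- FALSE
  }
  if (!"work_hours" %in% names(resp)) resp$work_hours <- NA_character_
  resp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(~ score_pase_one(.x, weights)) |>
    dplyr::ungroup()
}
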