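#' Construct an accelerometer epoch series
#'
#' A lightweight container for a uniaxial count stream recorded in fixed
#' epochs (15 s by default). Timestamps are implicit: `start` plus
#' `epoch_seconds` times the epoch index, which enforces the strictly
#' increasing, gap-free spacing the downstream processing assumes. Missing
#' spans must be encoded as zero-count epochs (or the days trimmed) before
#' construction.
#'
#' @param counts Integer vector of non-negative epoch counts.
#' @param subject_id Subject identifier.
#' @param start POSIXct start time of the first epoch.
#' @param epoch_seconds Epoch length in seconds; must divide 60.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(counts, subject_id = "S1",
                         start = as.POSIXct("2009-03-02 00:00:00",
                                            tz = "UTC"),
                         epoch_seconds = 15) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("epoch counts must be finite and non-negative", call. = FALSE)
  }
  if (60 %% epoch_seconds != 0) {
    stop("`epoch_seconds` must divide 60", call. = FALSE)
  }
  structure(list(subject_id = subject_id, start = start,
                 epoch_seconds = epoch_seconds,
                 counts = as.integer(round(counts))),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s: %d epochs of %ds starting %s\n",
              x$subject_id, length(x$counts), x$epoch_seconds,
              format(x$start, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Collapse an epoch series to counts per minute
#'
#' Sums each minute's epochs (4 epochs for 15-s data) into a single
#' counts/min value. The stream is first aligned to a minute boundary by
#' trimming leading epochs; a trailing partial minute is dropped with a
#' warning.
#'
#' @param es An [epoch_series()].
#' @return A `minute_series`: a tibble with columns `time`, `counts` and a
#'   logical `wear` column (all `NA` until [detect_nonwear()] runs), with the
#'   subject id attached as an attribute.
#' @export
to_minutes <- function(es) {
  stopifnot(inherits(es, "epoch_series"))
  per_min <- 60L %/% es$epoch_seconds
  counts <- es$counts
  start <- es$start
  offset <- as.numeric(start) %% 60
  if (offset != 0) {
    skip <- ceiling((60 - offset) / es$epoch_seconds)
    counts <- counts[-seq_len(skip)]
    start <- start + (60 - offset)
  }
  tail_len <- length(counts) %% per_min
  if (tail_len != 0) {
    warning("dropping trailing partial minute (", tail_len, " epochs)",
            call. = FALSE)
    counts <- counts[seq_len(length(counts) - tail_len)]
  }
  n_min <- length(counts) %/% per_min
  cpm <- as.integer(colSums(matrix(counts, nrow = per_min)))
  out <- tibble::tibble(
    time = start + 60 * (seq_len(n_min) - 1L),
    counts = cpm,
    wear = rep(NA, n_min)
  )
  attr(out, "subject_id") <- es$subject_id
  class(out) <- c("minute_series", class(out))
  out
}

#' Flag non-wear minutes in a minute series
#'
#' Non-wear time is defined as 60 or more minutes of consecutive zero counts.
#' Every maximal run of zero-count minutes at least `min_zero_run` long is
#' flagged non-wear in full; shorter zero runs, and all non-zero minutes,
#' are wear. The rule is strict: a single non-zero minute breaks the run (no
#' spike tolerance). Applying the detector twice gives the same flags.
#'
#' @param m A `minute_series` from [to_minutes()].
#' @param min_zero_run Minimum length, in minutes, of a zero run that counts
#'   as non-wear (default 60).
#' @return `m` with the `wear` column filled in.
#' @export
detect_nonwear <- function(m, min_zero_run = 60) {
  stopifnot(inherits(m, "minute_series"))
  z <- m$counts == 0
  r <- rle(z)
  nonwear_run <- r$values & r$lengths >= min_zero_run
  m$wear <- !inverse.rle(list(values = nonwear_run, lengths = r$lengths))
  m
}

#' Freedson counts-per-minute cut-points
#'
#' The published thresholds mapping uniaxial hip counts/min to intensity:
#' sedentary < 100, light 100-1951, moderate 1952-5724 (about 3.0-5.9 MET),
#' vigorous >= 5725 (>= 6.0 MET). The bands are contiguous and cover all
#' non-negative counts.
#'
#' @param light_min,moderate_min,vigorous_min Lower bounds (counts/min) of
#'   the light, moderate and vigorous bands.
#' @return An object of class `cutpoints`.
#' @export
freedson_cutpoints <- function(light_min = 100, moderate_min = 1952,
                               vigorous_min = 5725) {
  breaks <- c(light_min, moderate_min, vigorous_min)
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
    stop("cut-points must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(breaks = breaks,
                 bands = c("sedentary", "light", "moderate", "vigorous")),
            class = "cutpoints")
}

#' Classify counts/min into intensity bands
#'
#' @param counts_per_min Numeric vector of non-negative counts/min.
#' @param cutpoints A [freedson_cutpoints()] object.
#' @return Character vector of band names.
#' @export
#' @examples
#' classify_band(c(0, 99, 100, 1951, 1952, 5724, 5725))
classify_band <- function(counts_per_min, cutpoints = freedson_cutpoints()) {
  if (any(counts_per_min < 0)) {
    stop("counts/min must be non-negative", call. = FALSE)
  }
  as.character(cut(counts_per_min, breaks = c(0, cutpoints$breaks, Inf),
                   right = FALSE, labels = cutpoints$bands))
}

#' Force non-wear over journal-reported off-body periods
#'
#' Studies often collect a simple wear journal (waking/sleeping times,
#' periods the monitor was off). This optional mask forces `wear = FALSE`
#' over the reported intervals after [detect_nonwear()] has run; it never
#' turns non-wear back into wear.
#'
#' @param m A `minute_series` with wear flags.
#' @param journal A tibble with POSIXct columns `start` and `end`
#'   (half-open intervals `[start, end)`).
#' @return `m` with the mask applied.
#' @export
apply_wear_journal <- function(m, journal) {
  stopifnot(inherits(m, "minute_series"))
  for (i in seq_len(nrow(journal))) {
    masked <- m$time >= journal$start[i] & m$time < journal$end[i]
    m$wear[masked] <- FALSE
  }
  m
}

#' Per-day wear and intensity summaries
#'
#' Accumulates wear minutes and intensity-band minutes per calendar day.
#' Band minutes are counted over wear time only: non-wear minutes belong to
#' no band, so the four band totals sum to the day's wear minutes. A day is
#' valid when it holds at least `min_wear_minutes` (default 600, i.e. 10 h)
#' of wear.
#'
#' @param m A `minute_series`; wear flags are computed with the default
#'   60-min rule if still missing.
#' @param cutpoints A [freedson_cutpoints()] object.
#' @param min_wear_minutes Wear minutes required for a valid day.
#' @return A tibble with one row per day: `date`, `wear_minutes`,
#'   `sedentary_min`, `light_min`, `moderate_min`, `vigorous_min`,
#'   `counts_sum`, `valid`.
#' @export
summarize_days <- function(m, cutpoints = freedson_cutpoints(),
                           min_wear_minutes = 600) {
  stopifnot(inherits(m, "minute_series"))
  if (anyNA(m$wear)) m <- detect_nonwear(m)
  band <- classify_band(m$counts, cutpoints)
  tibble::tibble(date = as.Date(m$time, tz = "UTC"), wear = m$wear,
                 counts = m$counts, band = band) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      wear_minutes = sum(.data$wear),
      sedentary_min = sum(.data$wear & .data$band == "sedentary"),
      light_min = sum(.data$wear & .data$band == "light"),
      moderate_min = sum(.data$wear & .data$band == "moderate"),
      vigorous_min = sum(.data$wear & .data$band == "vigorous"),
      counts_sum = sum(.data$counts[.data$wear]),
      .groups = "drop"
    ) |>
    dplyr::mutate(valid = .data$wear_minutes >= min_wear_minutes)
}

#' Weekly accelerometer summary for one subject
#'
#' Applies the validity rules (a valid day holds >= 600 wear minutes; a
#' subject is included with >= 5 valid days) and converts valid-day averages
#' to weekly totals: weekly band minutes are the mean over valid days times
#' 7, regardless of whether 5, 6 or 7 days were valid. The overall intensity
#' `counts_per_min` is total counts over wear time divided by wear minutes,
#' across valid days. Subjects failing the inclusion rule still get a row
#' (with `included = FALSE`) so that downstream exclusion is explicit.
#'
#' @param m A `minute_series`.
#' @param cutpoints A [freedson_cutpoints()] object.
#' @param min_wear_minutes Wear minutes for a valid day (default 600).
#' @param min_valid_days Valid days required for inclusion (default 5).
#' @return A one-row tibble: `subject_id`, `n_valid_days`, `included`,
#'   `counts_per_min`, `wear_min_wk`, `sedentary_min_wk`, `light_min_wk`,
#'   `moderate_min_wk`, `vigorous_min_wk`, `mvpa_min_wk`, `total_pa_min_wk`.
#' @export
summarize_subject <- function(m, cutpoints = freedson_cutpoints(),
                              min_wear_minutes = 600, min_valid_days = 5) {
  days <- summarize_days(m, cutpoints, min_wear_minutes)
  valid <- days[days$valid, ]
  n_valid <- nrow(valid)
  weekly <- function(x) if (n_valid == 0) NA_real_ else mean(x) * 7
  cpm <- if (n_valid == 0 || sum(valid$wear_minutes) == 0) NA_real_ else
    sum(valid$counts_sum) / sum(valid$wear_minutes)
  tibble::tibble(
    subject_id = attr(m, "subject_id") %||% NA_character_,
    n_valid_days = n_valid,
    included = n_valid >= min_valid_days,
    counts_per_min = cpm,
    wear_min_wk = weekly(valid$wear_minutes),
    sedentary_min_wk = weekly(valid$sedentary_min),
    light_min_wk = weekly(valid$light_min),
    moderate_min_wk = weekly(valid$moderate_min),
    vigorous_min_wk = weekly(valid$vigorous_min),
    mvpa_min_wk = weekly(valid$moderate_min + valid$vigorous_min),
    total_pa_min_wk = weekly(valid$light_min + valid$moderate_min +
                               valid$vigorous_min)
  )
}

#' Summarize a list of epoch series
#'
#' Convenience wrapper running [to_minutes()], [detect_nonwear()] and
#' [summarize_subject()] over a cohort.
#'
#' @param epochs A list of [epoch_series()] objects.
#' @inheritParams summarize_subject
#' @return A tibble with one row per subject.
#' @export
summarize_cohort <- function(epochs, cutpoints = freedson_cutpoints(),
                             min_wear_minutes = 600, min_valid_days = 5) {
  purrr::map_dfr(epochs, function(es) {
    summarize_subject(detect_nonwear(to_minutes(es)), cutpoints,
                      min_wear_minutes, min_valid_days)
  })
}

#' Write an epoch series to CSV
#'
#' Two columns: `timestamp` (ISO-8601) and `axis1` (counts per epoch).
#'
#' @param es An [epoch_series()].
#' @param path Output file path.
#' @export
write_epoch_csv <- function(es, path) {
  ts <- es$start + es$epoch_seconds * (seq_along(es$counts) - 1L)
  readr::write_csv(
    tibble::tibble(timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   axis1 = es$counts),
    path)
  invisible(path)
}

#' Read an epoch series from CSV
#'
#' Expects columns `timestamp` (ISO-8601) and `axis1`; the epoch length is
#' inferred from the timestamp spacing, which must be constant.
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier to attach (defaults to the file name
#'   without extension).
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, subject_id = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(), axis1 = readr::col_integer()))
  if (nrow(df) > 1) {
    spacing <- unique(diff(as.numeric(df$timestamp)))
    if (length(spacing) != 1) {
      stop("epoch timestamps are not evenly spaced in ", path, call. = FALSE)
    }
  } else {
    spacing <- 15
  }
  epoch_series(df$axis1,
               subject_id = subject_id %||%
                 sub("\\.csv$", "", basename(path)),
               start = df$timestamp[1], epoch_seconds = spacing)
}
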