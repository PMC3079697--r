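# Independent oracles used across the suite.

# One-way ANOVA by explicit sums (independent of the package's
# variance_components()).
oracle_anova <- function(t0, t1) {
  n <- length(t0)
  k <- 2
  mi <- (t0 + t1) / 2
  g <- mean(c(t0, t1))
  msb <- k * sum((mi - g)^2) / (n - 1)
  msw <- sum((t0 - mi)^2 + (t1 - mi)^2) / (n * (k - 1))
  list(msb = msb, msw = msw,
       icc = (msb - msw) / (msb + msw),
       sem = sqrt(msw))
}

# Same decomposition through R's fitted ANOVA machinery.
oracle_aov <- function(t0, t1) {
  n <- length(t0)
  d <- data.frame(y = c(t0, t1), s = factor(rep(seq_len(n), 2)))
  tab <- summary(stats::aov(y ~ s, data = d))[[1]]
  list(msb = tab[["Mean Sq"]][1], msw = tab[["Mean Sq"]][2])
}

# Brute-force non-wear scanner: a minute is non-wear iff the maximal run of
# consecutive zeros containing it is at least `min_run` long. Written as a
# per-minute outward scan, unlike the package's run-length encoding.
oracle_nonwear <- function(counts, min_run = 60) {
  n <- length(counts)
  wear <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (counts[i] != 0) next
    lo <- i
    while (lo > 1 && counts[lo - 1] == 0) lo <- lo - 1
    hi <- i
    while (hi < n && counts[hi + 1] == 0) hi <- hi + 1
    if (hi - lo + 1 >= min_run) wear[i] <- FALSE
  }
  wear
}

# Minute-series constructor for tests: counts per minute -> epoch series
# (each minute split into 4 equal epochs; counts must be divisible by 4).
minute_stream <- function(counts_per_min, subject_id = "T1") {
  stopifnot(all(counts_per_min %% 4 == 0))
  epoch_series(rep(counts_per_min / 4, each = 4), subject_id = subject_id)
}

# Recursive permutation enumerator, written independently of the package's.
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# cohort_config() warns that one default agreement target is structurally
# unattainable; tests use the config with that warning acknowledged.
quiet_cfg <- function(...) suppressWarnings(cohort_config(...))
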