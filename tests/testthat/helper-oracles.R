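# Independent brute-force oracles used to verify the pipeline. These are
# deliberately naive (linear scans, raw-sum formulas, stats::lm refits) and
# share no code with the implementation.

# all maximal zero runs of length >= min_bout, by explicit linear scan
oracle_zero_runs <- function(counts, min_bout = 5L) {
  runs <- list()
  start <- NA_integer_
  for (i in seq_along(counts)) {
    if (counts[i] == 0L) {
      if (is.na(start)) start <- i
    } else if (!is.na(start)) {
      runs[[length(runs) + 1L]] <- c(start, i - start)
      start <- NA_integer_
    }
  }
  if (!is.na(start)) {
    runs[[length(runs) + 1L]] <- c(start, length(counts) - start + 1L)
  }
  runs <- Filter(function(r) r[2] >= min_bout, runs)
  if (!length(runs)) {
    return(data.frame(start0 = integer(), len = integer()))
  }
  m <- do.call(rbind, runs)
  data.frame(start0 = m[, 1] - 1L, len = m[, 2])
}

# label every minute sleep/wake then aggregate per phase, independently of
# sleep_metrics()
oracle_phase_metrics <- function(counts, zt0, min_bout = 5L) {
  runs <- oracle_zero_runs(counts, min_bout)
  asleep <- logical(length(counts))
  for (i in seq_len(nrow(runs))) {
    asleep[(runs$start0[i] + 1L):(runs$start0[i] + runs$len[i])] <- TRUE
  }
  zt <- (zt0 + seq_along(counts) - 1L) %% 1440L
  is_day <- zt < 720L
  res <- lapply(c(TRUE, FALSE), function(day) {
    sel <- is_day == day
    nb <- 0L
    for (i in seq_len(nrow(runs))) {
      mins <- (runs$start0[i] + 1L):(runs$start0[i] + runs$len[i])
      if (any(sel[mins])) nb <- nb + 1L
    }
    waking <- sum(sel & !asleep)
    data.frame(phase = if (day) "day" else "night",
               total = sum(sel & asleep), bout_number = nb,
               waking_activity = if (waking > 0L) sum(counts[sel]) / waking
                                 else NA_real_)
  })
  do.call(rbind, res)
}

# time asleep before 0-based minute t by backwards scan
oracle_time_asleep <- function(counts, t, min_sleep = 5L) {
  k <- 0L
  i <- t                       # 1-based index of 0-based minute t - 1
  while (i >= 1L && counts[i] == 0L) { k <- k + 1L; i <- i - 1L }
  if (k >= min_sleep) k else NA_integer_
}

# OLS by raw-sum normal equations (textbook formulas, not centered sums)
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  sigma2 <- rss / (n - 2)
  se_slope <- sqrt(sigma2 * n / (n * sxx - sx^2))
  f <- (slope / se_slope)^2
  list(slope = slope, intercept = intercept, se_slope = se_slope,
       rss = rss, f = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# ANCOVA by fitting the three nested models with stats::lm and comparing RSS
oracle_ancova <- function(groups) {
  df <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(x = groups[[i]]$x, y = groups[[i]]$y, g = factor(i))
  }))
  rss <- function(m) sum(stats::residuals(m)^2)
  m_sep <- stats::lm(y ~ g * x, data = df)
  m_com <- stats::lm(y ~ g + x, data = df)
  m_one <- stats::lm(y ~ x, data = df)
  g <- length(groups); n <- nrow(df)
  f_slopes <- ((rss(m_com) - rss(m_sep)) / (g - 1)) / (rss(m_sep) / (n - 2 * g))
  f_int <- ((rss(m_one) - rss(m_com)) / (g - 1)) / (rss(m_com) / (n - g - 1))
  list(f_slopes = f_slopes,
       p_slopes = stats::pf(f_slopes, g - 1, n - 2 * g, lower.tail = FALSE),
       f_intercepts = f_int,
       p_intercepts = stats::pf(f_int, g - 1, n - g - 1, lower.tail = FALSE))
}

# random activity trace with roughly block-structured zeros so bouts occur
random_trace <- function(n = 1440L, p_active = 0.5, zt0 = 0L,
                         fly_id = "rnd", lam = 2) {
  counts <- ifelse(stats::runif(n) < p_active, stats::rpois(n, lam) + 1L, 0L)
  activity_trace(fly_id, counts, zt0_offset_min = zt0)
}
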