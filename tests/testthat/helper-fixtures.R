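# Fixture builders and independent brute-force oracles used across tests.

make_samples <- function(site_id, sample_date, parameter, value,
                         depth_m = 0.5, below_detection = FALSE,
                         detection_limit = NA_real_) {
  data.frame(site_id = site_id, sample_date = as.Date(sample_date),
             depth_m = depth_m, parameter = parameter, value = value,
             below_detection = below_detection,
             detection_limit = detection_limit, stringsAsFactors = FALSE)
}

# One measurement per listed (site, year); handy for anomaly-stage tests.
samples_from_grid <- function(grid, parameter = "temperature") {
  make_samples(site_id = grid$site_id,
               sample_date = sprintf("%d-07-15", grid$year),
               parameter = parameter, value = grid$value)
}

# Deliberately naive re-implementation of the anomaly pipeline with explicit
# loops and sorting, independent of the package internals.
oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

oracle_quantile_type7 <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

oracle_pipeline <- function(samples, min_sites_per_year = 1) {
  samples$year <- as.integer(format(samples$sample_date, "%Y"))
  anoms <- data.frame()
  for (p in unique(samples$parameter)) {
    sp <- samples[samples$parameter == p, ]
    for (s in unique(sp$site_id)) {
      ss <- sp[sp$site_id == s, ]
      ann <- data.frame()
      for (y in sort(unique(ss$year))) {
        ann <- rbind(ann, data.frame(
          year = y, med = oracle_median(ss$value[ss$year == y])))
      }
      ref <- oracle_median(ann$med)
      for (i in seq_len(nrow(ann))) {
        anoms <- rbind(anoms, data.frame(
          site_id = s, year = ann$year[i], parameter = p,
          anomaly = ann$med[i] - ref, stringsAsFactors = FALSE))
      }
    }
  }
  yearly <- data.frame()
  for (p in unique(anoms$parameter)) {
    ap <- anoms[anoms$parameter == p, ]
    for (y in sort(unique(ap$year))) {
      v <- ap$anomaly[ap$year == y]
      if (length(v) < min_sites_per_year) next
      yearly <- rbind(yearly, data.frame(
        year = y, parameter = p,
        median_anomaly = oracle_median(v),
        p25 = oracle_quantile_type7(v, 0.25),
        p75 = oracle_quantile_type7(v, 0.75),
        min = min(v), max = max(v), n_sites = length(v),
        stringsAsFactors = FALSE))
    }
  }
  list(anomalies = anoms, yearly = yearly)
}

# Closed-form simple linear regression (normal equations), independent of lm.
oracle_ols <- function(x, y) {
  n <- length(x)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  tstat <- b1 / se
  list(slope = b1, intercept = b0,
       p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

# Random small monitoring cohort for property tests.
random_cohort <- function(n_sites, n_years, parameter = "tp",
                          start_year = 2001) {
  rows <- list()
  for (s in seq_len(n_sites)) {
    yrs <- sort(sample(start_year + 0:(n_years - 1),
                       size = sample(2:n_years, 1)))
    for (y in yrs) {
      k <- sample(1:4, 1)
      rows[[length(rows) + 1]] <- make_samples(
        site_id = sprintf("s%02d", s),
        sample_date = sprintf("%d-%02d-10", y, sample(5:10, k, replace = TRUE)),
        parameter = parameter,
        value = round(stats::rlnorm(k, log(15), 0.5), 3))
    }
  }
  do.call(rbind, rows)
}
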