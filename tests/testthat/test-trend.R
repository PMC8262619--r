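yearly_df <- function(years, anomalies, parameter = "temperature",
                      n_sites = 10) {
  data.frame(year = years, parameter = parameter,
             median_anomaly = anomalies,
             p25 = anomalies - 1, p75 = anomalies + 1,
             min = anomalies - 2, max = anomalies + 2,
             n_sites = n_sites, low_n_flag = n_sites == 3,
             stringsAsFactors = FALSE)
}

test_that("fit_trend matches closed-form OLS and handles degenerate input", {
  years <- 1993:2016
  exact <- yearly_df(years, 0.05 * (years - 2000))
  f <- fit_trend(exact)
  expect_equal(f$slope, 0.05)
  expect_lt(f$p_value, 1e-12)

  flat <- yearly_df(years, rep(0, length(years)))
  f0 <- fit_trend(flat)
  expect_equal(f0$slope, 0)
  expect_equal(f0$p_value, 1)

  set.seed(19)
  y <- stats::rnorm(length(years))
  noisy <- yearly_df(years, y)
  fn <- fit_trend(noisy)
  oracle <- oracle_ols(years, y)
  expect_equal(fn$slope, oracle$slope)
  expect_equal(fn$intercept, oracle$intercept)
  expect_equal(fn$p_value, oracle$p_value)

  expect_error(fit_trend(yearly_df(2001:2002, c(0, 1))), "at least 3")
  expect_error(fit_trend(yearly_df(rep(2001, 3), c(0, 1, 2))), "identical")
})

test_that("fit_trend type-I error is near nominal under the null", {
  set.seed(909)
  years <- 1993:2016
  n_reps <- 1000
  rejections <- 0
  for (r in seq_len(n_reps)) {
    f <- fit_trend(yearly_df(years, stats::rnorm(length(years))))
    if (f$p_value <= 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_reps
  se2 <- 2 * sqrt(0.05 * 0.95 / n_reps)
  expect_gte(rate, 0.05 - se2)
  expect_lte(rate, 0.05 + se2)
})

test_that("scaling anomalies scales the slope and preserves the p-value", {
  set.seed(77)
  years <- 1995:2012
  y <- stats::rnorm(length(years), 0.02 * (years - 2000), 0.5)
  f1 <- fit_trend(yearly_df(years, y))
  for (c_scale in c(0.001, 3, 1000)) {
    f2 <- fit_trend(yearly_df(years, c_scale * y))
    expect_equal(f2$slope, c_scale * f1$slope)
    expect_equal(f2$p_value, f1$p_value)
  }
})

test_that("statistical criterion applies the alpha cut inclusively", {
  f <- function(p) structure(list(p_value = p), class = "trend_fit")
  expect_true(criterion_statistical(f(0.065), alpha = 0.10))
  expect_false(criterion_statistical(f(0.14), alpha = 0.10))
  expect_true(criterion_statistical(f(0.013), alpha = 0.10))
  expect_true(criterion_statistical(f(0.10), alpha = 0.10))
})

test_that("pattern criterion detects one-sided clustering of high years", {
  years <- 2000:2011
  up <- yearly_df(years, c(rep(-1, 6), rep(1, 6)))
  expect_true(criterion_pattern(up))
  expect_equal(attr(criterion_pattern(up), "direction"), "increasing")

  alternating <- yearly_df(years, rep(c(1, -1), 6))
  expect_false(criterion_pattern(alternating))

  down <- yearly_df(years, c(rep(1, 6), rep(-1, 6)))
  expect_equal(attr(criterion_pattern(down), "direction"), "decreasing")
})

test_that("pattern criterion holds exactly at the two-thirds share", {
  # 12 years, midpoint splits 2000-2005 / 2006-2011; 9 positive years of
  # which 6 are late, 3 negative years all early
  years <- 2000:2011
  anom <- c(-1, -1, -1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  ys <- yearly_df(years, anom)
  expect_true(criterion_pattern(ys, pattern_fraction = 2 / 3))
  expect_false(criterion_pattern(ys, pattern_fraction = 0.7))
})

test_that("zero anomalies are excluded from the pattern counts", {
  years <- 2000:2011
  with_zero <- yearly_df(years, c(-1, -1, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1))
  expect_true(criterion_pattern(with_zero))
  expect_error(criterion_pattern(yearly_df(2000:2002, c(1, 0, -1))),
               "at least 4")
})

test_that("magnitude criterion compares |slope| to the registry inclusively", {
  reg <- threshold_derivations()
  f <- function(p, s) structure(list(parameter = p, slope = s),
                                class = "trend_fit")
  expect_true(criterion_magnitude(f("temperature", 0.044), reg))
  expect_false(criterion_magnitude(f("tp", 0.05), reg))
  expect_true(criterion_magnitude(f("tp", 0.1), reg))   # boundary attains
  expect_true(criterion_magnitude(f("chla", -0.04), reg))  # magnitude only
  expect_error(criterion_magnitude(f("secchi", 1), reg), "no slope threshold")
})

test_that("threshold registry derives each value from its printed basis", {
  reg <- threshold_derivations()
  expect_equal(reg$threshold[reg$parameter == "temperature"], 2 / 100)
  expect_equal(reg$threshold[reg$parameter == "chla"], 3.5 / 100)
  expect_equal(reg$threshold[reg$parameter == "tn"], 350 / 100)
  expect_equal(reg$threshold[reg$parameter == "tp"], 10 / 100)
  expect_equal(reg$threshold[reg$parameter == "np_ratio"], (61 - 35) / 100)
  expect_true(all(reg$threshold > 0))
})

test_that("assess_trend counts criteria and signs the direction", {
  years <- 1993:2016
  strong <- yearly_df(years, 0.05 * (years - mean(years)))
  a <- assess_trend(strong)
  expect_equal(a$n_criteria_met, 3)
  expect_equal(a$classification, "trend")
  expect_equal(a$direction, "increasing")
  expect_equal(a$symbol, "++")

  flat <- yearly_df(years, rep(c(0.001, -0.001), 12))
  a0 <- assess_trend(flat)
  expect_equal(a0$classification, "no_trend")
  expect_equal(a0$direction, "none")
  expect_equal(a0$symbol, "0")

  falling <- yearly_df(years, -0.05 * (years - mean(years)))
  ad <- assess_trend(falling)
  expect_equal(ad$classification, "trend")
  expect_equal(ad$direction, "decreasing")
  expect_equal(ad$symbol, "--")
})

test_that("classification bands follow the met-criteria count", {
  reg <- threshold_derivations()
  all3 <- trend_rubric("temperature", 0.05, 0.01, TRUE, reg)
  expect_equal(all3$classification, "trend")
  one <- trend_rubric("tp", 0.05, 0.013, FALSE, reg)
  expect_equal(one$n_criteria_met, 1)
  expect_equal(one$classification, "weak_trend")
  expect_equal(one$symbol, "+")
  none <- trend_rubric("tp", 0.0083, 0.86, FALSE, reg)
  expect_equal(none$classification, "no_trend")
})

test_that("leave_year_out refits against an independent oracle", {
  years <- 1994:2005
  on_line <- yearly_df(years, 0.1 * (years - 2000))
  res <- leave_year_out(on_line, 1999)
  expect_equal(res$reduced$slope, res$full$slope)

  set.seed(5)
  y <- stats::rnorm(length(years))
  y[1] <- -8  # influential early year
  noisy <- yearly_df(years, y)
  res2 <- leave_year_out(noisy, 1994)
  oracle <- oracle_ols(years[-1], y[-1])
  expect_equal(res2$reduced$slope, oracle$slope)
  expect_lt(abs(res2$reduced$slope), abs(res2$full$slope))

  expect_warning(res3 <- leave_year_out(noisy, 1890), "not among")
  expect_equal(res3$reduced$slope, res3$full$slope)
})

test_that("first exceedance day averages site-year first crossings", {
  one <- make_samples("a", c("2001-05-20", "2001-06-11", "2001-07-01"),
                      "temperature", c(20, 26, 27))
  r1 <- first_exceedance_day(one, threshold = 25)
  expect_equal(r1$mean_day, as.integer(format(as.Date("2001-06-11"), "%j")))

  two <- rbind(
    make_samples("a", "2001-06-01", "temperature", 26),
    make_samples("b", "2001-06-21", "temperature", 26),
    make_samples("c", "2001-06-21", "temperature", 20))
  r2 <- first_exceedance_day(two, threshold = 25)
  d <- as.integer(format(as.Date(c("2001-06-01", "2001-06-21")), "%j"))
  expect_equal(r2$mean_day, mean(d))
  expect_equal(r2$n_no_exceedance, 1)

  cold <- make_samples("a", "2001-06-01", "temperature", 18)
  expect_error(first_exceedance_day(cold), "no site-year exceeds")
})

test_that("a warming series first exceeds earlier in later windows", {
  set.seed(99)
  cfg <- sim_config(n_sites = 15, enrollment_years = 1993, dropout_prob = 0,
                    visits_per_bin = c(temperature = 8),
                    site_effect = list(temperature = list(
                      dist = "normal", mean = 24, sd = 0.5)),
                    noise = list(temperature = list(sd = 1)),
                    trend = c(temperature = 0.15), seed = 21)
  sim <- simulate_program(cfg)
  early <- first_exceedance_day(sim$samples, 25, years = 1993:1995)
  late <- first_exceedance_day(sim$samples, 25, years = 2014:2016)
  expect_lt(late$mean_day, early$mean_day)
})

test_that("detection-limit sensitivity reruns the pipeline and compares", {
  cfg <- sim_config(n_sites = 10, visits_per_bin = c(tp = 2),
                    site_effect = list(tp = list(dist = "lognormal",
                                                 meanlog = log(15), sdlog = 0.6)),
                    noise = list(tp = list(sdlog = 0.4)),
                    trend = c(tp = 0), detection_limit = c(tp = 1),
                    enrollment_years = 1993, dropout_prob = 0, seed = 12)
  sim <- simulate_program(cfg)
  expect_lt(mean(sim$samples$below_detection), 0.02)  # lightly censored
  res <- detection_limit_sensitivity(sim$samples, eligibility_config("uriww"),
                                     compute_np = FALSE)
  expect_true(all(res$agreement$agree))
  # uncensored data: the two runs are identical
  clean <- sim$samples
  clean$below_detection <- FALSE
  res2 <- detection_limit_sensitivity(clean, eligibility_config("uriww"),
                                      compute_np = FALSE)
  expect_identical(summary(res2$all)$table, summary(res2$above_detection)$table)
})
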