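test_that("annual site medians collapse replicates robustly", {
  one <- make_samples("a", "2001-07-01", "tp", 7)
  expect_equal(annual_site_medians(one)$annual_median, 7)
  expect_equal(annual_site_medians(one)$n_samples, 1L)

  outlier <- make_samples("a", sprintf("2001-07-%02d", 1:3), "chla",
                          c(10, 20, 1000))
  expect_equal(annual_site_medians(outlier)$annual_median, 20)

  even <- make_samples("a", c("2001-07-01", "2001-08-01"), "tp", c(4, 6))
  expect_equal(annual_site_medians(even)$annual_median, 5)
})

test_that("site references default to the median of annual medians", {
  grid <- data.frame(site_id = "a", year = 2001:2003, value = c(1, 2, 3))
  sym <- annual_site_medians(samples_from_grid(grid))
  refs <- site_reference_medians(sym)
  expect_equal(refs$reference_median, 2)
  expect_equal(refs$n_years, 3L)

  single <- annual_site_medians(samples_from_grid(
    data.frame(site_id = "b", year = 2005, value = 9)))
  refs1 <- site_reference_medians(single)
  an <- compute_anomalies(single, refs1)
  expect_equal(an$anomaly, 0)
})

test_that("raw reference basis uses all reference-period measurements", {
  s <- make_samples("a", c("2001-07-01", "2001-08-01", "2002-07-01"),
                    "tp", c(1, 9, 4))
  sym <- annual_site_medians(s)
  # annual medians 5 and 4 -> annual basis 4.5; raw basis median(1,9,4) = 4
  expect_equal(site_reference_medians(sym)$reference_median, 4.5)
  expect_equal(site_reference_medians(sym, basis = "raw",
                                      samples = s)$reference_median, 4)
  expect_error(site_reference_medians(sym, basis = "raw"), "samples")
})

test_that("anomalies subtract the site reference exactly", {
  grid <- data.frame(site_id = "a", year = 2001:2003, value = c(22, 23, 21))
  sym <- annual_site_medians(samples_from_grid(grid))
  an <- compute_anomalies(sym, site_reference_medians(sym))
  expect_equal(an$anomaly[an$year == 2002], 1)
  const <- data.frame(site_id = "c", year = 2001:2005, value = 17)
  symc <- annual_site_medians(samples_from_grid(const))
  expect_equal(compute_anomalies(symc, site_reference_medians(symc))$anomaly,
               rep(0, 5))
  expect_error(compute_anomalies(sym, site_reference_medians(symc)),
               "missing reference")
})

test_that("anomalies are invariant to shifting one site by a constant", {
  set.seed(31)
  samples <- random_cohort(5, 6)
  sym <- annual_site_medians(samples)
  an0 <- compute_anomalies(sym, site_reference_medians(sym))
  shifted <- samples
  target <- shifted$site_id == "s01"
  shifted$value[target] <- shifted$value[target] + 42
  sym2 <- annual_site_medians(shifted)
  an1 <- compute_anomalies(sym2, site_reference_medians(sym2))
  ord <- function(a) a[order(a$site_id, a$year), "anomaly"]
  expect_equal(ord(an1), ord(an0))
})

test_that("per-site anomaly median is zero for odd year counts", {
  set.seed(57)
  for (rep in 1:10) {
    n_years <- sample(c(3, 5, 7, 9), 1)
    grid <- data.frame(site_id = "a", year = 2000 + seq_len(n_years),
                       value = round(stats::runif(n_years, 0, 50), 2))
    sym <- annual_site_medians(samples_from_grid(grid))
    an <- compute_anomalies(sym, site_reference_medians(sym))
    expect_equal(stats::median(an$anomaly), 0)
  }
})

test_that("downstream results depend on a site-year only through its median", {
  base <- rbind(
    samples_from_grid(data.frame(site_id = "a", year = 2001:2004,
                                 value = c(5, 6, 7, 8))),
    samples_from_grid(data.frame(site_id = "b", year = 2001:2004,
                                 value = c(9, 9, 9, 9))),
    samples_from_grid(data.frame(site_id = "c", year = 2001:2004,
                                 value = c(1, 3, 2, 4))))
  run <- function(s) {
    sym <- annual_site_medians(s)
    yearly_summaries(compute_anomalies(sym, site_reference_medians(sym)),
                     min_sites_per_year = 3)
  }
  y0 <- run(base)
  # replace site a's 2002 single value by a multiset with the same median
  swap <- base[!(base$site_id == "a" &
                   format(base$sample_date, "%Y") == "2002"), ]
  swap <- rbind(swap, make_samples("a", sprintf("2002-0%d-01", 5:7), "temperature",
                                   c(2, 6, 100)))
  y1 <- run(swap)
  expect_equal(y1$median_anomaly, y0$median_anomaly)
  expect_equal(y1$p25, y0$p25)
})

test_that("yearly summaries enforce the minimum-sites rule and flag low n", {
  an <- data.frame(
    site_id = c("a", "b", "a", "b", "c"),
    year = c(2001, 2001, 2002, 2002, 2002),
    parameter = "tp",
    anomaly = c(-1, 1, -1, 0, 2), stringsAsFactors = FALSE)
  ys <- yearly_summaries(an, min_sites_per_year = 3)
  expect_equal(ys$year, 2002)        # 2001 has two sites only
  expect_equal(ys$median_anomaly, 0)
  expect_equal(ys$n_sites, 3L)
  expect_true(ys$low_n_flag)
  excl <- attr(ys, "excluded_years")
  expect_equal(excl$year, 2001)
  expect_error(yearly_summaries(an, min_sites_per_year = 5), "no year")
})

test_that("pipeline matches the brute-force oracle on random cohorts", {
  set.seed(71)
  for (rep in 1:15) {
    samples <- random_cohort(sample(2:10, 1), sample(2:10, 1))
    sym <- annual_site_medians(samples)
    an <- compute_anomalies(sym, site_reference_medians(sym))
    ys <- yearly_summaries(an, min_sites_per_year = 1)
    oracle <- oracle_pipeline(samples, min_sites_per_year = 1)
    ord <- function(a) a[order(a$site_id, a$year), ]
    expect_equal(ord(an)$anomaly, ord(oracle$anomalies)$anomaly)
    oy <- oracle$yearly[order(oracle$yearly$parameter, oracle$yearly$year), ]
    expect_equal(ys$median_anomaly, oy$median_anomaly)
    expect_equal(ys$p25, oy$p25)
    expect_equal(ys$p75, oy$p75)
    expect_equal(ys$min, oy$min)
    expect_equal(ys$max, oy$max)
    expect_equal(ys$n_sites, oy$n_sites)
  }
})

test_that("yearly summary CSV round-trips with deterministic order", {
  set.seed(3)
  samples <- random_cohort(4, 5)
  sym <- annual_site_medians(samples)
  ys <- yearly_summaries(compute_anomalies(sym, site_reference_medians(sym)),
                         min_sites_per_year = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_yearly_summaries(ys, path)
  back <- utils::read.csv(path)
  expect_equal(back$median_anomaly, ys$median_anomaly)
  expect_equal(back$year, ys$year)
})
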