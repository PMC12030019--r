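test_that("histogram densities integrate to one for any input", {
  set.seed(23)
  inputs <- list(rnorm(500, 180, 25), runif(37), rexp(200), c(1, 2, 2, 3, 9))
  for (v in inputs) {
    h <- histogram_pdf(v)
    expect_equal(sum(h$bin_values * h$bin_width), 1, tolerance = 1e-9)
    expect_identical(sum(h$counts), length(v))
  }
})

test_that("single-bin mass and closed last bin behave as specified", {
  # all mass in the first bin except the closed right edge of the last
  v <- c(rep(1, 9), 2)
  h <- histogram_pdf(v, p = 2)
  expect_equal(h$bin_values, c(9, 1) / (10 * 0.5))
  # value exactly at the right edge of the last bin is included in it
  expect_identical(h$counts[2], 1L)
  expect_error(histogram_pdf(rep(5, 10)), "identical")
})

test_that("normal overlay uses sample moments and the closed-form peak", {
  set.seed(24)
  v <- rnorm(400)
  h <- histogram_pdf(v, p = 20, g = 100)
  expect_equal(h$overlay$mu, mean(v))
  expect_equal(h$overlay$sigma, sd(v))
  expect_length(h$overlay$x, 100L)
  # density at x = mu equals 1 / (sigma sqrt(2 pi))
  at_mu <- stats::approx(h$overlay$x, h$overlay$density, xout = h$overlay$mu)$y
  expect_equal(at_mu, 1 / (h$overlay$sigma * sqrt(2 * pi)), tolerance = 5e-3)
})

test_that("growth-rate arithmetic reproduces the survey percentages", {
  expect_equal(percent_growth(10, 51), 410.0)
  expect_equal(percent_growth(23, 36), 56.5)
  expect_equal(percent_growth(36, 54), 50.0)
  expect_equal(percent_growth(17, 17), 0.0)
  expect_error(percent_growth(0, 5), "positive")
  # monotone in the end count
  expect_true(percent_growth(20, 30) > percent_growth(20, 25))
})

test_that("height-gap arithmetic reproduces the plot comparisons", {
  expect_equal(height_gap_percent(212, 174), 21.8)
  expect_equal(height_gap_percent(100, 80), 25.0)
  expect_equal(height_gap_percent(150, 150), 0.0)
  expect_error(height_gap_percent(100, 0), "positive")
})

test_that("group report aggregates plots and combined groups", {
  path <- system.file("extdata", "survival_counts.csv", package = "growcast")
  surveys <- read.csv(path)
  rep <- group_report(surveys, groups = list(group1 = c("A1", "A2"),
                                             group5 = c("E1", "E2")))
  g1 <- rep$group_totals[rep$group_totals$group == "group1", ]
  expect_identical(g1$total_count[g1$date == as.Date("2024-04-22")], 33L)
  expect_identical(g1$total_count[g1$date == as.Date("2024-05-27")], 87L)
  gr <- rep$growth_rates
  expect_equal(gr$percent[gr$field == "A1"], 410.0)
  expect_equal(gr$percent[gr$field == "A2"], 56.5)
  g5 <- rep$group_totals[rep$group_totals$group == "group5", ]
  expect_equal(g5$percent[g5$date == as.Date("2024-05-27")], 50.0)
})

test_that("group report recovers an injected trend from synthetic surveys", {
  set.seed(25)
  dates <- seq(as.Date("2024-04-01"), by = 7, length.out = 8)
  rows <- do.call(rbind, lapply(seq_along(dates), function(i) {
    data.frame(date = dates[i], field = "S1",
               height_mm = rnorm(20, 150 + 5 * i, 3))
  }))
  rep <- group_report(rows)
  mh <- rep$per_plot$mean_height_mm[order(rep$per_plot$date)]
  fit <- coef(lm(mh ~ seq_along(mh)))[2]
  expect_gt(fit, 0)
  # constant heights give a flat mean series
  flat <- do.call(rbind, lapply(dates[1:3], function(d) {
    data.frame(date = d, field = "S2", height_mm = rep(120, 5))
  }))
  repf <- group_report(flat)
  expect_equal(unique(repf$per_plot$mean_height_mm), 120)
})
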