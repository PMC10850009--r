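test_that("SK criterion reproduces hand-computed cases", {
  # mu_m = mu_c gives SK = 0
  r0 <- stability_criterion(c(10, 10), mu_c = 10, u_com_rel = 5)
  expect_equal(r0$SK, 0)
  expect_true(r0$pass)
  # hand case: |10 - 11| / sqrt(0.5^2 + u_m^2)
  vals <- c(10.8, 11.0, 11.2)
  r <- stability_criterion(vals, mu_c = 10, u_com_rel = 5, k = 2)
  u_m <- sd(vals) / sqrt(3)
  expect_equal(r$u_c, 0.5)
  expect_equal(r$SK, 1 / sqrt(0.25 + u_m^2))
  expect_true(r$pass)
  # far-off monitoring mean fails
  r2 <- stability_criterion(c(12.9, 13.0, 13.1), mu_c = 10, u_com_rel = 5, k = 2)
  expect_false(r2$pass)
  expect_gt(r2$SK, 2)
  expect_error(stability_criterion(5, 10, 5), "at least 2",
               class = "certifyr_validation_error")
  expect_error(stability_criterion(c(10, 10), 10, 0), "zero",
               class = "certifyr_validation_error")
})

test_that("SK is symmetric in the deviation and monotone in the uncertainties", {
  up <- stability_criterion(c(10.95, 11.0, 11.05), 10, 5)
  dn <- stability_criterion(c(9.05, 9.0, 8.95), 10, 5)
  expect_equal(up$SK, dn$SK, tolerance = 1e-12)
  # larger u_c decreases SK for a fixed deviation
  sks <- vapply(c(2, 5, 10), function(u) {
    stability_criterion(c(10.9, 11.0, 11.1), 10, u)$SK
  }, numeric(1))
  expect_true(all(diff(sks) < 0))
  # raw-sd mode uses the spread, not the spread of the mean
  raw <- stability_criterion(c(10.9, 11.0, 11.1), 10, 5, u_m_mode = "sd")
  expect_lt(raw$SK, up$SK * 3)
})

test_that("monitoring data are append-only and only comments are editable", {
  ds <- read_lts(lts_csv())
  n0 <- nrow(ds$points)
  ds2 <- add_point(ds, "2024-01-01", 4.05, comment = "new point")
  expect_equal(nrow(ds2$points), n0 + 1)
  expect_equal(ds2$points$value[n0 + 1], 4.05)
  # comments are editable, twice, without touching values
  ds3 <- set_comment(ds2, 1, "first check")
  ds3 <- set_comment(ds3, 1, "revised comment")
  expect_equal(ds3$points$comment[1], "revised comment")
  expect_equal(ds3$points$value, ds2$points$value)
  # direct edits of protected fields are rejected downstream
  broken <- ds2
  broken$points$value[1] <- 99
  expect_error(lts_fit(broken), "protected",
               class = "certifyr_integrity_error")
  expect_error(add_point(broken, "2024-02-01", 4), "protected",
               class = "certifyr_integrity_error")
})

test_that("LTS regression adjusts the intercept by mu_LTS - mu_c", {
  # symmetric points around mu_c with zero slope
  f <- lts_csv(points = paste("2023-04-01,3.9,", "2023-07-01,4.1,",
                              "2023-10-01,3.9,", "2024-01-01,4.1,", sep = "\n"))
  fit <- lts_fit(read_lts(f))
  expect_equal(fit$mu_lts, 4)
  expect_equal(fit$b0_adj - fit$b0, fit$mu_lts - fit$mu_c)
  expect_equal(fit$b1, 0, tolerance = 0.03)
  # noiseless drift is recovered exactly
  dates <- as.Date("2023-01-01") + c(30, 120, 250, 400)
  m <- months_elapsed(dates, origin = as.Date("2023-01-01"))
  pts <- paste(sprintf("%s,%.10f,", format(dates, "%Y-%m-%d"), 4 + 0.01 * m),
               collapse = "\n")
  fit2 <- lts_fit(read_lts(lts_csv(points = pts)))
  expect_equal(fit2$b1, 0.01, tolerance = 1e-9)
  expect_error(lts_fit(read_lts(lts_csv(points = "2023-04-01,4,\n2023-07-01,4,"))),
               "at least 3", class = "certifyr_validation_error")
})

test_that("shelf life solves the certified-interval crossing", {
  # construct a fit with known adjusted line: b0' = mu_c, b1 = 0.1
  dates <- as.Date("2023-01-01") + round(seq(1, 12) / 12 * 365.25)
  m <- months_elapsed(dates, origin = as.Date("2023-01-01"))
  pts <- paste(sprintf("%s,%.10f,", format(dates, "%Y-%m-%d"), 4 + 0.1 * m),
               collapse = "\n")
  fit <- suppressWarnings(lts_fit(read_lts(lts_csv(points = pts, mu = "4.00",
                                                   value = "1",
                                                   definition = "1s"))))
  # noiseless: b0 = 4 = mu_c + (mu_lts - mu_c) cancels into b0' = b0 + bias
  sl <- lts_shelf_life(fit, U_abs = 1, use_ci = FALSE)
  # solve b0' + 0.1 x = 5
  expect_equal(sl$shelf_life_months, (5 - fit$b0_adj) / 0.1, tolerance = 1e-6)
  # flat noiseless line never leaves the interval
  pts0 <- paste(sprintf("%s,4.0,", format(dates, "%Y-%m-%d")), collapse = "\n")
  fit0 <- suppressWarnings(lts_fit(read_lts(lts_csv(points = pts0, mu = "4.00"))))
  expect_equal(lts_shelf_life(fit0, U_abs = 1)$shelf_life_months, Inf)
  # CI-based estimate is never longer than the point estimate
  fx <- make_fixture(fixture_spec_soil_hg(), seed = 13, dir = tempfile())
  fitn <- lts_fit(read_lts(fx$paths$lts))
  pt <- suppressWarnings(lts_shelf_life(fitn)$shelf_life_months)
  ci <- suppressWarnings(lts_shelf_life(fitn, use_ci = TRUE)$shelf_life_months)
  expect_lte(ci, pt)
  # line already outside at x = 0: zero shelf life with a warning
  far <- paste(sprintf("%s,%.4f,", format(dates, "%Y-%m-%d"), 6 + 0.1 * m),
               collapse = "\n")
  fitf <- suppressWarnings(lts_fit(read_lts(lts_csv(points = far, mu = "4.00",
                                                    value = "0.2",
                                                    definition = "1s"))))
  expect_warning(slf <- lts_shelf_life(fitf, U_abs = 0.4),
                 class = "certifyr_zero_shelf_life")
  expect_equal(slf$shelf_life_months, 0)
})

test_that("shelf life is invariant under a common shift of all dates", {
  base <- as.Date("2023-01-01")
  dates <- base + c(40, 100, 200, 300)
  m <- months_elapsed(dates, origin = base)
  mk <- function(offset_days) {
    d <- dates + offset_days
    pts <- paste(sprintf("%s,%.8f,", format(d, "%Y-%m-%d"), 4 + 0.02 * m),
                 collapse = "\n")
    meta_date <- format(base + offset_days, "%Y-%m-%d")
    f <- write_csv_lines(c(
      "# analyte: Hg", "# unit: mg/kg", "# certified_value: 4.00",
      "# uncertainty_value: 0.17", "# uncertainty_definition: 2s",
      sprintf("# certification_date: %s", meta_date),
      "date,value,comment", strsplit(pts, "\n")[[1]]))
    lts_shelf_life(lts_fit(read_lts(f)))$shelf_life_months
  }
  expect_equal(mk(0), mk(365), tolerance = 1e-9)
})
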