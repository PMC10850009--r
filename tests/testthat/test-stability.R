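test_that("an exact linear series is fit with zero slope uncertainty", {
  tab <- linear_series(5, b0 = 10, b1 = 1)
  res <- suppressWarnings(fit_stability(tab, t_cert = 24))
  expect_equal(res$b1, 1, tolerance = 1e-10)
  expect_equal(res$se_b1, 0, tolerance = 1e-8)
  expect_equal(res$u_stab_abs, 0, tolerance = 1e-7)

  const <- linear_series(5, b0 = 10, b1 = 0)
  res0 <- suppressWarnings(fit_stability(const, t_cert = 24))
  expect_equal(res0$b1, 0, tolerance = 1e-10)
  expect_equal(res0$u_stab_abs, 0, tolerance = 1e-7)
})

test_that("the slope standard error matches the closed form and u_stab scales in t_cert", {
  withr::with_seed(5, {
    dates <- as.Date("2022-01-01") + seq(0, 360, by = 30)
    m <- months_elapsed(dates)
    y <- 10 + 0.05 * m + rnorm(length(m), 0, 0.2)
    tab <- stab_table(dates, y)
    res <- fit_stability(tab, t_cert = 12)
    # closed-form OLS slope SE from residuals
    fit <- lm(y ~ m)
    sigma_hat <- sqrt(sum(residuals(fit)^2) / (length(m) - 2))
    se_closed <- sigma_hat / sqrt(sum((m - mean(m))^2))
    expect_equal(res$se_b1, se_closed, tolerance = 1e-10)
    expect_equal(res$u_stab_abs, abs(12 * res$se_b1))
    res24 <- fit_stability(tab, t_cert = 24)
    expect_equal(res24$u_stab_abs, 2 * res$u_stab_abs) # exact linearity
  })
  expect_error(fit_stability(linear_series(5), t_cert = 0), "positive",
               class = "certifyr_validation_error")
})

test_that("month re-encoding of a calendar grid reproduces the intended axis", {
  d <- as.Date(c("2022-01-01", "2022-01-15", "2022-02-01"))
  m <- months_elapsed(d)
  expect_equal(m[1], 0)
  expect_lt(abs(m[2] - 0.5), 0.05)  # 14 days ~ 0.46 months
  expect_lt(abs(m[3] - 1.0), 0.05)
})

test_that("per-temperature rates recover exact first-order kinetics", {
  ref_dates <- as.Date("2022-01-01")
  t_months <- c(0.5, 1, 2, 4)
  dates <- as.Date("2022-01-01") + round(t_months / 12 * 365.25)
  ref <- stab_table(ref_dates, rep(100, 3), temperature = -80)
  m <- months_elapsed(dates, origin = ref_dates)
  lvl <- stab_table(dates, 100 * exp(-0.01 * m), temperature = 20)
  tab <- dplyr::bind_rows(ref, lvl)
  rates <- suppressWarnings(keff_per_temperature(tab))
  expect_equal(rates$k_eff, 0.01, tolerance = 1e-10)
  expect_true(rates$included)

  # a level identical to the reference shows no degradation and is excluded
  flat <- stab_table(dates, rep(100, length(dates)), temperature = 40)
  rates2 <- suppressWarnings(keff_per_temperature(dplyr::bind_rows(ref, flat)))
  expect_false(rates2$included)
  expect_match(rates2$reason, "no degradation")

  expect_error(keff_per_temperature(
    dplyr::bind_rows(ref, stab_table(dates, c(-1, 1, 1, 1), temperature = 20))),
    "non-positive", class = "certifyr_validation_error")
})

test_that("the Arrhenius slope reproduces a constructed rate doubling", {
  # k doubling every 10 K implies b = -ln 2 / (1/T1 - 1/T2)
  T1 <- 300 - 273.15; T2 <- 310 - 273.15
  rates <- tibble::tibble(temperature = c(T1, T2), k_eff = c(0.01, 0.02),
                          included = TRUE)
  model <- suppressMessages(fit_arrhenius(rates))
  b_expected <- log(2) / (1 / 310 - 1 / 300)
  expect_equal(model$b, b_expected, tolerance = 1e-9)
  expect_true(model$exact)
  # exact two-point line: no prediction band, upper-CI shelf life refused
  expect_error(shelf_life(model, 100, 5, 28), "use_upper_ci")
  sl <- shelf_life(model, 100, 5, 28, use_upper_ci = FALSE)
  expect_gt(sl$months, 0)
  expect_error(fit_arrhenius(dplyr::filter(rates, temperature < 30)),
               "not estimable", class = "certifyr_validation_error")
})

test_that("shelf life follows (U/mu)/k and the CI bound shortens it", {
  fx <- make_fixture(fixture_spec_arrhenius(), seed = 8, dir = tempfile())
  tab <- read_stability(fx$paths$arrhenius)
  model <- fit_arrhenius(keff_per_temperature(tab))
  # arithmetic identity at the point estimate
  sl_pt <- shelf_life(model, mu_c = 100, U_abs = 5, temperature = 25,
                      use_upper_ci = FALSE)
  expect_equal(sl_pt$months, (5 / 100) / sl_pt$k_star)
  sl_ci <- shelf_life(model, mu_c = 100, U_abs = 5, temperature = 25)
  expect_lte(sl_ci$months, sl_pt$months)
  # monotone in temperature along a degrading line
  sl_multi <- shelf_life(model, 100, 5, c(10, 25, 40, 55))
  expect_true(all(diff(sl_multi$months) < 0))
  # no extrapolation outside the studied range
  expect_error(shelf_life(model, 100, 5, 80), "outside",
               class = "certifyr_validation_error")
  expect_error(shelf_life(model, -1, 5, 25), "mu_c",
               class = "certifyr_validation_error")
})

test_that("activation energy is recovered within its confidence interval", {
  # coverage of the fit CI over repeated synthetic studies
  hits <- vapply(1:40, function(seed) {
    fx <- make_fixture(fixture_spec_arrhenius(), seed = seed, dir = tempfile())
    model <- fit_arrhenius(keff_per_temperature(read_stability(fx$paths$arrhenius)))
    ci_b <- confint(model$fit)["inv_T", ]
    ea_ci <- sort(-ci_b * certifyr:::.R_GAS / 1000)
    ea_ci[1] <= 80 && 80 <= ea_ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
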