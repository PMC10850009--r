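# Stability evaluation: classical slope-based stability with the u_stab
# uncertainty contribution, and the accelerated (Arrhenius) analysis that
# turns per-temperature degradation rates into prospective expiry times.

#' Classical stability study: linear drift model
#'
#' Regresses the measured values of one analyte on elapsed months (ordinary
#' least squares).  A slope indistinguishable from zero indicates a stable
#' property; regardless of significance, an uncertainty contribution over the
#' planned lifetime is computed as
#' \deqn{u_{stab} = | t_{cert} \cdot s(b_1) |}
#' with \eqn{s(b_1)} the standard error of the slope and \eqn{t_{cert}} the
#' planned lifetime in months.
#'
#' @param series a stability table (see [read_stability()]) restricted to one
#'   analyte, or any data frame with columns `date` (`Date`) and `value`.
#' @param t_cert planned lifetime in months (> 0).
#' @param analyte optional analyte name to slice from `series`.
#' @return a one-row tibble with `b1`, `se_b1`, `p_slope`, `t_cert`,
#'   `u_stab_abs` and `u_stab_rel` (percent of the series mean).
#' @export
fit_stability <- function(series, t_cert, analyte = NULL) {
  stopifnot(is.data.frame(series))
  if (!is.null(analyte)) series <- filter(series, .data$analyte == !!analyte)
  if (!is.numeric(t_cert) || length(t_cert) != 1 || t_cert <= 0) {
    stop_validation("t_cert must be a positive number of months")
  }
  if (dplyr::n_distinct(series$date) < 3) {
    stop_validation("at least 3 distinct measurement dates are required")
  }
  x <- months_elapsed(series$date)
  fit <- lm(value ~ x, data = data.frame(value = series$value, x = x))
  cf <- summary(fit)$coefficients
  b1 <- unname(cf["x", "Estimate"])
  se_b1 <- unname(cf["x", "Std. Error"])
  p_slope <- unname(cf["x", "Pr(>|t|)"])
  u_abs <- abs(t_cert * se_b1)
  mu <- mean(series$value)
  tibble(
    analyte = if ("analyte" %in% names(series)) series$analyte[1] else NA_character_,
    n = nrow(series), b1 = b1, se_b1 = se_b1, p_slope = p_slope,
    t_cert = t_cert, u_stab_abs = u_abs,
    u_stab_rel = if (mu != 0) u_abs / abs(mu) * 100 else NA_real_
  )
}

#' Per-temperature effective degradation rates
#'
#' For an accelerated stability study, computes a first-order effective
#' reaction rate for every stressed storage temperature: the log-ratio of the
#' measured values to the mean of the reference level (the coldest
#' temperature, at which the material is assumed inert) is regressed on
#' elapsed months, and the rate is the negative slope,
#' \eqn{k_{eff}(T) = -b_1}.  Levels for which no degradation is observed
#' (non-positive rate estimate) or which carry fewer than 2 distinct time
#' points are excluded from the subsequent Arrhenius fit, with the reason
#' recorded.
#'
#' @param table a stability table with a `temperature` column (degrees
#'   Celsius); see [read_stability()].
#' @param analyte optional analyte to slice.
#' @param reference_temperature reference level; defaults to the coldest
#'   temperature present.
#' @return a tibble with one row per temperature level: `temperature`,
#'   `n`, `k_eff` (1/month), `se_k`, `included`, `reason`.
#' @export
keff_per_temperature <- function(table, analyte = NULL,
                                 reference_temperature = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(analyte)) table <- filter(table, .data$analyte == !!analyte)
  if (!"temperature" %in% names(table) || all(is.na(table$temperature))) {
    stop_validation("accelerated analysis requires a temperature column")
  }
  if (any(table$value <= 0)) {
    stop_validation("non-positive measurement values: log-ratio undefined")
  }
  ref_T <- reference_temperature %||% min(table$temperature)
  ref <- filter(table, .data$temperature == ref_T)
  if (nrow(ref) == 0) stop_validation("no measurements at the reference temperature %g", ref_T)
  ref_mean <- mean(ref$value)
  origin <- min(table$date)

  levels <- sort(setdiff(unique(table$temperature), ref_T))
  rows <- lapply(levels, function(T) {
    sl <- filter(table, .data$temperature == T)
    m <- months_elapsed(sl$date, origin = origin)
    if (dplyr::n_distinct(m) < 2) {
      return(tibble(temperature = T, n = nrow(sl), k_eff = NA_real_,
                    se_k = NA_real_, included = FALSE,
                    reason = "fewer than 2 time points"))
    }
    fit <- lm(y ~ m, data = data.frame(y = log(sl$value / ref_mean), m = m))
    cf <- summary(fit)$coefficients
    k <- -unname(cf["m", "Estimate"])
    se <- unname(cf["m", "Std. Error"])
    if (!is.finite(k) || k <= 0) {
      tibble(temperature = T, n = nrow(sl), k_eff = k, se_k = se,
             included = FALSE, reason = "no degradation (rate <= 0)")
    } else {
      tibble(temperature = T, n = nrow(sl), k_eff = k, se_k = se,
             included = TRUE, reason = NA_character_)
    }
  })
  out <- bind_rows(rows)
  attr(out, "reference_temperature") <- ref_T
  attr(out, "reference_mean") <- ref_mean
  out
}

#' Arrhenius model over per-temperature rates
#'
#' Fits the Arrhenius relation by unweighted ordinary least squares of
#' `ln k_eff` on inverse absolute temperature,
#' \deqn{\ln k = a + b \cdot (1/T)},
#' over the included temperature levels.  The activation energy follows from
#' the slope as \eqn{E_a = -b \cdot R}.  With only two included levels the
#' line is exact and no uncertainty band is available (flagged).
#'
#' @param rates a rate table from [keff_per_temperature()] (or a data frame
#'   with columns `temperature` in Celsius, `k_eff`, `included`).
#' @param ci_level confidence level for the prediction band (default 0.95).
#' @return an object of class `arrhenius_model`.
#' @export
fit_arrhenius <- function(rates, ci_level = 0.95) {
  stopifnot(is.data.frame(rates))
  if (!"included" %in% names(rates)) rates$included <- TRUE
  used <- filter(rates, .data$included)
  if (nrow(used) < 2) stop_validation("Arrhenius line not estimable (fewer than 2 included levels)")
  inv_T <- 1 / (used$temperature + 273.15)
  fit <- lm(lnk ~ inv_T, data = data.frame(lnk = log(used$k_eff), inv_T = inv_T))
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  exact <- nrow(used) == 2
  if (exact) {
    inform("only two temperature levels: Arrhenius line is exact, no residual degrees of freedom")
  }
  structure(list(
    fit = fit, a = a, b = b,
    Ea_J_mol = -b * .R_GAS,
    ci_level = ci_level,
    exact = exact,
    rates = rates,
    temperature_range = range(used$temperature)
  ), class = "arrhenius_model")
}

#' @export
print.arrhenius_model <- function(x, ...) {
  cat(sprintf("<arrhenius_model> ln k = %.4g + %.6g * (1/T); Ea = %.4g kJ/mol (%d levels)\n",
              x$a, x$b, x$Ea_J_mol / 1000, sum(x$rates$included)))
  invisible(x)
}

#' @export
tidy.arrhenius_model <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = c("a (intercept)", "b (1/T slope)"),
         estimate = cf[, 1], std.error = cf[, 2])
}

#' @export
glance.arrhenius_model <- function(x, ...) {
  tibble(a = x$a, b = x$b, Ea_kJ_mol = x$Ea_J_mol / 1000,
         n_levels = sum(x$rates$included), exact = x$exact,
         ci_level = x$ci_level)
}

# predicted ln k with prediction bounds at temperature T (Celsius)
arrhenius_predict <- function(model, T_c) {
  nd <- data.frame(inv_T = 1 / (T_c + 273.15))
  if (model$exact) {
    f <- predict(model$fit, newdata = nd)
    cbind(fit = f, lwr = NA_real_, upr = NA_real_)
  } else {
    predict(model$fit, newdata = nd, interval = "prediction",
            level = model$ci_level)
  }
}

#' Prospective shelf life from the Arrhenius model
#'
#' Converts the degradation rate at storage temperature T into the time after
#' which the accumulated degradation exhausts the relative uncertainty budget
#' of the certified value: `months = (U_abs / mu_c) / k*`.  By default the
#' upper bound of the prediction interval of `ln k` at T is used for `k*`,
#' which gives the conservative (shorter) shelf life; `use_upper_ci = FALSE`
#' uses the point estimate.  Temperatures outside the range covered by the
#' included study levels are refused (no extrapolation beyond the layout).
#'
#' @param model an `arrhenius_model`.
#' @param mu_c certified value (> 0).
#' @param U_abs absolute expanded uncertainty (> 0).
#' @param temperature storage temperature(s), degrees Celsius.
#' @param use_upper_ci use the upper prediction bound of ln k (default TRUE).
#' @return a tibble with one row per temperature: `temperature`, `k_star`,
#'   `months`.
#' @export
shelf_life <- function(model, mu_c, U_abs, temperature, use_upper_ci = TRUE) {
  stopifnot(inherits(model, "arrhenius_model"))
  if (!is.numeric(mu_c) || mu_c <= 0) stop_validation("mu_c must be positive")
  if (!is.numeric(U_abs) || U_abs <= 0) stop_validation("U_abs must be positive")
  rng <- model$temperature_range
  bad <- temperature < rng[1] - 1e-9 | temperature > rng[2] + 1e-9
  if (any(bad)) {
    stop_validation("temperature %g degC outside the studied range [%g, %g]; no extrapolation beyond the study layout",
                    temperature[bad][1], rng[1], rng[2])
  }
  pr <- arrhenius_predict(model, temperature)
  if (use_upper_ci && any(is.na(pr[, "upr"]))) {
    stop_validation("no prediction interval available (exact two-point line); use use_upper_ci = FALSE")
  }
  k_star <- exp(if (use_upper_ci) pr[, "upr"] else pr[, "fit"])
  tibble(temperature = temperature, k_star = unname(k_star),
         months = unname((U_abs / mu_c) / k_star),
         used_upper_ci = use_upper_ci)
}

#' Arrhenius plot: ln k against inverse temperature
#'
#' @param object an `arrhenius_model`.
#' @param ... unused.
#' @return a ggplot object with per-level rates (excluded levels hollow),
#'   the fitted line and its prediction band.
#' @export
autoplot.arrhenius_model <- function(object, ...) {
  pts <- object$rates |>
    filter(is.finite(.data$k_eff) & .data$k_eff > 0) |>
    mutate(inv_T = 1 / (.data$temperature + 273.15), lnk = log(.data$k_eff))
  grid_T <- seq(object$temperature_range[1], object$temperature_range[2],
                length.out = 100)
  pr <- arrhenius_predict(object, grid_T)
  band <- tibble(inv_T = 1 / (grid_T + 273.15), fit = pr[, "fit"],
                 lwr = pr[, "lwr"], upr = pr[, "upr"])
  p <- ggplot(pts, aes(x = .data$inv_T, y = .data$lnk))
  if (!object$exact) {
    p <- p + geom_line(data = band, aes(y = .data$lwr), linetype = "dotted",
                       colour = "red") +
      geom_line(data = band, aes(y = .data$upr), linetype = "dotted",
                colour = "red")
  }
  p +
    geom_line(data = band, aes(y = .data$fit), colour = "blue") +
    geom_point(aes(shape = .data$included), size = 3) +
    labs(x = "1 / T (1/K)", y = "ln k_eff",
         title = sprintf("Ea = %.1f kJ/mol", object$Ea_J_mol / 1000)) +
    theme_bw()
}
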