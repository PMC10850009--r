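# Post-certification monitoring: the SK stability criterion on replicate
# control measurements, and long-term stability (LTS) regression of dated
# monitoring values with prospective shelf-life estimation.

new_lts_dataset <- function(meta, points, source_file = NA_character_) {
  obj <- structure(
    list(meta = meta, points = points, source_file = source_file),
    class = "lts_dataset")
  obj$seal <- lts_seal(obj)
  obj
}

# checksum over the immutable fields (dates + values, not comments)
lts_seal <- function(dataset) {
  digest::digest(list(as.numeric(dataset$points$date), dataset$points$value),
                 algo = "sha256")
}

check_lts_seal <- function(dataset) {
  if (!identical(dataset$seal, lts_seal(dataset))) {
    stop_integrity(paste0(
      "LTS data points have been modified outside add_point()/set_comment(); ",
      "dates and values are protected against retrospective modification"))
  }
  invisible(dataset)
}

#' @export
print.lts_dataset <- function(x, ...) {
  cat(sprintf("<lts_dataset> %s [%s], certified %g +/- %g (%s), %d points\n",
              x$meta$analyte, x$meta$unit, x$meta$certified_value,
              x$meta$uncertainty_value, x$meta$uncertainty_definition,
              nrow(x$points)))
  invisible(x)
}

#' Append a monitoring data point
#'
#' Monitoring data are append-only: new points can be added at any time, but
#' the date and value of existing points can never be changed (only their
#' comments, via [set_comment()]).  Attempts to modify the points table by
#' other means are detected through an internal checksum and rejected by all
#' downstream computations.
#'
#' @param dataset an `lts_dataset`.
#' @param date measurement date (`Date` or ISO string).
#' @param value measured value in the certified unit.
#' @param comment optional free-text comment.
#' @return the extended `lts_dataset`.
#' @export
add_point <- function(dataset, date, value, comment = NA_character_) {
  stopifnot(inherits(dataset, "lts_dataset"))
  check_lts_seal(dataset)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    stop_validation("value must be a single finite number")
  }
  date <- if (inherits(date, "Date")) date else parse_iso_date(date)
  dataset$points <- bind_rows(dataset$points,
                              tibble(date = date, value = as.numeric(value),
                                     comment = as.character(comment)))
  dataset$seal <- lts_seal(dataset)
  dataset
}

#' Edit the comment of a monitoring data point
#'
#' @param dataset an `lts_dataset`.
#' @param index row index of the point.
#' @param text new comment text.
#' @return the updated `lts_dataset`; only the comment field changes.
#' @export
set_comment <- function(dataset, index, text) {
  stopifnot(inherits(dataset, "lts_dataset"))
  check_lts_seal(dataset)
  if (!is.numeric(index) || length(index) != 1 || index < 1 ||
      index > nrow(dataset$points)) {
    stop_validation("index out of range")
  }
  dataset$points$comment[index] <- as.character(text)
  dataset
}

#' SK stability criterion for post-certification monitoring
#'
#' Compares the mean of replicate monitoring measurements with the certified
#' value, scaled by the combined uncertainties of both:
#' \deqn{SK = |\mu_c - \mu_m| / \sqrt{u_c^2 + u_m^2}}
#' where \eqn{\mu_m} and \eqn{u_m = s/\sqrt{m}} are the mean and standard
#' uncertainty of the monitoring values and \eqn{u_c = u_{com} \cdot \mu_c}
#' is the absolute combined standard uncertainty of the certified value
#' (without expansion).  The material is considered stable for the parameter
#' when SK is smaller than the expansion factor k used at certification.
#'
#' @param values numeric vector of replicate monitoring measurements (m >= 2).
#' @param mu_c certified value.
#' @param u_com_rel relative combined standard uncertainty in percent (as in
#'   the uncertainty budget).
#' @param k expansion factor (default 2).
#' @param u_m_mode `"mean"` for the standard uncertainty of the mean
#'   (`sd/sqrt(m)`, the default) or `"sd"` for the raw standard deviation.
#' @return a one-row tibble with `mu_m`, `u_m`, `u_c`, `SK`, `k` and `pass`.
#' @export
#' @examples
#' stability_criterion(c(10.9, 11.0, 11.1), mu_c = 10, u_com_rel = 5, k = 2)
stability_criterion <- function(values, mu_c, u_com_rel, k = 2,
                                u_m_mode = c("mean", "sd")) {
  u_m_mode <- match.arg(u_m_mode)
  values <- as.numeric(values)
  if (length(values) < 2) stop_validation("at least 2 monitoring values are required")
  check_finite(values, "values")
  stopifnot(is.numeric(mu_c), is.numeric(u_com_rel), u_com_rel >= 0, k > 0)
  mu_m <- mean(values)
  u_m <- if (u_m_mode == "mean") sd(values) / sqrt(length(values)) else sd(values)
  u_c <- u_com_rel / 100 * mu_c
  denom <- sqrt(u_c^2 + u_m^2)
  if (denom == 0) stop_validation("both u_c and u_m are zero; SK undefined")
  SK <- abs(mu_c - mu_m) / denom
  tibble(m = length(values), mu_m = mu_m, u_m = u_m, u_c = u_c,
         SK = SK, k = k, pass = SK < k)
}

#' Long-term stability regression
#'
#' Fits the linear model `y = b0 + b1 * x` of monitoring values on elapsed
#' months since the certification date.  The intercept is additionally
#' reported adjusted for the offset between the mean of all recorded
#' monitoring data and the certified value, `b0' = b0 + mean(y) - mu_c`, and
#' the adjusted line is the basis of the prospective shelf-life estimate
#' ([lts_shelf_life()]).
#'
#' @param dataset an `lts_dataset` with at least 3 points.
#' @param ci_level confidence level for the regression band (default 0.95).
#' @return an object of class `lts_fit`.
#' @export
lts_fit <- function(dataset, ci_level = 0.95) {
  stopifnot(inherits(dataset, "lts_dataset"))
  check_lts_seal(dataset)
  pts <- dataset$points
  if (nrow(pts) < 3) stop_validation("LTS regression requires at least 3 points")
  x <- months_elapsed(pts$date, origin = dataset$meta$certification_date)
  fit <- lm(value ~ x, data = data.frame(value = pts$value, x = x))
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  mu_lts <- mean(pts$value)
  mu_c <- dataset$meta$certified_value
  structure(list(
    fit = fit, b0 = b0, b1 = b1,
    se_b1 = summary(fit)$coefficients["x", "Std. Error"],
    mu_lts = mu_lts, mu_c = mu_c,
    b0_adj = b0 + mu_lts - mu_c,
    ci_level = ci_level,
    months = x, values = pts$value, dataset = dataset
  ), class = "lts_fit")
}

#' @export
print.lts_fit <- function(x, ...) {
  cat(sprintf("<lts_fit> b0 = %.6g, b1 = %.6g /month, b0' = %.6g (mu_LTS = %.6g, mu_c = %.6g)\n",
              x$b0, x$b1, x$b0_adj, x$mu_lts, x$mu_c))
  invisible(x)
}

#' @export
tidy.lts_fit <- function(x, ...) {
  tibble(term = c("b0", "b1", "b0_adj"),
         estimate = c(x$b0, x$b1, x$b0_adj),
         std.error = c(summary(x$fit)$coefficients[1, 2], x$se_b1, NA_real_))
}

#' @export
glance.lts_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = length(x$values), r.squared = s$r.squared, sigma = s$sigma,
         mu_lts = x$mu_lts, mu_c = x$mu_c, b0_adj = x$b0_adj)
}

# adjusted mean line and CI half-width at months m
lts_band <- function(fitobj, m) {
  pr <- predict(fitobj$fit, newdata = data.frame(x = m),
                interval = "confidence", level = fitobj$ci_level)
  shift <- fitobj$b0_adj - fitobj$b0
  list(mid = pr[, "fit"] + shift, half = pr[, "fit"] - pr[, "lwr"])
}

#' Prospective shelf life from LTS monitoring
#'
#' Estimates the time, in months since certification, at which the adjusted
#' regression line (or, optionally, its confidence band) leaves the certified
#' interval `mu_c +/- U_abs`.  With `use_ci = FALSE` the crossing of the
#' point line is solved analytically; with `use_ci = TRUE` the earliest
#' non-negative month at which either band edge leaves the interval is found
#' by bracketing and bisection (to 1e-6 month).  A flat line whose band never
#' leaves the interval yields `Inf` (unbounded within the search horizon).
#'
#' @param fit an `lts_fit`.
#' @param U_abs absolute expanded uncertainty bounding the certified interval.
#' @param use_ci use the confidence band of the regression line for a more
#'   conservative estimate (default `FALSE`).
#' @param horizon_months search horizon for the band crossing (default 1200).
#' @return a one-row tibble with `shelf_life_months` (possibly `Inf`),
#'   `used_ci` and the line parameters.
#' @export
lts_shelf_life <- function(fit, U_abs = NULL, use_ci = FALSE,
                           horizon_months = 1200) {
  stopifnot(inherits(fit, "lts_fit"))
  U_abs <- U_abs %||% (2 * fit$dataset$meta$u_abs_1s)
  if (!is.numeric(U_abs) || U_abs <= 0) stop_validation("U_abs must be positive")
  mu_c <- fit$mu_c
  lower <- mu_c - U_abs
  upper <- mu_c + U_abs
  outside <- function(m) {
    if (use_ci) {
      b <- lts_band(fit, m)
      (b$mid + b$half) > upper || (b$mid - b$half) < lower
    } else {
      y <- fit$b0_adj + fit$b1 * m
      y > upper || y < lower
    }
  }
  if (outside(0)) {
    warn("monitoring line is outside the certified interval at month 0",
         class = "certifyr_zero_shelf_life")
    months <- 0
  } else if (!use_ci) {
    months <- if (fit$b1 == 0) Inf
      else if (fit$b1 > 0) (upper - fit$b0_adj) / fit$b1
      else (lower - fit$b0_adj) / fit$b1
    # a numerically flat line whose crossing lies beyond the search horizon
    # is reported as unbounded
    if (months > horizon_months) months <- Inf
  } else {
    # bracket the first crossing on a monthly grid, then bisect
    grid <- seq(0, horizon_months, by = 1)
    out <- vapply(grid, outside, logical(1))
    if (!any(out)) {
      months <- Inf
    } else {
      hi <- grid[which(out)[1]]
      lo <- if (hi == 0) 0 else hi - 1
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        if (outside(mid)) hi <- mid else lo <- mid
      }
      months <- hi
    }
  }
  tibble(shelf_life_months = months, used_ci = use_ci,
         mu_c = mu_c, U_abs = U_abs, b0_adj = fit$b0_adj, b1 = fit$b1)
}

#' Plot LTS monitoring data with regression line and certified limits
#'
#' @param object an `lts_fit`.
#' @param use_ci display the confidence band (default `TRUE`).
#' @param ... unused.
#' @return a ggplot object: monitoring points (comment-flagged points
#'   highlighted), adjusted regression line, certified value and +/- 2s
#'   lines, and the confidence band.
#' @export
autoplot.lts_fit <- function(object, use_ci = TRUE, ...) {
  pts <- tibble(months = object$months, value = object$values,
                has_comment = !is.na(object$dataset$points$comment))
  grid <- seq(min(0, pts$months), max(pts$months) * 1.1 + 1, length.out = 100)
  band <- lts_band(object, grid)
  line_df <- tibble(months = grid, fit = band$mid,
                    lwr = band$mid - band$half, upr = band$mid + band$half)
  mu_c <- object$mu_c
  s1 <- object$dataset$meta$u_abs_1s
  p <- ggplot(pts, aes(x = .data$months, y = .data$value))
  if (use_ci) {
    p <- p + geom_ribbon(data = line_df,
                         aes(x = .data$months, ymin = .data$lwr, ymax = .data$upr),
                         inherit.aes = FALSE, alpha = 0.2)
  }
  p +
    geom_line(data = line_df, aes(x = .data$months, y = .data$fit),
              inherit.aes = FALSE, colour = "blue") +
    geom_hline(yintercept = mu_c, colour = "red") +
    geom_hline(yintercept = mu_c + c(-2, 2) * s1, colour = "darkgreen",
               linetype = "dashed") +
    geom_point(aes(colour = .data$has_comment)) +
    labs(x = "months since certification",
         y = if (is.na(object$dataset$meta$unit)) "value"
             else object$dataset$meta$unit,
         colour = "comment") +
    theme_bw()
}
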