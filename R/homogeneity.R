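# Homogeneity evaluation of the nested design (N bottles x n replicates) by
# one-way ANOVA, yielding the between-bottle relative standard deviation
# s_bb and, when between-bottle variation is masked by within-bottle
# repeatability, the maximal maskable variation s_bb,min.

#' Evaluate a homogeneity study by one-way ANOVA
#'
#' Computes the mean squares between and within bottles, the between-bottle
#' standard deviation
#' \deqn{s_{bb} = \sqrt{(M_{between} - M_{within}) / n_0}}
#' and the maximal between-bottle variation maskable by repeatability
#' \deqn{s_{bb,min} = \sqrt{M_{within} / n_0} \cdot (2 / df_{within})^{1/4}.}
#' When `M_within >= M_between` the between-bottle effect is masked and
#' `s_bb` is set to 0.  For unbalanced designs the effective replicate count
#' \eqn{n_0 = (N_{tot} - \sum n_i^2 / N_{tot}) / (N - 1)} is used, which
#' reduces to n when all bottles have n replicates.  Both dispersion measures
#' are reported relative to the grand mean, in percent.
#'
#' @param table a homogeneity table as returned by [read_homogeneity()] (or
#'   any data frame with columns `analyte`, `bottle`, `value`).
#' @param analyte analyte name to evaluate; may be omitted when the table
#'   contains a single analyte.
#' @return an object of class `homogeneity_result`; see [tidy()] for the
#'   tabular summary.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   analyte = "Hg", bottle = rep(c("B1", "B2", "B3"), each = 2),
#'   value = c(10, 10, 12, 12, 14, 14))
#' tidy(evaluate_homogeneity(tab))
evaluate_homogeneity <- function(table, analyte = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(analyte)) {
    analytes <- unique(table$analyte)
    if (length(analytes) != 1) {
      stop_validation("table contains %d analytes; specify `analyte`", length(analytes))
    }
    analyte <- analytes
  }
  df <- filter(table, .data$analyte == !!analyte)
  if (nrow(df) == 0) stop_validation("no data for analyte '%s'", analyte)
  check_finite(df$value, "value")

  groups <- split(df$value, df$bottle)
  N <- length(groups)
  if (N < 2) stop_validation("at least 2 bottles are required")
  n_i <- lengths(groups)
  N_tot <- sum(n_i)
  df_within <- N_tot - N
  if (df_within < 1) stop_validation("no within-bottle degrees of freedom (need replicate measurements)")
  grand_mean <- mean(df$value)
  if (grand_mean == 0) stop_validation("grand mean is zero; relative dispersion undefined")

  means_i <- vapply(groups, mean, 0)
  ss_between <- sum(n_i * (means_i - grand_mean)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  M_between <- ss_between / (N - 1)
  M_within <- ss_within / df_within
  n0 <- (N_tot - sum(n_i^2) / N_tot) / (N - 1)

  masked <- M_within >= M_between
  s_bb <- if (masked) 0 else sqrt((M_between - M_within) / n0)
  s_bb_min <- sqrt(M_within / n0) * (2 / df_within)^0.25
  F_stat <- if (M_within > 0) M_between / M_within else NA_real_
  p_value <- if (is.na(F_stat)) NA_real_ else pf(F_stat, N - 1, df_within, lower.tail = FALSE)

  structure(list(
    analyte = analyte,
    unit = if ("unit" %in% names(df)) df$unit[1] else NA_character_,
    N = N, n0 = n0, n_total = N_tot,
    grand_mean = grand_mean,
    M_between = M_between, M_within = M_within,
    df_between = N - 1, df_within = df_within,
    F_stat = F_stat, p_value = p_value,
    s_bb_abs = s_bb, s_bb_min_abs = s_bb_min,
    s_bb_rel = s_bb / abs(grand_mean) * 100,
    s_bb_min_rel = s_bb_min / abs(grand_mean) * 100,
    masked = masked,
    data = select(df, all_of(intersect(c("analyte", "bottle", "replicate", "value"),
                                       names(df))))
  ), class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("<homogeneity_result> %s: N = %d bottles, n0 = %.3g\n",
              x$analyte, x$N, x$n0))
  cat(sprintf("  grand mean = %.6g, M_between = %.4g, M_within = %.4g (F = %.3g, p = %.3g)\n",
              x$grand_mean, x$M_between, x$M_within, x$F_stat, x$p_value))
  cat(sprintf("  s_bb = %.3g%%%s, s_bb,min = %.3g%%\n", x$s_bb_rel,
              if (x$masked) " (masked)" else "", x$s_bb_min_rel))
  invisible(x)
}

#' @export
tidy.homogeneity_result <- function(x, ...) {
  tibble(analyte = x$analyte, N = x$N, n0 = x$n0,
         grand_mean = x$grand_mean,
         M_between = x$M_between, M_within = x$M_within,
         df_between = x$df_between, df_within = x$df_within,
         F_stat = x$F_stat, p_value = x$p_value,
         s_bb_rel = x$s_bb_rel, s_bb_min_rel = x$s_bb_min_rel,
         masked = x$masked)
}

#' @export
glance.homogeneity_result <- function(x, ...) tidy(x)

#' Between-bottle uncertainty contribution
#'
#' The contribution transferred to the uncertainty budget is the greater of
#' `s_bb` and `s_bb,min` (in relative percent): when the between-bottle
#' effect is masked by repeatability, the maximal maskable variation is used
#' as a conservative bound.
#'
#' @param result a `homogeneity_result`.
#' @return a named numeric of length 1 (term `u_bb`), in percent.
#' @export
u_bb <- function(result) {
  stopifnot(inherits(result, "homogeneity_result"))
  c(u_bb = max(result$s_bb_rel, result$s_bb_min_rel))
}

#' Box plot of the homogeneity study per bottle
#'
#' @param object a `homogeneity_result`.
#' @param ... unused.
#' @return a ggplot object with per-bottle boxes and the grand mean line.
#' @export
autoplot.homogeneity_result <- function(object, ...) {
  ggplot(object$data, aes(x = .data$bottle, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_point() +
    geom_hline(yintercept = object$grand_mean, colour = "red",
               linetype = "dashed") +
    labs(x = "bottle", y = object$unit %||% "value",
         title = sprintf("%s: s_bb = %.2f%%, s_bb,min = %.2f%%%s",
                         object$analyte, object$s_bb_rel, object$s_bb_min_rel,
                         if (object$masked) " (masked)" else "")) +
    theme_bw()
}
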