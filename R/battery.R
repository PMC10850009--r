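# Certification study evaluation: per-laboratory summaries and the battery
# of normality, variance-homogeneity, compatibility and outlier tests with
# straggler (5%) / outlier (1%) verdicts.  Tests only report; excluding a
# laboratory is always an explicit user decision, and excluded laboratories
# keep their data (they are merely flagged, never deleted).

verdict_from_p <- function(p, alpha_straggler, alpha_outlier) {
  if (is.na(p)) return(NA_character_)
  if (p < alpha_outlier) "outlier"
  else if (p < alpha_straggler) "straggler"
  else "none"
}

verdict_from_crit <- function(stat, crit05, crit01, reject_low = FALSE) {
  if (is.na(stat)) return(NA_character_)
  sig05 <- if (reject_low) stat < crit05 else stat > crit05
  sig01 <- if (reject_low) stat < crit01 else stat > crit01
  if (sig01) "outlier" else if (sig05) "straggler" else "none"
}

normalize_exclusions <- function(exclusions, analyte = NA_character_) {
  if (is.null(exclusions) || length(exclusions) == 0) {
    return(tibble(lab_id = character(), analyte = character(),
                  reason = character(), test = character(), order = integer()))
  }
  if (is.character(exclusions)) {
    return(tibble(lab_id = exclusions, analyte = analyte,
                  reason = NA_character_, test = NA_character_,
                  order = seq_along(exclusions)))
  }
  stopifnot(is.data.frame(exclusions), "lab_id" %in% names(exclusions))
  out <- as_tibble(exclusions)
  if (!"analyte" %in% names(out)) out$analyte <- analyte
  if (!"reason" %in% names(out)) out$reason <- NA_character_
  if (!"test" %in% names(out)) out$test <- NA_character_
  out$order <- seq_len(nrow(out))
  out
}

#' Per-laboratory summary statistics
#'
#' Means and standard deviations of the replicate values of each laboratory,
#' sorted by mean (stable sort).  Excluded laboratories are flagged with
#' their exclusion order and reason but keep their data.
#'
#' @param table a certification table (see [read_certification()]).
#' @param analyte analyte to evaluate; may be omitted for single-analyte
#'   tables.
#' @param exclusions character vector of lab ids in exclusion order, or a
#'   data frame with columns `lab_id` and optionally `analyte`, `reason`,
#'   `test`.
#' @return a tibble with `lab_id`, `n`, `mean`, `sd`, `excluded`,
#'   `exclusion_order`, `exclusion_reason`.
#' @export
lab_summaries <- function(table, analyte = NULL, exclusions = NULL) {
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
  excl <- normalize_exclusions(exclusions, analyte)
  excl <- filter(excl, is.na(.data$analyte) | .data$analyte == !!analyte)
  out <- df |>
    group_by(.data$lab_id) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
              .groups = "drop") |>
    mutate(
      excluded = .data$lab_id %in% excl$lab_id,
      exclusion_order = match(.data$lab_id, excl$lab_id),
      exclusion_reason = excl$reason[match(.data$lab_id, excl$lab_id)]
    ) |>
    arrange(.data$mean)
  out
}

#' Single Grubbs test on laboratory means
#'
#' Tests the most extreme laboratory mean (either end) with the statistic
#' `G = max |m_i - mean(m)| / sd(m)` against the exact two-sided critical
#' value ([grubbs_crit()]).
#'
#' @param means named numeric vector of laboratory means (>= 3).
#' @param alpha_straggler,alpha_outlier significance levels for the
#'   straggler (5%) and outlier (1%) verdicts.
#' @return a one-row tibble with `test`, `statistic`, `lab`, `p_value`,
#'   `critical_05`, `critical_01`, `verdict`.
#' @export
grubbs_single <- function(means, alpha_straggler = 0.05, alpha_outlier = 0.01) {
  N <- length(means)
  if (N < 3) stop_validation("Grubbs test requires at least 3 laboratories")
  s <- sd(means)
  c05 <- grubbs_crit(N, alpha_straggler)
  c01 <- grubbs_crit(N, alpha_outlier)
  if (is.na(s) || s == 0) {
    warn("all laboratory means identical: Grubbs statistic undefined")
    return(tibble(test = "Grubbs (single)", statistic = NA_real_,
                  lab = NA_character_, p_value = NA_real_,
                  critical_05 = c05, critical_01 = c01, verdict = "none"))
  }
  dev <- abs(means - mean(means)) / s
  i <- which.max(dev)
  G <- dev[i]
  # invert the closed form to a Bonferroni-style p-value
  denom <- (N - 1)^2 - G^2 * N
  p <- if (denom <= 0) 0 else {
    t_g <- sqrt(G^2 * N * (N - 2) / denom)
    min(1, 2 * N * pt(t_g, df = N - 2, lower.tail = FALSE))
  }
  tibble(test = "Grubbs (single)", statistic = unname(G),
         lab = names(means)[i] %||% as.character(i), p_value = p,
         critical_05 = c05, critical_01 = c01,
         verdict = verdict_from_crit(G, c05, c01))
}

#' Double Grubbs test on laboratory means
#'
#' Tests the two highest and the two lowest laboratory means as a pair with
#' the SS-ratio statistic (residual sum of squares after removing the pair
#' over total sum of squares; small values are significant), against the
#' tabulated critical values of [grubbs_double_crit()].
#'
#' @inheritParams grubbs_single
#' @return a one-row tibble as in [grubbs_single()]; `lab` names the
#'   implicated pair.
#' @export
grubbs_double <- function(means, alpha_straggler = 0.05, alpha_outlier = 0.01) {
  N <- length(means)
  if (N < 4) stop_validation("double Grubbs test requires at least 4 laboratories")
  if (is.null(names(means))) names(means) <- as.character(seq_len(N))
  c05 <- grubbs_double_crit(N, alpha_straggler)
  c01 <- grubbs_double_crit(N, alpha_outlier)
  if (sd(means) == 0) {
    warn("all laboratory means identical: double Grubbs statistic undefined")
    return(tibble(test = "Grubbs (double)", statistic = NA_real_,
                  lab = NA_character_, p_value = NA_real_,
                  critical_05 = c05, critical_01 = c01, verdict = "none"))
  }
  ord <- order(means)
  xs <- means[ord]
  stat_high <- grubbs_double_stat(xs, N)                 # two largest
  stat_low <- grubbs_double_stat(rev(-xs), N)            # two smallest
  if (stat_high <= stat_low) {
    stat <- stat_high
    pair <- names(xs)[c(N - 1, N)]
  } else {
    stat <- stat_low
    pair <- names(xs)[c(1, 2)]
  }
  tibble(test = "Grubbs (double)", statistic = stat,
         lab = paste(pair, collapse = ","), p_value = NA_real_,
         critical_05 = c05, critical_01 = c01,
         verdict = verdict_from_crit(stat, c05, c01, reject_low = TRUE))
}

dixon_ratios <- function(xs, N) {
  v <- dixon_variant(N)
  lo <- switch(v,
    r10 = (xs[2] - xs[1]) / (xs[N] - xs[1]),
    r11 = (xs[2] - xs[1]) / (xs[N - 1] - xs[1]),
    r21 = (xs[3] - xs[1]) / (xs[N - 1] - xs[1]),
    r22 = (xs[3] - xs[1]) / (xs[N - 2] - xs[1]))
  hi <- switch(v,
    r10 = (xs[N] - xs[N - 1]) / (xs[N] - xs[1]),
    r11 = (xs[N] - xs[N - 1]) / (xs[N] - xs[2]),
    r21 = (xs[N] - xs[N - 2]) / (xs[N] - xs[2]),
    r22 = (xs[N] - xs[N - 2]) / (xs[N] - xs[3]))
  c(low = unname(lo), high = unname(hi))
}

#' Dixon ratio test on laboratory means
#'
#' Computes the Dixon ratio at both ends of the sorted laboratory means,
#' with the ratio variant selected by sample size (r10 for N = 3-7, r11 for
#' 8-10, r21 for 11-13, r22 for N >= 14), and compares the larger ratio with
#' the two-sided critical value ([dixon_crit()]).  Supported for
#' 3 <= N <= 30 (the tabulated range).
#'
#' @inheritParams grubbs_single
#' @return a one-row tibble as in [grubbs_single()].
#' @export
dixon <- function(means, alpha_straggler = 0.05, alpha_outlier = 0.01) {
  N <- length(means)
  dixon_variant(N) # errors outside 3..30
  if (is.null(names(means))) names(means) <- as.character(seq_len(N))
  c05 <- dixon_crit(N, alpha_straggler)
  c01 <- dixon_crit(N, alpha_outlier)
  xs <- sort(means)
  if (xs[N] == xs[1]) {
    warn("all laboratory means identical: Dixon ratio undefined")
    return(tibble(test = sprintf("Dixon (%s)", dixon_variant(N)),
                  statistic = NA_real_, lab = NA_character_,
                  p_value = NA_real_, critical_05 = c05, critical_01 = c01,
                  verdict = "none"))
  }
  r <- dixon_ratios(xs, N)
  if (r["high"] >= r["low"]) {
    stat <- unname(r["high"]); lab <- names(xs)[N]
  } else {
    stat <- unname(r["low"]); lab <- names(xs)[1]
  }
  tibble(test = sprintf("Dixon (%s)", dixon_variant(N)), statistic = stat,
         lab = lab, p_value = NA_real_, critical_05 = c05, critical_01 = c01,
         verdict = verdict_from_crit(stat, c05, c01))
}

#' Cochran test for an outlying laboratory variance
#'
#' Tests the largest within-laboratory variance with
#' `C = s_max^2 / sum(s_i^2)` against the exact closed-form critical value
#' ([cochran_crit()]), which is valid for any number of laboratories.  With
#' unbalanced replicate counts the minimum replicate degrees of freedom is
#' used (conservative) and a warning is raised.
#'
#' @param sds named numeric vector of per-laboratory standard deviations.
#' @param n_reps integer vector of replicate counts per laboratory (same
#'   order), or a single common count.
#' @inheritParams grubbs_single
#' @return a one-row tibble as in [grubbs_single()].
#' @export
cochran <- function(sds, n_reps, alpha_straggler = 0.05, alpha_outlier = 0.01) {
  sds <- sds[!is.na(sds)]
  N <- length(sds)
  if (N < 2) stop_validation("Cochran test requires at least 2 laboratories with estimable sd")
  if (is.null(names(sds))) names(sds) <- as.character(seq_len(N))
  if (length(n_reps) == 1) n_reps <- rep(n_reps, N)
  if (any(n_reps < 2)) stop_validation("Cochran test requires at least 2 replicates per laboratory")
  nu <- min(n_reps) - 1
  if (length(unique(n_reps)) > 1) {
    warn(sprintf("unbalanced replicate counts: using minimum df nu = %d (conservative)", nu),
         class = "certifyr_unbalanced_cochran")
  }
  c05 <- cochran_crit(N, nu, alpha_straggler)
  c01 <- cochran_crit(N, nu, alpha_outlier)
  if (all(sds == 0)) {
    warn("all laboratory standard deviations are zero: Cochran statistic undefined")
    return(tibble(test = "Cochran", statistic = NA_real_, lab = NA_character_,
                  p_value = NA_real_, critical_05 = c05, critical_01 = c01,
                  verdict = "none"))
  }
  C <- max(sds^2) / sum(sds^2)
  i <- which.max(sds^2)
  # Bonferroni-style p-value by inverting the closed form
  Fobs <- (N - 1) * C / (1 - C)
  p <- if (C >= 1) 0 else {
    min(1, N * pf(Fobs, df1 = nu, df2 = (N - 1) * nu, lower.tail = FALSE))
  }
  tibble(test = "Cochran", statistic = C, lab = names(sds)[i], p_value = p,
         critical_05 = c05, critical_01 = c01,
         verdict = verdict_from_crit(C, c05, c01))
}

#' Bartlett test of variance homogeneity across laboratories
#'
#' @param table a certification table slice for one analyte (columns
#'   `lab_id`, `value`), included laboratories only.
#' @inheritParams grubbs_single
#' @return a one-row tibble as in [grubbs_single()].
#' @export
bartlett_labs <- function(table, alpha_straggler = 0.05, alpha_outlier = 0.01) {
  groups <- split(table$value, table$lab_id)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2) stop_validation("Bartlett test requires >= 2 laboratories with >= 2 replicates")
  if (any(vapply(groups, sd, 0) == 0)) {
    warn("a laboratory has zero variance: Bartlett statistic undefined")
    return(tibble(test = "Bartlett", statistic = NA_real_, lab = NA_character_,
                  p_value = NA_real_, critical_05 = NA_real_,
                  critical_01 = NA_real_, verdict = "none"))
  }
  bt <- stats::bartlett.test(groups)
  k <- length(groups)
  tibble(test = "Bartlett", statistic = unname(bt$statistic),
         lab = NA_character_, p_value = unname(bt$p.value),
         critical_05 = stats::qchisq(1 - alpha_straggler, k - 1),
         critical_01 = stats::qchisq(1 - alpha_outlier, k - 1),
         verdict = verdict_from_p(bt$p.value, alpha_straggler, alpha_outlier))
}

#' Scheffé pairwise compatibility of laboratory means
#'
#' Tests every pair of laboratory means against the Scheffé simultaneous
#' bound \eqn{\sqrt{(N-1) F_{1-\alpha}(N-1, df_w)} \cdot s_p
#' \sqrt{1/n_i + 1/n_j}} with the pooled within-laboratory standard
#' deviation \eqn{s_p}.  A pair whose mean difference exceeds the bound is
#' incompatible at that level.
#'
#' @param table a certification table slice for one analyte, included
#'   laboratories only.
#' @inheritParams grubbs_single
#' @return a tibble with one row per unordered pair: `lab_i`, `lab_j`,
#'   `diff`, `bound_05`, `bound_01`, `incompatible_05`, `incompatible_01`.
#' @export
scheffe <- function(table, alpha_straggler = 0.05, alpha_outlier = 0.01) {
  groups <- split(table$value, table$lab_id)
  N <- length(groups)
  if (N < 3) stop_validation("Scheffe test requires at least 3 laboratories")
  n_i <- lengths(groups)
  df_w <- sum(n_i - 1)
  if (df_w == 0) stop_validation("no within-laboratory degrees of freedom")
  means <- vapply(groups, mean, 0)
  s2_pool <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df_w
  f05 <- qf(1 - alpha_straggler, N - 1, df_w)
  f01 <- qf(1 - alpha_outlier, N - 1, df_w)
  pairs <- utils::combn(names(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(s2_pool * (1 / n_i[[i]] + 1 / n_i[[j]]))
    d <- abs(means[[i]] - means[[j]])
    tibble(lab_i = i, lab_j = j, diff = d,
           bound_05 = sqrt((N - 1) * f05) * se,
           bound_01 = sqrt((N - 1) * f01) * se) |>
      mutate(incompatible_05 = .data$diff > .data$bound_05,
             incompatible_01 = .data$diff > .data$bound_01)
  })
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^4) / m2^2 - 3
}

#' Normality screening of laboratory means
#'
#' Runs a Lilliefors-corrected Kolmogorov-Smirnov test plus standardized
#' skewness and excess-kurtosis tests (moment statistics divided by their
#' null standard errors, referred to the standard normal) on the laboratory
#' means.
#'
#' @param means numeric vector of laboratory means.
#' @inheritParams grubbs_single
#' @return a tibble with one row per test (`KS (Lilliefors)`, `Skewness`,
#'   `Kurtosis`).
#' @export
normality_suite <- function(means, alpha_straggler = 0.05, alpha_outlier = 0.01) {
  N <- length(means)
  if (N < 3) stop_validation("normality screening requires at least 3 laboratory means")
  rows <- list()
  if (sd(means) == 0) {
    warn("degenerate spread: normality statistics undefined")
    return(tibble(test = c("KS (Lilliefors)", "Skewness", "Kurtosis"),
                  statistic = NA_real_, lab = NA_character_,
                  p_value = NA_real_, critical_05 = NA_real_,
                  critical_01 = NA_real_, verdict = "none"))
  }
  ks <- if (N >= 4) {
    lt <- nortest::lillie.test(means)
    tibble(test = "KS (Lilliefors)", statistic = unname(lt$statistic),
           lab = NA_character_, p_value = unname(lt$p.value),
           critical_05 = NA_real_, critical_01 = NA_real_,
           verdict = verdict_from_p(lt$p.value, alpha_straggler, alpha_outlier))
  } else {
    tibble(test = "KS (Lilliefors)", statistic = NA_real_,
           lab = NA_character_, p_value = NA_real_, critical_05 = NA_real_,
           critical_01 = NA_real_, verdict = NA_character_)
  }
  g1 <- sample_skewness(means)
  se_g1 <- sqrt(6 * N * (N - 1) / ((N - 2) * (N + 1) * (N + 3)))
  p_g1 <- 2 * pnorm(-abs(g1 / se_g1))
  sk <- tibble(test = "Skewness", statistic = g1, lab = NA_character_,
               p_value = p_g1,
               critical_05 = qnorm(1 - alpha_straggler / 2) * se_g1,
               critical_01 = qnorm(1 - alpha_outlier / 2) * se_g1,
               verdict = verdict_from_p(p_g1, alpha_straggler, alpha_outlier))
  ku <- if (N >= 4) {
    g2 <- sample_excess_kurtosis(means)
    se_g2 <- sqrt(24 * N * (N - 1)^2 /
                    ((N - 3) * (N - 2) * (N + 3) * (N + 5)))
    p_g2 <- 2 * pnorm(-abs(g2 / se_g2))
    tibble(test = "Kurtosis", statistic = g2, lab = NA_character_,
           p_value = p_g2,
           critical_05 = qnorm(1 - alpha_straggler / 2) * se_g2,
           critical_01 = qnorm(1 - alpha_outlier / 2) * se_g2,
           verdict = verdict_from_p(p_g2, alpha_straggler, alpha_outlier))
  } else {
    tibble(test = "Kurtosis", statistic = NA_real_, lab = NA_character_,
           p_value = NA_real_, critical_05 = NA_real_, critical_01 = NA_real_,
           verdict = NA_character_)
  }
  bind_rows(ks, sk, ku)
}

#' Quantile-quantile points of laboratory means
#'
#' @param means numeric vector of laboratory means.
#' @return a tibble of `(theoretical, sample)` normal-score pairs for
#'   external plotting.
#' @export
qq_points <- function(means) {
  n <- length(means)
  tibble(theoretical = stats::qnorm(stats::ppoints(n)),
         sample = sort(means))
}

#' Run the full certification test battery
#'
#' Computes laboratory summaries on the included subset and all tests of the
#' battery: normality screening of lab means (Lilliefors KS, skewness,
#' kurtosis), Bartlett variance homogeneity, Scheffé pairwise compatibility,
#' single and double Grubbs and Dixon tests on lab means, and the Cochran
#' variance-outlier test.  Verdicts are straggler (significant at the 5% but
#' not the 1% level) or outlier (significant at 1%).  The battery never
#' excludes a laboratory by itself; pass the user's decision via
#' `exclusions` and re-run.
#'
#' @inheritParams lab_summaries
#' @inheritParams grubbs_single
#' @return an object of class `certification_battery`; `tidy()` returns the
#'   test table, `$summaries` the laboratory summaries, `$scheffe` the
#'   pairwise compatibility table.
#' @export
evaluate_battery <- function(table, analyte = NULL, exclusions = NULL,
                             alpha_straggler = 0.05, alpha_outlier = 0.01) {
  stopifnot(alpha_straggler > alpha_outlier, alpha_outlier > 0,
            alpha_straggler < 1)
  if (is.null(analyte)) {
    analytes <- unique(table$analyte)
    if (length(analytes) != 1) {
      stop_validation("table contains %d analytes; specify `analyte`", length(analytes))
    }
    analyte <- analytes
  }
  summaries <- lab_summaries(table, analyte, exclusions)
  included <- filter(summaries, !.data$excluded)
  if (nrow(included) < 3) {
    stop_validation("test battery requires at least 3 included laboratories (have %d)",
                    nrow(included))
  }
  slice <- table |>
    filter(.data$analyte == !!analyte, .data$lab_id %in% included$lab_id)
  means <- setNames(included$mean, included$lab_id)
  sds <- setNames(included$sd, included$lab_id)

  tests <- bind_rows(
    normality_suite(means, alpha_straggler, alpha_outlier),
    bartlett_labs(slice, alpha_straggler, alpha_outlier),
    grubbs_single(means, alpha_straggler, alpha_outlier),
    if (length(means) >= 4) grubbs_double(means, alpha_straggler, alpha_outlier),
    if (length(means) <= 30) dixon(means, alpha_straggler, alpha_outlier),
    cochran(sds, included$n, alpha_straggler, alpha_outlier)
  )
  sch <- scheffe(slice, alpha_straggler, alpha_outlier)
  structure(list(
    analyte = analyte,
    summaries = summaries,
    tests = tests,
    scheffe = sch,
    exclusions = normalize_exclusions(exclusions, analyte),
    alpha_straggler = alpha_straggler,
    alpha_outlier = alpha_outlier
  ), class = "certification_battery")
}

#' @export
print.certification_battery <- function(x, ...) {
  cat(sprintf("<certification_battery> %s: %d labs (%d excluded)\n", x$analyte,
              nrow(x$summaries), sum(x$summaries$excluded)))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.certification_battery <- function(x, ...) x$tests

#' @export
glance.certification_battery <- function(x, ...) {
  inc <- filter(x$summaries, !.data$excluded)
  tibble(analyte = x$analyte, p = nrow(inc),
         n_excluded = sum(x$summaries$excluded),
         n_outlier_verdicts = sum(x$tests$verdict == "outlier", na.rm = TRUE),
         n_straggler_verdicts = sum(x$tests$verdict == "straggler", na.rm = TRUE))
}

#' Display the battery table in a chosen mode
#'
#' @param battery a `certification_battery`.
#' @param mode one of `"statistic"`, `"p-value"`, `"critical value"`,
#'   `"significance level"`.
#' @return a tibble with `test`, `lab` and the requested display column.
#' @export
battery_display <- function(battery,
                            mode = c("statistic", "p-value", "critical value",
                                     "significance level")) {
  mode <- match.arg(mode)
  t <- battery$tests
  switch(mode,
    "statistic" = select(t, "test", "lab", "statistic"),
    "p-value" = select(t, "test", "lab", "p_value"),
    "critical value" = select(t, "test", "lab", "critical_05", "critical_01"),
    "significance level" = t |>
      mutate(significance = dplyr::case_when(
        .data$verdict == "outlier" ~ ".01",
        .data$verdict == "straggler" ~ ".05",
        .data$verdict == "none" ~ "n.s.",
        TRUE ~ NA_character_)) |>
      select("test", "lab", "significance"))
}

#' Laboratory mean distribution plot
#'
#' Replicate values and laboratory means sorted by mean, with excluded
#' laboratories greyed out and candidate certified-value lines (mean of lab
#' means +/- 2 sd of lab means) overlaid.
#'
#' @param object a `certification_battery`.
#' @param table the certification table the battery was computed from.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.certification_battery <- function(object, table, ...) {
  sm <- object$summaries |> mutate(rank = row_number())
  sm$lab_f <- factor(sm$rank, levels = sm$rank, labels = sm$lab_id)
  df <- table |>
    filter(.data$analyte == object$analyte) |>
    left_join(select(sm, "lab_id", "lab_f", "excluded"), by = "lab_id")
  inc <- filter(sm, !.data$excluded)
  mu <- mean(inc$mean); s <- sd(inc$mean)
  ggplot(df, aes(x = .data$lab_f, y = .data$value,
                 colour = .data$excluded)) +
    geom_point(alpha = 0.6) +
    geom_point(data = sm, aes(x = .data$lab_f,
                              y = .data$mean), shape = 3, size = 3) +
    geom_hline(yintercept = mu, colour = "red") +
    geom_hline(yintercept = mu + c(-2, 2) * s, colour = "red",
               linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "grey60")) +
    labs(x = "laboratory (sorted by mean)", y = "value", colour = "excluded") +
    theme_bw()
}
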