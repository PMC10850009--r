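# Uncertainty budget: certified value as the unweighted mean of laboratory
# means, root-sum-of-squares combination of relative uncertainty
# contributions, expansion with k, and presentation rounding per DIN 1333.

#' Certified value: unweighted mean of laboratory means
#'
#' Every included laboratory contributes with equal weight, regardless of
#' its replicate count.
#'
#' @param summaries a laboratory summary table ([lab_summaries()]); excluded
#'   laboratories are dropped automatically.
#' @return the certified value `mu_c`.
#' @export
certified_mean <- function(summaries) {
  stopifnot(is.data.frame(summaries), "mean" %in% names(summaries))
  if ("excluded" %in% names(summaries)) {
    summaries <- filter(summaries, !.data$excluded)
  }
  if (nrow(summaries) < 2) stop_validation("at least 2 included laboratories are required")
  mean(summaries$mean)
}

#' Characterization uncertainty of the certified value
#'
#' The standard uncertainty of the mean of laboratory means,
#' `sd(lab means) / sqrt(p)`, expressed relative to the certified value in
#' percent.
#'
#' @inheritParams certified_mean
#' @return a named numeric of length 1 (term `u_char`), in percent.
#' @export
u_char <- function(summaries) {
  if ("excluded" %in% names(summaries)) {
    summaries <- filter(summaries, !.data$excluded)
  }
  p <- nrow(summaries)
  if (p < 2) stop_validation("at least 2 included laboratories are required")
  mu <- mean(summaries$mean)
  if (mu == 0) stop_validation("certified value is zero; relative uncertainty undefined")
  c(u_char = sd(summaries$mean) / sqrt(p) / abs(mu) * 100)
}

#' Combine relative uncertainty contributions
#'
#' Root-sum-of-squares combination of the named relative contributions (in
#' percent), expansion with factor k, and conversion to the absolute
#' expanded uncertainty when the certified value is supplied.
#'
#' @param terms named numeric vector of relative contributions in percent
#'   (e.g. `c(u_char = 1.2, u_bb = 0.9, u_rep = 0.5)`); all must be >= 0.
#' @param k expansion factor (> 0, default 2).
#' @param mu_c optional certified value for the absolute `U_abs`.
#' @return a one-row tibble with `u_com_rel`, `k`, `U_rel` and (if `mu_c`
#'   given) `U_abs`.
#' @export
#' @examples
#' combine_uncertainty(c(u_char = 3, u_bb = 4)) # u_com = 5
combine_uncertainty <- function(terms, k = 2, mu_c = NULL) {
  if (length(terms) < 1) stop_validation("at least one uncertainty term is required")
  if (any(!is.finite(terms)) || any(terms < 0)) {
    stop_validation("uncertainty terms must be finite and non-negative")
  }
  if (!is.numeric(k) || k <= 0) stop_validation("k must be positive")
  u_com <- sqrt(sum(terms^2))
  out <- tibble(u_com_rel = u_com, k = k, U_rel = k * u_com)
  if (!is.null(mu_c)) out$U_abs <- out$U_rel / 100 * mu_c
  out
}

# decimal exponent of the rounding position per DIN 1333: position of the
# first significant digit of U, one further right when that digit is 1 or 2
din1333_position <- function(U_abs) {
  stopifnot(U_abs > 0)
  e <- floor(log10(U_abs) + 1e-12)
  first_digit <- floor(U_abs / 10^e + 1e-9)
  if (first_digit <= 2) e - 1 else e
}

#' Round a certified value and its expanded uncertainty (DIN 1333)
#'
#' The uncertainty dictates the rounding position: the decimal place of its
#' first significant digit, or one more place when that digit is 1 or 2 (so
#' that e.g. 0.1686 keeps two significant digits).  The uncertainty is
#' always rounded up at that place; the value is rounded half away from
#' zero at the same place.  A user override of the number of decimal places
#' is honored.
#'
#' @param mu_c certified value.
#' @param U_abs absolute expanded uncertainty (> 0).
#' @param digits optional override: number of decimal places (negative for
#'   positions left of the decimal point).
#' @return a one-row tibble with `mu_c_rounded`, `U_abs_rounded`, `digits`.
#' @export
#' @examples
#' round_din1333(3.9962, 0.1686) # 4.00 +/- 0.17
round_din1333 <- function(mu_c, U_abs, digits = NULL) {
  if (!is.numeric(U_abs) || U_abs <= 0) stop_validation("U_abs must be positive")
  e <- if (is.null(digits)) din1333_position(U_abs) else -as.integer(digits)
  scale <- 10^e
  # protect exact grid points from floating-point round-up
  U_rounded <- ceiling(U_abs / scale - 1e-9) * scale
  mu_rounded <- sign(mu_c) * floor(abs(mu_c) / scale + 0.5) * scale
  tibble(mu_c_rounded = mu_rounded, U_abs_rounded = U_rounded, digits = -e)
}

#' Assemble the uncertainty budget for one analyte
#'
#' Convenience wrapper combining [certified_mean()], [u_char()], transferred
#' terms (e.g. `u_bb` from the homogeneity module, `u_stab` from the
#' stability module, a user-supplied `u_rep`), expansion and DIN 1333
#' rounding into the budget table.
#'
#' @inheritParams certified_mean
#' @param transferred named numeric vector of additional relative terms in
#'   percent.
#' @param k expansion factor (default 2).
#' @param digits optional rounding override (decimal places).
#' @return an object of class `uncertainty_budget`; `tidy()` gives the term
#'   table, `glance()` the one-row budget.
#' @export
uncertainty_budget <- function(summaries, transferred = numeric(0), k = 2,
                               digits = NULL) {
  if ("excluded" %in% names(summaries)) {
    included <- filter(summaries, !.data$excluded)
  } else {
    included <- summaries
  }
  mu <- certified_mean(summaries)
  terms <- c(u_char(summaries), transferred)
  comb <- combine_uncertainty(terms, k = k, mu_c = mu)
  rounded <- round_din1333(mu, comb$U_abs, digits = digits)
  structure(list(
    p = nrow(included), mu_c = mu, terms = terms,
    u_com_rel = comb$u_com_rel, k = k,
    U_rel = comb$U_rel, U_abs = comb$U_abs,
    mu_c_rounded = rounded$mu_c_rounded,
    U_abs_rounded = rounded$U_abs_rounded,
    rounding_digits = rounded$digits
  ), class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget> mu_c = %.6g (p = %d labs)\n", x$mu_c, x$p))
  cat(sprintf("  terms [%%]: %s\n",
              paste(sprintf("%s = %.3g", names(x$terms), x$terms), collapse = ", ")))
  cat(sprintf("  u_com = %.3g%%, k = %g, U = %.3g%% (abs %.4g)\n",
              x$u_com_rel, x$k, x$U_rel, x$U_abs))
  cat(sprintf("  certified: %s +/- %s (rounded at %d decimal place(s))\n",
              format(x$mu_c_rounded), format(x$U_abs_rounded), x$rounding_digits))
  invisible(x)
}

#' @export
tidy.uncertainty_budget <- function(x, ...) {
  tibble(term = names(x$terms), rel_pct = unname(x$terms))
}

#' @export
glance.uncertainty_budget <- function(x, ...) {
  tibble(p = x$p, mu_c = x$mu_c, u_com_rel = x$u_com_rel, k = x$k,
         U_rel = x$U_rel, U_abs = x$U_abs,
         mu_c_rounded = x$mu_c_rounded, U_abs_rounded = x$U_abs_rounded,
         digits = x$rounding_digits)
}
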