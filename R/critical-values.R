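# Critical values for the outlier tests of the certification battery.
#
# Single Grubbs and Cochran use exact closed forms valid for any sample
# size.  The Dixon ratio test and the double-Grubbs SS-ratio test rely on
# tabulated null quantiles; the tables shipped here were calibrated once by
# Monte-Carlo simulation (2e5 standard-normal replicates per N, fixed seed)
# and are cross-checked against fresh simulations in the test suite.  The
# Dixon values are two-sided (null distribution of the larger of the two
# one-ended ratios), matching a battery that always examines both extremes.

#' Critical value of the (single) Grubbs test
#'
#' Exact closed form for the two-sided Grubbs statistic
#' \eqn{G = \max_i |x_i - \bar x| / s} at level `alpha`:
#' \deqn{G_{crit} = \frac{N-1}{\sqrt N}\sqrt{\frac{t^2}{N-2+t^2}}, \quad
#'   t = t_{1-\alpha/(2N),\,N-2}.}
#'
#' @param N number of observations (>= 3).
#' @param alpha significance level.
#' @return critical value of G.
#' @export
grubbs_crit <- function(N, alpha) {
  stopifnot(N >= 3, alpha > 0, alpha < 1)
  t2 <- qt(alpha / (2 * N), df = N - 2, lower.tail = FALSE)^2
  (N - 1) / sqrt(N) * sqrt(t2 / (N - 2 + t2))
}

#' Critical value of the Cochran variance-outlier test
#'
#' Exact closed form valid for any number of laboratories N and replicate
#' degrees of freedom nu (it is not limited to the N <= 30/40 range of the
#' printed tables):
#' \deqn{C_{crit}(\alpha, N, \nu) = \left[1 + \frac{N-1}
#'   {F_{1-\alpha/N}(\nu, (N-1)\nu)}\right]^{-1}.}
#'
#' @param N number of laboratories (>= 2).
#' @param nu replicate degrees of freedom per laboratory (>= 1).
#' @param alpha significance level.
#' @return critical value of `C = s_max^2 / sum(s_i^2)`.
#' @export
#' @examples
#' cochran_crit(N = 3, nu = 2, alpha = 0.05) # 0.8709
cochran_crit <- function(N, nu, alpha) {
  stopifnot(N >= 2, nu >= 1, alpha > 0, alpha < 1)
  f <- qf(alpha / N, df1 = nu, df2 = (N - 1) * nu, lower.tail = FALSE)
  1 / (1 + (N - 1) / f)
}

# Dixon two-sided critical values (alpha 0.05 / 0.01), N = 3..30
# (simulation-calibrated null quantiles, 2e5 replicates per N; see header)
dixon_crit_table <- data.frame(N = 3:30,
  c05 = c(0.9709, 0.8290, 0.7098, 0.6273, 0.5687, 0.6070, 0.5651, 0.5286,
          0.6199, 0.5921, 0.5651, 0.5869, 0.5652, 0.5459, 0.5289, 0.5154,
          0.5005, 0.4881, 0.4787, 0.4682, 0.4585, 0.4505, 0.4424, 0.4362,
          0.4295, 0.4229, 0.4166, 0.4113),
  c01 = c(0.9941, 0.9202, 0.8236, 0.7414, 0.6820, 0.7187, 0.6715, 0.6335,
          0.7055, 0.6774, 0.6475, 0.6708, 0.6486, 0.6287, 0.6107, 0.5941,
          0.5808, 0.5661, 0.5560, 0.5435, 0.5337, 0.5248, 0.5179, 0.5103,
          0.5018, 0.4952, 0.4882, 0.4826))

# variant schedule by sample size
dixon_variant <- function(N) {
  if (N < 3 || N > 30) stop_validation("Dixon test supports 3 <= N <= 30 (got N = %d)", N)
  if (N <= 7) "r10" else if (N <= 10) "r11" else if (N <= 13) "r21" else "r22"
}

#' Critical value of the Dixon ratio test
#'
#' Two-sided critical values for the Dixon ratio statistic, with the ratio
#' variant selected by sample size (r10 for N = 3-7, r11 for 8-10, r21 for
#' 11-13, r22 for N >= 14).  Values are simulation-calibrated null quantiles
#' of the larger of the lower-end and upper-end ratios.
#'
#' @param N number of observations (3 to 30).
#' @param alpha significance level (0.05 or 0.01).
#' @return critical value of the Dixon ratio.
#' @export
dixon_crit <- function(N, alpha) {
  dixon_variant(N) # range check
  col <- if (isTRUE(all.equal(alpha, 0.05))) "c05"
         else if (isTRUE(all.equal(alpha, 0.01))) "c01"
         else stop_validation("tabulated Dixon levels are 0.05 and 0.01")
  dixon_crit_table[dixon_crit_table$N == N, col]
}

# Double-Grubbs SS-ratio lower critical values, N = 4..40
# (simulation-calibrated null quantiles, 2e5 replicates per N)
double_grubbs_crit_table <- data.frame(N = 4:40,
  c05 = c(0.00076, 0.01825, 0.05625, 0.10205, 0.14839, 0.19107, 0.23093,
          0.26699, 0.30041, 0.32950, 0.35645, 0.38055, 0.40403, 0.42481,
          0.44447, 0.46324, 0.48204, 0.49659, 0.51085, 0.52436, 0.53726,
          0.55028, 0.56085, 0.57273, 0.58190, 0.59144, 0.60115, 0.60888,
          0.61808, 0.62611, 0.63297, 0.64035, 0.64776, 0.65363, 0.65950,
          0.66580, 0.67272),
  c01 = c(0.00003, 0.00360, 0.01864, 0.04412, 0.07457, 0.10871, 0.14119,
          0.17533, 0.20415, 0.23400, 0.26020, 0.28571, 0.30825, 0.33108,
          0.35252, 0.37156, 0.39290, 0.40874, 0.42518, 0.44156, 0.45487,
          0.46768, 0.47914, 0.49449, 0.50247, 0.51815, 0.52755, 0.53725,
          0.54573, 0.55639, 0.56507, 0.57338, 0.58214, 0.58838, 0.59575,
          0.60318, 0.60963))

#' Critical value of the double-Grubbs test
#'
#' Lower critical values for the two-outlier Grubbs SS-ratio statistic
#' (residual sum of squares after removing the two most extreme values at
#' one end, divided by the total sum of squares; small values indicate an
#' outlying pair).  Tabulated for N = 4 to 40 (simulation-calibrated); for
#' larger N a Monte-Carlo value is computed on the fly.
#'
#' @param N number of observations (>= 4).
#' @param alpha significance level (0.05 or 0.01).
#' @param reps Monte-Carlo replicates for the N > 40 fallback.
#' @return critical value (reject when the statistic is below it).
#' @export
grubbs_double_crit <- function(N, alpha, reps = 2e4) {
  stopifnot(N >= 4)
  if (!isTRUE(all.equal(alpha, 0.05)) && !isTRUE(all.equal(alpha, 0.01))) {
    stop_validation("tabulated double-Grubbs levels are 0.05 and 0.01")
  }
  col <- if (isTRUE(all.equal(alpha, 0.05))) "c05" else "c01"
  if (N <= 40) {
    return(double_grubbs_crit_table[double_grubbs_crit_table$N == N, col])
  }
  # simulation fallback beyond the table, deterministic
  withr::with_seed(7211 + N, {
    stats <- replicate(reps, {
      x <- sort.int(rnorm(N))
      grubbs_double_stat(x, N)
    })
    unname(quantile(stats, alpha))
  })
}

# SS-ratio for removing the two largest of a sorted sample
grubbs_double_stat <- function(xs, N) {
  red <- xs[1:(N - 2)]
  sum((red - mean(red))^2) / sum((xs - mean(xs))^2)
}
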