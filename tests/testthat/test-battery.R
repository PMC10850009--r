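test_that("Grubbs statistic and verdict follow the definition", {
  m <- c(a = 1, b = 1, c = 1, d = 10)
  r <- grubbs_single(m)
  expect_equal(r$lab, "d")
  expect_equal(r$statistic, max(abs(m - mean(m))) / sd(m))
  # all equal: degenerate, no verdict
  expect_warning(r0 <- grubbs_single(c(a = 1, b = 1, c = 1)))
  expect_equal(r0$verdict, "none")
  expect_error(grubbs_single(c(1, 2)), "at least 3",
               class = "certifyr_validation_error")
})

test_that("closed-form Grubbs critical values match Monte-Carlo null rates", {
  reps <- 2e4
  withr::with_seed(31, {
    for (N in c(5, 10, 20)) {
      X <- matrix(rnorm(reps * N), nrow = reps)
      mu <- rowMeans(X)
      s <- sqrt((rowSums(X^2) - N * mu^2) / (N - 1))
      G <- do.call(pmax, as.data.frame(abs(X - mu))) / s
      for (alpha in c(0.05, 0.01)) {
        rate <- mean(G > grubbs_crit(N, alpha))
        expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / reps) + 0.002)
      }
    }
  })
})

test_that("double Grubbs implicates the extreme pair and enforces N >= 4", {
  m <- c(a = 1, b = 1, c = 1, d = 9, e = 10)
  r <- grubbs_double(m)
  expect_setequal(strsplit(r$lab, ",")[[1]], c("d", "e"))
  # statistic by hand: SS without the pair over total SS
  red <- c(1, 1, 1)
  expect_equal(r$statistic, sum((red - mean(red))^2) /
                 sum((m - mean(m))^2))
  expect_error(grubbs_double(c(1, 2, 3)), "at least 4",
               class = "certifyr_validation_error")
})

test_that("tabulated double-Grubbs critical values match a fresh simulation", {
  reps <- 2e4
  withr::with_seed(32, {
    for (N in c(6, 12)) {
      stats <- vapply(1:reps, function(i) {
        certifyr:::grubbs_double_stat(sort.int(rnorm(N)), N)
      }, numeric(1))
      for (alpha in c(0.05, 0.01)) {
        rate <- mean(stats < grubbs_double_crit(N, alpha))
        expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / reps) + 0.002)
      }
    }
  })
})

test_that("Dixon ratios follow the definitional arithmetic", {
  r <- dixon(c(a = 1, b = 2, c = 10))
  expect_equal(r$statistic, 8 / 9) # r10 at the high end
  expect_equal(r$lab, "c")
  # symmetric data: both ends give equal ratios, high end reported
  xs <- sort(c(1, 3, 5, 7, 9))
  ratios <- certifyr:::dixon_ratios(xs, 5)
  expect_equal(unname(ratios["low"]), unname(ratios["high"]))
  expect_error(dixon(rnorm(31)), "3 <= N <= 30",
               class = "certifyr_validation_error")
  expect_error(dixon(rnorm(2)), "3 <= N <= 30",
               class = "certifyr_validation_error")
})

test_that("tabulated Dixon critical values match a fresh null simulation", {
  reps <- 2e4
  withr::with_seed(33, {
    for (N in c(5, 9, 12, 20)) {
      stats <- vapply(1:reps, function(i) {
        xs <- sort.int(rnorm(N))
        max(certifyr:::dixon_ratios(xs, N))
      }, numeric(1))
      for (alpha in c(0.05, 0.01)) {
        rate <- mean(stats > dixon_crit(N, alpha))
        expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / reps) + 0.002)
      }
    }
  })
})

test_that("Cochran closed form reproduces the published table value and MC rates", {
  expect_equal(cochran_crit(3, 2, 0.05), 0.8709, tolerance = 5e-5)
  # equal variances give C = 1/N
  sds <- rep(2, 5)
  r <- cochran(sds, n_reps = 3)
  expect_equal(r$statistic, 1 / 5)
  expect_equal(r$verdict, "none")
  # Monte-Carlo null agreement, including an n > 30 case
  reps <- 2e4
  withr::with_seed(34, {
    for (cfg in list(c(N = 5, nu = 2), c(N = 35, nu = 3))) {
      N <- cfg["N"]; nu <- cfg["nu"]
      S2 <- matrix(stats::rchisq(reps * N, df = nu) / nu, nrow = reps)
      C <- S2[cbind(seq_len(reps), max.col(S2))] / rowSums(S2)
      for (alpha in c(0.05, 0.01)) {
        rate <- mean(C > cochran_crit(N, nu, alpha))
        expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / reps) + 0.002)
      }
    }
  })
  # unbalanced replicate counts: conservative nu with a warning
  expect_warning(cochran(c(1, 1, 2), n_reps = c(3, 4, 5)),
                 class = "certifyr_unbalanced_cochran")
})

test_that("Bartlett wrapper matches the textbook statistic", {
  tab <- cert_table(list(L1 = c(1, 2, 3), L2 = c(2, 3, 4), L3 = c(0, 2, 4)))
  r <- bartlett_labs(tab)
  bt <- stats::bartlett.test(split(tab$value, tab$lab_id))
  expect_equal(r$statistic, unname(bt$statistic))
  expect_equal(r$p_value, unname(bt$p.value))
  # identical variances: statistic ~ 0, p ~ 1
  tab0 <- cert_table(list(L1 = c(1, 2), L2 = c(5, 6), L3 = c(9, 10)))
  r0 <- bartlett_labs(tab0)
  expect_lt(r0$statistic, 1e-10)
  expect_gt(r0$p_value, 0.999)
})

test_that("Scheffe compatibility flags a strongly shifted laboratory", {
  tab <- cert_table(list(L1 = c(10.0, 10.1), L2 = c(10.1, 10.2),
                         L3 = c(9.9, 10.0), L4 = c(12.0, 12.1)))
  sch <- scheffe(tab)
  expect_equal(nrow(sch), choose(4, 2))
  with_l4 <- dplyr::filter(sch, lab_i == "L4" | lab_j == "L4")
  expect_true(all(with_l4$incompatible_01))
  others <- dplyr::filter(sch, lab_i != "L4" & lab_j != "L4")
  expect_false(any(others$incompatible_05))
  # all labs equal: everything compatible
  tab0 <- cert_table(list(L1 = c(1, 2), L2 = c(1, 2), L3 = c(1, 2)))
  expect_false(any(scheffe(tab0)$incompatible_05))
})

test_that("normality screening behaves on symmetric and simulated data", {
  m <- c(1, 2, 3, 4, 5, 6, 7)
  out <- normality_suite(m)
  sk <- dplyr::filter(out, test == "Skewness")
  expect_equal(sk$statistic, 0, tolerance = 1e-12)
  qq <- qq_points(m)
  expect_true(all(diff(qq$theoretical) > 0))
  expect_true(all(diff(qq$sample) >= 0))
  # under the null the suite rejects rarely
  withr::with_seed(35, {
    rej <- vapply(1:60, function(i) {
      out <- normality_suite(rnorm(20))
      any(out$verdict == "outlier", na.rm = TRUE)
    }, logical(1))
    expect_lt(mean(rej), 0.15)
  })
})

test_that("the battery is equivariant under laboratory relabeling", {
  withr::with_seed(36, {
    vals <- lapply(1:6, function(i) rnorm(4, mean = 10 + (i == 3) * 5))
  })
  names(vals) <- sprintf("L%d", 1:6)
  tab <- cert_table(vals)
  b1 <- evaluate_battery(tab)
  # relabel: swap L3 and L5
  relabel <- c(L1 = "L1", L2 = "L2", L3 = "L5", L4 = "L4", L5 = "L3", L6 = "L6")
  tab2 <- dplyr::mutate(tab, lab_id = unname(relabel[lab_id]))
  b2 <- evaluate_battery(tab2)
  expect_equal(b1$tests$statistic, b2$tests$statistic, tolerance = 1e-12)
  g1 <- dplyr::filter(b1$tests, test == "Grubbs (single)")$lab
  g2 <- dplyr::filter(b2$tests, test == "Grubbs (single)")$lab
  expect_equal(unname(relabel[g1]), g2)
})

test_that("exclusion never mutates data and re-inclusion restores the battery", {
  fx <- make_fixture(fixture_spec_soil_hg(), seed = 12, dir = tempfile())
  tab <- read_certification(fx$paths$certification)
  before <- evaluate_battery(tab, "Hg")
  with_excl <- evaluate_battery(tab, "Hg", exclusions = "L4")
  # the excluded lab keeps its data in the summaries
  expect_true("L4" %in% with_excl$summaries$lab_id)
  expect_equal(dplyr::filter(with_excl$summaries, lab_id == "L4")$mean,
               dplyr::filter(before$summaries, lab_id == "L4")$mean)
  after <- evaluate_battery(tab, "Hg") # re-inclusion
  expect_equal(before$tests, after$tests)
  # verdict ordering: every outlier verdict is also significant at 5%
  t <- with_excl$tests
  crit_based <- t[!is.na(t$statistic) & !is.na(t$critical_05) &
                    t$verdict == "outlier", ]
  expect_true(all(crit_based$test != "Grubbs (double)" |
                    crit_based$statistic < crit_based$critical_05))
})

test_that("battery preconditions and display modes work", {
  tab <- cert_table(list(L1 = c(1, 2), L2 = c(2, 3), L3 = c(3, 4)))
  expect_error(evaluate_battery(tab, exclusions = c("L1", "L2")),
               "at least 3", class = "certifyr_validation_error")
  b <- evaluate_battery(tab)
  expect_named(battery_display(b, "statistic"), c("test", "lab", "statistic"))
  expect_named(battery_display(b, "significance level"),
               c("test", "lab", "significance"))
})
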