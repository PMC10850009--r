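test_that("ANOVA mean squares match an independent linear-model fit", {
  # oracle: stats::anova on lm(value ~ bottle), on random unbalanced designs
  withr::with_seed(101, {
    for (i in 1:25) {
      N <- sample(3:8, 1)
      tab <- purrr::map_dfr(seq_len(N), function(b) {
        tibble::tibble(analyte = "X", bottle = sprintf("B%d", b),
                       value = rnorm(sample(2:5, 1), mean = 10 + rnorm(1)))
      })
      res <- evaluate_homogeneity(tab, "X")
      ora <- anova(lm(value ~ bottle, data = tab))
      expect_equal(res$M_between, ora$`Mean Sq`[1], tolerance = 1e-10)
      expect_equal(res$M_within, ora$`Mean Sq`[2], tolerance = 1e-10)
      expect_equal(res$df_between, ora$Df[1])
      expect_equal(res$df_within, ora$Df[2])
      expect_equal(res$F_stat, ora$`F value`[1], tolerance = 1e-10)
      expect_equal(res$p_value, ora$`Pr(>F)`[1], tolerance = 1e-10)
      # sums-of-squares identity
      ss_tot <- sum((tab$value - mean(tab$value))^2)
      expect_equal(res$M_between * res$df_between +
                     res$M_within * res$df_within, ss_tot, tolerance = 1e-10)
      # balanced-design df check
      expect_equal(res$df_between + res$df_within, nrow(tab) - 1)
    }
  })
})

test_that("s_bb follows the definitional sums of squares in a noiseless design", {
  tab <- homog_table(list(c(10, 10), c(12, 12), c(14, 14)))
  res <- evaluate_homogeneity(tab)
  expect_equal(res$M_within, 0)
  # M_between from first principles: n * var of bottle means
  expect_equal(res$M_between, 2 * var(c(10, 12, 14)))
  expect_false(res$masked)
  expect_equal(res$s_bb_abs, sqrt(res$M_between / 2))
  expect_equal(res$s_bb_min_rel, 0) # no within variance, nothing maskable
})

test_that("identical values give a fully degenerate result", {
  tab <- homog_table(list(rep(4, 4), rep(4, 4), rep(4, 4)))
  res <- evaluate_homogeneity(tab)
  expect_equal(res$M_between, 0)
  expect_equal(res$M_within, 0)
  expect_equal(res$s_bb_rel, 0)
  expect_equal(res$s_bb_min_rel, 0)
  expect_true(res$masked)
})

test_that("masking rule: s_bb = 0 exactly when M_within >= M_between", {
  withr::with_seed(77, {
    for (i in 1:50) {
      tab <- homog_table(lapply(1:4, function(b) rnorm(3, mean = 10,
                                                       sd = runif(1, 0.1, 2))))
      res <- evaluate_homogeneity(tab)
      expect_identical(res$masked, res$M_within >= res$M_between)
      expect_identical(res$s_bb_rel == 0, res$masked)
      if (res$M_within > 0) expect_gt(res$s_bb_min_rel, 0)
    }
  })
})

test_that("unbalanced designs use the effective replicate count n0", {
  tab <- homog_table(list(c(10, 11), c(12, 12, 13), c(14)))
  res <- evaluate_homogeneity(tab)
  n_i <- c(2, 3, 1)
  expect_equal(res$n0, (6 - sum(n_i^2) / 6) / 2)
  tab_bal <- homog_table(list(c(10, 11), c(12, 13), c(14, 15)))
  expect_equal(evaluate_homogeneity(tab_bal)$n0, 2)
})

test_that("u_bb transfers the greater of s_bb and s_bb_min", {
  res <- evaluate_homogeneity(homog_table(list(c(10, 10), c(12, 12), c(14, 14))))
  expect_equal(unname(u_bb(res)), max(res$s_bb_rel, res$s_bb_min_rel))
  # masked case: the floor wins
  res2 <- evaluate_homogeneity(homog_table(list(c(10, 14), c(11, 13), c(12, 12))))
  if (res2$masked) expect_equal(unname(u_bb(res2)), res2$s_bb_min_rel)
})

test_that("increasing the true between-bottle variance does not decrease mean s_bb", {
  mean_sbb <- vapply(c(0.5, 1.5, 3), function(truth) {
    vals <- vapply(1:15, function(seed) {
      fx <- make_fixture(fixture_spec_soil_hg(s_bb_rel = truth), seed = seed,
                         dir = tempfile())
      evaluate_homogeneity(read_homogeneity(fx$paths$homogeneity), "Hg")$s_bb_rel
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_sbb) > 0))
})

test_that("degenerate homogeneity inputs are refused", {
  expect_error(evaluate_homogeneity(homog_table(list(c(10), c(12)))),
               "degrees of freedom", class = "certifyr_validation_error")
  tab <- homog_table(list(c(-1, 1), c(-2, 2)))
  expect_error(evaluate_homogeneity(tab), "zero",
               class = "certifyr_validation_error")
})
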