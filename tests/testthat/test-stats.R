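test_that("one-way ANOVA matches hand-computed sums of squares and base R", {
  d <- anova_fixture()
  out <- oneway_anova(d)
  # group means 2, 3, 7 around grand mean 4: SSB = 3*(4+1+9) = 42
  # within-group deviations (-1,0,1) each: SSW = 6; F = (42/2)/(6/6) = 21
  expect_equal(out$ss_between, 42)
  expect_equal(out$ss_within, 6)
  expect_equal(out$statistic, 21)
  oracle <- summary(stats::aov(value ~ group, data = d))[[1]]
  expect_equal(out$statistic, oracle[["F value"]][1])
  expect_equal(out$p.value, oracle[["Pr(>F)"]][1])
})

test_that("ANOVA degenerate and invalid layouts are handled", {
  equal_means <- tibble::tibble(
    group = rep(c("a", "b"), each = 3), value = rep(c(1, 2, 3), 2)
  )
  out <- oneway_anova(equal_means)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  flat <- tibble::tibble(group = rep(c("a", "b"), each = 2), value = rep(5, 4))
  expect_equal(oneway_anova(flat)$statistic, 0)
  expect_error(
    oneway_anova(tibble::tibble(group = rep("a", 3), value = 1:3)), "2 groups"
  )
})

test_that("Tukey HSD agrees with the base-R oracle on a balanced layout", {
  d <- anova_fixture()
  out <- tukey_hsd(d)
  oracle <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  key <- paste0(out$group2, "-", out$group1)
  expect_equal(out$diff, unname(oracle[key, "diff"]))
  expect_equal(out$p.adj, unname(oracle[key, "p adj"]), tolerance = 1e-9)
})

test_that("Tukey HSD flags identical groups as indistinguishable", {
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 3),
    value = c(1, 2, 3, 1, 2, 3, 8, 9, 10)
  )
  out <- tukey_hsd(d)
  ab <- dplyr::filter(out, group1 == "a", group2 == "b")
  expect_equal(ab$p.adj, 1, tolerance = 1e-9)
  expect_false(ab$significant)
  expect_true(dplyr::filter(out, group1 == "a", group2 == "c")$significant)
})

test_that("Tukey significance is monotone in the mean difference", {
  withr::with_seed(12, {
    base <- rnorm(4, sd = 0.5)
    shifts <- c(0.5, 1.5, 3, 6)
    ps <- vapply(shifts, function(s) {
      d <- tibble::tibble(
        group = rep(c("ctl", "trt"), each = 4),
        value = c(base, base + s)
      )
      tukey_hsd(d)$p.adj
    }, numeric(1))
  })
  expect_true(all(diff(ps) < 0))
})

test_that("per-cell formate differs by P source the way the assay data show", {
  out <- tukey_hsd(formate_groups())
  sig_pairs <- dplyr::filter(out, significant)
  cross <- c(
    "phosphate.MPn", "phosphate.HMPn", "phosphite.MPn", "phosphite.HMPn"
  )
  got <- paste0(sig_pairs$group1, ".", sig_pairs$group2)
  expect_setequal(got, cross)
  mpn_hmpn <- dplyr::filter(out, group1 == "MPn", group2 == "HMPn")
  expect_false(mpn_hmpn$significant)
  expect_lt(oneway_anova(formate_groups())$p.value, 2.6e-4)
})

test_that("the Yates-corrected enrichment test reproduces the reported statistic", {
  t <- two_proportion_test(14, 219, 1, 187, alternative = "greater")
  expect_equal(round(t$chi2, 2), 8.15)
  expect_equal(t$df, 1L)
  expect_equal(round(t$p, 6), 0.002151)
})

test_that("equal proportions give a null statistic", {
  t <- two_proportion_test(5, 10, 5, 10)
  expect_equal(t$chi2, 0)
  expect_equal(t$p, 1)
})

test_that("the uncorrected statistic equals the direct 2x2 chi-square", {
  withr::with_seed(19, {
    for (i in 1:30) {
      n1 <- sample(10:200, 1)
      n2 <- sample(10:200, 1)
      x1 <- rbinom(1, n1, runif(1, 0.05, 0.95))
      x2 <- rbinom(1, n2, runif(1, 0.05, 0.95))
      t <- two_proportion_test(x1, n1, x2, n2, continuity = FALSE)
      obs <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
      expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
      expect_equal(t$chi2, sum((obs - expd)^2 / expd), tolerance = 1e-12)
      # and agrees with base R in both corrected and uncorrected forms
      expect_equal(
        t$chi2,
        unname(suppressWarnings(
          stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)
        )$statistic),
        tolerance = 1e-9
      )
      ty <- two_proportion_test(x1, n1, x2, n2, continuity = TRUE)
      py <- suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)
      )
      expect_equal(ty$chi2, unname(py$statistic), tolerance = 1e-9)
      expect_equal(ty$p, py$p.value, tolerance = 1e-9)
    }
  })
})

test_that("swapping the samples preserves chi-square and mirrors one-sided p", {
  a <- two_proportion_test(14, 219, 1, 187, alternative = "greater")
  b <- two_proportion_test(1, 187, 14, 219, alternative = "less")
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p, b$p)
  g <- two_proportion_test(1, 187, 14, 219, alternative = "greater")
  expect_equal(g$p, 1 - a$p)
})

test_that("count validation rejects impossible tables", {
  expect_error(two_proportion_test(5, 0, 1, 10), "positive")
  expect_error(two_proportion_test(11, 10, 1, 10), "exceed")
})
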