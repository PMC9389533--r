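test_that("confusion counts enumerate cells exactly", {
  cc <- confusion_counts(c("cancer", "cancer", "non_cancer"),
                         c("cancer", "non_cancer", "non_cancer"))
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 0L, fn = 1L, tn = 1L), ignore_attr = TRUE)
  same <- rep(c("cancer", "non_cancer"), 5)
  cc2 <- confusion_counts(same, same)
  expect_equal(cc2$fp + cc2$fn, 0L)
  expect_error(confusion_counts("cancer", c("cancer", "cancer")), "equal length")
})

test_that("diagnostic metrics reproduce the defining identities and degenerate cases", {
  m <- diagnostic_metrics(counts_2x2(tp = 48, fp = 14, fn = 5, tn = 50))
  expect_equal(m$sensitivity$estimate, 48 / 53)
  expect_equal(m$specificity$estimate, 50 / 64)
  expect_equal(m$accuracy$estimate, 98 / 117)
  # PLR/NLR identities hold to machine precision before any rounding
  expect_equal(m$plr$estimate,
               m$sensitivity$estimate / (1 - m$specificity$estimate),
               tolerance = 1e-12)
  expect_equal(m$nlr$estimate,
               (1 - m$sensitivity$estimate) / m$specificity$estimate,
               tolerance = 1e-12)
  # sens * n_pos and spec * n_neg recover the integer cells
  expect_equal(m$sensitivity$estimate * m$n_pos, 48)
  expect_equal(m$specificity$estimate * m$n_neg, 50)

  perfect <- diagnostic_metrics(counts_2x2(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(perfect$sensitivity$estimate, 1)
  expect_equal(perfect$specificity$estimate, 1)
  expect_equal(perfect$accuracy$estimate, 1)
  expect_equal(perfect$nlr$estimate, 0)
  expect_identical(perfect$plr$estimate, Inf)
  expect_true("plr_infinite" %in% perfect$flags)
})

test_that("Wilson intervals match prop.test and stay inside [0, 1]", {
  # closed form vs the interval prop.test inverts (no continuity correction)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    got <- wilson_ci(x, n)
    ref <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(c(got$lower, got$upper), as.numeric(ref), tolerance = 1e-9)
    expect_true(got$lower >= 0 && got$upper <= 1)
    expect_true(got$lower <= got$estimate && got$estimate <= got$upper)
  }
  # approaches the Wald interval for large n
  n <- 1e6; x <- 3e5
  wald_half <- qnorm(0.975) * sqrt(0.3 * 0.7 / n)
  got <- wilson_ci(x, n)
  expect_equal(got$upper - got$lower, 2 * wald_half, tolerance = 1e-3)
  # boundary case: one success of one trial
  one <- wilson_ci(1, 1)
  expect_equal(one$estimate, 1)
  expect_equal(round(one$lower, 2), 0.21)
  expect_equal(one$upper, 1)
})

test_that("stratified accuracy reports per-pathology Wilson intervals", {
  path <- rep(c("atrophy_IM", "IM"), c(16, 7))
  correct <- c(rep(c(TRUE, FALSE), c(10, 6)), rep(TRUE, 7))
  expect_warning(tab <- stratified_accuracy(path, correct), "empty strata")
  aim <- tab[tab$pathology == "atrophy_IM", ]
  expect_equal(aim$n, 16)
  expect_equal(round_report(aim$accuracy, 2), 0.63)  # 10/16, half rounds up
  im <- tab[tab$pathology == "IM", ]
  expect_equal(im$accuracy, 1)
  expect_true(im$lower < 1)
  expect_error(stratified_accuracy("polyp", TRUE), "unknown pathology")
})

test_that("Cohen's kappa matches hand evaluation and is symmetric and relabel-invariant", {
  a <- c("+", "+", "-", "-")
  b <- c("+", "-", "-", "-")
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.75)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.5)
  expect_equal(cohens_kappa(b, a)$kappa, k$kappa)
  relab <- c("+" = "cancer", "-" = "non_cancer")
  expect_equal(cohens_kappa(relab[a], relab[b])$kappa, k$kappa)
  # perfect agreement over >= 2 labels
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  # both raters constant: chance agreement is total, kappa undefined
  expect_error(cohens_kappa(rep("x", 5), rep("x", 5)), "undefined")
  # independent raters: kappa concentrates near zero
  set.seed(32)
  r1 <- sample(c("cancer", "non_cancer"), 10000, replace = TRUE)
  r2 <- sample(c("cancer", "non_cancer"), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(r1, r2)$kappa), 0.03)
})

test_that("kappa agrees with an established implementation", {
  skip_if_not_installed("e1071")
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    a <- sample(c("x", "y", "z"), n, replace = TRUE)
    b <- ifelse(runif(n) < 0.6, a, sample(c("x", "y", "z"), n, replace = TRUE))
    levs <- sort(unique(c(a, b)))
    tab <- table(factor(a, levs), factor(b, levs))
    ref <- e1071::classAgreement(tab)$kappa
    expect_equal(cohens_kappa(a, b)$kappa, ref, tolerance = 1e-12)
  }
})

test_that("McNemar test is exact-binomial by default with sane edge cases", {
  expect_equal(mcnemar_test(b = 0, c = 0)$p_value, 1.0)
  expect_equal(mcnemar_test(b = 5, c = 5)$p_value, 1.0)
  # 2 * P(X <= 2 | n = 12, p = 1/2) by direct binomial summation
  expect_equal(round(mcnemar_test(b = 10, c = 2)$p_value, 4), 0.0386)
  expect_equal(mcnemar_test(b = 10, c = 2)$p_value,
               2 * pbinom(2, 12, 0.5), tolerance = 1e-12)
  # from paired correctness vectors
  ca <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  cb <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  mt <- mcnemar_test(ca, cb)
  expect_equal(mt$b, 2); expect_equal(mt$c, 1)
  # asymptotic variant equals the chi-square on the discordants
  as <- mcnemar_test(b = 10, c = 2, method = "asymptotic")
  expect_equal(as$p_value, pchisq(64 / 12, 1, lower.tail = FALSE))
})

test_that("Pearson chi-square matches the closed-form 2x2 identity", {
  # severity table: moderate/severe vs mild x correct/wrong
  sev <- matrix(c(5, 6, 5, 0), 2, 2, byrow = TRUE)
  expect_equal(round(pearson_chi2_2x2(sev)$p_value, 3), 0.037)
  sex <- matrix(c(8, 5, 2, 1), 2, 2, byrow = TRUE)
  expect_equal(round(pearson_chi2_2x2(sex)$p_value, 3), 0.869)
  even <- matrix(10, 2, 2)
  expect_equal(pearson_chi2_2x2(even)$statistic, 0)
  expect_equal(pearson_chi2_2x2(even)$p_value, 1)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "degenerate")
  set.seed(34)
  for (i in 1:50) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    hand <- sum(tab) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(pearson_chi2_2x2(tab)$statistic, hand, tolerance = 1e-12)
  }
})

test_that("Fisher's exact test handles tiny and degenerate tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2)), 1.0)
  expect_equal(round(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2)), 4), 0.0079)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2)),
               2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 2, 3), 2, 2)), 1.0)
})

test_that("Mann-Whitney U handles exact, tied and large-sample regimes", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 orderings as extreme
  expect_equal(r$method, "exact")
  tied <- mann_whitney(c(7, 7), c(7, 7))
  expect_equal(tied$u, 2)  # n1 n2 / 2 under complete ties
  expect_equal(tied$p_value, 1)
  big <- mann_whitney(rnorm(50, 10), rnorm(50, 0))
  expect_lt(big$p_value, 1e-4)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  # the normal approximation tracks exact enumeration: coarsely at tiny n
  # (the exact null is a lattice with steps ~1/20, so deviations up to
  # ~0.13 are inherent) and closely by n1 = n2 = 30
  set.seed(35)
  for (i in 1:40) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.5)
    pe <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    pn <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    expect_lt(abs(pe - pn), 0.15)
  }
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30, 0.3)
    pe <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    pn <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    expect_lt(abs(pe - pn), 0.02)
  }
})
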