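test_that("one-way ANOVA matches the pooled t-test and a sum-of-squares oracle", {
  set.seed(101)
  a <- rnorm(8, 10, 2); b <- rnorm(8, 12, 2)
  res <- anovaOnewayPosthoc(c(a, b), rep(c("a", "b"), each = 8))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res@statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res@pValue, tt$p.value, tolerance = 1e-10)

  vals <- rnorm(30, rep(c(0, 0.5, 2), each = 10))
  grp <- rep(c("g1", "g2", "g3"), each = 10)
  res3 <- anovaOnewayPosthoc(vals, grp)
  orc <- oracleAnovaF(vals, grp)
  expect_equal(res3@statistic, orc$F, tolerance = 1e-10)
  expect_equal(res3@pValue, orc$p, tolerance = 1e-10)
  expect_equal(nrow(res3@postHoc), 3L)  # all pairs of three groups
  expect_true(all(res3@postHoc$p_adj >= 0 & res3@postHoc$p_adj <= 1))
})

test_that("degenerate and undersized ANOVA designs are handled explicitly", {
  res <- anovaOnewayPosthoc(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(res@degenerate)
  expect_true(is.na(res@statistic))
  expect_true(is.na(res@pValue))
  expect_error(anovaOnewayPosthoc(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 observations")
  expect_error(anovaOnewayPosthoc(c(1, 2), c("a", "a")), "2 groups")
})

test_that("Kruskal-Wallis handles ties, identical data, and matches the rank-sum test", {
  expect_equal(kruskalWallis(rep(3, 10), rep(c("a", "b"), 5))@statistic, 0)
  expect_equal(kruskalWallis(rep(3, 10), rep(c("a", "b"), 5))@pValue, 1)

  # two-group case: H equals the squared tie-corrected rank-sum z statistic
  set.seed(7)
  v <- sample(1:5, 24, replace = TRUE)
  g <- rep(c("a", "b"), each = 12)
  res <- kruskalWallis(v, g)
  w <- suppressWarnings(wilcox.test(v[g == "a"], v[g == "b"],
                                    correct = FALSE, exact = FALSE))
  expect_equal(res@pValue, w$p.value, tolerance = 1e-10)
  expect_equal(res@statistic, oracleH(v, g), tolerance = 1e-10)
})

test_that("asymptotic Kruskal-Wallis p agrees with exact enumeration on tiny samples", {
  cases <- list(
    list(v = c(1, 1, 3, 3, 3, 5, 3), g = rep(c("a", "b", "c"), c(2, 2, 3))),
    list(v = c(3, 2, 3, 5, 3, 4, 2), g = rep(c("a", "b", "c"), c(2, 2, 3))))
  for (cs in cases) {
    pAsym <- kruskalWallis(cs$v, cs$g)@pValue
    pExact <- oracleKWExactP(cs$v, cs$g)
    expect_lt(abs(pAsym - pExact), 0.02)
  }
})

test_that("ICC(2,1) matches an aov-based variance-components oracle", {
  # six rated targets, two raters
  m <- cbind(r1 = c(4, 5, 3, 4, 5, 2), r2 = c(4, 4, 3, 5, 5, 3))
  res <- iccAbsoluteAgreement(m)
  expect_equal(res@icc, oracleICC21(m), tolerance = 1e-10)

  # rater order and target relabeling do not matter
  expect_equal(iccAbsoluteAgreement(m[, 2:1])@icc, res@icc, tolerance = 1e-12)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(iccAbsoluteAgreement(m[perm, ])@icc, res@icc,
               tolerance = 1e-12)

  # identical columns: perfect agreement
  ident <- cbind(c(1, 4, 2, 5, 3), c(1, 4, 2, 5, 3))
  resI <- iccAbsoluteAgreement(ident)
  expect_equal(resI@icc, 1.0)
  expect_identical(resI@interpretation, "excellent")

  expect_error(iccAbsoluteAgreement(m[1, , drop = FALSE]), "2 rated targets")
})

test_that("independent raters give near-zero ICC labelled poor", {
  set.seed(5)
  r1 <- sample(1:5, 2000, replace = TRUE)
  r2 <- sample(r1)   # same marginal, no pairing
  res <- iccAbsoluteAgreement(cbind(r1, r2))
  expect_lt(abs(res@icc), 0.08)
  expect_identical(res@interpretation, "poor")
})

test_that("agreement bins partition the scale with lower-bin boundaries", {
  expect_identical(interpretICC(c(-0.3, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
                                  0.7, 0.8, 0.81, 1.0)),
                   c("poor", "poor", "poor", "fair", "fair", "moderate",
                     "moderate", "substantial", "substantial", "excellent",
                     "excellent"))
  # no gaps anywhere in (-Inf, 1]
  probe <- seq(-1, 1, by = 0.001)
  expect_false(anyNA(interpretICC(probe)))
})

test_that("Likert summaries format median (IQR) with type-7 quantiles", {
  s1 <- likertSummary(c(4, 4, 5, 5, 5), rep("Bv", 5))
  expect_identical(s1$formatted, "5 (4–5)")
  s2 <- likertSummary(rep(4, 6), rep("Br", 6))
  expect_identical(s2$formatted, "4 (4–4)")

  set.seed(11)
  v <- sample(1:5, 40, replace = TRUE)
  g <- sample(c("36", "40", "44", "48"), 40, replace = TRUE)
  tab <- likertSummary(v, g)
  for (i in seq_len(nrow(tab))) {
    sel <- v[g == tab$group[i]]
    expect_equal(tab$median[i], oracleQuantile7(sel, 0.5), tolerance = 1e-12)
    expect_equal(tab$q1[i], oracleQuantile7(sel, 0.25), tolerance = 1e-12)
    expect_equal(tab$q3[i], oracleQuantile7(sel, 0.75), tolerance = 1e-12)
  }

  # empty groups are reported as missing rows, not dropped
  g2 <- factor(rep("36", 5), levels = c("36", "40"))
  tab2 <- likertSummary(c(1, 2, 3, 4, 5), g2)
  expect_equal(nrow(tab2), 2L)
  expect_true(is.na(tab2$median[tab2$group == "40"]))
})
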