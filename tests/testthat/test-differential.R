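# Moderated t, BH adjustment, group comparisons, contingency tests and the
# cohort summary.

test_that("prior df 0 reduces the moderated t to the ordinary t", {
  e <- rand_expr(30, 12, seed = 1)
  a <- colnames(e)[1:6]; b <- colnames(e)[7:12]
  tab <- moderated_ttest(e, a, b, prior_df = 0)
  for (g in c(1, 10, 30)) {
    tt <- stats::t.test(unclass(e)[g, a], unclass(e)[g, b],
                        var.equal = TRUE)
    expect_equal(tab$t[g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p[g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderation interpolates monotonically between t and pooled z", {
  e <- rand_expr(200, 10, seed = 2)
  a <- colnames(e)[1:5]; b <- colnames(e)[6:10]
  t0 <- moderated_ttest(e, a, b, prior_df = 0)$t
  tinf <- moderated_ttest(e, a, b, prior_df = Inf)$t
  prev <- t0
  for (d0 in c(1, 4, 16, 64, 1e4)) {
    cur <- moderated_ttest(e, a, b, prior_df = d0)$t
    # each gene's statistic moves monotonically from t0 toward tinf
    expect_true(all((cur - prev) * (tinf - t0) >= -1e-8))
    prev <- cur
  }
})

test_that("estimated prior gives calibrated type-I error under the null", {
  fracs <- vapply(1:3, function(s) {
    e <- rand_expr(2000, 20, seed = s + 50)
    tab <- moderated_ttest(e, colnames(e)[1:10], colnames(e)[11:20])
    mean(tab$p < 0.05)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.05), 0.01)
})

test_that("planted fold changes are detected with high power", {
  set.seed(77)
  g <- 2000; n <- 40
  m <- matrix(rnorm(g * n, 8, 0.5), g, n,
              dimnames = list(sprintf("g%04d", 1:g), sprintf("s%02d", 1:n)))
  planted <- 1:100
  m[planted, 1:20] <- m[planted, 1:20] + 1   # 2-fold on log2 scale
  tab <- moderated_ttest(m, colnames(m)[1:20], colnames(m)[21:40])
  expect_gte(mean(tab$q[planted] < 0.05), 0.90)
  expect_lte(mean(tab$q[-planted] < 0.05), 0.05)
})

test_that("moderated t agrees closely with the limma oracle", {
  skip_if_not_installed("limma")
  e <- rand_expr(500, 16, seed = 9)
  grp <- rep(c(1, 0), each = 8)
  design <- cbind(Intercept = 1, grp = grp)
  fit <- limma::eBayes(limma::lmFit(unclass(e), design))
  mine <- moderated_ttest(e, colnames(e)[grp == 1], colnames(e)[grp == 0])
  expect_gt(cor(mine$t, fit$t[, "grp"]), 0.999)
  expect_equal(mine$log2fc, unname(fit$coefficients[, "grp"]),
               tolerance = 1e-8)
})

test_that("BH matches the exhaustive step-up oracle and p.adjust", {
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q >= p and step-up monotonicity hold on random vectors", {
  set.seed(13)
  tab <- moderated_ttest(rand_expr(300, 10, seed = 3),
                         sprintf("s%03d", 1:5), sprintf("s%03d", 6:10))
  expect_true(all(tab$q >= tab$p - 1e-12))
  o <- order(tab$p)
  expect_true(all(diff(tab$q[o]) >= -1e-12))
})

test_that("exact Wilcoxon enumerates rank splits", {
  res <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                       test = "wilcoxon")
  expect_equal(res$p, 0.1)      # 2 / choose(6,3) extreme splits
  expect_match(res$method, "exact")
  res2 <- group_compare(c(1, 2, 1, 2), c("a", "a", "b", "b"),
                        test = "wilcoxon")
  expect_equal(res2$p, 1)
  expect_warning(res3 <- group_compare(rep(3, 6), rep(c("a", "b"), 3),
                                       test = "wilcoxon"), "tied")
  expect_equal(res3$p, 1)
})

test_that("large-sample Wilcoxon approximates the exact path", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10) + 0.5
  exact <- metsubtype:::wilcoxon_ranksum(x, y, exact_max = 20)
  approx <- metsubtype:::wilcoxon_ranksum(x, y, exact_max = 5)
  expect_lt(abs(exact$p - approx$p), 0.05)
  expect_match(approx$method, "normal")
})

test_that("ANOVA p-values are uniform under a shared null", {
  ps <- vapply(1:200, function(s) {
    set.seed(s + 400)
    group_compare(rnorm(30), rep(c("a", "b", "c"), each = 10),
                  test = "anova")$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("contingency tests: chi-square and Fisher against enumeration", {
  res <- contingency_test(matrix(c(5, 5, 5, 5), 2), method = "chisq")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # Fisher p for [[1,9],[9,1]] by hypergeometric tail enumeration
  tab <- matrix(c(1, 9, 9, 1), 2)
  probs <- dhyper(0:10, 10, 10, 10)
  p_oracle <- sum(probs[probs <= dhyper(1, 10, 10, 10) + 1e-12])
  expect_equal(contingency_test(tab, method = "fisher")$p, p_oracle,
               tolerance = 1e-10)
  expect_lt(contingency_test(matrix(c(10, 0, 0, 10), 2),
                             method = "fisher")$p, 0.001)
  expect_warning(contingency_test(matrix(c(3, 4, 2, 5, 0, 0), 2),
                                  method = "fisher"), "2x2|zero-margin")
})

test_that("zero-margin rows are dropped with a warning", {
  m <- matrix(c(5, 0, 3, 2, 0, 4), 3, 2)
  expect_warning(res <- contingency_test(m, method = "chisq"),
                 "zero-margin")
  expect_true(is.finite(res$p))
})

test_that("cohort summary reproduces the printed-percentage arithmetic", {
  labels <- factor(rep(c("A", "B", "C", "D"), c(38, 19, 24, 45)))
  stage <- character(126)
  stage[labels == "A"] <- rep(c("I", "II", "III"), c(25, 8, 5))
  stage[labels == "B"] <- "I"
  stage[labels == "C"] <- "I"
  stage[labels == "D"] <- rep(c("I", "II", "III"), c(43, 1, 1))
  clin <- data.frame(stage = stage)
  tab <- cohort_summary(clin, labels)
  expect_match(tab[tab$variable == "n", "A"], "38 \\(30.2%\\)")
  stage1 <- tab[tab$variable == "stage" & tab$level == "I", ]
  expect_match(stage1$A, "25 \\(65.8%\\)")
  expect_match(stage1$Overall, "111 \\(88.1%\\)")
  expect_lt(tab$p[tab$variable == "stage" & tab$level == "I"], 0.001)
})

test_that("single-subtype summaries skip tests; NAs form a category", {
  clin <- data.frame(sex = c("F", "M", NA, "F"), age = c(60, 65, 70, NA))
  tab1 <- cohort_summary(clin, rep("A", 4))
  expect_true(all(is.na(tab1$p)))
  expect_match(tab1[tab1$level == "F", "Overall"], "2 \\(50.0%\\)")
  expect_true("NA" %in% tab1$level)
  tab2 <- cohort_summary(clin, c("A", "A", "B", "B"))
  expect_true(any(tab2$method == "fisher" | tab2$method == "chisq" |
                    tab2$method == "skipped"))
})
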