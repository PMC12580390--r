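test_that("contingency tables rebuild the printed response counts", {
  naic <- clinical_from_counts("NAIC", 16, 6, 4, 9)
  nac <- clinical_from_counts("NAC", 7, 17, 9, 36)
  all_pat <- dplyr::bind_rows(naic, nac)
  all_pat$MPRf <- factor(ifelse(all_pat$MPR, "Yes", "No"),
                         levels = c("Yes", "No"))

  tab <- build_contingency(all_pat, "MPRf", "histology")
  expect_equal(unclass(tab),
               matrix(c(23L, 23L, 13L, 45L), 2,
                      dimnames = list(c("Yes", "No"), c("SCC", "ADC"))))
  sub <- build_contingency(all_pat, "MPRf", "histology",
                           filter = list(arm = "NAIC"))
  expect_equal(as.vector(sub), c(16L, 6L, 4L, 9L))
  expect_error(build_contingency(all_pat, "MPRf", "histology",
                                 filter = list(arm = "nope")),
               "arm=nope")
})

test_that("chi-squared with Yates reproduces the reported response p-values", {
  expect_equal(round(chi2_test(matrix(c(23, 23, 13, 45), 2))$p, 3), 0.006)
  expect_equal(round(chi2_test(matrix(c(16, 4, 6, 9), 2))$p, 3), 0.038)
  expect_equal(round(chi2_test(matrix(c(23, 23, 22, 36), 2))$p, 3), 0.301)
  res <- chi2_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(chi2_test(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("chi-squared is transposition invariant and Yates never exceeds Pearson", {
  set.seed(409)
  for (rep in 1:25) {
    m <- matrix(rpois(4, 12) + 1L, 2)
    expect_equal(chi2_test(m)$p, chi2_test(t(m))$p)
    expect_lte(chi2_test(m, "on")$statistic, chi2_test(m, "off")$statistic)
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(round(fisher_exact_2x2(matrix(c(9, 2, 13, 11), 2))$p, 3), 0.150)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p, 1)
  set.seed(410)
  for (rep in 1:25) {
    m <- matrix(rpois(4, 6) + 1L, 2)
    p2 <- fisher_exact_2x2(m)$p
    expect_equal(p2, fisher_enum_oracle(m), tolerance = 1e-9)
    # two-sided p dominates either one-sided tail
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    lo <- stats::phyper(m[1, 1], r1, n - r1, c1)
    hi <- 1 - stats::phyper(m[1, 1] - 1, r1, n - r1, c1)
    expect_gte(p2 + 1e-12, min(lo, hi))
  }
})

test_that("test dispatch uses Fisher exactly when an expected count drops below 5", {
  expect_equal(dispatch_2x2_test(matrix(c(9, 2, 13, 11), 2))$method,
               "fisher_exact")
  expect_equal(dispatch_2x2_test(matrix(c(10, 3, 36, 55), 2))$method,
               "yates_chi2")  # min expected 5.75
})

test_that("exact Mann-Whitney equals full permutation enumeration", {
  set.seed(411)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:5, 1)
    if (rep %% 2 == 0) {
      # force ties by drawing from a tiny support
      x <- sample(1:4, n1, replace = TRUE)
      y <- sample(1:4, n2, replace = TRUE)
      if (length(unique(c(x, y))) == 1L) x[1] <- x[1] + 1
    } else {
      v <- sample(1:100, n1 + n2)
      x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    }
    expect_equal(mann_whitney(x, y, mode = "exact")$p, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(mann_whitney(c(1, 2), c(3, 4), mode = "exact")$p, 1 / 3,
               tolerance = 1e-12)
})

test_that("asymptotic Mann-Whitney uses the no-continuity-correction normal form", {
  x <- c(10, 9, 8, 7, 6, 5, 2); y <- c(4, 3, 2.5, 1)  # U = 3 on the min side
  res <- mann_whitney(x, y, mode = "asymptotic")
  expect_equal(res$p, 2 * pnorm(-11 / sqrt(28)), tolerance = 1e-12)
  expect_equal(round(res$p, 3), 0.038)
  # agrees with the reference implementation without continuity correction
  ref <- suppressWarnings(wilcox.test(x, y, correct = FALSE, exact = FALSE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # tie correction path
  set.seed(412)
  x2 <- sample(1:5, 12, TRUE); y2 <- sample(1:5, 9, TRUE)
  ref2 <- suppressWarnings(wilcox.test(x2, y2, correct = FALSE, exact = FALSE))
  expect_equal(mann_whitney(x2, y2, mode = "asymptotic")$p, ref2$p.value,
               tolerance = 1e-12)
})

test_that("degenerate and identical samples behave as documented", {
  expect_warning(res <- mann_whitney(c(3, 3), c(3, 3, 3)), "identical")
  expect_equal(res$p, 1)
  x <- c(1, 5, 7, 9)
  expect_equal(mann_whitney(x, x, mode = "exact")$p, 1)
})

test_that("auto mode dispatches on sample size", {
  expect_equal(mann_whitney(1:3, 4:6)$method, "mw_exact")
  expect_equal(mann_whitney(rnorm(10), rnorm(10))$method, "mw_asymptotic")
})

test_that("median and quartiles follow the configured convention", {
  expect_equal(unname(median_iqr(c(1, 2, 3, 4, 5))), c(3, 2, 4))
  expect_equal(unname(median_iqr(7)), c(7, 7, 7))
  expect_equal(unname(median_iqr(c(1, 2, 3, 4))), c(2.5, 1.75, 3.25))
  expect_equal(unname(median_iqr(c(1, 2, 3, 4), "haverage")),
               c(2.5, 1.25, 3.75))
})

test_that("dichotomization splits at the median with ties going high", {
  f <- dichotomize(c(1, 2, 3, 4))
  expect_equal(as.character(f), c("low", "low", "high", "high"))
  f5 <- dichotomize(c(1, 2, 3, 4, 5))
  expect_equal(as.character(f5), c("low", "low", "high", "high", "high"))
  expect_error(dichotomize(c(5, 5, 5)), "median split impossible")
  ft <- dichotomize(c(1, 9, 10), rule = 5)
  expect_equal(as.character(ft), c("low", "high", "high"))
  expect_equal(attr(ft, "cut"), 5)
})

test_that("univariate odds ratios use the cross product and Wald interval", {
  res <- or_from_2x2(6, 1, 1, 6)
  expect_equal(res$or, 36)
  se <- sqrt(1 / 6 + 1 + 1 + 1 / 6)
  expect_equal(res$ci_lower, exp(log(36) - qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(res$ci_upper, exp(log(36) + qnorm(0.975) * se), tolerance = 1e-9)
  expect_false(res$corrected)

  bal <- or_from_2x2(5, 5, 5, 5)
  expect_equal(bal$or, 1)
  expect_true(bal$ci_lower < 1 && bal$ci_upper > 1)

  zero <- or_from_2x2(0, 5, 5, 5)
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or) && zero$or > 0)

  pred <- factor(rep(c("low", "high"), c(7, 7)), levels = c("low", "high"))
  out <- c(rep(TRUE, 6), FALSE, TRUE, rep(FALSE, 6))
  expect_equal(univariate_or(pred, out)$or, 36)
  expect_error(univariate_or(pred, rep(TRUE, 14)), "constant")
})

test_that("the constructed 7-vs-4 ordering yields the reported ROC triple", {
  scores <- c(10, 9, 8, 7, 6, 5, 2, 4, 3, 2.5, 1)
  labels <- rep(c(TRUE, FALSE), c(7, 4))
  rr <- roc_curve(scores, labels)
  expect_equal(rr$auc, 25 / 28, tolerance = 1e-12)
  expect_equal(rr$sensitivity, 6 / 7, tolerance = 1e-12)
  expect_equal(rr$specificity, 1)
  expect_false(rr$flipped)
  # the same ordering carries the rank-test signal reported alongside
  expect_equal(round(mann_whitney(scores[1:7], scores[8:11],
                                  mode = "asymptotic")$p, 3), 0.038)
})

test_that("ROC handles separation, pure ties, and orientation", {
  sep <- roc_curve(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  tied <- roc_curve(rep(2, 6), rep(c(TRUE, FALSE), each = 3))
  expect_equal(tied$auc, 0.5)

  flip <- roc_curve(c(-5, -6, -7, -1, -2, -3), rep(c(TRUE, FALSE), each = 3))
  expect_true(flip$flipped)
  expect_equal(flip$auc, 1)

  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoidal AUC equals the U statistic and is transform invariant", {
  set.seed(413)
  for (rep in 1:25) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    scores <- c(rnorm(n1, 1), rnorm(n2))
    if (rep %% 3 == 0) scores <- round(scores)  # induce ties
    labels <- rep(c(TRUE, FALSE), c(n1, n2))
    rr <- roc_curve(scores, labels)
    # U-statistic identity on the oriented scores
    s <- if (rr$flipped) -scores else scores
    u <- mann_whitney(s[labels], s[!labels])$statistic
    expect_equal(rr$auc, u / (n1 * n2), tolerance = 1e-12)
    # complement identity: negating scores flips orientation, same AUC
    rr_neg <- roc_curve(-scores, labels)
    expect_equal(rr_neg$auc, rr$auc, tolerance = 1e-12)
    if (rr$auc > 0.5) expect_equal(rr_neg$flipped, !rr$flipped)
    # invariance under strictly increasing transforms
    rr_t <- roc_curve(exp(scores / 3), labels)
    expect_equal(rr_t$auc, rr$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(414)
  for (rep in 1:10) {
    scores <- round(rnorm(30), 1)
    labels <- rep(c(TRUE, FALSE), 15)
    rr <- roc_curve(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(max(rr$auc, 1 - rr$auc), max(ref, 1 - ref),
                 tolerance = 1e-12)
  }
})

test_that("group comparison table carries summaries and rank-test p-values", {
  d <- tibble::tibble(
    grp = rep(c("MPR", "NMPR"), c(7, 4)),
    nnd = c(10, 9, 8, 7, 6, 5, 2, 4, 3, 2.5, 1)
  )
  out <- compare_groups(d, "nnd", "grp", mode = "asymptotic")
  expect_equal(names(out)[2:3], c("MPR", "NMPR"))
  expect_equal(round(out$p, 3), 0.038)
  expect_match(out$MPR, "^7\\.0 \\(5\\.5, 8\\.5\\)$")
})

test_that("response tables dispatch the printed tests per outcome", {
  naic <- clinical_from_counts("NAIC", 16, 6, 4, 9)
  nac <- clinical_from_counts("NAC", 7, 17, 9, 36)
  all_pat <- dplyr::bind_rows(naic, nac)
  all_pat$ORR <- FALSE; all_pat$pCR <- FALSE
  rt <- response_table(all_pat, "MPR", "histology")
  expect_equal(unique(rt$method), "yates_chi2")
  expect_equal(round(rt$p[1], 3), 0.006)
  expect_match(rt$SCC[rt$level == "Yes"], "23 \\(50\\.0%\\)")
})
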