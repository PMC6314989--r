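test_that("coefficient of variation: hand values, scale invariance, errors", {
  expect_equal(cvValue(c(2, 2, 2)), 0)
  expect_equal(cvValue(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  set.seed(5)
  v <- rexp(40) + 0.1
  expect_equal(cvValue(v * 17), cvValue(v), tolerance = 1e-12)
  expect_error(cvValue(c(1)), "at least 2")
  expect_error(cvValue(c(-1, 1)), "zero mean")
  expect_error(cvValue(c(1, NA)), "NA")
})

test_that("variance-ratio test: identity, symmetry, and recovery of a known ratio", {
  a <- c(1, 2, 3, 4, 5)
  r <- varianceRatioTest(a, a)
  expect_equal(r$F, 1)
  expect_equal(r$p, 1)

  set.seed(8)
  x <- rnorm(60, sd = 2); y <- rnorm(60, sd = 1)
  fw <- varianceRatioTest(x, y)
  bw <- varianceRatioTest(y, x)
  expect_equal(fw$F, 1 / bw$F, tolerance = 1e-12)
  expect_equal(fw$p, bw$p, tolerance = 1e-12)
  expect_gt(fw$F, 2)   # true ratio 4, loose sampling band
  expect_lt(fw$F, 8)
  expect_lt(fw$p, 0.01)
  expect_error(varianceRatioTest(c(1, 1, 1), x), "zero variance")
})

test_that("ROC analysis: AUC equals the Mann-Whitney statistic (oracle)", {
  set.seed(31)
  for (rep in 1:8) {
    nPos <- sample(10:25, 1); nNeg <- sample(10:25, 1)
    vals <- c(rnorm(nPos, 1.0, 0.6), rnorm(nNeg, 2.6, 0.6))
    labs <- c(rep("abnormal", nPos), rep("normal", nNeg))
    roc <- rocAnalysis(vals, labs, positive = "abnormal")
    # low SBR = positive: AUC = P(abnormal < normal) = U / (n1 n2)
    u <- unname(wilcox.test(vals[labs == "normal"],
                            vals[labs == "abnormal"])$statistic)
    expect_equal(roc@auc, u / (nPos * nNeg), tolerance = 1e-12)
  }
})

test_that("ROC analysis: separation, chance level, cutoff accuracy, errors", {
  vals <- c(0.4, 0.7, 1.1, 2.6, 2.9, 3.3)
  labs <- rep(c("abnormal", "normal"), each = 3)
  roc <- rocAnalysis(vals, labs, positive = "abnormal")
  expect_equal(roc@auc, 1.0)
  expect_equal(roc@accuracy, 1.0)
  expect_gt(roc@cutoff, 1.1); expect_lt(roc@cutoff, 2.6)

  set.seed(17)
  vals2 <- rnorm(400)
  labs2 <- sample(rep(c("abnormal", "normal"), 200))
  roc2 <- rocAnalysis(vals2, labs2, positive = "abnormal")
  expect_lt(abs(roc2@auc - 0.5), 0.08)

  expect_equal(accuracyAtCutoff(vals, labs, "abnormal", cutoff = 2.0), 1.0)
  expect_equal(accuracyAtCutoff(vals, labs, "abnormal", cutoff = 0.5), 4 / 6)
  expect_error(rocAnalysis(vals, rep("abnormal", 6), "abnormal"), "both classes")
})

test_that("higher_is_positive direction mirrors the default", {
  vals <- c(0.4, 0.7, 1.1, 2.6, 2.9, 3.3)
  labs <- rep(c("low", "high"), each = 3)
  roc <- rocAnalysis(vals, labs, positive = "high", direction = "higher_is_positive")
  expect_equal(roc@auc, 1.0)
  expect_equal(roc@accuracy, 1.0)
})

test_that("method agreement: exact line, simulation direction, degenerate input", {
  x <- c(0.5, 1, 1.5, 2, 3)
  fit <- methodAgreement(x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_error(methodAgreement(x, rep(1, 5)), "zero variance")
  expect_error(methodAgreement(x, c(1, 2)), "unpaired")
  expect_error(methodAgreement(c(1, 2), c(1, 2)), "at least 3")
})

test_that("bootstrap AUC difference test returns sane values", {
  set.seed(23)
  labs <- rep(c("abnormal", "normal"), each = 15)
  good <- c(rnorm(15, 1), rnorm(15, 3))     # strong marker
  weak <- c(rnorm(15, 1.8), rnorm(15, 2.2)) # weak marker
  out <- aucDiffTest(good, weak, labs, positive = "abnormal", nBoot = 100)
  expect_gt(out$aucX, out$aucY)
  expect_true(out$p >= 0 && out$p <= 1)
})

test_that("cohort tables are validated", {
  df <- data.frame(subject_id = c("a", "b", "c", "d"),
                   group = rep(c("abnormal", "normal"), 2),
                   method = "count_based", side = "right",
                   sbr = c(0.5, 3, 0.9, 2.8))
  expect_invisible(validateCohort(df))
  expect_error(validateCohort(df[, -5]), "missing columns")
  bad <- df; bad$sbr[1] <- NA
  expect_error(validateCohort(bad), "NA")
})
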