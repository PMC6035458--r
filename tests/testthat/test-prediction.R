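test_that("SMOTE interpolates along minority segments", {
  # two points, k = 1: every synthetic point on the segment [a, b]
  ab <- rbind(a = c(0, 0), b = c(2, 4))
  syn <- smote(ab, k = 1, n_synthetic = 40, seed = 1)
  t <- syn[, 1] / 2
  expect_true(all(t >= 0 & t <= 1))
  expect_equal(syn[, 2], 4 * t, tolerance = 1e-12)

  # synthetic points stay inside the minority bounding box (convex hull
  # of segment interpolation)
  minority <- withr::with_seed(2, matrix(rnorm(24), 8, 3))
  syn2 <- smote(minority, k = 3, n_synthetic = 100, seed = 3)
  for (j in 1:3) {
    expect_true(all(syn2[, j] >= min(minority[, j]) - 1e-12))
    expect_true(all(syn2[, j] <= max(minority[, j]) + 1e-12))
  }
  expect_error(smote(minority[1, , drop = FALSE], 1, 5, 1), "at least 2")

  # balancing equalises class counts for arbitrary imbalance
  for (n1 in c(3, 7, 12)) {
    X <- withr::with_seed(n1, matrix(rnorm((n1 + 25) * 4), n1 + 25, 4))
    y <- rep(c(1, 0), c(n1, 25))
    bal <- rsdmtox:::smote_balance(X, y, k = 5, seed = 4)
    expect_equal(sum(bal$y == 1), sum(bal$y == 0))
    # originals untouched at the head
    expect_equal(bal$X[seq_along(y), ], X)
  }
})

test_that("AUC and ROC agree with each other and the pairwise oracle", {
  expect_equal(auc(1:10, rep(c(0, 1), each = 5)), 1)
  expect_equal(auc(10:1, rep(c(0, 1), each = 5)), 0)
  for (s in 1:10) {
    sc <- withr::with_seed(s, round(rnorm(30), 1))  # ties likely
    y <- withr::with_seed(50 + s, rbinom(30, 1, 0.4))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    a <- auc(sc, y)
    expect_equal(a, oracle_auc(sc, y), tolerance = 1e-12)
    roc <- roc_curve(sc, y)
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                   utils::tail(roc$tpr, -1)) / 2)
    expect_equal(a, trap, tolerance = 1e-12)
  }
  # invariant under monotone transform of scores
  sc <- withr::with_seed(7, rnorm(40))
  y <- rep(c(0, 1), 20)
  expect_equal(auc(sc, y), auc(exp(sc), y), tolerance = 1e-12)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("confusion metrics follow the exact formulas", {
  expect_equal(unname(suppressWarnings(confusion_metrics(3, 0, 0, 1))["SEN"]),
               0.75)
  expect_equal(unname(confusion_metrics(5, 5, 0, 0)["ACC"]), 1)
  expect_equal(unname(confusion_metrics(2, 2, 2, 2)["ACC"]), 0.5)
  expect_warning(out <- confusion_metrics(0, 3, 1, 0), "denominator")
  expect_true(is.na(out["SEN"]))
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("the SVM separates constructed data and is deterministic", {
  X <- rbind(withr::with_seed(1, matrix(rnorm(40, -1.5), 20, 2)),
             withr::with_seed(2, matrix(rnorm(40, 1.5), 20, 2)))
  y <- rep(c(0, 1), each = 20)
  m1 <- svm_fit(X, y)
  m2 <- svm_fit(X, y)
  expect_identical(m1$alpha, m2$alpha)
  s <- svm_decision(m1, X)
  expect_gt(auc(s, y), 0.95)
})

test_that("SFS picks the informative feature first", {
  config <- cv_config(repeats = 1, seed = 5)
  hits <- 0
  for (s in 1:10) {
    X <- withr::with_seed(s, matrix(rnorm(40 * 6), 40, 6))
    y <- rep(c(0, 1), each = 20)
    X[, 4] <- X[, 4] + 3 * y  # feature 4 separates perfectly
    fit <- svm_sfs(X, y, config, seed = s)
    hits <- hits + (fit$selected[1] == 4L)
    # accepted criterion sequence is non-decreasing
    expect_true(all(diff(fit$criterion) > 0))
  }
  expect_gte(hits, 9)
  # a single available feature is returned
  one <- svm_sfs(matrix(rnorm(20), 20, 1), rep(c(0, 1), 10),
                 cv_config(repeats = 1, seed = 1), seed = 2)
  expect_equal(one$selected, 1L)
})

test_that("repeated_cv is deterministic and leak-free by construction", {
  sc <- small_cohort_features()
  scr <- mwu_screen(sc$table)
  tab <- screened_table(sc$table, scr)
  config <- cv_config(repeats = 2, sfs_max = 3, seed = 17)
  r1 <- repeated_cv(tab, config = config)
  r2 <- repeated_cv(tab, config = config)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_identical(r1$ranking, r2$ranking)
  expect_false(identical(
    r1$per_repeat$AUC,
    repeated_cv(tab, config = cv_config(repeats = 2, sfs_max = 3,
                                        seed = 18))$per_repeat$AUC))
  # every validation instance scored exactly once per repeat
  expect_true(all(vapply(r1$pooled, function(p) {
    length(p$scores) == nrow(tab$features)
  }, logical(1))))
  expect_true(all(r1$per_repeat$AUC >= 0 & r1$per_repeat$AUC <= 1))
  expect_true(all(r1$ranking$frequency >= 0 & r1$ranking$frequency <= 1))
})

test_that("DeLong comparison: identical scores give z = 0, p = 1", {
  sc <- withr::with_seed(3, rnorm(50))
  y <- rep(c(0, 1), 25)
  out <- compare_rocs(sc, sc, y)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
  expect_error(compare_rocs(sc, sc[-1], y), "paired")
})

test_that("DeLong z agrees with a bootstrap AUC-difference distribution", {
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  a <- withr::with_seed(11, rnorm(n, mean = y * 1.2))
  b <- withr::with_seed(12, rnorm(n, mean = y * 0.4))
  out <- compare_rocs(a, b, y)
  boots <- withr::with_seed(13, vapply(1:2000, function(i) {
    idx <- sample.int(n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample.int(n, replace = TRUE)
    auc(a[idx], y[idx]) - auc(b[idx], y[idx])
  }, numeric(1)))
  z_boot <- (out$auc_a - out$auc_b) / stats::sd(boots)
  expect_equal(out$z, z_boot, tolerance = 0.1)
})

test_that("bonferroni is the clamped product", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(c(0.5, 0.9), m = 4), c(1, 1))
  expect_equal(bonferroni(c(0.01, 0.4)), c(0.02, 0.8))
})
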