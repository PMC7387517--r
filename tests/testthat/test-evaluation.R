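test_that("pearson correlation matches closed-form cases and errors on degenerate input", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "fmikeys_validation_error")
  expect_error(pearson_correlation(1:2, 1:2), class = "fmikeys_validation_error")
})

test_that("AUC equals the pairwise concordance probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # 3 of 4 pairs concordant, by hand
  expect_equal(roc_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "fmikeys_validation_error")

  withr::local_seed(11)
  for (i in 1:60) {
    n <- sample(6:25, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding plants ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC is antisymmetric under label flips and invariant to monotone transforms", {
  withr::local_seed(12)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)
    a <- roc_auc(scores, labels)$auc
    expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - a)
    expect_equal(roc_auc(exp(3 * scores), labels)$auc, a)
    expect_equal(roc_auc(rank(scores, ties.method = "average"), labels)$auc, a)
  }
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(13)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(28, 1, 0.4))
    scores <- round(rnorm(30), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref)
  }
})

test_that("bootstrap CIs are seeded, ordered and inside [0, 1]", {
  withr::local_seed(14)
  scores <- c(rnorm(50, 1), rnorm(50))
  labels <- rep(c(1, 0), each = 50)
  ci1 <- bootstrap_auc_ci(scores, labels, n_bootstrap = 300, seed = 2)
  ci2 <- bootstrap_auc_ci(scores, labels, n_bootstrap = 300, seed = 2)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  for (i in 1:50) {
    sc <- rnorm(14)
    lb <- c(0, 1, rbinom(12, 1, 0.5))
    ci <- bootstrap_auc_ci(sc, lb, n_bootstrap = 50, seed = i)
    expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= ci[2])
  }
  # perfectly separated, decently sized: a tight interval at the top
  ci <- bootstrap_auc_ci(c(rnorm(50) + 10, rnorm(50)), rep(c(1, 0), each = 50),
                         n_bootstrap = 300, seed = 3)
  expect_gt(ci[1], 0.95)
  expect_equal(ci[2], 1)
})

test_that("sensitivity at fixed specificity matches exhaustive enumeration", {
  s <- sensitivity_at_specificity(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0),
                                  n_bootstrap = 20, seed = 1)
  expect_equal(s$sensitivity, rep(1, 3))

  scores <- c(0.9, 0.7, 0.4, 0.6, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0, 0)
  s2 <- sensitivity_at_specificity(scores, labels, n_bootstrap = 20, seed = 1)
  for (i in seq_len(nrow(s2))) {
    o <- oracle_sens_at_spec(scores, labels, s2$specificity_target[i])
    expect_equal(s2$sensitivity[i], o$sens)
    expect_equal(s2$specificity[i], o$spec)
  }
  # non-increasing in the target, on random datasets
  withr::local_seed(15)
  for (i in 1:30) {
    sc <- rnorm(20)
    lb <- c(0, 1, rbinom(18, 1, 0.5))
    st <- sensitivity_at_specificity(sc, lb, n_bootstrap = 10, seed = i)
    att <- st$sensitivity[st$attained]
    expect_true(all(diff(att) <= 1e-12))
    # attainability itself is monotone: a harder target is never attainable
    # when an easier one is not
    expect_true(all(diff(st$attained) <= 0))
  }
  # unattainable target flagged, not thrown
  s3 <- sensitivity_at_specificity(c(1, 1), c(1, 0), targets = 0.9,
                                   n_bootstrap = 10, seed = 1)
  expect_false(s3$attained)
  expect_true(is.na(s3$sensitivity))
})

test_that("scenario reports select the right populations and columns", {
  man <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:39),
    group = rep(c("PD", "HC"), c(22, 17)),
    age = 60, sex = 1,
    updrs_22 = c(round(runif(22, 1, 4)), rep(0, 17)),
    updrs_23 = c(round(runif(22, 1, 4)), rep(0, 17)),
    updrs_31 = c(round(runif(22, 1, 4)), rep(0, 17)),
    de_novo = c(rep(1, 9), rep(0, 13), rep(0, 17))
  )
  withr::local_seed(16)
  idx <- tibble::tibble(
    subject_id = man$subject_id,
    n_valid_sessions = 10L,
    dRSi = man$updrs_22 + rnorm(39, 0, 0.3),
    dAFSi = man$updrs_23 + rnorm(39, 0, 0.3),
    dBSi = man$updrs_31 + rnorm(39, 0, 0.3)
  )
  t1 <- scenario_report(idx, man, "T1", n_bootstrap = 50, seed = 1)
  expect_equal(t1$n_subjects, 39)
  expect_equal(nrow(t1$correlations), 3)
  expect_true(all(t1$correlations$r > 0.8))

  # de novo screening population: 9 drug-naive PD + all 17 HC
  t2 <- scenario_report(idx, man, "T2", n_bootstrap = 50, seed = 1)
  expect_equal(t2$n_subjects, 26)
  expect_equal(t2$n_pos, 9)

  # self-report equal to the clinical label gives identical AUCs to T1
  t3 <- scenario_report(idx, man, "T3", n_bootstrap = 50, seed = 1)
  for (nm in names(t3$roc)) {
    expect_equal(t3$roc[[nm]]$auc, t1$roc[[nm]]$auc)
  }

  expect_error(scenario_report(idx, man[, c("subject_id", "group")], "T1"),
               regexp = "updrs_22", class = "fmikeys_validation_error")
  expect_error(
    scenario_report(idx, man[, setdiff(names(man), "de_novo")], "T2"),
    regexp = "de_novo", class = "fmikeys_validation_error"
  )
  td <- tidy(t1)
  expect_equal(nrow(td), 3)
  expect_true(all(c("auc", "ci_low", "ci_high", "r") %in% names(td)))
})
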