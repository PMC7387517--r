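test_that("LOSO produces one fold per subject with disjoint training sets", {
  fx <- fixture_pipeline()
  lo <- finetune_loso(fx$inputs, fx$cohort$subjects, fx$encoder,
                      finetune_config(22, epochs = 4, seed = 3))
  n_subj <- length(unique(fx$inputs$subject_id))
  expect_equal(nrow(lo$folds), n_subj)
  expect_setequal(lo$folds$held_out, unique(fx$inputs$subject_id))
  # each prediction comes from the fold that held its subject out
  expect_true(all(lo$predictions$subject_id ==
                    lo$folds$held_out[lo$predictions$fold]))
  # fold training sizes exclude exactly the held-out subject's inputs
  per_subj <- table(fx$inputs$subject_id)
  expect_equal(lo$folds$n_train,
               nrow(fx$inputs) - as.integer(per_subj[lo$folds$held_out]))
  expect_equal(lo$folds$n_test, as.integer(per_subj[lo$folds$held_out]))
  # every input predicted exactly once
  expect_equal(nrow(lo$predictions), nrow(fx$inputs))
})

test_that("LOSO excludes unlabelled subjects with a warning and is deterministic", {
  fx <- fixture_pipeline()
  man <- fx$cohort$subjects
  man$updrs_22[1] <- NA
  expect_warning(
    lo <- finetune_loso(fx$inputs, man, fx$encoder,
                        finetune_config(22, epochs = 2, seed = 3)),
    regexp = man$subject_id[1]
  )
  expect_false(man$subject_id[1] %in% lo$predictions$subject_id)

  l1 <- finetune_loso(fx$inputs, fx$cohort$subjects, fx$encoder,
                      finetune_config(23, epochs = 2, seed = 4))
  l2 <- finetune_loso(fx$inputs, fx$cohort$subjects, fx$encoder,
                      finetune_config(23, epochs = 2, seed = 4))
  expect_identical(l1$predictions, l2$predictions)
})

test_that("subject aggregation follows the clinic-mean and wild-quartile rules", {
  expect_equal(aggregate_subject_clinic(c(1, 2, 3)), 2)
  expect_equal(aggregate_subject_clinic(5), 5)
  withr::local_seed(6)
  x <- rnorm(100)
  expect_equal(aggregate_subject_clinic(x), sum(x) / 100)

  w <- aggregate_subject_wild(c(1, 2, 3, 4))
  expect_equal(c(w$q25, w$q50, w$q75), c(1.75, 2.5, 3.25))
  expect_equal(w$index, 2.5)
  wc <- aggregate_subject_wild(rep(7, 5))
  expect_equal(c(wc$q25, wc$q50, wc$q75, wc$index), rep(7, 4))
  # quartile ordering on random lists
  for (i in 1:200) {
    q <- aggregate_subject_wild(rnorm(sample(1:30, 1)))
    expect_true(q$q25 <= q$q50 && q$q50 <= q$q75)
  }
  expect_error(aggregate_subject_clinic(numeric(0)),
               class = "fmikeys_validation_error")
  expect_error(aggregate_subject_wild(numeric(0)),
               class = "fmikeys_validation_error")
})

test_that("index computation aggregates sessions and shifts equivariantly", {
  preds <- function(offset = 0) {
    tibble::tibble(
      subject_id = rep(c("a", "b"), each = 6),
      session_id = rep(sprintf("s%d", 1:6), 2),
      prediction = c(rep(1.5, 6), 2:7) + offset
    )
  }
  pl <- list(`22` = preds(), `23` = preds(), `31` = preds())
  idx <- compute_indices(pl, mode = "wild")
  expect_equal(nrow(idx), 2)
  # constant sessions: index equals the single-session prediction
  expect_equal(idx$dRSi[idx$subject_id == "a"], 1.5)
  expect_equal(idx$n_valid_sessions, c(6L, 6L))

  # clinic mode = mean of sessions
  idxc <- compute_indices(pl, mode = "clinic")
  expect_equal(idxc$dBSi[idxc$subject_id == "b"], mean(2:7))

  # adding a constant shifts every index by exactly that constant
  pl2 <- list(`22` = preds(10), `23` = preds(10), `31` = preds(10))
  idx2 <- compute_indices(pl2, mode = "wild")
  for (col in c("dRSi", "dAFSi", "dBSi", "q25_dRSi", "q75_dBSi")) {
    expect_equal(idx2[[col]], idx[[col]] + 10)
  }
  idx2c <- compute_indices(pl2, mode = "clinic")
  expect_equal(idx2c$dRSi, idxc$dRSi + 10)

  # per-session provenance is retained
  se <- session_estimates(idx)
  expect_equal(nrow(se), 2 * 6 * 3)
})

test_that("multi-seed summaries match independent mean/variance computation", {
  runs <- data.frame(seed = 1:5, r = c(0.5, 0.6, 0.7, 0.8, 0.9))
  s <- multi_seed_summary(runs)
  expect_equal(s$mean, 0.7)
  # two-pass variance oracle
  m <- sum(runs$r) / 5
  expect_equal(s$sd, sqrt(sum((runs$r - m)^2) / 4))
  same <- multi_seed_summary(data.frame(seed = 1:3, auc = rep(0.8, 3)))
  expect_equal(same$sd, 0)
  expect_error(multi_seed_summary(data.frame(seed = 1, r = 0.5)),
               class = "fmikeys_validation_error")
})

test_that("full-cohort hybrid fits predict on new inputs and print sensibly", {
  fx <- fixture_pipeline()
  p <- predict(fx$model31, fx$inputs[1:10, ])
  expect_equal(nrow(p), 10)
  expect_true(all(is.finite(p$prediction)))
  expect_output(print(fx$model31), "dBSi")
  expect_output(print(fx$encoder), "bottleneck")
})
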