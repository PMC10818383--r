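test_that("balanced accuracy is mean per-class recall", {
  expect_equal(balanced_accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  # constant prediction on balanced 2-class truth scores chance
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(0, 0, 0, 0)), 0.5)
  expect_equal(balanced_accuracy(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 2)),
               (0.5 + 1 + 1) / 3)
  expect_error(balanced_accuracy(integer(0), integer(0)))
})

test_that("balanced accuracy equals the brute-force oracle", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    k <- sample(2:4, 1)
    y <- sample(0:(k - 1), n, replace = TRUE)
    p <- sample(0:(k - 1), n, replace = TRUE)
    expect_equal(balanced_accuracy(y, p), oracle_balanced_accuracy(y, p),
                 tolerance = 1e-15)
  }
})

test_that("LOSO produces one leak-free fold per subject", {
  fx <- separable_features(n_subjects = 5, seed = 20)
  res <- loso_cross_validate(fx$x, fx$labels, fx$subjects, "RF", seed = 2)
  expect_equal(nrow(res$folds), 5)
  expect_setequal(res$folds$subject_id, unique(fx$subjects))
  # every fold's predictions belong to the held-out subject only
  expect_equal(sum(res$folds$n_test), length(fx$labels))
  # no leakage: scrambling the held-out subject's labels does not change
  # the model's predictions on that subject
  y2 <- fx$labels
  idx <- fx$subjects == "S1"
  set.seed(21)
  y2[idx] <- sample(y2[idx])
  res2 <- loso_cross_validate(fx$x, y2, fx$subjects, "RF", seed = 2)
  expect_identical(res$folds$predictions[[1]]$pred,
                   res2$folds$predictions[[1]]$pred)
})

test_that("every family separates a high-margin synthetic problem", {
  fx <- separable_features(n_subjects = 4, n_classes = 3, seed = 22)
  for (fam in c("RF", "SVM", "LDA")) {
    res <- loso_cross_validate(fx$x, fx$labels, fx$subjects, fam, seed = 3)
    expect_true(all(res$folds$balanced_accuracy == 1),
                label = paste(fam, "fold accuracies"))
  }
})

test_that("permuted labels score at chance level", {
  fx <- separable_features(n_subjects = 4, events_per_subject = 25,
                           seed = 23)
  set.seed(24)
  bas <- replicate(20, {
    y <- sample(fx$labels) # break the feature-label link
    res <- loso_cross_validate(fx$x, y, fx$subjects, "RF", seed = 4)
    mean(res$folds$balanced_accuracy)
  })
  # mean of fold-mean balanced accuracies within 3 sigma of chance
  expect_lt(abs(mean(bas) - 0.5), 3 * sd(bas) / sqrt(length(bas)) + 0.02)
})

test_that("the random search returns the argmax of its sampled settings", {
  fx <- separable_features(n_subjects = 4, seed = 25)
  tuned <- tune_hyperparameters(fx$x, fx$labels, fx$subjects, "RF",
                                n_iter = 5, seed = 9)
  expect_equal(nrow(tuned$scores), 5)
  expect_equal(tuned$params$score, max(tuned$scores$score))
  # n_iter = 1 returns the single sampled setting
  one <- tune_hyperparameters(fx$x, fx$labels, fx$subjects, "SVM",
                              n_iter = 1, seed = 9)
  expect_equal(nrow(one$scores), 1)
  # reproducible under the seed
  again <- tune_hyperparameters(fx$x, fx$labels, fx$subjects, "RF",
                                n_iter = 5, seed = 9)
  expect_identical(tuned$params, again$params)
  expect_error(tune_hyperparameters(fx$x, fx$labels, fx$subjects, "RF",
                                    n_iter = 0))
})

test_that("summaries conserve events and normalize rows", {
  fx <- separable_features(n_subjects = 4, seed = 26)
  res <- loso_cross_validate(fx$x, fx$labels, fx$subjects, "RF", seed = 5)
  cm <- confusion_matrices(res)
  expect_equal(sum(cm$summed), length(fx$labels))
  expect_equal(unname(rowSums(cm$row_ratio)), rep(1, nrow(cm$summed)),
               tolerance = 1e-12)
  g <- glance(res)
  expect_equal(g$mean_balanced_accuracy,
               mean(res$folds$balanced_accuracy))
  td <- tidy(res)
  expect_equal(nrow(td), 4)
  # single-fold summary: mean is the fold value, spread zero
  one <- res
  one$folds <- one$folds[1, ]
  g1 <- glance(one)
  expect_equal(g1$mean_balanced_accuracy, res$folds$balanced_accuracy[1])
  expect_equal(g1$sd_balanced_accuracy, 0)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("observation features outperform sensor-less prediction", {
  tabs <- small_tables()
  obs <- run_experiment(tabs$features, "ALL", "SET-OBSERVE", 3, "RF",
                        seed = 6)
  prd <- run_experiment(tabs$features, "ALL", "SET-PREDICT", 3, "RF",
                        seed = 6)
  expect_gte(glance(obs)$mean_balanced_accuracy,
             glance(prd)$mean_balanced_accuracy - 0.02)
})
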