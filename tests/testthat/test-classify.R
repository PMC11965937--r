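test_that("accuracy follows the confusion-count formula", {
  expect_equal(accuracy_from_counts(3, 5, 1, 1), 0.8)
  expect_equal(accuracy_from_counts(0, 10, 0, 0), 1.0)
  expect_equal(accuracy_from_counts(0, 0, 4, 6), 0.0)
  expect_error(accuracy_from_counts(0, 0, 0, 0), "no evaluated")
})

sep_data <- function(n = 40, seed = 61) {
  set.seed(seed)
  X <- matrix(c(stats::rnorm(n / 2, -5), stats::rnorm(n / 2, 5)), ncol = 1)
  y <- rep(c("easy", "difficult"), each = n / 2)
  list(X = X, y = y)
}

test_that("all three classifiers separate separable clusters and are seeded", {
  d <- sep_data()
  for (kind in c("svm", "knn", "ann")) {
    m <- fit_classifier(d$X, d$y, kind, seed = 3)
    pred <- predict(m, d$X)
    expect_identical(as.character(pred), d$y)
    m2 <- fit_classifier(d$X, d$y, kind, seed = 3)
    expect_identical(as.character(predict(m2, d$X)), as.character(pred))
  }
  expect_error(fit_classifier(d$X, rep("easy", 40), "svm"), "single class")
})

test_that("predicted accuracy equals the direct fraction of correct labels", {
  d <- sep_data(60, 62)
  m <- fit_classifier(d$X, d$y, "knn")
  pred <- predict(m, d$X)
  cc <- emgfatigue:::confusion_counts(d$y, pred)
  expect_equal(unname(accuracy_from_counts(cc["TP"], cc["TN"], cc["FP"],
                                           cc["FN"])),
               mean(as.character(pred) == d$y))
})

test_that("stratified folds balance sizes; grouped folds keep subjects whole", {
  study <- fixture_study()
  wide <- feature_table_wide(study$table, 2)

  rep_s <- cross_validate(wide, "stratified-window", 5, "knn", seed = 8)
  sizes <- table(rep_s$fold_assignment)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(rep_s$counts), nrow(wide))

  rep_g <- cross_validate(wide, "grouped-by-subject", 3, "knn", seed = 8)
  split_count <- tapply(rep_g$fold_assignment, wide$subject,
                        function(f) length(unique(f)))
  expect_true(all(split_count == 1))
  expect_equal(sum(rep_g$counts), nrow(wide))

  expect_error(cross_validate(wide, "grouped-by-subject", 10, "knn"),
               "fewer subjects")
})

test_that("cross-validation separates fatigue states on synthetic features", {
  study <- fixture_study()
  wide <- feature_table_wide(study$table, 4)
  rep_ <- cross_validate(wide, "stratified-window", 5, "svm", seed = 5)
  expect_gte(rep_$mean_accuracy, 0.9)
  rep2 <- cross_validate(wide, "stratified-window", 5, "svm", seed = 5)
  expect_identical(rep_$folds, rep2$folds)
})

test_that("label permutation drops accuracy to chance", {
  study <- fixture_study()
  wide <- feature_table_wide(study$table, 2)
  accs <- vapply(1:8, function(s) {
    wp <- wide
    set.seed(s)
    wp$label <- sample(wp$label)
    cross_validate(wp, "stratified-window", 5, "svm", seed = s)$mean_accuracy
  }, numeric(1))
  expect_lt(mean(accs), 0.65)
  expect_gt(mean(accs), 0.35)
})

test_that("the IMF sweep returns one accuracy per mode count", {
  study <- fixture_study()
  sw <- imf_sweep(study$table, "svm", max_k = 3, representation = "features",
                  seed = 4)
  expect_identical(sw$n_imfs, 1:3)
  expect_true(all(sw$accuracy_features >= 0 & sw$accuracy_features <= 1))
})
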