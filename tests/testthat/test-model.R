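# Small separable fixture: two informative features decide three classes.
make_separable_table <- function(n = 400, seed = 101) {
  withr::with_seed(seed, {
    lab <- sample(c("Normal", "AF", "Noisy"), n, replace = TRUE)
    af_evidence <- ifelse(lab == "AF", rnorm(n, 25, 3),
                          ifelse(lab == "Normal", rnorm(n, -30, 3),
                                 rnorm(n, 5, 3)))
    qrs_similarity <- ifelse(lab == "Noisy", rnorm(n, 0.1, 0.05),
                             rnorm(n, 0.95, 0.03))
    filler <- matrix(rnorm(n * 3), n, 3)
  })
  df <- data.frame(af_evidence = af_evidence,
                   qrs_similarity = qrs_similarity,
                   mean_rr_s = filler[, 1], rmssd_s = filler[, 2],
                   pnn50 = filler[, 3])
  list(features = df, labels = lab)
}

test_that("hyperparameter defaults match the training configuration", {
  p <- hyper_params()
  expect_equal(p$learning_rate, 0.1)
  expect_equal(p$iterations, 276L)
  expect_equal(p$early_stopping_rounds, 20L)
  expect_equal(p$depth, 8L)
  expect_equal(p$l2_leaf_reg, 3)
  expect_equal(p$bagging_temperature, 0.7)
  expect_equal(p$random_strength, 0.2)
  expect_equal(p$leaf_estimation, "Newton")
  expect_equal(p$loss, "MultiClass")
  expect_equal(p$eval_metric, "MCC")
  # overridable
  expect_equal(hyper_params(depth = 4)$depth, 4L)
})

test_that("training fits separable data and is seed-deterministic", {
  tab <- make_separable_table()
  fit <- suppressMessages(train_classifier(tab$features, tab$labels,
                                           hyper_params(random_seed = 3)))
  pred <- predict(fit, ecgaf:::as_feature_matrix(tab$features))
  lab_hat <- rhythm_classes()[max.col(pred)]
  cm <- confusion_matrix_ecg(tab$labels, lab_hat)
  expect_gte(multiclass_mcc(cm), 0.99)

  fit2 <- suppressMessages(train_classifier(tab$features, tab$labels,
                                            hyper_params(random_seed = 3)))
  hold <- ecgaf:::as_feature_matrix(make_separable_table(n = 50,
                                                         seed = 202)$features)
  expect_identical(predict(fit, hold), predict(fit2, hold))
})

test_that("training rejects degenerate inputs", {
  tab <- make_separable_table(n = 50)
  bad <- tab$features; bad$af_evidence[3] <- NA
  expect_error(suppressMessages(train_classifier(bad, tab$labels)),
               "finite")
  expect_error(suppressMessages(
    train_classifier(tab$features, rep("AF", 50))), "single class")
  expect_error(suppressMessages(
    train_classifier(tab$features, rep(c("AF", "Sinus"), 25))),
    "rhythm_classes")
})

test_that("backend gaps are flagged loudly and recorded", {
  tab <- make_separable_table(n = 60)
  expect_message(train_classifier(tab$features, tab$labels),
                 "bagging_temperature, random_strength")
  # silent when the unsupported options are disabled
  expect_no_message(train_classifier(
    tab$features, tab$labels,
    hyper_params(bagging_temperature = 0, random_strength = 0)))
})

test_that("permuted labels give near-zero validation MCC", {
  tab <- make_separable_table(n = 300, seed = 303)
  withr::with_seed(304, perm <- sample(tab$labels))
  cv <- suppressMessages(suppressWarnings(cross_validate(
    tab$features, perm, hyper_params(random_seed = 5, iterations = 80),
    n_folds = 5, seed = 5)))
  expect_lt(abs(cv$mean_mcc), 0.15)
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  tab <- make_separable_table(n = 200, seed = 404)
  cv <- suppressMessages(cross_validate(tab$features, tab$labels,
                                        hyper_params(iterations = 60),
                                        n_folds = 10, seed = 6))
  fold <- cv$fold_assignment
  expect_length(fold, 200)
  expect_true(all(fold %in% 1:10))
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), length(unique(tab$labels)))
  # each row validates exactly once by construction of the assignment
  expect_equal(sum(sizes), 200)
  expect_gte(cv$mean_mcc, 0.95)
  expect_length(cv$fold_mcc, 10)
  expect_true(all(cv$fold_best_iteration >= 1))
})

test_that("a class smaller than the fold count triggers a warning", {
  tab <- make_separable_table(n = 100, seed = 505)
  lab <- tab$labels
  lab[1:3] <- "Other"; lab[4:100] <- rep(c("Normal", "AF"), length.out = 97)
  expect_warning(suppressMessages(cross_validate(
    tab$features, lab, hyper_params(iterations = 30), n_folds = 10,
    seed = 1)), "best-effort")
})

test_that("feature ranking puts the decisive feature first", {
  withr::with_seed(606, {
    n <- 300
    lab <- sample(c("Normal", "AF"), n, replace = TRUE)
    df <- data.frame(af_evidence = ifelse(lab == "AF", 1, -1) + rnorm(n, 0, 0.01),
                     mean_rr_s = rnorm(n), rmssd_s = rnorm(n))
  })
  fit <- suppressMessages(train_classifier(df, lab))
  ranking <- rank_features(fit)
  expect_identical(ranking[1], "af_evidence")
  expect_setequal(as.character(ranking), colnames(df))
  imp <- attr(ranking, "importance")
  expect_true(all(imp >= 0))
  expect_gt(sum(imp), 0)
  expect_error(rank_features("not a model"), "trained")
})

test_that("top-k selection honours its bounds", {
  ranking <- paste0("f", 1:31)
  expect_length(select_top_k(ranking), 17)
  expect_identical(select_top_k(ranking, 31), ranking)
  expect_identical(select_top_k(ranking, 2), c("f1", "f2"))
  expect_error(select_top_k(ranking, 0), "k must lie")
  expect_error(select_top_k(ranking, 32), "k must lie")
})

test_that("importance curve rises from k = 1 on the separable fixture", {
  tab <- make_separable_table(n = 250, seed = 707)
  fit <- suppressMessages(train_classifier(tab$features, tab$labels,
                                           hyper_params(iterations = 60)))
  ranking <- rank_features(fit)
  curve <- suppressMessages(importance_curve(
    tab$features, tab$labels, hyper_params(iterations = 60), ranking,
    ks = c(1, 2, 5), n_folds = 4, seed = 8))
  expect_identical(curve$k, c(1, 2, 5))
  expect_gte(curve$mcc[curve$k == 1], 0.9) # the stump feature separates AF
  expect_gte(max(curve$mcc), curve$mcc[1] - 0.05)
})

test_that("final bundle round-trips through disk with identical output", {
  tab <- make_separable_table(n = 200, seed = 808)
  params <- hyper_params(random_seed = 9, iterations = 60)
  cv <- suppressMessages(cross_validate(tab$features, tab$labels, params,
                                        n_folds = 5, seed = 9))
  fit <- suppressMessages(train_classifier(tab$features, tab$labels,
                                           params))
  ranking <- rank_features(fit)
  sel <- select_top_k(ranking, 2)
  bundle <- suppressMessages(retrain_final(tab$features, tab$labels,
                                           params, sel, cv = cv,
                                           ranking = ranking))
  expect_identical(bundle$final_iterations, cv$median_best_iteration)
  expect_identical(bundle$selected_features, sel)
  expect_true(all(bundle$selected_features %in% bundle$feature_manifest))
  expect_true("bagging_temperature" %in% bundle$backend_gaps)

  hold <- make_separable_table(n = 40, seed = 809)
  p1 <- predict(bundle, hold$features)
  dir <- withr::local_tempdir()
  save_model_bundle(bundle, dir)
  back <- load_model_bundle(dir)
  p2 <- predict(back, hold$features)
  expect_equal(p1, p2, tolerance = 1e-12)

  # probabilities sum to one and the argmax matches the label
  expect_true(all(abs(rowSums(p1[, rhythm_classes()]) - 1) < 1e-9))
  expect_identical(as.character(p1$label),
                   rhythm_classes()[max.col(p1[, rhythm_classes()])])

  expect_error(predict(bundle, hold$features[, "mean_rr_s", drop = FALSE]),
               "missing selected feature")
  expect_error(suppressMessages(retrain_final(
    tab$features, tab$labels, params, c("af_evidence", "nope"), cv = cv)),
    "absent")
  expect_error(suppressMessages(retrain_final(
    tab$features, tab$labels, params, character(0), cv = cv)),
    "non-empty")
})

test_that("predicting from a recording equals predicting its feature row", {
  bm <- bench_model()
  bd <- bench_data()
  rec <- generate_ecg(synthetic_spec("AF", seed = 999))$recording
  row <- as.data.frame(t(extract_features(
    rec, ks_reference = bm$bundle$ks_reference)))
  expect_equal(predict(bm$bundle, rec), predict(bm$bundle, row),
               tolerance = 1e-12)
})
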