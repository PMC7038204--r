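#' Training hyperparameters for the boosted-tree classifier
#'
#' Defaults follow the published training configuration: learning rate 0.1,
#' 276 boosting iterations, early stopping after 20 rounds without
#' validation improvement, tree depth 8, L2 leaf regularisation 3, bagging
#' temperature 0.7, random strength 0.2, Newton leaf estimation, multiclass
#' loss, and the multiclass Matthews correlation coefficient (MCC) as the
#' validation metric. The xgboost backend natively performs Newton
#' (second-order) leaf estimation; `bagging_temperature` and
#' `random_strength` have no xgboost equivalent — they are retained in the
#' object, reported via `backend_gaps`, and flagged loudly at training
#' time.
#'
#' @param learning_rate Shrinkage per boosting step.
#' @param iterations Maximum number of boosting iterations.
#' @param early_stopping_rounds Patience for validation early stopping.
#' @param depth Tree depth.
#' @param l2_leaf_reg L2 regularisation on leaf weights.
#' @param bagging_temperature Bayesian-bootstrap intensity (not supported
#'   by the backend; recorded only).
#' @param random_strength Score-perturbation strength (not supported by the
#'   backend; recorded only).
#' @param leaf_estimation Leaf value estimation method.
#' @param loss Loss function identifier.
#' @param eval_metric Validation metric identifier.
#' @param random_seed Integer seed for the backend.
#' @return An object of class `ecgaf_hyper_params`.
#' @export
hyper_params <- function(learning_rate = 0.1, iterations = 276,
                         early_stopping_rounds = 20, depth = 8,
                         l2_leaf_reg = 3, bagging_temperature = 0.7,
                         random_strength = 0.2,
                         leaf_estimation = "Newton", loss = "MultiClass",
                         eval_metric = "MCC", random_seed = 1L) {
  structure(list(learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 depth = as.integer(depth), l2_leaf_reg = l2_leaf_reg,
                 bagging_temperature = bagging_temperature,
                 random_strength = random_strength,
                 leaf_estimation = leaf_estimation, loss = loss,
                 eval_metric = eval_metric,
                 random_seed = as.integer(random_seed)),
            class = "ecgaf_hyper_params")
}

backend_gaps <- function(params) {
  gaps <- character(0)
  if (params$bagging_temperature != 0)
    gaps <- c(gaps, "bagging_temperature")
  if (params$random_strength != 0)
    gaps <- c(gaps, "random_strength")
  gaps
}

# Canonical column ordering: training and prediction must present columns
# to the backend in the same order, so both subset through this helper.
as_feature_matrix <- function(features) {
  cols <- intersect(feature_names(), colnames(features))
  if (length(cols) == 0)
    stop("feature table has no recognised feature columns", call. = FALSE)
  m <- as.matrix(features[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

label_codes <- function(labels) {
  f <- factor(as.character(labels), levels = rhythm_classes())
  if (any(is.na(f))) stop("labels must be drawn from rhythm_classes()",
                          call. = FALSE)
  as.integer(f) - 1L
}

# Multiclass MCC as an xgboost custom validation metric.
mcc_eval_metric <- function(preds, dtrain) {
  lab <- xgboost::getinfo(dtrain, "label")
  k <- length(preds) / length(lab)
  pm <- if (is.matrix(preds)) preds
        else matrix(preds, ncol = k, byrow = TRUE)
  pred <- max.col(pm) - 1L
  cm <- table(factor(lab, levels = 0:(k - 1)),
              factor(pred, levels = 0:(k - 1)))
  list(metric = "mcc", value = mcc_from_matrix(unclass(cm)))
}

xgb_param_list <- function(params) {
  list(objective = "multi:softprob", num_class = 4L,
       eta = params$learning_rate, max_depth = params$depth,
       lambda = params$l2_leaf_reg, nthread = 1L,
       seed = params$random_seed)
}

check_training_table <- function(m, y) {
  if (any(!is.finite(m))) stop("non-finite feature values", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("labels contain a single class; at least 2 required",
         call. = FALSE)
}

#' Train the multiclass boosted-tree classifier
#'
#' Fits the gradient-boosted tree ensemble on a feature table with the
#' given [hyper_params()]. Deterministic for a fixed `random_seed`
#' (single-threaded backend).
#'
#' @param features Data frame or matrix containing (a subset of) the
#'   [feature_names()] columns.
#' @param labels Labels drawn from [rhythm_classes()]; at least two classes
#'   must be present.
#' @param params A [hyper_params()] object.
#' @param nrounds Number of boosting iterations (defaults to
#'   `params$iterations`).
#' @return A fitted `xgb.Booster` with the feature manifest attached.
#' @export
train_classifier <- function(features, labels, params = hyper_params(),
                             nrounds = params$iterations) {
  m <- as_feature_matrix(features)
  y <- label_codes(labels)
  check_training_table(m, y)
  gaps <- backend_gaps(params)
  if (length(gaps) > 0)
    message("NOTE: backend (xgboost) does not implement: ",
            paste(gaps, collapse = ", "),
            " -- recorded in the model bundle metadata")
  dtrain <- xgboost::xgb.DMatrix(m, label = y)
  fit <- xgboost::xgb.train(params = xgb_param_list(params), data = dtrain,
                            nrounds = nrounds, verbose = 0)
  attr(fit, "ecgaf_manifest") <- colnames(m)
  attr(fit, "ecgaf_backend_gaps") <- gaps
  fit
}

make_stratified_folds <- function(labels, n_folds, seed) {
  y <- as.character(labels)
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      if (length(idx) < n_folds)
        warning(sprintf(
          "class '%s' has %d members (< %d folds); stratified best-effort",
          cl, length(idx), n_folds), call. = FALSE)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation with MCC early stopping
#'
#' Splits the training table into `n_folds` label-stratified folds of
#' near-equal size; each fold serves as the validation set for exactly one
#' model trained on the remaining folds, with early stopping on that
#' fold's multiclass MCC.
#'
#' @inheritParams train_classifier
#' @param n_folds Number of folds (default 20).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `ecgaf_cv_result`: per-fold validation MCC
#'   and best iteration, with mean/sd summaries and the fold assignment.
#' @export
cross_validate <- function(features, labels, params = hyper_params(),
                           n_folds = 20, seed = 1L) {
  m <- as_feature_matrix(features)
  y <- label_codes(labels)
  check_training_table(m, y)
  if (nrow(m) < n_folds) stop("need at least n_folds rows", call. = FALSE)
  fold <- make_stratified_folds(labels, n_folds, seed)
  xp <- xgb_param_list(params)
  res <- lapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    dtr <- xgboost::xgb.DMatrix(m[tr, , drop = FALSE], label = y[tr])
    dva <- xgboost::xgb.DMatrix(m[!tr, , drop = FALSE], label = y[!tr])
    fit <- xgboost::xgb.train(
      params = xp, data = dtr, nrounds = params$iterations,
      evals = list(val = dva), custom_metric = mcc_eval_metric,
      maximize = TRUE,
      early_stopping_rounds = params$early_stopping_rounds, verbose = 0)
    best_iter <- as.integer(xgboost::xgb.attr(fit, "best_iteration"))
    best_score <- as.numeric(xgboost::xgb.attr(fit, "best_score"))
    # the backend reports a 0-based boosting index; convert to a count
    best_iter <- if (!length(best_iter) || is.na(best_iter))
      params$iterations else max(1L, best_iter + 1L)
    list(mcc = best_score, best_iteration = best_iter)
  })
  mcc <- vapply(res, `[[`, numeric(1), "mcc")
  best <- vapply(res, `[[`, integer(1), "best_iteration")
  structure(list(fold_mcc = mcc, fold_best_iteration = best,
                 mean_mcc = mean(mcc), sd_mcc = stats::sd(mcc),
                 median_best_iteration = as.integer(
                   ceiling(stats::median(best))),
                 n_folds = n_folds, fold_assignment = fold, seed = seed),
            class = "ecgaf_cv_result")
}

#' Rank features by ensemble importance
#'
#' Sorts the manifest by the trained ensemble's gain-based importance,
#' descending; features never used by a split receive importance 0; ties
#' are broken by manifest order.
#'
#' @param fit A trained ensemble from [train_classifier()].
#' @param manifest Feature names (defaults to the manifest recorded on the
#'   fit).
#' @return Character vector: the manifest sorted by importance, with the
#'   numeric importances attached as an attribute.
#' @export
rank_features <- function(fit, manifest = attr(fit, "ecgaf_manifest")) {
  if (!inherits(fit, "xgb.Booster"))
    stop("fit must be a trained ensemble", call. = FALSE)
  if (is.null(manifest)) stop("no feature manifest available", call. = FALSE)
  imp_tab <- xgboost::xgb.importance(model = fit)
  imp <- stats::setNames(numeric(length(manifest)), manifest)
  hit <- intersect(imp_tab$Feature, manifest)
  imp[hit] <- imp_tab$Gain[match(hit, imp_tab$Feature)]
  ord <- order(-imp, seq_along(manifest))
  structure(manifest[ord], importance = imp[ord])
}

#' Select the top-k features of a ranking
#'
#' @param ranking Output of [rank_features()].
#' @param k Number of features to keep (default 17).
#' @return Character vector of the first `k` names.
#' @export
select_top_k <- function(ranking, k = 17) {
  if (k < 1 || k > length(ranking))
    stop(sprintf("k must lie in [1, %d]", length(ranking)), call. = FALSE)
  as.character(ranking[seq_len(k)])
}

#' Held-out MCC as a function of the number of top-importance features
#'
#' For each requested `k`, cross-validates the classifier restricted to the
#' top-`k` features of the ranking and records the mean validation MCC.
#'
#' @inheritParams cross_validate
#' @param ranking Output of [rank_features()].
#' @param ks Integer vector of feature-count values to evaluate.
#' @param n_folds Folds per evaluation (a smaller default than the training
#'   protocol keeps the curve cheap; the plateau shape is what matters).
#' @return Data frame with columns `k` and `mcc`.
#' @export
importance_curve <- function(features, labels, params = hyper_params(),
                             ranking, ks, n_folds = 5, seed = 1L) {
  rows <- lapply(ks, function(k) {
    sel <- select_top_k(ranking, k)
    cv <- cross_validate(features[, c(sel), drop = FALSE], labels, params,
                         n_folds = n_folds, seed = seed)
    data.frame(k = k, mcc = cv$mean_mcc)
  })
  do.call(rbind, rows)
}

#' Re-train the final classifier on the selected features
#'
#' Trains on the full training table restricted to the selected features,
#' with the iteration count fixed to the median per-fold best iteration
#' from cross-validation (no early stopping at this stage), and packages
#' the result with everything needed at prediction time.
#'
#' @inheritParams train_classifier
#' @param selected_features Non-empty character vector of feature names.
#' @param cv An `ecgaf_cv_result` (fixes the iteration count); `NULL` falls
#'   back to `params$iterations`.
#' @param ranking Optional [rank_features()] output stored in the bundle.
#' @param ks_reference The `ks_reference` the features were extracted with.
#' @return An object of class `ecgaf_model_bundle`.
#' @export
retrain_final <- function(features, labels, params = hyper_params(),
                          selected_features, cv = NULL, ranking = NULL,
                          ks_reference = default_ks_reference()) {
  if (length(selected_features) == 0)
    stop("selected_features must be non-empty", call. = FALSE)
  missing <- setdiff(selected_features, colnames(features))
  if (length(missing) > 0)
    stop("selected features absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  nrounds <- if (!is.null(cv)) cv$median_best_iteration
             else params$iterations
  fit <- train_classifier(features[, selected_features, drop = FALSE],
                          labels, params, nrounds = nrounds)
  structure(list(
    model_raw = xgboost::xgb.save.raw(fit),
    params = params,
    feature_manifest = feature_names(),
    importance_ranking = if (is.null(ranking)) NULL
                         else as.character(ranking),
    selected_features = as.character(selected_features),
    ks_reference = ks_reference,
    class_order = rhythm_classes(),
    backend = paste0("xgboost ", as.character(utils::packageVersion(
      "xgboost"))),
    backend_gaps = backend_gaps(params),
    final_iterations = nrounds),
    class = "ecgaf_model_bundle")
}

bundle_booster <- function(bundle) {
  fit <- xgboost::xgb.load.raw(bundle$model_raw)
  fit
}

#' Classify recordings or feature rows with a trained model bundle
#'
#' Accepts either a feature table (rows in any column order containing the
#' bundle's selected features) or a single [ecg_recording()], which is run
#' through the full feature-extraction pipeline with the bundle's own KS
#' reference. Class probabilities are renormalised to sum exactly to 1.
#'
#' @param object An `ecgaf_model_bundle`.
#' @param newdata Feature data frame/matrix or an [ecg_recording()].
#' @param ... Unused.
#' @return Data frame with the predicted `label` (factor over
#'   [rhythm_classes()]) and one probability column per class.
#' @export
predict.ecgaf_model_bundle <- function(object, newdata, ...) {
  if (inherits(newdata, "ecg_recording"))
    newdata <- as.data.frame(t(extract_features(
      newdata, ks_reference = object$ks_reference)))
  missing <- setdiff(object$selected_features, colnames(newdata))
  if (length(missing) > 0)
    stop("missing selected feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as_feature_matrix(
    newdata[, object$selected_features, drop = FALSE])
  probs <- stats::predict(bundle_booster(object), m)
  probs <- probs / rowSums(probs)
  colnames(probs) <- object$class_order
  label <- factor(object$class_order[max.col(probs, ties.method = "first")],
                  levels = object$class_order)
  cbind(data.frame(label = label), as.data.frame(probs))
}

#' Serialise / load a model bundle as a directory
#'
#' The directory holds the backend-native model binary (`model.ubj`), a
#' JSON manifest (feature order, ranking, selection, class order,
#' hyperparameters, backend identity and gaps) and the KS reference as CSV.
#'
#' @param bundle An `ecgaf_model_bundle`.
#' @param dir Directory to write to / read from.
#' @return `save_model_bundle()`: `dir`, invisibly. `load_model_bundle()`:
#'   the restored bundle.
#' @export
save_model_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeBin(bundle$model_raw, file.path(dir, "model.ubj"))
  manifest <- bundle[c("feature_manifest", "importance_ranking",
                       "selected_features", "class_order", "backend",
                       "backend_gaps", "final_iterations")]
  manifest$params <- unclass(bundle$params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(data.frame(normalized_drr = as.numeric(
    bundle$ks_reference)), file.path(dir, "ks_reference.csv"),
    row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ks <- utils::read.csv(file.path(dir, "ks_reference.csv"))$normalized_drr
  path <- file.path(dir, "model.ubj")
  structure(list(
    model_raw = readBin(path, "raw", n = file.size(path)),
    params = do.call(hyper_params, as.list(manifest$params)),
    feature_manifest = manifest$feature_manifest,
    importance_ranking = manifest$importance_ranking,
    selected_features = manifest$selected_features,
    ks_reference = structure(sort(ks), class = "ks_reference"),
    class_order = manifest$class_order,
    backend = manifest$backend,
    backend_gaps = manifest$backend_gaps,
    final_iterations = manifest$final_iterations),
    class = "ecgaf_model_bundle")
}
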