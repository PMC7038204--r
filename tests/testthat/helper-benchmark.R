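# Desk-scale synthetic benchmark shared by the model and acceptance tests:
# 1000 labelled 30 s segments (430 Normal, 380 AF, 190 Noisy) split 80/20,
# with features extracted once and cached for the session.

.bench_cache <- new.env(parent = emptyenv())

bench_data <- function() {
  if (!is.null(.bench_cache$data)) return(.bench_cache$data)
  corpus <- simulate_corpus(c(Normal = 430, AF = 380, Noisy = 190),
                            seed = 77)
  sp <- split_dataset(corpus$recordings, corpus$labels,
                      test_fraction = 0.2, seed = 77)
  # AF reference from the training AF segments, via the full pipeline
  af_tr <- which(sp$train$labels == "AF")
  series <- lapply(sp$train$items[af_tr[seq_len(40)]], function(r) {
    filt <- bandpass_filter(r)
    tryCatch(build_beat_series(detect_r_peaks(filt), filt$fs),
             error = function(e) NULL)
  })
  ref <- build_ks_reference(Filter(Negate(is.null), series))
  train <- extract_feature_table(sp$train$items, sp$train$labels,
                                 ks_reference = ref)
  test <- extract_feature_table(sp$test$items, sp$test$labels,
                                ks_reference = ref)
  .bench_cache$data <- list(train = train, test = test, ks_reference = ref)
  .bench_cache$data
}

bench_model <- function() {
  if (!is.null(.bench_cache$model)) return(.bench_cache$model)
  bd <- bench_data()
  params <- hyper_params(random_seed = 7L)
  cv <- suppressMessages(cross_validate(bd$train, bd$train$label, params,
                                        n_folds = 20, seed = 7))
  fit <- suppressMessages(train_classifier(bd$train, bd$train$label,
                                           params))
  ranking <- rank_features(fit)
  selected <- select_top_k(ranking, 17)
  bundle <- suppressMessages(retrain_final(
    bd$train, bd$train$label, params, selected, cv = cv,
    ranking = ranking, ks_reference = bd$ks_reference))
  .bench_cache$model <- list(cv = cv, fit = fit, ranking = ranking,
                             selected = selected, bundle = bundle,
                             params = params)
  .bench_cache$model
}
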