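# Reference tuned settings for this protocol family; the default search box
# must contain them.
reference_optima <- list(
  rf = list(n_estimators = 283, max_depth = 25, max_features = 0.231),
  svm = list(C = 4.691, gamma = 0.013),
  ann = list(hidden_layer_sizes = 201, alpha = 0.155)
)

test_that("default search bounds bracket the reference optima", {
  space <- hyperparameter_space()
  for (model in names(reference_optima)) {
    bounds <- space[[model]]
    names(bounds) <- vapply(bounds, `[[`, character(1), "name")
    for (par in names(reference_optima[[model]])) {
      v <- reference_optima[[model]][[par]]
      expect_gte(v, bounds[[par]]$lower)
      expect_lte(v, bounds[[par]]$upper)
    }
  }
  expect_error(hyperparameter_space(budget = 5), "at least 10")
})

test_that("the reference optima are accepted as valid training settings", {
  d <- tiny_qsar()
  X <- unclass(d$descriptors)[1:80, 1:6]
  y <- d$labels[1:80]
  hp <- default_hyperparameters(ann_maxit = 50)
  models <- train_base_models(X, y, hp, seed = 1)
  expect_s3_class(models$rf$fit, "ranger")
  conf <- qsarvs:::base_confidences(models, X)
  expect_true(all(conf >= 0 & conf <= 1))
})

test_that("Bayesian tuning respects bounds, its seed, and separable data", {
  set.seed(20)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(X[, 1] > 0, 1, 0)        # linearly separable
  X[, 1] <- X[, 1] + sign(X[, 1])      # widen the margin
  space <- hyperparameter_space(budget = 10, seed = 2,
                                ann = list(hidden_layer_sizes = c(4, 16)))
  tuned <- tune_hyperparameters(X, y, space, folds = 5)
  for (model in c("rf", "svm", "ann")) {
    bounds <- space[[model]]
    names(bounds) <- vapply(bounds, `[[`, character(1), "name")
    for (par in names(tuned[[model]]$par)) {
      expect_gte(tuned[[model]]$par[[par]], bounds[[par]]$lower)
      expect_lte(tuned[[model]]$par[[par]], bounds[[par]]$upper)
    }
    expect_gte(tuned[[model]]$cv_auc, 0.99)
  }
  tuned2 <- tune_hyperparameters(X, y, space, folds = 5)
  expect_identical(tuned[c("rf", "svm", "ann")], tuned2[c("rf", "svm", "ann")])
  expect_identical(nrow(tuned$trace), 30L)
})

test_that("training refuses degenerate inputs", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(train_base_models(X, rep("active", 20), small_hp()), "single class")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(train_base_models(Xbad, rep(c("active", "inactive"), 10), small_hp()),
               "non-finite")
})

test_that("voting is exactly the weighted mean of base confidences", {
  d <- tiny_qsar()
  sel <- select_features(d$descriptors, d$labels)
  bases <- train_base_models(sel$matrix, d$labels, small_hp(), seed = 2)
  Z <- qsarvs:::base_confidences(bases, sel$matrix)

  equal <- build_ensemble(bases, "voting")
  expect_equal(predict_confidence(equal, sel$matrix)$conf_voting,
               rowMeans(Z), tolerance = 1e-15)
  w <- c(0.5, 0.3, 0.2)
  weighted <- build_ensemble(bases, "voting", weights = w)
  expect_equal(predict_confidence(weighted, sel$matrix)$conf_voting,
               as.numeric(Z %*% w), tolerance = 1e-15)
  expect_error(build_ensemble(bases, "averaging"), "unknown fusion")
})

test_that("stacking meta-features are out-of-fold and shaped (n, 3)", {
  d <- tiny_qsar()
  sel <- select_features(d$descriptors, d$labels)
  bases <- train_base_models(sel$matrix, d$labels, small_hp(), seed = 2)
  ens <- build_ensemble(bases, c("voting", "stacking"), sel$matrix, d$labels,
                        seed = 2)
  Z_oof <- ens$oof$meta_features
  expect_identical(dim(Z_oof), c(nrow(sel$matrix), 3L))
  expect_false(anyNA(Z_oof))
  expect_identical(sort(unique(ens$oof$fold)), 1:5)
  # the OOF confidences cannot coincide with in-fold (full-model) predictions
  Z_full <- qsarvs:::base_confidences(bases, sel$matrix)
  expect_gt(mean(abs(Z_oof - Z_full)), 1e-4)
  expect_error(build_ensemble(bases, "stacking"), "training matrix")
})

test_that("fused models keep pace with the best base model on held-out data", {
  d <- synth_qsar_dataset(n_active = 320, n_inactive = 80, n_features = 30,
                          n_constant = 2, n_duplicated = 3, n_independent = 5,
                          effect_size = 0.8, seed = 21)
  sel <- select_features(d$descriptors, d$labels)
  sp <- split_dataset(d$records, seed = 4)
  tr <- rownames(sel$matrix) %in% sp$train_ids
  bases <- train_base_models(sel$matrix[tr, ], d$labels[tr], small_hp(), seed = 2)
  ens <- build_ensemble(bases, c("voting", "stacking"), sel$matrix[tr, ],
                        d$labels[tr], seed = 2)
  y_te <- d$labels[!tr]
  conf <- predict_confidence(ens, sel$matrix[!tr, ])
  base_auc <- apply(qsarvs:::base_confidences(bases, sel$matrix[!tr, ]), 2,
                    function(s) roc_auc(y_te, s)$auc)
  expect_gte(roc_auc(y_te, conf$conf_voting)$auc, max(base_auc) - 0.02)
  expect_gte(roc_auc(y_te, conf$conf_stacking)$auc, max(base_auc) - 0.02)
})

test_that("prediction validates features, handles empty input, and is bit-stable", {
  d <- tiny_qsar()
  sel <- select_features(d$descriptors, d$labels)
  bases <- train_base_models(sel$matrix, d$labels, small_hp(), seed = 2)
  ens <- build_ensemble(bases, c("voting", "stacking"), sel$matrix, d$labels,
                        seed = 2)
  conf <- predict_confidence(ens, sel$matrix)
  expect_true(all(conf$conf_voting >= 0 & conf$conf_voting <= 1))
  expect_true(all(conf$conf_stacking >= 0 & conf$conf_stacking <= 1))

  empty <- sel$matrix[0, , drop = FALSE]
  expect_identical(nrow(predict_confidence(ens, empty)), 0L)

  wrong <- sel$matrix
  colnames(wrong)[2] <- "rogue_descriptor"
  expect_error(predict_confidence(ens, wrong), "rogue_descriptor|missing")

  bases2 <- train_base_models(sel$matrix, d$labels, small_hp(), seed = 2)
  ens2 <- build_ensemble(bases2, c("voting", "stacking"), sel$matrix, d$labels,
                         seed = 2)
  expect_identical(predict_confidence(ens2, sel$matrix), conf)
})

test_that("all models rank the single informative feature first by permutation importance", {
  set.seed(31)
  n <- 120
  X <- cbind(signal = rnorm(n), junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n))
  y <- ifelse(X[, "signal"] + rnorm(n, sd = 0.2) > 0, 1, 0)
  bases <- train_base_models(X, y, small_hp(), seed = 3)
  for (kind in c("rf", "svm", "ann")) {
    predictor <- function(m) qsarvs:::predict_base_model(bases[[kind]], m)
    imp <- permutation_importance(predictor, X, y, n_rep = 3, seed = 4)
    expect_identical(imp$descriptor[1], "signal")
  }
})
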