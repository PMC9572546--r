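#' Hyperparameter search space for the three base classifiers
#'
#' Box bounds for the Bayesian tuner. The defaults bracket typical optima for
#' kinase-activity panels: random forest `n_estimators` 50-500, `max_depth`
#' 3-30, `max_features` (fraction of descriptors per split) 0.05-1; RBF-kernel
#' SVM `C` 1e-2-1e2 and `gamma` 1e-4-1 on log scales; single-hidden-layer
#' neural network size 16-256 with L2 penalty `alpha` 1e-4-10 (log).
#'
#' @param budget Objective evaluations per model; default 50.
#' @param seed Integer seed for the tuner.
#' @param rf,svm,ann Optional per-model bound overrides, each a named list of
#'   `c(lower, upper)` pairs.
#' @return A `hyperparameter_space` object.
#' @export
hyperparameter_space <- function(budget = 50, seed = 1,
                                 rf = list(), svm = list(), ann = list()) {
  ov <- function(defaults, user) {
    for (nm in names(user)) {
      defaults[[nm]]$lower <- user[[nm]][1]
      defaults[[nm]]$upper <- user[[nm]][2]
    }
    unname(defaults)
  }
  rf_b <- ov(list(
    n_estimators = list(name = "n_estimators", type = "int", lower = 50, upper = 500),
    max_depth = list(name = "max_depth", type = "int", lower = 3, upper = 30),
    max_features = list(name = "max_features", type = "real", lower = 0.05, upper = 1)
  ), rf)
  svm_b <- ov(list(
    C = list(name = "C", type = "log", lower = 1e-2, upper = 1e2),
    gamma = list(name = "gamma", type = "log", lower = 1e-4, upper = 1)
  ), svm)
  ann_b <- ov(list(
    hidden_layer_sizes = list(name = "hidden_layer_sizes", type = "int", lower = 16, upper = 256),
    alpha = list(name = "alpha", type = "log", lower = 1e-4, upper = 10)
  ), ann)
  if (budget < 10) stop("budget must be at least 10", call. = FALSE)
  structure(list(rf = rf_b, svm = svm_b, ann = ann_b,
                 budget = budget, seed = as.integer(seed)),
            class = "hyperparameter_space")
}

#' Tune the base classifiers by Bayesian optimization under 10-fold CV
#'
#' For each of the three base models the tuner maximizes the mean stratified
#' 10-fold cross-validated AUC over the model's bound box. The fold
#' assignment is fixed across iterations and everything is deterministic
#' given the space's seed.
#'
#' @param matrix Standardized, selected feature matrix (training rows).
#' @param labels Binary labels.
#' @param space A [hyperparameter_space()].
#' @param folds Number of CV folds; default 10.
#' @return List with elements `rf`, `svm`, `ann` (each `list(par, cv_auc)`)
#'   and `trace` (per-iteration objective values for all three searches).
#' @export
tune_hyperparameters <- function(matrix, labels, space = hyperparameter_space(),
                                 folds = 10) {
  stopifnot(inherits(space, "hyperparameter_space"))
  m <- as.matrix(matrix)
  y <- as_binary_labels(labels)
  fold <- make_folds(y, folds = folds, seed = space$seed)
  cv_auc <- function(kind) {
    function(par) {
      aucs <- vapply(seq_len(folds), function(k) {
        tr <- fold != k
        model <- train_one_model(kind, m[tr, , drop = FALSE], y[tr], par,
                                 seed = space$seed)
        conf <- predict_base_model(model, m[!tr, , drop = FALSE])
        roc_auc(y[!tr], conf)$auc
      }, numeric(1))
      mean(aucs)
    }
  }
  out <- list()
  traces <- list()
  for (kind in c("rf", "svm", "ann")) {
    res <- bayes_optimize(cv_auc(kind), space[[kind]], budget = space$budget,
                          seed = space$seed)
    out[[kind]] <- list(par = res$best_par, cv_auc = res$best_value)
    traces[[kind]] <- cbind(model = kind,
                            res$trace[, c("iteration", "objective")])
  }
  out$trace <- do.call(rbind, traces)
  rownames(out$trace) <- NULL
  out
}

# Fit one base classifier of the given kind with the given hyperparameters.
train_one_model <- function(kind, matrix, labels, par, seed = 1) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  m <- as.matrix(matrix)
  if (!all(is.finite(m))) stop("feature matrix contains non-finite values", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  yf <- factor(ifelse(y == 1, "active", "inactive"),
               levels = c("inactive", "active"))
  fit <- switch(kind,
    rf = {
      ranger::ranger(
        x = as.data.frame(m), y = yf,
        num.trees = as.integer(par$n_estimators),
        max.depth = as.integer(par$max_depth),
        mtry = max(1L, min(ncol(m), floor(par$max_features * ncol(m)))),
        min.node.size = 1, probability = TRUE, importance = "impurity",
        seed = as.integer(seed), num.threads = 1
      )
    },
    svm = {
      set.seed(as.integer(seed))
      e1071::svm(m, yf, kernel = "radial", cost = par$C, gamma = par$gamma,
                 probability = TRUE, scale = FALSE)
    },
    ann = {
      set.seed(as.integer(seed))
      size <- as.integer(par$hidden_layer_sizes)
      maxit <- as.integer(par$maxit %||% 2000L)
      nnet::nnet(m, nnet::class.ind(yf)[, "active", drop = FALSE],
                 size = size, decay = par$alpha, maxit = maxit,
                 entropy = TRUE, trace = FALSE,
                 MaxNWts = (ncol(m) + 2L) * size + size + 10L)
    },
    stop("unknown base-model kind: ", kind, call. = FALSE)
  )
  structure(list(kind = kind, fit = fit, par = par,
                 feature_names = colnames(m), seed = as.integer(seed)),
            class = "qsar_base_model")
}

# Active-class probability from one fitted base model.
predict_base_model <- function(model, matrix) {
  m <- as.matrix(matrix)
  if (is.null(colnames(m))) colnames(m) <- model$feature_names
  if (!identical(colnames(m), model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(m))
    extra <- setdiff(colnames(m), model$feature_names)
    stop("feature mismatch",
         if (length(missing)) paste0("; missing: ", paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (!nrow(m)) return(numeric(0))
  switch(model$kind,
    rf = {
      p <- stats::predict(model$fit, data = as.data.frame(m),
                          num.threads = 1)$predictions
      unname(p[, "active"])
    },
    svm = {
      pred <- stats::predict(model$fit, m, probability = TRUE)
      unname(attr(pred, "probabilities")[, "active"])
    },
    ann = {
      as.numeric(stats::predict(model$fit, m))
    }
  )
}

#' Train the three base classifiers
#'
#' Fits the random forest, the RBF-kernel SVM (with probability output
#' enabled) and the single-hidden-layer neural network with the supplied
#' hyperparameters.
#'
#' @param matrix Standardized, selected feature matrix.
#' @param labels Binary labels (both classes required).
#' @param hyperparameters Named list with elements `rf`, `svm`, `ann`, each a
#'   named parameter list (as returned in `tune_hyperparameters()$<model>$par`
#'   or [default_hyperparameters()]).
#' @param seed Integer seed shared by all three fits.
#' @return Object of class `qsar_base_models`: list of three
#'   `qsar_base_model` objects.
#' @export
train_base_models <- function(matrix, labels, hyperparameters = default_hyperparameters(),
                              seed = 1) {
  models <- lapply(c(rf = "rf", svm = "svm", ann = "ann"), function(kind) {
    train_one_model(kind, matrix, labels, hyperparameters[[kind]], seed = seed)
  })
  structure(models, class = "qsar_base_models")
}

#' Default base-model hyperparameters
#'
#' Reference settings for a curated kinase-activity dataset of ~1400
#' compounds and ~100-150 selected descriptors: RF with 283 trees, depth 25
#' and 23.1% of features per split; RBF SVM with C = 4.691, gamma = 0.013;
#' a 201-unit hidden layer with L2 penalty 0.155.
#'
#' @param ann_maxit Maximum ANN training iterations; default 2000.
#' @return Named list with `rf`, `svm`, `ann` parameter lists.
#' @export
default_hyperparameters <- function(ann_maxit = 2000) {
  list(
    rf = list(n_estimators = 283L, max_depth = 25L, max_features = 0.231),
    svm = list(C = 4.691, gamma = 0.013),
    ann = list(hidden_layer_sizes = 201L, alpha = 0.155, maxit = ann_maxit)
  )
}

# Matrix of base-model active-class confidences, one column per base.
base_confidences <- function(bases, matrix) {
  vapply(bases, predict_base_model, numeric(nrow(as.matrix(matrix))),
         matrix = matrix)
}

#' Build a fused ensemble from the three base classifiers
#'
#' Soft voting averages the base confidences with the given weights (equal by
#' default). Stacking fits a logistic-regression meta-learner on
#' out-of-fold base confidences: each training compound's meta-features come
#' from base models fitted without it, so the meta-learner never sees a
#' sample's own in-fold prediction.
#'
#' @param base_models A `qsar_base_models` object (fitted on the full
#'   training set; used for prediction-time base confidences).
#' @param fusion Character vector, subset of `c("voting", "stacking")`; both
#'   by default.
#' @param matrix,labels Training data; required when `"stacking"` is built.
#' @param seed Seed for the stacking fold assignment and refits.
#' @param weights Voting weights over the three bases; default equal.
#' @param meta_folds Folds for the out-of-fold meta-features; default 5.
#' @return Object of class `ensemble_model`.
#' @export
build_ensemble <- function(base_models, fusion = c("voting", "stacking"),
                           matrix = NULL, labels = NULL, seed = 1,
                           weights = NULL, meta_folds = 5) {
  stopifnot(inherits(base_models, "qsar_base_models"))
  bad <- setdiff(fusion, c("voting", "stacking"))
  if (length(bad)) stop("unknown fusion strategy: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / 3, 3)
  weights <- weights / sum(weights)

  meta <- NULL
  oof_record <- NULL
  if ("stacking" %in% fusion) {
    if (is.null(matrix) || is.null(labels)) {
      stop("stacking requires the training matrix and labels", call. = FALSE)
    }
    m <- as.matrix(matrix)
    y <- as_binary_labels(labels)
    fold <- make_folds(y, folds = meta_folds, seed = seed)
    Z <- matrix(NA_real_, nrow(m), 3,
                dimnames = list(NULL, c("rf", "svm", "ann")))
    for (k in seq_len(meta_folds)) {
      tr <- fold != k
      for (kind in c("rf", "svm", "ann")) {
        refit <- train_one_model(kind, m[tr, , drop = FALSE], y[tr],
                                 base_models[[kind]]$par, seed = seed)
        Z[!tr, kind] <- predict_base_model(refit, m[!tr, , drop = FALSE])
      }
    }
    meta_df <- data.frame(y = y, Z)
    meta <- stats::glm(y ~ rf + svm + ann, data = meta_df,
                       family = stats::binomial())
    oof_record <- list(fold = fold, meta_features = Z)
  }
  structure(list(bases = base_models, fusion = fusion, weights = weights,
                 meta = meta, oof = oof_record, seed = as.integer(seed),
                 feature_names = base_models$rf$feature_names),
            class = "ensemble_model")
}

#' Per-compound active-class confidences from a fused ensemble
#'
#' @param model An `ensemble_model`.
#' @param matrix Feature matrix whose columns match the model's selected
#'   feature list (mismatches raise an error naming the offending
#'   descriptors).
#' @return Data frame with `compound_id` (row names of `matrix`, or row
#'   index) and one confidence column per built fusion strategy
#'   (`conf_voting`, `conf_stacking`), each in \[0, 1\].
#' @export
predict_confidence <- function(model, matrix) {
  stopifnot(inherits(model, "ensemble_model"))
  m <- as.matrix(matrix)
  out <- data.frame(
    compound_id = as.character(rownames(m) %||% seq_len(nrow(m))),
    stringsAsFactors = FALSE
  )
  if (!nrow(m)) {
    if ("voting" %in% model$fusion) out$conf_voting <- numeric(0)
    if ("stacking" %in% model$fusion) out$conf_stacking <- numeric(0)
    return(out)
  }
  Z <- base_confidences(model$bases, m)
  if ("voting" %in% model$fusion) {
    out$conf_voting <- as.numeric(Z %*% model$weights)
  }
  if ("stacking" %in% model$fusion) {
    zd <- as.data.frame(Z)
    names(zd) <- c("rf", "svm", "ann")
    out$conf_stacking <- as.numeric(
      stats::predict(model$meta, newdata = zd, type = "response"))
  }
  out
}
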