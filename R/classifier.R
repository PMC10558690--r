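#' Gradient-boosting model configuration
#'
#' Defaults mirror the screening study's hyperparameters: 100 estimators,
#' learning rate 0.1, maximum tree depth 4, exponential boosting loss (with
#' the node split quality driven by the boosting gradients), five-fold
#' cross-validation and an 80:20 train-test split with min-max scaling.
#'
#' @param n_estimators,learning_rate,max_depth Boosting hyperparameters.
#' @param cv_folds Number of stratified CV folds.
#' @param test_fraction Held-out test fraction in (0, 1).
#' @param seed Integer seed controlling splits, folds and fitting.
#' @param n_permutations Shuffles per feature for permutation importance.
#' @param elimination_tolerance Allowed mean-CV-AUROC slack during backward
#'   feature elimination.
#' @return A `model_config` list.
#' @export
model_config <- function(n_estimators = 100, learning_rate = 0.1,
                         max_depth = 4, cv_folds = 5, test_fraction = 0.2,
                         seed = 1, n_permutations = 10,
                         elimination_tolerance = 0.005) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    it_stop("test_fraction must be in (0, 1)", "invalid_config")
  }
  if (n_estimators < 1 || learning_rate <= 0 || max_depth < 1 ||
      cv_folds < 2) {
    it_stop("model hyperparameters must be positive", "invalid_config")
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds),
                 test_fraction = test_fraction, seed = seed,
                 n_permutations = as.integer(n_permutations),
                 elimination_tolerance = elimination_tolerance),
            class = "model_config")
}

#' Binarize an enrichment profile into tolerance labels
#'
#' Sites with positive combined enrichment are labelled 1 (tolerated), all
#' others 0; a score of exactly 0 is non-positive and labelled 0. Sites
#' missing from the initial library are dropped.
#'
#' @param profile An `enrichment_profile`.
#' @return data.frame: site, label.
#' @export
binarize <- function(profile) {
  keep <- !profile$missing
  data.frame(site = profile$site[keep],
             label = as.integer(profile$combined[keep] > 0))
}

#' Assemble a tolerance classification dataset
#'
#' Joins a site feature table with binarized labels on `site` and checks the
#' result is complete (no missing values).
#'
#' @param sites data.frame from [map_to_sites()].
#' @param labels data.frame from [binarize()].
#' @param protein_id Identifier carried per row.
#' @return A `tol_dataset`: list with `X` (numeric matrix), `y` (0/1),
#'   `feature_names`, `site`, `protein`.
#' @export
make_tol_dataset <- function(sites, labels, protein_id = "protein") {
  merged <- merge(sites, labels, by = "site")
  feats <- setdiff(names(merged)[vapply(merged, is.numeric, logical(1))],
                   c("site", "label"))
  X <- as.matrix(merged[feats])
  if (anyNA(X) || anyNA(merged$label)) {
    it_stop("dataset contains missing values after assembly", "invalid_input")
  }
  x <- list(X = X, y = merged$label, feature_names = feats,
            site = merged$site,
            protein = rep(protein_id, nrow(merged)))
  class(x) <- "tol_dataset"
  x
}

#' Concatenate per-protein datasets
#' @param ... `tol_dataset` objects with identical feature sets.
#' @return A combined `tol_dataset`.
#' @export
rbind_tol_datasets <- function(...) {
  ds <- list(...)
  feats <- ds[[1]]$feature_names
  for (d in ds) {
    if (!identical(d$feature_names, feats)) {
      it_stop("datasets have different feature sets", "shape_error")
    }
  }
  x <- list(X = do.call(rbind, lapply(ds, `[[`, "X")),
            y = unlist(lapply(ds, `[[`, "y")),
            feature_names = feats,
            site = unlist(lapply(ds, `[[`, "site")),
            protein = unlist(lapply(ds, `[[`, "protein")))
  class(x) <- "tol_dataset"
  x
}

# seeded stratified assignment of rows to k folds
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified train/test split with min-max scaling
#'
#' Splits rows 80:20 (by `config$test_fraction`), stratified by label, and
#' min-max scales features using ranges fit on the training rows only; test
#' values may fall outside [0, 1]. Constant training features are scaled to
#' 0 and flagged.
#'
#' @param dataset A `tol_dataset` (>= 10 rows).
#' @param config A [model_config()].
#' @return List with `train`, `test` (each `list(X, y, site, protein)`),
#'   `scaler` and `constant_features`.
#' @export
split_and_scale <- function(dataset, config = model_config()) {
  n <- nrow(dataset$X)
  if (n < 10L) it_stop("need >= 10 rows", "invalid_input")
  fold <- stratified_folds(dataset$y, round(1 / config$test_fraction),
                           subseed(config$seed, 11))
  test_idx <- which(fold == 1L)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(dataset$y[train_idx])) < 2L) {
    it_stop("a class is absent from the training split; reseed or rebalance",
            "degenerate_split")
  }
  Xtr <- dataset$X[train_idx, , drop = FALSE]
  mins <- apply(Xtr, 2, min)
  rng <- apply(Xtr, 2, max) - mins
  constant <- rng == 0
  rng[constant] <- 1
  scale_mat <- function(X) sweep(sweep(X, 2, mins), 2, rng, "/")
  pick <- function(idx) list(X = scale_mat(dataset$X[idx, , drop = FALSE]),
                             y = dataset$y[idx], site = dataset$site[idx],
                             protein = dataset$protein[idx])
  list(train = pick(train_idx), test = pick(test_idx),
       scaler = list(min = mins, range = rng),
       constant_features = dataset$feature_names[constant])
}

# exponential boosting loss (AdaBoost-type), as a custom xgboost objective
exp_objective <- function(preds, dtrain) {
  y <- xgboost::getinfo(dtrain, "label")
  ys <- 2 * y - 1
  e <- exp(pmin(-ys * preds, 30))
  list(grad = -ys * e, hess = e)
}

#' Fit the gradient-boosting tolerance classifier
#'
#' Boosted regression trees under the exponential loss, fit with the
#' configured number of estimators, learning rate and depth. Returns a
#' `tol_model` wrapping the booster with its feature names.
#'
#' @param X Numeric feature matrix.
#' @param y 0/1 labels.
#' @param config A [model_config()].
#' @return A `tol_model`.
#' @export
fit_gbm <- function(X, y, config = model_config()) {
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  dtr <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(max_depth = config$max_depth, eta = config$learning_rate,
                 nthread = 1, base_score = 0,
                 seed = as.integer(subseed(config$seed, 17)))
  booster <- xgboost::xgb.train(params = params, data = dtr,
                                nrounds = config$n_estimators,
                                obj = exp_objective, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(X),
                 config = config), class = "tol_model")
}

#' Predict tolerance scores
#'
#' Raw boosting margins; `type = "prob"` maps them through the exponential
#' loss link `1 / (1 + exp(-2 f))`.
#'
#' @param object A `tol_model`.
#' @param newdata Feature matrix with the model's columns.
#' @param type `"score"` (margin) or `"prob"`.
#' @param ... Ignored.
#' @export
predict.tol_model <- function(object, newdata, type = "score", ...) {
  newdata <- newdata[, object$feature_names, drop = FALSE]
  f <- predict(object$booster,
               xgboost::xgb.DMatrix(newdata, nthread = 1))
  if (type == "prob") 1 / (1 + exp(-2 * f)) else f
}

#' Area under the ROC curve
#' @param y 0/1 labels.
#' @param score Predicted ranking scores.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(y, score) {
  as.numeric(pROC::auc(response = y, predictor = score,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Average precision of a ranking
#'
#' Step-wise integral of the precision-recall curve:
#' \eqn{AP = \sum_n (R_n - R_{n-1}) P_n} over descending score thresholds.
#'
#' @inheritParams auroc
#' @return AP in [0, 1].
#' @export
average_precision <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  dr <- diff(c(0, recall))
  sum(dr * precision)
}

roc_points <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  data.frame(fpr = fpr, tpr = tpr)
}

pr_points <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  data.frame(recall = tp / sum(y), precision = tp / seq_along(y))
}

#' Cross-validated classifier evaluation
#'
#' Stratified k-fold cross-validation: per fold, the model is fit on the
#' remaining folds and scored on the held-out fold (ROC/AUROC and
#' precision-recall/AP); the final model is refit on all rows.
#'
#' @param X,y Training features and labels (typically the scaled training
#'   split).
#' @param config A [model_config()].
#' @return A `cv_report`: list with `fold_auroc`, `mean_auroc`, `fold_ap`,
#'   `mean_ap`, `roc_curves`, `pr_curves`, `model` (fit on all rows).
#' @export
cross_validate <- function(X, y, config = model_config()) {
  fold <- stratified_folds(y, config$cv_folds, subseed(config$seed, 23))
  for (f in seq_len(config$cv_folds)) {
    if (length(unique(y[fold == f])) < 2L) {
      it_stop("a fold contains a single class; stratification failed",
              "stratification_error")
    }
  }
  fold_auroc <- fold_ap <- numeric(config$cv_folds)
  roc_curves <- pr_curves <- vector("list", config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    m <- fit_gbm(X[tr, , drop = FALSE], y[tr], config)
    s <- predict(m, X[!tr, , drop = FALSE])
    fold_auroc[f] <- auroc(y[!tr], s)
    fold_ap[f] <- average_precision(y[!tr], s)
    roc_curves[[f]] <- roc_points(y[!tr], s)
    pr_curves[[f]] <- pr_points(y[!tr], s)
  }
  structure(list(fold_auroc = fold_auroc, mean_auroc = mean(fold_auroc),
                 fold_ap = fold_ap, mean_ap = mean(fold_ap),
                 roc_curves = roc_curves, pr_curves = pr_curves,
                 model = fit_gbm(X, y, config)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: mean AUROC %.3f (folds %s), mean AP %.3f\n",
              x$mean_auroc,
              paste(sprintf("%.3f", x$fold_auroc), collapse = ", "),
              x$mean_ap))
  invisible(x)
}

#' Benchmark the classifier against simple baselines on a test set
#'
#' Computes test AUROC and AP for the fitted model, for a seeded
#' random-score baseline, and for every single feature used directly as the
#' ranking score, with the feature's sign chosen on the training data.
#'
#' @param model A `tol_model`.
#' @param test,train Lists with `X` and `y` (as from [split_and_scale()]).
#' @param config A [model_config()].
#' @return data.frame: predictor, auroc, ap.
#' @export
evaluate_with_benchmarks <- function(model, test, train,
                                     config = model_config()) {
  rows <- list(data.frame(predictor = "model",
                          auroc = auroc(test$y, predict(model, test$X)),
                          ap = average_precision(test$y,
                                                 predict(model, test$X))))
  rnd <- with_seed(subseed(config$seed, 31), runif(length(test$y)))
  rows[[2]] <- data.frame(predictor = "random",
                          auroc = auroc(test$y, rnd),
                          ap = average_precision(test$y, rnd))
  for (nm in model$feature_names) {
    sgn <- if (auroc(train$y, train$X[, nm]) >= 0.5) 1 else -1
    s <- sgn * test$X[, nm]
    rows[[length(rows) + 1]] <- data.frame(
      predictor = nm, auroc = auroc(test$y, s),
      ap = average_precision(test$y, s))
  }
  do.call(rbind, rows)
}

#' Gini and permutation feature importance
#'
#' Gini importance is the booster's total impurity-gain share per feature
#' (non-negative, summing to 1); permutation importance is the mean drop in
#' classification accuracy when one feature's values are shuffled, over
#' `config$n_permutations` seeded repeats.
#'
#' @param model A `tol_model`.
#' @param X,y Data to permute and score (typically the training split).
#' @param config A [model_config()].
#' @return An `importance_report` data.frame: feature, gini, perm_mean,
#'   perm_sd.
#' @export
importance <- function(model, X, y, config = model_config()) {
  imp <- xgboost::xgb.importance(model = model$booster)
  gini <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  gini[imp$Feature] <- imp$Gain
  gini <- gini / sum(gini)
  acc <- function(Xm) mean((predict(model, Xm) > 0) == (y == 1))
  base <- acc(X[, model$feature_names, drop = FALSE])
  perm <- with_seed(subseed(config$seed, 37), {
    vapply(model$feature_names, function(nm) {
      drops <- vapply(seq_len(config$n_permutations), function(r) {
        Xp <- X
        Xp[, nm] <- X[sample(nrow(X)), nm]
        base - acc(Xp)
      }, numeric(1))
      c(mean(drops), sd(drops))
    }, numeric(2))
  })
  structure(data.frame(feature = model$feature_names, gini = unname(gini),
                       perm_mean = perm[1, ], perm_sd = perm[2, ],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("importance_report", "data.frame"))
}

#' Backward feature elimination under a performance guard
#'
#' Stepwise feature depletion: at each step, candidate features are tried
#' for removal in ascending Gini-importance order; the first whose removal
#' keeps the mean CV AUROC within `tolerance` of the best mean AUROC seen so
#' far is dropped. The procedure stops when no remaining feature can be
#' removed.
#'
#' @param X,y Features and labels (typically the scaled training split).
#' @param config A [model_config()].
#' @param tolerance Allowed AUROC slack (default from `config`).
#' @return List with `retained` (feature names), `trajectory` (data.frame:
#'   step, removed, mean_auroc), `final_auroc`.
#' @export
backward_eliminate <- function(X, y, config = model_config(),
                               tolerance = config$elimination_tolerance) {
  features <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  colnames(X) <- features
  if (length(features) < 2L) it_stop("need >= 2 features", "invalid_input")
  cv_auroc <- function(feats) {
    cross_validate(X[, feats, drop = FALSE], y, config)$mean_auroc
  }
  current <- features
  best <- cv_auroc(current)
  trajectory <- data.frame(step = 0L, removed = NA_character_,
                           mean_auroc = best)
  step <- 0L
  while (length(current) > 1L) {
    m <- fit_gbm(X[, current, drop = FALSE], y, config)
    imp <- importance(m, X[, current, drop = FALSE], y, config)
    order_try <- imp$feature[order(imp$gini)]
    removed <- NULL
    for (cand in order_try) {
      a <- cv_auroc(setdiff(current, cand))
      if (a >= best - tolerance) {
        removed <- cand
        current <- setdiff(current, cand)
        best <- max(best, a)
        step <- step + 1L
        trajectory <- rbind(trajectory,
                            data.frame(step = step, removed = cand,
                                       mean_auroc = a))
        break
      }
    }
    if (is.null(removed)) break
  }
  list(retained = current, trajectory = trajectory,
       final_auroc = trajectory$mean_auroc[nrow(trajectory)])
}
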