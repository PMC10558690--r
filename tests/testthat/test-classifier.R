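test_that("binarization labels positive enrichment 1, everything else 0", {
  prof <- profile_from_scores(c(0.5, -10, 0, 2, NA))
  lab <- binarize(prof)
  expect_equal(lab$label, c(1L, 0L, 0L, 1L))
  expect_equal(lab$site, c(1L, 2L, 3L, 4L))  # missing site dropped
})

test_that("the split is 80:20, scaling fits on train only, constants are flagged", {
  withr::with_seed(1, {
    X <- cbind(a = rnorm(100), b = runif(100), flat = rep(3, 100))
    y <- rep(c(0L, 1L), each = 50)
  })
  ds <- structure(list(X = X, y = y, feature_names = colnames(X),
                       site = 1:100, protein = rep("p", 100)),
                  class = "tol_dataset")
  sp <- split_and_scale(ds, model_config(seed = 4))
  expect_equal(length(sp$train$y), 80)
  expect_equal(length(sp$test$y), 20)
  expect_true(all(sp$train$X >= 0 & sp$train$X <= 1))
  expect_equal(sp$constant_features, "flat")
  expect_true(all(sp$train$X[, "flat"] == 0))
  # train-only fit: test values may leave [0, 1]
  expect_false(all(sp$test$X >= 0 & sp$test$X <= 1) &&
               isTRUE(all.equal(range(sp$test$X[, "a"]), c(0, 1))))
  # stratification keeps both classes in train
  expect_setequal(unique(sp$train$y), c(0L, 1L))

  ds1 <- ds; ds1$y <- rep(0L, 100)
  expect_error(split_and_scale(ds1, model_config()),
               class = "degenerate_split")
  ds2 <- ds; ds2$X <- ds$X[1:5, ]; ds2$y <- ds2$y[1:5]
  expect_error(split_and_scale(ds2), class = "invalid_input")
})

test_that("dataset assembly joins sites and rejects missing values", {
  sites <- data.frame(site = 1:6, f1 = rnorm(6), f2 = runif(6))
  labels <- data.frame(site = c(1:4, 6), label = c(1L, 0L, 1L, 0L, 1L))
  ds <- make_tol_dataset(sites, labels, "prot")
  expect_equal(nrow(ds$X), 5)
  expect_equal(ds$feature_names, c("f1", "f2"))
  sites$f1[2] <- NA
  expect_error(make_tol_dataset(sites, labels), class = "invalid_input")
})

test_that("cross-validation separates separable data and is reproducible", {
  withr::with_seed(7, {
    # discrete levels so every fold's training data brackets the boundary
    x <- sample(c(-2, -1, 1, 2), 120, replace = TRUE)
    X <- cbind(signal = x, junk = rnorm(120))
    y <- as.integer(x > 0)
  })
  cfg <- model_config(seed = 2)
  cv <- cross_validate(X, y, cfg)
  expect_equal(cv$mean_auroc, 1.0)
  expect_length(cv$fold_auroc, 5)
  cv2 <- cross_validate(X, y, cfg)
  expect_identical(cv$fold_auroc, cv2$fold_auroc)
  expect_identical(cv$fold_ap, cv2$fold_ap)
})

test_that("permuted labels yield chance-level cross-validated AUROC", {
  withr::with_seed(8, {
    X <- matrix(rnorm(120 * 4), 120)
    colnames(X) <- paste0("f", 1:4)
  })
  aurocs <- vapply(1:30, function(s) {
    y <- withr::with_seed(3000 + s, sample(rep(c(0L, 1L), each = 60)))
    cross_validate(X, y, model_config(seed = s, cv_folds = 5))$mean_auroc
  }, numeric(1))
  expect_gt(mean(aurocs), 0.4)
  expect_lt(mean(aurocs), 0.6)
})

test_that("ranking metrics behave at their extremes", {
  y <- c(0, 0, 1, 1)
  expect_equal(auroc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(y, c(0.9, 0.8, 0.2, 0.1)), 0)
  expect_equal(average_precision(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  # AP of a constant ranking equals the positive rate under tie order
  expect_equal(average_precision(c(1, 0, 1, 0), c(4, 3, 2, 1)), 5 / 6)
})

test_that("benchmarks report model, random and single-feature predictors", {
  withr::with_seed(9, {
    x <- rnorm(200)
    X <- cbind(signal = x, junk = rnorm(200))
    y <- as.integer(x + rnorm(200, 0, 0.4) > 0)
  })
  ds <- structure(list(X = X, y = y, feature_names = colnames(X),
                       site = seq_along(y), protein = rep("p", length(y))),
                  class = "tol_dataset")
  cfg <- model_config(seed = 5)
  sp <- split_and_scale(ds, cfg)
  model <- fit_gbm(sp$train$X, sp$train$y, cfg)
  bm <- evaluate_with_benchmarks(model, sp$test, sp$train, cfg)
  expect_setequal(bm$predictor, c("model", "random", "signal", "junk"))
  n0 <- sum(sp$test$y == 0); n1 <- sum(sp$test$y == 1)
  se <- sqrt((n0 + n1 + 1) / (12 * n0 * n1))
  expect_lt(abs(bm$auroc[bm$predictor == "random"] - 0.5), 3 * se)
  # the generating feature keeps pace with the model on near-separable data
  expect_lt(abs(bm$auroc[bm$predictor == "signal"] -
                bm$auroc[bm$predictor == "model"]), 0.05)
  expect_gt(bm$auroc[bm$predictor == "model"], 0.9)
})

test_that("importance measures identify the generating feature", {
  withr::with_seed(10, {
    x <- rnorm(300)
    X <- cbind(signal = x, n1 = rnorm(300), n2 = rnorm(300))
    y <- as.integer(x > 0)
  })
  cfg <- model_config(seed = 6)
  model <- fit_gbm(X, y, cfg)
  imp <- importance(model, X, y, cfg)
  expect_equal(sum(imp$gini), 1, tolerance = 1e-9)
  expect_true(all(imp$gini >= 0))
  expect_gt(imp$gini[imp$feature == "signal"], 0.9)
  expect_equal(imp$feature[which.max(imp$perm_mean)], "signal")
  expect_lt(max(abs(imp$perm_mean[imp$feature != "signal"])), 0.01)
})

test_that("a model trained on shuffled labels stays at chance on the test set", {
  withr::with_seed(11, {
    X <- matrix(rnorm(200 * 3), 200)
    colnames(X) <- paste0("f", 1:3)
    y <- sample(rep(c(0L, 1L), each = 100))
  })
  ds <- structure(list(X = X, y = y, feature_names = colnames(X),
                       site = 1:200, protein = rep("p", 200)),
                  class = "tol_dataset")
  cfg <- model_config(seed = 7)
  sp <- split_and_scale(ds, cfg)
  model <- fit_gbm(sp$train$X, sp$train$y, cfg)
  a <- auroc(sp$test$y, predict(model, sp$test$X))
  n0 <- sum(sp$test$y == 0); n1 <- sum(sp$test$y == 1)
  se <- sqrt((n0 + n1 + 1) / (12 * n0 * n1))
  expect_lt(abs(a - 0.5), 3.5 * se)
})

test_that("backward elimination honours its tolerance at the extremes", {
  withr::with_seed(12, {
    x <- rnorm(150)
    X <- cbind(signal = x, n1 = rnorm(150), n2 = rnorm(150),
               n3 = rnorm(150))
    y <- as.integer(x > 0)
  })
  cfg <- model_config(seed = 8)
  # tolerance 1: unconstrained removal down to a single feature
  free <- backward_eliminate(X, y, cfg, tolerance = 1)
  expect_length(free$retained, 1)
  # tolerance 0 on separable single-feature data keeps the separator
  strict <- backward_eliminate(X, y, cfg, tolerance = 0)
  expect_true("signal" %in% strict$retained)
  expect_error(backward_eliminate(X[, 1, drop = FALSE], y, cfg),
               class = "invalid_input")
})

test_that("boundary-noise threshold labels are learned well above chance", {
  pd <- planted_dataset(n = 400, n_noise = 5, seed = 13)
  cfg <- model_config(seed = 9)
  # realized flip rate close to its 10% calibration target
  expect_lt(abs(mean(pd$y != pd$clean) - 0.1), 0.05)
  cv <- cross_validate(pd$X, pd$y, cfg)
  expect_gte(cv$mean_auroc, 0.9)
  imp <- importance(cross_validate(pd$X, pd$y, cfg)$model, pd$X, pd$y, cfg)
  expect_true(imp$feature[which.max(imp$gini)] %in% pd$informative)
})
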