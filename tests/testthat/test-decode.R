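make_tfr <- function(ntrial = 40, chans = c("P3", "P4", "Pz"),
                     labels = rep(c("F1", "F4"), each = ntrial / 2)) {
  freqs <- seq(2, 48, 2)
  times <- seq(-0.8, 1.8, 0.1)
  set.seed(99)
  power <- array(stats::rexp(ntrial * length(chans) * 24 * length(times)),
                 dim = c(ntrial, length(chans), 24, length(times)))
  structure(list(power = power, freqs = freqs, times = times,
                 channels = data.frame(name = chans, type = "EEG"),
                 labels = labels, subject = "S01",
                 window_length = 0.4, fs = 250),
            class = "eeg_tfr")
}

test_that("feature extraction yields one column per channel with provenance", {
  tfr <- make_tfr()
  fs <- extract_features(tfr, list(band = c(26, 30), window = c(0.35, 0.65)))
  expect_equal(dim(fs$X), c(40, 3))
  expect_equal(fs$provenance$channel, c("P3", "P4", "Pz"))
  expect_false(anyNA(fs$X))
  # log features by default
  raw <- band_power(tfr, c(26, 30), c(0.35, 0.65))
  expect_equal(unname(fs$X), unname(log(raw)), tolerance = 1e-12)
})

test_that("duplicate feature columns from overlapping specs are rejected", {
  tfr <- make_tfr()
  expect_error(extract_features(tfr, list(
    list(band = c(26, 30), window = c(0.35, 0.65)),
    list(band = c(26, 30), window = c(0.35, 0.65), channels = "P4")
  )), "duplicate feature columns")
})

test_that("planted-effect channels carry the label information", {
  st <- processed_study(1)
  fs <- st$beta[["S01"]]
  keep <- fs$labels %in% c("F1", "F4")
  y <- as.numeric(fs$labels[keep] == "F4")
  r <- abs(suppressWarnings(stats::cor(fs$X[keep, ], y)))
  eff <- c("CP6", "TP10", "P8", "P4", "T8")
  on_eff <- r[fs$provenance$channel %in% eff]
  off_eff <- r[!(fs$provenance$channel %in% eff)]
  expect_gt(max(on_eff), max(off_eff))
})

test_that("a huge prior precision shrinks weights to zero and predicts the base rate", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  y <- rep(c("a", "b"), times = c(20, 30))
  fit <- fit_bayes_logistic(X, y, lambda = 1e8)
  expect_true(all(abs(fit$weights[-1]) < 1e-5))
  pr <- predict(fit, X, type = "prob")
  expect_equal(unname(pr), rep(0.6, 50), tolerance = 1e-3)
})

test_that("the MAP satisfies its optimality condition and matches a grid oracle", {
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  y <- c("n", "n", "p", "p")
  lambda <- 1
  fit <- fit_bayes_logistic(X, y, lambda = lambda)
  expect_lt(fit$grad_norm, 1e-6)
  # brute-force grid oracle over (intercept, weight)
  pen_ll <- function(b, w) {
    eta <- b + w * X[, 1]
    sum(ifelse(y == "p", stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE))) - lambda * w^2 / 2
  }
  grid <- expand.grid(b = seq(-4, 4, 0.01), w = seq(-1, 6, 0.01))
  ll <- mapply(pen_ll, grid$b, grid$w)
  best <- grid[which.max(ll), ]
  expect_equal(fit$weights[1], best$b, tolerance = 0.02)
  expect_equal(fit$weights[2], best$w, tolerance = 0.02)
  expect_gte(pen_ll(fit$weights[1], fit$weights[2]), max(ll) - 1e-8)
  # decision boundary separates the toy set like the oracle
  expect_identical(predict(fit, X, type = "class"), c("n", "n", "p", "p"))
})

test_that("separable data keep finite weights through the prior", {
  X <- matrix(c(-5, -4, 4, 5), 4, 1)
  fit <- fit_bayes_logistic(X, c(0, 0, 1, 1), lambda = 0.1)
  expect_true(all(is.finite(fit$weights)))
  expect_true(fit$converged)
})

test_that("stratified folds partition trials with balanced classes", {
  y <- rep(c("a", "b"), times = c(23, 27))
  folds <- make_stratified_folds(y, k = 5, seed = 1)
  expect_equal(sort(unique(folds)), 1:5)
  expect_length(folds, 50)
  tab <- table(y, folds)
  expect_true(all(abs(tab["a", ] - 23 / 5) < 1))
  expect_true(all(abs(tab["b", ] - 27 / 5) < 1))
  expect_error(make_stratified_folds(rep(c("a", "b"), c(3, 47)), k = 5),
               "stratification error")
})

test_that("cross-validation is at chance for permuted labels and high for separable data", {
  set.seed(8)
  X <- matrix(rnorm(120 * 6), 120, 6)
  y <- sample(rep(c("a", "b"), 60))      # labels independent of features
  cv <- crossval_accuracy(X, y, k = 5, seed = 2)
  expect_gt(cv$accuracy, 0.3)
  expect_lt(cv$accuracy, 0.7)
  # large-margin separable features
  y2 <- rep(c("a", "b"), 60)
  X2 <- matrix(rnorm(120 * 2), 120, 2)
  X2[, 1] <- X2[, 1] + ifelse(y2 == "b", 8, -8)
  cv2 <- crossval_accuracy(X2, y2, k = 5, seed = 2)
  expect_gte(cv2$accuracy, 0.95)
})

test_that("fold assignments cover all trials and predictions match a manual oracle", {
  set.seed(10)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(c("a", "b"), 30)
  cv <- crossval_accuracy(X, y, k = 5, seed = 4)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_length(cv$predictions, 60)
  # recompute fold 2 by hand: train-only standardization, same model
  te <- cv$folds == 2
  mu <- colMeans(X[!te, ]); sdv <- apply(X[!te, ], 2, sd)
  Xtr <- scale(X[!te, ], mu, sdv); Xte <- scale(X[te, ], mu, sdv)
  fit <- fit_bayes_logistic(Xtr, factor(y[!te]), lambda = 1)
  expect_identical(unname(predict(fit, Xte, type = "class")),
                   cv$predictions[te])
  # leakage check: test-fold feature values do not affect training
  X2 <- X; X2[te, ] <- X2[te, ] * 100 + 50
  cv2 <- crossval_accuracy(X2, y, k = 5, seed = 4)
  fit2 <- fit_bayes_logistic(Xtr, factor(y[!te]), lambda = 1)
  expect_identical(fit2$weights, fit$weights)
  expect_identical(cv2$folds, cv$folds)
})

test_that("one-vs-rest is at chance for permuted 4-class labels, perfect for one-hot", {
  set.seed(12)
  X <- matrix(rnorm(160 * 6), 160, 6)
  y <- sample(rep(paste0("F", 1:4), 40))
  cv <- one_vs_rest_accuracy(X, y, k = 5, seed = 3)
  expect_gt(cv$accuracy, 0.10)
  expect_lt(cv$accuracy, 0.40)
  # features that encode class identity exactly
  y2 <- rep(paste0("F", 1:4), 40)
  X2 <- stats::model.matrix(~ 0 + factor(y2)) * 3 +
    matrix(rnorm(160 * 4, sd = 0.01), 160, 4)
  cv2 <- one_vs_rest_accuracy(X2, y2, k = 5, seed = 3)
  expect_gte(cv2$accuracy, 0.99)
})

test_that("graded four-class accuracy beats chance and is bounded by the best pair", {
  set.seed(14)
  y <- rep(paste0("F", 1:4), 30)
  X <- matrix(rnorm(120 * 2, sd = 0.8), 120, 2)
  X[, 1] <- X[, 1] + as.integer(factor(y))    # graded signal
  cv4 <- one_vs_rest_accuracy(X, y, k = 5, seed = 6)
  pair_acc <- vapply(list(c("F1", "F2"), c("F1", "F3"), c("F1", "F4"),
                          c("F2", "F3"), c("F2", "F4"), c("F3", "F4")),
                     function(pr) {
                       keep <- y %in% pr
                       crossval_accuracy(X[keep, ], y[keep], k = 5,
                                         seed = 6)$accuracy
                     }, numeric(1))
  expect_gt(cv4$accuracy, 0.25 + 0.1)
  expect_lte(cv4$accuracy, max(pair_acc))
})

test_that("per-subject aggregation returns fold-mean accuracies and SEM", {
  st <- processed_study(1)
  d <- decode_subjects(st$beta[1:3], c("F1", "F4"), seed = 5)
  expect_length(d$subject_accuracy, 3)
  expect_equal(d$mean_accuracy, mean(d$subject_accuracy))
  expect_equal(d$chance, 0.5)
  expect_equal(d$subject_accuracy[[1]],
               mean(d$cv_results[[1]]$fold_accuracy))
})
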