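#' Extract single-trial band-power features
#'
#' One feature column per selected channel and band/window specification:
#' band- and window-averaged log power (log by default — power has a heavy
#' right tail and the log stabilizes it for classification). Feature
#' provenance (channel, band, window) is recorded and duplicated columns
#' arising from overlapping specifications are rejected.
#'
#' Standardization is deliberately NOT applied here: inside cross-validation
#' it must use training-fold statistics only, which
#' [crossval_accuracy()] does.
#'
#' @param tfr an `eeg_tfr`.
#' @param specs a single spec — `list(band =, window =, channels = NULL)` —
#'   or a list of such specs.
#' @param log log-transform the power features (default TRUE).
#' @return A `feature_set`: list with `X` (trials x features), `provenance`
#'   data.frame, `labels`, `subject`.
#' @export
extract_features <- function(tfr, specs, log = TRUE) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (!is.null(specs$band)) specs <- list(specs)
  cols <- list(); prov <- list()
  for (sp in specs) {
    chans <- if (is.null(sp$channels)) tfr$channels$name else sp$channels
    f <- band_power(tfr, sp$band, sp$window, channels = chans, log = log)
    cols[[length(cols) + 1]] <- f
    prov[[length(prov) + 1]] <- data.frame(
      channel = chans,
      f_lo = sp$band[1], f_hi = sp$band[2],
      t_lo = sp$window[1], t_hi = sp$window[2],
      stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, cols)
  provenance <- do.call(rbind, prov)
  key <- do.call(paste, provenance)
  if (anyDuplicated(key)) {
    stop("duplicate feature columns from overlapping specifications: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  colnames(X) <- paste0(provenance$channel, "_", provenance$f_lo, "-",
                        provenance$f_hi, "Hz")
  if (anyNA(X)) stop("feature matrix contains missing values")
  structure(list(X = X, provenance = provenance, labels = tfr$labels,
                 subject = tfr$subject),
            class = "feature_set")
}

#' MAP estimate of a Bayesian logistic classifier
#'
#' Binary logistic regression with a zero-mean isotropic Gaussian prior of
#' precision `lambda` on the weights (the intercept is unpenalized),
#' estimated by Newton iteratively-reweighted least squares on the
#' penalized log-likelihood. The prior guarantees finite weights even on
#' separable data. Predictive probabilities use the logistic link at the
#' MAP; `predict(..., moderated = TRUE)` applies the Laplace-approximate
#' moderation `plogis(eta / sqrt(1 + pi * s2 / 8))` with `s2` the predictive
#' variance from the inverse Hessian.
#'
#' @param X numeric trials x features matrix (no missing values).
#' @param y binary labels: factor, or any vector with exactly two unique
#'   values; the second level is coded 1.
#' @param lambda prior precision (> 0, default 1).
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return A `bayes_logistic` model: `weights` (intercept first), `lambda`,
#'   `levels`, `converged`, `n_iter`, `grad_norm`, and the Hessian of the
#'   negative penalized log-likelihood at the MAP.
#' @export
fit_bayes_logistic <- function(X, y, lambda = 1, max_iter = 100,
                               tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(lambda > 0, nrow(X) == length(y), !anyNA(X))
  f <- factor(y)
  if (nlevels(f) != 2) stop("both classes must be present (got ",
                            nlevels(f), ")")
  yy <- as.numeric(f == levels(f)[2])
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  D <- diag(c(0, rep(lambda, p - 1)), p)
  w <- numeric(p)
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xd %*% w)
    mu <- stats::plogis(eta)
    g <- as.vector(crossprod(Xd, yy - mu)) - D %*% w
    grad_norm <- sqrt(sum(g^2))
    if (grad_norm < tol) break
    wgt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * wgt, Xd) + D
    w <- w + solve(H, g)
  }
  if (grad_norm >= tol) {
    # re-evaluate at the final weights
    eta <- as.vector(Xd %*% w)
    mu <- stats::plogis(eta)
    g <- as.vector(crossprod(Xd, yy - mu)) - D %*% w
    grad_norm <- sqrt(sum(g^2))
  }
  if (grad_norm >= tol) {
    stop(sprintf(
      "IRLS did not converge in %d iterations (gradient norm %.3g, lambda %.3g)",
      max_iter, grad_norm, lambda))
  }
  eta <- as.vector(Xd %*% w)
  mu <- stats::plogis(eta)
  H <- crossprod(Xd * pmax(mu * (1 - mu), 1e-10), Xd) + D
  structure(list(weights = as.vector(w), lambda = lambda,
                 levels = levels(f), converged = TRUE, n_iter = it,
                 grad_norm = grad_norm, hessian = H),
            class = "bayes_logistic")
}

#' @param object a `bayes_logistic` model.
#' @param newdata trials x features matrix.
#' @param type `"prob"` for P(class 2) or `"class"` for hard labels.
#' @param moderated use Laplace-approximate moderated probabilities.
#' @param ... unused.
#' @rdname fit_bayes_logistic
#' @export
predict.bayes_logistic <- function(object, newdata, type = c("prob", "class"),
                                   moderated = FALSE, ...) {
  type <- match.arg(type)
  Xd <- cbind(1, as.matrix(newdata))
  eta <- as.vector(Xd %*% object$weights)
  if (moderated) {
    Hinv <- solve(object$hessian)
    s2 <- rowSums((Xd %*% Hinv) * Xd)
    eta <- eta / sqrt(1 + pi * s2 / 8)
  }
  pr <- stats::plogis(eta)
  if (type == "prob") pr else {
    object$levels[ifelse(pr > 0.5, 2L, 1L)]
  }
}

#' Stratified k-fold assignment
#'
#' Folds partition the trials; per-class counts per fold differ by at most
#' one trial. Errors if any class has fewer members than `k`.
#'
#' @param y label vector.
#' @param k number of folds.
#' @param seed seed for the within-class shuffles.
#' @return Integer fold id (1..k) per trial.
#' @export
make_stratified_folds <- function(y, k = 5, seed = NULL) {
  f <- factor(y)
  if (any(table(f) < k)) {
    stop("stratification error: every class needs at least k = ", k,
         " members")
  }
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(f)) {
    idx <- sample(which(f == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

standardize_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv < .Machine$double.eps * 100] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

cv_result <- function(fold_acc, confusion, k, seed, folds, predictions) {
  structure(list(fold_accuracy = fold_acc,
                 accuracy = mean(fold_acc),
                 sem = stats::sd(fold_acc) / sqrt(length(fold_acc)),
                 confusion = confusion, k = k, seed = seed,
                 folds = folds, predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold accuracy %.3f (SEM %.3f)\n",
              x$k, x$accuracy, x$sem))
  print(x$confusion)
  invisible(x)
}

#' Cross-validated two-class decoding accuracy
#'
#' Stratified k-fold cross-validation of the regularized logistic
#' classifier. Features are standardized with training-fold statistics
#' only; accuracy is the fraction of correct held-out predictions per fold,
#' summarized as the fold mean and SEM.
#'
#' @param X trials x features matrix or a `feature_set`.
#' @param y binary labels (defaults to the `feature_set` labels).
#' @param k number of folds (default 5).
#' @param lambda prior precision of the classifier.
#' @param seed fold-assignment seed.
#' @param moderated moderated predictive probabilities (see
#'   [fit_bayes_logistic()]).
#' @return A `cv_result` with per-fold accuracies, mean, SEM, pooled
#'   confusion counts, fold ids and held-out predictions.
#' @export
crossval_accuracy <- function(X, y = NULL, k = 5, lambda = 1, seed = NULL,
                              moderated = FALSE) {
  if (inherits(X, "feature_set")) {
    if (is.null(y)) y <- X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  f <- factor(y)
  if (nlevels(f) != 2) stop("crossval_accuracy needs exactly 2 classes")
  folds <- make_stratified_folds(f, k, seed)
  pred <- character(length(y))
  fold_acc <- numeric(k)
  for (fd in seq_len(k)) {
    te <- folds == fd
    if (length(unique(f[!te])) < 2) {
      stop("stratification error: a class is absent from a training fold")
    }
    st <- standardize_train_test(X[!te, , drop = FALSE],
                                 X[te, , drop = FALSE])
    fit <- fit_bayes_logistic(st$train, f[!te], lambda = lambda)
    pred[te] <- predict(fit, st$test, type = "class", moderated = moderated)
    fold_acc[fd] <- mean(pred[te] == as.character(f[te]))
  }
  cv_result(fold_acc, table(truth = as.character(f), predicted = pred),
            k, seed, folds, pred)
}

#' Cross-validated multi-class accuracy, one-vs-rest
#'
#' One binary classifier per class (that class against the rest); the
#' predicted class is the argmax of the predictive probabilities, ties
#' broken towards the lowest class index (first factor level).
#'
#' @inheritParams crossval_accuracy
#' @param y multi-class labels.
#' @return A `cv_result`.
#' @export
one_vs_rest_accuracy <- function(X, y = NULL, k = 5, lambda = 1,
                                 seed = NULL, moderated = FALSE) {
  if (inherits(X, "feature_set")) {
    if (is.null(y)) y <- X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  f <- factor(y)
  if (nlevels(f) < 2) stop("need at least 2 classes")
  folds <- make_stratified_folds(f, k, seed)
  pred <- character(length(y))
  fold_acc <- numeric(k)
  for (fd in seq_len(k)) {
    te <- folds == fd
    st <- standardize_train_test(X[!te, , drop = FALSE],
                                 X[te, , drop = FALSE])
    probs <- vapply(levels(f), function(lv) {
      yy <- factor(ifelse(f[!te] == lv, "pos", "rest"),
                   levels = c("rest", "pos"))
      if (length(unique(yy)) < 2) {
        stop("stratification error: class ", lv,
             " absent from a training fold")
      }
      fit <- fit_bayes_logistic(st$train, yy, lambda = lambda)
      predict(fit, st$test, type = "prob", moderated = moderated)
    }, numeric(sum(te)))
    probs <- matrix(probs, nrow = sum(te))
    pick <- apply(probs, 1, which.max)  # which.max takes the first maximum
    pred[te] <- levels(f)[pick]
    fold_acc[fd] <- mean(pred[te] == as.character(f[te]))
  }
  cv_result(fold_acc, table(truth = as.character(f), predicted = pred),
            k, seed, folds, pred)
}

#' Per-subject decoding summary
#'
#' Runs the per-subject cross-validation (two-class via
#' [crossval_accuracy()] when `classes` has length 2, otherwise
#' one-vs-rest) and aggregates: subject accuracies are the fold means
#' (models are never pooled across subjects), and the group summary is
#' their mean and SEM across subjects.
#'
#' @param feature_sets list of `feature_set` objects, one per subject.
#' @param classes which label values to decode (e.g. `c("F1", "F4")` or all
#'   four); trials with other labels are dropped.
#' @param k,lambda,seed forwarded to the CV routines.
#' @return List with `subject_accuracy`, `mean_accuracy`, `sem` (across
#'   subjects), `chance` (1 / number of classes) and the per-subject
#'   `cv_results`.
#' @export
decode_subjects <- function(feature_sets, classes, k = 5, lambda = 1,
                            seed = 1L) {
  stopifnot(length(feature_sets) >= 1, length(classes) >= 2)
  res <- vector("list", length(feature_sets))
  acc <- numeric(length(feature_sets))
  for (i in seq_along(feature_sets)) {
    fs <- feature_sets[[i]]
    keep <- fs$labels %in% classes
    Xi <- fs$X[keep, , drop = FALSE]
    yi <- factor(fs$labels[keep], levels = classes)
    r <- if (length(classes) == 2) {
      crossval_accuracy(Xi, yi, k = k, lambda = lambda,
                        seed = derive_seed(seed, i))
    } else {
      one_vs_rest_accuracy(Xi, yi, k = k, lambda = lambda,
                           seed = derive_seed(seed, i))
    }
    res[[i]] <- r
    acc[i] <- r$accuracy
  }
  names(acc) <- names(feature_sets)
  list(subject_accuracy = acc,
       mean_accuracy = mean(acc),
       sem = stats::sd(acc) / sqrt(length(acc)),
       chance = 1 / length(classes),
       cv_results = res)
}
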