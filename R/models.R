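#' Fixed model zoo configuration
#'
#' The evaluation models and their hyperparameters are fixed for a run:
#' classification uses SVM (C = 1, RBF kernel, "scale" gamma
#' \eqn{1/(p \cdot Var(X))}), LR (L2-penalized logistic regression, C = 1),
#' KNN (5 neighbors, Minkowski/Euclidean distance, uniform weights), RF
#' (100 trees, Gini impurity) and AdaBoost (50 stumps, real/SAMME.R
#' boosting, learning rate 1.0); regression uses SVR (RBF,
#' \eqn{\epsilon}-insensitive, C = 1, "scale" gamma) and an RF regressor
#' (100 trees). Every stochastic component is seeded with `random_state`.
#'
#' Library mapping (recorded here once): SVM/SVR via e1071/libsvm with
#' `gamma = 1/(p * var(X_train))`; LR via glmnet ridge at
#' `lambda = 1/(n * C)`; KNN via class::knn (Euclidean = Minkowski p = 2);
#' RF via randomForest; AdaBoost implemented in-package as real (SAMME.R)
#' boosting over rpart depth-1 stumps.
#'
#' @param task `"classification"` or `"regression"`.
#' @param random_state seed applied before each stochastic fit (default 0).
#' @return object of class `model_config` with a `models` name vector.
#' @export
model_config <- function(task = c("classification", "regression"),
                         random_state = 0L) {
  task <- match.arg(task)
  models <- if (task == "classification")
    c("SVM", "LR", "KNN", "RF", "AdaBoost") else c("SVR", "RF")
  structure(list(task = task, models = models,
                 random_state = as.integer(random_state)),
            class = "model_config")
}

# scikit-learn's gamma = "scale": 1 / (n_features * Var(all training values))
gamma_scale <- function(X) {
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

# Train `model` on (Xtr, ytr) and predict on Xte. Classification: ytr is a
# two-level factor (negative level first); returns predicted factor labels.
# Regression: ytr numeric; returns numeric predictions.
fit_predict <- function(model, Xtr, ytr, Xte, random_state = 0L) {
  n <- nrow(Xtr)
  # degenerate design (no training variance anywhere): every model reduces
  # to its intercept — the majority class, or the mean response
  if (all(apply(Xtr, 2L, stats::sd) == 0)) {
    if (is.factor(ytr)) {
      maj <- levels(ytr)[which.max(tabulate(ytr, nlevels(ytr)))]
      return(factor(rep(maj, nrow(Xte)), levels = levels(ytr)))
    }
    return(rep(mean(ytr), nrow(Xte)))
  }
  switch(model,
    SVM = {
      fit <- with_seed(random_state,
        e1071::svm(Xtr, ytr, kernel = "radial", cost = 1,
                   gamma = gamma_scale(Xtr), scale = FALSE))
      stats::predict(fit, Xte)
    },
    LR = {
      fit <- glmnet::glmnet(pad_for_glmnet(Xtr), ytr, family = "binomial",
                            alpha = 0, lambda = 1 / n, standardize = FALSE)
      pr <- as.numeric(stats::predict(fit, pad_for_glmnet(Xte), s = 1 / n,
                                      type = "response"))
      factor(levels(ytr)[1L + (pr > 0.5)], levels = levels(ytr))
    },
    KNN = {
      with_seed(random_state,
        class::knn(Xtr, Xte, cl = ytr, k = min(5L, n)))
    },
    RF = {
      with_seed(random_state, {
        fit <- randomForest::randomForest(Xtr, ytr, ntree = 100L)
        stats::predict(fit, Xte)
      })
    },
    AdaBoost = {
      fit <- with_seed(random_state,
        adaboost_fit(Xtr, ytr, n_estimators = 50L, learning_rate = 1))
      adaboost_predict(fit, Xte)
    },
    SVR = {
      fit <- with_seed(random_state,
        e1071::svm(Xtr, ytr, type = "eps-regression", kernel = "radial",
                   cost = 1, epsilon = 0.1, gamma = gamma_scale(Xtr),
                   scale = FALSE))
      as.numeric(stats::predict(fit, Xte))
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

# ---- AdaBoost (binary, real boosting / SAMME.R with depth-1 stumps) -------
#
# Each round fits a weighted rpart stump, converts its class-probability
# estimates into half-log-odds contributions h_m(x) = 0.5 log(p1/p0), and
# reweights samples by exp(-y * h_m(x)) with y in {-1, +1}. The final label
# is the sign of the (learning-rate scaled) sum of contributions.

adaboost_fit <- function(X, y, n_estimators = 50L, learning_rate = 1,
                         eps = 1e-6) {
  stopifnot(is.factor(y), nlevels(y) == 2L)
  n <- nrow(X)
  ypm <- ifelse(as.integer(y) == 2L, 1, -1)    # positive = second level
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(df)))  # formula-safe names
  w <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(maxdepth = 1L, minsplit = 2L, minbucket = 1L,
                               cp = 0, xval = 0L, maxcompete = 0L,
                               maxsurrogate = 0L)
  stumps <- vector("list", n_estimators)
  used <- 0L
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = cbind(df, .y = y), weights = w,
                        method = "class", control = ctrl)
    pr <- stats::predict(fit, df, type = "prob")
    p1 <- pmin(pmax(pr[, 2L], eps), 1 - eps)
    h <- 0.5 * log(p1 / (1 - p1))
    used <- used + 1L
    stumps[[used]] <- fit
    w <- w * exp(-learning_rate * ypm * h)
    s <- sum(w)
    if (!is.finite(s) || s <= 0) break
    w <- w / s
  }
  structure(list(stumps = stumps[seq_len(used)], levels = levels(y),
                 learning_rate = learning_rate, eps = eps),
            class = "profwise_adaboost")
}

adaboost_predict <- function(fit, Xte) {
  df <- as.data.frame(Xte)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  score <- numeric(nrow(df))
  for (st in fit$stumps) {
    pr <- stats::predict(st, df, type = "prob")
    p1 <- pmin(pmax(pr[, 2L], fit$eps), 1 - fit$eps)
    score <- score + fit$learning_rate * 0.5 * log(p1 / (1 - p1))
  }
  factor(fit$levels[1L + (score > 0)], levels = fit$levels)
}
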