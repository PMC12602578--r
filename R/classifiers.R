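#' Feature selectors and classifiers used by the evaluation grid
#'
#' Three tree-based importance selectors (DT, RF, XGB) and seven classifiers
#' (DT, ET, KNN, RF, SVM, XGB, SGD) behind one interface:
#' [feature_importance()] ranks features, [fit_classifier()] /
#' [predict_scores()] train and score. All fits are single-threaded and
#' seeded so the grid is deterministic. Hyperparameters are the libraries'
#' defaults at desk scale (200 trees for the forests, 50 boosting rounds,
#' depth-3 trees for XGBoost, k = 5 neighbours, radial-kernel SVM); the SGD
#' classifier is logistic regression fitted by stochastic gradient descent on
#' the log loss, so a probability score exists for the AUC.
#'
#' @name classifiers
NULL

SELECTORS <- c("DT", "RF", "XGB")
CLASSIFIERS <- c("DT", "ET", "KNN", "RF", "SVM", "XGB", "SGD")

# gradient-boosted trees on a binary outcome; probability of class "1"
# comes from predict(type = "response")
xgb_fit <- function(x, y) {
  xgboost::xgboost(x, factor(y, levels = c("0", "1")), nrounds = 50,
                   max_depth = 3, learning_rate = 0.3, nthreads = 1,
                   verbosity = 0)
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  force(code)
}

#' Importance scores for every feature from a tree-based selector
#'
#' @param x numeric matrix (samples x features).
#' @param y 0/1 outcome vector.
#' @param selector `"DT"` (rpart), `"RF"` (ranger impurity importance) or
#'   `"XGB"` (xgboost gain).
#' @param seed RNG seed for the stochastic selectors.
#' @return named numeric vector, one non-negative score per feature (0 for
#'   features the model never used).
#' @export
feature_importance <- function(x, y, selector, seed = 1L) {
  if (!selector %in% SELECTORS)
    stop("unknown selector '", selector, "'; valid: ",
         paste(SELECTORS, collapse = ", "))
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (selector == "DT") {
    df <- data.frame(.y = factor(y), x, check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(cp = 0, minsplit = 5,
                                                       xval = 0))
    vi <- fit$variable.importance
    imp[names(vi)] <- vi
  } else if (selector == "RF") {
    fit <- with_seed(seed,
      ranger::ranger(x = x, y = factor(y), num.trees = 200,
                     importance = "impurity", num.threads = 1,
                     seed = seed))
    imp[names(fit$variable.importance)] <- fit$variable.importance
  } else {
    fit <- with_seed(seed, xgb_fit(x, y))
    it <- xgboost::xgb.importance(model = fit)
    imp[it$Feature] <- it$Gain
  }
  imp
}

## logistic regression by stochastic gradient descent (log loss)
sgd_logistic_fit <- function(x, y, epochs = 30, eta0 = 0.5, seed = 1L) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd, `/`)
  w <- numeric(ncol(x) + 1)
  t <- 0
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(nrow(z))) {
        t <- t + 1
        eta <- eta0 / (1 + 0.01 * t)
        xi <- c(1, z[i, ])
        p <- stats::plogis(sum(w * xi))
        w <- w + eta * (y[i] - p) * xi
      }
    }
  })
  list(w = w, mu = mu, sd = sd)
}

sgd_logistic_predict <- function(fit, x) {
  z <- sweep(sweep(x, 2, fit$mu), 2, fit$sd, `/`)
  stats::plogis(drop(cbind(1, z) %*% fit$w))
}

#' Fit one of the seven grid classifiers
#'
#' @param name one of `"DT"`, `"ET"`, `"KNN"`, `"RF"`, `"SVM"`, `"XGB"`,
#'   `"SGD"`.
#' @param x numeric training matrix (samples x features).
#' @param y 0/1 outcome vector.
#' @param seed RNG seed.
#' @return a `radgrid_classifier` for [predict_scores()].
#' @export
fit_classifier <- function(name, x, y, seed = 1L) {
  if (!name %in% CLASSIFIERS)
    stop("unknown classifier '", name, "'; valid: ",
         paste(CLASSIFIERS, collapse = ", "))
  fit <- switch(
    name,
    DT = {
      df <- data.frame(.y = factor(y), x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 5, xval = 0))
    },
    ET = with_seed(seed,
      ranger::ranger(x = x, y = factor(y), num.trees = 200,
                     splitrule = "extratrees", num.random.splits = 1,
                     probability = TRUE, num.threads = 1, seed = seed)),
    KNN = list(x = x, y = y, k = 5,
               mu = colMeans(x),
               sd = {s <- apply(x, 2, stats::sd); s[s == 0] <- 1; s}),
    RF = with_seed(seed,
      ranger::ranger(x = x, y = factor(y), num.trees = 200,
                     probability = TRUE, num.threads = 1, seed = seed)),
    SVM = e1071::svm(x = x, y = factor(y), kernel = "radial",
                     scale = apply(x, 2, stats::sd) > 0),
    XGB = with_seed(seed, xgb_fit(x, y)),
    SGD = sgd_logistic_fit(x, y, seed = seed))
  structure(list(name = name, fit = fit, seed = seed),
            class = "radgrid_classifier")
}

#' Prediction scores (probability of pCR or a monotone surrogate)
#'
#' @param model a `radgrid_classifier`.
#' @param x numeric matrix on the training feature set.
#' @return numeric score per row; higher = more pCR-like. Probabilities for
#'   all classifiers except SVM, which uses the (orientation-corrected)
#'   decision values.
#' @export
predict_scores <- function(model, x) {
  fit <- model$fit
  switch(
    model$name,
    DT = {
      pr <- stats::predict(fit, data.frame(x, check.names = FALSE),
                           type = "prob")
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(x))
    },
    ET = ,
    RF = {
      pr <- stats::predict(fit, data = x, num.threads = 1)$predictions
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(x))
    },
    KNN = {
      ztr <- sweep(sweep(fit$x, 2, fit$mu), 2, fit$sd, `/`)
      zte <- sweep(sweep(x, 2, fit$mu), 2, fit$sd, `/`)
      with_seed(model$seed, {
        pred <- class::knn(ztr, zte, factor(fit$y), k = fit$k, prob = TRUE)
        pwin <- attr(pred, "prob")
        ifelse(pred == "1", pwin, 1 - pwin)
      })
    },
    SVM = {
      pr <- stats::predict(fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision values are oriented toward the first named class
      if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    },
    XGB = as.numeric(stats::predict(fit, x, type = "response")),
    SGD = sgd_logistic_predict(fit, x))
}
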