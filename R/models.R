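# The seven-classifier benchmark. Each entry of the model registry maps a
# short method name to an established algorithm family:
#   glmnet     elastic-net logistic regression
#   rf         random forest (ranger)
#   svmRadial  RBF-kernel support vector classifier (kernlab)
#   bayesglm   weak-Gaussian-prior (ridge-MAP) logistic regression;
#              no tuned hyperparameters
#   nn         single-hidden-layer feed-forward network (nnet)
#   knn        k-nearest neighbours (odd k)
#   pls        partial-least-squares discriminant analysis (mixOmics)
# Hyperparameters are tuned by capped uniform random search, scored by the
# mean fold-wise true positive rate (TB = positive class) under k-fold
# resampling of the training windows.

#' Tuning configuration
#'
#' @param resampling_folds Number of resampling folds within the training
#'   set (clamped to the training size with a warning when larger).
#' @param budget Maximum number of random hyperparameter points evaluated.
#' @param seed Integer seed; fold assignment depends only on this seed and
#'   the training size, so models tuned with the same seed share folds and
#'   their resampling profiles are pairwise comparable.
#' @return An object of class `tune_config`.
#' @export
tune_config <- function(resampling_folds = 200L, budget = 10L, seed = 1L) {
  cfg <- list(resampling_folds = as.integer(resampling_folds),
              budget = as.integer(budget), seed = as.integer(seed))
  if (cfg$resampling_folds < 2L) stop("tune_config: folds must be >= 2")
  if (cfg$budget < 1L) stop("tune_config: budget must be >= 1")
  class(cfg) <- "tune_config"
  cfg
}

#' Names of the benchmarked classifiers
#' @return Character vector of the seven method names.
#' @export
tb_methods <- function() {
  c("glmnet", "rf", "svmRadial", "bayesglm", "nn", "knn", "pls")
}

# --- registry -------------------------------------------------------------

sample_finite <- function(values, budget, what) {
  if (budget > length(values)) {
    warning("random-search budget ", budget, " exceeds the ", length(values),
            " distinct ", what, " values; deduplicated")
    budget <- length(values)
  }
  sample(values, budget)
}

model_registry <- function() {
  list(
    glmnet = list(
      space = function(budget)
        data.frame(alpha = runif(budget), lambda = 10^runif(budget, -4, 0)),
      fit = function(x, y, par)
        list(par = par,
             m = glmnet::glmnet(x, y, family = "binomial",
                                alpha = par$alpha, lambda = par$lambda)),
      predict = function(fit, x)
        as.character(predict(fit$m, x, s = fit$par$lambda, type = "class"))),
    rf = list(
      space = function(budget) {
        # mtry as a fraction of the feature count, resolved at fit time
        data.frame(mtry_frac = runif(budget, 0.05, 0.7),
                   min.node.size = sample(1:10, budget, replace = TRUE))
      },
      fit = function(x, y, par)
        ranger::ranger(x = x, y = y, num.trees = 300L,
                       mtry = max(1L, floor(par$mtry_frac * ncol(x))),
                       min.node.size = par$min.node.size,
                       classification = TRUE),
      predict = function(fit, x)
        as.character(predict(fit, data = x)$predictions)),
    svmRadial = list(
      space = function(budget)
        data.frame(C = 2^runif(budget, -5, 7),
                   sigma = 10^runif(budget, -3, 0)),
      fit = function(x, y, par)
        kernlab::ksvm(x, y, kernel = "rbfdot",
                      kpar = list(sigma = par$sigma), C = par$C,
                      scaled = FALSE),
      predict = function(fit, x) as.character(kernlab::predict(fit, x))),
    bayesglm = list(
      space = function(budget) data.frame(.none = 1),  # nothing to tune
      fit = function(x, y, par)
        glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 1e-3),
      predict = function(fit, x)
        as.character(predict(fit, x, s = 1e-3, type = "class"))),
    nn = list(
      space = function(budget)
        data.frame(size = sample(1:8, budget, replace = TRUE),
                   decay = 10^runif(budget, -4, 0)),
      fit = function(x, y, par)
        nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2L, drop = FALSE],
                   size = par$size, decay = par$decay, maxit = 200L,
                   trace = FALSE, MaxNWts = 20000L, entropy = TRUE),
      predict = function(fit, x) {
        p <- predict(fit, x)
        ifelse(p[, 1L] > 0.5, "TB", "CTL")
      }),
    knn = list(
      space = function(budget)
        data.frame(k = sample_finite(seq(3L, 31L, by = 2L), budget,
                                     "neighbour-count")),
      fit = function(x, y, par) list(x = x, y = y, k = par$k),
      predict = function(fit, x)
        as.character(class::knn(fit$x, x, fit$y, k = fit$k))),
    pls = list(
      space = function(budget)
        data.frame(ncomp = sample_finite(1:10, budget, "component-count")),
      fit = function(x, y, par) {
        nc <- min(par$ncomp, ncol(x), nrow(x) - 1L)
        mixOmics::plsda(x, y, ncomp = nc)
      },
      predict = function(fit, x) {
        colnames(x) <- colnames(fit$X)
        p <- predict(fit, newdata = x)
        as.character(p$class$max.dist[, fit$ncomp])
      })
  )
}

fold_tpr <- function(pred, truth) {
  pos <- truth == "TB"
  if (!any(pos)) return(NA_real_)
  sum(pred == "TB" & pos) / sum(pos)
}

#' Tune and fit one classifier on labeled windows
#'
#' Samples up to `budget` hyperparameter points uniformly from the method's
#' space, scores each by the mean fold-wise true positive rate (TB positive)
#' under k-fold resampling of the training windows, selects the best point,
#' and refits it on the full training set. Folds that contain no TB window
#' contribute a missing TPR and are excluded from the mean. The whole
#' procedure is a pure function of `(x, y, method, tune)`.
#'
#' @param x Numeric feature matrix (e.g. PCA scores from
#'   [preprocess_windows()]), one row per window.
#' @param y Window labels (`"TB"`/`"CTL"`); both classes must be present.
#' @param method One of [tb_methods()].
#' @param tune A [tune_config()].
#' @return An object of class `tb_fit` with the fitted classifier, the
#'   selected hyperparameters, and the resampling `profile` (fold-wise TPR
#'   of the selected point).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 3), 30))
#' y <- rep(c("CTL", "TB"), each = 30)
#' fit <- tb_train(x, y, "knn", tune_config(resampling_folds = 5, budget = 3))
#' table(predict(fit, x), y)
#' @export
tb_train <- function(x, y, method = "rf", tune = tune_config()) {
  method <- match.arg(method, tb_methods())
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x_%03d", seq_len(ncol(x)))
  y <- as_tb_factor(y)
  if (length(unique(y)) < 2L)
    stop("tb_train: training set contains a single class")
  if (nrow(x) != length(y)) stop("tb_train: nrow(x) != length(y)")
  reg <- model_registry()[[method]]

  set.seed(tune$seed)
  k <- tune$resampling_folds
  if (k > nrow(x)) {
    warning("tb_train: ", k, " folds exceed the ", nrow(x),
            " training windows; clamped")
    k <- nrow(x)
  }
  fold_id <- sample(rep_len(seq_len(k), nrow(x)))
  cand <- unique(reg$space(tune$budget))
  fit_seeds <- sample.int(.Machine$integer.max %/% 2L, nrow(cand) + 1L)

  prof <- matrix(NA_real_, nrow(cand), k)
  for (i in seq_len(nrow(cand))) {
    par <- cand[i, , drop = FALSE]
    for (f in seq_len(k)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L) next
      pred <- tryCatch(suppressWarnings({
        set.seed(fit_seeds[i] + f)
        m <- reg$fit(x[tr, , drop = FALSE], y[tr], par)
        reg$predict(m, x[!tr, , drop = FALSE])
      }), error = function(e) NULL)
      if (!is.null(pred)) prof[i, f] <- fold_tpr(pred, y[!tr])
    }
  }
  mean_tpr <- rowMeans(prof, na.rm = TRUE)
  mean_tpr[is.nan(mean_tpr)] <- -Inf
  best <- which.max(mean_tpr)
  set.seed(fit_seeds[nrow(cand) + 1L])
  model <- suppressWarnings(reg$fit(x, y, cand[best, , drop = FALSE]))
  train_pred <- suppressWarnings(reg$predict(model, x))
  structure(list(method = method, model = model,
                 par = cand[best, , drop = FALSE],
                 profile = prof[best, ], fold_id = fold_id,
                 mean_resampled_tpr = mean_tpr[best],
                 train_tpr = fold_tpr(train_pred, y),
                 n_features = ncol(x), tune = tune),
            class = "tb_fit")
}

#' Predict window classes from a fitted classifier
#'
#' @param object A `tb_fit` from [tb_train()].
#' @param newdata Feature matrix with the same columns as in training.
#' @param ... Unused.
#' @return Factor of `"CTL"`/`"TB"` predictions, one per row; empty input
#'   gives an empty factor.
#' @export
predict.tb_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(factor(character(0), levels = tb_classes()))
  if (ncol(newdata) != object$n_features)
    stop("predict.tb_fit: expected ", object$n_features,
         " feature columns, got ", ncol(newdata))
  if (is.null(colnames(newdata)))
    colnames(newdata) <- sprintf("x_%03d", seq_len(ncol(newdata)))
  reg <- model_registry()[[object$method]]
  set.seed(object$tune$seed)  # tie-breaks (e.g. knn) reproducible
  as_tb_factor(reg$predict(object$model, newdata))
}

#' @export
print.tb_fit <- function(x, ...) {
  cat("tb_fit: method '", x$method, "' on ", x$n_features, " features\n",
      sep = "")
  pars <- x$par[, setdiff(names(x$par), ".none"), drop = FALSE]
  if (ncol(pars) > 0L)
    cat("  selected: ",
        paste(names(pars), signif(unlist(pars), 4), sep = " = ",
              collapse = ", "), "\n", sep = "")
  cat(sprintf("  resampled TPR %.3f over %d folds (training TPR %.3f)\n",
              x$mean_resampled_tpr, length(x$profile), x$train_tpr))
  invisible(x)
}
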