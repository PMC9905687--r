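#' Regression evaluation metrics
#'
#' The four criteria used throughout: mean square error, mean absolute
#' error, explained variance score `1 - Var(y - yhat) / Var(y)`
#' (population variances, insensitive to a constant bias) and the
#' coefficient of determination. Two R-squared conventions are returned:
#' `r2` is the standard residual form `1 - SS_res / SS_tot`, and
#' `r2_printed` is the regression-sum ratio
#' `sum((yhat - ybar)^2) / sum((y - ybar)^2)`, which coincides with the
#' standard form for an in-sample least-squares fit but not in general.
#'
#' @param y measured values.
#' @param yhat estimated values.
#' @return A one-row tibble with columns `mse`, `mae`, `evs`, `r2`,
#'   `r2_printed`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  res <- y - yhat
  var_p <- function(x) mean((x - mean(x))^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant y: variance-normalized metrics undefined",
                     call. = FALSE)
  tibble::tibble(
    mse = mean(res^2),
    mae = mean(abs(res)),
    evs = 1 - var_p(res) / var_p(y),
    r2 = 1 - sum(res^2) / sst,
    r2_printed = sum((yhat - mean(y))^2) / sst
  )
}

MODEL_NAMES <- c("LR", "SVR", "GBDT", "RF", "MLP")

#' Regression model specification
#'
#' The five regressors compared in the pipeline, with the tuned
#' hyperparameters fixed: ordinary least squares (`LR`); RBF-kernel
#' support vector regression with `gamma = 1/p` and `C = 1` (`SVR`);
#' gradient-boosted trees with 100 rounds, learning rate 0.1 and
#' unrestricted depth (`GBDT`); random forest with 100 trees and all
#' features tried at each split (`RF`); and a single-hidden-layer
#' perceptron with 100 units trained by a quasi-Newton (BFGS) optimizer
#' with weight decay 1e-4 (`MLP`; the installed implementation uses
#' logistic hidden units). Features are z-score standardized inside each
#' training fold for SVR and MLP by default.
#'
#' @param name one of `"LR"`, `"SVR"`, `"GBDT"`, `"RF"`, `"MLP"`.
#' @param seed integer seed for the stochastic learners.
#' @param standardize z-score features (fit on training data)? Default
#'   `TRUE` for SVR and MLP.
#' @return An object of class `pn_model_spec`.
#' @export
model_spec <- function(name, seed = 1L,
                       standardize = name %in% c("SVR", "MLP")) {
  name <- match.arg(name, MODEL_NAMES)
  structure(list(name = name, seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "pn_model_spec")
}

#' Build a regressor from a specification
#'
#' Returns a fit/predict pair implementing the spec. All learners are
#' deterministic given the spec seed.
#'
#' @param spec a [model_spec()].
#' @return List with functions `fit(X, y)` and `predict(fit, X)` (`X` a
#'   numeric matrix).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "pn_model_spec"))
  switch(spec$name,
    LR = list(
      fit = function(X, y) {
        df <- as.data.frame(X)
        names(df) <- paste0("x", seq_len(ncol(X)))
        lm(y ~ ., data = cbind(df, y = y))
      },
      predict = function(fit, X) {
        df <- as.data.frame(X)
        names(df) <- paste0("x", seq_len(ncol(X)))
        suppressWarnings(unname(predict(fit, newdata = df)))
      }
    ),
    SVR = list(
      fit = function(X, y) {
        e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   gamma = 1 / ncol(X), cost = 1, scale = FALSE)
      },
      predict = function(fit, X) unname(predict(fit, X))
    ),
    GBDT = list(
      fit = function(X, y) {
        set.seed(spec$seed)
        xgboost::xgb.train(
          params = list(eta = 0.1, max_depth = 0, tree_method = "hist",
                        nthread = 1),
          data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
          nrounds = 100, verbose = 0
        )
      },
      predict = function(fit, X) {
        predict(fit, xgboost::xgb.DMatrix(X, nthread = 1))
      }
    ),
    RF = list(
      fit = function(X, y) {
        set.seed(spec$seed)
        randomForest::randomForest(x = X, y = y, ntree = 100, mtry = ncol(X))
      },
      predict = function(fit, X) unname(predict(fit, X))
    ),
    MLP = list(
      fit = function(X, y) {
        set.seed(spec$seed)
        nnet::nnet(x = X, y = y, size = 100, linout = TRUE, decay = 1e-4,
                   maxit = 100, MaxNWts = 50000, trace = FALSE)
      },
      predict = function(fit, X) as.vector(predict(fit, X))
    )
  )
}

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  list(mu = mu, sigma = sigma)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$mu, "-"), 2, std$sigma, "/")
}

#' k-fold cross-validation of one model
#'
#' Seeded shuffled partition into `k` near-equal folds (sizes differing by
#' at most one); every sample is predicted exactly once out-of-fold. The
#' headline metrics are the per-fold averages; pooled metrics over all
#' out-of-fold predictions are reported alongside (per-fold R-squared on
#' small folds is high-variance). For standardizing specs, the z-score is
#' fitted on each training fold and applied to its validation fold.
#'
#' @param X numeric feature matrix (n x p).
#' @param y numeric response (Pn).
#' @param spec a [model_spec()].
#' @param k number of folds (default 10).
#' @param seed seed for the fold partition.
#' @return Object of class `pn_cv`: list with `fold_metrics` (tibble, one
#'   row per fold), `summary` (per-fold means), `pooled` (metrics on the
#'   pooled out-of-fold predictions), `predictions` (tibble: row, fold,
#'   y, yhat), `spec`, `k`, `seed`.
#' @export
cross_validate <- function(X, y, spec, k = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("need at least k samples", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  folds <- sample(rep(seq_len(k), length.out = n))
  model <- build_model(spec)

  yhat <- rep(NA_real_, n)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]
    if (spec$standardize) {
      std <- fit_standardizer(Xtr)
      Xtr <- apply_standardizer(std, Xtr)
      Xte <- apply_standardizer(std, Xte)
    }
    fit <- model$fit(Xtr, ytr)
    pred <- model$predict(fit, Xte)
    yhat[test] <- pred
    m <- if (sd(y[test]) == 0) {
      tibble::tibble(mse = mean((y[test] - pred)^2),
                     mae = mean(abs(y[test] - pred)),
                     evs = NA_real_, r2 = NA_real_, r2_printed = NA_real_)
    } else {
      regression_metrics(y[test], pred)
    }
    fold_metrics[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), m)
  }
  fold_metrics <- dplyr::bind_rows(fold_metrics)
  summary <- dplyr::summarise(fold_metrics, dplyr::across(
    c("mse", "mae", "evs", "r2", "r2_printed"), ~mean(.x, na.rm = TRUE)
  ))
  structure(list(
    fold_metrics = fold_metrics,
    summary = summary,
    pooled = regression_metrics(y, yhat),
    predictions = tibble::tibble(row = seq_len(n), fold = folds, y = y,
                                 yhat = yhat),
    spec = spec, k = k, seed = seed
  ), class = "pn_cv")
}

#' @export
print.pn_cv <- function(x, ...) {
  cat(sprintf("<pn_cv> %s, %d-fold (seed %d)\n", x$spec$name, x$k, x$seed))
  cat(sprintf("  fold-averaged: MSE %.3f  MAE %.3f  EVS %.3f  R2 %.3f\n",
              x$summary$mse, x$summary$mae, x$summary$evs, x$summary$r2))
  cat(sprintf("  pooled:        MSE %.3f  MAE %.3f  EVS %.3f  R2 %.3f\n",
              x$pooled$mse, x$pooled$mae, x$pooled$evs, x$pooled$r2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pn_cv <- function(x, ...) x$fold_metrics

#' @exportS3Method generics::glance
glance.pn_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$spec$name, k = x$k),
    x$summary,
    dplyr::rename_with(x$pooled, ~paste0("pooled_", .x))
  )
}

#' Observed vs estimated Pn from a cross-validation
#'
#' @param object a `pn_cv`.
#' @param ... unused.
#' @return A ggplot of out-of-fold estimates against measurements.
#' @exportS3Method ggplot2::autoplot
autoplot.pn_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$y, y = .data$yhat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = expression(paste("measured Pn (", mu, "mol ", m^-2, " ", s^-1, ")")),
      y = expression(paste("estimated Pn (", mu, "mol ", m^-2, " ", s^-1, ")")),
      title = sprintf("%s, %d-fold cross-validation", object$spec$name,
                      object$k)
    ) +
    ggplot2::theme_minimal()
}
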