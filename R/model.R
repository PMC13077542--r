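# QSAR regressors mapping selected descriptors to relative log10 IE.
#
# Three algorithm families, tuned by cross-validated RMSE over small,
# small-n-safe grids, then refit on the full training data:
#   elastic_net   glmnet, mixing alpha in {0.1..1.0} x internal lambda path
#   random_forest randomForest, 500 trees, mtry in {p/3, sqrt(p), p/2}
#   gbt           xgboost, depth {2,3,4} x eta {0.05,0.1,0.3}, rounds by
#                 early-stopped CV
# Features are standardized inside the elastic-net path only; tree models
# consume raw descriptor values.

#' Split compounds into training and test sets
#'
#' Uniform random split without replacement, reproducible from the seed.
#' The conventional design for a 50-compound study is 42 training / 8 test.
#'
#' @param ids character vector of compound ids.
#' @param train_n number of training compounds; must be < length(ids).
#' @param seed integer seed.
#' @param stratify_on optional numeric vector aligned with `ids`; when
#'   given, sampling is stratified by its quartile (off by default).
#'
#' @return list of class `split_plan` with `train_ids`, `test_ids`, `seed`.
#' @export
make_split <- function(ids, train_n = 42, seed = 1, stratify_on = NULL) {
  n <- length(ids)
  if (train_n >= n) stop("train_n must be smaller than the number of ids")
  set.seed(seed)
  if (is.null(stratify_on)) {
    tr <- sample(ids, train_n)
  } else {
    q <- cut(rank(stratify_on, ties.method = "first"),
             breaks = 4, labels = FALSE)
    tr <- unlist(lapply(split(ids, q), function(g) {
      sample(g, round(length(g) * train_n / n))
    }), use.names = FALSE)
    # adjust to the exact requested size
    pool <- setdiff(ids, tr)
    if (length(tr) > train_n) tr <- sample(tr, train_n)
    if (length(tr) < train_n) tr <- c(tr, sample(pool, train_n - length(tr)))
  }
  structure(list(train_ids = tr, test_ids = setdiff(ids, tr), seed = seed),
            class = "split_plan")
}

default_hyper_grid <- function(algorithm, p) {
  switch(algorithm,
    elastic_net = list(alpha = seq(0.1, 1, by = 0.1)),
    random_forest = list(
      ntree = 500,
      mtry = sort(unique(pmax(1, floor(c(p / 3, sqrt(p), p / 2)))))),
    gbt = list(max_depth = c(2, 3, 4), eta = c(0.05, 0.1, 0.3),
               nrounds_max = 500, early_stopping = 25),
    stop("unknown algorithm: ", algorithm)
  )
}

make_fold_id <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' Train a QSAR ionization-efficiency model
#'
#' Hyperparameters are chosen by cross-validated RMSE over a grid, then the
#' winning configuration is refit on all training rows.
#'
#' @param X numeric matrix of selected descriptors (rows = compounds).
#' @param y numeric response (relative log10 IE), aligned with `X` rows.
#' @param algorithm one of `"elastic_net"`, `"random_forest"`, `"gbt"`.
#' @param hyper_grid optional named list overriding the default grid.
#' @param folds CV folds for tuning (default 5).
#' @param seed integer seed controlling fold assignment and the fit.
#'
#' @return Object of class `ie_model`: `algorithm`, `hyperparameters`,
#'   `fit` (opaque fitted state), `selected_features`, `cv_record`
#'   (per-configuration mean CV RMSE), `train_metrics` and `degenerate`
#'   (TRUE when `y` had zero variance).
#' @export
train_ie_model <- function(X, y, algorithm = c("gbt", "random_forest",
                                               "elastic_net"),
                           hyper_grid = NULL, folds = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  grid <- if (is.null(hyper_grid)) default_hyper_grid(algorithm, ncol(X))
          else hyper_grid
  if (length(grid) == 0) stop("empty hyperparameter grid")

  degenerate <- stats::var(y) == 0
  if (degenerate) {
    model <- structure(
      list(algorithm = algorithm, hyperparameters = list(constant = y[1]),
           fit = NULL, selected_features = colnames(X),
           cv_record = data.frame(), degenerate = TRUE),
      class = "ie_model")
    model$train_metrics <- evaluate_ie_model(model, X, y)
    return(model)
  }

  fold_id <- make_fold_id(nrow(X), folds, seed)
  fitted <- switch(algorithm,
    elastic_net = train_enet(X, y, grid, fold_id, seed),
    random_forest = train_rf(X, y, grid, fold_id, seed),
    gbt = train_gbt(X, y, grid, fold_id, seed))

  model <- structure(
    list(algorithm = algorithm, hyperparameters = fitted$hyperparameters,
         fit = fitted$fit, selected_features = colnames(X),
         cv_record = fitted$cv_record, degenerate = FALSE),
    class = "ie_model")
  model$train_metrics <- evaluate_ie_model(model, X, y)
  model
}

train_enet <- function(X, y, grid, fold_id, seed) {
  recs <- lapply(grid$alpha, function(a) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(X, y, alpha = a, foldid = fold_id,
                            type.measure = "mse", standardize = TRUE)
    i <- match(cv$lambda.min, cv$lambda)
    data.frame(alpha = a, lambda = cv$lambda.min,
               cv_rmse = sqrt(cv$cvm[i]))
  })
  recs <- do.call(rbind, recs)
  best <- recs[which.min(recs$cv_rmse), ]
  set.seed(seed)
  fit <- glmnet::glmnet(X, y, alpha = best$alpha, lambda = best$lambda,
                        standardize = TRUE)
  attr(fit, "feature_sd") <- apply(X, 2, stats::sd)
  list(fit = fit,
       hyperparameters = list(alpha = best$alpha, lambda = best$lambda),
       cv_record = recs)
}

train_rf <- function(X, y, grid, fold_id, seed) {
  recs <- lapply(grid$mtry, function(mt) {
    pr <- numeric(length(y))
    for (k in sort(unique(fold_id))) {
      tr <- fold_id != k
      set.seed(seed + k)
      rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                       ntree = grid$ntree, mtry = mt)
      pr[!tr] <- stats::predict(rf, X[!tr, , drop = FALSE])
    }
    data.frame(mtry = mt, cv_rmse = sqrt(mean((pr - y)^2)))
  })
  recs <- do.call(rbind, recs)
  best <- recs[which.min(recs$cv_rmse), ]
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = grid$ntree,
                                    mtry = best$mtry, importance = TRUE)
  list(fit = fit,
       hyperparameters = list(ntree = grid$ntree, mtry = best$mtry),
       cv_record = recs)
}

train_gbt <- function(X, y, grid, fold_id, seed) {
  if (is.null(grid$subsample)) grid$subsample <- 1
  combos <- expand.grid(max_depth = grid$max_depth, eta = grid$eta,
                        subsample = grid$subsample)
  recs <- lapply(seq_len(nrow(combos)), function(i) {
    params <- list(objective = "reg:squarederror", nthread = 1,
                   max_depth = combos$max_depth[i], eta = combos$eta[i],
                   subsample = combos$subsample[i])
    set.seed(seed)
    cv <- xgboost::xgb.cv(params = params,
                          data = xgboost::xgb.DMatrix(X, label = y),
                          nrounds = grid$nrounds_max, folds = split(
                            seq_along(y), fold_id),
                          early_stopping_rounds = grid$early_stopping,
                          verbose = 0)
    bi <- cv$early_stop$best_iteration
    if (is.null(bi)) bi <- which.min(cv$evaluation_log$test_rmse_mean)
    data.frame(max_depth = combos$max_depth[i], eta = combos$eta[i],
               subsample = combos$subsample[i], nrounds = bi,
               cv_rmse = cv$evaluation_log$test_rmse_mean[bi])
  })
  recs <- do.call(rbind, recs)
  best <- recs[which.min(recs$cv_rmse), ]
  set.seed(seed)
  fit <- xgboost::xgb.train(
    data = xgboost::xgb.DMatrix(X, label = y),
    params = list(objective = "reg:squarederror", nthread = 1,
                  max_depth = best$max_depth, eta = best$eta,
                  subsample = best$subsample),
    nrounds = best$nrounds, verbose = 0)
  list(fit = fit,
       hyperparameters = list(max_depth = best$max_depth, eta = best$eta,
                              subsample = best$subsample,
                              nrounds = best$nrounds),
       cv_record = recs)
}

#' Predict relative log10 IE for new compounds
#'
#' @param object an `ie_model`.
#' @param newdata matrix containing at least the model's selected features.
#' @param ... unused.
#' @return numeric vector of predicted log10 IE values.
#' @export
predict.ie_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$selected_features, colnames(newdata))
  if (length(miss)) {
    stop("newdata lacks model features: ", paste(miss, collapse = ", "))
  }
  X <- newdata[, object$selected_features, drop = FALSE]
  if (object$degenerate) {
    return(rep(object$hyperparameters$constant, nrow(X)))
  }
  switch(object$algorithm,
    elastic_net = as.numeric(stats::predict(object$fit, X)),
    random_forest = as.numeric(stats::predict(object$fit, X)),
    gbt = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(X))))
}

#' Goodness-of-fit metrics
#'
#' RMSE is the root mean square of (prediction - observation); R2 is
#' 1 - SSE/SST.  When `y` has zero variance R2 is undefined: it is reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param model an `ie_model`.
#' @param X feature matrix.
#' @param y observed responses.
#' @return list of class `fit_metrics`: `rmse`, `r2`, `degenerate`, `n`.
#' @export
evaluate_ie_model <- function(model, X, y) {
  pred <- stats::predict(model, X)
  rmse <- sqrt(mean((pred - y)^2))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- 0
    degenerate <- TRUE
  } else {
    r2 <- 1 - sum((y - pred)^2) / sst
    degenerate <- FALSE
  }
  structure(list(rmse = rmse, r2 = r2, degenerate = degenerate,
                 n = length(y)),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics> RMSE %.4f, R2 %.4f (n = %d)%s\n", x$rmse, x$r2,
              x$n, if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' @export
print.ie_model <- function(x, ...) {
  cat("<ie_model>", x$algorithm, "on", length(x$selected_features),
      "features\n")
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$train_metrics)) print(x$train_metrics)
  invisible(x)
}

#' Ranked feature importances
#'
#' Scores are non-negative, normalized to sum to one, in descending order;
#' ties are broken by feature name.  Elastic-net importances are absolute
#' standardized coefficients; random forest uses permutation importance
#' (non-negative part); gradient boosting uses split gain.
#'
#' @param model a fitted `ie_model`.
#' @param top_k how many features to return (default all).
#' @return data frame with columns `feature`, `score`.
#' @export
ie_importance <- function(model, top_k = Inf) {
  if (is.null(model$fit) && !model$degenerate) stop("model is not fitted")
  if (model$degenerate) stop("degenerate model has no importances")
  feats <- model$selected_features
  raw <- switch(model$algorithm,
    elastic_net = {
      b <- as.numeric(stats::coef(model$fit))[-1]  # drop intercept
      sds <- attr(model$fit, "feature_sd")
      if (is.null(sds)) sds <- rep(1, length(b))
      stats::setNames(abs(b) * sds, feats)
    },
    random_forest = {
      tab <- randomForest::importance(model$fit, type = 1, scale = FALSE)
      imp <- stats::setNames(tab[, 1], rownames(tab))
      imp[!is.finite(imp)] <- 0
      pmax(imp, 0)
    },
    gbt = {
      tab <- xgboost::xgb.importance(model = model$fit)
      out <- stats::setNames(rep(0, length(feats)), feats)
      out[tab$Feature] <- tab$Gain
      out
    })
  raw <- raw[feats]
  names(raw) <- feats
  total <- sum(raw)
  score <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  ord <- order(-score, names(score), method = "radix")
  res <- data.frame(feature = names(score)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  utils::head(res, top_k)
}

#' Save / load a fitted model bundle
#'
#' The bundle is a directory with a JSON manifest (algorithm,
#' hyperparameters, feature list, metrics) and the fitted state serialized
#' alongside.
#'
#' @param model an `ie_model`.
#' @param dir bundle directory (created if needed).
#' @export
save_ie_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format_version = 1L, algorithm = model$algorithm,
                   hyperparameters = model$hyperparameters,
                   selected_features = model$selected_features,
                   degenerate = model$degenerate,
                   train_metrics = unclass(model$train_metrics))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_ie_model
#' @export
load_ie_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
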