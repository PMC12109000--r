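#' Default hyperparameters of a model family
#'
#' The fixed hyperparameter sets of the three regression backends: elastic
#' net at mixing parameter 0.75 with the penalty weight chosen by
#' cross-validation; least-squares boosted regression trees with learning
#' rate 0.22, 463 boosting cycles, minimum leaf size 2, at most 12 splits
#' per tree and 5 variables sampled per node; and the compact residual
#' network trained for 50 epochs at learning rate 0.001 (Adam, batch 64),
#' hidden width chosen by [residual_net_width()].
#'
#' @param family One of `"lasso"`, `"boosted_trees"`, `"residual_net"`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(family = c("lasso", "boosted_trees",
                                               "residual_net")) {
  family <- match.arg(family)
  switch(family,
    lasso = list(alpha = 0.75),
    boosted_trees = list(
      learning_rate = 0.22, n_rounds = 463, min_leaf = 2,
      max_splits = 12, vars_to_sample = 5
    ),
    residual_net = list(
      epochs = 50, learning_rate = 0.001, batch_size = 64,
      param_budget = 840
    )
  )
}

#' Specify a blood-pressure regression model
#'
#' @param family Model family (see [default_hyperparameters()]).
#' @param target `"sbp"` or `"dbp"`.
#' @param mode `"calibration_free"` (32 input slots) or `"personalized"`
#'   (34 slots).
#' @param hyperparameters Named list; defaults per family.
#' @param cv_folds Cross-validation folds (10 for lasso and boosted trees,
#'   5 for the residual network; 0 disables CV bookkeeping for the tree and
#'   network families).
#' @param seed Training seed.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("lasso", "boosted_trees", "residual_net"),
                       target = c("sbp", "dbp"),
                       mode = c("calibration_free", "personalized"),
                       hyperparameters = NULL, cv_folds = NULL, seed = 1L) {
  family <- match.arg(family)
  target <- match.arg(target)
  mode <- match.arg(mode)
  hp <- modifyList(default_hyperparameters(family),
                   hyperparameters %||% list())
  cv <- cv_folds %||% if (family == "residual_net") 5L else 10L
  if (cv != 0 && cv < 2) stop("cv_folds must be 0 or >= 2")
  structure(
    list(
      family = family, target = target, mode = mode, hyperparameters = hp,
      cv_folds = as.integer(cv), seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

# subject-grouped fold assignment (prevents within-subject leakage)
group_folds <- function(subject_ids, k, seed) {
  subjects <- unique(subject_ids)
  perm <- with_seed(seed, sample(subjects))
  fold_of <- setNames(rep(seq_len(k), length.out = length(perm)), perm)
  as.integer(fold_of[subject_ids])
}

extract_xy <- function(examples, spec) {
  if (!is.data.frame(examples)) examples <- examples_to_frame(examples)
  cols <- feature_column_order(spec$mode)
  missing_cols <- setdiff(cols, names(examples))
  if (length(missing_cols)) {
    stop(
      "feature slot count mismatch for mode '", spec$mode, "': missing ",
      paste(missing_cols, collapse = ", ")
    )
  }
  X <- as.matrix(examples[, cols, drop = FALSE])
  bad <- which(!apply(is.finite(X), 1, all))
  if (length(bad)) {
    stop(
      "non-finite features in rows: ",
      paste(head(bad, 10), collapse = ", ")
    )
  }
  y <- examples[[paste0("target_", spec$target)]]
  list(
    X = X, y = y,
    subject = examples$subject_id %||% as.character(seq_len(nrow(X)))
  )
}

fit_boost <- function(X, y, hp, seed, nthread = 1L) {
  params <- list(
    objective = "reg:squarederror",
    eta = hp$learning_rate,
    max_leaves = hp$max_splits + 1,
    max_depth = 0,
    grow_policy = "lossguide",
    tree_method = "hist",
    min_child_weight = hp$min_leaf,
    colsample_bynode = min(1, hp$vars_to_sample / ncol(X)),
    base_score = mean(y),
    nthread = nthread,
    seed = seed
  )
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hp$n_rounds, verbose = 0)
}

#' Train a blood-pressure estimator
#'
#' Fits one regression backend to labeled examples. Cross-validation is
#' grouped by subject throughout: segments of one subject never straddle a
#' fold boundary, because within-subject segments are strongly dependent and
#' the target of the pipeline is subject-level generalization. Per-fold
#' validation losses are stored in the returned estimator's `training`
#' record; training is deterministic given `spec$seed`.
#'
#' @param examples A list of [build_example()] outputs or the data.frame
#'   built from them (feature columns plus `target_sbp`, `target_dbp`,
#'   `subject_id`).
#' @param spec A [model_spec()].
#' @return An object of class `bp_estimator`.
#' @export
train_estimator <- function(examples, spec) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- extract_xy(examples, spec)
  X <- xy$X
  y <- xy$y
  n <- nrow(X)
  hp <- spec$hyperparameters
  n_params <- switch(spec$family,
    lasso = ncol(X) + 1,
    boosted_trees = ncol(X) + 1,
    residual_net = residual_net_width(ncol(X), hp$param_budget)$n_params
  )
  if (n < 10 * n_params) {
    warning(
      "only ", n, " examples for ~", n_params, " fitted parameters ",
      "(fewer than the recommended 10x)"
    )
  }
  fit <- NULL
  cv <- NULL
  extra <- list()
  if (stats::var(y) < 1e-20) {
    # degenerate supervision: every family reduces to the constant fit
    extra$constant <- mean(y)
  } else if (spec$family == "lasso") {
    k <- max(spec$cv_folds, 3)
    foldid <- group_folds(xy$subject, k, derive_seed(spec$seed, 5))
    cvfit <- with_seed(spec$seed, glmnet::cv.glmnet(
      X, y, alpha = hp$alpha, foldid = foldid, keep = TRUE
    ))
    lam_i <- which(cvfit$lambda == cvfit$lambda.min)
    pre <- cvfit$fit.preval[, lam_i]
    cv <- data.frame(
      fold = seq_len(k),
      loss = vapply(seq_len(k), function(f) {
        mean((pre[foldid == f] - y[foldid == f])^2)
      }, numeric(1))
    )
    fit <- cvfit
  } else if (spec$family == "boosted_trees") {
    if (spec$cv_folds > 0) {
      foldid <- group_folds(xy$subject, spec$cv_folds,
                            derive_seed(spec$seed, 5))
      cv <- data.frame(fold = seq_len(spec$cv_folds), loss = vapply(
        seq_len(spec$cv_folds), function(f) {
          m <- fit_boost(X[foldid != f, , drop = FALSE], y[foldid != f],
                         hp, derive_seed(spec$seed, 100 + f))
          pred <- predict(m, xgboost::xgb.DMatrix(
            X[foldid == f, , drop = FALSE]
          ))
          mean((pred - y[foldid == f])^2)
        }, numeric(1)
      ))
    }
    fit <- fit_boost(X, y, hp, spec$seed)
    extra$raw <- xgboost::xgb.save.raw(fit)
  } else {
    width <- residual_net_width(ncol(X), hp$param_budget)
    xc <- colMeans(X)
    xs <- apply(X, 2, sd)
    xs[xs < 1e-12] <- 1
    ym <- mean(y)
    ys <- sd(y)
    if (!is.finite(ys) || ys < 1e-12) ys <- 1
    Xs <- sweep(sweep(X, 2, xc), 2, xs, `/`)
    ysc <- (y - ym) / ys
    if (spec$cv_folds > 0) {
      foldid <- group_folds(xy$subject, spec$cv_folds,
                            derive_seed(spec$seed, 5))
      cv <- data.frame(fold = seq_len(spec$cv_folds), loss = vapply(
        seq_len(spec$cv_folds), function(f) {
          m <- rn_train(Xs[foldid != f, , drop = FALSE], ysc[foldid != f],
                        width$width, hp$epochs, hp$learning_rate,
                        hp$batch_size, derive_seed(spec$seed, 200 + f))
          pred <- rn_predict(m, Xs[foldid == f, , drop = FALSE]) * ys + ym
          mean((pred - y[foldid == f])^2)
        }, numeric(1)
      ))
    }
    fit <- rn_train(Xs, ysc, width$width, hp$epochs, hp$learning_rate,
                    hp$batch_size, spec$seed)
    extra <- list(
      x_center = xc, x_scale = xs, y_center = ym, y_scale = ys,
      width = width$width, n_params = width$n_params,
      loss_curve = fit$loss_curve
    )
  }
  est <- structure(
    list(
      spec = spec, fit = fit, columns = feature_column_order(spec$mode),
      extra = extra,
      training = list(cv = cv, n = n, n_params = n_params)
    ),
    class = "bp_estimator"
  )
  tp <- predict(est, as.data.frame(X))
  est$training$train_rmse <- sqrt(mean((tp - y)^2))
  est$training$train_residuals <- tp - y
  est
}

#' Predict blood pressure for new feature vectors
#'
#' @param object A trained [train_estimator()] model.
#' @param newdata data.frame (or matrix with column names) holding at least
#'   the feature columns the model was trained on, in any order.
#' @param ... Unused.
#' @return Numeric vector of estimates in mm Hg (empty for empty input).
#' @export
predict.bp_estimator <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  if (nrow(newdata) == 0) {
    return(numeric(0))
  }
  missing_cols <- setdiff(object$columns, names(newdata))
  if (length(missing_cols)) {
    stop(
      "missing feature slots: ", paste(missing_cols, collapse = ", ")
    )
  }
  X <- as.matrix(newdata[, object$columns, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite features in prediction input")
  if (!is.null(object$extra$constant)) {
    return(rep(object$extra$constant, nrow(X)))
  }
  out <- switch(object$spec$family,
    lasso = as.numeric(predict(object$fit, newx = X, s = "lambda.min")),
    boosted_trees = {
      fit <- object$fit
      if (is.null(fit)) {
        fit <- xgboost::xgb.load.raw(object$extra$raw)
      }
      as.numeric(predict(fit, xgboost::xgb.DMatrix(X)))
    },
    residual_net = {
      ex <- object$extra
      Xs <- sweep(sweep(X, 2, ex$x_center), 2, ex$x_scale, `/`)
      rn_predict(object$fit, Xs) * ex$y_scale + ex$y_center
    }
  )
  if (!all(is.finite(out))) stop("model produced non-finite estimates")
  out
}

#' @export
print.bp_estimator <- function(x, ...) {
  cat(sprintf(
    "<bp_estimator> %s for %s (%s mode), %d training examples\n",
    x$spec$family, toupper(x$spec$target), x$spec$mode, x$training$n
  ))
  if (!is.null(x$training$train_rmse)) {
    cat(sprintf("  training RMSE: %.2f mm Hg\n", x$training$train_rmse))
  }
  if (!is.null(x$training$cv)) {
    cat(sprintf(
      "  CV RMSE (%d folds): %.2f mm Hg\n", nrow(x$training$cv),
      sqrt(mean(x$training$cv$loss))
    ))
  }
  invisible(x)
}

#' Save / load a trained estimator as a single-file bundle
#'
#' The bundle holds the model specification, the feature column order, the
#' fitted parameters (tree ensembles as raw bytes, so the bundle survives
#' across sessions) and the training summary.
#'
#' @param estimator A [train_estimator()] model.
#' @param path Bundle file path.
#' @return `path` (saving) or the restored `bp_estimator` (loading).
#' @export
save_estimator <- function(estimator, path) {
  stopifnot(inherits(estimator, "bp_estimator"))
  if (estimator$spec$family == "boosted_trees") {
    estimator$fit <- NULL # re-hydrated from the raw bytes on load
  }
  saveRDS(estimator, path)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  est <- readRDS(path)
  stopifnot(inherits(est, "bp_estimator"))
  est
}
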