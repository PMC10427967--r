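#' Model specification for one regression family
#'
#' The suite covers six standard regression families: partial least squares
#' (`"plsr"`), linear support vector regression (`"svr"`), random forest
#' (`"rf"`), gradient boosted regression (`"gbr"`), decision tree (`"dt"`)
#' and the LASSO (`"lasso"`). Hyperparameters are tuned by exhaustive grid
#' search with k-fold cross-validation scored by R2; ties go to the first
#' grid point in documented order.
#'
#' @param family one of `"plsr"`, `"svr"`, `"rf"`, `"gbr"`, `"dt"`, `"lasso"`.
#' @param grid data.frame of candidate hyperparameter combinations; defaults
#'   to [default_grid()] for the family.
#' @param cv_folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment and any stochastic
#'   fit (forests, boosting).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("plsr", "svr", "rf", "gbr", "dt", "lasso"),
                       grid = NULL, cv_folds = 5, seed = 1) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  abort_if(nrow(grid) == 0, "hyperparameter grid is empty")
  structure(list(family = family, grid = grid, cv_folds = cv_folds,
                 seed = seed), class = "model_spec")
}

#' Default hyperparameter grids
#'
#' LASSO penalty lambda: 7 log-spaced points in \[1e-3, 10\]; PLSR
#' components 1-4; SVR cost x epsilon; RF/GBR trees x depth; DT depth
#' (`NA` depth means unrestricted).
#'
#' @param family model family name.
#' @return data.frame, one row per grid point.
#' @export
default_grid <- function(family) {
  switch(family,
    lasso = data.frame(lambda = 10^seq(-3, 1, length.out = 7)),
    plsr = data.frame(ncomp = 1:4),
    svr = expand.grid(cost = c(0.1, 1, 10), epsilon = c(0.01, 0.1)),
    rf = expand.grid(ntree = c(100, 500), depth = c(2, 3, NA)),
    gbr = expand.grid(nrounds = c(100, 500), max_depth = c(2, 3)),
    dt = data.frame(depth = c(2, 3, 5, NA)),
    stop("unknown family: ", family))
}

# ---- family backends -------------------------------------------------------
# Each backend returns a 'family_fit' carrying what prediction and
# importance extraction need. Fits consume the current RNG stream; public
# operations wrap everything in with_seed().

fit_pls <- function(X, y, ncomp) {
  ncomp <- max(1, min(ncomp, ncol(X), nrow(X) - 1))
  if (ncol(X) == 1) {
    # degenerate single-predictor case: PLS reduces to simple regression
    fit <- stats::lm.fit(cbind(1, X), y)
    return(list(kind = "uni", coefs = fit$coefficients))
  }
  list(kind = "pls",
       model = mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                             scale = TRUE),
       ncomp = ncomp)
}

predict_pls <- function(fit, newX) {
  if (fit$kind == "uni")
    return(as.vector(cbind(1, newX) %*% fit$coefs))
  pr <- predict(fit$model, newdata = newX)
  as.vector(pr$predict[, 1, fit$ncomp])
}

pls_vip <- function(fit) {
  if (fit$kind == "uni") return(1)
  v <- mixOmics::vip(fit$model)
  v[, ncol(v)]
}

fit_family <- function(family, X, y, params) {
  p <- ncol(X)
  base <- list(family = family, params = params, features = colnames(X),
               x_sd = apply(X, 2, sd))
  fit <- switch(family,
    lasso = {
      Xf <- X; dummy <- FALSE
      if (p < 2) { Xf <- cbind(Xf, ..dummy.. = 0); dummy <- TRUE }
      list(model = glmnet::glmnet(Xf, y, alpha = 1, lambda = params$lambda,
                                  standardize = TRUE, maxit = 1e6),
           dummy = dummy)
    },
    plsr = list(model = fit_pls(X, y, params$ncomp)),
    # svm scales x and y internally, so its weight vector lives in
    # standardized space -- exactly what the importance rule needs
    svr = list(model = suppressWarnings(
      e1071::svm(X, y, kernel = "linear", cost = params$cost,
                 epsilon = params$epsilon, scale = TRUE))),
    rf = {
      maxnodes <- if (is.na(params$depth)) NULL else 2^params$depth
      list(model = randomForest::randomForest(
        X, y, ntree = params$ntree, maxnodes = maxnodes))
    },
    gbr = list(model = xgboost::xgb.train(
      params = list(max_depth = params$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0)),
    dt = {
      nm <- paste0("V", seq_len(p))
      df <- as.data.frame(X); names(df) <- nm
      df$.y <- y
      depth <- if (is.na(params$depth)) 30 else params$depth
      list(model = rpart::rpart(.y ~ ., data = df, method = "anova",
                                control = rpart::rpart.control(
                                  maxdepth = depth, minsplit = 2,
                                  cp = 1e-4, xval = 0)),
           name_map = setNames(colnames(X), nm))
    },
    stop("unknown family: ", family))
  structure(c(base, fit), class = "family_fit")
}

predict_family <- function(ff, newX) {
  newX <- as.matrix(newX)
  if (is.null(colnames(newX))) colnames(newX) <- ff$features
  newX <- newX[, ff$features, drop = FALSE]
  switch(ff$family,
    lasso = {
      Xf <- newX
      if (ff$dummy) Xf <- cbind(Xf, ..dummy.. = 0)
      as.vector(predict(ff$model, Xf))
    },
    plsr = predict_pls(ff$model, newX),
    svr = as.vector(predict(ff$model, newX)),
    rf = as.vector(predict(ff$model, newX)),
    gbr = as.vector(predict(ff$model,
                            xgboost::xgb.DMatrix(newX, nthread = 1))),
    dt = {
      df <- as.data.frame(newX)
      names(df) <- names(ff$name_map)
      as.vector(predict(ff$model, df))
    })
}

# raw (unnormalized) importance per input feature; nonnegative, named
raw_importance <- function(ff) {
  feats <- ff$features
  imp <- switch(ff$family,
    lasso = {
      co <- as.vector(coef(ff$model))[-1]       # drop intercept
      if (ff$dummy) co <- co[-length(co)]
      abs(co) * ff$x_sd                          # standardized coefficients
    },
    svr = {
      w <- as.vector(t(ff$model$coefs) %*% ff$model$SV)  # scaled space
      abs(w)
    },
    plsr = unname(pls_vip(ff$model)[seq_along(feats)]),
    rf = as.vector(randomForest::importance(ff$model)[feats, 1]),
    gbr = {
      out <- setNames(numeric(length(feats)), feats)
      if (length(feats) == 1) {
        # xgb.importance cannot summarize single-feature boosters
        out[feats] <- 1
      } else {
        tab <- xgboost::xgb.importance(model = ff$model)
        out[tab$Feature] <- tab$Gain
      }
      unname(out)
    },
    dt = {
      vi <- ff$model$variable.importance
      out <- setNames(numeric(length(feats)), feats)
      if (!is.null(vi)) out[ff$name_map[names(vi)]] <- vi
      unname(out)
    })
  setNames(pmax(imp, 0), feats)
}

# ---- cross-validated grid search -------------------------------------------

cv_fold_ids <- function(n, k) {
  fold <- integer(n)
  fold[sample.int(n)] <- rep_len(seq_len(k), n)
  fold
}

cv_score <- function(family, X, y, params, fold) {
  k <- max(fold)
  scores <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_family(family, X[tr, , drop = FALSE], y[tr], params)
    yhat <- predict_family(fit, X[!tr, , drop = FALSE])
    yte <- y[!tr]
    sst <- sum((yte - mean(yte))^2)
    if (sst > 0) scores[f] <- 1 - sum((yte - yhat)^2) / sst
  }
  mean(scores, na.rm = TRUE)
}

tune_impl <- function(spec, X, y) {
  n <- nrow(X)
  abort_if(spec$cv_folds > n, "cv_folds (%d) exceeds n samples (%d)",
           spec$cv_folds, n)
  fold <- cv_fold_ids(n, spec$cv_folds)
  grid <- spec$grid
  mean_r2 <- vapply(seq_len(nrow(grid)), function(i)
    cv_score(spec$family, X, y, as.list(grid[i, , drop = FALSE]), fold),
    numeric(1))
  best <- which.max(mean_r2)  # first max = first grid point on ties
  list(params = as.list(grid[best, , drop = FALSE]),
       cv_results = cbind(grid, cv_r2 = mean_r2))
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustively scores every grid point by k-fold cross-validated R2
#' (seeded fold shuffle, folds as equal as possible) and returns the
#' maximizer, with ties resolved toward the first grid point.
#'
#' @param spec a [model_spec()].
#' @param X line x feature matrix.
#' @param y a `composite_score` or named numeric vector.
#' @return list with `params` (chosen hyperparameters) and `cv_results`.
#' @export
tune_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  y <- score_vector(y, rownames(X))
  with_seed(spec$seed, tune_impl(spec, X, y))
}

# ---- same-family feature selection ----------------------------------------

select_impl <- function(spec, X, y, params) {
  ff <- fit_family(spec$family, X, y, params)
  imp <- raw_importance(ff)
  keep <- switch(spec$family,
    lasso = names(imp)[imp > 0],
    rf = names(imp)[imp > 0],
    gbr = names(imp)[imp > 0],
    dt = names(imp)[imp > 0],
    plsr = names(imp)[imp >= 1],               # VIP >= 1 rule
    svr = {
      # smallest prefix of |standardized coefficient| holding 50% of mass
      tot <- sum(imp)
      if (tot == 0) character(0)
      else {
        ord <- order_desc_stable(imp)
        cum <- cumsum(imp[ord]) / tot
        names(imp)[ord[seq_len(which(cum >= 0.5)[1])]]
      }
    })
  if (length(keep) == 0) {
    message(sprintf("%s selected no features; falling back to the full set",
                    spec$family))
    keep <- colnames(X)
  }
  keep
}

#' Same-family feature selection
#'
#' Fits the family on all features with the chosen hyperparameters and keeps
#' features by the family's own importance rule: nonzero coefficients
#' (LASSO), nonzero impurity importance (RF/GBR/DT), VIP >= 1 (PLSR), or the
#' top-50% mass of |standardized coefficient| (linear SVR). An empty
#' selection falls back to the full feature set with a message.
#'
#' @inheritParams tune_model
#' @param params chosen hyperparameters (from [tune_model()]).
#' @return character vector of selected feature ids (stable input order).
#' @export
select_features <- function(spec, X, y, params) {
  stopifnot(inherits(spec, "model_spec"))
  y <- score_vector(y, rownames(X))
  keep <- with_seed(spec$seed, select_impl(spec, X, y, params))
  colnames(X)[colnames(X) %in% keep]
}

# ---- leave-one-out evaluation ---------------------------------------------

loo_impl <- function(family, X, y, params) {
  n <- nrow(X)
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_family(family, X[-i, , drop = FALSE], y[-i], params)
    yhat[i] <- predict_family(fit, X[i, , drop = FALSE])
  }
  r_squared(y, yhat)
}

#' Pooled leave-one-out R2
#'
#' For each line, refits the model on the remaining lines with fixed
#' hyperparameters and a fixed feature subset, predicts the held-out line,
#' and computes `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` over the
#' pooled predictions. Unbounded below; at most 1.
#'
#' @inheritParams select_features
#' @param features feature subset to use (default: all columns of `X`).
#' @return LOO-R2 (scalar).
#' @export
loo_r2 <- function(spec, X, y, params, features = colnames(X)) {
  stopifnot(inherits(spec, "model_spec"))
  y <- score_vector(y, rownames(X))
  abort_if(nrow(X) < 3, "LOO evaluation needs >= 3 lines")
  abort_if(sd(y) == 0, "score has zero variance")
  Xs <- X[, features, drop = FALSE]
  with_seed(spec$seed, loo_impl(spec$family, Xs, y, params))
}

# ---- full per-family fit ---------------------------------------------------

#' Tune, select and evaluate one regression family
#'
#' The per-family workflow: grid-search CV tuning on all features, feature
#' selection with the same family, optional re-tuning on the selected
#' subset, a final fit with normalized importances, and pooled leave-one-out
#' R2 with fixed hyperparameters and features.
#'
#' @inheritParams tune_model
#' @param retune re-run the grid search on the selected subset
#'   (default `TRUE`).
#' @return an object of class `fitted_model`: family, chosen params,
#'   `selected_features`, `importance` (named, sums to 1), `loo_r2`,
#'   `cv_results` and the final fit.
#' @export
fit_model <- function(spec, X, y, retune = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  y <- score_vector(y, rownames(X))
  with_seed(spec$seed, {
    tuned <- tune_impl(spec, X, y)
    feats <- select_impl(spec, X, y, tuned$params)
    feats <- colnames(X)[colnames(X) %in% feats]
    Xs <- X[, feats, drop = FALSE]
    if (retune && length(feats) < ncol(X)) tuned <- tune_impl(spec, Xs, y)
    final <- fit_family(spec$family, Xs, y, tuned$params)
    imp <- raw_importance(final)
    degenerate <- sum(imp) == 0
    imp <- if (!degenerate) imp / sum(imp)
           else setNames(rep(1 / length(imp), length(imp)), names(imp))
    loo <- loo_impl(spec$family, Xs, y, tuned$params)
    structure(list(family = spec$family, params = tuned$params,
                   selected_features = feats, importance = imp,
                   degenerate_importance = degenerate,
                   loo_r2 = loo, cv_results = tuned$cv_results,
                   fit = final, seed = spec$seed),
              class = "fitted_model")
  })
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model [%s]: %d features, LOO-R2 = %.3f\n",
              x$family, length(x$selected_features), x$loo_r2))
  invisible(x)
}

#' Normalized variable importance of a fitted model
#'
#' Family-specific raw importances (|standardized coefficients| for
#' LASSO/SVR, VIP for PLSR, impurity importance for RF/GBR/DT) normalized
#' to sum to 1 over the model's selected features.
#'
#' @param fitted a `fitted_model` from [fit_model()].
#' @return named numeric vector summing to 1.
#' @export
model_importance <- function(fitted) {
  stopifnot(inherits(fitted, "fitted_model"))
  fitted$importance
}

#' Aggregate importance by chemical class
#'
#' Sums each model's normalized feature importances within chemical classes,
#' giving the per-class, per-family contribution profile. Each family's
#' class importances sum to 1.
#'
#' @param models named list of `fitted_model` objects (names = family).
#' @param feature_meta data.frame with `feature_id` and `chem_class`.
#' @return data.frame: one row per class, one column per family.
#' @export
importance_by_class <- function(models, feature_meta) {
  abort_if(anyNA(feature_meta$chem_class) || any(feature_meta$chem_class == ""),
           "every feature needs a chem_class")
  cls_of <- setNames(feature_meta$chem_class, feature_meta$feature_id)
  classes <- unique(feature_meta$chem_class)
  out <- matrix(0, length(classes), length(models),
                dimnames = list(classes, names(models)))
  for (m in names(models)) {
    imp <- models[[m]]$importance
    miss <- setdiff(names(imp), names(cls_of))
    abort_if(length(miss) > 0, "feature %s has no metadata entry", miss[1])
    agg <- tapply(imp, cls_of[names(imp)], sum)
    out[names(agg), m] <- agg
  }
  as.data.frame(out)
}

#' Run the standard regression suite
#'
#' Fits all requested families on the same line x feature matrix and score.
#'
#' @inheritParams tune_model
#' @param families character vector of family names (default all six).
#' @param cv_folds CV folds (default 5).
#' @param seed integer seed (each family derives its own stream from it).
#' @param retune re-tune on the selected subset (default `TRUE`).
#' @return named list of `fitted_model` objects.
#' @export
fit_suite <- function(X, y, families = c("plsr", "svr", "rf", "gbr", "dt", "lasso"),
                      cv_folds = 5, seed = 1, retune = TRUE) {
  out <- lapply(families, function(fam)
    fit_model(model_spec(fam, cv_folds = cv_folds, seed = seed), X, y,
              retune = retune))
  setNames(out, families)
}

# serializable form of a fitted model (drops the fit object)
fitted_model_record <- function(x) {
  list(family = x$family, params = x$params,
       selected_features = x$selected_features,
       importance = as.list(x$importance), loo_r2 = x$loo_r2)
}
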