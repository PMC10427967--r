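test_that("grid search returns the single grid point, picks sane LASSO penalties, and is deterministic", {
  sm <- signal_matrix(n = 10, p = 8, slope = 3, noise = 0.05)

  one <- model_spec("lasso", grid = data.frame(lambda = 0.01), seed = 2)
  expect_equal(tune_model(one, sm$X, sm$y)$params$lambda, 0.01)

  spec <- model_spec("lasso", grid = data.frame(lambda = c(0.001, 1000)),
                     seed = 2)
  tuned <- tune_model(spec, sm$X, sm$y)
  expect_equal(tuned$params$lambda, 0.001)   # huge penalty forces null model
  expect_lte(max(tuned$cv_results$cv_r2[tuned$cv_results$lambda == 1000]), 0)

  t2 <- tune_model(spec, sm$X, sm$y)
  expect_identical(tuned, t2)

  expect_error(tune_model(model_spec("lasso", cv_folds = 20), sm$X, sm$y),
               "cv_folds")
})

test_that("same-family selection keeps planted features and falls back when empty", {
  set.seed(3)
  X <- matrix(rnorm(10 * 51), 10, 51,
              dimnames = list(paste0("L", 1:10), paste0("f", 1:51)))
  y <- setNames(10 * X[, 1] + rnorm(10, sd = 0.01), rownames(X))
  spec <- model_spec("lasso", seed = 1)
  keep <- select_features(spec, X, y, params = list(lambda = 0.1))
  expect_true("f1" %in% keep)
  expect_lt(length(keep), 51)

  ynull <- setNames(rnorm(10), rownames(X))
  expect_message(
    keep2 <- select_features(spec, X, ynull, params = list(lambda = 1000)),
    "falling back")
  expect_setequal(keep2, colnames(X))

  # PLSR VIP on a single feature is 1 and the feature is kept
  X1 <- X[, 1, drop = FALSE]
  keep3 <- select_features(model_spec("plsr", seed = 1), X1, y,
                           params = list(ncomp = 1))
  expect_equal(keep3, "f1")
})

test_that("importances are normalized, reflect coefficients, and split between duplicates", {
  sm <- signal_matrix(n = 10, p = 2, noise = 0)
  # y = 2*z1 - 1*z2 on autoscaled features -> importances 2/3, 1/3
  Z <- scale(sm$X)
  y <- setNames(2 * Z[, 1] - 1 * Z[, 2], rownames(Z))
  fm <- fit_model(model_spec("lasso", grid = data.frame(lambda = 1e-4),
                             seed = 1), Z, y)
  expect_equal(sum(fm$importance), 1, tolerance = 1e-9)
  expect_equal(unname(fm$importance), c(2 / 3, 1 / 3), tolerance = 0.02)

  # single feature gets importance 1 in every family
  for (fam in c("lasso", "plsr", "dt", "rf")) {
    f1 <- fit_model(model_spec(fam, seed = 1),
                    Z[, 1, drop = FALSE], y)
    expect_equal(unname(f1$importance), 1, tolerance = 1e-9)
  }

  # two identical informative features share RF importance
  set.seed(9)
  X <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("L", 1:10), paste0("f", 1:6)))
  X[, 2] <- X[, 1]
  yy <- setNames(X[, 1] * 3 + rnorm(10, sd = 0.1), rownames(X))
  shares <- vapply(1:3, function(s) {
    f <- fit_model(model_spec("rf", grid = data.frame(ntree = 300, depth = NA),
                              seed = s), X, yy)
    imp <- f$importance
    imp["f1"] / (imp["f1"] + imp["f2"])
  }, numeric(1))
  expect_true(all(shares > 0.2 & shares < 0.8))
})

test_that("importance aggregation by class is exact bookkeeping", {
  fm <- structure(list(family = "lasso",
                       importance = c(a = 0.4, b = 0.3, c = 0.3)),
                  class = "fitted_model")
  meta <- data.frame(feature_id = c("a", "b", "c", "d"),
                     chem_class = c("PC", "PC", "SM", "PE"))
  out <- importance_by_class(list(lasso = fm), meta)
  expect_equal(out["PC", "lasso"], 0.7)
  expect_equal(out["SM", "lasso"], 0.3)
  expect_equal(sum(out$lasso), 1)

  # permuting feature metadata rows leaves class sums unchanged
  out2 <- importance_by_class(list(lasso = fm), meta[c(3, 1, 4, 2), ])
  expect_equal(out["PC", "lasso"], out2["PC", "lasso"])

  meta_bad <- meta; meta_bad$chem_class[2] <- ""
  expect_error(importance_by_class(list(lasso = fm), meta_bad), "chem_class")
})

test_that("LOO-R2 is near 1 on noiseless linear data and guards degenerate input", {
  sm <- signal_matrix(n = 10, p = 5, slope = 2, noise = 0)
  # vanishing LASSO penalty approaches the OLS fit
  expect_gte(loo_r2(model_spec("lasso", seed = 1), sm$X, sm$y,
                    list(lambda = 1e-3)), 0.99)
  # PLSR through the tuned final-model protocol
  expect_gte(fit_model(model_spec("plsr", seed = 1), sm$X, sm$y)$loo_r2, 0.99)
  yc <- setNames(rep(1, 10), rownames(sm$X))
  expect_error(loo_r2(model_spec("lasso"), sm$X, yc, list(lambda = 0.01)),
               "zero variance")
})

test_that("LOO-R2 on shuffled responses shows no leakage", {
  meds <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(10 * 20), 10, 20,
                dimnames = list(paste0("L", 1:10), paste0("f", 1:20)))
    y <- setNames(sample(3 * X[, 1]), rownames(X))
    loo_r2(model_spec("lasso", seed = s), X, y, list(lambda = 0.01))
  }, numeric(1))
  expect_lte(median(meds), 0)
})

test_that("fit_model is reproducible at a fixed seed across stochastic families", {
  sm <- signal_matrix(n = 10, p = 12, slope = 2, noise = 0.2, seed = 6)
  for (fam in c("rf", "gbr")) {
    a <- fit_model(model_spec(fam, seed = 7), sm$X, sm$y)
    b <- fit_model(model_spec(fam, seed = 7), sm$X, sm$y)
    expect_identical(a$importance, b$importance)
    expect_identical(a$loo_r2, b$loo_r2)
    expect_lte(a$loo_r2, 1)
  }
})

test_that("the full suite achieves strong LOO-R2 on strongly informative synthetic data", {
  hits <- vapply(1:5, function(s) {
    study <- generate_study(synthetic_spec(
      n_features = c(40, 5, 5), n_informative = 5, effect_size = 4,
      replicate_noise_sd = 0.15, n_replicates_nmr = 2,
      batch_location_shift = 0, batch_scale_factor = 1, seed = s))
    sc <- composite_score(study$assays)
    M <- aggregate_by_line(suppressWarnings(autoscale(study$ms_lipid)))
    fm <- fit_model(model_spec("lasso", seed = s), M, sc)
    fp <- fit_model(model_spec("plsr", seed = s), M, sc)
    (fm$loo_r2 >= 0.8) + (fp$loo_r2 >= 0.8)
  }, numeric(1))
  expect_gte(sum(hits), 8)   # >= 80% of the 10 family-runs
})
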