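#' Top-fraction importance features of one model
#'
#' Takes the top `ceil(fraction * m)` features of a fitted model by
#' normalized importance, where `m` is the number of features that entered
#' the model's final fit. Ties are broken by stable input feature order.
#'
#' @param fitted a `fitted_model`, or a named numeric importance vector.
#' @param fraction fraction of features to keep (default 0.20).
#' @return character vector of feature ids.
#' @export
top_fraction_features <- function(fitted, fraction = 0.20) {
  imp <- if (inherits(fitted, "fitted_model")) fitted$importance else fitted
  abort_if(is.null(names(imp)), "importance vector must be named")
  abort_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  k <- ceiling(fraction * length(imp))
  names(imp)[order_desc_stable(imp)[seq_len(k)]]
}

#' Build a cross-model consensus panel
#'
#' A feature enters the panel when it is flagged as important by at least
#' `min_models` model families. The per-feature membership map (which
#' families flagged it) is retained.
#'
#' @param family_sets named list mapping family name to its important
#'   feature set (character vectors).
#' @param min_models minimum number of flagging families (default 2).
#' @return an object of class `consensus_panel`: `features`, `membership`
#'   (named list feature -> families), `counts`, `min_models`.
#' @export
build_consensus <- function(family_sets, min_models = 2) {
  abort_if(length(family_sets) < 2, "need feature sets from >= 2 families")
  abort_if(is.null(names(family_sets)) || any(names(family_sets) == ""),
           "family_sets must be named by family")
  all_feats <- unique(unlist(family_sets, use.names = FALSE))
  membership <- lapply(setNames(all_feats, all_feats), function(f)
    names(family_sets)[vapply(family_sets, function(s) f %in% s, logical(1))])
  counts <- lengths(membership)
  feats <- all_feats[counts >= min_models]
  structure(list(features = feats,
                 membership = membership[feats],
                 counts = counts[feats],
                 min_models = min_models,
                 family_sets = family_sets),
            class = "consensus_panel")
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat(sprintf("consensus_panel: %d features flagged by >= %d of %d families\n",
              length(x$features), x$min_models, length(x$family_sets)))
  if (length(x$features) > 0) {
    show <- head(order(-x$counts), 10)
    for (i in show)
      cat(sprintf("  %s (%d: %s)\n", x$features[i], x$counts[i],
                  paste(x$membership[[x$features[i]]], collapse = ", ")))
  }
  invisible(x)
}

#' Important-feature sets for every family, including SR
#'
#' Applies the top-fraction rule to each standard fitted model and the
#' variable-presence rule to the symbolic-regression run, yielding the
#' per-family sets that feed [build_consensus()].
#'
#' @param models named list of `fitted_model` objects.
#' @param sr_run optional `sr_run`; its set is features with SR variable
#'   presence at least `presence_min`.
#' @param top_fraction fraction for the standard families (default 0.20).
#' @param presence_min SR presence cutoff (default 0.10).
#' @param r2_min,complexity_max SR qualifying-model thresholds.
#' A model whose importances are degenerate (all-zero raw importance, e.g. a
#' LASSO that kept the full set only through the empty-selection fallback)
#' found no signal and contributes an empty set rather than an arbitrary
#' top-k.
#'
#' @return named list of character vectors.
#' @export
family_feature_sets <- function(models, sr_run = NULL, top_fraction = 0.20,
                                presence_min = 0.10, r2_min = 0.90,
                                complexity_max = 300) {
  sets <- lapply(models, function(m) {
    if (inherits(m, "fitted_model") && isTRUE(m$degenerate_importance))
      return(character(0))
    top_fraction_features(m, fraction = top_fraction)
  })
  if (!is.null(sr_run))
    sets$sr <- sr_important_features(sr_run, presence_min = presence_min,
                                     r2_min = r2_min,
                                     complexity_max = complexity_max)
  sets
}

#' Refit every family on the consensus panel
#'
#' Restricts the feature matrix to the panel and re-runs hyperparameter
#' tuning and pooled leave-one-out evaluation per family (no re-selection:
#' the panel is the feature set).
#'
#' @param panel a `consensus_panel` (or character vector of feature ids).
#' @param X line x feature matrix containing the panel features.
#' @param y a `composite_score` or named numeric vector.
#' @param families families to refit (default the six standard ones).
#' @param cv_folds CV folds (default 5).
#' @param seed integer seed.
#' @return named list of `fitted_model`-style records with `loo_r2`.
#' @export
consensus_refit <- function(panel, X, y,
                            families = c("plsr", "svr", "rf", "gbr", "dt", "lasso"),
                            cv_folds = 5, seed = 1) {
  feats <- if (inherits(panel, "consensus_panel")) panel$features else panel
  abort_if(length(feats) == 0,
           "consensus panel is empty; consider lowering min_models")
  miss <- setdiff(feats, colnames(X))
  abort_if(length(miss) > 0, "panel feature %s not in matrix", miss[1])
  Xp <- X[, feats, drop = FALSE]
  y <- score_vector(y, rownames(X))
  names(y) <- rownames(X)
  out <- lapply(families, function(fam) {
    spec <- model_spec(fam, cv_folds = cv_folds, seed = seed)
    with_seed(seed, {
      tuned <- tune_impl(spec, Xp, y)
      final <- fit_family(fam, Xp, y, tuned$params)
      imp <- raw_importance(final)
      degenerate <- sum(imp) == 0
      imp <- if (!degenerate) imp / sum(imp)
             else setNames(rep(1 / length(imp), length(imp)), names(imp))
      structure(list(family = fam, params = tuned$params,
                     selected_features = feats, importance = imp,
                     degenerate_importance = degenerate,
                     loo_r2 = loo_impl(fam, Xp, y, tuned$params),
                     cv_results = tuned$cv_results, fit = final, seed = seed),
                class = "fitted_model")
    })
  })
  setNames(out, families)
}

#' Outlier-line ablation refit
#'
#' Drops one line, re-tunes on the remaining lines with a reduced fold count
#' (default 3), and recomputes pooled leave-one-out R2 using the *same*
#' consensus panel (not re-selected). Used to test whether the consensus
#' models depend on a single atypical line.
#'
#' @inheritParams consensus_refit
#' @param exclude_line line id to drop.
#' @param cv_folds CV folds after exclusion (default 3).
#' @return named list of refit records, as in [consensus_refit()].
#' @export
ablation_refit <- function(panel, X, y, exclude_line,
                           families = c("plsr", "svr", "rf", "gbr", "dt", "lasso"),
                           cv_folds = 3, seed = 1) {
  abort_if(!(exclude_line %in% rownames(X)),
           "line %s not present in matrix", exclude_line)
  keep <- setdiff(rownames(X), exclude_line)
  abort_if(length(keep) < 4, "exclusion leaves fewer than 4 lines")
  abort_if(length(keep) < cv_folds, "exclusion leaves fewer lines than folds")
  y <- score_vector(y, rownames(X))
  names(y) <- rownames(X)
  consensus_refit(panel, X[keep, , drop = FALSE], y[keep],
                  families = families, cv_folds = cv_folds, seed = seed)
}

# serializable record of a consensus panel
consensus_panel_record <- function(panel) {
  list(min_models = panel$min_models,
       features = panel$features,
       counts = as.list(panel$counts),
       membership = panel$membership,
       family_sets = panel$family_sets)
}
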