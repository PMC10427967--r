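#' Filter reports
#'
#' Every filter returns, alongside the filtered table, a `filter_report`
#' recording the rule, its parameters, and an exact partition of the input
#' features into removed and kept.
#'
#' @param rule rule name.
#' @param removed character vector of removed feature ids.
#' @param kept character vector of kept feature ids.
#' @param params named list of parameters used.
#' @return object of class `filter_report`.
#' @export
filter_report <- function(rule, removed, kept, params = list()) {
  abort_if(length(intersect(removed, kept)) > 0,
           "filter report: removed and kept overlap")
  structure(list(rule = rule, removed = removed, kept = kept,
                 n_kept = length(kept), params = params),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: removed %d, kept %d\n",
              x$rule, length(x$removed), x$n_kept))
  invisible(x)
}

#' Blank-ratio and QC-presence feature filter
#'
#' Keeps a feature iff its mean signal over experimental samples is at least
#' `blank_ratio` times its mean signal over blank samples, and it is nonzero
#' in at least a `qc_presence` fraction of pooled-QC injections. Blank and QC
#' samples remain in the returned table for audit.
#'
#' @param table a `feature_table` containing at least one blank and one
#'   qc_pool sample.
#' @param blank_ratio required experimental/blank mean ratio (default 5).
#' @param qc_presence required nonzero fraction among QC injections
#'   (default 0.5).
#' @return list with elements `table` (stage `"filtered"`) and `report`.
#' @export
blank_qc_filter <- function(table, blank_ratio = 5, qc_presence = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  roles <- table$sample_meta$role
  abort_if(!any(roles == "blank"), "no blank samples in table")
  abort_if(!any(roles == "qc_pool"), "no qc_pool samples in table")
  expv <- ft_values(table, "experimental")
  blv <- ft_values(table, "blank")
  qcv <- ft_values(table, "qc_pool")
  exp_mean <- colMeans(expv)
  blank_mean <- colMeans(blv)
  presence <- colMeans(qcv != 0)
  keep <- (exp_mean >= blank_ratio * blank_mean) & (presence >= qc_presence)
  fid <- table$feature_meta$feature_id
  out <- ft_subset(table, features = fid[keep])
  out$stage <- "filtered"
  list(table = out,
       report = filter_report("blank_qc", fid[!keep], fid[keep],
                              list(blank_ratio = blank_ratio,
                                   qc_presence = qc_presence)))
}

#' Relative-standard-deviation feature filter
#'
#' Computes RSD = sd/|mean| per feature over experimental samples. The
#' default direction removes features with RSD *below* the threshold
#' (discarding near-constant features); `mode = "remove_above"` gives the
#' conventional QC-repeatability reading. Features with mean zero have
#' undefined RSD and are removed with a message.
#'
#' @param table a `feature_table` with >= 2 experimental samples.
#' @param threshold RSD threshold as a fraction (default 0.25).
#' @param mode `"remove_below"` (default) or `"remove_above"`.
#' @return list with elements `table` (stage `"filtered"`) and `report`.
#' @export
rsd_filter <- function(table, threshold = 0.25,
                       mode = c("remove_below", "remove_above")) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  expv <- ft_values(table, "experimental")
  abort_if(nrow(expv) < 2, "RSD filter needs >= 2 experimental samples")
  m <- colMeans(expv)
  s <- apply(expv, 2, sd)
  rsd <- s / abs(m)
  undefined <- m == 0
  if (any(undefined))
    message(sprintf("%d feature(s) with zero mean removed (undefined RSD)",
                    sum(undefined)))
  keep <- if (mode == "remove_below") rsd >= threshold else rsd <= threshold
  keep[undefined] <- FALSE
  fid <- table$feature_meta$feature_id
  out <- ft_subset(table, features = fid[keep])
  out$stage <- "filtered"
  list(table = out,
       report = filter_report("rsd", fid[!keep], fid[keep],
                              list(threshold = threshold, mode = mode)))
}

#' Median normalization across samples
#'
#' Rescales each sample so that all sample medians equal the global median
#' of sample medians: values are multiplied by
#' `median(sample medians) / median(sample)`.
#'
#' @param table a `feature_table` at stage raw or filtered.
#' @return the normalized `feature_table` (stage `"normalized"`).
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  abort_if(!(table$stage %in% c("raw", "filtered")),
           "median_normalize expects a raw or filtered table (got %s)", table$stage)
  med <- apply(table$values, 1, median)
  zero <- rownames(table$values)[med == 0]
  abort_if(length(zero) > 0, "sample %s has median 0", zero[1])
  target <- median(med)
  out <- table
  out$values <- sweep(table$values, 1, target / med, "*")
  out$stage <- "normalized"
  out
}

#' Autoscale features (unit variance, zero mean)
#'
#' Per feature, subtracts the mean and divides by the SD computed over
#' experimental samples; the same transform is applied to any blank/QC rows.
#' Zero-SD features are set to zero with a warning. The operation is
#' idempotent.
#'
#' @param table a `feature_table` with >= 2 experimental samples.
#' @return the scaled `feature_table` (stage `"scaled"`).
#' @export
autoscale <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  expv <- ft_values(table, "experimental")
  abort_if(nrow(expv) < 2, "autoscale needs >= 2 experimental samples")
  m <- colMeans(expv)
  s <- apply(expv, 2, sd)
  const <- s == 0
  if (any(const)) {
    warning(sprintf("%d constant feature(s) set to 0 by autoscaling", sum(const)))
    s[const] <- 1
  }
  out <- table
  out$values <- sweep(sweep(table$values, 2, m, "-"), 2, s, "/")
  out$values[, const] <- 0
  out$stage <- "scaled"
  out
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Adjusts per-batch location and scale of every feature with the parametric
#' empirical-Bayes ComBat model (via the sva package): features are
#' standardized, per-batch/per-feature effects are shrunk toward batch-level
#' hyperpriors, removed, and the grand location/scale restored. A
#' single-batch table is returned unchanged. Features with zero variance
#' within some batch are left uncorrected with a warning.
#'
#' @param table a `feature_table`; every batch must have >= 2 samples.
#' @param batch_key sample-metadata column holding the batch label
#'   (default `"batch_id"`).
#' @param mean_only if `TRUE`, adjust location only.
#' @return the corrected `feature_table` (same stage).
#' @export
combat_correct <- function(table, batch_key = "batch_id", mean_only = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  batch <- table$sample_meta[[batch_key]]
  abort_if(is.null(batch), "no sample metadata column '%s'", batch_key)
  tab <- table(batch)
  if (length(tab) < 2) return(table)
  small <- names(tab)[tab < 2]
  abort_if(length(small) > 0, "batch %s has fewer than 2 samples", small[1])

  v <- table$values
  # features with no variation within some batch break the EB scale model
  ok <- rep(TRUE, ncol(v))
  for (b in names(tab)) {
    vb <- v[batch == b, , drop = FALSE]
    ok <- ok & (apply(vb, 2, sd) > 0)
  }
  if (any(!ok))
    warning(sprintf("%d feature(s) with zero within-batch variance left uncorrected",
                    sum(!ok)))
  out <- table
  if (any(ok)) {
    dat <- t(v[, ok, drop = FALSE])
    corrected <- suppressMessages(
      sva::ComBat(dat = dat, batch = batch, mean.only = mean_only,
                  par.prior = TRUE))
    out$values[, ok] <- t(corrected)
  }
  out
}

#' NMR timepoint differencing
#'
#' For each (line, replicate) culture flask, subtracts the baseline-day
#' value from the target-day value, producing one row per flask of net
#' change features. Works on experimental samples only.
#'
#' @param nmr_table a `feature_table` with per-sample `day` metadata.
#' @param baseline_day baseline day (default 1).
#' @param target_day target day.
#' @return a `feature_table` at stage `"differenced"`, one sample per flask.
#' @export
day_difference <- function(nmr_table, baseline_day = 1, target_day) {
  stopifnot(inherits(nmr_table, "feature_table"))
  sm <- nmr_table$sample_meta
  keep <- sm$role == "experimental" & sm$day %in% c(baseline_day, target_day)
  sm <- sm[keep, , drop = FALSE]
  v <- nmr_table$values[keep, , drop = FALSE]
  flask <- paste(sm$line_id, sm$replicate_id, sep = "_")
  out_rows <- list(); out_meta <- list()
  for (fl in unique(flask)) {
    i_base <- which(flask == fl & sm$day == baseline_day)
    i_tgt <- which(flask == fl & sm$day == target_day)
    abort_if(length(i_base) != 1 || length(i_tgt) != 1,
             "flask %s lacks exactly one sample on days %d and %d",
             fl, baseline_day, target_day)
    out_rows[[fl]] <- v[i_tgt, ] - v[i_base, ]
    out_meta[[fl]] <- data.frame(
      sample_id = fl, line_id = sm$line_id[i_tgt], batch_id = sm$batch_id[i_tgt],
      role = "experimental", day = NA_integer_,
      replicate_id = sm$replicate_id[i_tgt], stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, out_rows)
  feature_table(values, do.call(rbind, out_meta), nmr_table$feature_meta,
                stage = "differenced")
}

#' PLSR-guided variance filtering
#'
#' For each candidate fraction `p` in `percent_grid`, retains the top-`p`
#' fraction of features by variance across lines, fits a partial least
#' squares regression of the potency score on them, and records the pooled
#' leave-one-out R2. Returns the subset maximizing it (ties resolved toward
#' the smaller fraction).
#'
#' @param X line x feature matrix (replicate means), or a `feature_table`
#'   which is aggregated by line first.
#' @param y a `composite_score` or named numeric vector covering all lines.
#' @param percent_grid fractions to scan (default 0.05 to 1 by 0.05).
#' @param ncomp PLS components (default `min(2, n_lines - 2)`).
#' @return list with `features` (chosen ids), `fraction`, `loo_r2` of the
#'   winner, and `grid` (data.frame of fraction vs LOO-R2).
#' @export
variance_filter_select <- function(X, y, percent_grid = seq(0.05, 1, by = 0.05),
                                   ncomp = NULL) {
  abort_if(length(percent_grid) == 0, "percent_grid is empty")
  if (inherits(X, "feature_table")) X <- aggregate_by_line(X)
  y <- score_vector(y, rownames(X))
  n <- nrow(X)
  if (is.null(ncomp)) ncomp <- max(1, min(2, n - 2))
  vars <- apply(X, 2, var)
  ord <- order_desc_stable(vars)
  grid <- sort(percent_grid)
  scores <- vapply(grid, function(p) {
    k <- max(1, ceiling(p * ncol(X)))
    Xi <- X[, ord[seq_len(k)], drop = FALSE]
    pls_loo_r2(Xi, y, ncomp = min(ncomp, ncol(Xi)))
  }, numeric(1))
  best <- which.max(scores)  # grid ascending, which.max takes first => smaller p
  k <- max(1, ceiling(grid[best] * ncol(X)))
  list(features = colnames(X)[ord[seq_len(k)]],
       fraction = grid[best], loo_r2 = scores[best],
       grid = data.frame(fraction = grid, loo_r2 = scores))
}

# internal: pooled LOO-R^2 of a PLS regression (used by the variance filter)
pls_loo_r2 <- function(X, y, ncomp = 2) {
  n <- nrow(X)
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
    yhat[i] <- predict_pls(fit, X[i, , drop = FALSE])
  }
  r_squared(y, yhat)
}
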