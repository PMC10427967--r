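#' IDO activity normalized per cell per day
#'
#' Converts a measured mass of L-kynurenine to the standard activity unit
#' pg/cell/day.
#'
#' @param kynurenine_mass L-kynurenine produced, in pg (>= 0).
#' @param cell_count number of cells in the well (> 0).
#' @param duration assay duration in days (> 0).
#' @return activity in pg/cell/day. Vectorized.
#' @export
ido_activity_per_cell <- function(kynurenine_mass, cell_count, duration) {
  abort_if(any(cell_count <= 0), "cell_count must be > 0")
  abort_if(any(duration <= 0), "duration must be > 0")
  abort_if(any(kynurenine_mass < 0), "kynurenine_mass must be >= 0")
  kynurenine_mass / (cell_count * duration)
}

#' Composite potency score from the functional assay panel
#'
#' Autoscales the five assay variables across lines and takes each line's
#' first principal component coordinate as its composite functional score.
#' The PC1 sign is oriented so that the loading-weighted mean over the four
#' T-cell proliferation variables is positive: higher proliferation (weaker
#' suppression, lower potency) maps to a higher score, so the most potent
#' lines have the lowest scores.
#'
#' @param panel a [potency_assay_panel()] with >= 3 lines.
#' @return an object of class `composite_score`: data.frame of `line_id` and
#'   `score`, with attributes `variance_explained` (PC1 fraction),
#'   `variance_fractions` (all components), `loadings` and `orientation`.
#' @export
composite_score <- function(panel) {
  stopifnot(inherits(panel, "potency_assay_panel"))
  abort_if(nrow(panel) < 3, "composite score needs >= 3 lines")
  vars <- assay_variables()
  M <- as.matrix(panel[, vars])
  rownames(M) <- panel$line_id
  zero <- vars[apply(M, 2, sd) == 0]
  abort_if(length(zero) > 0, "assay variable %s has zero variance", zero[1])
  Z <- scale(M)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  fractions <- pc$sdev^2 / sum(pc$sdev^2)
  prolif <- c("cd4_d1", "cd8_d1", "cd4_d2", "cd8_d2")
  flip <- if (mean(pc$rotation[prolif, 1]) < 0) -1 else 1
  score <- flip * pc$x[, 1]
  out <- data.frame(line_id = panel$line_id, score = unname(score),
                    stringsAsFactors = FALSE)
  structure(out,
            variance_explained = fractions[1],
            variance_fractions = fractions,
            loadings = flip * pc$rotation[, 1],
            orientation = flip,
            class = c("composite_score", "data.frame"))
}

#' @export
print.composite_score <- function(x, ...) {
  cat(sprintf("composite_score for %d lines (PC1 explains %.1f%% of variance)\n",
              nrow(x), 100 * attr(x, "variance_explained")))
  print.data.frame(x, ...)
  invisible(x)
}

# internal: coerce a composite_score (or named vector) to a vector aligned
# with the given line ids
score_vector <- function(y, line_ids) {
  if (inherits(y, "composite_score")) y <- setNames(y$score, y$line_id)
  abort_if(is.null(names(y)), "score vector must be named by line id")
  miss <- setdiff(line_ids, names(y))
  abort_if(length(miss) > 0, "no score for line %s", miss[1])
  unname(y[line_ids])
}

#' Univariate feature screening against the potency score
#'
#' Fits an ordinary least squares regression of the score on each feature
#' separately, reports slope, R2 (the squared Pearson correlation), the
#' two-sided p-value for the slope, and Benjamini-Hochberg q-values across
#' features, sorted by R2 descending. Constant features are recorded with
#' R2 = 0, p = 1.
#'
#' @param X line x feature matrix (one row per line), or a `feature_table`
#'   which is aggregated by line first.
#' @param y a `composite_score` or named numeric vector.
#' @return data.frame with columns `feature_id`, `slope`, `r2`, `p`, `q`.
#' @export
univariate_screen <- function(X, y) {
  if (inherits(X, "feature_table")) X <- aggregate_by_line(X)
  y <- score_vector(y, rownames(X))
  n <- nrow(X)
  abort_if(n < 4, "univariate screening needs >= 4 lines")
  abort_if(sd(y) == 0, "score has zero variance")
  sx <- apply(X, 2, sd)
  const <- sx == 0
  r <- rep(0, ncol(X))
  r[!const] <- as.vector(cor(y, X[, !const, drop = FALSE]))
  slope <- ifelse(const, 0, r * sd(y) / ifelse(const, 1, sx))
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  p[const] <- 1
  q <- p.adjust(p, method = "BH")
  out <- data.frame(feature_id = colnames(X), slope = slope, r2 = r^2,
                    p = p, q = q, stringsAsFactors = FALSE)
  out <- out[order_desc_stable(out$r2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
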