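# Small fixtures built in code; all randomness is locally seeded.

# minimal valid feature table: n samples x p features, all experimental
tiny_table <- function(n = 3, p = 2, seed = 1, stage = "raw",
                       values = NULL) {
  set.seed(seed)
  if (is.null(values))
    values <- matrix(exp(rnorm(n * p, mean = 2)), n, p)
  dimnames(values) <- NULL
  sm <- data.frame(sample_id = paste0("S", seq_len(n)),
                   line_id = paste0("L", seq_len(n)),
                   batch_id = "B1", role = "experimental",
                   stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = paste0("f", seq_len(p)),
                   chem_class = "PC", platform = "ms_lipid",
                   stringsAsFactors = FALSE)
  feature_table(values, sm, fm, stage = stage)
}

# table with experimental + blank + qc samples and hand-set feature means
filter_fixture <- function(exp_vals, blank_vals, qc_vals) {
  p <- ncol(exp_vals)
  n_e <- nrow(exp_vals); n_b <- nrow(blank_vals); n_q <- nrow(qc_vals)
  values <- rbind(exp_vals, blank_vals, qc_vals)
  rownames(values) <- c(paste0("E", seq_len(n_e)), paste0("B", seq_len(n_b)),
                        paste0("Q", seq_len(n_q)))
  sm <- data.frame(
    sample_id = rownames(values),
    line_id = c(paste0("L", seq_len(n_e)), rep("none", n_b + n_q)),
    batch_id = "B1",
    role = c(rep("experimental", n_e), rep("blank", n_b), rep("qc_pool", n_q)),
    stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = paste0("f", seq_len(p)),
                   stringsAsFactors = FALSE)
  feature_table(values, sm, fm)
}

# line x feature matrix with named rows, planted linear signal in column 1
signal_matrix <- function(n = 10, p = 20, slope = 1, noise = 0.01, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("L", seq_len(n)), paste0("f", seq_len(p))))
  y <- setNames(slope * X[, 1] + rnorm(n, sd = noise), rownames(X))
  list(X = X, y = y)
}

# write a small GMT file, return its path
write_gmt_fixture <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# assay panel that is exactly rank 1 (all variables affine in one vector)
rank1_panel <- function(n = 6) {
  z <- seq_len(n)
  potency_assay_panel(data.frame(
    line_id = paste0("L", seq_len(n)),
    cd4_d1 = 40 + 2 * z, cd8_d1 = 50 + 3 * z,
    cd4_d2 = 20 + 1 * z, cd8_d2 = 30 + 4 * z,
    ido = 10 + 5 * z))
}

# independent brute-force consensus oracle: per-feature membership count
consensus_oracle <- function(family_sets, min_models) {
  feats <- unique(unlist(family_sets))
  counts <- vapply(feats, function(f)
    sum(vapply(family_sets, function(s) f %in% s, logical(1))), integer(1))
  feats[counts >= min_models]
}

# exhaustive hypergeometric upper tail by enumeration of all draws
ora_enum_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # first K elements form the pathway
  mean(hits >= k)
}
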