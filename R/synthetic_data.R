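#' Specification for a synthetic MSC metabolomics study
#'
#' Defines the generative model used to emulate a multi-platform MSC potency
#' study: a single latent potency factor per cell line drives both the
#' functional assay panel and a small planted subset of informative features
#' on each platform, with replicate noise, two-batch location/scale effects
#' and non-monotonic NMR time trajectories over culture days 1-3.
#'
#' Effect sizes are expressed in units of the feature-level noise SD: an
#' informative feature's (log-scale) line mean moves by
#' `effect_size * replicate_noise_sd` per latent-potency SD. Raw intensities
#' are generated log-normal so tables are strictly positive.
#'
#' @param n_lines number of MSC lines (default 10).
#' @param n_replicates_nmr replicate flasks per line for NMR (default 10).
#' @param n_features named or unnamed vector of feature counts for the three
#'   platforms `ms_lipid`, `ms_polar`, `nmr` (default 200 each).
#' @param n_informative number of informative (potency-associated) features
#'   per platform (default 5).
#' @param effect_size slope of informative-feature mean vs latent potency in
#'   feature-noise-SD units (default 3).
#' @param donor_noise_sd assay noise SD in percentage points of CFSE
#'   dilution (default 3).
#' @param replicate_noise_sd log-intensity noise SD per sample (default 0.2).
#' @param batch_location_shift additive log-scale shift applied to batch 2
#'   (default 0.5).
#' @param batch_scale_factor multiplicative factor on log-scale deviations in
#'   batch 2 (default 1.3).
#' @param nmr_days culture days sampled for NMR media (default 1:3).
#' @param seed integer seed; every draw is deterministic given it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lines = 10, n_replicates_nmr = 10,
                           n_features = c(ms_lipid = 200, ms_polar = 200, nmr = 200),
                           n_informative = 5, effect_size = 3,
                           donor_noise_sd = 3, replicate_noise_sd = 0.2,
                           batch_location_shift = 0.5, batch_scale_factor = 1.3,
                           nmr_days = 1:3, seed = 1) {
  if (length(n_features) == 1) n_features <- rep(n_features, 3)
  if (is.null(names(n_features))) names(n_features) <- c("ms_lipid", "ms_polar", "nmr")
  abort_if(n_lines < 3, "n_lines must be >= 3 (got %d)", n_lines)
  abort_if(any(n_informative > n_features) || n_informative < 0,
           "n_informative must be within [0, n_features]")
  abort_if(batch_scale_factor <= 0, "batch_scale_factor must be > 0")
  abort_if(donor_noise_sd < 0 || replicate_noise_sd < 0, "noise SDs must be >= 0")
  structure(list(
    n_lines = n_lines, n_replicates_nmr = n_replicates_nmr,
    n_features = n_features, n_informative = n_informative,
    effect_size = effect_size, donor_noise_sd = donor_noise_sd,
    replicate_noise_sd = replicate_noise_sd,
    batch_location_shift = batch_location_shift,
    batch_scale_factor = batch_scale_factor,
    nmr_days = nmr_days, seed = seed), class = "synthetic_spec")
}

ms_chem_classes <- function(platform) {
  if (platform == "ms_lipid")
    c("PC", "PE", "PE-O", "SM", "PS", "PI", "Cer", "TG")
  else c("amino-acid", "sugar", "organic-acid", "nucleotide", "amine")
}

# batch assignment: first half of lines to batch B1, rest to B2
line_batches <- function(line_ids) {
  b <- rep("B1", length(line_ids))
  b[seq_along(line_ids) > length(line_ids) / 2] <- "B2"
  setNames(b, line_ids)
}

apply_batch_effect <- function(logv, batch, mu, shift, scale) {
  # location shift plus scaling of log-deviations around the feature baseline
  in2 <- batch == "B2"
  if (any(in2)) {
    dev <- sweep(logv[in2, , drop = FALSE], 2, mu, "-")
    logv[in2, ] <- sweep(dev * scale, 2, mu, "+") + shift
  }
  logv
}

#' Generate a seeded synthetic study
#'
#' Draws a latent potency per line (higher = more immunosuppressive), builds
#' the five-variable assay panel as noisy affine transforms of it (IDO is
#' partly decoupled with extra noise, mirroring real mid-range IDO outliers),
#' and generates three platform feature tables in which only the planted
#' informative features track latent potency. NMR features evolve over days
#' with per-feature trajectory shapes (linear, saturating or non-monotonic);
#' informative NMR signal is carried in the day-differences.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `ms_lipid`, `ms_polar`, `nmr`
#'   (feature tables), `assays` (a `potency_assay_panel`) and `truth`
#'   (latent potency, informative ids and effect signs per platform).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_lines
    line_ids <- sprintf("L%02d", seq_len(n))
    latent <- rnorm(n)
    names(latent) <- line_ids
    batches <- line_batches(line_ids)

    assays <- make_assay_panel(line_ids, latent, spec$donor_noise_sd)

    truth <- list(latent_potency = latent, informative = list(),
                  effect_signs = list())
    tables <- list()
    for (pf in c("ms_lipid", "ms_polar")) {
      g <- make_ms_table(spec, pf, line_ids, latent, batches)
      tables[[pf]] <- g$table
      truth$informative[[pf]] <- g$informative
      truth$effect_signs[[pf]] <- g$signs
    }
    g <- make_nmr_table(spec, line_ids, latent, batches)
    tables$nmr <- g$table
    truth$informative$nmr <- g$informative
    truth$effect_signs$nmr <- g$signs
    truth$nmr_trajectory <- g$trajectory

    c(tables, list(assays = assays, truth = truth))
  })
}

make_assay_panel <- function(line_ids, latent, noise_sd) {
  n <- length(line_ids)
  clamp <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)
  # proliferation falls with potency; ranges echo observed CFSE spans
  panel <- data.frame(
    line_id = line_ids,
    cd4_d1 = clamp(57 - 10 * latent + rnorm(n, sd = noise_sd)),
    cd8_d1 = clamp(65 - 11 * latent + rnorm(n, sd = noise_sd)),
    cd4_d2 = clamp(28 - 9 * latent + rnorm(n, sd = noise_sd)),
    cd8_d2 = clamp(26 - 8 * latent + rnorm(n, sd = noise_sd)),
    # IDO rises with potency but is partly decoupled (3x noise)
    ido = pmax(50 + 15 * latent + rnorm(n, sd = 3 * noise_sd), 0),
    stringsAsFactors = FALSE)
  potency_assay_panel(panel)
}

make_ms_table <- function(spec, platform, line_ids, latent, batches) {
  p <- spec$n_features[[platform]]
  n <- length(line_ids)
  fid <- paste0(sub("ms_", "", platform), "_", sprintf("%03d", seq_len(p)))
  informative <- sample(fid, spec$n_informative)
  signs <- setNames(sample(c(-1, 1), spec$n_informative, replace = TRUE),
                    informative)
  mu <- rnorm(p, mean = 10, sd = 0.8)
  beta <- setNames(numeric(p), fid)
  beta[informative] <- signs * spec$effect_size * spec$replicate_noise_sd

  logv <- matrix(rnorm(n * p, sd = spec$replicate_noise_sd), n, p)
  logv <- sweep(logv, 2, mu, "+") + outer(latent, beta)
  rownames(logv) <- line_ids; colnames(logv) <- fid
  logv <- apply_batch_effect(logv, batches[line_ids], mu,
                             spec$batch_location_shift, spec$batch_scale_factor)

  sm <- data.frame(sample_id = line_ids, line_id = line_ids,
                   batch_id = unname(batches[line_ids]), role = "experimental",
                   day = NA_integer_, replicate_id = "r1",
                   stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = fid, annotation = fid,
                   chem_class = sample(ms_chem_classes(platform), p, replace = TRUE),
                   platform = platform, nmr_shift_ppm = NA_real_,
                   stringsAsFactors = FALSE)
  list(table = feature_table(exp(logv), sm, fm, stage = "raw"),
       informative = informative, signs = signs)
}

make_nmr_table <- function(spec, line_ids, latent, batches) {
  p <- spec$n_features[["nmr"]]
  n <- length(line_ids)
  reps <- spec$n_replicates_nmr
  days <- spec$nmr_days
  # NMR features are named by chemical shift (ppm), the field convention
  ppm <- sort(round(runif(p, 0.5, 9.5), 2), decreasing = TRUE)
  fid <- formatC(ppm, format = "f", digits = 3)
  while (anyDuplicated(fid)) {
    d <- duplicated(fid)
    ppm[d] <- ppm[d] - 0.005
    fid <- formatC(ppm, format = "f", digits = 3)
  }
  informative <- sample(fid, spec$n_informative)
  signs <- setNames(sample(c(-1, 1), spec$n_informative, replace = TRUE),
                    informative)
  mu <- rnorm(p, mean = 10, sd = 0.8)
  beta <- setNames(numeric(p), fid)
  beta[informative] <- signs * spec$effect_size * spec$replicate_noise_sd

  shape <- sample(c("linear", "saturating", "non_monotonic"), p, replace = TRUE)
  amp <- rnorm(p, sd = 0.4)
  traj_val <- function(s, a, day) {
    t <- day - min(days)
    switch(s,
           linear = a * t / 2,
           saturating = a * (1 - exp(-1.5 * t)),
           non_monotonic = a * c(0, 1, -0.6)[t + 1])
  }
  ramp <- function(day) (day - min(days)) / (max(days) - min(days))

  grid <- expand.grid(rep = seq_len(reps), line = line_ids, day = days,
                      stringsAsFactors = FALSE)
  ns <- nrow(grid)
  logv <- matrix(rnorm(ns * p, sd = spec$replicate_noise_sd), ns, p)
  for (j in seq_len(p)) {
    tj <- vapply(grid$day, function(d) traj_val(shape[j], amp[j], d), 0)
    logv[, j] <- logv[, j] + mu[j] + tj +
      beta[j] * latent[grid$line] * ramp(grid$day)
  }
  sample_ids <- sprintf("%s_r%02d_d%d", grid$line, grid$rep, grid$day)
  rownames(logv) <- sample_ids; colnames(logv) <- fid
  logv <- apply_batch_effect(logv, batches[grid$line], mu,
                             spec$batch_location_shift, spec$batch_scale_factor)

  sm <- data.frame(sample_id = sample_ids, line_id = grid$line,
                   batch_id = unname(batches[grid$line]), role = "experimental",
                   day = grid$day, replicate_id = sprintf("r%02d", grid$rep),
                   stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = fid, annotation = "",
                   chem_class = "nmr-feature", platform = "nmr",
                   nmr_shift_ppm = ppm, stringsAsFactors = FALSE)
  list(table = feature_table(exp(logv), sm, fm, stage = "raw"),
       informative = informative, signs = signs,
       trajectory = data.frame(feature_id = fid, shape = shape, amplitude = amp,
                               stringsAsFactors = FALSE))
}

#' Augment an MS table with blank and pooled-QC samples
#'
#' Adds process blanks (low-level background) and pooled-QC injections
#' (per-feature mean of experimental samples plus small noise). A
#' configurable subset of features can be planted to fail the downstream
#' blank-ratio rule (blank signal at half the experimental mean) or the
#' QC-presence rule (zero intensity in `qc_dropout` of QC injections), to
#' exercise [blank_qc_filter()].
#'
#' @param table an MS `feature_table` at stage raw.
#' @param n_blanks,n_qcs numbers of blank and pooled-QC samples (default 3, 6).
#' @param blank_dominated feature ids to make blank-dominated (default none).
#' @param qc_absent feature ids to make QC-absent (default none).
#' @param qc_dropout fraction of QC injections zeroed for `qc_absent`
#'   features (default 0.6).
#' @param seed integer seed.
#' @return the augmented `feature_table`.
#' @export
generate_blanks_and_qcs <- function(table, n_blanks = 3, n_qcs = 6,
                                    blank_dominated = character(),
                                    qc_absent = character(),
                                    qc_dropout = 0.6, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  fid <- table$feature_meta$feature_id
  stray <- setdiff(c(blank_dominated, qc_absent), fid)
  abort_if(length(stray) > 0, "unknown feature id: %s", stray[1])
  with_seed(seed, {
    expv <- ft_values(table, role = "experimental")
    fmean <- colMeans(expv)
    # blanks: background at ~1/1000 of signal; blank-dominated at 1/2
    blank_mu <- fmean / 1000
    blank_mu[fid %in% blank_dominated] <- fmean[fid %in% blank_dominated] / 2
    blanks <- t(vapply(seq_len(n_blanks),
                       function(i) blank_mu * exp(rnorm(length(fid), sd = 0.1)),
                       numeric(length(fid))))
    rownames(blanks) <- sprintf("blank_%02d", seq_len(n_blanks))
    qcs <- t(vapply(seq_len(n_qcs),
                    function(i) fmean * exp(rnorm(length(fid), sd = 0.05)),
                    numeric(length(fid))))
    rownames(qcs) <- sprintf("qc_%02d", seq_len(n_qcs))
    if (length(qc_absent) > 0) {
      n_zero <- ceiling(qc_dropout * n_qcs)
      for (f in qc_absent) qcs[seq_len(n_zero), f] <- 0
    }
    batch0 <- table$sample_meta$batch_id[1]
    extra_sm <- data.frame(
      sample_id = c(rownames(blanks), rownames(qcs)),
      line_id = "none", batch_id = batch0,
      role = c(rep("blank", n_blanks), rep("qc_pool", n_qcs)),
      day = NA_integer_, replicate_id = "r1", stringsAsFactors = FALSE)
    feature_table(rbind(table$values, blanks, qcs),
                  rbind(table$sample_meta, extra_sm),
                  table$feature_meta, stage = table$stage)
  })
}
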