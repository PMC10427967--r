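#' Default end-to-end pipeline configuration
#'
#' Produces the configuration list consumed by [run_pipeline()], set up for
#' a fully synthetic demonstration study. Every block mirrors one analysis
#' stage; replace the `synth` block with an `inputs` block (file paths) to
#' run on real data.
#'
#' @param seed integer seed propagated to every stochastic stage.
#' @return a nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    synth = list(
      n_lines = 10, n_replicates_nmr = 10,
      n_features = c(ms_lipid = 200, ms_polar = 200, nmr = 200),
      n_informative = 5, effect_size = 3,
      n_blanks = 3, n_qcs = 6, n_blank_dominated = 5, n_qc_absent = 5),
    preprocess = list(
      blank_ratio = 5, qc_presence = 0.5,
      rsd_threshold = 0.25, rsd_mode = "remove_below",
      baseline_day = 1, target_days = c(2, 3),
      percent_grid = seq(0.05, 1, by = 0.05)),
    suite = list(
      families = c("plsr", "svr", "rf", "gbr", "dt", "lasso"),
      cv_folds = 5, retune = TRUE),
    sr = list(
      enabled = TRUE, population = 120, generations = 25, restarts = 6),
    consensus = list(
      min_models = 2, top_fraction = 0.20, presence_min = 0.10,
      r2_min = 0.90, complexity_max = 300),
    ablation = list(exclude_line = NULL, cv_folds = 3),
    enrichment = list(gmt = NULL))
}

#' Load and validate a pipeline configuration
#'
#' Accepts a configuration list or a YAML file path, merges it over
#' [default_pipeline_config()] (so partial configs are valid) and checks
#' that a data source (`synth` or `inputs` block) is present.
#'
#' @param config list or YAML path.
#' @return the merged configuration list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(!is.list(config), "config must be a list or a YAML file path")
  base <- default_pipeline_config(config$seed %||% 1)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_cfg(base, config)
  abort_if(is.null(cfg$synth) && is.null(cfg$inputs),
           "config needs either a 'synth' or an 'inputs' block")
  cfg
}

# preprocess one MS table: blank/QC filter -> RSD filter -> median
# normalization -> batch correction -> autoscaling -> line aggregation
preprocess_ms <- function(table, cfg) {
  f1 <- blank_qc_filter(table, cfg$blank_ratio, cfg$qc_presence)
  exp_only <- ft_subset(
    f1$table,
    samples = f1$table$sample_meta$sample_id[
      f1$table$sample_meta$role == "experimental"])
  f2 <- rsd_filter(exp_only, cfg$rsd_threshold, cfg$rsd_mode)
  norm <- median_normalize(f2$table)
  corrected <- combat_correct(norm)
  scaled <- suppressWarnings(autoscale(corrected))
  list(matrix = aggregate_by_line(scaled), table = scaled,
       reports = list(blank_qc = f1$report, rsd = f2$report))
}

# preprocess NMR: batch correction -> per-timepoint differencing ->
# line aggregation -> PLS-guided variance filtering
preprocess_nmr <- function(table, cfg, score) {
  corrected <- combat_correct(table)
  out <- list()
  for (d in cfg$target_days) {
    diffed <- day_difference(corrected, cfg$baseline_day, d)
    M <- aggregate_by_line(diffed)
    sel <- variance_filter_select(M, score, percent_grid = cfg$percent_grid)
    out[[paste0("nmr_day", d)]] <- list(
      matrix = M[, sel$features, drop = FALSE], full_matrix = M,
      selection = sel, diff_table = diffed)
  }
  out
}

analyze_dataset <- function(M, score, cfg, seed) {
  models <- fit_suite(M, score, families = cfg$suite$families,
                      cv_folds = cfg$suite$cv_folds, seed = seed,
                      retune = cfg$suite$retune)
  sr_run <- NULL
  if (isTRUE(cfg$sr$enabled)) {
    st <- sr_settings(population = cfg$sr$population,
                      generations = cfg$sr$generations,
                      restarts = cfg$sr$restarts)
    sr_run <- sr_fit(M, score, settings = st, seed = seed)
  }
  sets <- family_feature_sets(
    models, sr_run, top_fraction = cfg$consensus$top_fraction,
    presence_min = cfg$consensus$presence_min,
    r2_min = cfg$consensus$r2_min,
    complexity_max = cfg$consensus$complexity_max)
  panel <- build_consensus(sets, min_models = cfg$consensus$min_models)
  refit <- if (length(panel$features) > 0)
    consensus_refit(panel, M, score, families = cfg$suite$families,
                    cv_folds = cfg$suite$cv_folds, seed = seed) else NULL
  list(models = models, sr_run = sr_run, sets = sets, panel = panel,
       consensus = refit, screen = univariate_screen(M, score))
}

#' Run the end-to-end consensus-modeling pipeline
#'
#' Executes, in order: study synthesis (or loading), platform-specific
#' preprocessing, composite potency scoring, univariate screening, the
#' regression suite plus symbolic regression per dataset, consensus panel
#' construction and consensus refitting, optional outlier-line ablation,
#' and optional pathway over-representation analysis. All intermediate
#' artifacts plus a run manifest (configuration, seeds, content hashes) are
#' written to `out_dir`; a rerun with the same configuration reproduces the
#' artifacts bit-for-bit.
#'
#' @param config configuration list or YAML path (see
#'   [default_pipeline_config()]).
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  cfg <- load_pipeline_config(config)
  seed <- cfg$seed %||% 1

  # ---- stage: data ----
  if (!is.null(cfg$synth)) {
    sp <- cfg$synth
    spec <- synthetic_spec(
      n_lines = sp$n_lines, n_replicates_nmr = sp$n_replicates_nmr,
      n_features = unlist(sp$n_features), n_informative = sp$n_informative,
      effect_size = sp$effect_size, seed = seed)
    study <- generate_study(spec)
    for (pf in c("ms_lipid", "ms_polar")) {
      noninf <- setdiff(study[[pf]]$feature_meta$feature_id,
                        study$truth$informative[[pf]])
      study[[pf]] <- generate_blanks_and_qcs(
        study[[pf]], n_blanks = sp$n_blanks, n_qcs = sp$n_qcs,
        blank_dominated = head(noninf, sp$n_blank_dominated),
        qc_absent = head(rev(noninf), sp$n_qc_absent),
        seed = seed + 1)
    }
  } else {
    inp <- cfg$inputs
    study <- list(
      ms_lipid = read_feature_table(inp$ms_lipid$values, inp$ms_lipid$sample_meta,
                                    inp$ms_lipid$feature_meta),
      ms_polar = read_feature_table(inp$ms_polar$values, inp$ms_polar$sample_meta,
                                    inp$ms_polar$feature_meta),
      nmr = read_feature_table(inp$nmr$values, inp$nmr$sample_meta,
                               inp$nmr$feature_meta),
      assays = read_assay_panel(inp$assays), truth = NULL)
  }

  # ---- stage: potency score ----
  score <- composite_score(study$assays)

  # ---- stage: preprocessing ----
  ms <- list(ms_lipid = preprocess_ms(study$ms_lipid, cfg$preprocess),
             ms_polar = preprocess_ms(study$ms_polar, cfg$preprocess))
  nmr <- preprocess_nmr(study$nmr, cfg$preprocess, score)

  # ---- stage: modeling & consensus per dataset ----
  datasets <- c(lapply(ms, `[[`, "matrix"), lapply(nmr, `[[`, "matrix"))
  analyses <- lapply(datasets, analyze_dataset, score = score, cfg = cfg,
                     seed = seed)

  # ---- stage: MS union consensus model ----
  ms_union_feats <- union(analyses$ms_lipid$panel$features,
                          analyses$ms_polar$panel$features)
  ms_union <- NULL
  if (length(ms_union_feats) > 0) {
    Mu <- cbind(ms$ms_lipid$matrix, ms$ms_polar$matrix)
    ms_union <- list(
      features = ms_union_feats,
      consensus = consensus_refit(ms_union_feats, Mu, score,
                                  families = cfg$suite$families,
                                  cv_folds = cfg$suite$cv_folds, seed = seed))
    if (!is.null(cfg$ablation$exclude_line)) {
      ms_union$ablation <- ablation_refit(
        ms_union_feats, Mu, score, exclude_line = cfg$ablation$exclude_line,
        families = cfg$suite$families, cv_folds = cfg$ablation$cv_folds,
        seed = seed)
    }
  }

  # features consensual in both NMR timepoint datasets
  nmr_names <- grep("^nmr_day", names(analyses), value = TRUE)
  nmr_common <- if (length(nmr_names) == 2)
    intersect(analyses[[nmr_names[1]]]$panel$features,
              analyses[[nmr_names[2]]]$panel$features) else character(0)

  # ---- stage: enrichment ----
  enrich <- NULL
  if (!is.null(cfg$enrichment$gmt)) {
    db <- read_gmt(cfg$enrichment$gmt)
    fm <- rbind(study$ms_lipid$feature_meta, study$ms_polar$feature_meta)
    ann <- fm$annotation[match(ms_union_feats, fm$feature_id)]
    ann <- ann[!is.na(ann) & ann != ""]
    mapped <- map_query(ann, db)
    enrich <- list(mapped = mapped,
                   result = if (length(mapped$mapped) > 0)
                     ora(mapped$mapped, db) else NULL)
  }

  result <- list(config = cfg, study = study, score = score,
                 preprocessed = c(ms, nmr), analyses = analyses,
                 ms_union = ms_union, nmr_common = nmr_common,
                 enrichment = enrich)

  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_artifacts(result, out_dir)
  }
  invisible(result)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  write_assay_panel(result$study$assays, p("assays.csv"))
  write.csv(data.frame(line_id = result$score$line_id,
                       score = result$score$score),
            p("composite_score.csv"), row.names = FALSE, quote = FALSE)
  for (nm in names(result$analyses)) {
    an <- result$analyses[[nm]]
    write_result_json(lapply(an$models, fitted_model_record),
                      p(nm, "_models.json"))
    write_result_json(consensus_panel_record(an$panel), p(nm, "_panel.json"))
    if (!is.null(an$consensus))
      write_result_json(lapply(an$consensus, fitted_model_record),
                        p(nm, "_consensus.json"))
    write.csv(an$screen, p(nm, "_screen.csv"), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$ms_union))
    write_result_json(c(list(features = result$ms_union$features),
                        lapply(result$ms_union$consensus, fitted_model_record)),
                      p("ms_union_consensus.json"))
  if (!is.null(result$enrichment$result))
    write_enrichment_tsv(result$enrichment$result, p("enrichment.tsv"))

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mscpotency")),
    seed = result$config$seed,
    config = result$config,
    artifacts = lapply(setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f))))
  write_result_json(manifest, file.path(out_dir, "manifest.json"))
  manifest
}
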