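test_that("study generation is deterministic given the seed", {
  spec <- synthetic_spec(n_features = c(ms_lipid = 30, ms_polar = 20, nmr = 25),
                         n_replicates_nmr = 3, seed = 11)
  a <- generate_study(spec)
  b <- generate_study(spec)
  expect_identical(a$ms_lipid$values, b$ms_lipid$values)
  expect_identical(a$nmr$values, b$nmr$values)
  expect_identical(as.data.frame(a$assays), as.data.frame(b$assays))
  expect_identical(a$truth$informative, b$truth$informative)

  c <- generate_study(synthetic_spec(n_features = c(30, 20, 25),
                                     n_replicates_nmr = 3, seed = 12))
  expect_false(identical(a$ms_lipid$values, c$ms_lipid$values))
})

test_that("degenerate specs are rejected", {
  expect_error(synthetic_spec(n_lines = 2), "n_lines")
  expect_error(synthetic_spec(n_informative = 500), "n_informative")
  expect_error(synthetic_spec(batch_scale_factor = 0), "batch_scale_factor")
})

test_that("zero effect size yields null association with latent potency", {
  rs <- unlist(lapply(1:8, function(s) {
    study <- generate_study(synthetic_spec(
      n_features = c(40, 5, 5), n_informative = 0, effect_size = 0,
      n_replicates_nmr = 2, batch_location_shift = 0, batch_scale_factor = 1,
      seed = s))
    M <- aggregate_by_line(study$ms_lipid)
    cor(study$truth$latent_potency, M)
  }))
  # signed correlations center on zero under the null
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("strong planted signal is recovered as the top univariate features", {
  study <- generate_study(synthetic_spec(
    n_features = c(100, 5, 5), n_informative = 5, effect_size = 6,
    replicate_noise_sd = 0.1, n_replicates_nmr = 2,
    batch_location_shift = 0, batch_scale_factor = 1, seed = 5))
  sc <- composite_score(study$assays)
  scr <- univariate_screen(aggregate_by_line(study$ms_lipid), sc)
  expect_setequal(scr$feature_id[1:5], study$truth$informative$ms_lipid)
})

test_that("recoverability grows with effect size", {
  mean_planted_r <- function(es, s) {
    study <- generate_study(synthetic_spec(
      n_features = c(60, 5, 5), n_informative = 5, effect_size = es,
      n_replicates_nmr = 2, seed = s))
    M <- aggregate_by_line(study$ms_lipid)
    mean(abs(cor(study$truth$latent_potency,
                 M[, study$truth$informative$ms_lipid])))
  }
  for (s in 1:3)
    expect_gt(mean_planted_r(3, s), mean_planted_r(0.5, s))
})

test_that("assay panel variables are strongly inter-correlated", {
  cors <- vapply(1:5, function(s) {
    study <- generate_study(synthetic_spec(n_features = c(5, 5, 5),
                                           n_replicates_nmr = 2, seed = s))
    C <- abs(cor(as.matrix(as.data.frame(study$assays)[, -1])))
    mean(C[upper.tri(C)])
  }, numeric(1))
  expect_true(all(cors >= 0.6))
})

test_that("NMR tables carry day structure and informative day-differences", {
  spec <- synthetic_spec(n_features = c(5, 5, 40), n_informative = 4,
                         effect_size = 5, replicate_noise_sd = 0.1,
                         n_replicates_nmr = 4,
                         batch_location_shift = 0, batch_scale_factor = 1,
                         seed = 2)
  study <- generate_study(spec)
  sm <- study$nmr$sample_meta
  expect_setequal(unique(sm$day), 1:3)
  expect_equal(nrow(sm), 10 * 4 * 3)
  d3 <- day_difference(study$nmr, 1, 3)
  M <- aggregate_by_line(d3)
  r <- abs(cor(study$truth$latent_potency, M))
  planted <- study$truth$informative$nmr
  expect_gt(mean(r[, planted]), max(r[, setdiff(colnames(M), planted)]) - 0.2)
})

test_that("planted blank-dominated and QC-absent features fail exactly the rules", {
  study <- generate_study(synthetic_spec(n_features = c(40, 5, 5),
                                         n_replicates_nmr = 2, seed = 3))
  fid <- study$ms_lipid$feature_meta$feature_id
  bd <- fid[3:6]; qa <- fid[10:12]
  aug <- generate_blanks_and_qcs(study$ms_lipid, blank_dominated = bd,
                                 qc_absent = qa, seed = 9)
  expv <- ft_values(aug, "experimental"); blv <- ft_values(aug, "blank")
  fails_blank <- fid[colMeans(expv) < 5 * colMeans(blv)]
  expect_setequal(fails_blank, bd)

  res <- blank_qc_filter(aug)
  expect_setequal(res$report$removed, c(bd, qa))

  # no planted failures -> nothing removed
  aug0 <- generate_blanks_and_qcs(study$ms_lipid, seed = 9)
  expect_length(blank_qc_filter(aug0)$report$removed, 0)

  # 60% QC dropout fails the 50% presence rule
  qcv <- ft_values(aug, "qc_pool")
  expect_true(all(colMeans(qcv[, qa] != 0) < 0.5))
})
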