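test_that("blank/QC filter applies the 5x and 50% rules", {
  # f1: exp mean 10 vs blank 1 (kept); f2: exp mean 4 vs blank 1 (removed);
  # f3: kept by blanks but absent in 2/3 QCs (removed)
  exp_vals <- matrix(c(10, 10, 4, 4, 50, 50), 2, 3)
  blank_vals <- matrix(c(1, 1, 1, 1, 1, 1), 2, 3)
  qc_vals <- matrix(c(10, 10, 10, 4, 4, 4, 50, 0, 0), 3, 3)
  ft <- filter_fixture(exp_vals, blank_vals, qc_vals)
  res <- blank_qc_filter(ft)
  expect_equal(res$report$kept, "f1")
  expect_setequal(res$report$removed, c("f2", "f3"))
  expect_equal(res$table$stage, "filtered")
  # partition invariant
  expect_setequal(c(res$report$removed, res$report$kept),
                  ft$feature_meta$feature_id)
  # blanks and QCs retained for audit
  expect_setequal(unique(res$table$sample_meta$role),
                  c("experimental", "blank", "qc_pool"))

  no_blank <- tiny_table(3, 2)
  expect_error(blank_qc_filter(no_blank), "no blank")
})

test_that("RSD filter direction and undefined-RSD handling", {
  # f1 constant (RSD 0), f2 = {1,3} (RSD ~0.707), f3 mean zero at scaled stage
  vals <- matrix(c(5, 5, 1, 3, -1, 1), 2, 3)
  ft <- tiny_table(2, 3, values = abs(vals))
  ft$values <- vals; ft$stage <- "scaled"   # allow negatives
  msg <- capture_messages(res <- rsd_filter(ft))
  expect_match(paste(msg, collapse = ""), "zero mean")
  expect_equal(res$report$kept, "f2")          # 0.707 >= 0.25 kept
  expect_setequal(res$report$removed, c("f1", "f3"))

  res2 <- suppressMessages(rsd_filter(ft, mode = "remove_above"))
  expect_false("f2" %in% res2$report$kept)     # conventional reading
  expect_true("f1" %in% res2$report$kept)      # RSD 0 <= 0.25 kept

  # hand oracle: sd/|mean| of {1,3} is sqrt(2)/2
  expect_equal(sd(c(1, 3)) / mean(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("median normalization equalizes sample medians", {
  set.seed(4)
  A <- exp(rnorm(10, mean = 2))
  ft <- tiny_table(2, 10, values = rbind(A, 2 * A))
  out <- median_normalize(ft)
  expect_equal(out$values[1, ], out$values[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  ftr <- tiny_table(5, 10, seed = 8)
  out2 <- median_normalize(ftr)
  med <- apply(out2$values, 1, median)
  expect_equal(max(med) - min(med), 0, tolerance = 1e-9)

  one <- tiny_table(1, 6, seed = 2)
  expect_equal(median_normalize(one)$values, one$values, tolerance = 1e-12)

  z <- tiny_table(3, 3)
  z$values[2, ] <- 0
  expect_error(median_normalize(z), "median 0")
})

test_that("autoscaling centers, scales, warns on constants and is idempotent", {
  ft <- tiny_table(6, 5, seed = 3)
  out <- autoscale(ft)
  expect_equal(unname(colMeans(out$values)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(out$values, 2, sd)), rep(1, 5), tolerance = 1e-12)

  twice <- autoscale(out)
  expect_equal(twice$values, out$values, tolerance = 1e-12)

  cf <- tiny_table(4, 2)
  cf$values[, 1] <- 7
  expect_warning(outc <- autoscale(cf), "constant")
  expect_equal(unname(outc$values[, 1]), rep(0, 4))
})

test_that("ComBat correction is a fixed point on one batch and preserves shape", {
  ft <- tiny_table(6, 4, seed = 5)
  out <- combat_correct(ft)
  expect_equal(out$values, ft$values, tolerance = 1e-9)

  ft2 <- tiny_table(8, 5, seed = 6)
  ft2$sample_meta$batch_id <- rep(c("B1", "B2"), each = 4)
  out2 <- combat_correct(ft2)
  expect_identical(dimnames(out2$values), dimnames(ft2$values))
  expect_false(isTRUE(all.equal(out2$values, ft2$values)))

  ft3 <- tiny_table(5, 4)
  ft3$sample_meta$batch_id <- c("B1", "B1", "B1", "B1", "B2")
  expect_error(combat_correct(ft3), "fewer than 2 samples")
})

test_that("ComBat removes a pure location shift between batches", {
  set.seed(10)
  n <- 30; p <- 50
  vals <- matrix(rnorm(n * p, mean = 8, sd = 0.3), n, p)
  vals[16:30, ] <- vals[16:30, ] + 4
  ft <- tiny_table(n, p, values = vals)
  ft$sample_meta$batch_id <- rep(c("B1", "B2"), each = 15)
  out <- combat_correct(ft)
  pre <- colMeans(vals[16:30, ]) - colMeans(vals[1:15, ])
  post <- colMeans(out$values[16:30, ]) - colMeans(out$values[1:15, ])
  expect_lt(max(abs(post) / abs(pre)), 0.10)
})

test_that("day differencing computes flask-level net change", {
  spec <- synthetic_spec(n_features = c(5, 5, 10), n_replicates_nmr = 3,
                         seed = 4)
  study <- generate_study(spec)
  d3 <- day_difference(study$nmr, 1, 3)
  expect_equal(d3$stage, "differenced")
  expect_equal(nrow(d3$values), 10 * 3)

  # arithmetic on one flask/feature
  sm <- study$nmr$sample_meta
  i1 <- which(sm$line_id == "L01" & sm$replicate_id == "r01" & sm$day == 1)
  i3 <- which(sm$line_id == "L01" & sm$replicate_id == "r01" & sm$day == 3)
  expect_equal(unname(d3$values["L01_r01", 1]),
               unname(study$nmr$values[i3, 1] - study$nmr$values[i1, 1]))

  # constant trajectories difference to zero
  const <- study$nmr
  const$values <- matrix(5, nrow(const$values), ncol(const$values),
                         dimnames = dimnames(const$values))
  expect_true(all(day_difference(const, 1, 2)$values == 0))

  # unmatched flask errors with its name
  broken <- ft_subset(study$nmr,
                      samples = setdiff(sm$sample_id, "L01_r01_d1"))
  expect_error(day_difference(broken, 1, 3), "L01_r01")

  # differencing then line-averaging equals averaging then differencing
  M_diff <- aggregate_by_line(d3)
  day_mean <- function(d) {
    idx <- sm$day == d
    tab <- feature_table(study$nmr$values[idx, , drop = FALSE],
                         sm[idx, ], study$nmr$feature_meta)
    aggregate_by_line(tab)
  }
  expect_equal(M_diff, day_mean(3) - day_mean(1), tolerance = 1e-9)
})

test_that("PLS-guided variance filter finds the informative subset", {
  set.seed(21)
  n <- 10; p <- 30
  X <- matrix(rnorm(n * p, sd = 0.3), n, p,
              dimnames = list(paste0("L", 1:n), paste0("f", 1:p)))
  y <- setNames(rnorm(n, sd = 2), rownames(X))
  X[, 7] <- y + rnorm(n, sd = 0.05)   # high-variance, perfectly predictive
  sel <- variance_filter_select(X, y, percent_grid = c(0.1, 0.5, 1.0))
  expect_true("f7" %in% sel$features)
  expect_gt(sel$loo_r2, 0.8)

  full <- variance_filter_select(X, y, percent_grid = 1.0)
  expect_setequal(full$features, colnames(X))

  expect_error(variance_filter_select(X, y, percent_grid = numeric(0)),
               "empty")
})

test_that("variance filter on pure noise does not manufacture strong fits", {
  r2s <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(10 * 25), 10, 25,
                dimnames = list(paste0("L", 1:10), paste0("f", 1:25)))
    y <- setNames(rnorm(10), rownames(X))
    variance_filter_select(X, y, percent_grid = c(0.2, 0.6, 1.0))$loo_r2
  }, numeric(1))
  expect_lte(median(r2s), 0.3)
})
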