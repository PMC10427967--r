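test_that("feature tables construct, validate and round-trip through disk", {
  ft <- tiny_table(3, 2)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(3, 2))

  paths <- replicate(3, tempfile(fileext = ".csv"))
  write_feature_table(ft, paths[1], paths[2], paths[3])
  back <- read_feature_table(paths[1], paths[2], paths[3])
  expect_equal(back$values, ft$values, tolerance = 1e-9)
  expect_equal(back$sample_meta$line_id, ft$sample_meta$line_id)
  expect_equal(back$feature_meta$feature_id, ft$feature_meta$feature_id)
})

test_that("validation rejects constructed invariant violations", {
  ft <- tiny_table(4, 3)

  dup_sample <- ft
  dup_sample$sample_meta$sample_id[2] <- dup_sample$sample_meta$sample_id[1]
  expect_error(validate_feature_table(dup_sample), "duplicate sample id")

  dup_feat <- ft
  dup_feat$feature_meta$feature_id[2] <- dup_feat$feature_meta$feature_id[1]
  expect_error(validate_feature_table(dup_feat), "duplicate feature id")

  neg <- ft; neg$values[1, 1] <- -1
  expect_error(validate_feature_table(neg), "negative raw abundance")

  nav <- ft; nav$values[2, 2] <- NA
  expect_error(validate_feature_table(nav), "missing abundance")

  bad_role <- ft; bad_role$sample_meta$role[1] <- "mystery"
  expect_error(validate_feature_table(bad_role), "invalid role")

  no_batch <- ft; no_batch$sample_meta$batch_id[3] <- NA
  expect_error(validate_feature_table(no_batch), "without batch_id")

  shrunk <- ft; shrunk$sample_meta <- ft$sample_meta[-1, ]
  expect_error(validate_feature_table(shrunk), "rows")

  # scaled stage admits negative values
  sc <- ft; sc$values[1, 1] <- -5; sc$stage <- "scaled"
  expect_silent(validate_feature_table(sc))

  # randomized corruption sweep: any single corruption must be rejected
  set.seed(7)
  for (i in 1:20) {
    bad <- tiny_table(5, 4, seed = i)
    kind <- sample(3, 1)
    if (kind == 1) bad$values[sample(5, 1), sample(4, 1)] <- -runif(1)
    if (kind == 2) bad$sample_meta$sample_id[sample(5, 2)] <- "same"
    if (kind == 3) bad$values[sample(5, 1), sample(4, 1)] <- NA
    expect_error(validate_feature_table(bad))
  }
})

test_that("duplicated sample id in a read table is rejected", {
  ft <- tiny_table(3, 2)
  paths <- replicate(3, tempfile(fileext = ".csv"))
  write_feature_table(ft, paths[1], paths[2], paths[3])
  tab <- read.csv(paths[1], check.names = FALSE)
  tab$sample_id[2] <- tab$sample_id[1]
  write.csv(tab, paths[1], row.names = FALSE, quote = FALSE)
  sm <- read.csv(paths[2]); sm$sample_id[2] <- sm$sample_id[1]
  write.csv(sm, paths[2], row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(paths[1], paths[2], paths[3]),
               "duplicate sample id")
})

test_that("GMT parsing follows the standard dialect", {
  path <- write_gmt_fixture(c(
    "setA\tdesc\tm1\tm2\tm3",
    "",
    "setB\tdesc\tm4\tm5"))
  db <- read_gmt(path)
  expect_named(db$sets, c("setA", "setB"))
  expect_length(db$sets$setA, 3)
  expect_true(length(db$background) <= 5)
  expect_setequal(db$background, c("m1", "m2", "m3", "m4", "m5"))

  expect_error(read_gmt(write_gmt_fixture("onlyname")), "no members")
  expect_error(read_gmt(write_gmt_fixture("name\tdesc")), "no members")

  expect_warning(
    db2 <- read_gmt(write_gmt_fixture("setC\tdesc\tm1\tm1\tm2")),
    "duplicated members")
  expect_equal(db2$sets$setC, c("m1", "m2"))
})

test_that("pathway_db enforces background containment and non-empty sets", {
  expect_error(pathway_db(list(a = c("x", "y")), background = "x"),
               "outside the background")
  expect_error(pathway_db(list(a = character(0))), "empty pathway set")
  db <- pathway_db(list(a = c("x", "y")), background = c("x", "y", "z"))
  expect_length(db$background, 3)
})

test_that("assay panels validate ranges and read/write as CSV", {
  p <- rank1_panel()
  expect_s3_class(p, "potency_assay_panel")
  path <- tempfile(fileext = ".csv")
  write_assay_panel(p, path)
  expect_equal(as.data.frame(read_assay_panel(path)), as.data.frame(p),
               tolerance = 1e-9)

  bad <- as.data.frame(p); bad$cd4_d1[1] <- 120
  expect_error(potency_assay_panel(bad), "out of \\[0,100\\]")
  bad <- as.data.frame(p); bad$ido[2] <- -1
  expect_error(potency_assay_panel(bad), "negative IDO")
  bad <- as.data.frame(p); bad$ido[2] <- NA
  expect_error(potency_assay_panel(bad), "missing")
})

test_that("JSON result round-trips preserve numeric values", {
  x <- list(loo_r2 = 0.123456789123456, features = c("a", "b"))
  path <- tempfile(fileext = ".json")
  write_result_json(x, path)
  back <- read_result_json(path)
  expect_identical(back$loo_r2, x$loo_r2)
  expect_identical(back$features, x$features)
})
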