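#' Construct a feature table
#'
#' A `feature_table` is the package's central container: a sample x feature
#' abundance matrix together with per-sample and per-feature metadata and a
#' processing-stage flag. It holds untargeted MS (lipid or small-polar) or NMR
#' media feature data at any stage of the preprocessing chain.
#'
#' @param values numeric matrix, one row per sample, one column per feature;
#'   rownames are sample ids and colnames feature ids (taken from
#'   `sample_meta`/`feature_meta` if absent).
#' @param sample_meta data.frame with columns `sample_id`, `line_id`,
#'   `batch_id`, `role` (one of `"experimental"`, `"blank"`, `"qc_pool"`),
#'   optional `day` (integer culture day, NMR only) and `replicate_id`.
#' @param feature_meta data.frame with columns `feature_id`, and optionally
#'   `annotation`, `chem_class`, `platform` (one of `"ms_lipid"`,
#'   `"ms_polar"`, `"nmr"`), `nmr_shift_ppm`.
#' @param stage processing stage, one of `"raw"`, `"filtered"`,
#'   `"normalized"`, `"scaled"`, `"differenced"`.
#'
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, sample_meta, feature_meta,
                          stage = c("raw", "filtered", "normalized",
                                    "scaled", "differenced")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)

  if (is.null(rownames(values))) rownames(values) <- sample_meta$sample_id
  if (is.null(colnames(values))) colnames(values) <- feature_meta$feature_id
  if (!("annotation" %in% names(feature_meta))) feature_meta$annotation <- ""
  if (!("chem_class" %in% names(feature_meta))) feature_meta$chem_class <- "unknown"
  if (!("platform" %in% names(feature_meta))) feature_meta$platform <- "ms_lipid"
  if (!("day" %in% names(sample_meta))) sample_meta$day <- NA_integer_
  if (!("replicate_id" %in% names(sample_meta)))
    sample_meta$replicate_id <- sample_meta$sample_id

  ft <- structure(
    list(values = values, sample_meta = sample_meta,
         feature_meta = feature_meta, stage = stage),
    class = "feature_table")
  validate_feature_table(ft)
  ft
}

#' Validate a feature table's invariants
#'
#' Checks dimension agreement, id uniqueness, required metadata fields,
#' allowed roles and, at stage `"raw"`, non-negativity of abundances. Errors
#' name the offending sample or feature id.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly, if valid.
#' @export
validate_feature_table <- function(ft) {
  abort_if(!inherits(ft, "feature_table"), "not a feature_table")
  v <- ft$values; sm <- ft$sample_meta; fm <- ft$feature_meta
  abort_if(!all(c("sample_id", "line_id", "batch_id", "role") %in% names(sm)),
           "sample metadata must contain sample_id, line_id, batch_id, role")
  abort_if(!("feature_id" %in% names(fm)),
           "feature metadata must contain feature_id")
  abort_if(nrow(v) != nrow(sm),
           "matrix has %d rows but %d sample metadata entries", nrow(v), nrow(sm))
  abort_if(ncol(v) != nrow(fm),
           "matrix has %d columns but %d feature metadata entries", ncol(v), nrow(fm))
  dup <- sm$sample_id[duplicated(sm$sample_id)]
  abort_if(length(dup) > 0, "duplicate sample id: %s", dup[1])
  dup <- fm$feature_id[duplicated(fm$feature_id)]
  abort_if(length(dup) > 0, "duplicate feature id: %s", dup[1])
  abort_if(!identical(rownames(v), as.character(sm$sample_id)),
           "matrix rownames do not match sample ids")
  abort_if(!identical(colnames(v), as.character(fm$feature_id)),
           "matrix colnames do not match feature ids")
  bad <- sm$sample_id[is.na(sm$batch_id) | sm$batch_id == ""]
  abort_if(length(bad) > 0, "sample without batch_id: %s", bad[1])
  bad <- sm$sample_id[!(sm$role %in% c("experimental", "blank", "qc_pool"))]
  abort_if(length(bad) > 0, "sample with invalid role: %s", bad[1])
  abort_if(anyNA(v), "missing abundance values are not allowed")
  if (ft$stage == "raw") {
    neg <- which(v < 0, arr.ind = TRUE)
    abort_if(nrow(neg) > 0, "negative raw abundance for feature %s",
             colnames(v)[neg[1, 2]])
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$sample_meta$role)),
                            table(x$sample_meta$role)), collapse = ", ")))
  cat(sprintf("  platform(s): %s\n",
              paste(unique(x$feature_meta$platform), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# ---- accessors -------------------------------------------------------------

#' Extract the abundance matrix of a feature table
#' @param ft a `feature_table`.
#' @param role optional role filter (e.g. `"experimental"`).
#' @return numeric matrix (samples x features).
#' @export
ft_values <- function(ft, role = NULL) {
  v <- ft$values
  if (!is.null(role)) v <- v[ft$sample_meta$role %in% role, , drop = FALSE]
  v
}

#' Subset a feature table by features and/or samples
#' @param ft a `feature_table`.
#' @param features character vector of feature ids to keep (default all).
#' @param samples character vector of sample ids to keep (default all).
#' @return a `feature_table`.
#' @export
ft_subset <- function(ft, features = NULL, samples = NULL) {
  keep_f <- if (is.null(features)) ft$feature_meta$feature_id else features
  keep_s <- if (is.null(samples)) ft$sample_meta$sample_id else samples
  missing_f <- setdiff(keep_f, ft$feature_meta$feature_id)
  abort_if(length(missing_f) > 0, "unknown feature id: %s", missing_f[1])
  missing_s <- setdiff(keep_s, ft$sample_meta$sample_id)
  abort_if(length(missing_s) > 0, "unknown sample id: %s", missing_s[1])
  out <- ft
  out$values <- ft$values[match(keep_s, rownames(ft$values)),
                          match(keep_f, colnames(ft$values)), drop = FALSE]
  out$sample_meta <- ft$sample_meta[match(keep_s, ft$sample_meta$sample_id), , drop = FALSE]
  out$feature_meta <- ft$feature_meta[match(keep_f, ft$feature_meta$feature_id), , drop = FALSE]
  rownames(out$sample_meta) <- NULL
  rownames(out$feature_meta) <- NULL
  out
}

#' Aggregate experimental samples to one row per cell line
#'
#' Averages replicate experimental samples of each line, producing the
#' line-level matrix used for univariate screening and model fitting.
#'
#' @param ft a `feature_table`.
#' @return numeric matrix with one row per `line_id` (sorted by first
#'   appearance), columns as in `ft`.
#' @export
aggregate_by_line <- function(ft) {
  sm <- ft$sample_meta
  keep <- sm$role == "experimental"
  abort_if(!any(keep), "no experimental samples to aggregate")
  v <- ft$values[keep, , drop = FALSE]
  lines <- unique(sm$line_id[keep])
  out <- matrix(0, length(lines), ncol(v),
                dimnames = list(lines, colnames(v)))
  for (l in lines)
    out[l, ] <- colMeans(v[sm$line_id[keep] == l, , drop = FALSE])
  out
}

# ---- file I/O --------------------------------------------------------------

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a feature table from delimited files
#'
#' The value file is CSV/TSV with a header row of feature ids and the first
#' column holding sample ids. Metadata files are keyed by `sample_id` and
#' `feature_id` respectively. All invariants are enforced on read; readers
#' fail loudly on missing values rather than impute.
#'
#' @param path path to the abundance table (CSV or TSV by extension).
#' @param sample_meta_path path to the sample metadata table.
#' @param feature_meta_path optional path to the feature metadata table; if
#'   omitted, minimal defaults are filled in.
#' @param stage processing stage to record (default `"raw"`).
#' @return a validated `feature_table`.
#' @export
read_feature_table <- function(path, sample_meta_path,
                               feature_meta_path = NULL, stage = "raw") {
  df <- read_delim_auto(path)
  sample_ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- sample_ids
  sm <- read_delim_auto(sample_meta_path)
  abort_if(!("sample_id" %in% names(sm)), "sample metadata lacks sample_id")
  sm <- sm[match(sample_ids, as.character(sm$sample_id)), , drop = FALSE]
  bad <- sample_ids[is.na(sm$sample_id)]
  abort_if(length(bad) > 0, "sample %s has no metadata entry", bad[1])
  sm$sample_id <- as.character(sm$sample_id)
  if (is.null(feature_meta_path)) {
    fm <- data.frame(feature_id = colnames(values), stringsAsFactors = FALSE)
  } else {
    fm <- read_delim_auto(feature_meta_path)
    abort_if(!("feature_id" %in% names(fm)), "feature metadata lacks feature_id")
    fm$feature_id <- as.character(fm$feature_id)
    fm <- fm[match(colnames(values), fm$feature_id), , drop = FALSE]
    bad <- colnames(values)[is.na(fm$feature_id)]
    abort_if(length(bad) > 0, "feature %s has no metadata entry", bad[1])
  }
  rownames(sm) <- NULL; rownames(fm) <- NULL
  feature_table(values, sm, fm, stage = stage)
}

#' Write a feature table to delimited files
#'
#' Inverse of [read_feature_table()]: writes the abundance matrix plus the
#' two metadata tables. Round-trips are value-identical up to float
#' formatting (values are written with full precision).
#'
#' @param ft a `feature_table`.
#' @param path abundance table destination (CSV).
#' @param sample_meta_path,feature_meta_path metadata destinations.
#' @return invisibly, the three paths.
#' @export
write_feature_table <- function(ft, path, sample_meta_path, feature_meta_path) {
  df <- data.frame(sample_id = rownames(ft$values), ft$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  write.csv(ft$sample_meta, sample_meta_path, row.names = FALSE, quote = FALSE)
  write.csv(ft$feature_meta, feature_meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, sample_meta_path, feature_meta_path))
}

# ---- potency assay panel ---------------------------------------------------

#' Construct a functional assay panel
#'
#' One row per MSC line with the five functional readouts used for the
#' composite potency score: CD4/CD8 %CFSE dilution (T-cell proliferation
#' under co-culture) for two PBMC donors, and IDO activity in pg
#' L-kynurenine per cell per day.
#'
#' @param df data.frame with columns `line_id`, `cd4_d1`, `cd8_d1`, `cd4_d2`,
#'   `cd8_d2` (each in \[0, 100\]) and `ido` (>= 0).
#' @return an object of class `potency_assay_panel` (a validated data.frame).
#' @export
potency_assay_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("line_id", assay_variables())
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0, "assay panel lacks column %s", miss[1])
  df <- df[, need]
  dup <- df$line_id[duplicated(df$line_id)]
  abort_if(length(dup) > 0, "duplicate line id: %s", dup[1])
  abort_if(anyNA(df), "assay panel contains missing values")
  for (v in c("cd4_d1", "cd8_d1", "cd4_d2", "cd8_d2")) {
    bad <- df$line_id[df[[v]] < 0 | df[[v]] > 100]
    abort_if(length(bad) > 0, "%s out of [0,100] for line %s", v, bad[1])
  }
  bad <- df$line_id[df$ido < 0]
  abort_if(length(bad) > 0, "negative IDO activity for line %s", bad[1])
  class(df) <- c("potency_assay_panel", "data.frame")
  df
}

assay_variables <- function() c("cd4_d1", "cd8_d1", "cd4_d2", "cd8_d2", "ido")

#' Read / write an assay panel as CSV
#' @param path CSV path.
#' @return [read_assay_panel()] returns a `potency_assay_panel`.
#' @export
read_assay_panel <- function(path) potency_assay_panel(read_delim_auto(path))

#' @param panel a `potency_assay_panel`.
#' @rdname read_assay_panel
#' @export
write_assay_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- pathway database ------------------------------------------------------

#' Construct a pathway database
#'
#' @param sets named list of character vectors of metabolite identifiers.
#' @param background character vector of identifiers forming the universe;
#'   defaults to the union of all set members.
#' @return object of class `pathway_db`.
#' @export
pathway_db <- function(sets, background = NULL) {
  abort_if(length(sets) == 0, "pathway database has no sets")
  abort_if(is.null(names(sets)) || any(names(sets) == ""),
           "every pathway set must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  empty <- names(sets)[lengths(sets) == 0]
  abort_if(length(empty) > 0, "empty pathway set: %s", empty[1])
  if (is.null(background)) {
    background <- unique(unlist(sets, use.names = FALSE))
  } else {
    background <- unique(as.character(background))
    stray <- setdiff(unlist(sets, use.names = FALSE), background)
    abort_if(length(stray) > 0,
             "set member %s is outside the background universe", stray[1])
  }
  structure(list(sets = sets, background = background), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d sets, background of %d identifiers\n",
              length(x$sets), length(x$background)))
  invisible(x)
}

#' Read pathway sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Blank lines are
#' skipped; a line without members is an error; duplicated members within a
#' set are removed with a warning.
#'
#' @param path GMT file path.
#' @param background optional explicit background universe.
#' @return a `pathway_db` with sets in file order.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  abort_if(length(lines) == 0, "GMT file is empty: %s", path)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    abort_if(length(parts) < 3,
             "GMT line for set '%s' has no members", parts[1])
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    abort_if(length(members) == 0,
             "GMT line for set '%s' has no members", parts[1])
    if (anyDuplicated(members)) {
      warning(sprintf("duplicated members in set '%s' were removed", parts[1]))
      members <- unique(members)
    }
    sets[[parts[1]]] <- members
  }
  pathway_db(sets, background = background)
}

# ---- JSON result serialization --------------------------------------------

#' Write / read an analysis result as JSON
#'
#' Generic serialization for fitted models, consensus panels and enrichment
#' tables. Numbers are written at full precision so that re-reading is
#' value-faithful.
#'
#' @param x a serializable result (list-like).
#' @param path destination / source path.
#' @return `read_result_json` returns the deserialized list.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
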