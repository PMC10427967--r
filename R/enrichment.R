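#' Map a query metabolite list onto a pathway database
#'
#' @param query character vector of metabolite identifiers (e.g. a consensus
#'   panel's annotations).
#' @param db a [pathway_db()].
#' @return list with `mapped` (query intersected with the background) and
#'   `unmapped` (reported verbatim).
#' @export
map_query <- function(query, db) {
  stopifnot(inherits(db, "pathway_db"))
  query <- unique(as.character(query))
  list(mapped = intersect(query, db$background),
       unmapped = setdiff(query, db$background))
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway set, tests whether the mapped query overlaps it more
#' than expected by chance when drawing `n` identifiers from the background
#' of size `N`: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`.
#' Benjamini-Hochberg q-values are computed across pathways and results are
#' sorted by p ascending.
#'
#' @param query character vector of metabolite identifiers; must lie within
#'   the background (map with [map_query()] first).
#' @param db a [pathway_db()].
#' @return data.frame with columns `pathway`, `K` (set size in background),
#'   `n` (query size), `k` (overlap), `N` (background size), `p`, `q`.
#' @export
ora <- function(query, db) {
  stopifnot(inherits(db, "pathway_db"))
  query <- unique(as.character(query))
  abort_if(length(query) == 0, "query is empty")
  stray <- setdiff(query, db$background)
  abort_if(length(stray) > 0,
           "query id %s is outside the background; use map_query() first",
           stray[1])
  N <- length(db$background)
  n <- length(query)
  rows <- lapply(names(db$sets), function(nm) {
    members <- intersect(db$sets[[nm]], db$background)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, K = K, n = n, k = k, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#' @param result data.frame from [ora()].
#' @param path destination path.
#' @export
write_enrichment_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
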