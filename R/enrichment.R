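#' Read gene sets in GMT format
#'
#' Each GMT line is tab-separated: set name, description, then member gene
#' ids. Duplicate members within a set are collapsed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (the sets); descriptions in
#'   attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Hypergeometric over-representation analysis with a custom background
#'
#' For each gene set, tests whether the query list is enriched relative to
#' an explicit background universe: with `N` background genes, `K` of them
#' in the set, `n` query genes, and `k` query genes in the set, the p-value
#' is the hypergeometric upper tail `P[X >= k]`. Query (and set) genes
#' outside the universe are dropped before testing; sets with no background
#' member are skipped. BH adjustment across the tested sets.
#'
#' @param query Character vector of query gene ids.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector: the background gene universe.
#' @return `data.frame` with `set`, `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   ordered by `p`; attribute `"n_query_dropped"` counts query ids outside
#'   the universe.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty background universe")
  query0 <- unique(query)
  query <- intersect(query0, universe)
  n_dropped <- length(query0) - length(query)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    out <- data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      adj_p = numeric(0))
    attr(out, "n_query_dropped") <- n_dropped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_bh(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- n_dropped
  out
}
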