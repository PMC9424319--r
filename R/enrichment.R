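#' Hypergeometric over-representation of a query list in one gene set
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap k between a query list (size n) and a gene set (size K) drawn
#' from a universe of N genes:
#' p = sum_{i = k}^{min(K, n)} C(K, i) C(N - K, n - i) / C(N, n).
#' Query and set members outside the universe are dropped (their counts are
#' reported), mirroring portal behavior.
#'
#' @param query Character vector of query gene ids.
#' @param gene_set Character vector of set member gene ids.
#' @param universe Character vector of all testable gene ids.
#' @param set_name Optional label carried into the result.
#' @return Object of class `EnrichmentResult`: `set_name`, `N`, `K`, `n`,
#'   `k`, `p`, `overlap_genes`, `n_dropped_query`, `n_dropped_set`.
#' @export
hypergeom_overlap <- function(query, gene_set, universe, set_name = NA_character_) {
  universe <- unique(trimws(universe))
  universe <- universe[nzchar(universe)]
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(trimws(query))
  gene_set <- unique(trimws(gene_set))
  q <- intersect(query, universe)
  if (length(q) == 0)
    stop("query has no genes in the universe", call. = FALSE)
  s <- intersect(gene_set, universe)
  N <- length(universe)
  K <- length(s)
  n <- length(q)
  overlap <- intersect(q, s)
  k <- length(overlap)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(set_name = set_name, N = N, K = K, n = n, k = k, p = p,
                 overlap_genes = overlap,
                 n_dropped_query = length(query) - n,
                 n_dropped_set = length(gene_set) - K),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap%s: k = %d of n = %d query genes in a %d-gene set (universe %d); p = %.3g\n",
              if (is.na(x$set_name)) "" else paste0(" [", x$set_name, "]"),
              x$k, x$n, x$K, x$N, x$p))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' q_(i) = min over j >= i of (m p_(j) / j), capped at 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation of a query list across a gene-set collection
#'
#' Runs [hypergeom_overlap()] for every set in the collection, applies the
#' Benjamini-Hochberg correction across the collection, sorts by ascending
#' p (set name breaks ties) and optionally filters at a q-value threshold.
#'
#' @param query Character vector of query gene ids.
#' @param coll A [gene_set_collection()].
#' @param universe Character vector of all testable gene ids.
#' @param q_max Q-value filter threshold (default 0.05).
#' @param filter If `TRUE` (default) keep only rows with `q <= q_max`.
#' @return Data frame of class `EnrichmentTable` with columns `set_name`,
#'   `N`, `K`, `n`, `k`, `p`, `q`, `overlap_genes` (semicolon-joined).
#' @export
enrich_collection <- function(query, coll, universe, q_max = 0.05,
                              filter = TRUE) {
  stopifnot(inherits(coll, "GeneSetCollection"))
  rows <- lapply(coll$sets, function(set) {
    r <- hypergeom_overlap(query, set$genes, universe, set_name = set$name)
    data.frame(set_name = r$set_name, N = r$N, K = r$K, n = r$n, k = r$k,
               p = r$p, overlap_genes = paste(r$overlap_genes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  if (isTRUE(filter)) out <- out[out$q <= q_max, , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("set_name", "N", "K", "n", "k", "p", "q", "overlap_genes")]
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' Columns: set_name, N, K, n, k, p, q, overlap_genes (semicolon-joined).
#'
#' @param x An `EnrichmentTable` from [enrich_collection()].
#' @param path Output path.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
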