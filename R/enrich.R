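#' Compound gene-set over-representation analysis
#'
#' One-sided hypergeometric test of each gene set against the query, with BH
#' correction across all tested sets.  The significant table keeps sets with
#' `q < alpha` that overlap at least `min_overlap` genes of the
#' `prioritized` set (by default the query itself, so the filter counts
#' prioritized genes rather than network-expanded ones when a seed list is
#' supplied).
#'
#' @param query gene symbols to test (e.g. expanded prioritized genes).
#' @param gmt named list of gene sets (as from [read_gmt()]).
#' @param universe background gene symbols (must contain the query).
#' @param min_overlap minimum overlap with `prioritized` for the filtered
#'   table (default 2).
#' @param prioritized genes the `min_overlap` filter counts (default:
#'   `query`).
#' @param alpha FDR level for the filtered table.
#' @return list `table` (all sets: `compound, k, K, n, N, p, q,
#'   overlap_genes, overlap_prioritized`) and `significant` (filtered rows).
#' @export
drug_enrichment <- function(query, gmt, universe, min_overlap = 2,
                            prioritized = query, alpha = 0.05) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  prioritized <- unique(toupper(prioritized))
  if (length(query) == 0L) {
    warnf("drug_enrichment: empty query")
    empty <- data.frame(compound = character(), k = integer(), K = integer(),
                        n = integer(), N = integer(), p = numeric(),
                        q = numeric(), overlap_genes = character(),
                        overlap_prioritized = integer())
    return(list(table = empty, significant = empty))
  }
  bad <- setdiff(query, universe)
  if (length(bad))
    stopf("drug_enrichment: query gene(s) outside universe: %s",
          paste(head(bad, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gmt), function(nm) {
    set <- intersect(unique(toupper(gmt[[nm]])), universe)
    K <- length(set)
    ov <- intersect(set, query)
    k <- length(ov)
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(compound = nm, k = k, K = K, n = n, N = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               overlap_prioritized = length(intersect(ov, prioritized)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_fdr(tab$p)
  tab <- tab[order(tab$p), c("compound", "k", "K", "n", "N", "p", "q",
                             "overlap_genes", "overlap_prioritized")]
  sig <- tab[tab$q < alpha & tab$overlap_prioritized >= min_overlap, , drop = FALSE]
  list(table = tab, significant = sig)
}
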