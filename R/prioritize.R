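#' Assemble the six-layer evidence profile of a pair
#'
#' The six prioritization layers are cross-ancestry consistency,
#' colocalization (tier at least suggestive), SMR support, open-chromatin
#' overlap, non-stratified differential expression and stratified
#' differential expression.  A missing layer counts as unsupported.  Tiers:
#' at least half means >= 3 of 6, more than half means >= 4 of 6.
#'
#' @param cross_ancestry,coloc,smr,atac,deg_nonstratified,deg_stratified
#'   logical flags (NA treated as FALSE, recorded as missing).
#' @return list `flags` (named logicals), `missing` (names of layers that
#'   were NA), `support_count`, `tier` (`"none"`, `"at_least_half"`,
#'   `"more_than_half"`).
#' @export
evidence_profile <- function(cross_ancestry = NA, coloc = NA, smr = NA,
                             atac = NA, deg_nonstratified = NA,
                             deg_stratified = NA) {
  flags <- c(cross_ancestry = cross_ancestry, coloc = coloc, smr = smr,
             atac = atac, deg_nonstratified = deg_nonstratified,
             deg_stratified = deg_stratified)
  missing <- names(flags)[is.na(flags)]
  flags[is.na(flags)] <- FALSE
  cnt <- sum(flags)
  tier <- if (cnt >= 4) "more_than_half" else if (cnt >= 3) "at_least_half" else "none"
  list(flags = flags, missing = missing, support_count = cnt, tier = tier)
}

#' Intersect genes with the druggable genome
#'
#' Case-insensitive exact symbol match against a druggable-gene list (e.g. a
#' tier-1 druggable-genome catalog).
#'
#' @param genes query gene symbols.
#' @param druggable druggable gene symbols (non-empty).
#' @return the matching subset of `genes` (original spelling preserved).
#' @export
druggable_intersect <- function(genes, druggable) {
  if (length(druggable) == 0L) stopf("druggable_intersect: empty druggable list")
  genes[toupper(genes) %in% toupper(druggable)]
}

#' Expand seed genes through an interaction network
#'
#' Adds first-degree neighbors of the seed genes that appear in the druggable
#' list; seeds are always retained, druggable or not.  Seeds absent from the
#' network contribute no neighbors (logged).
#'
#' @param seeds seed gene symbols.
#' @param edges data.frame with columns `gene_a, gene_b` (undirected).
#' @param druggable druggable gene symbols.
#' @return character vector: seeds plus druggable first-degree neighbors.
#' @export
network_expand <- function(seeds, edges, druggable) {
  up <- toupper
  in_net <- up(seeds) %in% up(c(edges$gene_a, edges$gene_b))
  if (any(!in_net))
    message("network_expand: seed(s) absent from network: ",
            paste(seeds[!in_net], collapse = ", "))
  nb <- character(0)
  if (nrow(edges)) {
    a_hit <- up(edges$gene_a) %in% up(seeds)
    b_hit <- up(edges$gene_b) %in% up(seeds)
    nb <- unique(c(edges$gene_b[a_hit], edges$gene_a[b_hit]))
    nb <- setdiff(nb[up(nb) %in% up(druggable)], seeds)
  }
  unique(c(seeds, nb))
}
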