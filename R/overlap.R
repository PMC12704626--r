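#' LD proxies of an index variant
#'
#' Returns the index variant together with all panel variants whose squared
#' Pearson correlation with it reaches `r2_min` (computed from dosages, or
#' read off a supplied LD correlation matrix).
#'
#' @param index variant key of the index variant.
#' @param panel either a dosage matrix (columns named by variant key) or a
#'   correlation matrix with matching dimnames.
#' @param r2_min minimum r-squared (default 0.8).
#' @return character vector of variant keys (index first).
#' @export
ld_proxies <- function(index, panel, r2_min = 0.8) {
  is_ld <- is.matrix(panel) && nrow(panel) == ncol(panel) &&
    !is.null(rownames(panel)) && identical(rownames(panel), colnames(panel)) &&
    all(abs(diag(panel) - 1) < 1e-8)
  if (is_ld) {
    if (!index %in% rownames(panel)) stopf("ld_proxies: index %s not in panel", index)
    r2 <- panel[index, ]^2
  } else {
    if (!index %in% colnames(panel)) stopf("ld_proxies: index %s not in panel", index)
    g0 <- panel[, index]
    if (sd(g0, na.rm = TRUE) == 0) stopf("ld_proxies: index %s is monomorphic", index)
    r2 <- suppressWarnings(as.vector(cor(g0, panel, use = "pairwise"))^2)
    names(r2) <- colnames(panel)
  }
  r2[is.na(r2)] <- 0
  union(index, names(r2)[r2 >= r2_min])
}

#' Overlap of variants with cell-type open-chromatin peaks
#'
#' Peaks use BED convention (0-based, half-open `[start, end)`); variant
#' positions are 1-based, so position p hits a peak when `start < p <= end`.
#' Only peaks whose label equals `cell_type` are considered; an unknown label
#' yields `FALSE` with a warning.
#'
#' @param variants data.frame with `chrom, pos` (1-based), and optionally
#'   `variant`.
#' @param peaks data.frame with `chrom, start, end, label` (BED columns).
#' @param cell_type label to match.
#' @return list `any` (logical) and `hits` (data.frame of variant/peak
#'   pairs).
#' @export
peak_overlap <- function(variants, peaks, cell_type) {
  hits <- data.frame(variant = character(), chrom = integer(),
                     pos = numeric(), start = numeric(), end = numeric())
  if (nrow(variants) == 0L) return(list(any = FALSE, hits = hits))
  pk <- peaks[peaks$label == cell_type, , drop = FALSE]
  if (nrow(pk) == 0L) {
    warnf("peak_overlap: no peaks labeled '%s'", cell_type)
    return(list(any = FALSE, hits = hits))
  }
  for (i in seq_len(nrow(variants))) {
    m <- pk$chrom == variants$chrom[i] &
      pk$start < variants$pos[i] & variants$pos[i] <= pk$end
    if (any(m)) {
      hits <- rbind(hits, data.frame(
        variant = if ("variant" %in% names(variants)) variants$variant[i]
                  else variant_key(variants$chrom[i], variants$pos[i]),
        chrom = variants$chrom[i], pos = variants$pos[i],
        start = pk$start[m], end = pk$end[m]))
    }
  }
  list(any = nrow(hits) > 0L, hits = hits)
}
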