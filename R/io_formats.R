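# Readers and writers for the pipeline's plain-text formats.  Readers
# validate schemas and report the file, line and column of violations;
# coordinate conventions are normalized on load (BED stays 0-based half-open
# in the `start`/`end` columns; all variant positions are 1-based).

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warnf("%s: unknown optional column(s): %s", path, paste(extra, collapse = ", "))
  for (cc in numeric_cols) {
    bad <- which(!is.na(df[[cc]]) & !is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad))
      stopf("%s: line %d, column %s: not numeric", path, bad[1] + 1L, cc)
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read GWAS summary statistics
#'
#' Tab-delimited dialect with 1-based positions: columns `CHR, POS, A1
#' (effect allele), A2, FREQ_A1, BETA, SE, Z, P, N_CASES, N_CONTROLS,
#' GENO_RATE, IS_PROXY (0/1)`.  On read, `P = 0` is clamped to the smallest
#' positive double with a warning.
#'
#' @param stats internal summary-statistic data.frame.
#' @param path file path.
#' @return `read_sumstats` returns the internal data.frame.
#' @export
write_sumstats <- function(stats, path) {
  out <- data.frame(CHR = stats$chrom, POS = stats$pos, A1 = stats$a1,
                    A2 = stats$a2, FREQ_A1 = stats$freq_a1, BETA = stats$beta,
                    SE = stats$se, Z = stats$z, P = stats$p,
                    N_CASES = stats$n_cases, N_CONTROLS = stats$n_controls,
                    GENO_RATE = stats$geno_rate %||% 1,
                    IS_PROXY = as.integer(stats$is_proxy %||% FALSE))
  write_tsv(out, path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  req <- c("CHR", "POS", "A1", "A2", "FREQ_A1", "BETA", "SE", "Z", "P",
           "N_CASES", "N_CONTROLS", "GENO_RATE", "IS_PROXY")
  df <- read_tsv_checked(path, req,
                         numeric_cols = c("POS", "FREQ_A1", "BETA", "SE", "Z",
                                          "P", "N_CASES", "N_CONTROLS",
                                          "GENO_RATE"))
  zero_p <- which(!is.na(df$P) & df$P == 0)
  if (length(zero_p)) {
    warnf("%s: %d zero P value(s) clamped to smallest positive double",
          path, length(zero_p))
    df$P[zero_p] <- .Machine$double.xmin
  }
  bad <- which(!is.na(df$P) & (df$P < 0 | df$P > 1))
  if (length(bad)) stopf("%s: line %d: P outside (0, 1]", path, bad[1] + 1L)
  bad <- which(!is.na(df$SE) & df$SE <= 0)
  if (length(bad)) stopf("%s: line %d: SE must be > 0", path, bad[1] + 1L)
  data.frame(variant = variant_key(df$CHR, df$POS), chrom = df$CHR,
             pos = df$POS, a1 = df$A1, a2 = df$A2, freq_a1 = df$FREQ_A1,
             beta = df$BETA, se = df$SE, z = df$Z, p = df$P,
             n_cases = df$N_CASES, n_controls = df$N_CONTROLS,
             geno_rate = df$GENO_RATE, is_proxy = df$IS_PROXY == 1,
             note = "", stringsAsFactors = FALSE)
}

#' Write / read expression-weight files
#'
#' Long TSV with columns `GENE, CELL_TYPE, CHR, POS, TSS, A1, A2, WEIGHT,
#' MODEL, H2P`; one row per (gene, variant).
#'
#' @param weight_sets list of `weight_set` objects.
#' @param path file path.
#' @return `read_weights` returns a named list of `weight_set` objects.
#' @export
write_weights <- function(weight_sets, path) {
  rows <- lapply(weight_sets, function(ws) {
    chrom <- as.integer(sub(":.*", "", ws$variants))
    pos <- as.numeric(sub(".*:", "", ws$variants))
    data.frame(GENE = ws$gene, CELL_TYPE = ws$cell_type, CHR = chrom,
               POS = pos, TSS = ws$tss, A1 = ws$a1 %||% NA, A2 = ws$a2 %||% NA,
               WEIGHT = unname(ws$weights), MODEL = ws$model_tag,
               H2P = ws$h2_p, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  req <- c("GENE", "CELL_TYPE", "CHR", "POS", "TSS", "A1", "A2", "WEIGHT",
           "MODEL", "H2P")
  df <- read_tsv_checked(path, req, numeric_cols = c("POS", "TSS", "WEIGHT", "H2P"))
  sets <- lapply(split(df, df$GENE), function(d) {
    v <- variant_key(d$CHR, d$POS)
    structure(list(gene = d$GENE[1], cell_type = d$CELL_TYPE[1], tss = d$TSS[1],
                   variants = v, weights = setNames(d$WEIGHT, v),
                   model_tag = d$MODEL[1], cv_r2 = NA, h2_p = d$H2P[1],
                   a1 = d$A1, a2 = d$A2),
              class = "weight_set")
  })
  sets[unique(df$GENE)]
}

#' Write / read an LD correlation matrix
#'
#' Square TSV: first column `VARIANT`, remaining columns one per variant.
#'
#' @param R correlation matrix with variant-key dimnames.
#' @param path file path.
#' @return `read_ld_matrix` returns the matrix.
#' @export
write_ld_matrix <- function(R, path) {
  df <- data.frame(VARIANT = rownames(R), R, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  R <- as.matrix(df[, -1, drop = FALSE])
  rownames(R) <- df$VARIANT
  if (nrow(R) != ncol(R)) stopf("%s: LD matrix not square", path)
  storage.mode(R) <- "double"
  R
}

#' Write / read counts and covariate tables
#'
#' Counts are genes x samples with a leading `GENE` column; covariates are
#' one row per sample.
#'
#' @param counts genes x samples matrix.
#' @param path file path.
#' @return matrices / data.frames on read.
#' @export
write_counts <- function(counts, path) {
  write_tsv(data.frame(GENE = rownames(counts), counts, check.names = FALSE), path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$GENE
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stopf("%s: negative counts", path)
  m
}

#' @rdname write_counts
#' @export
write_covariates <- function(covariates, path) write_tsv(covariates, path)

#' @rdname write_counts
#' @export
read_covariates <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read BED peak intervals
#'
#' Standard BED: 0-based half-open `[start, end)`, column 4 the cell-type
#' label, no header.  Lines with `start > end` or negative coordinates are
#' schema errors naming the line.
#'
#' @param peaks data.frame `chrom, start, end, label`.
#' @param path file path.
#' @return `read_bed` returns the data.frame.
#' @export
write_bed <- function(peaks, path) {
  write.table(peaks[, c("chrom", "start", "end", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stopf("%s: BED needs 4 columns (chrom, start, end, label)", path)
  names(df)[1:4] <- c("chrom", "start", "end", "label")
  bad <- which(df$start > df$end | df$start < 0)
  if (length(bad)) stopf("%s: line %d: invalid interval (start > end or negative)",
                         path, bad[1])
  df[, 1:4]
}

#' Write / read GMT gene sets
#'
#' Standard gene-matrix-transposed format: set name, description, then
#' tab-separated gene symbols; one set per line.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return `read_gmt` returns a named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("%s: line %d: GMT line needs name, description and >=1 gene", path, i)
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' Write / read interaction edge lists and plain gene lists
#'
#' Edges: TSV `GENE_A, GENE_B, SOURCE`.  Gene lists: one symbol per line.
#'
#' @param edges data.frame `gene_a, gene_b, source`.
#' @param path file path.
#' @return data.frame / character vector on read.
#' @export
write_edges <- function(edges, path) {
  write_tsv(data.frame(GENE_A = edges$gene_a, GENE_B = edges$gene_b,
                       SOURCE = edges$source %||% "synthetic"), path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- read_tsv_checked(path, c("GENE_A", "GENE_B", "SOURCE"))
  data.frame(gene_a = df$GENE_A, gene_b = df$GENE_B, source = df$SOURCE,
             stringsAsFactors = FALSE)
}

#' @rdname write_edges
#' @export
write_gene_list <- function(genes, path) { writeLines(genes, path); invisible(path) }

#' @rdname write_edges
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  out <- readLines(path)
  out[nzchar(out)]
}

#' Write / read the simulation truth table
#'
#' Two TSVs: `<stem>_genes.tsv` (gene, locus, chrom, tss, cell type, causal
#' stratum, liability beta) and `<stem>_eqtl.tsv` (gene, variant, weight).
#'
#' @param truth a `truth_table`.
#' @param stem path stem (without suffix).
#' @return `read_truth_table` returns the `truth_table`.
#' @export
write_truth_table <- function(truth, stem) {
  write_tsv(truth$genes, paste0(stem, "_genes.tsv"))
  write_tsv(truth$eqtl, paste0(stem, "_eqtl.tsv"))
  invisible(stem)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(stem) {
  genes <- read_tsv_checked(paste0(stem, "_genes.tsv"),
                            c("gene", "locus", "chrom", "tss", "cell_type",
                              "causal_stratum", "beta_liability"),
                            numeric_cols = c("tss", "beta_liability"))
  eqtl <- read_tsv_checked(paste0(stem, "_eqtl.tsv"),
                           c("gene", "variant", "weight"),
                           numeric_cols = "weight")
  structure(list(genes = genes, eqtl = eqtl), class = "truth_table")
}
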