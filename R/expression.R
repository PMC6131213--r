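# Expression-atlas arithmetic: FPKM, detectable and tissue-specific gene
# sets, and the log-scale heat-map matrix.

#' FPKM expression matrix from fragment counts
#'
#' `FPKM[g, t] = counts[g, t] / (length_kb[g] * library_size_millions[t])` —
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param counts genes x tissues matrix of non-negative fragment counts.
#' @param gene_lengths gene lengths in bp, in row order of `counts` (or
#'   named).
#' @param library_sizes mapped fragments per tissue, in column order (or
#'   named); must be positive.
#' @return numeric matrix of FPKM values with the dimnames of `counts`.
#' @export
fpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (!is.null(names(library_sizes)) && !is.null(colnames(counts)))
    library_sizes <- library_sizes[colnames(counts)]
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(gene_lengths <= 0)) stopf("gene lengths must be positive")
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  sweep(counts / (gene_lengths / 1000), 2, library_sizes / 1e6, "/")
}

#' Genes with detectable expression
#'
#' A gene is detectable when its FPKM exceeds `threshold` (strictly) in at
#' least one tissue.
#'
#' @param matrix FPKM matrix (genes x tissues).
#' @param threshold FPKM threshold (1 by default).
#' @return character vector of detectable gene ids (row names).
#' @export
detectable_genes <- function(matrix, threshold = 1) {
  rownames(matrix)[apply(matrix > threshold, 1, any)]
}

#' Tissue-specific genes
#'
#' A gene is tissue-specific when its FPKM exceeds 1 in exactly one tissue
#' and is below 1 in all other tissues. Both inequalities are strict, so a
#' gene sitting exactly at 1 in any other tissue is excluded; set
#' `other_max_inclusive = TRUE` to allow FPKM equal to 1 in other tissues.
#'
#' @param matrix FPKM matrix with at least two tissue columns.
#' @param threshold FPKM threshold (1 by default).
#' @param other_max_inclusive treat "below threshold" as `<=` rather than
#'   `<` for the other tissues.
#' @return data.frame with columns `gene_id`, `tissue`.
#' @export
tissue_specific_genes <- function(matrix, threshold = 1,
                                  other_max_inclusive = FALSE) {
  if (ncol(matrix) < 2L) stopf("need at least two tissues")
  above <- matrix > threshold
  below <- if (other_max_inclusive) matrix <= threshold else matrix < threshold
  sel <- rowSums(above) == 1L & rowSums(below) == ncol(matrix) - 1L
  idx <- which(sel)
  data.frame(gene_id = rownames(matrix)[idx],
             tissue = colnames(matrix)[apply(matrix[idx, , drop = FALSE] >
                                               threshold, 1, which)],
             stringsAsFactors = FALSE)
}

#' Log-scale heat-map matrix
#'
#' `log2(FPKM + pseudocount)` restricted to a gene subset, rows ordered by
#' maximum expression (descending) and optionally truncated to the top
#' rows — the layout of an expression-atlas heat map.
#'
#' @param matrix FPKM matrix.
#' @param genes gene ids to keep (default all rows).
#' @param pseudocount added before the log (must be positive unless all
#'   values are positive).
#' @param top keep only the `top` most-expressed genes (e.g. 100), or `NULL`
#'   for all.
#' @return numeric matrix of log2-transformed values.
#' @export
heatmap_matrix <- function(matrix, genes = rownames(matrix), pseudocount = 1,
                           top = NULL) {
  if (any(matrix < 0)) stopf("negative expression values")
  if (pseudocount <= 0 && any(matrix == 0))
    stopf("pseudocount must be positive when zeros are present")
  m <- matrix[rownames(matrix) %in% genes, , drop = FALSE]
  m <- log2(m + pseudocount)
  m <- m[order(apply(m, 1, max), decreasing = TRUE), , drop = FALSE]
  if (!is.null(top)) m <- utils::head(m, top)
  m
}
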