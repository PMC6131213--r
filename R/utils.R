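#' @importFrom stats median rnbinom runif rbinom setNames uniroot filter rlnorm cor
#' @importFrom utils write.table read.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna_vec <- function(n) {
  sample(DNA_BASES, n, replace = TRUE)
}

random_dna <- function(n) {
  paste(random_dna_vec(n), collapse = "")
}

# Substitute each selected base with one of the three other bases.
mutate_bases <- function(bases, rate) {
  if (rate <= 0) return(bases)
  hit <- which(runif(length(bases)) < rate)
  if (length(hit) == 0L) return(bases)
  cur <- bases[hit]
  # draw replacement uniformly from the 3 non-identical bases
  shift <- sample.int(3L, length(hit), replace = TRUE)
  idx <- (match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L
  bases[hit] <- DNA_BASES[idx]
  bases
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  paste(mutate_bases(strsplit(seq, "", fixed = TRUE)[[1]], rate), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single fraction in [0, 1]", name)
}

# Hamming identity (in percent) between two equal-length DNA strings.
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- utf8ToInt(a)
  vb <- utf8ToInt(b)
  100 * sum(va == vb) / length(va)
}

# fraction of window bases covered by a set of (possibly overlapping) intervals
interval_union_width <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = starts, end = ends))))
}

empty_genes_df <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), family_id = character(),
             stringsAsFactors = FALSE)
}

empty_intervals_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Assign gene order ranks along each chromosome
#'
#' Genes are ranked by start coordinate within each chromosome (1, 2, ...).
#' Rank differences, not absolute ranks, drive the tandem-array gene-distance
#' rule and synteny chaining.
#'
#' @param genes data.frame with at least `gene_id`, `chrom`, `start` columns.
#' @return the same data.frame, sorted by chromosome and start, with a `rank`
#'   column added (1-based, consecutive within chromosome).
#' @export
gene_ranks <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start") %in% names(genes)))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chrom, FUN = seq_along)
  rownames(genes) <- NULL
  genes
}
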