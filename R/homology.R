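# Pairwise local alignment with BLAST-style bit scores and e-values, plus an
# all-vs-all driver with a k-mer prefilter and a reader for 12-column
# tab-delimited hit tables.

# Karlin-Altschul lambda for a match/mismatch scoring scheme under uniform
# base composition: solves sum_ij p_i p_j exp(lambda * s_ij) = 1
karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}

#' Local pairwise homology hit with bit score and e-value
#'
#' Smith-Waterman local alignment under a match/mismatch substitution scheme
#' with affine gaps, rescaled to a bit score via the Karlin-Altschul
#' statistic (`bit = (lambda * S - ln K) / ln 2`) and an e-value
#' `E = m * n * 2^(-bit)` with `m` the query length and `n` the effective
#' database length.
#'
#' @param seq_a,seq_b query and subject nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param match,mismatch substitution scores (defaults +1/-2, the classic
#'   megablast-like scheme).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param db_size effective database length `n`; defaults to the subject
#'   length. For all-vs-all searches pass the total database size so
#'   e-values are comparable to a database search.
#' @param K Karlin-Altschul K (0.621, the ungapped uniform-composition
#'   value; the e-value scale, not the ranking, depends on it).
#' @param query_id,subject_id optional ids copied to the output.
#' @return one-row data.frame with BLAST-outfmt6-style columns: `query`,
#'   `subject`, `identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
pairwise_homology <- function(seq_a, seq_b, match = 1, mismatch = -2,
                              gap_open = 5, gap_extend = 2, db_size = NULL,
                              K = 0.621, query_id = "query",
                              subject_id = "subject") {
  a <- Biostrings::DNAString(as.character(seq_a))
  b <- Biostrings::DNAString(as.character(seq_b))
  if (length(a) == 0L || length(b) == 0L) stopf("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  S <- Biostrings::score(aln)
  lambda <- karlin_lambda(match, mismatch)
  bit <- (lambda * S - log(K)) / log(2)
  m <- length(a)
  n <- if (is.null(db_size)) length(b) else db_size
  evalue <- m * n * 2^(-bit)
  p <- as.character(Biostrings::alignedPattern(aln))
  alen <- nchar(p)
  nmat <- Biostrings::nmatch(aln)
  data.frame(query = query_id, subject = subject_id,
             identity = if (alen > 0) 100 * nmat / alen else 0,
             align_length = alen,
             mismatches = Biostrings::nmismatch(aln),
             gap_opens = sum(Biostrings::nindel(aln)@insertion[, 1L],
                             Biostrings::nindel(aln)@deletion[, 1L]),
             q_start = Biostrings::start(Biostrings::pattern(aln)),
             q_end = Biostrings::end(Biostrings::pattern(aln)),
             s_start = Biostrings::start(Biostrings::subject(aln)),
             s_end = Biostrings::end(Biostrings::subject(aln)),
             e_value = evalue, bit_score = bit,
             score = S, stringsAsFactors = FALSE)
}

#' All-vs-all homology hits with a k-mer prefilter
#'
#' Candidate pairs sharing at least `min_shared_kmers` distinct k-mers are
#' aligned with [pairwise_homology()]; hits passing `e_value_max` are
#' returned. Self-hits are dropped. The prefilter trades sensitivity to very
#' diverged homologs for desk-scale speed.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of gene
#'   sequences.
#' @param seqs_b optional second set; when given, only cross-set pairs are
#'   aligned (for between-genome searches).
#' @param e_value_max e-value cutoff for reported hits.
#' @param kmer prefilter k-mer length.
#' @param min_shared_kmers minimum distinct shared k-mers for a candidate
#'   pair.
#' @param ... passed to [pairwise_homology()].
#' @return data.frame of hits (both hit directions are reported for
#'   within-set searches).
#' @export
all_vs_all_hits <- function(seqs, seqs_b = NULL, e_value_max = 1e-5,
                            kmer = 8, min_shared_kmers = 40, ...) {
  seqs <- Biostrings::DNAStringSet(seqs)
  cross <- !is.null(seqs_b)
  if (cross) seqs_b <- Biostrings::DNAStringSet(seqs_b)
  all_seqs <- if (cross) c(seqs, seqs_b) else seqs
  db_size <- sum(Biostrings::width(all_seqs))
  prof <- Matrix::Matrix(
    (Biostrings::oligonucleotideFrequency(all_seqs, width = kmer) > 0) * 1,
    sparse = TRUE)
  shared <- as.matrix(Matrix::tcrossprod(prof))
  n_a <- length(seqs)
  idx <- which(shared >= min_shared_kmers, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  if (cross)
    idx <- idx[idx[, 1L] <= n_a & idx[, 2L] > n_a, , drop = FALSE]
  ids <- names(all_seqs)
  rows <- list()
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    h <- pairwise_homology(all_seqs[[i]], all_seqs[[j]], db_size = db_size,
                           query_id = ids[i], subject_id = ids[j], ...)
    if (h$e_value <= e_value_max) rows[[length(rows) + 1L]] <- h
  }
  if (length(rows) == 0L)
    return(pairwise_homology("A", "A")[0, , drop = FALSE])
  res <- do.call(rbind, rows)
  if (!cross) {
    rev <- res
    rev$query <- res$subject; rev$subject <- res$query
    rev$q_start <- res$s_start; rev$q_end <- res$s_end
    rev$s_start <- res$q_start; rev$s_end <- res$q_end
    res <- rbind(res, rev)
  }
  rownames(res) <- NULL
  res
}

#' Read a 12-column tab-delimited homology hit table
#'
#' Column order follows BLAST tabular output (outfmt 6): query, subject,
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score.
#'
#' @param path file path.
#' @return data.frame with the same column names as [pairwise_homology()].
#' @export
read_homology_hits <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stopf("expected 12 tab-delimited columns in %s", path)
  df <- df[, 1:12]
  names(df) <- c("query", "subject", "identity", "align_length", "mismatches",
                 "gap_opens", "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")
  df
}

#' Write hits as a 12-column tab-delimited table
#' @param hits data.frame from [all_vs_all_hits()] or [pairwise_homology()].
#' @param path output path.
#' @export
write_homology_hits <- function(hits, path) {
  cols <- c("query", "subject", "identity", "align_length", "mismatches",
            "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}
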