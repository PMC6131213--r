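# Readers and writers for the standard formats the pipeline touches. FASTA
# goes through Biostrings; GFF3 is read with rtracklayer and written with a
# plain emitter (gene/mRNA/exon with a family_id attribute); BED output is
# 0-based half-open.

#' Write a genome as wrapped FASTA
#' @param genome named [Biostrings::DNAStringSet] or character vector.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 80)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits one gene/mRNA/exon trio per (single-exon) gene model, carrying the
#' simulator's `family_id` attribute on the gene line.
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   optional `family_id`).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    fam <- if (!is.null(g$family_id)) sprintf(";family_id=%s", g$family_id) else ""
    writeLines(c(
      sprintf("%s\tgenomescape\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id, fam),
      sprintf("%s\tgenomescape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tgenomescape\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.e1;Parent=%s.t1",
              g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id)), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses rtracklayer to parse the file and returns the gene-level records in
#' the package's gene-table layout (ranks included).
#'
#' @param path GFF3 file.
#' @return gene table data.frame.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  df <- data.frame(gene_id = gr$ID,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$family_id)) df$family_id <- gr$family_id
  gene_ranks(df)
}

#' Write intervals as BED6
#'
#' Converts from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention. The `score` column carries `score_col`
#' when given (e.g. telomere copy number).
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional name /
#'   strand columns.
#' @param path output path.
#' @param name_col,score_col,strand_col column names to use, or `NULL`.
#' @export
write_bed6 <- function(df, path, name_col = NULL, score_col = NULL,
                       strand_col = NULL) {
  bed <- data.frame(chrom = df$chrom,
                    start = df$start - 1L,
                    end = df$end,
                    name = if (!is.null(name_col)) df[[name_col]] else ".",
                    score = if (!is.null(score_col)) df[[score_col]] else 0,
                    strand = if (!is.null(strand_col)) df[[strand_col]] else ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a contact matrix set as a tab-delimited triple list
#'
#' One `chrom <TAB> bin_i <TAB> bin_j <TAB> count` row per upper-triangle
#' bin pair (bins are 0-based indices).
#'
#' @param cms named list of `contact_matrix` objects.
#' @param path output path.
#' @export
write_contacts <- function(cms, path) {
  rows <- lapply(cms, function(cm) {
    ut <- which(upper.tri(cm$counts, diag = TRUE), arr.ind = TRUE)
    data.frame(chrom = cm$chrom, bin_i = ut[, 1L] - 1L, bin_j = ut[, 2L] - 1L,
               count = cm$counts[ut], stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contact matrix set from a tab-delimited triple list
#' @param path file written by [write_contacts()].
#' @param bin_size bin width in bp.
#' @return named list of `contact_matrix` objects.
#' @export
read_contacts <- function(path, bin_size) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "bin_i", "bin_j", "count"),
                   stringsAsFactors = FALSE)
  lapply(split(df, df$chrom), function(d) {
    n <- max(d$bin_i, d$bin_j) + 1L
    m <- matrix(0L, n, n)
    m[cbind(d$bin_i + 1L, d$bin_j + 1L)] <- d$count
    m[cbind(d$bin_j + 1L, d$bin_i + 1L)] <- d$count
    structure(list(chrom = d$chrom[1], bin_size = bin_size, counts = m),
              class = "contact_matrix")
  })
}

#' Write a counts matrix as TSV with a tissue header row
#' @param counts genes x tissues matrix.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix written by [write_counts_tsv()]
#' @param path TSV with a `gene_id` column and one column per tissue.
#' @return integer matrix with gene row names.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a plain key:value run configuration file
#'
#' Lines look like `section.key: value`; `#` starts a comment. Values are
#' coerced to numeric where possible. Unknown sections or keys (not present
#' in [default_config()]) are rejected.
#'
#' @param path configuration file.
#' @return a run configuration list (see [default_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stopf("config keys are section.key, got '%s'", key)
    sec <- parts[1]; k <- parts[2]
    if (is.null(cfg[[sec]]) || !k %in% names(cfg[[sec]]))
      stopf("unknown config key '%s'", key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[sec]][[k]] <- if (!is.na(num)) num else val
  }
  cfg
}
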