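# Assembly summary statistics and terminal telomere detection.

#' NX contiguity statistic
#'
#' `nx_value(lengths, 0.5)` is the classic N50: the largest length `L` such
#' that sequences of length `>= L` jointly contain at least `fraction` of the
#' assembly's bases. At an exact boundary the boundary-crossing length is
#' returned (standard N50 convention).
#'
#' @param lengths positive sequence lengths in bp.
#' @param fraction fraction of total assembly size, in (0, 1).
#' @return the NX length in bp.
#' @examples
#' nx_value(c(2, 2, 2, 3, 3, 4, 8, 8), 0.5)
#' @export
nx_value <- function(lengths, fraction = 0.5) {
  if (length(lengths) == 0L) stopf("empty length list")
  if (any(lengths <= 0)) stopf("sequence lengths must be positive")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= fraction * cs[length(cs)])[1]]
}

#' Summarise an assembly
#'
#' Computes total size, sequence count, NX for X in 10..90, and assembly gaps
#' (maximal runs of the ambiguous base `N`).
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character vector
#'   of sequences).
#' @return list of class `assembly_summary` with fields `total_size`,
#'   `n_sequences`, `nx` (named vector N10..N90), `gap_count`, `gap_bases`.
#' @export
assembly_summary <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0L) stopf("assembly has no sequences")
  lens <- Biostrings::width(genome)
  fracs <- seq(0.1, 0.9, by = 0.1)
  nx <- vapply(fracs, function(f) nx_value(lens, f), numeric(1))
  names(nx) <- sprintf("N%d", round(100 * fracs))
  gap_count <- 0L
  gap_bases <- 0L
  for (i in seq_along(genome)) {
    m <- gregexpr("N+", as.character(genome[[i]]))[[1]]
    if (m[1] != -1L) {
      gap_count <- gap_count + length(m)
      gap_bases <- gap_bases + sum(attr(m, "match.length"))
    }
  }
  structure(list(total_size = sum(as.numeric(lens)),
                 n_sequences = length(genome),
                 nx = nx, gap_count = gap_count, gap_bases = gap_bases),
            class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf("assembly: %d sequences, %s bp, N50 = %s bp, %d gaps (%s bp)\n",
              x$n_sequences, format(x$total_size, big.mark = ","),
              format(x$nx[["N50"]], big.mark = ","), x$gap_count,
              format(x$gap_bases, big.mark = ",")))
  invisible(x)
}

#' Completeness percentage from an ortholog benchmark count
#'
#' @param found orthologs found in the assembly.
#' @param total orthologs in the benchmark set.
#' @return integer percentage, `round(100 * found / total)`.
#' @examples
#' busco_percent(1352, 1440)
#' @export
busco_percent <- function(found, total) {
  if (total <= 0) stopf("total must be positive")
  if (found < 0 || found > total) stopf("found must be in [0, total]")
  as.integer(round(100 * found / total))
}

#' Detect terminal telomere tracks
#'
#' Scans a window at each chromosome end for the longest tandem run of the
#' telomeric motif, searching both the motif and its reverse complement at
#' each end (plant telomeres read as the motif on one strand and its reverse
#' complement on the other). A run qualifies when it has at least `min_copies`
#' consecutive copies, each within `max_divergence` of the motif. At most one
#' call is reported per end.
#'
#' @param genome named [Biostrings::DNAStringSet] or character vector.
#' @param motif telomeric repeat unit (default the plant consensus
#'   `TTTAGGG`); must be at least 5 bp.
#' @param min_copies minimum tandem copies for a call.
#' @param terminal_window how far from each end to search (bp); clipped with
#'   a warning when longer than the chromosome.
#' @param max_divergence per-copy mismatch fraction tolerated.
#' @return data.frame with columns `chrom`, `end_label`, `start`, `end`,
#'   `copy_number`, `motif` (one row per called end).
#' @export
detect_telomeres <- function(genome, motif = "TTTAGGG", min_copies = 10,
                             terminal_window = 10000, max_divergence = 0.1) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (nchar(motif) < 5L) stopf("motif must be at least 5 bp")
  motifs <- unique(c(toupper(motif), revcomp(toupper(motif))))
  out <- list()
  for (ch in names(genome)) {
    L <- Biostrings::width(genome[ch])
    win <- terminal_window
    if (win > L) {
      warning(sprintf("terminal_window clipped to chromosome length on %s", ch))
      win <- L
    }
    s <- as.character(genome[[ch]])
    for (lab in c("left", "right")) {
      seg <- if (lab == "left") substr(s, 1L, win) else substr(s, L - win + 1L, L)
      off <- if (lab == "left") 0L else L - win
      best <- NULL
      for (m in motifs) {
        run <- longest_tandem_run(seg, m, max_divergence)
        if (!is.null(run) && (is.null(best) || run$copies > best$copies)) {
          best <- run
          best$motif <- m
        }
      }
      if (!is.null(best) && best$copies >= min_copies) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, end_label = lab,
          start = best$start + off, end = best$end + off,
          copy_number = best$copies, motif = best$motif,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), end_label = character(),
                      start = integer(), end = integer(),
                      copy_number = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# longest run of consecutive motif copies (each copy <= max_divergence
# mismatches as a fraction of motif length) within a sequence segment
longest_tandem_run <- function(seg, motif, max_divergence) {
  k <- nchar(motif)
  max_mm <- floor(k * max_divergence)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seg),
                                   max.mismatch = max_mm)
  st <- IRanges::start(hits)
  if (length(st) == 0L) return(NULL)
  st <- sort(unique(st))
  # chain starts spaced exactly one motif length apart
  brk <- c(0L, which(diff(st) != k), length(st))
  runs <- diff(brk)
  best <- which.max(runs)
  i0 <- brk[best] + 1L
  i1 <- brk[best + 1L]
  list(start = st[i0], end = st[i1] + k - 1L, copies = runs[best])
}
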