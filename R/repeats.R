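# Tandem monomer discovery, satellite array scanning, and windowed density
# tracks for the genome landscape.

#' Discover dominant tandem repeat periodicities and their consensus monomer
#'
#' Periods are detected from a k-mer recurrence-distance histogram: the
#' distances between successive occurrences of each k-mer vote for candidate
#' periods, so a satellite array of monomer length `p` produces a strong
#' spike at `p` (and weaker harmonics at its multiples). For each supported
#' period the consensus monomer is the per-column majority base of the
#' period-phased stack of frames.
#'
#' @param sequence a character scalar or [Biostrings::DNAString].
#' @param min_period,max_period period search range in bp
#'   (`max_period >= min_period >= 10`).
#' @param k k-mer length used for recurrence voting.
#' @param min_support minimum number of recurrence votes for a reported
#'   period (calibrated so random sequence reports nothing).
#' @param top_n maximum number of periods reported.
#' @return data.frame with columns `period`, `support`, `consensus`, ranked
#'   by support; zero rows when no periodicity is supported or the sequence
#'   is shorter than `3 * min_period`.
#' @export
find_tandem_monomer <- function(sequence, min_period = 100, max_period = 1000,
                                k = 13, min_support = 25, top_n = 3) {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  if (min_period < 10 || max_period < min_period)
    stopf("need max_period >= min_period >= 10")
  n <- nchar(sequence)
  empty <- data.frame(period = integer(), support = integer(),
                      consensus = character(), stringsAsFactors = FALSE)
  if (n < 3 * min_period) return(empty)
  pos <- seq_len(n - k + 1L)
  kmers <- substring(sequence, pos, pos + k - 1L)
  ord <- order(kmers, pos)
  km_s <- kmers[ord]
  pos_s <- pos[ord]
  same <- km_s[-1L] == km_s[-length(km_s)]
  d <- diff(pos_s)[same]
  d <- d[d >= min_period & d <= max_period]
  if (length(d) == 0L) return(empty)
  tab <- sort(table(d), decreasing = TRUE)
  tab <- tab[tab >= min_support]
  if (length(tab) == 0L) return(empty)
  tab <- utils::head(tab, top_n)
  periods <- as.integer(names(tab))
  cons <- vapply(periods, function(p) phased_consensus(sequence, p), character(1))
  data.frame(period = periods, support = as.integer(tab), consensus = cons,
             stringsAsFactors = FALSE)
}

# majority base per column over consecutive period-length frames
phased_consensus <- function(sequence, period) {
  n <- nchar(sequence)
  starts <- seq(1L, n - period + 1L, by = period)
  frames <- substring(sequence, starts, starts + period - 1L)
  m <- matrix(unlist(strsplit(frames, "", fixed = TRUE), use.names = FALSE),
              nrow = length(frames), byrow = TRUE)
  paste(apply(m, 2L, function(col) names(which.max(table(col)))), collapse = "")
}

#' Scan a genome for tandem arrays of a known monomer
#'
#' Finds monomer matches on both strands by seeding on the monomer prefix and
#' verifying full-length identity, merges matches separated by at most
#' `max_gap` bp into arrays, then partitions each array into consecutive
#' monomer-length frames anchored at its first match. Copy number is the
#' number of frames at or above `min_identity`, and `mean_identity` is the
#' mean per-element identity to the monomer over those frames.
#'
#' @param genome named [Biostrings::DNAStringSet] or character vector.
#' @param monomer the repeat monomer sequence.
#' @param min_copies minimum copies to report an array.
#' @param min_identity minimum per-element percent identity to the monomer.
#' @param max_gap maximum gap (bp) merged into one array; defaults to two
#'   monomer lengths.
#' @param seed_length prefix length used for match seeding.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `monomer_length`, `copy_number`, `mean_identity`.
#' @export
scan_repeat_arrays <- function(genome, monomer, min_copies = 5,
                               min_identity = 70, max_gap = NULL,
                               seed_length = 20) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!nzchar(monomer)) stopf("monomer must be non-empty")
  ml <- nchar(monomer)
  if (is.null(max_gap)) max_gap <- 2L * ml
  seed_length <- min(seed_length, ml)
  out <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    L <- nchar(s)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") s else revcomp(s)
      hits <- scan_monomer_strand(subject, monomer, min_identity, max_gap,
                                  min_copies, seed_length)
      if (is.null(hits) || nrow(hits) == 0L) next
      if (strand == "-") {
        st <- L - hits$end + 1L
        hits$end <- L - hits$start + 1L
        hits$start <- st
      }
      hits$chrom <- ch
      hits$strand <- strand
      out[[length(out) + 1L]] <- hits
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), monomer_length = integer(),
                      copy_number = integer(), mean_identity = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), c("chrom", "start", "end", "strand",
                                            "monomer_length", "copy_number",
                                            "mean_identity")]
  rownames(res) <- NULL
  res
}

scan_monomer_strand <- function(s, monomer, min_identity, max_gap, min_copies,
                                seed_length) {
  ml <- nchar(monomer)
  subj <- Biostrings::DNAString(s)
  seed <- substr(monomer, 1L, seed_length)
  mm <- ceiling(seed_length * (1 - min_identity / 100))
  st <- IRanges::start(Biostrings::matchPattern(seed, subj, max.mismatch = mm))
  st <- st[st + ml - 1L <= nchar(s)]
  if (length(st) == 0L) return(NULL)
  ned <- Biostrings::neditStartingAt(monomer, subj, starting.at = st,
                                     with.indels = FALSE)
  keep <- 100 * (ml - ned) / ml >= min_identity
  st <- st[keep]
  if (length(st) == 0L) return(NULL)
  rng <- IRanges::reduce(IRanges::IRanges(st, st + ml - 1L),
                         min.gapwidth = max_gap + 1L)
  rows <- list()
  for (i in seq_along(rng)) {
    a <- IRanges::start(rng)[i]
    b <- IRanges::end(rng)[i]
    fr <- seq(a, b - ml + 1L, by = ml)
    ned <- Biostrings::neditStartingAt(monomer, subj, starting.at = fr,
                                       with.indels = FALSE)
    ids <- 100 * (ml - ned) / ml
    pass <- ids >= min_identity
    if (sum(pass) < min_copies) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = a, end = fr[max(which(pass))] + ml - 1L,
      monomer_length = ml, copy_number = sum(pass),
      mean_identity = mean(ids[pass]), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Mean element-to-consensus identity of repeat elements
#'
#' Each element is globally aligned to the monomer; identity is alignment
#' matches over alignment columns, averaged over elements and expressed in
#' percent.
#'
#' @param elements character vector or [Biostrings::DNAStringSet] of repeat
#'   elements (at least one).
#' @param monomer consensus monomer sequence.
#' @return mean percent identity.
#' @export
mean_element_identity <- function(elements, monomer) {
  if (length(elements) == 0L) stopf("no elements supplied")
  elements <- as.character(elements)
  ids <- vapply(elements, function(e) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(e),
                                         Biostrings::DNAString(monomer),
                                         type = "global")
    100 * Biostrings::nmatch(aln) /
      nchar(as.character(Biostrings::alignedPattern(aln)))
  }, numeric(1), USE.NAMES = FALSE)
  mean(ids)
}

#' Windowed coverage density track
#'
#' Fraction of each sliding window's bases covered by the union of the given
#' intervals. Windows start at 1, `step + 1`, `2 * step + 1`, ... and the last
#' window is truncated at the chromosome end, so a chromosome yields
#' `ceiling(chrom_length / step)` windows.
#'
#' @param intervals data.frame with `start`, `end` columns (1-based
#'   inclusive), or an [IRanges::IRanges]. May be empty.
#' @param chrom_length chromosome length in bp (> 0).
#' @param window window width in bp (50 kb by default).
#' @param step distance between window starts (25 kb by default).
#' @return data.frame of class `density_track` with columns `start`, `end`,
#'   `density`; `window` and `step` stored as attributes.
#' @export
windowed_density <- function(intervals, chrom_length, window = 50000,
                             step = 25000) {
  if (chrom_length <= 0) stopf("chrom_length must be positive")
  if (inherits(intervals, "IRanges")) {
    ir <- intervals
  } else if (is.null(intervals) || nrow(intervals) == 0L) {
    ir <- IRanges::IRanges()
  } else {
    if (any(intervals$start < 1 | intervals$end > chrom_length))
      stopf("intervals must lie within [1, chrom_length]")
    ir <- IRanges::IRanges(intervals$start, intervals$end)
  }
  w_start <- seq(1L, chrom_length, by = step)
  w_end <- pmin(w_start + window - 1L, chrom_length)
  cov <- IRanges::coverage(IRanges::reduce(ir), width = chrom_length)
  sums <- IRanges::viewSums(IRanges::Views(cov, start = w_start, end = w_end))
  res <- data.frame(start = w_start, end = w_end,
                    density = as.numeric(sums) / (w_end - w_start + 1))
  attr(res, "window") <- window
  attr(res, "step") <- step
  class(res) <- c("density_track", "data.frame")
  res
}

#' Joined per-window landscape table
#'
#' Builds the windowed density tracks underlying a genome landscape figure:
#' gene density, LTR retrotransposon density, and centromeric repeat array
#' density per window, across all chromosomes, with telomere call positions
#' attached as an attribute.
#'
#' @param chrom_lengths named vector of chromosome lengths (or a
#'   [Biostrings::DNAStringSet], whose widths are used).
#' @param gene_intervals,ltr_intervals data.frames with `chrom`, `start`,
#'   `end`.
#' @param arrays repeat arrays as returned by [scan_repeat_arrays()] (may be
#'   empty or `NULL`).
#' @param telomeres telomere calls from [detect_telomeres()] (may be `NULL`).
#' @param window,step window geometry in bp, as in [windowed_density()].
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_density`,
#'   `ltr_density`, `cent_density`; telomere calls in `attr(, "telomeres")`.
#' @export
landscape_table <- function(chrom_lengths, gene_intervals, ltr_intervals,
                            arrays = NULL, telomeres = NULL,
                            window = 50000, step = 25000) {
  if (inherits(chrom_lengths, "DNAStringSet"))
    chrom_lengths <- setNames(Biostrings::width(chrom_lengths),
                              names(chrom_lengths))
  tracks <- list(gene = gene_intervals, ltr = ltr_intervals, cent = arrays)
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (is.null(tr) || nrow(tr) == 0L) next
    bad <- setdiff(unique(tr$chrom), names(chrom_lengths))
    if (length(bad))
      stopf("%s track references unknown chromosomes: %s", nm,
            paste(bad, collapse = ", "))
  }
  per_chrom <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    sub <- function(tr) {
      if (is.null(tr) || nrow(tr) == 0L) return(NULL)
      tr[tr$chrom == ch, c("start", "end"), drop = FALSE]
    }
    base <- windowed_density(sub(gene_intervals), L, window, step)
    d <- data.frame(chrom = ch, start = base$start, end = base$end,
                    gene_density = base$density,
                    ltr_density = windowed_density(sub(ltr_intervals), L,
                                                   window, step)$density,
                    cent_density = windowed_density(sub(arrays), L,
                                                    window, step)$density,
                    stringsAsFactors = FALSE)
    d
  })
  res <- do.call(rbind, per_chrom)
  rownames(res) <- NULL
  attr(res, "telomeres") <- telomeres
  attr(res, "window") <- window
  attr(res, "step") <- step
  res
}
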