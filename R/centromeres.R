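# Centromere calling from three evidence tracks: centromeric satellite
# arrays, pericentromeric LTR density, and depressed intra-chromosomal Hi-C
# interaction.

#' Relative intra-chromosomal interaction track from a Hi-C contact matrix
#'
#' Per-bin total intra-chromosomal contact (row sum excluding the diagonal),
#' smoothed by a running mean over `smooth_bins` bins and divided by the
#' chromosome median, so 1 means a typical bin and values well below 1 mark
#' interaction-depressed (candidate centromeric) bins. The statistic is
#' invariant to rescaling the whole matrix.
#'
#' @param matrix a `contact_matrix` (fields `chrom`, `bin_size`, `counts`)
#'   as produced by [generate_contact_matrix()], or a plain symmetric count
#'   matrix.
#' @param smooth_bins running-mean width (odd; 3 by default).
#' @param bin_size,chrom used when `matrix` is a plain matrix.
#' @return data.frame with columns `chrom`, `start`, `end`, `stat`.
#' @export
contact_depression_track <- function(matrix, smooth_bins = 3,
                                     bin_size = NULL, chrom = NA_character_) {
  if (inherits(matrix, "contact_matrix")) {
    counts <- matrix$counts
    bin_size <- matrix$bin_size
    chrom <- matrix$chrom
  } else {
    counts <- matrix
    if (is.null(bin_size)) stopf("bin_size required for a plain matrix")
  }
  n <- nrow(counts)
  if (n < 5L) stopf("need at least 5 bins")
  rs <- rowSums(counts) - diag(counts)
  if (all(rs == 0)) stopf("all-zero contact matrix")
  sm <- running_mean(rs, smooth_bins)
  stat <- sm / median(sm)
  data.frame(chrom = chrom,
             start = (seq_len(n) - 1L) * bin_size + 1L,
             end = seq_len(n) * bin_size,
             stat = stat, stringsAsFactors = FALSE)
}

# centered running mean with shrinking windows at the edges
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  h <- w %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Call a centromere on one chromosome from up to three evidence tracks
#'
#' The call is seeded by centromere-specific repeat arrays overlapping the
#' Hi-C depression region (the contiguous run of bins with relative
#' interaction below `depression_threshold` around the minimum). When repeat
#' and Hi-C evidence disagree on location the repeat arrays win; when no
#' qualifying array exists, a depressed region is used as the seed only if
#' LTR density supports it. Borders are then extended window by window while
#' LTR density exceeds `ltr_threshold` (allowing one sub-threshold window) or
#' further arrays occur. With neither array support nor a depressed region
#' the chromosome is reported as `no_call` — the signature of a chromosome
#' whose centromere is not represented in the assembly.
#'
#' @param chrom chromosome id.
#' @param arrays repeat arrays from [scan_repeat_arrays()] (any chromosome;
#'   filtered internally). Arrays with fewer than `min_copies` copies are
#'   ignored as stray monomers.
#' @param ltr_track windowed LTR density for this chromosome
#'   ([windowed_density()] output; `start`/`end`/`density`).
#' @param depression relative-interaction track from
#'   [contact_depression_track()], or `NULL` when Hi-C is unavailable.
#' @param ltr_threshold LTR density above which the centromere border keeps
#'   extending (0.85 by default).
#' @param depression_threshold relative interaction below which bins count as
#'   depressed (0.6 by default, calibrated on simulations with planted
#'   depression factors 0.2-0.5).
#' @param min_copies minimum array copy number for centromere support.
#' @param gap_tolerance sub-threshold LTR windows tolerated while extending.
#' @return one-row data.frame: `chrom`, `status` (`called`/`no_call`),
#'   `start`, `end`, `size`, and logical evidence flags `repeat_array`,
#'   `ltr_density`, `hic_depression`.
#' @export
call_centromere <- function(chrom, arrays = NULL, ltr_track = NULL,
                            depression = NULL, ltr_threshold = 0.85,
                            depression_threshold = 0.6, min_copies = 5,
                            gap_tolerance = 1) {
  arr <- if (!is.null(arrays) && nrow(arrays))
    arrays[arrays$chrom == chrom & arrays$copy_number >= min_copies, , drop = FALSE]
  else NULL
  if (!is.null(depression) && "chrom" %in% names(depression) &&
      !all(is.na(depression$chrom)))
    depression <- depression[depression$chrom %in% c(chrom, NA), , drop = FALSE]

  no_call <- data.frame(chrom = chrom, status = "no_call",
                        start = NA_integer_, end = NA_integer_,
                        size = NA_integer_, repeat_array = FALSE,
                        ltr_density = FALSE, hic_depression = FALSE,
                        stringsAsFactors = FALSE)

  depr_region <- NULL
  if (!is.null(depression) && nrow(depression)) {
    below <- depression$stat < depression_threshold
    if (any(below)) {
      i_min <- which.min(depression$stat)
      run <- contiguous_run(below, i_min)
      depr_region <- c(depression$start[run[1]], depression$end[run[2]])
    }
  }

  have_arrays <- !is.null(arr) && nrow(arr) > 0L
  if (!have_arrays && is.null(depr_region)) return(no_call)

  used_arrays <- FALSE
  if (have_arrays) {
    # cluster arrays, prefer the cluster overlapping the depressed region,
    # otherwise the one with most total copies (repeat evidence wins)
    cl <- cluster_arrays(arr)
    pick <- NULL
    if (!is.null(depr_region)) {
      ov <- vapply(cl, function(d)
        any(d$end >= depr_region[1] & d$start <= depr_region[2]), logical(1))
      if (any(ov)) pick <- cl[ov][[which.max(vapply(cl[ov], function(d)
        sum(d$copy_number), numeric(1)))]]
    }
    if (is.null(pick))
      pick <- cl[[which.max(vapply(cl, function(d) sum(d$copy_number),
                                   numeric(1)))]]
    seed <- c(min(pick$start), max(pick$end))
    used_arrays <- TRUE
  } else {
    # depression-only seed needs LTR support to qualify as a call
    seed <- depr_region
    if (is.null(ltr_track)) return(no_call)
    in_seed <- ltr_track$end >= seed[1] & ltr_track$start <= seed[2]
    if (!any(in_seed) || !any(ltr_track$density[in_seed] > ltr_threshold))
      return(no_call)
  }

  interval <- seed
  ltr_used <- FALSE
  if (!is.null(ltr_track) && nrow(ltr_track)) {
    interval <- extend_borders(seed, ltr_track, arr, ltr_threshold, gap_tolerance)
    in_call <- ltr_track$end >= interval[1] & ltr_track$start <= interval[2]
    ltr_used <- any(ltr_track$density[in_call] > ltr_threshold)
  }
  hic_used <- !is.null(depr_region) &&
    depr_region[1] <= interval[2] && depr_region[2] >= interval[1]

  data.frame(chrom = chrom, status = "called",
             start = interval[1], end = interval[2],
             size = interval[2] - interval[1] + 1L,
             repeat_array = used_arrays, ltr_density = ltr_used,
             hic_depression = hic_used, stringsAsFactors = FALSE)
}

contiguous_run <- function(flag, i) {
  lo <- i
  while (lo > 1L && flag[lo - 1L]) lo <- lo - 1L
  hi <- i
  while (hi < length(flag) && flag[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}

cluster_arrays <- function(arr, max_cluster_gap = 500000L) {
  arr <- arr[order(arr$start), , drop = FALSE]
  grp <- cumsum(c(1L, diff(arr$start) > max_cluster_gap))
  unname(split(arr, grp))
}

# extend the seed interval outward window by window while LTR density stays
# above threshold (with gap tolerance) or a supporting array occurs
extend_borders <- function(seed, ltr_track, arr, ltr_threshold, gap_tolerance) {
  tr <- ltr_track[order(ltr_track$start), , drop = FALSE]
  supports <- function(i) {
    if (tr$density[i] > ltr_threshold) return(TRUE)
    !is.null(arr) && nrow(arr) > 0L &&
      any(arr$end >= tr$start[i] & arr$start <= tr$end[i])
  }
  lo <- seed[1]; hi <- seed[2]
  # leftward
  i <- max(which(tr$start < lo), 0L)
  gaps <- 0L
  while (i >= 1L) {
    if (supports(i)) {
      lo <- min(lo, tr$start[i]); gaps <- 0L
    } else {
      gaps <- gaps + 1L
      if (gaps > gap_tolerance) break
    }
    i <- i - 1L
  }
  # rightward
  idx <- which(tr$end > hi)
  i <- if (length(idx)) min(idx) else nrow(tr) + 1L
  gaps <- 0L
  while (i <= nrow(tr)) {
    if (supports(i)) {
      hi <- max(hi, tr$end[i]); gaps <- 0L
    } else {
      gaps <- gaps + 1L
      if (gaps > gap_tolerance) break
    }
    i <- i + 1L
  }
  c(lo, hi)
}

#' Call centromeres across a genome
#'
#' Convenience wrapper running [call_centromere()] per chromosome.
#'
#' @param chroms chromosome ids.
#' @param arrays repeat arrays ([scan_repeat_arrays()]).
#' @param ltr_tracks named list of per-chromosome LTR density tracks.
#' @param depressions named list of per-chromosome depression tracks (or
#'   `NULL` when Hi-C is unavailable).
#' @param ... passed to [call_centromere()].
#' @return data.frame of per-chromosome calls.
#' @export
call_centromeres <- function(chroms, arrays = NULL, ltr_tracks = NULL,
                             depressions = NULL, ...) {
  do.call(rbind, lapply(chroms, function(ch)
    call_centromere(ch, arrays = arrays,
                    ltr_track = ltr_tracks[[ch]],
                    depression = depressions[[ch]], ...)))
}

#' Summarise centromere calls
#'
#' @param calls data.frame from [call_centromeres()] (at least one row).
#' @return list with `n_called`, `n_no_call`, `no_call_chroms`, and (over
#'   called chromosomes) `mean_size`, `min_size`, `max_size`.
#' @export
centromere_summary <- function(calls) {
  if (nrow(calls) == 0L) stopf("no centromere calls supplied")
  called <- calls[calls$status == "called", , drop = FALSE]
  out <- list(n_called = nrow(called),
              n_no_call = sum(calls$status == "no_call"),
              no_call_chroms = calls$chrom[calls$status == "no_call"])
  if (nrow(called)) {
    out$mean_size <- mean(called$size)
    out$min_size <- min(called$size)
    out$max_size <- max(called$size)
  }
  out
}
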