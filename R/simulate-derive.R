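# Derived genomes: assembly-collapse ("V1-like") degradation and a diverged
# ortholog "second species". Both operate on a sim_genome and keep the truth
# ledger consistent through every coordinate-changing edit.

# ---- coordinate machinery ---------------------------------------------------

# positions after removing sorted non-overlapping intervals `exc` (start/end,
# 1-based inclusive); callers guarantee no remapped feature overlaps a cut
remap_after_excision <- function(p, exc) {
  if (is.null(exc) || nrow(exc) == 0L) return(p)
  exc <- exc[order(exc$start), , drop = FALSE]
  cw <- cumsum(exc$end - exc$start + 1L)
  idx <- findInterval(p, exc$start)
  p - c(0L, cw)[idx + 1L]
}

excise_from_seq <- function(s, exc) {
  if (nrow(exc) == 0L) return(s)
  exc <- exc[order(exc$start), , drop = FALSE]
  starts <- c(1L, exc$end + 1L)
  ends <- c(exc$start - 1L, nchar(s))
  keep <- starts <= ends
  paste(substring(s, starts[keep], ends[keep]), collapse = "")
}

insert_into_seq <- function(s, after_pos, insert) {
  paste0(substr(s, 1L, after_pos), insert, substr(s, after_pos + 1L, nchar(s)))
}

# apply a vectorized position-mapping function to every coordinate table of a
# simulation state, restricted to one chromosome
remap_state <- function(sim, chrom, fn) {
  fix <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    on <- df$chrom == chrom
    for (cl in cols) df[[cl]][on] <- fn(df[[cl]][on])
    df
  }
  sim$annotations$genes <- fix(sim$annotations$genes, c("start", "end"))
  sim$annotations$ltr <- fix(sim$annotations$ltr, c("start", "end"))
  sim$truth$telomeres <- fix(sim$truth$telomeres, c("start", "end"))
  sim$truth$centromeres <- fix(sim$truth$centromeres,
                               c("start", "end", "array_start", "array_end"))
  sim$truth$ltr_intervals <- fix(sim$truth$ltr_intervals, c("start", "end"))
  sim$truth$inversions <- fix(sim$truth$inversions, c("start", "end"))
  sim
}

ordered_members <- function(sim, array_id) {
  g <- sim$annotations$genes
  fam <- paste0("fam_", array_id)
  m <- g[g$family_id == fam, , drop = FALSE]
  m[order(m$start), , drop = FALSE]
}

# excise all bases from the end of the last kept member to the end of the last
# member (gene bodies plus intergenic spacers), shifting downstream coordinates
collapse_array <- function(sim, seqs, array_id, keep) {
  m <- ordered_members(sim, array_id)
  if (nrow(m) <= keep) return(list(sim = sim, seqs = seqs, exc = NULL))
  chrom <- m$chrom[1]
  exc <- data.frame(start = m$end[keep] + 1L, end = m$end[nrow(m)])
  removed <- m$gene_id[(keep + 1L):nrow(m)]
  g <- sim$annotations$genes
  sim$annotations$genes <- g[!g$gene_id %in% removed, , drop = FALSE]
  sim <- remap_state(sim, chrom, function(p) remap_after_excision(p, exc))
  seqs[chrom] <- excise_from_seq(seqs[chrom], exc)
  ta <- sim$truth$tandem_arrays
  i <- ta$array_id == array_id
  ta$size[i] <- keep
  ta$members[i] <- list(m$gene_id[seq_len(keep)])
  sim$truth$tandem_arrays <- ta
  list(sim = sim, seqs = seqs, exc = exc, chrom = chrom)
}

# invert the enclosing interval of a run of consecutive genes: sequence is
# reverse-complemented, gene coordinates mirrored and strands flipped
apply_gene_run_inversion <- function(sim, seqs, chrom, run_genes, pad = 0L) {
  g <- sim$annotations$genes
  sel <- g$gene_id %in% run_genes
  a <- min(g$start[sel]) - pad
  b <- max(g$end[sel]) + pad
  s <- seqs[chrom]
  seqs[chrom] <- paste0(substr(s, 1L, a - 1L), revcomp(substr(s, a, b)),
                        substr(s, b + 1L, nchar(s)))
  ns <- a + b - g$end[sel]
  ne <- a + b - g$start[sel]
  g$start[sel] <- ns
  g$end[sel] <- ne
  g$strand[sel] <- ifelse(g$strand[sel] == "+", "-", "+")
  sim$annotations$genes <- g
  sim$truth$inversions <- rbind(sim$truth$inversions,
    data.frame(chrom = chrom, start = a, end = b, stringsAsFactors = FALSE))
  list(sim = sim, seqs = seqs)
}

# sample a run of `run_len` consecutive genes on `chrom` whose enclosing
# interval avoids `forbidden` intervals; NULL when impossible
sample_gene_run <- function(sim, chrom, run_len, forbidden, flank = 0L, pad = 0L) {
  g <- sim$annotations$genes
  g <- g[g$chrom == chrom, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  n <- nrow(g)
  lo <- 1L + flank
  hi <- n - run_len + 1L - flank
  if (hi < lo) return(NULL)
  starts <- if (hi == lo) lo else sample(lo:hi)
  for (s0 in starts) {
    ids <- g$gene_id[s0:(s0 + run_len - 1L)]
    a <- g$start[s0] - pad
    b <- g$end[s0 + run_len - 1L] + pad
    bad <- FALSE
    if (!is.null(forbidden) && nrow(forbidden)) {
      f <- forbidden[forbidden$chrom == chrom, , drop = FALSE]
      if (nrow(f) && any(f$end >= a & f$start <= b)) bad <- TRUE
    }
    if (!bad) return(ids)
  }
  NULL
}

# ---- degraded "V1-like" assembly -------------------------------------------

#' Degrade a synthetic genome into a short-read-like assembly
#'
#' Emulates the characteristic failures of short-read draft assemblies:
#' a sampled fraction of tandem gene arrays collapse to a few members (the
#' excess gene bodies and their spacers are excised and downstream coordinates
#' shift left), segments are inverted (mis-oriented scaffolds), and
#' pericentromeric sequence can be replaced by a gap of ambiguous bases.
#'
#' @param sim a `sim_genome` from [generate_genome()].
#' @param collapse_fraction fraction of collapsible tandem arrays (size >
#'   `collapse_keep`) that collapse.
#' @param collapse_keep members retained by each collapsed array.
#' @param inversion_count number of gene-run inversions to plant.
#' @param drop_pericentromere replace centromeric/pericentromeric sequence
#'   with `N` gaps and drop the corresponding annotations.
#' @param seed integer seed.
#' @param max_retries resampling attempts for an inversion that overlaps a
#'   collapse junction before giving up with an error.
#' @return a new `sim_genome` whose truth ledger records collapsed arrays and
#'   planted inversions. With all knobs at identity the input is returned
#'   unchanged.
#' @export
degrade_assembly <- function(sim, collapse_fraction = 0.5, collapse_keep = 4,
                             inversion_count = 0, drop_pericentromere = FALSE,
                             seed = 1, max_retries = 100) {
  stopifnot(inherits(sim, "sim_genome"))
  assert_fraction(collapse_fraction, "collapse_fraction")
  if (collapse_fraction == 0 && inversion_count == 0 && !drop_pericentromere)
    return(sim)
  with_seed(seed, {
    seqs <- setNames(as.character(sim$genome), names(sim$genome))
    junctions <- empty_junctions()

    ta <- sim$truth$tandem_arrays
    eligible <- ta$array_id[ta$size > collapse_keep]
    n_c <- round(collapse_fraction * length(eligible))
    chosen <- if (n_c > 0) sample(eligible, n_c) else character()
    for (aid in chosen) {
      orig <- ta$size[ta$array_id == aid]
      res <- collapse_array(sim, seqs, aid, collapse_keep)
      sim <- res$sim; seqs <- res$seqs
      if (!is.null(res$exc)) {
        # earlier junctions on the same chromosome shift with this excision too
        on <- junctions$chrom == res$chrom
        junctions$pos[on] <- remap_after_excision(junctions$pos[on], res$exc)
        junctions <- rbind(junctions,
          data.frame(chrom = res$chrom, pos = res$exc$start,
                     stringsAsFactors = FALSE))
      }
      sim$truth$collapsed_arrays <- rbind(sim$truth$collapsed_arrays,
        data.frame(array_id = aid, original_size = orig,
                   collapsed_size = collapse_keep, stringsAsFactors = FALSE))
    }

    if (drop_pericentromere) {
      cen <- sim$truth$centromeres
      for (i in seq_len(nrow(cen))) {
        ch <- cen$chrom[i]
        w <- cen$end[i] - cen$start[i] + 1L
        seqs[ch] <- paste0(substr(seqs[ch], 1L, cen$start[i] - 1L),
                           strrep("N", w),
                           substr(seqs[ch], cen$end[i] + 1L, nchar(seqs[ch])))
        ltr <- sim$annotations$ltr
        drop <- ltr$chrom == ch & ltr$start >= cen$start[i] & ltr$end <= cen$end[i]
        sim$annotations$ltr <- ltr[!drop, , drop = FALSE]
        sim$truth$ltr_intervals <- sim$annotations$ltr
      }
      sim$truth$centromeres <- cen[0, , drop = FALSE]
    }

    if (inversion_count > 0) {
      chroms <- names(seqs)
      for (k in seq_len(inversion_count)) {
        done <- FALSE
        for (try in seq_len(max_retries)) {
          ch <- chroms[(k + try - 2L) %% length(chroms) + 1L]
          forbidden <- rbind(junction_intervals(junctions),
                            sim$truth$inversions[, c("chrom", "start", "end")],
                            fixed_feature_intervals(sim))
          run <- sample_gene_run(sim, ch, sample(4:8, 1L), forbidden)
          if (!is.null(run)) {
            res <- apply_gene_run_inversion(sim, seqs, ch, run)
            sim <- res$sim; seqs <- res$seqs
            done <- TRUE
            break
          }
        }
        if (!done)
          stopf("could not place inversion %d without overlapping a collapsed region", k)
      }
    }

    sim$annotations$genes <- gene_ranks(sim$annotations$genes)
    sim$genome <- Biostrings::DNAStringSet(seqs)
    sim
  })
}

empty_junctions <- function() {
  data.frame(chrom = character(), pos = integer(), stringsAsFactors = FALSE)
}

junction_intervals <- function(junctions) {
  if (nrow(junctions) == 0L) return(empty_intervals_df())
  data.frame(chrom = junctions$chrom, start = junctions$pos,
             end = junctions$pos, stringsAsFactors = FALSE)
}

# telomere and centromere/pericentromere intervals, which an inversion must
# never straddle (a gene run crossing the centromere is not a plausible
# scaffold mis-orientation)
fixed_feature_intervals <- function(sim) {
  rbind(sim$truth$telomeres[, c("chrom", "start", "end")],
        sim$truth$centromeres[, c("chrom", "start", "end")])
}

# ---- diverged ortholog genome ----------------------------------------------

#' Generate a diverged ortholog genome (a synthetic second species)
#'
#' Mutates the whole genome at a uniform substitution rate, preserves gene
#' order, and then applies lineage-specific edits: tandem-array expansions or
#' contractions and planted inversions of gene runs. Chromosomes and genes are
#' renamed with `prefix` and the gene-level orthology map is recorded in the
#' truth ledger.
#'
#' @param sim a `sim_genome`.
#' @param substitution_rate per-base substitution probability.
#' @param inversion_count planted inversions (runs of 5-8 genes, each flanked
#'   by at least 5 collinear genes so both orientations are recoverable).
#' @param lineage_array_spec list of `list(array_id =, new_size =)` entries;
#'   `new_size` below the current size contracts the array (members excised),
#'   above it expands it (extra mutated copies inserted after the last member).
#' @param prefix name prefix for the new species' chromosomes and genes.
#' @param seed integer seed.
#' @return a `sim_genome` for the second species; `truth$ortholog_map` holds
#'   the gene id correspondence (contracted members and inserted copies are
#'   unmapped).
#' @export
generate_ortholog_genome <- function(sim, substitution_rate = 0.06,
                                     inversion_count = 0,
                                     lineage_array_spec = list(),
                                     prefix = "b", seed = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  assert_fraction(substitution_rate, "substitution_rate")
  with_seed(seed, {
    old_names <- names(sim$genome)
    new_names <- paste0(prefix, "_", old_names)
    seqs <- setNames(vapply(as.character(sim$genome), function(s)
      paste(mutate_bases(strsplit(s, "", fixed = TRUE)[[1]], substitution_rate),
            collapse = ""), character(1), USE.NAMES = FALSE), new_names)

    b <- sim
    rn <- function(x) new_names[match(x, old_names)]
    b$annotations$genes$chrom <- rn(b$annotations$genes$chrom)
    old_ids <- b$annotations$genes$gene_id
    b$annotations$genes$gene_id <- paste0(prefix, "_", old_ids)
    for (tb in c("ltr")) b$annotations[[tb]]$chrom <- rn(b$annotations[[tb]]$chrom)
    for (tb in c("telomeres", "centromeres", "ltr_intervals", "inversions"))
      if (nrow(b$truth[[tb]])) b$truth[[tb]]$chrom <- rn(b$truth[[tb]]$chrom)
    b$truth$inversions <- b$truth$inversions[0, , drop = FALSE]
    b$truth$tandem_arrays$chrom <- rn(b$truth$tandem_arrays$chrom)
    b$truth$tandem_arrays$members <-
      I(lapply(b$truth$tandem_arrays$members, function(m) paste0(prefix, "_", m)))
    omap <- data.frame(gene_a = old_ids, gene_b = paste0(prefix, "_", old_ids),
                       stringsAsFactors = FALSE)

    for (spec in lineage_array_spec) {
      aid <- spec$array_id
      new_size <- spec$new_size
      ta <- b$truth$tandem_arrays
      if (!aid %in% ta$array_id) stopf("unknown array id '%s'", aid)
      cur <- ta$size[ta$array_id == aid]
      if (new_size < cur) {
        m <- ordered_members(b, aid)
        removed <- m$gene_id[(new_size + 1L):nrow(m)]
        res <- collapse_array(b, seqs, aid, new_size)
        b <- res$sim; seqs <- res$seqs
        omap <- omap[!omap$gene_b %in% removed, , drop = FALSE]
      } else if (new_size > cur) {
        m <- ordered_members(b, aid)
        last <- m[nrow(m), ]
        ch <- last$chrom
        glen <- last$end - last$start + 1L
        member_seq <- substr(seqs[ch], last$start, last$end)
        ins_pieces <- character(0)
        new_rows <- list()
        cur_off <- 0L
        for (k in seq_len(new_size - cur)) {
          spacer <- random_dna(300L)
          copy <- mutate_dna(member_seq, 0.02)
          ins_pieces <- c(ins_pieces, spacer, copy)
          new_rows[[k]] <- data.frame(
            gene_id = sprintf("%s_x%d", last$gene_id, k),
            chrom = ch,
            start = last$end + cur_off + 300L + 1L,
            end = last$end + cur_off + 300L + glen,
            strand = last$strand, family_id = last$family_id,
            rank = NA_real_, stringsAsFactors = FALSE)
          cur_off <- cur_off + 300L + glen
        }
        ins_w <- cur_off
        b <- remap_state(b, ch, function(p) ifelse(p > last$end, p + ins_w, p))
        seqs[ch] <- insert_into_seq(seqs[ch], last$end,
                                    paste(ins_pieces, collapse = ""))
        b$annotations$genes <- rbind(b$annotations$genes, do.call(rbind, new_rows))
        i <- b$truth$tandem_arrays$array_id == aid
        b$truth$tandem_arrays$size[i] <- new_size
        b$truth$tandem_arrays$members[i] <-
          list(c(m$gene_id, vapply(new_rows, function(r) r$gene_id, character(1))))
      }
    }

    if (inversion_count > 0) {
      chroms <- new_names
      for (k in seq_len(inversion_count)) {
        done <- FALSE
        for (try in seq_len(100L)) {
          ch <- chroms[(k + try - 2L) %% length(chroms) + 1L]
          forbidden <- rbind(b$truth$inversions[, c("chrom", "start", "end")],
                             fixed_feature_intervals(b))
          run <- sample_gene_run(b, ch, sample(6:9, 1L), forbidden, flank = 5L)
          if (!is.null(run)) {
            res <- apply_gene_run_inversion(b, seqs, ch, run)
            b <- res$sim; seqs <- res$seqs
            done <- TRUE
            break
          }
        }
        if (!done) stopf("could not place ortholog inversion %d", k)
      }
    }

    b$annotations$genes <- gene_ranks(b$annotations$genes)
    b$genome <- Biostrings::DNAStringSet(seqs)
    b$truth$ortholog_map <- omap
    b
  })
}
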