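# Collinear synteny: anchor selection, block chaining by rank-gap-bounded
# monotone chains, syntenic depth, dot-plot and microsynteny layouts, and
# conserved vs lineage-specific tandem arrays.

#' Select syntenic anchor pairs from homology hits
#'
#' Keeps, for every query and subject gene, its `top_k` hits by bit score
#' (ties broken by e-value then id, so the result is independent of hit
#' order) and reports the pairs that survive in both directions. With
#' `top_k = 1` the anchors form a partial matching (reciprocal best hits).
#'
#' @param genes_a,genes_b gene tables of the two genomes.
#' @param hits hit table; both hit directions are understood.
#' @param e_value_max e-value cutoff.
#' @param top_k hits retained per gene.
#' @return data.frame with columns `gene_a`, `gene_b`, `bit_score`,
#'   `e_value`.
#' @export
anchor_pairs <- function(genes_a, genes_b, hits, e_value_max = 1e-5,
                         top_k = 1) {
  if (nrow(hits) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  in_a <- hits$query %in% genes_a$gene_id & hits$subject %in% genes_b$gene_id
  in_b <- hits$query %in% genes_b$gene_id & hits$subject %in% genes_a$gene_id
  pairs <- rbind(
    data.frame(gene_a = hits$query[in_a], gene_b = hits$subject[in_a],
               bit_score = hits$bit_score[in_a], e_value = hits$e_value[in_a],
               stringsAsFactors = FALSE),
    data.frame(gene_a = hits$subject[in_b], gene_b = hits$query[in_b],
               bit_score = hits$bit_score[in_b], e_value = hits$e_value[in_b],
               stringsAsFactors = FALSE))
  pairs <- pairs[pairs$e_value <= e_value_max, , drop = FALSE]
  if (nrow(pairs) == 0L) return(pairs)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b, -pairs$bit_score), ,
                 drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("gene_a", "gene_b")]), , drop = FALSE]
  ord <- order(-pairs$bit_score, pairs$e_value, pairs$gene_a, pairs$gene_b)
  pairs <- pairs[ord, , drop = FALSE]
  keep_a <- stats::ave(seq_len(nrow(pairs)), pairs$gene_a,
                       FUN = seq_along) <= top_k
  keep_b <- stats::ave(seq_len(nrow(pairs)), pairs$gene_b,
                       FUN = seq_along) <= top_k
  out <- pairs[keep_a & keep_b, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain anchors into collinear synteny blocks
#'
#' Within each chromosome pair, maximal-scoring chains of anchors are found
#' by longest increasing (forward) or decreasing (inverted) subsequence
#' dynamic programming on gene-rank pairs: each anchor contributes +1 and
#' rank gaps are linearly penalised, with consecutive anchors at most
#' `max_rank_gap` ranks apart in both genomes. Chains are extracted greedily
#' by score, their anchors removed, and the search repeated; chains with
#' fewer than `min_anchors` anchors are discarded, and no anchor belongs to
#' two blocks.
#'
#' @param anchors data.frame from [anchor_pairs()] (columns `gene_a`,
#'   `gene_b`).
#' @param genes_a,genes_b gene tables (ranks recomputed internally).
#' @param min_anchors minimum anchors per block (5, the usual collinearity
#'   default).
#' @param max_rank_gap maximum rank gap between consecutive anchors (25).
#' @param gap_penalty score penalty per skipped rank.
#' @return data.frame of class `synteny_blocks`, one row per block:
#'   `block_id`, `chrom_a`, `chrom_b`, `orientation` (`forward`/`inverted`),
#'   `n_anchors`, `span_a_start`, `span_a_end`, `span_b_start`,
#'   `span_b_end`, and `anchors` (list column of gene_a/gene_b data.frames
#'   ordered along genome a).
#' @export
chain_blocks <- function(anchors, genes_a, genes_b, min_anchors = 5,
                         max_rank_gap = 25, gap_penalty = 0.05) {
  empty <- data.frame(block_id = character(), chrom_a = character(),
                      chrom_b = character(), orientation = character(),
                      n_anchors = integer(), span_a_start = integer(),
                      span_a_end = integer(), span_b_start = integer(),
                      span_b_end = integer(), stringsAsFactors = FALSE)
  empty$anchors <- I(list())
  if (nrow(anchors) == 0L) return(structure(empty, class = c("synteny_blocks",
                                                             "data.frame")))
  ga <- gene_ranks(genes_a)
  gb <- gene_ranks(genes_b)
  ia <- match(anchors$gene_a, ga$gene_id)
  ib <- match(anchors$gene_b, gb$gene_id)
  if (anyNA(ia) || anyNA(ib)) stopf("anchors reference unknown genes")
  tbl <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                    chrom_a = ga$chrom[ia], chrom_b = gb$chrom[ib],
                    ra = ga$rank[ia], rb = gb$rank[ib],
                    sa = ga$start[ia], ea = ga$end[ia],
                    sb = gb$start[ib], eb = gb$end[ib],
                    stringsAsFactors = FALSE)
  blocks <- list()
  for (key in unique(paste(tbl$chrom_a, tbl$chrom_b, sep = "\r"))) {
    sub <- tbl[paste(tbl$chrom_a, tbl$chrom_b, sep = "\r") == key, ,
               drop = FALSE]
    repeat {
      best <- NULL
      for (orient in c("forward", "inverted")) {
        ch <- best_chain(sub$ra, if (orient == "forward") sub$rb else -sub$rb,
                         max_rank_gap, gap_penalty)
        if (!is.null(ch) &&
            (is.null(best) || ch$score > best$score)) {
          best <- ch
          best$orientation <- orient
        }
      }
      if (is.null(best) || length(best$idx) < min_anchors) break
      m <- sub[best$idx, , drop = FALSE]
      m <- m[order(m$ra), , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom_a = m$chrom_a[1], chrom_b = m$chrom_b[1],
        orientation = best$orientation, n_anchors = nrow(m),
        span_a_start = min(m$sa), span_a_end = max(m$ea),
        span_b_start = min(m$sb), span_b_end = max(m$eb),
        anchors = I(list(m[, c("gene_a", "gene_b", "ra", "rb")])),
        stringsAsFactors = FALSE)
      sub <- sub[-best$idx, , drop = FALSE]
      if (nrow(sub) < min_anchors) break
    }
  }
  if (length(blocks) == 0L)
    return(structure(empty, class = c("synteny_blocks", "data.frame")))
  res <- do.call(rbind, blocks)
  res <- res[order(res$chrom_a, res$span_a_start), , drop = FALSE]
  res <- cbind(block_id = sprintf("blk%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("synteny_blocks", "data.frame"))
}

# best-scoring chain with strictly increasing x and y, rank gaps bounded by
# max_gap, score = n_anchors - penalty * skipped ranks
best_chain <- function(x, y, max_gap, penalty) {
  n <- length(x)
  if (n == 0L) return(NULL)
  ord <- order(x, y)
  xs <- x[ord]; ys <- y[ord]
  dp <- rep(1, n)
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      gx <- xs[j] - xs[i]
      gy <- ys[j] - ys[i]
      if (gx > 0L && gy > 0L && gx <= max_gap && gy <= max_gap) {
        cand <- dp[i] + 1 - penalty * (gx - 1L + gy - 1L)
        if (cand > dp[j]) {
          dp[j] <- cand
          prev[j] <- i
        }
      }
    }
  }
  jbest <- which.max(dp)
  idx <- integer()
  j <- jbest
  while (j != 0L) {
    idx <- c(j, idx)
    j <- prev[j]
  }
  list(idx = ord[idx], score = dp[jbest])
}

#' Syntenic depth profile of a block set
#'
#' For each block, counts how many block spans (including its own) cover its
#' span in each genome; a block is 1:1 when both its spans are covered
#' exactly once. Reports the block-wise fraction of 1:1 blocks and, since
#' the denominator convention differs between tools, also the base-wise
#' fraction (block-covered bases at depth 1). Both are symmetric under
#' swapping the genomes.
#'
#' @param blocks a `synteny_blocks` data.frame.
#' @return list with `per_block` (block id, `depth_a`, `depth_b`,
#'   `one_to_one`), `fraction_1to1` (percent of blocks), and
#'   `fraction_1to1_bases` (percent of covered bases).
#' @export
syntenic_depth <- function(blocks) {
  if (nrow(blocks) == 0L)
    return(list(per_block = data.frame(), fraction_1to1 = NA_real_,
                fraction_1to1_bases = NA_real_))
  depth_of <- function(chr, s, e) {
    vapply(seq_along(s), function(i)
      sum(chr == chr[i] & e >= s[i] & s <= e[i]), integer(1))
  }
  da <- depth_of(blocks$chrom_a, blocks$span_a_start, blocks$span_a_end)
  db <- depth_of(blocks$chrom_b, blocks$span_b_start, blocks$span_b_end)
  per_block <- data.frame(block_id = blocks$block_id, depth_a = da,
                          depth_b = db, one_to_one = da == 1L & db == 1L,
                          stringsAsFactors = FALSE)
  base_frac <- function(chr, s, e) {
    tot <- 0; single <- 0
    for (ch in unique(chr)) {
      sel <- chr == ch
      cov <- IRanges::coverage(IRanges::IRanges(s[sel], e[sel]))
      rl <- S4Vectors::runLength(cov)
      rv <- S4Vectors::runValue(cov)
      tot <- tot + sum(rl[rv >= 1])
      single <- single + sum(rl[rv == 1])
    }
    100 * single / tot
  }
  list(per_block = per_block,
       fraction_1to1 = 100 * mean(per_block$one_to_one),
       fraction_1to1_bases = mean(c(
         base_frac(blocks$chrom_a, blocks$span_a_start, blocks$span_a_end),
         base_frac(blocks$chrom_b, blocks$span_b_start, blocks$span_b_end))))
}

#' Dot-plot coordinate table of a block set
#'
#' One row per anchor with the genomic midpoints of the paired genes,
#' suitable for a macrosynteny dot plot.
#'
#' @param blocks a `synteny_blocks` data.frame.
#' @param genes_a,genes_b gene tables supplying coordinates.
#' @return data.frame with `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `block_id`, `orientation`.
#' @export
dotplot_table <- function(blocks, genes_a, genes_b) {
  if (nrow(blocks) == 0L)
    return(data.frame(chrom_a = character(), pos_a = numeric(),
                      chrom_b = character(), pos_b = numeric(),
                      block_id = character(), orientation = character(),
                      stringsAsFactors = FALSE))
  mid <- function(g) setNames((g$start + g$end) / 2, g$gene_id)
  ma <- mid(genes_a); mb <- mid(genes_b)
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    an <- blocks$anchors[[i]]
    data.frame(chrom_a = blocks$chrom_a[i], pos_a = unname(ma[an$gene_a]),
               chrom_b = blocks$chrom_b[i], pos_b = unname(mb[an$gene_b]),
               block_id = blocks$block_id[i],
               orientation = blocks$orientation[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify tandem arrays as syntenically conserved or lineage-specific
#'
#' An array of genome A is conserved when at least one member is an anchor
#' of a block and its partner gene belongs to an array of genome B (and vice
#' versa). Arrays on chromosomes absent from all blocks are classified
#' lineage-specific with a warning. Also tallies arrays exceeding
#' `size_threshold` copies in one genome whose anchored partner is a single
#' copy (no array) in the other — the signature of a strong lineage-specific
#' expansion.
#'
#' @param arrays_a,arrays_b array tables from [call_tandem_arrays()].
#' @param blocks a `synteny_blocks` data.frame.
#' @param size_threshold copy-number threshold for the expansion tally
#'   (strictly greater than; 10 by default).
#' @return list: `conserved` (array_a, array_b, size_a, size_b),
#'   `specific_a`, `specific_b` (array ids), `n_conserved`, `n_specific`,
#'   `big_vs_single_a`, `big_vs_single_b` (counts), `size_pairs`.
#' @export
classify_syntenic_arrays <- function(arrays_a, arrays_b, blocks,
                                     size_threshold = 10) {
  anchor_map <- if (nrow(blocks))
    do.call(rbind, lapply(blocks$anchors, function(a)
      a[, c("gene_a", "gene_b")]))
  else data.frame(gene_a = character(), gene_b = character())
  member_of <- function(arrays) {
    if (nrow(arrays) == 0L)
      return(setNames(character(0), character(0)))
    setNames(rep(arrays$array_id, arrays$size), unlist(arrays$members))
  }
  in_b <- member_of(arrays_b)
  in_a <- member_of(arrays_a)
  blk_chroms_a <- unique(blocks$chrom_a)
  blk_chroms_b <- unique(blocks$chrom_b)

  classify_side <- function(arrays, map_from, map_to, other_member,
                            blk_chroms) {
    conserved <- list(); specific <- character(); big_single <- 0L
    for (i in seq_len(nrow(arrays))) {
      if (!arrays$chrom[i] %in% blk_chroms) {
        warning(sprintf("array %s lies on chromosome %s absent from blocks",
                        arrays$array_id[i], arrays$chrom[i]))
        specific <- c(specific, arrays$array_id[i])
        next
      }
      partners <- map_to[match(arrays$members[[i]], map_from)]
      partners <- partners[!is.na(partners)]
      hit <- other_member[partners]
      hit <- hit[!is.na(hit)]
      if (length(hit)) {
        conserved[[length(conserved) + 1L]] <- data.frame(
          array = arrays$array_id[i], partner_array = hit[1],
          size = arrays$size[i], stringsAsFactors = FALSE)
      } else {
        specific <- c(specific, arrays$array_id[i])
        if (arrays$size[i] > size_threshold && length(partners) > 0L)
          big_single <- big_single + 1L
      }
    }
    list(conserved = if (length(conserved)) do.call(rbind, conserved) else
      data.frame(array = character(), partner_array = character(),
                 size = integer(), stringsAsFactors = FALSE),
      specific = specific, big_single = big_single)
  }

  side_a <- classify_side(arrays_a, anchor_map$gene_a, anchor_map$gene_b,
                          in_b, blk_chroms_a)
  side_b <- classify_side(arrays_b, anchor_map$gene_b, anchor_map$gene_a,
                          in_a, blk_chroms_b)
  size_b_of <- setNames(arrays_b$size, arrays_b$array_id)
  conserved <- side_a$conserved
  names(conserved) <- c("array_a", "array_b", "size_a")
  conserved$size_b <- unname(size_b_of[conserved$array_b])
  list(conserved = conserved,
       specific_a = side_a$specific, specific_b = side_b$specific,
       n_conserved = nrow(conserved),
       n_specific = length(side_a$specific) + length(side_b$specific),
       big_vs_single_a = side_a$big_single,
       big_vs_single_b = side_b$big_single,
       size_pairs = conserved[, c("size_a", "size_b")])
}

#' Gene-level microsynteny layout for a region
#'
#' Orders the genes of a region in genome A together with the genes of the
#' syntenic partner region in genome B, marking the anchor pairing; unpaired
#' genes (for example extra members of an expanded array) carry `NA`
#' partners.
#'
#' @param region_a list/row with `chrom`, `start`, `end` in genome A.
#' @param blocks a `synteny_blocks` data.frame.
#' @param genes_a,genes_b gene tables.
#' @return data.frame with `genome` (`"a"`/`"b"`), `gene_id`, `start`,
#'   `end`, `strand`, `partner`, `paired`; zero rows (with a message) when
#'   the region overlaps no block.
#' @export
microsynteny_view <- function(region_a, blocks, genes_a, genes_b) {
  hit <- blocks[blocks$chrom_a == region_a$chrom &
                  blocks$span_a_end >= region_a$start &
                  blocks$span_a_start <= region_a$end, , drop = FALSE]
  if (nrow(hit) == 0L) {
    message("region overlaps no synteny block")
    return(data.frame(genome = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), partner = character(),
                      paired = logical(), stringsAsFactors = FALSE))
  }
  amap <- do.call(rbind, lapply(hit$anchors, function(a)
    a[, c("gene_a", "gene_b")]))
  ga <- genes_a[genes_a$chrom == region_a$chrom &
                  genes_a$end >= region_a$start &
                  genes_a$start <= region_a$end, , drop = FALSE]
  ga <- ga[order(ga$start), , drop = FALSE]
  partner <- amap$gene_b[match(ga$gene_id, amap$gene_a)]
  pg <- genes_b[genes_b$gene_id %in% partner[!is.na(partner)], , drop = FALSE]
  # partner region: all genome-b genes between the outermost partners
  if (nrow(pg)) {
    chb <- pg$chrom[1]
    gb <- genes_b[genes_b$chrom == chb &
                    genes_b$end >= min(pg$start) &
                    genes_b$start <= max(pg$end), , drop = FALSE]
    gb <- gb[order(gb$start), , drop = FALSE]
  } else {
    gb <- genes_b[0, , drop = FALSE]
  }
  back <- amap$gene_a[match(gb$gene_id, amap$gene_b)]
  back[!back %in% ga$gene_id] <- NA
  rbind(
    data.frame(genome = "a", gene_id = ga$gene_id, start = ga$start,
               end = ga$end, strand = ga$strand, partner = partner,
               paired = !is.na(partner), stringsAsFactors = FALSE),
    data.frame(genome = "b", gene_id = gb$gene_id, start = gb$start,
               end = gb$end, strand = gb$strand, partner = back,
               paired = !is.na(back), stringsAsFactors = FALSE))
}
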