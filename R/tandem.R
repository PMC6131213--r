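# Tandem gene array calling and cross-assembly comparison.

#' Call tandem gene arrays from gene order and homology hits
#'
#' Implements the classic tandem-duplicate rule: two genes are tandem-linked
#' when they lie on the same chromosome, their hit passes the e-value cutoff,
#' and their gene-order ranks differ by at most `max_gene_distance` genes.
#' Arrays are the single-linkage connected components of that graph (so a
#' pair beyond the distance limit can still join one array through an
#' intermediate member), restricted to components of two or more genes.
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, ...); ranks are
#'   (re)computed with [gene_ranks()].
#' @param hits homology hit table (`query`, `subject`, `e_value`); self-hits
#'   and duplicate pairs are dropped, hit direction is ignored.
#' @param e_value_max maximum e-value for a qualifying hit (1e-5 by default).
#' @param max_gene_distance maximum rank difference for a qualifying pair
#'   (10 by default).
#' @return data.frame with one row per array: `array_id`, `chrom`, `size`,
#'   and `members` (list column of gene ids ordered by rank), sorted by
#'   chromosome and first member.
#' @export
call_tandem_arrays <- function(genes, hits, e_value_max = 1e-5,
                               max_gene_distance = 10) {
  genes <- gene_ranks(genes)
  unknown <- setdiff(unique(c(hits$query, hits$subject)), genes$gene_id)
  if (length(unknown))
    stopf("hits reference unknown gene ids: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  h <- hits[hits$e_value <= e_value_max & hits$query != hits$subject, ,
            drop = FALSE]
  if (nrow(h)) {
    # canonical undirected pairs, deduplicated
    a <- pmin(h$query, h$subject)
    b <- pmax(h$query, h$subject)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    a <- a[keep]; b <- b[keep]
    ia <- match(a, genes$gene_id)
    ib <- match(b, genes$gene_id)
    ok <- genes$chrom[ia] == genes$chrom[ib] &
      abs(genes$rank[ia] - genes$rank[ib]) <= max_gene_distance
    ia <- ia[ok]; ib <- ib[ok]
  } else {
    ia <- ib <- integer()
  }
  comp <- union_find_components(nrow(genes), ia, ib)
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes >= 2L])
  rows <- lapply(big, function(cc) {
    m <- genes[comp == cc, , drop = FALSE]
    m <- m[order(m$rank), , drop = FALSE]
    data.frame(chrom = m$chrom[1], size = nrow(m),
               first_rank = m$rank[1], stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    out <- data.frame(array_id = character(), chrom = character(),
                      size = integer(), stringsAsFactors = FALSE)
    out$members <- I(list())
    return(out)
  }
  out <- do.call(rbind, rows)
  out$members <- I(lapply(big, function(cc) {
    m <- genes[comp == cc, , drop = FALSE]
    m$gene_id[order(m$rank)]
  }))
  out <- out[order(out$chrom, out$first_rank), , drop = FALSE]
  out$array_id <- sprintf("arr%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("array_id", "chrom", "size", "members")]
}

# iterative union-find with path halving
union_find_components <- function(n, ia, ib) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Compare tandem arrays between two assemblies of the same genome
#'
#' Arrays of the new assembly are matched to arrays of the old assembly by
#' largest shared (mapped) membership, ties broken by chromosome and
#' position. Gene models are classified shared / old-only / new-only from
#' the gene map, and new arrays with no mapped member hitting any old gene
#' are counted as novel.
#'
#' @param arrays_old,arrays_new array tables from [call_tandem_arrays()].
#' @param gene_map data.frame with columns `old_id`, `new_id` linking gene
#'   models of the two annotations (best reciprocal homology, or simulator
#'   truth).
#' @param genes_old,genes_new optional full gene tables used for the
#'   gene-model Venn counts; defaults to genes appearing in arrays/map.
#' @return list of class `assembly_comparison`: `matched` (old/new sizes and
#'   `delta = new - old` per matched array), `novel_new_arrays`,
#'   `pct_novel_arrays`, `pct_novel_genes`, and `venn` (shared, old_only,
#'   new_only gene-model counts).
#' @export
compare_assemblies <- function(arrays_old, arrays_new, gene_map,
                               genes_old = NULL, genes_new = NULL) {
  old_of <- setNames(gene_map$old_id, gene_map$new_id)
  member_index <- function(arrays) {
    if (nrow(arrays) == 0L) return(data.frame(gene = character(),
                                              array = character()))
    data.frame(gene = unlist(arrays$members),
               array = rep(arrays$array_id, arrays$size),
               stringsAsFactors = FALSE)
  }
  mi_old <- member_index(arrays_old)
  mi_new <- member_index(arrays_new)
  rows <- list()
  novel <- character()
  for (i in seq_len(nrow(arrays_new))) {
    mem <- arrays_new$members[[i]]
    mapped <- old_of[mem]
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped) == 0L) {
      novel <- c(novel, arrays_new$array_id[i])
      next
    }
    hit_arrays <- mi_old$array[match(mapped, mi_old$gene)]
    hit_arrays <- hit_arrays[!is.na(hit_arrays)]
    if (length(hit_arrays) == 0L) {
      # members map to old genes but none sits in an old array: the array as
      # a unit is new, though its genes are not novel
      rows[[length(rows) + 1L]] <- data.frame(
        new_array = arrays_new$array_id[i], old_array = NA_character_,
        chrom = arrays_new$chrom[i], old_size = length(unique(mapped)),
        new_size = arrays_new$size[i],
        delta = arrays_new$size[i] - length(unique(mapped)),
        stringsAsFactors = FALSE)
      next
    }
    tab <- sort(table(hit_arrays), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) {
      # tie: prefer same chromosome, then leftmost
      cand <- arrays_old[arrays_old$array_id %in% best, , drop = FALSE]
      cand <- cand[order(cand$chrom != arrays_new$chrom[i],
                         vapply(cand$members, function(m) m[1], character(1))), ]
      best <- cand$array_id[1]
    }
    old_size <- arrays_old$size[arrays_old$array_id == best]
    rows[[length(rows) + 1L]] <- data.frame(
      new_array = arrays_new$array_id[i], old_array = best,
      chrom = arrays_new$chrom[i], old_size = old_size,
      new_size = arrays_new$size[i], delta = arrays_new$size[i] - old_size,
      stringsAsFactors = FALSE)
  }
  matched <- if (length(rows)) do.call(rbind, rows) else
    data.frame(new_array = character(), old_array = character(),
               chrom = character(), old_size = integer(),
               new_size = integer(), delta = integer(),
               stringsAsFactors = FALSE)

  old_universe <- if (!is.null(genes_old)) genes_old$gene_id else
    unique(c(gene_map$old_id, mi_old$gene))
  new_universe <- if (!is.null(genes_new)) genes_new$gene_id else
    unique(c(gene_map$new_id, mi_new$gene))
  shared_new <- new_universe[new_universe %in% gene_map$new_id &
                               old_of[new_universe] %in% old_universe]
  venn <- c(shared = length(shared_new),
            old_only = sum(!old_universe %in% gene_map$old_id[
              gene_map$new_id %in% new_universe]),
            new_only = length(new_universe) - length(shared_new))
  novel_genes <- unlist(arrays_new$members[arrays_new$array_id %in% novel])
  structure(list(matched = matched,
                 novel_new_arrays = novel,
                 pct_novel_arrays = if (nrow(arrays_new))
                   100 * length(novel) / nrow(arrays_new) else NA_real_,
                 pct_novel_genes = if (nrow(mi_new))
                   100 * length(novel_genes) / nrow(mi_new) else NA_real_,
                 venn = venn),
            class = "assembly_comparison")
}

#' Mean percent copy gain for a size class of arrays
#'
#' Mean over matched arrays whose *new* size falls in `[class_min,
#' class_max]` of `100 * (new - old) / old`.
#'
#' @param comparison an `assembly_comparison` from [compare_assemblies()].
#' @param class_min,class_max size-class bounds on the new array size
#'   (`class_max = Inf` for an open class such as "more than 10").
#' @return mean percent gain; `numeric(0)` when the class is empty.
#' @export
size_class_gain <- function(comparison, class_min, class_max = Inf) {
  m <- comparison$matched
  m <- m[!is.na(m$old_array) & m$new_size >= class_min &
           m$new_size <= class_max & m$old_size > 0, , drop = FALSE]
  if (nrow(m) == 0L) return(numeric(0))
  mean(100 * (m$new_size - m$old_size) / m$old_size)
}
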