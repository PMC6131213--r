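#' Simulation configuration for synthetic genomes
#'
#' Describes the "stated world" of a synthetic chromosome set: terminal
#' telomere tracks, one centromeric satellite array per chromosome built from
#' a fixed-length monomer with a given per-base divergence, pericentromeric
#' LTR-dense fields, and gene models including tandem gene arrays. All
#' downstream detectors are exercised against genomes generated from such a
#' configuration, with every planted feature recorded in a ground-truth
#' ledger.
#'
#' Coordinates throughout the package are 1-based inclusive (the R/Bioconductor
#' convention); GFF3 output is written as-is and BED output converts to
#' 0-based half-open.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param telomere_motif telomeric repeat unit (plant consensus `TTTAGGG`).
#' @param telomere_copies tandem copies planted per telomere track.
#' @param telomere_ends which ends carry a track, per chromosome: one of
#'   `"both"`, `"left"`, `"right"`, `"none"`; recycled to `n_chromosomes`.
#' @param centromere_monomer_length satellite monomer length in bp (317 by
#'   default, the length characteristic of the Rubus-type centromeric repeat).
#' @param centromere_copy_range integer min/max of monomer copies per array.
#' @param monomer_divergence per-base substitution probability applied to each
#'   planted monomer copy (0.11 yields ~89% identity to the consensus).
#' @param ltr_field_density target fraction of pericentromeric bases covered
#'   by LTR retrotransposon annotations.
#' @param pericentromere_width width (bp) of the LTR-dense field on each side
#'   of the satellite array.
#' @param n_genes_per_chrom number of singleton gene models per chromosome
#'   (tandem-array members are additional).
#' @param gene_length_range min/max gene length in bp.
#' @param tandem_array_spec list of `c(size, divergence)` pairs; each spawns
#'   one tandem gene array of `size` members mutated at `divergence` from a
#'   common progenitor, distributed round-robin across chromosomes.
#' @param no_centromere_chrom index of one chromosome to plant *without* a
#'   centromeric array (only `stray_monomers` isolated monomers and no
#'   pericentromeric field), or `NA` for none.
#' @param stray_monomers isolated monomer copies planted on the
#'   centromere-free chromosome.
#' @param seed integer seed; a fixed seed and configuration give byte-identical
#'   outputs.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_chromosomes = 3,
                              chrom_length = 400000,
                              telomere_motif = "TTTAGGG",
                              telomere_copies = 40,
                              telomere_ends = "both",
                              centromere_monomer_length = 317,
                              centromere_copy_range = c(110, 300),
                              monomer_divergence = 0.11,
                              ltr_field_density = 0.9,
                              pericentromere_width = 50000,
                              n_genes_per_chrom = 30,
                              gene_length_range = c(600, 1500),
                              tandem_array_spec = list(c(26, 0.05), c(10, 0.05),
                                                       c(5, 0.05), c(3, 0.05),
                                                       c(2, 0.05)),
                              no_centromere_chrom = NA_integer_,
                              stray_monomers = 4,
                              seed = 1) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              telomere_motif = toupper(telomere_motif),
              telomere_copies = as.integer(telomere_copies),
              telomere_ends = rep_len(telomere_ends, n_chromosomes),
              centromere_monomer_length = as.integer(centromere_monomer_length),
              centromere_copy_range = as.integer(centromere_copy_range),
              monomer_divergence = monomer_divergence,
              ltr_field_density = ltr_field_density,
              pericentromere_width = as.integer(pericentromere_width),
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              gene_length_range = as.integer(gene_length_range),
              tandem_array_spec = tandem_array_spec,
              no_centromere_chrom = as.integer(no_centromere_chrom),
              stray_monomers = as.integer(stray_monomers),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_chromosomes < 1L) stopf("n_chromosomes must be >= 1")
  if (cfg$chrom_length < 1L) stopf("chrom_length must be positive")
  if (nchar(cfg$telomere_motif) < 5L) stopf("telomere motif must be >= 5 bp")
  if (cfg$centromere_monomer_length < 10L) stopf("monomer length must be >= 10 bp")
  if (cfg$centromere_copy_range[1] < 1L) stopf("centromere_copy_range minimum must be >= 1")
  if (cfg$centromere_copy_range[2] < cfg$centromere_copy_range[1])
    stopf("centromere_copy_range must be (min, max) with max >= min")
  assert_fraction(cfg$monomer_divergence, "monomer_divergence")
  assert_fraction(cfg$ltr_field_density, "ltr_field_density")
  for (a in cfg$tandem_array_spec) {
    if (length(a) != 2L || a[1] < 1) stopf("tandem_array_spec entries must be c(size, divergence)")
    assert_fraction(a[2], "tandem_array_spec divergence")
  }
  if (!all(cfg$telomere_ends %in% c("both", "left", "right", "none")))
    stopf("telomere_ends must be both/left/right/none")
  # sizing feasibility: planted features must fit inside a chromosome
  tel <- 2L * nchar(cfg$telomere_motif) * cfg$telomere_copies
  cen <- cfg$centromere_copy_range[2] * cfg$centromere_monomer_length
  peri <- 2L * cfg$pericentromere_width
  gene_max <- cfg$gene_length_range[2]
  arr_bases <- sum(vapply(cfg$tandem_array_spec, function(a) a[1], numeric(1))) *
    (gene_max + 600)
  genes <- cfg$n_genes_per_chrom * (gene_max + 200) + arr_bases
  if (tel + cen + peri + genes > cfg$chrom_length)
    stopf("sizing error: planted features (%d bp) exceed chrom_length (%d bp)",
          tel + cen + peri + genes, cfg$chrom_length)
  invisible(cfg)
}

new_truth_set <- function() {
  list(telomeres = data.frame(chrom = character(), end_label = character(),
                              start = integer(), end = integer(),
                              copies = integer(), stringsAsFactors = FALSE),
       centromeres = data.frame(chrom = character(), start = integer(),
                                end = integer(), array_start = integer(),
                                array_end = integer(), copy_number = integer(),
                                stringsAsFactors = FALSE),
       ltr_intervals = empty_intervals_df(),
       tandem_arrays = data.frame(array_id = character(), chrom = character(),
                                  size = integer(), stringsAsFactors = FALSE),
       inversions = empty_intervals_df(),
       collapsed_arrays = data.frame(array_id = character(),
                                     original_size = integer(),
                                     collapsed_size = integer(),
                                     stringsAsFactors = FALSE),
       specific_genes = data.frame(gene_id = character(), tissue = character(),
                                   stringsAsFactors = FALSE),
       monomer = NA_character_)
}

#' Generate a synthetic genome with planted landscape features
#'
#' Builds an i.i.d.-uniform background sequence per chromosome and plants, at
#' known coordinates: terminal telomere tracks (motif tandem on the left end,
#' reverse-complement tandem on the right), one centromeric satellite array of
#' mutated monomer copies flanked by pericentromeric LTR-dense annotation
#' fields, and gene models including tandem gene arrays whose members diverge
#' from a shared progenitor. Every planted feature is recorded in the
#' returned truth set.
#'
#' @param config a [simulation_config()].
#' @return object of class `sim_genome`: list with `genome`
#'   (named [Biostrings::DNAStringSet]), `annotations` (list of `genes` and
#'   `ltr` data.frames), `truth` (planted-feature ledger) and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(cfg) {
  ml <- cfg$centromere_monomer_length
  monomer <- random_dna(ml)
  motif <- cfg$telomere_motif
  tel_unit <- strsplit(motif, "", fixed = TRUE)[[1]]
  tel_rc <- strsplit(revcomp(motif), "", fixed = TRUE)[[1]]
  tel_len <- length(tel_unit) * cfg$telomere_copies
  L <- cfg$chrom_length

  truth <- new_truth_set()
  truth$monomer <- monomer
  genes_all <- list()
  ltr_all <- list()
  seqs <- character(cfg$n_chromosomes)
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))

  # distribute tandem arrays round-robin across chromosomes
  arr_chrom <- if (length(cfg$tandem_array_spec))
    (seq_along(cfg$tandem_array_spec) - 1L) %% cfg$n_chromosomes + 1L else integer()

  for (i in seq_len(cfg$n_chromosomes)) {
    chrom <- chrom_names[i]
    bases <- random_dna_vec(L)
    ends <- cfg$telomere_ends[i]
    tl <- if (ends %in% c("both", "left")) tel_len else 0L
    tr <- if (ends %in% c("both", "right")) tel_len else 0L
    if (tl > 0L) {
      bases[seq_len(tl)] <- rep(tel_unit, cfg$telomere_copies)
      truth$telomeres <- rbind(truth$telomeres,
        data.frame(chrom = chrom, end_label = "left", start = 1L, end = tl,
                   copies = cfg$telomere_copies, stringsAsFactors = FALSE))
    }
    if (tr > 0L) {
      bases[(L - tr + 1L):L] <- rep(tel_rc, cfg$telomere_copies)
      truth$telomeres <- rbind(truth$telomeres,
        data.frame(chrom = chrom, end_label = "right", start = L - tr + 1L,
                   end = L, copies = cfg$telomere_copies, stringsAsFactors = FALSE))
    }

    has_cen <- !(!is.na(cfg$no_centromere_chrom) && i == cfg$no_centromere_chrom)
    if (has_cen) {
      copies <- sample(cfg$centromere_copy_range[1]:cfg$centromere_copy_range[2], 1L)
      alen <- copies * ml
      cen_start <- (L - alen) %/% 2L + 1L
      cen_end <- cen_start + alen - 1L
      arr <- unlist(lapply(seq_len(copies), function(k)
        mutate_bases(strsplit(monomer, "", fixed = TRUE)[[1]], cfg$monomer_divergence)))
      bases[cen_start:cen_end] <- arr
      peri_l <- c(cen_start - cfg$pericentromere_width, cen_start - 1L)
      peri_r <- c(cen_end + 1L, cen_end + cfg$pericentromere_width)
      ltr <- rbind(plant_ltr_field(chrom, peri_l[1], peri_l[2], cfg$ltr_field_density),
                   plant_ltr_field(chrom, peri_r[1], peri_r[2], cfg$ltr_field_density))
      ltr_all[[chrom]] <- ltr
      truth$centromeres <- rbind(truth$centromeres,
        data.frame(chrom = chrom, start = peri_l[1], end = peri_r[2],
                   array_start = cen_start, array_end = cen_end,
                   copy_number = copies, stringsAsFactors = FALSE))
      arms <- list(c(tl + 1L, peri_l[1] - 1L), c(peri_r[2] + 1L, L - tr))
    } else {
      # centromere-free chromosome: a few isolated stray monomers, flat LTR
      mid <- L %/% 2L
      if (cfg$stray_monomers > 0L) {
        for (k in seq_len(cfg$stray_monomers)) {
          pos <- mid + (k - (cfg$stray_monomers + 1L) %/% 2L) * 5000L
          bases[pos:(pos + ml - 1L)] <-
            mutate_bases(strsplit(monomer, "", fixed = TRUE)[[1]], cfg$monomer_divergence)
        }
      }
      gap <- cfg$stray_monomers * 5000L + 10000L
      arms <- list(c(tl + 1L, mid - gap %/% 2L), c(mid + gap %/% 2L, L - tr))
    }

    # gene blocks: singleton genes plus this chromosome's tandem arrays
    blocks <- list()
    for (ai in which(arr_chrom == i)) {
      spec <- cfg$tandem_array_spec[[ai]]
      blocks[[length(blocks) + 1L]] <- make_array_block(ai, spec[1], spec[2], cfg)
    }
    for (k in seq_len(cfg$n_genes_per_chrom)) {
      glen <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
      blocks[[length(blocks) + 1L]] <-
        list(type = "single", members = random_dna(glen),
             spacers = character(0), strand = sample(c("+", "-"), 1L))
    }
    blocks <- blocks[sample.int(length(blocks))]
    placed <- place_blocks(chrom, blocks, arms, bases)
    bases <- placed$bases
    g <- placed$genes
    # ids assigned in positional order
    g <- g[order(g$start), , drop = FALSE]
    g$gene_id <- sprintf("%s_g%03d", chrom, seq_len(nrow(g)))
    single <- g$array == ""
    g$family_id <- ifelse(single, paste0("fam_", g$gene_id), paste0("fam_", g$array))
    genes_all[[chrom]] <- g
    seqs[i] <- paste(bases, collapse = "")
  }

  genes <- do.call(rbind, genes_all)
  rownames(genes) <- NULL
  # truth tandem arrays with ordered member ids
  ta <- genes[genes$array != "", , drop = FALSE]
  if (nrow(ta)) {
    sp <- split(ta, ta$array)
    truth$tandem_arrays <- data.frame(
      array_id = names(sp),
      chrom = vapply(sp, function(d) d$chrom[1], character(1)),
      size = vapply(sp, nrow, integer(1)),
      stringsAsFactors = FALSE)
    truth$tandem_arrays$members <- I(lapply(sp, function(d) d$gene_id[order(d$start)]))
    rownames(truth$tandem_arrays) <- NULL
  } else {
    truth$tandem_arrays$members <- I(list())
  }
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "family_id")]
  ltr <- if (length(ltr_all)) do.call(rbind, ltr_all) else empty_intervals_df()
  rownames(ltr) <- NULL
  truth$ltr_intervals <- ltr

  genome <- Biostrings::DNAStringSet(setNames(seqs, chrom_names))
  structure(list(genome = genome,
                 annotations = list(genes = gene_ranks(genes), ltr = ltr),
                 truth = truth, config = cfg),
            class = "sim_genome")
}

# A block is one or more gene bodies plus spacers, planted contiguously. All
# members share the block strand; minus-strand members are planted as the
# reverse complement of their gene sequence, so strand-aware extraction
# recovers the family sequence.
make_array_block <- function(ai, size, divergence, cfg) {
  glen <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
  base <- strsplit(random_dna(glen), "", fixed = TRUE)[[1]]
  members <- vapply(seq_len(size), function(m)
    paste(mutate_bases(base, divergence), collapse = ""), character(1))
  spacers <- if (size > 1L)
    vapply(seq_len(size - 1L), function(m) random_dna(sample(200:600, 1L)),
           character(1)) else character(0)
  list(type = "array", id = sprintf("ta%02d", ai),
       members = members, spacers = spacers,
       strand = sample(c("+", "-"), 1L))
}

plant_ltr_field <- function(chrom, from, to, density) {
  out <- list()
  pos <- from
  while (pos < to) {
    len <- sample(3000:8000, 1L)
    end <- min(pos + len - 1L, to)
    out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = pos, end = end,
                                          stringsAsFactors = FALSE)
    gap <- max(1L, round(len * (1 - density) / density * runif(1, 0.6, 1.4)))
    pos <- end + 1L + gap
  }
  do.call(rbind, out)
}

# lay gene blocks into arm intervals with random intergenic gaps
place_blocks <- function(chrom, blocks, arms, bases) {
  arms <- Filter(function(a) a[2] > a[1], arms)
  arm_len <- vapply(arms, function(a) a[2] - a[1] + 1, numeric(1))
  n <- length(blocks)
  genes <- list()
  if (n == 0L) {
    return(list(bases = bases, genes = data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), array = character(), stringsAsFactors = FALSE)))
  }
  # split blocks across arms proportionally to arm length
  n_per <- round(n * arm_len / sum(arm_len))
  n_per[length(n_per)] <- n - sum(n_per[-length(n_per)])
  idx0 <- 1L
  for (a in seq_along(arms)) {
    na <- n_per[a]
    if (na <= 0) next
    bl <- blocks[idx0:(idx0 + na - 1L)]
    idx0 <- idx0 + na
    built <- lapply(bl, build_block)
    widths <- vapply(built, function(b) nchar(b$seq), integer(1))
    leftover <- arm_len[a] - sum(widths)
    if (leftover < (na + 1L) * 100L)
      stopf("sizing error: gene blocks do not fit in arm of %s", chrom)
    w <- runif(na + 1L)
    gaps <- floor(leftover * w / sum(w))
    cursor <- arms[[a]][1]
    for (k in seq_len(na)) {
      cursor <- cursor + gaps[k]
      b <- built[[k]]
      bw <- nchar(b$seq)
      bases[cursor:(cursor + bw - 1L)] <- strsplit(b$seq, "", fixed = TRUE)[[1]]
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = chrom,
        start = cursor + b$offsets$off,
        end = cursor + b$offsets$off + b$offsets$len - 1L,
        strand = b$strand,
        array = if (b$type == "array") b$id else "",
        stringsAsFactors = FALSE)
      cursor <- cursor + bw
    }
  }
  list(bases = bases, genes = do.call(rbind, genes))
}

# concatenate members and spacers into the planted block sequence,
# reverse-complementing minus-strand members
build_block <- function(b) {
  size <- length(b$members)
  planted <- if (b$strand == "-")
    vapply(b$members, revcomp, character(1), USE.NAMES = FALSE) else b$members
  pieces <- character(0)
  offs <- integer(size); lens <- nchar(b$members)
  cur <- 0L
  for (m in seq_len(size)) {
    offs[m] <- cur
    sp <- if (m < size) b$spacers[m] else ""
    pieces <- c(pieces, planted[m], sp)
    cur <- cur + lens[m] + nchar(sp)
  }
  list(type = b$type, id = b$id %||% "", strand = b$strand,
       seq = paste(pieces, collapse = ""),
       offsets = data.frame(off = offs, len = lens))
}

#' Extract gene sequences from a simulated genome
#'
#' Returns the spliced (single-exon) gene sequence of every annotated gene,
#' reverse-complemented for minus-strand genes so homologous genes yield
#' comparable sequences regardless of orientation.
#'
#' @param sim a `sim_genome`.
#' @return named [Biostrings::DNAStringSet] keyed by gene id.
#' @export
gene_sequences <- function(sim) {
  s <- setNames(as.character(sim$genome), names(sim$genome))
  g <- sim$annotations$genes
  seqs <- substr(s[g$chrom], g$start, g$end)
  minus <- g$strand == "-"
  seqs[minus] <- vapply(seqs[minus], revcomp, character(1), USE.NAMES = FALSE)
  Biostrings::DNAStringSet(setNames(seqs, g$gene_id))
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosomes, %s bp total, %d genes, %d tandem arrays\n",
              length(x$genome),
              format(sum(Biostrings::width(x$genome)), big.mark = ","),
              nrow(x$annotations$genes), nrow(x$truth$tandem_arrays)))
  invisible(x)
}
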