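# End-to-end orchestration: a preset "raspberry-like" world, a run
# configuration with per-module parameter groups, and run_report(), which
# executes the full landscape pipeline on a synthetic genome set and writes
# the summary tables.

#' Raspberry-like simulation preset
#'
#' A seven-chromosome world with the qualitative layout of a small Rosaceae
#' genome assembly: telomere tracks at both ends of four chromosomes and at
#' one end of two more (ten tracks in total), a centromeric satellite array
#' of a 317-bp monomer with ~11% per-copy divergence on six chromosomes,
#' one chromosome carrying only four stray monomers and no pericentromeric
#' enrichment (an unassembled-centromere analog), pericentromeric LTR fields
#' at 90% density, and tandem gene arrays of 2-26 copies. Chromosome
#' lengths are desk-scale (1.2 Mb) rather than tens of Mb; the satellite
#' copy-number range 110-1204 follows the per-chromosome range reported for
#' real Rosaceae centromeric arrays.
#'
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
raspberry_preset <- function(seed = 1) {
  simulation_config(
    n_chromosomes = 7,
    chrom_length = 1200000,
    telomere_motif = "TTTAGGG",
    telomere_copies = 40,
    telomere_ends = c("left", "both", "both", "right", "both", "none", "both"),
    centromere_monomer_length = 317,
    centromere_copy_range = c(110, 1204),
    monomer_divergence = 0.11,
    ltr_field_density = 0.9,
    pericentromere_width = 80000,
    n_genes_per_chrom = 40,
    gene_length_range = c(600, 1500),
    tandem_array_spec = list(c(26, 0.05), c(12, 0.05), c(10, 0.05),
                             c(6, 0.05), c(5, 0.05), c(4, 0.05), c(4, 0.05),
                             c(3, 0.05), c(3, 0.05), c(2, 0.05), c(2, 0.05),
                             c(2, 0.05)),
    no_centromere_chrom = 6L,
    stray_monomers = 4,
    seed = seed)
}

#' Default run configuration
#'
#' Per-module parameter groups with the package defaults; the structure that
#' [read_run_config()] validates against and [run_report()] consumes.
#'
#' @param seed integer seed used by every stochastic stage.
#' @return nested named list.
#' @export
default_config <- function(seed = 1) {
  list(
    simulation = list(preset = "raspberry-like", seed = seed),
    telomere = list(motif = "TTTAGGG", min_copies = 10,
                    terminal_window = 10000, max_divergence = 0.1),
    repeats = list(min_copies = 5, min_identity = 70, window = 50000,
                   step = 25000, min_period = 100, max_period = 600),
    hic = list(use = 1, bin_size = 25000, decay_exponent = 1,
               depression_factor = 0.3, noise_dispersion = 0.05),
    centromere = list(ltr_threshold = 0.85, depression_threshold = 0.6,
                      smooth_bins = 3),
    degrade = list(collapse_fraction = 0.6, collapse_keep = 4,
                   inversion_count = 2),
    ortholog = list(substitution_rate = 0.06, inversion_count = 2,
                    contract_array = "ta02", contract_to = 1),
    tandem = list(e_value_max = 1e-5, max_gene_distance = 10),
    synteny = list(e_value_max = 1e-5, top_k = 1, min_anchors = 5,
                   max_rank_gap = 25),
    expression = list(n_tissues = 10, specific_fraction = 0.1,
                      library_size = 2e7, threshold = 1))
}

#' Run the full landscape pipeline and write a report bundle
#'
#' Simulates a genome set from the configured preset, then runs every
#' analysis stage — assembly summary, telomere detection, tandem monomer
#' discovery and satellite array scanning, windowed density tracks,
#' centromere calling (with Hi-C contact simulation unless disabled),
#' tandem array calling with a degraded-assembly comparison, synteny against
#' a simulated ortholog genome with depth and array classification, and the
#' expression-atlas filters — writing one TSV/JSON artefact per section
#' into `out_dir`.
#'
#' @param config configuration list from [default_config()] or
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a named list with the in-memory results of all seven
#'   sections.
#' @export
run_report <- function(config = default_config(), out_dir = tempfile("report"),
                       quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$simulation$seed
  out <- list()

  say("[simulate] generating genome (seed %d)", seed)
  sim_cfg <- if (!is.null(config$simulation$config))
    config$simulation$config else raspberry_preset(seed = seed)
  sim <- generate_genome(sim_cfg)
  write_genome_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_gff3(sim$annotations$genes, file.path(out_dir, "genes.gff3"))
  out$simulation <- sim

  say("[stats] assembly summary")
  summ <- assembly_summary(sim$genome)
  jsonlite::write_json(list(total_size = summ$total_size,
                            n_sequences = summ$n_sequences,
                            nx = as.list(summ$nx),
                            gap_count = summ$gap_count,
                            gap_bases = summ$gap_bases),
                       file.path(out_dir, "assembly_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  out$assembly <- summ

  say("[telomeres] scanning chromosome ends")
  tel <- detect_telomeres(sim$genome, motif = config$telomere$motif,
                          min_copies = config$telomere$min_copies,
                          terminal_window = config$telomere$terminal_window,
                          max_divergence = config$telomere$max_divergence)
  write_bed6(tel, file.path(out_dir, "telomeres.bed"),
             name_col = "end_label", score_col = "copy_number")
  out$telomeres <- tel

  say("[repeats] monomer discovery and array scan")
  monomer <- discover_monomer(sim$genome,
                              min_period = config$repeats$min_period,
                              max_period = config$repeats$max_period)
  arrays <- scan_repeat_arrays(sim$genome, monomer,
                               min_copies = config$repeats$min_copies,
                               min_identity = config$repeats$min_identity)
  write.table(arrays, file.path(out_dir, "repeat_arrays.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  land <- landscape_table(sim$genome,
                          sim$annotations$genes[, c("chrom", "start", "end")],
                          sim$annotations$ltr, arrays, tel,
                          window = config$repeats$window,
                          step = config$repeats$step)
  write.table(land, file.path(out_dir, "landscape.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out$repeats <- list(monomer = monomer, arrays = arrays, landscape = land)

  say("[centromeres] calling from evidence tracks")
  chroms <- names(sim$genome)
  ltr_tracks <- setNames(lapply(chroms, function(ch) {
    iv <- sim$annotations$ltr
    windowed_density(iv[iv$chrom == ch, , drop = FALSE],
                     Biostrings::width(sim$genome[ch]),
                     window = config$repeats$window,
                     step = config$repeats$step)
  }), chroms)
  depressions <- NULL
  if (isTRUE(config$hic$use == 1)) {
    cms <- generate_contact_matrix(sim, bin_size = config$hic$bin_size,
                                   decay_exponent = config$hic$decay_exponent,
                                   depression_factor = config$hic$depression_factor,
                                   noise_dispersion = config$hic$noise_dispersion,
                                   seed = seed)
    write_contacts(cms, file.path(out_dir, "contacts.tsv"))
    depressions <- lapply(cms, contact_depression_track,
                          smooth_bins = config$centromere$smooth_bins)
  } else {
    warning("Hi-C input disabled: centromere calls lack hic_depression evidence")
  }
  calls <- call_centromeres(chroms, arrays = arrays, ltr_tracks = ltr_tracks,
                            depressions = depressions,
                            ltr_threshold = config$centromere$ltr_threshold,
                            depression_threshold = config$centromere$depression_threshold)
  write.table(calls, file.path(out_dir, "centromere_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cen_sum <- centromere_summary(calls)
  jsonlite::write_json(cen_sum, file.path(out_dir, "centromere_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  out$centromeres <- list(calls = calls, summary = cen_sum)

  say("[tandem] homology search and array comparison")
  seqs <- gene_sequences(sim)
  hits <- all_vs_all_hits(seqs, e_value_max = config$tandem$e_value_max)
  arrays_new <- call_tandem_arrays(sim$annotations$genes, hits,
                                   e_value_max = config$tandem$e_value_max,
                                   max_gene_distance = config$tandem$max_gene_distance)
  degraded <- degrade_assembly(sim,
                               collapse_fraction = config$degrade$collapse_fraction,
                               collapse_keep = config$degrade$collapse_keep,
                               inversion_count = config$degrade$inversion_count,
                               seed = seed + 1L)
  keep <- degraded$annotations$genes$gene_id
  hits_old <- hits[hits$query %in% keep & hits$subject %in% keep, , drop = FALSE]
  arrays_old <- call_tandem_arrays(degraded$annotations$genes, hits_old,
                                   e_value_max = config$tandem$e_value_max,
                                   max_gene_distance = config$tandem$max_gene_distance)
  gene_map <- data.frame(old_id = keep, new_id = keep, stringsAsFactors = FALSE)
  comparison <- compare_assemblies(arrays_old, arrays_new, gene_map,
                                   genes_old = degraded$annotations$genes,
                                   genes_new = sim$annotations$genes)
  write.table(array_table(arrays_new), file.path(out_dir, "tandem_arrays.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(comparison$matched, file.path(out_dir, "tandem_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(comparison$venn),
                       file.path(out_dir, "tandem_venn.json"),
                       auto_unbox = TRUE, digits = NA)
  out$tandem <- list(arrays = arrays_new, arrays_degraded = arrays_old,
                     comparison = comparison,
                     gain_gt10 = size_class_gain(comparison, 11),
                     gain_5to9 = size_class_gain(comparison, 5, 9))

  say("[synteny] ortholog genome, chaining, depth")
  la_spec <- list()
  if (nzchar(config$ortholog$contract_array %||% "") &&
      config$ortholog$contract_array %in% sim$truth$tandem_arrays$array_id)
    la_spec <- list(list(array_id = config$ortholog$contract_array,
                         new_size = config$ortholog$contract_to))
  ortho <- generate_ortholog_genome(sim,
                                    substitution_rate = config$ortholog$substitution_rate,
                                    inversion_count = config$ortholog$inversion_count,
                                    lineage_array_spec = la_spec,
                                    seed = seed + 2L)
  seqs_b <- gene_sequences(ortho)
  cross <- all_vs_all_hits(seqs, seqs_b, e_value_max = config$synteny$e_value_max)
  anchors <- anchor_pairs(sim$annotations$genes, ortho$annotations$genes,
                          cross, e_value_max = config$synteny$e_value_max,
                          top_k = config$synteny$top_k)
  blocks <- chain_blocks(anchors, sim$annotations$genes,
                         ortho$annotations$genes,
                         min_anchors = config$synteny$min_anchors,
                         max_rank_gap = config$synteny$max_rank_gap)
  depth <- syntenic_depth(blocks)
  hits_b <- all_vs_all_hits(seqs_b, e_value_max = config$tandem$e_value_max)
  arrays_b <- call_tandem_arrays(ortho$annotations$genes, hits_b,
                                 e_value_max = config$tandem$e_value_max,
                                 max_gene_distance = config$tandem$max_gene_distance)
  cls <- classify_syntenic_arrays(arrays_new, arrays_b, blocks)
  write.table(blocks[, setdiff(names(blocks), "anchors")],
              file.path(out_dir, "synteny_blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dotplot_table(blocks, sim$annotations$genes,
                            ortho$annotations$genes),
              file.path(out_dir, "dotplot.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(fraction_1to1 = depth$fraction_1to1,
                            fraction_1to1_bases = depth$fraction_1to1_bases,
                            n_blocks = nrow(blocks),
                            n_conserved_arrays = cls$n_conserved,
                            n_specific_arrays = cls$n_specific),
                       file.path(out_dir, "synteny_depth.json"),
                       auto_unbox = TRUE, digits = NA)
  out$synteny <- list(ortholog = ortho, blocks = blocks, depth = depth,
                      arrays_classified = cls)

  say("[expression] atlas filters")
  expr <- generate_expression_counts(sim,
                                     n_tissues = config$expression$n_tissues,
                                     specific_fraction = config$expression$specific_fraction,
                                     library_size = config$expression$library_size,
                                     seed = seed + 3L)
  write_counts_tsv(expr$counts, file.path(out_dir, "counts.tsv"))
  fp <- fpkm(expr$counts, expr$gene_lengths, expr$library_sizes)
  det <- detectable_genes(fp, threshold = config$expression$threshold)
  spec <- tissue_specific_genes(fp, threshold = config$expression$threshold)
  writeLines(det, file.path(out_dir, "detectable_genes.txt"))
  write.table(spec, file.path(out_dir, "tissue_specific_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  out$expression <- list(fpkm = fp, detectable = det, specific = spec)

  jsonlite::write_json(list(
    sections = c("simulation", "assembly", "telomeres", "repeats",
                 "centromeres", "tandem", "synteny", "expression"),
    seed = seed,
    total_size = summ$total_size,
    n50 = summ$nx[["N50"]],
    n_telomere_tracks = nrow(tel),
    n_repeat_arrays = nrow(arrays),
    centromeres = cen_sum,
    n_tandem_arrays = nrow(arrays_new),
    fraction_1to1 = depth$fraction_1to1,
    n_detectable = length(det),
    n_tissue_specific = nrow(spec)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  say("report written to %s", out_dir)
  invisible(out)
}

# flatten the members list column for TSV output
array_table <- function(arrays) {
  data.frame(array_id = arrays$array_id, chrom = arrays$chrom,
             size = arrays$size,
             members = vapply(arrays$members, paste, character(1),
                              collapse = ","),
             stringsAsFactors = FALSE)
}

# discover the dominant satellite monomer from the central region of each
# chromosome and return the consensus of the best-supported period
discover_monomer <- function(genome, min_period = 100, max_period = 600,
                             center_width = 150000) {
  best <- NULL
  for (ch in names(genome)) {
    L <- Biostrings::width(genome[ch])
    mid <- L %/% 2L
    w <- min(center_width, L) %/% 2L
    seg <- substr(as.character(genome[[ch]]), max(1L, mid - w), min(L, mid + w))
    cand <- find_tandem_monomer(seg, min_period = min_period,
                                max_period = max_period)
    if (nrow(cand) && (is.null(best) || cand$support[1] > best$support))
      best <- cand[1, ]
  }
  if (is.null(best)) stopf("no tandem monomer discovered")
  best$consensus
}
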