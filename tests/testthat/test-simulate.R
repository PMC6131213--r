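test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 3)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth$centromeres, b$truth$centromeres)
})

test_that("planted features are consistent with the emitted sequence", {
  sim <- tiny_sim()
  s <- setNames(as.character(sim$genome), names(sim$genome))
  # telomere intervals are exact motif tandems
  for (i in seq_len(nrow(sim$truth$telomeres))) {
    tr <- sim$truth$telomeres[i, ]
    unit <- if (tr$end_label == "left") "TTTAGGG" else "CCCTAAA"
    expect_identical(unname(substr(s[tr$chrom], tr$start, tr$end)),
                     strrep(unit, tr$copies))
  }
  # every truth interval lies within chromosome bounds
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  for (tab in c("telomeres", "centromeres", "ltr_intervals")) {
    df <- sim$truth[[tab]]
    expect_true(all(df$start >= 1 & df$end <= lens[df$chrom]))
  }
  # distinct centromeres do not overlap (they sit on distinct chromosomes)
  expect_false(any(duplicated(sim$truth$centromeres$chrom)))
})

test_that("zero monomer divergence plants identical centromeric elements", {
  cfg <- tiny_cfg(seed = 9, n_chromosomes = 1, monomer_divergence = 0,
                  tandem_array_spec = list())
  sim <- generate_genome(cfg)
  cen <- sim$truth$centromeres
  seg <- substr(as.character(sim$genome[[1]]), cen$array_start, cen$array_end)
  expect_identical(seg, strrep(sim$truth$monomer, cen$copy_number))
})

test_that("a 26-member tandem array spec yields 26 gene records sharing a family", {
  cfg <- tiny_cfg(seed = 13, n_chromosomes = 1,
                  tandem_array_spec = list(c(26, 0.05)),
                  n_genes_per_chrom = 5)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$truth$tandem_arrays), 1)
  expect_equal(sim$truth$tandem_arrays$size, 26)
  g <- sim$annotations$genes
  fam <- g[g$family_id == "fam_ta01", ]
  expect_equal(nrow(fam), 26)
  # GFF3 round-trips the family annotation
  path <- tempfile(fileext = ".gff3")
  write_gff3(g, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("\tgene\t.*family_id=fam_ta01", lines)), 26)
})

test_that("oversized feature demands raise a sizing error", {
  expect_error(simulation_config(chrom_length = 50000,
                                 centromere_copy_range = c(110, 300)),
               "sizing")
})

test_that("degrade_assembly with all knobs at identity is a no-op", {
  sim <- tiny_sim()
  d <- degrade_assembly(sim, collapse_fraction = 0, inversion_count = 0,
                        drop_pericentromere = FALSE)
  expect_identical(as.character(d$genome), as.character(sim$genome))
  expect_identical(d$annotations, sim$annotations)
})

test_that("array collapse keeps the requested members and shifts coordinates", {
  sim <- tiny_sim() # has a 10-member array ta01
  d <- degrade_assembly(sim, collapse_fraction = 1, collapse_keep = 4,
                        inversion_count = 0, seed = 2)
  g <- d$annotations$genes
  expect_equal(sum(g$family_id == "fam_ta01"), 4)
  expect_equal(d$truth$collapsed_arrays$original_size[
    d$truth$collapsed_arrays$array_id == "ta01"], 10)
  # genome got shorter by the excised bases
  expect_lt(sum(Biostrings::width(d$genome)),
            sum(Biostrings::width(sim$genome)))
  # surviving gene sequences are untouched
  s_old <- gene_sequences(sim)
  s_new <- gene_sequences(d)
  for (id in names(s_new))
    expect_identical(as.character(s_new[[id]]), as.character(s_old[[id]]))
})

test_that("a planted inversion is exactly one reverse-complemented interval", {
  sim <- tiny_sim()
  base <- degrade_assembly(sim, collapse_fraction = 1, collapse_keep = 4,
                           inversion_count = 0, seed = 6)
  inv <- degrade_assembly(sim, collapse_fraction = 1, collapse_keep = 4,
                          inversion_count = 1, seed = 6)
  expect_equal(nrow(inv$truth$inversions), 1)
  tr <- inv$truth$inversions
  s1 <- as.character(base$genome[[tr$chrom]])
  s2 <- as.character(inv$genome[[tr$chrom]])
  # sequence diff oracle: the differing region is [start, end] and it equals
  # the reverse complement of the original
  diffs <- which(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  expect_gte(min(diffs), tr$start)
  expect_lte(max(diffs), tr$end)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s1, tr$start, tr$end))))
  expect_identical(substr(s2, tr$start, tr$end), rc)
  # inverted genes flipped strand
  ginv <- inv$annotations$genes
  gbase <- base$annotations$genes
  inside <- ginv$start >= tr$start & ginv$end <= tr$end &
    ginv$chrom == tr$chrom
  flipped <- merge(ginv[inside, c("gene_id", "strand")],
                   gbase[, c("gene_id", "strand")], by = "gene_id")
  expect_true(all(flipped$strand.x != flipped$strand.y))
})

test_that("drop_pericentromere gaps out the centromeric region", {
  sim <- tiny_sim()
  d <- degrade_assembly(sim, collapse_fraction = 0, inversion_count = 0,
                        drop_pericentromere = TRUE)
  expect_equal(nrow(d$truth$centromeres), 0)
  cen <- sim$truth$centromeres[1, ]
  seg <- substr(as.character(d$genome[[cen$chrom]]), cen$start, cen$end)
  expect_identical(seg, strrep("N", cen$end - cen$start + 1))
  expect_equal(sum(Biostrings::width(d$genome)),
               sum(Biostrings::width(sim$genome)))
})

test_that("an identity ortholog preserves gene order", {
  sim <- tiny_sim()
  o <- generate_ortholog_genome(sim, substitution_rate = 0,
                                inversion_count = 0, seed = 4)
  ga <- sim$annotations$genes
  gb <- o$annotations$genes
  expect_equal(nrow(ga), nrow(gb))
  expect_equal(gb$gene_id, paste0("b_", ga$gene_id))
  expect_equal(gb$rank, ga$rank)
  expect_equal(gb$strand, ga$strand)
  expect_identical(as.character(o$genome[[1]]), as.character(sim$genome[[1]]))
})

test_that("lineage array contraction leaves the requested copy number", {
  cfg <- tiny_cfg(seed = 17, n_chromosomes = 1,
                  tandem_array_spec = list(c(12, 0.05)),
                  n_genes_per_chrom = 15)
  sim <- generate_genome(cfg)
  o <- generate_ortholog_genome(sim, substitution_rate = 0.05,
                                lineage_array_spec =
                                  list(list(array_id = "ta01", new_size = 1)),
                                seed = 8)
  expect_equal(sum(o$annotations$genes$family_id == "fam_ta01"), 1)
  expect_equal(o$truth$tandem_arrays$size, 1)
  # removed members have no ortholog mapping
  expect_equal(nrow(o$truth$ortholog_map), nrow(sim$annotations$genes) - 11)
})

test_that("lineage array expansion inserts extra diverged members", {
  cfg <- tiny_cfg(seed = 18, n_chromosomes = 1,
                  tandem_array_spec = list(c(3, 0.05)),
                  n_genes_per_chrom = 12)
  sim <- generate_genome(cfg)
  o <- generate_ortholog_genome(sim, substitution_rate = 0.05,
                                lineage_array_spec =
                                  list(list(array_id = "ta01", new_size = 6)),
                                seed = 8)
  expect_equal(sum(o$annotations$genes$family_id == "fam_ta01"), 6)
  expect_gt(sum(Biostrings::width(o$genome)),
            sum(Biostrings::width(sim$genome)))
  expect_equal(o$truth$tandem_arrays$size, 6)
})

test_that("contact matrices are symmetric, deterministic, and depressed at centromeres", {
  # centromere ~20% of the chromosome, so the chromosome median row sum is a
  # meaningful background reference
  sim <- cached("hic_sim", generate_genome(
    tiny_cfg(seed = 19, n_chromosomes = 1, chrom_length = 400000,
             pericentromere_width = 25000, tandem_array_spec = list(),
             n_genes_per_chrom = 10)))
  cms <- generate_contact_matrix(sim, bin_size = 10000, depression_factor = 1,
                                 decay_exponent = 2, noise_dispersion = 0,
                                 seed = 1)
  m <- cms[[1]]$counts
  expect_true(isSymmetric(unname(m)))
  # interior row sums constant (up to edge effects) without depression
  rs <- rowSums(m)
  interior <- rs[10:(length(rs) - 9)]
  expect_lt(diff(range(interior)) / median(interior), 0.05)

  cms2 <- generate_contact_matrix(sim, bin_size = 10000, seed = 5)
  cms3 <- generate_contact_matrix(sim, bin_size = 10000, seed = 5)
  expect_identical(cms2[[1]]$counts, cms3[[1]]$counts)

  dep <- generate_contact_matrix(sim, bin_size = 10000,
                                 depression_factor = 0.2,
                                 noise_dispersion = 0, seed = 1)
  cen <- sim$truth$centromeres[1, ]
  starts <- (seq_len(nrow(dep[[1]]$counts)) - 1L) * 10000 + 1
  in_cen <- starts >= cen$start & starts + 9999 <= cen$end
  rs <- rowSums(dep[[1]]$counts)
  expect_lt(mean(rs[in_cen]), 0.5 * median(rs))

  expect_error(generate_contact_matrix(sim, bin_size = 1e7), "bin_size")
})

test_that("expression counts plant the configured specific and detectable sets", {
  sim <- tiny_sim()
  none <- generate_expression_counts(sim, specific_fraction = 0, seed = 2)
  expect_equal(nrow(none$specific_genes), 0)
  ex <- generate_expression_counts(sim, n_tissues = 10,
                                   specific_fraction = 0.1, seed = 2)
  n <- nrow(sim$annotations$genes)
  expect_equal(nrow(ex$specific_genes), round(0.1 * n))
  expect_equal(dim(ex$counts), c(n, 10))
  expect_error(generate_expression_counts(sim, n_tissues = 1,
                                          specific_fraction = 0.1),
               "n_tissues")
})
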