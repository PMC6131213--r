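test_that("find_tandem_monomer recovers a planted monomer exactly", {
  set.seed(1)
  mono <- random_dna_str(317)
  res <- find_tandem_monomer(strrep(mono, 50))
  expect_equal(res$period[1], 317)
  expect_identical(res$consensus[1], mono)
})

test_that("period estimates stay within 2 bp of the planted period under divergence", {
  set.seed(99)
  for (trial in 1:60) {
    period <- sample(150:450, 1)
    mono <- random_dna_str(period)
    arr <- paste(vapply(1:30, function(i)
      genomescape:::mutate_dna(mono, runif(1, 0, 0.15)), character(1)),
      collapse = "")
    res <- find_tandem_monomer(arr, min_period = 100, max_period = 600)
    expect_gt(nrow(res), 0)
    expect_lte(abs(res$period[1] - period), 2)
  }
})

test_that("random sequence yields no supported period", {
  set.seed(4)
  for (i in 1:10)
    expect_equal(nrow(find_tandem_monomer(random_dna_str(10000))), 0)
})

test_that("scan_repeat_arrays recovers planted arrays and their identity", {
  set.seed(2)
  mono <- random_dna_str(317)
  flank <- function(n) random_dna_str(n)
  exact <- paste0(flank(5000), strrep(mono, 110), flank(5000))
  res <- scan_repeat_arrays(c(chr = exact), mono)
  expect_equal(nrow(res), 1)
  expect_equal(res$copy_number, 110)
  expect_equal(res$mean_identity, 100)
  expect_equal(res$start, 5001)
  expect_equal(res$end, 5000 + 110 * 317)

  div <- paste0(flank(3000),
                paste(vapply(1:80, function(i)
                  genomescape:::mutate_dna(mono, 0.11), character(1)),
                  collapse = ""),
                flank(3000))
  resd <- scan_repeat_arrays(c(chr = div), mono)
  expect_equal(nrow(resd), 1)
  expect_equal(resd$copy_number, 80)
  expect_lt(abs(resd$mean_identity - 89), 3)
})

test_that("arrays separated by more than max_gap stay distinct", {
  set.seed(3)
  mono <- random_dna_str(317)
  two <- paste0(strrep(mono, 10), random_dna_str(2000), strrep(mono, 12))
  res <- scan_repeat_arrays(c(chr = two), mono, max_gap = 1000)
  expect_equal(nrow(res), 2)
  expect_equal(sort(res$copy_number), c(10, 12))
  merged <- scan_repeat_arrays(c(chr = two), mono, max_gap = 3000)
  expect_equal(nrow(merged), 1)
})

test_that("reverse-strand arrays are found with mapped coordinates", {
  set.seed(6)
  mono <- random_dna_str(317)
  rc_arr <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(strrep(mono, 20))))
  s <- paste0(random_dna_str(4000), rc_arr, random_dna_str(4000))
  res <- scan_repeat_arrays(c(chr = s), mono)
  expect_equal(nrow(res), 1)
  expect_equal(res$strand, "-")
  expect_equal(res$copy_number, 20)
  expect_equal(res$start, 4001)
  expect_equal(res$end, 4000 + 20 * 317)
})

test_that("planted arrays in a full simulation are recovered near-exactly", {
  sim <- tiny_sim()
  res <- scan_repeat_arrays(sim$genome, sim$truth$monomer)
  cen <- sim$truth$centromeres
  expect_equal(nrow(res), nrow(cen))
  for (i in seq_len(nrow(cen))) {
    r <- res[res$chrom == cen$chrom[i], ]
    expect_equal(r$copy_number, cen$copy_number[i])
    expect_gte(jaccard(r$start, r$end, cen$array_start[i], cen$array_end[i]),
               0.99)
  }
})

test_that("mean_element_identity follows alignment arithmetic", {
  set.seed(8)
  mono <- random_dna_str(100)
  expect_equal(mean_element_identity(c(mono, mono), mono), 100)
  one_sub <- paste0("A", substr(mono, 2, 100))
  if (substr(mono, 1, 1) == "A") one_sub <- paste0("C", substr(mono, 2, 100))
  expect_equal(mean_element_identity(one_sub, mono), 99)
  expect_error(mean_element_identity(character(0), mono), "no elements")
  # for substitution-only divergence the global alignment reduces to the
  # hamming identity oracle
  for (i in 1:10) {
    el <- genomescape:::mutate_dna(mono, 0.05)
    expect_equal(mean_element_identity(el, mono),
                 genomescape:::hamming_identity(el, mono))
  }
})

test_that("windowed_density computes per-window covered fractions", {
  none <- windowed_density(NULL, 100000)
  expect_true(all(none$density == 0))
  expect_equal(nrow(none), ceiling(100000 / 25000))

  one <- windowed_density(data.frame(start = 25001, end = 75000), 100000)
  expect_equal(one$density[2], 1)

  d <- windowed_density(data.frame(start = 1, end = 25000), 100000)
  expect_equal(d$density, c(0.5, 0, 0, 0))

  expect_error(windowed_density(NULL, 0), "positive")
  expect_error(windowed_density(data.frame(start = 0, end = 10), 100),
               "within")
})

test_that("windowed_density is invariant to interval order and splitting", {
  set.seed(10)
  iv <- data.frame(start = sort(sample.int(90000, 20)))
  iv$end <- iv$start + sample.int(3000, 20)
  base <- windowed_density(iv, 100000)
  shuffled <- windowed_density(iv[sample.int(nrow(iv)), ], 100000)
  expect_equal(base, shuffled, ignore_attr = TRUE)
  # split the first interval into two adjacent pieces
  sp <- rbind(data.frame(start = iv$start[1], end = iv$start[1] + 100),
              data.frame(start = iv$start[1] + 101, end = iv$end[1]),
              iv[-1, ])
  expect_equal(windowed_density(sp, 100000)$density, base$density)
})

test_that("landscape_table joins density tracks and flags unknown chromosomes", {
  sim <- tiny_sim()
  arrays <- scan_repeat_arrays(sim$genome, sim$truth$monomer)
  tel <- detect_telomeres(sim$genome)
  land <- landscape_table(sim$genome,
                          sim$annotations$genes[, c("chrom", "start", "end")],
                          sim$annotations$ltr, arrays, tel,
                          window = 20000, step = 10000)
  expect_equal(nrow(land), sum(ceiling(Biostrings::width(sim$genome) / 10000)))
  # genes and LTR fields are planted disjointly: densities anticorrelate
  expect_lt(cor(land$gene_density, land$ltr_density), 0)
  # centromeric density peaks inside the planted array
  cen <- sim$truth$centromeres[1, ]
  peak <- land[which.max(land$cent_density), ]
  expect_equal(peak$chrom, cen$chrom)
  expect_gte(peak$end, cen$array_start)
  expect_lte(peak$start, cen$array_end)
  expect_identical(attr(land, "telomeres"), tel)

  empty <- landscape_table(sim$genome, NULL, NULL, NULL, NULL)
  expect_true(all(empty$gene_density == 0 & empty$ltr_density == 0 &
                    empty$cent_density == 0))
  bad <- data.frame(chrom = "nope", start = 1, end = 10)
  expect_error(landscape_table(sim$genome, bad, NULL), "nope")
})
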