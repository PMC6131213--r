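# two toy genomes with identity-mapped genes for structural tests
toy_genes <- function(n, chrom = "c1", prefix = "a") {
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)), chrom = chrom,
             start = seq_len(n) * 2000, end = seq_len(n) * 2000 + 900,
             strand = rep(c("+", "-"), length.out = n),
             stringsAsFactors = FALSE)
}

toy_anchors <- function(n, prefix_a = "a", prefix_b = "b") {
  data.frame(gene_a = sprintf("%s%03d", prefix_a, seq_len(n)),
             gene_b = sprintf("%s%03d", prefix_b, seq_len(n)),
             stringsAsFactors = FALSE)
}

ortho_world <- function() {
  cached("ortho_world", {
    sim <- tiny_sim()
    o2 <- generate_ortholog_genome(sim, substitution_rate = 0.05,
                                   inversion_count = 2, seed = 12)
    o0 <- generate_ortholog_genome(sim, substitution_rate = 0.05,
                                   inversion_count = 0, seed = 13)
    list(sim = sim, o2 = o2, o0 = o0)
  })
}

truth_anchors <- function(o) {
  data.frame(gene_a = o$truth$ortholog_map$gene_a,
             gene_b = o$truth$ortholog_map$gene_b, stringsAsFactors = FALSE)
}

test_that("anchor_pairs keeps reciprocal best hits independent of hit order", {
  hits <- data.frame(
    query = c("a001", "a001", "a002", "b001"),
    subject = c("b001", "b002", "b002", "a003"),
    e_value = c(1e-40, 1e-10, 1e-30, 1e-20),
    bit_score = c(200, 60, 150, 90), stringsAsFactors = FALSE)
  ga <- toy_genes(3, prefix = "a")
  gb <- toy_genes(3, prefix = "b")
  anch <- anchor_pairs(ga, gb, hits)
  shuffled <- anchor_pairs(ga, gb, hits[c(3, 1, 4, 2), ])
  expect_equal(anch, shuffled)
  # top_k = 1 gives a partial matching
  expect_false(any(duplicated(anch$gene_a)))
  expect_false(any(duplicated(anch$gene_b)))
  # a001-b001 beats a001-b002; b001's best is a001 (bit 200 > 90)
  expect_true(any(anch$gene_a == "a001" & anch$gene_b == "b001"))
})

test_that("self-synteny chains one forward block per chromosome", {
  n <- 30
  ga <- toy_genes(n, prefix = "a")
  gb <- toy_genes(n, prefix = "b")
  blocks <- chain_blocks(toy_anchors(n), ga, gb)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$orientation, "forward")
  expect_equal(blocks$n_anchors, n)
  d <- syntenic_depth(blocks)
  expect_equal(d$fraction_1to1, 100)
  dp <- dotplot_table(blocks, ga, gb)
  expect_equal(nrow(dp), n)
  expect_equal(dp$pos_a, dp$pos_b)
})

test_that("planted inversions produce the planted number of inverted blocks", {
  w <- ortho_world()
  anch <- truth_anchors(w$o2)
  blocks <- chain_blocks(anch, w$sim$annotations$genes,
                         w$o2$annotations$genes)
  expect_equal(sum(blocks$orientation == "inverted"),
               nrow(w$o2$truth$inversions))
  # anchors are strictly monotone within blocks and used at most once
  all_anchor_genes <- unlist(lapply(blocks$anchors, function(a) a$gene_a))
  expect_false(any(duplicated(all_anchor_genes)))
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$anchors[[i]]
    expect_true(all(diff(a$ra) > 0))
    if (blocks$orientation[i] == "forward") expect_true(all(diff(a$rb) > 0))
    else expect_true(all(diff(a$rb) < 0))
  }
})

test_that("an unduplicated ortholog genome is fully 1:1", {
  w <- ortho_world()
  anch <- truth_anchors(w$o0)
  blocks <- chain_blocks(anch, w$sim$annotations$genes,
                         w$o0$annotations$genes)
  expect_equal(nrow(blocks), length(w$sim$genome))
  expect_true(all(blocks$orientation == "forward"))
  d <- syntenic_depth(blocks)
  expect_equal(d$fraction_1to1, 100)
  expect_equal(d$fraction_1to1_bases, 100)
  # every gene anchored
  expect_equal(sum(blocks$n_anchors), nrow(w$sim$annotations$genes))
  # no inter-chromosomal blocks when none are planted
  expect_true(all(sub("^b_", "", blocks$chrom_b) == blocks$chrom_a))
})

test_that("random anchor scatter rarely chains into a block", {
  # sparse anchors over genome-scale gene counts: random increasing runs are
  # broken by the rank-gap bound
  set.seed(51)
  n_with_block <- 0
  ga <- toy_genes(500, prefix = "a")
  gb <- toy_genes(500, prefix = "b")
  for (i in 1:100) {
    anch <- data.frame(gene_a = sprintf("a%03d", sample.int(500, 20)),
                       gene_b = sprintf("b%03d", sample.int(500, 20)))
    blocks <- chain_blocks(anch, ga, gb, min_anchors = 5, max_rank_gap = 25)
    if (nrow(blocks) > 0) n_with_block <- n_with_block + 1
  }
  expect_lte(n_with_block, 5)
})

test_that("chaining matches the exhaustive best-chain oracle on small instances", {
  set.seed(52)
  for (trial in 1:60) {
    n <- sample(4:12, 1)
    x <- sample.int(30, n)
    y <- sample.int(30, n)
    got <- genomescape:::best_chain(x, y, max_gap = 10, penalty = 0.05)
    want <- chain_oracle(x, y, max_gap = 10, penalty = 0.05)
    expect_equal(got$score, want, tolerance = 1e-9)
  }
})

test_that("syntenic depth flags duplicated spans symmetrically", {
  blocks <- structure(data.frame(
    block_id = c("b1", "b2", "b3"),
    chrom_a = "c1", chrom_b = c("d1", "d1", "d2"),
    orientation = "forward", n_anchors = 6L,
    span_a_start = c(1, 100000, 200000), span_a_end = c(50000, 150000, 250000),
    span_b_start = c(1, 1, 1), span_b_end = c(50000, 50000, 50000),
    stringsAsFactors = FALSE), class = c("synteny_blocks", "data.frame"))
  blocks$anchors <- I(list(NULL, NULL, NULL))
  d <- syntenic_depth(blocks)
  # blocks b1 and b2 share their span on d1: depth 2 on genome b
  expect_equal(d$per_block$depth_b, c(2L, 2L, 1L))
  expect_equal(d$per_block$depth_a, c(1L, 1L, 1L))
  expect_equal(d$fraction_1to1, 100 / 3)
  # swapping genomes leaves the fractions unchanged
  swapped <- blocks
  swapped[, c("chrom_a", "chrom_b")] <- blocks[, c("chrom_b", "chrom_a")]
  swapped[, c("span_a_start", "span_a_end")] <-
    blocks[, c("span_b_start", "span_b_end")]
  swapped[, c("span_b_start", "span_b_end")] <-
    blocks[, c("span_a_start", "span_a_end")]
  d2 <- syntenic_depth(swapped)
  expect_equal(d2$fraction_1to1, d$fraction_1to1)
  expect_equal(d2$fraction_1to1_bases, d$fraction_1to1_bases)
})

test_that("syntenic arrays classify as conserved or lineage-specific", {
  n <- 30
  ga <- toy_genes(n, prefix = "a")
  gb <- toy_genes(n, prefix = "b")
  blocks <- chain_blocks(toy_anchors(n), ga, gb)
  arr <- function(ids, chrom = "c1") {
    out <- data.frame(array_id = paste0("arr_", ids[1]), chrom = chrom,
                      size = length(ids), stringsAsFactors = FALSE)
    out$members <- I(list(ids))
    out
  }
  arrays_a <- rbind(arr(sprintf("a%03d", 1:12)), arr(sprintf("a%03d", 20:22)))
  arrays_b <- rbind(arr(sprintf("b%03d", 20:22)))
  cls <- classify_syntenic_arrays(arrays_a, arrays_b, blocks)
  # the 3-member array is conserved with equal sizes; the 12-member array has
  # single-copy partners only
  expect_equal(cls$n_conserved, 1)
  expect_equal(cls$conserved$size_a, 3)
  expect_equal(cls$conserved$size_b, 3)
  expect_equal(cls$big_vs_single_a, 1)
  # identical array sets: everything conserved
  arrays_b2 <- rbind(arr(sprintf("b%03d", 1:12)), arr(sprintf("b%03d", 20:22)))
  cls2 <- classify_syntenic_arrays(arrays_a, arrays_b2, blocks)
  expect_equal(cls2$n_conserved, 2)
  expect_equal(cls2$size_pairs$size_a, cls2$size_pairs$size_b)
  expect_equal(cls2$big_vs_single_a, 0)
  # no blocks: nothing conserved
  cls3 <- suppressWarnings(
    classify_syntenic_arrays(arrays_a, arrays_b, blocks[0, ]))
  expect_equal(cls3$n_conserved, 0)
})

test_that("microsynteny pairs region genes and flags expansions", {
  n <- 20
  ga <- toy_genes(n, prefix = "a")
  gb <- toy_genes(n, prefix = "b")
  blocks <- chain_blocks(toy_anchors(n), ga, gb)
  region <- list(chrom = "c1", start = 2000, end = 21000)
  mv <- microsynteny_view(region, blocks, ga, gb)
  expect_equal(sum(mv$genome == "a"), 10)
  expect_true(all(mv$paired[mv$genome == "a"]))
  # strand concordance for an identity mapping
  a_side <- mv[mv$genome == "a", ]
  b_side <- mv[mv$genome == "b", ]
  expect_equal(a_side$strand,
               b_side$strand[match(a_side$partner, b_side$gene_id)])
  # extra unpaired gene in b appears with NA partner
  gb_plus <- rbind(gb, data.frame(gene_id = "b_extra", chrom = "c1",
                                  start = 5000, end = 5400, strand = "+",
                                  stringsAsFactors = FALSE))
  mv2 <- microsynteny_view(region, blocks, ga, gb_plus)
  expect_true("b_extra" %in% mv2$gene_id)
  expect_false(mv2$paired[mv2$gene_id == "b_extra"])
  # region outside any block
  expect_message(
    empty <- microsynteny_view(list(chrom = "c9", start = 1, end = 10),
                               blocks, ga, gb),
    "no synteny block")
  expect_equal(nrow(empty), 0)
})
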