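make_genes <- function(ranks, chrom = "c1") {
  data.frame(gene_id = sprintf("g%02d", ranks), chrom = chrom,
             start = ranks * 1000, end = ranks * 1000 + 500,
             strand = "+", stringsAsFactors = FALSE)
}

make_hits <- function(pairs, e = 1e-10) {
  data.frame(query = pairs[, 1], subject = pairs[, 2], identity = 95,
             align_length = 400, mismatches = 10, gap_opens = 0,
             q_start = 1, q_end = 400, s_start = 1, s_end = 400,
             e_value = e, bit_score = 500, stringsAsFactors = FALSE)
}

test_that("pairwise_homology scores agree with a Smith-Waterman oracle", {
  set.seed(31)
  for (i in 1:25) {
    a <- random_dna_str(sample(8:14, 1))
    b <- random_dna_str(sample(8:14, 1))
    h <- pairwise_homology(a, b)
    expect_equal(h$score, sw_oracle(a, b))
  }
})

test_that("identical genes self-hit with vanishing e-value", {
  set.seed(32)
  g <- random_dna_str(300)
  h <- pairwise_homology(g, g)
  expect_lt(h$e_value, 1e-50)
  expect_equal(h$identity, 100)
  expect_equal(h$align_length, 300)
})

test_that("unrelated sequences rarely reach the tandem e-value cutoff", {
  set.seed(33)
  n_signif <- 0
  for (i in 1:100) {
    h <- pairwise_homology(random_dna_str(300), random_dna_str(300),
                           db_size = 1e6)
    if (h$e_value <= 1e-5) n_signif <- n_signif + 1
  }
  expect_lte(n_signif, 1)
})

test_that("tandem linkage is transitive but distance-bounded", {
  genes <- make_genes(1:12)
  # (1,3) and (3,12) qualify; (1,12) spans 11 ranks but joins transitively
  arr <- call_tandem_arrays(genes, make_hits(rbind(c("g01", "g03"),
                                                   c("g03", "g12"))))
  expect_equal(nrow(arr), 1)
  expect_equal(arr$size, 3)
  expect_equal(arr$members[[1]], c("g01", "g03", "g12"))

  # rank distance 11 alone exceeds the 10-gene rule
  far <- call_tandem_arrays(genes, make_hits(rbind(c("g01", "g12"))))
  expect_equal(nrow(far), 0)

  # a hit above the e-value cutoff does not link
  weak <- call_tandem_arrays(make_genes(c(1, 2)),
                             make_hits(rbind(c("g01", "g02")), e = 1e-3))
  expect_equal(nrow(weak), 0)

  expect_error(call_tandem_arrays(make_genes(1:2),
                                  make_hits(rbind(c("g01", "gXX")))),
               "unknown gene")
})

test_that("array calling equals an independent graph-component oracle", {
  skip_if_not_installed("igraph")
  set.seed(34)
  for (trial in 1:150) {
    n <- sample(5:50, 1)
    genes <- make_genes(seq_len(n),
                        chrom = sample(c("c1", "c2"), n, replace = TRUE))
    genes <- gene_ranks(genes)
    n_hits <- sample(0:40, 1)
    if (n_hits == 0) next
    pairs <- cbind(sample(genes$gene_id, n_hits, replace = TRUE),
                   sample(genes$gene_id, n_hits, replace = TRUE))
    evals <- 10^runif(n_hits, -30, 0)
    hits <- make_hits(pairs)
    hits$e_value <- evals
    got <- call_tandem_arrays(genes, hits)

    # oracle: igraph components over qualifying edges
    q <- hits[hits$e_value <= 1e-5 & hits$query != hits$subject, ]
    ia <- match(q$query, genes$gene_id)
    ib <- match(q$subject, genes$gene_id)
    ok <- genes$chrom[ia] == genes$chrom[ib] &
      abs(genes$rank[ia] - genes$rank[ib]) <= 10
    gr <- igraph::graph_from_data_frame(
      data.frame(from = q$query[ok], to = q$subject[ok]),
      directed = FALSE, vertices = genes$gene_id)
    comp <- igraph::components(gr)$membership
    want <- unname(sort(table(comp)[table(comp) >= 2], decreasing = TRUE))
    expect_equal(sort(got$size, decreasing = TRUE), as.integer(want))
    # identical membership partition
    got_sets <- lapply(got$members, sort)
    want_sets <- unname(lapply(split(names(comp), comp), sort))
    want_sets <- want_sets[vapply(want_sets, length, 1L) >= 2]
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
  }
})

test_that("array partition ignores id relabeling and hit direction", {
  genes <- make_genes(1:8)
  hits <- make_hits(rbind(c("g01", "g02"), c("g02", "g03"), c("g05", "g06")))
  a <- call_tandem_arrays(genes, hits)
  flipped <- hits
  flipped$query <- hits$subject
  flipped$subject <- hits$query
  b <- call_tandem_arrays(genes, rbind(hits, flipped))
  expect_equal(a$size, b$size)
  expect_equal(a$members, b$members)
})

test_that("tightening the e-value cutoff never merges arrays", {
  set.seed(35)
  genes <- make_genes(1:20)
  pairs <- cbind(sample(genes$gene_id, 25, TRUE),
                 sample(genes$gene_id, 25, TRUE))
  hits <- make_hits(pairs)
  hits$e_value <- 10^runif(25, -12, -2)
  loose <- call_tandem_arrays(genes, hits, e_value_max = 1e-3)
  strict <- call_tandem_arrays(genes, hits, e_value_max = 1e-8)
  # every strict array must be contained in a loose array
  for (m in strict$members) {
    containing <- vapply(loose$members, function(x) all(m %in% x), logical(1))
    expect_true(any(containing))
  }
})

test_that("a planted 26-member array is recovered at full size from homology", {
  w <- tandem26_world()
  arr <- call_tandem_arrays(w$sim$annotations$genes, w$hits)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$size, 26)
  expect_setequal(arr$members[[1]], w$sim$truth$tandem_arrays$members[[1]])
})

test_that("cross-assembly comparison quantifies collapsed arrays", {
  w <- tandem26_world()
  sim <- w$sim
  deg <- degrade_assembly(sim, collapse_fraction = 1, collapse_keep = 4,
                          seed = 3)
  keep <- deg$annotations$genes$gene_id
  hits_old <- w$hits[w$hits$query %in% keep & w$hits$subject %in% keep, ]
  arrays_new <- call_tandem_arrays(sim$annotations$genes, w$hits)
  arrays_old <- call_tandem_arrays(deg$annotations$genes, hits_old)
  expect_equal(arrays_old$size, 4)
  cmp <- compare_assemblies(arrays_old, arrays_new,
                            data.frame(old_id = keep, new_id = keep),
                            genes_old = deg$annotations$genes,
                            genes_new = sim$annotations$genes)
  expect_equal(cmp$matched$delta, 22)
  # new-only gene models equal the planted excised members
  excised <- setdiff(sim$annotations$genes$gene_id, keep)
  expect_equal(unname(cmp$venn["new_only"]), length(excised))
  expect_equal(unname(cmp$venn["old_only"]), 0)
})

test_that("identical and disjoint annotations hit the comparison extremes", {
  genes <- make_genes(1:6)
  hits <- make_hits(rbind(c("g01", "g02"), c("g04", "g05")))
  arrays <- call_tandem_arrays(genes, hits)
  idmap <- data.frame(old_id = genes$gene_id, new_id = genes$gene_id)
  same <- compare_assemblies(arrays, arrays, idmap, genes, genes)
  expect_true(all(same$matched$delta == 0))
  expect_equal(length(same$novel_new_arrays), 0)
  expect_equal(unname(same$venn["new_only"]), 0)

  disjoint <- compare_assemblies(arrays[0, ], arrays,
                                 data.frame(old_id = character(),
                                            new_id = character()),
                                 genes_old = genes[0, ], genes_new = genes)
  expect_equal(disjoint$pct_novel_arrays, 100)
})

test_that("size_class_gain averages percent gains within the class", {
  cmp <- list(matched = data.frame(
    new_array = c("a", "b", "c"), old_array = c("x", "y", "z"),
    chrom = "c1", old_size = c(4, 10, 10), new_size = c(6, 13, 17),
    delta = c(2, 3, 7), stringsAsFactors = FALSE))
  expect_equal(size_class_gain(cmp, 5, 9), 50)
  expect_equal(size_class_gain(cmp, 11), 50)
  expect_length(size_class_gain(cmp, 100), 0)
})
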