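# Shared fixtures: small synthetic worlds built once per session, plus
# independent oracles used across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a compact 2-chromosome world exercising every feature type
tiny_cfg <- function(seed = 7, ...) {
  args <- list(
    n_chromosomes = 2, chrom_length = 200000,
    centromere_copy_range = c(60, 110), pericentromere_width = 30000,
    n_genes_per_chrom = 20,
    tandem_array_spec = list(c(10, 0.05), c(5, 0.05), c(3, 0.05)),
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

tiny_sim <- function() cached("tiny_sim", generate_genome(tiny_cfg()))

tiny_hits <- function() cached("tiny_hits", all_vs_all_hits(gene_sequences(tiny_sim())))

# a single-chromosome world carrying one 26-member tandem array, with its
# all-vs-all homology hits
tandem26_world <- function() {
  cached("tandem26", {
    cfg <- tiny_cfg(seed = 41, n_chromosomes = 1,
                    tandem_array_spec = list(c(26, 0.05)),
                    n_genes_per_chrom = 8)
    sim <- generate_genome(cfg)
    list(sim = sim, hits = all_vs_all_hits(gene_sequences(sim)))
  })
}

# interval Jaccard index
jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1) + 1)
  inter / ((a2 - a1 + 1) + (b2 - b1 + 1) - inter)
}

# brute-force NX oracle: walk the sorted lengths accumulating bases
nx_oracle <- function(lengths, fraction) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (L in s) {
    acc <- acc + L
    if (acc >= fraction * total) return(L)
  }
}

# exhaustive best-chain oracle: depth-first over every valid chain
chain_oracle <- function(x, y, max_gap, penalty) {
  n <- length(x)
  best <- -Inf
  extend <- function(i, score) {
    if (score > best) best <<- score
    for (j in seq_len(n)) {
      gx <- x[j] - x[i]
      gy <- y[j] - y[i]
      if (gx > 0 && gy > 0 && gx <= max_gap && gy <= max_gap)
        extend(j, score + 1 - penalty * (gx - 1 + gy - 1))
    }
  }
  for (i in seq_len(n)) extend(i, 1)
  best
}

# mini affine-gap Smith-Waterman oracle (match/mismatch scoring)
sw_oracle <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                      gap_ext = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)   # ending in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (consume b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
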