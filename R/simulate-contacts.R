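# Hi-C contact matrices and multi-tissue expression count tables for the
# synthetic genomes.

#' Simulate binned intra-chromosomal Hi-C contact matrices
#'
#' Expected contact counts between bins `i` and `j` follow the standard
#' distance-decay law `base_contacts * (1 + |i - j|)^(-decay_exponent)`. Bin
#' pairs where either bin overlaps a planted centromere are multiplied by
#' `depression_factor`, reproducing the depressed intra-chromosomal
#' interaction profile seen over centromeres in Hi-C heat maps. Counts are
#' drawn from a negative binomial with the given dispersion (0 = noise off,
#' expected counts rounded) and symmetrised.
#'
#' @param sim a `sim_genome`.
#' @param bin_size bin width in bp; must be smaller than every chromosome.
#' @param decay_exponent contact distance-decay exponent.
#' @param depression_factor multiplicative depression over centromeric bins.
#' @param noise_dispersion negative binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 disables noise.
#' @param base_contacts expected diagonal contact count.
#' @param seed integer seed.
#' @return named list of `contact_matrix` objects (one per chromosome), each
#'   with fields `chrom`, `bin_size`, `counts`.
#' @export
generate_contact_matrix <- function(sim, bin_size = 25000, decay_exponent = 1,
                                    depression_factor = 0.3,
                                    noise_dispersion = 0.05,
                                    base_contacts = 200, seed = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  assert_fraction(depression_factor, "depression_factor")
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  if (any(bin_size >= lens))
    stopf("bin_size (%d) must be smaller than every chromosome", bin_size)
  cen <- sim$truth$centromeres
  with_seed(seed, {
    out <- lapply(names(lens), function(ch) {
      n <- ceiling(lens[[ch]] / bin_size)
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      mu <- base_contacts * (1 + d)^(-decay_exponent)
      ci <- cen[cen$chrom == ch, , drop = FALSE]
      if (nrow(ci)) {
        bin_start <- (seq_len(n) - 1L) * bin_size + 1L
        bin_end <- pmin(bin_start + bin_size - 1L, lens[[ch]])
        in_cen <- rep(FALSE, n)
        for (r in seq_len(nrow(ci)))
          in_cen <- in_cen | (bin_end >= ci$start[r] & bin_start <= ci$end[r])
        mask <- outer(in_cen, in_cen, "|")
        mu[mask] <- mu[mask] * depression_factor
      }
      counts <- matrix(0L, n, n)
      ut <- upper.tri(mu, diag = TRUE)
      vals <- if (noise_dispersion > 0)
        rnbinom(sum(ut), mu = mu[ut], size = 1 / noise_dispersion)
      else as.integer(round(mu[ut]))
      counts[ut] <- vals
      counts <- counts + t(counts) - diag(diag(counts))
      structure(list(chrom = ch, bin_size = bin_size, counts = counts),
                class = "contact_matrix")
    })
    setNames(out, names(lens))
  })
}

#' Simulate a multi-tissue expression count matrix
#'
#' Genes are partitioned into tissue-specific (planted so their FPKM exceeds
#' 1 in exactly one tissue and stays below 1 elsewhere), broadly detectable,
#' and undetectable (FPKM below 1 everywhere) classes. Counts are negative
#' binomial around the target FPKM back-converted through gene length and
#' library size.
#'
#' @param sim a `sim_genome` (genes and lengths are taken from its
#'   annotations).
#' @param n_tissues number of tissues (>= 2 whenever `specific_fraction > 0`).
#' @param specific_fraction fraction of genes planted as tissue-specific.
#' @param detectable_fraction fraction of genes detectable (FPKM > 1 in at
#'   least one tissue); the default mirrors an atlas in which roughly
#'   two-thirds of newly annotated genes are expressed. Must be >=
#'   `specific_fraction`.
#' @param library_size mapped fragments per tissue library.
#' @param dispersion negative binomial dispersion of counts.
#' @param seed integer seed.
#' @return list with `counts` (genes x tissues integer matrix),
#'   `gene_lengths`, `library_sizes`, `specific_genes` (data.frame gene_id,
#'   tissue), `detectable_genes` (character), and `truth` (the input truth
#'   ledger with `specific_genes` filled in).
#' @export
generate_expression_counts <- function(sim, n_tissues = 10,
                                       specific_fraction = 0.1,
                                       detectable_fraction = 6070 / 9301,
                                       library_size = 2e7,
                                       dispersion = 0.05, seed = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  assert_fraction(specific_fraction, "specific_fraction")
  assert_fraction(detectable_fraction, "detectable_fraction")
  if (specific_fraction > 0 && n_tissues < 2)
    stopf("n_tissues must be >= 2 when specific_fraction > 0")
  if (detectable_fraction < specific_fraction)
    stopf("detectable_fraction must be >= specific_fraction")
  genes <- sim$annotations$genes
  n <- nrow(genes)
  lens <- setNames(genes$end - genes$start + 1L, genes$gene_id)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  with_seed(seed, {
    n_spec <- round(specific_fraction * n)
    n_det <- round(detectable_fraction * n)
    grp <- sample(c(rep("specific", n_spec), rep("broad", n_det - n_spec),
                    rep("off", n - n_det)))
    target <- matrix(0, n, n_tissues, dimnames = list(genes$gene_id, tissues))
    spec_tissue <- character(0)
    for (g in seq_len(n)) {
      target[g, ] <- switch(grp[g],
        specific = runif(n_tissues, 0.005, 0.05),
        broad = rlnorm(n_tissues, log(8), 0.5),
        off = runif(n_tissues, 0.001, 0.03))
    }
    spec_idx <- which(grp == "specific")
    own <- sample.int(n_tissues, length(spec_idx), replace = TRUE)
    for (k in seq_along(spec_idx))
      target[spec_idx[k], own[k]] <- runif(1, 5, 50)
    lib <- setNames(rep(library_size, n_tissues), tissues)
    mu <- target * (lens / 1000) * (library_size / 1e6)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n, n_tissues, dimnames = dimnames(target))
    spec <- data.frame(gene_id = genes$gene_id[spec_idx],
                       tissue = tissues[own], stringsAsFactors = FALSE)
    truth <- sim$truth
    truth$specific_genes <- spec
    list(counts = counts, gene_lengths = lens, library_sizes = lib,
         specific_genes = spec,
         detectable_genes = genes$gene_id[grp != "off"],
         truth = truth)
  })
}
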