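# Fixture builders used across test files. All fixtures are constructed in
# code; nothing is read from disk unless a test writes it first.

# Build a geno_matrix from per-locus genotype-string vectors.
# Each element of `cols` is a character vector over samples; ref/alt are
# inferred from the observed alleles (alphabetical), with an arbitrary alt
# added for monomorphic loci. Use `alleles` to override per locus.
gm_fixture <- function(cols, samples = NULL, chrom = NULL, pos = NULL,
                       qual = 35, depth = NULL, alleles = NULL) {
  m <- length(cols)
  n <- length(cols[[1]])
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(n))
  if (is.null(chrom)) chrom <- rep("Chr1", m)
  if (is.null(pos)) pos <- 1000 * seq_len(m)
  calls <- do.call(cbind, cols)
  rownames(calls) <- samples
  ref <- character(m)
  alts <- vector("list", m)
  for (j in seq_len(m)) {
    if (!is.null(alleles) && !is.null(alleles[[j]])) {
      ref[j] <- alleles[[j]][1]
      alts[[j]] <- alleles[[j]][-1]
    } else {
      g <- calls[, j]
      obs <- sort(unique(as.vector(genotype_alleles(g[g != "NN"]))))
      if (length(obs) == 0) obs <- "A"
      ref[j] <- obs[1]
      alts[[j]] <- if (length(obs) > 1) obs[-1] else setdiff(c("A", "C", "G", "T"), obs)[1]
    }
  }
  loci <- tibble::tibble(
    locus_id = paste0(chrom, "-", pos), chrom = chrom, pos = pos,
    ref = ref, alts = alts, qual = rep_len(qual, m))
  geno_matrix(calls, loci, depth = depth)
}

# Independent brute-force PIC: literal double loop over allele pairs.
pic_bruteforce <- function(freqs) {
  l <- length(freqs)
  s1 <- 0
  for (i in seq_len(l)) s1 <- s1 + freqs[i]^2
  s2 <- 0
  if (l >= 2) {
    for (i in seq_len(l - 1)) {
      for (j in (i + 1):l) s2 <- s2 + 2 * freqs[i]^2 * freqs[j]^2
    }
  }
  1 - s1 - s2
}

# Naive sliding-window substring counter over both strands, pure base R.
count_occurrences_naive <- function(pattern, contigs) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  total <- 0
  for (s in contigs) {
    for (p in unique(c(pattern, rc(pattern)))) {
      w <- nchar(p)
      if (nchar(s) < w) next
      starts <- seq_len(nchar(s) - w + 1)
      total <- total + sum(vapply(starts, function(i) substr(s, i, i + w - 1) == p,
                                  logical(1)))
    }
  }
  total
}

# Random small coverage instance for greedy-vs-exact trials.
random_instance <- function(seed, n_samples = 10, n_loci = 8) {
  set.seed(seed)
  cols <- lapply(seq_len(n_loci), function(j) {
    a <- sample(c("A", "G"), 1)
    g <- sample(c("AA", "AG", "GG", "NN"), n_samples, replace = TRUE,
                prob = c(0.35, 0.3, 0.25, 0.1))
    g
  })
  gm_fixture(cols)
}
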