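test_that("population filter attributes one failure per rule on a planted fixture", {
  n <- 12
  hetero <- rep(c("AG", "AA"), each = 6)
  cols <- list(
    hetero,                                   # fails mean depth (planted below)
    c("AG", rep("AA", n - 1)),                # MAF 1/24 < 0.05
    c(rep("NN", 5), hetero[6:12]),            # call rate 7/12 < 0.7
    hetero,                                   # qual 20 < 30
    c(rep("AG", 4), "AT", "AT", rep("AA", 6)),# 3 observed alleles
    hetero                                    # clean
  )
  depth <- matrix(8, n, 6)
  gm <- gm_fixture(cols, qual = c(40, 40, 40, 20, 40, 40), depth = depth,
                   alleles = list(NULL, c("A", "G"), NULL, NULL,
                                  c("A", "G", "T"), NULL))
  gm$depth[, 1] <- 2
  res <- population_filter(gm)
  expect_equal(n_loci(res$matrix), 1)
  expect_equal(locus_ids(res$matrix), locus_ids(gm)[6])
  expect_equal(res$locus_fates$fate,
               c("mean_depth", "maf", "completeness", "qual", "allele_count",
                 "pass"))
  expect_equal(res$report$n_failed, rep(1L, 5))
  # counts are monotone and survivors + failures = input
  expect_true(all(diff(res$report$n_out) <= 0))
  expect_equal(sum(res$report$n_failed) + n_loci(res$matrix), n_loci(gm))
  expect_equal(tidy(res), res$report)
})

test_that("thresholds are inclusive where the rules say so", {
  n <- 10
  # MAF exactly 0.05: 1 alt copy in 2n = 20
  cols <- list(c("AG", rep("AA", n - 1)))
  gm <- gm_fixture(cols, qual = 40, depth = matrix(5, n, 1))
  res <- population_filter(gm)
  expect_equal(n_loci(res$matrix), 1) # MAF >= 0.05 inclusive; depth 5 inclusive

  # disabled thresholds act as identity on SNP loci
  gm2 <- gm_fixture(list(c("AG", "NN", rep("AA", 8))), qual = NA_real_)
  crit <- filter_criteria(min_mean_depth = 0, min_maf = 0,
                          min_completeness = 0, min_qual = 0)
  res2 <- population_filter(gm2, crit)
  expect_equal(n_loci(res2$matrix), 1)
})

test_that("filter requires the fields its thresholds use", {
  gm <- gm_fixture(list(c("AG", "AA")), qual = 40) # no depth attached
  expect_error(population_filter(gm), "depth")
})

test_that("flank cleanliness uses strict >50 separation", {
  loci <- tibble::tibble(chrom = c("c1", "c1"), pos = c(100, 149))
  expect_equal(flank_cleanliness(loci, radius = 50), c(FALSE, FALSE))
  loci2 <- tibble::tibble(chrom = c("c1", "c1"), pos = c(100, 151))
  expect_equal(flank_cleanliness(loci2, radius = 50), c(TRUE, TRUE))
  # single SNP on a chromosome is clean; other chromosomes don't interfere
  loci3 <- tibble::tibble(chrom = c("c1", "c2"), pos = c(100, 120))
  expect_equal(flank_cleanliness(loci3, radius = 50), c(TRUE, TRUE))
})

test_that("flank uniqueness counts both strands and matches the naive scan", {
  sim <- simulate_reference_with_snps(n_snps = 3, contig_len = 3000,
                                      spacing = 700, duplicate_window = TRUE,
                                      seed = 5)
  ref <- sim$reference
  contigs <- as.character(ref)
  for (j in seq_len(nrow(sim$loci))) {
    w <- extract_flank_window(ref, sim$loci[j, ], each_side = 100)
    seqstr <- paste0(w$upstream_seq, w$ref, w$downstream_seq)
    naive <- count_occurrences_naive(seqstr, contigs)
    expect_equal(flank_uniqueness(w, ref), naive == 1)
  }
  # the duplicated-window SNP is non-unique by construction
  last <- nrow(sim$loci)
  w_dup <- extract_flank_window(ref, sim$loci[last, ], each_side = 100)
  expect_false(flank_uniqueness(w_dup, ref))

  # planting only the reverse complement elsewhere still breaks uniqueness
  w1 <- extract_flank_window(ref, sim$loci[1, ], each_side = 100)
  s1 <- paste0(w1$upstream_seq, w1$ref, w1$downstream_seq)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s1), "")[[1]]), collapse = "")
  ref_rc <- c(ref, Biostrings::DNAStringSet(c(extra = paste0("ACGT", rc, "TGCA"))))
  expect_false(flank_uniqueness(w1, ref_rc))
  expect_equal(count_occurrences_naive(s1, as.character(ref_rc)), 2)

  # degenerate window is an error
  wshort <- w1
  wshort$upstream_seq <- ""
  wshort$downstream_seq <- ""
  expect_error(flank_uniqueness(wshort, ref), "degenerate")
})

test_that("KASP candidate cascade applies its four rules in order", {
  sim <- simulate_reference_with_snps(n_snps = 6, contig_len = 6000,
                                      spacing = 800, neighbor_at = 49,
                                      duplicate_window = TRUE, seed = 9)
  ref <- sim$reference
  loci <- sim$loci
  n <- 50
  m <- nrow(loci)
  calls <- matrix("NN", n, m,
                  dimnames = list(sprintf("S%02d", 1:n), loci$locus_id))
  for (j in seq_len(m)) {
    het <- genotype_string(loci$ref[[j]], loci$alts[[j]][1])
    hom <- genotype_string(loci$ref[[j]], loci$ref[[j]])
    calls[, j] <- rep(c(het, hom), length.out = n)
  }
  depth <- matrix(8, n, m)
  gm <- geno_matrix(calls, loci, depth = depth)
  gm$depth[, 2] <- 3  # fails the mean-depth rule
  # locus 3: one alt copy in 100 -> MAF 0.01, PIC ~0.0196 <= 0.020 (fails PIC,
  # still biallelic)
  gm$calls[, 3] <- genotype_string(loci$ref[[3]], loci$ref[[3]])
  gm$calls[1, 3] <- genotype_string(loci$ref[[3]], loci$alts[[3]][1])

  res <- kasp_candidate_filter(gm, ref)
  fates <- res$locus_fates$fate
  # SNP 1 and the neighbour (last row) fail flank cleanliness
  expect_equal(fates[1], "flank_clean")
  expect_equal(fates[m], "flank_clean")
  expect_equal(fates[2], "depth_biallelic")
  expect_equal(fates[3], "pic")
  expect_equal(fates[6], "flank_unique")  # duplicated window = last planted SNP
  # survivors re-check clean against every predicate
  surv <- res$matrix
  expect_true(all(flank_cleanliness(surv$loci, 50)))
  st <- locus_stats(surv)
  expect_true(all(st$pic > 0.020))

  # PIC exactly at the threshold is removed (strictly greater required)
  expect_false(0.020 > 0.020)
})

test_that("cascade output is invariant to input locus order", {
  n <- 12
  hetero <- rep(c("AG", "AA"), each = 6)
  cols <- list(hetero, c("AG", rep("AA", n - 1)), c(rep("NN", 5), hetero[6:12]),
               hetero, hetero)
  gm <- gm_fixture(cols, qual = c(40, 40, 40, 20, 40), depth = matrix(8, n, 5))
  perm <- c(3, 5, 1, 4, 2)
  gmp <- subset_loci(gm, loci = perm)
  r1 <- population_filter(gm)
  r2 <- population_filter(gmp)
  expect_setequal(locus_ids(r1$matrix), locus_ids(r2$matrix))
})
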