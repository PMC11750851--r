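test_that("Wallace rule matches the hand count and homopolymer boundary", {
  # 10 G/C + 11 A/T in the FAM tail: 4*10 + 2*11 = 62
  expect_equal(melting_temperature("GAAGGTGACCAAGTTCATGCT", method = "wallace"), 62)
  expect_equal(melting_temperature("AAAAAAAAAA", method = "wallace"), 20)
})

test_that("nearest-neighbor Tm is duplex-symmetric and rejects ambiguity codes", {
  set.seed(3)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
    expect_equal(melting_temperature(seq), melting_temperature(rc),
                 tolerance = 1e-9)
  }
  expect_error(melting_temperature("ACGTNACGTN"), "ambiguity")
  expect_error(melting_temperature("ACGT"), "shorter")
  # sanity: a typical 20-mer melts in a PCR-usable range
  tm <- melting_temperature("ACGTACGGCCTAAGCGTTCA")
  expect_gt(tm, 40)
  expect_lt(tm, 75)
})

test_that("assays designed on a balanced synthetic contig validate clean", {
  sim <- simulate_reference_with_snps(n_snps = 5, contig_len = 5000,
                                      spacing = 800, seed = 21)
  n_ok <- 0
  for (j in seq_len(5)) {
    w <- extract_flank_window(sim$reference, sim$loci[j, ], each_side = 120)
    assay <- design_kasp_assay(w, alleles = c(sim$loci$ref[[j]],
                                              sim$loci$alts[[j]][1]))
    if (inherits(assay, "kasp_failure")) {
      # a locally GC-rich flank can be genuinely undesignable; the failure
      # must say which constraint blocked it
      expect_gte(length(assay$diagnostics), 1)
      next
    }
    n_ok <- n_ok + 1
    expect_s3_class(assay, "kasp_assay")
    expect_true(all(assay$validation$pass))
    expect_lte(assay$product_len, 120)

    fam <- assay$primer_fam$body_seq
    vic <- assay$primer_vic$body_seq
    # bodies differ at exactly the 3' terminal base, which equals each allele
    expect_equal(nchar(fam), nchar(vic))
    d <- which(strsplit(fam, "")[[1]] != strsplit(vic, "")[[1]])
    expect_equal(d, nchar(fam))
    expect_equal(substr(fam, nchar(fam), nchar(fam)), assay$allele_fam)
    expect_equal(substr(vic, nchar(vic), nchar(vic)), assay$allele_vic)
    # tails byte-exact
    expect_equal(assay$primer_fam$full_seq, paste0(kasp_tails()[["FAM"]], fam))
    expect_equal(assay$primer_vic$full_seq, paste0(kasp_tails()[["VIC"]], vic))
  }
  expect_gte(n_ok, 3) # most clean SNPs on a balanced contig are designable
})

test_that("reconstructed amplicon is an exact reference substring", {
  sim <- simulate_reference_with_snps(n_snps = 3, contig_len = 4000,
                                      spacing = 900, seed = 8)
  contig <- as.character(sim$reference[["ctg1"]])
  n_ok <- 0
  for (j in 1:3) {
    locus <- sim$loci[j, ]
    w <- extract_flank_window(sim$reference, locus, each_side = 120)
    assay <- design_kasp_assay(w, alleles = c(locus$ref[[1]], locus$alts[[1]][1]))
    if (inherits(assay, "kasp_failure")) next
    n_ok <- n_ok + 1
    ref_primer <- if (assay$allele_fam == locus$ref[[1]]) {
      assay$primer_fam$body_seq
    } else {
      assay$primer_vic$body_seq
    }
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", assay$primer_common$body_seq),
                             "")[[1]]), collapse = "")
    start <- locus$pos - (nchar(ref_primer) - 1)
    amplicon <- substr(contig, start, start + assay$product_len - 1)
    # amplicon starts with the ref-allele primer and ends with the common
    # primer's template
    expect_equal(substr(amplicon, 1, nchar(ref_primer)), ref_primer)
    expect_equal(substr(amplicon, nchar(amplicon) - nchar(rc) + 1, nchar(amplicon)),
                 rc)
    expect_equal(nchar(amplicon), assay$product_len)
  }
  expect_gte(n_ok, 1)
})

test_that("degenerate windows fail with diagnostics; allele swap only swaps tails", {
  w_bad <- structure(list(locus_id = "x-150", chrom = "x", pos = 150, ref = "A",
                          upstream_seq = strrep("A", 100),
                          downstream_seq = strrep("A", 100),
                          each_side = 100, truncated = FALSE),
                     class = "flank_window")
  fail <- design_kasp_assay(w_bad, alleles = c("A", "G"))
  expect_s3_class(fail, "kasp_failure")
  expect_gte(length(fail$diagnostics), 1)

  sim <- simulate_reference_with_snps(n_snps = 5, contig_len = 5000,
                                      spacing = 800, seed = 33)
  # use the first designable SNP of the batch
  j <- which(vapply(seq_len(5), function(j) {
    w <- extract_flank_window(sim$reference, sim$loci[j, ], each_side = 120)
    inherits(design_kasp_assay(w, alleles = c(sim$loci$ref[[j]],
                                              sim$loci$alts[[j]][1])),
             "kasp_assay")
  }, logical(1)))[1]
  expect_false(is.na(j))
  w <- extract_flank_window(sim$reference, sim$loci[j, ], each_side = 120)
  a1 <- design_kasp_assay(w, alleles = c(sim$loci$ref[[j]], sim$loci$alts[[j]][1]))
  a2 <- design_kasp_assay(w, alleles = c(sim$loci$alts[[j]][1], sim$loci$ref[[j]]))
  # unordered allele input: same bodies, same FAM/VIC assignment (alphabetical)
  expect_equal(a1$primer_fam$body_seq, a2$primer_fam$body_seq)
  expect_equal(a1$primer_vic$body_seq, a2$primer_vic$body_seq)
  expect_equal(a1$allele_fam, a2$allele_fam)
})

test_that("validation boundaries: product 120 passes, GC 0.60 fails, tails exact", {
  sim <- simulate_reference_with_snps(n_snps = 1, contig_len = 2000,
                                      spacing = 500, seed = 14)
  w <- extract_flank_window(sim$reference, sim$loci[1, ], each_side = 120)
  assay <- design_kasp_assay(w, alleles = c(sim$loci$ref[[1]],
                                            sim$loci$alts[[1]][1]))
  expect_s3_class(assay, "kasp_assay")

  # product exactly at the limit is inclusive
  a120 <- assay
  a120$product_len <- 120L
  v <- validate_assay(a120)
  expect_true(v$pass[v$rule == "product_within_max"])
  a121 <- assay
  a121$product_len <- 121L
  v2 <- validate_assay(a121)
  expect_false(v2$pass[v2$rule == "product_within_max"])

  # GC exactly at 0.60 fails the strict rule
  g <- assay
  g$primer_common$body_seq <- paste0(strrep("GC", 6), strrep("AT", 4)) # 12/20 GC
  vg <- validate_assay(g)
  expect_false(vg$pass[vg$rule == "gc_below_max"])

  # a single substituted tail base trips the tail-exactness flag
  t <- assay
  t$primer_fam$full_seq <- sub("^G", "T", t$primer_fam$full_seq)
  vt <- validate_assay(t)
  expect_false(vt$pass[vt$rule == "tails_exact"])
})

test_that("design_assays maps over a candidate matrix with pass flags", {
  sim <- simulate_reference_with_snps(n_snps = 4, contig_len = 4000,
                                      spacing = 800, seed = 27)
  n <- 6
  calls <- matrix("NN", n, nrow(sim$loci),
                  dimnames = list(sprintf("S%d", 1:n), sim$loci$locus_id))
  for (j in seq_len(nrow(sim$loci))) {
    calls[, j] <- rep(c(genotype_string(sim$loci$ref[[j]], sim$loci$alts[[j]][1]),
                        genotype_string(sim$loci$ref[[j]], sim$loci$ref[[j]])),
                      length.out = n)
  }
  gm <- geno_matrix(calls, sim$loci)
  out <- design_assays(gm, sim$reference)
  expect_equal(nrow(out), 4)
  expect_gte(sum(out$designed), 1)
  emitted <- out[out$designed, ]
  expect_true(all(emitted$all_rules_pass))
  expect_true(all(emitted$product_len <= 120))
  expect_true(all(emitted$gc_fam < 0.6 & emitted$gc_vic < 0.6 &
                    emitted$gc_common < 0.6))
  expect_true(all(emitted$tm_fam >= 57 & emitted$tm_fam <= 63))
  expect_true(all(emitted$tm_common >= 57 & emitted$tm_common <= 63))
  # failed rows carry a diagnostic failure object
  if (any(!out$designed)) {
    expect_true(all(vapply(out$assay[!out$designed],
                           function(a) inherits(a, "kasp_failure"), logical(1))))
  }
})
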