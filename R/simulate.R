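#' Simulation configuration for structured genotype data
#'
#' Defaults describe a reduced-representation SNP panel for a structured
#' collection of clonally propagated cultivars: four subpopulations (sized
#' like the study collection's groups), moderate differentiation
#' (Fst = 0.1), a heterozygote deficit (f = 0.25), 10% missing calls,
#' sequencing depth around 6.6x, and two duplicate cultivar groups of sizes
#' 4 and 2.
#'
#' @param n_samples Number of samples (default 50).
#' @param n_loci Number of biallelic SNP loci (default 500).
#' @param subpop_sizes Integer vector of subpopulation sizes summing to
#'   `n_samples` (default `c(14, 5, 23, 8)`).
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`
#'   (default 0.1).
#' @param maf_bounds Ancestral allele-frequency bounds, Uniform draw
#'   (default `c(0.05, 0.5)`).
#' @param inbreeding Within-individual inbreeding coefficient f in `[0, 1]`:
#'   P(het) = 2pq(1-f) (default 0.25).
#' @param missing_rate I.i.d. probability a call is missing (default 0.10).
#' @param duplicate_group_sizes Sizes of duplicate cultivar groups to inject
#'   (default `c(4, 2)`; use `integer(0)` for none).
#' @param depth_mean,depth_dispersion Negative-binomial read depth
#'   parameters: mean and size (default 6.6 and 3).
#' @param qual_mean,qual_sd Normal site-quality parameters, floored at 0
#'   (default 40 and 8).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 50, n_loci = 500,
                       subpop_sizes = c(14, 5, 23, 8),
                       fst = 0.1, maf_bounds = c(0.05, 0.5),
                       inbreeding = 0.25, missing_rate = 0.10,
                       duplicate_group_sizes = c(4, 2),
                       depth_mean = 6.6, depth_dispersion = 3,
                       qual_mean = 40, qual_sd = 8,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility", call. = FALSE)
  stopifnot(fst >= 0, fst < 1, missing_rate >= 0, missing_rate < 1,
            inbreeding >= 0, inbreeding <= 1,
            sum(subpop_sizes) == n_samples,
            all(duplicate_group_sizes <= n_samples))
  structure(list(n_samples = n_samples, n_loci = n_loci,
                 subpop_sizes = subpop_sizes, fst = fst,
                 maf_bounds = maf_bounds, inbreeding = inbreeding,
                 missing_rate = missing_rate,
                 duplicate_group_sizes = duplicate_group_sizes,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 qual_mean = qual_mean, qual_sd = qual_sd, seed = seed),
            class = "sim_config")
}

#' Simulate genotypes under a structured (Balding-Nichols) population
#'
#' Ancestral frequency \eqn{p_0 \sim U(bounds)} per locus; each
#' subpopulation draws its frequency from
#' \eqn{Beta(p_0(1-F)/F, (1-p_0)(1-F)/F)} (exactly \eqn{p_0} when F = 0).
#' Genotypes are drawn with inbreeding coefficient f:
#' P(AA) = p^2 + fpq, P(Aa) = 2pq(1-f), P(aa) = q^2 + fpq. Missing calls are
#' i.i.d. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return A list: `matrix` (a [geno_matrix()], no depth/qual yet) and
#'   `truth` (list with `ancestral_freq`, `subpop_freq` matrix,
#'   `subpop_of` sample labels, `ref_allele`, `alt_allele`).
#' @export
simulate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_loci
    k <- length(config$subpop_sizes)
    subpop_of <- rep(seq_len(k), times = config$subpop_sizes)
    p0 <- stats::runif(m, config$maf_bounds[1], config$maf_bounds[2])
    f_st <- config$fst
    subpop_freq <- matrix(0, nrow = k, ncol = m)
    for (i in seq_len(k)) {
      subpop_freq[i, ] <- if (f_st == 0) p0 else
        stats::rbeta(m, p0 * (1 - f_st) / f_st, (1 - p0) * (1 - f_st) / f_st)
    }
    # allele pair per locus: ref/alt drawn without replacement
    pair <- replicate(m, sample(c("A", "C", "G", "T"), 2))
    ref <- pair[1, ]; alt <- pair[2, ]

    f <- config$inbreeding
    p_mat <- subpop_freq[subpop_of, , drop = FALSE] # n x m, freq of REF allele
    u <- matrix(stats::runif(n * m), n, m)
    q_mat <- 1 - p_mat
    p_hom_ref <- p_mat^2 + f * p_mat * q_mat
    p_het <- 2 * p_mat * q_mat * (1 - f)
    gt_class <- ifelse(u < p_hom_ref, 0L, ifelse(u < p_hom_ref + p_het, 1L, 2L))
    calls <- matrix("NN", n, m)
    for (j in seq_len(m)) {
      g <- character(n)
      g[gt_class[, j] == 0L] <- genotype_string(ref[j], ref[j])
      g[gt_class[, j] == 1L] <- genotype_string(ref[j], alt[j])
      g[gt_class[, j] == 2L] <- genotype_string(alt[j], alt[j])
      calls[, j] <- g
    }
    if (config$missing_rate > 0) {
      calls[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <- "NN"
    }
    chrom <- paste0("Chr", ((seq_len(m) - 1) %% 20) + 1)
    pos <- 1000 * (((seq_len(m) - 1) %/% 20) + 1)
    loci <- tibble::tibble(locus_id = paste0(chrom, "-", pos),
                           chrom = chrom, pos = pos,
                           ref = ref, alts = as.list(alt))
    rownames(calls) <- sprintf("CES%03d", seq_len(n))
    gm <- geno_matrix(calls, loci)
    list(matrix = gm,
         truth = list(ancestral_freq = p0, subpop_freq = subpop_freq,
                      subpop_of = subpop_of, ref_allele = ref, alt_allele = alt))
  })
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Overwrite designated samples with duplicate-group copies
#'
#' Emulates indistinguishable cultivar groups: each group's members are
#' overwritten with the calls (including the missing pattern) of the
#' group's seed sample. Groups are drawn without overlap from the sample
#' list using the given seed.
#'
#' @param gm A [geno_matrix()].
#' @param group_sizes Integer sizes (size-1 groups are no-ops).
#' @param seed Integer seed for member selection.
#' @return A list: `matrix` (modified [geno_matrix()]) and `groups` (list of
#'   sample-id vectors; first element is the copied-from seed sample).
#' @export
inject_duplicate_groups <- function(gm, group_sizes, seed) {
  if (sum(group_sizes) > n_samples(gm)) {
    stop("duplicate groups exceed sample count", call. = FALSE)
  }
  withr_seed(seed, {
    pool <- sample(sample_ids(gm))
    groups <- list()
    calls <- gm$calls
    depth <- gm$depth
    for (gs in group_sizes) {
      members <- pool[seq_len(gs)]
      pool <- pool[-seq_len(gs)]
      members <- sort(members)
      if (gs > 1) {
        for (mm in members[-1]) {
          calls[mm, ] <- calls[members[1], ]
          if (!is.null(depth)) depth[mm, ] <- depth[members[1], ]
        }
      }
      groups[[length(groups) + 1]] <- members
    }
    list(matrix = geno_matrix(calls, gm$loci, depth = depth), groups = groups)
  })
}

#' Attach simulated per-locus depth, quality and planted filter violations
#'
#' Draws per-sample read depth from a negative binomial and site quality
#' from a floored normal, then (optionally) plants one clean violation of
#' each population-filter rule on designated loci: low depth, low MAF
#' (all-but-one-copy monomorphic), low completeness, low quality, and a
#' third allele.
#'
#' @param gm A [geno_matrix()].
#' @param config A [sim_config()].
#' @param plant_violations Integer count per rule (default 0). Uses the
#'   first `5 * plant_violations` loci, one rule each in the fixed rule
#'   order.
#' @return A list: `matrix` (with depth and qual attached) and `truth`
#'   (tibble `locus_id`, `planted_rule`).
#' @export
simulate_locus_metadata <- function(gm, config, plant_violations = 0) {
  withr_seed(config$seed + 1L, {
    n <- n_samples(gm); m <- n_loci(gm)
    depth <- matrix(stats::rnbinom(n * m, mu = config$depth_mean,
                                   size = config$depth_dispersion), n, m)
    qual <- pmax(0, stats::rnorm(m, config$qual_mean, config$qual_sd))
    calls <- gm$calls
    loci <- gm$loci
    loci$qual <- qual
    planted <- tibble::tibble(locus_id = character(0), planted_rule = character(0))
    if (plant_violations > 0) {
      rules <- c("mean_depth", "maf", "completeness", "qual", "allele_count")
      need <- 5 * plant_violations
      if (need > m) stop("not enough loci to plant violations", call. = FALSE)
      tgt <- seq_len(need)
      rule_of <- rep(rules, each = plant_violations)
      # interleaved balanced pattern (het/hom-ref alternating): MAF ~0.25,
      # complete, biallelic - guaranteed clean against every other rule
      balanced <- function(ref, alt) {
        g <- rep(genotype_string(ref, ref), n)
        g[seq(1, n, by = 2)] <- genotype_string(ref, alt)
        g
      }
      for (t in seq_along(tgt)) {
        j <- tgt[t]
        rule <- rule_of[t]
        alleles <- c(loci$ref[[j]], loci$alts[[j]][1])
        calls[, j] <- balanced(alleles[1], alleles[2])
        depth[, j] <- pmax(depth[, j], 5)
        loci$qual[j] <- max(loci$qual[j], 31)
        if (rule == "mean_depth") {
          depth[, j] <- pmin(stats::rnbinom(n, mu = 2,
                                            size = config$depth_dispersion), 4)
        } else if (rule == "maf") {
          calls[, j] <- genotype_string(alleles[1], alleles[1])
          calls[1, j] <- genotype_string(alleles[1], alleles[2]) # one alt copy
        } else if (rule == "completeness") {
          calls[seq_len(ceiling(0.5 * n)), j] <- "NN"
        } else if (rule == "qual") {
          loci$qual[j] <- stats::runif(1, 5, 25)
        } else if (rule == "allele_count") {
          third <- setdiff(c("A", "C", "G", "T"), alleles)[1]
          loci$alts[[j]] <- c(loci$alts[[j]], third)
          k3 <- max(2, ceiling(0.15 * n)) # keep every allele above the MAF floor
          calls[seq(2, by = 2, length.out = k3), j] <-
            genotype_string(alleles[1], third)
        }
        planted <- dplyr::bind_rows(planted, tibble::tibble(
          locus_id = loci$locus_id[j], planted_rule = rule))
      }
      # non-planted loci must deterministically clear every threshold
      clean <- setdiff(seq_len(m), tgt)
      depth[, clean][depth[, clean] < 5] <- 5
      loci$qual[clean] <- pmax(loci$qual[clean], 31)
      for (j in clean) {
        g <- calls[, j]
        al <- as.vector(genotype_alleles(g[g != "NN"]))
        tabs <- if (length(al)) table(al) else table(character(0))
        mafj <- if (length(tabs) < 2) 0 else min(tabs) / sum(tabs)
        if (mean(g != "NN") < 0.75 || mafj < 0.05 || length(tabs) != 2) {
          calls[, j] <- balanced(loci$ref[[j]], loci$alts[[j]][1])
        }
      }
    }
    list(matrix = geno_matrix(calls, loci, depth = depth), truth = planted)
  })
}

#' Simulate a reference genome with planted SNPs
#'
#' Builds random GC-balanced contigs and plants biallelic SNPs with clean
#' flanks, plus optional deliberately dirty cases: a close neighbour
#' variant at a given distance, and a duplicated flank window copied
#' elsewhere in the genome.
#'
#' @param n_snps Clean SNPs to plant (default 10).
#' @param contig_len Contig length in bases (default 10000).
#' @param spacing Distance between planted SNPs (default 500; must exceed
#'   twice the uniqueness window for clean cases).
#' @param neighbor_at Optional distance at which to plant a neighbour
#'   variant next to the first SNP (e.g. 49 to violate a 50-base radius).
#' @param duplicate_window Copy the +/-100-base window of the last SNP to a
#'   second contig, making it non-unique? Default `FALSE`.
#' @param seed Integer seed.
#' @return A list: `reference` (DNAStringSet), `loci` (locus tibble; the
#'   neighbour variant, when planted, is the last row), `truth` (tibble
#'   `locus_id`, `clean_flank`, `unique_flank`).
#' @export
simulate_reference_with_snps <- function(n_snps = 10, contig_len = 10000,
                                         spacing = 500, neighbor_at = NULL,
                                         duplicate_window = FALSE, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  withr_seed(seed, {
    bases <- c("A", "C", "G", "T")
    contig <- paste(sample(bases, contig_len, replace = TRUE), collapse = "")
    pos <- 200 + spacing * (seq_len(n_snps) - 1)
    stopifnot(max(pos) + 200 <= contig_len)
    ref <- vapply(pos, function(p) substr(contig, p, p), "")
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    loci <- tibble::tibble(locus_id = paste0("ctg1-", pos), chrom = "ctg1",
                           pos = pos, ref = ref, alts = as.list(alt))
    clean <- rep(TRUE, n_snps)
    uniq <- rep(TRUE, n_snps)
    if (!is.null(neighbor_at)) {
      np <- pos[1] + neighbor_at
      nref <- substr(contig, np, np)
      nalt <- sample(setdiff(bases, nref), 1)
      loci <- dplyr::bind_rows(loci, tibble::tibble(
        locus_id = paste0("ctg1-", np), chrom = "ctg1", pos = np,
        ref = nref, alts = list(nalt)))
      clean <- c(clean, rep(TRUE, 1))
      uniq <- c(uniq, TRUE)
      clean[1] <- FALSE
      clean[length(clean)] <- FALSE
    }
    seqs <- c(ctg1 = contig)
    if (duplicate_window) {
      p <- pos[n_snps]
      win <- substr(contig, p - 100, p + 100)
      filler <- paste(sample(bases, 400, replace = TRUE), collapse = "")
      seqs <- c(seqs, ctg2 = paste0(filler, win, filler))
      uniq[n_snps] <- FALSE
    }
    reference <- Biostrings::DNAStringSet(seqs)
    list(reference = reference, loci = loci,
         truth = tibble::tibble(locus_id = loci$locus_id,
                                clean_flank = clean, unique_flank = uniq))
  })
}

#' Hudson-style Fst estimator from subpopulation labels
#'
#' Ratio-of-averages Hudson estimator, averaged over all subpopulation
#' pairs: per locus and pair, numerator
#' \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, with \eqn{n} counted in
#' allele copies. Used to check that the simulator's differentiation
#' parameter is recoverable.
#'
#' @param gm A [geno_matrix()].
#' @param subpop_of Integer/character subpopulation label per sample.
#' @return Estimated Fst (single number).
#' @export
hudson_fst <- function(gm, subpop_of) {
  stopifnot(length(subpop_of) == n_samples(gm))
  pops <- unique(subpop_of)
  if (length(pops) < 2) stop("need >= 2 subpopulations", call. = FALSE)
  num_total <- 0
  den_total <- 0
  # per-pop allele frequency of the ref allele, per locus
  freq_n <- function(pop) {
    idx <- which(subpop_of == pop)
    sapply(seq_len(n_loci(gm)), function(j) {
      g <- gm$calls[idx, j]
      g <- g[g != "NN"]
      if (!length(g)) return(c(NA, 0))
      al <- as.vector(genotype_alleles(g))
      c(mean(al == gm$loci$ref[[j]]), length(al))
    })
  }
  fr <- lapply(pops, freq_n)
  names(fr) <- as.character(pops)
  cmb <- utils::combn(length(pops), 2)
  for (k in seq_len(ncol(cmb))) {
    a <- fr[[cmb[1, k]]]; b <- fr[[cmb[2, k]]]
    p1 <- a[1, ]; n1 <- a[2, ]; p2 <- b[1, ]; n2 <- b[2, ]
    ok <- !is.na(p1) & !is.na(p2) & n1 > 1 & n2 > 1
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    num_total <- num_total + sum(num[ok])
    den_total <- den_total + sum(den[ok])
  }
  num_total / den_total
}
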