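#' Allele frequencies of one locus column
#'
#' Counts two allele copies per called sample; missing calls are excluded
#' from the denominator.
#'
#' @param calls Character vector of canonical genotype strings (`"NN"` for
#'   missing).
#' @return A list with `freqs` (named numeric vector, allele -> frequency)
#'   and `n_called`.
#' @examples
#' allele_frequencies(c("AA", "AG", "GG", "AG"))
#' @export
allele_frequencies <- function(calls) {
  called <- calls != "NN"
  if (!any(called)) {
    stop("undefined statistic: all calls missing at this locus", call. = FALSE)
  }
  al <- as.vector(genotype_alleles(calls[called]))
  tab <- table(al)
  list(freqs = stats::setNames(as.numeric(tab) / sum(tab), names(tab)),
       n_called = sum(called))
}

#' Polymorphic information content
#'
#' PIC for a locus with allele frequencies \eqn{P_i}:
#' \deqn{PIC = 1 - \sum_i P_i^2 - \sum_{i<j} 2 P_i^2 P_j^2}
#' with both summations running over the distinct alleles of the locus.
#' Monomorphic loci give 0. For a biallelic locus with frequencies p, q this
#' reduces to \eqn{1 - (p^2+q^2) - 2p^2q^2}, with maximum 0.375 at p = 0.5.
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return PIC value in `[0, 0.375]` for biallelic loci.
#' @examples
#' pic(c(0.479, 0.521)) # ~0.375
#' pic(c(0.125, 0.875)) # ~0.195
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  p2 <- freqs^2
  cross <- sum(p2)^2 - sum(p2^2) # equals 2 * sum_{i<j} p_i^2 p_j^2
  1 - sum(p2) - cross
}

#' Expected heterozygosity (gene diversity)
#'
#' \eqn{H_E = 1 - \sum_i P_i^2}, uncorrected for sample size.
#'
#' @inheritParams pic
#' @return Expected heterozygosity in `[0, 1)`.
#' @export
expected_heterozygosity <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

check_freqs <- function(freqs) {
  if (length(freqs) < 1 || any(freqs < 0)) {
    stop("allele frequencies must be non-negative", call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > 1e-8) {
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Observed heterozygosity
#'
#' Fraction of called samples whose two alleles differ.
#'
#' @inheritParams allele_frequencies
#' @return Proportion heterozygous among non-missing calls.
#' @export
observed_heterozygosity <- function(calls) {
  called <- calls != "NN"
  if (!any(called)) {
    stop("undefined statistic: all calls missing at this locus", call. = FALSE)
  }
  al <- genotype_alleles(calls[called])
  mean(al[, 1] != al[, 2])
}

#' Per-locus genetic index suite
#'
#' For every locus of a genotype matrix, computes the standard marker
#' informativeness bundle: allele counts, minor allele frequency, observed
#' and expected heterozygosity, PIC, effective number of alleles
#' (\eqn{N_e = 1/\sum P_i^2}), per-site nucleotide diversity (defined equal
#' to \eqn{H_E}, i.e. per-site heterozygosity without pairwise-sample
#' correction), and the inbreeding coefficient
#' \eqn{F_{IS} = 1 - H_{obs}/H_{exp}} (NA where \eqn{H_{exp} = 0}).
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with one row per locus and columns `locus_id`, `chrom`,
#'   `pos`, `n_called`, `n_alleles`, `maf`, `het_obs`, `het_exp`, `pic`,
#'   `ne`, `pi_site`, `fis`. All-missing loci yield NA statistics.
#' @export
locus_stats <- function(gm) {
  rows <- purrr::map(seq_len(n_loci(gm)), function(j) {
    g <- gm$calls[, j]
    if (all(g == "NN")) {
      return(tibble::tibble(n_called = 0L, n_alleles = NA_integer_,
                            maf = NA_real_, het_obs = NA_real_, het_exp = NA_real_,
                            pic = NA_real_, ne = NA_real_, pi_site = NA_real_,
                            fis = NA_real_))
    }
    af <- allele_frequencies(g)
    he <- expected_heterozygosity(af$freqs)
    ho <- observed_heterozygosity(g)
    tibble::tibble(
      n_called = af$n_called,
      n_alleles = length(af$freqs),
      maf = if (length(af$freqs) == 1) 0 else min(af$freqs),
      het_obs = ho,
      het_exp = he,
      pic = pic(af$freqs),
      ne = 1 / sum(af$freqs^2),
      pi_site = he,
      fis = if (he > 0) 1 - ho / he else NA_real_
    )
  })
  dplyr::bind_cols(gm$loci[, c("locus_id", "chrom", "pos")],
                   dplyr::bind_rows(rows))
}

#' Population-level summary of the locus index suite
#'
#' Arithmetic mean of each per-locus index over loci where it is defined
#' (the inbreeding coefficient is averaged over loci with non-zero expected
#' heterozygosity), in the conventional report order.
#'
#' @param gm A [geno_matrix()].
#' @return A one-row tibble: `n_sites`, `n_polymorphic`, `het_obs`,
#'   `het_exp`, `pi_site`, `fis`, `pic`, `ne`, `maf`.
#' @export
population_summary <- function(gm) {
  if (n_loci(gm) == 0) stop("empty genotype matrix", call. = FALSE)
  st <- locus_stats(gm)
  if (all(is.na(st$het_exp))) stop("no locus with defined statistics", call. = FALSE)
  tibble::tibble(
    n_sites = nrow(st),
    n_polymorphic = sum(st$n_alleles >= 2, na.rm = TRUE),
    het_obs = mean(st$het_obs, na.rm = TRUE),
    het_exp = mean(st$het_exp, na.rm = TRUE),
    pi_site = mean(st$pi_site, na.rm = TRUE),
    fis = if (all(is.na(st$fis))) NA_real_ else mean(st$fis, na.rm = TRUE),
    pic = mean(st$pic, na.rm = TRUE),
    ne = mean(st$ne, na.rm = TRUE),
    maf = mean(st$maf, na.rm = TRUE)
  )
}

#' @method glance geno_matrix
#' @export
glance.geno_matrix <- function(x, ...) population_summary(x)

#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) locus_stats(x)

#' Round half-up for report display
#'
#' Report tables display indices rounded half-up (0.0005 -> 0.001), unlike
#' base R's round-half-even. Internal computations keep full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}
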