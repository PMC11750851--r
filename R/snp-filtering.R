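#' Filter criteria for the two SNP screening cascades
#'
#' Bundles the thresholds of the population-grade filter (depth, MAF,
#' completeness, site quality, biallelism) and the KASP-candidate filter
#' (flank cleanliness radius, flank uniqueness window, minimum PIC).
#'
#' @param min_mean_depth Minimum mean per-sample read depth (default 5).
#' @param min_maf Minimum minor allele frequency, inclusive (default 0.05).
#' @param min_completeness Minimum fraction of samples with a call,
#'   inclusive (default 0.70).
#' @param min_qual Minimum Phred-scaled site quality, inclusive (default 30).
#' @param required_allele_count Exact number of observed alleles (default 2).
#' @param flank_clean_radius No other variant within this many bases on
#'   either side (default 50).
#' @param uniqueness_window Flank half-width used for the uniqueness scan
#'   (default 100).
#' @param min_pic PIC must be strictly greater than this (default 0.020).
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_mean_depth = 5, min_maf = 0.05,
                            min_completeness = 0.70, min_qual = 30,
                            required_allele_count = 2,
                            flank_clean_radius = 50, uniqueness_window = 100,
                            min_pic = 0.020) {
  stopifnot(min_mean_depth >= 0, min_maf >= 0, min_qual >= 0,
            min_completeness >= 0, min_completeness <= 1,
            flank_clean_radius >= 0, uniqueness_window >= 0, min_pic >= 0)
  structure(list(min_mean_depth = min_mean_depth, min_maf = min_maf,
                 min_completeness = min_completeness, min_qual = min_qual,
                 required_allele_count = required_allele_count,
                 flank_clean_radius = flank_clean_radius,
                 uniqueness_window = uniqueness_window, min_pic = min_pic),
            class = "filter_criteria")
}

#' Population-grade SNP filter
#'
#' The preliminary screening cascade: retains loci with mean per-sample
#' depth >= `min_mean_depth`, MAF >= `min_maf`, call rate >=
#' `min_completeness`, site quality >= `min_qual` and exactly
#' `required_allele_count` observed alleles. Rules are applied in that fixed
#' order for reporting: each failing locus is attributed to the first rule
#' it violates. A threshold can be disabled by setting it to 0 (or `-Inf`);
#' an enabled depth/quality threshold requires the corresponding field.
#'
#' @param gm A [geno_matrix()].
#' @param criteria A [filter_criteria()].
#' @return A list of class `filter_result` with elements `matrix` (the
#'   filtered [geno_matrix()]), `report` (per-stage tibble: rule, n_in,
#'   n_failed, n_out) and `locus_fates` (tibble: locus_id, fate).
#' @export
population_filter <- function(gm, criteria = filter_criteria()) {
  if (criteria$min_mean_depth > 0 && is.null(gm$depth)) {
    stop("depth threshold enabled but the matrix carries no depth field",
         call. = FALSE)
  }
  if (criteria$min_qual > 0 && all(is.na(gm$loci$qual))) {
    stop("quality threshold enabled but loci carry no qual field", call. = FALSE)
  }
  st <- locus_stats(gm)
  mean_depth <- if (is.null(gm$depth)) rep(Inf, n_loci(gm)) else colMeans(gm$depth, na.rm = TRUE)
  call_rate <- colMeans(gm$calls != "NN")
  checks <- list(
    mean_depth = mean_depth >= criteria$min_mean_depth,
    maf = dplyr::coalesce(st$maf, 0) >= criteria$min_maf,
    completeness = call_rate >= criteria$min_completeness,
    qual = dplyr::coalesce(gm$loci$qual, -Inf) >= criteria$min_qual |
      criteria$min_qual <= 0,
    allele_count = dplyr::coalesce(st$n_alleles, 0L) == criteria$required_allele_count
  )
  finish_cascade(gm, checks)
}

# Shared cascade bookkeeping: first-failed-rule attribution in fixed order.
finish_cascade <- function(gm, checks) {
  fate <- rep("pass", n_loci(gm))
  for (rule in names(checks)) {
    fate[fate == "pass" & !checks[[rule]]] <- rule
  }
  surviving <- fate == "pass"
  n_in <- n_loci(gm)
  report <- purrr::imap_dfr(checks, function(ok, rule) {
    failed_here <- sum(fate == rule)
    out <- tibble::tibble(rule = rule, n_in = n_in, n_failed = failed_here,
                          n_out = n_in - failed_here)
    n_in <<- n_in - failed_here
    out
  })
  structure(list(
    matrix = subset_loci(gm, loci = which(surviving)),
    report = report,
    locus_fates = tibble::tibble(locus_id = locus_ids(gm), fate = fate)
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", nrow(x$locus_fates), " loci in, ",
      n_loci(x$matrix), " retained\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @method tidy filter_result
#' @export
tidy.filter_result <- function(x, ...) x$report

#' Flank cleanliness: no neighbouring variant within a radius
#'
#' A locus has clean flanks when no other variant lies within `radius`
#' bases on either side on the same chromosome (a neighbour at exactly
#' `radius` bases fails; separation must be strictly greater).
#'
#' @param loci Locus table (tibble with `chrom`, `pos`).
#' @param radius Bases each side (default 50).
#' @return Logical vector, one per locus, in input order.
#' @export
flank_cleanliness <- function(loci, radius = 50) {
  loci <- tibble::as_tibble(loci)
  out <- logical(nrow(loci))
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    p <- sort(loci$pos[idx])
    near <- vapply(loci$pos[idx], function(x) {
      any(abs(p - x) > 0 & abs(p - x) <= radius) || sum(p == x) > 1
    }, logical(1))
    out[idx] <- !near
  }
  out
}

#' Flank uniqueness: the SNP window occurs exactly once in the reference
#'
#' Tests whether the concatenated `upstream + ref + downstream` window
#' string occurs exactly once in the reference genome, counting both
#' strands. Matching is exact (no mismatches), implemented as a full-string
#' scan over every contig and its reverse complement.
#'
#' @param window A `flank_window` from [extract_flank_window()].
#' @param reference A `DNAStringSet` or FASTA path.
#' @param min_len Minimum usable window length; shorter windows are a
#'   degenerate-window error (default 31).
#' @return `TRUE` iff the window is unique in the reference.
#' @export
flank_uniqueness <- function(window, reference, min_len = 31) {
  reference <- as_reference(reference)
  seq <- paste0(window$upstream_seq, window$ref, window$downstream_seq)
  if (nchar(seq) < min_len) {
    stop("degenerate window (", nchar(seq), " < ", min_len, " bases) at ",
         window$locus_id, call. = FALSE)
  }
  pat <- Biostrings::DNAString(seq)
  hits_fwd <- sum(Biostrings::vcountPattern(pat, reference))
  hits_rev <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), reference))
  # A palindromic window would be double-counted; treat identical fwd/rev
  # coordinates as one occurrence.
  if (as.character(Biostrings::reverseComplement(pat)) == seq) {
    hits_rev <- 0
  }
  (hits_fwd + hits_rev) == 1
}

#' KASP-candidate filter cascade
#'
#' The marker-design screening applied after the population-grade filter,
#' in fixed order: flank cleanliness (no variant within
#' `flank_clean_radius`), mean depth and biallelism, flank uniqueness
#' against the reference (window of `uniqueness_window` bases each side),
#' then PIC strictly greater than `min_pic`.
#'
#' @inheritParams population_filter
#' @param reference A `DNAStringSet` or FASTA path.
#' @return A `filter_result` (see [population_filter()]).
#' @export
kasp_candidate_filter <- function(gm, reference, criteria = filter_criteria()) {
  reference <- as_reference(reference)
  st <- locus_stats(gm)
  mean_depth <- if (is.null(gm$depth)) rep(Inf, n_loci(gm)) else colMeans(gm$depth, na.rm = TRUE)
  clean <- flank_cleanliness(gm$loci, radius = criteria$flank_clean_radius)
  depth_biallelic <- mean_depth >= criteria$min_mean_depth &
    dplyr::coalesce(st$n_alleles, 0L) == 2L
  unique_flank <- vapply(seq_len(n_loci(gm)), function(j) {
    if (!clean[j] || !depth_biallelic[j]) return(NA) # not evaluated past failure
    w <- suppressWarnings(extract_flank_window(
      reference, gm$loci[j, ], each_side = criteria$uniqueness_window))
    flank_uniqueness(w, reference)
  }, logical(1))
  checks <- list(
    flank_clean = clean,
    depth_biallelic = depth_biallelic,
    flank_unique = dplyr::coalesce(unique_flank, TRUE),
    pic = dplyr::coalesce(st$pic, 0) > criteria$min_pic
  )
  finish_cascade(gm, checks)
}
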