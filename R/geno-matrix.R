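#' Genotype matrix of unordered biallelic calls
#'
#' `geno_matrix()` builds the central container of the package: a samples x
#' loci grid of unordered diploid allele-pair calls, plus a per-locus
#' metadata table. Calls are two-letter strings in canonical (alphabetical)
#' order, e.g. `"AG"` never `"GA"`; missing calls are `"NN"`.
#'
#' @param calls Character matrix, samples in rows (rownames = sample ids),
#'   loci in columns (colnames = locus ids). Entries are canonical genotype
#'   strings or `"NN"`.
#' @param loci Data frame with one row per locus, columns `locus_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alts` (list column of character
#'   vectors), and optionally `qual` and `region_class`. Row order must match
#'   the column order of `calls`.
#' @param depth Optional integer matrix of per-sample read depth, same
#'   dimensions and dimnames as `calls`.
#' @return An object of class `geno_matrix`.
#' @examples
#' gm <- geno_matrix(
#'   calls = matrix(c("AA", "AG", "GG"), nrow = 3,
#'                  dimnames = list(c("s1", "s2", "s3"), "Chr1-100")),
#'   loci = tibble::tibble(locus_id = "Chr1-100", chrom = "Chr1", pos = 100,
#'                         ref = "A", alts = list("G"), qual = 35)
#' )
#' gm
#' @export
geno_matrix <- function(calls, loci, depth = NULL) {
  stopifnot(is.matrix(calls), is.character(calls))
  loci <- tibble::as_tibble(loci)
  if (!all(c("locus_id", "chrom", "pos", "ref", "alts") %in% names(loci))) {
    stop("`loci` must have columns locus_id, chrom, pos, ref, alts", call. = FALSE)
  }
  if (!"qual" %in% names(loci)) loci$qual <- NA_real_
  if (!"region_class" %in% names(loci)) loci$region_class <- NA_character_
  if (ncol(calls) != nrow(loci)) {
    stop("call grid has ", ncol(calls), " columns but `loci` has ",
         nrow(loci), " rows", call. = FALSE)
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  }
  if (anyDuplicated(rownames(calls))) stop("sample ids must be unique", call. = FALSE)
  colnames(calls) <- loci$locus_id
  if (any(loci$pos < 1)) stop("locus positions must be >= 1", call. = FALSE)
  bad_ref <- purrr::map2_lgl(loci$ref, loci$alts, ~ .x %in% .y)
  if (any(bad_ref)) {
    stop("ref allele listed among alts at ", loci$locus_id[which(bad_ref)[1]],
         call. = FALSE)
  }
  validate_calls(calls, loci)
  if (!is.null(depth)) {
    stopifnot(all(dim(depth) == dim(calls)))
    dimnames(depth) <- dimnames(calls)
    if (any(depth < 0, na.rm = TRUE)) stop("depths must be non-negative", call. = FALSE)
  }
  structure(list(calls = calls, loci = loci, depth = depth),
            class = "geno_matrix")
}

validate_calls <- function(calls, loci) {
  for (j in seq_len(ncol(calls))) {
    col <- calls[, j]
    ok_alleles <- c(loci$ref[[j]], loci$alts[[j]])
    called <- col != "NN"
    if (!all(called | col == "NN")) stop("bad call state", call. = FALSE)
    al <- cbind(substr(col[called], 1, 1), substr(col[called], 2, 2))
    if (length(al) && !all(al %in% ok_alleles)) {
      bad <- which(called)[which(!(al[, 1] %in% ok_alleles & al[, 2] %in% ok_alleles))[1]]
      stop("call ", col[bad], " at locus ", loci$locus_id[[j]],
           " uses an allele outside {ref, alts}", call. = FALSE)
    }
    if (length(al) && !all(al[, 1] <= al[, 2])) {
      stop("non-canonical genotype string at locus ", loci$locus_id[[j]],
           " (alleles must be alphabetically ordered)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", n_samples(x), " samples x ", n_loci(x), " loci\n", sep = "")
  miss <- mean(x$calls == "NN")
  cat("  missing calls: ", sprintf("%.1f%%", 100 * miss),
      if (!is.null(x$depth)) "  (per-sample depth attached)" else "", "\n", sep = "")
  chroms <- unique(x$loci$chrom)
  cat("  chromosomes: ", paste(utils::head(chroms, 5), collapse = ", "),
      if (length(chroms) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname geno_matrix
#' @param x,gm A `geno_matrix`.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname geno_matrix
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' @rdname geno_matrix
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' @rdname geno_matrix
#' @export
locus_ids <- function(gm) gm$loci$locus_id

#' Subset a genotype matrix by locus and/or sample
#'
#' @param gm A `geno_matrix`.
#' @param loci Locus ids or logical/integer index over loci; `NULL` keeps all.
#' @param samples Sample ids or index; `NULL` keeps all.
#' @return A `geno_matrix`.
#' @export
subset_loci <- function(gm, loci = NULL, samples = NULL) {
  j <- if (is.null(loci)) seq_len(n_loci(gm)) else loci
  if (is.character(j)) j <- match(j, locus_ids(gm))
  if (anyNA(j)) stop("unknown locus id", call. = FALSE)
  i <- if (is.null(samples)) seq_len(n_samples(gm)) else samples
  if (is.character(i)) i <- match(i, sample_ids(gm))
  if (anyNA(i)) stop("unknown sample id", call. = FALSE)
  geno_matrix(gm$calls[i, j, drop = FALSE],
              gm$loci[j, , drop = FALSE],
              depth = if (!is.null(gm$depth)) gm$depth[i, j, drop = FALSE])
}

#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample = rep(sample_ids(x), times = n_loci(x)),
    locus_id = rep(locus_ids(x), each = n_samples(x)),
    genotype = as.vector(x$calls)
  )
}

#' Canonicalise an allele pair into a genotype string
#'
#' Unphased diploid calls are unordered pairs: `genotype_string("G", "A")`
#' and `genotype_string("A", "G")` both give `"AG"`. Missing alleles (NA)
#' give `"NN"`; a half-missing pair is rejected.
#'
#' @param a,b Single-nucleotide allele symbols (A/C/G/T) or `NA`.
#' @return Character vector of canonical genotype strings.
#' @export
genotype_string <- function(a, b) {
  miss_a <- is.na(a)
  miss_b <- is.na(b)
  if (any(miss_a != miss_b)) {
    stop("half-missing genotype: both alleles must be present or both missing",
         call. = FALSE)
  }
  out <- unname(ifelse(miss_a, "NN", paste0(pmin(a, b), pmax(a, b))))
  bad <- !miss_a & !(a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("alleles must be single nucleotides A/C/G/T", call. = FALSE)
  out
}

#' Split genotype strings back into allele pairs
#'
#' Inverse of [genotype_string()] on its canonical domain: `"NN"` maps to a
#' pair of `NA`s.
#'
#' @param g Character vector of genotype strings.
#' @return A two-column character matrix (`allele_a`, `allele_b`).
#' @export
genotype_alleles <- function(g) {
  a <- substr(g, 1, 1)
  b <- substr(g, 2, 2)
  a[g == "NN"] <- NA_character_
  b[g == "NN"] <- NA_character_
  cbind(allele_a = a, allele_b = b)
}

#' Locus table of a genotype matrix
#'
#' Returns the per-locus metadata as a tibble, with convenience columns
#' `n_alleles_observed` (distinct alleles among non-missing calls) and
#' `call_rate`.
#'
#' @param gm A `geno_matrix`.
#' @return A tibble with one row per locus.
#' @export
locus_table <- function(gm) {
  obs <- purrr::map_int(seq_len(n_loci(gm)), function(j) {
    g <- gm$calls[, j]
    length(unique(as.vector(genotype_alleles(g[g != "NN"]))))
  })
  dplyr::mutate(gm$loci,
                n_alleles_observed = obs,
                call_rate = colMeans(gm$calls != "NN"))
}
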