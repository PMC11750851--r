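#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads SNP rows (single-base ref and alt alleles) from a VCF 4.x file with
#' GT fields, skipping indel rows with a reported count. Multiallelic SNP
#' rows are loaded and flagged in the locus table; downstream filters remove
#' them. Missing genotypes (`./.`) become `"NN"` calls. Per-sample DP is
#' attached when present.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param verbose Print the skipped-indel count? Default `TRUE`.
#' @return A [geno_matrix()]; the number of skipped non-SNP rows is stored in
#'   the `skipped_indels` attribute.
#' @export
read_vcf <- function(path, verbose = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path, call. = FALSE)
  alts_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  is_snp <- nchar(fix$REF) == 1 & fix$REF %in% c("A", "C", "G", "T") &
    vapply(alts_list, function(a) length(a) >= 1 && all(nchar(a) == 1) &&
             all(a %in% c("A", "C", "G", "T")), logical(1))
  n_skip <- sum(!is_snp)
  if (verbose && n_skip > 0) {
    message("read_vcf: skipped ", n_skip, " non-SNP record(s)")
  }
  if (!any(is_snp)) stop("no SNP records in ", path, call. = FALSE)

  gt_raw <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  dp_raw <- if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[is_snp, , drop = FALSE]
  }
  fix <- fix[is_snp, , drop = FALSE]
  alts_list <- alts_list[is_snp]
  pos <- as.numeric(fix$POS)
  loci <- tibble::tibble(
    locus_id = paste0(fix$CHROM, "-", fix$POS),
    chrom = fix$CHROM, pos = pos, ref = fix$REF, alts = alts_list,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )

  calls <- matrix("NN", nrow = ncol(gt_raw), ncol = nrow(gt_raw),
                  dimnames = list(colnames(gt_raw), loci$locus_id))
  for (j in seq_len(nrow(gt_raw))) {
    alleles <- c(loci$ref[[j]], loci$alts[[j]])
    gt <- gt_raw[j, ]
    called <- !is.na(gt) & !grepl("^\\.([/|].)?", gt)
    idx <- strsplit(gt[called], "[/|]")
    bad_len <- lengths(idx) != 2
    if (any(bad_len)) stop("non-diploid GT at ", loci$locus_id[[j]], call. = FALSE)
    ia <- as.integer(vapply(idx, `[`, "", 1L)) + 1L
    ib <- as.integer(vapply(idx, `[`, "", 2L)) + 1L
    if (anyNA(ia) || anyNA(ib) || any(ia > length(alleles)) || any(ib > length(alleles))) {
      stop("GT allele index out of range at ", loci$locus_id[[j]], call. = FALSE)
    }
    calls[called, j] <- genotype_string(alleles[ia], alleles[ib])
  }
  depth <- if (!is.null(dp_raw)) {
    d <- t(dp_raw)
    storage.mode(d) <- "double"
    d
  }
  out <- geno_matrix(calls, loci, depth = depth)
  attr(out, "skipped_indels") <- n_skip
  out
}

#' Write a genotype matrix as a plain VCF 4.2 file
#'
#' Emits GT (and DP when depth is attached), loci sorted by chromosome then
#' position. Heterozygous calls are written with allele indices in the order
#' implied by the canonical genotype string.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  ord <- order(gm$loci$chrom, gm$loci$pos)
  loci <- gm$loci[ord, , drop = FALSE]
  calls <- gm$calls[, ord, drop = FALSE]
  depth <- if (!is.null(gm$depth)) gm$depth[, ord, drop = FALSE]
  fmt <- if (is.null(depth)) "GT" else "GT:DP"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kaspanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(depth)) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  )
  rows <- character(nrow(loci))
  for (j in seq_len(nrow(loci))) {
    alleles <- c(loci$ref[[j]], loci$alts[[j]])
    g <- calls[, j]
    gt <- rep("./.", length(g))
    called <- g != "NN"
    if (any(called)) {
      al <- genotype_alleles(g[called])
      gt[called] <- paste0(match(al[, 1], alleles) - 1L, "/",
                           match(al[, 2], alleles) - 1L)
    }
    cells <- if (is.null(depth)) gt else {
      dp <- depth[, j]
      paste0(gt, ":", ifelse(is.na(dp), ".", format(dp, trim = TRUE, scientific = FALSE)))
    }
    rows[j] <- paste(c(loci$chrom[[j]], format(loci$pos[[j]], scientific = FALSE),
                       ".", loci$ref[[j]], paste(loci$alts[[j]], collapse = ","),
                       ifelse(is.na(loci$qual[[j]]), ".",
                              format(loci$qual[[j]], trim = TRUE)),
                       ".", ".", fmt, cells), collapse = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read or write a samples x loci genotype TSV table
#'
#' The exchange format used for fingerprint tables: sample rows, locus
#' columns, two-letter genotype strings, `"NN"` for missing. Reading is
#' lossless with respect to genotype strings; locus metadata is parsed from
#' `chrom-pos` style column names where possible.
#'
#' @param path TSV path.
#' @param gm A [geno_matrix()] (for writing).
#' @return `read_genotype_table()` returns a [geno_matrix()];
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (names(tb)[1] != "sample") stop("first column must be `sample`", call. = FALSE)
  samples <- tb$sample
  calls <- as.matrix(tb[, -1, drop = FALSE])
  rownames(calls) <- samples
  ok <- matrix(grepl("^[ACGT]{2}$|^NN$", calls), nrow = nrow(calls))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("unparseable genotype '", calls[bad[1], bad[2]], "' at sample ",
         samples[bad[1]], ", column ", colnames(calls)[bad[2]], call. = FALSE)
  }
  loci <- loci_from_ids(colnames(calls), calls)
  geno_matrix(calls, loci)
}

# Reconstruct minimal locus metadata from "chrom-pos" column ids and the
# observed alleles (ref taken as the alphabetically first observed allele).
loci_from_ids <- function(ids, calls) {
  m <- regmatches(ids, regexec("^(.*)-([0-9]+)$", ids))
  chrom <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  pos <- vapply(m, function(x) if (length(x) == 3) as.numeric(x[3]) else NA_real_, 0)
  chrom[is.na(chrom)] <- ids[is.na(chrom)]
  pos[is.na(pos)] <- seq_len(sum(is.na(pos)))
  alle <- lapply(seq_along(ids), function(j) {
    g <- calls[, j]
    sort(unique(as.vector(genotype_alleles(g[g != "NN"]))))
  })
  ref <- vapply(alle, function(a) if (length(a)) a[1] else "A", "")
  alts <- lapply(seq_along(alle), function(j) {
    a <- setdiff(alle[[j]], ref[j])
    if (length(a)) a else setdiff(c("A", "C", "G", "T"), ref[j])[1]
  })
  tibble::tibble(locus_id = ids, chrom = chrom, pos = pos, ref = ref, alts = alts)
}

#' @rdname read_genotype_table
#' @export
write_genotype_table <- function(gm, path) {
  tb <- tibble::as_tibble(gm$calls)
  tb <- dplyr::bind_cols(tibble::tibble(sample = sample_ids(gm)), tb)
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Extract the flanking window around a SNP from a reference genome
#'
#' Returns up to `each_side` reference bases upstream and downstream of the
#' SNP position, excluding the SNP base itself. Windows truncated at contig
#' ends are flagged. In strict mode a reference-base/ref-allele mismatch is
#' an error; otherwise a warning.
#'
#' @param reference A `Biostrings::DNAStringSet` (e.g. from
#'   [read_reference()]) or path to a FASTA file.
#' @param locus One row of a locus table (list or single-row data frame with
#'   `chrom`, `pos`, `ref`, `locus_id`).
#' @param each_side Window half-width in bases (default 100).
#' @param strict Error on reference mismatch? Default `FALSE` (warn).
#' @return A list of class `flank_window` with elements `locus_id`, `chrom`,
#'   `pos`, `ref`, `upstream_seq`, `downstream_seq`, `each_side`,
#'   `truncated`.
#' @export
extract_flank_window <- function(reference, locus, each_side = 100, strict = FALSE) {
  reference <- as_reference(reference)
  chrom <- as.character(locus$chrom)
  if (!chrom %in% names(reference)) {
    stop("chromosome '", chrom, "' absent from reference", call. = FALSE)
  }
  contig <- reference[[chrom]]
  pos <- as.numeric(locus$pos)
  if (pos < 1 || pos > length(contig)) {
    stop("position ", pos, " outside contig ", chrom, call. = FALSE)
  }
  base <- as.character(Biostrings::subseq(contig, pos, pos))
  ref <- as.character(locus$ref)
  if (base != ref) {
    msg <- paste0("reference base ", base, " != ref allele ", ref,
                  " at ", chrom, ":", format(pos, scientific = FALSE))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  up_start <- max(1, pos - each_side)
  down_end <- min(length(contig), pos + each_side)
  up <- if (pos > 1) as.character(Biostrings::subseq(contig, up_start, pos - 1)) else ""
  down <- if (pos < length(contig)) as.character(Biostrings::subseq(contig, pos + 1, down_end)) else ""
  structure(list(
    locus_id = as.character(locus$locus_id), chrom = chrom, pos = pos, ref = ref,
    upstream_seq = up, downstream_seq = down, each_side = each_side,
    truncated = nchar(up) < each_side || nchar(down) < each_side
  ), class = "flank_window")
}

#' Load a reference genome FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` that trims FASTA
#' description lines to bare contig names.
#'
#' @param path FASTA path.
#' @return A `DNAStringSet` named by contig.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

as_reference <- function(x) {
  if (inherits(x, "DNAStringSet")) x else read_reference(x)
}
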