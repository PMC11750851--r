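# Universal KASP tail sequences (5'->3'), fixed by the genotyping chemistry.
KASP_FAM_TAIL <- "GAAGGTGACCAAGTTCATGCT"
KASP_VIC_TAIL <- "GAAGGTCGGAGTCAACGGATT"

#' KASP tail sequences
#'
#' The universal FAM and VIC tail sequences prepended to the allele-specific
#' primer bodies.
#'
#' @return Named character vector with elements `FAM` and `VIC`.
#' @export
kasp_tails <- function() c(FAM = KASP_FAM_TAIL, VIC = KASP_VIC_TAIL)

# SantaLucia (unified) nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), for the 10 Watson-Crick dimer steps.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9)

#' Oligonucleotide melting temperature
#'
#' Default method is the nearest-neighbor thermodynamic model (unified
#' duplex parameters) with entropic salt correction
#' `dS' = dS + 0.368 (n-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS' + R ln(C_T/4)) - 273.15`
#' at `monovalent_mM` monovalent salt and `oligo_nM` total strand
#' concentration (non-self-complementary assumption). The Wallace rule
#' `2(A+T) + 4(G+C)` is available as a fast fallback for short oligos.
#'
#' @param seq Nucleotide string (A/C/G/T only), length >= 8.
#' @param method `"nearest_neighbor"` (default) or `"wallace"`.
#' @param monovalent_mM Monovalent cation concentration, mM (default 50).
#' @param oligo_nM Total oligo concentration, nM (default 200).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("GAAGGTGACCAAGTTCATGCT", method = "wallace") # 62
#' @export
melting_temperature <- function(seq, method = c("nearest_neighbor", "wallace"),
                                monovalent_mM = 50, oligo_nM = 200) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (nchar(seq) < 8) stop("sequence shorter than 8 nt", call. = FALSE)
  bases <- strsplit(seq, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("ambiguity codes not supported: ", seq, call. = FALSE)
  }
  if (method == "wallace") {
    return(2 * sum(bases %in% c("A", "T")) + 4 * sum(bases %in% c("G", "C")))
  }
  steps <- paste0(bases[-length(bases)], bases[-1])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  # duplex initiation with terminal G/C vs A/T ends
  for (term in bases[c(1, length(bases))]) {
    if (term %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds + (-2.8)
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds_salt <- ds + 0.368 * (length(bases) - 1) * log(monovalent_mM / 1000)
  r_gas <- 1.987 # cal/(mol K)
  ct <- oligo_nM * 1e-9
  1000 * dh / (ds_salt + r_gas * log(ct / 4)) - 273.15
}

gc_fraction <- function(seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  mean(bases %in% c("G", "C"))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Design constraints for KASP assays
#'
#' @param gc_max Maximum GC fraction of primer bodies, exclusive
#'   (default 0.60: GC content must be strictly below 60%).
#' @param tm_min,tm_max Melting temperature window, degrees C, inclusive
#'   (default 57-63).
#' @param product_max Maximum PCR product size in bp, inclusive
#'   (default 120).
#' @param body_min,body_max Primer body length bounds in nt (default 16-32).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(gc_max = 0.60, tm_min = 57, tm_max = 63,
                               product_max = 120, body_min = 16, body_max = 32) {
  stopifnot(tm_min < tm_max, body_min >= 8, body_min <= body_max)
  structure(list(gc_max = gc_max, tm_min = tm_min, tm_max = tm_max,
                 product_max = product_max, body_min = body_min,
                 body_max = body_max),
            class = "design_constraints")
}

#' Design a tailed allele-specific (KASP) assay for one SNP
#'
#' Builds the two allele-specific primers and the common primer for a
#' biallelic SNP from its flanking window. Allele-specific primers run on
#' the reference forward strand and end 3' on the SNP base (one primer per
#' allele); their shared body is grown 5'-ward from the SNP until both
#' allele variants reach a melting temperature inside the constraint
#' window or the length bound is hit. The FAM tail goes to the
#' alphabetically first allele, VIC to the second. The common primer is
#' scanned on the reverse strand downstream of the SNP within the product
#' limit; the best candidate minimises |Tm - 60|, with shorter product as
#' tie-break. All constraints are re-validated post hoc.
#'
#' @param window A `flank_window` from [extract_flank_window()].
#' @param alleles Character vector of the two alleles (ref first); defaults
#'   to `c(window$ref, alt)` and must be supplied when the window carries no
#'   alt.
#' @param constraints A [design_constraints()].
#' @return A list of class `kasp_assay` (fields `locus_id`, `allele_fam`,
#'   `allele_vic`, `primer_fam`, `primer_vic`, `primer_common`,
#'   `product_len`, `validation`) when a candidate exists, otherwise a list
#'   of class `kasp_failure` with per-constraint diagnostics.
#' @export
design_kasp_assay <- function(window, alleles, constraints = design_constraints()) {
  stopifnot(inherits(window, "flank_window"), length(alleles) == 2)
  alleles <- sort(alleles) # alphabetical: first -> FAM, second -> VIC
  up <- toupper(window$upstream_seq)
  down <- toupper(window$downstream_seq)
  diagnostics <- character(0)

  # allele-specific body: suffix of upstream + allele base at the 3' end;
  # grown 5'-ward, keeping the length whose Tm (both alleles) sits in the
  # window, is GC-admissible, and is closest to 60 C
  as_len <- NA_integer_
  as_score <- Inf
  any_tm_ok <- FALSE
  for (L in seq(constraints$body_min, constraints$body_max)) {
    if (L - 1 > nchar(up)) break
    stem <- substr(up, nchar(up) - (L - 2), nchar(up))
    bodies <- paste0(stem, alleles)
    tms <- vapply(bodies, melting_temperature, numeric(1))
    tm_ok <- all(tms >= constraints$tm_min & tms <= constraints$tm_max)
    any_tm_ok <- any_tm_ok || tm_ok
    if (!tm_ok) next
    if (any(vapply(bodies, gc_fraction, numeric(1)) >= constraints$gc_max)) next
    score <- max(abs(tms - 60))
    if (score < as_score) {
      as_len <- L
      as_score <- score
    }
  }
  if (is.na(as_len)) {
    diagnostics <- c(diagnostics, if (!any_tm_ok) {
      "allele_tm: no body length reaches the Tm window for both alleles"
    } else {
      "allele_gc: every Tm-admissible body length has GC at or above the limit"
    })
  }

  # common primer: reverse strand, downstream of the SNP
  best <- NULL
  max_prod <- constraints$product_max
  for (len in seq(constraints$body_min, constraints$body_max)) {
    if (len > nchar(down)) break
    # offset s: first downstream base used by the common primer (1-based)
    max_s <- if (is.na(as_len)) nchar(down) - len + 1 else
      min(nchar(down) - len + 1, max_prod - as_len - len + 1)
    if (max_s < 1) next
    for (s in seq_len(max_s)) {
      tmpl <- substr(down, s, s + len - 1)
      # Tm and GC are strand-symmetric; evaluate on the template and
      # reverse-complement only the selected candidate
      tm <- melting_temperature(tmpl)
      if (tm < constraints$tm_min || tm > constraints$tm_max) next
      if (gc_fraction(tmpl) >= constraints$gc_max) next
      prod <- if (is.na(as_len)) NA_integer_ else as_len + s + len - 1
      score <- abs(tm - 60)
      if (is.null(best) || score < best$score ||
          (score == best$score && !is.na(prod) && prod < best$product_len)) {
        best <- list(tmpl = tmpl, tm = tm, s = s, len = len,
                     product_len = prod, score = score)
      }
    }
  }
  if (is.null(best)) {
    diagnostics <- c(diagnostics,
                     "common_primer: no downstream position satisfies Tm/GC/product constraints")
  }
  if (length(diagnostics) > 0 || is.na(as_len) || is.null(best)) {
    return(structure(list(locus_id = window$locus_id, alleles = alleles,
                          diagnostics = diagnostics), class = "kasp_failure"))
  }

  stem <- substr(up, nchar(up) - (as_len - 2), nchar(up))
  mk_oligo <- function(body, tail, strand) {
    list(body_seq = body, tail = tail,
         full_seq = paste0(if (tail == "FAM") KASP_FAM_TAIL
                           else if (tail == "VIC") KASP_VIC_TAIL else "", body),
         tm_body = melting_temperature(body), gc_body = gc_fraction(body),
         strand = strand)
  }
  assay <- structure(list(
    locus_id = window$locus_id,
    allele_fam = alleles[1], allele_vic = alleles[2],
    primer_fam = mk_oligo(paste0(stem, alleles[1]), "FAM", "forward"),
    primer_vic = mk_oligo(paste0(stem, alleles[2]), "VIC", "forward"),
    primer_common = mk_oligo(revcomp(best$tmpl), "none", "reverse"),
    product_len = best$product_len
  ), class = "kasp_assay")
  assay$validation <- validate_assay(assay, constraints)
  assay
}

#' @export
print.kasp_assay <- function(x, ...) {
  cat("<kasp_assay> ", x$locus_id, " (", x$allele_fam, "/", x$allele_vic, ")\n",
      "  FAM:    ", x$primer_fam$full_seq, "\n",
      "  VIC:    ", x$primer_vic$full_seq, "\n",
      "  common: ", x$primer_common$body_seq, "\n",
      "  product ", x$product_len, " bp; Tm ",
      sprintf("%.1f/%.1f/%.1f", x$primer_fam$tm_body, x$primer_vic$tm_body,
              x$primer_common$tm_body), " C\n", sep = "")
  invisible(x)
}

#' @export
print.kasp_failure <- function(x, ...) {
  cat("<kasp_failure> ", x$locus_id, "\n  ",
      paste(x$diagnostics, collapse = "\n  "), "\n", sep = "")
  invisible(x)
}

#' Validate a KASP assay against the design constraints
#'
#' Checks, per rule: GC strictly below the limit on all three bodies, Tm
#' inside the window (inclusive) for all three bodies, product size not
#' exceeding the limit (inclusive), allele-specific 3'-terminal bases equal
#' to their alleles, allele bodies identical except at the 3' terminus, and
#' tails byte-identical to the universal FAM/VIC sequences.
#'
#' @param assay A `kasp_assay`.
#' @param constraints A [design_constraints()].
#' @return A tibble: `rule`, `pass`.
#' @export
validate_assay <- function(assay, constraints = design_constraints()) {
  bodies <- c(assay$primer_fam$body_seq, assay$primer_vic$body_seq,
              assay$primer_common$body_seq)
  tms <- vapply(bodies, melting_temperature, numeric(1))
  gcs <- vapply(bodies, gc_fraction, numeric(1))
  fam_body <- assay$primer_fam$body_seq
  vic_body <- assay$primer_vic$body_seq
  same_len <- nchar(fam_body) == nchar(vic_body)
  diff_pos <- if (same_len) {
    which(strsplit(fam_body, "")[[1]] != strsplit(vic_body, "")[[1]])
  } else integer(0)
  tibble::tibble(
    rule = c("gc_below_max", "tm_in_window", "product_within_max",
             "terminal_base_matches_allele", "bodies_differ_only_at_3prime",
             "tails_exact"),
    pass = c(
      all(gcs < constraints$gc_max),
      all(tms >= constraints$tm_min & tms <= constraints$tm_max),
      !is.na(assay$product_len) && assay$product_len <= constraints$product_max,
      substr(fam_body, nchar(fam_body), nchar(fam_body)) == assay$allele_fam &&
        substr(vic_body, nchar(vic_body), nchar(vic_body)) == assay$allele_vic,
      same_len && length(diff_pos) == 1 && diff_pos == nchar(fam_body),
      identical(assay$primer_fam$full_seq, paste0(KASP_FAM_TAIL, fam_body)) &&
        identical(assay$primer_vic$full_seq, paste0(KASP_VIC_TAIL, vic_body))
    )
  )
}

#' Design KASP assays for every locus of a candidate matrix
#'
#' Maps [design_kasp_assay()] over the loci of a genotype matrix, pulling
#' flank windows from the reference.
#'
#' @param gm A [geno_matrix()] of biallelic candidate loci.
#' @param reference A `DNAStringSet` or FASTA path.
#' @param constraints A [design_constraints()].
#' @return A tibble with one row per locus: `locus_id`, `designed`
#'   (logical), `fam_primer`, `vic_primer`, `common_primer`, `tm_fam`,
#'   `tm_vic`, `tm_common`, `gc_fam`, `gc_vic`, `gc_common`, `product_len`,
#'   `all_rules_pass`, `assay` (list column of `kasp_assay`/`kasp_failure`).
#' @export
design_assays <- function(gm, reference, constraints = design_constraints()) {
  reference <- as_reference(reference)
  rows <- purrr::map(seq_len(n_loci(gm)), function(j) {
    locus <- gm$loci[j, ]
    w <- suppressWarnings(extract_flank_window(
      reference, locus, each_side = max(100, constraints$product_max)))
    a <- design_kasp_assay(w, alleles = c(locus$ref[[1]], locus$alts[[1]][1]),
                           constraints = constraints)
    if (inherits(a, "kasp_failure")) {
      tibble::tibble(locus_id = locus$locus_id, designed = FALSE,
                     fam_primer = NA_character_, vic_primer = NA_character_,
                     common_primer = NA_character_,
                     tm_fam = NA_real_, tm_vic = NA_real_, tm_common = NA_real_,
                     gc_fam = NA_real_, gc_vic = NA_real_, gc_common = NA_real_,
                     product_len = NA_integer_, all_rules_pass = FALSE,
                     assay = list(a))
    } else {
      tibble::tibble(locus_id = locus$locus_id, designed = TRUE,
                     fam_primer = a$primer_fam$full_seq,
                     vic_primer = a$primer_vic$full_seq,
                     common_primer = a$primer_common$body_seq,
                     tm_fam = a$primer_fam$tm_body, tm_vic = a$primer_vic$tm_body,
                     tm_common = a$primer_common$tm_body,
                     gc_fam = a$primer_fam$gc_body, gc_vic = a$primer_vic$gc_body,
                     gc_common = a$primer_common$gc_body,
                     product_len = as.integer(a$product_len),
                     all_rules_pass = all(a$validation$pass),
                     assay = list(a))
    }
  })
  dplyr::bind_rows(rows)
}
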