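#' Default genotype colour map for fingerprint rendering
#'
#' The fixed colour code for the ten homozygous/heterozygous biallelic
#' genotype classes plus no-call: AA=green, AG=light pink, CC=yellow,
#' CT=grey, GT=dark red, TT=blue, AC=pink, AT=orange, CG=light blue,
#' GG=purple, NN=white. Hex values are a package convention for the colour
#' names.
#'
#' @return Named character vector mapping genotype string to hex colour.
#' @export
default_color_map <- function() {
  c(AA = "#2ca02c",  # green
    AG = "#ffb6c1",  # light pink
    CC = "#ffd700",  # yellow
    CT = "#808080",  # grey
    GT = "#8b0000",  # dark red
    TT = "#1f77b4",  # blue
    AC = "#ff69b4",  # pink
    AT = "#ff7f0e",  # orange
    CG = "#add8e6",  # light blue
    GG = "#9467bd",  # purple
    NN = "#ffffff")  # white (no call)
}

#' Colour for one genotype string
#'
#' Deterministic lookup in a genotype colour map. Out-of-domain strings
#' (including non-canonical ones like `"GA"`) are an error, never a silent
#' white.
#'
#' @param genotype Genotype string, canonical two-letter or `"NN"`.
#' @param map Named colour vector (default [default_color_map()]).
#' @return Colour string.
#' @export
color_for_genotype <- function(genotype, map = default_color_map()) {
  if (length(genotype) != 1 || !genotype %in% names(map)) {
    stop("genotype '", genotype, "' is not in the colour-map domain ",
         "(canonicalize allele order first)", call. = FALSE)
  }
  unname(map[[genotype]])
}

#' Build the fingerprint table for a marker panel
#'
#' One fingerprint per sample: the ordered genotype strings over the panel
#' loci. Members of duplicate groups are annotated with their group
#' representative. The long form serialises directly; [write_fingerprint_tsv()]
#' writes the conventional orientation (loci as rows, samples as columns).
#'
#' @param gm A [geno_matrix()].
#' @param panel A `marker_panel` or character vector of locus ids
#'   (non-empty).
#' @return A tibble of class `fingerprint_tbl` in long form: `sample`,
#'   `locus_id` (ordered as the panel), `genotype`, `representative`.
#' @export
build_fingerprint_table <- function(gm, panel) {
  sel <- if (inherits(panel, "marker_panel")) panel$selected else panel
  if (length(sel) == 0) stop("empty marker panel", call. = FALSE)
  if (!all(sel %in% locus_ids(gm))) stop("panel loci absent from matrix", call. = FALSE)
  dup <- find_duplicate_groups(gm)
  rep_of <- stats::setNames(sample_ids(gm), sample_ids(gm))
  for (g in dup$groups) rep_of[g] <- g[1]
  samples <- sort(sample_ids(gm))
  tb <- tidyr::expand_grid(sample = samples, locus_id = sel)
  tb$genotype <- gm$calls[cbind(tb$sample, tb$locus_id)]
  tb$representative <- unname(rep_of[tb$sample])
  tb$locus_id <- factor(tb$locus_id, levels = sel)
  class(tb) <- c("fingerprint_tbl", class(tb))
  tb
}

#' Write / read a fingerprint TSV (loci as rows, samples as columns)
#'
#' @param fp A fingerprint table from [build_fingerprint_table()].
#' @param path Output path.
#' @return `path` invisibly (write); a tibble in the same long form (read).
#' @export
write_fingerprint_tsv <- function(fp, path) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(fp), "locus_id", "sample", "genotype"),
    names_from = "sample", values_from = "genotype")
  wide$locus_id <- as.character(wide$locus_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @export
read_fingerprint_tsv <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  tidyr::pivot_longer(wide, -"locus_id", names_to = "sample",
                      values_to = "genotype")
}

#' Render a colour-coded fingerprint heatmap
#'
#' Grid plot of the fingerprint table: loci as rows, samples as columns,
#' cells coloured by genotype class with a legend. Deterministic for a
#' given input (samples sorted, loci in panel order).
#'
#' @param fp A fingerprint table from [build_fingerprint_table()].
#' @param map Named colour vector (default [default_color_map()]).
#' @param transpose Put samples in rows instead? Default `FALSE`.
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(fp, map = default_color_map(), transpose = FALSE) {
  fp <- tibble::as_tibble(fp)
  bad <- setdiff(unique(fp$genotype), names(map))
  if (length(bad)) {
    stop("genotype(s) outside colour-map domain: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fp$locus_id <- factor(fp$locus_id, levels = rev(levels(factor(fp$locus_id))))
  aes <- if (transpose) {
    ggplot2::aes(x = .data$locus_id, y = .data$sample, fill = .data$genotype)
  } else {
    ggplot2::aes(x = .data$sample, y = .data$locus_id, fill = .data$genotype)
  }
  ggplot2::ggplot(fp, aes) +
    ggplot2::geom_tile(color = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = map, drop = FALSE, name = "Genotype") +
    ggplot2::labs(x = if (transpose) "SNP locus" else "Sample",
                  y = if (transpose) "Sample" else "SNP locus") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 5))
}

#' @method autoplot fingerprint_tbl
#' @export
autoplot.fingerprint_tbl <- function(object, ...) plot_fingerprint(object, ...)

#' Save a fingerprint heatmap to SVG and/or PNG
#'
#' @param fp A fingerprint table.
#' @param svg,png Optional output paths.
#' @param width,height Device size in inches.
#' @param ... Passed to [plot_fingerprint()].
#' @return Invisible named vector of the paths written.
#' @export
render_fingerprint_heatmap <- function(fp, svg = NULL, png = NULL,
                                       width = 10, height = 4, ...) {
  p <- plot_fingerprint(fp, ...)
  written <- character(0)
  if (!is.null(svg)) {
    grDevices::svg(svg, width = width, height = height)
    print(p)
    grDevices::dev.off()
    written["svg"] <- svg
  }
  if (!is.null(png)) {
    grDevices::png(png, width = width, height = height, units = "in", res = 150)
    print(p)
    grDevices::dev.off()
    written["png"] <- png
  }
  invisible(written)
}
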