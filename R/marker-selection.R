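#' Pairwise discrimination coverage of each locus
#'
#' For every locus, computes the set of unordered sample pairs the locus
#' separates: both calls non-missing and different. The universe of pairs to
#' cover is all pairs of samples with distinct full genotype profiles
#' (pairs inside duplicate groups, i.e. samples identical at every locus
#' including the missing pattern, are excluded). Pairs that differ only
#' where one member is missing are in the universe but may be uncoverable;
#' they surface in panel residuals.
#'
#' @param gm A [geno_matrix()] with at least two samples.
#' @return A list of class `pair_coverage`: `n_samples`, `sample_ids`,
#'   `universe` (integer pair codes), `coverage` (named list, locus id ->
#'   integer pair codes), `duplicate_groups` (from
#'   [find_duplicate_groups()]).
#' @export
discriminating_pairs <- function(gm) {
  n <- n_samples(gm)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  dup <- find_duplicate_groups(gm)
  dup_pairs <- unlist(lapply(dup$groups, function(members) {
    idx <- match(members, sample_ids(gm))
    pairs_of(idx, n)
  }))
  all_pairs <- pairs_of(seq_len(n), n)
  universe <- setdiff(all_pairs, dup_pairs)
  coverage <- lapply(seq_len(n_loci(gm)), function(j) {
    g <- gm$calls[, j]
    called <- which(g != "NN")
    if (length(called) < 2) return(integer(0))
    sep <- integer(0)
    for (a in seq_along(called)[-length(called)]) {
      i <- called[a]
      js <- called[(a + 1):length(called)]
      js <- js[g[js] != g[i]]
      if (length(js)) sep <- c(sep, pair_code(i, js, n))
    }
    intersect(sep, universe)
  })
  names(coverage) <- locus_ids(gm)
  structure(list(n_samples = n, sample_ids = sample_ids(gm),
                 universe = universe, coverage = coverage,
                 duplicate_groups = dup),
            class = "pair_coverage")
}

pair_code <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * n + hi
}

pairs_of <- function(idx, n) {
  if (length(idx) < 2) return(integer(0))
  cmb <- utils::combn(sort(idx), 2)
  pair_code(cmb[1, ], cmb[2, ], n)
}

decode_pairs <- function(codes, ids) {
  n <- length(ids)
  lo <- (codes - 1) %/% n + 1
  hi <- codes - (lo - 1) * n
  tibble::tibble(sample_a = ids[lo], sample_b = ids[hi])
}

#' Find groups of samples with identical genotype profiles
#'
#' Partitions samples into maximal groups whose profiles agree at every
#' locus, with missing matching only missing. Singleton groups are omitted.
#' Pairs of samples that differ only where one member is missing are not
#' grouped (a no-call is not evidence of identity) but are also not
#' separable by any locus; they are reported in `ambiguous_pairs`.
#'
#' @param gm A [geno_matrix()].
#' @return A list of class `duplicate_groups`: `groups` (list of sample-id
#'   vectors, each with a lexicographically-first representative as first
#'   element), `representatives`, and `ambiguous_pairs` (tibble of
#'   missing-masked unresolvable pairs).
#' @export
find_duplicate_groups <- function(gm) {
  if (n_samples(gm) < 1) stop("need at least 1 sample", call. = FALSE)
  key <- apply(gm$calls, 1, paste, collapse = "|")
  split_ids <- split(sample_ids(gm), key)
  groups <- Filter(function(g) length(g) > 1, unname(split_ids))
  groups <- lapply(groups, function(g) sort(g))
  ord <- order(vapply(groups, `[`, "", 1L))
  groups <- groups[ord]

  # ambiguous: distinct profiles, yet no locus has two differing calls
  n <- n_samples(gm)
  amb <- list()
  if (n >= 2 && n_loci(gm) >= 1) {
    cmb <- utils::combn(n, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      gi <- gm$calls[i, ]; gj <- gm$calls[j, ]
      if (identical(unname(gi), unname(gj))) next
      both <- gi != "NN" & gj != "NN"
      if (!any(gi[both] != gj[both])) {
        amb[[length(amb) + 1]] <- c(sample_ids(gm)[i], sample_ids(gm)[j])
      }
    }
  }
  amb_tb <- if (length(amb)) {
    m <- do.call(rbind, amb)
    tibble::tibble(sample_a = pmin(m[, 1], m[, 2]), sample_b = pmax(m[, 1], m[, 2]))
  } else tibble::tibble(sample_a = character(0), sample_b = character(0))
  structure(list(groups = groups,
                 representatives = vapply(groups, `[`, "", 1L),
                 ambiguous_pairs = amb_tb),
            class = "duplicate_groups")
}

#' @export
print.duplicate_groups <- function(x, ...) {
  cat("<duplicate_groups> ", length(x$groups), " group(s)\n", sep = "")
  for (g in x$groups) cat("  [", g[1], "] ", paste(g, collapse = ", "), "\n", sep = "")
  if (nrow(x$ambiguous_pairs)) {
    cat("  ", nrow(x$ambiguous_pairs), " ambiguous (missing-masked) pair(s)\n", sep = "")
  }
  invisible(x)
}

#' Greedy minimum marker panel (set cover with backward pruning)
#'
#' Iteratively selects the locus separating the most still-unseparated
#' sample pairs; ties are broken by higher PIC, then by chromosome:position
#' order. Selection stops when the universe is covered or no locus adds
#' coverage; a final backward pass drops any marker whose removal leaves
#' coverage complete. The result is a greedy-minimal panel — provably
#' minimum only when [exact_min_panel()] confirms.
#'
#' @param coverage A `pair_coverage` from [discriminating_pairs()].
#' @param pic_by_locus Optional named numeric vector (locus id -> PIC) used
#'   for tie-breaking.
#' @return A list of class `marker_panel`: `selected` (ordered locus ids),
#'   `steps` (tibble: locus_id, gain, covered_cum), `covered`, `residual`
#'   (integer pair codes), `residual_pairs` (decoded tibble), `n_samples`,
#'   `sample_ids`, `method`.
#' @export
greedy_min_panel <- function(coverage, pic_by_locus = NULL) {
  stopifnot(inherits(coverage, "pair_coverage"))
  locus_order <- names(coverage$coverage) # chrom:pos order as loaded
  pic_v <- if (is.null(pic_by_locus)) {
    stats::setNames(rep(0, length(locus_order)), locus_order)
  } else pic_by_locus[locus_order]
  pic_v[is.na(pic_v)] <- 0

  uncovered <- coverage$universe
  selected <- character(0)
  steps <- list()
  while (length(uncovered) > 0) {
    gains <- vapply(coverage$coverage, function(cv) length(intersect(cv, uncovered)),
                    integer(1))
    gains[selected] <- -1L
    best_gain <- max(gains)
    if (best_gain <= 0) break
    cand <- which(gains == best_gain)
    cand <- cand[order(-pic_v[cand], cand)] # PIC desc, then input (chrom:pos) order
    pick <- locus_order[cand[1]]
    uncovered <- setdiff(uncovered, coverage$coverage[[pick]])
    selected <- c(selected, pick)
    steps[[length(steps) + 1]] <- tibble::tibble(
      locus_id = pick, gain = best_gain,
      covered_cum = length(coverage$universe) - length(uncovered))
  }
  # backward prune: drop redundant markers, earliest-added first
  if (length(uncovered) == 0 && length(selected) > 1) {
    for (loc in selected) {
      rest <- setdiff(selected, loc)
      cov_rest <- unique(unlist(coverage$coverage[rest], use.names = FALSE))
      if (length(setdiff(coverage$universe, cov_rest)) == 0) {
        selected <- rest
      }
    }
  }
  covered <- unique(unlist(coverage$coverage[selected], use.names = FALSE))
  residual <- setdiff(coverage$universe, covered)
  structure(list(
    selected = selected,
    steps = if (length(steps)) dplyr::bind_rows(steps)[dplyr::bind_rows(steps)$locus_id %in% selected, ] else
      tibble::tibble(locus_id = character(0), gain = integer(0), covered_cum = integer(0)),
    covered = intersect(covered, coverage$universe),
    residual = residual,
    residual_pairs = decode_pairs(residual, coverage$sample_ids),
    n_samples = coverage$n_samples,
    sample_ids = coverage$sample_ids,
    method = "greedy-minimal"
  ), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$selected), " marker(s), method ", x$method, "\n", sep = "")
  cat("  covered ", length(x$covered), " pair(s), residual ",
      length(x$residual), "\n", sep = "")
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy marker_panel
#' @export
tidy.marker_panel <- function(x, ...) x$steps

#' @method glance marker_panel
#' @export
glance.marker_panel <- function(x, ...) {
  tibble::tibble(n_markers = length(x$selected),
                 n_covered = length(x$covered),
                 n_residual = length(x$residual),
                 method = x$method)
}

#' Exact minimum marker panel by exhaustive search
#'
#' Finds a provably minimum-cardinality subset of loci covering every
#' coverable pair, by enumerating subsets of increasing size. Intended as
#' the optimality oracle for [greedy_min_panel()] on small instances.
#'
#' @inheritParams greedy_min_panel
#' @param max_loci Refuse instances with more candidate loci than this
#'   (default 20).
#' @return A `marker_panel` with `method = "exact-minimum"`.
#' @export
exact_min_panel <- function(coverage, max_loci = 20) {
  stopifnot(inherits(coverage, "pair_coverage"))
  m <- length(coverage$coverage)
  if (m > max_loci) {
    stop("exact search refused: ", m, " candidate loci > budget ", max_loci,
         call. = FALSE)
  }
  locus_order <- names(coverage$coverage)
  coverable <- unique(unlist(coverage$coverage, use.names = FALSE))
  target <- intersect(coverage$universe, coverable)
  best <- character(0)
  if (length(target) > 0) {
    found <- FALSE
    for (k in seq_len(m)) {
      sets <- utils::combn(m, k, simplify = FALSE)
      for (s in sets) {
        cov <- unique(unlist(coverage$coverage[s], use.names = FALSE))
        if (length(setdiff(target, cov)) == 0) {
          best <- locus_order[s]
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  covered <- unique(unlist(coverage$coverage[best], use.names = FALSE))
  residual <- setdiff(coverage$universe, covered)
  structure(list(
    selected = best,
    steps = tibble::tibble(locus_id = best, gain = NA_integer_,
                           covered_cum = NA_integer_),
    covered = intersect(covered, coverage$universe),
    residual = residual,
    residual_pairs = decode_pairs(residual, coverage$sample_ids),
    n_samples = coverage$n_samples,
    sample_ids = coverage$sample_ids,
    method = "exact-minimum"
  ), class = "marker_panel")
}

#' Verify a marker panel against a genotype matrix
#'
#' Recomputes pairwise distinctness restricted to the panel loci, lists any
#' colliding sample pairs outside duplicate groups, and reports the
#' information-theoretic lower bound for biallelic co-dominant markers:
#' a panel distinguishing `m` distinct profiles needs at least
#' `ceil(log3(m))` markers (each marker has at most 3 genotype classes).
#'
#' @param gm A [geno_matrix()].
#' @param panel A `marker_panel` or character vector of locus ids.
#' @return A tibble (one row): `n_markers`, `n_distinct_profiles`,
#'   `n_collisions`, `lower_bound`, `meets_lower_bound`, `collisions`
#'   (list column of tibbles).
#' @export
verify_panel <- function(gm, panel) {
  sel <- if (inherits(panel, "marker_panel")) panel$selected else panel
  if (!all(sel %in% locus_ids(gm))) stop("panel loci absent from matrix", call. = FALSE)
  sub <- subset_loci(gm, loci = sel)
  dup <- find_duplicate_groups(gm)
  dup_members <- unlist(dup$groups)
  keep <- setdiff(sample_ids(gm), setdiff(dup_members, dup$representatives))
  subr <- subset_loci(sub, samples = keep)
  key <- apply(subr$calls, 1, paste, collapse = "|")
  n_profiles <- length(unique(key))
  coll <- list()
  cls <- split(sample_ids(subr), key)
  for (g in cls) {
    if (length(g) > 1) {
      cmb <- utils::combn(sort(g), 2)
      for (k in seq_len(ncol(cmb))) coll[[length(coll) + 1]] <- cmb[, k]
    }
  }
  coll_tb <- if (length(coll)) {
    m <- do.call(rbind, coll)
    tibble::tibble(sample_a = m[, 1], sample_b = m[, 2])
  } else tibble::tibble(sample_a = character(0), sample_b = character(0))
  # tolerance guards ceiling() against log() returning e.g. 4 + 1e-16 for 3^4
  lb <- if (n_profiles > 1) ceiling(log(n_profiles, base = 3) - 1e-9) else 0
  tibble::tibble(
    n_markers = length(sel),
    n_distinct_profiles = n_profiles,
    n_collisions = nrow(coll_tb),
    lower_bound = lb,
    meets_lower_bound = length(sel) >= lb,
    collisions = list(coll_tb)
  )
}

#' Identification-efficiency curve of an ordered panel
#'
#' After each marker added in panel order: the number of distinct genotype
#' profiles among samples and the fraction of universe pairs separated.
#' Both are non-decreasing in panel size.
#'
#' @param gm A [geno_matrix()].
#' @param panel A `marker_panel` or ordered character vector of locus ids.
#' @return A tibble: `n_markers`, `locus_id`, `n_distinct_profiles`,
#'   `frac_pairs_covered`.
#' @export
efficiency_curve <- function(gm, panel) {
  sel <- if (inherits(panel, "marker_panel")) panel$selected else panel
  cov <- discriminating_pairs(gm)
  u <- length(cov$universe)
  rows <- purrr::map(seq_along(sel), function(k) {
    loci_k <- sel[seq_len(k)]
    key <- apply(gm$calls[, loci_k, drop = FALSE], 1, paste, collapse = "|")
    covered <- unique(unlist(cov$coverage[loci_k], use.names = FALSE))
    tibble::tibble(n_markers = k, locus_id = sel[k],
                   n_distinct_profiles = length(unique(key)),
                   frac_pairs_covered = if (u == 0) 1 else length(covered) / u)
  })
  base_row <- tibble::tibble(n_markers = 0L, locus_id = NA_character_,
                             n_distinct_profiles = 1L,
                             frac_pairs_covered = if (u == 0) 1 else 0)
  dplyr::bind_rows(base_row, dplyr::bind_rows(rows))
}

#' Plot an identification-efficiency curve
#'
#' @param curve Tibble from [efficiency_curve()].
#' @return A ggplot object: distinct profiles against panel size.
#' @export
plot_efficiency_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_markers,
                                      y = .data$n_distinct_profiles)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Markers in panel", y = "Distinct genotype profiles",
                  title = "Identification efficiency of combined SNP markers") +
    ggplot2::theme_minimal()
}
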