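---
title: "Methods: SNP marker panels, KASP design and fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP marker panels, KASP design and fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspanel)
```

## The problem

Commercial plant collections — here motivated by *Cymbidium ensifolium*
orchid cultivars — need cheap, reproducible variety identification.
Reduced-representation sequencing (ddRAD-seq) of a few dozen cultivars
yields millions of SNPs; only a small fraction are usable as KASP
(kompetitive allele-specific PCR) genotyping assays, and only a handful are
needed to tell every cultivar apart. `kaspanel` implements that
engineering chain: filter variants, score their informativeness, select a
minimum discriminating marker combination, design tailed allele-specific
primers, and render the resulting DNA fingerprints.

## Genotype model

The central object is a samples × loci grid of unordered diploid calls.
Calls are canonical two-letter strings (`"AG"`, never `"GA"`) with `"NN"`
for missing; unphased data carry no allele order, so canonicalisation makes
encoding/decoding an identity. Only single-nucleotide ref/alt alleles enter
the matrix — indels are skipped at VCF parse time with a reported count.
Multiallelic SNP rows are loaded (I/O stays lossless) and removed
explicitly by the filters, which require exactly two observed alleles.

## Index suite

Per locus, with allele frequencies $P_i$ estimated from two copies per
called sample (missing calls excluded from the denominator):

* expected heterozygosity $H_E = 1 - \sum_i P_i^2$, **uncorrected** for
  sample size — the uncorrected form is what reproduces the panel's
  published endpoint pairs (MAF 0.479 → 0.499, MAF 0.125 → 0.219), which
  the test suite asserts;
* polymorphic information content
  $PIC = 1 - \sum_i P_i^2 - \sum_{i<j} 2 P_i^2 P_j^2$, summed over
  *distinct alleles*. The biallelic maximum is $PIC(0.5) = 0.375$ and
  $PIC \le H_E$ always. A brute-force double-loop evaluation is kept in the
  tests as an independent oracle;
* effective allele number $N_e = 1/\sum_i P_i^2$, hence
  $N_e = 1/(1 - \pi)$ identically;
* per-site nucleotide diversity $\pi$ defined equal to $H_E$ (per-site
  heterozygosity without pairwise-sample correction), matching the
  convention in which summary tables print identical HetExp and Pi columns;
* inbreeding coefficient $F_{IS} = 1 - H_{obs}/H_E$ per locus, undefined at
  monomorphic loci and averaged only where defined. Averaging ratios
  per locus differs in the third decimal from the ratio of averages; the
  package reports the former and makes no claim the two agree.

Report tables round half-up to 3 decimals; internal values keep full
precision.

## Filter cascades

Two cascades, each reporting per-rule attribution (a locus is charged to
the *first* rule it fails, in fixed order), so filter reports are exactly
reproducible:

1. **population filter** — mean per-sample depth ≥ 5×, MAF ≥ 0.05
   (inclusive), call rate ≥ 0.70, site quality Q ≥ 30, exactly 2 observed
   alleles. "Average depth" is the mean of per-sample DP at the locus, and
   "information integrity" is read as per-locus call rate; both readings
   are configurable interpretations, not the only possible ones.
2. **KASP-candidate filter** — flank cleanliness (no other variant within
   50 bases; separation must be strictly greater than the radius), mean
   depth and biallelism, flank uniqueness (the ±100 bp window occurs
   exactly once in the reference, both strands, exact match), and
   PIC > 0.020 (strict: the low threshold reflects manually assisted
   selection downstream).

Uniqueness is an exact-match scan rather than an external aligner call:
deterministic and dependency-free. A BLAST-style aligner would also accept
mismatched secondary hits; exact-match semantics are the conservative,
checkable reading, and precomputed hit counts can be substituted upstream
by filtering on them before calling the cascade.

## Minimum marker combinations

Distinguishing all cultivars is a minimum test cover: each locus "covers"
the sample pairs it separates (both calls present and different — a no-call
can never certify a difference), and the panel must cover all pairs of
distinct cultivars. Samples with byte-identical profiles (including the
missing pattern) form duplicate groups; their internal pairs are removed
from the universe and reported separately with a deterministic
(lexicographically first) representative, mirroring how indistinguishable
commercial varieties are handled in practice. Pairs that differ *only*
where one member is missing are listed as ambiguous: they are not evidence
of identity, but no marker can separate them either.

Set cover is NP-hard, so the package uses the standard greedy heuristic:
repeatedly take the locus covering the most uncovered pairs, tie-broken by
higher PIC then chromosome:position, then backward-prune redundant picks.
Panels are labelled *greedy-minimal*; an exhaustive solver
(`exact_min_panel()`, refused above 20 candidate loci) provides provable
minima for tests, and 200 seeded random instances confirm greedy is always
feasible and never below the optimum. A panel distinguishing $m$ profiles
needs at least $\lceil \log_3 m \rceil$ biallelic co-dominant markers
(three genotype classes per marker); `verify_panel()` reports that bound —
5 markers for 83 profiles — alongside recomputed collisions.

## KASP assay design

For a biallelic SNP the assay is two allele-specific primers (bodies
identical except the 3′-terminal base, which *is* the allele) plus one
common reverse-strand primer downstream. Constraints: body GC strictly
below 60%, body Tm in [57, 63] °C inclusive, product (outer 5′ body end to
outer 5′ body end, tails excluded) at most 120 bp inclusive.

* Tm uses the nearest-neighbor thermodynamic model (unified duplex
  parameters; entropic salt correction $0.368\,(n{-}1)\ln[\mathrm{Na^+}]$;
  defaults 50 mM monovalent salt, 200 nM oligo, non-self-complementary
  initiation), with the Wallace rule $2(A{+}T)+4(G{+}C)$ as a fast
  fallback. Concentrations are configurable; the defaults are ordinary
  KASP reaction conditions.
* The allele body grows 5′-ward from the SNP; among lengths where *both*
  allele variants sit in the Tm window and below the GC cap, the one
  closest to 60 °C wins. The common primer is scanned over downstream
  positions and lengths within the product limit; best candidate minimises
  |Tm − 60| with shorter product as tie-break.
* Universal tails (FAM `GAAGGTGACCAAGTTCATGCT`, VIC
  `GAAGGTCGGAGTCAACGGATT`) are excluded from Tm/GC: they are universal and
  non-templated in the first cycles. FAM goes to the alphabetically first
  allele — real assays assign dyes arbitrarily; fixing the convention makes
  runs reproducible. The common primer sits downstream by default; the
  literature does not fix an orientation.
* Deliberate destabilising mismatches near the 3′ end (common in commercial
  KASP design) are not modelled; neither are hairpin/dimer checks. Failures
  are first-class results carrying per-constraint diagnostics — on random
  GC-balanced sequence a minority of clean SNPs are still undesignable
  (typically a locally GC-rich flank), which is exactly why real conversion
  rates sit well below 100%.

Every emitted assay is re-validated post hoc; the amplicon reconstructed
from the primers is asserted (in tests) to be an exact reference substring.

## Fingerprints

Panel genotypes serialise as a loci × samples table using the fixed colour
code AA green, AG light pink, CC yellow, CT grey ("grew" in the source
legend is read as a typo for grey), GT dark red, TT blue, AC pink, AT
orange, CG light blue, GG purple, NN white. The colour names are the
contract; hex values are a package convention. Lookups are checked — a
non-canonical string like `"GA"` is an error, never silently white.

## Synthetic data

Every stage is testable offline through a Balding–Nichols generator:
ancestral frequency $p_0 \sim U(0.05, 0.5)$ (a post-filter
reduced-representation spectrum), subpopulation frequencies
$\mathrm{Beta}\!\left(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\right)$, and
genotypes drawn with inbreeding $f$: $P(\text{het}) = 2pq(1-f)$. Defaults
chosen once as the package's study preset: 50 samples in K = 4
subpopulations sized 14/5/23/8 (the structure analysis of the motivating
collection), $F = 0.1$, $f = 0.25$ (observed heterozygosity clearly below
expected in such collections), 10% i.i.d. missing calls, depth
NegBin(mean 6.6, size 3), quality Normal(40, 8) floored at zero, and two
injected duplicate groups of sizes 4 and 2 (copied calls including the
missing pattern). An 83-sample preset scales the group sizes to 24/9/37/13.

The generator reproduces what the pipeline *assumes* — biallelic sites,
exchangeable samples within subpopulations, i.i.d. missingness — and not
what real ddRAD data add: linkage disequilibrium, allele-specific dropout,
batch-structured missingness, genotyping error. Passing tests therefore
validate the algorithms, not the field performance of any particular panel.

Recovery checks: a Hudson-style ratio-of-averages $F_{ST}$ estimator over
all subpopulation pairs recovers the configured $F \in \{0.05, 0.1, 0.2\}$
within ±0.02 at 2,000 loci × 200 samples (the small sample-count bias from
inbreeding is an order of magnitude below that tolerance); planted
single-rule filter violations are recovered exactly; injected duplicate
groups are found exactly.

## Numerical and scale choices

* Frequencies must sum to 1 within 1e-8; the PIC identity against the
  brute-force oracle holds to 1e-12.
* The $\log_3$ lower bound subtracts 1e-9 before `ceiling()` to guard
  against floating-point `log` at exact powers of three.
* Test problem sizes — 200 greedy-vs-exact instances at ≤10 loci × ≤12
  samples, one 83 × 500 selection run, one 200 × 2,000-locus recovery run
  per $F$, 100 designed assays — complete in well under a minute each and
  were chosen as the smallest scales at which the corresponding guarantees
  are meaningfully exercised.
* All simulators are pure functions of (config, seed); the RNG state is
  restored after every call.

## Worked example

```{r example}
cfg <- sim_config(n_samples = 50, n_loci = 200, seed = 1)
sim <- simulate_structured_genotypes(cfg)
dup <- inject_duplicate_groups(sim$matrix, c(4, 2), seed = 2)
meta <- simulate_locus_metadata(dup$matrix, cfg)

filtered <- population_filter(meta$matrix)
filtered$report

st <- locus_stats(filtered$matrix)
panel <- greedy_min_panel(discriminating_pairs(filtered$matrix),
                          stats::setNames(st$pic, st$locus_id))
panel
verify_panel(filtered$matrix, panel)[, 1:5]

fp <- build_fingerprint_table(filtered$matrix, panel)
plot_fingerprint(fp)
```

## Known limitations

* Exact-match uniqueness is stricter than aligner-based uniqueness; loci
  unique by exact match may still have near-identical paralogous copies.
* The greedy panel is minimal only up to the heuristic; for candidate sets
  beyond the exact solver's reach, minimality is a lower-bound statement.
* Primer thermodynamics ignore secondary structure and mismatches; designs
  are candidates for wet-lab verification, not guaranteed assays.
* The depth model is per-sample negative binomial without sample effects;
  real libraries show strong per-sample depth correlation.
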