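---
title: "Scoring duplicated k-mer signatures in conserved non-coding elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring duplicated k-mer signatures in conserved non-coding elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Developmental enhancers often work through homotypic clusters of short
transcription-factor binding sites. In ascidians, K50-Paired homeodomain
factors (OTX, PITX, Goosecoid) bind a GATTA/TAATC core, and a *duplicated*
GATTA within a short distance of conserved non-coding DNA marks candidate
anterior neuroectoderm enhancers. `tagscan` implements the computational
side of that observation as a reusable pipeline:

1. build conserved non-coding elements (CNEs) from a pairwise whole-genome
   alignment by removing transcribed positions;
2. scan every canonical k-mer class (512 pentamer classes by default) for
   `c` conserved occurrences within a window of `W` bp inside one CNE;
3. associate CNEs with neighboring genes and score each (motif, tissue)
   pair with a binomial upper-tail enrichment score;
4. quantify robustness to annotation error, copy number and window size;
5. nominate candidate enhancer CNEs for a motif and tissue of interest.

## The motif-tissue score

For a signature (motif class, `c` copies, window `W`) let `n` be the number
of annotated genes flanked by at least one CNE carrying the signature, `k`
the number of those genes annotated in tissue `t`, and
`p = |genes annotated in t| / |all annotated genes|` the background tissue
fraction. The score is

    S = -log10 P[X >= k],   X ~ Binomial(n, p)

computed in log space and capped at 300 on underflow. The score needs no
sequence background model: the null hypothesis is that flanked genes are an
exchangeable sample from the annotated gene set. Genes absent from the
annotation table contribute neither to `n` nor to `p` — the background is
the annotated universe, not the whole genome. The logarithm base (default
10) and the tail convention (inclusive `P[X >= k]`, with an exclusive
alternative) are configurable; the base rescales scores but can never
change a ranking, and the inclusive tail is the standard enrichment
convention, so both switches exist mainly to document that the results do
not hinge on them.

Scores across the 512 classes and several tissues are reported as ranked
tables rather than corrected p-values: the analysis is a screen, and its
claim is that the planted (or biological) signature *ranks first* for its
tissue. An optional Benjamini-Hochberg column can be added by the user from
the full score table; it is not part of the core output.

## Window and conservation semantics

"Two copies within 125 bp" is implemented as start-to-start distance: among
the sorted occurrence offsets of a class, some `c` consecutive offsets must
satisfy `offset[i+c-1] - offset[i] <= W`. This is the weakest reading
consistent with the enhancer-dissection case the signature was derived
from (two sites separated by a 75-bp spacer, about 125 bp between site
starts); a span-inclusive mode (`window_mode = "span"`) that also counts
the trailing `k - 1` bases is available. Both members of a class are pooled
before the window test (forward-strand offsets of either word), windows
never span two CNEs, and by default an occurrence only counts when all `k`
of its bases are conserved (`require_conserved = FALSE` relaxes this).
Occurrence offsets are 1-based, the native R convention; all interval
containers are `GRanges` (1-based, closed), converted on BED import/export.

The conservation mask itself comes from the alignment: a reference position
is conserved when the aligned bases are identical, case-insensitively, and
both are in A/C/G/T — so gaps and Ns never match. Columns in which the
reference is gapped occupy no mask position.

## CNE construction

Aligned blocks minus transcribed intervals, keeping maximal fragments of at
least `min_length` bp (default 20 — the shortest element that can hold two
pentamers a few bases apart; the original study reports no threshold).
"Transcribed" defaults to exons so that intronic conserved sequence — where
many of the validated candidate elements lie — survives; a `transcribed:
genes` switch subtracts full gene spans instead, since the narrower and
wider readings of "transcribed regions" are both defensible. Genome-scale
counts from the original alignment (168,306 CNEs, mean 143 bp) depend on
that alignment and are treated as descriptive context, not as quantities
this package can reproduce.

## CNE-to-gene assignment

The assignment rule is the package's own reading of "neighboring genes": a
CNE overlapping a gene span belongs to that host gene (to all hosts if gene
spans overlap); an intergenic CNE is assigned to the nearest gene upstream
and the nearest gene downstream, ties broken to the smaller gene identifier.
`max_distance` defaults to unlimited, which suits compact genomes with
short intergenic regions; set it for large genomes. Strand is ignored —
enhancers act in either orientation.

## What the synthetic fixtures emulate

`make_fixture()` generates a two-chromosome genome of per-gene slots: a run
of 5' intergenic CNEs, then the gene (two 150-bp exons around a central
intron that holds one more CNE). Genes are partitioned into tissue
categories (default 60 anterior, 60 posterior, 180 epidermis of 300 genes,
a scaled-down analog of the 904-gene atlas); genes of the planted tissue
receive a duplicated planted motif in their intronic CNE with probability
`q = 0.4`, all other genes with `b = 0.05`, at conserved positions with
start-to-start distance uniform in 5-125 bp. The intronic placement
mirrors where the study's candidate elements preferentially lie (intronic
and 5'-proximal) and gives each planted duplicate an unambiguous host gene;
the intergenic CNEs, which may legitimately flank two genes, exercise the
two-nearest-flanks rule and contribute background. Per-base conservation is
Bernoulli(0.9), and chance occurrences of the planted motif in background
sequence are deliberately left in place.

The fixtures do **not** emulate realistic nucleotide composition (bases are
i.i.d. uniform), indels, multi-species alignments, overlapping genes or
multi-tissue gene labels. Passing the planted-recovery tests therefore
shows that the statistic and its plumbing are correct and well-powered
under a clean null, not that the biological screen would succeed on any
particular genome.

Fixture sizes used by the test suite (60-300 genes, 1-2 CNEs per gene,
mean CNE length 150 bp) keep a full 512-class scan of a fixture in the
low seconds while leaving the planted signal comfortably above the
512-way multiplicity floor of the score's null distribution.

## Robustness machinery

Annotation error is modelled by selecting `ceil(f G)` genes (default
`f = 0.1`) and cyclically rotating their entire label-sets, 100 replicates,
with empirical 2.5/97.5 percentile intervals. Rotation preserves every
category size exactly, so the background fraction `p` is constant across
replicates and replicate scores are directly comparable — the likeliest
reading of a fixed-score plot with error bars. A `resample` mode that
redraws label-sets from their empirical distribution is provided for
sensitivity analysis. One master seed draws an independent sub-seed per
replicate, so any single replicate is reproducible in isolation.

The sweep re-tests the signature over `W` in 25-300 bp and `c` in 1-4,
locating occurrences once and repeating only the window test. Two
monotonicity laws are built into the semantics and asserted in tests: the
flanked-gene set is non-decreasing in `W` and non-increasing in `c`.

## Numerical choices

* Binomial tails use `pbinom` on the log scale; accuracy against exact
  rational-arithmetic summation is 10+ significant digits for `n <= 200`.
* The two-tailed Fisher test uses the conditional point-probability rule
  (sum all tables with the observed margins whose probability does not
  exceed the observed one, with a 1e-7 relative tie guard), delegated to
  `stats::fisher.test` and cross-checked in the test suite against an
  exhaustive hypergeometric enumeration.
* The proportion table renders fractions truncated (not rounded) to two
  decimals, the convention such tables conventionally print; full
  precision is kept in a separate column.
* Motif ranking breaks score ties by ascending canonical word, so ranked
  output is deterministic.
* The spacer designer extends one base at a time in a seeded random order
  of A/C/G/T, backtracking one base whenever the newest k-window (either
  strand; the forbidden set is closed under reverse complement on load) is
  forbidden, and gives up after 1e6 node visits. The original procedure
  states neither seeding nor ordering; these choices make it reproducible
  and terminating.

## Known limitations

* The CNE-to-gene rule is heuristic; promoter-anchored or contact-based
  assignment is out of scope.
* Consensus k-mers only — no PWMs or degenerate IUPAC motifs, matching the
  design rationale that homeodomain subfamilies bind non-degenerate
  pentamer cores.
* With every fixture gene annotated, two-flank assignment necessarily
  credits some signatures to a neighbor; the enrichment score tolerates
  this dilution but per-gene attribution should not be over-interpreted.
* Scores across classes are dependent (shared CNEs), so the rank tables
  are a screen, not a calibrated multiple-testing procedure.
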