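# tagscan

Genome-wide detection of **duplicated, conserved short-motif signatures in
conserved non-coding elements (CNEs)**, and scoring of their association
with tissue-specific gene expression.

The motivating biology: K50-Paired homeodomain factors (OTX, PITX,
Goosecoid) bind a GATTA/TAATC core, and in the compact ascidian genome a
*pair* of conserved GATTA sites within ~125 bp of non-coding conserved DNA
is a signature of anterior neuroectoderm enhancers. `tagscan` generalises
that screen to any k-mer class: it builds CNEs from a pairwise whole-genome
alignment (MAF) by removing transcribed positions, scans all canonical
k-mer classes (512 pentamer classes; a class is a word pooled with its
reverse complement) for `c` conserved occurrences whose starts fall within
`W` bp inside one CNE, maps CNEs to host or nearest flanking genes, and
ranks motif-tissue associations with a binomial enrichment score.

## The score

For a signature (motif class, `c` copies, window `W`) and tissue `t`:

* `n` — annotated genes flanked by a CNE carrying the signature,
* `k` — those among them annotated in `t`,
* `p` — background tissue fraction, `|genes in t| / |annotated genes|`,

the **motif-tissue score** is

```
S = -log10 P[X >= k],    X ~ Binomial(n, p)
```

computed in log space, capped at 300. No sequence background model is
needed; the null is that flanked genes are an exchangeable sample of the
annotated gene set. Robustness utilities perturb a fraction of the
gene-tissue annotations (size-preserving label rotation, 100 replicates,
95% percentile intervals) and sweep `c` in 1..4 and `W` in 25..300 bp.

The package also ships a synthetic-fixture generator (genome + MAF + BED +
annotations with planted motif enrichment near genes of one tissue, plus a
truth record) and a backtracking designer for spacer sequences that avoid a
forbidden k-mer set (e.g. octamers with protein-binding-microarray
enrichment above 0.3).

## Worked example

Generate a fixture under the default study conditions (300 genes split
60/60/180 across anterior nervous system, posterior nervous system and
epidermis; planted GATTA duplicates near anterior genes at rate q = 0.4,
background rate b = 0.05), then run the scan and score it:

```r
library(tagscan)

params <- fixture_params(seed = 8)
fx     <- make_fixture(params)

cnes <- subtract_transcribed(fx$blocks, fx$exons, min_length = 20)
cne_stats(cnes)[1:2]
#> $count
#> [1] 606
#> $mean_length
#> [1] 148.665

inc <- scan_signatures(cnes, k = 5, copies = 2, window = 125)
asn <- assign_cnes_to_genes(cnes, fx$genes)
gi  <- gene_signature_incidence(inc, asn)
scores <- score_all_motifs(gi, fx$annotations,
                           c("anterior_ns", "posterior_ns", "epidermis"),
                           motifs = enumerate_motif_classes(5))
head(rank_motifs(scores, "anterior_ns"), 3)
#>   motif      tissue  n  k   p        S rank
#> 1 GATTA anterior_ns 53 29 0.2 7.609240    1
#> 2 GAGAA anterior_ns 11  6 0.2 1.933517    2
#> 3 CAAGA anterior_ns  6  4 0.2 1.770574    3
```

Of the 53 annotated genes flanked by a duplicated conserved GATTA, 29 are
anterior (10.6 expected under the 0.2 background), so the planted class
ranks first by a wide margin — the next class scores 1.9. Candidate
enhancer elements are the signature-bearing CNEs near anterior genes:

```r
cands <- select_candidate_cnes(cnes, inc, asn, fx$annotations,
                               "GATTA", "anterior_ns")
length(cands)
#> [1] 29
```

`run_pipeline()` (or the `inst/cli/tagscan` script) chains all stages from
a YAML config and writes the CNE BED + masks, incidence tables, the
per-tissue proportion table with its anterior-vs-posterior Fisher exact
test, score/rank tables, shuffle confidence intervals, the copy/window
sweep matrix, a candidates BED and a JSON run manifest.

See `vignettes/tagscan-methods.Rmd` for the model, parameter semantics,
what the synthetic data does and does not emulate, and numerical choices.

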