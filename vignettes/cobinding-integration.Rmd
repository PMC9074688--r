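---
title: "Co-binding and regulatory-mode classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-binding and regulatory-mode classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcobind)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and the numerical and design choices that were genuinely
open.

## The analysis in one paragraph

Two transcription factors are profiled by ChIP-seq in two conditions
(baseline and an inducing stimulus); RNA-seq spans two genotypes
(control and a knockout of the partner factor's gene family) crossed
with the same two treatments. The pipeline (i) classifies the induced
peaks of factor A by summit proximity to factor B's summits, (ii)
assigns peaks to genes through a padded window, (iii) detects loci
where induction *switches* the bound factor, (iv) calls
treatment-responsive and genotype-dependent genes from counts, and (v)
joins all evidence into a per-gene regulatory-mode class.

## Coordinates

Everything internal is 0-based half-open (BED convention). GTF input
(1-based inclusive) is converted at parse time; `GRanges` objects used
for overlap queries are built 1-based internally and never exposed.
One convention end-to-end is what keeps a 50 bp summit rule from
silently shifting by one. Chromosome names are compared as exact
strings; `read_peaks(normalize_chr=)` can strip or add a `"chr"`
prefix when two inputs disagree.

## Summit-proximity co-binding

The co-binding statistic is summit-based, not interval-based: two
factors whose summits sit within `max_summit_distance` (default 50 bp)
are taken to co-occupy a regulatory element. The threshold is
*inclusive* — "within 50 bp" includes exactly 50 — and matching is
many-to-one (two A summits may share the nearest B summit; the
fraction counts summits, not exclusive pairs). Equidistant partners
resolve to the lower coordinate by default. Because the A-perspective
fraction (share of A summits near a B summit) and the B-perspective
fraction differ whenever peak counts differ, `group_summits()` reports
both, along with raw Venn counts, so either convention can be quoted.

## Peak-to-gene annotation

A summit decides both the feature category and the gene assignment
(using one anchor for both keeps the genomic-distribution and
co-binding views consistent). A peak is assigned to *every* gene whose
body or ±50 kb window contains its summit — divergent promoters
legitimately claim one peak for two genes — and reports count
gene–peak pairs and unique genes separately. `upstream_pad` defaults
to 50,000 bp, the padding used by the upstream peak-calling/annotation
stack this pipeline is designed to sit behind. When a summit lies in
features of several genes, a fixed priority breaks the tie
(`five_utr > cds > three_utr > intron > upstream > downstream >
intergenic`): exonic features are more specific than positional ones.
Two edge conventions worth knowing: a `downstream` category (within
the pad 3′ of a gene end) is reported but can be merged into
`intergenic` (`merge_downstream = TRUE`), and an exonic summit in a
gene without an annotated CDS is counted with the 5′ UTR class rather
than inventing a separate category.

## Binding-switch detection

A switch locus is a baseline peak of the constitutive factor where,
upon stimulation, that factor's binding disappears and the partner's
appears. Presence/absence across conditions is *interval overlap*
(≥ 1 bp), not summit distance — loss and gain are track-level events
over a region. Detection is purely positional with no signal-strength
threshold: the biology supplies no quantitative loss/gain criterion,
so adding one would only create a hidden tuning knob. Calls are
annotated with the assigned gene and a 3′ UTR overlap flag, the
hallmark of the autoregulatory switch this analysis looks for.

## The count model and the Audic–Claverie test

Counts are normalized by median-of-ratios size factors (the classic
pseudo-reference scheme; `DESeq2`'s implementation is the cross-check
in the test suite, not the implementation). For a two-group contrast,
replicates are **pooled by summation** — the Audic–Claverie test is
defined for two libraries — with pooled effective library sizes
`sum(size factor) × mean(total count)`. Pooling trades per-replicate
variance information for the exact two-library test; the vignette's
honest caveat is that under strong biological overdispersion the
pooled test is anti-conservative, which is why direction calls also
require the fold-change gate (below) and why the generator documents
its dispersion assumptions.

The test itself: conditional on `x` in a library of size `n1`, the
count `y` in a library of size `n2` follows
`P(y|x) = (n2/n1)^y (x+y)! / (x! y! (1+n2/n1)^(x+y+1))` — a negative
binomial in `y` with size `x+1` and success probability
`n1/(n1+n2)`. Tails are accumulated in log space (log-sum-exp over the
log pmf); above `exact_limit = 10000` total counts a normal
approximation with continuity correction takes over to bound runtime
(p-values there are either astronomically small or far from any
decision boundary, so the approximation never changes a call at
α = 0.05). The two-sided value doubles the smaller *inclusive* tail,
the conservative exact-test convention; it reproduces
`p(0,0) = 1` and `p(5,0) = 1/32` at equal library sizes. The swapped
test `p(y,x,n2,n1)` agrees up to the boundary-point mass (the exact
identity is that the swapped lower tails are complementary); the
inclusive convention was kept in preference to exact swap-symmetry.

A gene is **responsive** when linear fold change ≥ 1.5 (on normalized
pooled means) *and* BH q < 0.05 — the conservative conjunction of the
fold rule and the stated significance cutoff; `fc_only = TRUE`
reproduces the threshold-only reading. Fold changes are linear, with a
+1 pseudocount applied to both pooled counts only when one of them is
zero (and flagged). **Dependence** is decided by re-running the same
contrast in the knockout genotype: response gone → dependent
(unchanged), response sign-flipped → dependent (reversed), response
kept → independent.

## Regulatory classes

For each gene, with peaks assigned through the 50 kb rule:

* **Class 1** — ≥ 1 co-bound (Group 1) peak and a dependent response.
* **Class 2** — ≥ 1 B-only (Group 3) peak, no co-bound peak, dependent
  response.
* **Class 3** — dependent response with no assigned peak of either
  factor (indirect target).
* **Class 4** — an annotated binding switch at the locus. Class 4 does
  not require differential expression — the switch maintains a
  constant output under stimulation — and therefore takes precedence
  over Classes 1–3 and bypasses the dependence filter.

Genes that fit no class (non-responsive, genotype-independent, or
bound only by factor A alone) are retained as `unclassified` with an
explicit reason; nothing is silently dropped. The A-only case is
deliberate: the class system's "direct target" notions are co-binding
and B-only binding, and forcing A-only genes into the indirect class
would blur the distinction the classes exist to draw.

## Coverage profiles and motifs

TSS-centered profile matrices bin a ±2 kb window (50 bp bins by
default; both are exposed, neither is asserted — the underlying
figures' parameters are a presentation choice) counting each read
interval into every bin it overlaps, flipping minus-strand anchors so
bins run 5′→3′, and scaling to reads per million. Reads are supplied
as plain intervals (BED-style), which keeps the package free of
alignment-file dependencies. Box-plot summaries use type-7 quantiles
and 1.5·IQR Tukey whiskers so every summary number is exactly
specified.

Motif scanning supports IUPAC consensus strings and count PWMs with
per-cell Laplace pseudocounts (`(count + α)/(N + 4α)` at uniform
background), scored as log-odds in bits on both strands. One
degeneracy rule is fixed package-wide: an `N` in the *sequence* is
unknown and matches only the motif code `N`. Enrichment uses
per-sequence dinucleotide-preserving shuffles (Euler-path
construction) with `empirical_p = (1 + #null ≥ obs)/(n_shuffles + 1)`.
The default SOX-like consensus `WWCAAW` is a configuration default
only; all asserted tests plant synthetic motifs. De-novo motif
discovery is out of scope.

## The synthetic generator

`simulate_study()` builds every input with planted truth:

* **Genome and genes** — 300 genes, one per private ~133 kb slot on
  2 × 20 Mb chromosomes. The slot width is the load-bearing choice:
  planted peaks are confined to narrow zones around slot centers so no
  peak can enter the 50 kb assignment window of a neighboring gene,
  which is what makes planted-class recovery exact rather than
  approximate. (A 10 Mb genome at the same gene count would overlap
  assignment windows and make exact recovery impossible by
  construction.)
* **Peaks** — 600 induced peaks per factor; baseline sets are
  persistent subsets at 1/3 of that (induction fold 3). A 70.4% share
  of induced A summits is planted within U{0..50} bp of a B summit,
  the rest ≥ 500 bp away (site spacing guarantees it); the planted
  offset jitter defaults to 0 so recovery is exact. Two switch loci
  sit in the 3′ UTRs of flagged genes.
* **Counts** — log-normal baselines (meanlog log 200, sdlog 1),
  negative-binomial replicates (3 per genotype × treatment), library
  depth 10⁶ jittered ±10%. Planted responsive genes change by linear
  FC 3 under treatment; dependent genes have the knockout response
  nulled (or sign-flipped for a 25% reversed share). The default
  dispersion is 0.02 — adenovirus-treated primary cell triplicates
  behave close to technical replication, and the replicate-pooled
  exact test presumes near-Poisson libraries; the generator exposes
  the knob precisely so that its effect on the pooled test is
  observable (the DE-recovery checks deliberately run at 0.05, and
  the end-to-end class-recovery condition at 0.01, i.e. strong
  effects and low noise).
* **Classes** — 20/30/100/2 genes planted as Classes 1–4 plus 100
  responsive-but-independent genes, giving 250 responsive genes of
  which 60% are dependent.

What the generator does *not* emulate: chromatin background and GC
bias, fragment-length effects, peak-calling noise, annotation
ambiguity, or dispersion heterogeneity across genes. Passing recovery
tests therefore demonstrate the *logic* of the pipeline — grouping,
windows, tails, precedence rules — not robustness to real ChIP-seq
artifacts.

## Problem sizes and determinism

The shipped checks run the exact-test oracle over all count pairs up
to 50, one hundred random grouping instances of ≤ 200 summits against
an O(n²) oracle, DE recovery at 2,000 genes × 12 samples, and the full
study at 300 genes / 600 peaks per factor — a few seconds each, chosen
so the whole suite stays interactive. All randomness flows through
explicit integer seeds; identical inputs produce byte-identical
reports (JSON output has fixed digits and no timestamps).

## Known limitations

* The pooled Audic–Claverie test inherits its anti-conservativeness
  under overdispersion; a dispersion-based GLM is deliberately out of
  scope (the point of the package is this exact scheme), and the
  fold-change gate is the pragmatic guard.
* Switch detection is binary and positional; a weak residual peak
  that still passes the upstream peak caller suppresses a call.
* Gene assignment by fixed windows cannot see enhancer–promoter
  looping; the 50 kb pad is a blunt, but stated, instrument.
* The boundary between Class 2 and "A-only/unclassified" depends on
  the upstream peak caller's sensitivity for factor A.
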