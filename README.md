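# tfcobind

Integration of ChIP-seq and RNA-seq evidence for a pair of transcription
factors that act as binding partners — the setting is an NF-κB factor
(RELA/p65) and an inducible SOX-family partner (SOX4) in TNF-stimulated
fibroblast-like synoviocytes, but every label is configurable. The
package answers three questions about such a pair:

1. **Where do the two factors co-bind?** Peak summits of factor A are
   classified against factor B's summits at a fixed distance *d*
   (default 50 bp, inclusive): Group 1 = co-bound (∃ B summit with
   |s_A − s_B| ≤ d on the same chromosome), Group 2 = A-only,
   Group 3 = B-only. Peaks are assigned to genes whose body or ±50 kb
   padding window contains the summit, and classified by genomic
   feature (upstream, 5′ UTR, CDS, intron, 3′ UTR, downstream,
   intergenic).
2. **Which genes respond to the stimulus, and does the response need
   the partner factor?** Counts are normalized by median-of-ratios size
   factors; replicate-pooled counts are compared between conditions
   with the Audic–Claverie exact test,

   P(y | x) = (n₂/n₁)^y · (x+y)! / (x!·y!·(1+n₂/n₁)^(x+y+1)),

   i.e. y | x ~ NegBin(x+1, n₁/(n₁+n₂)); two-sided p =
   min(1, 2·min(P(Y≤y|x), P(Y≥y|x))), BH-corrected. A gene is
   *responsive* at linear fold change ≥ 1.5 and q < 0.05, and
   *dependent* when its response vanishes or flips sign in the
   knockout genotype.
3. **How is each responsive gene regulated?** Class 1 = co-bound direct
   target, Class 2 = B-only direct target, Class 3 = indirect target
   (no binding of either factor), Class 4 = regulatory *binding
   switch*: a locus (typically a 3′ UTR) bound by B at baseline where
   induction removes B and brings in A — an autoregulatory hand-off
   that maintains rather than changes expression, so Class 4 is exempt
   from the differential-expression filter.

A seeded synthetic-data generator (`simulate_study()`) emulates this
whole design — co-bound summit planting, 3× peak induction, switch
loci in 3′ UTRs, negative-binomial counts with planted fold changes
and dependence — and records every planted fact in a truth manifest,
so each stage is validated by planted-structure recovery.

## Worked example

```r
library(tfcobind)

study <- simulate_study(sim_config(seed = 7, counts = list(nb_dispersion = 0.01)))
res <- run_integration(study$peaks, study$genes, study$cm)
res$report
#> integration_report
#>   co-binding: 422 co-bound / 178 A-only / 178 B-only (fraction A co-bound 0.703)
#>   responsive genes: 250; dependent: 150 (fraction 0.600)
#>   class counts: class1_cobound_direct=20, class2_rela_only=30, class3_indirect=100, class4_switch=2, unclassified=148
```

422 of the 600 induced SOX4 summits sit within 50 bp of a RELA summit
(the planted 70.4% co-binding share); 250 genes respond to TNF of which
150 (60%) need the SoxC genotype; and the four planted regulatory
classes (20 co-bound direct, 30 RELA-only, 100 indirect, 2 switch
genes) are recovered exactly. The `unclassified` rows keep their
reasons (not responsive, genotype-independent, or A-only binding).

Individual stages are ordinary functions, e.g.

```r
audic_claverie_p(5, 0, 1e6, 1e6)
#> [1] 0.03125
grp <- group_summits(study$peaks$SOX4$tnf, study$peaks$RELA$tnf)
switches <- detect_switch(study$peaks$RELA, study$peaks$SOX4)
```

File-based inputs (narrowPeak, BED12, count/metadata TSV) go through
`run_pipeline()`; `write_study()` exports a simulated study in those
formats.

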