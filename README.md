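# enhancerkit

Regulatory-genomics toolkit for the analysis pattern that surrounds a
stimulated transcription factor (TF): identify **typical and super
enhancers** from H3K27ac peaks and signal, predict **transcriptional
co-regulators** from motif enrichment in TF peak-summit flanks, assign
**target genes** by intersecting bound genes with differentially expressed
genes, and classify **co-binding** between two TF peak sets. It is aimed at
epigenomics analysts who have peak calls (BED), coverage (bedGraph), a TSS
annotation (BED) and a motif library (MEME minimal format) and want the
downstream regulatory calls as reproducible, tested R functions.

## The methods in brief

**Super-enhancer calling** (ROSE lineage). Distal H3K27ac peaks (boundary
≥ 1.5 kb or center ≥ 3 kb from the nearest TSS) are stitched when their gap
is < 12.5 kb, stitched regions are ranked by total H3K27ac signal, and the
ranked curve is scaled to the unit square. The cutoff is the tangency point
of a slope-1 line supporting the scaled curve from below — the index
minimising `y − x`. Enhancers above the tangency point are super enhancers:

```
is_super(e)  ⟺  signal(e) > signal(argmin_i [ s_(i)/s_max − (i−1)/(N−1) ])
```

**Co-regulator prediction** (average-odds + rank-sum). Each motif scores the
200 bp flanks of condition and control TF summits by the mean over all
windows, both strands, of the odds `∏ p_motif(b)/p_bg(b)`; enrichment is a
one-sided Wilcoxon rank-sum test (exact for small tie-free samples, normal
approximation with tie/continuity correction otherwise) at p ≤ 0.05. A motif
is a candidate co-regulator when enriched condition-vs-control but not in
the reverse direction.

**Targets and co-binding.** Peaks annotate to the nearest TSS; a target gene
is bound and differentially expressed; two summits < 200 bp apart are
co-bound (greedy nearest-first pairing).

A seeded generator, `simulate_regulome()`, builds a toy chromosome with
planted super enhancers, planted motif instances, planted DEGs and a
ground-truth record, so the whole pipeline is testable offline.

## Worked example

```r
library(enhancerkit)

sim <- simulate_regulome(sim_params(seed = 1))   # default study conditions

## 1. enhancers
calls <- call_enhancers(sim$k27_peaks, sim$genes, sim$k27_track)
calls
#> Enhancer calls (ok): 525 stitched regions from 908 distal peaks
#> Slope-1 tangency at rank 492 (signal 40.39): 33 super / 492 typical enhancers

truth_metrics(sim$truth, enhancer_calls = calls)
#> Recovery against planted truth:
#>   n_super_planted    25
#>   n_super_recovered  25
#>   se_sensitivity     1
#>   se_specificity     0.984

## 2. co-regulators (condition flanks vs control flanks)
fg  <- extract_flanks(sim$tf_peaks$stimA, sim$genome, 200, "stimA")
ctl <- extract_flanks(sim$tf_peaks$dmso,  sim$genome, 200, "dmso")
head(enrich_motifs(fg, ctl, sim$motifs), 2)
#>    motif_id u_statistic      p_value n_fg n_bg enriched
#> 1  M_TARGET       25635 5.480390e-07  200  200     TRUE
#> 2 M_DECOY10       20465 3.439271e-01  200  200    FALSE

## 3. targets and set algebra
ann <- annotate_peaks(sim$tf_peaks$stimA, sim$genes)
tg  <- call_targets(unique(ann$gene_id), sim$expression)
sum(tg$is_target)
#> [1] 41

summarize_sets(sprintf("g%03d", 1:475), sprintf("g%03d", 406:523))
#> Sets: |A|=475 |B|=118 intersection=70 union=523 (A only 405, B only 48)

## 4. co-binding between the two stimulation sets
cobinding(sim$tf_peaks$stimA, sim$tf_peaks$stimB, 200)
#> Co-binding: 30 overlapped pairs, 170 A-only, 170 B-only peaks
```

The first block says all 25 planted super enhancers were labelled super with
98.4% specificity; the second that the planted motif ranks first among 11
with p ≈ 5×10⁻⁷ while the best decoy is far from significant; the third that
41 bound-and-differentially-expressed genes are called targets and that a
475/118 gene pair with 70 shared members unions to 523; the fourth that
exactly the 30 planted < 200 bp summit pairs are recovered.

`run_pipeline(run_config(outdir, sim = sim_params(seed = 1)))` chains all
stages and writes TSV outputs plus a manifest with input digests and
per-stage counts.

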