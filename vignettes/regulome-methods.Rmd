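---
title: "Methods: enhancer calling, motif enrichment and target assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer calling, motif enrichment and target assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerkit)
```

# Scope and model

`enhancerkit` implements the regulatory-genomics computations that surround a
stimulated transcription factor (TF) such as p53 activated by a genotoxic drug
or an MDM2 inhibitor: which distal chromatin regions behave as enhancers and
super enhancers under the H3K27ac mark, which other TF motifs are over-represented
in the stimulated TF's binding-site flanks relative to a vehicle control
(candidate co-regulators), which genes the TF binds and regulates, and where
two TFs co-occupy the genome. Every coordinate is BED convention (0-based,
half-open) and all quantities are computed from four plain-text primitives:
peaks (BED), per-base signal (bedGraph), TSS annotation (BED), and motifs
(MEME minimal format).

# Enhancer identification

The procedure follows the stitched-enhancer (ROSE) lineage:

1. **Distal filtering.** An H3K27ac peak is kept when its boundary is at least
   1.5 kb from the nearest TSS *or* its center at least 3 kb. The two clauses
   are read as alternative sufficiency criteria — either one clears the peak
   as distal. The conjunctive reading is available through
   `pipeline_params(distal_rule = "and")` since the wording of the rule is
   genuinely ambiguous, but the disjunction is the default because it is the
   literal reading of "boundary 1.5 kb or center 3 kb".
2. **Stitching.** Distal peaks whose gap is strictly shorter than 12.5 kb are
   merged into one enhancer (single linkage per chromosome). The strictness
   matters at the boundary: a 12,499 bp gap merges, a 12,500 bp gap does not.
3. **Quantification.** Each stitched region's total signal is the area of the
   signal track intersected with the region (raw area; no input-track
   subtraction, which the pipeline deliberately does not model).
4. **Tangency cutoff.** Regions are sorted by total signal, ranks are scaled
   to $x \in [0,1]$ and signals to $y \in [0,1]$ (division by the maximum),
   and the cutoff is placed where a line of slope 1 is tangent to the scaled
   curve from below: the index minimising $y - x$, the touch point of the
   supporting slope-1 line. Enhancers with signal strictly greater than the
   tangency signal are super enhancers, the rest typical.

Numerical choices for the cutoff: ties in $y - x$ resolve to the
higher-signal side, which yields fewer super enhancers; equal-signal ties at
the cutoff are all typical (strict inequality), so the super set is always a
contiguous top-$k$ by signal; a flat curve (all signals equal) returns zero
super enhancers rather than erroring, because "no elbow" is a meaningful
empirical outcome; a curve with zero maximum signal or fewer than three
points is an error. The support-line construction was chosen over a discrete
scan of consecutive-point slopes because the discrete scan is unstable on
real landscapes — any two near-equal signal totals among the top regions
create a local slope below 1 and truncate the super set arbitrarily — while
the support line depends only on the curve's global geometry, coincides with
the slope-1 derivative condition on convex curves (for signals proportional
to $x^2$ it lands at $x = 0.5$ exactly), and is invariant under scaling all
signals by any positive constant.

# Co-regulator prediction

For each TF peak, the `width = 200` bp sequence centred on the summit is
extracted (windows clipped by a chromosome end are discarded and logged).
Each motif — a position weight matrix with a 1e-4 pseudocount applied at read
time so log-odds stay finite — scores each sequence by **average odds**: the
arithmetic mean over all windows on both strands of
$\prod_j p_\text{motif}(b_j)/p_\text{background}(b_j)$. Windows containing N
contribute a neutral odds of 1, which keeps window counts equal across
sequences of equal length; averaging over both strands makes the score
exactly invariant under reverse complementation (a tested invariant).

Enrichment of a condition flank set against the control flank set is a
one-sided Wilcoxon rank-sum test (alternative: condition scores larger),
exact by enumeration when the combined sample size is at most 25 with no
ties, otherwise the normal approximation with tie and continuity corrections.
Motifs are reported at raw p &le; 0.05 by default — matching the reporting
convention of average-odds/rank-sum motif enrichment tools — with an optional
Bonferroni flag.

A motif is retained as a **candidate co-regulator** when it is enriched in
the condition versus the control *and not* enriched in the reverse direction.
The reverse-direction test is this package's reading of "filtering conserved
and biased sites": motifs present equally in both sets (conserved) or biased
toward the control fail it. The control set itself defines the null; no
shuffled-sequence background is used.

# Targets, co-binding, profiles

Peaks are annotated to the gene with the nearest TSS (distance measured from
the summit; ties broken by the lexicographically smaller gene id; sign
oriented by gene strand with negative = upstream). A **target gene** is bound
*and* differentially expressed, with the DE direction carried through.
Set summaries obey inclusion–exclusion exactly, and the novel/reported split
is plain set algebra on the called target list.

Two peak sets **co-bind** where their summit-to-summit distance is strictly
below 200 bp (edge-to-edge distance is available via
`pipeline_params(cobind_mode = "edge")` since the underlying rule does not
say which distance was meant; summits are the default because they are the
anchor used everywhere else). Matching is greedy nearest-first with every
peak used at most once, which makes the partition deterministic, exhaustive
and disjoint.

`profile_matrix()` computes metagene-style average-signal profiles: each
anchor's $\pm$`flank` window is cut into `nbins` equal bins and the mean
signal density per bin is recorded; column means give the average curve.
Windows extending past the chromosome start treat missing bases as zero
signal.

# The synthetic landscape

`simulate_regulome()` generates the fixed study conditions the tests and the
acceptance checks run under. One 18 Mb chromosome carries:

* 450 genes at 4 kb spacing (jittered), with 50 TSS-proximal H3K27ac decoy
  peaks that the distal filter must remove;
* 525 enhancer slots at 30 kb pitch (so stitched regions can never merge
  across slots): 500 typical slots of 1–2 constituents with total signal
  drawn from an exponential with mean 10 area units, and 25 planted super
  slots of 5–7 clustered constituents (within the stitch gap) totalling
  50 × 10 units with ±20% uniform jitter — a multiplicative separation that
  places every planted region in the top signal ranks by construction;
* 200 TF summits per stimulation condition, half shared (same coordinate)
  with the 200-summit control set, 30 summit pairs planted 50–199 bp apart
  between the two stimulation sets, and an exact consensus of a designated
  10-bp motif written into the genome in 30% of each condition's flanks.
  Plants go only to condition-unique, non-cobound summits so control and
  cross-condition flanks stay clean, and the consensus (argmax per column)
  rather than a matrix sample is planted so recovery is monotone in the
  plant rate;
* 60 up- and 40 down-regulated DEGs, 80% of them drawn from bound genes;
* a ground-truth record of everything planted.

All draws come from one seeded stream in a documented order, with the genome
drawn last so that skipping sequence generation (`include_genome = FALSE`)
leaves every other component bit-identical; equal seeds give byte-identical
bundles. The signal model is piecewise-constant per constituent peak. The
generator emulates the *statistical shape* of a real landscape — a
long-tailed signal distribution with a separated high-signal class, planted
motif instances, DEGs enriched near binding — but not read-level noise,
GC/fragment-length bias, copy-number distortion, or replicate structure:
passing recovery tests demonstrates that the algorithms identify what was
planted under clean conditions, not that they are robust to every artefact
of real ChIP-seq.

Problem sizes in the test-suite property checks (100 random curves for the
tangency oracle, 500 rank-sum branch comparisons, 100 null-calibration
replicates of 50 + 50 flanks, and the default 525-enhancer landscape) were
chosen to make each check statistically meaningful at desk scale.

# Known limitations

* "Total signal" is raw area; no normalisation against an input track.
* Nearest-TSS annotation has no promoter/intron categorisation, and no
  promoter-proximal enhancer rescue exists.
* The rank-sum enrichment inherits the usual caveat of sequence-level tests:
  compositional differences between flank sets (GC skew) can register as
  enrichment for GC-rich motifs.
* Only single-sample enhancer calling is provided; differential
  super-enhancer analysis across conditions is out of scope.
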