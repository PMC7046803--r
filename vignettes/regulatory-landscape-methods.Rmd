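---
title: "Methods: miRNA regulatory-region occupancy and qPCR quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA regulatory-region occupancy and qPCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirreg)
library(dplyr)
```

## The problem

Circulating microRNAs are promising biomarkers in myasthenia gravis (MG):
the two serological subtypes carry distinct serum signatures — miR-150-5p,
miR-21-5p and miR-30e-5p in acetylcholine-receptor antibody seropositive
(AChR+) disease, and miR-151a-3p, miR-423-5p, let-7a-5p and let-7f-5p in
muscle-specific kinase antibody seropositive (MuSK+) disease. Which
transcription factors (TFs) drive these miRNAs is a question about their
regulatory regions: how many ChIP-seq binding sites for each TF fall in the
windows around each miRNA locus, whether those windows look like real
regulatory elements in histone-mark data, whether the bound intervals carry
the TF's sequence motif, and how occupancy aggregates by TF family and
disease subtype. `mirreg` implements that analysis as a reusable, tested
pipeline, together with the serum qPCR quantification stage (hemolysis QC,
comparative CT, group statistics) used to validate individual miRNAs in
patient cohorts.

## Regulatory windows

All coordinates are 0-based half-open (BED-native); GFF3 input is converted
at read time, at a single point. For each miRNA locus the pipeline builds:

* **Proximal promoter** — the `promoter_bp` window (default 2,000 bp)
  directly upstream of the locus: `[start − size, start)` on `+`, mirrored
  on `−`. Unstranded loci are rejected rather than defaulted, because
  promoter placement is meaningless without a strand.
* **Enhancer neighborhood** — everything within `enhancer_bp` (default
  10,000 bp) of the locus. Two genuinely open choices were decided here and
  are worth stating. First, the window is *symmetric from the locus edges*
  and *includes the locus body*; regulatory evidence in browser views
  flanks a locus on both sides, and edge-anchored windows are the only
  convention that keeps `enhancer_window(locus, 0) == locus`. Second, the
  enhancer window is *not* promoter-subtracted, so a peak 1 kb upstream is
  counted in both windows; joint "promoter/enhancer" reporting is common in
  this literature, and the per-miRNA deduplicated totals (below) provide
  the unambiguous count alongside.
* **Host-gene windows** — a miRNA encoded *entirely inside an intron* of a
  gene additionally gets that gene's promoter and enhancer windows, built
  from the gene's own interval and strand. Containment is strict: any exon
  overlap disqualifies, and genes without annotated exon structure are
  treated as single-exon (intron-free). Among nested candidate hosts the
  shortest gene wins — the most specific transcription unit — with a
  lexicographic tie-break so the assignment is deterministic.

## Occupancy counting

ChIP-seq peaks are unstranded intervals labelled with a TF. Counting is
overlap-by-at-least-one-base with no minimum-fraction option; interval
merging coalesces overlapping *and abutting* intervals (union of covered
bases), the semantics of clustered cross-cell-line evidence tracks. By
default, same-TF peaks are merged across cell lines before counting
(`merge_cell_lines = TRUE`): one genomic site supported in nine cell lines
is one binding site. Because windows of one miRNA overlap each other, the
occupancy object carries two count fields:

* `entries` — sites per `(miRNA, TF, region type)`; a peak can legitimately
  appear under several region types;
* `dedup_totals` — distinct merged sites per `(miRNA, TF)` over the union
  of that miRNA's windows.

Headline summaries (family totals, subtype comparisons) default to the
per-region sums, which matches enumerating "all binding sites in the
promoter, the enhancer, and the host-gene windows"; the deduplicated
variant is always emitted alongside, since published per-figure conventions
cannot always be pinned down. Rankings break ties lexicographically.

Histone marks classify each window with promoter-mark precedence: any
overlapping H3K4me3 peak → `active_promoter`; else H3K4me1 with H3K27ac →
`active_enhancer`; H3K4me1 alone → `poised_enhancer`; else `unmarked`.
Chromatin state is annotation by default — marks were overlaid in the
source analysis to increase confidence, not to filter — and an optional
`require_marked` switch restricts counting to marked windows.

## Motifs

Motif models are position weight matrices built from base-count matrices
with pseudocount 0.5 and a uniform background (neither is dictated by the
analysis being reproduced; both are recorded on the object and
overridable). Scores are summed log-odds in bits; `N` contributes the
background-expected score of 0. A window is a hit when its score reaches
`min_score_frac` (default 0.8) of the motif's maximum attainable score —
a scale-free threshold that behaves sensibly across motif widths. Both
strands are scanned; minus-strand hits are reported at plus-strand window
coordinates, and for palindromic motifs both strands of one window are
reported, as there is no basis to prefer either. Scanning is
peak-restricted by default (motifs are sought where the TF actually
binds); whole-region scanning is available by passing region sequences.
The IUPAC consensus uses a 0.6 single-base dominance rule, then a 0.8
top-two rule for degenerate codes, else `N`.

## qPCR quantification

* **Hemolysis QC**: `dCT = CT(miR-23a-3p) − CT(miR-451a)`; samples with
  `dCT > 7` cycles are excluded (a delta of exactly 7.0 passes). Samples
  missing either marker are un-assessable and excluded with a reason.
* **Comparative CT**: `dCT = CT(target) − mean(CT of references)`,
  relative expression `2^(−dCT)`. The arithmetic mean of reference CTs
  equals the geometric mean of their linear-scale quantities, which
  unifies the two normalization descriptions used for serum panels
  (multi-reference miRNA panels) and cell-culture assays (geometric mean
  of two stable miRNAs). Reference assay names are fully user-specified —
  deliberately so, because published serum panels sometimes name
  references ambiguously (e.g. a `-4p`/`-5p` discrepancy).
* **Log conversion** defaults to base 10 (the base is not dictated by the
  reproduced analysis; it is recorded in the output metadata), applied
  before statistics because qPCR expression values approach normality on
  the log scale.
* **Group comparison**: two groups → unpaired Welch t-test; more → one-way
  ANOVA followed by all pairwise unpaired t-tests, with mean/SD/min/max
  descriptives for boxplot-style reporting, plus a Spearman helper for
  covariate checks. Technical replicates are collapsed by mean CT before
  QC; there is no outlier handling beyond hemolysis QC, because none is
  part of the procedure being implemented. `2^(−ddCT)` fold changes come
  out of `fold_change()` on linear-scale values; both calibrator-relative
  and direct `2^(−dCT)` workflows are expressible.

## The synthetic-data generator

Real inputs for this analysis are versioned browser tracks that cannot be
bundled, so the package ships a generator that emulates their statistical
structure at desk scale with *planted, exactly recoverable truth*:

* a uniform-random multi-chromosome genome (default 2 × 200 kb);
* gene models (default 6 genes, 3 exons of 1.5–2.5 kb, introns 3–5 kb) and
  miRNA loci (default the 7 MG signature names, ~80–120 bp, both strands,
  about half intronic), laid out in disjoint territories so no two miRNAs'
  windows overlap;
* per-(miRNA, TF, region type) planted TF peaks (default 8 TFs, 0–6 sites
  of 20–30 bp each), placed inside the designated window, outside every
  other miRNA's windows, and pairwise disjoint with ≥1 bp clearance — so
  counts are unambiguous under the merge policy;
* background peaks (default 5/Mb) at least 1 bp clear of every tracked
  window, so they can never perturb a planted count;
* histone peaks co-placed with windows at per-mark probabilities (defaults
  favor H3K4me3 in promoter windows and H3K4me1/H3K27ac in enhancer
  windows, leaving some windows unmarked so every chromatin call class is
  exercised);
* one information-rich motif (default a 7-bp forkhead-like consensus at
  ~1.67 bits/column) embedded at recorded offsets and strands inside the
  designated TF's peaks, with rejection sampling to guarantee no chance
  occurrences elsewhere in those peaks;
* a qPCR block: group-structured CT tables where the target CT is the
  sample's mean reference CT plus a group-specific dCT draw, so noise-free
  settings recover group means exactly, and a designated fraction of
  samples is made hemolytic.

Intronic miRNAs are positioned inside an intron *and* far enough from the
host gene's transcription start that the host promoter window stays clear
of the miRNA's own enhancer window; this keeps every placement zone at its
full capacity and makes the planted-count bookkeeping exact. The truth
tables are computed inside the generator by plain pairwise scans over the
generated coordinates — not by the package's counting machinery — so
"pipeline reproduces truth" is a genuine two-route check. Everything is a
deterministic, byte-reproducible function of the seed, and the generator's
RNG use is isolated from the session's stream.

What the generator does **not** emulate: realistic peak-shape or
signal-level structure, overlapping regulatory neighborhoods of clustered
miRNAs (e.g. polycistronic let-7 loci), cell-line-specific binding,
sequence composition biases, amplification-efficiency variation in qPCR.
Passing the planted-truth suite therefore demonstrates correctness of the
counting, classification, scanning and quantification logic under clean
conditions — not robustness to the messiness of real tracks.

## Problem sizes and numerical choices

The test and acceptance workloads use the demo scale above (a landscape
simulates in about one second): 1,000 random instances for the
interval-engine oracle checks, 100 random (sequence, motif) pairs for the
scanner oracle, 1,000 null and 500 alternative simulations for the
statistical-stage calibration (the 2-SD shift at n = 20/group is compared
against the closed-form noncentral-t power). Score-threshold comparisons
use a 1e-9 tolerance so floating-point ties at the threshold are kept.
Degenerate inputs are contracts, not accidents: empty peak collections
tabulate to zeros with a warning, empty interval sets merge to empty sets,
sequences shorter than a motif scan to zero hits with a message, all-zero
PWM columns without pseudocount are errors, and a group comparison where
every group has zero variance is refused.

## Limitations

The published counts this pipeline's conventions were modeled on
(e.g. 52 vs 9 FOXO-group sites for the AChR+ vs MuSK+ miRNA sets) came
from manual inspection of versioned ENCODE hg19 browser tracks; without
those exact track versions, and with window/deduplication conventions only
partly specified in prose, they are not mechanically reproducible from
this repository. `scripts/encode_replication.R` documents a best-effort
re-computation for users who download the clustered TFBS track and supply
hg19 miRNA coordinates; it is not part of the test suite. The default
family map reproduces the source analysis's "FOXO" grouping, which mixes
FOXA/FOXM/FOXP forkhead factors — kept for fidelity, flagged here, and
fully overridable via the YAML group config.
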