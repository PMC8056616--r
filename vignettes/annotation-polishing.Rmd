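---
title: "Coverage-driven polishing of gene annotations: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-driven polishing of gene annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annopolish)
```

## The problem

Genome-guided transcriptome assemblers construct gene models from spliced
short-read alignments. Three structural error classes recur in their
output. Redundant transcripts whose exon–intron structure is a proper
subset of another model inflate the annotation without adding
information. Genes packed within a few tens of bases of each other on the
same strand get fused into one model when reads from the facing end exons
bleed across the inter-genic gap: the resulting annotation contains one
exon that really spans *end exon + gap + start exon*. And terminal exons
of a gene can over-extend across an antisense neighbour, typically up to
the neighbour's nearest intron, degrading boundary precision.

All three have a coverage signature. This package repairs them directly
from the per-base read-depth track and provides the evaluation machinery
to quantify the repair.

## The changepoint model

Per-base depth across an exon is modelled as a piecewise-stationary
exponential signal: within a segment the depths share one mean, and
changepoints are positions where the mean changes. The cost of a segment
`x_1..x_n` is twice its negative exponential log-likelihood at the
maximum-likelihood rate, with the segmentation-invariant constant `2n`
dropped:

$$C(x) = 2\,n \log\!\left(\tfrac{1}{n}\textstyle\sum_i x_i\right).$$

Exponential depths cannot be zero, while RNA-Seq coverage is full of
zeros; a pseudocount (default 1) is added to every depth before
likelihood evaluation. A constant shift changes no trough geometry — the
ordering of segment means and the location of their boundaries are
preserved — it only compresses ratios slightly, which the drop-ratio
threshold absorbs.

Changepoints are placed by greedy binary segmentation: among all active
segments, the single split with the largest gain
`gain(τ) = C(x) − C(x[1..τ]) − C(x[τ+1..n])` is applied while the gain
exceeds the penalty `β = m log n`, with `n` the full input length and
`m` the penalty multiplier (default 3, an MBIC-flavoured choice).
Segments shorter than twice the minimum segment length (default 20
bases, suppressing single-base artifacts) are never split, and recursion
stops at a configurable depth (default 10). Ties break toward the
smallest position, making the segmentation fully deterministic.

### Why a paired-changepoint proposal is necessary

Plain binary segmentation has a well-known blind spot that is *exactly*
the merged-gene signature: a narrow deep trough between two tall plateaus
of equal height. Consider 300 bases at depth 50, 40 at 2, 300 at 50
(pseudocount applied). Any single split leaves the trough inside one
half, whose mean is dominated by its flank — the best single-split gain
is about 2, far below `β = 3 log 640 ≈ 19`. Yet the *pair* of
changepoints bounding the trough has a joint gain of about 149. The
engine therefore augments each greedy step: when no single split of any
active segment passes `β`, it proposes the best pair of changepoints
carving an interior window out of a segment — the move familiar from
circular binary segmentation — accepted when the joint gain exceeds
`2β` (one penalty per changepoint). On clean steps the single proposal
fires first and behaviour is classical; the paired proposal only rescues
the trough geometry that motivates the package.

```{r engine}
x <- c(rep(50, 300), rep(2, 40), rep(50, 300))
binary_segmentation(x)
detect_trough(x)
```

### Trough qualification

Among interior segments (never the first or last — a terminal
low-coverage segment is a trimming scenario, not a split), the one with
the minimum mean qualifies as a trough only if its mean is at most
`trough_drop_ratio` (default 0.2) times the *smaller* of its two
neighbours' means. The default demands a fall to one fifth of both
flanks: deep enough that ordinary within-exon coverage ripple does not
qualify, while a true inter-genic gap — where depth drops to a handful of
stray reads against plateaus of tens — passes comfortably at any
realistic expression level.

## The three repair operators

**Redundancy removal** compares every pair of transcripts on the same
chromosome and strand. Removed are: multi-exonic duplicates (identical
intron chains, span contained; the longer span wins, ties go to the
lexicographically smaller id), multi-exonic models whose chain is a
proper contiguous subsequence of another's with span contained, and
mono-exonic models lying inside a single exon of another model or inside
another mono-exonic model. Decisions are made against the original set
and applied at once, so chains of containment resolve deterministically
and the operator is idempotent.

**Merged-gene splitting** only probes internal exons whose
strand-oriented sequence contains a premature stop codon in *all three*
reading frames — if any frame translates through, the exon is plausibly
coding and is left alone. (The screen uses the bare exon sequence rather
than the spliced transcript frame: the fused exon spans an inter-genic
gap, which belongs to no reading frame of either true gene, and the bare
sequence keeps the test local to the exon under suspicion.) A qualifying
trough splits the transcript: the left child keeps everything before the
trough, the right child everything after, and the trough bases belong to
neither — they model the inter-genic gap. Children become two distinct
genes (`.split1`/`.split2` suffixes), since a split locus is two genes,
not two isoforms; CDS attributes are dropped because coding-region
re-prediction is a downstream tool's job. A transcript is split at most
once per pass at the leftmost qualifying trough, and children re-enter
the queue, so loci fusing more than two genes resolve over successive
passes without special bookkeeping.

**Antisense end trimming** first finds every terminal exon sharing at
least one base with an exon of an opposite-strand transcript (a
configurable gap is available, default 0; unstranded models are never
touched). The implicated exon's coverage is segmented and, walking from
the outer end inward, the outermost changepoint whose outer-side segment
mean falls to at most the drop ratio times its inner neighbour's mean
marks the actual end; everything outside it is removed and the old
coordinates are recorded in a `trimmed` attribute. Restricting trimming
to antisense-implicated ends limits false modifications: an isolated
gene's gradual 3' coverage decay never triggers it.

The pipeline runs dedupe → split → trim → dedupe. Splitting and trimming
can create duplicates of models that were already present, so the final
de-duplication is not optional; the order of the middle two steps
follows from the data flow (splitting changes the exon set that trimming
inspects).

## Evaluation

Metrics follow the annotation-assessment convention in which
"specificity" is precision. At the base level, stranded exonic positions
are counted once per side regardless of isoform multiplicity; exon and
intron levels use exact coordinate identity over de-duplicated feature
sets. A multi-exonic transcript is recognized when its complete intron
chain matches a reference transcript's (end extents are free); a
mono-exonic transcript when shared bases are at least 80 % of the
*longer* of the two lengths — the symmetric denominator stops tiny
fragments inside long references from counting. A reference matched by
several predictions counts once toward sensitivity, while every matched
prediction counts toward specificity. A gene is recognized when at least
one of its transcripts is. The annotation edit distance of a prediction
is `1 − max (SN_t + SP_t)/2` over same-strand overlapping reference
transcripts, so 0 means perfect agreement with some reference transcript
and 1 means nothing overlaps.

The package carries a second, deliberately naive implementation of all
of this (`naive_compare_annotations()`): literal position sets and
double loops, sharing no code with the fast path. The test suite holds
the two implementations equal on corrupted annotation pairs; the naive
route also supplies the ground-truth reports of the pair generator.

## Confidence classes and tissue association

Gene-level evidence is three booleans — expressed in RNA-Seq, predicted
ab initio, protein-supported — plus a repeat flag. The two anchor rules
are: all three evidence types make a gene high-confidence, and a bare
ab-initio prediction with neither expression nor protein support is
low-confidence; any gene whose exonic bases lie at least half inside
repeat regions is demoted to low regardless. The remaining combinations
are filled symmetrically by a two-of-three rule, which reproduces both
anchors. Note one consequence users should know: an expressed-only gene
(no prediction, no protein) is *low* confidence under this rule. The
repeat threshold (50 % of exonic bases, boundary inclusive) is exposed
in configuration.

Tissue association reuses transcript recognition: a consolidated
transcript is "expressed in" a sample when that sample's assembly
contains a matching transcript (chain match, or 80 % mono-exonic
overlap). The row-wise OR over samples is exactly the expression flag
used for confidence.

## What the simulators emulate — and what they do not

The generators produce, under a single seed, a genome, a corrupted
annotation, a per-base coverage track and a truth record, for four
scenarios: a merged-gene locus (two same-strand genes, default 40 bp
gap, exonic plateaus at mean 50, gap and introns at 2, exponential noise
by default, Poisson available for misspecification checks; the fused
exon's sequence is tiled with a TAA-rich 12-mer cassette so the
three-frame screen fires by construction), an antisense-overlap locus
(the plus-strand gene's terminal exon extended to the far edge of the
neighbour's intron; coverage descends at the true boundary and stays low
across the over-extension — the regime where the extension is coverage
bleed rather than genuine antisense expression, which is when a
coverage-based trimmer can work at all), a combined chromosome (both
loci plus an exact-duplicate transcript and a mono-exonic fragment
inside a neighbour's exon), and a (prediction, reference) pair with
controlled corruption rates (drop, intron shift, end truncation,
spurious additions) whose truth metrics come from the naive oracle.

Real data differ in ways the fixtures deliberately ignore: coverage is
unstranded and overlapping genes superimpose their reads (the antisense
fixture models the low-neighbour regime for this reason), exon sequence
composition is not a stop cassette, plateaus are not flat (GC bias,
mappability), and splice-junction reads give introns nonzero depth.
Passing the fixture suite therefore demonstrates that the operators
implement their definitions and recover planted structure under the
noise model the detector assumes — not that every merged gene in a real
annotation will be found.

Default plateau means of 50 versus 2 reflect a moderately expressed gene
pair over background stray coverage; the 40 bp default gap matches the
tens-of-bases spacing at which assemblers actually fuse neighbouring
genes (and is twice the minimum segment length, the narrowest gap the
detector is allowed to resolve).

## Numerical choices and degenerate inputs

All internal coordinates are 1-based inclusive (GTF convention);
bedGraph and BED are converted on read. Unstranded (`.`) transcripts are
treated as `+` for sequence extraction and excluded from antisense
logic. Exponential costs are evaluated through means of
pseudocount-shifted depths, so logs are always finite; constant segments
give exactly zero gain and are rejected by any positive penalty. Inputs
shorter than twice (for splitting, three times) the minimum segment
length return a "too short" signal rather than an error, which callers
treat as no-change. Duplicate transcript ids across genes are a hard
error: every downstream structure keys on the id. Codons containing `N`
never match a stop codon.

Problem sizes in the shipped tests — fixtures of one or two kilobase
loci, 200-replicate recovery suites, 100-replicate end-to-end
comparisons — were chosen so the complete suite exercises every operator
at full stochastic depth while remaining comfortably interactive.

## Known limitations

The trimmer cannot recover a boundary when the antisense neighbour is
strongly expressed, because the unstranded depth never descends at the
true end; strand-split coverage tracks would remove this limitation and
fit the existing interfaces. The paired-changepoint proposal is
quadratic in segment length and is therefore only attempted when no
single split passes the penalty. Redundancy removal is quadratic per
(chromosome, strand) group, fine for assembler output at realistic
transcript densities per locus. The evaluator's matching is exact on
intron coordinates by design: one-base splice-site wobble counts as a
miss, as in the strictest annotation comparisons.
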