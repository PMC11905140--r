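---
title: "Methods: control-anchored CRISPR screen scoring, tiling profiles, conservation, and target stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: control-anchored CRISPR screen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescreen)
```

## What this package computes

`tilescreen` implements the computational core of a negative-selection
(dropout) CRISPR-Cas9 screening study in B-cell leukemia models: a focused
panel screen over DNA/RNA-methylation machinery genes, a high-density
gene-tiling screen along a single transcription factor's coding sequence,
per-residue sequence conservation of that factor, and the stratification
of its bound target genes into CoREST-dependent and CoREST-independent
classes from differential occupancy and expression. Every input can be
simulated with known ground truth, so the whole pipeline is testable
without any sequencing data.

## Quantification

Reads carry the spacer between two constant vector elements, the `CACCG`
cloning scar and the `GTTT` scaffold start. `extract_spacer()` takes the
20 nt after the *first* `CACCG` and accepts them only when followed by
`GTTT` inside the read. Matching against the library is exact
(0 mismatches) by default: the anchored extraction makes simple hashing
deterministic and sufficient, whereas aligner-based mapping would
introduce a mismatch-tolerance policy the screen design does not need.
A Hamming-distance-1 rescue is available (`max_mismatch = 1`), rejecting
ambiguous multi-hits; reads are used as-is (no reverse-complement scan)
because the vector places the anchor on the sequenced strand. Per-sample
accounting (`matched + unmatched + no_anchor = total`) is an enforced
invariant. The frequency of a guide is its read count over the sample's
total matched count.

## CRISPR scores and the two control anchors

The raw score is the log10 fold change of a guide's frequency from the
"initial" to the "final" point of amplification, per replicate. A
frequency pseudocount prevents $-\infty$ when a guide drops out entirely;
the default is $1/(\text{total matched reads})$ of the sample — one
read's worth of frequency — chosen because it adapts to sequencing depth
and vanishes in the deep-coverage limit. It is configurable.

Two normalizations anchor the scores to the controls:

* **Panel scheme** — subtract, per replicate, the mean raw score of the
  negative-control guides, so the negative-control mean is exactly 0.0.
* **Dual-anchor (tiling) scheme** — per replicate,
  $s = (\mathrm{raw} - m_{neg}) / (m_{neg} - m_{pos})$ with $m$ the
  control medians, pinning the negative-control median at 0.0 and the
  positive-control median (common essential genes) at $-1.0$. This makes
  scores comparable across replicates and cell contexts in units of
  "fraction of a typical essential-gene dropout". The transformation is
  affine, so it is invariant to affine changes of the raw scale, and both
  anchor identities hold exactly by construction — the test suite asserts
  them to $10^{-9}$.

Replicates are combined by the arithmetic mean of normalized scores (the
combiner is not dictated by the design; the mean keeps the anchors'
interpretation). Guides with zero counts at every timepoint are dropped
from scoring and reported rather than scored from pure pseudocounts.

## Gene ranking (robust rank aggregation)

Gene-level negative selection is scored with a simplified, single-level
variant of the alpha-RRA order statistic popularized by MAGeCK. All
scored guides are ranked ascending (most depleted first) and converted
to percentiles $u = \mathrm{rank}/N$, with average ranks for ties. For a
gene, only its guides with $u \le \alpha$ (default $\alpha = 0.25$) are
considered; with $m$ such guides and order statistics
$u_{(1)} \le \dots \le u_{(m)}$ the gene score is
$\rho = \min_k \mathrm{P}\!\left[\mathrm{Beta}(k, m-k+1) \le u_{(k)}\right]$,
and genes with no guide under the cutoff get $\rho = 1$. Significance is
a permutation tail probability over random guide-label assignments
($B \ge 100$, default 10,000), with the $+1$ correction
$p = (1 + \#\{\rho^* \le \rho\})/(B+1)$, so the attainable floor is
$1/(B+1)$. This is deliberately *not* a bit-compatible MAGeCK clone: the
mean–variance read-count model and negative-binomial testing are out of
scope, and the Beta parameters use the number of selected guides. The
permutation p-values are validated against exhaustive enumeration of
label assignments on a small instance, and parameter recovery (a planted
essential gene at $-0.5$ per doubling, 12.3 doublings, 1000x coverage,
3 replicates, recovered at rank 1 in at least 95% of 50 seeds) is part of
the test suite.

## Tiling profiles

Tiling guides are placed at every NGG protospacer-adjacent motif on both
strands of the coding sequence. The cut site is the blunt Cas9 cut
between protospacer positions 17 and 18 (3 bp 5' of the PAM), recorded as
the coding-strand nucleotide on the 5' side of the cut, so minus-strand
guides project onto the single coding-strand axis. Coordinates are
1-based closed throughout; residues are 1-based with
$\mathrm{residue} = \lceil nt/3 \rceil$.

Per-residue profiles are built **averaging first, smoothing second**:
guide scores are averaged within each residue over trinucleotide codons,
then smoothed with a Gaussian kernel
($w(t,j) = e^{-(t-j)^2/2\sigma^2}$, Nadaraya–Watson normalization).
Averaging first prevents locally dense protospacer clusters from
dominating the profile by guide count alone; the guide-level alternative
is available (`average_first = FALSE`) and a regression test pins the
implemented order. The default bandwidth is $\sigma = 5$ residues — about
two guide spacings (2.5 amino acids per guide) — wide enough to bridge
sampling noise between adjacent cut sites and narrow enough to resolve a
~30-residue zinc-finger motif; no bandwidth is dictated by the design, so
it is explicit and configurable. Boundary positions reuse the truncated,
renormalized kernel (no reflection padding), which keeps every output a
convex combination of inputs: profile extremes never exceed input
extremes and constants are preserved exactly.

## Conservation scoring

Columns of a pre-aligned multi-species protein alignment (8 species in
the emulated design) are scored by the Jensen–Shannon divergence, base 2,
between the column's residue distribution (uniform pseudocount $10^{-7}$)
and the BLOSUM62 marginal amino-acid frequencies — the standard
background of divergence-based conservation scoring. Following that
method's conventions, the base score is multiplied by
$(1 - \text{gap fraction})$ (gap penalty on by default) and mixed with
the mean base score of the $\pm 1$ flanking columns
($w = 3$, $\lambda_w = 0.5$); all four knobs are explicit because the
design states none of them. Columns where the reference sequence holds a
gap are omitted and the remaining scores re-indexed to reference residue
numbering, mirroring how deletion-site scores are dropped before mapping
onto the reference protein. Scores are bounded in $[0,1]$; JSD is
validated against a direct summation oracle to $10^{-12}$.

Sequence alignment itself is out of scope — input must be pre-aligned.

## Target classification

Promoters are the strand-aware windows from $-1$ kb to $+100$ bp around
the TSS (1-based closed; BED/narrowPeak inputs are converted from
0-based half-open on read). Only peaks with FDR $\le 0.05$ contribute;
a gene's signal per factor and condition is the sum of passing peak
scores overlapping its promoter. The stratification rule is threshold-
based, not model-based, because the workflow being implemented is a rule:
with floor $f = 1$ and ratio $r_X = (X_{kd}+f)/(X_{ctrl}+f)$,

* bound $\iff$ ZNF217 control signal $> 0$ and $r_{ZNF217} \le \delta_{bind}$
  (default 0.5, i.e. at least 2-fold occupancy loss);
* CoREST-dependent $\iff$ bound and ($r_{LSD1} \le \delta_{mark}$ or any
  histone mark H3K4me1/H3K4me2/H3K27ac has $r \ge 1/\delta_{mark}$);
  the remaining bound genes are CoREST-independent.

The "significant reduction"/"marked decrease" wording of the original
workflow is not quantified anywhere recoverable, so the defaults above
are declared package choices, echoed in every result, and configurable.
DE status intersects the classification at fold change $\ge 2$ (or
$\le 1/2$) with the provided significance flag; upstream DE testing is
consumed, not re-done. Partition identities
(dependent + independent = bound; every independent count bounded by the
matching bound count) are enforced invariants. Enhancer/super-enhancer
annotation from external databases is excluded; promoter-only assignment
is the implemented scope.

## The simulators and what they do (and do not) emulate

`simulate_screen()` draws initial abundances log-normal(sd 0.5) —
typical library skew — shared across replicates with log-normal(sd 0.1)
jitter, grows them as $2^{\text{effect} \times \text{doublings}}$, and
samples each library sample once, multinomially, at coverage x library
size reads. Defaults mirror the emulated design: doublings
$\log_2 5000 \approx 12.3$ (the lower bound of the 5,000–10,000x
amplification range), 1000x coverage, 3 replicates. The read model is
error-free (fixed 75-nt layout, constant qualities), so the multinomial
draws *are* the sequenced counts and double as the bookkeeping truth for
oracle tests; `write_screen_fastq()` materializes them byte-reproducibly.
Not modelled: sequencing errors, PCR jackpots, staggered primers,
guide-specific editing efficiency, and cell-to-cell variability beyond
the replicate jitter — so a passing recovery test demonstrates the
statistics, not robustness to those artefacts.

The tiling CDS generator fabricates an A/T background (which carries no
NGG/CCN sites) and plants isolated `GG` dinucleotides, forcing the PAM
count by construction — 416 guides over 3,120 nt reproduces the 7.5
bp/guide density. A real CDS would yield PAMs on both strands at
irregular spacing; enumeration handles that case and is property-tested
against a brute-force 23-mer scan, but the planted fixture is
deliberately regular. The alignment generator plants invariant columns
against background-drawn columns (gaps only in non-reference rows); real
alignments have phylogenetic correlation between sequences, which the
independence model ignores — hence conservation recovery is measured as
class separation (AUC), not as absolute score levels. The occupancy
generator realizes each planted class by 5-fold signal ratios under
log-normal noise and plants non-significant decoy peaks to exercise the
FDR filter.

## Numerical and degenerate-input policy

Explicit errors: duplicate guide ids or spacers (offenders named),
non-ACGT spacers, missing negative controls, coinciding control medians
(degenerate anchors), missing replicate pairings, even conservation
windows, all-gap columns (flagged, scored 0), malformed peak intervals,
fold-change thresholds $\le 1$. Constant inputs to correlation are
flagged `degenerate` rather than erroring. All-zero count columns warn
and yield zero frequencies flagged degenerate. Ties in ranking use
average ranks before percentile conversion. Every stochastic operation
takes an explicit seed and is deterministic given it.

## Problem sizes

The shipped analyses and tests run the full emulated designs: 963-guide
panel and 478-guide tiling libraries at 1000x coverage and 3 replicates,
500-column 8-sequence alignments, and 150–300-gene occupancy sets; the
repeated-seed recovery suites (50 screen seeds, 20 tiling/occupancy
seeds, 10 alignment seeds, 1,000 correlation nulls) complete in a few
minutes on one core. FASTQ round-trips are exercised on reduced
libraries because materializing 6 x ~1M reads as text adds nothing to
the property being tested.

## Known limitations

The RRA variant ranks negative selection only (no enrichment direction,
no MLE); spacer matching has no indel tolerance; conservation is
phylogeny-unaware (no tree weighting as in rate4site-style methods);
classification assigns promoter signal only and treats thresholds as
rules rather than fitted models; and the simulators' independence
assumptions understate the correlation structure of real screens.
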