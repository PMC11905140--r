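# tilescreen

Control-anchored scoring of focused and gene-tiling CRISPR dropout
screens, with the downstream analyses such screens feed: smoothed
per-residue essentiality profiles, Jensen–Shannon conservation scoring,
and CoREST-dependent vs CoREST-independent stratification of
transcription-factor target genes.

## The problem

In a negative-selection (dropout) CRISPR screen, cells carrying guides
that disrupt essential genes are depleted between an "initial" and a
"final" sampling point of population amplification. Turning sequencing
reads into biology takes a chain of small, bespoke computations:

1. **Quantification.** The 20-nt spacer sits between the `CACCG` cloning
   scar and the `GTTT` scaffold start; reads are anchored on those
   elements, spacers matched exactly against the library, and guide
   frequencies computed as count / total matched counts.
2. **CRISPR scores.** Per replicate, the score of a guide is the log10
   fold change of its frequency, control-anchored: for a gene panel, the
   negative-control *mean* is set at 0.0; for a tiling library, the
   negative-control *median* is set at 0.0 and the positive-control
   (common-essential) median at −1.0:
   s = (raw − m_neg) / (m_neg − m_pos).
3. **Gene ranking.** Genes are ranked by a robust-rank-aggregation order
   statistic (alpha-RRA style): guide percentiles u = rank/N, per-gene
   ρ = min_k P[Beta(k, m−k+1) ≤ u_(k)] over the guides with u ≤ α, with
   permutation p-values.
4. **Tiling profiles.** Tiling guides cover every NGG PAM of a coding
   sequence (cut 3 bp 5′ of the PAM, projected onto the coding strand);
   scores are averaged per residue over trinucleotide codons and smoothed
   with a Gaussian kernel (Nadaraya–Watson, σ = 5 residues) to map
   essential protein domains.
5. **Conservation.** Alignment columns are scored by Jensen–Shannon
   divergence (base 2) against the BLOSUM62 background frequencies, with
   gap penalty and a ±1-column window; reference-gap columns are omitted
   and scores re-indexed to reference residues.
6. **Target stratification.** Promoters are −1 kb..+100 bp around the
   TSS; FDR ≤ 0.05 peaks contribute summed signal; genes losing ≥ 2-fold
   factor occupancy upon knockdown are bound targets, split into
   CoREST-dependent (LSD1 loss or H3K4me1/H3K4me2/H3K27ac gain) and
   CoREST-independent, then intersected with ≥ 2-fold differential
   expression.

Every input — libraries, FASTQ, alignments, narrowPeak occupancy, DE
tables — can be simulated with known ground truth, so the pipeline is
fully testable offline.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on
simulated data and write tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_score_panel_screen.R
Rscript analysis/03_tiling_domains.R
Rscript analysis/04_conservation.R
Rscript analysis/05_target_classification.R
```

Output of a run (step 1 plants GENE05 essential at −0.5 per doubling in
a 963-guide panel screen, 3 replicates, 1000x coverage, ~12.3
doublings):

```
panel library: 963 guides; 900 gene-targeting, 41 negative, 22 positive controls
tiling library: 416 guides at 7.5 bp/guide over 3120 nt

negative-control mean normalized score per replicate: -1.4e-18 -1.06e-18 -7.19e-19
control medians: positive -1.83 vs negative 4.07e-05 (one-sided rank-sum p = 4.15e-11 )
top-ranked gene: GENE05 (rra score 9.51e-34 , p = 1e-04 )

feature summary (ranked by mean smoothed score):
     label start_res end_res mean_score min_score
1 ZF_block       100     400  -1.589131 -1.715302
2      ZF5       520     560  -1.435842 -1.606564
mean smoothed score inside features: -1.57 vs outside: -0.0106
efficacy correlation: Pearson r = -0.0475 (p = 0.334 )

invariant-vs-variable AUC: 0.97

classification vs planted truth: 0.993 agreement
bound targets: 151 ( 92 CoREST-independent, 59 CoREST-dependent )
bound & >=2-fold up: 18 of which independent: 10
```

Reading the numbers: the panel normalization pins the negative-control
mean at 0 (to machine precision) in every replicate; positive controls
drop by almost two orders of magnitude in frequency while negatives stay
flat; the planted essential gene tops the RRA ranking at the permutation
floor. In the tiling screen, the planted zinc-finger block and ZF5-like
motif are the most depleted regions of the smoothed profile (scores near
−1.6, i.e. deeper than a typical essential-gene dropout), the region
outside them sits at ~0, and the profile is uncorrelated with simulated
guide-efficacy scores. Conservation scoring separates planted invariant
columns from background-drawn ones at AUC 0.97, and the occupancy
classifier recovers ~99% of planted CoREST classes at log-normal noise
sd 0.2.

See `vignettes/tilescreen-methods.Rmd` for the models, parameter
defaults, and what the simulations do and do not emulate.

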