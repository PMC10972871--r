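---
title: "Estimating monoploid genome size from genome skims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating monoploid genome size from genome skims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Every sequence-based genome size estimator rests on the Lander–Waterman
relation

$$ C = L / G, $$

where $G$ is the genome size, $L$ the cumulative length of the sequenced
nucleotides and $C$ the depth of coverage. If $C$ can be measured, $G = L/C$
follows. skimsize measures $C$ from the depth of mapping of
six-frame-translated short reads on a set of single-copy consensus proteins
(SCP), which requires neither an assembly nor the ≳30X coverage that k-mer
spectra need: a few hundred conserved genes accumulate enough mapped reads
well below 1X, the regime of genome-skimming experiments on herbarium and
environmental samples.

Mapping on single-copy genes has one further property that matters in
plants, where whole-genome duplications are common: after a recent
polyploidisation, the single-copy genes are duplicated together with
everything else, so at a fixed total sequencing effort the depth of mapping
on the protein set is unchanged. The estimator therefore tracks the
*monoploid* genome size 1Cx (the DNA content of one basic chromosome set),
not the holoploid 1C, for any ploidy level. Flow cytometry, conversely,
measures 1C — which makes the two measurements complementary: their ratio
estimates the ploidy of a specimen,

$$ \hat p = 2 \cdot 1C_{\text{cytometry}} / 1Cx_{\text{estimated}}. $$

Protein-space mapping under-reports the true depth: reads that straddle an
exon junction (or a CDS/UTR boundary) fail to align on the protein. A
lineage-specific multiplicative slope $\beta \ge 1$ absorbs this loss:

$$ \widehat{1Cx} = \frac{L}{\beta \cdot D_{\text{SCP}}}, $$

where $D_{\text{SCP}}$ is the outlier-filtered mapping depth on the
retained proteins. $\beta$ is fitted by regressing the *theoretical* depth
$L / 1Cx_{\text{ref}}$ of samples of known genome size on their observed
SCP depth. A shipped slope table contains the pooled Angiosperm coefficient
(`all` = 1.56) and the uncalibrated `default` = 1; per-lineage slopes are
meant to be recalibrated by the user with `calibrate_groups()` on their own
reference samples.

## The pipeline

`estimate_genome_size()` runs four steps.

1. **Trimming.** Reads are truncated to their first 100 nt
   (`trim_reads()`). The calibration is performed on 100-nt reads and
   mapping efficiency depends on read length (longer reads overlap exon
   junctions more often), so the trim length is part of the calibration
   conditions, not a quality step. Reads already at or below the target
   length pass unchanged — removing them would bias $L$ — and `no_trim`
   skips the step when the input is exactly 100 nt. $L$ is always computed
   *after* trimming. The floor of 30 nt exists because a 10-residue
   translated read cannot produce a meaningful local alignment.

2. **Translated search.** The built-in aligner (`search_reads()`)
   six-frame-translates every read (stops as `*`, ambiguous codons as `X`),
   finds exact 5-mer amino-acid seeds against the protein set, and extends
   them by local Smith–Waterman alignment under BLOSUM62 with gap open 11 /
   extend 1. Raw scores are converted with the conventional gapped
   Karlin–Altschul parameters for that matrix ($\lambda = 0.267$,
   $K = 0.041$) to bitscores $(\lambda S - \ln K)/\ln 2$, and e-values use
   the effective search space (total read nt / 3) × (total protein
   residues). Hits above the e-value cutoff $10^{-5}$ are discarded. One
   hit per (read, protein) is kept (the best frame), and
   `best_hit_per_read()` then retains a single best hit per read —
   highest bitscore, ties broken by e-value and then protein id so runs
   are deterministic. Any external blastx-style tool can stand in for the
   built-in aligner through `run_external_search()`, which consumes the
   standard 12-column tabular output; the two backends share the same
   downstream contract.

3. **Outlier filtering.** Per-protein depths are computed in nucleotide
   space: the summed post-trim lengths of the reads mapped to a protein,
   divided by 3 × its residue count. The full read length is counted
   rather than the aligned span, reading "length of reads mapped" at face
   value; `use_full_read_length = FALSE` exposes the aligned-span
   alternative for sensitivity analysis. Proteins with depth more than
   1.96 sample standard deviations from the mean (two-sided normal
   P < 0.05) are removed — these are typically genes lost or duplicated in
   the sample, or proteins with promiscuous domains. Filtering is a single
   pass: mean and SD are not recomputed after removal, because the 1.96
   threshold presumes one normal-approximation test, not an iterative
   trim. With fewer than 3 proteins or zero spread the filter is a no-op
   (Z-scores are undefined there).

4. **Size equation.** $D_{\text{SCP}}$ is the total mapped nucleotides on
   retained proteins over their total nucleotide-equivalent length, and
   $\widehat{1Cx} = L / (\beta D_{\text{SCP}})$. A depth of zero raises a
   "no usable signal" error rather than returning an infinite size.

### Numerical and design choices in the aligner

A seeded heuristic search can in principle miss hits an exhaustive search
finds. Two measures keep the built-in aligner honest. First, between
seeding and gapped extension sits an ungapped pre-stage: on every seeded
diagonal the best-scoring ungapped segment is computed (a Kadane scan) and
gapped extension is triggered only when it reaches a raw score of 40. The
gate is conservative by construction: every gap costs at least 12, and
reads are at most 34 residues, so any alignment able to reach the ~90+ raw
score needed to pass the e-value cutoff necessarily contains an ungapped
run scoring far above 40. The gate therefore prunes random 5-mer
coincidences (the large majority of seeds on skim data, where most reads
are intergenic) without changing the reported hit set. Second, the test
suite compares the seeded search against an exhaustive six-frame
Smith–Waterman over all (read, protein) pairs with no seeding at all, and
requires identical hit pairs and scores.

## Calibration

`robust_slope()` implements M-estimation with Tukey's bisquare via
iteratively reweighted least squares: weights
$w(r) = (1 - (r/(c s))^2)^2$ for $|r| < c s$ (else 0), tuning constant
$c = 4.685$ (95% Gaussian efficiency), scale $s = 1.4826 \cdot
\mathrm{median}|r|$ (MAD about zero, the usual convention for regression
residuals) recomputed each iteration, convergence when the slope moves by
less than $10^{-8}$. The fit is initialised at the median of $y_i/x_i$, so
it is deterministic with no random restarts. The regression goes through
the origin: the estimator applies a single multiplicative slope, so a
nonzero intercept would have no consumer; `with_intercept = TRUE` exists
for diagnostic plots only. When the majority of points lie exactly on a
line the residual MAD collapses to zero; the fit stops there and reports
the exact slope rather than dividing by a zero scale. `calibrate_groups()`
applies the fitter per lineage plus once to the pooled points (`all`),
skipping groups with fewer than 3 samples.

Reference 1Cx values for calibration come from C-value databases:
`kew_one_cx()` computes $1Cx = 2 \cdot 1C / p$, and `cytotype_consensus()`
averages cytotypes of a species while rejecting species whose per-cytotype
1Cx values spread by more than 10% of their mean (range/mean; the
definition of "variation" is a package choice). C-values in picograms
convert at 1 pg = 978 Mb.

## What the simulator emulates — and what it does not

`make_genome()` builds a uniform-background genome (default GC 0.37,
typical of angiosperms) with non-overlapping single-copy genes placed
uniformly on random strands. Coding sequence is drawn from the 61 sense
codons so truth proteins are exact, stop-free translations; exon lengths
are multiples of 3, which keeps the truth proteins exact while intron
junctions still cause the read loss that $\beta$ models. Defaults are one
exon of 900–1500 bp per gene — a typical plant CDS of 300–500 residues —
with introns of 90–300 bp and error-free 100-nt reads; these defaults were
fixed once as the package's study conditions. `duplicate_genome()`
concatenates the sequence to a target ploidy (optionally with per-site
divergence), leaving the protein set and the truth monoploid size
unchanged, which is exactly the single-copy-gene model of ploidy
invariance. `sample_reads()` draws starts and strands uniformly;
`subsample_reads()` is Bernoulli, emulating depth titration by random read
selection. A `paralog_fraction` option inserts second copies of a subset
of genes to exercise the Z-score filter.

The simulator deliberately omits repeat landscapes, organellar and
bacterial contamination, sequencing error models, heterozygosity and
GC-coverage bias. Passing tests on simulated data therefore demonstrate
the correctness of the machinery (mapping, filtering, the size equation,
calibration, ploidy algebra) and its sampling behaviour at low depth; they
do not certify accuracy on real skims, where contamination screening and a
lineage-appropriate calibration remain the user's responsibility.

`titrate_depths()` evaluates a ladder of depths from one sequencing run by
read subsampling. Reads are processed independently, so restricting the
hit set of the full run to a subsample and recomputing e-values under the
subsample's (smaller) search space — `refilter_hits()` — reproduces an
independent search of the subsample; the shared search runs at a relaxed
cutoff ($10^{-3}$) so borderline hits that would pass only under the
smaller space are not lost.

## Validation problem sizes

The end-to-end properties are validated on simulated conditions chosen to
keep a full run on a single CPU short while leaving comfortable
statistical margins: size recovery and depth titration use 10-Mb genomes
with 100 single-exon genes (error-free 100-nt reads at 0.1–2X, five
replicate seeds); ploidy invariance uses a 2-Mb diploid against its exact
tetraploid at equal total read count; ploidy recovery uses twenty trials
of 0.3-Mb monoploid genomes at ploidies 2/4/8 with a slope calibrated
once on six diploid samples. Observed behaviour on these conditions:
about 5–6% absolute error at ≥0.5X with the uncalibrated slope (the
residual bias is the exon-junction read loss that a calibrated $\beta$
absorbs), error roughly tripling at 0.1X, sub-1% shift between diploid and
tetraploid runs, and ≥90% full ploidy recovery.

## Known limitations

- Genes with exons much shorter than the 100-nt read length defeat the
  junction-loss model: almost no read then fits inside an exon, the SCP
  depth collapses, and no fixed $\beta$ rescues the estimate.
- Contamination (bacterial, human, organellar) inflates $L$ without
  mapping to the proteins and biases sizes upward; screen read sets
  before estimation.
- Samples midway through post-polyploid diploidisation violate the
  single-copy assumption gene by gene; the Z-score filter removes the
  worst offenders but the estimate can land between 1Cx and 1C.
- The shipped slope table carries only the pooled coefficient; per-lineage
  accuracy requires user recalibration on samples of known size.
- The 12-column tabular interchange format does not record the reverse
  frame index, only the strand; hits parsed from such files carry frame
  ±1 information content, which is irrelevant downstream.
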