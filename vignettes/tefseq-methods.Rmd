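---
title: "Profiling elongation-factor occupancy on RNA polymerase II with tefseq"
author: "tefseq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling elongation-factor occupancy on RNA polymerase II with tefseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tefseq)
```

## The measurement and the model

NET-seq maps the 3' nucleotide of the nascent RNA held in transcriptionally
engaged RNA polymerase II (Pol2), giving strand-specific single-nucleotide
occupancy. TEF-seq is the variant in which a transcription elongation factor
(TEF) such as Paf1 is immunoprecipitated first, so reads report only the
polymerase molecules travelling with that factor. Comparing a TEF-seq library
with a matched Pol2 NET-seq library therefore measures, gene by gene and
nucleotide by nucleotide, how much of the factor rides on the polymerase.

`tefseq` implements the complete computational path from aligned reads to
that comparison:

1. **3'-end narrowing** (`narrowTo3Prime`): each uniquely aligned read
   contributes +1 at a single position — the 3'-most aligned base on its
   alignment strand. Total track mass equals the number of retained reads,
   which every downstream stage relies on. Because some library chemistries
   place the nascent-RNA 3' end at the read's 5' base on the opposite
   strand, a `reverse_complement` mode is provided; the default
   (`as_aligned`) follows the protocol this pipeline was built around.
2. **Background subtraction** (`fitScr1Ratio`, `subtractBackground`): IP
   libraries contain degraded mature transcripts that bind the affinity
   matrix non-specifically. An IP from an untagged strain captures the same
   background. For single IPs the tagged/no-tag ratio is calibrated on a
   Pol3-transcribed control gene (SCR1 in yeast, window chrV:442007-442458),
   where no Pol2-elongation-factor signal can occur: the window, trimmed by
   20 nt at the start and 50 nt at the end, is cut into 10-nt bins, per-bin
   tagged/no-tag ratios are averaged over bins with positive no-tag counts,
   and `ratio x no-tag` is subtracted genome-wide. For sequential IPs the
   background is Pol2-associated rather than mature RNA, so the ratio of
   total library sizes is used instead (`fitTotalReadRatio`).
3. **Metagene profiles** (`standardProfile`, `ratioProfile`,
   `nucleosomeProfile`): anchor-aligned 10-nt-binned averages with trimmed
   means.
4. **Differential occupancy** (`countGeneBody`, `nbDifferential`): a
   replicate-aware negative-binomial test of TEF versus Pol2 counts per
   gene.
5. **Divergent-promoter enrichment** (`findDivergentPairs`,
   `pairPermutationTest`): permutation test of whether a ranked gene group
   contains more head-to-head promoter pairs than chance.

A synthetic-data generator (`simulationConfig`, `simulateDataset`) produces
genomes, annotations, nucleosome maps, expectation tracks and sampled counts
with known truth, so each stage is verifiable without external data.

## Coordinates and containers

All in-memory coordinates are 0-based half-open on the forward genomic axis;
text files (isoform tables, the SCR1 window, SAM) are converted at the I/O
boundary from their native 1-based inclusive conventions. The TSS is the
first transcribed base and the TES/PAS the last (the two terms are used
interchangeably, as in the source annotations), so a minus-strand gene has
its TSS at the high-coordinate end. Signal lives in `StrandedTrack` objects
(one numeric vector per chromosome and strand, with a `state` recording
whether the track holds raw counts, expectations, subtracted signal or a
smoothed visualization product); profiles live in `BinnedProfile` objects
whose bins are labelled by the transcription-direction offset of their 5'
edge from the anchor.

## Annotation selection and divergent pairs

Transcript isoform tables give several isoforms per gene with an abundance
measure. `selectIsoforms` keeps, per gene, the most abundant isoform, then
the longest, then (for full ties) the lexicographically smallest isoform id —
the last rule is ours, added so the output is deterministic; the function is
idempotent. Divergent pairs are a minus-strand and a plus-strand gene
transcribed away from each other with TSSs at most 1200 nt apart and no
other annotated gene's TSS strictly between them. The "between" rule is
evaluated on TSS positions; a span-based variant (`between = "span"`) is
available because the criterion could plausibly be read either way.

## Trimmed-mean metagene profiles

Standard profiles anchor genes at the TSS (window -100..+1000) or the PAS
(window -400..+100) and report per-bin trimmed means of per-gene bin counts,
trimming 5% of values per tail so that extremely strong or weak genes do not
dominate. Pol2-normalized profiles form, per gene and bin, the ratio
`scaling[factor] * TEF / Pol2`, drop undefined ratios (non-positive Pol2
bins) and trim 10% per tail, which also suppresses single-nucleotide spikes.
Anchor-specific exclusions avoid averaging transition regions into the
profile: TSS-anchored profiles drop, per gene, every bin from 200 nt before
that gene's PAS onwards; PAS-anchored profiles drop genes of 500 nt or less
and every bin within 500 nt of the TSS. A bin is dropped whole if any part
of it lies in an excluded zone (the strictest reading of an exclusion), and
a bin with no eligible genes is reported missing rather than zero.

Three bookkeeping choices are ours and documented here because the
procedure's prose does not fix them: the trim count is `floor(trim * n)` per
tail (deterministic; conservative for small n); the anchor sits on a bin
edge and bins are labelled by their 5'-edge offset; and profiles are always
computed from unsmoothed tracks — the boundary-aware running mean
(`boundaryAwareRunningMean`, 11-nt window that never crosses a TSS, TES,
exon 3' end or intron 3' end) and the five-bin profile smoother
(`smoothProfile`) are presentation-layer products only.

The per-factor scaling constants (`defaultFactorScaling()`: Cet1 1,
Paf1 2.2, Pcf11 2.7, Spt6 0.47, Spt16 1.04, Set2 6, Ssu72 8; Rpb2
normalization 0.88 single-IP / 0.75 sequential-IP via
`rpb2NormalizationConstants()`) exist only to place different factors on one
arbitrary linear scale — they compensate for sequencing depth and IP
efficiency and have no effect on any test statistic computed within one
factor.

## Nucleosome-phased oscillation

Elongation factors exchange on Pol2 as it transcribes through nucleosomes.
To see this, `nucleosomeProfile` aligns the scaled TEF/Pol2 ratio on
nucleosome dyad centers: every (gene, dyad) instance with the dyad more than
50 nt past the TSS and before the PAS contributes a +/-100-nt window of
10-nt bins, orientation-flipped for minus-strand genes, optionally
restricted to nucleosome ordinals +2..+5. `oscillationTestByOrdinal`
formalizes the oscillation per ordinal by comparing the per-instance ratios
at the dyad-center bin with those at center +50 nt:

* The default is the field's stated procedure — a one-tailed two-sample
  Student t test on the trimmed (10% per tail) ratios. It is powerful, and
  on oscillating signal the trimming protects it from the heavy right tail
  that TEF/Pol2 ratios develop where Pol2 counts are small.
* A paired variant (`paired = TRUE`) pairs the two bins by instance and runs
  a one-sample Yuen test (trimmed mean over a winsorized-variance standard
  error) on the differences. We added it because the two bins of one
  instance are correlated — they share the gene's enrichment and the local
  oscillation phase — and because a plain t statistic computed on trimmed
  values is anticonservative under the null (the trimmed sample's SD
  understates the variability of a trimmed mean; the winsorized variance is
  the correct scale). The paired variant is the calibrated choice for
  negative controls such as phase-randomized dyad maps.

## Differential TEF-vs-Pol2 occupancy

Counting (`countGeneBody`) sums 3'-end counts over `[TSS+400, TES-200)` on
the gene's strand, skipping the regions near both gene ends where factors
show large recruitment/release transitions; genes of 600 nt or less have an
empty interval and are excluded. Counting always uses raw, unsubtracted
integer tracks: the negative-binomial model needs non-negative integers, and
the background enters both factor and polymerase libraries, so the global
subtraction scalar largely cancels in the ratio. (Whether counts should be
background-subtracted before testing is genuinely ambiguous; this is the one
place the package resolves it, and profiles keep using subtracted tracks.)

`nbDifferential` is a self-contained implementation of the standard NB
testing scheme, so the pipeline's behaviour is fully specified by this
package rather than by an external tool's version: median-of-ratios size
factors (the median taken in log space); per-gene method-of-moments
dispersion pooled over the two groups; a dispersion trend `a0 + a1/mu`
fitted by ordinary least squares on the raw moment estimates — the raw
estimates are kept in the fit even when negative, which is what keeps the
trend unbiased at two replicates per group — followed by linear-space
shrinkage `alpha = 0.2 raw+ + 0.8 trend` (weight configurable) and a floor
of 1e-8; and a Wald test of the log ratio of group means with model-based
variance `(1/m^2) sum_j (1/(mu s_j) + alpha)` per group. P values are
Benjamini-Hochberg adjusted and genes classified enriched/depleted/ns at an
adjusted-p threshold (default 0.05). When either group mean is zero a
pseudocount of 0.5 is added to both means and the gene is flagged. No
low-count filter is applied by default. Exact numerical agreement with any
particular external NB implementation is not promised — published gene-list
sizes additionally depend on that tool's version-specific dispersion and
filtering settings — but size factors are cross-checked against an
independent implementation in the test suite, and the test's calibration
(type-I error at nominal level) and power are verified by simulation.

One limitation worth knowing: the Wald variance is model-based, so
deterministically rescaling one library changes the per-sample shot-noise
term `mu/s_j` slightly; estimates are exactly invariant to such rescaling
but p values move by roughly one percent at typical counts.

## Permutation enrichment of divergent pairs

`pairPermutationTest` counts the divergent pairs fully inside a gene group,
then draws groups of the same size uniformly without replacement from the
universe (10,000 times by default) and reports enrichment and depletion
p values under the add-one convention `p = (#{null as-or-more extreme} + 1)
/ (n + 1)`, which keeps empirical p values strictly positive and makes a
"p < 1/n" claim impossible by construction. `exactPairEnrichment`
exhaustively enumerates all subsets on small universes and anchors the
permutation estimates in the test suite.

## The synthetic-data generator

The generator emulates the data-generating process the analysis assumes,
at desk scale. Defaults (fixed once, used by the tests and the acceptance
script):

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 200 | Pol2-transcribed genes on two 400-kb chromosomes |
| `gene_length` | 600-3000 nt | uniform gene lengths |
| `frac_divergent` | 0.2 | fraction of genes arranged as divergent pairs, TSS separation uniform in (100, 1200] |
| `rate_meanlog`, `rate_sdlog` | 0, 0.8 | log-normal per-gene transcription rates |
| `enrichment_values/probs` | 0 / +1.5 / -1.5 at 0.9 / 0.05 / 0.05 | per-gene log2 TEF enrichment point masses |
| `osc_amplitude`, `osc_period`, `osc_phase` | 0.2, 165 nt, pi | dyad-phased TEF oscillation; phase pi puts the TEF minimum at the dyad and the maximum ~82 nt away |
| `peak5_height/width` | 2, 80 nt | 5' Pol2 peak (exponential decay over the gene body) |
| `peak3_height/width` | 1, 50 nt | pre-PAS Pol2 peak |
| `contamination` | 0.25 | fraction of tagged reads that are mature-RNA background; equals the true tagged/no-tag ratio at equal depths |
| `control_bg_weight` | 0.05 | share of background mass on the Pol3-like control gene |
| `dispersion` | 0.05 | NB overdispersion, variance mu + 0.05 mu^2 |
| `reads_per_sample` | 1e6 | expected library size, 2 replicates per factor |

Nucleosome dyads are placed every 165 nt from each TSS (first dyad at
+100 nt), i.e. perfectly phased; the mature-RNA background is spread
uniformly over each gene's own transcript span with mass proportional to
rate x length, mirroring the degraded-transcript mechanism, and the
Pol3-like control gene carries background but no Pol2/TEF signal, exactly
the property the SCR1 calibration relies on. Counts are NB per position;
read records are emitted such that 3'-narrowing reproduces the counts
exactly.

What the generator deliberately does **not** emulate — and hence what
passing tests do not show about real data: mappability gaps and multimapper
losses, fuzzy or evicted nucleosomes (dyads are exact and perfectly
periodic), sequence-dependent library biases, overlapping transcription
units, introns in the simulated genes (intron boundary handling is tested
separately with constructed cases), and condition-dependent changes in the
background composition. Real-data quantities that depend on a particular
external tool's settings (published counts of significantly enriched or
depleted genes) are treated as approximate reproduction, not as test
oracles.

## Numerical and degenerate-input policy

Window bounds must be multiples of the bin width; even smoothing windows are
rejected. Bins with zero no-tag counts are excluded from background
calibration, with a warning when more than half are excluded and an error
when all are. Ratio profiles drop non-positive Pol2 bins. `oscillationTest`
reports NA below 3 values per sample. Heatmap rows clamp negatives to zero
before row normalization and all-zero rows stay all-zero. All-equal count
rows are handled by the dispersion floor. The problem sizes used by the
test suite (tiny constructed tracks; 30-200-gene genomes; 2,000-gene count
tables over 10 seeds) were chosen so that every stochastic check has
comfortable Monte-Carlo margins.
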