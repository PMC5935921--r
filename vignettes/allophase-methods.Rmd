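---
title: "Reference-free subgenome phasing and homoeolog expression bias: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free subgenome phasing and homoeolog expression bias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An allopolyploid genome carries two (or more) chromosome sets inherited from
divergent progenitor species. Each *homoeologous* gene pair consists of two
copies, one per progenitor, sitting at syntenic positions on a homoeologous
chromosome pair. When the progenitor genomes are unavailable — the usual
situation outside a handful of model crops — the copies cannot be assigned to
parental *subgenomes* by alignment. `allophase` implements a reference-free
phasing strategy that uses only the allopolyploid's own sequence: progenitor
genomes retain species-specific nucleotide composition and synonymous codon
preferences, so the two members of every homoeologous pair differ slightly
but *consistently* in GC content, most strongly at the third codon position.
On top of the phased subgenomes the package classifies *homoeolog expression
bias* — unequal expression of the two copies — from an RPKM time course.

## The dGC statistic and subgenome assignment

For a homoeologous pair with coding-region GC contents $GC_X$ (copy on
chromosome $X$, the member of the pair with higher global GC) and $GC_{X'}$,
the GC-content ratio is

$$\mathrm{dGC}_X = \frac{GC_X}{(GC_X + GC_{X'})/2}, \qquad
  \mathrm{dGC}_{X'} = \frac{GC_{X'}}{(GC_X + GC_{X'})/2},$$

so the two values always sum to 2 and $\mathrm{dGC}_X > 1$ means the $X$ copy
is GC-richer than its partner. `dgc_profiles()` computes this ratio (and its
third-codon-position analogue dGC3) for every pair, ordered along chromosome
$X$ from its 5′ end, and smooths each series with a simple moving average of
11 genes. N bases are excluded from GC numerator and denominator so
draft-assembly gaps cannot bias composition; pairs displaced by transposition
still enter the series at their position on chromosome $X$.

`assign_subgenomes()` then labels whole chromosomes: the polarity of each
position is the sign of the smoothed ratio minus 1, the majority polarity
sets the chromosome's default label (`Fso_h` for the high-ratio subgenome,
`Fso_l` for its counterpart), and sustained runs of *opposite* polarity
become flip-over (crossover) segments whose genes get the swapped label.
Three numerical choices matter here:

* **Which series drives polarity.** The default is the smoothed dGC3 series.
  When inter-subgenome divergence is dominated by synonymous substitutions,
  the third position carries roughly three times the amplitude of the
  whole-CDS ratio (each codon has one wobble position out of three), while
  the two series are structurally consistent in sign. The whole-CDS series
  is available via `series = "dgc"`.
* **Flip thresholds.** A candidate segment must span at least
  `min_flip_run = 20` genes (comfortably above the 11-gene smoothing window,
  so smoothing artefacts cannot qualify) with mean |smoothed ratio − 1| of
  at least `min_flip_effect = 0.01`. Anything shorter is treated as the
  brief reciprocal noise reversals seen on most chromosomes. Opposite runs
  separated by fewer than `min_flip_run` majority positions are consolidated
  — an interruption shorter than an acceptable segment is itself noise — but
  only when the merged span still clears the effect threshold, so a distant
  blip cannot dilute a genuine segment.
* **Edges and ties.** The moving average uses a truncated centred window at
  the series edges (output stays aligned with gene positions; flip calls
  depend on run length, not the edge convention). Positions with ratio
  exactly 1 carry polarity 0 and inherit the majority label. Chromosomes
  with fewer than `min_flip_run` pairs and mixed polarity are labelled by
  their mean ratio and flagged low-confidence.

`chromosome_summary()` tabulates, per chromosome pair and per flip segment,
predicted gene counts and homoeologous/non-homoeologous (singleton) splits,
keyed by the dGC-derived subgenome rather than by global GC — the two
disagree on roughly half of real chromosome pairs, because coding-region
composition and bulk chromosomal GC are only loosely coupled.
Percentages are rounded half-up to two decimals to match the conventional
table format. `fractionation_bias()` counts on how many chromosome pairs the
*high*-dGC side carries strictly more singletons (fractionation bias; ties
are reported separately) with an exact two-sided sign test.

## Codon-usage PCA

`codon_counts()`/`aggregate_usage()` build 64-codon tables per gene,
chromosome copy, segment, or subgenome; observations entering the PCA are
per-mil frequencies (counts × 1000 / total codons), which removes
chromosome-length effects. Columns are standardised and components come from
the eigen-decomposition of the correlation matrix; loadings are eigenvector
× √eigenvalue, so squared loadings sum to the eigenvalue and the eigenvalues
sum to the number of retained variables. Stop codons stay among the 64
variables; zero-variance columns are dropped with a message. Because
eigenvector sign is arbitrary, signs are fixed for reproducibility: PC1 so
its mean loading is negative (PC1 reflects shared gene-content variation and
conventionally carries uniformly negative loadings), PC2 so the mean score
of `Fso_h` observations is at least that of the rest, and the remaining
components by their largest-magnitude loading. `separation_check()` reports
the fraction of chromosome pairs whose `Fso_h` member scores higher on PC2;
`segment_pca()` applies the same machinery to sub-chromosomal segments, e.g.
to confirm that a dGC flip segment clusters with the opposite subgenome.
By default only homoeologous genes enter the chromosome tables (singletons
have no partner constraining their composition); `include_singletons = TRUE`
adds them.

## Expression bias

A pair is *expressed* at a timepoint when a copy reaches RPKM ≥ 1. Pairs in
which both copies stay below the threshold at every timepoint are removed
(`filter_expressed_pairs()`). `call_bias()` implements the per-timepoint
rule: both copies expressed and max/min ≥ 2 (inclusive — "two-fold or
greater") gives a call toward the higher copy; exactly one expressed copy
gives a silencing call toward it; otherwise the pair is neutral. The
silencing threshold deliberately equals the expressed threshold: silencing
is "no expression from one copy", and silencing calls are tallied separately
from fold-change histograms. log2 fold changes are oriented positive toward
`Fso_h` everywhere.

`consistency()` uses the strict reading of "continuously biased": the same
non-neutral direction at every evaluable timepoint; a pair biased at two
timepoints and neutral at one is `mixed`. Pairs with a not-expressed
timepoint are classified on the remaining ones and flagged, rather than
silently dropped. `synchrony()` ships two labelled methods — sign
concordance of consecutive changes (zero change as wildcard, flagged
degenerate) and a Pearson-correlation rule (r ≥ 0.8) — because the
literature definition of "synchronized" is not standardised; outputs carry
the method tag and no claim is made that either reproduces any particular
published percentage. Stratified reports (`strata_bias_report()`) assign a
pair to an RPKM stratum by the larger of its two copies (configurable to the
mean) and test the toward-h : toward-l split against 50:50.

Pathway/term statistics follow the field's conventions: 2×2 tests use
Fisher's exact test when any expected cell is below 5 and Pearson's
chi-squared otherwise; multiple testing across terms is Benjamini–Hochberg
(the standard FDR procedure). `fisher_2x2()` computes the two-sided p by
direct hypergeometric summation — all tables with the observed margins no
more probable than the observed one — and is cross-checked in the test suite
against both an exhaustive enumeration oracle and `stats::fisher.test`.

## Promoter motifs

Promoters are the 500 bp immediately upstream of the TSS on the gene's
strand (minus-strand promoters reverse-complemented; windows clipped at
chromosome ends are flagged truncated). `scan_iupac()` reports every
overlapping match of a degenerate IUPAC motif on the promoter sense
sequence; scanning the reverse complement too is available via
`both_strands`, since published motif scanners differ on this default.
Subgenome enrichment of a motif is a Fisher 2×2 test
(subgenome × presence) with BH adjustment across motifs — a deliberate
methodological substitution of an exact test for ranking-based motif
enrichment tools, documented here because the two do not compute the same
statistic. `motif_conditional_bias()` splits pairs by motif placement (both
copies / Fso_h copy only / Fso_l copy only) and compares per-timepoint
counts of pairs biased toward the motif side against the other side with
Welch's t-test, timepoints serving as the n = 3 replicates. A caveat is
inherited with that design: the replicates share the same pairs, so
pair-sampling noise repeats across timepoints and the test can reject
without any motif effect; treat small p-values as descriptive. The Welch
statistic is guarded for zero pooled variance (equal means give t = 0,
p = 1; unequal means ±∞, p = 0). De-novo motif discovery and motif
annotation against TF databases are out of scope; the module consumes
user-supplied IUPAC strings.

## The synthetic allopolyploid generator

Every stage is testable without external data because
`simulate_genome()`/`simulate_expression()` generate a genome and time
course with known truth. The generator reproduces the statistical structure
the methods exploit:

* **Two subgenomes with distinct GC3.** Defaults 49.2% (`Fso_h`) and 47.9%
  (`Fso_l`) — the compositional gap characteristic of the diatom system this
  package is modelled on. Codons are drawn per subgenome by first choosing
  the third-base *class* (GC- vs AT-ending) with a tilt solved per
  chromosome pair so the expected GC3 hits the target exactly, then the
  letter within the class from subgenome-specific preferences.
* **Synonymous-only divergence at third positions.** The amino-acid sequence
  of a pair is shared, and so is the subfamily (first-two-base) choice for
  the six-fold families, so the two copies differ only at wobble positions.
  This isolates the compositional signal the method uses and makes the dGC
  and dGC3 polarities structurally consistent — the behaviour reported for
  real allopolyploid genomes, where third-position divergence dominates. A
  whole-codon perturbation scheme was rejected at the design stage: it
  injects arbitrary-signed GC1/GC2 differences which, at a 1.3-point GC3
  gap and 400 codons per gene, would make the ≥ 99% dGC/dGC3 polarity
  agreement unattainable under binomial sampling noise.
* **Subgenome codon-usage divergence.** Within each third-base class the
  G-vs-C (and A-vs-T) preference of each synonymous family is
  Dirichlet-perturbed per subgenome with scale `codon_profile_divergence`
  (0 = identical profiles; GC3 is unaffected by construction). The default
  0.1 was calibrated on the generator itself: it is the value at which the
  codon-usage PCA separates *every* chromosome pair on PC2 across repeated
  simulations — the published behaviour the simulation is meant to emulate.
  Smaller values leave individual pairs within sampling noise of each
  other; substantially larger values inject usage differences whose
  direction is unrelated to the GC3 tilt and rotate the subgenome contrast
  away from a single component. The shipped acceptance script recomputes
  the separation fraction.
* **Gene-content variation.** Each chromosome pair draws its amino-acid
  composition from a Dirichlet around the uniform (concentration 40 per
  amino acid). This is what pushes shared gene-content variation onto PC1 —
  as in real data — leaving the subgenome contrast on PC2.
* **Fractionation and crossovers.** Each gene slot loses one copy with
  probability 0.08, the survivor sitting on the `Fso_h` side with
  probability 0.65 (fractionation bias). One chromosome pair receives a
  crossover: a terminal segment beyond a random breakpoint swaps subgenome
  identity on both physical chromosomes, emulating a post-hybridisation
  intergenomic rearrangement; truth records the breakpoint.
* **Expression.** Each pair draws a lognormal base RPKM (meanlog 2, sdlog 2
  on the natural scale — median ≈ 7 RPKM with a realistic heavy tail
  reaching the >500 stratum). 61% of pairs are fold-biased toward a random
  subgenome with log2 offset 1.5 + Exp(rate 2) (minimum 1.5, mean 2.0 —
  comfortably beyond the two-fold threshold so that log2-scale noise of
  sd 0.3 per copy leaves direction recall above 90%); 8% are silencing
  pairs whose silenced copy is drawn uniformly below the expressed
  threshold; 85% of biased pairs keep their direction across all three
  timepoints. Noise multiplies expressed values by $2^{N(0,0.3)}$; silenced
  draws are emitted as-is so they stay below threshold.

What the generator does **not** emulate: intergenic sequence and introns
(promoter analyses use separately simulated promoters), indels and
non-synonymous divergence, expression normalisation artefacts, and any
correlation between expression level and bias direction. Passing tests on
this generator therefore demonstrate that the statistics recover the
structure they are designed for at realistic effect sizes — not that any
particular real genome satisfies the generator's assumptions.

## Problem sizes and determinism

The default study conditions are 10 chromosome pairs × 300 gene slots × 400
codons (≈ 5,500 genes, ≈ 3.3 Mb of CDS) and a three-timepoint RPKM matrix —
large enough that the binomial SE of subgenome GC3 means is a few hundredths
of a percentage point, while a full simulate–phase–PCA–bias cycle runs in
seconds. All randomness flows through explicit seeds; a fixed seed gives
byte-identical outputs, which the test suite asserts.

## Known limitations

* Phasing needs a *pre-existing pair table*; homoeolog detection (synteny,
  reciprocal best hits) is upstream of this package.
* A chromosome pair whose true crossover splits it near 50:50 has an
  ill-defined "majority" label; labels remain internally consistent but the
  reported flip segment may be the complementary region.
* The dGC method assumes progenitors with measurably different composition;
  with equal GC3 and identical codon profiles the assignment is (correctly)
  no better than chance, as the symmetric-null tests assert.
* Percentages and sign tests in the chromosome summary treat the supplied
  gene annotation as complete; unannotated genes are invisible to
  fractionation statistics.
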