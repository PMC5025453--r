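---
title: "Methods: MAPKKK family analysis and cascade prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAPKKK family analysis and cascade prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkcascades)
```

This vignette is the package's account of the science behind each
module: the models and their assumptions, the parameters that matter,
the numerical conventions, and the design choices made where the
design was genuinely open.  Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Subfamily classification

Plant MAPKKKs fall into three subfamilies — MEKK, Raf and ZIK — that
differ both in a short signature inside the kinase domain and in where
the kinase domain sits in the protein.  The shipped signature set is

* ZIK: `GTPEFMAPE(L/V)(Y/F)`
* MEKK: `G(T/S)Px(F/W)MAPEV`
* Raf: `GTxx(W/Y)MAPE`

with `( / )` an alternation and `x` any residue.  The Raf consensus is
the least specific and also occurs in receptor-like kinases, so a
signature alone never suffices: `classify_subfamily()` additionally
requires the subfamily's domain placement.  A ZIK call needs an
N-terminal kinase domain (N-terminal flank at most `zik_max_nter = 60`
residues); a Raf call needs a C-terminal domain behind a long
N-terminal regulatory region (flank at least `raf_min_nter_frac = 0.25`
of the protein, and longer than the C-terminal flank); a MEKK
signature qualifies at any position.  When one sequence matches
several patterns, precedence is ZIK > MEKK > Raf: the ZIK and MEKK
patterns are the more specific ones (a MEKK instance with `W` at its
fifth position also contains a Raf match as a prefix).  An explicit
exclusion list lets users blacklist known receptor-like kinases.

Kinase-domain spans are *inputs* (from annotation or the simulator);
the package does not do profile-HMM domain detection.

Theoretical MW is the sum of average residue masses plus one water
(the `GG` dipeptide sums to 132.12 Da); pI is the root of the
Henderson–Hasselbalch net-charge function under a Bjellqvist-style pK
table (N-term 7.5, C-term 3.55, D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98,
K 10.0, R 12.0), found by bisection on pH 0–14 to 10⁻⁶.  Web tools use
slightly different pK sets, so agreement with them is monotonic rather
than exact: the root property and the ordering of acidic versus basic
compositions are what the tests assert.

## Gene structure

Coordinates are 0-based half-open internally; the GFF3 1-based closed
convention is converted at the I/O boundary only, which keeps the
intron/phase arithmetic free of off-by-one cases.  The phase of an
intron is the number of CDS bases 5′ of it (in transcript orientation)
modulo 3 — the standard convention; phase 0 falls between codons.
Introns lying entirely within a UTR are counted in the intron count
but carry an `NA` phase, since phase is CDS-defined.  The
kinase-domain intron pattern restricts to introns whose CDS offset
falls strictly inside the domain's codon range, so a domain covering
the whole CDS reproduces exactly the CDS-internal intron list.

Isoform comparisons classify the differing introns of two transcripts
of one gene by transcript end (5′/3′, by their mean position relative
to the cDNA midpoint), by region (inside/outside the domain codon
range when a domain span is supplied), and flag terminal-exon
extension.

## Molecular evolution

*Alignment.*  Global Needleman–Wunsch with affine gaps (Gotoh's
three-state recursion, compiled): a gap of length L costs
`gap_open + (L−1)·gap_extend`.  Tie-breaking is deterministic —
diagonal over up over left — so alignments are reproducible across
platforms.  Defaults: +1/−1 with gaps −2/−1 for nucleotides, BLOSUM62
with gaps −10/−1 for proteins.  Identity is counted over all columns
(excluding double gaps); coverage is the residue-against-residue
column count divided by the longer sequence's length.

*Tandem duplicates.*  A pair is tandem when both genes are on one
chromosome separated by at most `max_intervening = 1` other genes of
the supplied list, with identity > 70 % and coverage > 70 % of the
longer gene.  "Tightly linked" has no standard definition, so the
separation is configurable; adjacency is judged within the supplied
gene list, not against the whole genome annotation.  Qualifying pairs
sharing genes are clustered and one duplication event is counted per
cluster while all pairs are listed.

*Ka/Ks.*  The estimator is Nei–Gojobori (1986): per-codon synonymous
site fractions (averaged over the two sequences), pathway-averaged
difference counts for multi-hit codons (pathways through stop codons
are excluded unless all pathways are), and the Jukes–Cantor correction
`d = −¾ ln(1 − 4p/3)`.  Mutations *to* stop codons count as
nonsynonymous in site counting.  Proportions at or past the
correction's domain (p ≥ ¾), and ratios with Ks = 0, are `NA` markers
rather than numbers.  NG86 is a counting method with equal-rate
assumptions; it was chosen as the simplest estimator consistent with
the synonymous-only simulator, and no claim is made that it reproduces
values computed by likelihood methods on real alignments.

*Clock dating.*  `T = Ks/(2λ)` in Myr, with the default synonymous
rate λ = 6.1 × 10⁻⁹ substitutions · site⁻¹ · yr⁻¹ — the single rate
consistent with every (Ks, time) pair of the shipped duplicate-pair
table — and configurable for other lineages.

*Trees.*  Saitou–Nei neighbor joining with Q-criterion ties broken by
the lexicographically smallest pair of representative tip labels.  On
additive inputs the output's patristic distances reproduce the input
matrix (asserted to 10⁻⁹); negative branch lengths, which NJ can
produce on non-additive inputs, are reported as computed.

## Expression screens

All screens take expression values as given; log transforms happen
only inside named screens, with a configurable pseudocount
(`log2(x + 1)` by default, pseudocount 0 for data already on a log
scale).  CV uses the sample (n−1) standard deviation.  The
fold-change screen excludes genes whose two group means are both below
a floor of 1 — a low-expression filter — before applying the |log2fc|
cutoff (1 by default; 0.5 for the temperature screen).

The SAM-style test uses the two-class unpaired statistic
`d = (mean_b − mean_a)/(s + s0)` with pooled standard error and
`s0 = median(s)`; the full Tusher s0 grid search is deliberately out of
scope.  q-values are estimated by label permutation: at each observed
|d| threshold, the expected count of permuted statistics beyond it is
divided by the observed count, and the resulting rates are made
monotone non-increasing in |d| by a tail minimum.  Sampled
relabelings identical to the original grouping (or its complement)
are resampled away: they carry the signal rather than the null, and
with few samples they otherwise put a hard floor under every q-value.
With two groups of four, only 70 distinct relabelings exist, so
q-value resolution is inherently coarse at small n.

The two-way ANOVA screen requires a complete balanced design with
replicates (the v1 contract; unbalanced designs are an error, not a
silent approximation) and fits the fixed-effects model with
interaction per gene; "adjusted p" is Benjamini–Hochberg across genes,
applied separately per effect.

The duplicate-pair expression correlation is plain Pearson over shared
samples, with `NA` markers for absent genes and zero-variance
profiles.  The identity-vs-expression meta-statistic is computed over
the pairs that have an expression value (12 of the 15 shipped pairs),
not by imputing the missing ones.

## Circadian detection

A gene's time course is correlated against cosine templates
`cos(2π(t − φ)/P)` over a period grid (default {24 h} — the circadian
context fixes the period) and a phase grid (step 1 h); the best Pearson
r, period and phase are reported, ties broken toward the smallest
period then phase, and a gene is called cycling when best r ≥ 0.8.
This is a single-waveform reduction of template-correlation cycling
detectors; the template family is configurable but deliberately small,
since a correlation cutoff is the only exposed tuning.  Constant
series have undefined correlation and are never cycling.  At least two
full periods of sampling are required; the simulator's default design
samples every 4 h for 48 h.

## Promoter scanning

Elements are IUPAC consensi matched exactly on both strands;
minus-strand hits are reported at their plus-strand start coordinate.
Overlapping hits are all reported.  A sequence `N` matches only motif
positions whose allowed set is all four bases — ambiguous sequence
should not create specific-element hits.  The default dictionary
ships the consensi with published sequences (HSE `AAAAAATTTC`,
TCA-element `GAGAAGAATA`, ABRE `CCGCGTAGGC`, motif-IIb `CCGCCGCGC`,
CGTCA/TGACG motifs, circadian `CAANNNNATC`); light-responsive elements
without a printed consensus (sp1, G-box, ACE, 3-AF1) must be supplied
by the user.  Promoter windows are the 2 kb immediately upstream of
the gene's transcription start, strand-aware and truncated at contig
edges.

## Co-expression networks and cascades

From a genes × samples matrix: Pearson correlations (zero-variance
genes dropped with a warning), then for each gene its partners are
ranked by descending correlation — ties broken by ascending gene id,
a documented deterministic choice — and
`MR(i,j) = √(rank_i(j) · rank_j(i))`.  Low MR means strong, *mutual*
co-expression; edges with MR strictly below the cutoff (default 1500)
are retained.  Cascade prediction enumerates (MAPKKK, MKK, MPK)
triples with both MAPKKK–MKK and MKK–MPK edges present and one shared
subcellular localization; a MAPKKK–MPK edge is *not* required, since
biologically plausible cascades share MKK hubs.  Localization labels
are input annotations; the package does not predict localization.

## The synthetic-data module

The generators define the study conditions the tests run under; their
defaults are fixed, not tuned per test.

* `simulate_gene_family()` — default 73 genes in proportions
  24 MEKK : 43 Raf : 6 ZIK; kinase domains of 250–262 residues; each
  protein embeds exactly one concretized subfamily signature inside
  its domain (placed at ~70 % of the domain, where the
  activation-segment/APE region sits in real kinases) at a position
  consistent with the subfamily's domain-placement rule; intron counts
  are drawn per subfamily from 0–24 (MEKK), 1–16 (Raf) and 1–8 (ZIK).
  CDS are uniform synonymous back-translations; gene models cut the
  spliced sequence at uniform points, so intron placement is
  unstructured.
* `simulate_duplicate_pair()` — synonymous-only divergence: each codon
  is mutated with probability `p*·S_c`, where `S_c` is its NG86
  synonymous-site content and `p* = ¾(1 − e^{−4·Ks_target/3})` the
  Jukes–Cantor-inverted target proportion, by one uniformly chosen
  synonymous single-nucleotide change.  This makes the expected NG86
  difference count equal `p*·S` by construction, centring the
  estimate on the target without calibration constants.  At extreme
  targets (Ks ≳ 2) the per-codon probability saturates at 1 for the
  most degenerate codons and the estimate compresses slightly; the
  targets of interest here (≤ 2) are unaffected.  Nonsynonymous
  distance is exactly zero by construction.
* `simulate_expression()` — three optional blocks sharing one gene
  set: a two-group block with multiplicative planted effects (group B
  mean = baseline · 2^effect) and additive Gaussian noise; a diurnal
  block in which planned genes follow
  `amplitude·cos(2π(t − φ)/24) + baseline` (default amplitude 5, noise
  sd 1 — an amplitude-to-noise ratio of 5 — sampled every 4 h for
  48 h under condition labels LDHH/LDHC/LLHC); and a co-expression
  block in which each planted triad loads on a shared latent factor
  with loading √ρ (default ρ = 0.95), giving within-triad correlation
  ρ exactly in expectation.  Additive Gaussian noise matches the
  assumptions of the correlation-based detectors downstream.
* `simulate_promoters()` — i.i.d. uniform-ACGT background (which makes
  the chance-hit expectation `2(L−k+1)·Π|allowed(i)|/4` exact) with
  concretized elements inserted at non-overlapping random positions
  and strands.

Everything is deterministic under a fixed seed, with the caller's RNG
state restored afterwards.

What the generators do *not* emulate: microarray probe effects and
normalization artefacts, read-count noise (expression noise is
Gaussian, not negative binomial), base composition and codon-usage
bias, intron positional preferences, correlated evolution among sites,
and linkage between the expression blocks.  Passing recovery tests on
these fixtures therefore demonstrates that the estimators are
implemented correctly and behave as designed under their own
assumptions — not that they would achieve the same rates on real
compendium data.

## Problem sizes and test design

The suite's recovery experiments use sizes chosen to make their
statistics stable while keeping the full suite fast: classification
recovery over 10 seeds of 30–73 genes; NG86 consistency over 200
simulated pairs of 300 codons (mean estimate asserted within
[0.17, 0.23] at target 0.2); circadian sensitivity/specificity over 10
seeds of 60 genes; SAM null behaviour over 20 seeds of 200 genes with
100 permutations; Mutual-Rank oracle equivalence over 200 random
matrices up to n = 30; scanner oracle equivalence over 10,000 random
sequences.  `scripts/acceptance.R` re-runs the same designs from a
single command-line seed.

## Known limitations

* Homology search, domain-span detection, localization prediction and
  segmental-duplication discovery are out of scope: their outputs are
  inputs here.
* NG86 ignores transition/transversion and codon-frequency biases; no
  likelihood estimators are provided.
* The SAM q-value floor at very small sample sizes (see above).
* The NJ implementation is quadratic-memory and intended for family
  sized problems (tens of taxa), not phylogenomics.
* Balanced designs only for the two-way ANOVA screen.
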