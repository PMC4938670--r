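---
title: "Methods: sex-specific SNP linkage maps and assembly integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific SNP linkage maps and assembly integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

salmap reconstructs sex-specific SNP linkage maps from nuclear-family
pedigree genotypes and integrates them with a physical genome assembly, in
the style of high-density array studies in Atlantic salmon. This vignette
explains the models and procedures, the tunable parameters and their
defaults, the synthetic-data generator used to validate every stage, and
the design decisions taken where the methodology is genuinely open.

## The data model

Genotypes are biallelic calls (hom ref / het / hom alt / missing) for
individuals linked by a pedigree of nuclear families with shared sires.
All linkage inference rests on *resolved parental transmissions*: for a
parent heterozygous at a marker, the offspring genotype (helped by the
other parent's genotype) often determines which allele that parent
transmitted. A meiosis is informative for a marker pair only if the focal
parent is heterozygous at both markers and both transmissions are
resolved; ambiguous configurations (both parents het, offspring het) and
Mendelian-impossible ones are treated as unresolved.

## Quality control

Three pre-mapping filters, in order:

1. **Mendelian errors.** A trio is *checked* at a marker iff all three
   calls are present, and is an *error* iff the offspring genotype is
   impossible under Mendelian transmission (the 27 trio-genotype states
   reduce to a legality table). Individuals with error rate > 1% are
   removed first (one bad sample otherwise inflates many marker rates),
   then marker rates are recomputed and markers > 1% removed. At desk
   scale the binomial noise of per-marker rates around the threshold makes
   this filter deliberately aggressive — exactly as the same rule behaves
   on small designs in practice.
2. **Minor allele frequency.** MAF is computed over all non-missing calls
   of all individuals; markers with MAF strictly below 0.05 are removed
   (a marker at exactly the limit is kept).
3. **Segregation distortion.** Within each family with at least one het
   parent, offspring counts are tested against 1:1 (het x hom) or 1:2:1
   (het x het); family chi-squares and degrees of freedom are summed per
   marker and markers with p < 0.001 removed. Families contributing fewer
   than two informative offspring are skipped.

## Two-point linkage model

For a marker pair, each doubly heterozygous parent has an unknown linkage
phase. With `r` apparent recombinants among `n` resolved meioses of a
parent under an arbitrary reference phase, the likelihood is the equal-
prior phase mixture

L(theta) = prod over parents of 0.5 * [ theta^r (1-theta)^(n-r) +
theta^(n-r) (1-theta)^r ],

which is symmetric under theta -> 1-theta, so the MLE is folded into
[0, 0.5]. Theta is maximised by EM on the phase mixture (tolerance 1e-7);
the LOD is the log10 likelihood ratio against theta = 0.5. An exhaustive
likelihood-grid oracle (`two_point_grid()`) profiles the same likelihood
on an explicit grid and is used in the tests to validate the EM maximiser.
Sex-specific estimates restrict the mixture to parents of one sex.

## Linkage-group clustering and the plateau threshold

Groups are single-linkage components of the "LOD >= threshold" graph —
computed exactly via hierarchical clustering with single linkage on
-LOD, so a sweep over thresholds is a sweep over the merge spectrum. The
threshold is chosen by a plateau criterion, mirroring the logic of
choosing the level at which the expected karyotype emerges: the count of
linkage groups (ignoring fragments below `min_size = 5` markers) is a step
function of the threshold; the widest threshold interval with a constant
count, restricted to regimes where at least half the markers are assigned,
is the plateau, and its midpoint is the working threshold. The assigned-
fraction restriction excludes the degenerate regimes at both ends of the
sweep (everything merged / everything single). Leftover single markers are
then assigned to the group holding their best-LOD partner if that LOD
reaches half the clustering threshold and leads the runner-up group by at
least one LOD unit — the margin is a safeguard against ambiguous rescues.

## Marker ordering

Ordering minimises total map length, but at high marker density the
two-point length objective is nearly flat: adjacent markers separated by
~0.1 cM are indistinguishable with a few hundred meioses, and among the
tens of thousands of pairwise estimates there are always a few distant
pairs whose estimated recombination fraction is spuriously zero. A plain
local search over the length objective exploits exactly those estimates
and scrambles the global order. salmap therefore builds the order in three
stages:

1. **Spectral seriation.** The Fiedler vector of the normalised Laplacian
   of the pairwise-LOD similarity matrix recovers the global backbone of a
   banded linkage matrix.
2. **Rank refinement.** Each marker is iteratively pulled toward the
   LOD-weighted mean rank of its strongest partners.
3. **Consensus-block refinement.** Markers are sliced into blocks of 8
   along the current order; each parent's transmissions are phased by
   majority vote and a per-meiosis consensus haplotype is taken per block.
   Almost every meiosis is informative at block level, so block-pair
   recombination rates are far less noisy than marker-pair estimates; the
   blocks are re-ordered by 2-opt on those distances and each marker is
   re-localised against the ordered block consensuses. Four passes are
   run.

Tiny groups (<= 8 markers) are instead solved exactly by enumerating all
orders, and small groups (< 40) by greedy nearest-neighbour construction
from random restarts with 2-opt and single-marker reinsertion — at those
sizes the length objective is informative. Orientation is normalised so
the marker with the smallest identifier lies in the first half. Residual
*local* permutations among effectively co-segregating markers are an
irreducible property of two-point information at this density; the
distance estimator below is designed to be robust to them.

## Sex-specific distances

Along the fixed order, each parent's resolved transmissions are phased by
majority vote against each offspring's last resolved value. Genotyping
errors are then handled in three ways, all reflecting the physical
impossibility of a double crossover within a few tens of kilobases:

- calls sitting in reverting runs of at most two markers are removed
  per meiosis;
- a marker at which three or more of one parent's offspring show such
  blips is masked for that parent (the signature of a spurious
  heterozygous call in the parent, which otherwise fabricates simultaneous
  "recombinants" in half its offspring);
- a marker blipping across many meioses of many parents is masked
  entirely (it sits at the wrong place in the order, so its calls reflect
  a different locus).

Crossovers are then counted between consecutive informative positions —
at consensus-block resolution (blocks of 8) for orders of 100+ markers,
which absorbs residual fine-order noise; each detected crossover is
re-localised at marker resolution between the flanking blocks and its
mass spread uniformly over the intervals it may have occurred in.
Interval recombination fractions are events over observations, converted
to centimorgans with the Haldane function d = -50 ln(1 - 2 theta)
(consistent with the no-interference meiosis model; Kosambi is available
behind a flag), capped at 50 cM per interval and flagged. An isolated flip
of a *well-supported* block is kept (at block spacing, genuine double
crossovers do occur, especially in the male subtelomeric hot zones) unless
it recurs at the same block across meioses, which marks residual
mis-ordered block content rather than independent double crossovers.

The literal adjacent-pair two-point estimator is available as
`method = "pairwise"`; with realistic genotyping error it inflates each
sex map by an error floor of roughly twice the error rate per interval,
which at 2,000 markers amounts to hundreds of centimorgans — this is the
classic map-expansion artefact, and the reason the crossover-counting
estimator is the default.

## Physical integration

Marker flanks (35 bp either side, 71-mers) are matched exactly against
the assembly, treating the central SNP base as a one-base wildcard (the
array flank carries one allele and the reference may carry the other); the
reverse complement is searched too, and the SNP coordinate is the match
start plus the offset in both orientations. Multi-hit markers keep the hit
on the chromosome their linkage group corresponds to (majority vote of
uniquely placed markers) when exactly one hit lies there, and are
otherwise excluded from positional statistics. Unplaced contigs are
anchored to the chromosome whose linkage group claims a strict plurality
of the contig's placed markers (minimum support 1 by default — the
permissive "tentatively mapped" convention — configurable upward).
Genetic-physical concordance is the absolute Pearson correlation between
map and assembly positions (group orientation is arbitrary; a rank variant
is available). Discordance segments are maximal runs of at least 3
consecutive markers outside the longest physically-sorted subsequence with
monotone genetic order.

## Recombination landscape

Each chromosome is split into 50 windows of 2% of its physical length and
the local cM/Mb proxy is the genetic length across the window over its
span. By default the genetic length of an interval is re-estimated
*directly on the physical order* of the placed markers with the same
phased crossover-counting estimator ("direct" Marey estimator): once
markers are physically placed, crossovers can be located between
physically adjacent markers, which makes the landscape insensitive to
residual noise in the genetic marker order. The alternative
`method = "marey"` interpolates the fitted map positions piecewise-
linearly against physical position, restricted to the longest concordant
subsequence, with flat extrapolation beyond the terminal markers.
Windowed rates are folded by distance to the nearest telomere: window k of
50 maps to bin min(k, 51-k), bins are 2% of chromosome length, and bin
means are unweighted over all contributing defined windows (undefined
windows are excluded, not zero-filled, and flagged).

## Variant annotation

For each gene the canonical transcript is the most highly expressed
variant (ties: longest ORF, then lexicographic id). Its ORF is re-derived
from the spliced sequence: the longest ATG-initiated, stop-terminated
reading frame of at least 100 amino acids across the three forward frames
(ties to the 5'-most start); genes without a qualifying ORF are not
annotated. Uniquely placed SNPs are classified by precedence CDS > UTR >
splice region > intron > intergenic; CDS substitutions are translated
strand-aware with the standard genetic code into start/stop changes
(start-codon change, stop gain or loss), nonsynonymous or synonymous
calls. The splice region is the 8 intronic bases adjacent to each exon
boundary, approximating the common annotation default. SNPs overlapping
several genes take the highest-precedence category; placements on
unanchored contigs are classified but flagged off-chromosome and excluded
from per-chromosome tables.

## The synthetic-data generator

`simulate_study()` builds a self-consistent fixture set with a known truth
that is never consulted by pipeline stages. Desk-scale defaults were
chosen once as the study conditions:

- genome: 5 chromosomes x 20 Mb of uniform random sequence, with 22% of
  each chromosome logically excised as unplaced contigs (two windows per
  chromosome); excised windows are hard-masked in the chromosome records
  so placed and unplaced sequence are disjoint and flank matches unique;
- crossover landscapes: female intensity flat; male intensity elevated
  10-fold over the outer 10% of each chromosome end, interior rate
  1.25 cM/Mb; the female rate is derived so the female:male total genetic
  length ratio is exactly 1.5. With those defaults a 20 Mb chromosome is
  70 cM (male) and 105 cM (female);
- meiosis: crossover counts are Poisson with mean equal to the genetic
  length in Morgans (no interference, matching the Haldane map function
  downstream), positions drawn proportional to local intensity;
- pedigree: 10 sires x 20 dams (round-robin, two dams per sire), 8
  offspring per family — 160 offspring, preserving the shared-sire
  structure at a size that keeps the full pipeline in tens of seconds;
- markers: 2,000 SNPs placed uniformly (flanks must fit inside a single
  assembly target), founder genotypes drawn from allele frequencies with
  MAF uniform on [0.1, 0.5], genotyping errors as symmetric state flips at
  0.5% (no per-call error rate is published for array studies of this
  kind; 0.5% sits comfortably under the 1% Mendelian exclusion threshold),
  1% missingness;
- gene models: non-overlapping genes with 1-3 transcripts sharing a CDS
  (110-250 codons, valid start/stop, no internal stops), 2-5 exons,
  random introns of 80-400 bp and UTRs; exonic and intronic sequence is
  written into the genome (reverse-complemented on minus-strand genes) so
  that ORF prediction on the spliced transcript recovers exactly the
  constructed CDS. True effect categories are computed at generation time
  by an independent code path (position-set membership plus whole-protein
  translation of the mutated CDS).

What the generator does *not* emulate: linkage disequilibrium among
founders, crossover interference, allele-specific or batch genotyping
error structure, repetitive sequence (so multi-hit placements must be
engineered in tests), assembly errors (discordance tests build their own
translocations), and real transcript complexity (alternative splicing
beyond 3' UTR truncation). Passing tests therefore demonstrate correctness
of the algorithms under the stated stochastic model, not performance on
real array data.

## Numerical choices and degenerate inputs

- EM tolerance 1e-7 in theta, likelihoods in log space throughout;
  theta-hat folded into [0, 0.5]; LOD clipped at 0.
- Pairs with no informative meioses: theta undefined (NA), LOD 0; they
  never connect clusters and inherit 0-cM increments with a flag.
- Interval increments capped at 50 cM and flagged; monomorphic markers get
  MAF 0 and are removed; groups of size 1 map trivially at 0 cM.
- Ordering is deterministic given the seed; per-restart lengths are
  reported so order consistency across replicates can be assessed.
- Window boundaries are rounded to integer bp and tile each chromosome
  exactly; windowed rates integrate back to the track's genetic length to
  numerical precision.

## Problem sizes

The default validation runs use the desk-scale study conditions above
(2,000 markers, 160 offspring); the linkage-group recovery check uses 29
chromosomes of 4 Mb with ~60 markers each. A full simulate-QC-map-
integrate-landscape cycle takes well under two minutes on a single core.

## Known limitations

- Per-replicate map totals wobble around the simulated truth (roughly
  plus or minus 10%, with the female map occasionally inflated by residual
  local order noise), so recovery statistics are best read as averages
  over replicates; the published maps this workflow emulates show far
  stronger expansion, as their multipoint error handling is outside our
  scope.
- Absolute per-group cM lengths are validated against the simulator's
  truth, not against published per-chromosome values, whose map function
  and error handling are not reproducible from the text.
- Half-sib information is used only through shared-sire phase pooling;
  no multipoint hidden-state likelihood is computed.
- With a few hundred meioses, two-point information cannot rank markers
  inside co-segregating blocks, so some block-scale order noise always
  remains. The female Marey correlation typically reaches 0.97-0.99 on
  error-free fixtures, while the male correlation saturates around
  0.9-0.95 because most of the male map lies in the subtelomeric ends,
  exactly where block placement is decided by the fewest observable
  crossovers. The direct landscape estimator works on the physical order
  and is unaffected.
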