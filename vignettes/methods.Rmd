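---
title: "Methods: detecting mobile SINE chromatin boundaries on synthetic data"
author: "SINEBoundary maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting mobile SINE chromatin boundaries on synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Young B2 SINEs are Pol III-transcribed mouse retrotransposons whose recent
insertions are polymorphic between laboratory strains. Where such a copy has
inserted near a gene, the copy can act as a *boundary*: a DNA-methylation or
histone-modification domain that would otherwise spread across the region
stops at the insertion, and in the insertion-free strain (or allele of an F1
hybrid) the domain extends past the same position. SINEBoundary implements
the computational chain needed to study this phenomenon end to end:

1. discovery of insertionally polymorphic copies from a pairwise comparison
   of two strain genomes;
2. classification of sequences against a subfamily consensus library, with
   divergence statistics, consensus rebuilding, and neighbor-joining
   phylogenetics;
3. quantification of full-length medium-length RNAs (melRNA-seq):
   3'-adaptor-anchored full-length filtering, classification, exact-unique
   genome mapping, and normalization to reads per million 5.8S rRNA reads;
4. per-locus CpG methylation and the CpG-count-by-methylation stratified
   expression analysis;
5. repeat-density metaprofiles around ChIP-seq peak boundaries, summit and
   peak-set bookkeeping, and binding-vs-methylation stratification;
6. allele-specific analysis across a polymorphic insertion in F1 hybrids,
   including an operational chromatin boundary-shift detector.

The genuine study requires two mouse genomes and deep sequencing data, which
are far beyond desk scale. The package therefore ships a seeded
synthetic-data generator that produces *every* input the pipeline consumes,
together with the ground truth of what was planted, so each analysis can be
validated as a parameter-recovery problem.

# Polymorphic-insertion discovery

## Minimum-gap pairwise alignment

Strain comparison uses global alignment under match $+1$, mismatch $-1$,
**zero gap-opening cost and unit gap extension**. Under this scoring a gap
of length $L$ costs exactly $L$, so a 120-300 bp insertion is absorbed as a
single internal gap rather than fragmenting; this is the scoring the
original strain comparison used and the property the gap-extraction rules
rely on.

Two numerical points deserve note:

* **Degeneracy of the zero-opening optimum.** With no opening cost, an
  optimal alignment is massively non-unique: a long gap may be split into
  pieces at zero cost, and a DP traceback is free to scatter it.
  `alignMinGap()` therefore reports the *score* of the exact zero-opening
  problem but derives the reported *alignment* from a run with an epsilon
  opening cost (0.001), which breaks ties in favor of contiguous gaps — the
  structure practitioners see from BLAST with these settings. For every
  tested instance the epsilon-canonical alignment attains the exact optimal
  score, because sacrificing one integer score unit can never be repaid by
  the epsilon (segments are far below a thousand gap runs).
* **Quadratic cost guard.** The full DP refuses inputs whose length product
  exceeds a budget (25 million cells) with a catchable
  `dpBudgetExceeded` condition. Genome-scale comparisons go through
  `alignSeeded()`: 31-mer anchors that occur exactly once in each sequence
  are collapsed into co-diagonal blocks, the heaviest strictly collinear
  chain of blocks is selected by dynamic programming, and the short
  inter-anchor segments are aligned with the full minimum-gap DP. The chain
  step matters: a k-mer unique in each genome can still pair two *different*
  planted copies of the same subfamily, and such false anchors must lose to
  the heavier true chain. This assumes collinear genomes (no inversions or
  translocations), which is the regime of a strain-pair comparison.

## Gap rules and the occupancy filter

From the alignment, internal (non-terminal) gaps of 120-300 bp are
extracted. The source description requires the flanks to be "well aligned"
without quantifying it; the package's concrete rule is: within the
$2\times50$ alignment columns on each side, at least 50 aligned base pairs
at $\ge 90\%$ identity. Both numbers are exposed as parameters.

A gap becomes an insertion call iff a repeat hit covers **strictly more
than 80%** of the gapped region. The published rule reads ">80%", and the
strict reading is implemented and tested at the boundary (a hit spanning
exactly 0.80 of the gap is rejected). The occupancy denominator is the gap
length and the numerator the hit's span on the gap sequence.

Target-site duplications make the breakpoint ambiguous within the TSD; gaps
are slid to their leftmost equivalent position and the slack is reported as
the TSD-length estimate. All calls and truth records use the same leftmost
convention, so breakpoint accuracy is well defined.

# Repeat classification

`classifySequence()` aligns a query locally against every library entry on
both strands under match $+1$, mismatch $-1$, gap open $-2$, gap extend
$-1$ (the opening base pays the open cost, so a length-$L$ gap costs
$L+1$). Divergence is (mismatches + gap events) per aligned column — each
gap counts once, in the spirit of Kimura-style repeat divergence — and
occupancy is aligned query bases over query length. The minimum reportable
score of 20 suppresses chance hits on uniform background (verified
empirically on repeat-free random genomes). Ties between entries at equal
score are broken by younger age class first, then name, mirroring the
preference for re-annotating copies with the youngest matching subfamily.

`annotateGenome()` is a seeded scanner: 12-mer seeds shared with any
consensus (either strand) define candidate windows, windows are classified
by local alignment, and overlapping hits are resolved by score. It is a
deliberately simplified stand-in for RepeatMasker, adequate for divergences
up to about 15% under this scoring; it makes no attempt at RepeatMasker's
CpG-adjusted divergence correction.

`buildConsensus()` is anchor-based majority rule: each copy is aligned to
the anchor, per anchor column the majority base is emitted, strict gap
majorities drop the column, and base ties resolve in the fixed order
A < C < G < T. `pDistanceMatrix()` computes mismatches over both-aligned
sites from pairwise global alignments (no multiple alignment is attempted),
and `njTree()` wraps the classic Saitou-Nei algorithm, clamping negative
branch lengths to zero and recording the clamped deficit.

# melRNA-seq quantification

The computational half of melRNA-seq rests on one idea: a read that
contains the 3' adaptor captures the entire RNA molecule. `trimFilter()`
retains a read iff the adaptor occurs exactly (internally, or as an exact
adaptor prefix of at least 8 bases at the read end) and trims at its start;
trimmed sequences shorter than 20 bases are dropped, since exact-unique
mapping below that length is meaningless. Matching is exact because the
synthetic reads are error-free; real data would need the error-tolerant
mode of a dedicated trimmer.

Counting is at three levels: per library entry (with the reserved 5.8S and
5S surrogates counted separately), per family, and per locus. Locus
attribution follows the strict rule the original analysis reports: a read
counts iff its trimmed sequence occurs at **exactly one** genomic position
across both strands with zero mismatches, attributed to any annotated
repeat interval it overlaps by at least one base. Normalization is
RPM = count / n(5.8S) x 1e6 — reads per million 5.8S rRNA reads — an
internal-control normalization that is invariant under uniform library
scaling. TAP (5'-triphosphate removal) contrasts are ratios of
5.8S-normalized counts between treated and untreated libraries. Replicate
concordance is the Pearson correlation of log10(RPM + 0.5); the half-unit
pseudocount is the standard continuity choice.

# Methylation-expression stratification

Per-locus methylation pools the per-CpG calls inside the locus interval:
level = sum(methylated)/sum(total) over covered sites, which is
read-weighted and robust at low coverage (the unweighted per-site mean is
also reported since the two differ under uneven coverage). A locus with no
covered CpG has an *undefined* level, never zero.

Strata are the cross of CpG-count bins (defaults $\le 2$, 3-5, $\ge 6$ —
the analysis that motivated this package contrasts CpG-poor ($\le 2$) with
CpG-rich ($\ge 3$) copies, and the finer young/old split is worth keeping)
and methylation bins (default quartiles of [0,1], left-closed right-open
with the last bin closed, so 0.25 belongs to the upper bin and level 1.0 is
kept). "Expressed" means at least one uniquely mapped read in either of two
replicates. The per-stratum table reports the five-number summary of
log-RPM, the expressed fraction, and RPM-bin fractions with edges
$\le 1$, (1,10], (10,100], > 100.

# Boundary metaprofiles and binding stratification

`boundaryProfile()` aggregates, over every peak boundary, the fraction of
bases covered by a repeat class in fixed bins of signed distance from the
boundary. Peak *end* boundaries are mirrored so that positive distances
always point into the peak; the source plots do not state an orientation
convention, so this one is declared. Density is base coverage, not element
count, matching the "genomic occupancy" notion; the background is the
genome-wide covered fraction of the same class, which makes the
uniform-placement null have enrichment 1 by construction (verified by a
permutation test and by exact equality against a per-base brute-force
oracle on small instances). Bins running off a contig contribute only
their in-genome bases to the denominator; peaks shorter than the window
still contribute both boundaries, their interiors overlapping — the oracle
reproduces this double counting exactly.

Summit bookkeeping is half-open: a summit at a repeat's 0-based start
counts, at its end does not, and ties go to the higher-scoring repeat.
Peak-set intersection uses 1-base overlap (single link), reported pre-merge.
The binding-vs-methylation table categorizes copies by their number of
methylated CpGs (pooled level $\ge 0.5$; categories 0-4 and $\ge 5$) and
tests association with a chi-square on the bound/unbound contingency table,
reporting the direction as the sign of the count-binding correlation.

# Allelic analysis

Allelic fractions use Wilson 95% intervals (valid at the low per-SNP counts
typical of allele-resolved ChIP), pooled per region; the fold is reported
as insertion-free over carrier allele to match the direction in which such
effects are usually quoted. A region is "biased" iff the two-sided exact
binomial p-value is below 0.01 and the fold (or its inverse) is at least
1.5.

The original work locates domain edges visually; a reproducible detector is
required here, so the package declares one: the plateau is the median of
peak-interior bins (bins at or above half the maximum), the boundary is the
outer edge of the contiguous above-half-plateau run containing the maximum,
on the side of the supplied breakpoint, and a shift is called when the
carrier allele's boundary lies within one bin of the breakpoint while the
free allele's boundary lies at least three bins beyond it. Both tolerances
are parameters. This is an operationalization, not a claim about how the
original boundaries were drawn.

# The synthetic-data generator

One `SimConfig` (one seed) determines every output; each generator stage
draws from its own fixed offset of the master seed, so outputs do not
depend on invocation order, and identical configurations are byte-identical.

What the generator emulates, and the defaults:

* **Background genome**: i.i.d. uniform ACGT. This guarantees the planted
  copies are the only repeat-like sequence, making recovery tests
  unambiguous — at the price of no segmental duplications, no old repeat
  background, and unrealistically benign mappability.
* **Consensus library**: equal-length consensuses (default 190 bases, the
  B2 length scale) from a common ancestor, 15 private diagnostic positions
  per subfamily (so any pair differs at $\ge 30$ positions), CpG content by
  age class: young subfamilies carry 7 CpG sites, old ones 1, reflecting
  that evolutionarily young copies are CpG-rich. Two fixed arbitrary
  sequences of 158 and 121 bases stand in for 5.8S and 5S rRNA under
  reserved names.
* **Insertions**: 5'-truncated, point-mutated consensus derivatives
  (default 2% divergence) with a 9-bp target-site duplication, placed on a
  jittered grid that guarantees pairwise separation. Draws above the
  consensus length are clamped to it: modelling long poly-A tails would
  make gap occupancy depend on tail length, a regime the >80% rule never
  confronts at these scales. Lengths default to 120-300 bp.
* **Expression**: locus shares follow a Zipf law (exponent 1 — the
  power-law profile such libraries show), multiplied by the methylation
  coupling, then scaled to the non-rRNA read fraction.
* **5' chemistry** is a per-molecule label: 5.8S-surrogate molecules carry
  a ligatable monophosphate and enter both libraries; Pol III molecules
  (SINE and 5S surrogate) carry a triphosphate and enter the untreated
  library only at a 0.05 leak rate, but always after enzymatic treatment.
  The expected treated/untreated 5S enrichment is therefore 20-fold, the
  order of magnitude such validation experiments report. A 0.3 fraction of
  molecules is "degraded": 3'-truncated and adaptorless (the real fraction
  is not published; 0.3 is a deliberate stress setting).
* **Methylation coupling**: each locus gets a true level uniform on [0,1];
  the expression multiplier is $\exp(-s\,w\,m)$ with coupling strength
  $s = 5$ and attenuation $w = 1$ for copies with $\ge 3$ CpGs, $w = 0.25$
  for $\le 2$. The strength was chosen so the planted effect spans more
  than two orders of magnitude across the methylation range — unambiguous
  against the heavy-tailed Zipf variation in per-locus abundance — and the
  4-fold attenuation encodes that methylation matters much less for
  CpG-poor copies. Per-CpG counts are binomial at Poisson(30) depth.
* **Peaks and allelics**: half the peaks (configurable) anchor one edge
  exactly at a strain-A-specific insertion's leftmost breakpoint; the
  matching strain-B peak extends 1,500 bases beyond. SNPs on the shared
  background get Poisson(40) total reads, split 50:50 except inside
  extension regions, where the insertion-free allele receives
  fold/(fold+1) of reads (default fold 6, hence an expected free-allele
  fraction of 6/7 ≈ 0.857). Allelic coverage profiles are Poisson around a
  plateau of 30 reads per 100-bp bin.

What passing tests do **not** show about real data: no sequencing errors,
no PCR duplicates, no bisulfite conversion failure, no mappability
structure from old repeats, no reference bias in allelic counts, and
breakpoints that are always clean insertions rather than nested or
truncated-with-transduction events. The generator validates the
*analysis logic*, not the upstream read processing that real libraries
need.

# Problem sizes and seeds used by the checks

The shipped checks run, on one CPU, with fixed seeds: the strain-scan
recovery uses a 2 x 1 Mb pair with 100 strain-specific insertions
(150-250 bp at 2% divergence, consensus length 260 so the whole range is
attainable by truncation) plus two planted negative controls — a 110-bp
event (below the 120-bp floor once its 9-bp TSD is included) and a
low-occupancy gap; classification accuracy uses 500 copies at 5%
divergence; expression recovery uses 200,000 reads over ~120 loci on a
300 kb genome; the stratified-methylation check uses three seeds at 300
loci and 200,000 reads each; boundary calibration uses ten permutation
seeds. These sizes were chosen as the smallest at which the planted
effects are statistically unambiguous (binomial and order-statistic
arguments sketched above), so the checks are properties of the method,
not of luck.

# Known limitations

* The classifier and scanner are simplified stand-ins for RepeatMasker and
  BLAST: fixed scoring, no complexity adjustment, no fragment joining.
  They are adequate for the ≤15% divergence regime of young SINEs.
* `alignSeeded()` assumes collinearity; rearranged genomes would need a
  real chainer.
* NJ trees carry no bootstrap support; distances are pairwise p-distances,
  not model-corrected, and no multiple alignment is performed.
* The boundary-shift rule is an operational definition; different
  definitions move the located edge by a bin or two.
* Exact-unique read mapping is stricter than spliced/mismatch-tolerant
  mapping; on real data it undercounts diverged loci.
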