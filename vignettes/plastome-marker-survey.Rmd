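---
title: "Comparative plastome structure and marker informativeness: methods"
author: "plastrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome structure and marker informativeness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastrank)
```

## The problem

Land-plant chloroplast genomes (plastomes) are circular molecules of roughly
115--165 kb with a conserved quadripartite organisation: a large and a small
single-copy region (LSC, SSC) separated by two identical inverted repeats
(IRa, IRb). For shallow phylogenetic questions, whole plastomes are often
sequenced for a few representatives and then a handful of fast-evolving
introns and intergenic spacers are PCR-amplified across a much denser taxon
sample. Choosing those markers well matters: a good marker combines high
variability with a per-marker gene tree that resembles the whole-plastome
tree and is well supported.

`plastrank` implements that selection workflow end to end: structural
delineation and accounting of annotated plastomes, extraction of candidate
markers, per-marker alignment statistics and trees, and a composite
informativeness score that ranks the markers. A synthetic-plastome generator
with known phylogeny and per-marker rates makes every stage testable without
any sequence downloads.

## Quadripartite delineation

`detect_inverted_repeats()` finds the longest **exact** inverted-repeat pair
whose two copies split the circle into four non-empty regions. Exact
matching is deliberate: the two IR copies of a plastome are homogenised by
copy-correction and are typically identical, so heuristic alignment adds
risk without benefit. The search binary-searches the repeat length and, at
each length, matches double rolling hashes of all circular windows of the
sequence against windows of its reverse complement, verifying candidates
character by character (compiled code; ambiguity codes never match). The
result is rotation-invariant, and regions are labelled so that the circle
reads LSC, IRa, SSC, IRb with LSC the longer single-copy region. Two
structured failure modes exist: no qualifying repeat (`no-IR` error) and
several distinct maximal pairs of equal length (tie error naming both).

`min_ir` defaults to 10,000 bp -- real plastome IRs are 15--30 kb, and the
floor keeps chance repeats out of reach -- and is lowered explicitly for toy
genomes (the package floor is 100 bp).

Per-position class accounting (`class_stats()`) must resolve overlapping
annotations (e.g. an intron annotation inside a CDS, or the overlapping
ycf1/ndhF found at the IRa--SSC junction of real plastomes). Positions are
assigned with the deterministic precedence CDS > tRNA > rRNA > intron >
intergenic. Published class-length tables for real genomes may follow a
different (unstated) convention, so class lengths are treated as
convention-dependent descriptors rather than reproduction targets; region
lengths and GC have no such ambiguity. Gene counts follow the annotation's
features with IR duplicates counted separately, matching how plastome gene
tallies are conventionally printed (84 protein-coding / 37 tRNA / 8 rRNA in
Melastomataceae-type plastomes).

GC content is (G+C)/(A+C+G+T): ambiguity codes and Ns are excluded from
numerator and denominator, the convention used for deposited genomes with
gap-filled stretches. Cohort dispersion statistics use the sample (n−1)
standard deviation; fed the bundled published region table for the 16
Melastomataceae plastomes (`ref_region_table()`), `summarize_cohort()`
returns mean full length 155,806 bp and s.d. 616 / 250 / 126 bp for LSC /
IR / SSC -- the values the package's acceptance checks assert.

## Marker extraction

Introns are the gaps between consecutive exon parts of a multi-part gene,
strand-normalised and numbered in transcription order. Trans-spliced genes
(rps12-style, parts on opposite strands) are skipped with a warning: their
"intron" is discontiguous across the genome, tens of kb long, and not a
PCR-amplifiable fragment. Spacers are the inter-feature gaps between
adjacent gene-level features on the circle, named `left-right spacer` in
genome order. IR-duplicated markers are collated once per genome (first
copy in canonical orientation), the same single-copy treatment the
concatenation schemes apply.

"Suitable size for PCR amplification" is quantified nowhere in the
literature this workflow follows; the survey filter keeps spacers whose
*cohort mean* length falls in [400, 1600] bp (configurable). Published
surveys of this kind report mean marker lengths of roughly 640--1060 bp,
comfortably inside this window, while the window still excludes the tiny
(<100 bp) and the unwieldy multi-kb spacers.

## Alignment statistics and the six schemes

A variable site is a column with at least two distinct unambiguous bases; a
parsimony-informative site has at least two bases each carried by at least
two taxa. Gaps and IUPAC ambiguity are missing data everywhere -- in site
counts and in distances -- which also makes the degeneracy-recoded scheme
behave as intended.

Pairwise distances use the Kimura two-parameter (K80) model,
`d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`, with P and Q the transition and
transversion proportions over the columns where both sequences have
unambiguous bases (pairwise deletion; markers have ragged ends, and
complete deletion would waste most columns). When the log argument is
non-positive the pair is saturated: the distance is undefined and the pair
is excluded from means with a warning rather than clamped.

Whole-plastome inference conventionally builds several concatenation
schemes to control alignment and saturation artefacts. `build_schemes()`
produces six: all non-coding (ncs); ncs with poorly aligned columns
removed; all coding genes (cds); cds with arginine, leucine and serine
codons ambiguated; translated cds; and the union of filtered ncs plus
unambiguated cds ("full"), each with a marker-to-column partition map. One
IR copy is removed upstream (single-copy collation) so duplicated sequence
is not over-represented.

Two design points deserve note:

* **Codon ambiguation.** "Ambiguating" the six-fold degenerate amino acids
  is implemented as family-wise IUPAC degeneracy: Leu → `YTN`, Arg → `MGN`,
  Ser kept as its two codon families `TCN` / `AGY`. This removes the
  synonymous signal (including the Leu TTR/CTN and Arg AGR/CGN
  first-position degeneracies, encoded by Y and M) while preserving column
  count, and it is idempotent. Other recodings exist; this one was chosen
  because it is the established degeneracy convention and keeps the
  alignment geometry fixed.
* **Poorly-aligned-site filtering.** The filter is a deterministic
  gap-window mask: every sliding window of `window = 5` columns whose
  gap+ambiguity fraction exceeds `max_gap_frac = 0.5` is removed wholesale.
  It is a stand-in with the same role as entropy-based alignment-masking
  tools, not a reimplementation of any of them, so filtered column counts
  are not comparable tool-to-tool; downstream code treats them accordingly.

## Trees

The built-in engine is neighbor joining on K80 distances -- deterministic
(ties in the Q criterion broken by the lexicographic order of cluster
names), negative branch lengths clamped to zero, unrooted output. This is a
deliberate structural simplification: likelihood inference is a heavier
dependency than this desk-scale pipeline warrants, and externally computed
Newick trees can be injected as the reference (`reference` argument) by
users who run a likelihood engine. Consequences: bootstrap values and
per-marker RF distances from published likelihood analyses are
worked-example anchors, not quantities this engine reproduces bit-for-bit;
topology agreement is asserted only on simulated data where the truth is
known.

Support comes from the nonparametric bootstrap: columns resampled with
replacement, each replicate's NJ tree scored against the original tree's
internal bipartitions, support = percentage of successful replicates
(saturated replicates are dropped and logged). Replicate seeds are derived
from the user seed by counter, so results do not depend on evaluation
order. Tree comparison is the classic Robinson--Foulds symmetric difference
of nontrivial bipartitions, unnormalised (even integers up to 2(n−3) = 26
on 16 taxa); polytomies are allowed and simply contribute no splits.

## The composite score

Markers are ranked by a weighted mean of relative values,

```
score = (1 * v_rel + 2 * b_rel + 3 * d_rel) / 6
```

with v = variable sites, b = mean bootstrap and d = RF distance to the
reference tree. "Relative value" is division by the survey-wide column
maximum, with the distance inverted (`d_rel = 1 - d/max d`) so that
closeness to the reference scores high. Among the plausible normalisations
(column max, min-max range, rank-based) division-by-max is the simplest
that maps all metrics to [0, 1]; it reproduces the published top-10
ordering of the Melastomataceae survey exactly when the survey-wide metric
ranges (variable sites up to 507, bootstrap up to 82, RF up to 22) are
supplied -- which is why `rank_markers()` accepts explicit maxima for
ranking a subset of a larger survey. The score is scale-invariant in each
raw metric and monotone in each metric below its column maximum.

## The synthetic generator

`simulate_cohort()` emulates exactly the statistical structure the survey
assumes: a single underlying phylogeny with markers evolving along it at
heterogeneous rates. A Yule tree (default 16 taxa, root-to-tip height
scaled to 1) is drawn; each marker evolves independently under K80
(closed-form transition probabilities per branch, i.i.d. columns, uniform
root) at rate `base_rate × multiplier`. Defaults: `base_rate = 0.05`
substitutions/site root-to-tip and `kappa = 2`, giving pairwise divergences
around 0.05--0.1 for spacers -- the range observed between confamilial
plastomes; class multipliers rRNA 0.3 < tRNA 0.5 < CDS 0.7 < intron 1.3 <
spacer 1.8 encode the conventional conservation hierarchy. The toy
architecture is ~35 plastid-named genes on a ~62 kb circle with an 8.4 kb
IR block, four intron-bearing single-copy loci (one two-intron,
clpP-style), an intron-bearing tRNA inside the IR (exercising duplicate
deduplication), an rps19-style gene straddling the LSC--IRa junction, and a
dozen spacers in the PCR-suitable window.

No indels are simulated by default, so each evolved marker matrix is its
own alignment and extraction truths are exact to the byte; a gap-punching
utility exists solely to exercise gap handling and the masking filter. One
realism caveat follows: passing tests on simulator output demonstrates
correctness of the bookkeeping and estimators under the model, not
robustness to alignment error, rearrangement, or annotation noise in real
deposits -- real-data use should feed externally aligned FASTA into
`survey_alignments()`.

Two generator subtleties are handled explicitly rather than hidden. First,
the planted IR pair can extend outward by a base or two when flanking bases
happen to be complementary; the truth table records the *realised* maximal
IR per taxon, and structural tests compare against that. Second, marker
reproducibility is guaranteed by deriving each marker's seed from the
master seed and the marker index, so cohorts are byte-identical across
runs.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately desk-scale
sizes chosen to make the statistical assertions sharp but cheap: 100
random planted-IR architectures (0.6--2.4 kb circles), 16-taxon NJ recovery
from 20 kb concatenations at three seeds, K80 estimator recovery at 50 kb
(within three standard errors of the generating 0.1), a thousand random
alignments against brute-force site-count oracles, and 8-taxon surveys
with 50 bootstrap replicates. NJ topology recovery at 20 kb is a
statistical property, not a certainty: an occasional Yule draw contains an
internal edge of ~0.002 substitutions/site that no distance method
resolves at that length (the reference NJ implementation fails these trees
identically).

Other numerical choices: distances are computed in double precision with no
clamping (saturation is an explicit NA, not 0 or a cap); bootstrap support
is reported on the 0--100 scale; all RNG flows from a single integer seed;
the IR search verifies every hash match exactly, so hash collisions cannot
produce a wrong answer, only wasted work.

## Known limitations

* GenBank I/O covers the flat-file subset plastome deposits use (LOCUS,
  gene/CDS/tRNA/rRNA/intron/misc_feature keys, join/complement locations,
  /gene, /note, /pseudo, ORIGIN); it is not a general GenBank parser.
* The built-in tree engine is distance-based; likelihood or Bayesian
  supports must be supplied externally if required.
* Exact IR matching will under-segment a plastome whose IR copies truly
  differ (rare, but it happens in degraded deposits); the miss is loud (a
  shorter-than-expected IR or a no-IR error), not silent.
* The survey requires equal-length rows per marker; it does not align.
  Alignment is an explicit input boundary.
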