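---
title: "Methods: barcode-gap OTU delimitation with barcodekit"
author: "barcodekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-gap OTU delimitation with barcodekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekit)
```

`barcodekit` implements the distance-based analysis chain of a two-marker
DNA-barcoding survey — cytochrome c oxidase subunit I (COI, protein-coding,
~658 bp) and mitochondrial 16S rRNA (indel-bearing) — from raw sequence
screening to a consensus table of operational taxonomic units (OTUs) with
novelty and pseudogene annotations.  This vignette explains each model and
procedure, the tunable parameters, and the design decisions that were
genuinely open.

## Quality screening

A record passes QC only if its ungapped length strictly exceeds 90% of the
expected amplicon length (`min_len_frac = 0.90`) and, when per-base Phred
scores are available, strictly more than 85% of its bases reach Phred 30
(`min_phred = 30`, `min_frac_above = 0.85`).  Both rules are deliberately
strict inequalities ("more than"), so a record sitting exactly on a boundary
fails.  Plain FASTA input carries no qualities; such records skip the Phred
rule but never the length rule, because archival sequences must remain
usable.  Lengths are measured on ungapped residues: alignment gaps are
artefacts of the aligner, not bases.

## Distance models

Pairwise distances use **pairwise deletion**: for each pair, sites where
either sequence carries a gap or an IUPAC ambiguity code are excluded.  This
preserves indel-rich 16S pairs that complete deletion would destroy.
Ambiguity codes are excluded outright rather than fractionally matched —
simpler and exactly testable.  With `p` the proportion of differing sites,
`P` transitions (A–G, C–T) and `Q` transversions:

* JC69: `d = -(3/4) ln(1 - (4/3) p)`, defined for `p < 0.75`;
* K2P: `d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)`, requiring
  `1 - 2P - Q > 0` and `1 - 2Q > 0`.

Out-of-domain proportions mean the pair is saturated; the default policy is
a hard error naming the pairs, with an opt-in cap at the domain boundary for
exploratory use.  Distances feeding OTU delimitation are JC69 by default:
the correction named for the survey's trees is the natural choice, and the
delimitation is insensitive to it at barcoding depths (the K2P and raw-p
alternatives are one argument away).

## BIONJ trees and bootstrap

Trees are built with BIONJ — neighbour joining under the standard
Q-criterion, with Gascuel's variance-weighted averaging when two rows are
merged (weight `lambda` estimated from the running variance matrix and
clamped to `[0, 1]`).  The implementation is double precision throughout, so
an additive input matrix is reproduced to machine accuracy; the test suite
checks topological agreement with an independent BIONJ implementation on
noisy matrices.  Determinism matters for a pipeline: taxa are sorted by
label before agglomeration and Q-ties break by lexicographic pair order, so
permuting the input changes nothing.  Negative branch-length estimates, a
known artefact of distance agglomeration, are clamped to zero with the
deficit moved to the sibling branch; the raw estimates still drive the row
reduction so downstream distances stay unbiased.  Clamp counts are recorded
on the tree.

Node support uses Felsenstein's nonparametric bootstrap: alignment columns
resampled with replacement, matrix and tree rebuilt per replicate, support =
fraction of completed replicates containing the same bipartition.  A
replicate whose resampling produces an incomparable or saturated pair is
discarded and counted; the denominator is completed replicates.  The default
is 100 replicates — a conventional choice balancing stability of the support
values against runtime.  Supports are reported, not acted on: no topology is
pruned by a support threshold.

## ABGD: barcode-gap delimitation

The delimitation scans a geometric series of priors `P` on the maximal
intraspecific divergence, `P_k = p_min (p_max/p_min)^{k/(steps-1)}`.  The
defaults are the standard two-marker settings: COI `p_min = 0.001`,
`p_max = 0.1`, relative gap width `x = 1.125`, 10 steps; 16S `p_max = 0.05`,
`x = 1.5`.  The smaller COI `x` reflects that the default 1.5 is often not
sensitive enough to partition dense COI data.

For one prior, the detector sorts all pairwise distances and scans
consecutive gaps `g_i = d_{i+1} - d_i`:

* a gap is a **candidate** when its far edge exceeds the prior
  (`d_{i+1} > P`) — distances below the prior are intraspecific by
  assumption and cannot end a barcode gap;
* a candidate is **significant** when `g_i > x * max(s_i, P)`, where `s_i`
  is the mean of the preceding consecutive gaps (or the median of all gaps
  when fewer than `min_gap_context = 2` precede).

The `max(s_i, P)` scale is the package's own definition of the detector and
deserves a word.  A pure ratio-to-local-gap rule degenerates in the dense
intraspecific cloud: tied distances drive the local mean gap to zero, making
the first jump out of a run of ties "significant" at every prior and
producing near-singleton partitions at small priors.  Requiring the gap to
be wide on the scale of the prior itself encodes the method's semantics —
under an assumed maximal intraspecific divergence `P`, a believable barcode
gap must be substantial relative to `P`, not merely to its tied neighbours.
This plays the role of the coalescent-derived limit in the original
formulation of the method, which is out of scope here.

Partitioning is single linkage with edges strictly below the gap midpoint
(the gap itself is never bridged), applied recursively: inside each group
the detector runs again on intra-group distances only, until no significant
gap remains or a group has fewer than 3 members (two specimens yield one
internal distance — no gap is definable).  Group labels are the smallest
member specimen id, which makes partitions order-independent.

Across the prior series the **modal partition** — the grouping returned by
the most priors, ties resolved toward the smaller prior — is selected
automatically, replacing the histogram-guided judgment a human analyst would
apply; an explicit prior can override it.  The distance histogram (bin width
0.005) is emitted for exactly that diagnostic purpose.

## Cross-marker consensus

Specimens are linked when either marker co-groups them; connected components
of that join graph are conflict blocks.  Where the two markers disagree, the
finer grouping is accepted only if each extra group diverges from every
other specimen of its block by at least 0.05 substitutions/site in COI *or*
0.03 in 16S ("at least" — inclusive bounds); otherwise the option producing
fewer OTUs wins.  Divergence is measured within the conflict block, not
against the whole dataset: the conflict is local, and this reading is
directly testable.  Specimens sequenced for a single marker inherit that
marker's group.  When the two partitions cross (neither refines the other)
the finer candidate is their common refinement, resolved finest-first, and
the coarser is the marker grouping with fewer groups; such blocks are
flagged in the conflict log.  Blocks with no usable distances on either
marker resolve to the coarser option and are tagged unresolved.

## Reference matching, novelty and contamination

In place of live GenBank/BOLD queries the pipeline matches against a local
reference FASTA (`refID|taxon|target_or_nontarget`).  Identity comes from a
global alignment with free terminal gaps (match +1, mismatch −1, a gap of
length k costs 5 + 2k), reported as matches over aligned columns excluding
terminal overhangs — a deterministic approximation of BLAST identity for
same-locus, near-full-length amplicons, checked in the tests against an
independent dynamic-programming oracle.  Classification is strict: a COI
query is *known* only above 95% identity, a 16S query only above 97%;
boundary values are new.  Queries above 95% identity to a non-target
reference are flagged as contamination and dropped before delimitation.
Name comparison strips open-nomenclature qualifiers (cf., aff., nr.) and
classifies genus/epithet agreement, including the "better resolution" case
where the reference is only determined to genus.

## Pseudogene screening

Nuclear copies of mitochondrial genes (NUMTs) betray themselves in a coding
marker through frameshifts, in-frame stop codons, unusual translations, or
deviant GC content.  The screen applies, per COI sequence: (1) stop count in
the best reading frame under the invertebrate mitochondrial code
(translation table 5 — TAA/TAG are stops, AGA/AGG serine, TGA tryptophan)
and a frameshift check (ungapped length mod 3 against the expectation, plus
any internal gap run not a multiple of 3 in aligned mode); (2) amino-acid
p-distance to the cohort's modal translation, flagged above 0.20 — a
quantitative stand-in for "unusually divergent amino-acid sequence", which
field practice applies qualitatively; (3) GC% standard score within the
marker cohort, flagged at `|z| > 3`.  The z-cutoff is a deliberate default:
no principled universal GC threshold exists, and 3 standard deviations keeps
false positives near zero while catching the ~0.1 GC-fraction shifts typical
of diverged NUMTs.  GC% uses unambiguous bases only.  Across markers, the
per-specimen (COI GC%, 16S GC%) Pearson correlation is reported: both genes
share the mitochondrial AT bias, so specimens far off the trend are
suspects.  Flagged sequences are *reported, never removed* — a sequence from
a vouchered specimen identifies that species whether or not it is a
pseudogene.

## The synthetic-data generator

Every stage is testable against `generate_dataset()`, which builds datasets
with known species truth.  Its design:

* **Star-wise species structure.**  One random base ancestor per marker
  (GC fraction 0.38, a typical decapod mitochondrial value); each species
  receives a private, disjoint set of `ceil(inter_div * L / 2)` diagnostic
  sites mutated away from the ancestral state.  Any two specimens of
  different species therefore differ at `>= inter_div * L` sites — the
  interspecific floor is exact, and interspecific distances sit near
  `inter_div` rather than near saturation, matching the divergence regime
  such surveys report (~0.10 substitutions/site between COI clusters, ~0.05
  in 16S) and keeping JC69 well-defined.  No tree-shaped interspecific
  structure is simulated; gap recovery does not need it.
* **Intraspecific noise.**  Each specimen mutates `Binomial(L, intra_div/2)`
  sites confined to non-diagnostic positions, so within-species p-distances
  concentrate near `intra_div` while the interspecific floor is untouched.
* **Coding integrity.**  COI-like records are kept stop-free in frame 1
  under table 5 (mutations that would create TAA/TAG are redrawn), matching
  genuine mitochondrial sequences; the 16S-like marker receives random
  deletions at rate `indel_rate_16S`, emitted as alignment gaps so no
  aligner is needed downstream.
* **Defect injection.**  `inject_pseudogene()` produces exactly the defects
  the screen detects: a 1-base deletion, an in-frame TAA/TAG, or a
  synonymous-site GC shift (default +0.12) — the round trip is what the
  tests exercise.
* **Reproducibility.**  One master seed; every record draws from a private
  substream keyed by a stable hash of its specimen id, so insertion order
  can never change output, and identical configs give byte-identical files.

What the generator does *not* emulate: rate heterogeneity across sites,
realistic codon usage, coalescent genealogies, chimeras, or sequencing-error
models beyond per-base Phred draws.  Tests passing on this generator
therefore demonstrate the machinery (gap detection, screening, consensus
logic) under clean conditions, not performance on difficult real data with
ragged barcode gaps.

The generator's GC variation is mutational noise only — there is no
specimen-level GC driver shared between markers — so the cross-marker GC
correlation of a default synthetic survey is near zero.  The correlation
machinery itself is tested with a dedicated shared-driver simulation and a
permutation envelope.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script were chosen to exercise
every code path at desk scale: 50 replicate 20-species x 5-specimen surveys
for delimitation recovery, 200 random matrices (n <= 10) against the
clustering oracle, 100 random pairs (length <= 60) against the alignment
oracle, closed-form grids at 1e-9, and one full 100-specimen pipeline run
with 100 bootstrap replicates.  Ties in the Q-criterion, in group labelling
and in best-hit selection all break lexicographically; degenerate inputs
(empty sequences, all-identical distances, zero-variance GC cohorts,
blocks without distances) are handled explicitly and tested.

## Known limitations

* The gap detector is this package's own concrete definition; it is not a
  byte-level reimplementation of the original ABGD program, whose windowed
  slope estimation differs in detail.  Accession-level OTU counts from real
  surveys are therefore implementation-sensitive.
* Whether real analyses ran delimitation on corrected or uncorrected
  distances is often unstated; the default here is JC69 and configurable.
* BLAST identity is approximated by global ends-free alignment; on partial
  or chimeric hits the two can disagree.
* Multiple sequence alignment is out of scope: the pipeline consumes
  pre-aligned (or synthetic-aligned) input.
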