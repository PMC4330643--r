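---
title: "Methods: surveying the eIF4E family with capclade"
author: "capclade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying the eIF4E family with capclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capclade)
```

## The scientific setting

eIF4E proteins recognise the mRNA 5′ cap through a conserved cupped-hand
fold: the 7-methylguanosine base is sandwich-stacked between W56 and W102
(murine numbering), W166 contacts the methyl group, E103 hydrogen-bonds the
base, and R112, R157 and K162 neutralise the triphosphate bridge; the
S/TVxxFW motif ending at W73 on helix 1 binds the eIF4G scaffold.
Dinoflagellates — eukaryotes that lean on translational rather than
transcriptional control — carry large eIF4E families whose members differ
exactly at these functional positions, so a careful family survey couples a
homology census with residue-level annotation anchored on the murine
reference, a phylogeny, and a taxon-aware partition of that phylogeny.
`capclade` packages each of these stages with the parameter conventions of
such surveys and a simulator that makes the whole chain testable offline.

## Census model

The census is a fixpoint iteration. Starting from seed queries, every
database sequence is aligned to every query by exact Smith–Waterman local
alignment under BLOSUM62 with affine gap penalties (open 11, extend 1; a
gap of length $L$ costs $11 + L$). A subject is accepted when

$$E = K\,m\,n\,e^{-\lambda S} \le 10^{-10}
  \quad\text{and}\quad \text{aligned columns} \ge 130,$$

with the gapped Karlin–Altschul constants $\lambda = 0.267$, $K = 0.041$,
$m$ the query length and $n$ the pooled database residue count. Accepted
subjects join the query set and the search repeats until no novel member
appears. Both thresholds are configurable (`search_params()`); the
130-residue rule is implemented as a filter, since on full-length family
members a true hit spans most of the ~160-residue core and the rule mostly
guards against fragment and domain-sharing artifacts. Unknown residues (X)
score zero against everything, so runs of X neither attract nor repel an
alignment. Novelty is by sequence identifier: identical sequences under
different ids are reported separately, not collapsed. The census operates
on protein sequences; six-frame translation of nucleotide data is upstream
of this package.

## Reference anchoring instead of a full multiple alignment

Every accepted sequence is aligned pairwise to full-length murine eIF4E-1
(217 aa, packaged) with free end gaps, giving each residue either a murine
position or an insertion code `(after_position, offset)`. Alignments are
trimmed to the cap-binding core — five residues upstream of W43 through ten
downstream of W166, i.e. murine 38–176, 139 positions — and stacked into a
matrix whose column $j$ *is* murine position $j$. Insertions never create
columns; they are carried per row.

This replaces a simultaneous multiple alignment on purpose: the stacked
columns are deterministic, independent of which other sequences are
present, and already expressed in the coordinate system used to talk about
cap-binding residues. The cost is that alignment-ambiguous regions (e.g.
around R157, which sits next to the clade-1 insertion window) are resolved
by each pairwise alignment independently; columns adjacent to insertions
should be read with that caveat. Downstream statistics use only the 139
match columns, and bootstrap resampling also operates on those columns.

## Diagnostic annotation

Per sequence we report the states at the ten diagnostic murine positions,
summed insertion lengths inside the W73–W102 and W130–W166 windows, the
C-terminal extension beyond murine 176 (measured on the untrimmed
sequence), and the hexamer at 68–73 matched against `[ST]V..[FWYL][WFYL]`
with a charge-based variant call on the two variable positions (Q/N polar,
D/E acidic, K/R basic). The clade classifier applies ordered rules, first
match wins: aromatic loss at 43 (Y/F/L) → metazoan-Class-II-like; both
window insertions ≥ 5 residues and H112 → clade-1-like; C112 with V/A at
162 → clade-2-like; canonical W56/R112/K162 without window insertions →
clade-3-like; otherwise unclassified. The ordering and the 5-residue
insertion threshold are design choices that make the three clade
descriptions mutually exclusive; both are parameters. Two consequences are
intentional: the murine reference itself satisfies the canonical rule set
and classifies clade-3-like, and sub-clade-level characters (the W102→R of
the 3b type, the long carboxy extension of the 2a type) are recorded as
evidence but never drive the label — sub-clade resolution belongs to the
tree, not the rules.

## Phylogeny at desk scale

The tree stage is deliberately a distance pipeline: Kimura-corrected
distances $d = -\ln(1 - p - 0.2p^2)$ over mutually non-gap match columns
(set to 5.2 with a warning where the argument is non-positive, i.e.
$p \gtrsim 0.854$), Saitou–Nei neighbor-joining (negative branches clamped
to zero with the deficit moved to the sister edge), and nonparametric
bootstrap by resampling the 139 match columns. It stands in for a full
maximum-likelihood topology search, which is out of scope; published
bootstrap percentages from large ML analyses are not expected to be
reproduced numerically.

Likelihood machinery is nonetheless included for what it is needed for:
scoring fixed topologies. `tree_log_likelihood` implements Felsenstein
pruning under LG/WAG/JTT exchangeabilities with discrete-gamma rates (mean
rate of each of $k$ equal-probability categories, default 4), gaps and X
as missing data. It is validated against a matrix-exponential closed form
(two taxa) and an independent implementation, and is invariant under
rerooting. The gamma shape is estimated by one-dimensional bounded search
on [0.05, 10]; `pairwise_distance(..., "lg_ml")` provides the matching
two-sequence ML branch length.

A note on frequency models: on data simulated cleanly under LG with LG
frequencies, plugging the alignment's empirical frequencies into the model
yields a slightly *higher* likelihood than the LG frequencies essentially
always — ordinary overfitting of nineteen plug-in parameters. The
direction reverses exactly when the pooled empirical frequencies are a
poor stand-in for the generating frequencies of most lineages, e.g. when
composition-biased rows contaminate the pool; that is the regime of real
family alignments with biased ciliate members, and `compare_frequencies`
run on the simulated family (which includes such lineages) prefers the
model frequencies consistently. The package therefore demonstrates this
model-selection direction under contamination, not under clean simulation.

## Clades and sub-clades

Major clades are defined post hoc from the rooted tree: descending from
the root, wherever at least two child subtrees each contain both a core
dinoflagellate and a heterokont, the descent recurses; otherwise the node
roots a major clade. Clades are numbered by decreasing core-dinoflagellate
content. The default rooting is a midpoint rule restricted to the two
groups that define the partition: the root is placed at the midpoint of
the longest core-dinoflagellate↔heterokont path. A global midpoint is
fragile here — a composition-biased long-branch lineage (the ciliates) can
own the tree's longest path and drag the root onto its pendant edge,
collapsing the partition — while the group-restricted midpoint targets the
backbone the rule reasons about. An explicit outgroup override is
available.

Sub-clades are maximal monophyletic groups of core-dinoflagellate leaves
inside a major clade, lettered by decreasing species count (ties by size,
then traversal order). Two refinements: syndinean and *Perkinsus* leaves
are masked during the monophyly check, so those early-branching lineages
never split a sub-clade; and a single-leaf lineage attached directly at
the major-clade root is retained, so one-copy-per-species sub-clades are
not lost. Singletons anywhere deeper are left unplaced. The lettering is a
convention — matching groups matter, letters need not coincide with any
published labelling.

## Composition, identity and logos

Composition bias per row is a χ² test of the row's amino-acid counts
against expected counts $N_i f_a$ from the pooled alignment frequencies
(gaps and X excluded everywhere), expected cells below 1 pooled into one
rare-residue cell, flagged at α = 0.05. Percent identity divides matches
by mutually non-gap columns; a whole-sequence variant aligns untrimmed
records first. Column variability is the fraction of columns with ≥ 2
distinct residues among columns with ≥ 2 residues. Logo information per
column is $R = \max(0,\ \log_2 20 - H - e_n)$ with the small-sample
correction $e_n = 19/(2 n \ln 2)$, letter heights $p_a R$; with $n = 1$
the correction exceeds $\log_2 20$ and $R$ clamps to zero, and for an
invariant column $R \to \log_2 20 \approx 4.32$ bits.

## The synthetic family: what it emulates, and what it does not

`simulate_family` evolves the murine core (139 aa) down an explicit guide
tree under LG: three clade ancestors receive their residue signatures
(states, insertions, motif, C-terminal extension) before descent; each
clade carries three core-dinoflagellate sub-clades over eleven species
plus separator lineages — heterokont pairs in every clade, a syndinean
pair in clade 1, a *Perkinsus* pair in clade 3, composition-biased ciliates
in clade 1 — interleaved along a short spine so that sub-clades are
maximal pure groups in the guide tree, as outgroup lineages interleave
among sub-clades in real family trees.

Default conditions (units: expected substitutions/site): clade stem 0.40,
sub-clade stem 0.22, spine 0.12, separator lineages 0.15 + 0.10, per-copy
branches 0.02, sub-clade divergence (0.03, 0.08, 0.15) from a to c —
encoding the conservation ranking a > b > c — copy numbers 1–3 for the
first sub-clade of each clade and 1 elsewhere, and species presence
(11,11,11)/(11,11,8)/(11,6,5), so six of nine sub-clades carry all eleven
species and the family size per species centres near eleven. The ciliates
are biased by per-site resampling (weight 0.5) toward an
FIKN-enriched target — the caricature of an AT-rich proteome — strong
enough that a 139-column χ² flags a biased row with high probability.
These are the generator's fixed study conditions, not tuning knobs.

Two simplifications matter for interpretation. There is no indel process
along branches — insertions enter only through clade signatures — so the
murine numbering of every simulated site is exact; real families
accumulate scattered indels that make anchoring genuinely harder. And
composition bias is a post hoc site resampling, not a biased substitution
process; it produces the tested symptom (χ² deviation, long branches)
without modelling a mechanism. Passing the recovery tests therefore shows
the pipeline's logic is correct under controlled realistic divergences,
not that anchoring or NJ are robust to arbitrary real-data pathology.

## Numerical and design choices

* Alignment engine: Biostrings' exact affine-gap implementations (local
  and ends-free global), with BLOSUM62 from the same package, X zeroed.
  Tests cross-check the scores against an independent plain-R Gotoh
  recursion and, for tiny strings, exhaustive enumeration.
* NJ: ape's implementation behind `nj_tree()`, plus the negative-branch
  clamping described above; bipartition counting via `ape::prop.clades`.
* LG/WAG/JTT tables come from phangorn's model data; the rate matrix is
  normalised to one expected substitution per site and exponentiated via
  the symmetrised eigendecomposition cached in the model object.
* Kimura distances cap at 5.2 where undefined; ties in NJ follow ape's
  deterministic order; bootstrap replicates draw from one seeded RNG and
  restore the caller's RNG state.
* Problem sizes in the tests and the acceptance script (a ~137-sequence
  family, 100–1000 bootstrap replicates, 200-row null calibrations,
  10⁴-site branch-length recovery) were chosen as the smallest sizes at
  which the measured quantities are stable; they are the package's own
  validation conditions.
* Degenerate inputs: empty FASTA files parse to empty sets; all-gap rows
  are skipped with warnings in composition tests; sequences with no
  residue in the core window raise a "no core domain" error and are
  dropped (with a log line) by the pipeline runner; trees with fewer than
  three taxa are rejected by NJ.

## Known limitations

Census novelty is id-based, so redundant database entries inflate member
counts exactly as they do in real surveys. The anchored stacking resolves
each row independently, so insertion-adjacent columns can disagree with a
simultaneous multiple alignment. The partition rule assumes heterokonts
are a meaningful outgroup signal; on trees where heterokonts are absent or
misplaced it degrades to a single unresolved partition with a warning.
Nucleotide-level analyses (dN/dS, codon models) are out of scope, as is
any maximum-likelihood or Bayesian topology search.
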