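# capclade

Census, annotation and phylogenetic partitioning of the eIF4E cap-binding
protein family in dinoflagellates and their relatives.

## The problem

Core dinoflagellates regulate gene expression mostly at the level of
translation, and the eukaryotic translation initiation factor 4E (eIF4E) —
the protein that binds the 7-methylguanosine cap at the mRNA 5′ end — is a
natural control point. Dinoflagellate transcriptomes carry unusually many
eIF4E family members, and making sense of that diversity requires a chain
of steps: find every family member in a set of protein databases, put all
of them on a common residue coordinate system, inspect the residues known
to contact the cap and the eIF4G scaffold, build a phylogeny, partition it
into clades and sub-clades by taxon representation, and quantify
conservation and amino-acid composition bias. `capclade` implements that
chain as a reusable, fully offline-testable R toolkit, aimed at molecular
evolution researchers studying protein families in alveolates and
heterokonts (or any group with a good structural reference).

## What it computes

* **Census** (`iterative_census`): iterative, query-expanding homology
  search by exact Smith–Waterman local alignment (BLOSUM62, affine gaps
  11/1). A subject is accepted when its Karlin–Altschul E-value
  `E = K·m·n·e^(−λS)` (λ = 0.267, K = 0.041) is at most 1e-10 **and** the
  alignment covers ≥ 130 residues; accepted subjects join the query set
  and the search repeats to a fixpoint.
* **Anchoring** (`align_to_reference`, `trim_core`, `stack_alignment`):
  each member is aligned pairwise to murine eIF4E-1 with free end gaps, so
  every residue carries a murine position or an insertion code. Alignments
  are trimmed to the cap-binding core — five residues upstream of W43 to
  ten downstream of W166, murine 38–176 — and stacked into a 139-column
  alignment whose column *j* is murine position *j*; insertions ride along
  as per-row annotations.
* **Annotation** (`residue_states`, `scan_eif4g_motif`,
  `classify_diagnostics`): states at the diagnostic positions (W43, W46,
  W56, W73, W102, E103, R112, R157, K162, W166), insertion lengths in the
  W73–W102 and W130–W166 windows, the S/TVxxFW eIF4G motif ending at W73,
  and a rule-based clade call (clade-1-like: Y56/H112 plus both window
  insertions; clade-2-like: C112 with V/A162; clade-3-like: canonical
  W56/R112/K162; metazoan-Class-II-like: aromatic loss at position 43).
* **Phylogeny** (`distance_matrix`, `nj_tree`, `bootstrap_support`,
  `tree_log_likelihood`): Kimura-corrected protein distances
  `d = −ln(1 − p − 0.2p²)`, neighbor-joining, nonparametric column
  bootstrap over the 139 match columns, and Felsenstein pruning
  likelihoods under LG (or WAG/JTT) with discrete-gamma rates for scoring
  fixed topologies and comparing frequency models.
* **Clades** (`partition_major_clades`, `find_subclades`,
  `representation_table`): major clades are maximal subtrees containing
  both core dinoflagellates and heterokonts; lettered sub-clades are
  maximal monophyletic core-dinoflagellate groups (syndinean/Perkinsus
  leaves are masked); representation tables count members per sub-clade
  and species.
* **Statistics** (`composition_chi2`, `percent_identity`,
  `column_variability`, `logo_matrix`): per-row amino-acid composition
  χ² against pooled alignment frequencies, pairwise identities, variable
  column fractions and sequence-logo information content with the
  small-sample correction.
* **Simulator** (`simulate_family`): a synthetic family with three
  signature-carrying clades, nine core-dinoflagellate sub-clades across
  eleven species, heterokont/syndinean/Perkinsus lineages and
  composition-biased ciliates — with full truth labels, so every stage
  above is testable without downloads.

## Worked example

```r
library(capclade)

fam  <- simulate_family(sim_config(seed = 1))   # synthetic study conditions
cen  <- iterative_census(fam$seeds, fam$records)
alns <- lapply(fam$records, align_to_reference)
m    <- stack_alignment(lapply(alns, trim_core))
tree <- bootstrap_support(m, B = 100, seed = 1)
part <- find_subclades(
  partition_major_clades(tree, setNames(fam$truth$group, fam$truth$id)),
  setNames(fam$truth$species, fam$truth$id))
part
representation_table(part, cen)
```

which prints

```
clade partition: 3 major clades, 0 unplaced leaves
  eIF4E-1: 58 leaves (ciliate 3, core_dino 51, heterokont 2, syndinean 2)
  eIF4E-2: 43 leaves (core_dino 39, heterokont 4)
  eIF4E-3: 36 leaves (core_dino 32, heterokont 2, perkinsus 2)
  9 sub-clades: 1a 1b 1c 2a 2b 2c 3a 3b 3c
representation: 9 sub-clades x 11 species; 6 fully represented
   n_members n_species  full
1a        29        11  TRUE
1b        11        11  TRUE
1c        11        11  TRUE
2a        20        11  TRUE
2b        11        11  TRUE
2c         8         8 FALSE
3a        21        11  TRUE
3b         6         6 FALSE
3c         5         5 FALSE
```

The census recovered all 137 planted members; the tree partitions into the
three generating clades and nine sub-clades; six sub-clades carry all
eleven species; `subclade_accuracy(part, fam$truth)` returns 100. Sequence
logos per sub-clade come from `logo_matrix(m$matrix[ids, ])`, and
composition outliers (the long-branch biased ciliate lineages) from
`composition_chi2(m)`.

A thin command-line front end mirroring these stages ships in
`inst/scripts/capclade.R`
(`Rscript inst/scripts/capclade.R census --queries q.faa --db db.faa ...`).

## Scope notes

The phylogeny stage is a desk-scale distance pipeline (NJ + bootstrap +
fixed-topology LG+Γ scoring), not a maximum-likelihood topology search;
bootstrap percentages from large published ML analyses are not expected to
be matched numerically. Readers for FASTA, Newick, NEXUS (TreeBase
dialect, TRANSLATE tables, interleaved matrices) and TSV are included so
the same machinery applies directly to deposited alignments and trees.
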