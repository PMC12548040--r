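---
title: "Reconstructing and comparing B cell clonal lineage trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and comparing B cell clonal lineage trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrforest)
```

## The model

During an immune response, B cells descending from a single V(D)J
recombination event diversify by somatic hypermutation (SHM) while
competing for antigen. bcrforest represents each such clonotype as a
germline-rooted lineage tree: the root is the unmutated germline
reference, every other node is a unique observed receptor sequence
(optionally a CDR3-only or otherwise region-restricted view), and edge
weights are sequence distances or inferred substitution counts. Unlike a
classical phylogeny, observed sequences may sit at internal positions and
nodes may have any number of children — ancestors are routinely sampled
alongside their descendants in repertoire data, and one variant can seed
many.

## Tree construction

Five algorithms build a tree from a clonotype:

* **default** — iterative minimum-distance attachment: starting from the
  germline, repeatedly attach the outside node with the globally smallest
  distance to any node already in the tree. This is Prim's construction,
  so its total weight always equals the minimum spanning tree's; what the
  tie-break changes is *which* optimal tree is returned.
* **mst** — a germline-rooted minimum spanning tree of the complete
  distance graph.
* **nj** — neighbor joining with inferred internal ancestors, re-rooted
  at the germline leaf. Negative branch lengths are clamped to zero with
  the deficit moved to the sibling branch, keeping weights valid for
  downstream metrics. Below four taxa the agglomeration is degenerate and
  variants attach directly to the germline.
* **mp** — maximum parsimony: Fitch small parsimony scored over
  topologies, searched by nearest-neighbor interchange (NNI) from the NJ
  start tree, or exhaustively for up to 7 leaves (provably optimal). Edge
  weights come from a deterministic Fitch traceback that retains the
  parent state on ties; inferred nodes receive the traceback sequences.
* **ml** — maximum likelihood under JC69 or K80 (base frequencies 1/4,
  no rate heterogeneity), likelihood by Felsenstein pruning, branch
  lengths optimised coordinate-wise by bounded 1-D search (tolerance
  1e-6), topology by NNI. K80 with kappa = 1 reduces exactly to JC69.
  Richer substitution models (including antibody-specific ones) are
  supported by importing externally computed trees in Newick format
  rather than re-implementing them.

Distances are computed on nucleotide sequences: Hamming for pre-aligned
sets (the ambiguity code `N` matches any base by default, so sequencing
uncertainty does not inflate distances; configurable) and Levenshtein for
unequal lengths. The default algorithm compares raw, not
length-normalized, distances.

### Tie-breaking

Minimum-distance construction frequently ties on discrete distances. The
tie-break criterion first restricts the candidate parents: `breadth`
(most current descendants), `depth` (fewest), `mutational_load_min`/
`_max` (path weight from the germline), `expansion_max`/`_min` (cell
count). Because several parents can still tie, a lexicographic fallback
on child-then-parent id makes every run reproducible; `random` instead
draws uniformly among tied pairs under a mandatory seed. The ordering
(criterion first, lexicographic last) was an open design point; we chose
it so that the named biological criteria always dominate the arbitrary
fallback.

## Internal-node handling

Phylogenetic methods introduce inferred ancestors (MRCAs). In antibody
repertoires these are often themselves sampled — appearing as inferred
nodes with zero branch length to an observed terminal — or represent
unsampled cells. Three removal modes convert bifurcating output into
multifurcating lineage networks: `zero_length_only` merges inferred nodes
with a zero-length sampled terminal (preserving mutational ordering;
iterated to a fixed point, hence idempotent; when two terminals tie at
zero length the higher-cell-count one merges and the event is logged);
`replace_by_closest_descendant` substitutes each inferred node by its
nearest sampled descendant bottom-up (favors depth; ties broken by cell
count then id); `link_to_parent` deletes inferred nodes and re-attaches
every sampled node to its closest sampled ancestor at the connecting path
weight, exactly preserving germline path weights (favors breadth).
Because the mode changes the apparent trajectory, it is stamped into the
tree and comparisons refuse mixed-mode inputs unless explicitly allowed.

## Quantifying topology

`compute_tree_metrics()` reports node/leaf counts, depths in both edge
counts and cumulative edge weight (the field uses both conventions, so
both are emitted), out-degrees, and the Sackin index (sum of leaf depths
in edge counts — the classical unweighted definition; the weighted depth
is available separately). Two size-normalized summaries (Sackin per leaf,
mean/max depth ratio) are included so that lineages of different sizes
compare on branching pattern.

The Laplacian spectral density uses the modified graph Laplacian
`M = Diag(rowSums(P)) − P` with `P` the patristic distance matrix over
*all* nodes (root and inferred included). Its eigenvalues are summarised
by the principal eigenvalue (lineage richness), and by the sample
skewness (asymmetry; deep vs shallow branching) and sample excess
kurtosis (peakedness; imbalance) of the natural-log-transformed positive
eigenvalues. The density itself is a Gaussian KDE with Silverman's
rule-of-thumb bandwidth; the moments are deliberately computed on the
ln-eigenvalue sample rather than the KDE grid so they do not depend on
grid resolution. Zero-weight edges are nudged to 1e-9 and eigenvalues
within 1e-8 of zero are treated as the structural zero.

## Comparing trees

The generalized branch length distance (GBLD) between two
germline-rooted trees normalizes each tree's branch lengths to sum to 1
and returns `P + W`: `P` is one minus the Jaccard overlap of the sampled
(non-germline) label sets, and `W` is the mean absolute difference of
normalized germline-to-node path weights over shared labels (0 over an
empty shared set, since `P` already saturates at 1). This concrete
operationalization — overlap plus root-path differences — is frozen by
the test suite; per-edge rather than root-path weighting is a plausible
alternative reading of the quantity and would be introduced behind a
versioned flag rather than by silently changing results. GBLD is
symmetric, zero on identical trees, scale-invariant and bounded by 2.

`robustness_report()` rebuilds one clonotype with several construction
methods (after a common removal mode) and reports the mean off-diagonal
GBLD; `compare_identical_sequences()` reports directed-edge Jaccard and
per-node parent agreement for trees over the same sequences (these two
measures differ: for a 3-variant star vs chain the former is 1/5, the
latter 1/3); `compare_across()` z-scores the metric matrix (constant
columns dropped), clusters by average-linkage on Euclidean distances and
returns a 2-D principal-component embedding — both steps deterministic.

## Protein-language-model likelihoods

The package consumes per-residue likelihood matrices exported by any PLM
(one CSV per node, or one long-format CSV); no model code runs here, so
identical inputs from any model give identical results. The
pseudolikelihood of a sequence is the **mean** (not sum) log-probability
of the observed residue per position, making values comparable across
variant lengths; probabilities are floored at 1e-12 because PLM exports
sometimes contain zeros, and rows off by up to 1e-3 from unit sum are
renormalized with a warning. Edge profiles classify aligned positions as
mutated or conserved (gap positions are excluded and counted separately)
and score the child residue under both the parent's and the child's
model — which of the two is "right" is not settled, so both are reported.
`likelihood_vs_evolution()` correlates node pseudolikelihood with
weighted germline distance (Spearman and Pearson), omitting trees with
fewer than 3 points or zero variance with an explicit reason. A
column-frequency stand-in scorer (additive smoothing, pseudo-count 1)
provides a deterministic test substrate.

## Structural evolution

Structures are alpha-carbon traces read from PDB files, with the
temperature-factor column interpreted as pLDDT, as structure predictors
emit it; CA-only geometry is robust to side-chain noise at this scale.
RMSD uses least-squares superposition (Kabsch/SVD, reflections
disallowed) over positionally mapped residues — predicted models carry
arbitrary author numbering, so alignment position, not residue number,
defines correspondence. Biophysical summaries are mean Kyte–Doolittle
hydropathy and integer net charge at neutral pH ((K+R) − (D+E),
His = 0); pKa-based charge requires external tools and is out of scope.
Antibody–antigen interfaces are CA pairs within 5.0 Å (a common coarse
contact cutoff; configurable). Lineage reports correlate edge RMSD with
edge mutation count and node RMSD-to-germline with germline distance,
skipping and listing nodes without structures.

## The simulator

`simulate_lineage()` generates ground-truth clonal lineages: a uniform
random germline (default 300 nt), a Poisson branching process (mean 1.5
offspring/node, 4 generations), Binomial(L, 0.01) substitutions per
edge, 80% sampling, geometric cell counts (mean 3) and one-way isotype
switching IgM→IgG→IgA (probability 0.3 per generation). A central
codon-aligned 30 nt window is annotated as the junction, standing in for
the CDR3. All draws come from one seeded stream, so output files are
byte-reproducible. `simulate_structures()` adds synthetic "predicted"
structures: an ideal helix-like CA trace whose residues are displaced
once per mutation event in a random direction, with the displacement
inherited by all descendants — so structural divergence accumulates
along the lineage exactly as mutations do — and seeded pLDDT values in
[60, 95].

What the simulator does *not* emulate: AID hot-spot motifs, selection,
indels (substitution-only SHM keeps every cross-module fixture
alignment-free; indels are a flagged extension), real isotype-switching
biology, or any feature of real predictor error. Passing tests therefore
demonstrate algorithmic correctness on known ground truth, not
performance on real repertoires.

## Problem sizes and numerical choices

The test and verification suites run at desk scale, chosen so each suite
completes in well under two minutes: 6-node matrices for exhaustive
spanning-tree enumeration (Cayley count 1,296), 4–5 taxa for additive NJ
recovery, 6-leaf alignments for NNI-vs-exhaustive parsimony (105
topologies), 10-point sets for superposition checks, and simulated
lineages of roughly 5–30 variants elsewhere. Branch-length optimisation
runs to 1e-6; Newick round-trips are checked to 1e-9; zero-length
tolerance is 1e-9 throughout.

## Limitations

No bootstrap support, GTR/codon or antibody-specific substitution models
(import trees via Newick instead); no germline reconstruction from V/J
references; no 10x contig parser (convert to AIRR first); no mmCIF, 3Di,
free-energy or pKa computations; no statistical testing of
cluster–metadata association. Paired heavy/light chains are analysed by
concatenation with a recorded breakpoint; how to weight per-chain
contributions when only one chain differs is an open question we resolve
by simple concatenation.
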