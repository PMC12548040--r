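# bcrforest

Infer and compare B cell clonal lineage trees from immune-repertoire
sequencing data.

B cells descending from one V(D)J recombination event (a *clonotype*)
diversify by somatic hypermutation relative to an unmutated germline
reference. `bcrforest` reconstructs each clonotype as a germline-rooted,
multifurcation-capable lineage tree — nodes are unique receptor
sequences, edges their clonal relationship — and quantifies evolution
within and across repertoires. It is written for immunologists and
computational biologists working with AIRR-format single-cell or bulk
BCR data.

## What it computes

* **Tree construction** from a distance matrix (iterative
  minimum-distance attachment with configurable tie-breaking; a
  germline-rooted minimum spanning tree; neighbor joining with inferred
  ancestors) or from an alignment (Fitch maximum parsimony with NNI or
  exhaustive search; maximum likelihood under JC69/K80 with pruning and
  branch-length optimisation). Externally built phylogenies import via
  Newick; trees export to Newick and GraphML.
* **Internal-node handling**: three algorithms converting bifurcating
  phylogenies into multifurcating lineage networks (merge zero-length
  inferred/terminal pairs; replace by closest descendant; link to
  sampled ancestor with path weights preserved).
* **Topology metrics**: depths, out-degrees, Sackin imbalance
  `S = Σ_leaves depth(leaf)`, and the Laplacian spectral density of the
  patristic-distance Laplacian `M = Diag(rowSums P) − P`, summarised by
  the principal eigenvalue λ\*, asymmetry (skewness) and peakedness
  (excess kurtosis) of the ln-eigenvalues.
* **Tree comparison**: the generalized branch length distance
  `GBLD = P + W ∈ [0, 2]` (label-overlap penalty plus mean normalized
  root-path difference), construction-method robustness reports,
  edge-agreement reports, and deterministic clustering/PCA over metric
  matrices.
* **PLM likelihoods**: attach per-residue likelihood matrices exported
  by any protein language model, compute per-sequence pseudolikelihoods
  (mean log-probability per position), profile mutated vs conserved
  residues along edges, and correlate likelihood with distance from the
  germline.
* **Structural evolution**: CA-trace PDB input with pLDDT in the
  B-factor column, Kabsch-superposition RMSD, Kyte–Doolittle
  hydropathy and net charge, antibody–antigen interface detection, and
  lineage-level RMSD/mutation correlations.
* **A seeded SHM simulator** producing AIRR TSV, FASTA, truth JSON and
  synthetic structures with full ground truth, used throughout the test
  suite.

## Worked example

```r
library(bcrforest)

cfg <- simulation_config(seed = 7, generations = 3, branching_rate = 2,
                         mutation_rate = 0.02, sampling_fraction = 1)
sim <- simulate_lineage(cfg)
cl <- sim$clonotype
cl
#> <clonotype> 'clonotype_1': 5 variant(s), 13 cell(s), germline 300 nt

tree <- build_lineage(cl, method = "default", metric = "hamming")
tree
#> <lineage_tree> 6 nodes (1 germline, 5 sampled), root 'germline'
#>   info: method=default, tie_break=none, clonotype_id=clonotype_1

parent_recovery(sim, tree)
#> [1] 1

m <- compute_tree_metrics(tree)
c(sackin = m$sackin, max_depth_subs = m$max_depth_weighted,
  lambda_star = round(m$lambda_star, 2))
#>      sackin max_depth_subs    lambda_star
#>           6             20         109.75

robustness_report(cl, methods = c("default", "mst", "nj"))$robustness
#> [1] 0.1956
```

The simulated clonotype has 5 unique variants over 13 cells; the default
reconstruction recovers every true parent (`parent_recovery = 1`) since
sampling was complete and all pairwise distances distinct. The deepest
variant sits 20 substitutions from the germline; the Sackin index of 6
reflects a shallow, star-ish expansion. The mean GBLD of 0.196 across
the three distance-based methods says the topology is moderately, not
perfectly, stable under method choice — typical when discrete distances
tie.

A thin command-line wrapper over the same functions ships in
`inst/cli/forest.R` (`simulate`, `build`, `metrics`, `compare`
subcommands; run it with `Rscript`). All coordinates anywhere in the
package are 0-based, half-open.

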