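---
title: "Methods: structure-first fold expansion and mutation-tolerance profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-first fold expansion and mutation-tolerance profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trefoilscan)
```

## The problem

The β-trefoil fold — three similar β-β-β-loop-β lobes arranged with
pseudo-threefold symmetry, ~150 residues — recurs across functions
(cytokines, growth factors, lectins, toxins, inhibitors) and across
kingdoms at sequence identities far too low for sequence search to connect
them. A fold-expansion survey therefore works structure-first: superpose
candidate structures onto trefoil representatives, keep hits by
superposition quality and coverage, classify which domain architectures are
new, and ask how tolerant the fold is to mutation by profiling a
structure-anchored alignment. `trefoilscan` implements that pipeline and a
synthetic-data generator that plants every signal the pipeline is supposed
to detect, so each stage can be validated quantitatively.

This vignette documents the models, parameters and numerical choices, and
what the synthetic validation does and does not establish.

## Filtering model

A structure-search hit is kept iff

* `rmsd < rmsd_max` (strict), and
* `aligned_length / query_length >= coverage_min` (inclusive).

The two presets are `iteration1` (2 Å, 80 %) and `iteration2` (3 Å, 30 %).
The mixed strictness is deliberate: the operational filter commands these
thresholds come from compare rmsd with `<` and coverage with `>=`, and the
boundary matters in practice — a hit at exactly 30 % coverage passes, a hit
at exactly 3 Å does not. Coverage is always computed against the query
length; target-length coverage is out of scope. Rows with a non-positive
query length are data errors: they are rejected and counted per row rather
than aborting a run.

Kingdom assignment scans the `;`-separated lineage ranks in order against a
fixed vocabulary (bacteria; fungi; metazoa; viridiplantae/plantae/
streptophyta/chlorophyta; a set of protozoan phyla), falling back to
`unknown`, which keeps the mapping total without guessing.

## Structural kernel

`kabsch()` computes the least-squares proper rotation via SVD of the 3×3
cross-covariance matrix, with the determinant forced to +1 — protein
backbones are chiral, so reflections are never admitted. Near-collinear
inputs are flagged (`degenerate = TRUE`) and still return the optimal rmsd;
the rotation about the degenerate axis is arbitrary. The test suite checks
the implementation against an independently coded quaternion closed form
(Horn's 4×4 key matrix) to 1e-8, and against 100 random rigid transforms
per case for optimality.

`align_structures()` is a deliberately small stand-in for production
structure-search engines, used so the pipeline runs end-to-end without
external services. It alternates (i) Kabsch superposition on the current
correspondence and (ii) extraction of a new monotone correspondence by
dynamic programming on the inter-structure Cα distance matrix with score
`dist_cutoff − d_ij`; cells with non-positive score cannot be matched and no
gap penalty is applied, which mimics distance-cutoff structural aligners.
`dist_cutoff` defaults to 5 Å, the conventional fold-level contact scale.

Seeding needs care on a pseudo-symmetric chain: the three lobes (and, for
locally regular backbones, even small register shifts) produce fragment
pairs that superpose almost as well as the true register. The aligner
therefore collects the best fragment pair per register offset, screens the
best twelve offsets with a single superpose-and-DP pass, and fully refines
the three candidates with the most matches, returning the longest (ties:
lowest-rmsd) alignment. Non-convergence within `max_iter` returns the best
correspondence seen with `converged = FALSE`.

`reference_msa()` builds the structure-based multiple alignment as a star
alignment: every member is aligned pairwise to one reference and stacked,
one column per reference residue. A star alignment is reproducible and
independent of input order given the reference — a progressive-tree
alternative would introduce order and guide-tree dependencies without
changing what the downstream entropy profile measures. Residues of a member
not matched to any reference position are dropped and counted in the
report; members below a coverage floor (default 0.5) are excluded and
listed.

## Synthetic study conditions

`simulation_config()` fixes the study conditions; the defaults are the
conditions under which the acceptance checks run and are not tuned per
test:

* 64 taxa, 150 columns, 7 planted core positions (drawn once per seed);
* random topology (`ape::rtree`) with i.i.d. exponential branch lengths,
  mean 0.1 substitutions/site;
* uniform 20-state replacement at rate 1 per site per unit branch length;
* isotropic Cα noise evolving as Brownian motion along the tree, variance
  `structure_noise_scale²` (default 1.5²) per unit of expected per-site
  divergence on each branch;
* gaps i.i.d. per cell at 5 %, never at core columns; a gapped residue is
  also removed from that taxon's structure, so structure-based alignment
  re-creates the gap pattern.

Two considerations fixed the branch-length scale. Free columns must
essentially never be monomorphic across 64 taxa, otherwise "zero entropy"
would not single out the planted core: total expected substitutions per
column ≈ 126 edges × 0.1 × 1 ≈ 12, so the chance a column sees no change is
e⁻¹² ≈ 6×10⁻⁶. At the same time pairwise identities must span a wide range
(roughly 0.1–0.9 here) so the rmsd-identity coupling has dynamic range.

The coordinate noise is tree-correlated rather than independent per taxon.
Independent noise with scale proportional to divergence fails to reproduce
the inverse rmsd-identity coupling reliably: two deeply diverged sister
taxa are nearly identical in sequence yet each carries large independent
noise, so their pairwise rmsd is large — in pilot runs the Spearman ρ was
below −0.5 in only about two-thirds of replicates. With Brownian motion
along the tree the structural displacement between two taxa accumulates
with the tree path separating them, exactly as their sequence divergence
does, and ρ is reliably near −0.9. A taxon's marginal deviation from the
template still grows with its divergence.

The template trace (`make_template_structure()`) places three near-copies
of one lobe (0.15 Å jitter) at 120° around an axis. Each lobe is a compact
serpentine bundle of radial strands, echoing a β-hairpin bundle: compactness
matters because short-fragment superposition only pins the global frame of
a structure whose extent is comparable in all directions, and irregular
strand lengths keep local geometry position-dependent. The trace is
self-avoiding by construction (non-adjacent Cα pairs > 3 Å).

### Labels and the two core modes

Kingdom labels follow the four deepest clades of the true tree, so the
background (free-column) divergence is kingdom-structured. Function labels
are assigned round-robin along the tip order — orthogonal to the tree, the
situation a convergently evolved functional site would produce.

The planted core has two wirings:

* `core_signal = "invariant"` (default): one residue type per core column
  across all taxa — exactly zero entropy. This is the mutation-tolerance
  condition: the 7 planted columns are the entropy minimum, and bottom-k
  selection must recover them.
* `core_signal = "function"`: each function group carries its own signature
  residue at every core column (entropy = 2 bits at 4 equal groups). This
  is the clustering condition: a tree built from the 7 core columns alone
  separates the function groups perfectly, while the full gap-filtered
  alignment clusters by kingdom. Note the two conditions are deliberately
  separate: on a clade-heavy tree some background columns fall below 2 bits,
  so function-coded cores need not be the global entropy minimum.

## Conservation analytics

Columns with gap fraction ≥ 10 % are removed before profiling, so entropy
is not confounded with alignment coverage. Entropy is reported in bits
(log base 2); the base is a monotone rescaling and changes no ordering.
Gaps are excluded from the probability mass rather than treated as a 21st
symbol — after the 10 % filter the difference is minor, and exclusion keeps
"variability" about residues, not about coverage. All-gap columns are an
error carrying the column index. Low-entropy selection offers both a
threshold mode and bottom-k with deterministic tie-breaks (lower original
column index first); the pipeline's defaults follow the 9-candidates-then-
7-core shape, both exposed as parameters because no principled universal
threshold exists.

## Phylogenetics

Distances are p-distances over pairwise comparable (both non-gap) columns;
pairs with no comparable columns are flagged and imputed at the matrix
maximum rather than silently zeroed. Trees are built by neighbor joining —
deterministic given the stated tie-break (lexicographically smallest pair
of cluster labels on Q ties), exact on additive matrices, and simple enough
to verify against an exhaustive least-squares topology oracle at five taxa.
Negative branch lengths are clamped to zero with the removed deficit
recorded. Maximum-likelihood methods would add model choices without
serving the purity comparison any better.

Clade purity cuts the k−1 longest internal branches (ties broken
deterministically) and scores the fraction of leaves matching their group's
plurality label. `k = 4` matches the number of planted function groups and
deep clades. The `k = leaf count` case returns the singleton partition
directly; between that and `k − 1 >` (number of internal branches) the
function errors, since only internal branches are cut. The package reports
purity numbers only; whether clustering-by-function indicates convergent
evolution is an interpretation outside the code's scope.

## Pipeline determinism and problem sizes

Every stochastic step routes through one seed (`with_seed()` restores the
caller's RNG state), and `run_pipeline()` reruns bit-identically for a
fixed config. The analysis drivers and acceptance script use 64-taxon
families (the study condition) for sequence-level stages; the quadratic
structure-MSA stage runs on a 24-member subset in the drivers and the test
suite uses 6–16-member families at 60–90 residues, sizes chosen to keep a
full validation run in the low minutes while leaving every statistical
check comfortably powered.

## Known limitations

* The generator's evolution model is intentionally minimal: uniform
  replacement, no rate matrices, no indel histories (gaps are i.i.d.
  per cell), no secondary-structure constraints. Passing tests show the
  pipeline detects planted signals under these idealized conditions; they
  do not certify performance on real structure-search output, where noise
  is neither isotropic nor tree-Brownian and alignments carry systematic
  error.
* `align_structures()` trades accuracy for transparency; it is not a
  competitor to production aligners and has no significance statistics
  (no Z-scores, no E-values).
* Domain identity is name-equality on annotation tables; no HMM scanning
  is performed, and trefoil domain boundaries must be given as input.
* The DALI-dialect parser pins the summary-table field mapping
  (field 3 = rmsd, field 4 = aligned length) and rejects other layouts
  loudly rather than guessing.
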