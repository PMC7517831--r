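---
title: "Ensemble virtual screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble virtual screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleVS)
```

## The problem

A single crystal structure is a snapshot of a flexible receptor. Docking a
compound library against one snapshot biases the screen toward ligands that
fit that particular conformation. Parallel (ensemble) virtual screening
instead docks against several representative conformations, validates each
one independently, and fuses the per-structure evidence — docking scores and
pharmacophore fit values — into a single re-scoring classifier. ensembleVS
implements that workflow end to end for any kinase-like target: the binding
sites of an ensemble of receptor–ligand complexes are clustered, per-structure
docking score tables (from any external engine) are validated, complex-based
pharmacophore models are generated and scored, and a Laplacian-corrected
naive Bayes classifier combines everything before a tiered screening funnel
with drug-likeness filters produces the final candidate list.

Docking itself is deliberately out of scope: the package consumes score
tables, which keeps the pipeline engine-agnostic and testable without
commercial software.

## Binding-site clustering

Sites are extracted as all residues having a heavy atom within 10 Å of any
ligand heavy atom (hydrogens are ignored in the distance test; alternate
locations keep altloc ' '/'A'). Because all ensemble members are the same
protein, residue correspondence is simply the intersection of residue keys,
and superposition is ordinary least-squares Kabsch fitting on shared
C-alpha atoms — a full multiple structural alignment would only be needed
for non-identical sequences. Reflections are excluded (the rotation always
has determinant +1), so a chiral site can never be "fitted" to its mirror
image.

The pairwise RMSD matrix is clustered by UPGMA (average linkage). The tree
module of the visualization tool used in the original protocol does not
document its algorithm, so the method is fixed here to UPGMA and both the
matrix and the Newick tree are exported, making it easy to substitute
another linkage. Node heights use the ultrametric convention (two leaves at
distance d merge at height d/2; the cophenetic distance between them is d).
The number of clusters k is a parameter (default 8) because no cut rule is
implied by "the ensemble falls into eight types"; within each cluster the
structure with the numerically smallest (best) resolution is the
representative, with lexicographic id as the deterministic tie-break.

## Benchmark construction

Validation sets pair known actives with presumed-inactive decoys at a fixed
ratio (default 1:20, i.e. 800 actives with 16,000 decoys at the scale the
workflow was designed around). Records are deduplicated by canonical SMILES
(earliest id wins). Decoys are chosen by MaxMin diversity picking on ECFP4
circular fingerprints (radius 2; OpenBabel's 4096-bit implementation) with
Tanimoto distance: the first pick is seeded, every later pick maximizes the
minimum distance to the current selection, and ties break by lexicographic
id so a seed fully determines the set. Actives are removed from the decoy
candidate pool by canonical structure before selection to prevent label
leakage. No attempt is made to property-match decoys to actives
(DUD-E-style matching is a different design with different biases).

## Docking validation

Two properties of a docking setup are checked per structure:

* **Scoring power** — the re-docked pose of the co-crystallized ligand must
  reproduce the crystallographic conformation: heavy-atom RMSD ≤ 2.0 Å,
  inclusive. The RMSD is computed in the receptor frame without
  re-superposition (the pose is already in the receptor's coordinate
  system), and may be symmetry-corrected: the minimum over all graph
  automorphisms of the element-colored molecular graph (VF2 enumeration),
  so a benzene ring rotated by 60° scores 0 rather than ~2.8 Å.
* **Screening power** — a Welch two-sample t-test (two-sided,
  Welch–Satterthwaite degrees of freedom) between active and decoy score
  distributions. Welch's form is used because group sizes are strongly
  unbalanced (e.g. 800 vs 16,000) and variance equality cannot be assumed.
  Degenerate inputs are handled explicitly: two identical constant groups
  report t = 0, p = 1 with a warning rather than an error.

Per structure, the docking mode (SP or XP) whose distributions separate more
strongly — the smaller p-value — is carried forward; ties go to XP. The
protocol literature phrases this as choosing the mode with the "higher"
p-value while bolding the smaller ones; we read that as higher significance,
and expose `prefer = "larger_p"` for the literal reading.

## Complex-based pharmacophores

Ligand features are perceived by simple, documented rules: donors are N/O
bearing a hydrogen; acceptors are N/O with non-positive formal charge (so a
hydroxyl is both); hydrophobic centers are centroids of connected groups of
two or more apolar carbons; ring-aromatic centers are aromatic ring
centroids (rings are aromatic when all bonds are MDL type 4 or a six-ring of
C/N alternates single/double); charged centers collapse carboxylates to the
COO centroid. Aromaticity and protonation perception is intentionally
minimal — inputs are expected to carry explicit charges and reasonable bond
orders, as prepared structures do.

A feature is kept only when the receptor offers a complement: a polar
receptor heavy atom within 3.5 Å for donors/acceptors, at least three
apolar receptor carbons within 4.5 Å of a hydrophobic or aromatic centroid,
and an oppositely charged receptor group within 5.5 Å for ionizable
features. These are standard hydrogen-bond and contact ranges and are
configurable. Hydrogen-bond angle criteria are omitted by default: the
information needed to justify a particular angular cutoff is not available
in score-table-level inputs, and distance-only filters are transparent.

All subsets of the complemented features with at least `min_features`
(default 3) members are enumerated (the complemented set is capped at 12
features) and ranked by a selectivity score. The proprietary
regression-based selectivity score of the original tooling is unpublished,
so selectivity is defined here as empirical rarity against a background
library: `-log10(max(m, 0.5) / N)` where m of N background molecules match
the model. A model everything matches scores 0; rarer is higher; the 0.5
floor keeps never-matched models finite. The surrogate preserves the intent
of a selectivity score — rank models by how hard they are to satisfy by
chance — without claiming to reproduce externally fitted coefficients. The
top 10 models are returned, ties broken by fewer features then lexicographic
letter code, so the ordering is a total order and runs are reproducible.

Fit values map a molecule onto all features of a model: over every conformer
and every type-compatible injective assignment, matched centers are
superposed (Kabsch) and per-feature displacements d computed; the assignment
is valid iff every d ≤ tolerance (default 1.6 Å), and the fit is
`sum(w * (1 - d / t))` — linear displacement penalty, with a squared variant
behind a flag since the reference implementation's exact formula is
unpublished. The fit is bounded by the weight sum, attained exactly at
perfect coincidence; only the relative ranking of fit values matters
downstream because the NB layer discretizes them. Discrimination of each
model is summarized by the rank AUC of its fit values on a labeled set,
with AUC > 0.7 as the acceptability gate.

## Naive Bayes fusion

The descriptor matrix X holds the chosen per-structure docking scores and
the fit values of the gated models; Y is the 0/1 inhibitor label. Each
continuous column is discretized by equal-frequency binning (default 10
bins, frozen at training time); missing values get a reserved bin because a
failure to dock is informative, not ignorable. Each (column, bin) event F
receives the Laplacian-corrected weight

    w_F = ln((A + 1) / (B * p + 1))

with A = actives showing F, B = all training rows showing F, and
p = N_active / N the base rate. This is the standard stabilization obtained
by adding K = 1/p virtual samples at the base rate: an event never seen in
training (A = B = 0) contributes ln(1) = 0, and an event present at exactly
the base rate (A = B p) is also weightless. A compound's score is the sum of
its per-column weights — monotone in the posterior log-odds under the
independence assumption. Ranking quality is measured by rank-based
(Mann–Whitney) AUC with midrank ties.

Both apparent (train = test) and stratified cross-validated AUC are
available; the apparent figure is what single-set protocols report, the
cross-validated one is the honest generalization estimate, and the package
reports them separately rather than choosing.

## The screening funnel

Stage sizes default to 10,000 → 2,000 → 100 from a screening library of any
size (the workflow was designed around ~2,000,000 compounds). Stage 1 ranks
by docking score aggregated across structures; "best" (minimum) is the
default aggregation because the protocol ranks compounds by their best
docking score across the ensemble, with mean and rank-sum as alternatives.
Stage 2 re-ranks survivors by best fit value over the selected models,
stage 3 by NB score, and stage 4 applies Lipinski (MW ≤ 500, logP ≤ 5,
HBD ≤ 5, HBA ≤ 10; zero violations by default, one allowed behind a flag)
and Veber (rotatable bonds ≤ 10, TPSA ≤ 140 Å²) filters. All ties anywhere
break by lexicographic compound id, making the whole funnel bit-identical
across runs. The manual purchasing step that reduced the final 100 to 50 in
the original campaign is human judgement and is not modeled.

MW, logP and TPSA come from OpenBabel (atom-contribution logP; provenance is
recorded because absolute logP differs across estimators); Lipinski's
donor/acceptor counts use the classic OH+NH and N+O definitions; rotatable
bonds are counted on the package's own molecular graph (acyclic single bonds
between non-terminal heavy atoms, amide C–N excluded).

## Synthetic fixtures: what they do and do not show

The generators produce three kinds of inputs:

* **Score benchmarks** — Gaussian class-conditional scores per column with
  chosen means and a missing-cell rate. Gaussians are used because the
  ranking AUC has the closed form `pnorm(d / sqrt(2))` for class separation
  d, giving exact targets for tests (e.g. d' = √2 → AUC = Φ(1) ≈ 0.841).
  Defaults are the validation-set scale: 800 actives, 16,000 decoys.
* **Toy complexes** — minimal PDB/SDF pairs with planted feature fragments
  (ether acceptor, hydroxyl donor, ethane hydrophobe, benzene ring,
  acetate, ammonium) whose receptor partners sit at chosen distances, so
  each feature's survival of the complementation filters is known a priori.
  A polar atom is perceived as both donor and acceptor and a benzene ring as
  both aromatic and hydrophobic; the generator's expectation accounts for
  this. Ionic partner offsets should stay above the 3.5 Å H-bond threshold
  so the charged group's oxygens/nitrogens do not also complement as
  acceptors — the defaults (5.0 Å) respect this.
* **Libraries** — curated drug-like and rule-violating SMILES, extended
  with inert suffixes (methylene units, a halogen) for uniqueness. Drug-like
  variants are guaranteed to pass all six filter rules up to the curated
  capacity (an error is raised beyond it); violator variants always fail at
  least one rule by a wide margin.

Passing tests on these fixtures demonstrates that the geometry, counting,
ranking and fusion machinery is correct. They do not demonstrate chemical
realism: toy complexes have no protein fold, Gaussian scores have no docking
physics, and the library spans a tiny slice of chemistry. Conclusions about
a real target still require real structures and a real docking engine.

## Numerical choices and problem sizes

* Kabsch uses SVD with a determinant guard; rank-deficient (collinear)
  covariance falls back to the proper branch.
* Fit-value matching allows a 1e-9 Å slack at the tolerance boundary so
  "exactly at tolerance" is matched with fit 0.
* Model size is capped at 8 features and assignment enumeration at 50,000
  to bound the combinatorial search; automorphism enumeration is capped at
  10,000 mappings.
* Equal-frequency bin cuts merge duplicate quantiles; constant columns
  collapse to one bin with a warning.
* The test suite exercises the funnel at the full 2,000,000-compound scale
  once and at a few-hundred-compound scale elsewhere; statistical tests use
  16,800 to 20,000 rows, matching the validation-set conditions. The
  structure-level diversity selection is tested at the 40-active/800-decoy
  scale, which runs the identical code path as the full 800/16,000
  construction.

## Known limitations

* Feature perception is rule-based and minimal; tautomers, pH-dependent
  protonation and directional hydrogen-bond geometry are not modeled.
* The selectivity surrogate is a rarity estimate, not a reproduction of the
  proprietary regression score; absolute selectivity values are not
  comparable across background libraries of different composition.
* Excluded-volume spheres and flexible receptor features are not supported.
* The NB classifier assumes descriptor independence given the class; heavy
  correlation between structures' scores inflates apparent confidence,
  which is why the cross-validated AUC is worth reporting alongside.
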