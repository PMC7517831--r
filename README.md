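# ensembleVS

Parallel multi-structure (ensemble) virtual screening in R, for
computational chemists prioritizing compound libraries against a flexible
protein target. A single crystal structure biases a screen toward one
receptor conformation; ensembleVS screens against several representative
conformations and fuses the evidence:

1. **Binding-site clustering** — extract the ≤10 Å site around each bound
   ligand, superpose shared Cα atoms (Kabsch), cluster the pairwise RMSD
   matrix with UPGMA, and pick the best-resolution representative per
   cluster.
2. **Benchmark construction** — deduplicate actives by canonical SMILES and
   select decoys at a fixed ratio (default 1:20) by MaxMin diversity picking
   on ECFP4 fingerprints with Tanimoto distance.
3. **Docking validation** — ingest per-structure docking score tables from
   any engine; check *scoring power* (re-dock pose RMSD ≤ 2.0 Å,
   symmetry-corrected over graph automorphisms) and *screening power*
   (Welch t-test between active and decoy score distributions); pick the
   better mode (SP/XP) per structure.
4. **Complex-based pharmacophores** — perceive ligand features (HBA, HBD,
   HYD, NI, PI, RA), keep those with a receptor complement within standard
   interaction distances, enumerate feature subsets (≥3 features), rank by
   an empirical-rarity selectivity score, and compute displacement-penalty
   fit values `Σ w(1 − d/t)` for screening molecules.
5. **Naive Bayes fusion** — discretize the chosen docking-score and
   fit-value columns into equal-frequency bins and train the
   Laplacian-corrected classifier with per-bin weights

   ```
   w = ln((A + 1) / (B·p + 1)),   p = N_active / N
   ```

   (A = actives with the bin, B = all rows with it). Ranking quality is the
   Mann–Whitney AUC; apparent and cross-validated AUC are both available.
6. **Screening funnel** — rank by aggregated docking score, take the top
   10,000; re-rank by best fit value, keep 2,000; re-rank by NB score, keep
   100; apply Lipinski (MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10) and Veber
   (rotatable bonds ≤ 10, TPSA ≤ 140 Å²) filters. Fully deterministic:
   every tie anywhere breaks by compound id.

Synthetic fixture generators (score benchmarks with closed-form AUC, toy
receptor–ligand complexes with planted interaction geometry, curated
drug-like/rule-violating libraries) make the whole pipeline testable with
no commercial software and no downloads.

## Worked example

```r
library(ensembleVS)

# a synthetic labeled benchmark: 800 actives vs 16,000 decoys, two
# receptor structures with separated score distributions
bench <- make_score_benchmark(score_benchmark_spec(
  n_active = 800, n_decoy = 16000,
  columns = data.frame(structure_id = c("S1", "S2"), mode = "XP",
                       mu_active = -8.6, mu_decoy = -7.4, sigma = 1),
  seed = 202))

# screening power of structure S1
act <- bench$scores$scores[bench$labels == 1, "S1.XP"]
dec <- bench$scores$scores[bench$labels == 0, "S1.XP"]
screening_power(act, dec, "S1", "XP")
#> Screening power S1/XP: t = -32.493, df = 877.1, p = 1.18e-152 (n = 800 vs 16000)

# fuse docking scores with a naive Bayes classifier and measure the AUC
dm <- assemble_matrix(scores = bench$scores, labels = bench$labels)
nb <- train_nb(dm, n_bins = 10)
roc_auc(score_nb(nb, dm), dm$label)
#> ROC AUC = 0.8738 (800 actives vs 16000 decoys)
```

The t-test confirms the planted active/decoy separation (actives score more
negative, i.e. better), and the NB classifier turns the two score columns
into a single ranking whose AUC reflects the combined signal.

A thin command line lives at `inst/cli/ensemble-vs.R`:

```sh
Rscript inst/cli/ensemble-vs.R simulate --what scores --seed 4 --out sim
Rscript inst/cli/ensemble-vs.R cluster --pdb-dir structures/ --ligand-map ligands.yaml --k 8 --out ens
```

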