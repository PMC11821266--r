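---
title: "Interrogating dataset bias in binding-affinity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrogating dataset bias in binding-affinity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Machine-learning scoring functions predict the binding affinity of a
protein–ligand complex (as pK = −log10 of Ki, Kd or IC50 in molar) from its
3D structure. On standard benchmarks their apparent accuracy can be inflated
by *dataset bias*: predictive signal carried by ligand identity or pocket
identity alone, exploitable without modelling the interaction at all. A
model that has merely memorized "big hydrophobic ligands bind tighter" or
"kinase-like pockets cluster around pK 7" will look accurate wherever train
and test sets share ligands or pocket families.

sfbias makes that failure mode measurable. It provides:

* **bias-only baselines** that by construction cannot see the 3D
  interaction — any scoring function that fails to beat them has not
  demonstrably learned structure;
* **bias-resistant benchmark splits** that remove specific shortcuts;
* **structural stress tests** (steric-clash translations, RMSD-binned decoy
  poses) that probe whether a model reacts to pose quality at all;
* **bootstrapped metrics** so comparisons carry calibrated uncertainty;
* a **synthetic complex generator** with known ground-truth bias structure,
  so the entire pipeline is testable end to end without any external
  download.

## The bias baselines

All four baselines are random-forest regressors of pK on deliberately
impoverished feature views:

* **LigandBias** — 2D ligand descriptors only. Descriptors are functions of
  the molecular graph and element identities (never 3D coordinates), so
  every conformer and pose of a molecule featurizes identically, and the
  model predicts the same affinity for a ligand whatever protein it is
  bound to. Its accuracy is therefore an estimate of pure ligand bias.
* **ProteinBias** — counts of each amino-acid type in the pocket, defined
  as every residue with any heavy atom within 15 Å of any ligand heavy
  atom. The features carry residue identities but no geometry, so accuracy
  reflects pocket-identity bias.
* **EnsembleBias** — the unweighted mean of LigandBias and ProteinBias
  predictions; it can exploit both biases but can never combine the two
  views inside one model.
* **BothBias** — a single model on the concatenated feature vector
  (ligand block first, then the 21 pocket counts), which can learn
  interactions between the two bias sources but still sees no 3D
  information.

Hyperparameters are selected by cross-validated RMSE (5 folds by default)
over a small documented grid of forest configurations (trees ∈ {200, 500},
mtry ∈ {√p, p/3}, minimum node size ∈ {1, 5}, trimmed by a trial budget),
then the winner is refit on all non-excluded records. A fixed grid was
chosen over an AutoML search deliberately: the selection trajectory is
reproducible from the seed, and the baselines' job is to bound bias, not to
squeeze out the last centile of accuracy. Training is single-threaded and
seeded, so predictions are bit-reproducible.

### Descriptor schema

The ligand descriptor battery is computed from the 2D graph with implicit
hydrogens inferred from default valences (so molecular weight of an H-free
ethanol SDF is still 46.07). The schema is frozen on the training set: any
descriptor producing a non-finite value, or an absolute value above
`overflow_threshold` (default 1e8 — "extremely large" is necessarily a
convention, so it is a parameter), on *any* training ligand is excluded,
with the exclusion and its reason logged. Retained names are sorted, so two
builds on the same ligands serialize byte-identically. At predict time a
failing descriptor is imputed with its training median and a warning; the
model never silently sees a different feature space than it was trained on.

## Benchmark construction

* **Zero ligand bias** — complexes are clustered by identical ligand (full
  27-character InChI-Key: "identical" is read strictly, so stereoisomers
  and salt forms are different ligands). Clusters with at least two members
  whose mean pK lies in [6, 7] (inclusive endpoints) and whose sample
  variance (n−1 denominator) exceeds 1 (strictly) form the test set.
  Centering the means removes the trick of scoring clusters by their
  average; requiring spread means a per-ligand constant prediction cannot
  correlate with the test labels. Records sharing an InChI-Key with the
  test set are also dropped from the train side — leaving them in would let
  a ligand-memorizing model see the test ligands during training, which is
  exactly what the benchmark exists to prevent (the exclusion is
  toggleable and recorded in the split's rule metadata).
* **Peptide holdout** — ligand codes containing "MER" (case-insensitively:
  component codes are conventionally upper case but files vary) mark
  peptide ligands; they are held out wholesale. Scoring them well requires
  generalization from small molecules to peptides.
* **Time split** — complexes deposited in the cutoff year *or later*
  (inclusive; default 2019) are the test set. Records with no year are
  excluded from both sides and reported rather than guessed.

Every split is checked by a generic validator: train/test disjointness,
coverage accounting (train + test + excluded = dataset), and the rule
predicate recomputed on every test member.

## Structural stress tests

* **Clash series** — the ligand is translated rigidly into the protein
  along the unit vector from the closest ligand heavy atom to the closest
  protein heavy atom, 1 Å at a time for ten steps. The direction is
  computed once from the unperturbed complex; exact distance ties break on
  the lowest (ligand index, protein index) pair so the construction is
  deterministic. Because the motion is a rigid translation, the in-place
  RMSD of pose k is exactly k·step and all interatomic distances are
  preserved — both are asserted to 1e-9 in the tests.
* **RMSD binning** — candidate poses are binned by in-place RMSD to the
  crystal pose using edges 0–1, 1–2, 2–4, 4–6, 6–8, 8–10, 10–15, 15–20,
  20–25, 25–30 Å. Bins are half-open [lo, hi) with the last bin closed at
  30: the printed ranges are ambiguous at the boundaries and a fixed
  convention prevents a pose being assigned twice. Within each bin the pose
  closest to the bin midpoint is selected (ties to the lowest pose id);
  empty bins stay empty. RMSD is computed without superposition — pose
  accuracy is positional — over matched atom orders; symmetry-corrected
  RMSD (e.g. for flipped aromatic rings) is out of scope in this version
  and would shift borderline bin assignments for symmetric ligands.

## Metrics

Accuracy is reported as Pearson's R, the coefficient of determination
R² = 1 − SS_res/SS_tot (not the square of Pearson R; it can be negative),
and RMSE, each with a percentile bootstrap confidence interval: pairs are
resampled with replacement (10 000 draws by default) and the 2.5%/97.5%
quantiles of the resampled metric form the 95% interval. The point estimate
is always the full-sample metric, never the bootstrap mean. The percentile
method was chosen over BCa because it is cheap, deterministic and adequate
at the sample sizes involved. Resamples on which a metric is undefined
(zero variance) are redrawn rather than dropped, keeping the effective
number of resamples fixed; the redraw count is reported. Zero variance in
the full sample raises an undefined-metric error that report tables render
as NA — never silently as 0.

Report tables flag, per benchmark and metric, the best cell (highest
Pearson R or R², lowest RMSE) and every cell whose interval overlaps the
best cell's interval ("tied"). Interval overlap was chosen over
"best interval contains the other point" as the tie rule; it is the more
conservative reading and is recorded in the report so it can be flipped.
The "point ± half-width" label uses the larger half-width when the interval
is asymmetric; exact bounds are always emitted alongside.

## The synthetic generator

The generator emulates exactly the statistical structure the baselines
exploit, and nothing else:

* **Ligands** come from a built-in curated list of 40 drug-like molecules
  (3–41 heavy atoms), converted from line notation with deterministic
  compact 3D coordinates. Each molecule's fixed `ligand_effect` is a
  centered, scaled heavy-atom count, so ligand identity carries a
  recoverable size-like signal.
* **Pockets** are geometric residue scatters, not folded proteins: rigid
  N–CA–C templates placed 5–11 Å from the ligand centroid (safely inside
  the 15 Å shell), with optional distractor residues beyond 15 Å but
  within 30 Å. The construction guarantees that pocket featurization at
  threshold 15 recovers the requested composition exactly (verified at
  generation time, with placement retries). Each pocket's fixed
  `pocket_effect` is a hydropathy-weighted sum of its composition.
* **Labels** follow pK = base + α·ligand_effect + β·pocket_effect +
  N(0, σ²), with Gaussian noise in pK space, matching the regression
  target's scale. Defaults — 500 complexes, library of 40, duplicate-ligand
  fraction 0.5, α = β = 1, σ = 0.3 pK, base 6, years uniform on 2010–2022,
  10% peptide-coded ligands — were chosen once to give pK values spanning
  roughly 2–11 with signal-to-noise typical of curated affinity data, and
  to make every split builder exercisable.
* The **zero-bias testbed** plants identical-ligand clusters with
  controlled mean (inside [6, 7]) and spread (variance > 1, produced by
  pocket differences; α must be 0 so ligand identity cannot explain the
  spread), against background complexes whose ligand groups deliberately
  fail the filter while covering pK 3.5–9.5 so pocket-view models can be
  trained off-testbed.
* **Decoy poses** are centroid-centered rigid rotations plus translations.
  Rotating about the centroid makes the in-place RMSD decompose exactly as
  rmsd² = rmsd_rot² + |t|², so the translation magnitude supplies the
  exact remainder and realized RMSDs hit their targets to floating-point
  precision.

What the generator does *not* emulate: binding physics, docking
energetics, realistic protein folds, experimental affinity noise
structure (censored qualifiers, inter-assay disagreement), or chemical
series correlation between ligands. Passing the recovery tests therefore
shows that the pipeline's machinery is correct — that ligand signal is
found by ligand-view models and only by them, that the splits do what
their rules claim — not that any particular real dataset carries this or
that amount of bias.

## Problem sizes and numerical conventions

The shipped tests run the recovery experiments at 500 complexes with an
80/20 split over 5 seeds, the filter-exactness checks over 10 random
testbed configurations, brute-force geometry oracles over 50–100 random
fixtures, and bootstrap coverage at 500 replicate datasets of 200 points
with 1000 resamples — sizes chosen so the whole suite completes in a few
minutes on one core while keeping seed-averaged margins wide. Other
conventions: affinity qualifiers (>, <, ~) are parsed and stored but
treated as exact values by default (no censoring model is fitted; a switch
excludes qualified records); Ki, Kd and IC50 are merged onto one pK scale
while the measurement type is retained for re-stratification; hydrogens
are excluded from all distance computations (their placement is
inconsistent across structure files) but kept in molecules when present;
PDB parsing keeps altloc A and insertion codes; non-standard residues
count in an UNK bucket so pocket size is conserved.

## Worked example

```{r example}
library(sfbias)

records <- generate_dataset(generator_config(n_complexes = 300, seed = 1))
split <- time_split(records, cutoff_year = 2019)
train <- records[records$complex_id %in% split$train_ids, ]
test <- records[records$complex_id %in% split$test_ids, ]

ligand_model <- train_bias_model(train, "ligand", train_config(seed = 1))
pocket_model <- train_bias_model(train, "pocket", train_config(seed = 1))

preds <- dplyr::bind_rows(
  dplyr::mutate(predict(ligand_model, test), model = "LigandBias",
                benchmark = "time_split"),
  dplyr::mutate(predict(pocket_model, test), model = "ProteinBias",
                benchmark = "time_split"),
  dplyr::mutate(ensemble_predict(ligand_model, pocket_model, test),
                model = "EnsembleBias", benchmark = "time_split")
)
report <- build_report(preds, test, metrics = c("pearson_r", "rmse"),
                       n_boot = 2000, seed = 1)
autoplot(report)
```

## Known limitations

* The descriptor battery is small (~30 graph descriptors) compared with a
  full cheminformatics battery; it suffices to encode ligand identity on
  the synthetic library but underestimates what ligand bias alone can
  memorize on real chemical series.
* RMSD is not symmetry-corrected; for highly symmetric ligands binned
  decoys may sit in a lower bin than a symmetry-aware computation would
  assign.
* The exclusion report substitutes transparency for fidelity: which real
  complexes parse depends on toolkit versions, so exact exclusion
  membership of any published dataset is not reproducible bit-for-bit,
  only auditable.
* Tree-ensemble baselines extrapolate poorly outside the training feature
  range; pocket-view predictions on compositions far from anything seen in
  training saturate rather than extrapolate.
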