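# ALtox

Somatic-mutation-based prediction of immunoglobulin λ light-chain (LC)
toxicity in AL amyloidosis.

In AL amyloidosis a clonal free λ light chain misfolds and forms toxic
aggregates. A mature LC differs from its germline V-J precursor only by the
somatic mutations (SMs) acquired during affinity maturation, and those few
substitutions — and their position in the LC homodimer structure — carry the
toxicity signal. ALtox is the complete analysis chain for that idea, aimed at
computational immunologists and protein scientists working with labeled LC
repertoires:

- **S<sub>mut</sub> encoding** — align each LC to its germline, transfer
  Kabat–Chothia labels, renumber progressively `1..N`, and encode each
  position as `X` (germline-identical), the mutated residue, or `.`
  (uncovered). `SYELTQPP` vs germline `SYVLTQPP` → `XXEXXXXX`.
- **Per-position enrichment** — for each position *i*, the 2×2 table of
  mutated/non-mutated counts in *tox* vs *nox* sequences, tested with
  Fisher's exact test and summarized by the odds ratio
  OR<sup>i</sup> = (tox<sup>i</sup><sub>M</sub>/tox<sup>i</sup><sub>NM</sub>) /
  (nox<sup>i</sup><sub>M</sub>/nox<sup>i</sup><sub>NM</sub>).
- **Feature families** — AMP (token per position), MAP and DAP (token pairs
  at monomeric / dimeric Cβ contacts under a strict 7.5 Å cutoff from a
  homodimer structure), GLVJ (germline rearrangement baseline).
- **Experiment grid** — 7 family subsets × 4 learners (naive Bayes, ridge
  logistic, pruned CART, random forest) × ±SMOTE = 56 experiments under
  stratified 10-fold CV; AUC, sensitivity, specificity, accuracy, balanced
  accuracy, F1; operating point by Youden's J = max<sub>c</sub>[Se(c) + Sp(c) − 1].
- **Information-gain ranking** of value-level features (`49-A`, `56X-59X`
  style) with a 0.01-bit cutoff, plus incremental-feature and random-label
  control experiments.
- **Germline reversion** — rank a toxic sequence's SMs by feature importance
  and restore germline residues one at a time until the predicted phenotype
  flips.
- **Simulator** — synthetic labeled repertoires with planted discriminative
  SMs and toy homodimer structures with designed contact maps, so every
  stage is testable offline.

## Worked example

Simulate a labeled repertoire with one planted toxic mutation (an alanine
at scheme position 49, carried by 55% of toxic and 4% of non-toxic
sequences over a 3% background mutation rate), encode it, and run the
analysis:

```r
library(ALtox)

spec <- simSpec(nTox = 150, nNox = 200, backgroundRate = 0.03,
                plantedEffects = data.frame(position = 49, aa = "A",
                                            p_tox = 0.55, p_nox = 0.04),
                seed = 42)
sim <- generateRepertoire(spec)
sme <- encodeDataset(sim$records, sim$germlines)

subset(positionStats(sme), position == 49)
#>  position kc_label tox_M nox_M odds_ratio            p
#>        49       46    92    12   24.85057 8.833006e-31

fs  <- assembleFeatureMatrix(sme, "AMP")
crossValidate(fs, "random_forest", folds = 10, seed = 1)
#> ExperimentReport [random_forest, 10-fold CV, 114 features]
#>   AUC 0.787 | Se 0.700 | Sp 0.725 | Acc 0.714 | BalAcc 0.712 | F1 0.677
#>   Youden J = 0.550 at threshold 0.670 (Se 0.640, Sp 0.910)

head(infoGainRank(fs), 3)[, c("name", "info_gain_bits", "count_tox", "count_nox")]
#>   name info_gain_bits count_tox count_nox
#> 1 49-A     0.31469017        89         6
#> 2 49-X     0.27810972        58       188
#> 3  6-X     0.02352085       150       190
```

The planted position is recovered as strongly tox-enriched (92 of 150
toxic vs 12 of 200 non-toxic sequences mutated there, OR ≈ 25), the
classifier separates the classes well above chance, and the `49-A`
indicator tops the information-gain ranking. Note the `kc_label` column:
scheme position 49 corresponds to Kabat–Chothia label 46 here, because
the bundled reference carries a CDR1 insertion block that the progressive
renumbering absorbs. With a trained model, `greedyRevert()` flips such a
sequence back to a predicted non-toxic phenotype by restoring the
germline residue at position 49.

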