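---
title: "Predicting light-chain toxicity from somatic mutations: methods and design"
author: "ALtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting light-chain toxicity from somatic mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ALtox)
```

## The problem

In AL (light-chain) amyloidosis, a clonal plasma cell secretes a free
immunoglobulin λ light chain (LC) that misfolds, aggregates and damages
organs. Whether a given LC is proteotoxic is not readable from its sequence
at a glance: mature LCs differ from their unmutated germline V-J precursor
by a handful of somatic mutations (SMs) acquired during affinity
maturation, and it is these few substitutions — and their structural
context — that carry the toxicity signal. ALtox implements the full
analysis chain for this hypothesis: encode each LC as its SM difference
from the germline, test per-position mutation enrichment between toxic
(*tox*) and non-toxic (*nox*) repertoires, derive sequence- and
structure-contact features, train classifiers under a defined experiment
grid, rank features by information gain, and use the ranking to design
minimal germline reversions that neutralize a predicted-toxic sequence.

## Numbering and the S~mut~ encoding

LCs of different lengths are only comparable after a common numbering.
Each LC is globally aligned to its own germline
(Needleman–Wunsch, linear gaps), Kabat-Chothia labels are transferred
through the alignment (insertion columns get the preceding label with the
next insertion letter, e.g. `30A`), and the sorted union of labels across
the dataset and the germline reference is renumbered progressively
`1..N` — a CDR1 block `30A..30F` occupies positions 31..36 and everything
downstream shifts. The scheme size `N` is a property of the loaded
reference set, not a hard-coded constant.

The encoding itself is per position: `"X"` where the LC equals its
germline, the mature residue where it differs (an SM), and `"."` where the
LC does not cover the position (e.g. V-region-only fragments). `SYELTQPP`
against germline `SYVLTQPP` encodes as `XXEXXXXX`:

```{r}
smutEncoding("SYELTQPP", "SYVLTQPP")$string
```

The encoding is invertible over covered positions (germline + tokens
reconstruct the LC), and the SM count equals the Hamming distance over
covered positions — both properties are enforced by the test suite.

### Alignment scoring

Defaults are match +1, mismatch −1, gap −4, linear gap costs, with
deterministic traceback (match/mismatch preferred over a gap in the LC,
over a gap in the germline). LC-versus-own-germline alignments are
near-identity, so results are insensitive to the exact values, with one
caveat that fixed the gap default: at gap −2, a point substitution inside
a short sequence repeat (λ frameworks contain motifs like `SSS` and
`SGSKSG`) lets a gapped alignment outscore the substitution-only reading,
which would shift the numbering and be rejected as an inconsistency. At
gap −4 we observed no such event in 60,000 simulated mutated sequences.
The scoring is an argument of `globalAlign()` for users who want the
softer setting.

## Per-position enrichment statistics

For every scheme position the four counts (tox mutated / not mutated, nox
mutated / not mutated) form a 2×2 table. The association measure is the
plain cross-product odds ratio (tox~M~/tox~NM~)/(nox~M~/nox~NM~), reported
as `Inf`/`0` for zero cells without continuity correction; the 95% CI uses
the Haldane–Anscombe +0.5 correction so it stays finite; the p-value is
the two-sided Fisher exact test as defined by `stats::fisher.test` (sum of
point masses not exceeding the observed one). The suite checks this
against exhaustive hypergeometric enumeration for every table with margins
≤ 12. Positions are tri-partitioned at α = 0.05 into tox-enriched
(OR > 1), nox-enriched (OR < 1) and non-significant; no multiple-testing
correction is applied by default, matching the per-position α convention
of this analysis style (`adjust = "BH"` is available). Two conventions for
uncovered positions are implemented: the default counts `"."` as
not-mutated (a truncated read is germline-like at unreported positions);
`missingAsNM = FALSE` drops those sequences from that position's table.

SM-load distributions between repertoires are compared with a two-sided
Welch t-test on per-sequence SM counts (`pdsmCompare()`), with the
degenerate constant-groups case defined as p = 1 for equal means.

## Feature families

* **AMP** — one categorical variable per scheme position: the mutated
  residue, `"X"`, or `"."`.
* **MAP** — one variable per monomeric contact pair: the two position
  tokens joined as `"A-X"`, for pairs whose Cβ atoms lie strictly closer
  than 7.5 Å within a chain of the homodimer structure.
* **DAP** — the same for chain-crossing pairs; a position may pair with
  itself across the two-fold axis.
* **GLVJ** — the germline V-J rearrangement as a single categorical
  baseline variable.

Glycine contributes its Cα as the Cβ surrogate; alternate locations
resolve by highest occupancy, then alphabetical altloc; the 7.5 Å cutoff
is a strict inequality; no sequence-separation filter is applied within
chains. Features stay categorical end to end — unmutated-pair values like
`"X-X"` are informative categories, not absences — and are one-hot
expanded only inside backends that need numeric input, with the expansion
recorded so importances map back to named features.

## Classification protocol

The experiment grid crosses the 7 non-empty family subsets with four
backends — naive Bayes (Bayesian-network surrogate), ridge logistic
regression, pruned CART (a J48 stand-in) and random forest (100 trees) —
each with and without SMOTE, for 56 experiments. Exact parameter parity
with other ML toolkits is not promised; the grid structure, protocol and
metric definitions are. Evaluation is stratified 10-fold cross-validation
with pooled out-of-fold scores; *tox* is the positive class.

SMOTE uses the nominal-feature variant: a synthetic minority row takes
each categorical value by majority vote among the k = 5 Hamming-nearest
minority neighbours of a random base instance (ties toward the base value,
then alphabetical), until the training classes are equal. Balancing
happens strictly inside each training fold; the report records which
sequences seeded synthetic rows, and the suite asserts held-out folds
never contribute.

Metrics are sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy,
balanced accuracy, F1 = 2TP/(2TP+FP+FN), and the rank-statistic
(Mann–Whitney) AUC; undefined ratios are reported as missing, never as 0.
The operating point maximizes Youden's J = Se + Sp − 1 by exhaustive scan
over unique out-of-fold score cutpoints (ties toward higher sensitivity,
then lower threshold).

Feature ranking uses information gain in bits, computed on value-level
indicator variables — `49-A` (an SM to alanine at position 49),
`56X-59X` (an unmutated contact pair) — because those are the variables
the nominal-attribute formulation defines, and because reversion needs
value-level ranks. Indicators below 0.01 bits are dropped; ties break by
name. Whether such a filter should be applied once globally or per fold is
genuinely open; rankings for reporting and reversion are computed once on
the full matrix, while all performance claims come from classifiers that
never see the ranking.

Two controls are built in: `randomLabelControl()` relabels half of a
single-class subset and must score at chance (AUC ≈ 0.5) if the CV
protocol is leak-free, and `incrementalFeatureExperiment()` retrains on
nested prefixes of the top 10 features per family (30 classifiers when all
three families contribute) to trace how much signal the head of the
ranking carries.

### Unseen categories at prediction time

A new sequence can carry a token never observed in training at some
feature (a rare mutation). Backends cannot score unseen factor levels, so
prediction substitutes the feature's training-majority level — for the
sparse features at hand this is almost always the uninformative `"X"` /
`"X-X"` value, i.e. the substitution is toward "no signal", never toward
toxicity.

## Germline reversion

Given a predicted-toxic sequence, each of its SMs is scored by the best
general rank among the ranked features it currently realizes (its own
position-residue feature, and any contact-pair feature containing the
position with matching tokens; best rank wins, ties by position).
`greedyRevert()` then restores germline residues one SM at a time in that
order, re-encoding and re-predicting after each step, until the label
flips to *nox* or candidates are exhausted. Steps only ever restore the
germline residue; a family-restricted ranking can be passed by filtering
the ranking table. The general-rank default reflects the "largest
information gain" selection language; both readings are supported.

## The simulator and what passing tests mean

`generateRepertoire()` draws, per sequence: a germline by class-conditional
usage; background SMs at a uniform per-position rate (default 0.03, a
typical replacement load for a moderately mutated LC), substituting
uniformly over the 19 non-germline residues; then planted single-position
and pair effects with class-conditional probabilities. Generation is a
pure function of the spec, seed included. The bundled
`toyGermlineSet()` holds four hand-written, clearly synthetic λ-like
germlines (105–112 residues, two with insertion-letter blocks).
`generateToyStructure()` writes a two-chain PDB whose geometry realizes a
requested contact pattern exactly (interface positions 5 Å across chains,
designated monomeric neighbours < 7.5 Å, everything else > 9 Å).

The simulator emulates the statistical structure the analysis assumes —
class-conditional SM frequencies, germline usage skew, contact-localized
effects — and deliberately omits much of real somatic hypermutation:
hotspot and transition biases, clonal lineage structure, CDR3 length
variation, indels. Passing tests therefore demonstrate that the machinery
recovers planted signal of known strength under clean conditions; they do
not certify performance on clinical repertoires, which requires external
data.

Test and acceptance problem sizes are chosen to exercise the claims at
desk scale: parameter recovery uses 5 planted positions at odds ratio ≈ 8
(carrier rates 0.30 vs 0.051) with 500 sequences per class over 20 seeds;
the null-control average uses 400 single-class sequences over 10 seeds;
the alignment-optimality check enumerates all alignments for all string
pairs up to length 3 over a 3-letter alphabet plus random length-4–5
pairs.

## Known limitations

* Germline assignment is an input; the package does not call germlines
  from nucleotide data.
* κ-isotype references, mmCIF structures and constant-region handling are
  out of scope.
* The four backends are ecosystem-native equivalents, not re-implementations
  of any specific toolkit's learners, so absolute metric values on a given
  dataset will differ from other stacks even under the same protocol.
* Reversion explores the greedy rank-guided path (optionally exhaustive
  subsets for ≤ 10 SMs via repeated calls); it does not model stability
  (ΔΔG) or suggest non-germline substitutions.
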