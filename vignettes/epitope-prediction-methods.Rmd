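---
title: "Methods: windowed SVM prediction of B-cell epitopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed SVM prediction of B-cell epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episvm)
```

## The prediction problem and the two-stage design

A linear B-cell epitope is a contiguous antigen segment recognized by
antibodies. `episvm` predicts, for every residue of an antigen chain, a
real-valued propensity to belong to an epitope. The unit of classification
is the 20-mer: a chain of length $L \ge 20$ is decomposed into all $L-19$
overlapping windows, each window is encoded as a feature vector and scored
by a radial-basis SVM whose calibrated output approximates the probability
that the 20-mer is an epitope, and each residue then aggregates the scores
of the 1–20 windows covering it into its propensity. The two stages are
deliberately decoupled: the fragment classifier is trained and evaluated on
labeled 20-mer datasets, while the aggregation step turns any fragment
scorer into a whole-chain predictor.

## Inputs and per-residue channels

Four information channels feed the encoding:

* **Sequence** — the chain itself, restricted to the 20 canonical amino
  acids. Ambiguity codes (X/B/Z/U/J/O) are rejected in strict mode or
  mapped to a configurable fallback residue in lenient mode, so that scale
  and profile lookups stay total. Strictness is the default because silent
  substitutions mask upstream data problems.
* **Dipeptide antigenicity (RAAP)** — a 400-entry ordered-pair scale,
  supplied as a file and conventionally renormalized into $(-1, 1)$. The
  renormalization implemented is a linear min–max map (with an
  interior-shrinking factor of $1-10^{-9}$ so endpoints stay strictly
  inside the open interval); only affine structure matters downstream.
* **Secondary structure and solvent accessibility** — per-residue H/E/C
  labels and accessibility values from an external structure predictor,
  consumed as files. Absolute surface areas are divided by the residue's
  extended Ala-X-Ala tripeptide reference area and clipped to $[0,1]$;
  clipping is needed because predictors occasionally emit areas above the
  reference, and downstream invariants require RSA $\in [0,1]$. A residue
  is *buried* iff its RSA is below 25% (the boundary counts as exposed).
* **Conservation** — from the weighted observation percentage (WOP) block
  of a PSI-BLAST ASCII profile. For a profile row $P$ (percentages divided
  by 100) and background $P^b$,
  $\mathrm{CON} = \sum_{i=1}^{20} P_i \log_2(P_i / P^b_i)$, with
  $0 \log 0 := 0$. The background is configurable; the default is the
  Robinson–Robinson frequency table, with a uniform 1/20 option, because
  the conservation definition leaves the background open and
  Robinson–Robinson is the standard profile background. Raw WOP rows are
  used exactly as emitted — divided by 100 but *not* renormalized to sum
  to one — so the score is a Kullback–Leibler divergence (hence
  non-negative) only when the row is a proper distribution. All-zero WOP
  rows do occur; they are replaced by the average WOP vector of all
  same-type residues with non-zero rows in the training set. That fallback
  table is computed at training time and serialized inside the model
  artifact; when a chain must be annotated without a model (exploratory
  use), the table is derived from the chain's own non-zero rows and any
  residue type never observed non-zero falls back to the background
  profile, with a message.

## The 198-feature encoding

The encoding has 11 groups with cardinalities
8/33/30/29/12/6/6/30/28/6/10. The canonical order — group order as listed,
listing order within groups, sliding-window features by window size
$n = 5,\dots,18$ ascending with max before min — is frozen and
snapshot-tested, because trained models and selection manifests refer to
features by name and position.

Notable conventions, each chosen where the feature definitions leave room:

* **Entropies** are computed exactly as defined, $\sum_c p_c \ln p_c$
  (natural log, values $\le 0$); the sign is irrelevant to the classifier.
* **Empty selections** (e.g., the strand-restricted RSA mean of a fragment
  with no strand residues) encode as 0, and the matching counts as 0. Zero
  is the conventional neutral input for standardized SVM features and
  keeps every vector total.
* **Longest-segment ties** go to the leftmost maximal run, and ties in
  cross-channel window selection (two windows sharing the extremal mean)
  go to the leftmost window — determinism over arbitrary preference.
* **The per-residue RAAP channel.** The scale is defined on dipeptides, but
  class- and exposure-restricted means (RAAP_ss, RAAP_Bd/Ed, RAAP_ss_Bd/Ed,
  RAAP over longest segments) need a per-residue value. Each residue takes
  the mean of its incident dipeptide scores — one at either terminus, two
  in the interior. This keeps restricted means on the residue coordinate
  system without double-weighting interior dipeptides within a selection.
  Window-restricted RAAP statistics (max/min_RAAP_slide_n and the
  cross-channel avg_RAAP features) instead use the window's $n-1$ interior
  dipeptide scores, so a window of $n$ residues contributes exactly its own
  dipeptides.
* **Similarity features** count, for each substring length, the *distinct*
  multi-mers present in both peptides, summed over lengths. The definition
  ("the number of the same AAs, the same 2-mers, 3-mers, etc. present in
  both fragments") also admits position-pair counting; distinct counting is
  the default as the minimal reading, and the positional semantics is
  available behind `mode = "positional"`. Both are validated against their
  own brute-force enumerators. The five highest scores per library side
  are reported; sides with fewer than five members pad with 0 ("no
  similarity"). Under cross-validation a training fragment never
  contributes to its own similarity features (exact duplicates at other
  indices do), which is the hygiene required to keep fold evaluation
  honest.

One caveat documented rather than asserted: the plausible-looking invariant
"min sliding-window mean $\le$ channel mean $\le$ max sliding-window mean"
holds only when the window size tiles the fragment (here $n \in \{5, 10\}$
for 20-mers). For non-divisor sizes a channel with mass at both termini
defeats it, so the property tests restrict to tiling sizes.

## Classifier, hyperparameters, selection

The SVM uses the RBF kernel with features standardized to zero mean and
unit variance on the training data (RBF kernels on raw mixed-scale inputs
are dominated by the widest-range features). Probability outputs come from
the standard sigmoid calibration of margin scores with a seed fixed before
fitting; scores land in $[0,1]$ and a fragment is called an epitope iff its
score exceeds 0.5 — an exact 0.5 is a negative call, matching the strict
reading of "<0.5 / >0.5".

Hyperparameters come from a stratified 10-fold grid search over
$C = 2^{-2},\dots,2^{4}$ and $\gamma = 2^{-11},\dots,2^{0}$ (84 pairs),
maximizing pooled cross-validated MCC at the 0.5 cutoff, with ties broken
toward the smallest $C$ then the smallest $\gamma$. The reference operating
points are $C = 2^3$, $\gamma = 2^{-10}$ for the full 198-feature model and
$C = 2^0$, $\gamma = 2^{-9}$ (the package defaults) for a selected-subset
model.

Feature selection is a wrapper procedure: features are ranked by their mean
absolute biserial correlation over the training folds,
$\mathrm{BCC} = (M_e - M_{ne})\sqrt{n_e n_{ne}/n}/stdev$ with the
population standard deviation (the formula's normalizer pairs naturally
with the population form; the ranking is insensitive to the choice since
$n$ is fixed — note the statistic is the classical point-biserial scaled by
$\sqrt{n}$ and can exceed $[-1,1]$). Backward elimination then sweeps the
features in ascending $|\mathrm{BCC}|$ order, removing a feature whenever
removal does not lower the cross-validated MCC, and repeats full sweeps
until none can be removed; the final MCC therefore never falls below the
initial one. One seeded fold partition is used for the entire procedure —
re-randomizing folds per attempt would make acceptance decisions
incommensurable and the outcome non-deterministic.

## Propensity schemes

Each residue's score multiset (sizes 1–20; interior residues, at least 20
positions from both termini, have exactly 20) is aggregated by one of:
maximum, average, median (mean of the middle two for even counts), or the
distance scheme — the mean of the $k$ scores farthest from 0.5, i.e., the
most confident window predictions. The default is the distance scheme with
$k = 16$, the operating point that maximized chain-level AUC in the
method's published tuning; $k = 20$ reduces exactly to the average scheme
on full multisets. Residues near the termini with $m < k$ scores use all
$m$ (the only total extension of the rule); ties in $|s - 0.5|$ are
included by ascending window offset for determinism. Chains shorter than
20 residues are rejected outright — the encoding is defined on 20-mers and
any padding rule would be invented.

## Evaluation

Binary metrics follow the standard confusion-table formulas. The MCC uses
the numerator $TP \cdot TN - FP \cdot FN$; a zero factor in the denominator
yields MCC 0 by convention (degenerate folds would otherwise crash model
selection), and undefined ratio metrics report NA with a warning. The AUC
is implemented twice — as the tie-corrected Mann–Whitney rank statistic and
as an explicit threshold-sweep ROC with trapezoidal integration — and the
two are asserted equal on random inputs; an independent implementation
(pROC) is cross-checked in the tests. The per-chain success rate counts a
chain as correct when the mean propensity of its native epitope residues
strictly exceeds the chain-wide mean; equality counts as failure, and
chains without epitope residues are excluded from the denominator with a
message.

## The synthetic-data generator

The generator fabricates everything the pipeline consumes — labeled 20-mer
datasets with aligned channels, a toy dipeptide scale, antigen chains with
embedded epitope segments, WOP matrices, and truth intervals — with planted
class structure controlled by explicit effect sizes:

* a **composition/scale effect** (`delta_raap`, default 0.6): pairs of
  epitope-favored residues (D, E, K, N, Q, R, S, T — hydrophilic types) get
  an additive scale shift, and epitope sequences are simultaneously
  enriched in those residues (85% vs 25% mixture weight), so `avg_RAAP`
  separates the classes;
* an **exposure effect** (`delta_rsa`, default 0.2) shifting the mean RSA
  of epitope residues upward, on top of a coil/RSA coupling shared by both
  classes so that combined structure-accessibility features carry signal;
* a **conservation effect** (`delta_con`, default 2) concentrating epitope
  WOP rows on the native residue;
* a **structure effect** (`delta_ss`, default 0.3) shifting epitope
  secondary structure toward coil; and
* **motifs** pasted into epitope fragments, driving the similarity
  features.

Channels are generated jointly per residue, residues are otherwise i.i.d.
from the background frequencies, and all-zero WOP rows are injected at 5%
to exercise the fallback machinery end to end. With every effect at 0 and
no motifs the classes are exchangeable by construction, which is the basis
of the null calibration check. Defaults were chosen once as a signal
strength a strongly informative real feature set would show (the strongest
published single feature in this problem separates classes by roughly a
class-conditional standard deviation) and are not adjusted against test
outcomes.

What passing on synthetic data does and does not show: the generator plants
independent, stationary signals with i.i.d. background residues; real
epitope data has correlated channels, redundant homologous fragments, and
much weaker, heterogeneous effects. Recovery of planted structure
(held-out fragment AUC $\ge 0.9$ under the documented strong-signal
conditions, chance-level AUC under the null) validates the machinery — the
encoding, the hygiene of fold-local similarity libraries, the aggregation —
not the biological error rate, which can only be measured on curated
epitope datasets with real PSI-BLAST and structure-predictor outputs.

## Problem sizes and numerical choices

The validation suite runs at deliberately modest sizes, chosen so the full
suite completes in minutes on one core while keeping every estimate stable:
200 + 200 fragments with a 50/50 held-out split for parameter recovery,
3-fold cross-validation and a 25-feature shortlist for the end-to-end
selection demonstration, 60-residue chains for profile checks, and
exhaustive window-law checks for $L = 20..60$. Grid search at the full
84-pair grid and elimination over all 198 features are the same code paths
at larger loop counts.

Other numerical details: sliding-window means are computed from cumulative
sums (exact for these magnitudes); `sd_RAAP` is the sample standard
deviation of the 19 dipeptide scores; the libsvm decision values are
re-oriented so larger always means epitope before any AUC computation; and
model artifacts bundle the scaler, calibration, manifest, fallback table,
and similarity library so a reloaded model reproduces its scores exactly.

## Known limitations

* Secondary structure, accessibility, and PSI-BLAST profiles are consumed
  as files; the package does not run those predictors.
* The dipeptide antigenicity scale is an input, not re-derived from
  epitope statistics.
* Propensities are emitted as a continuous track; discrete epitope calls
  with boundaries are out of scope.
* The probability calibration inherits libsvm's internal cross-validation;
  decision values are exactly reproducible, calibrated probabilities are
  reproducible for a fixed fitted model (save/load is exact) but can move
  by small amounts between independent refits.
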