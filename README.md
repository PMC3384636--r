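# episvm

Sequence-based prediction of linear B-cell epitopes from antigen chains.

Identifying the immunogenic regions of an antigen — the residues recognized
by B-cell receptors and antibodies — guides epitope mapping, vaccine design,
and immunotherapy, but experimental mapping is slow and expensive. `episvm`
implements a two-stage, sequence-only predictor for researchers who have an
antigen sequence plus the standard per-residue predictions that accompany it
(secondary structure, solvent accessibility, and a PSI-BLAST profile) and
want a per-residue epitope propensity track.

## The model

**Stage 1 — fragment classification.** The antigen chain of length *L* is
decomposed into all *L* − 19 overlapping 20-mers. Each 20-mer is encoded as
a named 198-dimensional feature vector in 11 groups:

| Group | Features | Content |
|---|---|---|
| SS | 8 | helix/strand/coil contents, Σ *p* ln *p* entropy, segment counts |
| RA | 33 | buried/exposed contents and entropy, class-mean RSA, sliding-window RSA extrema (*n* = 5..18) |
| RP | 30 | mean and SD of the 19 dipeptide antigenicity (RAAP) scores, sliding-window extrema |
| CS | 29 | mean conservation Σᵢ *P*ᵢ log₂(*P*ᵢ/*P*ᵢᵇ), sliding-window extrema |
| SS+RA, SS+CS, SS+RP | 24 | class- and longest-segment-restricted channel means |
| RP+RA, RP+CS | 58 | exposure-restricted RAAP means; RAAP means over the window extremizing RSA or conservation |
| SS+RA+RP | 6 | RAAP means restricted jointly by structure class and exposure |
| SIM | 10 | the five highest multi-mer similarity scores against known epitope and non-epitope 20-mer libraries |

Conservation uses the weighted observation percentages (WOP) of a PSI-BLAST
profile divided by 100 against a background frequency table
(Robinson–Robinson by default); all-zero profile rows are replaced by the
training-set average WOP vector of the same residue type. Similarity between
two 20-mers counts the distinct substrings (1-mers, 2-mers, …) present in
both. A radial-basis SVM (standardized inputs, sigmoid-calibrated
probability outputs; defaults *C* = 2⁰, *γ* = 2⁻⁹) scores each 20-mer, with
score > 0.5 read as "epitope".

**Stage 2 — propensity aggregation.** Every residue inherits the scores of
the 1–20 windows covering it and aggregates them with one of four schemes:
maximum, average, median, or the *distance scheme* (default, *k* = 16),
which averages only the *k* scores farthest from the 0.5 decision boundary —
the most confident window predictions. With *k* = 20 the distance scheme
equals the average scheme.

The package also implements the accompanying model-building machinery:
stratified-CV grid search over *C* and *γ*, feature ranking by mean absolute
biserial correlation BCC = (*M*ₑ − *M*ₙₑ)·sqrt(*n*ₑ·*n*ₙₑ/*n*)/*stdev*,
backward elimination under cross-validated MCC, the evaluation suite
(accuracy/sensitivity/specificity/precision/F/MCC, rank- and ROC-based AUC,
per-chain success rate), and a synthetic-data generator with planted class
structure so the whole pipeline is testable without external predictors.

## Worked example

Everything below runs from a synthetic fixture — no external predictors
needed. Real inputs would come from `read_fasta()`, `read_ss_rsa()`,
`read_wop()`, `read_dipeptide_scale()`, and `read_fragments()`.

```r
library(episvm)

spec  <- fixture_spec(seed = 42, n_epitope = 100, n_non_epitope = 100)
data  <- gen_fragment_dataset(spec)
feats <- extract_features(data$fragments, data$library, data$scale)
model <- svm_train(feats, C = 2^0, gamma = 2^-9, seed = 1,
                   library = data$library, scale = data$scale,
                   fallback_table = data$fallback_table)
model
#> <epitope_model> RBF SVM: C = 1, gamma = 0.001953125, 198 features, 200 training fragments

chain <- gen_chain_with_epitopes(fixture_spec(seed = 42, n_chains = 1,
                                              chain_length = c(60, 60)))[[1]]
ann     <- annotate_chain(chain$chain, chain$ss_rsa, chain$wop,
                          fallback_table = model$fallback_table)
profile <- predict_chain(ann, model, scheme = "distance", k = 16)
head(profile, 5)
#> # A tibble: 5 × 3
#>   position residue propensity
#>      <int> <chr>        <dbl>
#> 1        1 L            0.140
#> 2        2 N            0.150
#> 3        3 S            0.141
#> 4        4 E            0.129
#> 5        5 R            0.114

truth <- intervals_to_truth(chain$truth, nrow(ann))   # planted: 43-57
auc_score(profile$propensity, truth)
#> [1] 0.933
success_rate(tibble::tibble(chain_id = "synthetic_chain_1",
                            propensity = profile$propensity,
                            is_epitope = truth))
#> # A tibble: 1 × 4
#>   success_rate n_success n_evaluated n_excluded
#>          <dbl>     <int>       <int>      <int>
#> 1            1         1           1          0

autoplot(profile, truth = chain$truth)   # propensity track, epitope shaded
```

The low propensities at the start of the chain and the elevated track over
residues 43–57 (the planted epitope) are what a successful prediction looks
like: the chain-level AUC of 0.93 says planted epitope residues outrank
background residues, and the success-rate row says the epitope's mean
propensity exceeds the chain-wide mean.

A thin command-line wrapper (`inst/cli/episvm.R`) exposes
`fixtures`/`train`/`predict`/`evaluate` subcommands over the same functions.

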