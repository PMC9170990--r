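---
title: "Predicting lysine succinylation sites: models, encodings and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine succinylation sites: models, encodings and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Succinylation is a post-translational modification that transfers a succinyl
group onto the side chain of a lysine residue, with substantial consequences
for protein conformation and cellular regulation. Experimentally mapping which
lysines in a proteome are succinylated is slow and expensive, so sequence-based
predictors are used to triage candidate sites. `sucstack` implements such a
predictor: given a protein sequence and a candidate lysine, it scores the
probability that the site is succinylated, using only the local sequence
context.

The unit of analysis is a 21-residue peptide window: the candidate lysine plus
`r = 10` residues upstream and downstream. Windows that run off a protein
terminus are completed by mirror-image padding — the missing flank is filled
with the reversal of the residues on the opposite side of the lysine, so the
window extends palindromically around its center. The equations this rule
derives from are printed ambiguously in the source literature (the N- and
C-terminal labels appear swapped relative to the strings they annotate); we
adopt the only reading under which both cases produce palindromic extensions,
and fall back to `'X'` only when the opposite flank is itself too short. This
choice is recorded here as a package decision rather than asserted as the
original authors' intent.

## Feature encodings

Five encoders turn a window into one 811-dimensional vector
(15 + 420 + 200 + 16 + 160, concatenated in the fixed order below).

**Grouping weights (EBGW, 15 dims).** The 20 amino acids are partitioned into
four physicochemical groups (neutral/non-polar, neutral/polar, acidic, basic).
Three binary sequences mark membership in the unions G1∪G2, G1∪G3 and G1∪G4;
each is summarized by its running frequency of ones `f(n) = w(n)/n` sampled at
`n = 4, 8, 12, 16, 20` (`K = 5` sampling points, step `Q = floor(21/5) = 4`).
Because `5 × 4 = 20`, the final window position is never sampled; we accept
this as the literal consequence of the sampling formula. Non-standard residues
(`'X'`) belong to no group and contribute zeros.

**One-hot (420 dims).** Per position, a 20-bit indicator over the alphabet
`ACDEFGHIKLMNPQRSTVWY`; `'X'` becomes an all-zero block. This is the only
encoder that preserves position exactly.

**CBOW k-mer embeddings (200 dims).** Windows are split into overlapping
2-mers and, separately, 3-mers (words containing `'X'` are never formed). One
word2vec CBOW model with negative sampling is trained per word length on the
*training* windows only; a window is encoded as the token-mean of its 2-mer
embeddings concatenated with the token-mean of its 3-mer embeddings.
Out-of-vocabulary words contribute zero vectors but still count in the
denominator. Training hyperparameters are the classic word2vec defaults —
embedding dimension 100 (forced by the 100 × 2 output width), one-sided
context 5, 50 epochs, 5 negative samples, initial learning rate 0.025 with
linear decay — and the implementation (in C++, with a self-contained xorshift
RNG) is bit-reproducible from the seed. The mean is taken over word *tokens*,
not unique words, which is the natural reading when words repeat.

**Chaos-game representation (16 dims).** Each residue is first
reverse-translated to a fixed representative codon, chosen so base composition
stays balanced across amino acids. The chaos-game iteration
`CGR_i = 0.5 (CGR_{i-1} + g_i)` is run from the square's center with corner
coefficients A = (0,0), C = (0,1), G = (1,0), T = (1,1); the printed
coefficient order is used as-is (any other corner assignment merely permutes
cells). The 63 points of a fully standard window are binned on a 4 × 4 grid of
half-open cells (upper edges closed on the last row/column — the only total
assignment), and each raw count is passed through the logistic
`1/(1 + e^{-count})`. Applied to raw counts, the logistic saturates near 1 for
any cell holding four or more points; we keep this literal behavior as the
default because it is what the method prints, and expose
`cgr_frequency_normalize = TRUE` to divide counts by the number of points
first for users who want unsaturated features.

**Physicochemical wavelet summaries (AAF_DWT, 160 dims).** Ten amino-acid
property scales (consensus normalized hydrophobicity, positive charge,
partition energy, net charge, conformational preferences for all and for
antiparallel beta-strands, mean polarity, the z3 principal property, apparent
partition energy from the Wertz–Scheraga index, and IFH scale weights) are
taken from the AAindex database as shipped with seqinr and standardized to
zero mean / unit variance over the 20 amino acids at load time; the
standardization is idempotent, so restandardizing a standardized table is a
no-op, which the package exploits as a self-check. Each property maps the
window to a length-21 series (`'X'` → 0) that is decomposed by a level-3 Haar
wavelet transform into four subbands (approximation at level 3, then details
3, 2, 1). The transform uses half-sample symmetric extension at odd lengths —
the dominant convention for short biological signals; the package pins the
choice with an independently coded filter-bank oracle in its test suite. Each
subband is summarized by max, min, mean and population standard deviation,
ordered as all maxima, all minima, all means, all standard deviations.

## Feature selection

The fused 811-dim vectors are reduced by LASSO: minimize
`Σ (y_i − wᵀx_i)² + λ‖w‖₁` with labels coded 0/1 as a regression response (a
literal reading of the selection objective), optimized by coordinate descent
via glmnet. Columns are standardized internally; `λ` defaults to 5-fold
cross-validated squared error over a logarithmic grid. Two protocol details
matter:

* **Where selection happens.** Selecting features on the full dataset and then
  cross-validating leaks test information into the selector. The default
  protocol refits the selector inside every training fold;
  `global_lasso = TRUE` reproduces the original global-selection
  protocol for comparison.
* **Empty selections.** On signal-free data, cross-validated LASSO correctly
  prefers the intercept-only model, but the downstream classifiers need at
  least one column. When that happens the penalty is relaxed to the largest
  value on the regularization path that admits one feature; this floor only
  engages on (near-)null data.

## Classifiers

**Broad learning system (BLS).** Implemented from scratch as the standard
one-shot construction, since the printed hyperparameters (`N1 = 3` feature
nodes per window, `N2 = 100` mapping windows, `N3 = 100` enhancement nodes,
shrinkage `s = 0.9`, ridge `c = 2^-30`) are exactly the knobs of that
construction: random linear feature maps (uniform on [−1, 1]) rescaled
per-window to [0, 1], a random column-orthonormal enhancement layer with tanh
activations shrunk so pre-activations lie within `[-s, s]`, and output weights
solved in closed form as a ridge system. No sparse-autoencoder fine-tuning and
no incremental node addition: neither is used by the evaluation protocol the
package implements. Scores are the raw ridge outputs clipped to [0, 1];
clipping (rather than a second calibration fit) suffices because the
meta-learner re-weights the scores anyway. With `n_enhance = 0` and identity
activation the model collapses to ridge regression on the mapped features,
which the test suite exploits as a closed-form oracle. The ridge solve runs
with `tol = 0` because at very small `c` the system is near-singular by
design (the interpolation regime).

**Stacking ensemble.** Layer one: linear SVM (`C = 1`, `gamma = 1`), the BLS
above, and leaf-wise gradient-boosted trees (learning rate 0.27, max depth 40,
51 leaves, 587 rounds — run through xgboost's `lossguide` grower, which is the
leaf-wise algorithm those settings describe). Layer two: a weakly L2-penalized
logistic meta-learner over the spliced vector [3 base scores ⊕ selected
original features] — 305 inputs when 302 features survive selection, which is
the only arithmetic consistent with the printed meta width. How the
meta-training inputs are generated is not specified in the source literature;
the package defaults to the canonical construction, out-of-fold scores from an
internal stratified 5-fold so no meta-training row is ever scored by a base
model that saw it, with `oof = FALSE` available for the in-sample variant.
SVM scores are sigmoid-calibrated on training decision values; this
calibration is fitted deterministically in R rather than through libsvm's
internal cross-validation, whose unseeded RNG would break end-to-end
reproducibility. Boosted-tree scores are native probabilities.

## Evaluation

Confusion-matrix metrics are Sn, Sp, Acc, MCC and F1, with the 0-convention
for vanishing MCC/F1 denominators; AUC uses the midrank statistic, identical
to trapezoidal ROC integration. Cross-validation is stratified (the source
protocol says only "randomly divided"; stratification prevents class-starved
folds and is seeded for reproducibility), and the *entire* pipeline — CBOW
training, encoding, selection, base and meta fits — is refit per fold. The
decision threshold for confusion counts is 0.5.

## The synthetic generator and what passing means

`generate_fixture()` emulates the compositional asymmetry reported around real
succinylation sites — lysine, glycine and alanine enriched near positives,
serine near negatives — by mixing a uniform background over the 20 amino
acids with the class-specific enriched set at mixture weight `effect`. At
`effect = 0` the classes are exchangeable by construction. It does **not**
emulate position-specific motifs, homology structure between proteins, or the
class-ratio drift of real PTM databases; a pipeline that separates these
fixtures is shown to recover planted compositional signal without leakage,
not to reach any particular accuracy on real proteomes.

The package's end-to-end checks run a signal-recovery experiment at 500 + 500
windows, `effect = 0.5`, with a stratified 20% holdout, averaged over 10
seeds (3 seeds in the faster acceptance script): the stacked model's held-out
AUC must exceed 0.85 and match or beat every base learner, and at
`effect = 0` held-out AUC must stay at chance level — the sensitive detector
of leakage through CBOW or LASSO fitting. These problem sizes were chosen as
the smallest at which the base learners' tuned settings (587 boosting rounds,
300 mapped BLS features) are exercised meaningfully while the whole suite
stays comfortably runnable on a laptop core.

The cross-validated accuracies published for this family of predictors were
measured on a specific curated PTM corpus with its own tuning history; nothing
of that kind is asserted by this package's tests, which only state what the
synthetic experiments themselves compute. `cross_validate()` with
`global_lasso = TRUE` and `oof = FALSE` reproduces the original
order-of-operations on any dataset the user supplies.

## Numerical conventions worth knowing

* Coordinates: site annotations are 1-based; the window center is index
  `r` 0-based internally. Every interface documents which it uses.
* Subband standard deviations are population (divide by n) statistics.
* All stochastic stages draw their seeds deterministically from one user seed
  via a stage-name hash, so stages can be re-run in isolation.
* Determinism: two full fits from the same seed and data produce identical
  predictions (xgboost is pinned to one thread; the CBOW trainer and BLS use
  seeded self-contained RNG streams).
* Degenerate inputs fail loudly: single-class labels, constant feature
  matrices, annotations pointing at non-lysine residues, and empty LASSO
  selections all raise errors rather than propagating silently.
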