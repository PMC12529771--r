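---
title: "Latent molecular descriptors from a SMILES autoencoder: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent molecular descriptors from a SMILES autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`latentmol` implements a recurrent sequence-to-sequence autoencoder over
SMILES strings. A molecule's canonical SMILES is tokenized at character
level — except the two-character halogens `Cl` and `Br`, which are single
tokens — framed by start/end tokens and padded to a fixed width. The
encoder is a stack of LSTM layers; the final hidden and cell states of the
layers are concatenated and passed through a fully connected layer with a
hyperbolic-tangent activation. The output of that layer, a fixed-length
real vector $\xi$ (512 coordinates in the full-scale configuration), is the
molecular descriptor.

The decoder maps $\xi$ through $2L$ dense heads (one per hidden and cell
state of each of the $L$ decoder LSTM layers) to initialize its own LSTM
stack, which predicts the token sequence one step at a time through a
softmax output layer. Training is teacher-forced: the decoder input at
step $t$ is the ground-truth token at $t-1$. At inference, decoding is
greedy: the argmax token is fed back until the end token or the step
budget.

Two auxiliary mechanisms shape the latent space:

* **Latent noise.** During training (only), zero-mean Gaussian noise with
  standard deviation 0.05 is added to $\xi$, so nearby latent points decode
  to the same molecule — the property that makes perturbation and
  interpolation meaningful.
* **Property regression.** Thirteen per-property MLP stacks
  (512–256–128–1, ReLU then linear) read the same latent vector and
  regress the molecule's physicochemical profile (MolWt, MolLogP, QED,
  Min/MaxPartialCharge, NumValenceElectrons, HeavyAtomCount,
  NumHAcceptors, NumHDonors, LabuteASA, BalabanJ, MolMR, TPSA), z-scored
  by a scaler fitted on the training corpus. The joint loss is the
  decoder's categorical cross-entropy plus $\lambda$ times the sum of the
  per-property mean squared errors; $\lambda$ is exposed (default 1) so the
  heads can be weighted or disabled.

The total loss is optimized with Adam. Defaults mirror the full-scale
reference configuration: 3 LSTM layers of 1024 units, latent 512, learning
rate $10^{-4}$, batch 256.

### Design choices the architecture description leaves open

* **Which states feed the bottleneck.** "The cell and hidden states of
  each LSTM cell were concatenated" is ambiguous between the top layer and
  all layers; we default to all layers (`bottleneck = "all"`) and expose
  `"last"` as a configuration flag.
* **Masked encoding.** The encoder carry-masks past each sequence's true
  length, so trailing pad tokens are exact no-ops. Encodings are therefore
  independent of padding width and batch composition (a property the test
  suite asserts bit-exactly), and batches can be trimmed or
  length-bucketed purely for speed.
* **Decoder-init activation.** The activation of the initial-state dense
  heads is unstated; we use tanh so the injected states stay in the
  LSTM's natural operating range.
* **Teacher forcing.** The training scheme is described as feeding the
  ground-truth previous token, which is plain teacher forcing; that is
  what we implement.
* **Encoder input reversal.** The encoder reads the content tokens in
  reverse order (`reverse_input = TRUE`, the default; decoder output
  order is unchanged). Reversal shortens the temporal path between the
  tokens the decoder must emit first and the encoder states that carry
  them — the classical sequence-to-sequence trick — and markedly
  accelerates convergence of exact reconstruction. The latent descriptor
  is unaffected in kind: it remains a deterministic encoding of the
  molecule.
* **Loss masking.** Cross-entropy is averaged over non-pad target
  positions (through the end token); pads carry no loss.
* **Optimizer details.** The Adam moment decays are not specified by the
  architecture description; we use $\beta_1 = 0.9$ and $\beta_2 = 0.98$
  (the lower second-moment decay speeds recurrent-network convergence in
  short training budgets), a global gradient-norm clip of 5, orthogonal
  initialization of recurrent weights, forget-gate biases of 1, and an
  optional cosine learning-rate schedule used when a model is trained to
  convergence on a fixed corpus.

All gradients are computed analytically in compiled code
(`src/autoencoder.cpp`) and validated against central-difference numerical
differentiation in the test suite.

## Latent-space operations

For latent vectors $\xi$ the package provides the canonical algebra:
similarity search by Euclidean distance (ascending, index tie-break);
perturbation $\xi_i = \xi_Q + \delta\,\xi_r$ with $\xi_r \sim N(0, I)$ and
$\delta = 0.2$ as the default vicinity-sampling scale; two-point
interpolation $\xi_i = \xi_1 + \tfrac{i}{n}(\xi_2 - \xi_1)$; weighted
blends $\xi_{new} = \sum_j \omega_j \xi_j$ with $\sum_j \omega_j = 1$;
Gaussian "semirandom" sampling from per-dimension normal fits of a latent
corpus (the latent marginals of a trained model are near-Gaussian, and
independent per-dimension sampling is implemented as described — a
full-covariance variant would be a straightforward extension); and
descriptor directions: PCA of a latent corpus, ordinary least squares of a
descriptor on the PC scores of a *disjoint* held-out set, and the
direction as the unit-normalized weighted sum of loading vectors mapped
back to latent coordinates, so pairwise angles and directed walks live in
one frame.

## Downstream pipelines

**Protonation-state ranking.** A state-penalty table (an energy-like score
per enumerated protonation state, lower = more populated at the reference
pH) is binarized: the minimum-penalty state of each parent is class 1, all
others class 0, ties to the lowest state index with a warning. Because
only the ordering of penalties enters, the pipeline is scale-free in the
penalty units. A feed-forward classifier (1024–512–512–1, ReLU/sigmoid,
binary cross-entropy, Adam $10^{-4}$, batch 128) is trained with 5-fold
cross-validation and early stopping (patience 5). Folds are stratified at
the parent level — all states of a parent share a fold — because
splitting a parent's states across folds would leak near-duplicate
molecules into validation. The final model either refits on all data or
keeps the per-fold models as an averaging ensemble (`final =
"ensemble"`), which lowers ranking variance; an optional decoupled
weight decay regularizes the classifier. At inference the predominant
state is the argmax of the predicted probability, never a thresholded
set: even when several states clear 0.5, or none does, exactly one
state is returned.
State enumeration itself is an external adapter; the module consumes
pre-enumerated state SMILES or state latents.

**ADMET heads.** Fourteen endpoints (caco2, lipo, sol as regression; the
rest binary classification) share one architecture (2048–1024–1024–1,
ReLU; linear or sigmoid output), mean-absolute-error or binary
cross-entropy loss, Adam starting at $10^{-4}$ and decayed by 10% per
epoch, 5-fold cross-validation with patience 10. Class imbalance is
handled by random undersampling (seed 42) or SMOTE (5 neighbours,
synthetic minority points as convex combinations of a point and one of
its minority nearest neighbours). Resampling happens inside each training
fold only — validation folds are never resampled, since balancing
validation data would inflate every reported metric. Regression targets
are z-scored for optimization and inverse-transformed for reporting, so
MAE is on the original scale.

**Virtual screening.** Given a library of latent vectors with
active/decoy labels, each iteration samples $n \in \{1, 5, 10\}$ actives
as queries, removes them from the pool (ranking compounds already in hand
would trivially inflate enrichment), ranks the rest by maximum cosine
similarity to the query set, and records ROC-AUC (midrank Mann–Whitney)
and the enrichment factor at the top 1%:
$EF = \frac{\text{actives in top } \lceil fN \rceil / \lceil fN \rceil}
{\text{actives} / N}$, with the ceiling convention so small libraries
never produce an empty bucket. EF equals 1 for a random ranking — the
calibration the acceptance script verifies — and the maximum Tanimoto
similarity over Morgan fingerprints is provided as the classical
comparator.

## Synthetic data: what it emulates, and what it does not

The `fixtures` generators make every stage testable offline:

* `toy_corpus()` draws branched alkane/ether/amine trees and simple
  benzene-cored aromatics from a constrained grammar (atom valences
  enforced by construction), canonicalizes them with the chemistry
  toolkit and passes them through the full curation filter, so every
  output molecule is valid, unique, canonical and curation-stable.
* `penalty_table()` plants a hidden linear rule: state penalties are
  $\mathrm{softplus}(s\,w^\top\xi + \varepsilon)$ for a shared direction
  $w$, so the minimum-penalty state is predictable from the latent alone
  with strength controlled by $s$ ($s = 0$ reduces recovery to chance).
* `admet_table()` plants linear regression targets with configurable
  signal-to-noise, or classification labels thresholded to a requested
  prevalence.
* `screening_library()` draws actives from a displaced compact cluster
  and decoys from the background; zero displacement with unit spread is
  the exact null.

These fixtures emulate the *structure* of the real tasks (grouped states,
imbalanced endpoints, clustered actives), not the chemistry of real
screening decks or ADMET panels: passing the planted-recovery tests shows
the pipelines learn what is learnable and stay calibrated under the null,
not that real-data accuracies are reproduced. Real corpora at the scale
of the reference model (hundreds of millions of molecules, commercial
state-penalty labels, public screening benchmarks) are deliberately out
of scope.

## Reference benchmark sizes

Two desk-scale benchmarks are defined once in `R/benchmark.R` and used by
both the test suite and `scripts/acceptance.R`:

* **Reconstruction.** 500 grammar molecules with 4–15 heavy atoms (corpus
  seed 1); a reduced autoencoder (2 × 256 LSTM, latent 64, no property
  heads, Adam $10^{-3}$, batch 64, latent noise 0.05) trained with cosine
  learning-rate annealing until full reconstruction or 200 epochs; the
  reported quantity is the percentage of molecules whose encoding
  greedy-decodes back to the exact input string. The corpus size, model
  reduction and epoch cap were chosen so the run completes on a single
  CPU while leaving the task non-trivial (the corpus does not fit in the
  decoder's unconditioned language model).
* **Null screening.** 200 "actives" and 9,800 "decoys" drawn i.i.d. from
  one multivariate normal (library seed 7); 500 iterations of 5-query
  max-cosine ranking; mean EF@1% ≈ 1 within Monte-Carlo error.

Seeds fan out from one global seed via `derive_seed(seed, component)`
(a multiplicative hash, kept below $2^{31}$), so each stochastic stage is
isolated and every command is bit-reproducible on one platform.

## Numerical choices and degenerate inputs

* Distance/similarity ties break by ascending library index, so rankings
  are total orders and runs are reproducible.
* Zero-norm latent vectors cannot be cosine-scored; they are ranked last
  with a warning rather than silently dropped.
* `fit_scaler()` refuses constant property columns by name; inverse and
  forward transforms round-trip to double precision.
* One-class metric calls return `NA` AUCs while the thresholded metrics
  are still computed; ROC-AUC uses midranks so tied scores are handled
  exactly.
* SMOTE requires more minority samples than neighbours and suggests
  undersampling otherwise; undersampling never modifies a surviving row.
* The tokenizer fails loudly on out-of-vocabulary characters (naming the
  character and position) and over-length sequences; inference never
  silently skips molecules.

## Known limitations

* The chemistry bridge shells out to the system `python` RDKit per batch;
  it is fast for corpus-scale batches but not for one-molecule calls in a
  tight loop.
* Greedy decoding only: no beam search or stochastic decoding, matching
  the deterministic regeneration protocol; sampling-based generation
  would require only a decoder-side extension.
* The full-scale configuration (221M-molecule corpora, 111-token
  sequences, 54M parameters) is expressible in `ae_config()` but not
  trainable at desk scale; the package's claims at that scale are limited
  to configuration fidelity.
* Descriptor directions assume a linear descriptor–latent relationship;
  strongly nonlinear descriptors will show lower regression correlations
  and less reliable walk monotonicity.
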