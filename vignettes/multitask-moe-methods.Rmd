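---
title: "Multitask mixture-of-experts models for sparse toxicity tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask mixture-of-experts models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cardiotoxicity is not one endpoint but a cascade: molecular initiating
events (e.g. hERG channel inhibition, aryl hydrocarbon receptor binding),
key events (mitochondrial dysfunction, oxidative stress), modes of action
(changes in action potential, inotropy, vasoactivity) and apical adverse
effects reported for marketed drugs. Data for these endpoints come from
different sources, so a chemicals-by-endpoints label table is *sparse*
(each endpoint covers only part of the chemical space) and *imbalanced*
(actives are usually the minority). `moetox` models such a table with a
single multitask network instead of one model per endpoint, on the
hypothesis that endpoints along one biological cascade share structure a
joint representation can exploit.

## Model

Every molecule is encoded by one or more fixed-length representations
(branches). The network is:

* **Experts.** One MLP per branch, ReLU activations, ending in a shared
  hidden width. Expert representation rows are L2-normalized before
  mixing (see *Design choices*).
* **Gate.** A single affine map from the concatenation of the raw branch
  inputs to K logits, followed by a row-wise softmax. The weights are
  therefore non-negative and sum to one per molecule; reported "gate
  weights" are means over the evaluation rows. With one branch the gate
  is omitted and the model is a plain multitask network, so
  encoder-comparison experiments share every non-input parameter count.
* **Trunk and towers.** The mixed representation `Σ g_k h_k` feeds a
  shared trunk MLP and then one small tower per task, each emitting one
  logit. Sigmoid probabilities; class = active when probability ≥ the
  threshold (ties go to active — the screening-oriented choice; default
  threshold 0.5).

### Losses

The element loss is a class-balanced binary cross-entropy with the
positive class up-weighted by the task's negative/positive training-count
ratio. Unobserved molecule–task pairs are masked: they contribute exactly
zero to the loss and to every gradient, so sparse tables train without
imputation and one forward pass serves all tasks. The per-task loss is
the mean over that task's observed entries and the scalar loss the mean
over tasks with at least one observed entry — per-task (not per-element)
pooling, so densely labelled endpoints do not dominate.

The uncertainty-weighted variant combines per-task losses `L_i` as
`Σ L_i/σ_i² + Σ log σ_i` with `σ_i = exp(log_sigma_i)` trainable. The
`1/σ²` factor lets the optimiser down-weight noisy tasks; the `log σ`
penalty prevents the weights from collapsing to zero; the exponential
parameterisation keeps σ positive. At σ ≡ 1 the objective reduces exactly
to the plain sum, and for a fixed task loss the stationary point is
σ² = 2L — both are asserted in the test suite, and analytic gradients of
both objectives (through the full network, gate included) are checked
against central finite differences.

### Training

Minibatch Adam (defaults: learning rate 1e-3, batch 128, up to 300
epochs) with early stopping on the validation loss (patience 20); the
returned parameters are those of the best validation epoch. Full rows are
batched and masking handles sparsity, so no per-task data loaders exist.
Dropout (default 0.2) applies to hidden activations only. All training is
bit-reproducible from the config seed: parameter draws, shuffling and
dropout masks all derive from it.

These optimizer values are conventions, not tuned constants; every one is
exposed in `train_config()` / `moe_config()`.

## Data protocol

* **Standardization.** Stereochemistry markers are removed textually and
  the SMILES canonicalized with OpenBabel. Structures are rejected as
  `inorganic` (no carbon), `organometallic` (an element outside
  {H,B,C,N,O,F,Si,P,S,Cl,Se,Br,I} covalently bonded to carbon — the
  filter is named in the protocol we follow, the element list is ours),
  `mixture` (multi-fragment SMILES are rejected outright, no
  largest-fragment rescue), or `unparseable`; when several apply the
  first in that order is reported. Duplicate canonical structures merge
  their labels with the same any-positive OR rule used to collapse
  assay outcomes into endpoint labels.
* **Encoders.** Circular (Morgan-style, ECFP) fingerprints — default 1024
  bits, radius 2, computed via OpenBabel's ECFP and folded from its
  native 4096 bits by modular OR — and a physicochemical descriptor
  battery (OpenBabel properties plus element, bond-order and ring
  counts). Descriptor batteries are library-dependent, so no column
  count is asserted anywhere. Fingerprints pass through untouched;
  descriptors get train-median imputation and z-scaling fitted on
  training rows only. Learned embeddings (CDDD- or ChemBERTa-like) plug
  in through `register_encoder()`; the package ships no pretrained
  weights.
* **Splitting.** Train/validation/holdout at 8:1:1 with a greedy
  per-endpoint stratification: endpoints are visited from least to most
  numerous (ties by name) and each endpoint's still-unassigned molecules
  are apportioned class-stratified by largest-remainder quotas.
  The pass is *deficit-aware*: it counts how many of the endpoint's
  molecules earlier endpoints already placed in each partition and fills
  the shortfall, keeping each endpoint's total class balance as close to
  the ratios as the earlier assignments allow. Without this, endpoints
  processed late (whose molecules overlap earlier endpoints heavily)
  inherit near-binomial class drift. A class smaller than the number of
  partitions goes entirely to train, with a warning. The same machinery
  produces k-fold CV partitions, and baselines train on the merged
  train+validation rows since they have no use for a validation set.

## Baselines, evaluation, applicability domain

Per-endpoint random forests (ranger) with a grid search over number of
trees {100, 300, 500}, maximum depth {unlimited, 10, 20} and minimum node
size {1, 3, 5} (the protocol names the axes; the values are ours),
selected by median F1 over 5 stratified folds, ties by grid order.

Metrics per endpoint: sensitivity, specificity, balanced accuracy, F1,
MCC; zero-denominator ratios are reported as missing, never as zero, and
excluded (with a count) from means. Pooled metrics sum the TP/TN/FP/FN
counts across endpoints before applying the same formulas. The imbalance
diagnostic is the mean |sensitivity − specificity| across endpoints. Gate
weights across k rebuilt models are summarised as mean ± t-based 95%
half-width (df = k − 1). Endpoint groups (e.g. in-vitro vs in-vivo
endpoint sets) roll up per-molecule: active if predicted active on at
least one endpoint of the group.

The applicability domain uses the Local Outlier Factor in novelty mode,
fitted per encoder on training features only (k-distances and local
reachability densities; k = 20 neighbours; Euclidean by default, with a
Jaccard option for binary fingerprints since the geometry of 0/1 vectors
differs — which metric the original protocol used is not recorded).
"Substantially lower density" needs a number: we flag LOF > 1.5, exposed
in `fit_ad()`. Per-encoder flags combine as consensus `all` (out of
domain only if every encoder agrees — permissive) or `any` (restrictive);
`all`-flags are provably a subset of `any`-flags.

## Synthetic data: what it does and does not show

`synth_generate()` draws a latent factor z ~ N(0, I) per molecule; branch
features are an informativeness-scaled linear map of z plus unit noise
(informativeness 0 yields a pure-noise branch); task logits are
task-specific linear read-outs of z (scale 3, logit noise sd 1 by
default) with intercepts calibrated by 1-D root finding so the expected
positive rate hits the configured prevalence; masks are
missing-completely-at-random per task. This reproduces the *statistical*
shape that motivates the method — shared structure across endpoints,
imbalance, sparsity — so passing tests demonstrate the machinery works
where its assumptions hold. It deliberately does not emulate chemistry:
no descriptor correlation structure, no scaffold clusters, and MCAR
missingness instead of the source-driven (structural) missingness of real
multi-source tables. Results on synthetic data therefore support the
implementation, not any claim about a particular real dataset.

## Simulation studies and their conditions

Three packaged studies fix the experimental conditions once:

* **Gate identifiability** (`run_gate_study()`): 2000 molecules, 4 tasks,
  two 16-feature branches with informativeness 1 vs 0, five replicate
  seeds. Trained with learning rate 3e-3 and patience 40 (defaults
  elsewhere are 1e-3/20): the gate bias needs more optimizer steps than
  the predictive layers, and since the returned model is the best
  validation epoch, slower settings would report a gate that has not yet
  finished moving. The mean trained gate weight on the informative
  branch exceeds 0.7.
* **Multitask benefit** (`run_multitask_benefit_study()`): 2000
  molecules, 12 tasks on an 8-dimensional latent, prevalence 10–40%,
  missingness 40–80% with the four smallest tasks at ~400 observed
  labels, five seeds; the multitask network beats per-task random
  forests (same features, merged train+validation) on those four tasks.
* **Imbalance handling** (`run_imbalance_study()`): 1500 molecules, four
  10%-prevalence tasks, five seeds; balanced BCE vs plain BCE at
  threshold 0.5 — balanced training shrinks the sensitivity–specificity
  gap by a large factor.

Split-quality checks use an 8000-molecule, 8-task table with per-task
coverage 50%/20%. The coverage choice matters: when every task covers
most molecules, the last-processed tasks have nearly all their members
pre-assigned and a ±3-point stratification band is statistically out of
reach for 10% partitions at those cell sizes; partial, multi-source-like
coverage is both more realistic and the regime the greedy heuristic is
designed for. These problem sizes keep the full test suite and the
reproduction script to a few minutes on one CPU while leaving each
property's margin wide.

## Design choices on genuinely open points

* **Expert normalization.** A mixture can silence a useless branch two
  ways: move the gate, or shrink that expert's output toward zero. The
  second leaves the gate uninterpretable as encoder importance, which
  defeats the purpose of gate analysis. L2-normalizing expert rows
  removes the shrinkage escape route, so relative contribution is
  controlled by the gate alone (`moe_config(normalize_experts = )`,
  default on for multi-branch models).
* **Gate input.** The gate reads the concatenated raw branch inputs (not
  the expert outputs), one weight vector per molecule; reported weights
  are row means. The gate's internal depth is not specified anywhere, so
  the simplest simplex-normalizing map (affine + softmax) is used.
* **Per-task loss pooling.** Averaging per task rather than per element
  is chosen so a 8000-label endpoint cannot drown a 200-label one; the
  alternative reading (per-element mean) is noted as ambiguous in the
  source protocol.
* **Duplicate label conflicts** merge by the OR rule, consistent with the
  any-positive labelling philosophy; the original conflict policy is not
  recorded.
* **Classification ties** at the threshold go to active, favouring
  sensitivity in a screening context.
* **Numerical details.** BCE uses the softplus form for stability at
  large |logit|; constant descriptor columns scale as no-ops (sd set
  to 1); all-missing columns are dropped with a warning; gradient-check
  tests evaluate at a generic parameter point because zero-initialised
  biases park ReLU pre-activations exactly on their kink, where central
  differences are one-sided; per-stage RNG streams are derived from the
  user seed so split/synthesis/training randomness do not interact.

## Known limitations

* Pure-R training: fine for tables up to tens of thousands of molecules
  and moderate layer widths, not for large fingerprint inputs with wide
  experts; there is no GPU path.
* The gate is linear; strongly input-dependent encoder relevance might
  need a deeper gate.
* MCAR synthetic missingness understates the difficulty of structural
  missingness; stratification quality on real multi-source tables should
  be re-checked with the packaged diagnostics.
* The applicability domain covers fixed encoders only; embeddings that
  require a trained model are excluded by construction.
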