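---
title: "Modeling read coverage from DNA sequence with scan-based layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling read coverage from DNA sequence with scan-based layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Supervised sequence-to-function models read a long window of genomic DNA
and predict, for every 32-bp bin, the expected read coverage of many
functional-genomics assays at once (RNA-seq, CAGE, DNase-seq, 3' RNA-seq).
The state of the art couples a convolutional trunk, which condenses
one-hot DNA into a coarse embedding while detecting local motifs, with
long-range layers that integrate regulatory context over hundreds of
kilobases.  Because attention is quadratic in sequence length, there is
active interest in sub-quadratic replacements: selective state-space
(Mamba-style) recurrences, implicit long convolutions (Hyena-style), and
striped stacks that alternate state-space and attention layers.

`covscan` implements this model family and everything around it -- data
transforms, the composite count loss, the training schedule, a seeded
synthetic regulatory genome, and the downstream variant-effect scoring
pipeline -- in R with compiled kernels for the recurrence and convolution
inner loops.  Everything is desk-scale verifiable: each nontrivial
numeric path has an independent oracle (a sequential scan, a direct
convolution, dense attention, closed forms) that the tests compare
against.

## Data model and transforms

A window is a fixed-length one-hot matrix `(L, 4)` with columns A, C, G,
T.  Ambiguous bases and augmentation-vacated positions are all-zero rows,
so a zero row-sum always means "no information here".  Coverage is a
`(L/32, T)` nonnegative matrix with per-track metadata: assay class,
strand, and a pairing identifier that links every forward-stranded track
to exactly one reverse-stranded partner.

* **Squash transform.** Raw coverage is compressed by the invertible
  monotone map `min(x^{3/4}, 384) + max(0, x^{3/4} - 384)`, implemented
  exactly in this two-branch form.  Algebraically the branches sum to
  `x^{3/4}`; the two-branch form matters because the natural variant
  soft-clips the above-threshold term, and `squash()` exposes an optional
  `clip_exponent` for that variant (off by default, matching the printed
  formula).
* **Binning** is by sum, not mean: coverage is count-like and the loss is
  a Poisson likelihood, so pooling must conserve total counts (and does
  so exactly; the tests assert it).
* **Cropping.** 2,048 bins are dropped from each end before the loss at
  full scale (8 bins in the desk-scale configuration, the same fraction
  of a 8,192-bp window); edge bins lack flanking context.
* **Augmentation.** Reverse complementation reverses bins and exchanges
  each FWD/REV track pair (unstranded tracks are reversed in bin order
  only); sequence shifts of up to 3 nt translate the one-hot rows and
  zero the vacated ones while leaving the output bins untouched.
  `revcomp_augment()` is an involution, which the tests check on random
  instances.
* **Folds and splits.** Windows are shuffled (seeded) and cut into six
  near-equal contiguous blocks; four rotations each assign one fold to
  validation and a different fold to test (4:1:1), with pairwise distinct
  test folds.  The grouping rule (contiguous blocks after a seeded
  shuffle) is a package choice; whether fold boundaries should respect
  chromosome contiguity is left to the caller, who controls window order.

## Layers

### Selective state-space (Mamba-style) layers

Per channel `d` and state `n`, the discretized recurrence is

    h_t = exp(delta_t A) * h_{t-1} + bbar_t x_t,     y_t = <C_t, h_t> + D x_t

with input-dependent step size `delta_t = softplus(...)`, input and
readout projections `B_t`, `C_t`, and a diagonal state matrix `A`
initialized to `-(1..N)` per channel.  Step-size biases are initialized
so the initial `delta` spans about `[1e-3, 1e-1]`.  The input matrix is
discretized with the simplified Euler rule `bbar = delta * B_t` by
default; the full zero-order hold `(exp(delta A) - 1)/A * B_t` is
available behind `method = "zoh"` (with a series fallback near `A = 0`).

Three implementations of the same recurrence coexist deliberately:

1. `ssm_scan_sequential()` -- the O(L N) step-by-step oracle;
2. `ssm_scan_associative()` -- a parallel prefix over the monoid
   `(a1, b1) o (a2, b2) = (a1 a2, a2 b1 + b2)`, with a blocked variant
   whose `checkpoint_every` bounds the working set without changing
   values;
3. a compiled recurrence (used inside the layer) whose forward and
   adjoint are exact and are finite-difference-checked in the tests.

The **bidirectional** layer runs the scan forward and on the
length-reversed sequence, with the input projection *tied* between the
two directions; the backward branch also applies a configurable channel
permutation before the tied projection -- the feature-space analogue of
complementation.  The default permutation is the identity: beyond the
first sequence-derived layer the 64- or 768-dimensional embedding has no
intrinsic complement structure, so an arbitrary nontrivial permutation
would be unmotivated.  Both branches share the multiplicative gate and
the single output projection; each keeps its own scan parameters.  The
two directions are combined additively before the output projection, and
the whole layer is residual: zeroing the output projection gives the
identity map exactly.

### Convolutional trunk and Hyena-style layers

Trunk blocks apply, in order: channel normalization, GELU, a "same"
convolution, and twofold max-pooling.  Five blocks convert a
`(393216, 4)` input to `(12288, 768)` -- 32-bp resolution at embedding
width 768.  The channel schedule interpolates geometrically from 4 to
the embedding width (kernel width 15 in the first block, 5 thereafter);
these are configuration, not constants, since only the endpoints are
fixed by the architecture.

The package also keeps, as a standalone operation, the identity that
motivated abandoning serial dilated convolutions:
`compose_dilated_kernels()` collapses any serial stack of single-channel
dilated linear convolutions into one long kernel (support width
`1 + sum(d_i (w_i - 1))`), exact in exact arithmetic.

Hyena-style layers generate their long convolution kernels implicitly
with a SIREN coordinate network (2 hidden layers, width 32, frequency 30)
windowed by a learnable exponential-decay envelope, apply them with an
FFT long convolution (`length-2L` transforms, so linear rather than
circular), and interleave elementwise gating over `order = 2` branches
after short nearest-neighbour convolutions (optionally channel-mixing,
applied to all short convolutions when enabled).  Bidirectionality comes
for free by centering the kernel (index 0 at offset `-L/2`) instead of
padding it causally.

**The 1/L initialization rule.**  A SIREN initialized for unit output
variance produces a long-convolution output whose variance grows in
proportion to the kernel length `L`; stacked at depth this explodes
activations.  Scaling the final SIREN layer so kernel-entry variance is
proportional to `1/L` keeps depth-8 stacks bounded.  Both behaviours are
kept reproducible: the stability sweep with the `1/L` rule and the
blow-up under `"unit"` initialization are regression tests.

### Attention, positional encodings, U-Net wrap

Attention blocks are pre-LayerNorm multi-head softmax attention (4 heads,
query/key dimension 64 at full scale) plus a pointwise feed-forward
sublayer (expansion 2, GELU -- the expansion factor is a package choice).
Three positional modes: none (the block is then permutation-equivariant,
tested), rotary embeddings (scores depend only on the relative offset,
tested numerically), and a geometric threshold basis of 32 features
(half symmetric in `|offset|`, half signed) used as additive relative
logits.  `chunked_attention()` streams over key chunks with running
max/denominator accumulation and equals dense attention for every chunk
length -- including chunk length 1 and logits around plus or minus 80.

The U-Net wrapper pools twofold `pool_rounds` times (two rounds for the
transformer path, 128-bp resolution; one for striped stacks), applies the
wrapped layers at the coarse resolution, and upsamples back by
nearest-neighbour repetition followed by a pointwise linear combination
with the skip.  An additive (rather than concatenating) skip combination
is the default -- it preserves the embedding width, keeps the wrapper
residual-friendly, and the choice is exposed in the parameters.

## Loss, schedule, training

For each track with predicted rates `lambda_i` over bins and observed
counts `x_i` (totals `Lambda`, `X`):

    loss = (Lambda - X log Lambda) + w * ( - sum_i x_i log(lambda_i / Lambda) )

The Poisson term scores total counts, the multinomial term their
positional distribution.  At `w = 1` the gradient equals the independent
per-bin Poisson NLL gradient exactly (an identity the tests verify
numerically); the training default `w = 4` upweights the positional
term.  Heads emit `softplus` rates plus a floor of `1e-6`, so log-ratios
and gradients are always finite.

The optimizer is Adam (`beta1 = 0.9`, `beta2 = 0.999`) with linear
warm-up (`lr * min(1, step / warmup_steps)`), gradient clipping first per
block -- a block being one named layer group: a conv block, an attention
block, a Mamba layer, the head -- then globally, an L2 regularizer with
coefficient `1e-6` on all trainable parameters, and batch size 2 with an
epoch defined as one pass over the shuffled training windows.  Both
augmentations are applied per example.  Early stopping watches the
validation mean Pearson r with a patience of 5 epochs (the stopping
metric is stated at full scale, the rule itself is a package choice) and
restores the best parameters.

Full-scale constants (learning rate `1e-4`, 10,000 warm-up steps,
clipping 5.0/10.0) are the `train_config()` defaults.  The desk-scale
recipe (`desk_train_config()`) raises the learning rate to `5e-3`,
shortens warm-up to 50 steps and loosens clipping to 100/1000: a model
three orders of magnitude smaller, with a loss summed over hundreds
rather than millions of bins, sits at a very different gradient scale,
and the full-scale bounds would silently rescale almost every step.

Gradients are hand-derived per layer (R with compiled kernels for the
scan recurrence and adjoint, im2col, depthwise convolution and GELU) and
validated end to end against central finite differences on tiny
instances; Hyena layers are provided as forward/analysis components and
are not wired into the training loop.

## The synthetic regulatory genome

The generator emulates exactly the data features the models and tests
need, with known ground truth:

* random background sequence with planted motif instances on both
  strands: a TSS-like consensus (`TATATAAG`) that drives a CAGE-like
  point source at its start, an RNA-seq-like block 1,024 bp downstream
  in the motif's orientation, a 3'-RNA-seq-like point at the block end
  and broad accessibility; and a GC-box-like consensus (`GGGCGGGG`)
  driving a smooth DNase-like peak;
* eight tracks: CAGE, RNA and 3' RNA forward/reverse pairs plus two
  unstranded tracks;
* Poisson count noise around the deterministic rate field, background
  0.5 counts/bin -- signal amplitudes (point masses of 15-30 counts,
  blocks of 4 counts/bin) chosen once so that a tiny model can learn the
  map in minutes while peaks remain well above background;
* variants with known effects: motif-destroying substitutions (the true
  effect is the signed change in total rate) and strictly neutral
  background substitutions, verified at generation time to change the
  rate field not at all.

Rates are computed by scanning the *sequence itself* on both strands, so
reverse-complementing a window and exchanging paired tracks reproduces
the generative rates exactly -- the property that makes the equivariance
and augmentation tests meaningful.  What the generator does **not**
emulate: chromatin-state spatial correlation, splicing structure,
linkage disequilibrium among variants, assay-specific noise beyond
Poisson counting.  Passing desk-scale tests therefore demonstrates that
the machinery -- encodings, layers, loss, optimization, scoring -- works,
not that the model family reaches any particular accuracy on real
genomes.

## Variant scoring and classification

For a variant centered in a window, each ensemble member predicts all
tracks for the reference and the alternate allele.  Per track, two
summaries feed the classifier: the signed log of the bin-sum of
differences, `sign(S) log(1 + |S|)` with `S = sum_b (alt_b - ref_b)`
(the `log1p` form pins zero differences at exactly zero and compresses
scale symmetrically -- the precise transform is a package choice), and
the L2 norm of per-bin log-ratios with an `eps = 1e-6` pseudocount.
Summaries are computed on the modeling (squashed) scale, i.e. on the
rates the model actually emits.  Features concatenate across ensemble
members (four data-split models at full scale).  A random forest (1,000
trees, seeded) is evaluated by stratified 5-fold cross-validation;
AUROC comes from the rank statistic over out-of-fold scores (tested
against the trapezoidal ROC integral and an independent implementation)
and Spearman correlates scores with a PIP-like target.

Per-track Pearson r and `r^2 = 1 - SSE/SST` are computed over bins
concatenated across windows by default; per-window averaging is a flag
(`mode = "per_window"`), since the corresponding full-scale description
is ambiguous between the two.

The pipeline's parameter-recovery benchmark scores synthetic variants
with the ground-truth rate oracle rather than a trained desk model: the
benchmark isolates the scoring-and-classification machinery, and a model
trained for minutes on a toy corpus is not a meaningful single-base
effect predictor.  The classifier separates large-effect from null
variants essentially perfectly, and permuted labels land at chance --
both recomputed by `scripts/acceptance.R` at every run.

## Problem sizes and numerical choices

The test suite and the acceptance script run at these sizes (chosen as
the package's desk-scale study conditions): scan-oracle equivalence on
100 random instances with `L` in {16, 257, 1024} and `N` in {1, 8, 16};
convolution oracles at `L` up to 512; a real trunk forward pass at the
full 393,216-bp window; learnability on a 48-window corpus of 8,192-bp
windows (40 train, 4 validation for checkpoint selection on the noisy
counts, 4 held out for evaluation against the true rates), striped model
`[Mamba x2 + UNet(attention, RoPE)] x1` at `d_model = 64` with 8 tracks,
1,200 optimizer steps, against a label-shuffled control trained
identically; variant recovery on 2,000 variants (1,000 effect, 1,000
null).  Forty training windows matter: with substantially fewer, the
held-out correlation plateaus around half its asymptote because the
motif-detector filters see too few planted instances to generalize.

Numerical details worth knowing: the scan uses 64-bit floats throughout
(the stated 32-bit tolerances are then conservative); `exp`-space decays
are never clamped since `delta > 0` and `A < 0` at initialization keep
them in `(0, 1]`; max-pooling ties break toward the earlier position;
the FFT length is the next power of two at or above `2L`; RMSNorm uses
`eps = 1e-6`, Layer/BatchNorm `1e-5`; trunk "batch" normalization
computes statistics per sequence over positions (batch size 2 makes
cross-example statistics noisy, and per-sequence statistics keep
single-example inference identical to training).

## Known limitations

* Training supports the conv / Mamba / attention / U-Net path; Hyena
  layers are inference/analysis components here.
* The backward-scan channel permutation is configurable but defaults to
  identity; no claim is made that any permutation makes the bidirectional
  layer exactly equivariant (the diagnostic `equivariance_gap()` measures
  departures, and the strictly equivariant construction in the tests is a
  separate toy).
* The desk-scale learnability number is a property of the synthetic task;
  it says nothing about accuracy on real compendia, which require
  GPU-scale training outside this package's scope.
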