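---
title: "Methods: augmentation, spatial filtering and the attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmentation, spatial filtering and the attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amanet)
```

## The problem

Motor-imagery brain–computer interfaces decode which movement a subject is
imagining from a few seconds of multichannel EEG. Imagined movement
modulates band power of the sensorimotor mu (8–12 Hz) and beta (18–26 Hz)
rhythms with a class-specific spatial topography (event-related
desynchronization/synchronization). Two obstacles dominate: per-subject
training sets are tiny (tens to a few hundred trials), and the informative
rhythms sit well below the noise floor of single channels. This package
implements a full decoding pipeline built around three ideas:

1. **Augmentation** — overlapping sliding windows multiply the sample count;
   amplitude scaling by a factor $\beta \in [0.9, 1.1]$ simulates
   inter-trial gain variation without touching time–frequency structure.
2. **Supervised spatial filtering (CSP)** — common spatial patterns project
   the montage onto a small set of variance-contrast directions computed by
   a generalized eigendecomposition of class covariances.
3. **A compact convolutional classifier** — multi-scale temporal
   convolutions, a grouped spatial convolution, efficient channel attention
   (ECA) and a depthwise separable fusion stage, ending in a small dense
   head trained with softmax cross-entropy computed from raw logits.

## Data augmentation block

A trial $X \in \mathbb{R}^{C \times T}$ is segmented into windows of
`window_size` = 500 samples at `stride` = 125, giving
$\lfloor (T - 500)/125 \rfloor + 1$ windows (five for $T = 1000$). *Known
ambiguity:* this architecture is described elsewhere with strides of both
75 and 125; only 125 is consistent with five overlapping sub-windows at
$T = 1000$, so 125 is the default and the stride is configurable.

**CSP.** Per-window covariances $X X^\top$ are normalized by their trace and
averaged within class. For two classes the filters $w$ solve
$\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_2) w$; the `n_pairs` largest- and
smallest-$\lambda$ eigenvectors are kept ($C_1 = 2\,$`n_pairs` output
channels: 12 for the four-class default, 2 for a binary montage). No canonical multiclass extension exists for this filter-pair scheme; we
use one-vs-rest and keep the $C_1/K$ variance-maximizing eigenvectors per
class, the common OVR-CSP practice consistent with $C_1 = 12$ at $K = 4$.
Numerical choices: a ridge $\varepsilon I$ with
$\varepsilon = 10^{-8}\,\overline{\mathrm{diag}}$ guards rank; each filter
row is sign-fixed so its largest-magnitude coefficient is positive
(eigenvectors are otherwise sign-ambiguous, which would make tests and
serialization flaky). Because the filters come from a whitening
construction, $W (\Sigma_1 + \Sigma_2) W^\top = I$ holds to numerical
precision, and for every filter the class-0 and class-1 variance ratios sum
to exactly one. Note the positional pairing
"$\lambda_i + \lambda_{n+1-i} = 1$" holds only when the whitened spectrum is
symmetric (true in textbook diagonal examples, not in general); the
per-filter identity is the invariant we test.

**Leakage contract.** `augment()` fits the bank on training windows only and
applies it to both sides; the bank carries a fingerprint of the trials it
saw, and cross-validation asserts per fold that this set is disjoint from
the validation trials.

**Scaling.** Each training window is multiplied once by
$\beta \sim U(0.9, 1.1)$ (a truncated normal with the same bounds is
available, as is per-epoch resampling behind `scale_per_epoch`). The oft-quoted "default value 0.1" for this perturbation is read here as
the half-width of the scaling band.
Test windows are never scaled under the default `scale_train_only = TRUE`.

## The network

For $C_1 = 12$, $T_1 = 500$ the stage chain is

| stage | output |
|---|---|
| multi-scale temporal block | $(8, 12, 500)$ |
| spatial/temporal refinement (ST) | $(16, 1, 125)$ |
| channel attention (ECA) | $(16, 1, 125)$ |
| depthwise separable fusion (DSF) | $(16, 1, 15)$ |
| flatten → hidden → logits | $240 \to 32 \to K$ |

- **Multi-scale block:** three parallel temporal convolutions with kernels
  (8, 16, 24), each $F_1 = 8$ filters, each followed by batch norm and ELU.
  How the branches are "fused along the channel dimension" is not specified;
  we concatenate to $3F_1$ channels and apply a learned 1×1 pointwise
  projection back to $F_1$ (default), consistent with the architecture's general use of pointwise
  convolution for channel integration; an element-wise sum is available as
  `ms_fusion = "sum"`.
- **ST block:** grouped spatial convolution (`groups` $= F_1$, multiplier
  $D = 2$) collapses the $C_1$ axis, then a temporal convolution of length
  $K_1/4 = 16$, average pooling by 4, one dropout
  (its position within the block is a free choice; we place it after
  pooling).
- **ECA:** global average pooling gives one descriptor per latent channel; a
  bias-free $k$-tap 1-D convolution across the channel axis and a sigmoid
  produce gates in $(0,1)$ that rescale each channel. The adaptive size rule
  is $k = \mathrm{odd}\big[(\log_2 C + b)/\gamma\big]$ with $\gamma = 2$,
  $b = 1$ (nearest odd integer, ties upward) — 3 at $C = 12$. Descriptions of this block sometimes index its channels by $C_1$, but the
  block sits after the spatial convolution where the channel axis has
  $F_1 D = 16$ latent channels; we apply it there, since the quantity being
  gated is the latent feature channel, not the CSP channel. The default is a fixed $k = 3$; `eca_mode =
  "adaptive"` computes the rule (which yields 3 at 16 channels too, so the
  default configuration is unaffected). Channel-axis padding is zero by
  default, circular optionally.
- **DSF block:** depthwise temporal convolution ($K_2 = 32$ taps per
  channel), pointwise 1×1 to $F_2$ channels, batch norm, ELU, pooling by 8,
  dropout. $F_2$ must equal $F_1 D$ only when this block is ablated (the
  pass-through preserves channels).
- **Classifier:** dense to 32 ($= 2F_2$), ELU, dropout, dense to $K$; the
  loss consumes raw logits through a numerically stable fused
  log-softmax/NLL.

Numerical conventions: "same" padding pads $\lfloor k/2 \rfloor$ left and
$k - 1 - \lfloor k/2 \rfloor$ right, so even kernels also preserve length
exactly; pooling uses floor division ($500 \to 125 \to 15$); batch norm uses
$\varepsilon = 10^{-5}$ and momentum 0.1 with biased batch variance for
normalization (unbiased in the running estimate); weights are fan-in
uniform, biases zero, the ECA convolution bias-free, all drawn from a
single stream seeded by `model_config(seed = )`.

## Why there is no deep-learning framework underneath

No torch-class framework exists in the target environment, so the forward
and reverse passes are written in the package: temporal/depthwise
convolutions and the fused batch-norm+ELU run as RcppArmadillo kernels, the
rest is base R on BLAS. Correctness is not taken on faith — the test suite
checks every analytic gradient against central finite differences at
relative tolerance $10^{-4}$ for the full model and for every ablated
architecture. Training uses Adam (learning rate $10^{-3}$, batch 32) with
per-epoch reshuffling from a seeded stream; evaluation mode is a pure
function of weights and input, which is what makes the bit-identical
determinism contract testable.

## Training and evaluation protocol

Cross-validation is stratified and **trial-level**: all windows of a trial
stay on one side of every split, and CSP is refitted inside each fold on
the training side only. (Whether the reference protocol split before or
after windowing is not stated; window-level splitting would leak trial
identity into validation, so trial-level is the defensible default and is
flagged in reports.) Metrics: window-level accuracy, trial-level majority
vote (ties toward the lowest class id), Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$, and the full confusion matrix. Metrics
are reported at the final epoch; there is no early stopping. Defaults
mirror the reference protocol (300 epochs, dropout 0.3, seed 1234, 10
folds); the test suite runs heavily scaled-down versions of these numbers
and says so where it does.

Ablations: `WMNet` (windowed data only), `WMANet` (+ECA), `CMNet` (CSP, no
window expansion or scaling), `AMNet` (CSP + augmentation), `AMANet`
(everything), plus independent module toggles (`no-multiscale` replaces the
three branches by the single middle kernel (1,16); `no-st` averages over
the spatial axis and duplicates channels; `no-dsf` reduces to the final
pooling). The sweep harness crosses kernel triplets, attention choices
(built-ins `eca`/`none`, extensions via `register_attention()`),
window/stride pairs and width parameters, reporting a tidy table with the
closed-form window count per cell.

## The synthetic world

`make_separable_spec()` fixes two canonical problems used by the acceptance
suite. Each class is an amplitude-modulated sinusoid (carrier at the band
center, AM at half the bandwidth, random phases per trial) projected
through a unit spatial pattern, plus white Gaussian noise — white by
default so periodogram band-power oracles are exact; a 1/f-shaped option
exists because real EEG noise is pink.

- **easy**: 2 classes, both 10 ± 1 Hz mu bursts at amplitude 2, expressed on
  orthogonal single-channel patterns, noise SD 0.4, 250 Hz, 4-s trials.
  Linearly separable by design: a sanity floor, not a benchmark.
- **hard**: 4 classes in overlapping mu/beta bands (9, 11, 19, 23 Hz,
  bandwidths 2–3 Hz) at amplitude 1, mixing vectors with pairwise cosine
  exactly 0.5 (Cholesky of $0.5 + 0.5I$), noise SD 1.5 — per-channel SNR is
  well below 0 dB, so spatial filtering genuinely matters.

These values were fixed once, before any acceptance measurement, as what a
practitioner would call plausibly calibrated; they are not tuned. What a
green test establishes: the pipeline separates band-limited,
spatially-mixed oscillations under heavy noise, respects its leakage
contracts, and is bit-reproducible. What it does not establish: performance
on real EEG — the generator has no 1/f background by default, no artifacts,
no nonstationarity, no inter-subject variability, and its spatial mixing is
far cleaner than scalp physics.

## Known limitations and honest caveats

- Headline accuracies reported for this architecture on the BCI
  Competition and High-Gamma datasets require those external datasets and
  are out of scope here; no number in this package should be read as
  reproducing them.
- On the synthetic sets the ECA module's contribution is within seed noise:
  the attention mechanism reweights latent channels whose informativeness
  is already fairly uniform after CSP on clean synthetic mixtures. The
  ablation acceptance check therefore orders a large effect (CSP +
  augmentation vs. neither) robustly, while the ECA-on/off comparison is
  close to a tie whose sign flips in nearby configurations (epoch counts,
  training-set sizes) and should not be over-interpreted in either
  direction. The acceptance harness runs the small-sample regime
  (8 training trials per class, 20 epochs): with ample trials every
  variant, including the no-CSP baseline, saturates near ceiling and the
  comparison degenerates.
- Parameter totals quoted for this architecture vary (21.3K vs 22K at the
  same configuration); `count_parameters()` reports this package's actual
  count and no attempt is made to force either figure.
- GDF/EDF parsing is intentionally absent; epoch containers are RDS or
  CSV+JSON here (no HDF5/NPZ reader exists in the target R environment),
  and the README documents the two-line conversion.
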