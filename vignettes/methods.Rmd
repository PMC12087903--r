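---
title: "Adaptive spatial-temporal graph networks for EEG emotion recognition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive spatial-temporal graph networks for EEG emotion recognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adstgnn)
```

## The problem

Emotion recognition from EEG is hampered by two structural facts: the signal
lives on an irregular sensor graph (electrodes over the scalp, with
functional coupling that does not follow the physical grid), and the signal
distribution shifts strongly between people. `adstgnn` implements a graph
neural network that addresses both: the channel graph is *learned* from the
data rather than fixed a priori, and a domain-adversarial branch aligns
feature distributions between a labeled source domain and an unlabeled
target domain (another subject, or later trials of the same subject).

The model consumes the field's standard feature representation: per-second
differential entropy (DE). For a band-limited Gaussian segment with variance
$\sigma^2$, $\mathrm{DE} = \tfrac12 \log(2\pi e \sigma^2)$ nats; one value
per channel per frequency band per second, so a trial is an
$L \times N \times F_{de}$ array. `compute_de_features()` extracts these
from raw signal (zero-phase Butterworth band-pass, per-epoch variance), but
the model itself is agnostic to how the DE array was produced.

## Model

One model input is a temporal context window
$X \in \mathbb{R}^{T \times N \times F_{de}}$, $T = 2d + 1$ one-second
samples centred on the sample being classified; a trial of length $L$
yields $L - 2d$ windows, each carrying the trial's label.

The pipeline per window:

1. **Temporal attention.** A bilinear score
   $Q = V_e\,\sigma\big((X' U_1) U_2 (U_3 X'') + b_e\big)$ over the $T$
   samples, row-softmaxed to a row-stochastic $T \times T$ matrix $Q'$;
   the window is re-weighted as $\hat X_t = \sum_s X_s Q'_{s,t}$.
2. **Spatial attention.** The mirrored construction over channels yields a
   row-stochastic $N \times N$ matrix $P'$, computed once per window and
   shared across its $T$ segments (the score has no per-segment structure).
3. **Adaptive adjacency.** With per-channel features
   $x_1, \dots, x_N \in \mathbb{R}^{F_{de}}$ (the window's time-averaged
   node features) and a learnable weight vector $w$,
   $$A_{mn} = \frac{\exp(-\mathrm{ReLU}(w^\top |x_m - x_n|))}
                   {\sum_{n'} \exp(-\mathrm{ReLU}(w^\top |x_m - x_{n'}|))},$$
   a row-stochastic affinity that is large for channels with similar
   spectra. $w$ is learned by minimizing the graph loss
   $$L_{gcn} = \tau \sum_{m,n} \lVert x_m - x_n \rVert_2^2\, A_{mn}
       + \lVert A \rVert_F^2,$$
   smoothness (strong edges should connect similar channels) plus a
   Frobenius term that discourages concentrated rows.
4. **Chebyshev spectral convolution.** $L = D - A_{sym}$,
   $\tilde L = \tfrac{2}{\lambda_{max}} L - I$, and the recursion
   $\xi_0 = I$, $\xi_1 = \tilde L$, $\xi_k = 2 \tilde L \xi_{k-1} -
   \xi_{k-2}$ give a $K$-term polynomial filter basis;
   $$X^{sgc}_t = \sum_{k=0}^{K-1} (\xi_k \odot P')\, \hat X_t\, \theta_k,$$
   applied independently per time step, with the spatial attention as an
   element-wise edge mask and $\theta_k \in \mathbb{R}^{F_{de} \times
   F_{out}}$ mixing bands and setting the output width.
5. **Temporal convolution.** $X^{tgc} = \mathrm{ReLU}(\Phi *
   \mathrm{ReLU}(X^{sgc}))$, a zero-padded 1-D convolution along time
   (default kernel length 3, the smallest context-mixing kernel).
6. **Heads.** Mean over time and node-major flattening give a vector of
   length $N \cdot F_{out}$ (310 at the 62-channel defaults), fed to a
   fully connected extractor $f(\cdot)$ (310-64-64-64), then a linear
   classifier head and — through a gradient reversal layer — a binary
   domain discriminator $d(\cdot)$ (64-64-64-2, softmax).

Training solves
$$\min_{\theta_f} \max_{\theta_d}\; L_{classifier} + L_{gcn}
  - \lambda\, L_{disc},$$
with $L_{disc} = -\sum_i \log d(f_i^S) - \sum_j \log(1 - d(f_j^T))$. The
discriminator minimizes $L_{disc}$; the reversal layer hands the extractor
$-\lambda$ times the discriminator's input gradient, so the extractor makes
source and target features indistinguishable while staying discriminative
for emotion. Target windows enter only $L_{disc}$; their labels are never
used.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 3 | context radius in seconds; window length $T = 2d+1$ |
| `K` | 2 | Chebyshev order bound; information from up to $K-1$ hops |
| `F_out` | 5 | per-node output width of the spatial convolution |
| `tau` | 1e-2 | weight of the smoothness term in $L_{gcn}$ |
| `lr` | 1e-3 | RMSprop learning rate |
| `batch_size` | 96 | source windows per step (target batch paired 1:1) |
| `lambda_variant` | `decreasing` | $\lambda(p) = 2/(1-e^{-p}) - 1$ |

The $\lambda$ schedule deserves a note. The decreasing form starts very
large (it diverges as $p \to 0^+$; training starts at epoch 1, i.e.
$p = 1/\text{max\_epochs}$) and relaxes toward 1, emphasizing alignment
early; because RMSprop normalizes per-parameter gradient magnitudes, the
large early $\lambda$ changes the *balance* of gradient directions, not the
step size, and is stable in practice. The conventional increasing DANN
warm-up $2/(1+e^{-\gamma p}) - 1$ ships as `dann_increasing`
($\gamma = 10$) for users who prefer it.

## Design choices where the construction was open

* **Gradient routing for the graph.** $w$ is updated from
  $\nabla_w L_{gcn}$ only; the classification path treats the adjacency and
  the Chebyshev basis as constants (stop-gradient). This matches the
  definition of the adaptive graph update, and avoids differentiating
  through the Laplacian's top eigenvalue. All other parameters — attention,
  $\theta_k$, $\Phi$, extractor, heads — receive exact reverse-mode
  gradients, each verified against central finite differences in the test
  suite.
* **$|x_m - x_n|$ is the element-wise absolute difference.** A signed
  difference would flip sign with pair order and the ReLU would zero half
  the graph arbitrarily; the absolute difference makes the ReLU argument a
  true dissimilarity.
* **$w$ starts small and positive** ($|N(0, 0.1)|$). At $w = 0$ the ReLU
  has zero subgradient everywhere and no gradient signal could ever move
  the graph off uniform; a positive start makes the affinity a genuine
  similarity kernel from epoch 0.
* **Symmetrization.** The graph is undirected but row-softmax $A$ is
  asymmetric; the spectral path uses $(A + A^\top)/2$ so the Laplacian has
  a real spectrum, while $L_{gcn}$ keeps the raw $A$ as defined.
* **Attention as an edge mask.** $\xi_k \odot P'$ (Hadamard) rather than a
  matrix product: masking preserves the polynomial's locality semantics
  (a disconnected graph stays disconnected; the test suite asserts this).
* **Per-step spatial filtering.** The spatial convolution keeps the time
  axis (applied independently at each $t$) so the temporal convolution has
  a sequence to convolve; collapsing time earlier would leave the
  temporal stage nothing to do.
* **Time collapse is mean pooling**, the least committal reduction to the
  $N \cdot F_{out}$ extractor input.
* **Ablation bypasses** substitute the neutral element of each usage site:
  identity $Q'$ (no temporal mixing), all-ones mask for $P'$ (no edge
  re-weighting), `knn_adjacency()` for the adaptive graph (with the graph
  loss dropped, since nothing is learnable there), and removal of the
  discriminator branch ($\lambda \equiv 0$).
* **Evaluation granularity.** Accuracy is reported per window (each
  centred second votes once); trial-level majority-vote accuracy is
  reported alongside, since either convention is defensible.

## Numerical choices

Softmaxes are computed with max-subtraction. Discriminator probabilities
are clamped at $10^{-7}$ inside logs. A zero-variance DE epoch is floored
at $\sigma^2 = 10^{-12}$ with a warning (the DE of a constant is
$-\infty$). An edgeless graph falls back to $\lambda_{max} = 2$ with a
warning. Ties in argmax predictions resolve to the lowest class index.
All randomness (initialization, shuffling, batching, simulation) flows
from explicit seeds; two runs with the same configuration and seed produce
byte-identical reports.

## The synthetic generator

`generate_dataset()` simulates DE features directly rather than simulating
raw EEG and extracting DE — the model consumes DE, so this isolates the
method under test. Per subject $s$ and trial of class $c$:
$$x_t = g_s \odot (\mu_c + z_t) + o_s + \varepsilon_t,$$
where $z_t$ is AR(1) over time with innovations correlated within channel
blocks (the graph structure the adjacency should recover), $\mu_c$ are
class mean patterns `class_sep` noise-SD units apart, and the per-subject
gain/offset $(g_s, o_s)$ realize the affine subject shift — the simplest
shift a DANN can provably reduce. What it does *not* emulate: nonstationary
artifacts, electrode drift, nonlinear subject differences, label noise, or
volume-conduction structure. Passing tests on this generator demonstrate
that the machinery works as specified, not that real-data accuracies
transfer.

Three presets anchor the test suite: `tiny_within` (1 subject, 15 trials,
$L = 30$, $N = 8$, clearly separable, no shift), `tiny_cross` (4 subjects,
no shift — the null control), and `shifted_cross` (4 subjects,
gain/offset SD 0.5).

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen once: the capacity check
trains on the 216 source windows of `tiny_within` at the full defaults
($d = 3$); the domain-adaptation ablation runs leave-one-subject-out on
the 4-subject shifted preset at $d = 1$ with 30 epochs, paired over 5
seeds (3 for the null control); graph recovery trains 10 epochs on
block-structured single-subject data and compares the learned mean
adjacency to the block ground truth by Spearman correlation. At these
sizes the adversarial gain is a direction, not a headline number: the
benchmark-scale accuracies of the literature require the full 62-channel
corpora and far longer training.

## Known limitations

* Pure-R training: fine for $N \lesssim 64$ and desk-scale studies;
  a GPU implementation would be needed for large sweeps.
* The discriminator assumes exactly two domains (source vs target);
  multi-source alignment is out of scope.
* `read_seed_layout()` covers the public precomputed-DE directory layout
  (including zlib-compressed MAT v5 elements) but not structs, cell
  arrays, or v7.3/HDF5 MAT files.
* DE feature smoothing (moving average / linear dynamical system) is
  deliberately not applied by the readers; features pass through
  unmodified.

## A worked example

```{r example, eval = FALSE}
sim <- make_fixture("shifted_cross", seed = 1)
cfg <- model_config(d = 1, max_epochs = 30, batch_size = 48, seed = 1)
report <- run_cross_subject(sim$dataset, cfg)
report
#> <eval_report> 4 folds: mean accuracy 47.50% (sd 13.93)
#>   S01          51.67%
#>   S02          26.67%
#>   S03          55.00%
#>   S04          56.67%
```

(Chance is 33.3% for 3 classes; the per-fold spread reflects how strongly
each synthetic subject's affine shift distorts its features.)
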