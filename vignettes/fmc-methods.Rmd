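---
title: "Feature multi-connection networks: model, training recipe, and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature multi-connection networks: model, training recipe, and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmcnet)
```

## The problem and the model

Deciding whether a lymph node visible on rectal MRI harbors metastasis is a
binary image-classification problem with clinical stakes: nodal status drives
the choice between endoscopic and surgical resection in colorectal cancer.
Radiologists judge a node suspicious by three criteria — irregular borders,
heterogeneous internal signal, and a round (rather than oval) shape.

`fmcnet` implements a family of five-convolutional-layer networks in the
AlexNet mold in which the deeper convolutional outputs are *re-routed
forward*: conv3, conv4 and conv5 feature maps are concatenated channel-wise
into a **merged layer** that feeds the dense classifier head.  The idea is
that mid-level features (edges, local texture — exactly what the three
radiological criteria describe) are otherwise consumed by later layers and
lost to the classifier; wiring them forward makes them directly available
without adding depth or widening any convolutional layer.

The merged layer performs three operations:

1. **Concatenation** of the transmitted maps (they share spatial dimensions,
   13×13 in the full-size geometry, so concatenation needs no resampling);
   with full widths 384 + 384 + 256 this yields a 1024-channel map.
2. **Lp reduction** to one value per channel,
   \(F_c = \left(\sum_{x,y} |F_{x,y,c}|^p\right)^{1/p}\).
   The exponent is configurable with default \(p = 2\); \(p = 1\) is the
   per-channel activation sum and \(p \to \infty\) approaches max-pooling.
   Absolute values keep the root real for odd \(p\); the maps entering the
   reduction are post-ReLU, so this changes nothing in practice.
3. **Linear projection** to the merged width \(D\) followed by a ReLU; the
   result is the input of the first dense layer.

Wiring variants A–E ablate the connection pattern (which maps feed conv5 and
the merged layer); `FMC` is the full pattern — conv4 reads conv3, conv5 reads
concat(conv3, conv4), and the merged layer reads all three.  A structural
invariant holds across the family: every variant has exactly 5 conv layers
with the same per-layer widths as the plain backbone, verified by
`summarize_depth_width()`.

Local response normalization with \(k = 2\), \(n = 5\), \(\alpha = 0.0004\),
\(\beta = 0.75\) follows conv1 and conv2, the placement of the original
AlexNet; the source architecture adopts that backbone and specifies the LRN
hyperparameters but not the placement.

## Interpretation of the merge operator

The connectivity rule is stated in the source work both as an "adding" of
features \(x_n + x_{n+1} + \dots + x_{l-1}\) and, in its algorithm table, as
concatenation ("`+` indicates concatenate operation").  Element-wise addition
is ill-defined across unequal channel counts (384 vs 256), so `fmcnet`
implements `+` as channel concatenation throughout and treats the textual
"adding" as informal.  Variant D's description ("conv3's output as an
additional input of conv4") duplicates conv4's only existing input and would
merely double a channel block; D is therefore realized with C's merge wiring
(merged layer fed by conv4 and conv5), which preserves the one property that
distinguishes it in the ablation table.  Variant A is given a merged layer
fed by conv5 alone so that the family differs only in wiring.  These readings
resolve genuinely ambiguous figures; both are isolated in the wiring table of
`build_architecture()` and trivial to change.

## Training recipe

The loss is mean binary cross-entropy over the batch (predictions clipped at
`1e-7` before the logarithms).  The optimizer is implemented from its update
equations rather than delegated to a framework, so the equations themselves
are testable:

\[v_{i+1} = \mu v_i - \lambda \varepsilon w_i - \varepsilon
\left\langle \partial L / \partial w \right\rangle_{D_i}, \qquad
w_{i+1} = w_i + v_{i+1}.\]

Defaults are learning rate \(\varepsilon = 10^{-4}\), momentum
\(\mu = 0.95\), weight decay \(\lambda = 10^{-6}\), 200 epochs — the
transfer-learning settings of the source experiment.  (The printed update
equation there carries the constants 0.9 and 0.0005, while the surrounding
text states 0.95 and \(10^{-6}\); the text values are presented as the
experiment's settings, so they are the defaults, and both are configurable.)
"Decay" is implemented as the per-step weight decay term \(\lambda
\varepsilon w_i\) that the update equation's structure implies, not as a
learning-rate schedule.  Batch size is never stated in the source; the
default is 32.

Transfer learning freezes the first three convolutional layers (general
features) and retrains the rest.  When a checkpoint initializes a layer whose
input was widened by a skip connection (conv5 under the FMC wiring), the
checkpoint kernels are copied into the leading input-channel slice and only
the extra slice is freshly initialized, preserving the transferred features.
Model selection retains the epoch with the highest validation accuracy
(earliest on ties); the source reports a validation split but no selection
rule.

**Initialization.**  Without a pretrained checkpoint, weights are
scaled-Gaussian (He) with sd \(\sqrt{2/\text{fan-in}}\).  One adjustment
matters: the Lp-reduced vector scales like \(\sqrt{HW}\) times the activation
scale (for \(p = 2\), a sum of \(HW\) squared activations under the root), so
the merged projection's effective fan-in includes the collapsed spatial
extent.  Without this correction the initial logits sit deep in saturation
and from-scratch training on small datasets intermittently collapses to a
constant predictor; with it, training is stable across seeds.  The source
work always starts from pretrained weights and never faces this regime.

## Synthetic benchmark

The clinical MRI dataset behind the source work (3,364 patients; 1,646
positive, 1,718 negative nodes, each > 3 mm in diameter) is private.  The
package therefore ships a generator of lymph-node-like grayscale patches
whose classes differ exactly along the three radiological criteria:

* **Border irregularity** — the nodal boundary is an ellipse whose radius is
  perturbed by a sum of low-order sinusoids (orders 3–8, random phases),
  amplitudes scaled so the RMS radial perturbation equals the irregularity
  parameter.  Any monotone "irregularity knob" would do; this one is simple
  and auditable.
* **Heterogeneity** — interior intensity is the base level modulated by
  multiplicative Gaussian speckle smoothed with a small kernel (σ = 1 px) and
  normalized so the std/mean contrast equals the heterogeneity parameter.
  This mimics heterogeneous signal without committing to MRI physics.
* **Roundness** — the minor/major axis ratio; positives are rounder.

Phenotypes are drawn from class-conditional truncated normals.  Negative
nodes default to irregularity 0.03, heterogeneity 0.05, roundness 0.75;
positive means are interpolated away from those by a `separation` factor
(default 1: irregularity 0.11, heterogeneity 0.20, roundness 0.92), so
`separation = 0` gives identically distributed classes (a no-signal control)
and larger values an easier task.  The default effect sizes were chosen once
to make the default task learnable but not linearly trivial — the class
distributions overlap substantially, as clinical reader performance (accuracy
0.63–0.67 for experienced radiologists) suggests they should.  Node diameters
are uniform between `min_diameter_px` (default 16 px, the pixel analog of the
3 mm inclusion threshold at roughly 0.2 mm/px) and 70% of the patch side; the
source states only that patch size followed lesion size, so patch intensity
statistics and geometry here are free parameters.  Default cohort structure
(3,364 samples, 1,646 positive) mirrors the clinical dataset.

What the generator does **not** emulate: MRI acquisition physics (bias
fields, coil profiles, T2 contrast), anatomy surrounding the node,
partial-volume effects, or inter-rater segmentation variability.  Passing the
recovery tests therefore demonstrates that the implementation can learn the
three stated criteria from images — not that it reaches any particular
performance on clinical data.

## Data handling

Patches are 8-bit grayscale PNGs listed in a CSV manifest
(`path,label,border_irregularity,heterogeneity,roundness,diameter_px`).
Preprocessing rescales to [0, 1], bilinearly resizes to the network input
size, standardizes with mean/sd computed **on the training split only**, and
replicates the grayscale plane to 3 channels to match the AlexNet-style stem
(the source fine-tunes an ImageNet-pretrained backbone but never states how
grayscale input is handled).  A zero-variance image falls back to
mean-centering with a warning.

The 80/10/10 split is stratified by label (the source says only "randomly";
stratification stabilizes the small validation and test estimates) with exact
global counts from largest-remainder rounding, ties resolved in train,
validation, test order — 3,364 records split 2,691/337/336.  Splitting is by
record; the source implies one node per patient, making record- and
patient-level splits equivalent.

## Evaluation

`confusion()` uses threshold 0.5 with the ≥ convention (unstated in the
source).  The panel — sensitivity, specificity, PPV, NPV, accuracy — is
computed from closed forms; zero-denominator metrics are reported as
undefined rather than zero.  ROC curves sweep all distinct thresholds with
the grouped-threshold (midpoint) tie convention; AUC is the trapezoid
integral, which the test suite cross-checks against the tie-corrected
rank-statistic formula and an external reference implementation.  For any
single confusion matrix, accuracy is a weighted mean of sensitivity and
specificity and must lie between them; the package asserts this identity.
(The source's headline panel — sensitivity 0.8732, specificity 0.8741,
accuracy 0.8358 on a near-balanced test set — violates it, so the exact
evaluation protocol behind that table is not recoverable; the identity is
enforced here regardless.)

The merged-width search sweeps powers of two from 32 to 4096, trains on the
training split, selects on validation accuracy (smallest width on ties), and
reserves the test split for the final model only, avoiding selection leakage
the source does not discuss.  The ablation harness trains each wiring variant
under identical seeds and reports the per-variant panel.

## Class-activation heat maps

The heat map is \(M_c = \sum_k w_{c,k} f_k\) over the merged concatenated
feature map.  Because the classifier is not directly connected to the
convolutional maps, \(w_{c,k}\) is defined as the composed linear path from
the Lp-pooled channel vector through the merged projection and dense layers
to the class logit, ignoring the intervening nonlinearities — the standard
class-activation assumption.  A conv5-only mode is provided for the reading
under which only the final convolutional layer is visualized.  Overlays
min-max normalize the map (a constant map becomes all zeros, with a
warning), bilinearly upsample to the image, apply a jet-like colormap with
red at the high end, and alpha-blend over the grayscale input.

## Problem sizes, numerical choices, and limitations

The `tiny` profile (64×64 input, conv widths 16/32/48/48/32, merged width
128, dense widths 64) exists so that the whole pipeline — training included —
runs in minutes on one CPU core; the `full` profile reproduces the AlexNet
geometry (227×227, widths 96/256/384/384/256, merged width 1024).  The
package's own verification protocol trains the tiny FMC from scratch on 400
synthetic patches (80/10/10) for 15 epochs at learning rate 0.01, which
recovers test AUC ≥ 0.9 across seeds at separation 1.5 and stays at chance on
separation-0 data; the zero-signal control is scored on an independent
200-patch set so the Monte-Carlo error of its AUC is small.  Tie-breaks are
deterministic everywhere (max-pooling takes the first maximum; width and
model selection take the earliest/smallest candidate); all randomness flows
from explicit seeds, so identical configs rerun bit-identically.

Known limitations: no GPU path and no automatic differentiation — gradients
are hand-derived for this fixed layer vocabulary (verified against numerical
differentiation), so arbitrary new layer types require writing their
backward pass; no data augmentation or learning-rate schedules (none are
described in the source); the comparison baselines of the source (ResNet152,
DenseNet161, domain-adaptation methods, SVM heads) and its reader study are
out of scope; and no claim is made about clinical MRI performance, which the
private data renders unreproducible.
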