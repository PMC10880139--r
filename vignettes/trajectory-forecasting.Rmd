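---
title: "Methods: calibrated multi-agent forecasting of severity trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated multi-agent forecasting of severity trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trajcast)
```

## The model

`trajcast` predicts an ordinal severity label at the baseline and at each of
T future time points from one baseline image and a handful of scalar
clinical variables. The architecture separates concerns the way a clinic
does. A *radiologist* block R sees only imaging: a small residual CNN
reduces the image to a grid of super-pixel (or super-voxel) cells, each cell
becomes a token of width CX, and a pre-norm transformer encoder with one
[CLS] token contextualizes them. Baseline diagnosis logits come from an FFN
over the average-pooled output sequence. A *context* block C sees only the
clinical variables, one token per variable; its [CLS] output is the
contextual summary of the patient's background. A *general practitioner*
block P sees both: by default every one of the N+1 radiologist output
vectors is concatenated channel-wise with a copy of the context token,
K learnable [CLS] tokens are prepended, and after encoding, the first T+1
output vectors feed the per-horizon prediction heads. Each transformer
layer is the standard pre-norm pair `z = MSA(LN(h)) + h`,
`h = MLP(LN(z)) + z`, with scaled-dot-product multi-head attention and a
GELU MLP. A notational alternative in which query/key/value states chain
across layers is not used: each layer projects its own layer-normalized
input, which is the only reading consistent with the residual update
equations.

Assumptions worth stating: the image is mandatory and carries the baseline
severity signal; clinical variables may be missing and are represented by a
dedicated missing slot in their one-hot encoding (a learned missing token)
rather than being imputed; trajectories are predicted from baseline data
only (no follow-up images are consumed at inference time).

## The loss

Severity forecasting across T+1 horizons is a multi-task problem with tasks
of different difficulty and different class counts. Per task the package
minimizes the calibrated upper bound

$$\mathcal{L}_{CLUB}(t) = \tau_t\,\mathcal{L}_{CE}(t) + (1-\tau_t)\log N_{c_t},$$

a convex combination of cross-entropy and the task's maximum-entropy
constant. For $\tau \in (0,1]$ it upper-bounds the temperature-scaled
cross-entropy $-\log\left(g_c^{\tau}/\sum_{c'} g_{c'}^{\tau}\right)$ by the
reverse Hölder inequality, with equality iff $\tau = 1$; its gradients
factor as $\partial\mathcal{L}_{CLUB}/\partial\theta =
\tau\,\partial\mathcal{L}_{CE}/\partial\theta$ and
$\partial\mathcal{L}_{CLUB}/\partial\tau = \mathcal{L}_{CE} - \log N_c$, so
$\tau_t$ acts as a learnable per-task weight whose optimum reflects task
difficulty relative to chance. The temperatures are parameterized through
noise scalars: $\rho_t = 1/(\sigma_t^2+\varepsilon)$, $\tilde\rho =
\mathrm{softmax}(\rho)$, $\tau_t = \tilde\rho_t/\max(\tilde\rho)$. The
softmax stops all temperatures from drifting to 1 jointly, and the final
rescaling pins $\max(\tau)=1$ so values do not shrink with the number of
tasks. Missing labels are handled by masking:
$\mathcal{L}_{prog} = (\sum_t I_t)^{-1}\sum_t I_t\,\mathcal{L}_{CLUB}(t)$,
and an L1 consistency term $\|f_0^R - f_0\|_1$ ties the radiologist's and
practitioner's baseline logits together with coefficient $\lambda$. The
consistency term is computed on every sample, including those with masked
follow-ups; the prognosis term is averaged over samples with at least one
observed label.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `depths` (R, C, P) | 2, 2, 4 | P benefits most from depth; R and C stay shallow |
| `k_cls` | T+1 | one [CLS] per output head; `1` shares a single head token |
| `head_mode` | common | one FFN for all horizons; `separate` for per-horizon heads |
| `fusion` | channel | context token concatenated per feature vector; `sequence` appends it as a token |
| `pool` | mean | average pooling of R's output for diagnosis; `cls` uses the first vector |
| `lambda` | 0.5 | consistency weight; 0 disables the term |
| `epsilon` | 1e-6 | keeps ρ finite for any σ; negligible distortion for σ in [0.1, 10] |
| `sigma_init` | 1 | all τ start at 1, i.e. training begins as plain cross-entropy |
| `quantize_bins` | 4 | one-hot bins for continuous covariates |
| `lr` | 1e-4 | conservative Adam rate for larger runs; small from-scratch models train at 1e-3 |

Quantization ranges (min/max per continuous variable) are computed on the
training records only and stored with the model, so validation data cannot
leak into the encoding. When a value falls outside the stored range it is
clipped, which is the limiting behaviour of "relative position in the
interval".

Two genuinely open design points were resolved as follows. With `k_cls = 1`
the single [CLS] output vector is fed to all T+1 heads — the sequence
provides one summary token and the heads differentiate horizons. In
attention extraction, the relevant row (the context [CLS] row of block C's
last layer over the M variable positions; the horizon-t [CLS] row of block
P's last layer over the N imaging positions) is averaged over heads
arithmetically and renormalized over the kept positions, so maps remain
comparable across K and across fusion modes; [CLS] self-weight and
cross-modal positions are excluded. The temperature factor multiplying the
CE term stays attached to the graph by default (a `detach_tau` flag treats
it as constant in that product), keeping the full Algorithm-style mapping —
including the softmax, the max and the division — differentiable, with a
subgradient at max ties.

## The synthetic cohort

The generator emulates exactly the statistical structure the model assumes:
a latent per-subject progression rate drawn uniformly from
`progression_rate_range` and shifted linearly by the standardized bmi
covariate (`covariate_effect`, default 0.15); a Markov severity chain that
advances one grade per step with that probability (monotone when
`progressive`, clipped at the top grade); a baseline image whose two bright
bands narrow strictly with the baseline grade, plus grade-count bright
blobs on the outer band edges, morphology jitter and optional Gaussian
noise; independent per-label missingness with the baseline always observed;
and two categorical plus two continuous covariates of which only bmi is
informative. Covariate distributions (age ~ N(60, 8) clipped to [40, 80],
bmi ~ N(27, 4) clipped to [18, 40]) are realistic for an osteoarthritis-age
cohort.

What passing tests on this cohort do show: the architecture can extract a
geometric severity signal from raw pixels, fuse an informative scalar
covariate, respect label masks, learn calibrated multi-task weights, and
recover the generative structure (held-out balanced accuracy ≈ 1 at the
baseline horizon, above-chance at follow-ups). What they do not show:
performance on real radiographs or PET volumes, where the severity signal
is far subtler than a band gap, where covariate effects are entangled, and
where label noise exists; nothing here validates clinical utility.

## Numerical choices

GELU is exact (`x · Φ(x)`). Softmaxes subtract the row maximum;
cross-entropy is computed via log-sum-exp. Layer normalization uses
population variance with eps 1e-5. [CLS] and positional embeddings are
truncated-normal (sd 0.02); linear maps use uniform Kaiming-style
initialization. The L1 consistency term uses the sign subgradient (0 at
ties). Degenerate inputs are defined: a zero-token sequence encodes to the
[CLS] outputs alone; a record whose labels are all masked contributes only
the consistency term; a horizon with no observed validation labels reports
`NA` metrics; `max.col` ties break to the first class. ECE uses 10
equal-width bins over (0, 1]; balanced accuracy averages recall over
classes present in the evaluation labels only; one-vs-one AUROC averages
the ordered-pair rank statistics (Hand–Till) and skips pairs with an absent
class with a warning.

All differentiation is reverse-mode on an explicit tape; every registered
gradient — including the fused multi-head attention and im2col convolutions
— is validated against central finite differences in the test suite, and
the batch-vectorized forward pass is asserted numerically identical to the
per-record one.

## Problem sizes

Tests and the acceptance script use sizes chosen so the whole suite runs
comfortably on one CPU: the recovery experiment trains a width-32 model
(depths 2/2/2, 4 heads, K = T+1) on 480 of 600 subjects for 30 epochs at
batch size 32 and Adam lr 1e-3 — the standard small-network rate; the
package default of 1e-4 reflects fine-tuning-scale runs — and evaluates the
held-out 120, repeated over three seeds. Ablation smoke runs use 24
subjects, 32×32 images and 2 epochs.

## Limitations

Single image per subject (no multi-scan fusion); no pretrained backbones,
so nothing here speaks to transfer learning; attention maps are
interpretability signals, not localization ground truth; the Markov
trajectory model cannot express remission under the default progressive
setting; 8-bit PNG serialization quantizes 2D image intensities to 1/255
(NIfTI volumes round-trip losslessly); training is single-threaded — the
design favours exactness and testability over throughput.
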