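# trajcast

Forecasting ordinal disease-severity trajectories from a baseline medical
image and scalar clinical variables, with calibration-aware multi-task
training — entirely in R, on a single CPU.

## The problem

In chronic progressive disorders (structural knee osteoarthritis graded on
the Kellgren–Lawrence scale, the cognitively-normal → MCI → dementia spectrum
in Alzheimer's disease), clinicians want more than a diagnosis: given a
baseline radiograph or PET volume plus the patient's background (age, sex,
BMI, risk factors), they want the severity grade *y₀* now and at each of T
future visits, i.e. the trajectory *y₀, y₁, …, y_T*. Follow-up labels are
frequently missing, the classes are imbalanced, and — since predictions feed
clinical decisions — the predicted probabilities should be *calibrated*, not
just accurate.

`trajcast` implements a clinically-inspired multi-agent transformer for this
disease trajectory forecasting (DTF) problem:

- **Block R ("radiologist")** — a transformer encoder over tokens extracted
  from the raw image by a small residual CNN; an FFN over the
  average-pooled output sequence emits baseline diagnosis logits *f₀ᴿ*.
- **Block C ("context")** — a transformer over per-variable clinical tokens
  (continuous variables quantized into 4 one-hot bins, categoricals one-hot,
  missingness as a dedicated slot); its [CLS] output *h̄C₀* summarizes the
  patient's background.
- **Block P ("general practitioner")** — fuses modalities channel-wise (a
  copy of *h̄C₀* concatenated onto every imaging feature vector), prepends K
  learnable [CLS] tokens (K = 1 or T+1), and emits one logit vector *f_t*
  per horizon through a common or per-horizon FFN head.

Training minimizes

```
L = L_prog + λ · L_cons,      λ = 0.5 by default
L_prog = (1/Σ I_t) Σ_t I_t · L_CLUB(t)          (I_t = label observed)
L_cons = ‖f₀ᴿ − f₀‖₁                             (agent agreement)
```

where the **CLUB loss** (Calibrated Loss based on Upper Bound) for task t is

```
L_CLUB(t) = τ_t · L_CE(t) + (1 − τ_t) · log Nc_t ,   τ_t ∈ (0, 1]
```

an upper bound on temperature-scaled cross-entropy (tight iff τ_t = 1,
via the reverse Hölder inequality). The per-task inverse temperatures are
learned through noise parameters σ_t under the constraint
ρ_t = 1/(σ_t²+ε), ρ̃ = softmax(ρ), τ_t = ρ̃_t / max(ρ̃), which keeps
max(τ) = 1 and prevents the trivial all-ones solution. Evaluation reports
balanced accuracy (BA), expected calibration error (ECE) and one-vs-one
multiclass AUROC per horizon.

Because no deep-learning framework is assumed, the package ships its own
reverse-mode autodiff tape, im2col 2D/3D convolutions and transformer
encoders in base R matrix code, plus a synthetic longitudinal cohort
generator whose images encode severity through a joint-space-narrowing-like
band gap — so the whole pipeline is testable end to end without any
external imaging data.

## Worked example

```r
library(trajcast)

cfg <- trajectory_config(n_subjects = 200, t_future = 2,
                         n_classes = c(2, 2, 2), image_size = c(64, 64),
                         noise_sd = 0, covariate_effect = 0.15, seed = 11)
cohort <- generate_cohort(cfg)

mcfg <- dtf_config(2, c(2, 2, 2), image_size = c(64, 64),
                   cx = 32, cm = 32, depths = c(2, 2, 2), k_cls = 3)
rc <- run_config(mcfg, epochs = 10, batch_size = 32, lr = 1e-3, lambda = 0.5)
ckpt <- train_dtf(rc, cohort)

tail(ckpt$log, 3)
#>    epoch prognosis consistency     total
#> 8      8 0.1707105   0.1722172 0.2568191
#> 9      9 0.1623996   0.1579367 0.2413680
#> 10    10 0.1572982   0.1567418 0.2356691

evaluate_dtf(ckpt, cohort)
#> Per-horizon metrics:
#>  horizon    ba    ece auroc
#>        0 1.000 0.0461 1.000
#>        1 0.918 0.0424 0.954
#>        2 0.946 0.0750 0.964
```

The loss log shows both the masked prognosis term and the radiologist /
practitioner consistency term shrinking; the report gives per-horizon
balanced accuracy (1.0 = every class perfectly recalled), calibration error
(lower is better) and one-vs-one AUROC on the training cohort. Attention
maps for interpretation:

```r
att <- extract_attention(ckpt$model, cohort[[1]], t = 1)
att$clinical   # weights over sex/site/age/bmi, sum to 1
att$imaging    # map over the CNN token grid, sums to 1
```

A thin CLI mirrors this workflow
(`exec/trajcast generate|train|evaluate|attend`).

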