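---
title: "Estimating gait kinetics from smartphone video with multi-modal knowledge transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gait kinetics from smartphone video with multi-modal knowledge transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkt)
```

## The problem

External knee moments — the knee adduction moment (KAM) and knee flexion
moment (KFM) — and the three components of the ground reaction force (GRF)
are the standard kinetic measures of gait. They normally require a motion
capture laboratory with force plates. This package implements a
video-only estimator: two smartphone cameras provide 2-D joint-center
positions for eleven joints (44 channels after the two image axes of both
cameras), and a neural network maps 50-frame windows (0.5 s at 100 Hz) of
those positions to per-frame kinetics. KAM and KFM are expressed in
percent body weight times height, GRFs in body weights, so the mapping is
subject-size independent.

Two ideas carry the method:

1. **Augmented joint kinematics.** The positions are differentiated twice
   by backward finite differences (`derive_velocity()`,
   `derive_acceleration()`), and position, velocity and acceleration are
   treated as three separate input modalities. The first velocity frame is
   set to zero; the first two and the last acceleration frames are set to
   zero. These edge rules make windows self-contained; differencing is
   applied per trial before windowing.
2. **Multi-modal knowledge transfer.** A *teacher* network additionally
   sees eight inertial measurement units (IMUs: 24 acceleration and 24
   angular-velocity channels) — information a camera cannot provide. Its
   knowledge is transferred to the video-only *student* in two steps:
   first the student encoder is trained so that a linear projection of its
   fused features matches a (fixed) linear projection of the trained
   teacher's concatenated encoder features, under a root-mean-square
   feature-alignment (FA) loss; then the encoder is frozen and only the
   fusion module and output head are trained on the kinetics loss.

## Architectures

The **student** (`gait_model()` variant `aug_mfm_gate_bilstm_attngcn`)
encodes each of the three kinematic modalities with a batch-normalization
layer followed by two stacked bidirectional LSTM layers (width `C`,
dropout after each layer). In parallel, a spatial branch reshapes each
modality into an 11-node skeleton graph (4 features per node: two cameras
times two axes): a per-node linear score, softmax-normalized over the
nodes, weights each joint (the attention should concentrate on the leg
that generates the kinetics), and a graph convolution
`ReLU(A V W + b)` with a self-looped, row-normalized adjacency `A`
(`skeleton_graph()`) propagates information between connected joints
before a fully connected projection restores width `C`. The temporal
(3`C`) and spatial (3`C`) streams are merged by a gated network:
`W_gate = sigmoid(FC([x_bilstm, x_gcn]))`, fused
`= W_gate * x_bilstm + (1 - W_gate) * x_gcn`. A multi-fusion module (MFM,
below) refines the fused stream, and a fully connected head (one hidden
ReLU layer) emits the five kinetics per frame.

The **teacher** (variant `imu_jcp_mfm`) uses three Bi-LSTM encoders —
IMU accelerations, IMU angular velocities, joint positions — whose
concatenated features pass through the same MFM and a single linear
output layer.

Eight student variants and four teacher variants form the ablation grid
(`student_variants()`, `teacher_variants()`): position-only input, early
fusion of the three modalities into one encoder, per-modality encoders
with plain concatenation, GCN-only and attention-GCN-only spatial
encoders, additive and gated combination of both branches, and finally
the gated model with the MFM.

### The multi-fusion module

The MFM is a composite of four submodules on the fused 3`C` stream, each
reweighting or mixing the three `C`-wide modality blocks from a different
angle; the module output is the input plus the sum of the selected
submodule outputs, so any subset preserves the width and the empty set is
the identity. The four submodules are this package's own design, built
from the module names and the contract that they capture complementary
views of inter-modality interaction:

* **LWF** (linear weighted fusion): a learned per-channel sigmoid gate.
* **WFF** (weighted feature fusion): per-frame softmax weights over the
  three modality blocks, computed from the full fused vector.
* **MHAF** (multi-head attention fusion): scaled dot-product attention
  across the three modality blocks as tokens.
* **TMF** (temporal mean fusion): a gate computed from the concatenation
  of each frame with its window-mean context, modelling slow temporal
  structure.

### Optimisation

All models train with Adam (learning rate 0.001 by default), RMSE loss
over all predicted frames, batch size 64, at most 40 epochs with early
stopping after 10 epochs without validation improvement, retaining the
weights of the best validation epoch (`train_config()`). Validation is a
held-out training subject by default, preventing window-level leakage; a
fraction-based split is available. Kinetics targets are standardized per
component on the training set inside `train_model()` and predictions are
mapped back to physical units — an internal conditioning device that
leaves the reported metrics unchanged in meaning.

Since no deep-learning framework is assumed, the networks run on a small
reverse-mode automatic differentiation engine written for this package
(dense matrices, BLAS-backed, with fused backpropagation-through-time for
the LSTM direction). Its gradients are tested against central finite
differences for every operation and for the full encoders.

### Knowledge transfer, in detail

Step 1 optimises the student encoder and a trainable linear projection of
its features against a *frozen* random linear projection of the frozen
teacher's features. A design note: with both projections trainable the
zero map trivially minimises the FA loss, and we observed exactly this
collapse (the alignment loss shrinking by scale contraction while the
downstream student got worse). Freezing the teacher-side projection — in
the spirit of hint-based distillation, where the teacher's representation
is a fixed target — removes the degenerate minimum; only the student-side
projection adapts. Step 2 freezes the encoder completely, including the
batch-normalization statistics (a strict reading of frozen weights), and
trains the MFM and head on the kinetics RMSE off the frozen features.

The knowledge-distillation baseline (`train_student_kd()`) instead trains
the full student jointly on `L_student + alpha * L_KD`, where `L_KD`
matches the student's predictions (and optionally projected features) to
the teacher's; `alpha_sweep()` crosses `alpha` in {0.1, 0.3, 0.5, 0.7,
0.9} with both loss variants.

## The synthetic gait simulator

Real recordings of this kind (17 treadmill-walking subjects with
synchronized cameras, IMUs and force plates) cannot ship with a package,
so `simulate_gait()` generates data with the same structure and a known
forward model, making every stage testable end to end:

* **Kinematics.** Each joint-axis path is a sum of sinusoids: gait
  harmonics at the subject's stride frequency (0.8–1.2 Hz; vertical
  motion at twice that frequency; left/right limbs in antiphase; three
  harmonics with 1/k amplitude decay) plus three small channel-specific
  sinusoids on a jittered 0.5–12 Hz grid representing soft-tissue and
  impact vibration. Closed-form first and second derivatives are
  therefore exact. Subjects differ in stature, mass, stride frequency and
  jittered amplitudes (`subject_effect_sd`, default 10%).
* **Cameras.** Perspective projection (3 m distance) of the sagittal and
  frontal views, a small fixed roll per camera, and a slow multiplicative
  scale jitter per trial (handheld zoom/distance drift), then Gaussian
  pixel noise (default 0.005 of height, about 9 mm of pose-estimator
  error), per-frame mid-hip re-centering and height normalization. The
  re-centering makes the two hip channels exact mirror images — an exact
  collinearity the forward model accounts for by carrying all hip weight
  on the left-hip channels.
* **IMUs.** Eight sensors (pelvis, trunk, thighs, shanks, feet) report
  the analytic segment acceleration plus gravity and the angular velocity
  of their segment vector (`w = s x s' / |s|^2`), with small Gaussian
  noise (0.02 in SI units).
* **Kinetics.** A strictly linear forward model
  `K = P Cp + V Cv + A Ca` over the noise-free camera positions, their
  velocities, and the *segment accelerations* — the IMU-privileged
  signal. Camera noise is amplified roughly 100-fold by double
  differencing, so a video-only model cannot recover the acceleration
  term cleanly while the teacher reads it directly: the teacher's
  advantage, and what knowledge transfer can usefully transfer, exist in
  the simulator by construction.

Several generator choices were forced by identifiability rather than
realism alone: orthographic cameras would make camera-2 vertical channels
exactly collinear with camera-1 channels, and a single shared gait
harmonic series would leave the 112 forward coefficients unidentifiable
from any finite recording; perspective, camera roll, scale jitter and the
per-channel vibration grid give `recover_forward_coefficients()` a
well-posed least-squares problem, verified to recover the generating
coefficients to machine precision on noise-free data.

What the simulator does **not** model: pose-estimator failure modes
(occlusion, identity switches), soft-tissue artifact with realistic
spectra, non-stationary gait, force-plate noise structure, and any true
musculoskeletal inverse dynamics. Tests passing on this generator
demonstrate that the algorithms are implemented correctly and that the
transfer mechanism works when a privileged signal exists; they do not
certify accuracy on real gait data.

## Evaluation

`nrmse()` is the RMSE as a percentage of the ground-truth range of the
evaluated subject and component (per-subject normalization matches the
per-subject averaging); `pcc()` is Pearson correlation over the subject's
concatenated frames. `loso_folds()` builds leave-one-subject-out folds
(test subject excluded from training at window level; one training
subject held out for validation). `aggregate_report()` reports component
means ± sd across subjects and an **overall** value defined as the
unweighted mean of the five component values — the convention is checked
against the published tables shipped in
`reference_component_metrics()`: the five student components average to
4.68% NRMSE / 0.951 PCC and the teacher's to 3.63%, matching the printed
overall values. `compare_models()` is a paired-t surrogate (with
Bonferroni correction) for the repeated-measures ANOVA of the original
analysis, and is labelled as such.

## Desk-scale experiment profiles

Training the full models at publication scale (hidden width 64, 17
subjects, 40 epochs, leave-one-subject-out) is a GPU-days workload. The
package's experiment functions therefore default to desk-scale profiles,
chosen once as the package's study conditions:

* `kt_benefit_experiment()`: 10 simulated subjects with two 6-second
  trials each, hidden width 32, batch size 32, learning rate 0.003, 12
  epochs per stage, 5 replicate seeds; one held-out test subject and one
  validation subject. Under this profile the seed-averaged ordering
  teacher ≤ student+KT ≤ student-without-KT is reproducible, with the
  transfer helping in essentially every seed.
* The noise-free sanity run (see the test suite) zeroes every stochastic
  dial, including the between-subject coefficient jitter, so the kinetics
  are one exact linear function shared by all subjects. It uses 8
  subjects, dense windows (stride 25), hidden width 48 (the concatenated
  encoder must be wider than the 112 forward-model features), no dropout,
  and a four-stage annealed learning-rate schedule (5e-3 down to 2e-4).
  The slow part of this fit is the recurrent encoders learning to
  reconstruct the velocity features by temporal differencing: with
  per-frame features alone the best attainable NRMSE on held-out data is
  about 3.7%, and the annealed schedule is what carries the network below
  2%.

Numerical conventions worth knowing: batch-normalization variances are
clamped at 1e-5 (constant channels stay finite); the NRMSE of a constant
ground-truth series is an error, not infinity; window counts follow
`floor((T - 50)/stride) + 1` with half-open windows; short trials are
skipped with a warning; zero-padded steps (`pad_step_to_length()`, 152
frames) carry their true length so the padding is removed exactly.

## Limitations

The published accuracy figures for real gait data are not reproducible
at desk scale and are not claimed by this package; the acceptance
machinery checks conventions, oracles and orderings instead of absolute
real-data errors. The MFM submodules are the package's own formulation
of the four named fusion mechanisms. Finite differencing without
smoothing amplifies camera noise in the acceleration modality by design;
low-pass filtering before differencing is deliberately out of scope.
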