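---
title: "Models and methods behind ethomotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ethomotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ethomotif turns markerless pose-estimation time series of one or two mice
(DeepLabCut-style tracking tables: per frame and body part, x, y and a
tracking likelihood) into behavioral readouts along two routes: supervised
annotation of named behaviors (contacts, look-around, wall interactions,
the stopped-and-huddled posture) and unsupervised discovery of behavioral
clusters with a time-aware variational embedding, followed by the
downstream statistics a stress-phenotyping study needs (habituation
binning, enrichment, behavioral entropy, explainability, composite
Z-scores). This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic validation data can and
cannot show.

## Coordinate conventions and preprocessing

Coordinates follow the image convention: origin at the top-left of the
frame, y increasing downward, frames numbered from zero. Pixel data are
converted to millimeters by a user-supplied `px_per_mm` calibration
(`to_mm()`); no automatic calibration is attempted because the recording
geometry is not recoverable from tracking tables alone. Missing detections
are stored as `likelihood = 0`, never dropped, so frame indices always
align with video time.

Cleaning proceeds in four stages, in this order:

1. **Savitzky-Golay smoothing.** Each coordinate series is replaced by a
   local least-squares polynomial fit over a sliding window of one second
   (`frame_rate` frames, rounded up to odd). The polynomial order defaults
   to half the window but is capped at `window - 2`, since a fit of order
   `>= window - 1` interpolates and stops filtering.
2. **Likelihood-based quality flagging.** A centered, edge-truncated
   moving average (window: one second) is fitted to each part's
   likelihood series; frames deviating *below* it by at least 3 residual
   standard deviations are flagged. Flagging is one-sided because upward
   confidence spikes are benign. Two guards matter in practice: frames
   with likelihood below an absolute floor (default 0.5) are always
   flagged — a confidence that low is unreliable no matter what its
   local average is — and residual SDs below 1e-10 are treated as zero so
   constant series are never flagged on floating-point noise.
3. **Iterative ridge imputation.** Flagged cells are treated as missing,
   initialized by temporal interpolation, and then filled by round-robin
   regression: each incomplete coordinate is regressed (closed-form ridge,
   penalty 1e-2) on all other body-part coordinates at the same frame,
   iterating until the relative change falls below 1e-3 (at most 10
   rounds). Because the skeleton is nearly rigid, the other parts encode
   both the animal's position and its heading, so occluded parts are
   recoverable to roughly the posture-jitter scale. Frames in which every
   part is flagged carry no spatial information and fall back to temporal
   interpolation. Because the smoothing stage mixes a flagged frame's
   corrupted coordinates into its window-mates, the pipeline dilates the
   imputation mask by the smoothing half-window.
4. **Jump correction.** A second moving-average model is fitted to the
   coordinates themselves; points at least 3 residual SDs away are
   replaced by interpolation from unflagged neighbors. Detection and
   replacement are iterated until a full pass flags nothing, which makes
   the operation exactly idempotent. The residual scale uses the plain SD
   by default: it adapts the threshold to the animal's overall movement
   roughness so that only gross teleports are touched (a robust MAD
   variant is available for heavily corrupted series, but on heterogeneous
   motion it under-estimates the scale and starts chasing real movement).

Published pipelines of this style fit their moving-average models
without stating window or centering conventions; both are configuration
here (`preprocess_config()`), defaulting to centered one-second windows.

## Kinematic features

`extract_features()` computes egocentric coordinates (a rigid per-frame
transform putting the animal's center at the origin and its center-to-
front-spine axis on +y; if the two reference points coincide the previous
frame's rotation is reused), all pairwise distances within and across
animals, four joint angles per animal (head, neck and two spine vertices —
the anatomical set is configurable since no canonical list exists), four
shoelace polygon areas (full outline, head, torso, back) and time
derivatives. Speeds are computed on arena-frame (not egocentric)
coordinates so locomotion is captured; first-order derivatives are
frame-to-frame differences scaled by the frame rate, padded by repeating
the first value so all series keep full length; higher orders are finite
differences of the lower order.

## Supervised annotation

The rule-based annotators are pure per-frame predicates on distances and
speeds, all thresholds in mm and mm/s, all comparisons strict, and every
flag gated on a tracking likelihood of at least 0.85 for all involved
parts. Defaults (contact 15 mm, still 40 mm/s, head movement 20 mm/s,
wall sniff 10 mm, climb overhang 5 mm) are sensible for adult mice in a
38 cm arena and are configuration, not constants; they are echoed into
output metadata. Annotators are deliberately independent: several can be
true on the same frame.

The stopped-and-huddled classifier is shipped as a training harness rather
than fixed weights: a gradient-boosting machine on a frozen,
versioned registry of 26 per-frame variables (adjacent head/spine
distances, spine stretch, limb-anchor distances, the four areas and their
derivatives, six part speeds). Features are standardized twice — within
each session, which removes body-size differences, and across the training
set — and class imbalance is handled by SMOTE applied to training folds
only. Performance is reported as balanced accuracy over stratified k-fold
cross-validation or a leave-one-dataset-out loop. A subtlety worth knowing:
when checking the harness against label permutations, permute the pooled
label vector across sessions. A within-session permutation preserves each
session's behavior prevalence, which is itself learnable from the
session's kinematics, and therefore scores above chance without any
label-feature association.

All annotator outputs pass through Kleinberg burst smoothing: the gaps
between positive frames feed a hierarchy of exponential gap models whose
baseline rate is anchored to the *full observation window* (events per
frame over the whole series), each level multiplying the rate by `s`
(default 2) with a level-up cost of `gamma * log(n_events)` (default
gamma 1). The minimum-cost state sequence is found by dynamic programming;
frames inside bursts of level >= 1 are kept and merged, positives outside
any qualifying burst are dropped. Anchoring the baseline to the
observation window rather than to the event span is a deliberate choice:
with span-only anchoring, a single dense block of detections defines the
baseline itself and would be discarded as "not bursty", which is exactly
wrong for behavioral bouts.

## The unsupervised embedding

Sessions are converted to annotated graphs: one node per body part with
three features per frame (egocentric x, y and arena-frame speed), edges
along the skeleton annotated with inter-part distances, plus nose-nose,
nose-tail and tail-tail edges between animals in dyadic sessions. Windows
of one second (stride 1 by default) are standardized twice (per animal,
then globally per channel; scalers are stored). Note that the center's
egocentric coordinates are identically zero by construction and stay so.

The model is a mixture-of-Gaussians variational autoencoder for
spatio-temporal graphs. The encoder processes each node (and edge)
independently with a temporal block — a same-padded 1-D convolution
(kernel 5) followed by two GRU layers — then shares information across the
skeleton with a CensNet-style co-convolution in which node
representations aggregate over the normalized adjacency plus the averaged
incident-edge representations, and edge representations aggregate over the
line graph plus their endpoints. Mean-pooled node and edge summaries map
to an 8-dimensional diagonal-Gaussian posterior. The latent prior is a
mixture of K diagonal Gaussians — one component per behavioral cluster —
and the decoder mirrors the encoder (dense layer, per-node/edge GRUs
seeded from the latent code plus learned node identity embeddings, linear
read-out) emitting per-frame Gaussian means with unit variance.

The training loss is the negative evidence lower bound: the Gaussian
reconstruction error of node and edge features plus the KL divergence
between the variational posterior and the mixture prior, computed with
the standard mixture decomposition (responsibility-weighted Gaussian KLs
plus a categorical KL between responsibilities and mixture weights), plus
an L1 penalty on the node embeddings of the graph layer (weight 0.25 by
default) that balances inter-animal interaction against individual
behavior in dyadic graphs. Cluster assignment is the argmax of the
mixture posterior of the latent code — component weight times component
density, normalized — always evaluated in log space with log-sum-exp so
extreme separations cannot produce NaN; ties break toward the lowest
index. The responsibilities in the loss are computed from the latent mean
and treated as constants during backpropagation, the standard practice for
this model family.

Everything is trained with a hand-written reverse-mode automatic
differentiation tape over matrix operations (verified against finite
differences in the test suite), the Nadam optimizer (learning rate 0.001),
gradient clipping by global norm at 0.75, up to 150 epochs with early
stopping on the total validation loss (patience 15) and best-epoch weights
restored. The validation split is made at the video level, never at the
window level, taking 10% of videos (rounded up). Two stabilizers matter:
a reconstruction-only warm-up precedes mixture training, after which the
mixture is initialized by k-means on the warm-up latents (component
variances from the cluster scatter, weights from cluster frequencies);
and at every epoch end a component whose average responsibility falls
below 1% of its uniform share is revived by moving its mean onto a
randomly encoded window. Without revival, mixture components collapse
often enough to merge distinct motifs.

## Downstream statistics

*Global embeddings* summarize a session as the K-vector of time
proportions per cluster. *Habituation binning* scans growing windows
(10–600 s, every second by default), computing at each length the exact
earth-mover (Wasserstein-1) distance between the two conditions' clouds
of global embeddings; the argmax is the optimal bin length and the
distance is then reported over consecutive non-overlapping bins of that
length. The distance is computed exactly, as a minimum-cost assignment
(Jonker–Volgenant shortest augmenting paths in C++) with unequal sample
sizes handled by replicating both clouds to the least common multiple of
their sizes; no estimator or entropic regularization is involved.

*Enrichment* compares per-session cluster proportions between conditions
with two-sided Mann-Whitney U tests per cluster and bin,
Benjamini-Hochberg adjusted jointly across all cluster-by-bin tests;
fully tied samples give p = 1. *Behavioral entropy* counts transitions
(including self-transitions) between consecutive non-overlapping windows
— overlapping stride-1 labels are thinned to window stride first, since
stride-1 counting inflates self-transitions through autocorrelation —
pools them per condition, row-normalizes, finds the stationary
distribution by power iteration from uniform (L1 tolerance 1e-10, capped
at 1e5 iterations, with a warning for chains that do not converge) and
reports its Shannon entropy in nats.

*Cluster-number selection* trains the model over a k range (5–25 by
default, five repeats each), scores each k by the leave-one-out
cross-validated AUC of a logistic regression separating the conditions in
global-embedding space, and picks the smallest k within one standard
deviation (of the best k's repeats) of the global maximum. The embedding
step is injectable so the selection rule can be exercised without
training dozens of deep models.

*Explainability* describes each window by a frozen, versioned registry of
per-window means — exactly 52 features for one animal (11 speeds, 11
skeleton distances and their 11 derivatives, 4 angles, 4 areas and 4 area
derivatives, spine stretch and its derivative, the ear-to-ear distance,
and 4 supervised-annotator fractions) and 111 for a dyad (each animal's
52 plus four inter-animal distances and three dyadic annotator
fractions) — and fits a gradient-boosting classifier from these
statistics to cluster labels, with standardization and SMOTE on training
folds only and cross-validation grouped by video so no video ever spans a
fold boundary. Feature importance is reported as mean absolute Shapley
values from a permutation explainer: marginal contributions along random
feature orderings against a background sample (default 100 rows), whose
telescoping sum makes attributions exactly additive per sample.

*Composite Z-scores* express each subject's readout in control-group
standard deviations (sample SD, denominator n-1), flip the sign of tests
where the behavior of interest decreases, and average across tests. Two
presets are included: a stress-physiology pair (relative adrenal weight
and day-21 body weight, both positive) and a social-interaction battery
(look-around and huddle positive; speed, nose-to-tail and nose-to-body
negative). The supporting Pearson correlation excludes points more than 5
residual SDs from the least-squares line.

## The synthetic cohort generator

Every stage is validated against simulated sessions with complete ground
truth (`simulate_session()`, `simulate_dyad()`, `simulate_cohort()`). An
animal is a rigid 11-part skeleton (realistic adult-mouse proportions,
~70 mm nose-to-tail) driven by a Markov regime chain over kinematic
motifs; the default repertoire is darting (150 mm/s, straight), walking
(50 mm/s) and a huddle-like still motif (2 mm/s, skeleton shrunk to 55%).
Dynamics are deliberately band-limited, as real trajectories are: speed
relaxes continuously toward the active motif's mean (AR(1), ~0.3 s
timescale), heading integrates a smooth AR(1) angular velocity
(~0.5 s timescale, diffusion-scaled so path roughness is frame-rate
invariant), posture jitter is AR(1) with ~0.6 s correlation, and wall
encounters steer the animal back at a bounded turn rate (4 rad/s) rather
than reflecting instantaneously. On top of this biological truth the
generator adds white 2 mm tracking noise, occlusion runs (likelihood
collapses below 0.2, coordinates corrupted by 50 mm noise) and
single-frame 200 mm tracking jumps, all with recorded masks. Dyadic
sessions script approach/contact/side-by-side bouts with exact dyadic
labels; scripted placements are clamped inside the arena and approaches
converge monotonically onto their contact waypoint by construction.

Condition effects emulate an arousal phase: during the first
`arousal_window_s` seconds (default 120 s of 600 s sessions) the stressed
condition's transition matrix is blended toward a huddle-locking matrix
(self-transition 0.99) with linearly growing weight — no effect at the
session start, full strength at the window end — after which both
conditions share a common matrix (self-transitions 0.95). The ramp is
deliberate: the growing-window distance scan identifies the time at
which *accumulated* group differences peak, and with a constant-strength
effect that accumulation plateaus as soon as the regime chain mixes
(tens of seconds), leaving the argmax to sampling noise anywhere on the
plateau. A ramp peaking at the window boundary makes the construct the
scan is supposed to recover well defined. The stressed condition also
ends up with measurably lower behavioral entropy.

What passing tests on this generator do *not* show: robustness to
identity swaps in multi-animal tracking, to non-rigid postures (rearing,
grooming distort the skeleton in ways a scaled template does not), to
arena-dependent lighting artifacts, or to motifs that differ only in
subtle posture dynamics rather than speed and shape. The generator is a
validation instrument, not a claim about mouse behavior.

## Study scales used by the test suite and acceptance script

Simulation sizes were chosen so each check exercises the intended
statistics at desk scale: preprocessing recovery uses twenty 60 s
sessions; the rule-annotator oracle runs on a 5,000-frame dyad; motif
recovery trains the reduced model (hidden width 16, latent dimension 8,
K = 3) on four 450 s sessions at 10 fps — about 30 minutes of video —
with window stride 10 and up to 35 epochs, across up to three seeds;
habituation binning and entropy use five cohorts of ten 600 s sessions
per condition, with downstream statistics driven by the regime ground
truth so their behavior is isolated from embedding quality; enrichment
calibration uses 200 null replicates of 10 clusters by 4 bins. The
acceptance script reruns the same computations at comparable scales from
a single command-line seed.

## Known limitations

- The embedding trains on CPU in R; at full stride-1, hour-long,
  25 fps scale it is slow compared to GPU implementations. The
  architecture widths default to desk scale and are configurable.
- The exact assignment-based Wasserstein distance is intended for
  cohort-sized clouds (tens of sessions); pathological coprime sample
  sizes inflate the lcm-replicated problem and are rejected above 3000
  points.
- HDF5 tracking tables are not read; use the CSV export of the tracking
  software.
- The huddle classifier harness learns whatever labels it is given; the
  shipped defaults reproduce a separable stopped-and-huddled motif on
  synthetic data and are not a substitute for lab-specific labeled
  frames.
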