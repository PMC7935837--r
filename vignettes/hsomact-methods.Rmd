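---
title: "Hierarchical SOMs for online skeleton action recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical SOMs for online skeleton action recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsomact)
```

## The problem

A depth-camera skeleton tracker delivers a stream of posture frames — 20
named joints, each with (x, y, z) in meters — while a person performs one
action after another with no pauses and no markers. The recognizer must
decide, *while the stream is running*, which action is being performed and
roughly when one action ends and the next begins. This package implements a
three-layer architecture for that task built entirely from
self-organizing maps (SOMs) and a one-layer supervised read-out, together
with the preprocessing that makes skeleton data comparable across actors and
viewpoints, and a seeded synthetic generator that reproduces the statistical
structure the architecture assumes.

## The architecture

### Preprocessing

Every frame is mapped into an ego-centered coordinate system anchored at the
stomach joint: the lateral axis points from the right hip to the left hip,
the forward axis is the unit normal of the stomach–hips plane, and the
vertical axis completes a right-handed triad. The frame is then scaled so
the stomach-to-neck segment has length `target_len` (default 1, making all
further quantities dimensionless body units). The composition is exactly
invariant under any global rigid motion and any uniform scaling of the
skeleton — the invariance suite checks this to 1e-6 over fuzzed poses.

An attention mechanism then reduces dimensionality: the four joints with the
largest accumulated displacement (summed per-frame displacement magnitude;
the frame rate is assumed constant) are kept, and their coordinates are
concatenated in ascending joint order into a 12-dimensional posture vector.
Ties in motion break toward the lower joint index so the layout is
deterministic. Offline, attention is computed over the whole sequence;
online it is evaluated from a trailing buffer of 15 frames, and only
(re-)evaluated at pattern-window resets so the input semantics stay fixed
within a window. The first online evaluation waits until the buffer is
full: motion sums over two or three frames are dominated by tracker noise,
and a wrong joint set would garble the entire first window. One exception
to reset-only re-evaluation exists, for robustness: if no key activation
arrives for a full buffer span, attention is re-evaluated immediately. A
noise fluke at a reset can otherwise hand the attention to a near-static
joint, freezing the layer-1 winner — and since re-evaluation normally
waits for a window reset that now never comes, the stream would stay dead
indefinitely.

### SOM layers

Both lattice layers use the same competitive-learning rules. Each neuron
holds a weight vector; the net input is the Euclidean distance
`s_ij = ||x - w_ij||`; the activity is `y_ij = exp(-s_ij / sigma)`; the
winner is the argmax of activity (ties resolve row-major); adaptation moves
every weight toward the input by `alpha(t) * G(t)` with a Gaussian
neighborhood `G = exp(-d / (2 sigma_nb(t)^2))` centered on the winner, and
every weight vector is renormalized to unit length after each step. The
neighborhood kernel uses the *unsquared* lattice distance by default — the
form the architecture is defined with — and a `squared_distance` switch
selects the textbook squared-distance Gaussian. Under the unsquared kernel
the lattice distance at which the kernel falls to 1/e is `2 sigma_nb^2`, so
the package parameterizes the default schedules by that *radius*: the
initial width makes the 1/e radius half the lattice, and the width decays
exponentially to `nb_sigma_end` (1 lattice unit for layer 1, 0.5 for
layer 2) over the training run. Adaptation strength decays exponentially
from `alpha0` with time constant equal to the total step count. Any
monotone-to-zero schedule satisfies the architecture's contract; these
particular forms were chosen so that the quantization error visibly
plateaus at the problem sizes this package targets.

Inputs are *not* normalized — only weights are. Matching is therefore
effectively directional: the winner is the best-aligned unit vector. This
matters for two numerical decisions discussed below.

### Key activations and pattern windows

The stream of layer-1 winners is compressed by collapsing consecutive
repeats: a posture counts as *key* only if it elicits a different winner
than its predecessor. This is what makes the representation robust to
performance speed — duplicating every frame k times provably leaves the key
sequence unchanged, and the test suite asserts this exactly. Non-consecutive
repeats are kept: a neuron may fire again later in the action.

Key activations are blocked into consecutive, non-overlapping windows of
fixed length `T` (default 30). `mean_key_length()` implements the rule that
seeds `T` from the mean key-trace length of a training set (rounded half
up), after which it is an ordinary configuration value. Each window is
encoded as a `2T`-vector with slot q holding `((row+1)/I, (col+1)/J)` of the
q-th key activation; unfilled slots hold 0, which is unambiguous because
every filled entry is positive. Online, a buffer absorbs winners one at a
time (collapsing duplicates, including across window resets), emits each
completed window and resets; feeding any winner stream step by step
reproduces batch segmentation exactly.

### Output layer

The second-layer activity map (length `L = rows x cols`) feeds a one-layer
supervised network with one unit per action class. Activities are cosine
similarities `y_i = (a . w_i) / (||a|| ||w_i||)`; learning moves weights by
`w_i <- w_i + beta * a * (d_i - y_i)` against one-hot targets, with rows
normalized once at initialization and never again. The bracket `(d - y)`
descends the squared error; the flag `sign_as_printed` restores the
ascending variant `(y - d)` for auditability. On mutually orthogonal inputs
the rule provably reaches perfect argmax accuracy within a few dozen
epochs, which the test suite asserts.

### The streaming recognizer and its certainty gate

One *iteration* is the arrival of a unique posture frame (an exact repeat of
the previous frame is ignored). Each iteration: preprocess, attend,
quantize with layer 1, push the winner through the online buffer. Whenever
a new key activation arrives, the current zero-padded window is classified
and the prediction feeds a certainty gate: a label is emitted only after
`n_c` consecutive identical predictions (default 5, the low end of the
architecture's 5–7 band, minimizing latency), only while the window already
holds at least `gate_min_fill` key activations (default 10 — certainty over
a nearly empty window is meaningless, and without this guard a two-key
window can produce a stable spurious emission), and the same label is not
re-emitted until the next window reset. A completed window resets the
buffer, the gate, and re-evaluates attention, in that order, after the
iteration has been scored.

## Numerical decisions

**The activity sharpness at the head interface.** With unit-norm weights
and pattern vectors of norm ~4, net inputs across the second-layer lattice
span a band whose *meaningful* differences (winner vs. runner-up regions)
are a few hundredths. An exponential factor much larger than that scale
flattens the map: with `sigma = 1e6` all activities differ only in the 6th
decimal, and the class signal reaching the cosine read-out is smaller than
the read-out's own training jitter, so no learning rule can use it (we
verified this analytically and empirically before settling the design).
For winner *selection* the factor is irrelevant — exp is monotone — so
layer 1 keeps the large default. The map fed to the head uses
`layer2_sigma_exp = 0.02`, the scale of real net-input differences, and is
computed *winner-relative*: `a = exp(-(s - min s)/sigma)`. The shift is a
positive rescaling that the cosine metric cannot see; it exists purely so
the values neither underflow at sharp sigma nor vary over orders of
magnitude between inputs during head training.

**Substring training for phase 2.** In a running stream, a freshly reset
window picks up the ongoing action at an arbitrary key offset, and the
window the gate classifies grows one key at a time. Training layer 2 and
the head only on action-*aligned* windows therefore leaves the online
recognizer classifying inputs it has never seen (we measured chance-level
online accuracy in exactly this configuration). Phase 2 consequently trains
on contiguous *substrings* of each training key trace: complete offset
windows for the second-layer SOM, and substrings of length
`substr_min_len` (12) up to `T` at several offsets for the head, capped per
class so long traces do not bias it. Substrings shorter than ~12 keys are
left out deliberately: several actions share short sub-movements (the
arm-lift onset most prominently), so very short windows are intrinsically
ambiguous and training on them only dilutes the head. The runtime windowing
is untouched — fixed, non-overlapping blocks of `T`.

**Online scoring.** An emission is attributed to the ground-truth interval
containing the majority of its window's source frames (ties to the earlier
interval). An interval's recognized label is its *last* attributed emission
— the recognizer's settled answer: with confusable onsets an early wrong
emission is often corrected within the same action once discriminative keys
arrive. Intervals with no emission count as wrong and are tallied
separately. Emission-level accuracy (correct emissions / all emissions) and
per-iteration accuracy curves per class are reported alongside.

## The synthetic generator

`generator_config()` defines the study conditions the package is tested
under: ten one-arm action primitives (vertical/horizontal waves, punch,
hammer, catch, throw, tennis swing, drawing an X, a tick, a circle) as
parametric displacement curves of the right hand, followed by the wrist,
elbow and shoulder at amplitudes 1 : 0.8 : 0.45 : 0.2 — distal joints sweep
wide arcs, the shoulder stays nearly static, matching the trajectory
structure of real skeleton recordings. Per sequence the generator draws a
base frame count (40–60), a speed multiplier (0.7–1.3) with a smooth
within-sequence speed profile (slow phases produce runs of near-identical
postures), additive AR(1) tracker noise (stationary SD 2 mm, correlation
0.95 — skeleton trackers drift smoothly; independent per-frame noise at
realistic amplitudes makes the thin stomach–hip triangle's normal jitter
and, through the lever arm of distal joints, breaks the motion-based
attention contract), and a global yaw (±180°), translation (±1 m per axis)
and scale (0.8–1.2) that the ego transform and size scaling must undo. A
`shared_onset` switch prepends an identical arm-lift segment to the six
classes that naturally begin by raising the arm, reproducing the
confusable-beginnings difficulty of real action sets.

What the generator does *not* emulate: biomechanical constraints (no
inverse kinematics — joints move along curves, segment lengths are not
exactly preserved under noise), two-arm or leg actions, actor-specific
style, occlusion dropouts, and within-class variation of the trajectory
*shape* (instances differ by timing, noise and viewpoint, not by idiosyncratic
path deformation). Passing benchmarks on these data therefore demonstrates
the architecture's segmentation and invariance machinery, not performance
on any real motion-capture corpus.

## Benchmarks and problem sizes

Two scaled benchmark experiments accompany the package (they are also what
`scripts/acceptance.R` recomputes): a five-class problem with 12 sequences
per class and a ten-class problem with `shared_onset` enabled and 10
sequences per class, each split 80/20 stratified by class, trained with the
default configuration (30x30 posture SOM, 35x35 pattern SOM, T = 30,
N output units). These sizes keep a full train-and-evaluate cycle in the
low minutes on one CPU while preserving the qualitative structure of the
original experimental design — including offline accuracy exceeding online
accuracy on unsegmented streams, and five-class performance exceeding
ten-class performance. Expect roughly: perfect training-set accuracy and
~90-100% held-out offline accuracy on the five-class problem; ~80-100%
offline on the ten-class problem; online accuracy on the ten-class
shared-onset streams typically lands between 0.4 and 0.8 depending on the
generator seed (about 0.63 at the shipped benchmark seeds). Online varies
far more than offline: a set of three shuffled streams contains only 60
scoring opportunities, window boundaries fall differently in every
concatenation, and six of the ten classes open with an identical arm lift,
so early emissions within those actions are intrinsically ambiguous and
must be corrected by later ones.

## Known limitations

- The slot-positional window encoding makes window comparison sensitive to
  temporal alignment; speed robustness holds exactly only for *exact* frame
  repeats (the key-collapse guarantee), while smooth speed variation changes
  the sampling density along the trajectory and with it the key-trace
  length. Coarser first-layer quantization absorbs more of this variation
  at the cost of posture discrimination.
- The certainty gate trades latency for stability; with `n_c = 5` and the
  fill guard, actions shorter than ~15 key activations in a misaligned
  window can pass without any emission.
- All randomness is driven by explicit seeds; training is bit-reproducible
  for identical (data, configuration) and is deliberately single-threaded.

## A worked call

```{r example, eval = FALSE}
cfg <- generator_config(classes = action_primitives()[1:5], seed = 42)
dataset <- generate_dataset(cfg, 12, seed = 42)
split <- split_dataset(dataset, 0.8, seed = 7)
model <- train_model(split$train, hsom_config(seed = 3))
glance(evaluate_offline(model, split$test))
stream <- generate_stream(cfg, c("punch", "draw_x", "wave_vertical"),
                          seed = 99)
online <- evaluate_online(model, list(stream))
tidy(online)
plot_iteration_curves(online)
```
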