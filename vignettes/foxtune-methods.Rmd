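---
title: "Methods: the contracted fox optimizer and its evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the contracted fox optimizer and its evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxtune)
```

# The optimization model

The FOX family models a red fox hunting prey under snow by sound. The state
is a population of `n_agents` positions in a box, a per-agent vector of
simulated sound travel times `T` resampled uniformly in `[0, 1]` each
iteration, and an elite archive of the best position and fitness seen so far
(minimization convention throughout; maximize by negating the objective).

Per agent per iteration a uniform draw `r` against `r_threshold = 0.5`
selects the phase, with exploitation on `r >= 0.5` (the inclusive side
follows the algorithm's stated branch rule):

* **Exploitation.** The sound speed toward the incumbent best is
  `Sp_S = BestX / T` elementwise; the travel distance `Sp_S * T` halves into
  the fox–prey distance (the signal made a round trip); the jump height is
  the ballistic `0.5 * g * (mean(T)/2)^2` with `g = 9.81`. The candidate is
  `Dist * Jump * c1` when a second draw `p` exceeds `p_threshold = 0.18`
  (a northeast pounce) and `Dist * Jump * c2` otherwise, with defaults
  `c1 = 0.18`, `c2 = 0.82` inside their admissible ranges `[0, 0.18]` and
  `[0.19, 1]`. The three-step distance chain algebraically collapses to
  `0.5 * BestX`; we keep the intermediate quantities as separate, testable
  functions and verify the collapse as a property.
* **Exploration.** `BestX * u * (MinT * a)` with fresh uniform `u`, `MinT`
  the minimum over agents of the mean travel time, and `a` decaying
  linearly from 2 to 0 over the run, `a = 2 * (1 - it/max_iter)`. A printed
  variant of this coefficient that *grows* with the iteration count
  contradicts its role of shrinking exploration as the search matures; the
  decaying form is the default and the growing form remains available as
  `legacy_a = TRUE` for comparison runs.

Candidates are clamped to the box (projection — the simplest contract that
keeps every visited position feasible), evaluated, and replace their agent
unconditionally; only the elite archive is greedy, so the best-so-far
history is non-increasing by construction. A non-finite objective value
keeps the agent's previous fitness and logs a warning rather than poisoning
the population.

## The contracted variant (CFOA)

Two modifications define the contracted variant:

* **Lévy-flight exploration.** The uniform multiplier is replaced by a
  heavy-tailed step `w = A / |B|^(1/xi)`, `A ~ N(0, sigma^2)`,
  `B ~ N(0, 1)`, with index `xi = 3/2` and `sigma` from the standard
  step-scale closed form
  `[Gamma(1+xi) sin(pi xi/2) / (Gamma((1+xi)/2) xi 2^((xi-1)/2))]^(1/xi)`
  (`sigma(1) = 1` exactly, `sigma(1.5) ≈ 0.6966`). `|B|` is floored at
  `1e-12` so steps are always finite. Only the exploration displacement is
  Lévy-driven; the phase-selection draw `r` stays uniform, since the
  substituted displacement is the one concretely defined by the variant.
* **Elimination phase.** Every `ep = 40` iterations the `et = 30` agents
  with the worst (highest) fitness are culled and resampled uniformly in
  the current box, then re-evaluated immediately (each event adds `et`
  evaluations to the exact budget `n_agents * (max_iter + 1)`). Before
  resampling, any dimension where a *surviving* agent's coordinate
  magnitude exceeds `th = 60%` of that dimension's absolute magnitude has
  both limits scaled by `expand_factor = 1.25` about zero, so the box is
  monotonically non-shrinking. The threshold is quoted ambiguously in its
  source (80 in one sentence, 60% in the operational description); the
  operational 60% is the default and both are configurable. The expansion
  magnitude is unspecified anywhere, so any finite factor above 1
  qualifies; 1.25 is the default.

Determinism is a hard contract: the per-iteration draw order is fixed (the
full time matrix, then `r`, then `p`, then the full exploration-multiplier
block, drawn whether or not each row explores), so a seed reproduces a run
bit for bit regardless of branch outcomes.

## Benchmarks and the trial protocol

The registry ships eight classical analytic functions (sphere, Rosenbrock,
Rastrigin, Ackley, Griewank, Schwefel 2.21, the Lévy surface, Zakharov)
with documented boxes and known minima. The trial protocol runs an
optimizer 25 times with consecutive seeds and reports Best / Mean / StD
(sample standard deviation; 0 by convention for a single run) in the
conventional comparison-table layout. The only built-in comparator is
random search at the identical evaluation budget — published competitor
metaheuristics are deliberately out of scope, and external benchmark suites
that require shift/rotation data plug in through the objective contract
(`function(numeric vector) -> scalar`).

A caveat the tests make explicit: the exploitation move contracts the
population toward scaled copies of the incumbent best, so origin-centered
minima (like the sphere's) collapse to numerical zero quickly. This flatters
the optimizer on origin-symmetric functions; the hyperparameter-recovery
check below probes the harder non-origin case.

# The imaging pipeline

## CLAHE

Contrast-limited adaptive histogram equalization is built from four
primitives so each step is independently testable: per-tile histogram,
clipping, cumulative distribution, and rescaling onto the `L` levels,
`C'(k) = (L-1) * C(k) / n_pixels`. Choices that the generic description
leaves open:

* `n_pixels` is the **per-tile** pixel count. Using the whole-image count
  would break the mapping's normalization for any multi-tile grid.
* Clipping is literal by default — `H'(k) = min(H(k), T)`, discarding the
  excess. The standard redistribution (excess spread uniformly, total
  conserved, remainder round-robin from bin 0) is available behind
  `redistribute = TRUE`.
* The clip limit is accepted either as an absolute count or as a fraction
  of the tile pixel count (`clip_unit`), since both conventions circulate.
* Ragged images are reflect-padded on the bottom/right to a grid multiple,
  and the output is cropped back; tiles therefore stay uniform.
* Tile mappings merge by bilinear interpolation between the four
  surrounding tile centers (edge tiles replicated), the conventional
  artifact-free choice; `merge = "nearest"` applies each tile's own map,
  which is the mode that per-tile oracles can check exactly.

With a single tile and a clip limit at or above the maximum bin count the
output equals plain global histogram equalization pixel-exactly — this is
the oracle the tests use. Output values live in `[0, L-1]` unrounded.

## Normalization, resize, augmentation

Min–max normalization maps onto `[0, 1]`; a constant image is defined as
all zeros with a warning (the formula's denominator vanishes). Resizing is
bilinear to `target x target` with the grayscale plane replicated across
channels; both 227 and 512 circulate as network input sizes, so the target
is an argument with 227 as the default.

Augmentation samples rotation (±7°), x/y shear (±0.03), x/y translation
(±35 px) and x/y scale (0.4–3) uniformly from their intervals, composes a
single affine transform in the fixed order scale → shear → rotate →
translate about the image center, and warps with bilinear resampling and
zero fill. Axis reflections are deterministic flags, off by default.
Composition order and fill are unspecified by the description; fixing them
is what makes augmented outputs reproducible. The degenerate configuration
(all intervals collapsed to identity values) returns the image unchanged,
which the tests assert exactly.

## Losses, class weights, metrics

Cross entropy uses the sum convention over samples (`reduce = "mean"`
optional); the true-class probability is floored at `1e-12` before the
logarithm. The weighted variant multiplies each sample's log-probability by
its true class's weight and reduces exactly to plain cross entropy at unit
weights; the focal variant decays each sample by `(1 - p)^delta` and
reduces at `delta = 0`. The focusing exponent default is 2, the
conventional choice where none is stated. Class weights update from
per-class error rates `Er = 1 - TPR` through a monotone transform
(identity, cube, or `exp(s*y)` with slope 1, 10 or 100), normalized to sum
to one; an all-zero denominator yields uniform weights with a warning. The
class count is an argument (3 for the reference collection; probability
vectors of other lengths work unchanged).

Metrics derive from a true-by-predicted confusion matrix. The binary
formula set (accuracy, sensitivity, precision, F1) applies per class via
one-vs-rest reduction with macro averaging for more than two classes;
undefined ratios (empty predicted or true class) report 0 with a warning.
A brute-force per-formula oracle cross-checks every metric on random
matrices in the tests.

The depthwise-separable convolution cost functions implement
`C_nor = h w d_i d_j k^2`, `C_sep = h w d_i (d_j + k^2)`; their ratio
`d_j k^2 / (d_j + k^2)` is independent of the spatial size and input depth,
asserted as an identity.

# The synthetic data generator

The generator emulates the *structure* of the reference three-class
brain-MRI collection: grayscale images with a bright head-like elliptical
background (peak 120 of 255, soft falloff) plus Gaussian pixel noise
(default sd 8) and one class-conditional hyperintense blob (+80):

* class 1 (meningioma-like): a single round blob at 0.22–0.3 image-widths
  from center — peripheral;
* class 2 (pituitary-like): a small near-central blob;
* class 3 (glioma-like): a large irregular blob of 2–4 overlapping lobes.

Default per-class counts mirror the reference collection (708/930/1426) and
512-pixel images; tests and examples use 32–64 pixels and tens of images
per class, which keeps the whole suite around a minute. What the generator
does **not** emulate: anatomy, scanner physics, intensity inhomogeneity,
partial-volume effects, inter-subject variability, or any overlap between
class geometries. Passing tests therefore demonstrate that the pipeline's
mechanics are correct and that the tuner can exploit a clean signal — not
that any accuracy level transfers to real MRI data.

Records round-trip through a minimal MAT v5 container (numeric arrays,
uncompressed, little-endian) holding `image`, `label` and optionally
`mask`; the reader also accepts records wrapped in a `cjdata` struct with
`tumorMask` naming, the layout used by the public collection, treating
unknown fields as optional. PNG export provides a human-viewable side
channel.

# Hyperparameter tuning

The search space covers the four scaled-network knobs: depth multiplier
(0.25–1), width multiplier (0.25–1), input resolution (grid
128/227/256/384/512, nearest-point snapping, ties to the smaller), and
dropout rate (0–0.5). The reference configuration (0.5, 0.75, 512, 0.2)
encodes and decodes exactly.

`tune()` optimizes in the per-dimension **normalized unit box** and maps
back through the decode rule. The raw coordinates span three orders of
magnitude (0.5 for dropout versus 384 pixels for resolution), and the
optimizer's moves are multiplicative rescalings of the incumbent best, so
unnormalized search would be severely anisotropic. This normalization is a
property of the tuner; the public `decode_position()` contract is
unchanged.

The shipped objective is a deliberately small stand-in for network
training that still consumes the pipeline end to end: images are resampled
per the resolution knob (working size capped at 64 px to stay desk-scale),
features are an 8×8 pooled intensity grid, a 4×4 edge-energy grid, six
radial ring means, and a hyperintense-lesion block (area and radial
centroid above an absolute threshold of 0.66 of the intensity ceiling —
placed above the synthetic background's peak so blob geometry reads out
linearly). The width and depth multipliers rescale the spatial and edge
feature blocks against a shared ridge penalty; dropout enters through its
exact marginalized form for linear models, the adaptive ridge penalty
`rate/(1-rate) * diag(X'X)` that is the expectation of training under unit
masking — deterministic where sampled masks would make the fitness an
artifact of the mask draw. A ridge one-vs-rest linear classifier
(`lambda = 0.1`) fits on a stratified 80/20 split and the fitness is
`1 - validation accuracy`. Real network training plugs in through the same
contract, `function(hyperparams, seed) -> fitness`.

The stratified splitter takes, per class, the nearest integer to
`frac * n_class` samples uniformly at random — the rule that reproduces
the reference collection's printed 2451/613 split from its class sizes.

## A known limitation: refinement near non-origin optima

Because exploration rescales *all* coordinates of the best position jointly
(`BestX * w * (MinT * a)`), fine one-coordinate-at-a-time refinement near
an optimum away from the origin only happens through lucky joint draws or
the elimination phase's uniform resamples. On a quadratic centered at the
reference configuration, recovery of all four hyperparameters within 10% of
their interval widths succeeds for most but not all seeds at the
60-agent / 200-iteration protocol (roughly nine in ten in our measurements).
This is a property of the algorithm's move structure, not of the
implementation, and is the flip side of the contraction that makes it so
fast on origin-centered benchmarks.

# Numerical conventions

* Travel times and `|B|` in Lévy steps floored at `1e-12`; true-class
  probabilities at `1e-12`.
* Probability-vector rows must sum to 1 within `1e-9`.
* Resolution snapping breaks ties toward the smaller grid point;
  `which.min` on absolute distance.
* Sample standard deviation (`n-1`) in trial statistics; 0 for one run.
* The splitter's nearest integer is `floor(x + 0.5)` (half rounds up),
  independent of platform rounding mode.
* Worst-`k` selection in the elimination phase uses `order(fitness,
  decreasing = TRUE)`, so ties resolve by index order, deterministically.

# Problem sizes

The test suite uses 3–60 agents, 5–200 iterations, images of 16–64 pixels,
and datasets of up to 150 images; the acceptance computations use the full
60-agent / 200-iteration / 25-run protocol on the 10-D sphere, one million
Lévy draws for the tail-index estimate, and 150 synthetic images. The whole
suite runs in about a minute on one core.
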