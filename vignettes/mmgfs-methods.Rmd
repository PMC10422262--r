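---
title: "Swarm-based wrapper feature selection for MMG movement recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-based wrapper feature selection for MMG movement recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mechanomyography (MMG) is the low-frequency (< 100 Hz) mechanical vibration
produced by laterally oscillating muscle fibers during contraction, recorded
here with accelerometers on four thigh muscle sites. Classifying knee and
ankle movements from multichannel MMG is useful for rehabilitation-training
interfaces, and with four channels and four feature families the feature
space (108 columns) is far larger than the information it carries. `mmgfs`
implements the full recognition pipeline with the feature-selection step as
its core: a *wrapper* that searches the space of feature subsets directly by
the cross-validated accuracy of the downstream classifier, driven by two
continuous swarm optimizers — the chameleon swarm algorithm (CSA) and the
grasshopper optimization algorithm (GOA) — whose positions are decoded into
binary masks by a transfer function and a threshold $T$.

## Preprocessing

Raw recordings are band-pass filtered to 5–100 Hz (4th-order Butterworth,
applied forward–backward with `signal::filtfilt` so filtering is zero-phase
and burst onsets are not displaced). Movements are segmented by short-time
energy: the mean squared amplitude pooled over channels in a sliding window
(default 32 samples = 128 ms at 250 Hz, hop 16), thresholded at a *relative*
fraction (default 0.1) of the maximum windowed energy. Active runs closer
than 0.2 s are merged and segments shorter than 0.3 s dropped. The window,
hop and threshold are conventions of this package — chosen as typical values
for muscle-burst detection — and are all configurable; the relative
threshold makes segmentation invariant to the overall gain of the
acquisition chain.

## Feature families

Per channel and segment, four families are extracted (27 features per
channel; 108 over four channels):

* **TD (10)** — RMS, unbiased variance, zero crossings, waveform length,
  slope sign changes, log detector, mean absolute value, v-order, simple
  square integral, average amplitude change. The ZC/SSC dead-bands default
  to 0 and are configurable; counts depend on them. The v-order exponent
  defaults to $v = 3$, which makes it distinct from RMS ($v = 2$).
* **FD (2)** — mean power frequency and median frequency of a Welch PSD
  (Hann window, segments of `min(256, n)` samples, 50 % overlap).
* **WE (11)** — level-4 wavelet-packet node energies. The transform uses
  periodized orthonormal Daubechies filters (default `db4`), implemented in
  the package because circular convolution keeps the transform exactly
  orthonormal: the 16 terminal-node energies sum to the signal energy to
  machine precision (the test tolerance of 1 % leaves room for the
  zero-padding bookkeeping on awkward lengths). Terminal nodes are
  frequency-ordered by the usual Paley-to-sequency (band-mirroring)
  permutation; at 250 Hz the bands are 7.8125 Hz wide and exactly the 11
  bands spanning 7.8125–93.75 Hz lie inside the 5–100 Hz passband, so 11
  energies are kept per channel.
* **NLD (4)** — approximate, sample and fuzzy entropy plus Lempel–Ziv
  complexity. Entropies use the field-standard $m = 2$, tolerance
  $r = 0.2\,\mathrm{SD}$ (making them amplitude-scale invariant) and fuzzy
  exponent 2; fuzzy entropy removes each template's own mean. Sample
  entropy with no matches at length $m+1$ returns the finite upper bound
  $\ln B$ with a warning instead of infinity. LZC binarizes at the median
  and normalizes the 1976 parsing count by $n / \log_2 n$.

No normalization is applied at extraction time: z-scoring happens inside
cross-validation from training-fold statistics only, so no information leaks
from held-out folds (the label-shuffling test in the suite confirms accuracy
collapses to chance).

## The optimizers

Both optimizers maximize an arbitrary fitness over a box, run for a fixed
iteration budget, and are deterministic given their seed; the best-so-far
fitness trace is non-decreasing by construction. Positions that leave the
box are clamped to the violated bound.

**CSA** iterates three phases. *Prey search*: with probability $1 - P_p$ a
coordinate moves by $p_1 r_2 (P_{ij} - G_j) + p_2 r_1 (G_j - x_{ij})$
(personal best $P$, global best $G$); otherwise it explores with a uniform
jump scaled by $\mu = e^{-(\alpha t / T)^3}$, which decays from 1 so
exploration fades over the run. *Eye rotation*: each position is rotated
about its own coordinate centroid by a planar (Givens) rotation in two
random dimensions with an angle uniform in $[-\pi, \pi]$ — an isometry of
the centroid offset. *Hunt*: a PSO-like velocity update
$v \leftarrow \omega v + c_1 r_1 (G - x) + c_2 r_2 (P - x)$ with inertia
$\omega = (1 - t/T)^{p_w t/T}$, followed by the kinematic position step
$\Delta x = (v_{new}^2 - v_{old}^2) / 2a$ with
$a = 2590\,(1 - e^{-\log_{10} t})$. Because $a(1) = 0$ and $a$ divides the
step, it is floored at $10^{-6}$; everywhere else the formula is used as
stated. Defaults $P_p = 0.1$, $\alpha = 4$, $c_1 = 2.0$, $c_2 = 1.8$,
$p_w = 1$ follow the algorithm's original description; the search-phase
gains default to $p_1 = 2.0$, $p_2 = 1.8$, mirroring the hunt gains.

**GOA** moves each individual under summed pairwise social forces
$s(r) = f e^{-r/l} - e^{-r}$ ($f = 0.5$, $l = 1.5$: repulsive up close,
attractive at mid range, with a single comfort distance) applied along the
unit vector between individuals and scaled by $c \cdot c\,(ub - lb)/2$ —
the decay coefficient $c$ enters twice, once inside the sum and once
outside — plus attraction to the best solution found. $c$ decays linearly
from 1 to $10^{-5}$. Individuals at exactly coincident positions contribute
zero force.

Two printed-formula points were resolved in favor of sane dynamics:
initialization uses $Lb + r(Ub - Lb)$ (the stated $Ub + r(Ub - Lb)$ leaves
the box for any $r > 0$), and the exploration coefficient is implemented so
that it *decays* with iteration ($\mu(T) = e^{-\alpha^3}$), matching the
accompanying description of diminishing exploration.

## Wrapper selection

One optimizer coordinate per feature, searched in $[0, 1]$ (configurable).
At evaluation time a coordinate is pushed through a transfer function —
default S1, the logistic $1/(1 + e^{-x})$; S2, S3 and the V-family
$|\tanh x|$, $|x/\sqrt{1 + x^2}|$ are available, the absolute value keeping
V outputs in $[0,1]$ — and the feature is kept iff the value is *strictly*
greater than $T$. On $[0, 1]$ the S1 outputs span $[0.5, 0.731]$, so the
conventional grid $T \in \{0.3, \dots, 0.6\}$ walks solutions from
select-all to sparse. An all-zero mask is repaired to the single largest
transformed coordinate, since the fitness is undefined at $R = 0$ and a
classifier without inputs is meaningless; a value exactly equal to $T$ is
not selected. The optimizer's dynamics stay continuous throughout —
binarization only interprets positions at evaluation time, it never feeds
back into them.

Fitness is $\alpha\,acc + (1 - \alpha)(1 - R/N)$ with $\alpha = 0.99$:
almost all weight on the cross-validated accuracy with a light parsimony
pressure on the selected count $R$ out of $N$ features.

Candidate masks are scored by stratified cross-validation (default 10-fold)
of an RBF-kernel soft-margin SVM (`e1071`, one-vs-one for four classes,
$C = 10$, $\gamma = 1/(R \cdot \overline{\mathrm{var}})$, which is $1/R$
after z-scoring; no nested hyperparameter search — the wrapper is expensive
enough). The fold assignment is fixed once per run so all fitness
comparisons are consistent, which also means a mask's fitness is
deterministic: evaluations are memoized per mask, a pure speed-up with no
semantic effect. A single stratified holdout mode (`cv_config(mode =
"holdout")`) is available as a cheaper surrogate for large sweep
experiments. Reported metrics are the fold-mean accuracy, the pooled
held-out row-normalized percent confusion matrix (rows sum to 100; the
diagonal is the per-class recognition rate), and the fold-mean selected
count (constant per mask, so equal to $R$).

## The synthetic generator

Human MMG recordings of this kind are rarely public, so the package ships
a seeded generator that emulates the structure of a typical session: 4
classes × 100 repetitions × 4 channels at 250 Hz, each movement a
band-limited (5–100 Hz) noise burst between rest periods. Class identity is
encoded the two ways channel subsets matter in practice: a per-channel
amplitude gain row (default: one dominant and one secondary channel per
class, swapped within the knee/ankle pairs) and a class spectral centroid
(defaults 30/36/42/48 Hz, bandwidth ±15 Hz). Trial-to-trial variability —
the dominant source of difficulty in real muscle data — is emulated by
log-normal gain jitter (SD 0.3) and Gaussian centroid jitter (SD 4 Hz);
these defaults were set so that the full 108-feature, 10-fold accuracy of
the default dataset lands in the 0.85–0.95 operating range typical of
4-class movement recognition. The rest-noise floor is 5 % of the burst
amplitude, which the relative energy threshold separates cleanly; every
generated movement is pushed through the *real* preprocessing path, and a
movement that does not segment into exactly one burst is an error, not a
repair.

What the generator does **not** emulate: biomechanics (no motion artifact
beyond the band limits, no fatigue drift, no electrode/sensor placement
variability, no between-subject structure, no class imbalance). Passing
tests on synthetic data therefore demonstrate that the pipeline's machinery
is correct and well-calibrated, not that the recognition rates transfer to
human recordings.

A second, abstract generator plants `k` class-informative Gaussian columns
among pure-noise columns and is used to validate the selector: with
`n = 200, p = 50, k = 5`, effect size 3, the wrapper recovers at least 4 of
the 5 informative columns in the large majority of seeds.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise: the sphere benchmark in
$D = 10$ (population 30, 500 iterations, 10 seeds); planted recovery at
`n = 200, p = 50` with population 20, 30 iterations, 5-fold fitness, 10
seeds; and the threshold sweep on the default 400-segment dataset at a
reduced wrapper budget (population 10, 20 iterations, holdout fitness, 5
seeds) — sizes chosen to probe each property at the smallest scale where it
is informative. Other numerical conventions: sample indices are 0-based
half-open in all interchange formats; zero-variance columns are centred but
not scaled; `lb = ub` is allowed as a degenerate search box; wavelet inputs
are zero-padded to a multiple of $2^{level}$ (energy-neutral).

## Known limitations

* The per-node energies of the periodized transform differ slightly from
  implementations using other boundary or filter-phase conventions; totals
  and band ordering agree.
* GOA as specified (no distance remapping) collapses diversity quickly once
  $c$ is small; it is cheaper per improvement than CSA but explores less —
  visible in the threshold sweep, where its accuracy responds worse to
  rising $T$ than CSA's. This mirrors the qualitative contrast the method
  was designed to expose.
* The wrapper's cost is one cross-validated SVM fit per *distinct* mask per
  run; with 10-fold CV on hundreds of segments, budget population × iters
  accordingly or use holdout mode.
* `select_features` fixes one fold assignment per run; reported accuracies
  are honest for that assignment but, like any wrapper, optimistically
  biased as estimates of generalization — compare against a held-out
  replicate for unbiased numbers.
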