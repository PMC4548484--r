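---
title: "Fractional Mel cepstra for two-class speaker-state detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional Mel cepstra for two-class speaker-state detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frcc)
```

## The problem

Magnitude Fourier analysis discards the phase of a signal: the amplitude
spectra of `cos(w0 t)` and `cos(w0 t + theta)` are identical.  If a speaker
state (calm versus stressed/deceptive speech) perturbs mainly the *phase and
chirp structure* of voiced speech rather than its power spectrum, features
built on the ordinary spectrum — MFCC above all — cannot see the difference.
The fractional Fourier transform (FrFT) generalizes the Fourier transform to
a rotation by an angle $\alpha$ in the time–frequency plane,

$$S_\alpha(u) = \int s(t)\, K_\alpha(t,u)\, dt, \qquad
K_\alpha(t,u) = \sqrt{\tfrac{1 - i\cot\alpha}{2\pi}}
  \exp\!\Big(i\,\tfrac{t^2+u^2}{2}\cot\alpha - i t u \csc\alpha\Big),$$

with $\alpha = p\,\pi/2$; $\alpha = \pi/2$ is the ordinary transform,
$\alpha = 0$ the identity and $\alpha = \pi$ time reversal.  For
$\alpha \ne \pi/2$ the magnitude $|S_\alpha(u)|$ of a phase-shifted cosine
*retains* the phase offset, and a linear chirp is compacted into a narrow
pulse at the matched angle.  Fractional Mel cepstral coefficients (FrCC)
exploit this: they are MFCC computed on the FrFT magnitude spectrum, with
the fractional frequency axis mapped by $u = f\,\sin\alpha$ before Mel
warping.  At $\alpha = \pi/2$, FrCC and MFCC coincide exactly, which is the
central identity the test suite verifies.

Because no public corpus accompanies the protocol this package emulates
(two-class 8 kHz/16-bit utterances, SNR above 25 dB), a seeded synthetic
generator provides the study corpora; see "What the generator does and does
not emulate" below.

## Discretizing the fractional transform

The kernel above is continuous; a discrete implementation must pick a grid.
We sample both $t$ and $u$ on the symmetric dimensionless grid
$t_k = (k - N/2)\,\Delta_\alpha$ with

$$\Delta_\alpha = \sqrt{2\pi\,|\sin\alpha| / N}.$$

This spacing is the unique symmetric choice for which the middle factor
$e^{-i t u \csc\alpha}$ sampled on the grid is exactly a centered DFT, making
the weighted kernel matrix *exactly unitary* for every $\alpha$ — not merely
unitary in the continuum limit.  At $\alpha = \pi/2$ the grid reduces to the
usual $\sqrt{2\pi/N}$ lattice and the matrix to the centered unitary DFT.
The fast path factorizes the same matrix as
chirp-multiply $\to$ centered FFT $\to$ chirp-multiply, in $O(N\log N)$, and
agrees with the entrywise kernel quadrature to machine precision; the slow
matrix is kept as the oracle that guards the FFT phase and index
bookkeeping.  Angles within $10^{-6}$ of a multiple of $\pi$ are routed
through the analytic identity/reversal branches, where $\csc\alpha$ is
numerically singular.

**The additivity trade-off.**  Sampling-type discrete FrFTs tie each order
to its own grid, so the index-space composition
`frft(frft(x, a1), a2)` is only approximately equal to `frft(x, a1 + a2)`:
the intermediate vector is re-interpreted on a grid of different spacing (a
dilation), and no choice of test signal removes the mismatch.  This is a
known structural property of unitary sampling-type discretizations, not an
implementation defect.  The analytic additivity law is restored by
`frft_compose()`, which between stages divides out the accumulated quadratic
chirp phase, resamples the smooth remainder onto the next grid by sinc
interpolation, and re-chirps.  For pulse-like signals the composed and
direct transforms then agree to near machine precision.  Eigendecomposition
discretizations would make naive composition exact but sacrifice the exact
correspondence with the sampled kernel — here the kernel correspondence and
exact unitarity were chosen as the primary contracts, since feature
extraction applies only single transforms.

## The FrCC front end

Frames of 20 ms advance by 10 ms (the protocol geometry at 8 kHz: 160
samples, hop 80), after first-order pre-emphasis (0.97) and a Hamming taper
— conventional MFCC choices, left unstated by the emulated protocol, adopted
so that the $\alpha = \pi/2$ branch is a textbook MFCC.  Frames are
zero-padded to `n_fft = 256` and transformed; the magnitude on the
nonnegative-$u$ half-axis (128 bins) enters a bank of `n_mels = 24`
unit-peak triangular filters whose edges are equally spaced in
$\mathrm{mel}(u) = 1125 \ln(1 + u/700)$ over $(0, (f_s/2)\sin\alpha]$ and
snapped to spectrum bins.  Only $\sin\alpha$ enters the bank, so orders
symmetric about $\pi/2$ share one filterbank; the transform itself still
distinguishes them (chirp direction).  Filter amplitudes are floored at
`log_floor = 1e-10` before the natural logarithm — an all-zero frame then
yields a constant log-energy vector whose cepstra vanish — and an
orthonormal type-II DCT over the $M = 24$ filters,

$$\mathrm{FrCC}_n = \sqrt{2/M} \sum_{k=1}^{M} \log E_k
  \cos[\pi (k - 0.5) n / M], \qquad n = 1,\dots,12,$$

keeps 12 coefficients.  The order-0 term is dropped, which also makes the
cepstra exactly invariant to amplitude scaling of the frame.  Twelve delta
coefficients (regression half-width 2 frames, edges replicated) complete the
24-dimensional vector.  `n_mels = 24` is the common choice for 8 kHz speech;
the normalization $\sqrt{2/M}$ makes the DCT orthonormal over the filter
energies (a per-coefficient rescaling otherwise, with no effect on any
classifier downstream).

## Classifiers

**Fisher LDA.**  For class matrices $X_1, X_2$ the discriminant maximizes
$J(w) = (w^\top(\mu_1-\mu_2))^2 / (w^\top d_w w)$ with $d_w$ the pooled
within-class scatter; the closed form is $w = d_w^{-1}(\mu_1 - \mu_2)$.  The
threshold is left open by the underlying method description; we use the
midpoint of the projected class means — the equal-prior choice, symmetric in
the classes — and assign scores $y \ge t$ to class one.  When $d_w$ is
ill-conditioned (24-dimensional features from short recordings can be
rank-deficient) a ridge $10^{-8}\,\mathrm{tr}(d_w)/d$ is added before
inversion.  Decisions are *frame-level*: each frame vector is classified
independently and accuracy is the fraction of correctly labeled test frames.

**Discrete HMM.**  Feature sequences are vector-quantized against a k-means
codebook (`stats::kmeans`, seeded; inputs with fewer distinct rows than
codewords fall back to duplicated centroids, and nearest-centroid ties go to
the lowest index).  One $(N, M, A, B, \pi)$ model per class is trained by
multi-sequence Baum–Welch with per-step scaling constants accumulated in log
space; the log-likelihood trace is non-decreasing and rows are floored at
$10^{-12}$ and renormalized so the stochasticity invariants hold at every
iteration.  Initialization draws Dirichlet(1) rows under a recorded seed.
Defaults $N = 3$ states and $M = 4$ symbols follow the method's illustrative
state/symbol alphabet; nothing in the protocol fixes them, so both are
configurable.  A test utterance is assigned by the larger forward
log-likelihood (*utterance-level* decision; ties to class one).  The
granularity difference is deliberate: the sequence model exists precisely to
accumulate contextual evidence across frames, which is why it outperforms
frame-level LDA on the same split.

## Evaluation and the order sweep

The corpus is split 30%/70% per class at the *utterance* level (train
counts rounded half-down), never at the frame level — overlapping frames of
one recording must not straddle the split.  `angle_sweep()` evaluates the
chosen back-end at each order of the grid under one fixed split; the default
grid is the 99 interior points $0.01\pi, \dots, 0.99\pi$ (a step of
$0.01\pi$ on the open interval has 99 interior points, although the emulated
protocol describes the same grid as 100 groups).  Ties on held-out accuracy
break toward the order closest to $\pi/2$, preferring the conventional
transform when no gain exists.  Reported statistics are accuracy,
sensitivity $TP/(TP+FN)$ and specificity $TN/(FP+TN)$ with deceptive speech
as the positive class, and the per-class vector variance ratios
$R = \sum_i \|a_i - \bar a\|^2 / \sum_j \|b_j - \bar b\|^2$ comparing FrCC
(numerator) against MFCC (denominator) cluster tightness.

## What the generator does and does not emulate

`gen_corpus()` produces balanced, labeled, seed-reproducible utterances:
a randomized fundamental (120–220 Hz) drives a $1/h$-weighted harmonic stack
under raised-cosine syllable envelopes (8 syllables/s, 10% gaps); each
syllable adds a formant-like linear frequency glide whose chirp rate and
per-syllable phase jitter are the class-dependent parameters (defaults
4,000 Hz/s versus −28,000 Hz/s, and 0.05 versus 0.6 rad — glide speeds
within the range of natural formant transitions); white noise is added at
30 dB SNR and the sum passes a 16-bit quantization round trip.  Chirp-rate
separation is the deliberate mechanism: linear chirps are exactly what a
matched fractional order compacts, so the corpus is sensitive to $\alpha$
*by construction* (the −28 kHz/s glide predicts a matched order near
$\cos\alpha = cN/f_s^2 \approx 0.11$, i.e. $\alpha \approx 0.46\pi$, which
is where the sweep lands).  Setting both classes' chirp rates and jitters
equal yields a null corpus whose two classes are distributionally identical
— the guard against pipeline leakage.

What it does **not** emulate: phonetic content, coarticulation, prosody,
speaker identity, recording-channel effects, or any psychophysiological
mechanism of deception.  Passing tests therefore demonstrate that the
pipeline is correct, order-sensitive and leak-free on signals engineered to
contain order-detectable structure — they say nothing about detection rates
on real deceptive speech.

## Numerical choices and degenerate inputs

* Orders within $10^{-6}$ of $n\pi$: analytic identity/reversal branches.
* Filterbank edge collisions (possible at coarse spectral resolution) are
  resolved by bumping snapped edges to keep filter centers distinct.
* All-zero frames: the log floor engages; no error.  `NaN` frames: error.
* LDA with coincident class means: degenerate-direction error; singular
  scatter after ridge regularization: error.
* Baum–Welch rows are floored and renormalized each iteration; `max_iter =
  0` returns the seeded initialization unchanged.
* Every stochastic step (corpus, split, k-means, HMM initialization)
  consumes an explicit seed, and seeded helpers save and restore the global
  RNG state.

## Problem sizes used by the test suite

The unit suite runs transforms at $N \le 256$, LDA oracle searches over
10,000 random directions in 2 and 5 dimensions, exhaustive HMM path
enumeration at $N=3, M=4, T=5$, Baum–Welch parameter recovery from 200
sequences of length 50, and end-to-end sweeps on corpora of 10 utterances
per class of 0.8 s (the generator's study conditions) over the full 99-point
grid for 5 seeds.  These sizes were chosen so the whole suite completes in a
few minutes on one core while keeping every statistical check at sample
sizes where its expected behaviour is unambiguous.

## Known limitations

* Naive `frft()` composition is not additive across orders (see above); use
  `frft_compose()` when composing.
* `frft_compose()`'s interpolation assumes signals concentrated well inside
  the grid; it is not meant for full-band vectors.
* The LDA threshold assumes equal priors and roughly symmetric projected
  spread; heavily imbalanced corpora would warrant a likelihood-based
  threshold.
* Discrete-symbol HMMs with a small codebook discard most of the feature
  geometry; continuous-density emissions are out of scope.
* The synthetic benchmark is a mechanism check, not evidence about real
  deceptive speech.
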