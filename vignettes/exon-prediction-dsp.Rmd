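---
title: "Period-3 exon prediction by digital signal processing"
author: "exonDSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Period-3 exon prediction by digital signal processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonDSP)
```

## The problem and the signal model

Eukaryotic genes are mosaics of coding exons and non-coding introns.
Because codons are triplets and their three positions have unequal base
composition, coding DNA carries a weak periodic component with period 3:
viewed as a discrete-time signal, an exon has excess energy at the angular
frequency $\omega_0 = 2\pi/3$ (equivalently, at DFT bin $k = N/3$ of a
window of length $N$). Introns and intergenic DNA, to first order, do not.
Every method in this package is a different way of measuring that
period-3 energy as a function of position and turning the resulting
per-base evidence track into discrete exon calls.

A DNA string $s[n]$ over $\{A,C,G,T\}$ enters the numeric domain in one of
three ways:

* **Binary indicator sequences** $u_A, u_C, u_G, u_T$: one-hot channels
  with $u_b[n] = 1$ iff $s[n] = b$. At every position
  $u_A[n]+u_C[n]+u_G[n]+u_T[n] = 1$, which implies that the four channel
  DFTs cancel exactly at every non-DC bin — a useful internal consistency
  check that the test suite exercises.
* **EIIP mapping**: each base is replaced by its electron-ion interaction
  pseudopotential ($A = 0.126$, $T = 0.1335$, $C = 0.134$, $G = 0.0806$),
  giving one real-valued signal.
* **Weighted combination** $a\,u_A + c\,u_C + g\,u_G + t\,u_T$: the
  single-channel signal of the reduced-computation methods. With the EIIP
  constants as weights this reproduces the EIIP signal exactly; the
  package default keeps only the G channel ($a=c=t=0$, $g=1$), the single
  channel with the strongest periodicity in this setting. The weights are
  fully configurable because no single choice is canonical.

Coordinates are 1-based inclusive in all user-facing I/O (the GenBank
convention); BED output converts to 0-based half-open at the boundary.
Sub-regions extracted with `extractRegion()` keep absolute record
coordinates through an origin offset, so calls on a cut such as positions
7021–15020 of a 42.8-kb record are reported in record coordinates.
Non-ACGT letters follow a declared policy: `"strict"` (default) errors at
the first offending position, `"zero"` zeroes all four indicators there,
locally breaking the sum-to-one identity — acceptable for sparse ambiguity
codes, documented as such.

## Sliding-window DFT methods

For a window of length $N$ (a multiple of 3) starting at $s$, the binary
method evaluates
$$S[k] = |U_A[k]|^2 + |U_T[k]|^2 + |U_C[k]|^2 + |U_G[k]|^2, \qquad k = N/3,$$
and the EIIP method the single-channel power $|X_e[k]|^2$. The window
slides one base at a time (a short-time Fourier transform with a
rectangular window, the window type used throughout). High values of the
resulting track flag windows with codon-like periodicity.

Because $k/N = 1/3$ for every window, the window DFT at the period-3 bin
equals a phase factor times a windowed sum of $x[n]e^{-2\pi i n/3}$; the
implementation computes all windows in one pass over cumulative sums. The
direct per-window DFT remains the normative semantics: the tests compare
the fast path against brute-force evaluation of the transform sum and
require agreement to $10^{-9}$ relative on random sequences.

Two conventions matter when reading the track:

* **Window length**: default 240. This is the window found to give the
  best-defined exon boundaries for the *C. elegans* specimen this package
  is modelled on; 351 is common elsewhere in the literature and remains a
  supported override. The track has $N_{\text{seq}} - N + 1$ values.
* **Positional assignment**: a window's value is plotted at its center
  (start $+ N/2$) by default, because boundary readout is then symmetric;
  `"left"` reproduces left-anchored plots.

An improved spectral measure combining the four channel coefficients has
been reported to outperform the plain power sum, but its concrete form is
not available; `slidingTrack()` therefore accepts a `measure` function
(four complex window coefficients in, one non-negative real out) instead
of silently substituting an alternative. The default is the power sum
above.

## Narrowband filtering methods

The filter methods replace the window DFT with a causal second-order IIR
filter whose gain peaks sharply at $\omega_0 = 2\pi/3$. Each indicator
channel is filtered and the output powers summed,
$$Y(n) = |y_A(n)|^2 + |y_T(n)|^2 + |y_C(n)|^2 + |y_G(n)|^2,$$
or, in the reduced-computation variant, the single combined channel is
filtered once and squared. By linearity the four-channel track equals the
sum of single-channel tracks, a property the tests assert exactly.

**Filter 1 (all-pass-derived anti-notch).** From a second-order all-pass
$A(z)$ the complementary pair $G(z) = \tfrac12(1 + A(z))$ (notch) and
$H(z) = \tfrac12(1 - A(z))$ (anti-notch) is formed; power complementarity
$|G|^2 + |H|^2 = 1$ holds at every frequency by construction. A
second-order all-pass with denominator $(1, a_1, a_2)$ has two free
parameters, and one must choose what is exact: with denominator
$1 - 2R\cos\omega_0 z^{-1} + R^2 z^{-2}$ the *poles* sit exactly at
$Re^{\pm j\omega_0}$ but the notch zero lands slightly off $\omega_0$ (off
by $\mathcal{O}((1-R)^2)$, about $2\times10^{-3}$ in gain at $R = 0.992$);
with denominator $1 - (1+R^2)\cos\omega_0 z^{-1} + R^2 z^{-2}$ the *zeros*
of $G$ sit exactly on the unit circle at $\pm\omega_0$ while the pole
radius stays exactly $R$. `designFilter1()` uses the second
parameterization — a notch is defined by where its zero is, and the
package's correctness checks require $|G(e^{j\omega_0})| = 0$ to machine
precision. `designAllpass()` exposes the first, pole-centered form for
users who want the textbook building block. The two coincide as
$R \to 1$. The pole radius default $R = 0.992$ gives a sharp,
well-conditioned passband; it is a free design parameter here because no
value is published for the original figures.

**Filter 2 (single peaking filter).** A direct second-order resonator
with unit gain at $\omega_0$ and a prescribed $-3$ dB bandwidth:
$b = \frac{\beta}{1+\beta}(1, 0, -1)$,
$a = (1, \frac{-2\cos\omega_0}{1+\beta}, \frac{1-\beta}{1+\beta})$ with
$\beta = \tan(\text{bw}/2)$. The bandwidth (default $0.02\pi$
rad/sample, again a free parameter) controls the stop-band attenuation
that gives this design its advantage on noisy indicator channels. The
$-3$ dB width is exact in the sense that the two half-power crossings are
separated by exactly the design bandwidth.

Filtering is a single causal forward pass with zero initial conditions
(via the `signal` package) — no forward-backward filtering, matching how
such exon plots are produced. The first $\approx 5/(1-R)$ output samples
are start-up transient; tracks carry this figure as metadata but are not
trimmed.

## Haar wavelet denoising

The exon evidence lives in the low-frequency half of the track's
spectrum, while much of the inter-exon noise does not. A single-level
discrete wavelet decomposition splits the track into halfband
approximation and detail subbands (each downsampled by 2); zeroing the
detail band entirely and reconstructing suppresses the upper halfband.
One level suffices because the wanted components span roughly
$[0, \pi/2]$; deeper levels are supported for experimentation (the
classical three-level subband cascade is the documented example).

Numerical choices:

* **Orthonormal Haar** (pairwise sums and differences scaled by
  $1/\sqrt2$), so energy is partitioned exactly across subbands and
  Parseval-based checks are meaningful. Whether the original plots used
  orthonormal or unnormalized scaling is not determinable from them;
  orthonormality was chosen for its invariants.
* **Odd lengths** are extended by duplicating the edge sample
  (half-sample symmetric extension) and reconstruction trims back; this
  avoids the energy leakage of zero padding. Exact energy partition
  consequently holds when no extension occurs at any level, and the
  energy tests use such lengths.
* **Denoising is computed as nested pairwise means**, which is
  algebraically identical to analyze → zero details → synthesize (the
  $\sqrt2$ factors cancel) but uses exact halving, so denoising an
  already-denoised track is an exact no-op. The equivalence of the two
  routes is itself tested.
* Reconstruction of a non-negative power track by this route is
  non-negative, but the general synthesis path is not sign-preserving,
  so track denoising clamps any negative output to zero and reports a
  count; power semantics require non-negativity.

## From tracks to exon calls

No boundary-extraction rule was published alongside these methods; the
caller implements the half-power reading that the filter-method
discussion implies — noise is problematic exactly when it is "stronger
than the half power values of the exon peaks". Concretely, in order:

1. optional centered moving-average smoothing (span 1, i.e. off, for
   DFT tracks, whose sliding window already averages; 450 for filter
   tracks, the context length reported to suit the filter method);
2. threshold $T = f \cdot \max(\text{track})$ with $f = 0.5$ by default —
   a *relative* rule, making calls invariant under uniform scaling;
3. maximal runs $\ge T$ become candidates;
4. candidates separated by $\le$ 30 nt are merged;
5. merged candidates shorter than 50 nt are dropped.

The global maximum (rather than per-peak local maxima) keeps the rule
deterministic. All five numbers are prominently configurable because the
half-power fraction is the pivotal unspecified step of the whole
pipeline. `evaluateCalls()` scores a call set against reference
intervals: per-exon detection by any overlap, absolute boundary errors
against the largest-overlap call, false-positive calls, and
nucleotide-level sensitivity/precision.

**A structural consequence worth knowing.** With a relative half-power
threshold, an exon can only be called if its evidence peak reaches half
of the global maximum. A window (or smoothing span) of length $W$ caps
the peak of an exon of length $L < W$ at roughly $(L/W)^2$ (DFT power) or
$L/W'$ (filter track smoothed over $W'$, relative to the longest exon)
of a full-window exon's plateau — independent of how strong the codon
bias is. With the default $W = 240$ and the bundled five-exon layout
(lengths 112–350 nt), the 112-nt exon peaks at $\approx 0.22$ of the
maximum and cannot cross the half-power threshold under any bias, and
the 179-nt exon sits almost exactly at the threshold. Detail-suppression
denoising cannot change this: averaging never raises a peak relative to
the global maximum. This mirrors the original observation that the first
(112-nt) exon of the specimen was indistinguishable from inter-exon
noise in the reduced-computation plot. Callers targeting short exons
should lower `thresholdFraction`, shorten the window, or both; the
defaults deliberately reproduce the published operating point rather
than an optimized one.

## The synthetic-genome generator

`generateGenome()` plants the period-3 signature directly: background
positions are iid from a background distribution (uniform by default)
and exon positions are drawn from codon-position-specific base
probabilities. The default bias puts 0.55 on one base per codon position
(G, C, A at positions 1, 2, 3) and 0.15 on the rest — moderate on
purpose, so that recovery is nontrivial; the expected period-3 component
of each indicator channel inside an exon then has amplitude
$|0.55 - 0.15| = 0.4$ per codon. The default layout is 8000 nt with five
exons of lengths 112/331/263/179/350 at the relative positions of the
NCBI annotation of the AF099922 region 7021–15020, so tests exercise a
realistic multi-exon geometry fully offline. Generation is deterministic
given the seed and restores the caller's RNG state.

What the generator does *not* emulate: splice-site motifs, GC-content
gradients, repeats, codon usage beyond first-order position bias, and
reading-frame continuity across introns. Passing tests on synthetic
genomes therefore demonstrate correct signal processing and calling on
the period-3 model, not gene-finding performance on real genomes — the
bundled synthetic specimen is clearly labelled synthetic and stands in
for the real GenBank record only geometrically.

## Problem sizes and tolerances used in the checks

The test suite runs entirely on generated data: random sequences up to
300 nt for brute-force DFT cross-checks (tolerance $10^{-9}$ relative),
Haar round trips up to length $10^4$ at depths to 5 (tolerance
$10^{-10}$), filter-response identities on 1024–4096-point frequency
grids ($10^{-9}$–$10^{-10}$), and end-to-end runs on the 8000-nt
five-exon fixture. The acceptance script recomputes the same quantities
from scratch at a caller-supplied seed.

## Known limitations

* Single strand only; no reverse-complement scan, RNA alphabets, or
  quality scores.
* The half-power caller is the declared reading of an unpublished rule;
  published exon tables from these methods fall on a coarse coordinate
  grid whose rounding step is unknown, so cell-level reproduction of
  such tables is not attempted.
* No reading-frame determination, splice-site modelling, or
  probabilistic gene finding — the package is a signal-processing
  front end, not a gene finder.
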