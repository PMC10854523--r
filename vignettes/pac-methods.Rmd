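---
title: "Methods: phase-amplitude coupling during navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-amplitude coupling during navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacnav)
```

## The model and its assumptions

`pacnav` quantifies phase-amplitude coupling (PAC): the modulation of a
fast oscillation's envelope by the phase of a co-occurring slow (theta)
oscillation in hippocampal local field potentials. The estimator is the
normalized Kullback-Leibler modulation index of Tort and colleagues.
For a phase band and an amplitude band, the instantaneous phase
$\phi(t)$ and envelope $A(t)$ are taken from the analytic signal of the
band-passed series, $\phi$ is binned into $N = 18$ bins of 20 degrees,
the mean envelope per bin is normalized to a distribution $P$, and

$$\mathrm{MI} = \frac{\log N - H(P)}{\log N},
  \qquad H(P) = -\sum_j P_j \log P_j,$$

with natural logarithms and the convention $0 \log 0 = 0$ (the base
cancels in the ratio). MI is exactly 0 for a uniform $P$ and exactly 1
for a point mass; it is invariant to amplitude scaling (so electrode
gain does not matter) and to cyclic rotation of $P$ (so it measures
coupling *strength*, not the preferred phase).

The method assumes the phase band is narrow enough that instantaneous
phase is well defined, and that the amplitude band is wide enough to
contain the modulation sidebands at $f_A \pm f_p$ — otherwise genuine
modulation is filtered away. Both assumptions shape the defaults below.

Two companion statistics carry the phase information MI discards: the
Pearson correlation between each trial's $P$ and a session-standard
distribution (the mean $P$ at a reference condition), which falls when
coupling drifts in phase across trials, and circular statistics (mean
resultant vector, Fisher 95% CI, Rayleigh test) of the theta phases at
fast-envelope peaks. Pearson is the default correlation; the type is a
config option because rank correlation is equally defensible for
18-bin vectors.

## Filtering and numerical choices

**Zero-phase FIR band-pass.** Band extraction uses a linear-phase FIR
filter (frequency-sampling design) applied with group-delay
compensation, which is exactly zero-phase. The design places a flat
passband over the nominal band, extended by 5% of the bandwidth, with
explicit transition bands outside it (roughly `max(2, 0.2 * bandwidth)`
Hz wide, pinned so the low-side stopband begins one octave below the
lower edge). Two properties motivated this over the common
forward-backward (squared-magnitude) IIR Butterworth: a component at
the nominal band edge is passed at essentially unit gain rather than
half amplitude, and very narrow low-frequency bands (e.g. 1-3 Hz at
2 kHz) remain numerically stable, where high-order IIR coefficients
degenerate. Measured on 10 s test signals: gain 0.97 at the 6 Hz edge of
a 3-6 Hz band, below 0.09 one octave outside, and 99.97% of filtered
white-noise variance inside a 140-180 Hz band's 130-190 Hz window.

The filter order follows the transition width (the Hamming-window rule
`3.3 fs / width`) and is capped at a third of the signal length, so
1 s epochs get shorter, blunter filters — one reason the pipeline
filters continuous recordings rather than epochs (below).

**Analytic signal.** Phase and envelope come from the frequency-domain
Hilbert construction. Phase 0 is the positive peak of the oscillation
(cosine convention); histograms report degrees, internals radians.
FFT convolution lengths are padded to 2-3-5-smooth sizes; without
padding, recordings whose length has a large prime factor make R's
mixed-radix FFT quadratically slow.

**Edge trimming.** 50 ms is dropped from both ends of phase/envelope
series before any statistic, the standard guard against filter edge
transients.

**Empty phase bins** are an error naming the offending bin, never a
silent `NaN`: a 1 s epoch always covers every 20-degree bin for theta
frequencies of 2 Hz and above, so an empty bin indicates a truncated or
mislabeled epoch.

**Welch PSD** uses 1 s Hann windows at 50% overlap, scaled so the PSD
integrates to the signal variance; theta power per epoch integrates the
PSD over the configured theta band.

## Comodulogram grids and bandwidths

The grid spans phase frequencies 2-20 Hz in 1 Hz steps (19 centers) and
amplitude frequencies 20-180 Hz in 5 Hz steps (33 centers). Grid steps
fix the centers but not the bandwidths; the package uses phase bands of
center ±1 Hz (adjacent bands touch, phase stays well defined) and
amplitude bands of center ±15 Hz, wide enough to pass sidebands at
$f_A \pm f_p$ for theta-range $f_p$. Cells whose amplitude band reaches
the Nyquist frequency are flagged `NA`, never silently zeroed. Each band
is filtered once and reused across the grid, and per-phase-band bin
indices are precomputed, so a full 19 x 33 map on 10 s at 2 kHz takes
under a second.

## Behavioural segmentation

**Maze arm.** Analysis windows are 1000 ms, from 250 ms before the
animal's first contact with an infrared detector to 750 ms after; only
the first contact per detector per trial counts, and windows truncated
by the recording edges are dropped with a message. Running speed is
detector-pair distance over crossing interval, with the geometry
(straight-line or along-path distances) supplied by the user, since
either convention is defensible.

**Flight arm.** GPS fixes are labeled DM (within 300 m of the release
site), LN (within 200 m of the loft) and ER (everything between);
distances are haversine on a 6371 km sphere. If a fix is inside both
radii — impossible at the study's 1.5 km release-loft separation but
possible in principle — temporal precedence decides: DM before the
first en-route fix, LN after. Non-overlapping 1 s windows inherit the
label of their fixes; windows containing a phase boundary (mixed
labels) are dropped rather than majority-labeled, so every epoch is
purely one phase. DM epochs are computed but excluded from statistics
by default (`include_dm = FALSE`), because hovering near the release
site mixes search behaviour into the navigation contrast. Flight speed
is the mean of the ~10 fix speeds per 1 s window. Trajectory similarity
is the symmetric mean nearest-neighbour haversine distance between two
tracks — the threshold of 200 m classifies "same path"; the metric
itself is a package choice (robust to unequal fix counts) since
distance-to-previous-trajectory admits several definitions.

**Bad channels.** A channel is flagged when more than 10% of its
consecutive differences are exactly zero (flatline) or its robust SD
(MAD) exceeds 5x the median across channels. The causes (intermittent
connections, electrode separation, motion noise) are observable; these
thresholds are the package's operationalization and deliberately target
persistent faults — the MAD is insensitive to brief transients by
design.

**Channel selection** takes, per channel, the session-averaged mean
epoch MI at the band pair of interest and picks the argmax, breaking
exact ties toward the lowest channel id (logged).

## Pipeline design choices

Per-epoch MI is computed from distributions of single 1000 ms epochs
and averaged within condition — not from concatenated epochs, whose
splice points would inject phase discontinuities. For epoch statistics
the pipeline band-passes the *continuous* recording once per band and
slices the phase/envelope series at epoch boundaries: this avoids both
the per-epoch filter-order cap and per-epoch edge trimming, since
filter transients exist only at the recording ends. The standalone
`mi_for_pair()` keeps the self-contained filter-extract-trim-bin chain
for isolated signals.

The surrogate null circularly time-shifts the envelope relative to the
phase by uniform random offsets of at least 100 ms — preserving both
marginal spectra while destroying their alignment — rather than
phase-scrambling, which also whitens the envelope's autocorrelation.
Mandatory seeds make every stochastic step reproducible; unseeded calls
error rather than silently drawing.

Group comparisons are thin contracts over standard routines:
`stats::kruskal.test` for the omnibus H, Dunn's pairwise z-tests with
tie correction computed in-package (no installed package provides
them) with Bonferroni adjustment (the adjustment is not dictated by the
study design; Bonferroni is the conservative default), `stats::wilcox.test`
for Mann-Whitney p-values with the tie-corrected normal-approximation Z
reported alongside U, and `stats::cor.test` for Spearman. All tests are
two-sided.

## What the synthetic generator emulates — and what it does not

The LFP generator produces

$$x(t) = a_\theta \sin(2\pi f_p t)
  + a_A \, m(t) \sin(2\pi f_A t) + \varepsilon(t),$$

where the modulator $m(t) = (1-\chi) + \chi (1 + \cos(\phi_\theta(t) -
\phi_0))/2$ is a raised cosine of the theta carrier's instantaneous
phase $\phi_\theta$, $\chi \in [0,1]$ is the coupling depth, $\phi_0$
the preferred phase, and $\varepsilon$ white Gaussian noise. The raised
cosine yields the unimodal phase-amplitude distributions seen in real
couplings; defining it on the instantaneous phase (rather than on
$2\pi f_p t$ directly) makes the injected $\phi_0$ exactly the quantity
the analysis recovers, so simulation-recovery checks are
self-consistent. Defaults — theta 50 uV, fast carrier 10 uV, noise
15 uV — are plausible hippocampal LFP magnitudes chosen once; no
published amplitude calibration exists for these recordings.

For narrow analysis bands such as beta2 (20-30 Hz), a pure tone at
$f_A = 25$ Hz puts the modulation sidebands ($25 \pm 7.5$ Hz) outside
the band, so the flight-session generator uses the `hf_carrier =
"noise"` option: the fast carrier becomes narrowband noise (8 Hz
bandwidth, RMS-matched to the sine), emulating a broadband rhythm whose
modulation survives band-pass filtering. The default remains the sine
model.

The maze generator injects coupling in the second around each
navigation-position event and an uncoupled, theta-halved signal at the
goal; the flight generator couples the ER span only. GPS tracks advance
along the release-loft great circle at a nominal 15 m/s with a smooth
(5 s averaged) lateral Gaussian deviation, default SD 20 m, matching
the 100-200 m route corridors of trained pigeons; optional smooth speed
variability supports speed-correlation analyses.

Not emulated: 1/f background spectra (noise is white by default),
non-sinusoidal theta waveform asymmetry, movement artifacts, volume
conduction across channels, biomechanics of flight, or any
sensory-cue-driven path structure. Passing tests therefore demonstrate
that the estimator chain is correct and well calibrated on signals with
known ground truth — not that real avian recordings meet the model's
assumptions.

## Problem sizes and numerical tolerances

Simulation-based checks use 10 s signals at 2 kHz for single-pair and
comodulogram recovery (a full 19 x 33 map in under a second), 20-30 s
for preferred-phase recovery (the 2 SD envelope-peak threshold is
deliberately selective, so longer signals provide enough peaks), twenty
seeds for the white-noise null, 200 circular-shift surrogates, maze
sessions of 18-20 trials, single ~100 s flights at 1 kHz, and 2000
replicates for type-I-error calibration of the group tests. Analytic
identities (MI endpoints, closed-form circular results, oracle
equivalence against direct KL summation) are asserted at 1e-12;
filter-dependent quantities at the tolerances the filter design
guarantees (5% passband, 20 dB one octave out).

## Known limitations

- MI on short epochs is biased upward by sampling noise (more so at low
  phase frequencies, where 1 s holds few theta cycles); comparisons
  should therefore contrast conditions with equal epoch lengths, as the
  pipeline does, rather than interpret absolute MI.
- The Fisher circular CI is undefined for dispersed samples (it returns
  a flagged `NA`); very small peak samples (n below ~8) can render the
  Rayleigh test underpowered.
- The epoch-capped FIR order blurs adjacent 1 Hz phase bands in
  per-epoch comodulograms; grid argmax on continuous 10 s signals is
  accurate to one grid step.
- The recording container is a plain-text CSV dialect; it is simple and
  portable but not efficient for hours-long high-channel-count
  sessions.
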