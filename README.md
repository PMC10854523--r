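# pacnav

Phase–amplitude coupling (PAC) analysis for hippocampal local field
potentials (LFPs) recorded during goal-directed navigation.

## The problem

During navigation, the hippocampus coordinates activity across frequency
bands: the phase of a slow theta-band oscillation can modulate the
amplitude of faster rhythms (high-frequency oscillations in walking
animals, beta2 during flight). This cross-frequency coupling tends to be
present while the animal is actively navigating and to vanish near the
goal. Quantifying it requires a pipeline that runs from raw multichannel
recordings and behavioural data (infrared beam crossings in a maze, or a
10 Hz GPS track on a homing flight) to coupling statistics and group
comparisons. `pacnav` implements that pipeline for R, together with a
fully seeded synthetic-data generator so every stage is testable without
access to animal recordings.

## The statistic

For a phase (slow) band $f_p$ and an amplitude (fast) band $f_A$:

1. Band-pass the signal in both bands (zero-phase FIR), extract the
   instantaneous phase $\phi(t)$ of the slow band and the envelope
   $A(t)$ of the fast band from the analytic signal, and trim 50 ms from
   each end.
2. Bin $\phi$ into $N = 18$ bins of 20°, average $A$ within each bin,
   and normalize the bin means to the **phase–amplitude distribution**
   $P$, with $\sum_j P_j = 1$.
3. The **modulation index** is the Kullback–Leibler distance of $P$ from
   the uniform distribution, normalized to $[0, 1]$:

   $$\mathrm{MI} = \frac{\log N - H(P)}{\log N}, \qquad
     H(P) = -\sum_{j=1}^{N} P_j \log P_j .$$

   MI is 0 iff $P$ is uniform (no coupling) and 1 iff all fast-band
   amplitude concentrates in a single phase bin.

Because MI is invariant to rotations of $P$, it ignores *where* in the
theta cycle the amplitude concentrates; the package therefore also
correlates each trial's $P$ with a session-standard distribution
(`distribution_correlation`), summarizes theta phases at fast-envelope
peaks with circular statistics (mean resultant vector, Rayleigh test),
and scans MI over a frequency grid (phase 2–20 Hz × amplitude
20–180 Hz) as a comodulogram.

## Worked example

Simulate 10 s of LFP in which the phase of a 6 Hz theta rhythm
modulates the envelope of a 150 Hz fast oscillation with depth 0.9, and
estimate the coupling:

```r
library(pacnav)

cfg <- pac_sim_config(fs = 2000, duration = 10, f_p = 6, f_A = 150,
                      depth = 0.9, noise_sd = 5, seed = 42)
rec <- simulate_pac_signal(cfg)
mi_for_pair(rec$data[, 1], rec$fs, f_p_band = c(5, 7), f_A_band = c(135, 165))
#> [1] 0.05607213
comodulogram(rec$data[, 1], rec$fs)
#> Comodulogram: 19 phase x 33 amplitude frequencies
#>   max MI = 0.05656 at fp = 5 Hz, fA = 155 Hz
```

The single-pair MI (0.056) is three orders of magnitude above the
white-noise floor (about 1e-4 to 4e-3 across the grid), and the
comodulogram's maximum falls one grid step from the injected pair
(6 Hz, 150 Hz) — within the grid resolution of ±1 Hz / ±5 Hz. The
preferred coupling phase is recovered by the circular summary of theta
phases at fast-envelope peaks (here injected at 45°):

```r
print(circular_summary(phases_at_hf_peaks(theta_phase, hf_envelope)))
#> Circular summary: n = 7
#>   avgAng = 42.6 deg, r = 0.937, 95% CI [24.0, 61.1] deg
#>   Rayleigh z = 6.152, p = 0.000436
```

A full maze session — coupling injected at navigation positions S8, S9,
S10 but not at the goal G1 — reproduces the navigate-vs-goal contrast
end to end:

```r
sim <- simulate_maze_session(10, pac = pac_sim_config(depth = 0.9, noise_sd = 5),
                             seed = 7)
res <- run_maze_analysis(sim$recording, sim$events)
res$tests$positions_corr
#> Kruskal-Wallis with Dunn's post hoc
#>   statistic = 24.25, df = 3, p = 2.218e-05
#>   pairwise (adjusted):
#>      pair          z        p_adj significant
#>  G1 - S10 -3.1560047 9.596776e-03        TRUE
#>   G1 - S8 -4.6479342 2.011655e-05        TRUE
#>   G1 - S9 -3.6724419 1.441463e-03        TRUE
#>  S10 - S8 -1.4919295 8.143058e-01       FALSE
#>  S10 - S9 -0.5164371 1.000000e+00       FALSE
#>   S8 - S9  0.9754924 1.000000e+00       FALSE
```

Every pairwise difference against the goal is significant; the
navigation positions do not differ from each other. The flight arm
(`run_flight_analysis`) works analogously from a recording plus GPS
track: fixes are labeled DM / ER / LN (decision-making within 300 m of
the release site, local navigation within 200 m of the loft, en route
between), 1 s epochs inherit the labels, and ER is contrasted with LN by
Mann–Whitney, with Spearman correlations of speed against MI and theta
power.

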