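---
title: "Methods: signed functional networks from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed functional networks from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccgnet)
```

## Overview

`ccgnet` turns binned multi-trial spike trains into signed, directed
functional networks and characterizes their topology at three scales:
pairwise connections, two- and three-neuron motifs, and network modules.
The intended setting is multi-area extracellular recordings (hundreds of
units across several cortical areas, many stimulus repeats), and a synthetic
generator with planted couplings provides ground truth for validating every
stage.

## Connection detection

For an ordered pair of units A and B, the cross-correlogram at non-negative
lag $\tau$ is

$$\mathrm{CCG}_{AB}(\tau) = \frac{\frac{1}{M}\sum_{i=1}^{M}\sum_{t=1}^{N}
x_A^i(t)\,x_B^i(t+\tau)}{\theta(\tau)\sqrt{\lambda_A\lambda_B}},
\qquad \theta(\tau) = N - \tau,$$

with $M$ trials of $N$ bins, binary trains $x^i$, and $\lambda$ the mean
spike count per bin (making the CCG dimensionless; rates are not converted
to Hz inside the normalization). Only non-negative lags are evaluated so
that each ordering of the pair carries its own curve and bidirectional
connections remain identifiable.

Slow shared rate fluctuations are removed by jitter correction: the
expected correlogram under uniform redistribution of spikes within fixed
25 ms windows (per trial) is subtracted. We compute this expectation
analytically by replacing every spike of *both* trains with a uniform mass
over its window — the exact expectation of the interval-jitter null, with
no resampling noise, and symmetric under exchanging source and target. A
seeded Monte-Carlo mode (default 50 resamples) is provided and agrees with
the analytic expectation within sampling error; it exists as a cross-check,
not as the default path.

Detection scans durations $D = 1,\dots,\tau_{max}+1$ ($\tau_{max} = 12$
bins). For each $D$ the moving averages of the corrected CCG over the whole
lag axis form a reference set whose mean and standard deviation gate
candidate windows with onsets $t_0 \in [0, \tau_{max}-D+1]$ at $n = 4$
standard deviations; a window crossing above (below) the band is a positive
(negative) connection, the smallest qualifying duration wins, and the
window's Z-score is the connection significance. A constant curve (zero
spread) never triggers. The lag axis used for the reference set defaults to
100 bins: the moving-average statistics are then estimated from ~100
windows rather than the ~13 candidate onsets, which stabilizes the band.
Whether to form the reference set over the full correlogram support or only
near zero lag was genuinely open; we chose the full axis, and the candidate
windows are *not* excluded from the reference statistics (the band is
computed from all windows, literally).

Zero-lag peaks are treated as one primary direction of communication: when
both orderings are significant only at lag 0, the more significant
direction is kept and the other survives only through a significant
non-zero-lag window; exact ties break lexicographically by unit id.

Pairs whose raw correlogram carries too little mass are unreliable; the
normalized entropy of the raw CCG (Shannon entropy of the lag distribution
over its maximum) must reach 0.9. The raw rather than corrected curve is
used because the corrected curve can be negative and has no probability
reading. Units must fire at least 2 spikes/s under every stimulus type to
enter the analysis at all.

Connection weight is the signed extremum of the corrected CCG inside the
winning window. The window mean was the alternative; the extremum was
chosen because downstream analyses treat peak correlogram values as
connection strengths.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| bin width | 1 | ms | binning of spike trains |
| `tau_max` | 12 | bins | maximum candidate onset lag |
| `n_sigma` | 4 | — | significance multiplier |
| `jitter_window` | 25 | bins | slow-correlation removal scale |
| `entropy_threshold` | 0.9 | — | pair reliability filter |
| `min_rate_hz` | 2 | spikes/s | unit inclusion |
| `lag_axis` | 100 | bins | reference-set support |

## Reference models

Four nested null models randomize a network while preserving progressively
more structure: `erdos_renyi` (node count, edge count, sign/weight label
multiset), `degree_preserving` (plus every node's in/out degree),
`pair_preserving` (plus the multiset of unordered pair states: null,
unidirectional, bidirectional) and `signed_pair_preserving` (plus the
signed pair states). The pair-preserving models are implemented by
double-edge swaps restricted within pair-state (respectively
signed-pair-state) categories; this preserves degrees exactly, which a
plain reshuffle of pair states across node pairs would not. Swaps with
degenerate endpoints are rejected; a category in which no admissible swap
exists is left in place (its constraints admit essentially one
realization). Burn-in is 10 accepted swaps per edge — no mixing criterion
is standard here, and the conservation suites verify the invariants rather
than the mixing time. Weights travel jointly with their sign label during
reassignment, since edge signs derive from weight signs. An optional
distance-preserving variant restricts all randomization to preserve the
discretized (default 10 equal-count bins) pairwise-distance histogram.

## Motif analysis

Three-node subgraphs are catalogued by exhaustive enumeration of all
labeled digraphs, restriction to weakly connected ones, and canonical
minimization over node permutations; sorting classes by edge count,
connected pairs, mutual pairs and canonical code reproduces the
conventional 13-class numbering (feedforward loop = 6, fully reciprocal
triangle = 13). Signed classes fix the sign pattern; all-positive variants
are labeled `p<k>`, all-negative `n<k>`. A signed class is pFFLb when it
contains at least one all-positive feedforward loop.

Subgraph intensity is the geometric mean of absolute edge strengths, and a
class's intensity sums over its instances (with unit weights it equals the
count). Absolute weights are used because a geometric mean of negative
weights is undefined; the sign pattern lives in the class label. Each
unordered triple contributes to exactly one class. Significance is the
intensity Z-score against a surrogate ensemble (default
signed-pair-preserving, 200 replicates), with the ensemble spread in its
population form. When aggregating Z-scores across replicate sessions,
values beyond 2 standard deviations of the replicate set are masked, per
class.

## Module detection

Signed modularity weighs positive within-module mass against negative
within-module mass, each against a degree-based expectation
$p_{ij}^\pm = k_i^{out,\pm} k_j^{in,\pm} / m^\pm$ with separate resolutions
$\gamma^+, \gamma^-$; in weighted mode, degrees and masses use absolute
strengths. The sum runs over all ordered pairs including $i=j$: the
diagonal null term is partition-independent, and including it makes the
single-module modularity of an all-positive network exactly zero — the
identity that anchors the scale. (Restricting to $i \ne j$, which we
initially considered, breaks that identity.)

Optimization is a Louvain scheme on the signed modularity matrix: seeded
random node sweeps with greedy moves, then aggregation, iterated to
convergence; the quality never decreases across accepted moves. Modules
below 4 nodes are marked unassigned after convergence (isolated singletons,
pairs and triplets are noise at this scale), but the reported Q refers to
the full partition. One degenerate case is worth noting: for a single
positive edge, merging and splitting the two endpoints tie at $Q = 0$
exactly, and the greedy optimizer (which requires strict gains) leaves them
separate.

Resolutions are selected by maximizing the difference between the empirical
modularity (best of many seeded runs; the production default is 200) and
the mean modularity of signed-pair-preserving surrogates (one run each, a
deliberate computational-budget asymmetry) over a grid: 13 log-spaced
$\gamma^+$ in $[0.5, 2]$ and a narrow $\gamma^-$ band around 1, since
positive connections dominate and $\gamma^-$ has little leverage. The
modularity Z-score uses the same surrogate ensemble. Consensus over
repeated runs assigns nodes iteratively to the most-voted module (ties:
larger module, then lexicographic node set), and multi-resolution module
ids are inherited from the largest finer-resolution submodule (ties: larger
submodule id), with node ordering by seeded two-opt minimization of the
summed Hamming distance between module-id sequences within a 10-node
window, per area.

Module-area agreement uses per-module coverage
($\max_j |M_i \cap A_j| / |A_j|$) and purity
($\max_j |M_i \cap A_j| / |M_i|$), their module-size-weighted averages, and
the pair-counting adjusted Rand index. Nodes unassigned by the size filter
are excluded from the contingency table by default; a flag re-admits them
as singleton modules for sensitivity analysis.

## The MA test

Comparing the correlation of a common variable with two others (e.g.,
firing rate against within-area and across-area connection counts) uses
the modified asymptotic test for overlapping correlations: single-
correlation confidence limits with $\widehat{var}(r) = (1-r^2)^2/n$ are
combined through the estimated correlation between the two correlation
estimates into limits $(L, U)$ for $r_1 - r_2$; $r_1$ is declared higher
when $L > 0$. The normal quantile $z_{\alpha/2}$ is the upper $\alpha/2$
point. The cross-product radicands can turn (slightly) negative for
extreme estimated correlations between the estimates; they are floored at
zero with a warning. Benjamini-Hochberg adjustment and the
Cochran-Armitage trend test wrap the standard routines.

## Synthetic data: what it emulates, and what it does not

The generator plants a known answer behind every stage. Baseline activity
is Bernoulli-per-bin at 1 ms bins (at ≤ 100 spikes/s the per-bin
probability stays ≤ 0.1, so the thinned-Poisson approximation error is
negligible and trains are natively binary). Defaults are the conditions the
detection stage is designed for: 20 Hz baselines, transmission probability
0.5, lags of 2–4 bins with durations 1–2 (mono- and short polysynaptic
timescales), 100 trials of 2 s, three areas with 400 µm between centroids.
A positive coupling adds, per source spike, a target spike at a lag drawn
uniformly from the coupling's window with the transmission probability; a
negative coupling deletes target spikes in that window — a minimal
generative reading of co-silencing, which the literature defines only
through its detected signature. Shared slow modulation is a sinusoidal
envelope (200 ms period, relative amplitude 0.5, random phase per trial)
multiplying all rates, spanning several 25 ms jitter windows so the
correction has something to remove. Trial lengths per stimulus block are
free parameters; 2 s at 1 ms bins is a realistic passive-viewing repeat.

What the generator does *not* emulate: refractoriness and bursting,
cell-type structure, oscillations, common input from unobserved units,
rate nonstationarity across the session, and realistic lag jitter of
polysynaptic chains. Passing recovery tests therefore demonstrates the
pipeline's correctness under its own assumptions, not robustness to every
feature of cortical data.

One structural property of the detector deserves emphasis because it came
out of validating the jitter correction. A smooth envelope (any stationary
sinusoid) modulates the correlogram by $\cos$-shaped ripple whose maximum
deviation over the lag axis is bounded near $\sqrt{2}$ of the ripple's own
spread; since the detection band is $4$ standard deviations *of the
window reference set*, which absorbs the ripple, smooth comodulation alone
cannot cross the band — with or without correction. Jitter correction
removes the ripple from the curve (the corrected expectation is flat, as
the null-calibration tests verify) but under this windowed detection rule
it does not reduce, and can slightly increase, the false-positive count on
sinusoidally comodulated sessions: flattening the curve also deflates the
reference spread. The correction's value here is making the corrected
correlogram an unbiased, lag-flat estimate — the property the calibration
suite asserts — rather than suppressing an artifact this detector was
already insensitive to.

## Numerical choices and problem sizes

The CCG stage runs on a sparse trial-concatenated spike matrix (zero-padded
between trials so no coincidence spans a trial boundary) with one sparse
cross-product per lag; the analytic jitter expectation uses a dense smoothed
matrix. Both are exact, not approximations. Statistical calibrations in the
test suite use desk-scale configurations chosen once: 16–30 node networks
with 50-replicate ensembles and 150–200 draws for null calibrations
(the scored draw and its reference ensemble are generated from the same
base network's null space, which makes them exchangeable and the Z-scores
exactly centred), 20-seed repetitions for recovery and modularity checks,
and 100 random instances for exhaustive-oracle comparisons. Calibration
statements about per-class motif Z-scores are restricted to classes whose
intensity distribution is non-degenerate (present with at least ~5
instances on average); rare classes have heavy-tailed, discrete Z-scores
for which a mean-zero assertion is not meaningful at any affordable
ensemble size.

## Known limitations

- The detector's reference-set construction makes it conservative against
  smooth slow structure (see above) but windows are tested without
  multiplicity correction beyond the 4-sigma level itself.
- Degree-preserving randomization by rejection swaps has no formal mixing
  guarantee; conservation is verified, uniformity is approximate.
- Louvain is greedy and stochastic; small networks occasionally miss the
  exhaustive optimum in a single run (best-of-restarts is the supported
  protocol).
- The MA test is asymptotic; for very small n or |r| near 1 its coverage
  degrades and inputs at |r| = 1 are rejected.
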