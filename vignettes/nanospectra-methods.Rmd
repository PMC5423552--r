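---
title: "Models and methods behind nanospectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanospectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanospectra)
```

# The problem

A sub-nanometre pore in a silicon-nitride membrane passes an ionic current
that drops when a denatured, SDS-charged protein threads through it. The
time series of the *fractional blockade current*,
$|I - I_{\mathrm{open}}|/I_{\mathrm{open}}$, recorded during one
translocation is a *nanospectrum*: a noisy, single-molecule fingerprint of
the amino-acid sequence. Because the pore waist accommodates roughly four
residues, the instantaneous blockade level reflects a sliding window — a
*quadromer* — rather than a single residue, and the signal cannot currently
be decoded into a sequence de novo. What is feasible is *identification*:
matching a nanospectrum against a database of candidate proteins, exactly as
top-down mass spectrometry matches spectra against protein databases.

This package implements that pipeline end to end: event detection from raw
current traces, three forward models that predict a theoretical nanospectrum
from a sequence, database search scored by the coefficient of determination,
decoy-calibrated p-values, consensus averaging over repeated translocations,
and fluctuation-frequency length estimation. A simulator generates traces
with the same statistical structure, providing ground truth for every stage.

# Forward models

For a protein $P$ of length $|P|$ and window size $k$ (default $k = 4$), a
translocation reads $|P| + k - 1$ windows: the $|P| - k + 1$ full $k$-mers
plus $2(k-1)$ shorter prefixes and suffixes at the start and end of the
passage, when fewer than $k$ residues occupy the waist. All three models
emit one value per window, so their output aligns index-by-index with an
empirical spectrum discretized into $|P| + k - 1$ points under the
assumption of uniform translocation velocity.

**Mean Volume (MV).** The blockade level of a window is the mean
crystallographic volume of its residues; edge windows average over the
residues present. Volumes (nm$^3$) come from the crystallographic set
shipped in `inst/extdata/aa_properties.tsv`; they reproduce exactly the
four-group partition used below under the thresholds 0.11, 0.15 and
0.2 nm$^3$.

**Support Vector Regression (SVR).** The 20 residues are partitioned by
volume into Minuscule ($\le 0.11$), Small $(0.11, 0.15]$, Intermediate
$(0.15, 0.2]$ and Large ($> 0.2$ nm$^3$): {G,A,S,C}, {T,D,P,N,V},
{E,Q,H,L,I,M,K} and {R,F,Y,W} respectively. A window is encoded as its
group composition, a 4-tuple ordered (Large, Intermediate, Small,
Minuscule); e.g. `GQLD` becomes $(0, 2, 1, 1)$. There are only
$\binom{7}{3} = 35$ such compositions against $20^4 = 160{,}000$ raw
quadromers, which controls overfitting when training data are scarce. An
$\varepsilon$-SVR with an RBF kernel ($C = 1000$, $\gamma = 0.001$,
$\varepsilon = 0.01$, via libsvm) maps compositions to observed signal
levels.

**Random Forest (RF).** Hydrophilic residues bind water and change their
effective volume, so the RF model keeps the residue order and encodes each
window position as a (volume, hydrophilicity) pair — hydrophilicity from
the Kyte–Doolittle hydropathy scale by default, pluggable through
`use_aa_properties()`. Because blockade current is assumed order-free
within the waist, training sets are expanded by `augment_permute()`:
each window is replicated with its residues randomly permuted and the same
signal value (default 10 permutations per pair). Defaults are 100 trees and
unrestricted depth, with a seed for reproducibility.

**Edge handling.** For SVR and RF, edge windows are padded to length $k$
with a neutral pseudo-residue `-` carrying zero volume and hydrophilicity
and contributing to no composition group — representing a pore occupied by
fewer than $k$ residues. The MV model instead averages over the residues
present, which is the natural reading of the mean-volume definition.

# Identification and p-values

Given a spectrum $S$ and candidate $P$, $S$ is discretized into $|P| + 3$
contiguous regions (region means; any remainder samples are assigned one
each to the earliest regions), z-normalized, and compared with the
z-normalized model output by $R^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$
with $SS_{\mathrm{tot}}$ about the observed mean. Both vectors being
z-scored, $R^2$ can be negative and is at most 1. Since a molecule can
thread in either direction, both orientations of each candidate are scored
by default and the better kept. Candidates are ranked by $R^2$, ties broken
lexicographically by id; the search re-discretizes the spectrum per
candidate length, so mixed-length databases are handled correctly.

Significance is calibrated empirically: decoys are uniform shuffles of the
matched sequence (same length and residue multiset), and the p-value is the
fraction of decoys scoring strictly above the match — ties do not count
against it. The pseudocount variant $(r+1)/(N+1)$ is reported alongside,
since the plain estimator returns exactly zero whenever no decoy wins. The
test suite verifies that under the null — a spectrum scored against a
protein exchangeable with its decoys — these p-values are uniform, which is
what makes them interpretable.

# Consensus and length estimation

Single translocations are noisy; averaging several spectra from the same
protein suppresses uncorrelated noise as $1/\sqrt{n}$, and clusters of 5–10
spectra are typically enough to improve identification materially. Members
are resampled to a common length (linear interpolation on the normalized
event index; the median member length by default), z-normalized and
averaged pointwise. Orientation is *not* inferred before averaging —
deducing it per molecule is an open problem — so a consensus over mixed
orientations partially symmetrizes the signal; identification still
succeeds in the regimes the tests cover because decoy scores degrade
faster than the true-protein score.

The *fluctuation frequency* of a blockade — local maxima per millisecond —
correlates with protein length and needs no database. Peak counting uses a
moving-average smoother (window `length/(2 * max_length)` samples, with
`max_length = 200` residues by default) and a prominence criterion: a
maximum counts only if it rises above the higher flanking minimum by at
least `min_prominence` (default 0.5) times the event's fluctuation standard
deviation. Without the prominence rule, arbitrarily small noise wiggles
count as peaks and the estimate measures the sampling rate rather than the
molecule. Plateau maxima count once, at their leftmost sample. A
one-dimensional Gaussian mixture (via mclust, unequal variances) then
assigns spectra to length classes by maximum responsibility.

# Signal processing choices

* **Event detection.** Blockades are regions deviating from the open-pore
  baseline by more than 5 baseline-noise standard deviations for at least
  1 ms. The noise level is first estimated from first differences
  (`mad(diff(x))/sqrt(2)`), which is insensitive to how much of the trace
  is spent inside events, and the baseline is anchored at the upper current
  level (occlusion only lowers the current); both are then re-estimated
  from the non-event samples and detection repeated. Event edges extend to
  the half-threshold crossing so flanks are not clipped, and runs separated
  by less than the minimum duration merge into one event. An optional
  plausibility filter drops events whose mean fractional blockade falls
  outside a window such as [0.05, 0.5].
* **Standard deviation convention.** Population (divide by $N$)
  throughout — z-normalization and consensus noise estimates; this affects
  constants only, never rankings.
* **Normalization order.** Spectra are discretized first and z-normalized
  second, both in identification and when building training pairs.
* **Degenerate inputs.** Constant vectors cannot be z-normalized (error);
  constant spectra in correlation matrices yield flagged `NA`, never a
  silent zero; candidates longer than a spectrum's sample count are skipped
  with a warning rather than failing the whole search.

# The simulator

`simulate_blockade()` inverts the forward model: the per-window response of
a protein (reversed with probability `orientation_prob`, default 0.5 —
molecules can enter either end first) is z-scored, scaled by a fluctuation
amplitude around a mean blockade depth, dilated in time so each window
occupies an equal share of the event duration, and overlaid with white
Gaussian noise. `simulate_trace()` embeds such events in an open-pore
baseline at random non-overlapping offsets and converts to raw current via
$I = I_{\mathrm{open}}(1 - f)$. Defaults mirror the targeted acquisition
conditions: 250 kHz sampling, durations uniform on 1–20 ms, mean
fractional blockades uniform on 0.05–0.5, fluctuation amplitude 0.05 and
noise 0.01 of the open-pore current (noise at 20% of the signal sd — a
realistic single-event signal-to-noise for this class of measurement). A
`velocity_jitter` mode perturbs per-window dwell times to stress-test the
uniform-velocity assumption.

What the simulator deliberately does **not** emulate: multi-level events
from residual structure or co-occupying molecules (culled manually in
practice; an optional bimodality filter hook exists but real multi-level
morphology is richer), 1/f and drift noise (white noise only by default,
with an optional drift term), pore clogging, per-residue dwell-time
variation of real translocations, and pore-to-pore response differences.
Passing tests therefore demonstrate the *algorithmic* correctness and
calibration of the pipeline under its stated assumptions, not instrument
performance on laboratory data.

# Test and verification scale

The suite verifies the MV model exhaustively against a substring-mean
oracle for every protein of length $\le 8$ over a four-letter alphabet
spanning all volume groups ($k \le 4$), the $R^2$ arithmetic against an
independent implementation on 100 random pairs, null p-value uniformity on
200 simulated replicates with 400 decoys each, end-to-end recovery of a
68-residue protein among 999 composition-matched decoys over 50 simulated
traces at cluster sizes 1, 5 and 10, detection recall on 200 strong
embedded events, and the $\sqrt{n}$ consensus law over 100 trials. These
sizes were chosen as the smallest at which the corresponding statistical
statements are stable.

One calibration note: at the fixed SVR hyperparameters the composition
feature cannot exceed roughly $r \approx 0.96$ against exact per-window
mean volumes on a held-out protein (within-group volume spread is invisible
to the feature), so the suite asserts $r > 0.95$ at the composition level
against the closed-form conditional mean and $r > 0.9$ at the spectrum
level — the honest decomposition of the self-consistency claim.

# Known limitations

* Identification confidence is bounded by decoy-database resolution; a
  p-value of 0 means "better than all $N$ decoys", hence the pseudocount
  companion.
* Consensus averaging without orientation inference dilutes signal for
  strongly asymmetric proteins; orientation-aware clustering is future
  work.
* The volume table and hydrophilicity scale are module parameters, not
  facts of nature; any table reproducing the four-group partition can be
  substituted, and conclusions about borderline residues (e.g. C, V, E)
  depend on it.
* Fluctuation-frequency length estimation assumes the peak rate scales
  with read positions per unit time; heavy smoothing or non-uniform
  velocity biases it.
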