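---
title: "Unmixing fixed-time and scaled-time EEG components with scalerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing fixed-time and scaled-time EEG components with scalerp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalerp)
```

## The problem

Scalp EEG is a superposition: every sample mixes whatever event-related
responses are active at that moment.  Conventional ERPs deal with this by
averaging epochs time-locked to one event, which assumes each response
occupies a fixed wall-clock window around its event.  During timed
intervals this assumption fails twice over.  First, cue-locked and
response-locked activity overlap whenever the interval is short relative
to the analysis windows.  Second, some neural activity appears to stretch
or compress with the produced interval itself — a *scaled-time* component
that is a function of the fraction of the interval elapsed, not of
milliseconds since an event.  Averaging smears such a component and
misattributes it to the fixed-time waveforms.

`scalerp` estimates both families jointly by regression on the
*continuous* recording (the rERP approach).  The model at one sensor is

$$ Y = X\beta + \varepsilon $$

where the design matrix $X$ (samples × predictors) contains:

* one block of stick functions per fixed-time component — column $j$
  carries a 1 at lag $j$ relative to every event of that type, so a
  1,000 ms window at 200 Hz is exactly 200 columns; overlapping events
  sum, which is what lets least squares deconvolve them;
* one block of `n_points` columns for the scaled-time component.  Each
  trial contributes the area-averaging (box-kernel) resampling operator
  `resize_box(n_points, D)` on its own cue-to-response rows, where $D$ is
  that trial's interval in samples.  Columns therefore index *elapsed
  fraction*; two trials of different duration load the same columns.

When events do not overlap at all, the least-squares estimate of a fixed
block reproduces the conventional epoch average exactly (this is asserted
to 1e-10 in the tests).

## Regularization

With overlapping regressors the normal equations can be poorly
conditioned, so the solver minimizes

$$ \lVert X\beta - Y\rVert^2 + \lambda \lVert L\beta \rVert^2 $$

with $L$ the scaled first-difference operator (rows
$\tfrac12(e_j - e_{j+1})$), i.e. a smoothness penalty on each estimated
waveform.  Two choices deserve a note:

* **$L^\top L$ vs $L$.**  The unique minimizer of the objective above
  solves $(X^\top X + \lambda L^\top L)\beta = X^\top Y$.  A variant that
  places the non-symmetric $\lambda L$ directly in the normal equations
  circulates in the literature; it does not minimize the stated objective.
  The default is $L^\top L$; `fit_rerp(..., literal = TRUE)` reproduces
  the other variant for audit.
* **Blockwise penalty.**  $L$ never couples columns of different
  components: smoothing the end of the cue waveform into the start of the
  response waveform would tie unrelated quantities together.  Width-1
  blocks simply contribute no penalty rows.

$\lambda$ is chosen per recording by 10-fold cross-validation at a single
target channel, over the grid
$\{0.001, 0.01, 0, 1, 10, 100, 1000, 10^4, 10^5\}$, with exact ties broken
toward the larger candidate.  Folds are *contiguous* blocks of retained
samples by default: EEG noise is strongly autocorrelated, and randomly
interleaved folds let the training set memorize the held-out noise,
biasing $\lambda$ low.  A randomized fold scheme remains available
(`contiguous = FALSE`) since both conventions are defensible.

## Diagnostics and validation quantities

**VIF.**  The fixed and scaled regressors necessarily co-occur in time,
so collinearity is the method's main failure mode.  `compute_vif()`
reports $1/(1-R^2_j)$ per column (centered columns, implicit intercept),
with 10 as the conventional flag level.  Identifiability improves with
interval variability across trials — which is why the simulator treats
interval jitter as a first-class parameter.

**Unmixed datasets.**  `reconstruct_unmixed()` recombines the residual
with either the fixed or the scaled contribution
(`fixed_only = X_f\beta_f + \varepsilon`, likewise `scaled_only`), so
that downstream analyses can be run on a signal containing only one
family plus noise.  The identity
`fixed_only + scaled_only − residual = Y` is asserted on every fit.

**Scaling index.**  Per condition, cue-to-response epochs are stretched
(box kernel) to a common duration, averaged — stretch first, then
average — and the longest condition's waveform is predicted from each
shorter condition's stretched waveform by simple linear regression with
intercept.  The index is the mean $R^2$.  The regression-with-intercept
definition makes the index invariant to affine amplitude transforms and
bounded in $[0, 1]$; the paper-style alternative without intercept would
conflate amplitude and shape differences.  On data whose only
interval-spanning signal is truly scale-invariant the index is 1 by
construction.

**Cluster-based permutation test.**  `cluster_permutation_test()` tests
the scaled-time waveform against zero across participants.  For each
electrode, the spatial cluster is the electrode plus its template
neighbors; a temporal cluster is a maximal run of fraction-points where
**all** electrodes of the spatial cluster exceed the cell-level critical
$t$ (the literal "all included electrodes" rule; the common any-electrode
variant is an option).  Cluster mass is the spatial mean of the summed
$|t|$ within the run.  The null flips each participant's entire waveform
with a fair coin and records the maximum mass per spatial cluster.

One deliberate deviation from a literal per-cluster comparison: observed
masses are declared significant against the per-permutation maximum over
*all* spatial clusters (the max-statistic convention).  Comparing each
spatial cluster only to its own null does not control the family-wise
error over electrodes; with the global null the test is calibrated for
any neighbor graph, and the package's calibration test verifies a
family-wise false-positive rate statistically indistinguishable from the
nominal 0.05 (200 null repetitions, exact binomial check).  Per-cluster
nulls are still returned for audit.  P values use the add-one convention
$(\#\{\text{null} \ge \text{obs}\} + 1)/(n_{perm} + 1)$, so $p = 0$ never
occurs.

**PCA latency analysis.**  To relate the scaled component's latency to
behavior, trials are grouped into equal-sized response-time bins
(early / on time / late), the `scaled_only` signal is averaged per bin and
electrode, and the bin×electrode waveforms (rows mean-centered) are
decomposed by SVD.  PC1 recovers the common waveform; PC2 approximates
its temporal derivative, so adding or subtracting PC2 shifts the waveform
earlier or later — a first-order Taylor expansion in latency.  Sign
conventions are fixed (PC1 positively aligned with the grand mean, PC2
positively correlated with PC1's forward difference) so PC2 scores have a
reproducible direction.  Per-bin PC2 scores feed a one-way
repeated-measures ANOVA (`rm_anova()`) reporting $F$, $\eta_p^2 =
SS_Q/(SS_Q + SS_{sQ})$ and $\eta_g^2 = SS_Q/(SS_Q + SS_S + SS_{sQ})$.
The observation layout (bins × electrodes as rows of one PCA) is a
reconstruction — the source analyses are not fully explicit about it —
but it satisfies the two properties that define the method (PC1 ≈ shape,
PC2 ≈ derivative).  When the bin effect's sum of squares is exactly zero,
$F$ and both $\eta$ are reported as 0 rather than 0/0.

## The simulator and what a green test establishes

`simulate_dataset()` generates the stated validation world: 50 trials per
condition with cue→response intervals of 0.8, 1.65 and 2.5 s at 200 Hz, a
fixed cue-locked component on (−200, 800) ms, a fixed response-locked
component on (−800, 200) ms, and one scaled template stretched per trial
with the same box kernel the design matrix uses.  Values the sources
leave open were fixed once as follows:

* **Component shapes** (`default_shapes()`): raised-cosine curves — a
  biphasic cue transient, a ramp-plus-peak response shape, a slow
  negative half-cycle for the scaled template (the classic CNV-like
  morphology) — all zero-mean over their support and within ±20 µV,
  a physiological scalp range.
* **Noise**: AR(1) with coefficient 0.95 scaled to a stationary RMS, a
  reasonable stand-in for 1/f-dominated EEG background; white noise is
  retained for analytic tests.  Recovery acceptance runs at *signal-RMS
  parity* (noise RMS equal to the RMS of the summed noiseless signal).
* **Interval jitter**: Gaussian, SD 0.15 s, truncated at ±3 SD — roughly
  the trial-to-trial variability of produced intervals in timing tasks,
  and enough variability for the scaled block to be identifiable.
* **Inter-trial gap**: uniform 1.2–2.0 s between response and next cue,
  which makes adjacent fixed windows overlap occasionally (as in real
  recordings) without degenerate designs.

The simulator does *not* emulate ocular or muscle artifacts, channel
drift, bad channels, or realistic scalp topographies (per-channel
component weights are scalar draws).  A green recovery test therefore
establishes that the estimator inverts the stated generative model at a
realistic SNR — not that preprocessing of real recordings is handled, nor
that the production-task effect sizes are reproduced (those require the
original datasets).

## Numerical choices and degenerate inputs

* `resize_box` rows are normalized to sum to 1 (amplitude-preserving);
  the matrix is exact fractional bin overlap, and boundary bins when
  compressing below `n_points` follow the overlap-integral definition.
* The solver uses a Cholesky factorization of the normal equations and
  falls back to a minimum-norm SVD solution (with a warning) if the
  system is singular at $\lambda = 0$.
* Events whose fixed windows exceed the recording keep their truncated
  support; the clipped rows are flagged `edge` rather than silently
  dropping trials.
* Zero-variance cells in $t$ maps are reported as ±Inf with a flag;
  zero-variance targets make the scaling index `NA` with a warning;
  zero-variance paired differences flag Cohen's $d$ as undefined.
* Epoch rejection applies the step rule (max consecutive-sample
  difference > 50 µV) and the range rule (max − min > 150 µV) on the
  epochs as stored, i.e. after baseline correction.

## Known limitations

* No spline or otherwise nonlinear time bases; one scaled component per
  model.
* $\lambda$ is selected at one target channel and shared across channels.
* EDF and EEGLAB `.set` input require conversion to the native format
  upstream; only BrainVision and the native interchange are read
  directly.
* The cluster test's "all electrodes" rule is conservative for large
  spatial clusters; use `rule = "any"` for the common relaxed variant.
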