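---
title: "Theta-band representational similarity and connectivity analysis of narrative-insight EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-band representational similarity and connectivity analysis of narrative-insight EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetalink)
```

## The scientific problem

In narrative-insight experiments, participants repeatedly view short
video events from several storylines (events A, B and X per story) in a
*pre* phase, then learn — either by imagining the link or by observing a
linking video — that A and B belong to one narrative while X does not,
and finally view all events again in a *post* phase. The question is how
this insight reconfigures the neural representation of the events: does
the similarity between the theta-band (4–7 Hz) EEG power patterns of A
and B increase from pre to post, does it depend on the mode of insight
(imagination vs. observation), and is it altered by inhibitory brain
stimulation (cTBS vs. sham) applied before the insight phase?

`thetalink` implements the complete analysis chain for this design —
time-frequency decomposition, time-by-time representational similarity
analysis (RSA), cluster-based permutation statistics, sliding-window
imaginary coherence, and follow-up/brain–behavior statistics — together
with a synthetic session generator, so that every stage of the pipeline
can be validated end to end without access to human data.

## The synthetic session generator

`simulate_session()` emulates one experimental cohort. Its signal model
per trial is deliberately minimal but targets exactly the statistics
the pipeline estimates:

* **Background**: `1/f^beta` noise (default `beta = 1`), one source per
  channel, mixed *instantaneously* by a random orthonormal matrix. A
  zero-lag mixture contributes nothing to imaginary coherence, so the
  connectivity null is true by construction.
* **Event patterns**: during the 0–2 s stimulus window, each event
  carries a theta oscillation (4, 5, 6, 7 Hz components) whose
  per-channel amplitude is the square root of a latent *power* pattern
  over channels × theta frequencies. The pattern lives in the power
  domain because downstream RSA correlates baseline-corrected power;
  mixing in that domain makes the planted similarity act linearly.
  Patterns change over the stimulus window (default: two 1 s segments
  with independent patterns) — event representations in real data are
  dynamic, and this also decorrelates the time-by-time similarity map
  across segments. Patterns are canonical (stimulus-driven): all
  subjects share them, drawn from a session-level random stream, while
  all subject-level randomness (noise, phases, trial order) uses
  per-subject streams.
* **Integration (`alpha`)**: in the post phase the linked events' power
  patterns become `(1 - alpha) * own + alpha * shared(story)` with
  `alpha` taken from the subject's group × mode cell. The shared
  narrative pattern is drawn with a wider spread (squared-exponential
  entries) than the event-specific ones, so a given `alpha` produces a
  reliably positive A–B power correlation per channel. The A–B overlap
  (correlation of the latent patterns) is monotone in `alpha`, which is
  tested property-style over `{0, 0.3, 0.6, 0.9}`.
* **Coupling (`gamma`)**: a 5.5 Hz source is added to designated channel
  pairs (defaults: C4–Fp1, C6–Fp1, T8–Fp1, T8–AF7) with the second
  channel delayed by `lag_phase` (default 90°), scaled by the
  group × phase × mode coupling strength. Because the source is planted
  channel-locally (never mixed), the imaginary coherence of the planted
  pair follows the analytic two-source formula
  `Im(C) = sin(phase) * P_s / (P_s + P_n)`.
* **Behavior**: per-subject recall counts are Poisson with a log-linear
  group effect on linked-event detail and linking-event naming — the
  simplest count model that yields group differences for the
  brain–behavior correlation stage.

Trial tables reproduce the design arithmetic: 10 stories × 3 events ×
18 repetitions per phase (540 non-target trials), block-structured
pseudorandom order (every video appears once per block, no immediate
repeats across block boundaries), target trials interleaved at 11% of
each phase, ITIs uniform on 700–1300 ms. Stimulation metadata follow
the standard cTBS protocol (3-pulse 50 Hz triplets at 5 Hz for 40 s =
600 pulses at 80% of motor threshold).

What the generator does **not** emulate: volume conduction through a
forward model, ocular/muscle artifacts, bad channels, subject-specific
pattern idiosyncrasy, or the insight-phase EEG itself. Passing tests
therefore demonstrate the correctness and calibration of the analysis
machinery — not that real EEG would show these effects.

## Preprocessing

The chain is `epoch (-2..3 s) -> average reference -> demean/detrend ->
DFT notch -> (amplitude rejection) -> downsample`, in that fixed order.
The notch is a per-trial least-squares fit-and-subtract of a
sine/cosine pair at 50 Hz (implemented jointly with the mean and trend
as one projection, which removes the same subspace as the sequential
steps). Amplitude rejection (peak-to-peak threshold, default 150 µV) is
an automated stand-in for visual artifact screening; synthetic runs
that plant no artifacts disable it. Downsampling requires an integer
factor and applies a zero-phase FIR low-pass at 80% of the target
Nyquist before decimation.

## Time-frequency decomposition and features

`hanning_tfr()` computes power with sliding Hanning windows of
`n_cycles / f` seconds (default 5 cycles), on a frequency grid of
2–45 Hz in 1 Hz steps and an output time grid with 50 ms spacing — the
spacing is fixed by the 41 time points that the 0–2 s feature window
must contain. Window lengths are rounded to an odd number of samples
for symmetric centring. Power is amplitude-calibrated: a stationary
sinusoid of amplitude `a` at a bin frequency yields `a^2 / 2` at every
valid time and frequency, so band power ratios are comparable across
frequencies (checked against a periodogram oracle). Output bins whose
window is not fully supported by the epoch are *missing*, never zero.

Baseline correction subtracts the mean power over −1.8 to −1 s. At
4 Hz the five-cycle window (1.25 s) is not fully supported over the
whole baseline inside a −2..3 s epoch; the mean is therefore taken over
the *valid* part of the window per frequency, and an error is raised
only when a frequency has no valid baseline bin at all.

Single-trial power is averaged within each (subject, story, event,
phase) cell — across the 18 repetitions — before any correlation;
averaging across stories happens *after* correlation, on the Fisher-z
maps. The alternative reading (averaging patterns across stories before
correlating) would correlate story-averaged patterns instead, and is
deliberately not the default because the similarity of interest is
story-specific.

## Representational similarity maps

For each electrode, phase and mode, the theta feature vectors (power at
4, 5, 6, 7 Hz) of two events are correlated at every pair of time
points, giving a 41 × 41 Pearson map, Fisher-z transformed with
clipping at `1 - 1e-6`. Correlations are computed within story only (A
with B for linked, A with X for non-linked; each within-story pair used
exactly once, no cross-story pairs) and the z maps averaged across the
mode's stories with pairwise exclusion of missing bins. This yields 8
conditions per electrode and subject: {linked, non-linked} × {pre,
post} × {imagination, observation}. Difference waves are signed
weighted sums over conditions; the built-in contrasts are the
(post − pre) × (imagination − observation) interaction for linked and
non-linked pairs and the four-way difference-of-differences.

## Cluster-based permutation statistics

The group comparison is an independent-samples cluster-based
permutation t-test. Per voxel (electrode × time × time bin, or channel
pair × window for coherence) a pooled-variance t is computed; voxels
with `|t|` above the two-tailed critical value at `alpha_cluster =
0.001` are clustered — same channel and 4-connected grid bins, or
neighbouring channels at the same bin — separately by sign. The cluster
statistic is the mass (sum of t). Group labels are permuted (default
10,000 draws; scaled runs use 500) and each cluster's Monte Carlo p is
`(b + 1) / (n_perm + 1)` against the permutation distribution of the
maximum |mass|, with `ci_range = 1.96 * sqrt(p (1 - p) / n_perm)`.
Design choices: a single |t| threshold with sign-separated clusters and
a max-|mass| null (the standard two-sided configuration); mass rather
than cluster size; the `(b + 1)/(N + 1)` estimator to avoid zero
p-values.

Channel neighbourhoods come from the packaged spherical 64-electrode
montage: two channels are neighbours when their chord distance is below
a quantile of all pairwise distances (default 0.10, giving median
degree 7). For connectivity, channel-pair nodes are neighbours when
they share one channel and the two non-shared channels are neighbours;
pairs are also connected across adjacent time windows.

An exhaustive oracle (`exhaustive_null()`, and
`cluster_test(permutations = "exhaustive")`) enumerates all label
partitions when `C(nA + nB, nA)` is at most 20,000 and reports the
exact proportion (observed labelling included). The Monte Carlo engine
is validated against it, and its cluster-level type-I error is checked
on 100 null datasets (16 vs 16 subjects, 8 channels, 11 × 11 maps,
500 permutations) against the binomial band [0.01, 0.12] around the
nominal 0.05.

## Imaginary coherence

Cross-spectra at the mean theta frequency (5.5 Hz) are estimated in
0.5 s windows sliding over 0–2 s in 50 ms steps (31 windows), with dpss
(Slepian) tapers for the stated ±1.5 Hz smoothing. The taper count
`K = max(1, round(2 T W) - 1)` equals 1 here — the stated
time-bandwidth product (0.75) is at the edge of multitaper validity, so
the single leading Slepian sequence (computed exactly from the standard
tridiagonal eigenproblem) is used and the count is exposed in the
configuration. Imaginary coherence per pair is
`Im(S_ij / sqrt(S_ii S_jj))`, carried *signed* through contrasts and the
cluster test; magnitudes appear only in descriptive summaries. Linked
stacks average the event-A and event-B coherence; the non-linked event
X is kept separate. Trials are pooled across a mode's stories for
better-conditioned cross-spectra (the per-story-then-average
alternative is noisier for the same data).

One numerical caveat is documented rather than hidden: for a *real*
quadrature signal pair, the finite-window tapered estimator cannot
reach `|Im(C)| = 1` exactly — negative-frequency leakage of the taper
bounds the magnitude slightly below 1 (about 0.998 for the default
window). The exactness property `|Im(C)| = 1` holds at the coherency
level (an exactly quadrature cross-spectrum), which is how it is
tested; the signal-level test asserts a purely imaginary coherency
(real part cancels exactly on a balanced phase grid) of magnitude
above 0.99.

## Follow-up statistics

Cluster means (per subject and condition, over the cluster's voxels)
feed the univariate stage: classic paired t within groups (df = n − 1,
effect size `d_z = t / sqrt(n)` exactly), Welch t for group contrasts
(the convention behind fractional dfs), and the 2 × 2 group × time
interaction whose F equals the squared pooled t on difference scores
(an algebraic identity that is tested to 1e-10), with generalized eta
squared `SS_int / (SS_int + SS_subject + SS_within-error)`.
Brain–behavior association uses Pearson or Spearman correlation with
`t = r sqrt(n-2) / sqrt(1-r^2)`, and two independent correlations are
compared with the Fisher r-to-z test. Behavioral outliers are excluded
at mean ± 3 SD (computed once on the full sample). The repeated-measures
effect size printed in the field's reports is not uniquely defined by a
printed t and n; this package reports `d_z` and labels it explicitly.

## Scaled problem sizes

The default configuration carries the full study parameters (64
channels, 256 Hz, 10 stories × 18 repetitions, 10,000 permutations).
The validation suites run the same code on scaled sessions chosen as
the smallest designs whose planted effects are still reliably
recoverable: an 8-channel montage (Fp1, AF7, FT7, T7, TP7, P7, C4,
T8), 8 stories × 4 repetitions at 64 Hz with epochs of −2..2.7 s,
pattern SNR 2 on channels FT7/T7/TP7, 16 subjects per group, and 500
permutations. With integration planted at `alpha = 0.6` in the
sham/imagination cell and no planted coupling, the linked interaction
contrast yields a significant cluster covering the planted channels in
essentially every seeded replicate, and the detection rate is
non-decreasing in `alpha` over `{0, 0.3, 0.6, 0.9}`.

## Degenerate inputs and tie-breaks

Zero-variance feature vectors give missing correlations, excluded
pairwise from story averages; a condition with only missing bins is an
error. Zero-variance differences in the paired t give a signed infinite
t (p = 0). A notch at or above Nyquist, a downsampling factor that is
not an integer, epochs that do not admit the analysis window, and empty
design cells are errors that name the offending parameter. Cluster
results order clusters by |mass|; an empty supra-threshold set is a
valid empty result, not an error.

## Serialization

Arrays and tables exchange through plain-text containers: epoch sets as
a directory of TSV + JSON (`write_epochs()`), configurations as YAML
(`write_config()`), and run reports as a schema-versioned JSON master
file plus TSV tables (`write_report()`). Channel naming everywhere
follows the packaged montage labels (e.g. "FT7", "TP7"); connectivity
cluster members are reported as pair labels such as "C4-Fp1".

## Known limitations

* The generator's canonical (subject-shared) patterns make group
  effects more homogeneous than real cohorts; between-subject pattern
  variability would lower power at the same SNR.
* Bad-channel interpolation, ICA artifact removal and source-space
  analyses are out of scope.
* The 0.03–100 Hz online acquisition filter is hardware-side and not
  replicated; synthetic data are generated band-limited.
* Only the 4–7 Hz band is analysed; the TFR supports the full 2–45 Hz
  grid but no other band is wired into the RSA.
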