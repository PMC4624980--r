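---
title: "Cortico-acoustic correlation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortico-acoustic correlation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cacor)
```

This vignette is the package's account of its science: the model behind the
cortico-acoustic correlation (CACor), the assumptions it rests on, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. The measurement problem

Tone onsets in continuous sound evoke transient cortical responses — a
negativity around 100 ms and a positivity around 180 ms after the onset,
with a fronto-central scalp topography (the auditory N1–P2 complex). In
naturalistic music the onsets come every few hundred milliseconds, so the
responses overlap and epoch averaging is impossible for all but strictly
isochronous stimuli. The backward-model alternative asks the converse
question: how well can a linear readout of the EEG reconstruct a stimulus
feature that marks the onsets?

The feature used here is the **audio power slope**: the waveform's power in
50 ms frames with 50% overlap (a 40 Hz series, also reported as the Sound
intensity descriptor), smoothed with a 3-tap Gaussian kernel, differentiated,
and linearly resampled to the EEG rate of 100 Hz. Positive peaks of this
series are auditory "edges". Negative slopes (offsets) are retained: the
regression decides what is informative.

## 2. The reconstruction model

With preprocessed EEG $x(t) \in \mathbb{R}^C$ and power slope $y(t)$, the
package fits

$$\hat y(t) = \sum_{c=1}^{C}\sum_{\ell=0}^{L} w[c,\ell]\, x_c(t+\ell) + b,
\qquad L = 30 \text{ samples} = 300 \text{ ms},$$

estimated by ridge regression in covariance form,
$w = ((1-\lambda)\hat\Sigma + \lambda\nu I)^{-1}\hat c_{xy}$ with
$\nu = \operatorname{mean}\operatorname{diag}\hat\Sigma$, $X$ and $y$
mean-centred and the intercept stored. The embedded design has
$C\cdot(L{+}1)$ columns (1891 for the 61-channel montage) and strongly
requires regularization; $\lambda$ is the analytic Ledoit–Wolf optimum
toward $\nu I$, clipped to $[0,1]$.

**Direction of the embedding.** The design row for stimulus sample $t$
contains the EEG at $t \ldots t+300$ ms — the window in which the brain
response to that sample occurs. An embedding over *past* EEG ($t-\ell$)
looks symmetric but is not: with a causal response kernel,
$\operatorname{cov}(x_c(t-\ell), y(t)) = \sum_k k_k \rho_y(\ell+k) = 0$ for a
serially uncorrelated target, i.e. the model could reconstruct nothing but
the stimulus's own periodicity. The package therefore embeds forward,
zero-pads the last $L$ samples of each recording, excludes those rows from
the training loss, and never lets the embedding span the boundary between
concatenated training presentations. Projections are consequently aligned
sample-for-sample with the power slope (no bulk delay).

**Cross-validation.** For three presentations of a stimulus by one subject,
each filter is trained on the concatenation of two presentations and applied
to the third. A significant held-out CACor therefore reflects stimulus-driven
structure that generalizes across presentations, not overfitting.

## 3. Significance under autocorrelation

Both series are strongly serially correlated, so naive correlation tests are
invalid. Two independent routes are implemented and reported side by side:

* **Phase-randomized surrogates** of the power slope: the amplitude spectrum
  (hence autocorrelation) is preserved while phases are randomized;
  $p = (1 + \#\{r_{surr} \ge r_{obs}\})/(n_{surr}+1)$, one-sided positive by
  default (a negative reconstruction correlation is not evidence of onset
  tracking), two-sided available. Randomizing the stimulus side keeps every
  property of the EEG projection fixed. The surrogate correlations are
  computed in the frequency domain (a surrogate's variance is
  spectrum-invariant and its covariance with the projection is a
  phase-rotated cross-spectrum sum), which is exactly distribution-equivalent
  to explicit surrogate construction and removes the per-surrogate inverse
  transform.
* **Effective degrees of freedom**:
  $1/N^* = 1/N + (2/N)\sum_{j=1}^{J}\frac{N-j}{N}\hat\rho_{xx}(j)\hat\rho_{yy}(j)$,
  $J$ capped at 2 s of lag for CACor (10 s for the slow feature series),
  $N^*$ clipped to $[2, N]$, and a $t$ test on $N^*-2$ df. For two AR(1)
  series with $\phi = 0.9$ this reproduces the closed form
  $N^* \approx N(1-\phi^2)/(1+\phi^2)$.

Multiplicity: per-presentation flags are Bonferroni-corrected across all
presentations of a stimulus (27 in the reference design); the **CACor score**
of a stimulus is the count of significant presentations. Feature-wise partial
correlations are FDR-controlled (Benjamini–Hochberg, $q = 0.05$). Profile
correlations between stimulus-level score/feature vectors use Spearman's rho
with an exact permutation $p$ for $n \le 9$ stimuli.

## 4. Preprocessing defaults

| parameter | default | why |
|---|---|---|
| lowpass | Chebyshev-I, pass 42 Hz, stop 49 Hz | stated band edges; order (11 at 500 Hz) chosen for ≤ 1 dB ripple, ≥ 40 dB stopband |
| resampling | decimation to 100 Hz | the lowpass doubles as the anti-alias filter |
| highpass | 1 Hz Butterworth, order 2 | removes drift; order unstated, 2 is the conventional choice |
| filter application | zero-phase (forward–backward) | any filter latency would otherwise be absorbed, asymmetrically, by the embedding |
| embedding | $L = 30$ lags at 100 Hz | response latencies 0–300 ms |
| time-resolved CACor | 3 s windows, 90% overlap | 0.3 s step, a 3.33 Hz correlation time course |
| surrogates | $n_{surr} = 999$, $\alpha = 0.05$ | p floor 0.001 < the Bonferroni threshold 0.05/27 |

Audio descriptors use two frame grids: 50 ms/50% (intensity, spectral
centroid, entropy, flux) and 3 s/33% (sharpness, fluctuation
centroid/entropy, pulse clarity, key clarity). Pulse clarity
(autocorrelation-peak ratio of the onset-strength envelope in the 0.25–2 s
lag band) and key clarity (maximal Pearson correlation of a 12-bin chroma
with the 24 Krumhansl–Kessler key profiles) are documented simplifications of
the usual MIR composites: their tests assert ordering properties (isochronous
beats above Poisson onsets; a triad above noise), never toolbox parity. The
fluctuation band is fixed to 0–10 Hz with the DC bin excluded. Sound
intensity stays in linear power units.

## 5. Pattern interpretation

Backward-model weights are not topographies; the package reports the
activation pattern $A = \hat\Sigma w / \operatorname{var}(\hat y)$, reshaped
to channels × lags. $A$ is reduced by SVD to the smallest subspace holding
98% of squared singular mass and decomposed by a recursive (RAP-style) MUSIC
scan: at each step the dipole grid of a single-sphere analytic head model
(unit conducting sphere; electrodes from a built-in, geometrically
constructed 10–20/10–10 table; shells at radii 0.3–0.85; three orthogonal
moments per point; average-referenced gains) is searched for the
best-oriented forward field with maximal subspace correlation, the field is
projected out, and the scan repeats — up to 4 components, stopping when the
subspace correlation drops below 0.8. Component time courses are the
least-squares representation of each map in the retained pattern
($\tau = P^\top a$); they are filter-like weightings over lags 0–300 ms,
*not* ERP waveforms, and their sign is arbitrary. Per-subject component
selection uses the absolute cosine to an ERP-derived reference topography
(subject-wise peak of the onset ERP at Fz inside 0.13–0.28 s, topography
averaged over ±10 ms, averaged across subjects, unit-normalized); absolute
cosine was chosen over Euclidean distance because topography comparisons
should be scale- and polarity-invariant.

**What "ground truth pattern" means.** For an autocorrelated target the true
activation pattern of the estimation problem is *not* the generating kernel:
$\operatorname{cov}(x_c(t+\ell), y(t)) \propto
\operatorname{map}_c \sum_m k_m \rho_y(\ell - m)$ — the kernel convolved
with the target's autocorrelation. `ground_truth_pattern(slope = ...)`
computes this; against it the fitted patterns reach cosine ≈ 0.99 at SNR 1,
whereas against the raw kernel the cosine is bounded near 0.4 for the
chord-sequence stimulus *at any* SNR. Kernel-latency recovery (N1/P2 extrema
within ±30 ms) is therefore checked with a weakly autocorrelated synthetic
target, where the two definitions coincide.

## 6. Rating (tension) analysis

Continuous rating sets are screened by all pairwise Pearson correlations
with phase-randomized surrogate significance; the stimulus lag is estimated
by cross-correlating the z-scored grand-average rating with sound intensity
over 0–3 s in 10 ms steps, falling back to exactly 1.0 s when no clear peak
exists (maximum below 0.1, or not exceeding the zero-lag value). "Clear
peak" needed an operational definition the source analysis left implicit;
the 0.1 floor keeps white-noise cross-correlation maxima from masquerading
as peaks. Activity analysis counts, per 1 s window with 50% overlap, the
raters whose net rating change is positive (rising) or negative (falling);
window significance compares max(rise, fall) against the 95th percentile of
a null built from independent circular time shifts of each rater — each
rater's autocorrelation is preserved, alignment is destroyed. The
**Coordination Score** is reported as the fraction of significant windows
(durations differ between stimuli; the raw count is also returned).

## 7. The synthetic world

The generator exists so that every claim in the test suite is checked
against a known truth:

* **Stimulus**: isochronous major-triad chord sequences — 350 ms chords,
  17.5 ms linear ramps, 420 ms inter-onset interval, root changing every
  7–11 repetitions — the one reference stimulus whose parameters are fully
  stated.
* **EEG**: source = power slope convolved with a biphasic N1–P2 kernel
  (negative lobe at 100 ms, positive at 180 ms, within the 0–300 ms
  embedding span), projected through the scalp field of a radial
  fronto-central dipole computed with the package's own spherical head
  model; plus independent 1/f-amplitude noise per channel (unit RMS, knee at
  1 Hz) and a common-mode 10 Hz alpha component (amplitude 0.3). `snr` is
  the per-channel signal-to-noise amplitude ratio at coupling 1; `coupling`
  scales the stimulus-driven part.
* **Ratings**: rater = coupling·latent(t − lag) + (1 − coupling)·smooth
  idiosyncratic fluctuation + white noise, clipped at zero (the joystick
  floor). The idiosyncratic term is stationary Gaussian-smoothed noise with
  a 0.25 s correlation scale: slow enough to move like a rating, fast
  enough that independent raters are actually uncorrelated (a literal random
  walk would give |r| ≈ 0.4 between independent raters and make the
  independence checks meaningless).

What the generator does **not** emulate: eye/muscle/movement artifacts (the
reference pipeline removed them by ICA with visual selection, which is out
of scope — inputs are assumed pre-cleaned), volume conduction beyond the
single sphere, between-subject response variability, and the timbral
richness of real music. A green test therefore establishes that the
machinery is correct and calibrated, not that any particular real stimulus
set will yield a given score profile.

The end-to-end check uses nine stimuli with coupling grades 0–1, three
subjects × three presentations, 30 s stimuli, a 19-channel montage, and
generator SNR 0.125. The SNR was calibrated once so that the coupling grades
straddle the detection threshold — the situation the method is for, and the
shape of the reference score profile (scores from 0/27 up to 24/27): at
higher SNR all nonzero couplings saturate at the maximal score and a profile
correlation measures nothing but tie-handling. Simulated worlds throughout
the suite use smaller montages and shorter durations than the
9-subject/61-channel reference design purely for run-time; all statistics
under test are size-invariant.

## 8. Numerical choices and degenerate inputs

* The 3-sample Gaussian smoother uses $\sigma = 1$ sample, normalized to
  unit sum; the slope is a forward difference scaled by the frame rate
  (units power/s; scale is irrelevant downstream, where only correlations
  are used).
* All time windows are half-open $[t, t + \text{len})$ in samples; window
  starts tile at exact multiples of the step (a 60 s series gives exactly
  191 time-resolved windows).
* Correlation of anything with zero variance is an error, not a silent NaN;
  all-zero analysis frames yield NaN feature values, and NaN frames are
  propagated by resampling (never interpolated across) and dropped listwise
  in correlations; windows with fewer than 10 finite pairs return NaN.
* A zero-variance embedded design yields $\lambda = 1$; singular ridge
  systems fall back to a pivoted least-squares solve.
* Surrogate p-values are floored at $1/(n_{surr}+1)$; effective-df p-values
  at the smallest positive double. $N^* \le 2$ returns $p = 1$ with a
  warning.
* MUSIC tie-breaks: component matching prefers higher explained variance,
  then lower index; map signs are arbitrary and all comparisons are
  absolute-cosine.
* Pulse-clarity onset envelopes below $10^{-9}$ of the mean envelope power
  are treated as silence (floating-point residue on constant tones is not an
  onset train).

## 9. Known limitations

* The spherical head model is self-consistent but anatomically idealized;
  dipole locations are in model coordinates, not MNI space. Sources between
  grid shells localize to the nearest shell (field cosines ~0.95).
* EDF support is minimal (16-bit, uniform per-signal rate); BrainVision raw
  formats are not read.
* The built-in electrode table is geometric (idealized sphere), not
  digitized positions.
* Phase-randomization assumes stationarity; for strongly non-stationary
  ratings the pairwise surrogate test is mildly anticonservative (documented
  in its test).
* Exact permutation p-values for profile correlations are limited to
  $n \le 9$ stimuli (362,880 permutations); larger sets use the $t$
  approximation.
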