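# cacor: cortico-acoustic correlation analysis of EEG responses to continuous sound

When people listen to ongoing music or other continuous sound, note onsets
evoke phase-locked cortical responses (the auditory N1–P2 complex). With
naturalistic stimuli these responses overlap and cannot be isolated by
classical epoch averaging. `cacor` implements the stimulus-reconstruction
alternative: a linear backward model reconstructs the stimulus's **audio
power slope** — the first derivative of its short-time power, whose positive
peaks mark note onsets — from the multichannel EEG, and the Pearson
correlation between reconstruction and true power slope, the
**cortico-acoustic correlation (CACor)**, quantifies how strongly a
listener's cortex tracked the onset structure of one stimulus presentation.

It is intended for researchers analysing continuous-listening EEG
experiments (single subjects, repeated presentations), and for methodological
work on envelope/onset-following responses.

## The model

For EEG `x(t) ∈ R^C` (preprocessed to the 1–42 Hz band at 100 Hz) and power
slope `y(t)`, the package fits the temporally embedded ridge regression

    ŷ(t) = Σ_{c=1}^{C} Σ_{ℓ=0}^{L} w[c,ℓ] · x_c(t+ℓ) + b,      L = 30,

so each stimulus sample is estimated from the brain response within 0–300 ms
after it. The weights solve the covariance-form ridge problem

    w = ((1−λ) Σ̂ + λ ν I)⁻¹ ĉ_xy,   ν = mean diag(Σ̂),

with the shrinkage intensity `λ` determined analytically (Ledoit–Wolf).
Filters are trained on two presentations and evaluated on the held-out third
(leave-one-recording-out), so a significant held-out CACor reflects genuine,
generalizing stimulus tracking. Significance is assessed twice, respecting
the serial correlation of both series: against Fourier phase-randomized
surrogates of the power slope, and with a t test on effective degrees of
freedom `1/N* = 1/N + (2/N) Σ_j ((N−j)/N) ρ̂_xx(j) ρ̂_yy(j)`.

For interpretation, filters are converted to activation patterns
`A = Σ̂ w / var(ŷ)`, reduced by SVD (98% variance), and decomposed by a
recursive MUSIC scan of a spherical-head dipole grid into non-orthogonal
scalp components with time courses. The package also extracts nine acoustic
descriptors (sound intensity, sharpness, spectral centroid/entropy/flux,
fluctuation centroid/entropy, pulse clarity, key clarity), analyses
continuous tension-rating sets (inter-rater correlation, stimulus lag,
windowed rise/fall activity with a circular-shift permutation null, and a
Coordination Score), and ships a forward-model synthetic-data generator
(chord-sequence stimuli, N1–P2 kernel, 1/f + alpha noise) used by the entire
test suite.

## Worked example

```r
library(cacor)

# a 30 s isochronous chord sequence and its power slope at 100 Hz
tone  <- synth_tone_sequence(duration = 30, seed = 1)
slope <- power_slope(frame_power(tone$wave), eeg_rate = 100)

# three synthetic presentations of the same stimulus by one subject
montage <- c("Fz","FCz","Cz","CPz","Pz","F3","F4","C3","C4","P3","P4",
             "Fp1","Fp2","O1","O2","T7","T8","FC1","FC2")
recordings <- lapply(1:3, function(k)
  synth_eeg(slope, snr = 1, coupling = 1, labels = montage,
            seed = 100 + k, presentation_index = k))

fit <- cacor(recordings, slope, n_surrogates = 999, seed = 2)
summary(fit)
#> CACor summary (subject S1, stimulus stim)
#>  presentation         r p_perm      p_pyper    n_eff significant
#>             1 0.9813555  0.001 5.307713e-33 45.36893        TRUE
#>             2 0.9777433  0.001 9.559200e-32 45.94951        TRUE
#>             3 0.9775318  0.001 8.041244e-32 46.19094        TRUE
#> mean r = 0.979; 3/3 presentations significant (Bonferroni, alpha = 0.05)
```

Each row is one held-out presentation: `r` is its CACor, `p_perm` the
one-sided surrogate p-value (floor 1/(n_surr+1) = 0.001), `p_pyper` the
effective-df p-value, and `n_eff` the effective sample count after the
autocorrelation correction (note how strongly the ~3000 raw samples shrink).
At generator SNR 1 the planted onset response is recovered essentially
perfectly; at realistic single-trial SNRs the correlations are far smaller
and the significance machinery does the work.

Decomposing the learned filter locates the planted source:

```r
fac   <- svd_reduce(fit$patterns[[1]], var_frac = 0.98)
H     <- build_leadfield(lookup_electrode_positions(montage), n_per_shell = 48)
comps <- music_decompose(fac, H)
#> MUSIC: 1 component(s); first at (-0.07, 0.37, 0.53), subspace correlation 0.995
match_component(comps, frontocentral_map(montage))$similarity
#> 0.996
```

The single component sits under the fronto-central midline — the generator's
dipole is at (0, 0.35, 0.55) — and its map matches the N1–P2 reference
topography with |cosine| 0.996.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end behaviour from scratch: it synthesizes a
graded five-stimulus study (coupling 0 → 1), runs the full
presentation-level CACor analysis with both significance routes, reports the
CACor score profile and its Spearman correlation with the generator's
coupling grades on stderr, and writes the JSON report to `--out`. All
randomness derives from `--seed`.
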