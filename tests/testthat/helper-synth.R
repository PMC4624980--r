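# Shared fixtures: a small montage and compact synthetic worlds keep the
# regression-heavy tests fast; the generator itself defaults to the full
# 61-channel montage.

small_montage <- function() {
  c("Fz", "FCz", "Cz", "CPz", "Pz", "F3", "F4", "C3", "C4", "P3", "P4",
    "Fp1", "Fp2", "O1", "O2", "T7", "T8", "FC1", "FC2")
}

# chord-sequence stimulus + slope at 100 Hz
make_slope <- function(duration = 20, seed = 3) {
  tone <- synth_tone_sequence(duration = duration, seed = seed)
  power_slope(frame_power(tone$wave), eeg_rate = 100)$values
}

# three presentations of one subject
make_presentations <- function(y, snr = 1, coupling = 1, seed = 10,
                               labels = small_montage()) {
  lapply(1:3, function(k)
    synth_eeg(y, snr = snr, coupling = coupling, labels = labels,
              seed = seed + k, presentation_index = k))
}

cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# a smooth weakly autocorrelated target (near-white after smoothing),
# for kernel-identifiability checks
make_white_slope <- function(n = 2000, seed = 1) {
  set.seed(seed)
  as.numeric(stats::filter(rnorm(n + 4), rep(1 / 3, 3), sides = 2))[3:(n + 2)]
}
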