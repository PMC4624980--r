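# Synthetic data: tone-sequence audio, forward-model EEG coupled to the
# audio power slope through an N1-P2-like spatio-temporal kernel, and groups
# of continuous ratings with controllable coordination.

#' Synthesize an isochronous chord sequence
#'
#' Major-triad chords with linear rise/fall ramps; the root note changes to
#' a random chromatic tone after every 7-11 repetitions. Defaults follow the
#' reference stimulus: 350 ms chords (17.5 ms ramps) at a 420 ms
#' inter-onset interval.
#'
#' @param duration total duration in seconds.
#' @param rate audio sampling rate in Hz.
#' @param ioi inter-onset interval in seconds.
#' @param chord_len chord duration in seconds (must be < `ioi`).
#' @param rise_fall ramp length in seconds.
#' @param jitter fractional onset jitter (uniform in +/- `jitter * ioi`).
#' @param seed RNG seed.
#' @return List with `wave` (a [waveform()]) and `onsets` (exact onset times
#'   in seconds).
#' @export
synth_tone_sequence <- function(duration = 60, rate = 8000, ioi = 0.42,
                                chord_len = 0.35, rise_fall = 0.0175,
                                jitter = 0, seed = 1) {
  if (chord_len >= ioi) stop("chord_len must be smaller than ioi")
  set.seed(seed)
  n_onsets <- floor(duration / ioi)
  base_onsets <- (seq_len(n_onsets) - 1) * ioi
  if (jitter > 0)
    base_onsets <- pmax(0, base_onsets +
                          stats::runif(n_onsets, -jitter, jitter) * ioi)
  x <- numeric(round(duration * rate))
  n_chord <- round(chord_len * rate)
  ramp_n <- max(1, round(rise_fall * rate))
  envl <- c(seq(0, 1, length.out = ramp_n),
            rep(1, max(0, n_chord - 2 * ramp_n)),
            seq(1, 0, length.out = ramp_n))[seq_len(n_chord)]
  # random root changes every 7-11 repetitions
  roots_midi <- integer(n_onsets)
  i <- 1
  while (i <= n_onsets) {
    run <- sample(7:11, 1)
    roots_midi[i:min(n_onsets, i + run - 1)] <- sample(0:11, 1)
    i <- i + run
  }
  tt <- seq_len(n_chord) / rate
  for (k in seq_len(n_onsets)) {
    f0 <- 220 * 2^(roots_midi[k] / 12)
    chord <- (sin(2 * pi * f0 * tt) +
              sin(2 * pi * f0 * 2^(4 / 12) * tt) +
              sin(2 * pi * f0 * 2^(7 / 12) * tt)) / 3
    s <- round(base_onsets[k] * rate)
    idx <- (s + 1):min(s + n_chord, length(x))
    x[idx] <- x[idx] + (chord * envl)[seq_along(idx)]
  }
  x <- x / max(1e-12, max(abs(x))) * 0.9
  list(wave = waveform(x, rate), onsets = base_onsets[base_onsets < duration])
}

#' N1-P2-like response kernel
#'
#' Biphasic kernel over 0-300 ms: a negative Gaussian lobe at the N1 latency
#' and a positive one at the P2 latency.
#'
#' @param rate sampling rate in Hz.
#' @param n1_latency,p2_latency lobe latencies in seconds (defaults 0.10 and
#'   0.18).
#' @param n1_amp,p2_amp lobe amplitudes (positive numbers; the N1 lobe enters
#'   negatively).
#' @param n1_width,p2_width Gaussian widths in seconds.
#' @param span kernel support in seconds (default 0.3, the embedding span).
#' @return Numeric kernel sampled at `rate` over `[0, span]`.
#' @export
n1p2_kernel <- function(rate = 100, n1_latency = 0.10, p2_latency = 0.18,
                        n1_amp = 1, p2_amp = 0.8,
                        n1_width = 0.015, p2_width = 0.025, span = 0.3) {
  if (n1_latency < 0 || n1_latency > span || p2_latency < 0 ||
      p2_latency > span)
    stop("kernel latencies must lie within [0, span]")
  t <- seq(0, span, by = 1 / rate)
  -n1_amp * exp(-0.5 * ((t - n1_latency) / n1_width)^2) +
    p2_amp * exp(-0.5 * ((t - p2_latency) / p2_width)^2)
}

#' Fronto-central dipole field on a montage
#'
#' Unit-norm scalp field of a radial dipole under the fronto-central midline
#' (the typical N1-P2 topography), computed with the spherical head model.
#'
#' @param labels montage channel labels (default [default_montage()]).
#' @param location dipole location inside the unit sphere.
#' @return Unit-norm named channels vector.
#' @export
frontocentral_map <- function(labels = default_montage(),
                              location = c(0, 0.35, 0.55)) {
  pos <- lookup_electrode_positions(labels)
  v <- dipole_potential(pos, location, location / sqrt(sum(location^2)))
  v <- v - mean(v)
  v <- v / sqrt(sum(v^2))
  names(v) <- labels
  v
}

pink_noise <- function(n, rate, f_knee = 1) {
  # 1/f amplitude spectrum above f_knee, flat below; unit RMS
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  freqs <- (seq_len(n) - 1) * rate / n
  freqs <- pmin(freqs, rate - freqs)
  amp <- 1 / sqrt(pmax(freqs, f_knee))
  x <- Re(stats::fft(f * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Forward-model synthetic EEG
#'
#' EEG = coupling * snr * (spatial map x source) + 1/f noise (independent
#' per channel, unit RMS) + common-mode 10 Hz alpha. The source is the audio
#' power slope convolved with an N1-P2-like kernel and scaled to unit RMS,
#' so `snr` is the signal-to-noise amplitude ratio per channel at the
#' map's RMS.
#'
#' @param slope power slope values at the EEG rate (a [feature_series()] or
#'   numeric vector).
#' @param rate EEG rate in Hz (default 100).
#' @param snr signal-to-noise amplitude ratio (>= 0).
#' @param coupling coupling strength in [0, 1].
#' @param kernel response kernel (default [n1p2_kernel()] at `rate`).
#' @param spatial_map unit-norm channels vector (default the fronto-central
#'   dipole field on `labels`).
#' @param labels montage labels (default [default_montage()]).
#' @param alpha_amp amplitude of the common-mode 10 Hz component.
#' @param seed RNG seed.
#' @param subject_id,stimulus_id,presentation_index identity fields.
#' @return An [eeg_recording()].
#' @export
synth_eeg <- function(slope, rate = 100, snr = 1, coupling = 1,
                      kernel = NULL, spatial_map = NULL,
                      labels = default_montage(), alpha_amp = 0.3,
                      seed = 1, subject_id = "S1", stimulus_id = "stim",
                      presentation_index = 1L) {
  y <- if (inherits(slope, "feature_series")) slope$values else
    as.numeric(slope)
  if (snr < 0) stop("snr must be >= 0")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  set.seed(seed)
  if (is.null(kernel)) kernel <- n1p2_kernel(rate)
  if (is.null(spatial_map)) spatial_map <- frontocentral_map(labels)
  n <- length(y)
  nch <- length(labels)
  src <- stats::convolve(y, rev(kernel), type = "open")[seq_len(n)]
  s <- stats::sd(src)
  if (s > 0) src <- src / s
  eeg <- matrix(0, nch, n)
  for (c in seq_len(nch)) eeg[c, ] <- pink_noise(n, rate)
  phase <- stats::runif(1, 0, 2 * pi)
  alpha <- alpha_amp * sin(2 * pi * 10 * (seq_len(n) - 1) / rate + phase)
  eeg <- eeg + rep(alpha, each = nch)
  # per-channel signal RMS = snr * |map_c| / rms(map) so the map-weighted
  # average channel has amplitude ratio snr against the unit-RMS noise
  sig <- (coupling * snr * sqrt(nch)) * outer(as.numeric(spatial_map), src)
  eeg <- eeg + sig
  eeg_recording(eeg, rate, labels,
                subject_id = subject_id, stimulus_id = stimulus_id,
                presentation_index = presentation_index)
}

#' Ground-truth spatio-temporal pattern of the generator
#'
#' The activation pattern the regression should recover. With `slope = NULL`
#' this is the outer product of the generating spatial map and the response
#' kernel at the embedding lags -- the correct target only for a white
#' (serially uncorrelated) slope. For an autocorrelated target the true
#' activation pattern of the estimation problem is the kernel smeared by the
#' target autocorrelation, cov(x_c(t - l), y(t)) proportional to
#' map_c * sum_m kernel_m rho_y(l - m); passing the actual `slope` computes
#' that.
#'
#' @param rate EEG rate in Hz.
#' @param L lag count.
#' @param kernel,spatial_map,labels as in [synth_eeg()].
#' @param slope optional target series whose sample autocorrelation smears
#'   the kernel.
#' @return channels x (L+1) matrix.
#' @export
ground_truth_pattern <- function(rate = 100, L = 30, kernel = NULL,
                                 spatial_map = NULL,
                                 labels = default_montage(), slope = NULL) {
  if (is.null(kernel)) kernel <- n1p2_kernel(rate)
  if (is.null(spatial_map)) spatial_map <- frontocentral_map(labels)
  nk <- length(kernel)
  tprof <- if (is.null(slope)) {
    kernel[seq_len(L + 1)]
  } else {
    y <- if (inherits(slope, "feature_series")) slope$values else
      as.numeric(slope)
    maxlag <- L + nk
    rho_full <- as.numeric(stats::acf(y, lag.max = maxlag,
                                      plot = FALSE)$acf)
    # cov(e(t+l), y(t)) = sum_m kernel_m rho(l - m): kernel convolved with
    # the (symmetric) target autocorrelation
    vapply(0:L, function(l)
      sum(kernel * rho_full[abs(l - (seq_len(nk) - 1)) + 1]), 0)
  }
  outer(as.numeric(spatial_map), tprof)
}

smooth_gauss <- function(x, sd_samples) {
  half <- max(1, ceiling(3 * sd_samples))
  k <- exp(-0.5 * ((-half):half / sd_samples)^2)
  k <- k / sum(k)
  as.numeric(stats::filter(c(rep(x[1], half), x, rep(x[length(x)], half)),
                           k, sides = 2))[(half + 1):(half + length(x))]
}

#' Synthetic continuous-rating group
#'
#' Each rater follows the latent tension series (delayed by `lag`) with
#' weight `coupling`, plus an independent smooth idiosyncratic fluctuation
#' (Gaussian-smoothed noise, 0.25 s correlation scale -- slow enough to move
#' like a rating, fast enough that independent raters decorrelate) with
#' weight `1 - coupling`, and white observation noise; ratings are clipped
#' at zero (the joystick floor).
#'
#' @param latent numeric latent tension series.
#' @param rate sampling rate in Hz (default 50).
#' @param n_raters number of raters (default 14).
#' @param coupling coupling in [0, 1].
#' @param noise_sd observation noise SD relative to the latent SD.
#' @param lag response lag in seconds (default 1).
#' @param seed RNG seed.
#' @param stimulus_id identity field.
#' @return A [rating_set()].
#' @export
synth_ratings <- function(latent, rate = 50, n_raters = 14, coupling = 0.8,
                          noise_sd = 0.1, lag = 1, seed = 1,
                          stimulus_id = "stim") {
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  set.seed(seed)
  latent <- as.numeric(latent)
  n <- length(latent)
  k <- round(lag * rate)
  lagged <- c(rep(latent[1], k), latent)[seq_len(n)]
  lagged <- (lagged - mean(lagged)) / max(1e-12, stats::sd(lagged))
  ratings <- matrix(0, n_raters, n)
  for (i in seq_len(n_raters)) {
    walk <- smooth_gauss(stats::rnorm(n), sd_samples = 0.25 * rate)
    walk <- (walk - mean(walk)) / max(1e-12, stats::sd(walk))
    r <- coupling * lagged + (1 - coupling) * walk +
      noise_sd * stats::rnorm(n)
    ratings[i, ] <- pmax(0, r + 2)   # joystick floor at zero deflection
  }
  rating_set(ratings, rate, stimulus_id)
}
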