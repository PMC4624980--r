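# Acoustic and musical descriptors of an audio waveform.
#
# Two frame grids are used throughout: short frames of 50 ms with 50%
# overlap (power, spectral features; a 40 Hz series) and long frames of 3 s
# with 33% overlap (sharpness, fluctuation, pulse clarity, key clarity; a
# 0.5 Hz series). The regression target is the power slope: the smoothed
# first derivative of the short-frame power.

frame_index_matrix <- function(n, frame, step) {
  n_frames <- floor((n - frame) / step) + 1
  if (n_frames < 1) stop("input shorter than one analysis frame")
  starts <- (seq_len(n_frames) - 1) * step
  outer(seq_len(frame), starts, "+")
}

#' Short-time power of a waveform
#'
#' Mean squared amplitude per 50 ms frame with 50% overlap (a 40 Hz series).
#' This series is also the Sound intensity feature, reported in linear power
#' units.
#'
#' @param w a [waveform()].
#' @param frame_len frame length in seconds.
#' @param overlap fractional overlap of successive frames.
#' @return A [feature_series()] named `"sound_intensity"`.
#' @export
frame_power <- function(w, frame_len = 0.05, overlap = 0.5) {
  stopifnot(inherits(w, "waveform"))
  frame <- round(frame_len * w$rate)
  step <- round(frame * (1 - overlap))
  idx <- frame_index_matrix(length(w$samples), frame, step)
  p <- colMeans(matrix(w$samples[idx]^2, nrow = frame))
  feature_series("sound_intensity", p, rate = w$rate / step,
                 frame_len = frame / w$rate, frame_step = step / w$rate)
}

gauss3 <- function() {
  k <- exp(-0.5 * (-1:1)^2)
  k / sum(k)
}

smooth3 <- function(x) {
  k <- gauss3()
  n <- length(x)
  xs <- c(x[1], x, x[n])
  k[1] * xs[1:n] + k[2] * xs[2:(n + 1)] + k[3] * xs[3:(n + 2)]
}

#' Audio power slope
#'
#' The regression target: the short-time power series is smoothed with a
#' 3-sample Gaussian kernel, differentiated (forward difference scaled by
#' the frame rate, units power/s), and linearly resampled to the EEG rate.
#' Negative slopes are retained.
#'
#' @param p power series from [frame_power()].
#' @param eeg_rate target sampling rate in Hz (default 100).
#' @return A [feature_series()] named `"power_slope"` at `eeg_rate`.
#' @export
power_slope <- function(p, eeg_rate = 100) {
  stopifnot(inherits(p, "feature_series"))
  if (eeg_rate <= 0) stop("eeg_rate must be positive")
  sm <- smooth3(p$values)
  d <- diff(sm) * p$rate
  v <- resample_linear(d, from = p$rate, to = eeg_rate)
  feature_series("power_slope", v, rate = eeg_rate)
}

long_frames <- function(x, rate, frame_len = 3, overlap = 1 / 3) {
  frame <- round(frame_len * rate)
  step <- round(frame * (1 - overlap))
  n_frames <- floor((length(x) - frame) / step) + 1
  if (n_frames < 1) stop("input shorter than one 3 s frame")
  list(frame = frame, step = step, n = n_frames,
       starts = (seq_len(n_frames) - 1) * step)
}

#' Sharpness (onset density)
#'
#' Mean half-wave-rectified first difference of the short-time power,
#' evaluated in 3 s frames with 33% overlap. High values indicate dense,
#' salient auditory edges.
#'
#' @param p power series from [frame_power()].
#' @param frame_len,overlap long-frame parameters (3 s, 33%).
#' @return A [feature_series()] named `"sharpness"`.
#' @export
sharpness <- function(p, frame_len = 3, overlap = 1 / 3) {
  stopifnot(inherits(p, "feature_series"))
  lf <- long_frames(p$values, p$rate, frame_len, overlap)
  d <- pmax(diff(p$values), 0)
  vals <- vapply(lf$starts, function(s) {
    i <- (s + 1):min(s + lf$frame - 1, length(d))
    mean(d[i])
  }, 0)
  feature_series("sharpness", vals, rate = p$rate / lf$step,
                 frame_len = lf$frame / p$rate, frame_step = lf$step / p$rate)
}

frame_spectra <- function(w, frame_len = 0.05, overlap = 0.5) {
  frame <- round(frame_len * w$rate)
  step <- round(frame * (1 - overlap))
  idx <- frame_index_matrix(length(w$samples), frame, step)
  segs <- matrix(w$samples[idx], nrow = frame)
  sp <- stats::mvfft(segs)
  nb <- frame %/% 2 + 1
  pow <- Mod(sp[seq_len(nb), , drop = FALSE])^2
  freqs <- (seq_len(nb) - 1) * w$rate / frame
  list(pow = pow, freqs = freqs, rate = w$rate / step,
       frame_len = frame / w$rate, frame_step = step / w$rate)
}

spectrum_centroid_entropy <- function(pow, freqs) {
  tot <- colSums(pow)
  ok <- tot > 0
  centroid <- rep(NaN, ncol(pow))
  entropy <- rep(NaN, ncol(pow))
  if (any(ok)) {
    pn <- sweep(pow[, ok, drop = FALSE], 2, tot[ok], "/")
    centroid[ok] <- colSums(pn * freqs)
    h <- -colSums(ifelse(pn > 0, pn * log(pn), 0))
    entropy[ok] <- h / log(nrow(pow))
  }
  list(centroid = centroid, entropy = entropy)
}

#' Spectral centroid, entropy and flux
#'
#' Per 50 ms frame (50% overlap): power-weighted mean frequency (Hz),
#' normalized Shannon entropy of the unit-sum power spectrum (in [0, 1]),
#' and Euclidean distance between successive unit-sum spectra (first frame
#' NaN). All-zero frames yield NaN.
#'
#' @param w a [waveform()].
#' @param frame_len,overlap frame parameters.
#' @return A list of three [feature_series()]: `centroid`, `entropy`, `flux`.
#' @export
spectral_features <- function(w, frame_len = 0.05, overlap = 0.5) {
  stopifnot(inherits(w, "waveform"))
  fs <- frame_spectra(w, frame_len, overlap)
  ce <- spectrum_centroid_entropy(fs$pow, fs$freqs)
  tot <- colSums(fs$pow)
  pn <- sweep(fs$pow, 2, ifelse(tot > 0, tot, 1), "/")
  pn[, tot == 0] <- NaN
  flux <- c(NaN, sqrt(colSums((pn[, -1, drop = FALSE] -
                               pn[, -ncol(pn), drop = FALSE])^2)))
  mk <- function(name, v)
    feature_series(name, v, rate = fs$rate, frame_len = fs$frame_len,
                   frame_step = fs$frame_step)
  list(centroid = mk("spectral_centroid", ce$centroid),
       entropy = mk("spectral_entropy", ce$entropy),
       flux = mk("spectral_flux", flux))
}

envelope_series <- function(x, rate, frame_len = 0.05, step_len = 0.01) {
  frame <- round(frame_len * rate)
  step <- round(step_len * rate)
  idx <- frame_index_matrix(length(x), frame, step)
  env <- colMeans(matrix(x[idx]^2, nrow = frame))
  list(env = env, rate = rate / step)
}

#' Fluctuation centroid and entropy
#'
#' Per 3 s frame (33% overlap): the amplitude-envelope spectrum in 0-10 Hz
#' (DC excluded) is summarized by its centre of mass (Hz) and normalized
#' Shannon entropy (rhythmic complexity). Silent frames yield NaN.
#'
#' @param w a [waveform()].
#' @param frame_len,overlap long-frame parameters.
#' @param max_freq upper edge of the fluctuation band in Hz.
#' @return A list of two [feature_series()]: `centroid`, `entropy`.
#' @export
fluctuation_features <- function(w, frame_len = 3, overlap = 1 / 3,
                                 max_freq = 10) {
  stopifnot(inherits(w, "waveform"))
  lf <- long_frames(w$samples, w$rate, frame_len, overlap)
  cent <- rep(NaN, lf$n); entr <- rep(NaN, lf$n)
  for (i in seq_len(lf$n)) {
    seg <- w$samples[(lf$starts[i] + 1):(lf$starts[i] + lf$frame)]
    if (all(seg == 0)) next
    es <- envelope_series(seg, w$rate)
    env <- es$env - mean(es$env)
    sp <- Mod(stats::fft(env))^2
    nb <- length(env) %/% 2 + 1
    freqs <- (seq_len(nb) - 1) * es$rate / length(env)
    band <- which(freqs > 0 & freqs <= max_freq)
    p <- sp[band]
    if (sum(p) <= 0) { cent[i] <- 0; entr[i] <- 0; next }
    pn <- p / sum(p)
    cent[i] <- sum(pn * freqs[band])
    entr[i] <- -sum(ifelse(pn > 0, pn * log(pn), 0)) / log(length(pn))
  }
  mk <- function(name, v)
    feature_series(name, v, rate = w$rate / lf$step,
                   frame_len = lf$frame / w$rate,
                   frame_step = lf$step / w$rate)
  list(centroid = mk("fluctuation_centroid", cent),
       entropy = mk("fluctuation_entropy", entr))
}

#' Pulse clarity
#'
#' Per 3 s frame: the onset-strength envelope (half-wave-rectified first
#' difference of a fine-grained power envelope) is autocorrelated; clarity is
#' the maximum normalized autocorrelation in the lag range 0.25-2 s, clipped
#' to [0, 1]. A simplified autocorrelation-peak composite; tests use ordering
#' properties, not absolute parity with other toolboxes.
#'
#' @param w a [waveform()].
#' @param frame_len,overlap long-frame parameters.
#' @param lag_range lag window in seconds searched for a periodicity peak.
#' @return A [feature_series()] named `"pulse_clarity"`.
#' @export
pulse_clarity <- function(w, frame_len = 3, overlap = 1 / 3,
                          lag_range = c(0.25, 2)) {
  stopifnot(inherits(w, "waveform"))
  lf <- long_frames(w$samples, w$rate, frame_len, overlap)
  vals <- rep(NaN, lf$n)
  for (i in seq_len(lf$n)) {
    seg <- w$samples[(lf$starts[i] + 1):(lf$starts[i] + lf$frame)]
    if (all(seg == 0)) next
    es <- envelope_series(seg, w$rate)
    onset <- pmax(diff(es$env), 0)
    # envelope fluctuations at floating-point scale are not onsets
    if (stats::sd(onset) <= 1e-9 * mean(es$env)) { vals[i] <- 0; next }
    onset <- onset - mean(onset)
    ac <- stats::acf(onset, lag.max = min(length(onset) - 1,
                                          round(lag_range[2] * es$rate)),
                     plot = FALSE, demean = FALSE)$acf[, 1, 1]
    lags <- seq_along(ac) - 1
    win <- lags >= round(lag_range[1] * es$rate) &
           lags <= round(lag_range[2] * es$rate)
    vals[i] <- min(1, max(0, max(ac[win]) / ac[1]))
  }
  feature_series("pulse_clarity", vals, rate = w$rate / lf$step,
                 frame_len = lf$frame / w$rate, frame_step = lf$step / w$rate)
}

krumhansl_profiles <- function() {
  major <- c(6.35, 2.23, 3.48, 2.33, 4.38, 4.09,
             2.52, 5.19, 2.39, 3.66, 2.29, 2.88)
  minor <- c(6.33, 2.68, 3.52, 5.38, 2.60, 3.53,
             2.54, 4.75, 3.98, 2.69, 3.34, 3.17)
  profs <- matrix(0, 24, 12)
  for (k in 0:11) {
    profs[k + 1, ] <- major[((0:11 - k) %% 12) + 1]
    profs[k + 13, ] <- minor[((0:11 - k) %% 12) + 1]
  }
  rownames(profs) <- c(paste0(0:11, "maj"), paste0(0:11, "min"))
  profs
}

chroma_vector <- function(seg, rate, fmin = 55, fmax = 2000) {
  sp <- Mod(stats::fft(seg))^2
  nb <- length(seg) %/% 2 + 1
  freqs <- (seq_len(nb) - 1) * rate / length(seg)
  keep <- freqs >= fmin & freqs <= fmax
  if (!any(keep) || sum(sp[keep]) == 0) return(rep(0, 12))
  pc <- (round(12 * log2(freqs[keep] / 440) + 69) %% 12)
  as.numeric(tapply(sp[seq_len(nb)][keep], factor(pc, levels = 0:11), sum,
                    default = 0))
}

#' Key clarity
#'
#' Per 3 s frame: a 12-bin chroma vector is correlated with the 24
#' Krumhansl-Kessler major/minor key profiles; clarity is the maximum
#' Pearson correlation (in [-1, 1]). Silent frames yield NaN.
#'
#' @param w a [waveform()].
#' @param frame_len,overlap long-frame parameters.
#' @return A [feature_series()] named `"key_clarity"`.
#' @export
key_clarity <- function(w, frame_len = 3, overlap = 1 / 3) {
  stopifnot(inherits(w, "waveform"))
  lf <- long_frames(w$samples, w$rate, frame_len, overlap)
  profs <- krumhansl_profiles()
  vals <- rep(NaN, lf$n)
  for (i in seq_len(lf$n)) {
    seg <- w$samples[(lf$starts[i] + 1):(lf$starts[i] + lf$frame)]
    if (all(seg == 0)) next
    ch <- chroma_vector(seg, w$rate)
    if (stats::sd(ch) == 0) { vals[i] <- 0; next }
    vals[i] <- max(apply(profs, 1, function(pr) stats::cor(ch, pr)))
  }
  feature_series("key_clarity", vals, rate = w$rate / lf$step,
                 frame_len = lf$frame / w$rate, frame_step = lf$step / w$rate)
}

#' Resample a feature series by linear interpolation
#'
#' NaN frames are propagated: a target sample bracketed by any NaN source
#' sample is NaN rather than interpolated across.
#'
#' @param f a [feature_series()].
#' @param target_rate target rate in Hz.
#' @return A [feature_series()] at `target_rate`.
#' @export
resample_series <- function(f, target_rate) {
  stopifnot(inherits(f, "feature_series"))
  if (target_rate <= 0) stop("target_rate must be positive")
  if (abs(target_rate - f$rate) < 1e-12) return(f)
  x <- f$values
  n <- length(x)
  t_src <- (seq_len(n) - 1) / f$rate
  t_new <- seq(0, t_src[n], by = 1 / target_rate)
  bad <- !is.finite(x)
  xf <- x; xf[bad] <- 0
  v <- stats::approx(t_src, xf, xout = t_new, rule = 2)$y
  if (any(bad)) {
    badf <- stats::approx(t_src, as.numeric(bad), xout = t_new, rule = 2)$y
    v[badf > 0] <- NaN
  }
  feature_series(f$name, v, rate = target_rate,
                 frame_len = f$frame_len, frame_step = 1 / target_rate)
}

#' Extract the full nine-feature set of a stimulus
#'
#' Sound intensity, sharpness, spectral centroid/entropy/flux, fluctuation
#' centroid/entropy, pulse clarity and key clarity.
#'
#' @param w a [waveform()].
#' @return Named list of nine [feature_series()].
#' @export
extract_features <- function(w) {
  p <- frame_power(w)
  sp <- spectral_features(w)
  fl <- fluctuation_features(w)
  list(sound_intensity = p,
       sharpness = sharpness(p),
       spectral_centroid = sp$centroid,
       spectral_entropy = sp$entropy,
       spectral_flux = sp$flux,
       fluctuation_centroid = fl$centroid,
       fluctuation_entropy = fl$entropy,
       pulse_clarity = pulse_clarity(w),
       key_clarity = key_clarity(w))
}

#' Global feature profile over a stimulus set
#'
#' NaN-ignoring mean of every feature series of every stimulus.
#'
#' @param features_by_stimulus named list (one entry per stimulus) of named
#'   lists of [feature_series()] as returned by [extract_features()].
#' @return A data frame with one row per stimulus and one column per feature.
#' @export
global_profile <- function(features_by_stimulus) {
  stopifnot(length(features_by_stimulus) >= 1)
  rows <- lapply(names(features_by_stimulus), function(st) {
    fl <- features_by_stimulus[[st]]
    vals <- vapply(names(fl), function(fn) {
      v <- fl[[fn]]$values
      if (!any(is.finite(v)))
        stop("feature '", fn, "' of stimulus '", st, "' is all-NaN")
      mean(v[is.finite(v)])
    }, 0)
    as.data.frame(as.list(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(features_by_stimulus)
  out
}
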