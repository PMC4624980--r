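# Acoustic feature extraction.

test_that("frame power: constants, silence, frame count, quadratic scaling", {
  w <- waveform(rep(0.5, 8000), 8000)
  p <- frame_power(w)
  expect_true(all(abs(p$values - 0.25) < 1e-12))
  expect_equal(p$rate, 40)
  # floor((8000-400)/200)+1 = 39 frames for 1 s at 8 kHz
  expect_equal(length(p$values), 39)
  expect_true(all(frame_power(waveform(numeric(4000), 8000))$values == 0))
  # amplitude-scale quadratic
  set.seed(1)
  w2 <- waveform(rnorm(4000, sd = 0.1), 8000)
  expect_equal(frame_power(waveform(3 * w2$samples, 8000))$values,
               9 * frame_power(w2)$values, tolerance = 1e-12)
})

test_that("power slope: zero on constants, localized peak at a step", {
  p <- feature_series("sound_intensity", rep(0.3, 100), 40)
  sl <- power_slope(p, 100)
  expect_true(all(abs(sl$values) < 1e-14))
  expect_equal(sl$rate, 100)
  # step increase: brute-force oracle = diff of 3-tap-smoothed step
  step <- c(rep(0, 50), rep(1, 50))
  k <- exp(-0.5 * (-1:1)^2); k <- k / sum(k)
  sm <- stats::filter(c(step[1], step, step[100]), k, sides = 2)[2:101]
  oracle <- diff(as.numeric(sm)) * 40
  sl2 <- power_slope(feature_series("p", step, 40), 40)  # same rate: no interp
  expect_equal(sl2$values, oracle, tolerance = 1e-12)
  expect_true(all(oracle >= 0))
  expect_equal(sum(oracle > 1e-9), 3)   # peak confined to the step
})

test_that("slope of the chord sequence is periodic at the inter-onset interval", {
  y <- make_slope(duration = 30, seed = 2)
  a <- stats::acf(y, lag.max = 60, plot = FALSE)$acf[-1, 1, 1]
  peak_lag <- (30:55)[which.max(a[30:55])] / 100
  expect_lt(abs(peak_lag - 0.42), 0.026)  # within one 25 ms frame
})

test_that("sharpness is the mean rectified power difference", {
  alt <- rep(c(0, 1), 70)   # alternating power at 40 Hz
  s <- sharpness(feature_series("p", alt, 40))
  expect_true(all(abs(s$values - 0.5) < 0.02))
  # monotonically decreasing power -> 0
  dec <- seq(1, 0, length.out = 140)
  expect_true(all(sharpness(feature_series("p", dec, 40))$values == 0))
  # linearity in amplitude
  set.seed(2)
  p <- abs(rnorm(200))
  expect_equal(sharpness(feature_series("p", 2 * p, 40))$values,
               2 * sharpness(feature_series("p", p, 40))$values,
               tolerance = 1e-12)
})

test_that("spectral features: centroid, entropy extremes, flux", {
  t <- (0:15999) / 8000
  tone <- waveform(sin(2 * pi * 1000 * t), 8000)
  sf <- spectral_features(tone)
  fin <- is.finite(sf$centroid$values)
  expect_true(all(abs(sf$centroid$values[fin] - 1000) < 8000 / 400))
  expect_true(all(sf$entropy$values[fin] < 0.35))
  expect_true(all(sf$flux$values[which(fin)[-1]] < 1e-6))
  set.seed(3)
  noise <- waveform(rnorm(16000, sd = 0.2), 8000)
  en <- spectral_features(noise)$entropy$values
  expect_gt(mean(en, na.rm = TRUE), 0.9)
  expect_true(all(en >= 0 & en <= 1, na.rm = TRUE))
  # silence -> NaN frames
  sil <- spectral_features(waveform(numeric(4000), 8000))
  expect_true(all(is.nan(sil$centroid$values)))
})

test_that("fluctuation features find the modulation rate", {
  set.seed(4)
  t <- (0:47999) / 8000   # 6 s
  am <- (1 + 0.9 * sin(2 * pi * 4 * t)) * rnorm(48000, sd = 0.2)
  fl <- fluctuation_features(waveform(am, 8000))
  expect_true(all(abs(fl$centroid$values - 4) < 1.5))
  un <- fluctuation_features(waveform(rnorm(48000, sd = 0.2), 8000))
  # unmodulated noise is rhythmically more complex
  expect_gt(mean(un$entropy$values), mean(fl$entropy$values))
  # silence -> NaN
  expect_true(all(is.nan(
    fluctuation_features(waveform(numeric(24001), 8000))$centroid$values)))
})

test_that("pulse clarity ranks isochronous above irregular onsets", {
  mk_train <- function(onsets, dur = 6, rate = 8000) {
    x <- numeric(dur * rate)
    for (o in onsets) {
      i <- round(o * rate) + 1
      j <- min(i + 79, length(x))
      x[i:j] <- x[i:j] + sin(2 * pi * 800 * (0:(j - i)) / rate)
    }
    waveform(x / max(abs(x)), rate)
  }
  iso <- mk_train(seq(0, 5.5, by = 0.42))
  set.seed(5)
  pois <- mk_train(sort(runif(length(seq(0, 5.5, by = 0.42)), 0, 5.5)))
  pc_iso <- mean(pulse_clarity(iso)$values, na.rm = TRUE)
  pc_pois <- mean(pulse_clarity(pois)$values, na.rm = TRUE)
  expect_gt(pc_iso, pc_pois)
  expect_true(pc_iso >= 0 && pc_iso <= 1)
  # amplitude invariance
  half <- waveform(iso$samples * 0.5, iso$rate)
  expect_equal(pulse_clarity(half)$values, pulse_clarity(iso)$values,
               tolerance = 1e-9)
  # constant tone: no onsets
  flat <- waveform(sin(2 * pi * 440 * (0:47999) / 8000), 8000)
  expect_true(all(pulse_clarity(flat)$values < 0.5))
})

test_that("key clarity identifies a C-major triad and is shift-invariant", {
  rate <- 8000
  t <- (0:47999) / rate
  triad <- function(root_hz)
    sin(2 * pi * root_hz * t) + sin(2 * pi * root_hz * 2^(4 / 12) * t) +
    sin(2 * pi * root_hz * 2^(7 / 12) * t)
  c_major <- waveform(triad(261.63) / 3, rate)
  kc <- key_clarity(c_major)
  expect_true(all(kc$values > 0.8))
  # transposition by a semitone preserves clarity
  cs_major <- waveform(triad(261.63 * 2^(1 / 12)) / 3, rate)
  expect_equal(mean(key_clarity(cs_major)$values), mean(kc$values),
               tolerance = 0.05)
  # near-uniform chroma: low clarity
  set.seed(6)
  noise <- waveform(rnorm(48000, sd = 0.2), rate)
  expect_lt(max(abs(key_clarity(noise)$values)), 0.5)
})

test_that("series resampling: identity, constants, ramps, NaN propagation", {
  f <- feature_series("x", seq(0, 1, length.out = 41), 40)
  expect_identical(resample_series(f, 40), f)
  r <- resample_series(f, 100)
  # evaluate back at original points: linear ramp is reproduced exactly
  back <- cacor:::resample_linear(r$values, 100, 40)
  expect_equal(back, f$values, tolerance = 1e-9)
  g <- feature_series("x", c(1, NaN, 3, 4, 5), 1)
  rg <- resample_series(g, 2)
  expect_true(any(is.nan(rg$values)))
  expect_false(is.nan(rg$values[length(rg$values)]))
})

test_that("global profile is the NaN-ignoring mean and errors on all-NaN", {
  fs <- list(
    a = list(f1 = feature_series("f1", c(1, NaN, 3), 1),
             f2 = feature_series("f2", rep(7, 5), 1)),
    b = list(f1 = feature_series("f1", c(4, 4), 1),
             f2 = feature_series("f2", c(0, 1), 1)))
  prof <- global_profile(fs)
  expect_equal(prof["a", "f1"], 2)
  expect_equal(prof["a", "f2"], 7)
  expect_equal(prof["b", "f2"], 0.5)
  fs$a$f1 <- feature_series("f1", c(NaN, NaN), 1)
  expect_error(global_profile(fs), "all-NaN")
})

test_that("extract_features returns the nine named descriptors", {
  tone <- synth_tone_sequence(duration = 7, seed = 1)
  feats <- extract_features(tone$wave)
  expect_named(feats, c("sound_intensity", "sharpness", "spectral_centroid",
                        "spectral_entropy", "spectral_flux",
                        "fluctuation_centroid", "fluctuation_entropy",
                        "pulse_clarity", "key_clarity"))
  # chord sequence: high pulse clarity, high key clarity
  expect_gt(mean(feats$pulse_clarity$values, na.rm = TRUE), 0.4)
  expect_gt(mean(feats$key_clarity$values, na.rm = TRUE), 0.6)
})
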