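# Core value types. Lightweight S3 records; validation at construction.

#' Mono audio waveform
#'
#' @param samples numeric vector of amplitudes, nominally in [-1, 1].
#' @param rate sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (any(!is.finite(samples)))
    stop("waveform samples must be finite")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %.3f s at %g Hz>\n",
              length(x$samples) / x$rate, x$rate))
  invisible(x)
}

#' Multichannel EEG recording
#'
#' Channels on rows, samples on columns. Positions are 3-D unit-sphere
#' coordinates (x toward the right ear, y toward the nasion, z up).
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate sampling rate in Hz.
#' @param channel_labels character vector of 10-20/10-10 channel names.
#' @param positions optional channels x 3 matrix; looked up from the built-in
#'   montage table when omitted.
#' @param subject_id,stimulus_id,presentation_index identifiers for the
#'   experimental design (three presentations of each stimulus per subject in
#'   the reference design; any positive presentation index is accepted).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_labels,
                          positions = NULL,
                          subject_id = NA_character_,
                          stimulus_id = NA_character_,
                          presentation_index = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels))
    stop("rows of data must match number of channel labels")
  if (rate <= 0) stop("rate must be positive")
  if (is.null(positions)) {
    positions <- lookup_electrode_positions(channel_labels)
  } else {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3)
      stop("positions must be a channels x 3 matrix")
  }
  if (!is.na(presentation_index) && presentation_index < 1)
    stop("presentation_index must be a positive integer")
  structure(list(data = data, rate = as.numeric(rate),
                 channel_labels = channel_labels, positions = positions,
                 subject_id = subject_id, stimulus_id = stimulus_id,
                 presentation_index = presentation_index),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples at %g Hz (%s/%s #%s)>\n",
              nrow(x$data), ncol(x$data), x$rate,
              x$subject_id, x$stimulus_id, x$presentation_index))
  invisible(x)
}

#' Set of continuous behavioural ratings
#'
#' @param ratings raters x samples numeric matrix (nonnegative joystick
#'   deflection, arbitrary units).
#' @param rate sampling rate in Hz (50 Hz in the reference design).
#' @param stimulus_id stimulus identifier.
#' @return An object of class `rating_set`.
#' @export
rating_set <- function(ratings, rate, stimulus_id = NA_character_) {
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "double"
  if (rate <= 0) stop("rate must be positive")
  structure(list(ratings = ratings, rate = as.numeric(rate),
                 stimulus_id = stimulus_id),
            class = "rating_set")
}

#' @export
print.rating_set <- function(x, ...) {
  cat(sprintf("<rating_set: %d raters x %d samples at %g Hz>\n",
              nrow(x$ratings), ncol(x$ratings), x$rate))
  invisible(x)
}

#' Per-frame feature series
#'
#' A uniformly sampled sequence of per-frame feature values. The series rate
#' is the reciprocal of the frame step; sample k covers the half-open time
#' window [k * frame_step, k * frame_step + frame_len).
#'
#' @param name feature identifier.
#' @param values numeric vector (NaN marks degenerate frames).
#' @param rate series sampling rate, 1/frame_step, in Hz.
#' @param frame_len analysis frame length in seconds.
#' @param frame_step frame step in seconds.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(name, values, rate, frame_len = NA_real_,
                           frame_step = 1 / rate) {
  if (rate <= 0) stop("rate must be positive")
  structure(list(name = as.character(name), values = as.numeric(values),
                 rate = as.numeric(rate), frame_len = as.numeric(frame_len),
                 frame_step = as.numeric(frame_step)),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series '%s': %d frames at %g Hz>\n",
              x$name, length(x$values), x$rate))
  invisible(x)
}

#' Run configuration with method defaults
#'
#' Collects every tunable of the pipeline. Defaults equal the stated values
#' of the reference analysis wherever one exists.
#'
#' @param ... named overrides of any default listed below.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    eeg_rate = 100,              # Hz after decimation
    lowpass_pass = 42,           # Hz Chebyshev-I passband edge
    lowpass_stop = 49,           # Hz stopband edge
    lowpass_ripple_db = 1,
    lowpass_atten_db = 40,
    highpass_hz = 1,
    n_lags = 30,                 # temporal embedding 0..30 samples = 0-300 ms
    power_frame = 0.050,         # s, 50% overlap
    power_overlap = 0.5,
    long_frame = 3.0,            # s frames for slow features, 33% overlap
    long_overlap = 1 / 3,
    tr_window = 3.0,             # s time-resolved CACor window
    tr_overlap = 0.9,            # -> 0.3 s step, 3.33 Hz
    n_surrogates = 999,
    alpha = 0.05,
    fdr_q = 0.05,
    pyper_max_lag_cacor = 2,     # s
    pyper_max_lag_partial = 10,  # s
    activity_window = 1.0,       # s, 50% overlap
    activity_overlap = 0.5,
    n_activity_perm = 499,
    rating_rate = 50,            # Hz joystick sampling
    lag_max = 3.0,               # s rating-vs-intensity search grid
    lag_step = 0.01,             # s
    lag_fallback = 1.0,          # s when cross-correlation has no clear peak
    svd_var_frac = 0.98,
    music_n_max = 4,
    music_min_subcorr = 0.8,
    grid_radii = c(0.3, 0.475, 0.65, 0.85),
    grid_points_per_shell = 64,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "run_config")
}
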