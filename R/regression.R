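# EEG preprocessing and temporally-embedded shrinkage-ridge stimulus
# reconstruction.
#
# The model: the EEG (channels x samples) is augmented with lagged copies of
# itself (lags 0..L samples, L = 30 at 100 Hz = 0-300 ms of response
# latency), and the embedded design is regressed onto the audio power slope.
# Regularization adds a ridge to the empirical covariance with an
# analytically determined shrinkage weight (Ledoit-Wolf toward a scaled
# identity). Filters are trained on two concatenated presentations and
# applied to the held-out third (leave-one-recording-out).

#' Generic EEG preprocessing
#'
#' Chebyshev type-I lowpass (42 Hz passband, 49 Hz stopband), decimation to
#' 100 Hz, then a 1 Hz Butterworth highpass. All filters are applied
#' zero-phase (forward-backward), yielding the broadband 1-42 Hz signal.
#'
#' @param e an [eeg_recording()] at >= 200 Hz (or already at 100 Hz, in
#'   which case only the filters are applied).
#' @param cfg a [run_config()].
#' @return An [eeg_recording()] at 100 Hz.
#' @export
preprocess_eeg <- function(e, cfg = run_config()) {
  stopifnot(inherits(e, "eeg_recording"))
  fs <- e$rate
  target <- cfg$eeg_rate
  if (fs < target) stop("EEG rate below ", target, " Hz")
  nyq <- fs / 2
  ord <- cheb1_order(cfg$lowpass_pass / nyq, cfg$lowpass_stop / nyq,
                     cfg$lowpass_ripple_db, cfg$lowpass_atten_db)
  lp <- cheby1_sos(ord, cfg$lowpass_ripple_db, cfg$lowpass_pass / nyq)
  dat <- t(apply(e$data, 1, function(x) filtfilt_sos(lp, x)))
  if (fs > target) {
    if (abs(fs / target - round(fs / target)) < 1e-9) {
      q <- as.integer(round(fs / target))
      dat <- dat[, seq(1, ncol(dat), by = q), drop = FALSE]
    } else {
      dat <- t(apply(dat, 1, function(x) resample_linear(x, fs, target)))
    }
  }
  hp <- butter_sos(2, cfg$highpass_hz / (target / 2), "high")
  dat <- t(apply(dat, 1, function(x) filtfilt_sos(hp, x)))
  eeg_recording(dat, target, e$channel_labels, e$positions,
                e$subject_id, e$stimulus_id, e$presentation_index)
}

#' Temporal embedding of an EEG recording
#'
#' Builds the samples x (channels*(L+1)) design matrix for backward-model
#' stimulus reconstruction: column (c, lag) at row t holds channel c at
#' sample t+lag, so the design row for stimulus sample t spans the EEG
#' response within 0 to L samples (0-300 ms at the defaults) after it.
#' Zero-padded at the recording end. Columns are ordered channel-major: all
#' lags of channel 1, then all lags of channel 2, and so on. With 61
#' channels and L = 30 this yields 61*31 = 1891 columns.
#'
#' @param e an [eeg_recording()] (or bare channels x samples matrix).
#' @param L number of lags (default 30; lags 0..L).
#' @return An object of class `embedded_design`: list with `matrix`, `L`,
#'   `n_channels`, `rate`.
#' @export
embed_eeg <- function(e, L = 30) {
  dat <- if (inherits(e, "eeg_recording")) e$data else as.matrix(e)
  rate <- if (inherits(e, "eeg_recording")) e$rate else NA_real_
  n_ch <- nrow(dat)
  n <- ncol(dat)
  if (L < 0) stop("L must be >= 0")
  if (L >= n) stop("L must be smaller than the number of samples")
  X <- matrix(0, n, n_ch * (L + 1))
  for (c in seq_len(n_ch)) {
    xc <- dat[c, ]
    for (l in 0:L) {
      col <- (c - 1) * (L + 1) + l + 1
      if (l == 0) X[, col] <- xc
      else X[1:(n - l), col] <- xc[(l + 1):n]
    }
  }
  structure(list(matrix = X, L = L, n_channels = n_ch, rate = rate),
            class = "embedded_design")
}

#' Analytic shrinkage intensity
#'
#' Ledoit-Wolf optimal shrinkage of the empirical covariance toward nu*I
#' (nu = mean diagonal), clipped to [0, 1]. Degenerate (zero-variance)
#' designs return 1.
#'
#' @param X an `embedded_design` or numeric matrix (rows = observations).
#' @return Shrinkage weight lambda in [0, 1].
#' @export
analytic_shrinkage <- function(X) {
  M <- if (inherits(X, "embedded_design")) X$matrix else as.matrix(X)
  n <- nrow(M)
  if (n < 2) stop("need at least 2 observations")
  M <- sweep(M, 2, colMeans(M))
  S <- crossprod(M) / n
  nu <- mean(diag(S))
  if (nu == 0) return(1)
  T_ <- diag(nu, ncol(S))
  d2 <- sum((S - T_)^2)
  if (d2 < 1e-30) return(1)
  b2 <- sum(crossprod(M^2) / n - S^2) / n
  max(0, min(1, b2 / d2))
}

#' Fit a spatio-temporal ridge filter
#'
#' Covariance-form ridge regression of the embedded EEG onto the target
#' series: w = ((1-lambda) S + lambda nu I)^-1 cov(X, y), with X and y
#' mean-centred internally and the intercept stored. The last L rows of
#' each training segment (zero-padded embedding tail) are excluded from the
#' loss.
#'
#' @param X an `embedded_design`.
#' @param y numeric target (audio power slope at the EEG rate), length
#'   matching `nrow(X$matrix)`.
#' @param lambda shrinkage in [0, 1]; `NULL` selects it analytically.
#' @param exclude_rows optional integer rows to ignore when fitting (defaults
#'   to the last L rows).
#' @return An object of class `st_filter`: list with `weights`
#'   (channels x (L+1)), `intercept`, `lambda`, `L`, `n_channels`,
#'   `training_ids`.
#' @export
fit_ridge <- function(X, y, lambda = NULL, exclude_rows = NULL) {
  stopifnot(inherits(X, "embedded_design"))
  M <- X$matrix
  if (length(y) != nrow(M)) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(y))) stop("y must be finite")
  if (is.null(exclude_rows) && X$L > 0)
    exclude_rows <- (nrow(M) - X$L + 1):nrow(M)
  if (length(exclude_rows)) {
    M <- M[-exclude_rows, , drop = FALSE]
    y <- y[-exclude_rows]
  }
  n <- nrow(M)
  mx <- colMeans(M)
  my <- mean(y)
  Mc <- sweep(M, 2, mx)
  yc <- y - my
  if (is.null(lambda)) {
    S <- crossprod(Mc) / n
    nu <- mean(diag(S))
    if (nu == 0) {
      lambda <- 1
    } else {
      d2 <- sum((S - diag(nu, ncol(S)))^2)
      b2 <- sum(crossprod(Mc^2) / n - S^2) / n
      lambda <- if (d2 < 1e-30) 1 else max(0, min(1, b2 / d2))
    }
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
    S <- crossprod(Mc) / n
    nu <- mean(diag(S))
  }
  cxy <- crossprod(Mc, yc) / n
  A <- (1 - lambda) * S
  diag(A) <- diag(A) + lambda * nu
  w <- tryCatch(solve(A, cxy),
                error = function(err) qr.solve(A, cxy, tol = 1e-12))
  intercept <- my - sum(mx * w)
  structure(list(weights = matrix(w, X$n_channels, X$L + 1, byrow = TRUE),
                 intercept = intercept, lambda = lambda,
                 L = X$L, n_channels = X$n_channels,
                 training_ids = NULL),
            class = "st_filter")
}

#' Apply a spatio-temporal filter to a recording
#'
#' Projection value at sample t is sum over channels and lags of
#' w[c, lag] * eeg[c, t + lag] plus the intercept (zero-padded at the
#' recording end), i.e. the one-dimensional EEG projection that estimates the
#' power slope at t from the brain response it evokes.
#'
#' @param f an `st_filter`.
#' @param e an [eeg_recording()] with the training channel count.
#' @return An object of class `projection`: list with `values`, `rate`, and
#'   identity fields of `e`.
#' @export
apply_filter <- function(f, e) {
  stopifnot(inherits(f, "st_filter"), inherits(e, "eeg_recording"))
  if (nrow(e$data) != f$n_channels)
    stop("channel count mismatch between filter and recording")
  Xd <- embed_eeg(e, f$L)
  w <- as.numeric(t(f$weights))
  vals <- as.numeric(Xd$matrix %*% w) + f$intercept
  structure(list(values = vals, rate = e$rate, L = f$L,
                 subject_id = e$subject_id, stimulus_id = e$stimulus_id,
                 presentation_index = e$presentation_index),
            class = "projection")
}

embed_concat <- function(recs, L) {
  parts <- lapply(recs, function(r) embed_eeg(r, L))
  mats <- lapply(parts, `[[`, "matrix")
  n_each <- vapply(mats, nrow, 0L)
  offs <- cumsum(c(0, n_each[-length(n_each)]))
  # embedding never spans a segment boundary: the zero-padded tail rows of
  # every segment are excluded from the training loss
  excl <- unlist(mapply(function(o, n) o + (n - min(L, n - 1) + 1):n,
                        offs, n_each, SIMPLIFY = FALSE))
  structure(list(matrix = do.call(rbind, mats), L = L,
                 n_channels = parts[[1]]$n_channels,
                 rate = parts[[1]]$rate),
            class = "embedded_design") -> X
  list(X = X, exclude = excl)
}

#' Leave-one-recording-out cross-validated projections
#'
#' For each of three presentations of a stimulus by one subject, trains a
#' filter on the concatenation of the other two (the temporal embedding is
#' zero-padded at each concatenation boundary, never spanning it) and
#' applies it to the held-out presentation.
#'
#' @param recs list of (at least 3) [eeg_recording()]s with equal channel
#'   sets, one per presentation.
#' @param y audio power slope at the EEG rate; recycled per presentation
#'   (every presentation plays the same stimulus).
#' @param L lag count.
#' @param lambda optional fixed shrinkage (default analytic per fold).
#' @return List with `projections` (one `projection` per presentation, each
#'   from the filter trained without it) and `filters` (one `st_filter` per
#'   fold, with `training_ids` recording the presentations used).
#' @export
crossval_projections <- function(recs, y, L = 30, lambda = NULL) {
  k <- length(recs)
  if (k < 3) stop("need at least 3 presentations (>= 2 for training)")
  n_ch <- nrow(recs[[1]]$data)
  for (r in recs) if (nrow(r$data) != n_ch) stop("channel sets differ")
  projections <- vector("list", k)
  filters <- vector("list", k)
  for (i in seq_len(k)) {
    train <- recs[-i]
    emb <- embed_concat(train, L)
    ytrain <- rep(y, length.out = nrow(emb$X$matrix))
    f <- fit_ridge(emb$X, ytrain, lambda = lambda,
                   exclude_rows = emb$exclude)
    f$training_ids <- vapply(train, function(r)
      as.integer(r$presentation_index), 0L)
    filters[[i]] <- f
    projections[[i]] <- apply_filter(f, recs[[i]])
  }
  list(projections = projections, filters = filters)
}

#' Onset-locked ERP average
#'
#' Segments a recording into fixed-length epochs starting at tone onsets and
#' averages them. No baseline correction is applied (the input is already
#' highpass-filtered). Epochs running past the end of the recording are
#' dropped.
#'
#' @param e an [eeg_recording()].
#' @param onsets onset times in seconds.
#' @param epoch_len epoch length in seconds (default 0.3).
#' @return List with `epoch` (channels x samples average), `n_used`,
#'   `n_dropped`, `times` (seconds relative to onset), `channel_labels`.
#' @export
erp_average <- function(e, onsets, epoch_len = 0.3) {
  stopifnot(inherits(e, "eeg_recording"))
  len <- round(epoch_len * e$rate)
  starts <- round(onsets * e$rate) + 1
  ok <- starts >= 1 & (starts + len - 1) <= ncol(e$data)
  if (!any(ok)) stop("no usable epochs")
  acc <- matrix(0, nrow(e$data), len)
  for (s in starts[ok]) acc <- acc + e$data[, s:(s + len - 1)]
  list(epoch = acc / sum(ok), n_used = sum(ok), n_dropped = sum(!ok),
       times = (seq_len(len) - 1) / e$rate,
       channel_labels = e$channel_labels)
}

#' Cortico-acoustic correlation model for one subject and stimulus
#'
#' The central fitting function: runs leave-one-recording-out
#' cross-validated shrinkage-ridge reconstruction of the audio power slope
#' from the presentations of one stimulus, computes the held-out
#' cortico-acoustic correlation (CACor) of every presentation with both
#' significance routes (phase-randomized surrogates and effective-df
#' correction), and transforms each training filter into its interpretable
#' spatio-temporal pattern.
#'
#' @param recordings list of >= 3 preprocessed [eeg_recording()]s (same
#'   subject, same stimulus, one per presentation) at the power-slope rate.
#' @param slope the audio power slope, a [feature_series()] from
#'   [power_slope()] (or a bare numeric vector at the EEG rate).
#' @param L lag count of the temporal embedding (default 30).
#' @param lambda optional fixed shrinkage; default analytic.
#' @param n_surrogates surrogate count for the permutation test.
#' @param cfg a [run_config()] supplying test parameters.
#' @param seed RNG seed for the surrogate draw.
#' @param patterns logical: also compute the activation pattern of every
#'   training filter (doubles the fitting cost; default `TRUE`).
#' @return An object of class `cacor_fit` with components `results` (data
#'   frame: presentation, r, p_perm, p_pyper, n_eff), `projections`,
#'   `filters`, `patterns`, `slope`, `L`, `lambda`, `subject_id`,
#'   `stimulus_id`.
#' @seealso [summary.cacor_fit()], [predict.cacor_fit()], [coef.cacor_fit()]
#' @export
cacor <- function(recordings, slope, L = 30, lambda = NULL,
                  n_surrogates = 999, cfg = run_config(), seed = NULL,
                  patterns = TRUE) {
  y <- if (inherits(slope, "feature_series")) slope$values else
    as.numeric(slope)
  n <- ncol(recordings[[1]]$data)
  if (length(y) > n) y <- y[seq_len(n)]
  if (length(y) < n) stop("slope shorter than the recordings")
  cv <- crossval_projections(recordings, y, L = L, lambda = lambda)
  if (!is.null(seed)) set.seed(seed)
  rate <- recordings[[1]]$rate
  rows <- lapply(seq_along(cv$projections), function(i) {
    pr <- cv$projections[[i]]
    keep <- seq_len(length(pr$values) - L)
    r <- cacor_coef(pr$values[keep], y[keep])
    st <- surrogate_test(pr$values[keep], y[keep],
                         n_surr = n_surrogates)
    pe <- pyper_effective_df(pr$values[keep], y[keep], rate = rate,
                             max_lag = cfg$pyper_max_lag_cacor, r = r,
                             alternative = "greater")
    data.frame(presentation = i, r = r, p_perm = st$p,
               p_pyper = pe$p, n_eff = pe$n_eff)
  })
  pats <- if (patterns) {
    lapply(seq_along(cv$filters), function(i) {
      emb <- embed_concat(recordings[-i], L)
      filter_to_pattern(cv$filters[[i]], emb$X, exclude_rows = emb$exclude)
    })
  } else NULL
  structure(list(results = do.call(rbind, rows),
                 projections = cv$projections, filters = cv$filters,
                 patterns = pats, slope = y, L = L,
                 lambda = vapply(cv$filters, `[[`, 0, "lambda"),
                 rate = rate,
                 subject_id = recordings[[1]]$subject_id,
                 stimulus_id = recordings[[1]]$stimulus_id),
            class = "cacor_fit")
}

#' @export
print.cacor_fit <- function(x, ...) {
  cat(sprintf("Cortico-acoustic correlation fit (subject %s, stimulus %s)\n",
              x$subject_id, x$stimulus_id))
  cat(sprintf("  %d presentations, embedding 0-%d lags at %g Hz, lambda = %s\n",
              nrow(x$results), x$L, x$rate,
              paste(signif(x$lambda, 3), collapse = "/")))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cacor_fit <- function(object, alpha = 0.05, ...) {
  res <- object$results
  n <- nrow(res)
  flags <- correct_presentations(res$p_perm, n, alpha = alpha)
  out <- list(results = cbind(res, significant = flags),
              score = cacor_score(flags),
              mean_r = mean(res$r), alpha = alpha,
              subject_id = object$subject_id,
              stimulus_id = object$stimulus_id)
  class(out) <- "summary.cacor_fit"
  out
}

#' @export
print.summary.cacor_fit <- function(x, ...) {
  cat(sprintf("CACor summary (subject %s, stimulus %s)\n",
              x$subject_id, x$stimulus_id))
  print(x$results, row.names = FALSE)
  cat(sprintf("mean r = %.3f; %d/%d presentations significant (Bonferroni, alpha = %g)\n",
              x$mean_r, x$score, nrow(x$results), x$alpha))
  invisible(x)
}

#' @export
coef.cacor_fit <- function(object, fold = 1, ...) {
  object$filters[[fold]]$weights
}

#' @export
predict.cacor_fit <- function(object, newdata, fold = 1, ...) {
  apply_filter(object$filters[[fold]], newdata)
}

#' @export
plot.cacor_fit <- function(x, fold = 1, ...) {
  pat <- x$patterns[[fold]]$pattern
  graphics::image(x = (0:x$L) / x$rate * 1000, y = seq_len(nrow(pat)),
                  z = t(pat[nrow(pat):1, , drop = FALSE]),
                  xlab = "lag (ms)", ylab = "channel",
                  main = "spatio-temporal pattern", ...)
  invisible(x)
}
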