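# Continuous-rating processing: inter-rater homogeneity, stimulus lag,
# activity analysis, and the Coordination Score.

#' Pairwise correlations between raters with surrogate significance
#'
#' Pearson correlations of all rater pairs; each pair is tested against
#' phase-randomized surrogates of both ratings, and the percentage of
#' significantly correlated pairs is returned. Constant raters yield NaN
#' pairs, excluded from the percentage.
#'
#' @param rs a [rating_set()] with at least 2 raters.
#' @param n_surr surrogates per pair (default 199).
#' @param alpha test level.
#' @param seed optional RNG seed.
#' @return List with `r` (raters x raters matrix), `significant` (logical
#'   matrix), `pct_significant`.
#' @export
pairwise_rating_correlation <- function(rs, n_surr = 199, alpha = 0.05,
                                        seed = NULL) {
  stopifnot(inherits(rs, "rating_set"))
  m <- nrow(rs$ratings)
  if (m < 2) stop("need at least 2 raters")
  if (!is.null(seed)) set.seed(seed)
  R <- matrix(NA_real_, m, m)
  sig <- matrix(NA, m, m)
  const <- apply(rs$ratings, 1, stats::sd) == 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (const[i] || const[j]) next
    xi <- rs$ratings[i, ]; xj <- rs$ratings[j, ]
    r <- stats::cor(xi, xj)
    # correlation of two independently phase-randomized series: the phase
    # difference is again uniform, so rotating one side is equivalent
    surr <- surrogate_corrs(xi, xj, n_surr)
    p <- (1 + sum(abs(surr) >= abs(r))) / (n_surr + 1)
    R[i, j] <- R[j, i] <- r
    sig[i, j] <- sig[j, i] <- p <= alpha
  }
  diag(R) <- 1
  pairs <- sig[upper.tri(sig)]
  list(r = R, significant = sig,
       pct_significant = 100 * mean(pairs[!is.na(pairs)]))
}

#' Optimal lag between mean rating and sound intensity
#'
#' Cross-correlates the z-scored grand-average rating with the z-scored
#' sound intensity on a 0-3 s lag grid in 10 ms steps and returns the lag
#' that maximizes the correlation. When the cross-correlation sequence has
#' no clear peak (maximum does not exceed the zero-lag value by
#' `prominence`), the fallback lag of 1.0 s is returned.
#'
#' @param mean_rating numeric grand-average rating series.
#' @param intensity a [feature_series()] (sound intensity) or numeric
#'   series at `rate`.
#' @param rate sampling rate of `mean_rating` in Hz.
#' @param max_lag,step lag grid in seconds (defaults 3 s, 10 ms).
#' @param fallback fallback lag in seconds (default 1.0).
#' @param prominence required excess over the zero-lag correlation.
#' @param peak_min minimum correlation for a peak to count as clear.
#' @return Lag in seconds.
#' @export
optimal_lag <- function(mean_rating, intensity, rate,
                        max_lag = 3, step = 0.01, fallback = 1.0,
                        prominence = 0.01, peak_min = 0.1) {
  x <- as.numeric(mean_rating)
  ints <- if (inherits(intensity, "feature_series")) {
    resample_linear(intensity$values, intensity$rate, rate)
  } else as.numeric(intensity)
  n <- min(length(x), length(ints))
  if (n < 10 * rate) stop("series overlap shorter than 10 s")
  x <- x[seq_len(n)]; ints <- ints[seq_len(n)]
  if (stats::sd(ints) == 0 || stats::sd(x) == 0) return(fallback)
  zx <- (x - mean(x)) / stats::sd(x)
  zi <- (ints - mean(ints)) / stats::sd(ints)
  lags <- seq(0, max_lag, by = step)
  cc <- vapply(lags, function(lg) {
    k <- round(lg * rate)
    if (k >= n - 2) return(NA_real_)
    stats::cor(zx[(k + 1):n], zi[1:(n - k)])
  }, 0)
  if (all(!is.finite(cc))) return(fallback)
  best <- which.max(cc)
  if (cc[best] < peak_min) return(fallback)   # no clear peak anywhere
  if (best == 1) return(0)
  if (cc[best] <= cc[1] + prominence) return(fallback)
  lags[best]
}

#' Lag-correct and resample a rating set
#'
#' Advances all ratings by `lag` seconds (the ratings lag behind the
#' stimulus; trailing samples are dropped) and linearly resamples to the
#' target rate.
#'
#' @param rs a [rating_set()].
#' @param lag nonnegative lag in seconds.
#' @param target_rate output rate in Hz (default 10/3, the time-resolved
#'   CACor rate).
#' @return A [rating_set()] at `target_rate`.
#' @export
align_and_resample <- function(rs, lag, target_rate = 10 / 3) {
  stopifnot(inherits(rs, "rating_set"))
  if (lag < 0) stop("lag must be nonnegative")
  k <- round(lag * rs$rate)
  n <- ncol(rs$ratings)
  if (k >= n) stop("lag exceeds the recording")
  dat <- rs$ratings[, (k + 1):n, drop = FALSE]
  if (abs(target_rate - rs$rate) > 1e-12) {
    dat <- t(apply(dat, 1, function(x)
      resample_linear(x, rs$rate, target_rate)))
  }
  rating_set(dat, target_rate, rs$stimulus_id)
}

activity_windows <- function(n, rate, window_len = 1, overlap = 0.5) {
  win <- round(window_len * rate)
  step <- max(1, round(win * (1 - overlap)))
  if (n < win) stop("window longer than the recording")
  n_win <- floor((n - win) / step) + 1
  list(win = win, step = step, n_win = n_win,
       starts = (seq_len(n_win) - 1) * step)
}

rise_fall_pct <- function(ratings, wins) {
  m <- nrow(ratings)
  first <- ratings[, wins$starts + 1, drop = FALSE]
  last <- ratings[, wins$starts + wins$win, drop = FALSE]
  d <- last - first
  list(rise = 100 * colSums(d > 0) / m,
       fall = 100 * colSums(d < 0) / m)
}

#' Windowed rise/fall activity indices
#'
#' For each 50%-overlapping 1 s window, the percentage of raters whose
#' rating rises (net change over the window > 0) and falls (< 0); flat
#' ratings count for neither.
#'
#' @param rs a [rating_set()].
#' @param window_len,overlap window parameters (1 s, 50%).
#' @return An object of class `activity_result` with `rise_pct`, `fall_pct`,
#'   `window_len`, `overlap`, `rate` (window rate), and placeholders for the
#'   significance fields filled by [activity_significance()].
#' @export
activity_index <- function(rs, window_len = 1, overlap = 0.5) {
  stopifnot(inherits(rs, "rating_set"))
  wins <- activity_windows(ncol(rs$ratings), rs$rate, window_len, overlap)
  rf <- rise_fall_pct(rs$ratings, wins)
  structure(list(rise_pct = rf$rise, fall_pct = rf$fall,
                 sig_mask = NULL, coordination_score = NA_real_,
                 n_significant = NA_integer_,
                 window_len = window_len, overlap = overlap,
                 rate = rs$rate / wins$step),
            class = "activity_result")
}

#' Permutation significance of coordinated rating activity
#'
#' Null distribution from independent circular time shifts of each rater
#' (preserving every rater's autocorrelation while destroying alignment):
#' a window is significantly coordinated when its observed max(rise, fall)
#' proportion exceeds the 95th percentile of the permutation null for that
#' window. The Coordination Score is the fraction of significant windows
#' (the count is also reported).
#'
#' @param rs a [rating_set()] with >= 2 raters.
#' @param n_perm number of permutations (default 499, minimum 199).
#' @param alpha test level (default 0.05).
#' @param window_len,overlap window parameters.
#' @param seed optional RNG seed.
#' @return An `activity_result` with `sig_mask`, `coordination_score`
#'   (fraction), `n_significant` (count) filled in.
#' @export
activity_significance <- function(rs, n_perm = 499, alpha = 0.05,
                                  window_len = 1, overlap = 0.5,
                                  seed = NULL) {
  stopifnot(inherits(rs, "rating_set"))
  m <- nrow(rs$ratings)
  if (m < 2) stop("coordination is undefined for a single rater")
  if (n_perm < 199) stop("n_perm must be at least 199")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(rs$ratings)
  wins <- activity_windows(n, rs$rate, window_len, overlap)
  res <- activity_index(rs, window_len, overlap)
  obs <- pmax(res$rise_pct, res$fall_pct)
  null_max <- matrix(0, n_perm, wins$n_win)
  for (b in seq_len(n_perm)) {
    shifts <- sample.int(n, m, replace = TRUE)
    shifted <- rs$ratings
    for (i in seq_len(m)) {
      s <- shifts[i] %% n
      if (s > 0) shifted[i, ] <- c(rs$ratings[i, (n - s + 1):n],
                                   rs$ratings[i, 1:(n - s)])
    }
    rf <- rise_fall_pct(shifted, wins)
    null_max[b, ] <- pmax(rf$rise, rf$fall)
  }
  crit <- apply(null_max, 2, stats::quantile, probs = 1 - alpha,
                names = FALSE, type = 1)
  sig <- obs > crit
  res$sig_mask <- sig
  res$n_significant <- sum(sig)
  res$coordination_score <- mean(sig)
  res
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("<activity_result: %d windows of %g s>\n",
              length(x$rise_pct), x$window_len))
  if (!is.null(x$sig_mask))
    cat(sprintf("  coordination score %.3f (%d/%d windows significant)\n",
                x$coordination_score, x$n_significant, length(x$sig_mask)))
  invisible(x)
}
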