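# CACor statistics: correlation, autocorrelation-aware significance
# (phase-randomized surrogates; effective degrees of freedom), multiplicity
# handling, aggregation into scores and profiles, partial correlations.

#' Pearson correlation between projection and target
#'
#' @param p numeric vector (EEG projection values) or a `projection`.
#' @param y numeric target series of equal length.
#' @return Pearson r.
#' @export
cacor_coef <- function(p, y) {
  x <- if (inherits(p, "projection")) p$values else as.numeric(p)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("series lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input to correlation")
  stats::cor(x, y)
}

#' Fourier phase-randomized surrogate of a series
#'
#' Preserves the amplitude spectrum (hence the autocorrelation) while
#' randomizing phases; DC and Nyquist bins are kept real.
#'
#' @param y numeric vector.
#' @return Surrogate vector of the same length.
#' @export
phase_randomize <- function(y) {
  n <- length(y)
  f <- stats::fft(y)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half >= 1) {
    ph <- stats::runif(half, 0, 2 * pi)
    rot <- exp(1i * ph)
    f[2:(half + 1)] <- f[2:(half + 1)] * rot
    f[n:(n - half + 1)] <- Conj(f[2:(half + 1)])
  }
  Re(stats::fft(f, inverse = TRUE)) / n
}

# Correlations of x with n_surr phase-randomized surrogates of y, computed
# in the frequency domain: a surrogate's variance equals y's (amplitude
# spectrum preserved) and its covariance with x is the phase-rotated
# cross-spectrum sum, so no inverse transforms are needed. Distributionally
# identical to correlating against explicit phase_randomize(y) draws.
surrogate_corrs <- function(x, y, n_surr) {
  n <- length(y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  X <- stats::fft(xc)
  Y <- stats::fft(yc)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  cross <- Conj(X[2:(half + 1)]) * Y[2:(half + 1)]
  nyq <- if (n %% 2 == 0) Re(Conj(X[n / 2 + 1]) * Y[n / 2 + 1]) else 0
  phases <- matrix(stats::runif(n_surr * half, 0, 2 * pi), n_surr)
  rot <- matrix(complex(modulus = 1, argument = phases), n_surr)
  cov_n2 <- 2 * Re(rot %*% cross) + nyq      # n^2 * covariance * n/(n)
  as.numeric(cov_n2) / n / sqrt(sum(xc^2) * sum(yc^2))
}

#' Surrogate-data significance of a correlation
#'
#' Tests an observed correlation against correlations with Fourier
#' phase-randomized surrogates of the target series (stimulus side), keeping
#' all properties of the EEG projection fixed. One-sided positive by default
#' (CACor is directional); two-sided available.
#'
#' @param p projection values (numeric or `projection`).
#' @param y target series.
#' @param n_surr number of surrogates (default 999, minimum 99).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param seed optional RNG seed recorded with the result.
#' @return List with `r`, `p` (floor 1/(n_surr+1)), `n_surr`, `seed`.
#' @export
surrogate_test <- function(p, y, n_surr = 999,
                           alternative = c("greater", "two.sided"),
                           seed = NULL) {
  alternative <- match.arg(alternative)
  if (n_surr < 99) stop("n_surr must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  x <- if (inherits(p, "projection")) p$values else as.numeric(p)
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("constant target series")
  r_obs <- cacor_coef(x, y)
  r_surr <- surrogate_corrs(x, y, n_surr)
  exceed <- if (alternative == "greater") sum(r_surr >= r_obs)
            else sum(abs(r_surr) >= abs(r_obs))
  list(r = r_obs, p = (1 + exceed) / (n_surr + 1), n_surr = n_surr,
       seed = seed)
}

#' Effective degrees of freedom for correlated series
#'
#' Effective-sample-size correction for the correlation of two autocorrelated
#' series: 1/N* = 1/N + (2/N) sum_j ((N-j)/N) rho_xx(j) rho_yy(j), summed to
#' lag J = max_lag * rate; N* is clipped to [2, N] and the p-value uses a
#' t statistic on N*-2 degrees of freedom.
#'
#' @param x,y numeric series of equal length.
#' @param rate sampling rate in Hz.
#' @param max_lag maximal autocorrelation lag in seconds (2 s for CACor,
#'   10 s for feature partial correlations).
#' @param r optional precomputed correlation of `x` and `y`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return List with `n_eff`, `p`, `r`, `df`.
#' @export
pyper_effective_df <- function(x, y, rate, max_lag = 2, r = NULL,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  J <- min(round(max_lag * rate), n %/% 2 - 1)
  if (J < 1) stop("max_lag too small for the series length")
  axx <- stats::acf(x, lag.max = J, plot = FALSE)$acf[-1, 1, 1]
  ayy <- stats::acf(y, lag.max = J, plot = FALSE)$acf[-1, 1, 1]
  j <- seq_len(J)
  inv_nstar <- 1 / n + (2 / n) * sum((n - j) / n * axx * ayy)
  n_eff <- max(2, min(n, 1 / inv_nstar))
  if (is.null(r)) r <- stats::cor(x, y)
  df <- n_eff - 2
  if (df <= 0) {
    warning("effective sample size <= 2; p set to 1")
    return(list(n_eff = n_eff, p = 1, r = r, df = df))
  }
  tstat <- r * sqrt(df / max(1e-12, 1 - r^2))
  p <- if (alternative == "greater") stats::pt(tstat, df, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tstat), df)
  list(n_eff = n_eff, p = min(1, max(.Machine$double.xmin, p)), r = r,
       df = df)
}

#' Bonferroni significance flags across presentations
#'
#' @param p_values per-presentation p-values.
#' @param n number of presentations corrected for (27 in the reference
#'   design: nine subjects, three presentations).
#' @param alpha family-wise level (default 0.05).
#' @return Logical flags, `p <= alpha / n`.
#' @export
correct_presentations <- function(p_values, n = length(p_values),
                                  alpha = 0.05) {
  if (n < 1) stop("n must be a positive count")
  p_values <= alpha / n
}

#' CACor score: count of significant presentations
#'
#' @param flags logical significance flags.
#' @return Integer count.
#' @export
cacor_score <- function(flags) {
  sum(as.logical(flags))
}

#' Grand-average CACor
#'
#' Averages projections element-wise across presentations and computes the
#' group-level CACor with both significance routes.
#'
#' @param projections list of `projection`s (or numeric vectors) of equal
#'   length.
#' @param y target series.
#' @param rate sampling rate in Hz.
#' @param n_surr surrogate count.
#' @param max_lag Pyper maximal lag in seconds.
#' @return List with `r`, `p_perm`, `p_pyper`, `n_eff`, `ga` (the averaged
#'   projection).
#' @export
grand_average_cacor <- function(projections, y, rate, n_surr = 999,
                                max_lag = 2) {
  vals <- lapply(projections, function(p)
    if (inherits(p, "projection")) p$values else as.numeric(p))
  len <- unique(vapply(vals, length, 0L))
  if (length(len) != 1) stop("projections differ in length")
  ga <- Reduce(`+`, vals) / length(vals)
  if (stats::sd(ga) == 0) stop("grand-average projection has zero variance")
  r <- cacor_coef(ga, y)
  st <- surrogate_test(ga, y, n_surr = n_surr)
  pe <- pyper_effective_df(ga, y, rate = rate, max_lag = max_lag, r = r,
                           alternative = "greater")
  list(r = r, p_perm = st$p, p_pyper = pe$p, n_eff = pe$n_eff, ga = ga)
}

#' Time-resolved CACor
#'
#' Pearson correlation in 90%-overlapping 3 s windows (step 0.3 s), yielding
#' a correlation time course at 3.33 Hz. Windows are [t, t + 3 s) with start
#' times at exact multiples of the step. Windows with fewer than 10 finite
#' pairs give NaN.
#'
#' @param ga projection values (grand average) or any numeric series.
#' @param y target series of equal length.
#' @param rate input sampling rate in Hz.
#' @param window_len window length in seconds.
#' @param overlap fractional overlap (default 0.9).
#' @return A [feature_series()] named `"time_resolved_cacor"` at
#'   1/(window_len*(1-overlap)) Hz.
#' @export
time_resolved_cacor <- function(ga, y, rate, window_len = 3, overlap = 0.9) {
  x <- if (inherits(ga, "projection")) ga$values else as.numeric(ga)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("series lengths differ")
  win <- round(window_len * rate)
  step <- round(win * (1 - overlap))
  if (length(x) < win) stop("series shorter than one window")
  n_win <- floor((length(x) - win) / step) + 1
  vals <- vapply(seq_len(n_win), function(k) {
    i <- ((k - 1) * step + 1):((k - 1) * step + win)
    xs <- x[i]; ys <- y[i]
    ok <- is.finite(xs) & is.finite(ys)
    if (sum(ok) < 10) return(NaN)
    if (stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0) return(NaN)
    stats::cor(xs[ok], ys[ok])
  }, 0)
  feature_series("time_resolved_cacor", vals, rate = rate / step,
                 frame_len = win / rate, frame_step = step / rate)
}

#' Partial correlation controlling for other features
#'
#' Residualizes target and feature on the control series by least squares
#' and correlates the residuals; significance via the effective-df
#' correction (default maximal lag 10 s) on the residual series. NaN frames
#' are dropped listwise. Collinear control columns are dropped with a
#' warning.
#'
#' @param target numeric series (e.g. time-resolved CACor values).
#' @param feature numeric series of interest.
#' @param controls matrix or list of control series (may be empty).
#' @param rate sampling rate in Hz (3.33 for profile-rate series).
#' @param max_lag Pyper maximal lag in seconds (default 10).
#' @return List with `r`, `p`, `n_eff`, `n_used`.
#' @export
partial_correlation <- function(target, feature, controls = NULL,
                                rate = 10 / 3, max_lag = 10) {
  target <- as.numeric(target)
  feature <- as.numeric(feature)
  C <- if (is.null(controls)) NULL else {
    if (is.list(controls)) do.call(cbind, lapply(controls, as.numeric))
    else as.matrix(controls)
  }
  ok <- is.finite(target) & is.finite(feature)
  if (!is.null(C)) ok <- ok & apply(is.finite(C), 1, all)
  if (sum(ok) < 10) stop("fewer than 10 complete observations")
  t_ <- target[ok]; f_ <- feature[ok]
  if (!is.null(C)) {
    C <- C[ok, , drop = FALSE]
    qrC <- qr(cbind(1, C))
    if (qrC$rank < ncol(C) + 1)
      warning("collinear control series; dependent columns dropped")
    rt <- qr.resid(qrC, t_)
    rf <- qr.resid(qrC, f_)
  } else {
    rt <- t_ - mean(t_)
    rf <- f_ - mean(f_)
  }
  if (stats::sd(rt) == 0 || stats::sd(rf) == 0)
    stop("zero-variance residuals")
  r <- stats::cor(rt, rf)
  pe <- pyper_effective_df(rt, rf, rate = rate, max_lag = max_lag, r = r)
  list(r = r, p = pe$p, n_eff = pe$n_eff, n_used = sum(ok))
}

#' Benjamini-Hochberg FDR flags
#'
#' @param p_values numeric p-values.
#' @param q FDR level (default 0.05).
#' @return Logical flags.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  stats::p.adjust(p_values, method = "BH") <= q
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, factorial(n), n)
  row <- 1
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation between two stimulus profiles
#'
#' Spearman rho with mid-ranked ties; for n <= 9 the two-sided p-value is
#' exact (all n! permutations), otherwise the t approximation is used.
#'
#' @param a,b numeric profiles over a shared stimulus set (n >= 4). Named
#'   vectors are aligned by name.
#' @return List with `rho`, `p`, `n`, `exact`.
#' @export
profile_correlation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  n <- length(a)
  if (n < 4 || length(b) != n) stop("need matched profiles with n >= 4")
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("constant profile ranks")
  rho <- stats::cor(ra, rb)
  if (n <= 9) {
    perms <- all_permutations(n)
    rac <- ra - mean(ra)
    rbc <- rb - mean(rb)
    num <- as.numeric(matrix(rbc[perms], nrow(perms)) %*% rac)
    rhos <- num / (stats::sd(ra) * stats::sd(rb) * (n - 1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    exact <- FALSE
  }
  list(rho = rho, p = p, n = n, exact = exact)
}
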