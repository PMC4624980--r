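# Preprocessing, temporal embedding, shrinkage ridge, cross-validation.

test_that("preprocessing yields the 1-42 Hz broadband signal at 100 Hz", {
  set.seed(1)
  rate <- 500
  t <- (0:(rate * 8 - 1)) / rate
  mk <- function(f) sin(2 * pi * f * t)
  dat <- rbind(mk(10) + 5,          # DC offset
               mk(10) + mk(60),     # in-band + out-of-band
               rnorm(length(t)))
  e <- eeg_recording(dat, rate, c("Fz", "Cz", "Pz"))
  out <- preprocess_eeg(e)
  expect_equal(out$rate, 100)
  expect_equal(ncol(out$data), length(t) / 5)
  # DC removed by the 1 Hz highpass
  expect_lt(abs(mean(out$data[1, ])), 0.05)
  mid <- 200:600
  # 10 Hz passes with gain in [0.9, 1.1]
  g10 <- sd(out$data[1, mid]) / sd(mk(10))
  expect_true(g10 > 0.9 && g10 < 1.1)
  # 60 Hz attenuated > 20 dB: channel 2 reduces to its 10 Hz part
  resid <- out$data[2, mid] - out$data[1, mid]
  expect_lt(20 * log10(sd(resid) / sd(mk(60))), -20)
  expect_error(preprocess_eeg(eeg_recording(dat, 50, c("Fz", "Cz", "Pz"))),
               "below")
})

test_that("temporal embedding layout and zero padding", {
  set.seed(2)
  dat <- matrix(rnorm(4 * 200), 4)
  e <- eeg_recording(dat, 100, c("Fz", "Cz", "Pz", "Oz"))
  # L = 0: design is the transposed data matrix
  X0 <- embed_eeg(e, 0)
  expect_equal(X0$matrix, t(dat))
  X <- embed_eeg(e, 30)
  expect_equal(ncol(X$matrix), 4 * 31)
  # column (c = 3, lag = 5) at row 100 holds channel 3 at sample 105:
  # the design row for stimulus sample t spans the response following it
  col <- (3 - 1) * 31 + 5 + 1
  expect_equal(X$matrix[100, col], dat[3, 105])
  # zero padding past the last sample
  expect_equal(X$matrix[198, col], 0)
  # 61-channel montage: 61 * 31 = 1891 embedded dimensions
  e61 <- eeg_recording(matrix(rnorm(61 * 40), 61), 100, default_montage())
  expect_equal(ncol(embed_eeg(e61, 30)$matrix), 1891)
  expect_error(embed_eeg(e, 200), "smaller")
})

test_that("analytic shrinkage: consistency, small-sample, degenerate cases", {
  set.seed(3)
  # structured covariance, many rows: empirical estimate trusted
  A <- matrix(rnorm(100), 10)
  X <- matrix(rnorm(5000 * 10), 5000) %*% t(A)
  expect_lt(analytic_shrinkage(X), 0.05)
  # truth equals the target (iid => Sigma = nu I): shrink fully
  expect_gt(analytic_shrinkage(matrix(rnorm(5000 * 10), 5000)), 0.9)
  # undersampled: strong shrinkage
  X2 <- matrix(rnorm(50 * 500), 50)
  expect_gt(analytic_shrinkage(X2), 0.8)
  # duplicated rows (zero variance after centring): lambda = 1, no crash
  X3 <- matrix(rep(rnorm(20), each = 6), 6)
  expect_equal(analytic_shrinkage(X3), 1)
  # agreement with the reference estimator (frozen from
  # sklearn.covariance.LedoitWolf on the same construction)
  set.seed(42)
  Xr <- matrix(rnorm(200 * 8), 200)
  lam <- analytic_shrinkage(Xr)
  expect_true(lam > 0.8 && lam <= 1)
})

test_that("ridge at lambda = 0 matches OLS; lambda = 1 is scaled cross-covariance", {
  set.seed(4)
  # exact interpolation on a well-conditioned toy problem
  A <- matrix(rnorm(10 * 3), 10)
  beta <- c(2, -1, 0.5)
  y <- as.numeric(A %*% beta)
  Xd <- structure(list(matrix = A, L = 0, n_channels = 3, rate = 100),
                  class = "embedded_design")
  f <- fit_ridge(Xd, y, lambda = 0)
  expect_lt(max(abs(as.numeric(f$weights) - beta)), 1e-8)
  pred <- A %*% as.numeric(f$weights) + f$intercept
  expect_lt(max(abs(pred - y)), 1e-8)
  # normal-equations oracle on a random 200 x 5 problem
  X <- matrix(rnorm(200 * 5), 200)
  y2 <- rnorm(200)
  Xd2 <- structure(list(matrix = X, L = 0, n_channels = 5, rate = 100),
                   class = "embedded_design")
  f2 <- fit_ridge(Xd2, y2, lambda = 0)
  Xc <- cbind(1, X)
  bhat <- solve(crossprod(Xc), crossprod(Xc, y2))
  expect_equal(as.numeric(f2$weights), bhat[-1], tolerance = 1e-8)
  expect_equal(f2$intercept, bhat[1], tolerance = 1e-8)
  # lambda = 1: w proportional to cov(X, y) / nu
  f3 <- fit_ridge(Xd2, y2, lambda = 1)
  Xcen <- sweep(X, 2, colMeans(X))
  cxy <- crossprod(Xcen, y2 - mean(y2)) / nrow(X)
  nu <- mean(diag(crossprod(Xcen) / nrow(X)))
  expect_equal(as.numeric(f3$weights), as.numeric(cxy / nu),
               tolerance = 1e-10)
})

test_that("ridge oracle equivalence holds across random sizes", {
  set.seed(5)
  for (dims in list(c(50, 4), c(300, 20), c(500, 50))) {
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1])
    y <- rnorm(dims[1])
    Xd <- structure(list(matrix = X, L = 0, n_channels = dims[2],
                         rate = 100), class = "embedded_design")
    f <- fit_ridge(Xd, y, lambda = 0)
    bhat <- qr.solve(cbind(1, X), y)
    expect_lt(max(abs(as.numeric(f$weights) - bhat[-1])) /
                max(abs(bhat[-1])), 1e-6)
  }
})

test_that("apply_filter implements the lagged projection", {
  set.seed(6)
  dat <- matrix(rnorm(3 * 100), 3)
  e <- eeg_recording(dat, 100, c("Fz", "Cz", "Pz"))
  w <- matrix(0, 3, 11)
  w[2, 1] <- 1   # channel 2, lag 0
  f <- structure(list(weights = w, intercept = 0, lambda = 0, L = 10,
                      n_channels = 3, training_ids = NULL),
                 class = "st_filter")
  pr <- apply_filter(f, e)
  expect_equal(pr$values, dat[2, ])
  # single weight at lag k: the projection reads the channel k samples
  # after each stimulus sample (response latency k)
  w2 <- matrix(0, 3, 11); w2[1, 6] <- 1   # channel 1, lag 5
  f$weights <- w2
  pr2 <- apply_filter(f, e)
  expect_equal(pr2$values[1:95], dat[1, 6:100])
  expect_true(all(pr2$values[96:100] == 0))
})

test_that("training-data correlation matches the OLS bound", {
  set.seed(7)
  y <- make_white_slope(600)
  labs <- c("Fz", "Cz", "Pz", "C3", "C4")
  rec <- synth_eeg(y, snr = 2, coupling = 1, labels = labs, seed = 8)
  X <- embed_eeg(rec, 10)
  f <- fit_ridge(X, y, lambda = 0)
  pr <- apply_filter(f, rec)
  keep <- 1:590
  r_fit <- cor(pr$values[keep], y[keep])
  # OLS oracle on the same (centred) rows
  M <- X$matrix[keep, ]
  bhat <- qr.solve(cbind(1, M), y[keep])
  r_ols <- cor(as.numeric(cbind(1, M) %*% bhat), y[keep])
  expect_gte(r_fit, r_ols - 1e-9)
})

test_that("cross-validation recovers planted coupling and nulls shuffled targets", {
  y <- make_slope(duration = 12, seed = 9)
  recs <- make_presentations(y, snr = 5, coupling = 1, seed = 20)
  cv <- crossval_projections(recs, y, L = 30)
  keep <- seq_len(length(y) - 30)
  rs <- vapply(cv$projections, function(p) cor(p$values[keep], y[keep]), 0)
  expect_true(all(rs > 0.9))
  # training ids exclude the held-out presentation
  for (i in 1:3)
    expect_false(i %in% cv$filters[[i]]$training_ids)
  # shuffled target: correlations near zero
  set.seed(10)
  ysh <- sample(y)
  cvn <- crossval_projections(recs, ysh, L = 30)
  rsn <- vapply(cvn$projections, function(p) cor(p$values[keep], ysh[keep]), 0)
  expect_lt(max(abs(rsn)), 0.15)
  expect_error(crossval_projections(recs[1:2], y), "at least 3")
})

test_that("shrinkage path is continuous in lambda", {
  y <- make_slope(duration = 10, seed = 11)
  labs <- small_montage()
  recs <- make_presentations(y, snr = 1, coupling = 1, seed = 30,
                             labels = labs)
  keep <- seq_len(length(y) - 30)
  grid <- c(0, 1e-4, 1e-3, 1e-2, 0.1, 0.3, 0.6, 1)
  rs <- vapply(grid, function(lam) {
    cv <- crossval_projections(recs[1:3], y, L = 30, lambda = lam)
    cor(cv$projections[[3]]$values[keep], y[keep])
  }, 0)
  expect_true(all(is.finite(rs)))
  expect_true(all(abs(diff(rs)) < 0.5))
})

test_that("ERP averaging: identity, length, noise suppression", {
  rate <- 100
  n <- 3000
  onsets <- seq(0.5, 28, by = 0.42)
  kern <- n1p2_kernel(rate)
  clean <- matrix(0, 2, n)
  for (o in onsets) {
    i <- round(o * rate) + 1
    j <- min(i + 30, n)
    clean[, i:j] <- clean[, i:j] + rbind(kern[1:(j - i + 1)],
                                         -0.5 * kern[1:(j - i + 1)])
  }
  e <- eeg_recording(clean, rate, c("Fz", "Cz"))
  avg <- erp_average(e, onsets, 0.3)
  expect_equal(ncol(avg$epoch), 30)
  # identical epochs (no overlap at IOI 420 ms > 300 ms): average == epoch
  first <- round(onsets[1] * rate) + 1
  expect_equal(avg$epoch, clean[, first:(first + 29)], tolerance = 1e-12)
  # with noise: average within 4 sd / sqrt(n_epochs) of truth
  set.seed(12)
  noisy <- eeg_recording(clean + rnorm(2 * n, sd = 1), rate, c("Fz", "Cz"))
  avg2 <- erp_average(noisy, onsets, 0.3)
  tol <- 4 / sqrt(avg2$n_used)
  expect_lt(max(abs(avg2$epoch - avg$epoch)), tol * 2)
  # epochs past the end are dropped and counted
  avg3 <- erp_average(e, c(onsets, 29.9), 0.3)
  expect_equal(avg3$n_dropped, 1)
  expect_error(erp_average(e, 40, 0.3), "no usable epochs")
})

test_that("cacor fit object: methods and bookkeeping", {
  y <- make_slope(duration = 10, seed = 13)
  recs <- make_presentations(y, snr = 2, coupling = 1, seed = 40)
  fit <- cacor(recs, y, L = 30, n_surrogates = 99, seed = 3)
  expect_s3_class(fit, "cacor_fit")
  expect_equal(nrow(fit$results), 3)
  expect_true(all(fit$results$r > 0.5))
  expect_true(all(fit$results$n_eff <= length(y)))
  sm <- summary(fit)
  expect_equal(sm$score, sum(sm$results$significant))
  expect_equal(dim(coef(fit)), c(length(small_montage()), 31))
  pr <- predict(fit, recs[[1]], fold = 1)
  expect_equal(length(pr$values), ncol(recs[[1]]$data))
  expect_output(print(fit), "presentations")
})
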