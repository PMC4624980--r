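# Activation-pattern transform, SVD reduction, spherical leadfield, MUSIC.

make_design <- function(M, L = 0, n_channels = ncol(M)) {
  structure(list(matrix = M, L = L, n_channels = n_channels, rate = 100),
            class = "embedded_design")
}

make_filter <- function(w, L, n_channels) {
  structure(list(weights = matrix(w, n_channels, L + 1, byrow = TRUE),
                 intercept = 0, lambda = 0, L = L, n_channels = n_channels,
                 training_ids = NULL), class = "st_filter")
}

test_that("pattern transform: whitened designs, scaling, inverse recovery", {
  set.seed(1)
  n <- 20000; p <- 6
  M <- matrix(rnorm(n * p), n)         # near-identity covariance
  w <- c(1, -2, 0.5, 0, 3, -1)
  f <- make_filter(w, 0, p)
  A <- filter_to_pattern(f, make_design(M))$pattern
  expect_gt(abs(cosine(as.numeric(A), w)), 0.995)
  # invariant to positive rescaling of w (up to scale)
  A2 <- filter_to_pattern(make_filter(5 * w, 0, p), make_design(M))$pattern
  expect_gt(abs(cosine(as.numeric(A), as.numeric(A2))), 1 - 1e-12)
  # correlated design: w proportional to Sigma^-1 A recovers the filter
  B <- matrix(rnorm(p * p), p)
  Mc <- M %*% B
  A3 <- filter_to_pattern(f, make_design(Mc))$pattern
  S <- stats::cov(Mc) * (n - 1) / n
  w_back <- solve(S, as.numeric(t(A3)))
  expect_gt(abs(cosine(w_back, w)), 1 - 1e-6)
})

test_that("pattern transform recovers a planted single-source mixing", {
  set.seed(2)
  n <- 8000; p <- 8
  a <- rnorm(p); a <- a / sqrt(sum(a^2))
  s <- rnorm(n)
  M <- outer(s, a) + matrix(rnorm(n * p, sd = 0.3), n)
  X <- make_design(M)
  f <- fit_ridge(X, s, lambda = 0)
  A <- filter_to_pattern(f, X)$pattern
  expect_gt(abs(cosine(as.numeric(A), a)), 0.95)
  # degenerate: zero weights -> zero projected variance
  expect_error(filter_to_pattern(make_filter(rep(0, p), 0, p), X),
               "zero variance")
})

test_that("svd_reduce keeps the minimal subspace for the variance target", {
  # rank-1 matrix: one component explains everything
  r1 <- outer(c(1, 2, 3), c(2, -1))
  out <- svd_reduce(r1, 0.98)
  expect_equal(out$k, 1)
  expect_equal(out$var_explained, 1)
  # singular values 3 and 1: 9/10 of squared mass in the first
  M <- diag(c(3, 1))
  expect_equal(svd_reduce(M, 0.9)$k, 1)
  expect_equal(svd_reduce(M, 0.91)$k, 2)
  # reconstruction error bound and monotonicity in var_frac
  set.seed(3)
  P <- matrix(rnorm(20 * 31), 20)
  prev_k <- 0
  for (vf in c(0.5, 0.8, 0.95, 0.99, 1)) {
    o <- svd_reduce(P, vf)
    rec <- o$spatial %*% (o$d[seq_len(o$k)] * t(o$temporal))
    rel <- sqrt(sum((P - rec)^2) / sum(P^2))
    expect_lte(rel, sqrt(1 - vf) + 1e-12)
    expect_gte(o$k, prev_k)
    prev_k <- o$k
  }
  expect_error(svd_reduce(matrix(0, 3, 3)), "zero")
})

test_that("leadfield: average reference, vertex maximum, finiteness", {
  pos <- lookup_electrode_positions(default_montage())
  H <- build_leadfield(pos, n_per_shell = 32)
  expect_equal(ncol(H$gain), 3 * nrow(H$grid))
  expect_true(all(is.finite(H$gain)))
  expect_true(all(colSums(abs(H$gain)) > 0))
  # average reference: columns sum to zero
  expect_lt(max(abs(colSums(H$gain))), 1e-12)
  # radial dipole under the vertex peaks at Cz
  v <- cacor:::dipole_potential(pos, c(0, 0, 0.65), c(0, 0, 1))
  v <- v - mean(v)
  expect_equal(default_montage()[which.max(abs(v))], "Cz")
  # central dipole reduces to the classical closed form 3 m.e / (4 pi)
  vc <- cacor:::dipole_potential(pos, c(0, 0, 1e-12), c(0, 0, 1))
  expect_equal(vc, 3 / (4 * pi) * unname(pos[, 3]), tolerance = 1e-4)
  expect_error(build_leadfield(pos * 1.01), "unit sphere")
  expect_error(build_leadfield(pos[1:4, ]), "at least 8")
})

test_that("MUSIC recovers one and two dipole sources", {
  pos <- lookup_electrode_positions(default_montage())
  H <- build_leadfield(pos, n_per_shell = 48)
  dp <- function(loc, o) {
    v <- cacor:::dipole_potential(pos, loc, o)
    v - mean(v)
  }
  set.seed(4)
  # single source: exact localization, near-unit cosine
  loc <- H$grid[40, ]
  f1 <- dp(loc, c(0.3, -0.5, 0.8) / sqrt(0.98))
  P <- outer(f1, n1p2_kernel(100)) +
    matrix(rnorm(61 * 31, sd = 0.002 * max(abs(f1))), 61)
  comps <- music_decompose(svd_reduce(P, 0.98), H, n_max = 4)
  expect_gte(length(comps), 1)
  expect_lte(length(comps), 4)
  expect_gt(abs(cosine(comps[[1]]$spatial_map, f1)), 0.99)
  expect_lt(sqrt(sum((comps[[1]]$dipole_location - loc)^2)), 1e-9)
  # spatial maps are unit norm; explained variance in (0, 1]
  for (cp in comps) {
    expect_equal(sum(cp$spatial_map^2), 1, tolerance = 1e-9)
    expect_true(cp$explained_variance > 0 && cp$explained_variance <= 1)
  }
  # two well-separated equal-power sources
  loc2 <- H$grid[150, ]
  f2 <- dp(loc2, c(1, 0, 0))
  tc1 <- n1p2_kernel(100)
  tc2 <- sin(2 * pi * (0:30) / 15)
  P2 <- outer(f1 / sqrt(sum(f1^2)), tc1) + outer(f2 / sqrt(sum(f2^2)), tc2)
  comps2 <- music_decompose(svd_reduce(P2, 0.98), H, n_max = 4)
  expect_gte(length(comps2), 2)
  c1 <- max(vapply(comps2, function(cp) abs(cosine(cp$spatial_map, f1)), 0))
  c2 <- max(vapply(comps2, function(cp) abs(cosine(cp$spatial_map, f2)), 0))
  expect_gt(c1, 0.95)
  expect_gt(c2, 0.95)
})

test_that("reference pattern: peak picking, latency invariance, dipole ERP", {
  labs <- default_montage()
  pos <- lookup_electrode_positions(labs)
  field <- cacor:::dipole_potential(pos, c(0, 0.35, 0.55), c(0, 0.537, 0.844))
  field <- field - mean(field)
  rate <- 100
  times <- (0:29) / rate
  mk_erp <- function(peak_t) {
    amp <- exp(-0.5 * ((times - peak_t) / 0.02)^2)
    list(epoch = outer(field, amp), times = times, channel_labels = labs,
         n_used = 100, n_dropped = 0)
  }
  # single subject, deterministic peak
  ref1 <- reference_pattern(list(mk_erp(0.2)), channel = "Fz")
  expect_gt(abs(cosine(ref1, field)), 0.98)
  expect_equal(sum(ref1^2), 1, tolerance = 1e-12)
  # two subjects, identical topography at different latencies
  ref2 <- reference_pattern(list(mk_erp(0.15), mk_erp(0.25)), channel = "Fz")
  expect_gt(abs(cosine(ref2, field)), 0.98)
  expect_error(reference_pattern(list(mk_erp(0.2)), channel = "XX"),
               "not in montage")
})

test_that("component matching is sign-invariant with sensible tie-breaks", {
  set.seed(5)
  ref <- rnorm(10); ref <- ref / sqrt(sum(ref^2))
  other <- rnorm(10); other <- other / sqrt(sum(other^2))
  mk <- function(map, ev) list(spatial_map = map / sqrt(sum(map^2)),
                               time_course = rnorm(5),
                               dipole_location = c(0, 0, 0.5),
                               orientation = c(0, 0, 1), subcorr = 0.9,
                               explained_variance = ev)
  comps <- list(mk(other, 0.5), mk(ref, 0.4))
  m <- match_component(comps, ref)
  expect_equal(m$index, 2)
  expect_equal(m$similarity, 1, tolerance = 1e-9)
  # flipping a component's sign changes nothing
  comps_f <- list(mk(other, 0.5), mk(-ref, 0.4))
  m2 <- match_component(comps_f, ref)
  expect_equal(m2$index, 2)
  expect_equal(m2$similarity, 1, tolerance = 1e-9)
  # orthogonal reference: low-similarity warning, tie broken by variance
  o1 <- c(1, rep(0, 9)); o2 <- c(0, 1, rep(0, 8))
  ref_orth <- c(rep(0, 8), 1, 0)
  expect_warning(m3 <- match_component(list(mk(o1, 0.3), mk(o2, 0.6)),
                                       ref_orth), "low")
  expect_equal(m3$index, 2)
})
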