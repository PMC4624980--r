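# Interpretation of regression filters: activation-pattern transform,
# SVD subspace reduction, spherical-head leadfield, and a recursive MUSIC
# decomposition into dipole-related scalp components.

#' Transform a backward-model filter into an activation pattern
#'
#' Backward-model weights are not interpretable as scalp topographies; the
#' corresponding forward (activation) pattern is A = Cov(X) w / var(X w),
#' reshaped to channels x (L+1).
#'
#' @param f an `st_filter` from [fit_ridge()].
#' @param X the `embedded_design` the filter was trained on.
#' @param exclude_rows rows excluded from training (zero-padded embedding).
#' @return An object of class `st_pattern`: list with `pattern`
#'   (channels x (L+1)), `L`, `n_channels`.
#' @export
filter_to_pattern <- function(f, X, exclude_rows = NULL) {
  stopifnot(inherits(f, "st_filter"), inherits(X, "embedded_design"))
  M <- X$matrix
  if (is.null(exclude_rows) && X$L > 0)
    exclude_rows <- (nrow(M) - X$L + 1):nrow(M)
  if (length(exclude_rows)) M <- M[-exclude_rows, , drop = FALSE]
  Mc <- sweep(M, 2, colMeans(M))
  w <- as.numeric(t(f$weights))
  s <- as.numeric(Mc %*% w)
  v <- sum(s^2) / length(s)
  if (v <= 0) stop("projected source has zero variance")
  a <- crossprod(Mc, s) / nrow(Mc) / v
  structure(list(pattern = matrix(a, f$n_channels, f$L + 1, byrow = TRUE),
                 L = f$L, n_channels = f$n_channels),
            class = "st_pattern")
}

#' SVD subspace reduction of a spatio-temporal pattern
#'
#' Keeps the smallest number of singular triplets whose cumulative squared
#' singular values cover at least `var_frac` of the total.
#'
#' @param P an `st_pattern` (or bare channels x lags matrix).
#' @param var_frac fraction of variance to retain (default 0.98).
#' @return List with `spatial` (channels x k), `temporal` (lags x k),
#'   `d` (all singular values), `k`, `var_explained`.
#' @export
svd_reduce <- function(P, var_frac = 0.98) {
  M <- if (inherits(P, "st_pattern")) P$pattern else as.matrix(P)
  if (var_frac <= 0 || var_frac > 1) stop("var_frac must be in (0, 1]")
  if (all(M == 0)) stop("zero pattern matrix")
  sv <- svd(M)
  cum <- cumsum(sv$d^2) / sum(sv$d^2)
  k <- which(cum >= var_frac - 1e-12)[1]
  list(spatial = sv$u[, seq_len(k), drop = FALSE],
       temporal = sv$v[, seq_len(k), drop = FALSE],
       d = sv$d, k = k, var_explained = cum[k])
}

legendre_terms <- function(c_, nmax) {
  # P_n(c) and P'_n(c) for n = 1..nmax by recurrence, columns = n
  m <- length(c_)
  P <- matrix(0, m, nmax + 1)   # col j = P_{j-1}
  dP <- matrix(0, m, nmax + 1)
  P[, 1] <- 1
  if (nmax >= 1) { P[, 2] <- c_; dP[, 2] <- 1 }
  for (n in 1:(nmax - 1)) {
    P[, n + 2] <- ((2 * n + 1) * c_ * P[, n + 1] - n * P[, n]) / (n + 1)
    dP[, n + 2] <- dP[, n] + (2 * n + 1) * P[, n + 1]
  }
  list(P = P[, -1, drop = FALSE], dP = dP[, -1, drop = FALSE])
}

# Surface potential of a current dipole inside a homogeneous unit sphere
# (insulating exterior), via the Legendre series
#   V = K sum_n f^(n-1) (2n+1)/n [ n (u.b^)P_n(c) + (u.e^ - (u.b^)c) P'_n(c) ]
# with c = e^.b^; reduces to V = 3 (m.e^)/(4 pi sigma) for a central dipole.
dipole_potential <- function(electrodes, pos, moment, nmax = 80) {
  f <- sqrt(sum(pos^2))
  if (f >= 1) stop("dipole outside the unit sphere")
  if (f < 1e-9) {
    return(3 / (4 * pi) * as.numeric(electrodes %*% moment))
  }
  bhat <- pos / f
  c_ <- as.numeric(electrodes %*% bhat)
  ue <- as.numeric(electrodes %*% moment)
  ub <- sum(bhat * moment)
  lt <- legendre_terms(c_, nmax)
  n <- seq_len(nmax)
  coef <- f^(n - 1) * (2 * n + 1) / n
  rad <- lt$P %*% (coef * n)
  tang_base <- lt$dP %*% coef
  v <- ub * rad + (ue - ub * c_) * tang_base
  as.numeric(v) / (4 * pi)
}

#' Build a spherical-head leadfield
#'
#' Analytic single-sphere dipole model: unit conducting sphere, electrodes on
#' the surface, dipole grid on concentric shells, three orthogonal moments
#' per grid point. Columns are average-referenced (each sums to zero over
#' electrodes).
#'
#' @param electrodes electrodes x 3 matrix of unit-sphere positions (rows
#'   must be unit vectors to within 1e-6).
#' @param radii shell radii of the dipole grid (all < 1).
#' @param n_per_shell approximate grid points per shell (Fibonacci sphere).
#' @return An object of class `head_model`: list with `electrodes`, `grid`
#'   (points x 3), `gain` (electrodes x 3*points).
#' @export
build_leadfield <- function(electrodes,
                            radii = c(0.3, 0.475, 0.65, 0.85),
                            n_per_shell = 64) {
  electrodes <- as.matrix(electrodes)
  if (nrow(electrodes) < 8) stop("need at least 8 electrodes")
  norms <- sqrt(rowSums(electrodes^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("electrode positions must lie on the unit sphere")
  if (any(radii >= 1)) stop("grid radii must be < 1")
  # Fibonacci sphere points on each shell
  grid <- do.call(rbind, lapply(radii, function(r) {
    i <- seq_len(n_per_shell) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n_per_shell
    s <- sqrt(pmax(0, 1 - z^2))
    r * cbind(s * cos(phi), s * sin(phi), z)
  }))
  ng <- nrow(grid)
  gain <- matrix(0, nrow(electrodes), 3 * ng)
  I3 <- diag(3)
  for (g in seq_len(ng)) {
    for (m in 1:3) {
      col <- (g - 1) * 3 + m
      v <- dipole_potential(electrodes, grid[g, ], I3[, m])
      gain[, col] <- v - mean(v)   # average reference
    }
  }
  structure(list(electrodes = electrodes, grid = grid, gain = gain,
                 radii = radii, n_per_shell = n_per_shell),
            class = "head_model")
}

orth_basis <- function(M, tol = 1e-10) {
  sv <- svd(M)
  keep <- sv$d > tol * sv$d[1]
  sv$u[, keep, drop = FALSE]
}

#' Recursive MUSIC decomposition of a pattern subspace
#'
#' Sequentially (RAP-style) scans the dipole grid for the source whose
#' best-oriented forward field has maximal subspace correlation with the
#' retained spatial subspace, projects it out, and repeats. Stops at `n_max`
#' components or when the subspace correlation falls below `min_subcorr`
#' (always emitting at least one component). Components are unit-norm scalp
#' fields and need not be orthogonal.
#'
#' @param factors output of [svd_reduce()].
#' @param H a `head_model` from [build_leadfield()].
#' @param n_max maximum number of components (default 4).
#' @param min_subcorr subspace-correlation stopping threshold (default 0.8).
#' @return List of components, each with `spatial_map` (unit norm),
#'   `time_course` (lags vector), `dipole_location`, `orientation`,
#'   `subcorr`, `explained_variance`.
#' @export
music_decompose <- function(factors, H, n_max = 4, min_subcorr = 0.8) {
  stopifnot(inherits(H, "head_model"))
  Us <- as.matrix(factors$spatial)
  if (ncol(Us) < 1) stop("empty signal subspace")
  d <- factors$d[seq_len(factors$k)]
  # pattern reconstructed from the retained factors, for time courses and
  # explained variance
  P <- Us %*% (d * t(as.matrix(factors$temporal)))
  ng <- nrow(H$grid)
  comps <- list()
  A <- NULL   # found fields
  for (it in seq_len(n_max)) {
    if (is.null(A)) {
      Q_A <- NULL
      Usp <- orth_basis(Us)
    } else {
      QA <- orth_basis(A)
      proj <- function(M) M - QA %*% crossprod(QA, M)
      Usp <- orth_basis(proj(Us))
      if (ncol(Usp) == 0) break
      Q_A <- proj
    }
    best <- list(subcorr = -1)
    for (g in seq_len(ng)) {
      G <- H$gain[, ((g - 1) * 3 + 1):(g * 3), drop = FALSE]
      if (!is.null(Q_A)) G <- Q_A(G)
      qrg <- qr(G)
      rank <- qrg$rank
      if (rank == 0) next
      Qg <- qr.Q(qrg)[, seq_len(rank), drop = FALSE]
      sv <- svd(crossprod(Qg, Usp))
      sc <- sv$d[1]
      if (sc > best$subcorr) {
        # orientation: back-transform the leading left-singular vector
        R <- qr.R(qrg)[seq_len(rank), seq_len(rank), drop = FALSE]
        o3 <- rep(0, 3)
        o3[qrg$pivot[seq_len(rank)]] <- backsolve(R, sv$u[, 1])
        if (all(abs(o3) < 1e-15)) next
        o3 <- o3 / sqrt(sum(o3^2))
        best <- list(subcorr = sc, g = g, orient = o3)
      }
    }
    if (best$subcorr < 0) break
    if (it > 1 && best$subcorr < min_subcorr) break
    Gfull <- H$gain[, ((best$g - 1) * 3 + 1):(best$g * 3), drop = FALSE]
    a <- as.numeric(Gfull %*% best$orient)
    a <- a / sqrt(sum(a^2))
    tc <- as.numeric(crossprod(P, a))
    ev <- sum(tc^2) / sum(P^2)
    comps[[it]] <- list(spatial_map = a, time_course = tc,
                        dipole_location = H$grid[best$g, ],
                        orientation = best$orient,
                        subcorr = best$subcorr,
                        explained_variance = ev)
    A <- cbind(A, a)
  }
  comps
}

#' ERP-derived reference topography
#'
#' For each subject, finds the latency of maximum absolute amplitude at a
#' chosen channel inside a search window of the onset ERP, averages the
#' scalp topography over +/- 10 ms around it, then averages across subjects
#' and unit-normalizes.
#'
#' @param erps list of per-subject ERP averages from [erp_average()].
#' @param channel channel label at which the peak is located (default "Fz").
#' @param search_window latency window in seconds (default 0.13-0.28).
#' @param half_width half-width of the topography average in seconds.
#' @param rate sampling rate of the epochs in Hz.
#' @return Unit-norm channels vector (named with channel labels).
#' @export
reference_pattern <- function(erps, channel = "Fz",
                              search_window = c(0.13, 0.28),
                              half_width = 0.010, rate = 100) {
  stopifnot(length(erps) >= 1)
  topo <- NULL
  for (e in erps) {
    ci <- match(toupper(channel), toupper(e$channel_labels))
    if (is.na(ci)) stop("channel not in montage: ", channel)
    tt <- e$times
    win <- which(tt >= search_window[1] & tt <= search_window[2])
    if (!length(win)) stop("search window outside the epoch")
    pk <- win[which.max(abs(e$epoch[ci, win]))]
    around <- which(abs(tt - tt[pk]) <= half_width + 1e-12)
    tp <- rowMeans(e$epoch[, around, drop = FALSE])
    topo <- if (is.null(topo)) tp else topo + tp
  }
  topo <- topo / length(erps)
  topo <- topo / sqrt(sum(topo^2))
  names(topo) <- erps[[1]]$channel_labels
  topo
}

#' Select the MUSIC component most similar to a reference topography
#'
#' Similarity is the absolute cosine between unit-normalized maps
#' (sign-invariant). Ties are broken by larger explained variance, then by
#' lower component index.
#'
#' @param comps list of components from [music_decompose()].
#' @param ref reference channels vector.
#' @return List with `component`, `index`, `similarity`.
#' @export
match_component <- function(comps, ref) {
  if (!length(comps)) stop("no components to match")
  ref <- ref / sqrt(sum(ref^2))
  sims <- vapply(comps, function(cp) {
    a <- cp$spatial_map
    abs(sum(a * ref) / sqrt(sum(a^2)))
  }, 0)
  evs <- vapply(comps, `[[`, 0, "explained_variance")
  ord <- order(-sims, -evs, seq_along(comps))
  best <- ord[1]
  if (sims[best] < 0.3)
    warning("best component similarity to reference is low (",
            signif(sims[best], 3), ")")
  list(component = comps[[best]], index = best, similarity = sims[best])
}
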