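# Top-level orchestration: presentation-level CACor tables and score
# profiles, between-stimulus profile correlations, and within-stimulus
# partial-correlation tables.

#' Build an in-memory synthetic study
#'
#' Generates a stimulus set of isochronous chord sequences and, per stimulus,
#' subject and presentation, forward-model EEG with the requested coupling
#' grade. The workhorse behind the end-to-end property checks.
#'
#' @param couplings named numeric vector: one coupling grade in [0, 1] per
#'   stimulus (names become stimulus ids).
#' @param n_subjects,n_presentations design size (reference design: 9 and 3).
#' @param duration stimulus duration in seconds.
#' @param snr signal-to-noise amplitude ratio of the forward model.
#' @param labels montage labels.
#' @param rate EEG rate in Hz.
#' @param seed master seed; per-recording seeds are derived from it.
#' @return List of class `study`: per stimulus a list with `wave`, `onsets`,
#'   `slope` (at the EEG rate), `coupling`, and `recordings` (list of
#'   subjects, each a list of presentations).
#' @export
synth_study <- function(couplings, n_subjects = 3, n_presentations = 3,
                        duration = 30, snr = 1,
                        labels = default_montage(), rate = 100, seed = 1) {
  if (is.null(names(couplings)))
    names(couplings) <- sprintf("stim%02d", seq_along(couplings))
  study <- list()
  for (si in seq_along(couplings)) {
    st <- names(couplings)[si]
    tone <- synth_tone_sequence(duration = duration, seed = seed + 1000 * si)
    slope <- power_slope(frame_power(tone$wave), eeg_rate = rate)
    n_eeg <- length(slope$values)   # slope ends at the last full frame
    recs <- list()
    for (su in seq_len(n_subjects)) {
      subj <- sprintf("S%02d", su)
      recs[[subj]] <- lapply(seq_len(n_presentations), function(pr)
        synth_eeg(slope$values, rate = rate, snr = snr,
                  coupling = couplings[[si]], labels = labels,
                  seed = seed + 1000 * si + 10 * su + pr,
                  subject_id = subj, stimulus_id = st,
                  presentation_index = pr))
    }
    study[[st]] <- list(wave = tone$wave, onsets = tone$onsets,
                        slope = slope, coupling = couplings[[si]],
                        recordings = recs)
  }
  structure(study, class = "study")
}

#' Presentation-level CACor analysis of a study
#'
#' For every stimulus and subject, runs the leave-one-recording-out
#' cross-validated reconstruction and computes per-presentation CACor with
#' both significance routes; flags significance with Bonferroni correction
#' over all presentations of a stimulus, aggregates CACor scores and the
#' grand-average CACor.
#'
#' @param study a `study` from [synth_study()] (or the same structure built
#'   from files).
#' @param L lag count.
#' @param n_surrogates surrogate count per presentation.
#' @param alpha family-wise level.
#' @param cfg a [run_config()].
#' @param seed RNG seed for the surrogate draws.
#' @return List with `table` (data frame of all presentations: stimulus,
#'   subject, presentation, r, p_perm, p_pyper, n_eff, sig_perm, sig_pyper),
#'   `scores` (per-stimulus CACor score from the permutation route),
#'   `scores_pyper`, `grand_average` (per-stimulus list).
#' @export
run_presentation_analysis <- function(study, L = 30, n_surrogates = 999,
                                      alpha = 0.05, cfg = run_config(),
                                      seed = 1) {
  set.seed(seed)
  rows <- list()
  ga <- list()
  for (st in names(study)) {
    stim <- study[[st]]
    projections <- list()
    for (subj in names(stim$recordings)) {
      fit <- cacor(stim$recordings[[subj]], stim$slope, L = L,
                   n_surrogates = n_surrogates, cfg = cfg,
                   patterns = FALSE)
      res <- fit$results
      res$stimulus <- st
      res$subject <- subj
      rows[[length(rows) + 1]] <- res
      projections <- c(projections, fit$projections)
    }
    rate <- stim$recordings[[1]][[1]]$rate
    y <- stim$slope$values
    keep <- seq_len(length(y) - L)
    vals <- lapply(projections, function(p) p$values[keep])
    ga[[st]] <- grand_average_cacor(vals, y[keep], rate = rate,
                                    n_surr = n_surrogates,
                                    max_lag = cfg$pyper_max_lag_cacor)
  }
  tab <- do.call(rbind, rows)
  tab$sig_perm <- FALSE
  tab$sig_pyper <- FALSE
  scores <- integer(0)
  scores_pyper <- integer(0)
  for (st in unique(tab$stimulus)) {
    i <- tab$stimulus == st
    n <- sum(i)
    tab$sig_perm[i] <- correct_presentations(tab$p_perm[i], n, alpha)
    tab$sig_pyper[i] <- correct_presentations(tab$p_pyper[i], n, alpha)
    scores[st] <- cacor_score(tab$sig_perm[i])
    scores_pyper[st] <- cacor_score(tab$sig_pyper[i])
  }
  list(table = tab, scores = scores, scores_pyper = scores_pyper,
       grand_average = ga)
}

#' Between-stimulus profile correlations
#'
#' Spearman correlations (exact permutation p for n <= 9) between the CACor
#' score profile, the Coordination score profile, and each feature profile.
#'
#' @param scores named CACor score profile (stimulus -> score).
#' @param feature_profiles data frame from [global_profile()] (rows =
#'   stimuli).
#' @param coordination optional named Coordination score profile.
#' @return Data frame with columns `profile`, `rho`, `p`.
#' @export
run_profile_analysis <- function(scores, feature_profiles,
                                 coordination = NULL) {
  stimuli <- names(scores)
  out <- list()
  for (fn in colnames(feature_profiles)) {
    fp <- feature_profiles[stimuli, fn]
    names(fp) <- stimuli
    pc <- profile_correlation(scores, fp)
    out[[length(out) + 1]] <- data.frame(profile = fn, rho = pc$rho,
                                         p = pc$p)
  }
  if (!is.null(coordination)) {
    pc <- profile_correlation(scores, coordination[stimuli])
    out[[length(out) + 1]] <- data.frame(profile = "coordination",
                                         rho = pc$rho, p = pc$p)
  }
  do.call(rbind, out)
}

#' Within-stimulus partial-correlation tables
#'
#' Relates the time-resolved CACor (and, when provided, the mean tension
#' rating) of one stimulus to the nine feature time courses at the
#' time-resolved rate: for each feature, the partial correlation controlling
#' for the remaining features, with effective-df p-values (maximal lag 10 s)
#' and FDR flags per target.
#'
#' @param tr_cacor time-resolved CACor [feature_series()] (or numeric).
#' @param features named list of feature series resampled to the same rate
#'   (numeric vectors or [feature_series()]).
#' @param mean_tension optional mean tension rating series at the same rate.
#' @param rate series rate in Hz (default 10/3).
#' @param max_lag Pyper maximal lag in seconds.
#' @param q FDR level.
#' @return Data frame with columns `target`, `feature`, `r`, `p`,
#'   `significant`.
#' @export
run_within_stimulus_analysis <- function(tr_cacor, features,
                                         mean_tension = NULL, rate = 10 / 3,
                                         max_lag = 10, q = 0.05) {
  as_vals <- function(f) if (inherits(f, "feature_series")) f$values else
    as.numeric(f)
  fv <- lapply(features, as_vals)
  n <- min(vapply(fv, length, 0L))
  fv <- lapply(fv, function(v) v[seq_len(n)])
  targets <- list(cacor = as_vals(tr_cacor)[seq_len(n)])
  if (!is.null(mean_tension))
    targets$tension <- as_vals(mean_tension)[seq_len(n)]
  out <- list()
  for (tn in names(targets)) {
    rows <- lapply(names(fv), function(fn) {
      ctrl <- fv[names(fv) != fn]
      pc <- partial_correlation(targets[[tn]], fv[[fn]],
                                controls = ctrl, rate = rate,
                                max_lag = max_lag)
      data.frame(target = tn, feature = fn, r = pc$r, p = pc$p)
    })
    tabt <- do.call(rbind, rows)
    tabt$significant <- fdr_correct(tabt$p, q = q)
    out[[tn]] <- tabt
  }
  do.call(rbind, out)
}
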