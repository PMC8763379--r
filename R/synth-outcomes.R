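# Longitudinal outcome simulation for the mixed-model stage.

#' Measurement times and phase labels for a two-phase session design
#'
#' Emulates a single-day protocol in which each subject creates
#' `n_baseline` datasets without feedback and then `n_feedback` datasets
#' with biofeedback coaching. Defaults assume roughly 10 minutes per
#' dataset and a 20-minute break between phases while the feedback display
#' and coaching are set up; optional Gaussian jitter perturbs the nominal
#' times. With these defaults the dichotomous phase indicator and
#' per-subject normalized time are very highly correlated (|r| > 0.9),
#' which is why models should include one or the other, never both.
#'
#' @param n_baseline,n_feedback datasets per phase (defaults 3 and 3).
#' @param dataset_minutes nominal minutes between consecutive datasets.
#' @param break_minutes extra minutes between the last baseline and first
#'   feedback dataset.
#' @param jitter_sd standard deviation (minutes) of Gaussian timing jitter;
#'   draws come from the caller's RNG state.
#' @return data frame with columns `phase` (0 baseline / 1 feedback) and
#'   `time_min` (minutes from the first measurement), sorted in time.
#' @export
experiment2_times <- function(n_baseline = 3L, n_feedback = 3L,
                              dataset_minutes = 10, break_minutes = 20,
                              jitter_sd = 0) {
  stopifnot(n_baseline >= 1L, n_feedback >= 1L)
  t_base <- (seq_len(n_baseline) - 1L) * dataset_minutes
  t_feed <- max(t_base) + break_minutes +
    seq_len(n_feedback) * dataset_minutes
  tt <- c(t_base, t_feed)
  if (jitter_sd > 0) {
    tt <- tt + stats::rnorm(length(tt), 0, jitter_sd)
    tt <- sort(tt) - min(tt)
  }
  data.frame(phase = rep(c(0, 1), c(n_baseline, n_feedback)),
             time_min = tt)
}

#' Simulate longitudinal outcomes from a random-intercept model
#'
#' Draws `Y_ij = beta0 + b_i + beta1 * X_ij + eps_ij` with independent
#' normal subject intercepts `b_i` and residuals `eps_ij`. The covariate
#' carrying the effect is chosen by `covariate_kind` in the configuration:
#' a dichotomous phase indicator, per-subject normalized time, or both
#' columns (effect on phase). Measurement times follow the two-phase
#' session layout of [experiment2_times()] when phase is involved, and are
#' uniformly spaced otherwise.
#'
#' @param cfg an [outcome_gen_config()].
#' @return data frame with columns `subject`, `measurement`, `time_min`,
#'   the covariate column(s) (`phase` and/or `time_norm`) and the outcome
#'   `Y`. Identical configuration (including seed) gives an identical
#'   table.
#' @examples
#' cfg <- outcome_gen_config(n_subjects = 4, n_measurements = 6,
#'                           beta0 = 90, beta1 = 3, sigma_b = 2,
#'                           sigma_eps = 1, seed = 11)
#' head(generate_outcomes(cfg))
#' @export
generate_outcomes <- function(cfg) {
  stopifnot(inherits(cfg, "smg_outcome_config"))
  ns <- cfg$n_subjects
  nm <- cfg$n_measurements
  with_phase <- cfg$covariate_kind %in% c("phase", "both")
  tab <- with_substream(cfg$seed, "outcomes", 0L, {
    b <- stats::rnorm(ns, 0, cfg$sigma_b)
    rows <- vector("list", ns)
    for (i in seq_len(ns)) {
      if (with_phase) {
        n_base <- ceiling(nm / 2)
        des <- experiment2_times(n_baseline = n_base,
                                 n_feedback = nm - n_base)
      } else {
        des <- data.frame(phase = rep(NA_real_, nm),
                          time_min = (seq_len(nm) - 1L) * 10)
      }
      tn <- if (nm >= 2L) {
        (des$time_min - des$time_min[1L]) /
          (des$time_min[nm] - des$time_min[1L])
      } else {
        rep(0, nm)
      }
      x <- switch(cfg$covariate_kind,
                  phase = des$phase, both = des$phase, time = tn)
      eps <- stats::rnorm(nm, 0, cfg$sigma_eps)
      y <- cfg$beta0 + b[i] + cfg$beta1 * x + eps
      row <- data.frame(subject = sprintf("S%02d", i),
                        measurement = seq_len(nm),
                        time_min = des$time_min,
                        stringsAsFactors = FALSE)
      if (with_phase) row$phase <- des$phase
      if (cfg$covariate_kind %in% c("time", "both")) row$time_norm <- tn
      row$Y <- y
      rows[[i]] <- row
    }
    do.call(rbind, rows)
  })
  rownames(tab) <- NULL
  tab
}
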