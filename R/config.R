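#' Configuration for the synthetic ultrasound image generator
#'
#' Parameters controlling simulated sonomyography frame sequences: speckle
#' texture, class-specific deformation, repetition-level variability and
#' per-frame noise. The defaults reproduce the standard acquisition layout
#' of a cued-motion protocol: five motion classes, five repetitions per
#' class, 100 x 140 pixel frames, and a 4-second cue cycle
#' (1 s move, 1 s hold, 1 s return, 1 s rest).
#'
#' @param n_classes number of motion classes (>= 1); default 5.
#' @param n_repetitions repetitions (cue cycles) per class (>= 1); default 5.
#' @param frame_height,frame_width frame dimensions in pixels; default
#'   100 x 140.
#' @param frame_rate frames per second (>= 1). The cue cycle segments each
#'   last one second, so this is also the number of hold frames per
#'   repetition; default 10.
#' @param class_separation dimensionless amplitude of the class-specific
#'   deformation pattern (0 = all classes identical to rest). The default
#'   0.3 corresponds to ~1-pixel peak displacements between gestures at
#'   the default resolution -- subtle but classifiable differences.
#' @param rep_jitter standard deviation of the repetition-level perturbation
#'   of the deformation (relative amplitude jitter plus a proportional
#'   spatial offset of the pattern center). The default 0.5 (about +/-50%
#'   amplitude and ~2-pixel centering variation between repetitions) makes
#'   leave-one-out accuracy land in the low-to-high 90s like real naive
#'   users, rather than saturating at 100.
#' @param frame_noise standard deviation of per-frame additive Gaussian
#'   intensity noise (intensities live in `[0, 1]`); default 0.1.
#' @param speckle_smoothness correlation length (Gaussian sigma, pixels) of
#'   the base speckle texture; default 2.
#' @param seed RNG seed; fixes the full generated output bit-for-bit.
#' @return an object of class `smg_image_config` (a validated list).
#' @seealso [generate_dataset()], [make_class_template()]
#' @export
image_gen_config <- function(n_classes = 5L, n_repetitions = 5L,
                             frame_height = 100L, frame_width = 140L,
                             frame_rate = 10L,
                             class_separation = 0.3, rep_jitter = 0.5,
                             frame_noise = 0.1, speckle_smoothness = 2,
                             seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes),
    n_repetitions = as.integer(n_repetitions),
    frame_height = as.integer(frame_height),
    frame_width = as.integer(frame_width),
    frame_rate = as.integer(frame_rate),
    class_separation = as.numeric(class_separation),
    rep_jitter = as.numeric(rep_jitter),
    frame_noise = as.numeric(frame_noise),
    speckle_smoothness = as.numeric(speckle_smoothness),
    seed = as.integer(seed)
  )
  counts <- c("n_classes", "n_repetitions", "frame_height", "frame_width",
              "frame_rate")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop(sprintf("'%s' must be a count >= 1", nm), call. = FALSE)
    }
  }
  for (nm in c("class_separation", "rep_jitter", "frame_noise",
               "speckle_smoothness")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
    }
  }
  structure(cfg, class = "smg_image_config")
}

#' Configuration for the longitudinal outcome generator
#'
#' Parameters of the random-intercept data-generating model
#' \deqn{Y_{ij} = \beta_0 + b_i + \beta_1 X_{ij} + \epsilon_{ij},}
#' with \eqn{b_i \sim N(0, \sigma_b^2)} per subject and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma_\epsilon^2)} per measurement,
#' all draws independent. Used to exercise the mixed-model and
#' permutation-test machinery without any image data.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_measurements number of measurements per subject (>= 1).
#' @param beta0 fixed intercept.
#' @param beta1 fixed effect of the covariate `X`.
#' @param sigma_b standard deviation of the subject random intercept (>= 0).
#' @param sigma_eps residual standard deviation (>= 0).
#' @param covariate_kind which covariate carries the effect and is emitted:
#'   `"phase"` (dichotomous 0/1, first half of each subject's measurements
#'   baseline, second half feedback), `"time"` (per-subject normalized time
#'   in `[0, 1]`), or `"both"` (both columns emitted; the effect `beta1` is
#'   applied to phase).
#' @param seed RNG seed.
#' @return an object of class `smg_outcome_config`.
#' @seealso [generate_outcomes()]
#' @export
outcome_gen_config <- function(n_subjects = 8L, n_measurements = 6L,
                               beta0 = 90, beta1 = 3,
                               sigma_b = 2, sigma_eps = 1,
                               covariate_kind = c("phase", "time", "both"),
                               seed = 1L) {
  covariate_kind <- match.arg(covariate_kind)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_measurements = as.integer(n_measurements),
    beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
    sigma_b = as.numeric(sigma_b), sigma_eps = as.numeric(sigma_eps),
    covariate_kind = covariate_kind,
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1L || cfg$n_measurements < 1L) {
    stop("'n_subjects' and 'n_measurements' must be counts >= 1",
         call. = FALSE)
  }
  if (cfg$sigma_b < 0 || cfg$sigma_eps < 0) {
    stop("'sigma_b' and 'sigma_eps' must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "smg_outcome_config")
}

#' @export
print.smg_image_config <- function(x, ...) {
  cat("Synthetic SMG image generator configuration\n")
  cat(sprintf("  %d classes x %d repetitions, %dx%d px at %d fps\n",
              x$n_classes, x$n_repetitions, x$frame_height, x$frame_width,
              x$frame_rate))
  cat(sprintf("  class_separation = %g, rep_jitter = %g, frame_noise = %g\n",
              x$class_separation, x$rep_jitter, x$frame_noise))
  cat(sprintf("  speckle_smoothness = %g, seed = %d\n",
              x$speckle_smoothness, x$seed))
  invisible(x)
}

#' @export
print.smg_outcome_config <- function(x, ...) {
  cat("Longitudinal outcome generator configuration\n")
  cat(sprintf("  %d subjects x %d measurements, covariate: %s\n",
              x$n_subjects, x$n_measurements, x$covariate_kind))
  cat(sprintf("  beta0 = %g, beta1 = %g, sigma_b = %g, sigma_eps = %g, seed = %d\n",
              x$beta0, x$beta1, x$sigma_b, x$sigma_eps, x$seed))
  invisible(x)
}
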