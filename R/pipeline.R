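# End-to-end simulated-study pipeline:
# simulate -> extract -> classify -> feature metrics -> mixed-model stats.

#' Configuration of a full simulated study run
#'
#' Describes an experiment shaped like a two-phase biofeedback study: each
#' subject records `n_baseline` datasets without feedback and then
#' `n_feedback` datasets with feedback, all on one day. Per-subject skill
#' varies through a log-normal multiplier on the deformation amplitude
#' (inducing between-subject correlation of outcomes, i.e. the random
#' intercept), and the feedback phase can alter the deformation amplitude
#' and repetition jitter through the two gain parameters.
#'
#' @param image an [image_gen_config()]; per-dataset seeds are derived
#'   from `seed`, so `image$seed` is ignored.
#' @param n_subjects number of subjects.
#' @param n_baseline,n_feedback datasets per phase per subject.
#' @param subject_sd standard deviation of the per-subject log-normal
#'   multiplier on `class_separation`.
#' @param feedback_separation_gain multiplier on `class_separation` during
#'   the feedback phase (> 1 = movements become more distinct).
#' @param feedback_jitter_gain multiplier on `rep_jitter` during the
#'   feedback phase (< 1 = movements become more consistent).
#' @param dataset_minutes,break_minutes,jitter_sd session timing, see
#'   [experiment2_times()].
#' @param n_components PCA feature-space dimensionality.
#' @param include_rest treat rest as a class in classification.
#' @param n_permutations permutations per significance test.
#' @param alternative sidedness of the phase test (see
#'   [permutation_pvalue()]).
#' @param seed master seed; every stage draws from a named substream.
#' @return an object of class `smg_run_config`.
#' @export
run_config <- function(image = image_gen_config(),
                       n_subjects = 5L, n_baseline = 3L, n_feedback = 3L,
                       subject_sd = 0.15,
                       feedback_separation_gain = 1.2,
                       feedback_jitter_gain = 0.9,
                       dataset_minutes = 10, break_minutes = 20,
                       jitter_sd = 1,
                       n_components = 5L, include_rest = FALSE,
                       n_permutations = 1000L,
                       alternative = "greater",
                       seed = 1L) {
  stopifnot(inherits(image, "smg_image_config"),
            n_subjects >= 1L, n_baseline >= 1L, n_feedback >= 1L,
            subject_sd >= 0, feedback_separation_gain > 0,
            feedback_jitter_gain >= 0, n_permutations >= 1L)
  structure(list(image = image, n_subjects = as.integer(n_subjects),
                 n_baseline = as.integer(n_baseline),
                 n_feedback = as.integer(n_feedback),
                 subject_sd = subject_sd,
                 feedback_separation_gain = feedback_separation_gain,
                 feedback_jitter_gain = feedback_jitter_gain,
                 dataset_minutes = dataset_minutes,
                 break_minutes = break_minutes, jitter_sd = jitter_sd,
                 n_components = as.integer(n_components),
                 include_rest = include_rest,
                 n_permutations = as.integer(n_permutations),
                 alternative = alternative,
                 seed = as.integer(seed)),
            class = "smg_run_config")
}

stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run a full simulated biofeedback study
#'
#' Executes every stage in order for each subject and dataset: generate a
#' cued-motion dataset, cross-validate the nearest-class classifier,
#' project to the PCA feature space and compute the cluster metrics. The
#' per-dataset outcomes are assembled into a longitudinal table and the
#' phase effect on each outcome is tested with the permutation-tested
#' random-intercept mixed model.
#'
#' @param config an [run_config()].
#' @param out_dir optional directory; if given, writes `report.json` and
#'   `outcomes.csv` there.
#' @param verbose log stage progress to stderr.
#' @return an object of class `smg_report`: list with `outcomes` (one row
#'   per dataset: subject, dataset, phase, time_min, CA and the five
#'   metric totals), `models` (per-outcome phase-effect estimates and
#'   permutation p-values) and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "smg_run_config"))
  n_data <- config$n_baseline + config$n_feedback
  say <- function(...) if (verbose) message(sprintf(...))
  subj_mult <- with_substream(config$seed, "subjects", 0L,
                              exp(stats::rnorm(config$n_subjects, 0,
                                               config$subject_sd)))
  rows <- vector("list", config$n_subjects * n_data)
  for (i in seq_len(config$n_subjects)) {
    subject_id <- sprintf("S%02d", i)
    des <- with_substream(config$seed, "times", i,
                          experiment2_times(config$n_baseline,
                                            config$n_feedback,
                                            config$dataset_minutes,
                                            config$break_minutes,
                                            config$jitter_sd))
    for (d in seq_len(n_data)) {
      k <- (i - 1L) * n_data + d
      feedback <- des$phase[d] == 1
      img <- config$image
      img$class_separation <- img$class_separation * subj_mult[i] *
        if (feedback) config$feedback_separation_gain else 1
      img$rep_jitter <- img$rep_jitter *
        if (feedback) config$feedback_jitter_gain else 1
      img$seed <- substream_seed(config$seed, "dataset", k)
      say("subject %s dataset %d (%s)", subject_id, d,
          if (feedback) "feedback" else "baseline")
      dataset <- stage_call("simulate",
                            generate_dataset(img, subject = subject_id,
                                             session = 1L,
                                             phase = if (feedback)
                                               "feedback" else "baseline"))
      cv <- stage_call("classify",
                       loo_cross_validate(dataset,
                                          include_rest = config$include_rest))
      cloud <- stage_call("features",
                          fit_project_pca(dataset, config$n_components,
                                          include_rest = config$include_rest))
      met <- stage_call("features", feature_metrics(cloud))
      rows[[k]] <- data.frame(
        subject = subject_id, dataset = d,
        phase = des$phase[d], time_min = des$time_min[d],
        CA = cv$CA,
        WD = met$totals[["WD"]], IDNN = met$totals[["IDNN"]],
        IDAN = met$totals[["IDAN"]], MSD = met$totals[["MSD"]],
        MSA = met$totals[["MSA"]],
        stringsAsFactors = FALSE
      )
    }
  }
  outcomes <- do.call(rbind, rows)
  outcome_names <- c("CA", "WD", "IDNN", "IDAN", "MSD", "MSA")
  models <- stage_call("stats", {
    lapply(stats::setNames(outcome_names, outcome_names), function(nm) {
      pt <- permutation_pvalue(outcomes, nm, fixed = "phase",
                               test = "phase",
                               alternative = if (nm == "CA")
                                 config$alternative else "two.sided",
                               n_permutations = config$n_permutations,
                               seed = substream_seed(config$seed, "perm-test",
                                                     match(nm, outcome_names)))
      list(estimate = pt$estimate, t = pt$observed, p_value = pt$p_value,
           alternative = pt$alternative,
           sigma_b = pt$fit$sigma_b, sigma_eps = pt$fit$sigma_eps)
    })
  })
  report <- structure(list(outcomes = outcomes, models = models,
                           config = config), class = "smg_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(outcomes = outcomes, models = models,
           seed = config$seed),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.smg_report <- function(x, ...) {
  cat(sprintf("Simulated SMG study: %d subjects x %d datasets\n",
              x$config$n_subjects, x$config$n_baseline + x$config$n_feedback))
  agg <- stats::aggregate(CA ~ phase, data = x$outcomes, FUN = mean)
  for (r in seq_len(nrow(agg))) {
    cat(sprintf("  mean CA (%s) = %.1f%%\n",
                if (agg$phase[r] == 0) "baseline" else "feedback",
                agg$CA[r]))
  }
  cat("phase effects (permutation p):\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-5s beta1 = %8.4g   p = %.4g (%s)\n",
                nm, m$estimate, m$p_value, m$alternative))
  }
  invisible(x)
}
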