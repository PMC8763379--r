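# Random-intercept linear mixed models and permutation-based significance.
#
# Model: Y_ij = beta0 + b_i + beta' x_ij + eps_ij, with a normal random
# intercept b_i per subject and normal residuals. Fitting is by maximum
# likelihood (not REML) so that refits under permuted fixed effects have
# comparable likelihoods. The user-facing fit goes through lme4; the
# permutation loop uses an internal profile-likelihood fitter that
# exploits the single-grouping random-intercept structure and is two
# orders of magnitude faster on the small designs typical here (it is
# validated against lme4 in the test suite).

#' Per-subject normalized time covariate
#'
#' Maps each subject's measurement times to `[0, 1]`:
#' `(t - t_first) / (t_last - t_first)` within subject. The first
#' measurement maps to 0 and the last to 1.
#'
#' @param times numeric vector of measurement times.
#' @param subject vector of subject identifiers, same length.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' normalized_time(c(0, 30, 60), rep("a", 3)) # 0, 0.5, 1
#' @export
normalized_time <- function(times, subject) {
  stopifnot(length(times) == length(subject))
  out <- numeric(length(times))
  for (s in unique(subject)) {
    sel <- subject == s
    t_s <- times[sel]
    if (length(unique(t_s)) < 2L) {
      stop(sprintf("subject '%s' has no two distinct measurement times", s),
           call. = FALSE)
    }
    out[sel] <- (t_s - min(t_s)) / (max(t_s) - min(t_s))
  }
  out
}

# ---- internal profile-likelihood ML fitter ------------------------------

# ML fit of y = X beta + b_g + eps by profiling the likelihood over the
# variance ratio theta = sigma_b^2 / sigma_eps^2. For a random-intercept
# model, V_g^{-1} = (I - c_g J)/sigma_eps^2 with c_g = theta/(1+n_g theta),
# so all GLS quantities reduce to per-group sums: one cheap 1-D optimize.
lmm_profile_fit <- function(y, X, group) {
  n <- length(y)
  p <- ncol(X)
  g <- as.integer(factor(group))
  ng <- tabulate(g)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  GX <- rowsum(X, g)
  Gy <- rowsum(y, g)

  solve_at <- function(theta) {
    cg <- theta / (1 + ng * theta)
    XtWX <- XtX - crossprod(GX, cg * GX)
    XtWy <- Xty - crossprod(GX, cg * Gy)
    ytWy <- yty - sum(cg * Gy * Gy)
    beta <- solve(XtWX, XtWy)
    rss <- max(drop(ytWy - crossprod(beta, XtWy)), 0)
    sigma2 <- max(rss / n, 1e-300)
    # -2 log L up to the constant n (absorbed below)
    negll <- n * log(2 * pi * sigma2) + sum(log1p(ng * theta)) + n
    list(beta = drop(beta), sigma2 = sigma2, negll = negll / 2,
         XtWX = XtWX, theta = theta)
  }

  obj <- function(lt) solve_at(exp(lt))$negll
  opt <- stats::optimize(obj, interval = c(-18, 12), tol = 1e-9)
  cand <- solve_at(exp(opt$minimum))
  zero <- solve_at(0)
  fit <- if (zero$negll <= cand$negll) zero else cand
  vcov_beta <- fit$sigma2 * solve(fit$XtWX)
  se <- sqrt(diag(vcov_beta))
  list(beta = fit$beta, se = se,
       tstat = ifelse(se > 0, fit$beta / se, 0),
       sigma_eps = sqrt(fit$sigma2),
       sigma_b = sqrt(fit$theta * fit$sigma2),
       logLik = -fit$negll, vcov = vcov_beta)
}

# Build and rank-check the fixed-effect design matrix.
fixed_design <- function(data, fixed) {
  missing_cols <- setdiff(fixed, names(data))
  if (length(missing_cols) > 0L) {
    stop("covariate column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(lapply(data[fixed], as.numeric))))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

#' Fit a random-intercept linear mixed model
#'
#' Maximum-likelihood fit of
#' `outcome ~ fixed effects + (1 | subject)`. The default engine is
#' [lme4::lmer()]; `engine = "profile"` uses the package's internal
#' profile-likelihood fitter (identical model, much faster on small
#' designs; used inside [permutation_pvalue()]).
#'
#' @param data data frame of one row per measurement.
#' @param outcome name of the outcome column.
#' @param fixed character vector of fixed-covariate column names (an
#'   intercept is always included).
#' @param subject name of the subject (grouping) column.
#' @param engine `"lme4"` or `"profile"`.
#' @return an object of class `smg_lmm`: coefficient table (`estimate`,
#'   `se`, `tstat`), `sigma_b`, `sigma_eps`, `logLik`, and bookkeeping.
#' @examples
#' cfg <- outcome_gen_config(n_subjects = 6, seed = 3)
#' fit <- fit_lmm(generate_outcomes(cfg), "Y", "phase")
#' coef(fit)
#' @export
fit_lmm <- function(data, outcome, fixed, subject = "subject",
                    engine = c("lme4", "profile")) {
  engine <- match.arg(engine)
  if (!outcome %in% names(data)) {
    stop(sprintf("outcome column '%s' not in data", outcome), call. = FALSE)
  }
  if (!subject %in% names(data)) {
    stop(sprintf("subject column '%s' not in data", subject), call. = FALSE)
  }
  subj <- data[[subject]]
  if (length(unique(subj)) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  if (min(table(subj)) < 2L) {
    stop("every subject needs at least 2 measurements", call. = FALSE)
  }
  X <- fixed_design(data, fixed)
  y <- as.numeric(data[[outcome]])
  if (engine == "profile") {
    f <- lmm_profile_fit(y, X, subj)
    coefs <- data.frame(estimate = f$beta, se = f$se, tstat = f$tstat,
                        row.names = colnames(X))
    res <- list(coefficients = coefs, sigma_b = f$sigma_b,
                sigma_eps = f$sigma_eps, logLik = f$logLik)
  } else {
    fml <- stats::as.formula(sprintf(
      "%s ~ %s + (1 | %s)", outcome, paste(fixed, collapse = " + "),
      subject))
    m <- lme4::lmer(fml, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
    beta <- lme4::fixef(m)
    se <- sqrt(diag(as.matrix(stats::vcov(m))))
    vc <- as.data.frame(lme4::VarCorr(m))
    coefs <- data.frame(estimate = unname(beta), se = unname(se),
                        tstat = unname(ifelse(se > 0, beta / se, 0)),
                        row.names = names(beta))
    res <- list(coefficients = coefs,
                sigma_b = vc$sdcor[vc$grp == subject],
                sigma_eps = vc$sdcor[vc$grp == "Residual"],
                logLik = as.numeric(stats::logLik(m)))
  }
  res$engine <- engine
  res$outcome <- outcome
  res$fixed <- fixed
  res$subject <- subject
  res$n_obs <- length(y)
  res$n_subjects <- length(unique(subj))
  structure(res, class = "smg_lmm")
}

#' @export
print.smg_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (ML, engine %s): %s ~ %s + (1 | %s)\n",
              x$engine, x$outcome, paste(x$fixed, collapse = " + "),
              x$subject))
  print(round(x$coefficients, 4))
  cat(sprintf("sigma_b = %.4g, sigma_eps = %.4g, logLik = %.4g  (%d obs, %d subjects)\n",
              x$sigma_b, x$sigma_eps, x$logLik, x$n_obs, x$n_subjects))
  invisible(x)
}

#' @export
coef.smg_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' @export
summary.smg_lmm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Permutation p-value for a fixed effect of the mixed model
#'
#' Tests one fixed-effect coefficient by permuting the tested covariate's
#' values within each subject (all other columns held fixed), refitting
#' the model, and ranking the observed t-ratio (estimate / SE) among the
#' permuted ones. Within-subject exchange preserves the random-intercept
#' structure of the data. The add-one rule
#' `p = (1 + #extreme) / (1 + n_permutations)` guarantees a valid p-value
#' with floor `1/(n_permutations + 1)`.
#'
#' @param data data frame of measurements.
#' @param outcome,fixed,subject model specification as in [fit_lmm()].
#' @param test name of the tested covariate (must appear in `fixed`).
#' @param alternative `"two.sided"` (|t| comparison), `"greater"` or
#'   `"less"` (signed one-sided comparison).
#' @param n_permutations number of permuted samples (default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param engine fitting engine for observed and permuted fits (default
#'   the fast `"profile"` fitter; `"lme4"` gives the same statistics more
#'   slowly).
#' @return an object of class `smg_permtest`: list with `p_value`,
#'   `observed` (t-ratio), `estimate`, `permuted` (vector of permuted
#'   t-ratios), `alternative`, `n_permutations` and the observed
#'   [fit_lmm()] fit.
#' @export
permutation_pvalue <- function(data, outcome, fixed, test,
                               subject = "subject",
                               alternative = c("two.sided", "greater",
                                               "less"),
                               n_permutations = 1000L, seed = 1L,
                               engine = c("profile", "lme4")) {
  alternative <- match.arg(alternative)
  engine <- match.arg(engine)
  stopifnot(n_permutations >= 1L)
  if (!test %in% fixed) {
    stop(sprintf("tested covariate '%s' must be among the fixed effects",
                 test), call. = FALSE)
  }
  subj <- data[[subject]]
  groups <- split(seq_along(subj), subj)
  permutable <- vapply(groups, function(ix) {
    length(unique(data[[test]][ix])) > 1L
  }, logical(1L))
  if (!any(permutable)) {
    stop(sprintf(
      "covariate '%s' is constant within every subject and cannot be permuted",
      test), call. = FALSE)
  }
  fit_obs <- fit_lmm(data, outcome, fixed, subject, engine = engine)
  t_obs <- fit_obs$coefficients[test, "tstat"]
  perm_data <- data
  t_perm <- numeric(n_permutations)
  with_substream(seed, "permutation", 0L, {
    for (b in seq_len(n_permutations)) {
      xcol <- data[[test]]
      for (ix in groups) {
        xcol[ix] <- xcol[ix][sample.int(length(ix))]
      }
      perm_data[[test]] <- xcol
      fb <- fit_lmm(perm_data, outcome, fixed, subject, engine = engine)
      t_perm[b] <- fb$coefficients[test, "tstat"]
    }
  })
  extreme <- switch(alternative,
                    two.sided = sum(abs(t_perm) >= abs(t_obs)),
                    greater = sum(t_perm >= t_obs),
                    less = sum(t_perm <= t_obs))
  structure(list(
    p_value = (1 + extreme) / (1 + n_permutations),
    observed = t_obs,
    estimate = fit_obs$coefficients[test, "estimate"],
    permuted = t_perm,
    alternative = alternative,
    n_permutations = n_permutations,
    test = test, fit = fit_obs
  ), class = "smg_permtest")
}

#' @export
print.smg_permtest <- function(x, ...) {
  cat(sprintf("Permutation test of '%s' (%s, %d permutations)\n",
              x$test, x$alternative, x$n_permutations))
  cat(sprintf("  estimate = %.4g, t = %.3f, p = %.4g\n",
              x$estimate, x$observed, x$p_value))
  invisible(x)
}
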