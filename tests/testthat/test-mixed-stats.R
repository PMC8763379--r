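test_that("normalized time maps each subject's span onto [0, 1]", {
  expect_equal(normalized_time(c(0, 30, 60), rep("a", 3)), c(0, 0.5, 1))
  out <- normalized_time(c(5, 10, 0, 40), c("a", "a", "b", "b"))
  expect_equal(out, c(0, 1, 0, 1))
  expect_error(normalized_time(c(3, 3), c("a", "a")), "distinct")
})

test_that("noiseless data recovers the generating coefficients", {
  cfg <- outcome_gen_config(n_subjects = 4, n_measurements = 6,
                            beta0 = 90, beta1 = 3, sigma_b = 0,
                            sigma_eps = 1e-8, seed = 2)
  tab <- generate_outcomes(cfg)
  for (eng in c("lme4", "profile")) {
    fit <- fit_lmm(tab, "Y", "phase", engine = eng)
    expect_equal(unname(coef(fit)), c(90, 3), tolerance = 1e-5)
  }
})

test_that("with no subject variance the fit reduces to OLS", {
  cfg <- outcome_gen_config(n_subjects = 6, n_measurements = 6,
                            sigma_b = 0, sigma_eps = 1, seed = 7)
  tab <- generate_outcomes(cfg)
  fit <- fit_lmm(tab, "Y", "phase", engine = "profile")
  ols <- coef(lm(Y ~ phase, data = tab))
  # balanced design: the GLS and OLS fixed effects coincide
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
})

test_that("profile engine agrees with lme4 on random datasets", {
  for (s in 1:8) {
    cfg <- outcome_gen_config(n_subjects = sample(4:9, 1),
                              n_measurements = sample(4:8, 1),
                              beta1 = runif(1, -3, 3),
                              sigma_b = runif(1, 0, 3),
                              sigma_eps = runif(1, 0.3, 2), seed = 100 + s)
    tab <- generate_outcomes(cfg)
    tab$time_norm <- normalized_time(tab$time_min, tab$subject)
    f1 <- fit_lmm(tab, "Y", c("phase"), engine = "lme4")
    f2 <- fit_lmm(tab, "Y", c("phase"), engine = "profile")
    expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
                 tolerance = 1e-5)
    expect_equal(f2$coefficients$se, f1$coefficients$se, tolerance = 1e-4)
    expect_equal(f2$logLik, f1$logLik, tolerance = 1e-6)
    expect_equal(f2$sigma_eps, f1$sigma_eps, tolerance = 1e-4)
    expect_equal(f2$sigma_b, f1$sigma_b, tolerance = 1e-3)
  }
})

test_that("singular designs fail naming the collinear column", {
  cfg <- outcome_gen_config(seed = 3)
  tab <- generate_outcomes(cfg)
  tab$phase2 <- tab$phase
  expect_error(fit_lmm(tab, "Y", c("phase", "phase2")), "phase2")
  expect_error(fit_lmm(tab, "Y", "nope"), "nope")
  one <- tab[tab$subject == "S01", ]
  expect_error(fit_lmm(one, "Y", "phase"), "2 subjects")
})

test_that("permutation p-values are valid, bounded and deterministic", {
  cfg <- outcome_gen_config(n_subjects = 6, beta1 = 50, sigma_b = 1,
                            sigma_eps = 0.5, seed = 4)
  tab <- generate_outcomes(cfg)
  # overwhelming effect: the add-one floor is attained
  pt <- permutation_pvalue(tab, "Y", "phase", "phase",
                           alternative = "greater",
                           n_permutations = 99, seed = 1)
  expect_equal(pt$p_value, 1 / 100)
  pt2 <- permutation_pvalue(tab, "Y", "phase", "phase",
                            alternative = "greater",
                            n_permutations = 99, seed = 1)
  expect_identical(pt$permuted, pt2$permuted)
  expect_true(pt$p_value >= 1 / 100 && pt$p_value <= 1)

  # constant outcome: every permutation ties, p = 1
  tab$Y <- 5
  pt3 <- permutation_pvalue(tab, "Y", "phase", "phase",
                            n_permutations = 50, seed = 2)
  expect_equal(pt3$p_value, 1)

  # unpermutable covariate
  tab$flat <- as.numeric(tab$subject == "S01")
  expect_error(permutation_pvalue(tab, "Y", c("flat"), "flat",
                                  n_permutations = 10),
               "constant within every subject")
})

test_that("null p-values are roughly uniform and power rises with effect", {
  p_at_beta <- function(beta1, n_sims, n_perm = 60) {
    vapply(seq_len(n_sims), function(s) {
      tab <- generate_outcomes(outcome_gen_config(
        n_subjects = 8, n_measurements = 6, beta0 = 90, beta1 = beta1,
        sigma_b = 2, sigma_eps = 1, seed = 5000 + 17 * s + round(97 * beta1)))
      permutation_pvalue(tab, "Y", "phase", "phase",
                         alternative = "greater",
                         n_permutations = n_perm,
                         seed = s)$p_value
    }, numeric(1))
  }
  p0 <- p_at_beta(0, 60)
  expect_gt(mean(p0), 0.35) # coarse uniformity checks under the null
  expect_lt(mean(p0), 0.65)
  power <- c(mean(p0 <= 0.05),
             mean(p_at_beta(1.5, 60) <= 0.05),
             mean(p_at_beta(3, 60) <= 0.05))
  expect_true(all(diff(power) >= -0.05)) # monotone up to simulation noise
  expect_gt(power[3], 0.9)
})

test_that("phase and normalized time are collinear in a two-phase day", {
  des <- experiment2_times()
  tn <- normalized_time(des$time_min, rep("s", nrow(des)))
  expect_gt(abs(cor(des$phase, tn)), 0.9)
})
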