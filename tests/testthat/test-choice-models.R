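test_that("design columns are exact algebraic functions of the angles", {
  tr <- data.frame(theta_T = c(5, 3, 3, 2, -2),
                   theta_D = c(-5, -2, 2, 2, -2))
  X <- build_design(tr, candidate_predictors())
  expect_equal(unname(X[1, "consistency"]), 5 * abs(5 - (-5)))   # = 50
  expect_equal(attr(X, "report_divisor")[["consistency"]], 10)
  expect_equal(unname(X[4, "consistency"]), 0)           # theta_T == theta_D
  expect_equal(unname(X[, "congruency"]), c(0, 0, 1, 1, 1))
  expect_equal(unname(X[, "theta_TxD"]), tr$theta_T * tr$theta_D)
  expect_equal(unname(X[, "theta_TxabsD"]), tr$theta_T * abs(tr$theta_D))
  expect_equal(unname(X[, "abs_theta_D"]), abs(tr$theta_D))
  expect_error(build_design(tr, "A_x_theta_T"), "attention")
  expect_error(build_design(tr, "nonsense"), "unknown predictor")
})

test_that("reported coefficients rescale the consistency terms by 10", {
  tr <- gen_eq4_choices(4000, c(0, 0.4, -0.05, -0.02), seed = 71)
  X <- build_design(tr, c("theta_T", "theta_D", "consistency"))
  fit <- fit_choice_glm(X, tr$choice)
  rep <- report_coefficients(fit, X)
  expect_equal(rep[["consistency"]], 10 * fit$coefficients[["consistency"]])
  expect_equal(rep[["theta_T"]], fit$coefficients[["theta_T"]])
})

test_that("regression recovers the generating coefficients within 2 SE", {
  beta <- c(0, 0.5, -0.05, -0.02)
  tr <- gen_eq4_choices(20000, beta, seed = 72)
  X <- build_design(tr, c("theta_T", "theta_D", "consistency"))
  fit <- fit_choice_glm(X, tr$choice)
  expect_true(all(abs(fit$coefficients - beta) < 2 * fit$se))
  expect_lte(fit$loglik, 0)
})

test_that("coin-flip choices produce null coefficients", {
  tr <- generate_trials("exp1", 5000, seed = 73)
  set.seed(74)
  tr$choice <- rbinom(5000, 1, 0.5)
  X <- build_design(tr, c("theta_T", "theta_D", "consistency"))
  fit <- fit_choice_glm(X, tr$choice)
  expect_true(all(abs(fit$coefficients) < 3 * fit$se))
})

test_that("collinear designs raise an error naming the columns", {
  tr <- generate_trials("exp1", 500, seed = 75)
  set.seed(76)
  tr$choice <- rbinom(500, 1, 0.5)
  X <- build_design(tr, c("theta_T", "theta_D"))
  X <- cbind(X, dup = X[, "theta_T"])
  expect_error(fit_choice_glm(X, tr$choice), "dup")
})

test_that("separation triggers a flagged penalized refit", {
  X <- cbind(intercept = 1, x = c(-(10:1), 1:10))
  y <- as.integer(X[, "x"] > 0)
  fit <- fit_choice_glm(X, y)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
  expect_gt(fit$coefficients[["x"]], 0)
})

test_that("in-sample log-likelihood is monotone in model nesting", {
  tr <- gen_eq4_choices(6000, c(0.1, 0.4, -0.06, -0.015), seed = 77)
  preds <- list(character(0), "theta_T", c("theta_T", "theta_D"),
                c("theta_T", "theta_D", "consistency"))
  lls <- vapply(preds, function(p) {
    fit_choice_glm(build_design(tr, p), tr$choice)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-8))
})

test_that("stepwise selection recovers the generating predictor set", {
  tr <- gen_eq4_choices(50000, c(0, 0.5, -0.05, -0.02), seed = 78)
  expect_setequal(stepwise_select(tr),
                  c("theta_T", "theta_D", "consistency"))
  # no interaction in the generator: consistency must not be retained
  tr0 <- gen_eq4_choices(50000, c(0, 0.5, -0.05, 0), seed = 79)
  expect_false("consistency" %in% stepwise_select(tr0))
  # pure noise: with a 0.05 entry threshold over 7 candidates a single
  # false inclusion is expected on ~30% of runs, so allow at most one
  trn <- generate_trials("exp1", 5000, seed = 80)
  set.seed(81)
  trn$choice <- rbinom(5000, 1, 0.5)
  expect_lte(length(stepwise_select(trn)), 1)
})

test_that("binned sensitivity uses six equal-width distracter bins", {
  tr <- gen_norm_choices(40000, r = 1.5, tau = 0.4, rho = 0, seed = 82)
  X <- build_design(tr, c("theta_T", "theta_D", "consistency"))
  fit <- fit_choice_glm(X, tr$choice)
  bs <- binned_sensitivity(tr, fit, X)
  expect_equal(nrow(bs), 6)
  expect_equal(bs$bin_mid, seq(-10 + 10 / 6, 10 - 10 / 6, by = 10 / 3))
  # contextual variability: extreme distracter bins have shallower slopes
  expect_gt(mean(bs$slope[3:4]), mean(bs$slope[c(1, 6)]) + 0.01)
  # model-predicted slopes reproduce the same pattern
  expect_gt(mean(bs$model_slope[3:4]), mean(bs$model_slope[c(1, 6)]))
})

test_that("slopes are flat across distracter bins without normalization", {
  tr <- gen_norm_choices(30000, r = 1.5, tau = 0, rho = 0, seed = 83)
  bs <- binned_sensitivity(tr)
  z <- (bs$slope - mean(bs$slope)) / bs$se
  expect_true(all(abs(z) < 3))
})

test_that("cross-validated log-likelihood is deterministic and proper", {
  tr <- gen_eq4_choices(3000, c(0, 0.4, -0.05, -0.02), seed = 84)
  cv1 <- crossval_loglik(tr, c("theta_T", "theta_D", "consistency"),
                         k = 5, seed = 9)
  cv2 <- crossval_loglik(tr, c("theta_T", "theta_D", "consistency"),
                         k = 5, seed = 9)
  expect_identical(cv1, cv2)
  expect_lte(cv1, 0)
})

test_that("the generating model wins the cross-validated comparison", {
  wins <- vapply(1:20, function(s) {
    tr <- gen_eq4_choices(1500, c(0, 0.4, -0.05, -0.02), seed = 100 + s)
    full <- crossval_loglik(tr, c("theta_T", "theta_D", "consistency"),
                            k = 5, seed = s)
    mis <- crossval_loglik(tr, c("theta_D", "congruency"), k = 5, seed = s)
    full - mis
  }, numeric(1))
  expect_gt(mean(wins), 0)
  expect_gt(mean(wins > 0), 0.8)
})

test_that("BMS exceedance is symmetric for identical evidences", {
  lme <- matrix(rep(c(-100, -100, -100), each = 15), 15)
  res <- bms_exceedance(lme, seed = 1)
  expect_equal(sum(res$exceedance), 1, tolerance = 1e-12)
  expect_true(all(abs(res$exceedance - 1 / 3) < 0.01))
  expect_equal(sum(res$expected_freq), 1, tolerance = 1e-10)
  expect_error(bms_exceedance(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("a 10-nat dominant model attains near-certain exceedance", {
  lme <- cbind(rep(-500, 20), rep(-510, 20))
  res <- bms_exceedance(lme, seed = 2)
  expect_gt(res$exceedance[1], 0.99)
  # direct Dirichlet Monte-Carlo oracle from the fitted alpha
  set.seed(3)
  draws <- cbind(rgamma(2e5, res$alpha[1]), rgamma(2e5, res$alpha[2]))
  oracle <- mean(draws[, 1] > draws[, 2])
  expect_lt(abs(res$exceedance[1] - oracle), 0.01)
})

test_that("BMS ranking is invariant to shifting all evidences", {
  set.seed(4)
  lme <- matrix(rnorm(30, -200, 5), 10, 3)
  r1 <- bms_exceedance(lme, seed = 5)
  r2 <- bms_exceedance(lme + 123.4, seed = 5)
  expect_equal(r1$exceedance, r2$exceedance, tolerance = 1e-9)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-6)
})
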