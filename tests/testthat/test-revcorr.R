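# Shared image-level fixture: rendered target/distracter ensembles and
# their z-scored energies, built once per test run.
revcorr_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- test_spec(ppd = 8)
    bank <- build_filter_bank(spec)
    tr <- generate_trials("exp1", 1200, seed = 121)
    eT <- energy_profile(render_ensemble(tr, spec, "target"), bank)
    eD <- energy_profile(render_ensemble(tr, spec, "distracter"), bank)
    cache <<- list(spec = spec, bank = bank, tr = tr,
                   eT = eT, eD = eD,
                   zT = zscore_energies(eT), zD = zscore_energies(eD))
    cache
  }
})

test_that("energy-template observer leaves a flat distracter kernel while
           the target kernel tracks the template", {
  fx <- revcorr_fixture()
  ors <- fx$bank$orientations_deg
  tmpl0 <- (ors / 25) * exp(-ors^2 / 50)
  tmpl <- tmpl0 * 1.5 / sd(as.vector(fx$zT %*% tmpl0))
  pars <- observer_params("energy_template", template = tmpl)
  sim <- simulate_energy_observer(fx$tr, fx$zT, pars, seed = 122)
  k <- decision_kernel(sim$choice, fx$zT, fx$zD, ors)
  expect_equal(nrow(k), 181)
  expect_true(all(k$se > 0))
  expect_gt(cor(k$beta, tmpl), 0.6)
  expect_gte(mean(abs(k$beta_distracter) < 2 * k$se_distracter), 0.95)
})

test_that("ground-truth kernel separates CW from CCW and tapers beyond
           the signal range", {
  fx <- revcorr_fixture()
  ors <- fx$bank$orientations_deg
  k <- decision_kernel(as.integer(fx$tr$theta_T > 0), fx$zT,
                       orientations_deg = ors)
  expect_gt(mean(k$beta[ors > 0 & ors <= 10]), 0)
  expect_lt(mean(k$beta[ors < 0 & ors >= -10]), 0)
  peak <- max(abs(k$beta[abs(ors) <= 10]))
  expect_lt(mean(abs(k$beta[abs(ors) >= 30])), peak / 3)
})

test_that("choices unrelated to the stimuli give a null kernel", {
  # per-bin coverage at 2 SE has expectation ~0.954 but fluctuates several
  # points per draw because neighbouring bins are correlated; average over
  # independent choice vectors
  # (measured expectation ~0.95 with SD ~0.06 per draw at 1200 trials,
  # so the bound is set to catch real structure, not nominal coverage)
  fx <- revcorr_fixture()
  set.seed(123)
  cover <- vapply(1:8, function(i) {
    ch <- rbinom(nrow(fx$zT), 1, 0.5)
    k <- decision_kernel(ch, fx$zT,
                         orientations_deg = fx$bank$orientations_deg)
    mean(abs(k$beta) < 2 * k$se)
  }, numeric(1))
  expect_gte(mean(cover), 0.9)
})

test_that("kernel estimates converge toward the template with sample size", {
  fx <- revcorr_fixture()
  ors <- fx$bank$orientations_deg
  tmpl0 <- (ors / 25) * exp(-ors^2 / 50)
  tmpl <- tmpl0 * 1.5 / sd(as.vector(fx$zT %*% tmpl0))
  pars <- observer_params("energy_template", template = tmpl)
  sim <- simulate_energy_observer(fx$tr, fx$zT, pars, seed = 124)
  fit_mse <- function(n) {
    k <- decision_kernel(sim$choice[1:n], fx$zT[1:n, ], orientations_deg = ors)
    scale <- sum(k$beta * tmpl) / sum(tmpl^2)
    mean((k$beta - scale * tmpl)^2) / max(scale, 1e-6)^2
  }
  expect_lt(fit_mse(1200), fit_mse(300))
})

test_that("uncentered SVD conserves variance and reconstructs exactly", {
  fx <- revcorr_fixture()
  M <- rbind(fx$eT$energy, fx$eD$energy)
  dec <- svd_profiles(M)
  expect_equal(sum(dec$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(dec$variance_fraction >= 0))
  recon <- dec$scores %*% t(dec$components)
  expect_equal(recon, M, tolerance = 1e-8, ignore_attr = TRUE)
  # components orthonormal
  G <- t(dec$components) %*% dec$components
  expect_equal(G, diag(ncol(G)), tolerance = 1e-10, ignore_attr = TRUE)
  # rank-1 matrix puts all variance on the first component (and warns)
  expect_warning(r1 <- svd_profiles(outer(1:5, sin(1:181))),
                 "rank deficient")
  expect_equal(r1$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("the tilt component is antisymmetric and sign-aligned to CW", {
  fx <- revcorr_fixture()
  M <- rbind(fx$eT$energy, fx$eD$energy)
  thetas <- c(fx$tr$theta_T, fx$tr$theta_D)
  dec <- svd_profiles(M)
  expect_gte(sum(dec$variance_fraction[1:4]), 0.9)
  sel <- select_tilt_component(dec, thetas)
  expect_lte(sel$index, 4)
  # odd part dominates the component
  v <- sel$component
  odd <- (v - rev(v)) / 2
  expect_gte(sum(odd^2) / sum(v^2), 0.8)
  expect_gt(mean(sel$scores[thetas > 0]), 0)
  expect_gt(mean(sel$scores[thetas > 0] > 0), 0.5)
  # non-selected retained components correlate less with tilt
  expect_true(all(abs(sel$correlations[-sel$index]) <=
                    abs(sel$correlations[sel$index])))
  # selection fails cleanly when scores carry no tilt information
  expect_error(select_tilt_component(dec, sample(thetas)),
               "no retained component")
})

test_that("component-score regression mirrors the angular regression", {
  fx <- revcorr_fixture()
  ors <- fx$bank$orientations_deg
  tmpl0 <- (ors / 25) * exp(-ors^2 / 50)
  tmpl <- tmpl0 * 1.5 / sd(as.vector(fx$zT %*% tmpl0))
  pars <- observer_params("energy_template", template = tmpl)
  sim <- simulate_energy_observer(fx$tr, fx$zT, pars, seed = 125)
  dec <- svd_profiles(rbind(fx$eT$energy, fx$eD$energy))
  sel <- select_tilt_component(dec, c(fx$tr$theta_T, fx$tr$theta_D))
  n <- nrow(fx$tr)
  fit <- component_regression(sim, sel$scores[seq_len(n)],
                              sel$scores[n + seq_len(n)])
  expect_gt(fit$coefficients[["U_T"]] - 2 * fit$se[["U_T"]], 0)
  # a coin-flip outcome produces null component effects
  set.seed(126)
  null <- sim
  null$choice <- rbinom(n, 1, 0.5)
  fit0 <- component_regression(null, sel$scores[seq_len(n)],
                               sel$scores[n + seq_len(n)])
  expect_true(all(abs(fit0$coefficients) < 3 * fit0$se))
})

test_that("component regression recovers known score coefficients", {
  fx <- revcorr_fixture()
  dec <- svd_profiles(rbind(fx$eT$energy, fx$eD$energy))
  sel <- select_tilt_component(dec, c(fx$tr$theta_T, fx$tr$theta_D))
  n <- nrow(fx$tr)
  uT <- sel$scores[seq_len(n)]
  uD <- sel$scores[n + seq_len(n)]
  sdT <- sd(uT)
  beta <- c(0, 2 / sdT, -0.3 / sdT, -0.3 / sdT^2)
  y <- beta[1] + beta[2] * uT + beta[3] * uD + beta[4] * uT * abs(uT - uD)
  set.seed(127)
  sim <- fx$tr
  sim$choice <- as.integer(runif(n) < plogis(y))
  fit <- component_regression(sim, uT, uD)
  expect_true(all(abs(fit$coefficients - beta) < 2.5 * fit$se))
})
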