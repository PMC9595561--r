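#' Contextual-normalization transducer
#'
#' Maps the decision input `x = theta_T` to a decision variable
#' `y = (x - rho * mu) / (r + tau * sigma)` where `mu = (theta_T +
#' theta_D) / 2` is the context mean and `sigma = |theta_T - theta_D|` the
#' context variability. `rho` shifts the psychometric function along the
#' input axis (positive rho = repulsion from the distracter); `tau`
#' rescales its slope with context variability (positive tau = shallower
#' slope when target and distracter disagree, i.e. a consistency bias);
#' `r` is the baseline denominator setting overall sensitivity.
#'
#' @param theta_T,theta_D Boundary-relative orientations (degrees).
#' @param params List with `r` (> 0), `tau`, `rho`.
#' @return List of vectors `x`, `mu`, `sigma`, `y`, `p_cw`.
#' @export
transduce <- function(theta_T, theta_D, params) {
  mu <- (theta_T + theta_D) / 2
  sigma <- abs(theta_T - theta_D)
  denom <- params$r + params$tau * sigma
  if (any(denom <= 0)) {
    stop("transduce: denominator r + tau * sigma must be positive",
         call. = FALSE)
  }
  y <- (theta_T - params$rho * mu) / denom
  list(x = theta_T, mu = mu, sigma = sigma, y = y,
       p_cw = stats::plogis(y))
}

#' Negative log-likelihood of the normalization model
#'
#' Bernoulli negative log-likelihood of the observed choices under the
#' transducer, with probabilities clipped to `[1e-9, 1 - 1e-9]` so the
#' value stays finite at extreme decision variables. Invalid parameter
#' regions (non-positive denominator for some observed trial) return a
#' large finite penalty that grows with the violation, which keeps
#' derivative-free optimizers on track.
#'
#' @param params List with `r`, `tau`, `rho` — or, for the attention
#'   variant, `r_valid`, `r_neutral`, `r_invalid`, `tau`, `rho`.
#' @param trials Trial table with `choice` filled (and `cue_condition` for
#'   the attention variant).
#' @return Scalar negative log-likelihood (>= 0 for valid parameters).
#' @export
norm_nll <- function(params, trials) {
  if (!is.null(params$r_valid)) {
    r_vec <- r_by_condition(params, trials$cue_condition)
  } else {
    r_vec <- rep(params$r, nrow(trials))
  }
  sigma <- abs(trials$theta_T - trials$theta_D)
  denom <- r_vec + params$tau * sigma
  if (any(denom <= 1e-3)) {
    return(1e6 + 1e3 * sum(pmax(0, 1e-3 - denom)))
  }
  mu <- (trials$theta_T + trials$theta_D) / 2
  y <- (trials$theta_T - params$rho * mu) / denom
  p <- pmin(pmax(stats::plogis(y), 1e-9), 1 - 1e-9)
  -sum(ifelse(trials$choice == 1, log(p), log(1 - p)))
}

r_by_condition <- function(params, cue_condition) {
  r <- c(valid = params$r_valid, neutral = params$r_neutral,
         invalid = params$r_invalid)
  if (any(!cue_condition %in% names(r))) {
    stop("norm_nll: attention variant needs cue_condition in ",
         "{valid, neutral, invalid}", call. = FALSE)
  }
  unname(r[cue_condition])
}

#' Fit the normalization model by maximum likelihood
#'
#' Minimizes the negative log-likelihood over seeded multistart
#' Nelder-Mead runs on transformed parameters (`log r` enforces r > 0; the
#' denominator constraint is a soft barrier inside [norm_nll()]). Variants:
#' \describe{
#'   \item{full}{3 parameters (r, tau, rho).}
#'   \item{reduced}{tau = rho = 0; a plain logistic psychometric function
#'     of `theta_T` with slope 1/r, fitted by 1-D optimization.}
#'   \item{attention}{5 parameters — r varies by cue condition
#'     (r_valid, r_neutral, r_invalid) while tau and rho are shared.}
#' }
#'
#' @param trials Trial table with `choice` filled.
#' @param variant `"full"`, `"reduced"` or `"attention"`.
#' @param n_restarts Number of random starts (>= 1).
#' @param seed Integer seed for the starts.
#' @return A `norm_fit`: `params` (named list), `nll`, `variant`,
#'   `converged`, `n_restarts`, `restart_nlls`.
#' @export
fit_norm_model <- function(trials, variant = c("full", "reduced",
                                               "attention"),
                           n_restarts = 10, seed = 1L) {
  variant <- match.arg(variant)
  if (nrow(trials) < 200) {
    stop("fit_norm_model: need at least 200 trials", call. = FALSE)
  }
  if (variant == "reduced") {
    obj <- function(logr) {
      norm_nll(list(r = exp(logr), tau = 0, rho = 0), trials)
    }
    opt <- stats::optimize(obj, c(-4, 5), tol = 1e-8)
    return(structure(list(
      params = list(r = exp(opt$minimum), tau = 0, rho = 0),
      nll = opt$objective, variant = variant, converged = TRUE,
      n_restarts = 1L, restart_nlls = opt$objective, seed = seed),
      class = "norm_fit"))
  }

  unpack <- if (variant == "full") {
    function(v) list(r = exp(v[1]), tau = v[2], rho = v[3])
  } else {
    function(v) list(r_valid = exp(v[1]), r_neutral = exp(v[2]),
                     r_invalid = exp(v[3]), tau = v[4], rho = v[5])
  }
  npar <- if (variant == "full") 3L else 5L
  obj <- function(v) norm_nll(unpack(v), trials)

  set.seed(seed)
  starts <- lapply(seq_len(n_restarts), function(i) {
    logr <- stats::runif(if (variant == "full") 1 else 3, log(0.5), log(10))
    c(logr, stats::runif(1, 0, 0.5), stats::runif(1, -0.5, 0.5))
  })
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  })
  nlls <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(nlls)]]
  if (all(vapply(fits, `[[`, integer(1), "convergence") != 0)) {
    stop("fit_norm_model: no restart converged; nll range ",
         paste(round(range(nlls), 2), collapse = " - "), call. = FALSE)
  }
  structure(list(params = unpack(best$par), nll = best$value,
                 variant = variant,
                 converged = best$convergence == 0,
                 n_restarts = n_restarts, restart_nlls = nlls,
                 seed = seed),
            class = "norm_fit")
}

#' @export
print.norm_fit <- function(x, ...) {
  cat("norm_fit (", x$variant, "), nll = ", round(x$nll, 2), "\n", sep = "")
  pp <- unlist(x$params[!vapply(x$params, is.null, logical(1))])
  print(round(pp, 4))
  invisible(x)
}

#' Regression signature of simulated normalization-model choices
#'
#' Simulates choices on a trial set from given transducer parameters and
#' fits the consistency-bias regression (or its attention extension) to
#' the simulated choices, returning the regression fit. Used to map
#' transducer parameters onto regression-coefficient patterns and to sweep
#' tau or rho grids.
#'
#' @param params List with `r`, `tau`, `rho` (lapse optional).
#' @param trials Trial table (choices are overwritten).
#' @param predictors Predictor ids for the regression (default the
#'   consistency-bias set).
#' @param seed Integer seed for the simulated choices.
#' @return A `choice_glm` fit, with the design as attribute `design`.
#' @export
simulate_pattern <- function(params, trials,
                             predictors = c("theta_T", "theta_D",
                                            "consistency"),
                             seed = 1L) {
  obs <- observer_params("parametric", r = params$r, tau = params$tau,
                         rho = params$rho,
                         lapse = params$lapse %||% 0)
  sim <- simulate_parametric_observer(trials, obs, seed = seed)
  X <- build_design(sim, predictors)
  fit <- fit_choice_glm(X, sim$choice)
  attr(fit, "design") <- X
  fit
}

#' Sweep tau or rho and collect regression coefficients
#'
#' @param trials Trial table.
#' @param base_params Baseline `r`, `tau`, `rho`.
#' @param tau_grid,rho_grid Values to sweep (one of them, the other held
#'   at the baseline).
#' @param seed Integer seed. The same seed drives the simulated choices at
#'   every grid point (common random numbers), so differences between
#'   adjacent grid points reflect the parameter change rather than
#'   independent choice noise.
#' @return Data frame with the swept value and the fitted `beta` for each
#'   regression coefficient.
#' @export
sweep_pattern <- function(trials, base_params, tau_grid = NULL,
                          rho_grid = NULL, seed = 1L) {
  stopifnot(xor(is.null(tau_grid), is.null(rho_grid)))
  grid <- if (!is.null(tau_grid)) tau_grid else rho_grid
  which_par <- if (!is.null(tau_grid)) "tau" else "rho"
  out <- lapply(seq_along(grid), function(i) {
    p <- base_params
    p[[which_par]] <- grid[i]
    fit <- simulate_pattern(p, trials, seed = seed)
    data.frame(param = which_par, value = grid[i],
               t(fit$coefficients), check.names = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-validated likelihood of a normalization-model variant
#'
#' Stratified k-fold: the variant is fitted on each training fold and the
#' held-out choices are scored under the fitted transducer.
#'
#' @inheritParams fit_norm_model
#' @param k Number of folds.
#' @return Scalar summed held-out log-likelihood.
#' @export
crossval_norm_loglik <- function(trials, variant = "full", k = 10,
                                 n_restarts = 5, seed = 1L) {
  folds <- stratified_folds(trials$choice, k, seed)
  total <- 0
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_norm_model(trials[!test, , drop = FALSE], variant,
                          n_restarts = n_restarts, seed = seed + f)
    total <- total - norm_nll(fit$params, trials[test, , drop = FALSE])
  }
  total
}

#' Compare normalization-model variants across simulated subjects
#'
#' Computes each subject's cross-validated log-likelihood under every
#' variant and feeds the resulting evidence matrix to random-effects
#' Bayesian model selection.
#'
#' @param trials_by_subject List of trial tables with choices.
#' @param variants Character vector of variant names.
#' @param k Folds for the cross-validation.
#' @param n_restarts Restarts per training-fold fit.
#' @param seed Integer seed.
#' @return A `bms_result` with the evidence matrix attached as
#'   `attr(, "lme")`.
#' @export
compare_norm_models <- function(trials_by_subject,
                                variants = c("full", "reduced"),
                                k = 10, n_restarts = 5, seed = 1L) {
  stopifnot(length(variants) >= 2)
  lme <- matrix(NA_real_, length(trials_by_subject), length(variants),
                dimnames = list(NULL, variants))
  for (s in seq_along(trials_by_subject)) {
    for (v in seq_along(variants)) {
      lme[s, v] <- crossval_norm_loglik(trials_by_subject[[s]],
                                        variants[v], k = k,
                                        n_restarts = n_restarts,
                                        seed = seed + 97L * s)
    }
  }
  res <- bms_exceedance(lme, seed = seed)
  attr(res, "lme") <- lme
  res
}

#' Exclude simulated subjects performing at chance on either side
#'
#' Drops subjects whose accuracy on either probed side falls below the
#' threshold — the guard against observers that solve only one location.
#'
#' @param trials_by_subject List of trial tables with `choice`, `correct`
#'   and `probe_side`.
#' @param threshold Minimum per-side accuracy (default 0.55).
#' @return The list restricted to retained subjects, with the dropped
#'   indices in `attr(, "excluded")`.
#' @export
exclude_at_chance <- function(trials_by_subject, threshold = 0.55) {
  keep <- vapply(trials_by_subject, function(tr) {
    acc <- tapply(tr$correct, tr$probe_side, mean)
    all(acc >= threshold)
  }, logical(1))
  out <- trials_by_subject[keep]
  attr(out, "excluded") <- which(!keep)
  out
}
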