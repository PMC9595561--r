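#' Candidate predictors for the choice regressions
#'
#' The seven candidate predictors considered by the stepwise selection,
#' plus the attention interactions used in the cued experiment. Columns are
#' exact algebraic functions of the trial table:
#' \describe{
#'   \item{theta_T, theta_D}{boundary-relative orientations (degrees).}
#'   \item{abs_theta_D}{`|theta_D|`.}
#'   \item{congruency}{1 iff `sign(theta_T) == sign(theta_D)`.}
#'   \item{theta_TxD}{`theta_T * theta_D`.}
#'   \item{theta_TxabsD}{`theta_T * |theta_D|`.}
#'   \item{consistency}{`theta_T * |theta_T - theta_D|`; note the larger
#'     this value the LESS consistent target and distracter are, so a
#'     consistency bias appears as a negative coefficient.}
#'   \item{A_x_theta_T, A_x_theta_D, A_x_consistency}{interactions with the
#'     attention indicator `A` (-1 invalid, 0 neutral, +1 valid).}
#' }
#' @export
candidate_predictors <- function() {
  c("theta_T", "theta_D", "abs_theta_D", "congruency",
    "theta_TxD", "theta_TxabsD", "consistency")
}

#' Build a design matrix for a choice regression
#'
#' @param trials Trial table with at least `theta_T`, `theta_D` (and `A`
#'   when attention interactions are requested).
#' @param predictors Character vector of predictor ids (see
#'   [candidate_predictors()]); an intercept is always included.
#' @return A numeric matrix with named columns, attribute
#'   `report_divisor`: named vector of divisors used only when reporting
#'   coefficients so that unit changes are on comparable scales (10 for the
#'   consistency terms).
#' @export
build_design <- function(trials, predictors) {
  need_A <- any(grepl("^A_x_", predictors))
  if (need_A && (!"A" %in% names(trials) || anyNA(trials$A))) {
    stop("build_design: predictors involving A need an attention column ",
         "(cued design)", call. = FALSE)
  }
  tT <- trials$theta_T
  tD <- trials$theta_D
  cols <- list(intercept = rep(1, nrow(trials)))
  for (p in predictors) {
    cols[[p]] <- switch(
      p,
      theta_T = tT,
      theta_D = tD,
      abs_theta_D = abs(tD),
      congruency = as.numeric(sign(tT) == sign(tD)),
      theta_TxD = tT * tD,
      theta_TxabsD = tT * abs(tD),
      consistency = tT * abs(tT - tD),
      A_x_theta_T = trials$A * tT,
      A_x_theta_D = trials$A * tD,
      A_x_consistency = trials$A * tT * abs(tT - tD),
      stop("build_design: unknown predictor '", p, "'", call. = FALSE)
    )
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  div <- stats::setNames(rep(1, ncol(X)), colnames(X))
  div[colnames(X) %in% c("consistency", "A_x_consistency")] <- 10
  attr(X, "report_divisor") <- div
  X
}

#' Fit a binomial choice regression
#'
#' Maximum-likelihood GLM of binary choices on a design matrix. If the fit
#' separates (fitted probabilities collapse to 0/1), the model is refit
#' with a small ridge penalty and flagged.
#'
#' @param design Matrix from [build_design()] (includes the intercept).
#' @param choices 0/1 vector.
#' @param link `"logit"` or `"probit"`.
#' @return A `choice_glm` object: `coefficients`, `se`, `loglik`, `n`,
#'   `link`, `predictors`, `separation` flag.
#' @export
fit_choice_glm <- function(design, choices, link = c("logit", "probit")) {
  link <- match.arg(link)
  stopifnot(all(choices %in% c(0, 1)))
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("fit_choice_glm: collinear design; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, choices,
                   family = stats::binomial(link = link))
  )
  sep <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) ||
    any(abs(fit$coefficients) > 50)
  if (sep) {
    pen <- penalized_binomial(design, choices, link, lambda = 1e-3)
    beta <- pen$beta
    se <- pen$se
    ll <- pen$loglik
  } else {
    beta <- fit$coefficients
    eta <- as.vector(design %*% beta)
    p <- binomial_inv_link(eta, link)
    w <- fit$weights
    cov <- chol2inv(chol(crossprod(design * sqrt(w))))
    se <- sqrt(diag(cov))
    ll <- sum(stats::dbinom(choices, 1, pmin(pmax(p, 1e-12), 1 - 1e-12),
                            log = TRUE))
  }
  structure(list(coefficients = stats::setNames(beta, colnames(design)),
                 se = stats::setNames(se, colnames(design)),
                 loglik = ll, n = length(choices), link = link,
                 predictors = setdiff(colnames(design), "intercept"),
                 separation = sep),
            class = "choice_glm")
}

binomial_inv_link <- function(eta, link) {
  if (link == "logit") stats::plogis(eta) else stats::pnorm(eta)
}

# Ridge-penalized binomial regression by direct optimization; used as a
# flagged fallback when the unpenalized ML fit separates.
penalized_binomial <- function(X, y, link, lambda = 1e-3) {
  negll <- function(beta) {
    p <- pmin(pmax(binomial_inv_link(as.vector(X %*% beta), link),
                   1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p)) +
      lambda * sum(beta[-1]^2)
  }
  opt <- stats::optim(rep(0, ncol(X)), negll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  se <- tryCatch(sqrt(diag(solve(opt$hessian))),
                 error = function(e) rep(NA_real_, ncol(X)))
  p <- pmin(pmax(binomial_inv_link(as.vector(X %*% opt$par), link),
                 1e-12), 1 - 1e-12)
  list(beta = opt$par, se = se,
       loglik = sum(y * log(p) + (1 - y) * log(1 - p)))
}

#' @export
print.choice_glm <- function(x, ...) {
  cat("choice_glm (", x$link, " link), n = ", x$n,
      ", log-likelihood = ", round(x$loglik, 2),
      if (x$separation) " [penalized: separation]", "\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se,
               z = x$coefficients / x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Report coefficients on the comparable-units scale
#'
#' Divides the consistency-interaction coefficients' predictors by 10 for
#' reporting, i.e. multiplies those coefficients by 10, so that a unit
#' change in every reported predictor spans a comparable range. Fitting
#' always uses the raw columns.
#'
#' @param fit A `choice_glm`.
#' @param design The design matrix used to fit (for its divisor metadata).
#' @return Named vector of rescaled coefficients.
#' @export
report_coefficients <- function(fit, design) {
  div <- attr(design, "report_divisor")
  fit$coefficients * div[names(fit$coefficients)]
}

#' Stepwise forward/backward predictor selection
#'
#' Greedy knock-in / knock-out over the candidate set: repeatedly add the
#' candidate whose deviance chi-square test against the current model has
#' the smallest p-value below `p_enter`, then drop any retained predictor
#' whose removal test has p-value above `p_remove`, iterating to a
#' fixpoint. Degenerate data return the empty (intercept-only) set.
#'
#' @param trials Trial table with `choice` filled.
#' @param candidates Candidate predictor ids (default the 7-candidate set).
#' @param p_enter,p_remove Entry and removal thresholds (0.05 / 0.10).
#' @return Character vector of retained predictor ids.
#' @export
stepwise_select <- function(trials, candidates = candidate_predictors(),
                            p_enter = 0.05, p_remove = 0.10) {
  y <- trials$choice
  current <- character(0)
  ll_of <- function(preds) {
    fit_choice_glm(build_design(trials, preds), y)$loglik
  }
  ll_cur <- ll_of(current)
  repeat {
    changed <- FALSE
    # knock in
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      lls <- vapply(pool, function(p) ll_of(c(current, p)), numeric(1))
      pvals <- stats::pchisq(2 * (lls - ll_cur), df = 1,
                             lower.tail = FALSE)
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        current <- c(current, pool[best])
        ll_cur <- lls[best]
        changed <- TRUE
      }
    }
    # knock out
    if (length(current)) {
      lls <- vapply(current, function(p) ll_of(setdiff(current, p)),
                    numeric(1))
      pvals <- stats::pchisq(2 * (ll_cur - lls), df = 1,
                             lower.tail = FALSE)
      worst <- which.max(pvals)
      if (pvals[worst] > p_remove) {
        ll_cur <- lls[worst]
        current <- setdiff(current, current[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current
}

#' Target sensitivity within distracter-orientation bins
#'
#' Splits the distracter range [-10, 10] into 6 equal-width bins and, in
#' each, regresses choice on `theta_T` alone. Alongside the observed
#' slopes it computes the slopes predicted by a fitted consistency-bias
#' model: the fitted choice probabilities replace the binary outcomes in a
#' quasi-binomial per-bin regression.
#'
#' @param trials Trial table with `choice`.
#' @param fitted_model Optional `choice_glm` fitted with predictors
#'   `theta_T`, `theta_D`, `consistency` (with its design attached via
#'   `design` argument).
#' @param design Design matrix matching `fitted_model`.
#' @return Data frame: `bin`, `bin_mid`, `n`, `slope`, `se`,
#'   `model_slope` (NA when no model given).
#' @export
binned_sensitivity <- function(trials, fitted_model = NULL, design = NULL) {
  edges <- seq(-10, 10, length.out = 7)
  bin <- cut(trials$theta_D, edges, include.lowest = TRUE, labels = FALSE)
  p_model <- if (!is.null(fitted_model)) {
    binomial_inv_link(as.vector(design %*% fitted_model$coefficients),
                      fitted_model$link)
  } else NULL
  out <- lapply(seq_len(6), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) {
      return(data.frame(bin = b, bin_mid = mean(edges[b:(b + 1)]),
                        n = 0L, slope = NA_real_, se = NA_real_,
                        model_slope = NA_real_))
    }
    X <- cbind(intercept = 1, theta_T = trials$theta_T[idx])
    f <- fit_choice_glm(X, trials$choice[idx])
    ms <- NA_real_
    if (!is.null(p_model)) {
      mf <- suppressWarnings(
        stats::glm.fit(X, p_model[idx], family = stats::binomial())
      )
      ms <- mf$coefficients[["theta_T"]]
    }
    data.frame(bin = b, bin_mid = mean(edges[b:(b + 1)]),
               n = length(idx),
               slope = fit_coef(f, "theta_T"), se = f$se[["theta_T"]],
               model_slope = ms)
  })
  do.call(rbind, out)
}

fit_coef <- function(fit, name) fit$coefficients[[name]]

#' Stratified k-fold cross-validated log-likelihood
#'
#' Folds are stratified by choice so every training set sees both
#' responses; the fit on each training fold scores the held-out choices
#' and the per-fold held-out log-likelihoods are summed. Deterministic
#' under a fixed seed.
#'
#' @param trials Trial table with `choice`.
#' @param predictors Predictor ids defining the model.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @return Scalar summed held-out log-likelihood (<= 0).
#' @export
crossval_loglik <- function(trials, predictors, k = 10, seed = 1L) {
  stopifnot(k >= 2)
  folds <- stratified_folds(trials$choice, k, seed)
  X <- build_design(trials, predictors)
  total <- 0
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_choice_glm(X[!test, , drop = FALSE], trials$choice[!test])
    p <- binomial_inv_link(as.vector(X[test, , drop = FALSE] %*%
                                       fit$coefficients), fit$link)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    total <- total + sum(log(ifelse(trials$choice[test] == 1, p, 1 - p)))
  }
  total
}

# Fold ids stratified by a binary outcome; both classes spread over folds.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Random-effects Bayesian model selection
#'
#' Variational random-effects model selection over a subjects x models
#' matrix of log model evidences (here cross-validated log-likelihoods).
#' Iterates the Dirichlet updates `u_nk proportional to exp(lme_nk +
#' digamma(alpha_k) - digamma(sum alpha))`, `alpha_k = alpha0 + sum_n
#' u_nk` to convergence, then estimates exceedance probabilities — the
#' posterior probability that each model is the most frequent in the
#' population — by Monte-Carlo sampling from Dirichlet(alpha).
#'
#' @param lme n_subjects x n_models matrix of log evidences.
#' @param alpha0 Dirichlet prior concentration (default 1).
#' @param n_samples Monte-Carlo draws for the exceedance estimate.
#' @param seed Integer seed for the draws.
#' @return A `bms_result`: `alpha`, `expected_freq`, `exceedance`,
#'   `n_samples`.
#' @export
bms_exceedance <- function(lme, alpha0 = 1, n_samples = 1e5, seed = 1L) {
  lme <- as.matrix(lme)
  if (any(!is.finite(lme))) {
    stop("bms_exceedance: non-finite model evidences", call. = FALSE)
  }
  K <- ncol(lme)
  alpha <- rep(alpha0, K)
  for (it in seq_len(500)) {
    lu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  set.seed(seed)
  draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha,
                                                           each = n_samples)),
                  n_samples, K)
  winner <- max.col(draws, ties.method = "first")
  exceed <- tabulate(winner, K) / n_samples
  structure(list(alpha = alpha, expected_freq = alpha / sum(alpha),
                 exceedance = exceed, n_samples = n_samples,
                 model_names = colnames(lme)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("random-effects BMS over", length(x$alpha), "models\n")
  tab <- rbind(alpha = x$alpha, expected_freq = x$expected_freq,
               exceedance = x$exceedance)
  colnames(tab) <- x$model_names %||% paste0("M", seq_along(x$alpha))
  print(round(tab, 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
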