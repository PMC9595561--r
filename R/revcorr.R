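#' Decision kernel by per-bin probit regression
#'
#' For each orientation bin, an independent binomial probit regression of
#' choice on the z-scored target energy in that bin (and, in the
#' competitive variant, the z-scored distracter energy as a second
#' regressor). The per-bin slope coefficients, plotted over orientation,
#' form the decision kernel. Bins where the maximum-likelihood fit
#' separates are refit with a small ridge penalty and flagged.
#'
#' @param choices 0/1 outcome per trial — observed choices or ground-truth
#'   CW/CCW labels.
#' @param z_energy_target n_trials x n_bins z-scored target energies.
#' @param z_energy_distracter Optional matching distracter energies; when
#'   given, both regressors enter each per-bin model (competitive
#'   variant).
#' @param orientations_deg Orientation of each bin (for the output table).
#' @return A `decision_kernel` data frame: `orientation_deg`, `beta`,
#'   `se` (target coefficient), and when competitive `beta_distracter`,
#'   `se_distracter`; plus a `flagged` logical column.
#' @export
decision_kernel <- function(choices, z_energy_target,
                            z_energy_distracter = NULL,
                            orientations_deg = NULL) {
  stopifnot(all(choices %in% c(0, 1)))
  nb <- ncol(z_energy_target)
  if (is.null(orientations_deg)) orientations_deg <- seq(-45, 45,
                                                         length.out = nb)
  competitive <- !is.null(z_energy_distracter)
  out <- data.frame(orientation_deg = orientations_deg,
                    beta = NA_real_, se = NA_real_,
                    flagged = FALSE)
  if (competitive) {
    out$beta_distracter <- NA_real_
    out$se_distracter <- NA_real_
  }
  for (j in seq_len(nb)) {
    X <- if (competitive) {
      cbind(intercept = 1, target = z_energy_target[, j],
            distracter = z_energy_distracter[, j])
    } else {
      cbind(intercept = 1, target = z_energy_target[, j])
    }
    fit <- fit_choice_glm(X, choices, link = "probit")
    out$beta[j] <- fit$coefficients[["target"]]
    out$se[j] <- fit$se[["target"]]
    out$flagged[j] <- fit$separation
    if (competitive) {
      out$beta_distracter[j] <- fit$coefficients[["distracter"]]
      out$se_distracter[j] <- fit$se[["distracter"]]
    }
  }
  class(out) <- c("decision_kernel", "data.frame")
  out
}

#' Singular value decomposition of an energy-profile matrix
#'
#' Uncentered SVD of the stimuli x orientation matrix (targets and
#' distracters stacked). Components are the unit-norm right singular
#' vectors; each stimulus's score on a component is the projection of its
#' profile onto that component; variance fractions are the squared
#' singular values over their total.
#'
#' @param profile_matrix n_stimuli x n_bins matrix of energy profiles.
#' @return An `svd_decomposition`: `components` (n_bins x k, columns are
#'   components), `scores` (n_stimuli x k), `variance_fraction`,
#'   `singular_values`.
#' @export
svd_profiles <- function(profile_matrix) {
  X <- as.matrix(profile_matrix)
  if (nrow(X) < 2) {
    stop("svd_profiles: need at least 2 stimuli", call. = FALSE)
  }
  s <- svd(X)
  if (sum(s$d > 1e-12 * s$d[1]) < 2) {
    warning("svd_profiles: profile matrix is (near) rank deficient")
  }
  structure(list(components = s$v, scores = X %*% s$v,
                 variance_fraction = s$d^2 / sum(s$d^2),
                 singular_values = s$d),
            class = "svd_decomposition")
}

#' @export
print.svd_decomposition <- function(x, ...) {
  cat("svd_decomposition:", ncol(x$components), "components;",
      "variance fractions (top 4):",
      paste(round(utils::head(x$variance_fraction, 4), 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' Identify and sign-align the tilt-informative component
#'
#' Restricts attention to the minimum leading set of components reaching
#' the cumulative-variance threshold, then picks the one whose scores
#' correlate most strongly (point-biserial, in absolute value) with the
#' stimulus tilt sign. The component and its scores are sign-aligned so
#' clockwise stimuli score positive — a negative score then means the
#' stimulus is best captured by the mirror image of the component.
#'
#' @param decomp An `svd_decomposition`.
#' @param thetas Boundary-relative orientation of each stimulus (same row
#'   order as the profile matrix).
#' @param var_threshold Cumulative variance defining the retained set
#'   (default 0.95).
#' @return List: `index`, `sign` (+1/-1 alignment factor), `component`
#'   (aligned vector), `scores` (aligned), `correlations` (over retained
#'   components), `n_retained`.
#' @export
select_tilt_component <- function(decomp, thetas, var_threshold = 0.95) {
  cum <- cumsum(decomp$variance_fraction)
  n_keep <- which(cum >= var_threshold)[1]
  tilt <- sign(thetas)
  cors <- vapply(seq_len(n_keep), function(i) {
    stats::cor(decomp$scores[, i], tilt)
  }, numeric(1))
  if (all(abs(cors) <= 0.1)) {
    stop("select_tilt_component: no retained component correlates with ",
         "stimulus tilt (|r| <= 0.1)", call. = FALSE)
  }
  idx <- which.max(abs(cors))
  sgn <- if (cors[idx] >= 0) 1 else -1
  list(index = idx, sign = sgn,
       component = sgn * decomp$components[, idx],
       scores = sgn * decomp$scores[, idx],
       correlations = cors, n_retained = n_keep)
}

#' Choice regression on tilt-component scores
#'
#' The consistency-bias regression with the tilt-component scores of
#' target and distracter in place of their angular offsets:
#' `y = b0 + b1 * U_T + b2 * U_D + b3 * U_T * |U_T - U_D|`, optionally
#' extended with attention interactions (`A * U_T`, `A * U_D`,
#' `A * U_T * |U_T - U_D|`) for the cued design.
#'
#' @param trials Trial table with `choice` (and `A` if `attention`).
#' @param scores_target,scores_distracter Tilt-component score per trial.
#' @param attention Include the attention-interaction columns.
#' @return A `choice_glm` fit (logit link) with the design attached as
#'   attribute `design`.
#' @export
component_regression <- function(trials, scores_target, scores_distracter,
                                 attention = FALSE) {
  sc_trials <- trials
  sc_trials$theta_T <- scores_target
  sc_trials$theta_D <- scores_distracter
  preds <- c("theta_T", "theta_D", "consistency")
  if (attention) preds <- c(preds, "A_x_theta_T", "A_x_theta_D",
                            "A_x_consistency")
  X <- build_design(sc_trials, preds)
  colnames(X) <- sub("theta_T", "U_T",
                     sub("theta_D", "U_D",
                         sub("consistency", "U_consistency", colnames(X))))
  fit <- fit_choice_glm(X, trials$choice)
  attr(fit, "design") <- X
  fit
}
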