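#' Parameters of a simulated observer
#'
#' Two observer families are supported. The parametric observer applies the
#' contextual-normalization transducer to the boundary-relative
#' orientations in the trial table: `y = (theta_T - rho * mu) / (r + tau *
#' sigma)` with context mean `mu = (theta_T + theta_D) / 2` and context
#' variability `sigma = |theta_T - theta_D|`, then responds clockwise with
#' probability `1 / (1 + exp(-y))`. The energy-template observer instead
#' weights the z-scored energy profile of the rendered target by a
#' 181-bin template. A lapse parameter (default 0) mixes in uniform
#' guessing so simulated likelihoods stay finite at extreme transducer
#' values.
#'
#' @param kind `"parametric"` or `"energy_template"`.
#' @param r Baseline transducer denominator (> 0); smaller r = steeper
#'   psychometric slope.
#' @param tau Contextual-variability gain weight.
#' @param rho Contextual-expectation weight (positive = repulsion from the
#'   distracter).
#' @param lapse Probability of a uniform random choice, in `[0, 0.5]`.
#' @param template Numeric weight vector over the 181 orientation bins
#'   (energy_template only).
#' @param consistency_gain Energy observer only: if `TRUE`, divide its
#'   decision variable by `r + tau * |score_T - score_D|`, mirroring the
#'   normalization transducer at the energy level. Off by default.
#' @return An `observer_params` object.
#' @export
observer_params <- function(kind = c("parametric", "energy_template"),
                            r = 3, tau = 0, rho = 0, lapse = 0,
                            template = NULL, consistency_gain = FALSE) {
  kind <- match.arg(kind)
  if (r <= 0) stop("observer_params: r must be > 0", call. = FALSE)
  if (r + tau * 20 <= 0 || r <= 0) {
    stop("observer_params: r + tau * sigma must stay positive over ",
         "sigma in [0, 20]", call. = FALSE)
  }
  if (lapse < 0 || lapse > 0.5) {
    stop("observer_params: lapse must lie in [0, 0.5]", call. = FALSE)
  }
  if (kind == "energy_template" && is.null(template)) {
    stop("observer_params: energy_template observer needs a template",
         call. = FALSE)
  }
  structure(list(kind = kind, r = r, tau = tau, rho = rho, lapse = lapse,
                 template = template, consistency_gain = consistency_gain),
            class = "observer_params")
}

#' Simulate choices of the parametric (normalization) observer
#'
#' Fills the `choice` and `correct` columns of a trial table. The choice
#' probability is the logistic transform of the normalization transducer,
#' mixed with the lapse rate; `correct` compares the choice to the sign of
#' `theta_T`.
#'
#' @param trials Trial table from [generate_trials()].
#' @param params An `observer_params` of kind `"parametric"`.
#' @param seed Integer seed for the Bernoulli draws.
#' @return The trial table with `choice` (1 = CW, 0 = CCW), `correct`, and
#'   a `p_cw` column with the analytic choice probability.
#' @export
simulate_parametric_observer <- function(trials, params, seed = 1L) {
  stopifnot(inherits(params, "observer_params"),
            params$kind == "parametric")
  st <- transduce(trials$theta_T, trials$theta_D,
                  list(r = params$r, tau = params$tau, rho = params$rho))
  p <- params$lapse * 0.5 + (1 - params$lapse) * st$p_cw
  set.seed(seed)
  # inversion draw (u < p) so a shared seed couples simulations that differ
  # only in parameters (common random numbers)
  choice <- as.integer(stats::runif(nrow(trials)) < p)
  trials$p_cw <- p
  trials$choice <- choice
  trials$correct <- as.integer((choice == 1L) == (trials$theta_T > 0))
  trials
}

#' Simulate choices of the energy-template observer
#'
#' The decision variable is the inner product of a 181-bin template with
#' the z-scored energy profile of the rendered target stimulus; the
#' distracter plays no direct role unless `consistency_gain` is on, in
#' which case the decision variable is divided by
#' `r + tau * |score_T - score_D|` where the scores are the template
#' projections of target and distracter. Exists so that decision kernels
#' have a recoverable ground truth.
#'
#' @param trials Trial table.
#' @param z_energy_target n_trials x 181 z-scored target energies.
#' @param params `observer_params` of kind `"energy_template"`.
#' @param z_energy_distracter Optional matching distracter energies
#'   (required when `consistency_gain` is on).
#' @param seed Integer seed.
#' @return Trial table with `choice`, `correct`, `p_cw` filled.
#' @export
simulate_energy_observer <- function(trials, z_energy_target, params,
                                     z_energy_distracter = NULL, seed = 1L) {
  stopifnot(inherits(params, "observer_params"),
            params$kind == "energy_template")
  if (length(params$template) != ncol(z_energy_target)) {
    stop("simulate_energy_observer: template length must equal the number ",
         "of orientation bins (", ncol(z_energy_target), ")", call. = FALSE)
  }
  dv <- as.vector(z_energy_target %*% params$template)
  if (isTRUE(params$consistency_gain)) {
    if (is.null(z_energy_distracter)) {
      stop("simulate_energy_observer: consistency_gain needs distracter ",
           "energies", call. = FALSE)
    }
    sT <- dv
    sD <- as.vector(z_energy_distracter %*% params$template)
    dv <- sT / (params$r + params$tau * abs(sT - sD))
  }
  p <- params$lapse * 0.5 + (1 - params$lapse) * stats::plogis(dv)
  set.seed(seed)
  choice <- as.integer(stats::runif(nrow(trials)) < p)
  trials$p_cw <- p
  trials$choice <- choice
  trials$correct <- as.integer((choice == 1L) == (trials$theta_T > 0))
  trials
}

#' A stimulus-level observer with internal noise, for staircase runs
#'
#' On a trial with signal contrast `1 - noise_contrast` and target offset
#' `theta`, the internal decision variable is
#' `N((1 - noise_contrast) * theta, sigma_int)`; the observer responds CW
#' when it is positive. Expected accuracy marginalized over theta ~
#' U(-10, 10) is available in closed form via `attr(obs, "accuracy")`, a
#' function of noise contrast — monotone decreasing, which is what the
#' staircase requires.
#'
#' @param sigma_int Internal noise SD (degrees of decision evidence).
#' @return A function `obs(noise_contrast, theta)` returning 0/1 correct,
#'   with an `accuracy` attribute giving the analytic expected accuracy.
#' @export
contrast_observer <- function(sigma_int = 3) {
  stopifnot(sigma_int > 0)
  obs <- function(noise_contrast, theta) {
    cs <- 1 - noise_contrast
    x <- stats::rnorm(length(theta), cs * theta, sigma_int)
    as.integer((x > 0) == (theta > 0))
  }
  # E_theta[P(correct)] for theta ~ U(-10, 10): with a = cs / sigma_int,
  # (1/10) * int_0^10 Phi(a t) dt = Phi(10a) + (phi(10a) - phi(0)) / (10a)
  attr(obs, "accuracy") <- function(noise_contrast) {
    a <- (1 - noise_contrast) / sigma_int
    ifelse(a <= 0, 0.5,
           stats::pnorm(10 * a) +
             (stats::dnorm(10 * a) - stats::dnorm(0)) / (10 * a))
  }
  obs
}

#' Accelerated stochastic approximation staircase
#'
#' Adaptive staircase on the noise contrast, targeting a fixed accuracy
#' (default 0.75). Before the first response reversal the level moves by
#' `(c / n) * (resp - target_p)` (trial counter n), which lets the run
#' travel quickly from a starting level far from threshold; from the first
#' reversal on the step is `(c / (2 + m)) * (resp - target_p)` where `m`
#' counts response-direction reversals. `resp` is 1 for a correct
#' response, so a correct response raises the noise contrast (harder) and
#' an error lowers it. Levels are clipped to `[0, 1]`. The run stops after
#' `n_max` trials or once the step size falls below `step_floor`.
#'
#' @param observer A function `(noise_contrast, theta) -> 0/1` such as
#'   [contrast_observer()]; its accuracy must decrease with noise contrast.
#' @param target_p Target accuracy (default 0.75).
#' @param n_max Maximum number of staircase trials.
#' @param initial_level,initial_step Starting noise contrast and step `c`.
#' @param step_floor Stop once `c / (2 + m)` drops below this.
#' @param seed Integer seed (drives both theta sampling and the observer).
#' @return A `staircase_trace`: list with `levels`, `responses`,
#'   `n_shifts`, `converged_level`, `target_p`.
#' @export
run_staircase <- function(observer, target_p = 0.75, n_max = 800,
                          initial_level = 0.9, initial_step = 1,
                          step_floor = 0.002, seed = 1L) {
  set.seed(seed)
  level <- initial_level
  levels <- numeric(n_max)
  responses <- integer(n_max)
  m <- 0L
  prev_resp <- NA_integer_
  i <- 0L
  for (i in seq_len(n_max)) {
    theta <- stats::runif(1, -10, 10)
    resp <- observer(level, theta)
    levels[i] <- level
    responses[i] <- resp
    if (!is.na(prev_resp) && resp != prev_resp) m <- m + 1L
    prev_resp <- resp
    step <- if (m == 0L) initial_step / i else initial_step / (2 + m)
    level <- min(1, max(0, level + step * (resp - target_p)))
    if (step < step_floor) break
  }
  levels <- levels[seq_len(i)]
  responses <- responses[seq_len(i)]
  structure(list(levels = levels, responses = responses, n_shifts = m,
                 converged_level = level, target_p = target_p),
            class = "staircase_trace")
}

#' @export
print.staircase_trace <- function(x, ...) {
  cat("staircase_trace:", length(x$levels), "trials,", x$n_shifts,
      "reversals, converged noise contrast",
      round(x$converged_level, 3), "(target accuracy", x$target_p, ")\n")
  invisible(x)
}
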