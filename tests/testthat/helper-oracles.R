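# Shared fixtures and independent oracles used across the test files.

# Small raster for image-level tests: 32 x 32 px keeps the filter bank and
# energy computations fast while leaving > 5 px per carrier cycle.
test_spec <- function(ppd = 8, ...) stimulus_spec(pixels_per_deg = ppd, ...)

# Choices simulated directly from the consistency-bias regression
# y = b0 + b1*tT + b2*tD + b3*tT*|tT - tD| (independent of build_design).
gen_eq4_choices <- function(n, beta, seed, design = "exp1") {
  tr <- generate_trials(design, n, seed = seed)
  y <- beta[1] + beta[2] * tr$theta_T + beta[3] * tr$theta_D +
    beta[4] * tr$theta_T * abs(tr$theta_T - tr$theta_D)
  set.seed(seed + 1L)
  tr$choice <- as.integer(stats::runif(n) < stats::plogis(y))
  tr
}

# Trials with choices from the normalization transducer, computed directly
# (not via simulate_parametric_observer) so observer tests have an
# independent data path.
gen_norm_choices <- function(n, r, tau, rho, seed, design = "exp1",
                             r_by_cue = NULL) {
  tr <- generate_trials(design, n, seed = seed)
  sg <- abs(tr$theta_T - tr$theta_D)
  mu <- (tr$theta_T + tr$theta_D) / 2
  rr <- if (is.null(r_by_cue)) r else unname(r_by_cue[tr$cue_condition])
  p <- stats::plogis((tr$theta_T - rho * mu) / (rr + tau * sg))
  set.seed(seed + 1L)
  tr$choice <- as.integer(stats::runif(n) < p)
  tr$correct <- as.integer((tr$choice == 1L) == (tr$theta_T > 0))
  tr
}

# Independent gradient-descent fit of R(phi_n) = E * cos(phi_n - phi_max),
# vectorized over problems (rows of R). Minimizes the squared error by
# plain gradient descent with backtracking, from the best of a coarse
# phi grid. Oracle for the closed-form fit in energy_profile().
gd_cosine_fit <- function(R, phases, max_iter = 5000, tol = 1e-14) {
  np <- nrow(R)
  # coarse initialisation over 16 phases
  init_grid <- seq(0, 2 * pi, length.out = 17)[-17]
  best_sse <- rep(Inf, np)
  E <- numeric(np)
  phi <- numeric(np)
  for (p0 in init_grid) {
    cb <- cos(phases - p0)
    e0 <- as.vector(R %*% cb) / sum(cb^2)
    sse <- rowSums((R - outer(e0, cb))^2)
    upd <- sse < best_sse
    best_sse[upd] <- sse[upd]
    E[upd] <- e0[upd]
    phi[upd] <- p0
  }
  # preconditioned gradient descent: the SSE curvature is ~ 2*sum(cos^2)
  # in E and ~ 2*E^2*sum(sin^2) in phi, so the raw gradients are rescaled
  # by those factors before stepping (backtracking on the step length).
  nph <- length(phases)
  lr <- rep(1, np)
  sse <- best_sse
  for (it in seq_len(max_iter)) {
    cosm <- cos(outer(-phi, phases, "+"))   # cos(phi_n - phi)
    sinm <- sin(outer(-phi, phases, "+"))
    resid <- R - E * cosm
    gE <- -2 * rowSums(resid * cosm)
    gphi <- -2 * E * rowSums(resid * sinm)
    dE <- gE / nph
    dphi <- gphi / pmax(nph * E^2, 1e-12)
    E_new <- E - lr * dE
    phi_new <- phi - lr * dphi
    cosm2 <- cos(outer(-phi_new, phases, "+"))
    sse_new <- rowSums((R - E_new * cosm2)^2)
    ok <- sse_new <= sse + 1e-30
    E[ok] <- E_new[ok]
    phi[ok] <- phi_new[ok]
    lr[ok] <- pmin(lr[ok] * 1.2, 1)
    lr[!ok] <- lr[!ok] * 0.5
    moved <- pmax(abs(lr * dE), abs(lr * dphi))
    sse <- ifelse(ok, sse_new, sse)
    if (it > 20 && all(moved < 1e-12 | lr < 1e-14)) break
  }
  # canonicalize: E >= 0, phi in [0, 2pi)
  neg <- E < 0
  E[neg] <- -E[neg]
  phi[neg] <- phi[neg] + pi
  list(E = E, phi_max = phi %% (2 * pi))
}

# Circular distance between two phase vectors (radians in [0, pi]).
phase_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

render_ensemble <- function(trials, spec, role = c("target", "distracter")) {
  role <- match.arg(role)
  raw <- if (role == "target") trials$raw_orientation_T else
    trials$raw_orientation_D
  seeds <- if (role == "target") trials$stim_seed_T else trials$stim_seed_D
  npx <- round(spec$size_deg * spec$pixels_per_deg)^2
  t(vapply(seq_along(raw), function(i) {
    as.vector(render_stimulus(raw[i], seeds[i], spec, role)$pixels)
  }, numeric(npx)))
}
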