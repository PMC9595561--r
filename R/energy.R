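#' Build an oriented Gabor filter bank
#'
#' Filters share the stimulus spec's spatial frequency and Gaussian
#' envelope. Orientation runs from -45 to +45 degrees in steps of 0.5
#' (181 bins); each orientation is rendered at 5 phases, 0.2*pi to 1.8*pi
#' in steps of 0.4*pi — uniformly spaced modulo 2*pi, which is what makes
#' the closed-form cosine fit in [energy_profile()] exact. Filters are
#' stored mean-removed as a matrix with one row per (orientation, phase)
#' pair so a batch of stimuli reduces to one matrix product.
#'
#' @param spec A [stimulus_spec()]; defines grid, frequency and envelope.
#' @return A `filter_bank`: list with `orientations_deg` (length 181),
#'   `phases_rad` (length 5), `filters` (905 x n_pixels matrix,
#'   mean-removed), `filter_var` (per-filter pixel variance), `n_px`.
#' @export
build_filter_bank <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  orientations <- seq(-45, 45, by = 0.5)
  phases <- seq(0.2, 1.8, by = 0.4) * pi
  n <- round(spec$size_deg * spec$pixels_per_deg)
  npx <- n * n
  filt <- matrix(0, length(orientations) * length(phases), npx)
  k <- 0L
  for (th in orientations) {
    for (ph in phases) {
      k <- k + 1L
      filt[k, ] <- as.vector(make_gabor(th, ph, spec)$pixels)
    }
  }
  mu <- rowMeans(filt)
  filt <- filt - mu
  fv <- rowSums(filt^2) / (npx - 1)
  structure(list(orientations_deg = orientations, phases_rad = phases,
                 filters = filt, filter_var = fv, n_px = n),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("filter_bank:", length(x$orientations_deg), "orientations x",
      length(x$phases_rad), "phases on a", x$n_px, "x", x$n_px, "grid\n")
  invisible(x)
}

#' Response of one filter to one stimulus
#'
#' The regression slope of the stimulus pixels on the filter pixels,
#' `cov(S, F) / var(F)`, with both images mean-removed. Any fixed positive
#' rescaling of this convention cancels in the downstream per-bin
#' z-scoring of energies.
#'
#' @param stimulus A `stimulus_image` (or pixel matrix).
#' @param filter_pixels Pixel matrix of the filter.
#' @return Scalar response.
#' @export
filter_response <- function(stimulus, filter_pixels) {
  s <- if (inherits(stimulus, "stimulus_image")) stimulus$pixels else stimulus
  if (!identical(dim(s), dim(filter_pixels))) {
    stop("filter_response: stimulus and filter grids differ", call. = FALSE)
  }
  f <- as.vector(filter_pixels) - mean(filter_pixels)
  v <- sum(f^2)
  if (v == 0) stop("filter_response: zero-variance filter", call. = FALSE)
  sum((as.vector(s) - mean(s)) * f) / v
}

# All filter responses for a batch of stimuli: n_stim x n_filters matrix.
bank_responses <- function(pixel_matrix, bank) {
  if (ncol(pixel_matrix) != ncol(bank$filters)) {
    stop("energy: stimulus grid does not match the filter bank",
         call. = FALSE)
  }
  sm <- pixel_matrix - rowMeans(pixel_matrix)
  npx <- ncol(pixel_matrix)
  # slope = sum(s_centred * f_centred) / sum(f_centred^2)
  (sm %*% t(bank$filters)) / rep((npx - 1) * bank$filter_var,
                                 each = nrow(pixel_matrix))
}

#' Energy profile of one or more stimuli
#'
#' For each orientation bin the five phase responses are modelled as
#' `R(phi_n) = E * cos(phi_n - phi_max)`. Because the phases are uniformly
#' spaced modulo 2*pi, the least-squares solution is closed form:
#' `a = (2/5) sum R_n cos(phi_n)`, `b = (2/5) sum R_n sin(phi_n)`,
#' `E = sqrt(a^2 + b^2) >= 0`, `phi_max = atan2(b, a)` (wrapped to
#' `[0, 2*pi)`). An all-zero bin gets `E = 0` and `phi_max = 0`.
#'
#' @param stimuli A single `stimulus_image`, a list of them, or an
#'   n_stimuli x n_pixels matrix of vectorised images.
#' @param bank A [build_filter_bank()] result on the same grid.
#' @return An `energy_profile` object: list with `energy`
#'   (n_stimuli x 181), `phi_max` (same shape), `orientations_deg`.
#' @export
energy_profile <- function(stimuli, bank) {
  px <- stimulus_pixel_matrix(stimuli)
  R <- bank_responses(px, bank)
  n_or <- length(bank$orientations_deg)
  n_ph <- length(bank$phases_rad)
  cosb <- cos(bank$phases_rad)
  sinb <- sin(bank$phases_rad)
  E <- matrix(0, nrow(px), n_or)
  P <- matrix(0, nrow(px), n_or)
  for (j in seq_len(n_or)) {
    Rj <- R[, (j - 1) * n_ph + seq_len(n_ph), drop = FALSE]
    a <- (2 / n_ph) * (Rj %*% cosb)
    b <- (2 / n_ph) * (Rj %*% sinb)
    E[, j] <- sqrt(a^2 + b^2)
    P[, j] <- ifelse(E[, j] > 0, atan2(b, a) %% (2 * pi), 0)
  }
  structure(list(energy = E, phi_max = P,
                 orientations_deg = bank$orientations_deg),
            class = "energy_profile")
}

stimulus_pixel_matrix <- function(stimuli) {
  if (inherits(stimuli, "stimulus_image")) {
    matrix(as.vector(stimuli$pixels), nrow = 1)
  } else if (is.list(stimuli)) {
    t(vapply(stimuli, function(s) as.vector(s$pixels),
             numeric(length(as.vector(stimuli[[1]]$pixels)))))
  } else if (is.matrix(stimuli)) {
    stimuli
  } else {
    stop("energy_profile: unsupported stimulus container", call. = FALSE)
  }
}

#' Z-score energies within each orientation bin
#'
#' Standardizes each orientation bin to mean 0, SD 1 across the stimulus
#' ensemble. Target and distracter ensembles should be standardized
#' separately (pass each ensemble's matrix on its own).
#'
#' @param profiles An `energy_profile` or an n_stimuli x n_bins matrix.
#' @return Matrix of z-scored energies with the same shape.
#' @export
zscore_energies <- function(profiles) {
  E <- if (inherits(profiles, "energy_profile")) profiles$energy else profiles
  if (nrow(E) < 2) {
    stop("zscore_energies: need at least 2 stimuli in the ensemble",
         call. = FALSE)
  }
  mu <- colMeans(E)
  sdv <- apply(E, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zscore_energies: degenerate bin with zero variance",
         call. = FALSE)
  }
  sweep(sweep(E, 2, mu), 2, sdv, "/")
}
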