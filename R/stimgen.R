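#' Stimulus specification
#'
#' Bundles the parameters needed to render a noisy Gabor stimulus: a cosine
#' carrier under a circular Gaussian envelope, plus smoothed Gaussian pixel
#' noise. Signal and noise contrasts sum to 1, so `signal_contrast` alone
#' sets the signal-to-noise ratio of the composite.
#'
#' @param size_deg Side of the square patch in degrees of visual angle.
#' @param envelope_sd_deg SD of the Gaussian envelope (degrees).
#' @param spatial_freq_cpd Carrier spatial frequency (cycles/degree). The
#'   filter bank used for energy profiles must reuse this value.
#' @param pixels_per_deg Raster resolution (pixels per degree).
#' @param noise_smooth_sd_deg SD of the Gaussian used to smooth the pixel
#'   noise (degrees).
#' @param signal_contrast Weight of the signal in `[0, 1]`; the noise weight
#'   is `1 - signal_contrast`.
#' @param orientation_deg Carrier orientation in degrees; 0 is vertical,
#'   positive is clockwise.
#' @param phase_rad Carrier phase in `[0, 2*pi)`.
#'
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(size_deg = 4, envelope_sd_deg = 1,
                          spatial_freq_cpd = 2, pixels_per_deg = 32,
                          noise_smooth_sd_deg = 0.083,
                          signal_contrast = 0.35,
                          orientation_deg = 0, phase_rad = 0) {
  if (size_deg <= 0 || envelope_sd_deg <= 0 || spatial_freq_cpd <= 0 ||
      pixels_per_deg <= 0 || noise_smooth_sd_deg <= 0) {
    stop("stimulus_spec: size_deg, envelope_sd_deg, spatial_freq_cpd, ",
         "pixels_per_deg and noise_smooth_sd_deg must be positive",
         call. = FALSE)
  }
  if (signal_contrast < 0 || signal_contrast > 1) {
    stop("stimulus_spec: signal_contrast must lie in [0, 1]", call. = FALSE)
  }
  structure(list(size_deg = size_deg, envelope_sd_deg = envelope_sd_deg,
                 spatial_freq_cpd = spatial_freq_cpd,
                 pixels_per_deg = pixels_per_deg,
                 noise_smooth_sd_deg = noise_smooth_sd_deg,
                 signal_contrast = signal_contrast,
                 orientation_deg = orientation_deg,
                 phase_rad = phase_rad),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("stimulus_spec:", x$size_deg, "deg patch,",
      round(x$size_deg * x$pixels_per_deg), "px,",
      x$spatial_freq_cpd, "cpd, envelope sd", x$envelope_sd_deg,
      "deg, signal contrast", x$signal_contrast, "\n")
  invisible(x)
}

# Pixel-centre coordinate grids in degrees, centred on the patch.
pixel_grid <- function(spec) {
  n <- round(spec$size_deg * spec$pixels_per_deg)
  coords <- (seq_len(n) - (n + 1) / 2) / spec$pixels_per_deg
  list(n = n,
       x = matrix(coords, n, n, byrow = TRUE),  # columns: left -> right
       y = matrix(coords, n, n))                # rows: top -> bottom
}

#' Render a Gabor signal patch
#'
#' The carrier is a cosine grating of unit amplitude: for orientation 0 the
#' stripes are vertical and the luminance varies along the horizontal axis;
#' positive orientations rotate the grating clockwise. The envelope is an
#' isotropic Gaussian centred on the patch.
#'
#' @param orientation_deg Carrier orientation (degrees, 0 = vertical,
#'   positive = clockwise).
#' @param phase_rad Carrier phase (radians).
#' @param spec A [stimulus_spec()].
#' @return A `stimulus_image`: list with `pixels` (matrix), `spec`, `role`.
#' @export
make_gabor <- function(orientation_deg, phase_rad, spec,
                       role = c("target", "distracter")) {
  stopifnot(inherits(spec, "stimulus_spec"))
  role <- match.arg(role)
  g <- pixel_grid(spec)
  a <- orientation_deg * pi / 180
  # Modulation axis perpendicular to the stripes; mirroring x (left-right)
  # maps (orientation, phase) -> (-orientation, -phase).
  u <- g$x * cos(a) + g$y * sin(a)
  carrier <- cos(2 * pi * spec$spatial_freq_cpd * u + phase_rad)
  envelope <- exp(-(g$x^2 + g$y^2) / (2 * spec$envelope_sd_deg^2))
  structure(list(pixels = carrier * envelope,
                 spec = spec, role = role,
                 orientation_deg = orientation_deg,
                 phase_rad = phase_rad),
            class = "stimulus_image")
}

# Circular (FFT) convolution with an isotropic Gaussian of SD sd_px pixels.
gaussian_smooth <- function(mat, sd_px) {
  n <- nrow(mat)
  m <- ncol(mat)
  # centred kernel, wrapped
  kx <- stats::dnorm(pmin(0:(m - 1), m - (0:(m - 1))), sd = sd_px)
  ky <- stats::dnorm(pmin(0:(n - 1), n - (0:(n - 1))), sd = sd_px)
  kern <- outer(ky, kx)
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(mat) * stats::fft(kern), inverse = TRUE)) / (n * m)
}

#' Render a smoothed Gaussian noise patch
#'
#' Draws i.i.d. standard-normal pixel values, convolves them with a Gaussian
#' of SD `noise_smooth_sd_deg`, then recentres and rescales to zero mean and
#' unit pixel SD so that `signal_contrast` alone controls the
#' signal-to-noise ratio of the composite stimulus.
#'
#' @param spec A [stimulus_spec()].
#' @param seed Optional integer seed; when given the image is reproducible.
#' @return A `stimulus_image`.
#' @export
make_noise <- function(spec, seed = NULL, role = c("target", "distracter")) {
  stopifnot(inherits(spec, "stimulus_spec"))
  role <- match.arg(role)
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$size_deg * spec$pixels_per_deg)
  raw <- matrix(stats::rnorm(n * n), n, n)
  sm <- gaussian_smooth(raw, spec$noise_smooth_sd_deg * spec$pixels_per_deg)
  sm <- sm - mean(sm)
  sm <- sm / stats::sd(as.vector(sm))
  structure(list(pixels = sm, spec = spec, role = role, seed = seed),
            class = "stimulus_image")
}

#' Combine signal and noise into a composite stimulus
#'
#' `pixels = signal_contrast * gabor + (1 - signal_contrast) * noise`; the
#' two contrasts sum to 1.
#'
#' @param gabor,noise `stimulus_image` objects on the same pixel grid.
#' @param signal_contrast Signal weight in `[0, 1]`; defaults to the value
#'   in the gabor's spec.
#' @return A `stimulus_image`.
#' @export
compose_stimulus <- function(gabor, noise,
                             signal_contrast = gabor$spec$signal_contrast) {
  if (!identical(dim(gabor$pixels), dim(noise$pixels))) {
    stop("compose_stimulus: gabor and noise grids differ", call. = FALSE)
  }
  if (signal_contrast < 0 || signal_contrast > 1) {
    stop("compose_stimulus: signal_contrast must lie in [0, 1]",
         call. = FALSE)
  }
  px <- signal_contrast * gabor$pixels + (1 - signal_contrast) * noise$pixels
  structure(list(pixels = px, spec = gabor$spec, role = gabor$role,
                 signal_contrast = signal_contrast,
                 orientation_deg = gabor$orientation_deg,
                 phase_rad = gabor$phase_rad, noise_seed = noise$seed),
            class = "stimulus_image")
}

#' Render the composite stimulus for one trial-table row
#'
#' Convenience wrapper: Gabor at the recorded raw orientation with a phase
#' drawn from the stimulus seed, noise from the same seed, composed at the
#' spec's signal contrast.
#'
#' @param raw_orientation_deg Raw carrier orientation (boundary + offset).
#' @param stim_seed Integer seed recorded in the trial table.
#' @param spec A [stimulus_spec()].
#' @export
render_stimulus <- function(raw_orientation_deg, stim_seed, spec,
                            role = c("target", "distracter")) {
  role <- match.arg(role)
  set.seed(stim_seed)
  phase <- stats::runif(1, 0, 2 * pi)
  g <- make_gabor(raw_orientation_deg, phase, spec, role = role)
  nz <- make_noise(spec, seed = stim_seed + 1L, role = role)
  compose_stimulus(g, nz)
}

#' Generate a trial design table
#'
#' One row per trial. Target and distracter boundary-relative orientations
#' are sampled independently from U(-10, 10) degrees; the probed side is a
#' fair coin. Experiment layouts:
#' \describe{
#'   \item{exp1}{both decision boundaries vertical (0 deg).}
#'   \item{exp2}{orthogonal boundaries with a fixed ring-to-boundary map:
#'     left ring vertical (0 deg), right ring horizontal (90 deg).}
#'   \item{exp3_cued}{vertical boundaries; a spatial cue precedes the
#'     stimuli and matches the probed side with probability 0.70. The
#'     attention indicator `A` codes invalid = -1, valid = +1.}
#'   \item{exp3_neutral}{as exp3_cued but the cue is uninformative;
#'     `cue_condition` is `neutral` and `A = 0`.}
#' }
#' A stimulus duration column (100 or 200 ms, exp3 only) is recorded but has
#' no perceptual consequence in the simulators.
#'
#' @param design One of `"exp1"`, `"exp2"`, `"exp3_cued"`, `"exp3_neutral"`.
#' @param n_trials Number of trials (> 0).
#' @param seed Integer seed.
#' @return A `data.frame` trial table with columns `trial_id`, `theta_T`,
#'   `theta_D`, `boundary_T`, `boundary_D`, `probe_side`, `cue_condition`,
#'   `A`, `raw_orientation_T`, `raw_orientation_D`, `stim_seed_T`,
#'   `stim_seed_D`, `stim_duration_ms`, `choice`, `correct`.
#' @export
generate_trials <- function(design = c("exp1", "exp2", "exp3_cued",
                                       "exp3_neutral"),
                            n_trials, seed = 1L) {
  design <- match.arg(design)
  if (n_trials <= 0) stop("generate_trials: n_trials must be > 0",
                          call. = FALSE)
  set.seed(seed)
  theta_T <- stats::runif(n_trials, -10, 10)
  theta_D <- stats::runif(n_trials, -10, 10)
  probe_side <- ifelse(stats::runif(n_trials) < 0.5, "left", "right")

  cue_condition <- rep("none", n_trials)
  A <- rep(NA_real_, n_trials)
  duration <- rep(NA_real_, n_trials)
  if (design == "exp3_cued") {
    cue_side <- ifelse(stats::runif(n_trials) < 0.5, "left", "right")
    match_cue <- stats::runif(n_trials) < 0.70
    probe_side <- ifelse(match_cue, cue_side,
                         ifelse(cue_side == "left", "right", "left"))
    cue_condition <- ifelse(probe_side == cue_side, "valid", "invalid")
    A <- ifelse(cue_condition == "valid", 1, -1)
    duration <- sample(c(100, 200), n_trials, replace = TRUE)
  } else if (design == "exp3_neutral") {
    cue_condition <- rep("neutral", n_trials)
    A <- rep(0, n_trials)
    duration <- sample(c(100, 200), n_trials, replace = TRUE)
  }

  if (design == "exp2") {
    # fixed ring -> boundary map; the target boundary follows the probe
    boundary_T <- ifelse(probe_side == "left", 0, 90)
    boundary_D <- ifelse(probe_side == "left", 90, 0)
  } else {
    boundary_T <- rep(0, n_trials)
    boundary_D <- rep(0, n_trials)
  }

  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_trials)
  data.frame(
    trial_id = seq_len(n_trials),
    theta_T = theta_T, theta_D = theta_D,
    boundary_T = boundary_T, boundary_D = boundary_D,
    probe_side = probe_side, cue_condition = cue_condition, A = A,
    raw_orientation_T = wrap_orientation(boundary_T + theta_T),
    raw_orientation_D = wrap_orientation(boundary_D + theta_D),
    stim_seed_T = seeds[seq_len(n_trials)],
    stim_seed_D = seeds[n_trials + seq_len(n_trials)],
    stim_duration_ms = duration,
    choice = NA_integer_, correct = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Wrap a raw orientation into (-90, 90]; orientation is circular mod 180.
wrap_orientation <- function(deg) {
  out <- ((deg + 90) %% 180) - 90
  ifelse(out == -90, 90, out)
}
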