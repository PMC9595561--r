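#' Pipeline configuration
#'
#' Assembles the settings for a full simulated-cohort run. Two tiers: the
#' table tier works on orientations alone (choice regressions and the
#' normalization model); the image tier renders stimuli and runs the
#' reverse-correlation analyses. Every stochastic stage derives its seed
#' from the master seed, so a config reproduces its outputs exactly.
#'
#' @param design Experiment design id (see [generate_trials()]).
#' @param n_subjects Cohort size.
#' @param n_trials Trials per subject.
#' @param observer Named list of cohort-level observer parameter means and
#'   SDs: `r_mean`, `r_sd`, `tau_mean`, `tau_sd`, `rho_mean`, `rho_sd`.
#' @param render Run the image tier (rendering + energy + kernels).
#' @param spec A [stimulus_spec()] for the image tier.
#' @param fit_norm Fit the normalization model per subject.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = keep results in memory only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = "exp1", n_subjects = 24,
                            n_trials = 900,
                            observer = list(r_mean = 3, r_sd = 0.5,
                                            tau_mean = 0.15, tau_sd = 0.05,
                                            rho_mean = 0.3, rho_sd = 0.1),
                            render = FALSE,
                            spec = stimulus_spec(pixels_per_deg = 16),
                            fit_norm = FALSE, seed = 1L, out_dir = NULL) {
  structure(list(design = design, n_subjects = n_subjects,
                 n_trials = n_trials, observer = observer,
                 render = render, spec = spec, fit_norm = fit_norm,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the simulation-and-analysis pipeline
#'
#' Stages, in dependency order: generate trial tables for a cohort of
#' simulated subjects; draw each subject's transducer parameters from the
#' cohort distribution and simulate choices; apply the chance-performance
#' exclusion; fit the consistency-bias regression per subject (with
#' attention interactions for the cued design); optionally fit the
#' normalization model per subject; optionally render stimuli, compute
#' energy profiles, decision kernels and the SVD component regression.
#' Writes CSV/JSON outputs when `out_dir` is set and returns a manifest.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest` list: per-stage outputs (`trials`,
#'   `subject_params`, `coefficients`, `norm_fits`, `kernel`, ...),
#'   `files` (paths written), `elapsed` (seconds per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(config = config, files = character(0),
                   elapsed = numeric(0), warnings = character(0))
  tic <- function() proc.time()[["elapsed"]]
  stage_time <- function(t0) round(tic() - t0, 3)

  # --- generate + simulate ----------------------------------------------
  t0 <- tic()
  set.seed(config$seed)
  ob <- config$observer
  cohort <- data.frame(
    subject = seq_len(config$n_subjects),
    r = pmax(0.2, stats::rnorm(config$n_subjects, ob$r_mean, ob$r_sd)),
    tau = pmax(0, stats::rnorm(config$n_subjects, ob$tau_mean, ob$tau_sd)),
    rho = stats::rnorm(config$n_subjects, ob$rho_mean, ob$rho_sd)
  )
  trials <- lapply(seq_len(config$n_subjects), function(s) {
    tr <- generate_trials(config$design, config$n_trials,
                          seed = config$seed + 1000L * s)
    pars <- observer_params("parametric", r = cohort$r[s],
                            tau = cohort$tau[s], rho = cohort$rho[s])
    simulate_parametric_observer(tr, pars, seed = config$seed + 1000L * s + 1L)
  })
  manifest$subject_params <- cohort
  manifest$elapsed["simulate"] <- stage_time(t0)

  # --- exclusion --------------------------------------------------------
  trials <- exclude_at_chance(trials)
  manifest$excluded <- attr(trials, "excluded")
  manifest$trials <- trials

  # --- choice regressions ----------------------------------------------
  t0 <- tic()
  attention <- config$design == "exp3_cued"
  preds <- c("theta_T", "theta_D", "consistency")
  if (attention) preds <- c(preds, "A_x_theta_T", "A_x_theta_D",
                            "A_x_consistency")
  coefs <- lapply(trials, function(tr) {
    X <- build_design(tr, preds)
    fit <- fit_choice_glm(X, tr$choice)
    stats::setNames(report_coefficients(fit, X), colnames(X))
  })
  manifest$coefficients <- do.call(rbind, coefs)
  manifest$elapsed["regress"] <- stage_time(t0)

  # --- normalization-model fits ----------------------------------------
  if (config$fit_norm) {
    t0 <- tic()
    variant <- if (attention) "attention" else "full"
    manifest$norm_fits <- lapply(seq_along(trials), function(s) {
      fit_norm_model(trials[[s]], variant, n_restarts = 5,
                     seed = config$seed + 7L * s)
    })
    manifest$elapsed["fit_norm"] <- stage_time(t0)
  }

  # --- image tier: energies, kernels, SVD ------------------------------
  if (config$render) {
    t0 <- tic()
    tr <- trials[[1]]
    bank <- build_filter_bank(config$spec)
    pxT <- t(vapply(seq_len(nrow(tr)), function(i) {
      as.vector(render_stimulus(tr$raw_orientation_T[i], tr$stim_seed_T[i],
                                config$spec, "target")$pixels)
    }, numeric(bank$n_px^2)))
    pxD <- t(vapply(seq_len(nrow(tr)), function(i) {
      as.vector(render_stimulus(tr$raw_orientation_D[i], tr$stim_seed_D[i],
                                config$spec, "distracter")$pixels)
    }, numeric(bank$n_px^2)))
    eT <- energy_profile(pxT, bank)
    eD <- energy_profile(pxD, bank)
    zT <- zscore_energies(eT)
    zD <- zscore_energies(eD)
    manifest$kernel <- decision_kernel(tr$choice, zT, zD,
                                       bank$orientations_deg)
    dec <- svd_profiles(rbind(eT$energy, eD$energy))
    sel <- select_tilt_component(dec, c(tr$theta_T, tr$theta_D))
    n <- nrow(tr)
    manifest$svd <- dec
    manifest$tilt_component <- sel
    manifest$component_fit <- component_regression(
      tr, sel$scores[seq_len(n)], sel$scores[n + seq_len(n)],
      attention = attention)
    manifest$elapsed["revcorr"] <- stage_time(t0)
  }

  # --- outputs ----------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      trials = file.path(config$out_dir, "trials_subject1.csv"),
      coefficients = file.path(config$out_dir, "coefficients.csv"),
      subject_params = file.path(config$out_dir, "subject_params.csv")
    )
    write_trial_table(trials[[1]], paths["trials"])
    utils::write.csv(manifest$coefficients, paths["coefficients"],
                     row.names = FALSE)
    utils::write.csv(cohort, paths["subject_params"], row.names = FALSE)
    if (!is.null(manifest$kernel)) {
      paths["kernel"] <- file.path(config$out_dir, "decision_kernel.csv")
      write_kernel(manifest$kernel, paths["kernel"])
    }
    manifest$files <- paths
  }
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", x$config$design, "-", length(x$trials),
      "subjects x", x$config$n_trials, "trials\n")
  cat("stages run:", paste(names(x$elapsed), collapse = ", "), "\n")
  if (length(x$files)) cat("files:", paste(basename(x$files),
                                           collapse = ", "), "\n")
  invisible(x)
}

trial_table_columns <- c(
  "trial_id", "theta_T", "theta_D", "boundary_T", "boundary_D",
  "probe_side", "cue_condition", "A", "raw_orientation_T",
  "raw_orientation_D", "stim_seed_T", "stim_seed_D", "stim_duration_ms",
  "choice", "correct")

#' Write / read a trial table as CSV
#'
#' The exact column set of [generate_trials()] is enforced on read;
#' a missing column raises an error naming it.
#'
#' @param trials Trial table.
#' @param path File path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials[, intersect(c(trial_table_columns, "p_cw"),
                                      names(trials))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_table_columns, names(tr))
  if (length(missing)) {
    stop("read_trial_table: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr
}

#' Write / read a decision kernel as CSV
#' @param kernel A `decision_kernel` data frame.
#' @param path File path.
#' @export
write_kernel <- function(kernel, path) {
  utils::write.csv(as.data.frame(kernel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  k <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("orientation_deg", "beta", "se")
  missing <- setdiff(need, names(k))
  if (length(missing)) {
    stop("read_kernel: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(k) <- c("decision_kernel", "data.frame")
  k
}

#' Write / read a model fit as JSON
#' @param fit A `choice_glm` or `norm_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- unclass(fit)
  obj$design <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
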