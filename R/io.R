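#' Read progress curves from a long-format CSV file
#'
#' Expects a comma-separated file with dot decimals and the header columns
#' `curve_id, time_min, signal_au, inhibitor_nM, substrate_uM, enzyme_nM`
#' (one row per time point). Rows are reassembled into one
#' [progress_curve()] per `curve_id`, sorted by time. Missing columns are
#' reported by name; rows with non-numeric values are reported with their
#' line numbers; duplicated times within a curve are an error.
#'
#' @param path file path.
#' @return a named list of [progress_curve()] objects
#'   (class `progress_curve_set`).
#' @export
read_progress_curves <- function(path) {
  required <- c("curve_id", "time_min", "signal_au", "inhibitor_nM",
                "substrate_uM", "enzyme_nM")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  num_cols <- setdiff(required, "curve_id")
  bad_lines <- integer(0)
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    bad_lines <- union(bad_lines, which(is.na(v) & !is.na(d[[cl]])))
    d[[cl]] <- v
  }
  if (length(bad_lines))
    stop("malformed (non-numeric) values on line(s): ",
         paste(sort(bad_lines) + 1L, collapse = ", "))   # +1 for header
  curves <- lapply(split(d, d$curve_id), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    if (any(duplicated(g$time_min)))
      stop("duplicated time points within curve '", g$curve_id[1], "'")
    progress_curve(g$time_min, g$signal_au, g$inhibitor_nM[1],
                   g$substrate_uM[1], g$enzyme_nM[1], g$curve_id[1])
  })
  structure(curves, class = c("progress_curve_set", "list"))
}

#' Write progress curves to a long-format CSV file
#'
#' Inverse of [read_progress_curves()]; numeric values are written with 15
#' significant digits so that a write/read round trip is lossless well
#' beyond 12 digits.
#'
#' @param curves a list of [progress_curve()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_progress_curves <- function(curves, path) {
  stopifnot(all(vapply(curves, inherits, TRUE, "progress_curve")))
  d <- do.call(rbind, lapply(curves, as.data.frame))
  for (cl in setdiff(names(d), "curve_id"))
    d[[cl]] <- sprintf("%.15g", d[[cl]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble an experiment configuration
#'
#' Bundles scheme, design, noise and analysis options into a validated,
#' YAML-serializable configuration driving [run_pipeline()].
#'
#' @param scheme a [kinetic_scheme()] or the list of its arguments.
#' @param design an [assay_design()] or the list of its arguments.
#' @param noise a [noise_model()], the list of its arguments, or `NULL`.
#' @param options analysis options: `simulator` (`"closed_form"`/`"ode"`),
#'   `weighted`, `alpha` (linearity-test level), `run_modality`, and
#'   `michaelis` (a list with `substrate_uM`, `inhibitor_nM`, `sigma_rel`
#'   describing the steady-state grid to simulate for the modality stage).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(scheme, design, noise = NULL,
                              options = list()) {
  if (!inherits(scheme, "kinetic_scheme"))
    scheme <- do.call(kinetic_scheme, scheme)
  if (!inherits(design, "assay_design"))
    design <- do.call(assay_design, design)
  if (!is.null(noise) && !inherits(noise, "noise_model"))
    noise <- do.call(noise_model, noise)
  known <- c("simulator", "weighted", "alpha", "run_modality", "michaelis",
             "progress_weighting", "fix_offset")
  unknown <- setdiff(names(options), known)
  if (length(unknown))
    stop("unknown option key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(simulator = "closed_form", weighted = FALSE,
                   alpha = 0.05, run_modality = FALSE, michaelis = NULL,
                   progress_weighting = "none", fix_offset = FALSE)
  options <- utils::modifyList(defaults, options)
  structure(list(scheme = scheme, design = design, noise = noise,
                 options = options),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' The round trip `read_experiment_config(write_experiment_config(x))` is
#' lossless; unknown top-level or option keys are rejected with a message
#' naming them.
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` returns an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- list(
    scheme = .compact(unclass(config$scheme)),
    design = .compact(unclass(config$design)),
    noise = if (!is.null(config$noise)) .compact(unclass(config$noise)),
    options = .compact(config$options))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

.compact <- function(x) x[!vapply(x, is.null, TRUE)]

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("scheme", "design", "noise", "options")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  experiment_config(scheme = x$scheme, design = x$design,
                    noise = x$noise,
                    options = if (is.null(x$options)) list() else x$options)
}

#' Hash a configuration for provenance records
#'
#' Deterministic 32-bit FNV-1a hash of the YAML serialization, reported as
#' 8 hex digits in pipeline reports so that any output can be traced to the
#' exact configuration that produced it.
#'
#' @param config an [experiment_config()].
#' @return an 8-character hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_experiment_config(config, tmp)
  h <- .fnv1a32(paste(readLines(tmp), collapse = "\n"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full inhibition-kinetics analysis pipeline
#'
#' Executes, in order: simulation (or ingestion) of the progress-curve
#' family; per-curve biphasic fits ([batch_fit()]); linear and hyperbolic
#' kobs analysis with model comparison ([fit_kobs_linear()],
#' [fit_kobs_hyperbolic()], [compare_kobs_models()]); the vi-independence
#' test; and, when requested and a Michaelis grid is available, the global
#' modality fit ([global_fit_modality()]) with conversion of Kiapp to the
#' true Ki under the selected modality. Every numeric table in the report
#' is re-derivable from the returned intermediates; the report carries the
#' configuration hash and seed, so a rerun with the same config is
#' deterministic.
#'
#' @param config an [experiment_config()].
#' @param curves optional pre-loaded list of [progress_curve()] objects;
#'   when `NULL`, curves are simulated from the config's scheme, design
#'   and noise model.
#' @return an object of class `pipeline_report`: a list with elements
#'   `curves`, `fits` (per-curve parameter table), `kobs_profile`,
#'   `slow_binding` (kon/koff/Kiapp), `model_comparison`,
#'   `vi_independence`, `modality`, `Ki_true`, `notes`, `provenance`.
#' @export
run_pipeline <- function(config, curves = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  opts <- config$options
  notes <- character(0)

  if (is.null(curves))
    curves <- simulate_experiment(config$scheme, config$design,
                                  noise = config$noise,
                                  simulator = opts$simulator)

  prof <- batch_fit(curves, alpha = opts$alpha,
                    weighting = opts$progress_weighting,
                    fix_offset = opts$fix_offset)
  fit_table <- do.call(rbind, lapply(prof$fits, function(f)
    data.frame(curve_id = f$curve_id, inhibitor_nM = f$inhibitor_nM,
               vi = f$vi, vs = f$vs, kobs = f$kobs,
               converged = f$converged, linear = f$linear)))
  rownames(fit_table) <- NULL

  lin <- fit_kobs_linear(prof, weighted = opts$weighted)
  hyp <- if (nrow(prof$profile) >= 5L) fit_kobs_hyperbolic(prof) else NULL
  cmp <- if (!is.null(hyp)) compare_kobs_models(lin, hyp) else {
    notes <- c(notes,
               "two-step comparison skipped: fewer than 5 kobs points")
    NULL
  }
  vi_test <- test_vi_independence(prof, alpha = opts$alpha)

  modality_res <- NULL
  Ki_true <- NA_real_
  if (isTRUE(opts$run_modality)) {
    if (is.null(opts$michaelis)) {
      notes <- c(notes,
                 "modality stage skipped: no Michaelis grid in configuration")
    } else {
      mg <- .simulate_michaelis(config$scheme, opts$michaelis,
                                seed = if (!is.null(config$noise))
                                  config$noise$seed else 1L)
      modality_res <- global_fit_modality(mg)
      if (is.finite(lin$Kiapp))
        Ki_true <- ki_from_kiapp(lin$Kiapp, modality_res$selected,
                                 S = config$design$S0,
                                 Km = modality_res$Km,
                                 alpha = modality_res$alpha)
    }
  }

  out <- list(curves = curves, fits = fit_table, kobs_profile = prof,
              slow_binding = lin, hyperbolic = hyp,
              model_comparison = cmp, vi_independence = vi_test,
              modality = modality_res, Ki_true = Ki_true, notes = notes,
              provenance = list(
                config_hash = config_hash(config),
                seed = if (!is.null(config$noise)) config$noise$seed else NA,
                simulator = opts$simulator,
                package_version = as.character(
                  utils::packageVersion("slowbindr"))))
  class(out) <- "pipeline_report"
  out
}

# steady-state Michaelis grid simulated from the scheme, with relative
# Gaussian noise on the rates (the grid mirrors duplicate-well averages)
.simulate_michaelis <- function(scheme, layout, seed = 1L) {
  stopifnot(all(c("substrate_uM", "inhibitor_nM") %in% names(layout)))
  E0 <- if (!is.null(layout$enzyme_nM)) layout$enzyme_nM else 1
  g <- expand.grid(substrate_uM = layout$substrate_uM,
                   inhibitor_nM = layout$inhibitor_nM)
  v <- steady_rate(scheme, g$substrate_uM, g$inhibitor_nM, E0)
  sigma <- if (!is.null(layout$sigma_rel)) layout$sigma_rel else 0
  if (sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(curve_seed(seed, "michaelis_grid"))
    v <- pmax(v * (1 + rnorm(length(v), 0, sigma)), 0)
  }
  michaelis_grid(g$substrate_uM, g$inhibitor_nM, v, enzyme_nM = E0)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("==== Slow-binding inhibition analysis report ====\n")
  cat("config", x$provenance$config_hash, "| seed",
      x$provenance$seed, "| simulator", x$provenance$simulator, "\n\n")
  cat("-- per-curve progress fits --\n")
  print(x$fits, row.names = FALSE, digits = 4)
  cat("\n-- slow-binding constants --\n")
  print(x$slow_binding)
  if (!is.null(x$model_comparison))
    cat("  kobs dependence:", x$model_comparison$selected,
        sprintf("(delta AICc = %.2f)\n", x$model_comparison$delta_aicc))
  cat("  vi vs [I]:", x$vi_independence$verdict,
      sprintf("(p = %.3g)\n", x$vi_independence$p_value))
  if (!is.null(x$modality)) {
    cat("\n-- modality --\n")
    print(x$modality)
    if (is.finite(x$Ki_true))
      cat(sprintf("  true Ki (from Kiapp under %s) = %g nM\n",
                  x$modality$selected, x$Ki_true))
  }
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}
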