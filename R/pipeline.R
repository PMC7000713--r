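#' Run manifest for a pipeline invocation
#'
#' Records what was run: the command label, a content digest of the
#' resolved configuration (stable under key reordering), the seed, the
#' output files produced, and an ISO-8601 timestamp.
#'
#' @param command Command label.
#' @param config Resolved configuration (named list).
#' @param seed Integer seed or `NULL`.
#' @param outputs Character vector of output file paths.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed = NULL, outputs = character()) {
  structure(list(command = command,
                 config_digest = config_digest(config),
                 seed = seed,
                 outputs = outputs,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Run '%s' at %s\n  config digest: %s\n  seed: %s\n  outputs:\n%s",
              x$command, x$timestamp, x$config_digest,
              if (is.null(x$seed)) "none" else x$seed,
              paste0("    ", x$outputs, collapse = "\n")), "\n")
  invisible(x)
}

.default_prediction_quantities <- c(
  "extinction_ratio", "plant_biomass_ratio", "plant_flux_ratio",
  "animal_flux_ratio", "plant_mmax_exponent", "animal_mmax_exponent",
  "npp_biomass_exponent", "diffusivity_exponent")

#' Evaluate the headline scaling predictions
#'
#' Computes the requested constant-free predictions — fold-change ratios
#' for a configurable size factor and the scaling exponents — from the
#' allometric machinery, one row per quantity with the driving inputs
#' echoed.
#'
#' @param config A configuration file path or named list.  Recognized
#'   keys: `mass_ratio` (default 10), `extinction_exponent` (default 2.5),
#'   `quantities` (comma-separated subset of the defaults; empty string
#'   requests nothing).
#' @return A data frame with columns `quantity`, `input`, `value`.
#' @export
run_predictions <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  ratio <- config_number(config, "mass_ratio", 10)
  exp_ext <- config_number(config, "extinction_exponent", 2.5)
  wanted <- config[["quantities"]]
  wanted <- if (is.null(wanted)) .default_prediction_quantities
            else trimws(strsplit(as.character(wanted), ",")[[1]])
  wanted <- wanted[nzchar(wanted)]
  bad <- setdiff(wanted, .default_prediction_quantities)
  if (length(bad))
    stop("unknown prediction quantities: ", paste(bad, collapse = ", "))

  scal <- extinction_scaling(composite_override = exp_ext)
  prm <- flux_params()
  ps1 <- plant_size_spectrum(r_min = 1e-6, r_max = 1)
  ps2 <- plant_size_spectrum(r_min = 1e-6, r_max = ratio)
  as1 <- animal_size_spectrum(m_min = 1e-6, m_max = 1)
  as2 <- animal_size_spectrum(m_min = 1e-6, m_max = ratio)
  m_max_grid <- 10^seq(0, 3, length.out = 13)

  vals <- list(
    extinction_ratio = function() extinction_risk_ratio(scal, ratio),
    plant_biomass_ratio = function()
      plant_total_biomass(ps2) / plant_total_biomass(ps1),
    plant_flux_ratio = function()
      plant_total_flux(ps2, prm) / plant_total_flux(ps1, prm),
    animal_flux_ratio = function()
      animal_total_flux(as2, prm) / animal_total_flux(as1, prm),
    plant_mmax_exponent = function() plant_mmax_exponent(ps1),
    animal_mmax_exponent = function() {
      b <- vapply(m_max_grid, function(mm)
        animal_total_flux(animal_size_spectrum(m_min = 1e-6 * mm, m_max = mm),
                          prm, method = "quadrature"), numeric(1))
      unname(stats::coef(stats::lm(log(b) ~ log(m_max_grid)))[2])
    },
    npp_biomass_exponent = function() {
      m <- 10^seq(0, 3, length.out = 7)
      unname(stats::coef(stats::lm(log(npp_from_biomass(m, ps1, prm)) ~ log(m)))[2])
    },
    diffusivity_exponent = function() {
      mdl <- diffusivity_model()
      log(cohort_diffusivity(1e4, mdl) / cohort_diffusivity(1, mdl)) / log(1e4)
    })
  inputs <- c(extinction_ratio = sprintf("mass_ratio=%g, exponent=%g", ratio, exp_ext),
              plant_biomass_ratio = sprintf("r_max factor=%g", ratio),
              plant_flux_ratio = sprintf("r_max factor=%g", ratio),
              animal_flux_ratio = sprintf("m_max factor=%g", ratio),
              plant_mmax_exponent = "eta=2, mass_exponent=8/3",
              animal_mmax_exponent = "epsilon=3/4, quadrature",
              npp_biomass_exponent = "default spectrum",
              diffusivity_exponent = "exponent=1.17, masses 1-1e4 kg")
  out <- data.frame(quantity = wanted,
                    input = unname(inputs[wanted]),
                    value = vapply(wanted, function(q) vals[[q]](), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes the three analyses end to end — (1) headline scaling
#' predictions, (2) forest-plot generation and power-law recovery of the
#' biomass/largest-tree exponent, (3) fauna calibration and the
#' size-threshold nutrient-diffusion sweep — writing one delimited table
#' per stage under `outdir` plus a manifest.  Deterministic given
#' `(config, seed)`.
#'
#' @param config Configuration file path or named list.  Recognized keys
#'   (all optional): `seed`, `n_plots`, `noise_sd`, `stems_per_plot`,
#'   `reference_phi`, `loss_rate`, `n_thresholds`, `mass_ratio`,
#'   `extinction_exponent`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; overrides the config key.
#' @return A list with elements `predictions`, `plots`, `fit`, `model`,
#'   `sweep`, `manifest`, invisibly.
#' @export
run_full_pipeline <- function(config = list(), outdir = tempfile("megabiota_"),
                              seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(seed)) seed <- as.integer(config_number(config, "seed", 1))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    val <- force(expr)
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), s, units = "secs"))))
    val
  }
  paths <- character()
  emit <- function(obj, name) {
    p <- file.path(outdir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }

  predictions <- stage("predict", run_predictions(config))
  emit(predictions, "predictions.csv")

  gen_cfg <- generator_config(
    seed = seed,
    n_plots = as.integer(config_number(config, "n_plots", 200)),
    stems_per_plot = as.integer(config_number(config, "stems_per_plot", 2500)),
    noise_sd = config_number(config, "noise_sd", 0.2))
  plots <- stage("generate", generate_forest_plots(gen_cfg))
  emit(plots, "forest_plots.csv")

  fit <- stage("fit", fit_power_law(plots$m_max, plots$m_tot))
  emit(data.frame(exponent = fit$exponent, intercept = fit$intercept,
                  ci_low = fit$ci_low, ci_high = fit$ci_high, n = fit$n,
                  method = fit$method, ci_method = fit$ci_method,
                  covers_predicted_0.625 = prediction_covered(fit, 0.625)),
       "scaling_fit.csv")

  fauna <- pleistocene_community()
  model <- stage("calibrate", calibrate_model(
    fauna, target_phi = config_number(config, "reference_phi", 4.4)))
  emit(as.data.frame(fauna), "fauna_community.csv")

  domain <- generate_amazon_like_grid()
  n_thr <- as.integer(config_number(config, "n_thresholds", 8))
  # descend through the cohort mass range, dropping below the smallest
  # cohort exactly once so the sweep ends at zero transport
  lg <- log10(range(fauna$mass_kg))
  thresholds <- c(Inf, 10^seq(lg[2] - 0.25, lg[1] + 0.05,
                              length.out = n_thr - 1), 10^(lg[1] - 0.5))
  sweep <- stage("sweep", run_threshold_experiment(
    domain,
    sim_config(loss_rate = config_number(config, "loss_rate", 4.4e-6)),
    fauna, model, thresholds))
  emit(sweep, "threshold_sweep.csv")

  manifest <- run_manifest("run-all", config, seed, paths)
  message(sprintf("[run-all] %d outputs in %.2fs", length(paths),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(predictions = predictions, plots = plots, fit = fit,
                 model = model, sweep = sweep, manifest = manifest))
}
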