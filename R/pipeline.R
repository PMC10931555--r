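#' Pipeline run configuration
#'
#' Configuration for [run_pipeline()]: the seed, the output directory, which
#' modalities to run, the analysis windows, and the per-sample ground-truth
#' parameters used by the simulation stage.
#'
#' @param seed Integer master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param out_dir Output directory (created if missing).
#' @param modalities Character vector among `"sans"`, `"saxs"`, `"waxs"`,
#'   `"dsc"`, `"fluor"`; may be empty.
#' @param samples List of sample descriptors; each a named list with `label`
#'   and `bud_wt_pct` plus optional ground-truth overrides: `d_g` (nm),
#'   `d` (nm), `Tm` (degC), `dH` (J/g), `fwhm` (degC), `eta_Pyr4PC`,
#'   `eta_Pyr10PC`, `crystalline` (logical: add crystalline drug peaks to
#'   the WAXS band), `noise` (relative noise level for every generator).
#' @param kp_window,tail_window SANS analysis windows, nm^-1.
#' @param dsc_pre,dsc_post DSC baseline windows, degC.
#' @param M_bud,M_lipid Molar masses for the composition arithmetic, g/mol.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("pipeline-"),
                       modalities = c("sans", "saxs", "waxs", "dsc",
                                      "fluor"),
                       samples = list(list(label = "surfactant",
                                           bud_wt_pct = 0)),
                       kp_window = c(0.31, 1.14), tail_window = c(4, 5),
                       dsc_pre = c(2, 8), dsc_post = c(36, 40),
                       M_bud = 430.53, M_lipid = 762) {
  known <- c("sans", "saxs", "waxs", "dsc", "fluor")
  if (length(modalities) > 0 && !all(modalities %in% known)) {
    stop("unknown modality: ",
         paste(setdiff(modalities, known), collapse = ", "), call. = FALSE)
  }
  for (s in samples) {
    if (is.null(s$label) || is.null(s$bud_wt_pct)) {
      stop("each sample needs `label` and `bud_wt_pct`", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 modalities = modalities, samples = samples,
                 kp_window = kp_window, tail_window = tail_window,
                 dsc_pre = dsc_pre, dsc_post = dsc_post,
                 M_bud = M_bud, M_lipid = M_lipid),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [run_config()]; a `seed` field is
#' required. File paths referenced by the configuration must exist.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must contain a `seed` field",
                            call. = FALSE)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

# default ground truth per sample, overridable per sample entry
.sample_truth <- function(s) {
  list(
    d_g = s$d_g %||% 3.88,
    d = s$d %||% 7.8,
    Tm = s$Tm %||% 28.1,
    dH = s$dH %||% 18.0,
    fwhm = s$fwhm %||% 12.5,
    eta_Pyr4PC = s$eta_Pyr4PC %||% 1.87,
    eta_Pyr10PC = s$eta_Pyr10PC %||% 1.13,
    crystalline = isTRUE(s$crystalline),
    noise = s$noise %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_record <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end simulate-analyse-report pipeline
#'
#' For every sample and requested modality: generates the synthetic
#' measurement with the sample's ground-truth parameters and a seed derived
#' deterministically from the master seed, writes the raw data file
#' (3-column `.dat` for scattering, CSV otherwise) and its ground-truth JSON
#' sidecar, runs the corresponding analysis stage, and writes one JSON
#' result record. A combined summary table (one row per sample) is written
#' as `summary.csv`. Stage failures are re-raised with the stage name.
#' Output is deterministic given the configuration (no timestamps).
#'
#' @param config A [run_config()] or path to a YAML configuration.
#' @param quiet Suppress per-stage progress messages (sent to stderr).
#' @return The summary `data.frame`, invisibly.
#' @export
#' @examples
#' cfg <- run_config(seed = 7, modalities = "fluor",
#'                   samples = list(list(label = "s0", bud_wt_pct = 0)))
#' summ <- run_pipeline(cfg, quiet = TRUE)
#' summ$eta_Pyr10PC
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  rows <- list()
  for (si in seq_along(config$samples)) {
    s <- config$samples[[si]]
    truth <- .sample_truth(s)
    seed0 <- config$seed + 1000L * si
    row <- list(sample = s$label, bud_wt_pct = s$bud_wt_pct,
                lipid_per_drug = if (s$bud_wt_pct > 0) {
                  molar_ratio(sample_composition(s$bud_wt_pct,
                                                 M_bud = config$M_bud,
                                                 M_lipid = config$M_lipid))
                } else NA_real_,
                d = NA_real_, d_g = NA_real_, Tm = NA_real_, dH = NA_real_,
                fwhm = NA_real_, eta_Pyr4PC = NA_real_,
                eta_Pyr10PC = NA_real_)
    base <- file.path(config$out_dir, s$label)

    if ("sans" %in% config$modalities) {
      say("[%s] sans: simulate + Kratky-Porod fit", s$label)
      res <- stage("sans", {
        p <- sans_model_params(thickness_true = truth$d_g,
                               background_B = 0.05,
                               wavelength_spread = 0,
                               noise_level = truth$noise, seed = seed0 + 1L)
        crv <- gen_sans_curve(p)
        write_dat(crv, paste0(base, "_sans.dat"))
        write_ground_truth(p, paste0(base, "_sans_truth.json"))
        sub <- subtract_incoherent_background(crv, config$tail_window)
        fit <- kratky_porod_fit(sub, config$kp_window)
        write_json_record(unclass(fit), paste0(base, "_sans_result.json"))
        fit
      })
      row$d_g <- res$d_g
    }
    if (any(c("saxs", "waxs") %in% config$modalities)) {
      cryst <- if (truth$crystalline) {
        list(c(13.1, 0.03, 3), c(14.8, 0.03, 2.5), c(14.9, 0.03, 2.2),
             c(16.2, 0.03, 2))
      } else list()
      p <- lamellar_model_params(d_true = truth$d,
                                 crystalline_peaks = cryst,
                                 noise_level = truth$noise,
                                 seed = seed0 + 2L)
      crv <- gen_saxs_waxs_pattern(p)
      write_dat(crv, paste0(base, "_saxs_waxs.dat"))
      write_ground_truth(p, paste0(base, "_saxs_waxs_truth.json"))
      if ("saxs" %in% config$modalities) {
        say("[%s] saxs: lamellar peak fit", s$label)
        res <- stage("saxs", {
          fit <- fit_lamellar_peaks(crv, n_orders = 2)
          write_json_record(list(d = fit$d, d_sd = fit$d_sd,
                                 order_ratio = fit$order_ratio,
                                 peaks = fit$peaks),
                            paste0(base, "_saxs_result.json"))
          fit
        })
        row$d <- res$d
      }
      if ("waxs" %in% config$modalities) {
        say("[%s] waxs: chain band + crystalline peaks", s$label)
        stage("waxs", {
          wres <- analyze_waxs(crv)
          write_json_record(list(broad_center = wres$broad_center,
                                 broad_width = wres$broad_width,
                                 classification = wres$classification,
                                 sharp_peaks = wres$sharp_peaks),
                            paste0(base, "_waxs_result.json"))
        })
      }
    }
    if ("dsc" %in% config$modalities) {
      say("[%s] dsc: baseline + transition parameters", s$label)
      res <- stage("dsc", {
        p <- endotherm_params(Tm_true = truth$Tm, dH_true = truth$dH,
                              fwhm_true = truth$fwhm,
                              baseline_intercept = 0.05,
                              baseline_slope = 0.002,
                              noise_level = truth$noise, seed = seed0 + 3L)
        tg <- gen_thermogram(p)
        write_thermogram_csv(tg, paste0(base, "_dsc.csv"))
        write_ground_truth(tg, paste0(base, "_dsc_truth.json"))
        fit <- transition_params(
          baseline_correct(tg, config$dsc_pre, config$dsc_post))
        write_json_record(list(Tm = fit$Tm, dH = fit$dH, fwhm = fit$fwhm,
                               baseline = fit$baseline),
                          paste0(base, "_dsc_result.json"))
        fit
      })
      row$Tm <- res$Tm
      row$dH <- res$dH
      row$fwhm <- res$fwhm
    }
    if ("fluor" %in% config$modalities) {
      for (probe in c("Pyr4PC", "Pyr10PC")) {
        say("[%s] fluor: %s excimer/monomer ratio", s$label, probe)
        res <- stage("fluor", {
          p <- fluorescence_params(
            eta_true = truth[[paste0("eta_", probe)]],
            noise_level = truth$noise,
            seed = seed0 + 4L + (probe == "Pyr10PC"))
          fl <- gen_fluorescence(p)
          write_trace_csv(fl$monomer, paste0(base, "_", probe,
                                             "_monomer.csv"))
          write_trace_csv(fl$excimer, paste0(base, "_", probe,
                                             "_excimer.csv"))
          write_ground_truth(p, paste0(base, "_", probe, "_truth.json"))
          lp <- lateral_pressure(fl$excimer, fl$monomer,
                                 probe_label = probe)
          write_json_record(unclass(lp),
                            paste0(base, "_", probe, "_result.json"))
          lp
        })
        row[[paste0("eta_", probe)]] <- res$eta
      }
    }
    rows[[si]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  summary <- if (length(rows) > 0 && length(config$modalities) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame()
  }
  utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(summary)
}
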