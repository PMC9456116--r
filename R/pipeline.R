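#' Assemble a pipeline run configuration
#'
#' A validated list describing which analysis stages to run and with what
#' parameters. Any stage may be omitted. Inputs may be data frames (tidy
#' workflow) or CSV paths (file workflow); paths are resolved at run time.
#' The same structure can be written to / read from YAML with
#' [write_run_config()] / [read_run_config()].
#'
#' @param dielectric List: `spectra` (long spectra table or CSV path),
#'   optional `fit_window` (Hz), `tau_ref` (s, default 100),
#'   `e_alpha_window` (K).
#' @param crystallization List: `traces` (list of RI time-trace tibbles or
#'   CSV paths) or a ready `onset_table`; optional `smooth_width`,
#'   `drop_factor`.
#' @param thermo List: `tg_drug_k`, `tg_excipient_k`, `dcp_drug`,
#'   `dcp_excipient` (J/(g K)), optional `observed` (data frame
#'   `w_excipient`, `tg_obs_k` or CSV path).
#' @param dsc List: `traces` (list of DSC tibbles or paths).
#' @param ri_scan List: `traces` (list of RI scan tibbles or paths),
#'   optional `exclusion_halfwidth` (K).
#' @param seed Integer seed recorded in the log (the analysis stages are
#'   deterministic; the seed matters when configs drive simulation).
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   all intermediate tables and a summary there.
#' @return Object of class `amglass_config` (a list).
#' @export
run_config <- function(dielectric = NULL, crystallization = NULL,
                       thermo = NULL, dsc = NULL, ri_scan = NULL,
                       seed = 1L, output_dir = NULL) {
  cfg <- list(schema = "amglass-config/1", seed = as.integer(seed),
              output_dir = output_dir,
              dielectric = dielectric, crystallization = crystallization,
              thermo = thermo, dsc = dsc, ri_scan = ri_scan)
  structure(cfg, class = "amglass_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$schema, "amglass-config/1")) {
    abort("unrecognized config schema (expected 'amglass-config/1').")
  }
  structure(cfg, class = "amglass_config")
}

#' @rdname run_config
#' @param config An `amglass_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.resolve_table <- function(x, reader) {
  if (is.character(x)) reader(x) else as_tibble(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)), parent = e)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in dependency order:
#' dielectric spectra -> HN fits -> relaxation map -> VFT -> Tg / fragility
#' / windowed activation energy; RI time traces -> onset detection ->
#' Arrhenius nucleation fit -> coupling parameter (when the dielectric
#' stage supplies a matching-window activation energy); component
#' thermodynamics -> Couchman-Karasz prediction -> divergence table; DSC
#' and RI scans -> calorimetric / refractometric Tg. Any stage error aborts
#' with the stage name; results of completed stages are kept in the
#' returned (partial) bundle stored on the error condition where possible.
#'
#' @param config An [run_config()] object (or a YAML path).
#' @return A list of class `amglass_run` with elements per executed stage
#'   (`hn_fits`, `relaxation_map`, `vft`, `fragility`, `onsets`,
#'   `nucleation`, `coupling`, `ck`, `dsc_tg`, `scan_tg`) and a `summary`
#'   tibble of the headline numbers, plus a `log` record of parameters.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "amglass_config") || is.list(config))
  out <- list()
  log <- list(package_version = as.character(utils::packageVersion("amglass")),
              r_version = R.version.string,
              seed = config$seed, timestamp = format(Sys.time()),
              parameters = list())

  if (!is.null(config$dielectric)) {
    dc <- config$dielectric
    out$hn_fits <- .stage("dielectric", {
      spectra <- .resolve_table(dc$spectra, read_dielectric_spectra)
      lapply(split_spectra(spectra), fit_hn, fit_window = dc$fit_window)
    })
    out$relaxation_map <- .stage("relaxation_map",
                                 build_relaxation_map(out$hn_fits))
    out$vft <- .stage("vft", fit_vft(out$relaxation_map))
    out$fragility <- .stage("fragility", {
      fragility_report(out$vft, tau_ref = dc$tau_ref %||% 100,
                       e_alpha_window = dc$e_alpha_window)
    })
    log$parameters$dielectric <- dc[setdiff(names(dc), "spectra")]
  }

  if (!is.null(config$crystallization)) {
    cz <- config$crystallization
    out$onsets <- .stage("onset_detection", {
      if (!is.null(cz$onset_table)) {
        .resolve_table(cz$onset_table, read_onset_table)
      } else {
        traces <- lapply(cz$traces, .resolve_table, reader = read_ri_time_trace)
        onset_table(lapply(traces, detect_onset,
                           smooth_width = cz$smooth_width %||% 11,
                           drop_factor = cz$drop_factor %||% 10))
      }
    })
    out$nucleation <- .stage("nucleation_fit",
                             fit_nucleation_arrhenius(out$onsets))
    if (!is.null(out$fragility) && "e_alpha_kj_mol" %in% names(out$fragility)) {
      out$coupling <- .stage("coupling", {
        coupling_parameter(
          out$nucleation$e_nucl_kj_mol, out$fragility$e_alpha_kj_mol,
          window = c(out$fragility$t_low_k, out$fragility$t_high_k),
          e_nucl_se = sqrt(out$nucleation$covariance[2, 2]),
          e_alpha_se = out$fragility$e_alpha_se_kj_mol
        )
      })
    }
    log$parameters$crystallization <- cz[setdiff(names(cz),
                                                 c("traces", "onset_table"))]
  }

  if (!is.null(config$thermo)) {
    th <- config$thermo
    out$ck <- .stage("couchman_karasz", {
      k <- k_from_delta_cp(th$dcp_excipient, th$dcp_drug)
      res <- list(k = k)
      if (!is.null(th$observed)) {
        obs <- .resolve_table(th$observed, function(p) {
          readr::read_csv(p, show_col_types = FALSE)
        })
        res$divergence <- ck_divergence(obs, th$tg_drug_k,
                                        th$tg_excipient_k, k)
      }
      res
    })
  }

  if (!is.null(config$dsc)) {
    out$dsc_tg <- .stage("dsc_tg", {
      traces <- lapply(config$dsc$traces, .resolve_table,
                       reader = read_dsc_trace)
      purrr::map_dfr(traces, function(tr) {
        r <- tg_from_dsc_step(tr)
        tibble(tg_k = r$tg_k, step_height = r$step_height,
               heating_rate_k_min = r$heating_rate_k_min)
      })
    })
  }

  if (!is.null(config$ri_scan)) {
    out$scan_tg <- .stage("ri_scan_tg", {
      traces <- lapply(config$ri_scan$traces, .resolve_table,
                       reader = read_ri_scan)
      purrr::map_dfr(traces, function(tr) {
        r <- tg_from_bilinear(
          tr, exclusion_halfwidth = config$ri_scan$exclusion_halfwidth %||% 2)
        tibble(tg_k = r$tg_k, tg_se_k = r$tg_se_k,
               slope_glass = r$slope_glass, slope_liquid = r$slope_liquid)
      })
    })
  }

  out$summary <- .pipeline_summary(out)
  out$log <- log
  class(out) <- "amglass_run"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_bundle(out, config$output_dir)
  }
  out
}

.pipeline_summary <- function(out) {
  rows <- list()
  add <- function(quantity, value, units) {
    rows[[length(rows) + 1]] <<- tibble(quantity = quantity, value = value,
                                        units = units)
  }
  if (!is.null(out$fragility)) {
    add("tg_dielectric", out$fragility$tg_dielectric_k, "K")
    add("m_p", out$fragility$m_p, "")
    if ("e_alpha_kj_mol" %in% names(out$fragility)) {
      add("e_alpha", out$fragility$e_alpha_kj_mol, "kJ/mol")
    }
  }
  if (!is.null(out$nucleation)) {
    add("e_nucl", out$nucleation$e_nucl_kj_mol, "kJ/mol")
    add("log10_t_onset0", out$nucleation$log10_t_onset0, "log10(s)")
  }
  if (!is.null(out$coupling)) add("s_coupling", out$coupling$s_coupling, "")
  if (!is.null(out$ck)) add("ck_k", out$ck$k, "")
  if (!is.null(out$dsc_tg) && nrow(out$dsc_tg)) {
    add("tg_dsc", out$dsc_tg$tg_k[[1]], "K")
  }
  if (!is.null(out$scan_tg) && nrow(out$scan_tg)) {
    add("tg_refractometry", out$scan_tg$tg_k[[1]], "K")
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(quantity = character(), value = double(), units = character())
}

.write_bundle <- function(out, dir) {
  if (!is.null(out$relaxation_map)) {
    write_relaxation_map(out$relaxation_map,
                         file.path(dir, "relaxation_map.csv"))
  }
  if (!is.null(out$vft)) {
    readr::write_csv(tidy(out$vft), file.path(dir, "vft_fit.csv"))
  }
  if (!is.null(out$fragility)) {
    readr::write_csv(out$fragility, file.path(dir, "fragility.csv"))
  }
  if (!is.null(out$onsets)) {
    write_onset_table(out$onsets, file.path(dir, "onset_table.csv"))
  }
  if (!is.null(out$nucleation)) {
    readr::write_csv(tidy(out$nucleation), file.path(dir, "nucleation_fit.csv"))
  }
  if (!is.null(out$coupling)) {
    readr::write_csv(out$coupling, file.path(dir, "coupling.csv"))
  }
  if (!is.null(out$ck$divergence)) {
    readr::write_csv(out$ck$divergence, file.path(dir, "ck_divergence.csv"))
  }
  readr::write_csv(out$summary, file.path(dir, "summary.csv"))
  yaml::write_yaml(out$log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' @export
print.amglass_run <- function(x, ...) {
  cat("<amglass_run>\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Convert a temperature in degrees Celsius to kelvin
#'
#' All package internals use kelvin; convert at the boundary.
#' @param celsius Temperatures in degrees C.
#' @return Temperatures in K.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15
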