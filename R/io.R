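# CSV dialects: header row, unit-suffixed column names (temperature_K,
# tau_alpha_s, ...), decimal point, comma separator. Internal tibbles use
# lower-case snake names; readers rename at the boundary and validate.

.read_csv_checked <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s) %s.", basename(path),
                  paste(missing_cols, collapse = ", ")))
  }
  for (cl in intersect(numeric_cols, names(df))) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      abort(sprintf("%s: column `%s` is not numeric (first offending row: %s).",
                    basename(path), cl,
                    if (is.na(bad)) "?" else as.character(bad)))
    }
  }
  df
}

#' Read dielectric spectra from CSV
#'
#' Expected columns: `temperature_K`, `frequency_Hz`, `eps_imag` and
#' optionally `eps_real` (may be empty). Frequencies must be positive and
#' strictly ascending within each temperature block.
#'
#' @param path CSV file path.
#' @return Tibble with columns `temperature_k`, `frequency_hz`, `eps_real`
#'   (if present), `eps_imag`; one row per (temperature, frequency).
#' @export
read_dielectric_spectra <- function(path) {
  df <- .read_csv_checked(path, c("temperature_K", "frequency_Hz", "eps_imag"),
                          c("temperature_K", "frequency_Hz", "eps_imag",
                            "eps_real"))
  out <- dplyr::rename(df, temperature_k = "temperature_K",
                       frequency_hz = "frequency_Hz")
  split_rows <- split(seq_len(nrow(out)), out$temperature_k)
  for (rows in split_rows) {
    f <- out$frequency_hz[rows]
    if (any(f <= 0)) {
      abort(sprintf("%s: non-positive frequency at row %d.", basename(path),
                    rows[which(f <= 0)[1]]))
    }
    if (is.unsorted(f, strictly = TRUE)) {
      bad <- rows[which(diff(f) <= 0)[1] + 1L]
      abort(sprintf("%s: frequencies not strictly ascending at row %d.",
                    basename(path), bad))
    }
  }
  as_tibble(out)
}

#' Split a long spectra table into per-temperature spectra
#'
#' @param spectra Output of [read_dielectric_spectra()] (or any long table
#'   with `temperature_k`).
#' @return A named list of single-temperature tibbles.
#' @export
split_spectra <- function(spectra) {
  sp <- split(as_tibble(spectra), spectra$temperature_k)
  lapply(sp, as_tibble)
}

#' Write dielectric spectra to CSV
#' @param spectra Tibble as returned by [sim_hn_spectrum()] (with a
#'   `temperature_k` column) or [read_dielectric_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dielectric_spectra <- function(spectra, path) {
  out <- dplyr::rename(as_tibble(spectra), temperature_K = "temperature_k",
                       frequency_Hz = "frequency_hz")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an isothermal refractometry time trace from CSV
#'
#' Expected columns: `time_s`, `refractive_index`, and `temperature_K`
#' either as a column or supplied via `temperature_k`.
#'
#' @param path CSV file path.
#' @param temperature_k Optional temperature (K) when not a column.
#' @return Tibble: `temperature_k`, `time_s`, `refractive_index`.
#' @export
read_ri_time_trace <- function(path, temperature_k = NULL) {
  df <- .read_csv_checked(path, c("time_s", "refractive_index"))
  if ("temperature_K" %in% names(df)) {
    df <- dplyr::rename(df, temperature_k = "temperature_K")
  } else if (!is.null(temperature_k)) {
    df$temperature_k <- temperature_k
  } else {
    abort(sprintf("%s: no `temperature_K` column and no `temperature_k` argument.",
                  basename(path)))
  }
  if (any(df$refractive_index <= 1 | df$refractive_index >= 2)) {
    bad <- which(df$refractive_index <= 1 | df$refractive_index >= 2)[1]
    abort(sprintf("%s: refractive index outside (1, 2) at row %d.",
                  basename(path), bad))
  }
  as_tibble(df[c("temperature_k", "time_s", "refractive_index")])
}

#' Read a refractometry cooling/heating scan from CSV
#' @param path CSV with columns `temperature_K`, `refractive_index`.
#' @return Tibble: `temperature_k`, `refractive_index`.
#' @export
read_ri_scan <- function(path) {
  df <- .read_csv_checked(path, c("temperature_K", "refractive_index"))
  as_tibble(dplyr::rename(df, temperature_k = "temperature_K"))
}

#' Read a DSC trace from CSV
#' @param path CSV with columns `temperature_K`, `heat_flow_W_per_g` and
#'   optionally `heating_rate_K_min`.
#' @return Tibble: `temperature_k`, `heat_flow`, `heating_rate_k_min`.
#' @export
read_dsc_trace <- function(path) {
  df <- .read_csv_checked(path, c("temperature_K", "heat_flow_W_per_g"))
  out <- dplyr::rename(df, temperature_k = "temperature_K",
                       heat_flow = "heat_flow_W_per_g")
  if ("heating_rate_K_min" %in% names(out)) {
    out <- dplyr::rename(out, heating_rate_k_min = "heating_rate_K_min")
  }
  as_tibble(out)
}

#' Read / write an onset table
#'
#' CSV columns: `temperature_K`, `t_onset_s`, `flag`
#' (`detected`/`censored`; censored rows may have empty `t_onset_s`).
#'
#' @param path CSV file path.
#' @return Tibble: `temperature_k`, `t_onset_s`, `flag`.
#' @export
read_onset_table <- function(path) {
  df <- .read_csv_checked(path, c("temperature_K", "t_onset_s"),
                          c("temperature_K", "t_onset_s"))
  if (!"flag" %in% names(df)) df$flag <- "detected"
  bad <- which(df$flag == "detected" &
                 (is.na(df$t_onset_s) | df$t_onset_s <= 0))[1]
  if (!is.na(bad)) {
    abort(sprintf("%s: detected row %d has non-positive or missing onset time.",
                  basename(path), bad))
  }
  as_tibble(dplyr::rename(df, temperature_k = "temperature_K"))
}

#' @rdname read_onset_table
#' @param table Onset table tibble (`temperature_k`, `t_onset_s`, `flag`).
#' @export
write_onset_table <- function(table, path) {
  readr::write_csv(dplyr::rename(as_tibble(table),
                                 temperature_K = "temperature_k"), path)
  invisible(path)
}

#' Read / write a relaxation map
#'
#' CSV columns: `temperature_K`, `tau_alpha_s`, optional `tau_sd_s`.
#'
#' @param path CSV file path.
#' @return Tibble: `temperature_k`, `tau_alpha_s` (+ `tau_sd_s`).
#' @export
read_relaxation_map <- function(path) {
  df <- .read_csv_checked(path, c("temperature_K", "tau_alpha_s"))
  if (any(df$tau_alpha_s <= 0)) {
    abort(sprintf("%s: non-positive tau_alpha_s at row %d.", basename(path),
                  which(df$tau_alpha_s <= 0)[1]))
  }
  as_tibble(dplyr::rename(df, temperature_k = "temperature_K"))
}

#' @rdname read_relaxation_map
#' @param map Relaxation-map tibble.
#' @export
write_relaxation_map <- function(map, path) {
  readr::write_csv(dplyr::rename(as_tibble(map),
                                 temperature_K = "temperature_k"), path)
  invisible(path)
}
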