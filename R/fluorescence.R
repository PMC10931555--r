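#' Lateral-pressure parameter from excimer/monomer time traces
#'
#' The lateral-pressure parameter of a pyrene-labelled bilayer is the ratio
#' of the average excimer emission intensity (broad band, 480 nm) to the
#' average monomer band-I intensity (376 nm), eta = <I_excimer> /
#' <I_monomer>, both averaged over the time-based measurement. Its
#' uncertainty is propagated to first order (delta method) from the two
#' standard errors of the mean:
#' eta_sd = eta * sqrt((sem_e / mean_e)^2 + (sem_m / mean_m)^2).
#'
#' @param excimer [time_trace()] recorded at the excimer wavelength.
#' @param monomer [time_trace()] recorded at the monomer wavelength.
#' @param probe_label Optional probe tag (`"Pyr4PC"` or `"Pyr10PC"`).
#' @param expected_wavelengths Length-2 numeric `c(excimer, monomer)` in nm
#'   used to validate trace metadata (+/- 3 nm tolerance); set to `NULL` to
#'   skip the check.
#' @return An object of class `lateral_pressure_result`: `eta`, `eta_sd`
#'   (SEM-based, recorded in `error_type`), `n_samples_monomer`,
#'   `n_samples_excimer`, `probe_label`.
#' @export
#' @examples
#' tr <- gen_fluorescence(fluorescence_params(eta_true = 1.87))
#' lateral_pressure(tr$excimer, tr$monomer, probe_label = "Pyr4PC")$eta
lateral_pressure <- function(excimer, monomer,
                             probe_label = NA_character_,
                             expected_wavelengths = c(480, 376)) {
  stopifnot(inherits(excimer, "time_trace"), inherits(monomer, "time_trace"))
  if (length(excimer$I) < 10L || length(monomer$I) < 10L) {
    stop("each trace must contain at least 10 samples", call. = FALSE)
  }
  if (!is.null(expected_wavelengths)) {
    if (abs(excimer$wavelength - expected_wavelengths[1]) > 3 ||
        abs(monomer$wavelength - expected_wavelengths[2]) > 3) {
      stop(sprintf(paste0("wavelength metadata mismatch: expected excimer ",
                          "near %g nm and monomer near %g nm, got %g / %g"),
                   expected_wavelengths[1], expected_wavelengths[2],
                   excimer$wavelength, monomer$wavelength), call. = FALSE)
    }
  }
  mean_m <- mean(monomer$I)
  mean_e <- mean(excimer$I)
  if (mean_m <= 0) {
    stop("mean monomer intensity must be positive", call. = FALSE)
  }
  n_m <- length(monomer$I)
  n_e <- length(excimer$I)
  sem_m <- stats::sd(monomer$I) / sqrt(n_m)
  sem_e <- stats::sd(excimer$I) / sqrt(n_e)
  eta <- mean_e / mean_m
  eta_sd <- eta * sqrt((sem_e / mean_e)^2 + (sem_m / mean_m)^2)
  structure(list(eta = eta, eta_sd = eta_sd,
                 n_samples_monomer = n_m, n_samples_excimer = n_e,
                 probe_label = probe_label, error_type = "SEM-propagated"),
            class = "lateral_pressure_result")
}

#' @export
print.lateral_pressure_result <- function(x, ...) {
  cat("<lateral_pressure_result>\n")
  cat(sprintf("  eta = %.4f +/- %.4f (%s%s)\n", x$eta, x$eta_sd,
              x$error_type,
              if (!is.na(x$probe_label)) paste0(", ", x$probe_label) else ""))
  invisible(x)
}

#' Normalise an emission spectrum to monomer band I
#'
#' Rescales all intensities so that the local maximum nearest the monomer
#' band-I wavelength equals 100, the standard presentation of pyrene
#' emission spectra. The band is located by a local-maximum search inside
#' `band +/- tolerance` to tolerate small calibration offsets.
#'
#' @param spec An [emission_spectrum()].
#' @param band Monomer band-I wavelength, nm (default 376).
#' @param tolerance Search half-window around `band`, nm.
#' @return The normalised [emission_spectrum()]; `meta$normalisation` records
#'   the scale factor and band location used.
#' @export
#' @examples
#' sp <- gen_fluorescence(fluorescence_params(eta_true = 1.13))$spectrum
#' nsp <- normalize_spectrum(sp)
#' max(nsp$I[abs(nsp$wavelength - 480) < 5])  # ~113
normalize_spectrum <- function(spec, band = 376, tolerance = 3) {
  stopifnot(inherits(spec, "emission_spectrum"))
  if (band - tolerance < min(spec$wavelength) ||
      band + tolerance > max(spec$wavelength)) {
    stop("spectrum does not cover the monomer band", call. = FALSE)
  }
  sel <- which(spec$wavelength >= band - tolerance &
               spec$wavelength <= band + tolerance)
  i_band <- sel[which.max(spec$I[sel])]
  I_band <- spec$I[i_band]
  if (I_band <= 0) {
    stop("zero intensity at the monomer band: cannot normalise",
         call. = FALSE)
  }
  out <- spec
  out$I <- spec$I * (100 / I_band)
  out$meta$normalisation <- list(band_wavelength = spec$wavelength[i_band],
                                 scale = 100 / I_band)
  out
}
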