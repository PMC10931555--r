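#' Fluorescence emission spectrum container
#'
#' @param wavelength Emission wavelength grid in nm, strictly increasing.
#' @param I Intensity (counts/s or normalised), same length.
#' @param meta Named list of metadata (probe label, temperature, ...).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, I, meta = list()) {
  wavelength <- as.numeric(wavelength)
  I <- as.numeric(I)
  if (length(wavelength) != length(I)) {
    stop("`wavelength` and `I` must have the same length", call. = FALSE)
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("`wavelength` must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelength = wavelength, I = I, meta = meta),
            class = "emission_spectrum")
}

#' Fixed-wavelength fluorescence time trace container
#'
#' @param t Time grid in seconds, strictly increasing.
#' @param I Intensity in counts/s, non-negative.
#' @param wavelength Emission wavelength of the trace, nm.
#' @param meta Named list of metadata.
#' @return An object of class `time_trace`.
#' @export
time_trace <- function(t, I, wavelength, meta = list()) {
  t <- as.numeric(t)
  I <- as.numeric(I)
  if (length(t) != length(I)) {
    stop("`t` and `I` must have the same length", call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  if (any(I < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(t = t, I = I, wavelength = wavelength, meta = meta),
            class = "time_trace")
}

#' Parameters for the synthetic pyrene fluorescence generator
#'
#' Ground truth for [gen_fluorescence()]. The emission spectrum is the sum
#' of five narrow Gaussian monomer vibronic bands (band I at the monomer
#' wavelength, default 376 nm) and one broad unstructured excimer band
#' (default maximum 480 nm); the monomer and excimer scales are solved
#' exactly so that the spectrum satisfies I(excimer) / I(monomer) =
#' `eta_true`. Time traces at the two wavelengths are white-noise series
#' with means `monomer_mean` and `eta_true * monomer_mean`.
#'
#' @param eta_true Ground-truth excimer/monomer intensity ratio (> 0).
#' @param monomer_mean Mean monomer trace intensity, counts/s (> 0).
#' @param vibronic_band_positions Length-2 numeric: wavelength of monomer
#'   band I and of the excimer maximum, nm (default `c(376, 480)`).
#' @param trace_duration Trace length in seconds (default 120, the
#'   acquisition time).
#' @param sampling_interval Sampling step in seconds (default 0.5).
#' @param noise_level Relative noise (sd / mean) of the traces and spectrum.
#' @param seed Integer RNG seed.
#' @return An object of class `fluorescence_params`.
#' @export
fluorescence_params <- function(eta_true = 1.13, monomer_mean = 1e5,
                                vibronic_band_positions = c(376, 480),
                                trace_duration = 120,
                                sampling_interval = 0.5,
                                noise_level = 0, seed = 1L) {
  if (eta_true <= 0) stop("`eta_true` must be > 0", call. = FALSE)
  if (monomer_mean <= 0) stop("`monomer_mean` must be > 0", call. = FALSE)
  if (length(vibronic_band_positions) != 2L) {
    stop("`vibronic_band_positions` must be c(monomer, excimer)",
         call. = FALSE)
  }
  if (trace_duration <= 0 || sampling_interval <= 0) {
    stop("trace duration and sampling interval must be > 0", call. = FALSE)
  }
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  structure(list(eta_true = eta_true, monomer_mean = monomer_mean,
                 vibronic_band_positions = as.numeric(vibronic_band_positions),
                 trace_duration = trace_duration,
                 sampling_interval = sampling_interval,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "fluorescence_params")
}

# Monomer vibronic band offsets from band I (nm), relative amplitudes and
# Gaussian sigmas: five bands (I-V) of the pyrene monomer progression.
.monomer_bands <- list(offsets = c(0, 10, 20, 30, 41),
                       amplitudes = c(1.00, 0.62, 0.48, 0.30, 0.15),
                       sigma = 3)
.excimer_sigma <- 35

#' Generate synthetic pyrene emission data
#'
#' Returns the emission spectrum over 360-650 nm (0.5 nm increment) and the
#' two fixed-wavelength time traces (monomer and excimer). Noise-free, the
#' spectrum's intensity at the excimer maximum divided by its intensity at
#' monomer band I equals `eta_true` exactly, and the traces are constant at
#' `monomer_mean` and `eta_true * monomer_mean`.
#'
#' @param params A [fluorescence_params()] record.
#' @return A list with elements `spectrum` ([emission_spectrum()]),
#'   `monomer` and `excimer` (both [time_trace()]); ground truth in each
#'   object's metadata.
#' @export
#' @examples
#' out <- gen_fluorescence(fluorescence_params(eta_true = 1.13))
#' mean(out$excimer$I) / mean(out$monomer$I)
gen_fluorescence <- function(params) {
  stopifnot(inherits(params, "fluorescence_params"))
  lam_m <- params$vibronic_band_positions[1]
  lam_e <- params$vibronic_band_positions[2]
  lam <- seq(360, 650, by = 0.5)
  mb <- .monomer_bands
  mshape <- function(l) {
    Reduce(`+`, Map(function(off, amp) {
      gaussian_peak(l, lam_m + off, mb$sigma, amp)
    }, mb$offsets, mb$amplitudes))
  }
  eshape <- function(l) gaussian_peak(l, lam_e, .excimer_sigma, 1)
  # Solve a*M + b*E for exact band-I / excimer intensities (1, eta_true).
  A <- matrix(c(mshape(lam_m), eshape(lam_m),
                mshape(lam_e), eshape(lam_e)), 2, 2, byrow = TRUE)
  ab <- solve(A, c(1, params$eta_true))
  spec_I <- (ab[1] * mshape(lam) + ab[2] * eshape(lam)) * params$monomer_mean
  t <- seq(0, params$trace_duration, by = params$sampling_interval)
  n <- length(t)
  mu_m <- params$monomer_mean
  mu_e <- params$eta_true * params$monomer_mean
  Im <- rep(mu_m, n)
  Ie <- rep(mu_e, n)
  if (params$noise_level > 0) {
    eps <- with_local_seed(params$seed, {
      list(spec = stats::rnorm(length(lam), 0,
                               params$noise_level * pmax(spec_I, 0)),
           m = stats::rnorm(n, 0, params$noise_level * mu_m),
           e = stats::rnorm(n, 0, params$noise_level * mu_e))
    })
    spec_I <- pmax(spec_I + eps$spec, 0)
    Im <- pmax(Im + eps$m, 0)
    Ie <- pmax(Ie + eps$e, 0)
  }
  gt <- unclass(params)
  list(
    spectrum = emission_spectrum(lam, spec_I, meta = list(ground_truth = gt)),
    monomer = time_trace(t, Im, wavelength = lam_m,
                         meta = list(ground_truth = gt)),
    excimer = time_trace(t, Ie, wavelength = lam_e,
                         meta = list(ground_truth = gt))
  )
}

#' Read a time trace or spectrum from CSV
#'
#' Two-column CSV with a header row: (t, I) for traces, (wavelength, I) for
#' spectra.
#'
#' @param path CSV file path.
#' @param wavelength For traces: the emission wavelength of the trace, nm.
#' @return A [time_trace()].
#' @export
read_trace_csv <- function(path, wavelength) {
  tab <- utils::read.csv(path)
  time_trace(tab[[1]], tab[[2]], wavelength = wavelength)
}

#' @rdname read_trace_csv
#' @export
read_spectrum_csv <- function(path) {
  tab <- utils::read.csv(path)
  emission_spectrum(tab[[1]], tab[[2]])
}

#' Write a time trace or spectrum to CSV
#'
#' @param x A [time_trace()] or [emission_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  if (inherits(x, "time_trace")) {
    utils::write.csv(data.frame(t_s = x$t, I = x$I), path, row.names = FALSE)
  } else if (inherits(x, "emission_spectrum")) {
    utils::write.csv(data.frame(wavelength_nm = x$wavelength, I = x$I), path,
                     row.names = FALSE)
  } else {
    stop("`x` must be a time_trace or emission_spectrum", call. = FALSE)
  }
  invisible(path)
}
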