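#' Parameters for the synthetic SAXS/WAXS pattern generator
#'
#' Ground truth for [gen_saxs_waxs_pattern()]. The small-angle region holds
#' `n_orders` Lorentzian diffraction orders of a lamellar phase at
#' q_n = 2 pi n / d_true on a linear diffuse background (mirroring the peak
#' model used in the analysis stage). The wide-angle region holds one broad
#' Gaussian chain-packing band (liquid-like acyl chains, ~14 nm^-1) plus any
#' number of sharp Gaussian crystalline-drug peaks.
#'
#' @param d_true Ground-truth lamellar repeat distance in nm (> 0).
#' @param n_orders Number of diffraction orders (>= 1).
#' @param peak_widths Lorentzian half-widths at half maximum per order,
#'   nm^-1 (recycled to `n_orders`); all > 0.
#' @param peak_amplitudes Peak amplitudes above background per order
#'   (recycled).
#' @param bg_intercept,bg_slope Linear background coefficients over the
#'   small-angle window.
#' @param waxs_broad_center Centre of the broad chain band, nm^-1.
#' @param waxs_broad_width Gaussian sigma of the broad band, nm^-1.
#' @param waxs_broad_amplitude Height of the broad band.
#' @param crystalline_peaks List of `c(center, width, amplitude)` triples
#'   (width = Gaussian sigma, nm^-1) for sharp crystalline reflections;
#'   empty list for a fluid-only pattern.
#' @param q_grid_saxs,q_grid_waxs q grids for the two regions, nm^-1.
#' @param noise_level Relative counting-noise scale (>= 0).
#' @param seed Integer RNG seed.
#'
#' @return An object of class `lamellar_model_params`.
#' @export
lamellar_model_params <- function(d_true = 7.8,
                                  n_orders = 2L,
                                  peak_widths = 0.06,
                                  peak_amplitudes = c(100, 30),
                                  bg_intercept = 5,
                                  bg_slope = -0.5,
                                  waxs_broad_center = 14,
                                  waxs_broad_width = 1.3,
                                  waxs_broad_amplitude = 10,
                                  crystalline_peaks = list(),
                                  q_grid_saxs = seq(0.1, 3, by = 0.004),
                                  q_grid_waxs = seq(10, 18, by = 0.01),
                                  noise_level = 0,
                                  seed = 1L) {
  if (d_true <= 0) stop("`d_true` must be > 0", call. = FALSE)
  n_orders <- as.integer(n_orders)
  if (n_orders < 1L) stop("`n_orders` must be >= 1", call. = FALSE)
  peak_widths <- rep_len(as.numeric(peak_widths), n_orders)
  peak_amplitudes <- rep_len(as.numeric(peak_amplitudes), n_orders)
  if (any(peak_widths <= 0)) {
    stop("all `peak_widths` must be > 0 (zero-width peaks are degenerate)",
         call. = FALSE)
  }
  if (waxs_broad_width <= 0) stop("`waxs_broad_width` must be > 0",
                                  call. = FALSE)
  for (pk in crystalline_peaks) {
    if (length(pk) != 3L || pk[2] <= 0) {
      stop("each crystalline peak must be c(center, width > 0, amplitude)",
           call. = FALSE)
    }
  }
  centers <- vapply(crystalline_peaks, `[`, numeric(1), 1L)
  if (anyDuplicated(centers)) {
    stop("crystalline peak centers must be distinct", call. = FALSE)
  }
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  structure(list(d_true = d_true, n_orders = n_orders,
                 peak_widths = peak_widths,
                 peak_amplitudes = peak_amplitudes,
                 bg_intercept = bg_intercept, bg_slope = bg_slope,
                 waxs_broad_center = waxs_broad_center,
                 waxs_broad_width = waxs_broad_width,
                 waxs_broad_amplitude = waxs_broad_amplitude,
                 crystalline_peaks = crystalline_peaks,
                 q_grid_saxs = as.numeric(q_grid_saxs),
                 q_grid_waxs = as.numeric(q_grid_waxs),
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "lamellar_model_params")
}

# Lorentzian with half-width-at-half-maximum w and height A at the centre.
lorentzian <- function(q, center, w, A) A * w^2 / ((q - center)^2 + w^2)

gaussian_peak <- function(q, center, sigma, A) {
  A * exp(-(q - center)^2 / (2 * sigma^2))
}

#' Generate a synthetic SAXS/WAXS pattern
#'
#' Builds the noise-free lamellar diffraction pattern (Lorentzian orders at
#' q_n = 2 pi n / d on a linear background) over the small-angle grid and
#' the broad chain band plus optional crystalline peaks over the wide-angle
#' grid, then adds seeded counting noise (sd = noise_level * sqrt(I)).
#'
#' @param params A [lamellar_model_params()] record.
#' @return A [scattering_curve()] with modality `"SAXS/WAXS"` spanning both
#'   grids; ground truth in `meta$ground_truth`.
#' @export
#' @examples
#' p <- lamellar_model_params(d_true = 7.8, n_orders = 2)
#' crv <- gen_saxs_waxs_pattern(p)
#' crv$q[which.max(crv$I)]  # first-order peak near 2*pi/7.8 = 0.8055 nm^-1
gen_saxs_waxs_pattern <- function(params) {
  stopifnot(inherits(params, "lamellar_model_params"))
  qs <- params$q_grid_saxs
  qw <- params$q_grid_waxs
  Is <- params$bg_intercept + params$bg_slope * qs
  for (n in seq_len(params$n_orders)) {
    Is <- Is + lorentzian(qs, 2 * pi * n / params$d_true,
                          params$peak_widths[n], params$peak_amplitudes[n])
  }
  Iw <- gaussian_peak(qw, params$waxs_broad_center, params$waxs_broad_width,
                      params$waxs_broad_amplitude)
  for (pk in params$crystalline_peaks) {
    Iw <- Iw + gaussian_peak(qw, pk[1], pk[2], pk[3])
  }
  q <- c(qs, qw)
  I <- c(Is, Iw)
  sigma <- params$noise_level * sqrt(pmax(I, 0))
  if (params$noise_level > 0) {
    I <- I + with_local_seed(params$seed, stats::rnorm(length(q), 0, sigma))
  }
  scattering_curve(q = q, I = I,
                   sigma = if (params$noise_level > 0) sigma else NULL,
                   modality = "SAXS/WAXS",
                   meta = list(ground_truth = unclass(params)))
}
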