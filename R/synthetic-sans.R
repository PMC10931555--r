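#' Parameters for the synthetic SANS curve generator
#'
#' Ground-truth parameter record for [gen_sans_curve()]. Three form-factor
#' models are available, all parameterised by the bilayer thickness:
#'
#' * `"guinier_sheet"`: the thin-sheet Guinier law
#'   I(q) = C exp(-q^2 Rg^2) / q^2 + B, with Rg = thickness / sqrt(12).
#' * `"uniform_slab"`: the exact thickness form factor of a uniform slab,
#'   I(q) = C sinc^2(q t / 2) / q^2 + B (sinc x = sin(x)/x), whose low-q
#'   expansion reduces to the Guinier sheet.
#' * `"core_shell_vesicle"`: a monodisperse hollow sphere with shell
#'   thickness equal to the bilayer thickness, normalised so I(0) = C,
#'   dilute limit (structure factor unity).
#'
#' Instrument effects: Gaussian wavelength-spread smearing with
#' sigma_q = q (dlambda/lambda) / 2.355 (the spread is treated as a
#' FWHM-like quantity, the usual Gaussian surrogate for a velocity-selector
#' triangular distribution), and seeded counting noise with standard
#' deviation `noise_level * sqrt(I)`.
#'
#' @param model_kind `"guinier_sheet"`, `"uniform_slab"` or
#'   `"core_shell_vesicle"`.
#' @param thickness_true Ground-truth bilayer thickness in nm (> 0).
#' @param scale_C Intensity scale constant (> 0), relative units.
#' @param background_B Flat incoherent background level (>= 0).
#' @param vesicle_radius Mean shell radius in nm (core-shell model only);
#'   default 39.5 nm, half the 79 nm hydrodynamic diameter of extruded
#'   vesicles.
#' @param wavelength_spread Relative wavelength spread dlambda/lambda (>= 0);
#'   0 disables smearing. The instrument value is 0.10.
#' @param q_grid Strictly increasing positive q values in nm^-1; default 400
#'   log-spaced points over the measured 0.05-5 nm^-1 window.
#' @param noise_level Relative counting-noise scale (>= 0); 0 disables noise.
#' @param seed Integer RNG seed for the noise draw.
#'
#' @return An object of class `sans_model_params`.
#' @export
sans_model_params <- function(model_kind = c("guinier_sheet", "uniform_slab",
                                             "core_shell_vesicle"),
                              thickness_true = 3.88,
                              scale_C = 1,
                              background_B = 0,
                              vesicle_radius = 39.5,
                              wavelength_spread = 0,
                              q_grid = exp(seq(log(0.05), log(5),
                                               length.out = 400)),
                              noise_level = 0,
                              seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (!is.numeric(thickness_true) || thickness_true <= 0) {
    stop("`thickness_true` must be > 0", call. = FALSE)
  }
  if (scale_C <= 0) stop("`scale_C` must be > 0", call. = FALSE)
  if (background_B < 0) stop("`background_B` must be >= 0", call. = FALSE)
  if (vesicle_radius <= thickness_true / 2) {
    stop("`vesicle_radius` must exceed half the shell thickness",
         call. = FALSE)
  }
  if (wavelength_spread < 0) {
    stop("`wavelength_spread` must be >= 0", call. = FALSE)
  }
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  if (anyNA(q_grid) || any(q_grid <= 0)) {
    stop("`q_grid` must be positive (q = 0 is excluded: the thin-sheet ",
         "intensity diverges as q^-2)", call. = FALSE)
  }
  if (is.unsorted(q_grid, strictly = TRUE)) {
    stop("`q_grid` must be strictly increasing", call. = FALSE)
  }
  structure(list(model_kind = model_kind, thickness_true = thickness_true,
                 scale_C = scale_C, background_B = background_B,
                 vesicle_radius = vesicle_radius,
                 wavelength_spread = wavelength_spread,
                 q_grid = as.numeric(q_grid), noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "sans_model_params")
}

# Noise-free, unsmeared coherent model (no background), vectorised over q.
sans_model_intensity <- function(q, params) {
  t <- params$thickness_true
  C <- params$scale_C
  switch(params$model_kind,
    guinier_sheet = {
      Rg <- t / sqrt(12)
      C * exp(-(q * Rg)^2) / q^2
    },
    uniform_slab = {
      x <- q * t / 2
      C * (sin(x) / x)^2 / q^2
    },
    core_shell_vesicle = {
      r_in <- params$vesicle_radius - t / 2
      r_out <- params$vesicle_radius + t / 2
      A <- function(q, R) {
        x <- q * R
        (4 / 3) * pi * R^3 * 3 * (sin(x) - x * cos(x)) / x^3
      }
      v_shell <- (4 / 3) * pi * (r_out^3 - r_in^3)
      C * ((A(q, r_out) - A(q, r_in)) / v_shell)^2
    }
  )
}

# Gaussian resolution smearing of a model function f(q):
# I_s(q) = integral f(q') N(q'; q, sigma_q) dq', sigma_q = q*spread/2.355.
# Gauss-Hermite quadrature, nodes clipped to q' > 0 with weight renormalisation.
smear_model <- function(f, q, spread, n_nodes = 21L) {
  if (spread == 0) return(f(q))
  gh <- gauss_hermite_nodes(n_nodes)
  sigma <- q * spread / 2.355
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    qq <- q[i] + sqrt(2) * sigma[i] * gh$nodes
    ok <- qq > 0
    w <- gh$weights[ok] / sum(gh$weights[ok])
    out[i] <- sum(w * f(qq[ok]))
  }
  out
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue method.
gauss_hermite_nodes <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Generate a synthetic SANS curve
#'
#' Evaluates the chosen vesicle/sheet form-factor model on the q grid,
#' applies wavelength-spread smearing to the coherent part, adds the flat
#' incoherent background and seeded counting noise, and returns the result
#' as a [scattering_curve()] with the ground truth stored in the metadata.
#'
#' With `noise_level = 0` and `wavelength_spread = 0` the output equals the
#' closed-form model pointwise.
#'
#' @param params A [sans_model_params()] record.
#' @return A [scattering_curve()] with modality `"SANS"`; `meta$ground_truth`
#'   holds the generating parameters.
#' @export
#' @examples
#' p <- sans_model_params(thickness_true = sqrt(12), scale_C = 1)
#' crv <- gen_sans_curve(p)
#' # at q = 1 nm^-1 the Guinier sheet gives exp(-1)
#' crv$I[which.min(abs(crv$q - 1))]
gen_sans_curve <- function(params) {
  stopifnot(inherits(params, "sans_model_params"))
  q <- params$q_grid
  f <- function(qq) sans_model_intensity(qq, params)
  I <- smear_model(f, q, params$wavelength_spread) + params$background_B
  sigma <- params$noise_level * sqrt(pmax(I, 0))
  if (params$noise_level > 0) {
    I <- I + with_local_seed(params$seed, stats::rnorm(length(q), 0, sigma))
  }
  scattering_curve(q = q, I = I,
                   sigma = if (params$noise_level > 0) sigma else NULL,
                   modality = "SANS",
                   meta = list(ground_truth = unclass(params)))
}

# Run `expr` under a temporary RNG seed without disturbing the global state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write generator ground truth as a JSON sidecar
#'
#' Serialises the ground-truth parameter record carried in a synthetic
#' object's metadata (or any parameter record) to JSON, for test harnesses
#' that compare recovered against generating parameters.
#'
#' @param params A generator parameter record (any of the `*_params`
#'   classes) or a generated object whose `meta$ground_truth` is used.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(params, path) {
  if (!is.null(params$meta$ground_truth)) params <- params$meta$ground_truth
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
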