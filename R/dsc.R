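#' Baseline-correct a DSC thermogram
#'
#' Subtracts the straight line through the mean points of two flanking
#' windows (one before, one after the transition). After correction the
#' curve is close to zero inside both windows; a window whose corrected
#' signal spans more than 10% of the corrected peak amplitude is judged to
#' overlap the transition and an error is raised. (The anchoring
#' construction forces the *mean* residual in each window to zero, so
#' within-window structure, not the mean, is the usable overlap signal.)
#'
#' @param tg A [thermogram()].
#' @param pre_window,post_window Length-2 numeric temperature intervals
#'   (degC) flanking the transition; each must contain at least 5 points.
#' @return The corrected [thermogram()], with `meta$baseline` recording the
#'   fitted `c(intercept, slope)` and the windows.
#' @export
#' @examples
#' tg <- gen_thermogram(endotherm_params(baseline_slope = 0.002))
#' cor <- baseline_correct(tg, c(2, 8), c(36, 40))
#' cor$meta$baseline$slope
baseline_correct <- function(tg, pre_window = c(2, 8),
                             post_window = c(36, 40)) {
  stopifnot(inherits(tg, "thermogram"))
  win_mean <- function(w, name) {
    sel <- tg$T >= w[1] & tg$T <= w[2]
    if (sum(sel) < 5L) {
      stop(sprintf("%s window [%g, %g] contains fewer than 5 points",
                   name, w[1], w[2]), call. = FALSE)
    }
    sel
  }
  sel_pre <- win_mean(pre_window, "pre")
  sel_post <- win_mean(post_window, "post")
  x1 <- mean(tg$T[sel_pre]);  y1 <- mean(tg$cp_excess[sel_pre])
  x2 <- mean(tg$T[sel_post]); y2 <- mean(tg$cp_excess[sel_post])
  slope <- (y2 - y1) / (x2 - x1)
  intercept <- y1 - slope * x1
  out <- tg
  out$cp_excess <- tg$cp_excess - (intercept + slope * tg$T)
  amp <- max(abs(out$cp_excess))
  guard <- 1e-6 * max(diff(range(tg$cp_excess)), 1e-12)
  for (sel in list(sel_pre, sel_post)) {
    r <- out$cp_excess[sel]
    if (diff(range(r)) > max(0.1 * amp, guard)) {
      stop("baseline window overlaps the transition peak (corrected signal ",
           "inside the window spans more than 10% of the peak amplitude)",
           call. = FALSE)
    }
  }
  out$meta$baseline <- list(intercept = intercept, slope = slope,
                            pre_window = pre_window,
                            post_window = post_window)
  out
}

#' Extract transition parameters from a corrected thermogram
#'
#' From a baseline-corrected heating endotherm: the main-transition
#' temperature Tm is the temperature of the maximum of a locally smoothed
#' curve (Savitzky-Golay, quadratic, 11-point window by default) refined to
#' sub-grid precision by a parabola through the three points around the
#' maximum; the enthalpy dH is the trapezoidal integral of the excess heat
#' capacity over the full temperature range; the width FWHM is measured at
#' half the (smoothed) peak height by linear interpolation, using the first
#' crossing on each side of the maximum.
#'
#' @param tg A baseline-corrected [thermogram()].
#' @param smooth_n Savitzky-Golay window length (odd, >= 5); the filter is
#'   quadratic.
#' @return An object of class `thermogram_result`: `Tm` (degC), `dH` (J/g),
#'   `fwhm` (degC), `peak_height`, `baseline` (from the correction step, if
#'   recorded), `smooth_n`.
#' @export
#' @examples
#' tg <- baseline_correct(gen_thermogram(endotherm_params()))
#' transition_params(tg)
transition_params <- function(tg, smooth_n = 11L) {
  stopifnot(inherits(tg, "thermogram"))
  Tg <- tg$T
  cp_s <- smooth_sg(tg$cp_excess, n = as.integer(smooth_n))
  i_max <- which.max(cp_s)
  height <- cp_s[i_max]
  if (height <= 0 || i_max == 1L || i_max == length(Tg)) {
    stop("no positive interior peak: cooling scan, over-corrected baseline ",
         "or truncated transition", call. = FALSE)
  }
  Tm <- refine_vertex(Tg, cp_s, i_max)
  dH <- pracma::trapz(Tg, tg$cp_excess)
  half <- height / 2
  # first crossing on each side of the maximum, linearly interpolated
  iL <- i_max
  while (iL > 1L && cp_s[iL - 1L] > half) iL <- iL - 1L
  if (iL == 1L) stop("half height never reached on the low-T side",
                     call. = FALSE)
  TL <- interp_crossing(Tg[iL - 1L], Tg[iL], cp_s[iL - 1L], cp_s[iL], half)
  iR <- i_max
  while (iR < length(Tg) && cp_s[iR + 1L] > half) iR <- iR + 1L
  if (iR == length(Tg)) stop("half height never reached on the high-T side",
                             call. = FALSE)
  TR <- interp_crossing(Tg[iR], Tg[iR + 1L], cp_s[iR], cp_s[iR + 1L], half)
  structure(list(Tm = Tm, dH = dH, fwhm = TR - TL, peak_height = height,
                 baseline = tg$meta$baseline, smooth_n = smooth_n,
                 direction = tg$direction, scan_id = tg$scan_id),
            class = "thermogram_result")
}

interp_crossing <- function(x0, x1, y0, y1, level) {
  x0 + (level - y0) * (x1 - x0) / (y1 - y0)
}

#' @export
print.thermogram_result <- function(x, ...) {
  cat("<thermogram_result>\n")
  cat(sprintf("  Tm   = %.3f degC\n", x$Tm))
  cat(sprintf("  dH   = %.3f J/g\n", x$dH))
  cat(sprintf("  FWHM = %.3f degC\n", x$fwhm))
  invisible(x)
}

#' Average transition parameters over repeated heating scans
#'
#' Reports the per-parameter mean and standard deviation over two or more
#' heating-scan results (the convention of averaging the first and third
#' scans of a heating-cooling-heating regimen).
#'
#' @param results List of [transition_params()] results, all from heating
#'   scans.
#' @return An object of class `thermogram_summary` with elements `Tm`,
#'   `Tm_sd`, `dH`, `dH_sd`, `fwhm`, `fwhm_sd`, `n_scans`.
#' @export
#' @examples
#' r1 <- list(Tm = 28.0, dH = 18.2, fwhm = 12.4, direction = "heating")
#' r2 <- list(Tm = 28.2, dH = 17.8, fwhm = 12.6, direction = "heating")
#' average_scans(list(r1, r2))$Tm
average_scans <- function(results) {
  if (length(results) < 2L) {
    stop("need at least 2 heating-scan results", call. = FALSE)
  }
  dirs <- vapply(results, function(r) {
    if (is.null(r$direction)) "heating" else r$direction
  }, character(1))
  if (any(dirs != "heating")) {
    stop("mixed heating/cooling inputs: averaging is defined over heating ",
         "scans only", call. = FALSE)
  }
  grab <- function(f) vapply(results, function(r) as.numeric(r[[f]]),
                             numeric(1))
  Tm <- grab("Tm"); dH <- grab("dH"); fwhm <- grab("fwhm")
  structure(list(Tm = mean(Tm), Tm_sd = stats::sd(Tm),
                 dH = mean(dH), dH_sd = stats::sd(dH),
                 fwhm = mean(fwhm), fwhm_sd = stats::sd(fwhm),
                 n_scans = length(results)),
            class = "thermogram_summary")
}

#' @export
print.thermogram_summary <- function(x, ...) {
  cat(sprintf("<thermogram_summary> %d scans\n", x$n_scans))
  cat(sprintf("  Tm   = %.3f +/- %.3f degC\n", x$Tm, x$Tm_sd))
  cat(sprintf("  dH   = %.3f +/- %.3f J/g\n", x$dH, x$dH_sd))
  cat(sprintf("  FWHM = %.3f +/- %.3f degC\n", x$fwhm, x$fwhm_sd))
  invisible(x)
}
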