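#' Fit lamellar diffraction orders and derive the repeat distance
#'
#' Fits each diffraction order of a lamellar phase with a Lorentzian on a
#' linear local background (the standard model for fluid-lamellar lipid
#' reflections broadened by bilayer fluctuations) and converts the
#' first-order centre to the repeat distance d = 2 pi / q1, with
#' d_sd = 2 pi center_sd / q1^2. Each order is fitted in its own local
#' window (centre +/- 5 half-width guesses) for robustness against the
#' diffuse scattering between orders.
#'
#' Initial centres come from a smoothed peak picker (the most prominent
#' small-angle maximum is taken as the first order) unless `init_d`
#' supplies them as 2 pi n / init_d.
#'
#' @param curve A [scattering_curve()]; only q <= `q_max` is used, so a
#'   combined SAXS/WAXS pattern can be passed directly.
#' @param n_orders Number of diffraction orders to fit (>= 1).
#' @param init_d Optional initial repeat distance in nm overriding peak
#'   detection.
#' @param q_max Upper bound of the small-angle region considered, nm^-1.
#' @return An object of class `lamellar_result`: `peaks` (data.frame with
#'   `center`, `hwhm`, `amplitude`, `center_sd` per order), `bg_intercept`,
#'   `bg_slope` (first-order window), `d`, `d_sd`, `order_ratio`.
#' @export
#' @examples
#' crv <- gen_saxs_waxs_pattern(lamellar_model_params(d_true = 7.8))
#' fit_lamellar_peaks(crv, n_orders = 2)$d
fit_lamellar_peaks <- function(curve, n_orders = 2L, init_d = NULL,
                               q_max = 5) {
  stopifnot(inherits(curve, "scattering_curve"))
  n_orders <- as.integer(n_orders)
  if (n_orders < 1L) stop("`n_orders` must be >= 1", call. = FALSE)
  sel <- curve$q <= q_max
  q <- curve$q[sel]
  I <- curve$I[sel]
  if (length(q) < 10L) stop("too few small-angle points", call. = FALSE)

  if (is.null(init_d)) {
    pk <- detect_first_order(q, I)
    centers0 <- pk$center * seq_len(n_orders)
    w0 <- pk$hwhm
  } else {
    centers0 <- 2 * pi * seq_len(n_orders) / init_d
    w0 <- estimate_hwhm(q, I, centers0[1])
  }
  if (max(centers0) > max(q)) {
    stop(sprintf("order %d expected at q = %.3g nm^-1, beyond the data",
                 n_orders, max(centers0)), call. = FALSE)
  }

  peaks <- data.frame(center = numeric(0), hwhm = numeric(0),
                      amplitude = numeric(0), center_sd = numeric(0))
  bg <- c(NA_real_, NA_real_)
  for (n in seq_len(n_orders)) {
    res <- fit_one_lorentzian(q, I, centers0[n], w0)
    peaks <- rbind(peaks, res$peak)
    if (n == 1L) bg <- res$bg
  }
  q1 <- peaks$center[1]
  structure(list(
    peaks = peaks,
    bg_intercept = bg[1],
    bg_slope = bg[2],
    d = 2 * pi / q1,
    d_sd = 2 * pi * peaks$center_sd[1] / q1^2,
    order_ratio = if (n_orders >= 2L) peaks$center[2] / q1 else NA_real_
  ), class = "lamellar_result")
}

#' @export
print.lamellar_result <- function(x, ...) {
  cat("<lamellar_result>\n")
  cat(sprintf("  d = %.4f +/- %.4f nm (d = 2 pi / q1)\n", x$d, x$d_sd))
  if (!is.na(x$order_ratio)) {
    cat(sprintf("  order ratio q2/q1 = %.4f (2 for an ideal stack)\n",
                x$order_ratio))
  }
  for (i in seq_len(nrow(x$peaks))) {
    cat(sprintf("  order %d: q = %.4f nm^-1, hwhm = %.4f, A = %.4g\n", i,
                x$peaks$center[i], x$peaks$hwhm[i], x$peaks$amplitude[i]))
  }
  invisible(x)
}

# Most prominent local maximum of the lightly smoothed curve -> first order.
detect_first_order <- function(q, I) {
  Is <- smooth_sg(I)
  n <- length(Is)
  loc <- which(Is[2:(n - 1)] > Is[1:(n - 2)] & Is[2:(n - 1)] >= Is[3:n]) + 1L
  if (length(loc) == 0L) {
    stop("no detectable peak above background in the small-angle region",
         call. = FALSE)
  }
  # prominence relative to the lower of the two flanking minima
  prom <- vapply(loc, function(i) {
    left <- min(Is[1:i])
    right <- min(Is[i:n])
    Is[i] - max(left, right)
  }, numeric(1))
  scatter <- stats::mad(diff(I)) / sqrt(2)
  keep <- prom > 5 * max(scatter, 1e-12)
  if (!any(keep)) {
    stop("no detectable peak above background in the small-angle region",
         call. = FALSE)
  }
  i <- loc[keep][which.max(prom[keep])]
  list(center = q[i], hwhm = estimate_hwhm(q, I, q[i]))
}

# Half-width at half prominence around a given centre; conservative fallback.
estimate_hwhm <- function(q, I, center) {
  i0 <- which.min(abs(q - center))
  base <- stats::quantile(I, 0.1, names = FALSE)
  half <- base + (I[i0] - base) / 2
  iL <- i0
  while (iL > 1L && I[iL] > half) iL <- iL - 1L
  iR <- i0
  while (iR < length(q) && I[iR] > half) iR <- iR + 1L
  hw <- (q[iR] - q[iL]) / 2
  if (!is.finite(hw) || hw <= 0) hw <- 0.02 * center
  hw
}

smooth_sg <- function(I, n = 9L, p = 2L) {
  n <- min(n, if (length(I) %% 2L == 0L) length(I) - 1L else length(I))
  if (n < p + 2L) return(I)
  if (n %% 2L == 0L) n <- n - 1L
  as.numeric(signal::sgolayfilt(I, p = p, n = n))
}

# Lorentzian + linear background over a local window centre +/- 5 hwhm.
fit_one_lorentzian <- function(q, I, center0, hwhm0) {
  win <- q >= center0 - 5 * hwhm0 & q <= center0 + 5 * hwhm0
  if (sum(win) < 8L) {
    stop(sprintf("too few points around the expected peak at %.3g nm^-1",
                 center0), call. = FALSE)
  }
  qw <- q[win]
  Iw <- I[win]
  edge <- c(utils::head(Iw, 3), utils::tail(Iw, 3))
  qedge <- c(utils::head(qw, 3), utils::tail(qw, 3))
  b1_0 <- stats::cov(qedge, edge) / stats::var(qedge)
  b0_0 <- mean(edge) - b1_0 * mean(qedge)
  A0 <- max(Iw) - (b0_0 + b1_0 * qw[which.max(Iw)])
  c0 <- qw[which.max(Iw)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Iw ~ A * w^2 / ((qw - cc)^2 + w^2) + b0 + b1 * qw,
      start = list(A = max(A0, 1e-6), cc = c0, w = hwhm0,
                   b0 = b0_0, b1 = b1_0),
      lower = c(A = 0, cc = min(qw), w = 1e-6, b0 = -Inf, b1 = -Inf),
      upper = c(A = Inf, cc = max(qw), w = diff(range(qw)), b0 = Inf,
                b1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("Lorentzian fit did not converge near q = ",
           signif(center0, 4), " nm^-1: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  est <- summary(fit)$coefficients
  list(
    peak = data.frame(center = est["cc", "Estimate"],
                      hwhm = est["w", "Estimate"],
                      amplitude = est["A", "Estimate"],
                      center_sd = est["cc", "Std. Error"]),
    bg = c(est["b0", "Estimate"], est["b1", "Estimate"])
  )
}

#' Water-layer thickness from the lamellar decomposition
#'
#' The lamellar repeat distance is the sum of the bilayer thickness and the
#' interbilayer water layer, d = d_L + d_W; this returns d_W = d - d_L.
#'
#' @param d Repeat distance in nm.
#' @param d_L Lipid bilayer thickness in nm; must satisfy 0 < d_L < d.
#' @return Water-layer thickness d_W in nm.
#' @export
#' @examples
#' water_layer(7.8, 3.9)  # 3.9 nm
water_layer <- function(d, d_L) {
  if (!(d > d_L && d_L > 0)) {
    stop("need d > d_L > 0: a repeat distance not exceeding the bilayer ",
         "thickness is inconsistent", call. = FALSE)
  }
  d - d_L
}

#' Analyse a WAXS chain-packing region
#'
#' Fits the broad liquid-like acyl-chain band (~14 nm^-1) with a Gaussian on
#' a linear background, robustly (points deviating > 3 residual SD are
#' masked and the fit repeated, so sharp reflections do not bias the broad
#' band), then detects sharp crystalline-drug peaks as contiguous runs of
#' positive residual exceeding a z-score threshold. Local maxima inside a
#' run are reported as separate peaks; a run whose single maximum is much
#' wider than its fellows is flagged as a possible merge of unresolved
#' neighbours. Patterns with at least one sharp peak are classified
#' `"fluid+crystalline"`, otherwise `"fluid-only"`.
#'
#' @param curve A [scattering_curve()] containing the wide-angle region.
#' @param window Length-2 numeric WAXS window in nm^-1 (default 10-18).
#' @param z_threshold Residual z-score threshold for sharp-peak detection.
#' @param width_fraction Maximum sharp-peak sigma as a fraction of the broad
#'   band sigma.
#' @param min_prominence Minimum sharp-peak amplitude as a fraction of the
#'   broad band amplitude (suppresses sub-percent residual structure left
#'   by the broad-band model itself).
#' @param merge_width_factor A single-maximum run wider (half-max width)
#'   than this factor times the median sharp width is flagged `merged`.
#' @return An object of class `waxs_result`: `broad_center`, `broad_width`
#'   (Gaussian sigma), `sharp_peaks` (data.frame: `center`, `width`,
#'   `amplitude`, `merged`), `classification`.
#' @export
#' @examples
#' p <- lamellar_model_params(crystalline_peaks = list(c(13.1, 0.03, 3)))
#' analyze_waxs(gen_saxs_waxs_pattern(p))$sharp_peaks
analyze_waxs <- function(curve, window = c(10, 18), z_threshold = 4,
                         width_fraction = 0.2, min_prominence = 0.02,
                         merge_width_factor = 2) {
  stopifnot(inherits(curve, "scattering_curve"))
  sel <- curve$q >= window[1] & curve$q <= window[2]
  if (sum(sel) < 20L) stop("empty or too-sparse WAXS window", call. = FALSE)
  q <- curve$q[sel]
  I <- curve$I[sel]

  mask <- rep(TRUE, length(q))
  fit <- NULL
  for (iter in 1:3) {
    dat <- data.frame(qm = q[mask], Im = I[mask])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        Im ~ A * exp(-(qm - cc)^2 / (2 * s^2)) + b0 + b1 * qm,
        data = dat,
        start = list(A = max(I) - min(I), cc = q[which.max(smooth_sg(I))],
                     s = diff(range(q)) / 6, b0 = min(I), b1 = 0),
        lower = c(A = 0, cc = min(q), s = 1e-3, b0 = -Inf, b1 = -Inf),
        upper = c(A = Inf, cc = max(q), s = diff(range(q)), b0 = Inf,
                  b1 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) stop("broad-band fit did not converge: ",
                               conditionMessage(e), call. = FALSE)
    )
    cf <- stats::coef(fit)
    pred <- cf["A"] * exp(-(q - cf["cc"])^2 / (2 * cf["s"]^2)) +
      cf["b0"] + cf["b1"] * q
    resid <- I - pred
    # per-point scale: counting noise is heteroscedastic across the band,
    # so use the curve's sigma when present, a MAD estimate otherwise
    if (!is.null(curve$sigma)) {
      sd_r <- pmax(curve$sigma[sel], 1e-7 * max(abs(I)))
    } else {
      sd_r <- max(stats::mad(resid[mask]), 1e-7 * max(abs(I)))
    }
    new_mask <- abs(resid) <= 3 * sd_r
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  z <- resid / sd_r

  runs <- positive_runs(z > z_threshold, min_len = 2L)
  sharp <- data.frame(center = numeric(0), width = numeric(0),
                      amplitude = numeric(0), merged = logical(0))
  for (r in runs) {
    idx <- r[1]:r[2]
    rr <- resid[idx]
    nloc <- length(rr)
    loc <- which(rr >= c(-Inf, rr[-nloc]) & rr > c(rr[-1], -Inf))
    for (j in loc) {
      i <- idx[j]
      center <- refine_vertex(q, resid, i)
      half <- rr[j] / 2
      jL <- j; while (jL > 1L && rr[jL] > half) jL <- jL - 1L
      jR <- j; while (jR < nloc && rr[jR] > half) jR <- jR + 1L
      fw <- q[idx[jR]] - q[idx[jL]]
      sharp <- rbind(sharp, data.frame(
        center = center, width = fw / 2.3548, amplitude = resid[i],
        merged = FALSE))
    }
    if (length(loc) == 1L) {
      attr(sharp, "last_run_single") <- TRUE
    }
  }
  if (nrow(sharp) > 0L) {
    sharp <- sharp[sharp$width < width_fraction * cf["s"] &
                     sharp$amplitude >= min_prominence * cf["A"], ,
                   drop = FALSE]
    if (nrow(sharp) >= 3L) {
      med_w <- stats::median(sharp$width)
      sharp$merged <- sharp$width > merge_width_factor * med_w
    }
    rownames(sharp) <- NULL
  }
  structure(list(
    broad_center = unname(cf["cc"]),
    broad_width = unname(cf["s"]),
    bg_intercept = unname(cf["b0"]),
    bg_slope = unname(cf["b1"]),
    sharp_peaks = sharp,
    classification = if (nrow(sharp) > 0L) "fluid+crystalline"
                     else "fluid-only"
  ), class = "waxs_result")
}

#' @export
print.waxs_result <- function(x, ...) {
  cat("<waxs_result>\n")
  cat(sprintf("  broad chain band: center %.3f nm^-1, sigma %.3f nm^-1\n",
              x$broad_center, x$broad_width))
  cat(sprintf("  classification: %s\n", x$classification))
  if (nrow(x$sharp_peaks) > 0L) {
    for (i in seq_len(nrow(x$sharp_peaks))) {
      cat(sprintf("  sharp peak at %.3f nm^-1 (width %.3f%s)\n",
                  x$sharp_peaks$center[i], x$sharp_peaks$width[i],
                  if (x$sharp_peaks$merged[i]) ", possible merge" else ""))
    }
  }
  invisible(x)
}

# Contiguous TRUE runs of at least `min_len`; list of c(start, end) indices.
positive_runs <- function(flag, min_len = 2L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  Map(c, starts[keep], ends[keep])
}

# Sub-grid peak location: parabola through the three points around index i.
refine_vertex <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  x3 <- x[(i - 1):(i + 1)]
  y3 <- y[(i - 1):(i + 1)]
  denom <- (y3[1] - 2 * y3[2] + y3[3])
  if (abs(denom) < 1e-300) return(x[i])
  x[i] - 0.5 * (x3[3] - x3[1]) / 2 * (y3[3] - y3[1]) / denom
}
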