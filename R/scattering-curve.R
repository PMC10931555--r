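#' One-dimensional scattering curve
#'
#' Container for a reduced 1D small/wide-angle scattering curve: momentum
#' transfer `q` (nm^-1), intensity `I` (relative units) and an optional
#' per-point uncertainty `sigma`. Carries provenance metadata (modality,
#' temperature, sample label, processing history).
#'
#' @param q Numeric vector of momentum transfer values, strictly increasing,
#'   all positive, in nm^-1 (use [convert_q_units()] for Angstrom^-1 input).
#' @param I Numeric vector of intensities, same length as `q`, all finite.
#' @param sigma Optional numeric vector of per-point standard deviations.
#' @param modality One of `"SANS"`, `"SAXS"`, `"WAXS"`, `"SAXS/WAXS"`.
#' @param temperature Sample temperature in degrees Celsius (metadata only).
#' @param sample Sample label.
#' @param meta Named list of additional metadata (merged with the above).
#'
#' @return An object of class `scattering_curve`: a list with elements
#'   `q`, `I`, `sigma` and `meta`.
#' @export
#' @examples
#' sc <- scattering_curve(q = c(0.1, 0.2, 0.3), I = c(100, 25, 11))
#' sc
scattering_curve <- function(q, I, sigma = NULL,
                             modality = c("SANS", "SAXS", "WAXS", "SAXS/WAXS"),
                             temperature = NA_real_, sample = NA_character_,
                             meta = list()) {
  modality <- match.arg(modality)
  q <- as.numeric(q)
  I <- as.numeric(I)
  if (length(q) != length(I)) {
    stop("`q` and `I` must have the same length", call. = FALSE)
  }
  if (length(q) == 0L) stop("empty curve", call. = FALSE)
  if (anyNA(q) || any(q <= 0)) {
    stop("all `q` values must be positive and non-missing", call. = FALSE)
  }
  if (is.unsorted(q, strictly = TRUE)) {
    stop("`q` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(I))) stop("all intensities must be finite", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) {
      stop("`sigma` must have the same length as `q`", call. = FALSE)
    }
    if (any(sigma < 0, na.rm = TRUE)) {
      stop("`sigma` must be non-negative", call. = FALSE)
    }
  }
  meta <- utils::modifyList(
    list(modality = modality, temperature = temperature, sample = sample),
    meta
  )
  structure(list(q = q, I = I, sigma = sigma, meta = meta),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %s, %d points, q = %.4g-%.4g nm^-1\n",
              x$meta$modality, length(x$q), min(x$q), max(x$q)))
  if (!is.na(x$meta$temperature)) {
    cat(sprintf("  temperature: %g degC\n", x$meta$temperature))
  }
  if (!is.na(x$meta$sample)) cat(sprintf("  sample: %s\n", x$meta$sample))
  if (!is.null(x$meta$background_subtracted)) {
    cat(sprintf("  background subtracted: %.6g\n",
                x$meta$background_subtracted))
  }
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, I = x$I)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' Convert momentum-transfer units
#'
#' Converts a q grid between Angstrom^-1 and nm^-1 (1 A^-1 = 10 nm^-1).
#' The package works internally in nm^-1.
#'
#' @param q Numeric vector of momentum transfer values.
#' @param from,to Units: `"A^-1"` or `"nm^-1"`.
#' @return Numeric vector in the target units.
#' @export
#' @examples
#' convert_q_units(0.1, from = "A^-1", to = "nm^-1")  # 1 nm^-1
convert_q_units <- function(q, from = c("A^-1", "nm^-1"),
                            to = c("nm^-1", "A^-1")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(q)
  if (from == "A^-1") q * 10 else q / 10
}

#' Read a scattering curve from 2/3-column ASCII
#'
#' Reads the plain-text `.dat` convention used by SAS reduction software:
#' whitespace-separated columns (q, I [, sigma]) with `#`-prefixed header
#' lines.
#'
#' @param path File path.
#' @param q_units Units of the q column in the file; converted to nm^-1.
#' @param ... Passed to [scattering_curve()] (e.g. `modality`).
#' @return A [scattering_curve()].
#' @export
read_dat <- function(path, q_units = c("nm^-1", "A^-1"), ...) {
  q_units <- match.arg(q_units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "I", "sigma")[
                             seq_len(ncol(utils::read.table(path,
                               comment.char = "#", nrows = 1)))])
  if (ncol(tab) < 2L) {
    stop("expected at least 2 columns (q, I) in ", path, call. = FALSE)
  }
  q <- convert_q_units(tab[[1]], from = q_units, to = "nm^-1")
  sigma <- if (ncol(tab) >= 3L) tab[[3]] else NULL
  scattering_curve(q = q, I = tab[[2]], sigma = sigma, ...)
}

#' Write a scattering curve as 3-column ASCII
#'
#' Writes (q, I, sigma) with `#`-prefixed header lines recording the
#' metadata. Missing sigma is written as 0.
#'
#' @param curve A [scattering_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  sigma <- if (is.null(curve$sigma)) rep(0, length(curve$q)) else curve$sigma
  hdr <- c(
    sprintf("# modality: %s", curve$meta$modality),
    sprintf("# temperature_degC: %s", curve$meta$temperature),
    sprintf("# sample: %s", curve$meta$sample),
    "# columns: q[nm^-1] I[arb] sigma[arb]"
  )
  body <- sprintf("%.8g %.8g %.8g", curve$q, curve$I, sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}
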