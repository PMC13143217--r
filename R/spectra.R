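#' Build and validate a spectrum table
#'
#' A spectrum is the universal carrier in this package: a two-column tibble
#' with a strictly increasing wavelength grid (`wavelength_nm`, in 250--900 nm)
#' and matched finite values (`value`). Absorbance, transmission and
#' reflectance spectra all travel in this shape. Raw absorbance may contain
#' small negative values from baseline noise; these are preserved on input and
#' handled by [preprocess_replicate()].
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, within \[250, 900\].
#' @param value Numeric vector of the same length, all finite.
#' @return A tibble with columns `wavelength_nm` and `value`.
#' @examples
#' as_spectrum(400:700, rep(1, 301))
#' @export
as_spectrum <- function(wavelength_nm, value) {
  spec <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                         value = as.numeric(value))
  validate_spectrum(spec)
}

#' @param spec A data frame with columns `wavelength_nm` and `value`.
#' @rdname as_spectrum
#' @export
validate_spectrum <- function(spec) {
  if (!all(c("wavelength_nm", "value") %in% names(spec))) {
    stop("a spectrum needs columns `wavelength_nm` and `value`", call. = FALSE)
  }
  wl <- spec$wavelength_nm
  v <- spec$value
  if (length(wl) != length(v) || length(wl) < 2) {
    stop("a spectrum needs at least two matched wavelength/value pairs",
         call. = FALSE)
  }
  if (anyNA(wl) || anyNA(v) || !all(is.finite(v))) {
    stop("spectrum values must be finite and non-missing", call. = FALSE)
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (min(wl) < 250 || max(wl) > 900) {
    stop("wavelengths must lie within [250, 900] nm", call. = FALSE)
  }
  tibble::as_tibble(spec[c("wavelength_nm", "value")])
}

#' Default wavelength grid for peak and cutoff location
#'
#' 300--800 nm at 0.1 nm. Cutoffs and peaks located on this grid are precise
#' to well under the 1 nm at which results are reported.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_grid <- function() seq(300, 800, by = 0.1)

#' Govardovskii A1 visual-pigment template
#'
#' Evaluates the standard A1 (11-cis-retinal) visual-pigment absorbance
#' template at a given peak wavelength. The alpha band is
#' \deqn{S(\lambda) = 1 / (e^{A(a - x)} + e^{B(b - x)} + e^{C(c - x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda}, A = 69.7, B = 28, C = -14.9,
#' D = 0.674, b = 0.922, c = 1.104 and
#' \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}}.
#' The optional beta band is a Gaussian shoulder at short wavelengths with
#' peak \eqn{189 + 0.315\,\lambda_{max}}, bandwidth
#' \eqn{-40.5 + 0.195\,\lambda_{max}} and amplitude 0.26. The returned
#' spectrum is renormalized so its maximum on the grid is exactly 1.
#'
#' @param lambda_max Peak wavelength of the pigment in nm, within
#'   \[330, 620\] (the avian cone range plus margin).
#' @param grid Wavelength grid in nm (default [default_grid()]).
#' @param beta_band Include the short-wavelength beta band? Default `TRUE`.
#' @return A spectrum tibble (see [as_spectrum()]), peak-normalized.
#' @examples
#' lw <- govardovskii_absorbance(545)
#' cutoff_wavelength(lw, level = 0.05, side = "long") # ~ 643-644 nm
#' @export
govardovskii_absorbance <- function(lambda_max, grid = default_grid(),
                                    beta_band = TRUE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      !is.finite(lambda_max) || lambda_max < 330 || lambda_max > 620) {
    stop("`lambda_max` must be a single wavelength in [330, 620] nm",
         call. = FALSE)
  }
  if (min(grid) < 250 || max(grid) > 900) {
    stop("`grid` must lie within [250, 900] nm", call. = FALSE)
  }
  v <- govardovskii_values(grid, lambda_max, beta_band)
  as_spectrum(grid, v / max(v))
}

# Unnormalized template values; vectorized over `lam`. Kept separate so the
# fitting loop can avoid tibble construction.
govardovskii_values <- function(lam, lambda_max, beta_band = TRUE) {
  x <- lambda_max / lam
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  if (beta_band) {
    lam_beta <- 189 + 0.315 * lambda_max
    bw <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((lam - lam_beta) / bw)^2)
  }
  s
}

#' Normalize a spectrum to unit peak
#'
#' Divides all values by the maximum so the peak equals 1. Shape is preserved.
#' Idempotent.
#'
#' @param spec A spectrum tibble.
#' @return The peak-normalized spectrum.
#' @export
normalize_peak <- function(spec) {
  spec <- validate_spectrum(spec)
  m <- max(spec$value)
  if (m <= 0) {
    stop("cannot peak-normalize a spectrum with no positive values",
         call. = FALSE)
  }
  spec$value <- spec$value / m
  spec
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation at each requested grid point; exact at original grid
#' points. Extrapolation outside the measured range is refused.
#'
#' @param spec A spectrum tibble.
#' @param grid Target wavelengths in nm, within the range of `spec`.
#' @return The resampled spectrum.
#' @export
resample_spectrum <- function(spec, grid) {
  spec <- validate_spectrum(spec)
  if (min(grid) < min(spec$wavelength_nm) ||
      max(grid) > max(spec$wavelength_nm)) {
    stop("requested grid extends beyond the measured wavelength range; ",
         "extrapolation is not supported", call. = FALSE)
  }
  v <- stats::approx(spec$wavelength_nm, spec$value, xout = grid,
                     method = "linear", ties = "ordered")$y
  as_spectrum(grid, v)
}

#' Peak wavelength of a spectrum
#'
#' Grid argmax; among equal maxima the lowest wavelength is returned, so the
#' result is deterministic on plateaus.
#'
#' @param spec A spectrum tibble.
#' @return Wavelength of the maximum value, in nm.
#' @export
peak_wavelength <- function(spec) {
  spec <- validate_spectrum(spec)
  spec$wavelength_nm[which.max(spec$value)]
}

#' Sensitivity cutoff wavelength
#'
#' Walks away from the peak on the requested limb and returns the wavelength
#' where the normalized spectrum first falls to `level`, located by linear
#' interpolation between the bracketing grid points. Used with `level = 0.05`
#' for the 5% sensitivity cutoffs that bound the perception range.
#'
#' @param spec A spectrum tibble, normalized to peak 1.
#' @param level Fraction of the peak in (0, 1\].
#' @param side `"long"` (long-wavelength limb) or `"short"`.
#' @return Cutoff wavelength in nm.
#' @export
cutoff_wavelength <- function(spec, level = 0.05, side = c("long", "short")) {
  side <- match.arg(side)
  spec <- validate_spectrum(spec)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1) {
    stop("`level` must be a single fraction in (0, 1]", call. = FALSE)
  }
  peak_i <- which.max(spec$value)
  if (abs(spec$value[peak_i] - 1) > 1e-8) {
    stop("spectrum must be normalized to peak 1 (see normalize_peak())",
         call. = FALSE)
  }
  if (level == 1) {
    return(spec$wavelength_nm[peak_i])
  }
  if (side == "long") {
    wl <- spec$wavelength_nm[peak_i:nrow(spec)]
    v <- spec$value[peak_i:nrow(spec)]
  } else {
    wl <- rev(spec$wavelength_nm[1:peak_i])
    v <- rev(spec$value[1:peak_i])
  }
  below <- which(v < level)
  if (length(below) == 0) {
    stop("spectrum never falls to level ", level, " on the ", side,
         "-wavelength limb within the grid", call. = FALSE)
  }
  i <- below[1]
  # linear interpolation between the bracketing grid points
  w1 <- wl[i - 1]; w2 <- wl[i]
  v1 <- v[i - 1]; v2 <- v[i]
  w1 + (level - v1) * (w2 - w1) / (v2 - v1)
}

#' Read and write spectra as CSV
#'
#' The spectrum CSV dialect is two columns `wavelength_nm,value` with a
#' header, UTF-8, decimal point; lines starting with `#` are treated as
#' comments.
#'
#' @param path File path.
#' @return `read_spectrum_csv()` returns a spectrum tibble;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_spectrum(df)
}

#' @param spec A spectrum tibble.
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  readr::write_csv(validate_spectrum(spec), path)
  invisible(path)
}
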