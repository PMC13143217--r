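#' Mean reflectance of a marker material
#'
#' Arithmetic mean of the reflectance values over the grid points inside the
#' inclusive wavelength range (default 300--780 nm), yielding the single
#' scalar per material surface used for achromatic contrast analysis.
#' Fluorescent materials may exceed 100% reflectance; such values pass
#' through unchanged.
#'
#' @param spec A spectrum tibble of reflectance (percent).
#' @param range Length-2 inclusive wavelength range in nm.
#' @return Mean reflectance (same units as the input values).
#' @export
mean_reflectance <- function(spec, range = c(300, 780)) {
  spec <- validate_spectrum(spec)
  if (min(spec$wavelength_nm) > range[1] || max(spec$wavelength_nm) < range[2]) {
    stop("spectrum does not cover the requested range ", range[1], "-",
         range[2], " nm", call. = FALSE)
  }
  keep <- spec$wavelength_nm >= range[1] & spec$wavelength_nm <= range[2]
  mean(spec$value[keep])
}

#' Michelson contrast between two reflectances
#'
#' \deqn{C_m = |R_1 - R_2| / (R_1 + R_2)} — a relative measure independent of
#' absolute luminance, symmetric in its arguments and lying in \[0, 1\].
#'
#' @param r1,r2 Mean reflectances, >= 0, not both zero.
#' @return Contrast in \[0, 1\].
#' @examples
#' pairwise_michelson(70, 30) # 0.4
#' @export
pairwise_michelson <- function(r1, r2) {
  if (any(r1 < 0) || any(r2 < 0)) {
    stop("reflectances must be >= 0", call. = FALSE)
  }
  if (any(r1 + r2 == 0)) {
    stop("contrast is undefined when both reflectances are zero",
         call. = FALSE)
  }
  abs(r1 - r2) / (r1 + r2)
}

#' Is an internal contrast detectable by the bird?
#'
#' A brightness difference is detectable when the inverse contrast does not
#' exceed the species' peak contrast sensitivity: 1/C_m <= S, equivalently
#' C_m >= 1/S, boundary inclusive. Zero contrast is undetectable by
#' definition.
#'
#' @param cm Michelson contrast in \[0, 1\].
#' @param peak_sensitivity Peak contrast sensitivity (default 16.67, the
#'   black grouse value).
#' @return Logical.
#' @examples
#' classify_detectable(0.4)  # TRUE (1/0.4 = 2.5)
#' classify_detectable(0.05) # FALSE (1/0.05 = 20)
#' @export
classify_detectable <- function(cm, peak_sensitivity = 16.67) {
  if (any(cm < 0) || any(cm > 1)) stop("`cm` must lie in [0, 1]", call. = FALSE)
  ifelse(cm == 0, FALSE, 1 / cm <= peak_sensitivity)
}

#' Pairwise contrast matrix of one marker's materials
#'
#' Computes mean reflectances for every material of a marker, the symmetric
#' matrix of pairwise Michelson contrasts, its inverse, and detectability
#' flags against the species' peak contrast sensitivity. Markers composed of
#' a single material carry no internal contrast and are rejected.
#'
#' @param records Long-format reflectance tibble with columns `marker`,
#'   `material`, `component`, `wavelength_nm`, `reflectance_pct`, for one
#'   marker.
#' @param component `"diffuse"` (default) or `"diffuse_plus_specular"`; the
#'   two components are analysed separately, never mixed in one matrix.
#' @param threshold Peak contrast sensitivity for the detectability flag
#'   (default 16.67).
#' @param range Wavelength range for the mean (default 300--780 nm).
#' @return An object of class `contrast_matrix`: a list with `marker`,
#'   `materials`, `mean_reflectances`, `cm` (symmetric, zero diagonal),
#'   `inverse_cm` (`Inf` on the diagonal), `detectable` (logical matrix) and
#'   `threshold`. [tidy()] returns the unique off-diagonal pairs.
#' @export
contrast_matrix <- function(records, component = "diffuse",
                            threshold = 16.67, range = c(300, 780)) {
  stopifnot(all(c("marker", "material", "component", "wavelength_nm",
                  "reflectance_pct") %in% names(records)))
  marker <- unique(records$marker)
  if (length(marker) != 1) {
    stop("`contrast_matrix()` expects records for a single marker",
         call. = FALSE)
  }
  rec <- records[records$component == component, ]
  materials <- unique(rec$material)
  if (length(materials) < 2) {
    stop("marker ", marker, " has fewer than 2 materials for component '",
         component, "'; no internal contrast to analyse", call. = FALSE)
  }
  means <- vapply(materials, function(m) {
    one <- rec[rec$material == m, ]
    one <- one[order(one$wavelength_nm), ]
    mean_reflectance(as_spectrum(one$wavelength_nm, one$reflectance_pct),
                     range)
  }, numeric(1))
  n <- length(materials)
  cm <- outer(means, means, pairwise_michelson)
  diag(cm) <- 0
  inv <- 1 / cm
  det <- matrix(classify_detectable(cm, threshold), n, n)
  diag(det) <- FALSE
  dimnames(cm) <- dimnames(inv) <- dimnames(det) <-
    list(materials, materials)
  structure(
    list(marker = marker, component = component, materials = materials,
         mean_reflectances = means, cm = cm, inverse_cm = inv,
         detectable = det, threshold = threshold),
    class = "contrast_matrix"
  )
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat(sprintf(
    "<contrast_matrix> %s (%s): %d materials, %d pairs, %d detectable at sensitivity %.2f\n",
    x$marker, x$component, length(x$materials),
    choose(length(x$materials), 2),
    sum(x$detectable[upper.tri(x$detectable)]), x$threshold))
  invisible(x)
}

#' @rdname tidy.rhodopsin_fit
#' @export
tidy.contrast_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$cm), arr.ind = TRUE)
  tibble::tibble(
    marker = x$marker,
    component = x$component,
    material_a = x$materials[idx[, 1]],
    material_b = x$materials[idx[, 2]],
    cm = x$cm[idx],
    inverse_cm = x$inverse_cm[idx],
    detectable = x$detectable[idx])
}

#' Internal contrasts of every marker in a reflectance table
#'
#' Runs [contrast_matrix()] per marker and stacks the tidy pair tables;
#' markers with a single material are skipped and reported in the
#' `excluded_markers` attribute.
#'
#' @inheritParams contrast_matrix
#' @param records Long-format reflectance tibble covering one or more
#'   markers.
#' @return A tibble `marker, component, material_a, material_b, cm,
#'   inverse_cm, detectable` with attribute `excluded_markers`.
#' @export
marker_contrasts <- function(records, component = "diffuse",
                             threshold = 16.67, range = c(300, 780)) {
  markers <- unique(records$marker)
  out <- list()
  excluded <- character()
  for (m in markers) {
    rec <- records[records$marker == m, ]
    if (dplyr::n_distinct(rec$material[rec$component == component]) < 2) {
      excluded <- c(excluded, m)
      next
    }
    out[[m]] <- tidy(contrast_matrix(rec, component, threshold, range))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "excluded_markers") <- excluded
  res
}

#' Read a long-format reflectance CSV
#'
#' Expects columns `marker,material,component,wavelength_nm,reflectance_pct`;
#' `#` lines are comments.
#'
#' @param path File path.
#' @return A reflectance tibble.
#' @export
read_reflectance_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("marker", "material", "component", "wavelength_nm",
                  "reflectance_pct") %in% names(df)))
  tibble::as_tibble(df)
}
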