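#' C-type oil-droplet mid-transmission wavelength
#'
#' The C-type droplet of SWS2 cones has its 50% transmission point tied to
#' the pigment it screens by the empirical relationship
#' \eqn{C_{mid} = 0.82\,\lambda_{max,SWS2} + 75}.
#'
#' @param sws2_lambda_max SWS2 pigment peak in nm, in the plausible range
#'   \[420, 470\].
#' @return The C-type lambda-mid in nm.
#' @examples
#' c_type_lambda_mid(436) # 432.52
#' @export
c_type_lambda_mid <- function(sws2_lambda_max) {
  if (any(sws2_lambda_max < 420) || any(sws2_lambda_max > 470)) {
    stop("SWS2 lambda_max outside the plausible range [420, 470] nm",
         call. = FALSE)
  }
  0.82 * sws2_lambda_max + 75
}

#' Oil-droplet transmission spectrum
#'
#' Cone oil droplets act as long-pass cut-on filters. The transparent T-type
#' droplet of SWS1 cones transmits fully (T = 1 everywhere). C-, Y- and
#' R-type droplets are modelled as a logistic cut-on in wavelength,
#' \deqn{T(\lambda) = 1 / (1 + e^{-k(\lambda - \lambda_{mid})})}
#' which is 0.5 at `lambda_mid` by construction. Default slopes are the
#' moderate values k = 0.15 per nm for the C-type and 0.12 per nm for Y and R.
#'
#' @param droplet_type One of `"T"`, `"C"`, `"Y"`, `"R"`.
#' @param lambda_mid 50% transmission wavelength in nm (ignored for T-type);
#'   must lie within \[380, 650\].
#' @param k Logistic slope per nm (> 0; ignored for T-type). Defaults to 0.15
#'   for C and 0.12 for Y/R.
#' @param grid Wavelength grid in nm.
#' @return A spectrum tibble of transmissions in (0, 1\].
#' @examples
#' t <- droplet_transmission("Y", lambda_mid = 523)
#' @export
droplet_transmission <- function(droplet_type = c("T", "C", "Y", "R"),
                                 lambda_mid = NULL, k = NULL,
                                 grid = default_grid()) {
  droplet_type <- match.arg(droplet_type)
  if (droplet_type == "T") {
    return(as_spectrum(grid, rep(1, length(grid))))
  }
  if (is.null(k)) k <- if (droplet_type == "C") 0.15 else 0.12
  if (is.null(lambda_mid)) {
    stop("`lambda_mid` is required for C/Y/R droplets", call. = FALSE)
  }
  if (lambda_mid < 380 || lambda_mid > 650) {
    stop("`lambda_mid` must lie within [380, 650] nm", call. = FALSE)
  }
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  as_spectrum(grid, 1 / (1 + exp(-k * (grid - lambda_mid))))
}

#' Effective cone spectral sensitivity
#'
#' The effective sensitivity of a single cone is the pointwise product of its
#' visual-pigment absorbance (Govardovskii template at the fitted lambda-max)
#' and its oil-droplet transmission, renormalized to peak 1. The long-pass
#' droplet shifts the peak to longer wavelengths (except the transparent
#' T-type, which leaves the pigment curve unchanged) but does not alter the
#' long-wavelength limb, so the upper 5% cutoff stays that of the pigment.
#'
#' @param lambda_max Pigment peak in nm.
#' @param droplet_type One of `"T"`, `"C"`, `"Y"`, `"R"`.
#' @param lambda_mid Droplet 50% transmission wavelength in nm; `"auto"`
#'   derives the C-type value from [c_type_lambda_mid()]. Ignored for T-type.
#' @param k Logistic slope per nm; `NULL` uses the per-type default.
#' @param grid Wavelength grid in nm.
#' @param beta_band Include the template beta band? Default `TRUE`.
#' @param cone_name Optional label carried into reports.
#' @param cutoff_level Cutoff fraction (default 0.05). Cutoffs are referenced
#'   to the unfiltered pigment peak, not to the attenuated product's own
#'   maximum: a long-pass droplet transmits essentially fully on the
#'   long-wavelength limb, so the pigment alone sets the upper perception
#'   limit, and referencing the cutoff to the product's (possibly heavily
#'   attenuated) peak would artificially stretch both limbs.
#' @return An object of class `cone_sensitivity`: a list with the normalized
#'   `sensitivity` spectrum, `peak_nm`, `lower_cutoff_nm` and
#'   `upper_cutoff_nm` (either may be `NA` if the level is not crossed on the
#'   grid). Use [glance()] for a one-row summary.
#' @examples
#' rh2 <- effective_sensitivity(482, "Y", lambda_mid = 523)
#' rh2$peak_nm # ~ 530 nm
#' @export
effective_sensitivity <- function(lambda_max, droplet_type = "T",
                                  lambda_mid = "auto", k = NULL,
                                  grid = default_grid(), beta_band = TRUE,
                                  cone_name = NULL, cutoff_level = 0.05) {
  if (identical(lambda_mid, "auto")) {
    lambda_mid <- if (droplet_type == "C") c_type_lambda_mid(lambda_max) else NULL
  }
  pigment <- govardovskii_absorbance(lambda_max, grid, beta_band)
  droplet <- droplet_transmission(droplet_type, lambda_mid, k, grid)
  product <- pigment$value * droplet$value
  eff <- normalize_peak(as_spectrum(grid, product))
  # cutoff level rescaled from the pigment-peak scale onto the normalized
  # product so the droplet's attenuation does not move the limbs
  eff_level <- cutoff_level / max(product)
  lower <- tryCatch(cutoff_wavelength(eff, eff_level, "short"),
                    error = function(e) NA_real_)
  upper <- tryCatch(cutoff_wavelength(eff, eff_level, "long"),
                    error = function(e) NA_real_)
  structure(
    list(cone_name = cone_name %||% droplet_type,
         lambda_max = lambda_max, droplet_type = droplet_type,
         lambda_mid = lambda_mid, k = k,
         sensitivity = eff,
         peak_nm = peak_wavelength(eff),
         lower_cutoff_nm = lower, upper_cutoff_nm = upper,
         cutoff_level = cutoff_level),
    class = "cone_sensitivity"
  )
}

#' @export
print.cone_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<cone_sensitivity> %s: pigment %.0f nm x %s-droplet -> peak %.1f nm (%.0f%% cutoffs %.1f-%.1f nm)\n",
    x$cone_name, x$lambda_max, x$droplet_type, x$peak_nm,
    100 * x$cutoff_level, x$lower_cutoff_nm, x$upper_cutoff_nm))
  invisible(x)
}

#' @rdname tidy.rhodopsin_fit
#' @export
glance.cone_sensitivity <- function(x, ...) {
  tibble::tibble(cone = x$cone_name,
                 lambda_max = x$lambda_max,
                 droplet_type = x$droplet_type,
                 lambda_mid = x$lambda_mid %||% NA_real_,
                 peak_nm = x$peak_nm,
                 lower5_nm = x$lower_cutoff_nm,
                 upper5_nm = x$upper_cutoff_nm)
}

#' @rdname tidy.rhodopsin_fit
#' @export
tidy.cone_sensitivity <- function(x, ...) {
  dplyr::mutate(x$sensitivity, cone = x$cone_name, .before = 1)
}

#' Black grouse cone configuration
#'
#' The measured black grouse cone set: the four fitted pigment peaks with the droplet type,
#' mid-transmission wavelength and slope screening each cone. The C-type
#' lambda-mid is marked `"auto"` (derived from the SWS2 pigment); Y and R use
#' the Galliformes microspectrophotometry defaults 523 and 586 nm.
#'
#' @return A tibble `cone,lambda_max,droplet_type,lambda_mid,k`.
#' @export
black_grouse_cones <- function() {
  tibble::tibble(
    cone = c("SWS1", "SWS2", "Rh2", "LW"),
    lambda_max = c(393, 436, 482, 545),
    droplet_type = c("T", "C", "Y", "R"),
    lambda_mid = c(NA, NA, 523, 586),
    k = c(NA, 0.15, 0.12, 0.12)
  )
}

#' Effective sensitivities for a table of cones
#'
#' Runs [effective_sensitivity()] for each row of a cone configuration table
#' and returns the per-cone summary (peak and 5% cutoffs).
#'
#' @param cones Tibble with columns `cone,lambda_max,droplet_type,lambda_mid,k`
#'   (`lambda_mid` `NA` means `"auto"` for C-type and is ignored for T-type);
#'   default [black_grouse_cones()].
#' @param grid Wavelength grid in nm.
#' @param beta_band Include the template beta band? Default `TRUE`.
#' @return A tibble `cone,lambda_max,droplet_type,lambda_mid,peak_nm,lower5_nm,upper5_nm`.
#' @examples
#' cone_sensitivity_table()
#' @export
cone_sensitivity_table <- function(cones = black_grouse_cones(),
                                   grid = default_grid(), beta_band = TRUE) {
  purrr::pmap_dfr(cones, function(cone, lambda_max, droplet_type,
                                  lambda_mid, k, ...) {
    lm <- if (is.na(lambda_mid)) "auto" else lambda_mid
    kk <- if (is.null(k) || is.na(k)) NULL else k
    glance(effective_sensitivity(lambda_max, droplet_type, lambda_mid = lm,
                                 k = kk, grid = grid, beta_band = beta_band,
                                 cone_name = cone))
  })
}

#' Whole-eye perception range
#'
#' The perceived wavelength range is bounded below by the short-limb 5%
#' cutoff of the SWS1 pigment (its T-type droplet is transparent, so the
#' pigment alone sets the limit) and above by the long-limb 5% cutoff of the
#' LW pigment (droplet filtering does not alter the long-wavelength limb).
#' With the beta band enabled, the SWS1 short limb may stay above 5% across
#' the whole grid; the lower bound is then `NA` and in practice the bound is
#' set by ocular-media transmission, which is outside the scope of this model.
#'
#' @param lambda_maxes Named numeric vector with the four cones
#'   `SWS1`, `SWS2`, `Rh2`, `LW` (nm).
#' @param grid Wavelength grid in nm.
#' @param beta_band Include the template beta band? Default `TRUE`.
#' @return A tibble with columns `lower_nm` and `upper_nm`.
#' @examples
#' perception_range(c(SWS1 = 393, SWS2 = 436, Rh2 = 482, LW = 545))
#' @export
perception_range <- function(lambda_maxes, grid = default_grid(),
                             beta_band = TRUE) {
  need <- c("SWS1", "SWS2", "Rh2", "LW")
  if (!all(need %in% names(lambda_maxes))) {
    stop("`lambda_maxes` must name all four cones: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  sws1 <- govardovskii_absorbance(lambda_maxes[["SWS1"]], grid, beta_band)
  lw <- govardovskii_absorbance(lambda_maxes[["LW"]], grid, beta_band)
  lower <- tryCatch(cutoff_wavelength(sws1, 0.05, "short"),
                    error = function(e) NA_real_)
  upper <- cutoff_wavelength(lw, 0.05, "long")
  tibble::tibble(lower_nm = lower, upper_nm = upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
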