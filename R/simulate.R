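#' Simulate replicate absorbance spectra of a visual pigment
#'
#' Each replicate is the peak-normalized Govardovskii template plus
#' independent Gaussian noise at every grid point, optionally offset by a
#' replicate-specific random baseline — the structure of repeated UV-VIS
#' aliquot measurements of a purified rhodopsin. Seeded and bit-reproducible.
#'
#' @param lambda_max True pigment peak in nm.
#' @param n Number of replicates.
#' @param noise_sd Per-point Gaussian noise sd (absorbance units, on the
#'   peak-1 scale). Default 0.02.
#' @param grid Wavelength grid in nm (default 300--700 at 1 nm).
#' @param baseline_sd Sd of the per-replicate constant baseline offset
#'   (default 0).
#' @param seed Integer seed.
#' @param beta_band Include the template beta band? Default `TRUE`.
#' @param pigment Optional pigment label (default derived from `lambda_max`).
#' @return A long tibble `pigment, replicate_id, wavelength_nm, absorbance`.
#' @examples
#' reps <- simulate_absorbance_replicates(393, n = 7, seed = 42)
#' @export
simulate_absorbance_replicates <- function(lambda_max, n = 7,
                                           noise_sd = 0.02,
                                           grid = seq(300, 700, by = 1),
                                           baseline_sd = 0, seed = 1,
                                           beta_band = TRUE,
                                           pigment = NULL) {
  stopifnot(n >= 1, noise_sd >= 0, baseline_sd >= 0)
  pigment <- pigment %||% sprintf("pigment_%.0f", lambda_max)
  template <- govardovskii_absorbance(lambda_max, grid, beta_band)$value
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  purrr::map_dfr(seq_len(n), function(r) {
    offset <- if (baseline_sd > 0) stats::rnorm(1, 0, baseline_sd) else 0
    tibble::tibble(
      pigment = pigment,
      replicate_id = r,
      wavelength_nm = grid,
      absorbance = template + offset + stats::rnorm(length(grid), 0, noise_sd))
  })
}

#' Default contrast ladder for simulated reflex trials
#'
#' Twelve roughly log-spaced Michelson contrast levels spanning the tested
#' range 0.012--0.99 and containing the 0.06 level at which a sensitivity of
#' 16.67 thresholds.
#'
#' @return Numeric vector of contrasts, increasing.
#' @export
default_contrast_ladder <- function() {
  c(0.012, 0.02, 0.03, 0.045, 0.06, 0.09, 0.13, 0.20, 0.30, 0.45, 0.70, 0.99)
}

#' Simulate optocollic-reflex trials for a synthetic observer
#'
#' The observer responds to a grating of contrast c at spatial frequency f
#' exactly when its true sensitivity s(f) satisfies s(f) >= 1/c; an
#' independent lapse probability flips individual responses. Each frequency
#' by contrast combination is presented five times, and the stimulus
#' direction sequence is pseudorandom with at most three consecutive
#' identical directions.
#'
#' @param true_csf Tibble `spatial_frequency_cpd, sensitivity` giving the
#'   observer's generating CSF.
#' @param contrast_ladder Contrast levels tested at every frequency
#'   (default [default_contrast_ladder()]).
#' @param lapse_rate Probability of flipping each response (default 0).
#' @param individual_id Label for the simulated bird (default `"A"`).
#' @param seed Integer seed.
#' @return A trial tibble `individual_id, spatial_frequency_cpd, contrast,
#'   block_id, presentation_index, direction, response` consumable by
#'   [csf_points()].
#' @examples
#' csf_true <- tibble::tibble(spatial_frequency_cpd = c(0.5, 1, 1.5),
#'                            sensitivity = c(8, 16.67, 2))
#' trials <- simulate_ocr_trials(csf_true, seed = 7)
#' @export
simulate_ocr_trials <- function(true_csf,
                                contrast_ladder = default_contrast_ladder(),
                                lapse_rate = 0, individual_id = "A",
                                seed = 1) {
  stopifnot(all(c("spatial_frequency_cpd", "sensitivity") %in%
                  names(true_csf)),
            all(contrast_ladder > 0 & contrast_ladder <= 1),
            lapse_rate >= 0, lapse_rate < 1)
  combos <- tidyr::expand_grid(
    spatial_frequency_cpd = true_csf$spatial_frequency_cpd,
    contrast = sort(contrast_ladder)) |>
    dplyr::left_join(true_csf, by = "spatial_frequency_cpd")
  n_trials <- nrow(combos) * 5

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  directions <- direction_sequence(n_trials, max_run = 3)
  trials <- combos |>
    dplyr::mutate(block_id = dplyr::row_number()) |>
    tidyr::uncount(5, .id = "presentation_index") |>
    dplyr::mutate(
      individual_id = individual_id,
      direction = directions,
      response = .data$sensitivity >= 1 / .data$contrast)
  if (lapse_rate > 0) {
    flip <- stats::runif(n_trials) < lapse_rate
    trials$response <- xor(trials$response, flip)
  }
  dplyr::select(trials, "individual_id", "spatial_frequency_cpd", "contrast",
                "block_id", "presentation_index", "direction", "response")
}

# pseudorandom clockwise/anticlockwise sequence with bounded run length
direction_sequence <- function(n, max_run = 3) {
  dirs <- c("clockwise", "anticlockwise")
  out <- character(n)
  run <- 0L
  for (i in seq_len(n)) {
    if (i > 1 && run >= max_run) {
      out[i] <- setdiff(dirs, out[i - 1])
    } else {
      out[i] <- sample(dirs, 1)
    }
    run <- if (i > 1 && out[i] == out[i - 1]) run + 1L else 1L
  }
  out
}

#' Simulate a smooth marker reflectance spectrum
#'
#' A baseline plus a sum of Gaussian bumps on the 300--780 nm grid at 1 nm —
#' the smooth profiles typical of painted and retroreflective marker
#' materials. Amplitudes above 100% are allowed (fluorescent materials).
#'
#' @param baseline_pct Constant baseline reflectance in percent (>= 0).
#' @param bumps Optional tibble `center_nm, width_nm, amplitude_pct`
#'   (Gaussian sd in nm; amplitudes >= 0).
#' @param grid Wavelength grid in nm (default 300:780).
#' @param noise_sd Optional Gaussian measurement noise sd in percent
#'   (default 0, i.e. deterministic).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A spectrum tibble of reflectance in percent.
#' @examples
#' flat <- simulate_reflectance(50)
#' mean_reflectance(flat) # 50
#' @export
simulate_reflectance <- function(baseline_pct, bumps = NULL,
                                 grid = seq(300, 780, by = 1),
                                 noise_sd = 0, seed = 1) {
  stopifnot(baseline_pct >= 0, noise_sd >= 0)
  v <- rep(baseline_pct, length(grid))
  if (!is.null(bumps) && nrow(bumps) > 0) {
    stopifnot(all(c("center_nm", "width_nm", "amplitude_pct") %in%
                    names(bumps)),
              all(bumps$amplitude_pct >= 0), all(bumps$width_nm > 0))
    for (i in seq_len(nrow(bumps))) {
      v <- v + bumps$amplitude_pct[i] *
        exp(-((grid - bumps$center_nm[i]) / bumps$width_nm[i])^2 / 2)
    }
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    v <- pmax(0, v + stats::rnorm(length(grid), 0, noise_sd))
  }
  as_spectrum(grid, v)
}

#' Simulate a marker reflectance table
#'
#' Builds the long-format records table consumed by [marker_contrasts()]
#' from a material definition table of flat baselines (one smooth spectrum
#' per material, duplicated into the diffuse component).
#'
#' @param materials Tibble `marker, material, baseline_pct`.
#' @param component Component label for the generated spectra
#'   (default `"diffuse"`).
#' @inheritParams simulate_reflectance
#' @return A long reflectance tibble
#'   `marker, material, component, wavelength_nm, reflectance_pct`.
#' @export
simulate_marker_records <- function(materials, component = "diffuse",
                                    grid = seq(300, 780, by = 1),
                                    noise_sd = 0, seed = 1) {
  stopifnot(all(c("marker", "material", "baseline_pct") %in% names(materials)))
  purrr::pmap_dfr(
    materials,
    function(marker, material, baseline_pct, ...) {
      spec <- simulate_reflectance(baseline_pct, grid = grid,
                                   noise_sd = noise_sd,
                                   seed = seed + nchar(material))
      tibble::tibble(marker = marker, material = material,
                     component = component,
                     wavelength_nm = spec$wavelength_nm,
                     reflectance_pct = spec$value)
    })
}

#' Reference binocular-width profile used as generator truth
#'
#' A smooth synthetic elevation profile mirroring the measured black grouse
#' field: binocular width 28 deg in the horizontal plane (elevation 0), a
#' maximum overlap of 40 deg at elevation 30 deg, tapering to zero at the
#' extremes of the measured arc.
#'
#' @return A tibble `elevation_deg, binocular_width_deg` on a 10-degree
#'   ladder.
#' @export
default_field_truth <- function() {
  tibble::tibble(
    elevation_deg = seq(-40, 140, by = 10),
    binocular_width_deg = c(0, 6, 13, 20, 28, 33, 37, 40, 38, 35, 31, 27,
                            23, 19, 15, 11, 8, 4, 0))
}

#' Simulate visual-field perimeter measurements
#'
#' Works backwards from a true (infinity-referred) field map to what the
#' perimeter would read: per elevation, each eye's converged boundary sits at
#' minus half the binocular width (azimuths positive toward the measured
#' eye's side), the diverged boundary in the horizontal plane extends the
#' monocular field by the lateral width, and every true azimuth is mapped to
#' its perimeter reading with [perimeter_azimuth()] before Gaussian
#' measurement noise is added. Listed elevations are dropped to exercise
#' bill-holder interpolation downstream.
#'
#' @param true_widths Tibble `elevation_deg, binocular_width_deg`
#'   (default [default_field_truth()]).
#' @param lateral_each_deg True lateral field of each eye in the horizontal
#'   plane (default 162.5).
#' @param eye_separation_mm,perimeter_radius_mm Apparatus geometry
#'   (defaults 30 and 500).
#' @param noise_sd Gaussian measurement noise sd in degrees (default 0).
#' @param blocked_elevations Elevations whose converged measurements are
#'   dropped (default none).
#' @param seed Integer seed.
#' @param horizontal_elevation_deg Elevation of the horizontal plane
#'   (default 0).
#' @return A boundary tibble `eye, elevation_deg, azimuth_deg, kind` for
#'   [build_visual_field_map()].
#' @export
simulate_visual_field <- function(true_widths = default_field_truth(),
                                  lateral_each_deg = 162.5,
                                  eye_separation_mm = 30,
                                  perimeter_radius_mm = 500,
                                  noise_sd = 0, blocked_elevations = NULL,
                                  seed = 1,
                                  horizontal_elevation_deg = 0) {
  stopifnot(all(c("elevation_deg", "binocular_width_deg") %in%
                  names(true_widths)))
  conv <- tidyr::expand_grid(eye = c("left", "right"),
                             true_widths) |>
    dplyr::mutate(kind = "converged",
                  true_azimuth_deg = -.data$binocular_width_deg / 2)
  horiz <- true_widths$binocular_width_deg[
    true_widths$elevation_deg == horizontal_elevation_deg]
  div <- tibble::tibble(
    eye = c("left", "right"),
    elevation_deg = horizontal_elevation_deg,
    binocular_width_deg = horiz,
    kind = "diverged",
    true_azimuth_deg = horiz / 2 + lateral_each_deg)
  all <- dplyr::bind_rows(conv, div) |>
    dplyr::mutate(azimuth_deg = perimeter_azimuth(
      .data$true_azimuth_deg, eye_separation_mm, perimeter_radius_mm))
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    all$azimuth_deg <- all$azimuth_deg +
      stats::rnorm(nrow(all), 0, noise_sd)
  }
  if (!is.null(blocked_elevations)) {
    all <- all[!(all$kind == "converged" &
                   all$elevation_deg %in% blocked_elevations), ]
  }
  dplyr::select(all, "eye", "elevation_deg", "azimuth_deg", "kind")
}
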