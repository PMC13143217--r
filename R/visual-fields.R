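#' Correct a perimeter azimuth to an infinite viewing distance
#'
#' Visual-field boundaries are read off a perimeter of finite radius centred
#' on the head, but the eye sits half the interocular separation away from
#' the median plane, so the measured azimuth slightly misstates the direction
#' of the boundary ray. Treating one elevation as a planar construction, the
#' perimeter point at radius R and measured azimuth phi (from bill-forward,
#' positive toward the measured eye's side) lies at
#' (R sin phi, R cos phi), the eye at (e/2, 0); the corrected azimuth is the
#' direction of the ray from the eye to that point,
#' atan2(R sin phi - e/2, R cos phi). It converges to the measured azimuth as
#' R grows or e shrinks.
#'
#' @param measured_azimuth_deg Azimuth read on the perimeter, degrees.
#' @param eye_separation_mm Horizontal separation of the eye centres, >= 0.
#' @param perimeter_radius_mm Radius of the perimeter, > `eye_separation_mm`/2.
#' @return The corrected azimuth in degrees.
#' @examples
#' correct_to_infinity(90, 30, 500)
#' @export
correct_to_infinity <- function(measured_azimuth_deg, eye_separation_mm,
                                perimeter_radius_mm) {
  check_field_geometry(eye_separation_mm, perimeter_radius_mm)
  phi <- measured_azimuth_deg * pi / 180
  x <- perimeter_radius_mm * sin(phi) - eye_separation_mm / 2
  y <- perimeter_radius_mm * cos(phi)
  atan2(x, y) * 180 / pi
}

#' @description `perimeter_azimuth()` is the exact inverse: given the
#'   boundary-ray azimuth at the eye, it returns the azimuth of the point
#'   where that ray meets the perimeter, i.e. what the apparatus would read.
#' @param true_azimuth_deg Boundary-ray azimuth at the eye, degrees.
#' @rdname correct_to_infinity
#' @export
perimeter_azimuth <- function(true_azimuth_deg, eye_separation_mm,
                              perimeter_radius_mm) {
  check_field_geometry(eye_separation_mm, perimeter_radius_mm)
  psi <- true_azimuth_deg * pi / 180
  e2 <- eye_separation_mm / 2
  r <- perimeter_radius_mm
  # ray from (e2, 0) with direction (sin psi, cos psi); positive root of
  # |(e2 + t sin psi, t cos psi)| = r
  b <- e2 * sin(psi)
  t <- -b + sqrt(b^2 + r^2 - e2^2)
  atan2(e2 + t * sin(psi), t * cos(psi)) * 180 / pi
}

check_field_geometry <- function(e, r) {
  if (any(e < 0)) stop("`eye_separation_mm` must be >= 0", call. = FALSE)
  if (any(r <= e / 2)) {
    stop("perimeter radius must exceed half the eye separation", call. = FALSE)
  }
  invisible(TRUE)
}

#' Interpolate a blocked elevation
#'
#' Where the bill holder blocks the view, the binocular field width is
#' interpolated as the mean of the widths immediately above and below.
#'
#' @param width_above_deg,width_below_deg Neighbouring binocular widths in
#'   degrees, both present and >= 0.
#' @return The interpolated width in degrees.
#' @examples
#' interpolate_blocked_elevation(20, 30) # 25
#' @export
interpolate_blocked_elevation <- function(width_above_deg, width_below_deg) {
  if (anyNA(c(width_above_deg, width_below_deg))) {
    stop("cannot interpolate: a neighbouring elevation is missing",
         call. = FALSE)
  }
  if (any(width_above_deg < 0) || any(width_below_deg < 0)) {
    stop("binocular widths must be >= 0", call. = FALSE)
  }
  (width_above_deg + width_below_deg) / 2
}

#' Horizontal-plane visual-field decomposition
#'
#' The cyclopean field is the binocular overlap plus both lateral fields;
#' whatever remains of the full circle is the blind sector behind the head.
#'
#' @param binocular_deg Frontal binocular overlap in degrees.
#' @param lateral_each_deg Lateral field of each eye in degrees.
#' @return A one-row tibble with `cyclopean_deg` and `blind_deg`.
#' @examples
#' horizontal_summary(28, 162.5) # 353 and 7
#' @export
horizontal_summary <- function(binocular_deg, lateral_each_deg) {
  if (any(binocular_deg < 0) || any(lateral_each_deg < 0)) {
    stop("field widths must be >= 0", call. = FALSE)
  }
  cyclopean <- binocular_deg + 2 * lateral_each_deg
  if (any(cyclopean > 360 + 1e-9)) {
    stop("binocular + 2 x lateral exceeds 360 degrees; measurements are ",
         "inconsistent", call. = FALSE)
  }
  tibble::tibble(cyclopean_deg = cyclopean, blind_deg = 360 - cyclopean)
}

#' Vertical extent of the binocular field
#'
#' Total vertical span of the binocular field in the median sagittal plane:
#' the sum of its limits above and below the bill-tip direction.
#'
#' @param upper_limit_deg Degrees above the eye--bill-tip direction (>= 0).
#' @param lower_limit_deg Degrees below it (>= 0).
#' @return The vertical extent in degrees.
#' @examples
#' vertical_extent(135, 35) # 170
#' @export
vertical_extent <- function(upper_limit_deg, lower_limit_deg) {
  if (any(upper_limit_deg < 0) || any(lower_limit_deg < 0)) {
    stop("limits must be >= 0", call. = FALSE)
  }
  upper_limit_deg + lower_limit_deg
}

#' Build a visual-field map from perimeter boundary measurements
#'
#' Corrects every measured boundary azimuth to infinity, computes the
#' binocular width at each 10-degree elevation from the converged (forward)
#' boundaries of the two eyes, interpolates elevations blocked by the bill
#' holder, and derives the horizontal-plane sector decomposition from the
#' diverged (backward) boundaries at the horizontal elevation.
#'
#' Azimuths follow the package convention: measured from the bill-forward
#' direction, positive toward the measured eye's side, so a converged
#' boundary that crosses the median plane has a negative azimuth and the
#' binocular width at an elevation is `-(azimuth_left + azimuth_right)`
#' (floored at zero). Elevation 0 is the horizontal plane through the eyes;
#' positive elevations run up and over the head.
#'
#' @param boundaries Tibble with columns `eye` (`"left"`/`"right"`),
#'   `elevation_deg`, `azimuth_deg`, `kind` (`"converged"`/`"diverged"`),
#'   e.g. from [simulate_visual_field()] or [read_boundaries_csv()].
#' @param eye_separation_mm,perimeter_radius_mm Apparatus geometry passed to
#'   [correct_to_infinity()].
#' @param horizontal_elevation_deg Elevation of the horizontal plane
#'   (default 0).
#' @return An object of class `visual_field_map`: a list with
#'   `binocular_by_elevation` (tibble `elevation_deg, binocular_width_deg,
#'   interpolated`), `binocular_width_horizontal_deg`, `lateral_width_deg`,
#'   `cyclopean_width_deg`, `blind_width_deg`,
#'   `vertical_binocular_extent_deg`, `max_overlap_deg`,
#'   `max_overlap_elevation_deg`. Use [tidy()] / [glance()].
#' @export
build_visual_field_map <- function(boundaries, eye_separation_mm,
                                   perimeter_radius_mm,
                                   horizontal_elevation_deg = 0) {
  stopifnot(all(c("eye", "elevation_deg", "azimuth_deg", "kind") %in%
                  names(boundaries)))
  b <- dplyr::mutate(
    tibble::as_tibble(boundaries),
    corrected_deg = correct_to_infinity(.data$azimuth_deg, eye_separation_mm,
                                        perimeter_radius_mm))

  conv <- b |>
    dplyr::filter(.data$kind == "converged") |>
    dplyr::group_by(.data$elevation_deg) |>
    dplyr::summarise(
      n_eyes = dplyr::n_distinct(.data$eye),
      binocular_width_deg = pmax(0, -sum(.data$corrected_deg)),
      .groups = "drop") |>
    dplyr::filter(.data$n_eyes == 2) |>
    dplyr::select(-"n_eyes")

  # fill the 10-degree ladder; blocked elevations get the mean of neighbours
  ladder <- seq(min(conv$elevation_deg), max(conv$elevation_deg), by = 10)
  map <- tibble::tibble(elevation_deg = ladder) |>
    dplyr::left_join(conv, by = "elevation_deg") |>
    dplyr::mutate(interpolated = is.na(.data$binocular_width_deg))
  for (i in which(map$interpolated)) {
    if (i > 1 && i < nrow(map) &&
        !is.na(map$binocular_width_deg[i - 1]) &&
        !is.na(map$binocular_width_deg[i + 1])) {
      map$binocular_width_deg[i] <- interpolate_blocked_elevation(
        map$binocular_width_deg[i + 1], map$binocular_width_deg[i - 1])
    }
  }

  horiz_row <- map[map$elevation_deg == horizontal_elevation_deg, ]
  if (nrow(horiz_row) != 1 || is.na(horiz_row$binocular_width_deg)) {
    stop("no binocular width available at the horizontal elevation",
         call. = FALSE)
  }
  bin_h <- horiz_row$binocular_width_deg

  # lateral fields need the diverged boundaries in the horizontal plane
  div_h <- b |>
    dplyr::filter(.data$kind == "diverged",
                  .data$elevation_deg == horizontal_elevation_deg)
  conv_h <- b |>
    dplyr::filter(.data$kind == "converged",
                  .data$elevation_deg == horizontal_elevation_deg)
  lateral <- NA_real_
  cyclo <- NA_real_
  blind <- NA_real_
  if (nrow(div_h) == 2 && nrow(conv_h) == 2) {
    span <- dplyr::inner_join(
      dplyr::select(div_h, "eye", div = "corrected_deg"),
      dplyr::select(conv_h, "eye", conv = "corrected_deg"), by = "eye")
    # monocular span = binocular share + lateral field
    lateral <- mean(span$div - span$conv) - bin_h
    hs <- horizontal_summary(bin_h, lateral)
    cyclo <- hs$cyclopean_deg
    blind <- hs$blind_deg
  }

  known <- map[!is.na(map$binocular_width_deg), ]
  pos <- known$binocular_width_deg > 0
  vert <- if (any(pos)) {
    zero_cross_span(known$elevation_deg, known$binocular_width_deg)
  } else {
    0
  }
  max_i <- which.max(known$binocular_width_deg)

  structure(
    list(binocular_by_elevation = map,
         binocular_width_horizontal_deg = bin_h,
         lateral_width_deg = lateral,
         cyclopean_width_deg = cyclo,
         blind_width_deg = blind,
         vertical_binocular_extent_deg = vert,
         max_overlap_deg = known$binocular_width_deg[max_i],
         max_overlap_elevation_deg = known$elevation_deg[max_i],
         eye_separation_mm = eye_separation_mm,
         perimeter_radius_mm = perimeter_radius_mm),
    class = "visual_field_map"
  )
}

# span of elevations with positive width, extended to the linear zero
# crossings just beyond the outermost positive samples
zero_cross_span <- function(elev, width) {
  pos <- which(width > 0)
  lo_i <- pos[1]; hi_i <- pos[length(pos)]
  lo <- elev[lo_i]
  if (lo_i > 1) {
    lo <- stats::approx(width[c(lo_i - 1, lo_i)], elev[c(lo_i - 1, lo_i)],
                        xout = 0)$y
  }
  hi <- elev[hi_i]
  if (hi_i < length(elev)) {
    hi <- stats::approx(width[c(hi_i, hi_i + 1)], elev[c(hi_i, hi_i + 1)],
                        xout = 0)$y
  }
  hi - lo
}

#' @export
print.visual_field_map <- function(x, ...) {
  cat(sprintf(
    paste0("<visual_field_map> horizontal: binocular %.1f, lateral %.1f each,",
           " cyclopean %.1f, blind %.1f deg\n",
           "  vertical binocular extent %.1f deg;",
           " max overlap %.1f deg at elevation %.0f deg\n"),
    x$binocular_width_horizontal_deg, x$lateral_width_deg,
    x$cyclopean_width_deg, x$blind_width_deg,
    x$vertical_binocular_extent_deg,
    x$max_overlap_deg, x$max_overlap_elevation_deg))
  invisible(x)
}

#' @rdname tidy.rhodopsin_fit
#' @export
tidy.visual_field_map <- function(x, ...) x$binocular_by_elevation

#' @rdname tidy.rhodopsin_fit
#' @export
glance.visual_field_map <- function(x, ...) {
  tibble::tibble(
    binocular_deg = x$binocular_width_horizontal_deg,
    lateral_deg = x$lateral_width_deg,
    cyclopean_deg = x$cyclopean_width_deg,
    blind_deg = x$blind_width_deg,
    vertical_extent_deg = x$vertical_binocular_extent_deg,
    max_overlap_deg = x$max_overlap_deg,
    max_overlap_elevation_deg = x$max_overlap_elevation_deg)
}

#' Read visual-field boundary measurements from CSV
#'
#' Expects columns `eye,elevation_deg,azimuth_deg,kind`; `#` lines are
#' comments.
#'
#' @param path File path.
#' @return A boundary tibble for [build_visual_field_map()].
#' @export
read_boundaries_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("eye", "elevation_deg", "azimuth_deg", "kind") %in%
                  names(df)))
  tibble::as_tibble(df)
}
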