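#' Michelson contrast of a luminance pair
#'
#' \deqn{C_m = (I_{max} - I_{min}) / (I_{max} + I_{min})}
#' with luminances in cd m^-2. Ranges from 0 (no contrast) to 1 (perfect
#' black--white difference).
#'
#' @param i_min,i_max Minimum and maximum luminance, `i_max >= i_min >= 0`,
#'   not both zero.
#' @return Contrast in \[0, 1\].
#' @examples
#' michelson_contrast(20, 80) # 0.6
#' @export
michelson_contrast <- function(i_min, i_max) {
  if (any(i_min < 0) || any(i_max < i_min)) {
    stop("luminances must satisfy i_max >= i_min >= 0", call. = FALSE)
  }
  if (any(i_min + i_max == 0)) {
    stop("contrast is undefined when both luminances are zero", call. = FALSE)
  }
  (i_max - i_min) / (i_max + i_min)
}

#' Four-of-five response reliability rule
#'
#' Each frequency-by-contrast combination is presented five times; the
#' response is reliable if the optocollic reflex occurred in at least four of
#' the five presentations.
#'
#' @param responses Logical vector of exactly five trial responses.
#' @return `TRUE` if at least four responses are `TRUE`.
#' @examples
#' reliable_response(c(TRUE, TRUE, TRUE, TRUE, FALSE)) # TRUE
#' @export
reliable_response <- function(responses) {
  if (length(responses) != 5 || !is.logical(responses) || anyNA(responses)) {
    stop("`responses` must be exactly 5 non-missing logical values",
         call. = FALSE)
  }
  sum(responses) >= 4
}

#' Threshold contrasts per individual and spatial frequency
#'
#' Groups optocollic-reflex trials into five-presentation blocks per contrast
#' level, applies the four-of-five reliability rule, and takes the lowest
#' reliable contrast as the threshold. Sensitivity is the inverse threshold.
#' Frequencies with no reliable level at any contrast are retained with
#' `threshold_contrast = NA` and `no_threshold = TRUE` so the exclusion is
#' visible downstream.
#'
#' @param trials Tibble with columns `individual_id`,
#'   `spatial_frequency_cpd`, `contrast`, `response` (logical), five rows per
#'   individual x frequency x contrast combination, e.g. from
#'   [simulate_ocr_trials()] or [read_trials_csv()].
#' @return A tibble `individual_id, spatial_frequency_cpd,
#'   threshold_contrast, sensitivity, no_threshold`, sorted by frequency.
#' @export
csf_points <- function(trials) {
  need <- c("individual_id", "spatial_frequency_cpd", "contrast", "response")
  stopifnot(all(need %in% names(trials)))
  if (any(trials$contrast <= 0 | trials$contrast > 1)) {
    stop("contrasts must lie in (0, 1]", call. = FALSE)
  }
  if (any(trials$spatial_frequency_cpd <= 0)) {
    stop("spatial frequencies must be positive", call. = FALSE)
  }
  blocks <- trials |>
    dplyr::group_by(.data$individual_id, .data$spatial_frequency_cpd,
                    .data$contrast) |>
    dplyr::summarise(n_pres = dplyr::n(),
                     n_resp = sum(.data$response), .groups = "drop")
  if (any(blocks$n_pres != 5)) {
    stop("each individual x frequency x contrast block must hold exactly ",
         "5 presentations", call. = FALSE)
  }
  blocks |>
    dplyr::mutate(reliable = .data$n_resp >= 4) |>
    dplyr::group_by(.data$individual_id, .data$spatial_frequency_cpd) |>
    dplyr::summarise(
      threshold_contrast = if (any(.data$reliable)) {
        min(.data$contrast[.data$reliable])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(sensitivity = 1 / .data$threshold_contrast,
                  no_threshold = is.na(.data$threshold_contrast)) |>
    dplyr::arrange(.data$individual_id, .data$spatial_frequency_cpd)
}

#' Assemble a contrast sensitivity function for one individual
#'
#' Takes the per-frequency threshold table of a single individual (see
#' [csf_points()]), drops frequencies without a threshold, and extracts the
#' peak sensitivity, its spatial frequency (the optimal frequency; lowest
#' frequency on ties) and the high cut-off frequency (see
#' [cutoff_frequency()]).
#'
#' @param points Threshold tibble for one individual.
#' @return An object of class `csf`: a list with `individual_id`, `points`,
#'   `peak_sensitivity`, `peak_frequency_cpd`, `cutoff_frequency_cpd` (may be
#'   `NA`). Use [tidy()] for the points and [glance()] for the summary row.
#' @export
csf_fit <- function(points) {
  stopifnot(all(c("individual_id", "spatial_frequency_cpd",
                  "threshold_contrast", "sensitivity") %in% names(points)))
  id <- unique(points$individual_id)
  if (length(id) != 1) {
    stop("`csf_fit()` expects the points of a single individual; got ",
         length(id), call. = FALSE)
  }
  pts <- points |>
    dplyr::filter(!is.na(.data$threshold_contrast)) |>
    dplyr::arrange(.data$spatial_frequency_cpd)
  if (nrow(pts) == 0) {
    stop("no frequency reached a reliable threshold for individual ", id,
         call. = FALSE)
  }
  peak_i <- which.max(pts$sensitivity)
  obj <- structure(
    list(individual_id = id,
         points = pts,
         peak_sensitivity = pts$sensitivity[peak_i],
         peak_frequency_cpd = pts$spatial_frequency_cpd[peak_i],
         cutoff_frequency_cpd = NA_real_),
    class = "csf"
  )
  obj$cutoff_frequency_cpd <- cutoff_frequency(obj)
  obj
}

#' High cut-off spatial frequency of a CSF
#'
#' The highest spatial frequency detectable at full (Michelson 1) contrast,
#' i.e. where sensitivity falls to 1 on the descending high-frequency limb.
#' Located by log--log linear interpolation between the bracketing points
#' when the limb crosses 1 within the measured range, or by log--log linear
#' extrapolation of the two highest-frequency points otherwise. Returns `NA`
#' (no-cutoff outcome) when the descending limb has fewer than two points.
#'
#' @param csf A `csf` object from [csf_fit()].
#' @return Cut-off frequency in cycles per degree, or `NA`.
#' @export
cutoff_frequency <- function(csf) {
  stopifnot(inherits(csf, "csf"))
  pts <- csf$points
  desc <- pts[pts$spatial_frequency_cpd >= csf$peak_frequency_cpd, ]
  if (nrow(desc) < 2) return(NA_real_)
  f <- desc$spatial_frequency_cpd
  s <- desc$sensitivity
  if (s[length(s)] == 1) return(f[length(f)])
  if (any(s <= 1)) {
    i <- which(s <= 1)[1] # first point at/below sensitivity 1
    f1 <- f[i - 1]; f2 <- f[i]; s1 <- s[i - 1]; s2 <- s[i]
  } else {
    n <- length(f)
    f1 <- f[n - 1]; f2 <- f[n]; s1 <- s[n - 1]; s2 <- s[n]
    if (s2 >= s1) return(NA_real_) # limb not descending: no cutoff
  }
  # invert the log-log line through (f1,s1),(f2,s2) at s = 1
  slope <- (log10(s2) - log10(s1)) / (log10(f2) - log10(f1))
  10^(log10(f1) - log10(s1) / slope)
}

#' @export
print.csf <- function(x, ...) {
  cat(sprintf(
    "<csf> individual %s: peak sensitivity %.2f at %.2f cpd, cut-off %s cpd, %d frequencies\n",
    x$individual_id, x$peak_sensitivity, x$peak_frequency_cpd,
    ifelse(is.na(x$cutoff_frequency_cpd), "NA",
           sprintf("%.2f", x$cutoff_frequency_cpd)),
    nrow(x$points)))
  invisible(x)
}

#' @rdname tidy.rhodopsin_fit
#' @export
tidy.csf <- function(x, ...) x$points

#' @rdname tidy.rhodopsin_fit
#' @export
glance.csf <- function(x, ...) {
  tibble::tibble(individual_id = x$individual_id,
                 peak_sensitivity = x$peak_sensitivity,
                 peak_frequency_cpd = x$peak_frequency_cpd,
                 cutoff_frequency_cpd = x$cutoff_frequency_cpd,
                 n_frequencies = nrow(x$points))
}

#' Fit CSFs for every individual in a trial table
#'
#' @param trials Trial tibble (see [csf_points()]).
#' @return A named list of `csf` objects, one per individual.
#' @export
fit_csfs <- function(trials) {
  pts <- csf_points(trials)
  ids <- unique(pts$individual_id)
  stats::setNames(
    lapply(ids, function(id) {
      csf_fit(pts[pts$individual_id == id, ])
    }),
    ids)
}

#' Group summary of contrast sensitivity functions
#'
#' Averages individual CSFs the way group curves are usually presented:
#' per-individual peaks are extracted first, group optimal frequency and peak
#' sensitivity are their arithmetic means, and the mean curve averages
#' sensitivities at frequencies shared by all individuals. The minimal
#' perceivable brightness difference is the inverse of the mean peak
#' sensitivity.
#'
#' @param csfs A list of `csf` objects (e.g. from [fit_csfs()]), or a single
#'   `csf`.
#' @return A list with `per_individual` (tibble of [glance()] rows),
#'   `mean_peak_frequency_cpd`, `mean_peak_sensitivity`,
#'   `min_brightness_difference` (fraction), and `mean_curve`
#'   (tibble `spatial_frequency_cpd, sensitivity`).
#' @export
csf_summary <- function(csfs) {
  if (inherits(csfs, "csf")) csfs <- list(csfs)
  if (length(csfs) == 0) stop("need at least one CSF", call. = FALSE)
  per <- dplyr::bind_rows(lapply(csfs, glance))
  curves <- dplyr::bind_rows(lapply(csfs, tidy))
  mean_curve <- curves |>
    dplyr::group_by(.data$spatial_frequency_cpd) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n == length(csfs)) |>
    dplyr::select(-"n")
  list(per_individual = per,
       mean_peak_frequency_cpd = mean(per$peak_frequency_cpd),
       mean_peak_sensitivity = mean(per$peak_sensitivity),
       min_brightness_difference = 1 / mean(per$peak_sensitivity),
       mean_curve = mean_curve)
}

#' Read optocollic-reflex trials from CSV
#'
#' Expects columns `individual_id, spatial_frequency_cpd, contrast, block_id,
#' presentation_index, direction, response`; `#` lines are comments.
#'
#' @param path File path.
#' @return A trial tibble.
#' @export
read_trials_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("individual_id", "spatial_frequency_cpd", "contrast",
                  "response") %in% names(df)))
  df$response <- as.logical(df$response)
  tibble::as_tibble(df)
}

# round-half-down to `digits` decimals: 0.955 -> 0.95, matching how group
# means are conventionally printed in the source protocols. Internal.
round_half_down <- function(x, digits = 2) {
  p <- 10^digits
  ceiling(x * p - 0.5) / p
}
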