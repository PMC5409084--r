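#' Fit the nigericin high-K+ calibration line
#'
#' Ordinary least squares of the measured F495/F440 ratio on buffer pH.
#' The ratio-pH relation of the dye is near-linear over the working pH
#' range, so a straight line (rather than the full sigmoid) is fitted.
#'
#' @param points data.frame with columns `buffer_ph` (in \[5.5, 8.5\])
#'   and `ratio` (> 0), one row per calibration buffer.
#' @return A list of class `phiflux_calfit` with elements `slope`,
#'   `intercept`, `residual_sd` (0 when only two points), `ph_range`
#'   and `n_points`.
#' @export
#' @examples
#' pts <- data.frame(buffer_ph = c(6.5, 7.0, 7.5),
#'                   ratio = 0.5 + 1.2 * c(6.5, 7.0, 7.5))
#' fit_calibration(pts)$slope
fit_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("buffer_ph", "ratio") %in% names(points)))
  if (any(points$buffer_ph < 5.5 | points$buffer_ph > 8.5))
    stop("buffer_ph outside [5.5, 8.5]", call. = FALSE)
  if (any(points$ratio <= 0))
    stop("calibration ratios must be positive", call. = FALSE)
  if (length(unique(points$buffer_ph)) < 2)
    stop("insufficient data: need >= 2 distinct buffer pH values",
         call. = FALSE)
  fit <- stats::lm(ratio ~ buffer_ph, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0)
    stop("degenerate fit: zero calibration slope", call. = FALSE)
  n <- nrow(points)
  rsd <- if (n > 2) sqrt(sum(stats::residuals(fit)^2) / (n - 2)) else 0
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = rsd,
                 ph_range = range(points$buffer_ph),
                 n_points = n),
            class = "phiflux_calfit")
}

#' Convert fluorescence ratios to pH through a calibration fit
#'
#' Inverts the fitted line: `ph = (ratio - intercept) / slope`. Values
#' mapping more than 0.2 pH units outside the fitted buffer range are
#' returned (not rejected) and flagged in the `out_of_range` attribute.
#'
#' @param fit a [fit_calibration()] result.
#' @param ratio numeric vector of F495/F440 ratios.
#' @return pH values with a logical `out_of_range` attribute.
#' @export
ratio_to_ph <- function(fit, ratio) {
  stopifnot(inherits(fit, "phiflux_calfit"))
  if (fit$slope == 0) stop("degenerate calibration fit", call. = FALSE)
  ph <- (ratio - fit$intercept) / fit$slope
  flag <- ph < fit$ph_range[1] - 0.2 | ph > fit$ph_range[2] + 0.2
  attr(ph, "out_of_range") <- flag
  ph
}

#' Reproducibility of replicate calibrations
#'
#' Coefficient of variation (percent) of the fitted slopes across
#' replicate calibration curves. The slope governs the ratio-to-pH
#' conversion, so its dispersion is the quantity that propagates into
#' conversion error.
#'
#' @param fits list of [fit_calibration()] results (>= 2).
#' @return CV in percent: `100 * sd(slopes) / mean(slopes)`.
#' @export
calibration_cv <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "phiflux_calfit")))
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  m <- mean(slopes)
  if (m == 0) stop("undefined CV: mean slope is zero", call. = FALSE)
  100 * stats::sd(slopes) / m
}

#' Extract calibration points from a recorded trace
#'
#' For each `calibration_step` segment of the trace's annotation, the
#' mean F495/F440 ratio over the last `fraction` of the step window is
#' paired with the step's buffer pH. The early part of each step is
#' discarded because nigericin equilibration is not instantaneous.
#'
#' @param fluor a [fluorescence_trace()] whose annotation contains
#'   `calibration_step` segments.
#' @param fraction trailing fraction of each step used for the mean.
#' @return data.frame with columns `buffer_ph` and `ratio`, ready for
#'   [fit_calibration()].
#' @export
extract_calibration_points <- function(fluor, fraction = 0.6) {
  stopifnot(inherits(fluor, "phiflux_fluor"),
            fraction > 0 && fraction <= 1)
  seg <- segment_rows(trace_protocol(fluor), "calibration_step")
  out <- lapply(seq_len(nrow(seg)), function(i) {
    t0 <- seg$start_s[i] + (1 - fraction) * (seg$end_s[i] - seg$start_s[i])
    w <- trace_window(fluor, t0, seg$end_s[i])
    if (nrow(w) == 0)
      stop("insufficient data: no samples in calibration step at pH ",
           seg$ph_o[i], call. = FALSE)
    data.frame(buffer_ph = seg$ph_o[i], ratio = mean(w$f495 / w$f440))
  })
  do.call(rbind, out)
}
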