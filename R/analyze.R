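#' Convert a fluorescence trace to an intracellular pH trace
#'
#' Pointwise inversion of the calibration line on the F495/F440 ratio.
#' The protocol annotation is carried over; downstream analyses address
#' named segments, so calibration steps never leak into experiment
#' windows.
#'
#' @param fluor a [fluorescence_trace()].
#' @param fit a [fit_calibration()] result.
#' @return A [phi_trace()].
#' @export
convert_trace <- function(fluor, fit) {
  stopifnot(inherits(fluor, "phiflux_fluor"),
            inherits(fit, "phiflux_calfit"))
  bad <- which(fluor$f440 <= 0)
  if (length(bad))
    stop("data error: f440 <= 0 at sample index ", bad[1], call. = FALSE)
  ph <- as.numeric(ratio_to_ph(fit, fluor$f495 / fluor$f440))
  phi_trace(fluor$time_s, ph, trace_protocol(fluor))
}

#' Buffering capacity from the NH4Cl washout
#'
#' Applies the washout formula \eqn{\beta = \Delta[NH_4^+]_i / \Delta
#' pH_i}: the intracellular NH4+ present at the end of the exposure
#' (Henderson-Hasselbalch at the pre-washout pH) is divided by the pH
#' drop from the pre-washout level to the post-washout nadir. The
#' pre-washout pH is the mean over the last 15 s of the `nh4cl` segment;
#' the nadir is the minimum within 120 s after washout begins.
#'
#' @param phi a [phi_trace()] containing an `nh4cl` segment followed by a
#'   washout.
#' @param chem a [nh4_params()] object; by default the NH4Cl
#'   concentration and extracellular pH are taken from the trace's
#'   `nh4cl` segment annotation with pKa 9.2.
#' @param nadir_window_s search window for the post-washout nadir,
#'   seconds.
#' @return A list of class `phiflux_buffering` with `beta` (mmol/L per pH
#'   unit), `nh4_i_pre` (mM), `dph` (pH change across washout, negative),
#'   `ph_pre`, `ph_post` and `ph_mid`.
#' @export
buffering_capacity <- function(phi, chem = NULL, nadir_window_s = 120) {
  stopifnot(inherits(phi, "phiflux_phi"))
  prot <- trace_protocol(phi)
  nh4_seg <- segment_rows(prot, "nh4cl")[1, ]
  if (is.null(chem))
    chem <- nh4_params(total_nh4cl = nh4_seg$nh4cl_mM,
                       ph_o = nh4_seg$ph_o)
  stopifnot(inherits(chem, "phiflux_nh4"))
  after <- prot$segments[prot$segments$start_s >= nh4_seg$end_s - 1e-9 &
                           prot$segments$name %in% c("na_free", "recovery"), ]
  if (nrow(after) == 0)
    stop("protocol error: no washout (na_free/recovery) segment after ",
         "the nh4cl segment", call. = FALSE)
  pre_w <- trace_window(phi, nh4_seg$end_s - 15, nh4_seg$end_s)
  if (nrow(pre_w) == 0)
    stop("insufficient data: no samples in the last 15 s of the nh4cl ",
         "segment", call. = FALSE)
  ph_pre <- mean(pre_w$ph_i)
  post_w <- trace_window(phi, nh4_seg$end_s,
                         nh4_seg$end_s + nadir_window_s + 1e-9)
  if (nrow(post_w) == 0)
    stop("insufficient data: no samples within the nadir window",
         call. = FALSE)
  ph_post <- min(post_w$ph_i)
  if (ph_pre == ph_post)
    stop("undefined buffering capacity: no pH change across washout",
         call. = FALSE)
  nh4_pre <- nh4_internal(ph_pre, chem)
  structure(list(beta = nh4_pre / (ph_pre - ph_post),
                 nh4_i_pre = nh4_pre,
                 dph = ph_post - ph_pre,
                 ph_pre = ph_pre, ph_post = ph_post,
                 ph_mid = (ph_pre + ph_post) / 2),
            class = "phiflux_buffering")
}

#' Buffering models for net base uptake
#'
#' `beta_constant()` returns a flat buffering relation. In CO2/HCO3-
#' conditions a single washout-measured beta underestimates buffering at
#' higher pH, so `beta_co2_anchored()` extends the measurement with the
#' open-system bicarbonate shape: the CO2 coefficient is chosen so the
#' relation passes through the measured beta at the washout midpoint pH,
#' on top of the stated intrinsic component.
#'
#' @param beta a buffering capacity, mmol/L per pH unit.
#' @param buf a [buffering_capacity()] result.
#' @param beta_i assumed intrinsic buffering, mmol/L per pH unit.
#' @param pk_co2 CO2/HCO3- pK.
#' @return A function of pH returning buffering capacity.
#' @export
beta_constant <- function(beta) {
  stopifnot(is.numeric(beta), beta > 0)
  function(ph) rep(beta, length(ph))
}

#' @rdname beta_constant
#' @export
beta_co2_anchored <- function(buf, beta_i = 15, pk_co2 = 6.1) {
  stopifnot(inherits(buf, "phiflux_buffering"))
  coeff <- (buf$beta - beta_i) / (log(10) * 10^(buf$ph_mid - pk_co2))
  if (coeff <= 0) return(beta_constant(buf$beta))
  function(ph) beta_i + log(10) * coeff * 10^(ph - pk_co2)
}

#' Net base uptake as a function of intracellular pH
#'
#' Over the recovery segment, consecutive non-overlapping windows of
#' `window_s` seconds are fitted by least squares; each window's pH slope
#' (converted to pH/min) times the buffering capacity at the window's
#' mean pH gives a net base uptake estimate in mmol/L/min. Estimates are
#' binned on a regular pH grid (bins are `bin_width` wide, centred on
#' odd multiples of half the width) and averaged per bin.
#'
#' @param phi a [phi_trace()] with a recovery segment.
#' @param beta_model a single buffering capacity (mmol/L per pH unit) or
#'   a function of pH, e.g. from [beta_co2_anchored()].
#' @param window_s regression window length, seconds.
#' @param bin_width pH bin width.
#' @return A list of class `phiflux_uptake`: `profile` (data.frame
#'   `bin_center`, `uptake`, `n`) and `estimates` (one row per window:
#'   `t_mid`, `mean_ph`, `slope_per_min`, `uptake`).
#' @export
net_base_uptake <- function(phi, beta_model, window_s = 15,
                            bin_width = 0.05) {
  stopifnot(inherits(phi, "phiflux_phi"), window_s > 0, bin_width > 0)
  if (is.numeric(beta_model) && length(beta_model) == 1)
    beta_model <- beta_constant(beta_model)
  stopifnot(is.function(beta_model))
  rec <- segment_rows(trace_protocol(phi), "recovery")[1, ]
  starts <- seq(rec$start_s, rec$end_s - window_s, by = window_s)
  if (length(starts) == 0)
    stop("insufficient data: recovery segment shorter than one window",
         call. = FALSE)
  est <- lapply(starts, function(t0) {
    w <- trace_window(phi, t0, t0 + window_s)
    if (nrow(w) < 2) return(NULL)
    sl <- unname(stats::coef(stats::lm(ph_i ~ time_s, data = w))[2]) * 60
    mph <- mean(w$ph_i)
    data.frame(t_mid = t0 + window_s / 2, mean_ph = mph,
               slope_per_min = sl,
               uptake = sl * beta_model(mph))
  })
  est <- do.call(rbind, est)
  if (is.null(est) || nrow(est) == 0)
    stop("insufficient data: no complete regression window in recovery",
         call. = FALSE)
  centre <- (floor(est$mean_ph / bin_width) + 0.5) * bin_width
  prof <- stats::aggregate(est$uptake, by = list(bin_center = centre),
                           FUN = mean)
  names(prof)[2] <- "uptake"
  prof$n <- as.vector(table(centre)[as.character(prof$bin_center)])
  prof <- prof[order(prof$bin_center), ]
  rownames(prof) <- NULL
  structure(list(profile = prof, estimates = est),
            class = "phiflux_uptake")
}

#' Baseline and final plateau pH
#'
#' Mean pH over the first 60 s of the baseline segment and over the final
#' 60 s of the recovery segment, matching a 1-min recording of resting
#' and plateau levels.
#'
#' @param phi a [phi_trace()] with baseline and recovery segments of at
#'   least 60 s each.
#' @param window_s averaging window, seconds.
#' @return A list of class `phiflux_plateau` with `plateau_ph` and
#'   `baseline_ph`.
#' @export
plateau_ph <- function(phi, window_s = 60) {
  stopifnot(inherits(phi, "phiflux_phi"))
  prot <- trace_protocol(phi)
  base <- segment_rows(prot, "baseline")[1, ]
  rec <- segment_rows(prot, "recovery")[1, ]
  if (base$end_s - base$start_s < window_s ||
      rec$end_s - rec$start_s < window_s)
    stop("insufficient data: baseline and recovery segments must each ",
         "span >= ", window_s, " s", call. = FALSE)
  bw <- trace_window(phi, base$start_s, base$start_s + window_s)
  pw <- trace_window(phi, rec$end_s - window_s, rec$end_s)
  if (nrow(bw) == 0 || nrow(pw) == 0)
    stop("insufficient data: no samples in a plateau/baseline window",
         call. = FALSE)
  structure(list(plateau_ph = mean(pw$ph_i),
                 baseline_ph = mean(bw$ph_i)),
            class = "phiflux_plateau")
}

#' Resample the recovery on the common analysis grid
#'
#' Linear interpolation of pH onto the regular grid `start_s + k *
#' step_s`, `k = 1, ..., (end_s - start_s)/step_s`, with time referenced
#' to the reintroduction of Na+-containing buffer (the start of the
#' recovery segment). The half-open convention `(start_s, end_s]` yields
#' 280 points at the 60 s / 900 s / 3 s defaults.
#'
#' @param phi a [phi_trace()] whose recovery segment covers `end_s`
#'   seconds after Na+ reintroduction.
#' @param start_s,end_s grid limits, seconds after Na+ reintroduction
#'   (half-open: the first point lies one step after `start_s`).
#' @param step_s grid spacing, seconds.
#' @return Named numeric vector of pH values; names are the grid offsets
#'   in seconds.
#' @export
#' @examples
#' length(recovery_window(
#'   simulate_phi_trace(scenario_params("vsmc"), default_protocol())))
recovery_window <- function(phi, start_s = 60, end_s = 900, step_s = 3) {
  stopifnot(inherits(phi, "phiflux_phi"), end_s > start_s, step_s > 0)
  rec <- segment_rows(trace_protocol(phi), "recovery")[1, ]
  if (rec$end_s - rec$start_s < end_s)
    stop("insufficient data: recovery covers ",
         rec$end_s - rec$start_s, " s but the grid needs ", end_s, " s",
         call. = FALSE)
  offsets <- seq(start_s + step_s, end_s, by = step_s)
  grid <- rec$start_s + offsets
  w <- trace_window(phi, rec$start_s, rec$end_s + 1e-9)
  out <- stats::approx(w$time_s, w$ph_i, xout = grid, rule = 2)$y
  names(out) <- offsets
  out
}

#' Full per-cell analysis of one recording
#'
#' Convenience wrapper running the standard per-cell chain: calibration
#' from the trace's own nigericin steps, ratio-to-pH conversion,
#' buffering capacity from the washout, plateau/baseline means, net base
#' uptake with the CO2-anchored buffering relation (constant beta in
#' CO2-free recordings), and the recovery-window series.
#'
#' @param fluor a [fluorescence_trace()] with calibration steps.
#' @param window_s regression window for [net_base_uptake()].
#' @param bin_width pH bin width for [net_base_uptake()].
#' @param grid grid settings for [recovery_window()] as a list with
#'   `start_s`, `end_s`, `step_s`.
#' @return A list with elements `fit`, `phi`, `buffering`, `plateau`,
#'   `uptake` and `recovery`.
#' @export
analyze_cell <- function(fluor, window_s = 15, bin_width = 0.05,
                         grid = list(start_s = 60, end_s = 900,
                                     step_s = 3)) {
  fit <- fit_calibration(extract_calibration_points(fluor))
  phi <- convert_trace(fluor, fit)
  buf <- buffering_capacity(phi)
  rec <- segment_rows(trace_protocol(phi), "recovery")[1, ]
  bmod <- if (rec$co2_on) beta_co2_anchored(buf) else
    beta_constant(buf$beta)
  list(fit = fit,
       phi = phi,
       buffering = buf,
       plateau = plateau_ph(phi),
       uptake = net_base_uptake(phi, bmod, window_s, bin_width),
       recovery = recovery_window(phi, grid$start_s, grid$end_s,
                                  grid$step_s))
}
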