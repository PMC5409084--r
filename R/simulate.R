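#' Construct a pH trace object
#'
#' @param time_s sample times, seconds, strictly increasing.
#' @param ph_i intracellular pH values in \[5.5, 8.5\].
#' @param protocol the annotating [protocol_spec()].
#' @return data.frame of class `phiflux_phi` carrying the protocol as an
#'   attribute.
#' @export
phi_trace <- function(time_s, ph_i, protocol) {
  stopifnot(inherits(protocol, "phiflux_protocol"),
            length(time_s) == length(ph_i),
            all(diff(time_s) > 0))
  if (any(ph_i < 5.5 | ph_i > 8.5))
    stop("ph_i outside [5.5, 8.5]", call. = FALSE)
  structure(data.frame(time_s = time_s, ph_i = ph_i),
            protocol = protocol,
            class = c("phiflux_phi", "data.frame"))
}

#' Construct a fluorescence trace object
#'
#' @param time_s sample times, seconds, strictly increasing.
#' @param f495,f440 fluorescence at 495/440 nm excitation (arbitrary
#'   units); `f440` must be positive everywhere so the ratio is defined.
#' @param protocol the annotating [protocol_spec()].
#' @return data.frame of class `phiflux_fluor`.
#' @export
fluorescence_trace <- function(time_s, f495, f440, protocol) {
  stopifnot(inherits(protocol, "phiflux_protocol"),
            length(time_s) == length(f495),
            length(time_s) == length(f440),
            all(diff(time_s) > 0))
  if (any(f440 <= 0))
    stop("f440 must be positive everywhere", call. = FALSE)
  structure(data.frame(time_s = time_s, f495 = f495, f440 = f440),
            protocol = protocol,
            class = c("phiflux_fluor", "data.frame"))
}

#' Protocol annotation of a trace
#' @param trace a `phiflux_phi` or `phiflux_fluor` trace.
#' @return The [protocol_spec()] attached to the trace.
#' @export
trace_protocol <- function(trace) attr(trace, "protocol")

#' Restrict a trace to a time window, keeping its annotation
#' @param trace a `phiflux_phi` or `phiflux_fluor` trace.
#' @param from,to window bounds in seconds, half-open `[from, to)`.
#' @return The trace restricted to samples with `from <= time_s < to`.
#' @export
trace_window <- function(trace, from = -Inf, to = Inf) {
  keep <- trace$time_s >= from & trace$time_s < to
  out <- trace[keep, , drop = FALSE]
  attr(out, "protocol") <- attr(trace, "protocol")
  class(out) <- class(trace)
  out
}

#' Simulate a ground-truth intracellular pH trajectory
#'
#' Integrates the buffering-normalized flux balance
#' \deqn{\frac{dpH_i}{dt} = \frac{J(pH_i)}{60\,\beta(pH_i)}}
#' (fluxes in mmol/L/min, time in seconds) segment by segment with a
#' fixed-step fourth-order Runge-Kutta scheme, applying the instantaneous
#' NH3-equilibration jump of [nh4_step_jump()] at NH4Cl segment entry and
#' exit. During `calibration_step` segments nigericin clamps pHi to the
#' buffer pH with a first-order relaxation (time constant 2 s). The
#' integrated trajectory is then sampled at the protocol's acquisition
#' plan. The simulation is deterministic; photometric noise enters only in
#' [render_fluorescence()].
#'
#' @param params a [cell_params()] object.
#' @param protocol a [protocol_spec()].
#' @param ph0 initial pH; defaults to the steady state of the first
#'   segment's condition flags.
#' @param step_s integration step, seconds (must be <= 0.5).
#' @return A [phi_trace()] sampled per the protocol's plan.
#' @export
#' @examples
#' tr <- simulate_phi_trace(scenario_params("vsmc"), default_protocol())
#' range(tr$ph_i)
simulate_phi_trace <- function(params, protocol, ph0 = NULL,
                               step_s = 0.5) {
  stopifnot(inherits(params, "phiflux_cell"),
            inherits(protocol, "phiflux_protocol"),
            step_s > 0, step_s <= 0.5)
  seg <- protocol$segments
  if (is.null(ph0))
    ph0 <- analytic_plateau(params, co2_on = seg$co2_on[1],
                            dma_on = seg$dma_on[1], na_on = seg$na_on[1])
  dense_t <- numeric(0)
  dense_ph <- numeric(0)
  ph <- ph0
  prev_nh4 <- 0
  prev_pho <- seg$ph_o[1]
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (s$nh4cl_mM > 0 && prev_nh4 == 0) {
      ph <- nh4_step_jump(ph, params, s$nh4cl_mM, s$ph_o,
                          direction = "on", co2_on = s$co2_on)
    } else if (s$nh4cl_mM == 0 && prev_nh4 > 0) {
      ph <- nh4_step_jump(ph, params, prev_nh4, prev_pho,
                          direction = "off", co2_on = s$co2_on)
    }
    if (ph < 5.5 || ph > 8.5)
      stop("simulation error: pH ", signif(ph, 4), " outside [5.5, 8.5] ",
           "entering segment '", s$name, "'", call. = FALSE)
    times <- seq(s$start_s, s$end_s, by = step_s)
    if (times[length(times)] < s$end_s) times <- c(times, s$end_s)
    # plain-arithmetic right-hand side: the validated accessors are too
    # slow to call four times per integration step
    rhs <- if (s$name == "calibration_step") {
      local({ target <- s$ph_o; function(t, y, parms)
        list((target - y) / 2) })
    } else {
      local({
        nbc_a <- if (s$co2_on && s$na_on) params$g * params$a_nbc else 0
        nhe_a <- if (s$na_on && !s$dma_on) params$a_nhe else 0
        s_nbc <- params$ph_set_nbc; s_nhe <- params$ph_set_nhe
        jl <- params$j_load; bi <- params$beta_i
        bc <- if (s$co2_on) log(10) * params$hco3_coeff else 0
        pk <- params$pk_co2
        function(t, y, parms) {
          j <- nbc_a * max(0, s_nbc - y) + nhe_a * max(0, s_nhe - y) - jl
          list(j / (60 * (bi + bc * 10^(y - pk))))
        }
      })
    }
    sol <- deSolve::ode(y = ph, times = times, func = rhs, parms = NULL,
                        method = "rk4")
    phs <- sol[, 2]
    if (any(phs < 5.5 | phs > 8.5))
      stop("simulation error: pH left [5.5, 8.5] during segment '",
           s$name, "' (range ", signif(min(phs), 4), "-",
           signif(max(phs), 4), ")", call. = FALSE)
    keep <- if (i < nrow(seg)) times < s$end_s else rep(TRUE, length(times))
    dense_t <- c(dense_t, times[keep])
    dense_ph <- c(dense_ph, phs[keep])
    ph <- phs[length(phs)]
    prev_nh4 <- s$nh4cl_mM
    prev_pho <- s$ph_o
  }
  ts <- sample_times(protocol)
  phi <- stats::approx(dense_t, dense_ph, xout = ts, rule = 2)$y
  phi_trace(ts, phi, protocol)
}

#' Photometric model of the dual-excitation optics
#'
#' The forward ratio map is linear, `F495/F440 = intercept + slope * pHi`
#' (the nigericin calibration inverts it). Channel intensities carry
#' independent multiplicative lognormal noise with unit mean, and the
#' F440 baseline may drift linearly in time.
#'
#' @param slope ratio change per pH unit (non-zero).
#' @param intercept ratio at pH 0 (extrapolated).
#' @param f440_baseline mean F440 intensity, arbitrary units (> 0).
#' @param noise_cv coefficient of variation of the per-sample lognormal
#'   noise on each channel.
#' @param drift_per_min linear F440 drift per minute (fraction of
#'   baseline).
#' @return A list of class `phiflux_optics`.
#' @export
optics_params <- function(slope = 1.0, intercept = -5.0,
                          f440_baseline = 1000, noise_cv = 0.005,
                          drift_per_min = 0) {
  stopifnot(slope != 0, noise_cv >= 0)
  if (f440_baseline <= 0)
    stop("f440_baseline must be positive", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 f440_baseline = f440_baseline, noise_cv = noise_cv,
                 drift_per_min = drift_per_min),
            class = "phiflux_optics")
}

#' Render a noisy fluorescence trace from a pH trajectory
#'
#' Applies the forward optics map of [optics_params()] to a simulated pH
#' trace: `f440(t) = baseline * (1 + drift * t/60) * eta440(t)` and
#' `f495(t) = (intercept + slope * ph_i(t)) * baseline * (1 + drift *
#' t/60) * eta495(t)`, with independent unit-mean lognormal noise factors
#' per channel. At zero noise and drift the ratio reproduces the forward
#' map exactly. Reproducible given `seed`.
#'
#' @param phi a [phi_trace()].
#' @param optics an [optics_params()] object.
#' @param seed integer seed for the noise draws (NULL = use current RNG
#'   state).
#' @return A [fluorescence_trace()] with the same annotation.
#' @export
render_fluorescence <- function(phi, optics = optics_params(),
                                seed = NULL) {
  stopifnot(inherits(phi, "phiflux_phi"),
            inherits(optics, "phiflux_optics"))
  n <- nrow(phi)
  ratio <- optics$intercept + optics$slope * phi$ph_i
  base <- optics$f440_baseline *
    (1 + optics$drift_per_min * phi$time_s / 60)
  if (any(base <= 0))
    stop("drift drove the F440 baseline non-positive", call. = FALSE)
  noise <- with_seed(seed, list(e495 = rlnorm_cv(n, optics$noise_cv),
                                e440 = rlnorm_cv(n, optics$noise_cv)))
  fluorescence_trace(phi$time_s,
                     f495 = ratio * base * noise$e495,
                     f440 = base * noise$e440,
                     protocol = trace_protocol(phi))
}
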