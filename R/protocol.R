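#' Protocol specification for an ammonium-prepulse experiment
#'
#' A protocol is an ordered set of contiguous, non-overlapping time
#' segments, each carrying the condition flags that apply while it runs,
#' plus a sampling plan stating the acquisition interval per segment.
#' Segment times are seconds from trace start and half-open
#' `[start_s, end_s)`.
#'
#' @param segments data.frame with columns `name` (one of `baseline`,
#'   `nh4cl`, `na_free`, `recovery`, `plateau`, `calibration_step`),
#'   `start_s`, `end_s`, `co2_on`, `dma_on`, `na_on`, `nh4cl_mM`, `ph_o`.
#'   For `calibration_step` segments `ph_o` is the pH of the high-K+
#'   nigericin buffer.
#' @param sampling data.frame with columns `interval_s` and `segments`
#'   (comma-separated segment names the interval applies to). Segments not
#'   named default to 15 s.
#' @return A validated object of class `phiflux_protocol`.
#' @seealso [default_protocol()]
#' @export
protocol_spec <- function(segments, sampling = NULL) {
  need <- c("name", "start_s", "end_s", "co2_on", "dma_on", "na_on",
            "nh4cl_mM", "ph_o")
  if (!all(need %in% names(segments)))
    stop("protocol segments must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  segments <- as.data.frame(segments)[, need]
  ok_names <- c("baseline", "nh4cl", "na_free", "recovery", "plateau",
                "calibration_step")
  bad <- setdiff(segments$name, ok_names)
  if (length(bad))
    stop("unknown segment name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- nrow(segments)
  if (n < 1) stop("protocol needs at least one segment", call. = FALSE)
  if (any(segments$end_s <= segments$start_s))
    stop("protocol error: every segment needs end_s > start_s",
         call. = FALSE)
  if (n > 1) {
    if (any(diff(segments$start_s) <= 0))
      stop("protocol error: segments must be strictly increasing in time",
           call. = FALSE)
    if (any(abs(segments$end_s[-n] - segments$start_s[-1]) > 1e-9))
      stop("protocol error: segments must be contiguous (end of one = ",
           "start of next)", call. = FALSE)
  }
  if (any(segments$nh4cl_mM < 0))
    stop("nh4cl_mM must be non-negative", call. = FALSE)
  if (any(segments$nh4cl_mM > 0 & segments$name != "nh4cl"))
    stop("protocol error: nh4cl_mM > 0 only allowed in nh4cl segments",
         call. = FALSE)
  if (any(segments$na_on & segments$name == "na_free"))
    stop("protocol error: na_on must be FALSE in na_free segments",
         call. = FALSE)
  if (is.null(sampling))
    sampling <- data.frame(interval_s = 15,
                           segments = paste(unique(segments$name),
                                            collapse = ","))
  stopifnot(all(c("interval_s", "segments") %in% names(sampling)),
            all(sampling$interval_s > 0))
  structure(list(segments = segments,
                 sampling = as.data.frame(sampling)),
            class = "phiflux_protocol")
}

#' Default ammonium-prepulse protocol templates
#'
#' Three named condition templates of the same prepulse design:
#' 5 min baseline, NH4Cl exposure, brief Na+-free washout, long
#' Na+-containing recovery, then three 2-min nigericin calibration steps.
#' Sampling is every 3 s during washout and recovery (the periods of
#' interest) and every 15 s elsewhere.
#'
#' * `co2_dma`: CO2/HCO3- present throughout; 30 uM DMA (NHE inhibition)
#'   during washout and recovery; 20 mM NH4Cl for 3 min.
#' * `co2`: as above without DMA.
#' * `free`: nominally CO2/HCO3–-free throughout. With intrinsic-only
#'   buffering a 20 mM prepulse would acidify the model cell beyond the
#'   calibrated pH range, so this template uses a gentler 10 mM, 1-min
#'   exposure.
#'
#' @param condition one of `"co2_dma"`, `"co2"`, `"free"`.
#' @param ph_o extracellular pH of the experimental buffers.
#' @param calibration_ph pH values of the high-K+ nigericin calibration
#'   buffers, applied in order after recovery.
#' @param recovery_s duration of the recovery segment, seconds. The
#'   default is long enough for the model cohorts to settle at their
#'   steady-state plateau and covers the 60-900 s analysis window.
#' @return A `phiflux_protocol`.
#' @export
#' @examples
#' prot <- default_protocol("co2_dma")
#' prot$segments[, c("name", "start_s", "end_s", "dma_on")]
default_protocol <- function(condition = c("co2_dma", "co2", "free"),
                             ph_o = 7.4,
                             calibration_ph = c(6.5, 7.0, 7.5),
                             recovery_s = 2100) {
  condition <- match.arg(condition)
  co2 <- condition != "free"
  dma <- condition == "co2_dma"
  nh4_mM <- if (co2) 20 else 10
  nh4_dur <- if (co2) 180 else 60
  t0 <- 300                       # baseline end
  t1 <- t0 + nh4_dur              # NH4Cl end / washout start
  t2 <- t1 + 45                   # washout end / Na+ reintroduction
  t3 <- t2 + recovery_s           # recovery end / calibration start
  seg <- data.frame(
    name     = c("baseline", "nh4cl", "na_free", "recovery"),
    start_s  = c(0, t0, t1, t2),
    end_s    = c(t0, t1, t2, t3),
    co2_on   = co2,
    dma_on   = c(FALSE, FALSE, dma, dma),
    na_on    = c(TRUE, TRUE, FALSE, TRUE),
    nh4cl_mM = c(0, nh4_mM, 0, 0),
    ph_o     = ph_o
  )
  cal <- data.frame(
    name     = "calibration_step",
    start_s  = t3 + 120 * (seq_along(calibration_ph) - 1),
    end_s    = t3 + 120 * seq_along(calibration_ph),
    co2_on   = FALSE, dma_on = FALSE, na_on = FALSE, nh4cl_mM = 0,
    ph_o     = calibration_ph
  )
  protocol_spec(
    rbind(seg, cal),
    sampling = data.frame(
      interval_s = c(3, 15),
      segments = c("na_free,recovery",
                   "baseline,nh4cl,plateau,calibration_step"))
  )
}

# Acquisition times implied by a protocol's sampling plan: half-open per
# segment (the first sample of the next segment falls on the boundary).
sample_times <- function(protocol) {
  stopifnot(inherits(protocol, "phiflux_protocol"))
  seg <- protocol$segments
  plan <- protocol$sampling
  lookup <- rep(15, nrow(seg))
  for (i in seq_len(nrow(plan))) {
    names_i <- trimws(strsplit(plan$segments[i], ",")[[1]])
    lookup[seg$name %in% names_i] <- plan$interval_s[i]
  }
  out <- lapply(seq_len(nrow(seg)), function(i) {
    ts <- seq(seg$start_s[i], seg$end_s[i], by = lookup[i])
    ts[ts < seg$end_s[i]]
  })
  sort(unique(c(unlist(out), seg$end_s[nrow(seg)])))
}

# The segment rows matching `name`, or an error mentioning the caller's
# analysis so protocol problems are attributable.
segment_rows <- function(protocol, name, required = TRUE) {
  seg <- protocol$segments[protocol$segments$name %in% name, , drop = FALSE]
  if (required && nrow(seg) == 0)
    stop("protocol error: no '", paste(name, collapse = "/"),
         "' segment in annotation", call. = FALSE)
  seg
}
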