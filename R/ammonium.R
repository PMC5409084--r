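#' Ammonium chemistry parameters
#'
#' Constants of the Henderson-Hasselbalch calculation used for the
#' ammonium prepulse: total extracellular NH4Cl, the NH4+/NH3 pKa, and the
#' extracellular pH.
#'
#' @param total_nh4cl total extracellular NH4Cl, mM.
#' @param pka NH4+/NH3 pKa (dimensionless).
#' @param ph_o extracellular pH.
#' @return A list of class `phiflux_nh4`.
#' @export
nh4_params <- function(total_nh4cl = 20, pka = 9.2, ph_o = 7.4) {
  stopifnot(total_nh4cl > 0, pka >= 8.5 && pka <= 10)
  structure(list(total_nh4cl = total_nh4cl, pka = pka, ph_o = ph_o),
            class = "phiflux_nh4")
}

#' Intracellular NH4+ concentration from Henderson-Hasselbalch
#'
#' Assuming NH3 equilibrates freely across the membrane, the extracellular
#' NH3 concentration is `total / (1 + 10^(pka - ph_o))` and the
#' intracellular NH4+ concentration follows as
#' \deqn{[NH_4^+]_i = \frac{total}{1 + 10^{pKa - pH_o}} \, 10^{pKa - pH_i}}
#' One pH unit of intracellular acidification raises it ten-fold.
#'
#' @param ph_i intracellular pH (vectorized).
#' @param chem a [nh4_params()] object.
#' @return Intracellular NH4+ in mM.
#' @export
#' @examples
#' nh4_internal(7.0) # about 49.45 mM at the 20 mM / pKa 9.2 defaults
nh4_internal <- function(ph_i, chem = nh4_params()) {
  stopifnot(inherits(chem, "phiflux_nh4"))
  nh3_o <- chem$total_nh4cl / (1 + 10^(chem$pka - chem$ph_o))
  nh3_o * 10^(chem$pka - ph_i)
}

#' Instantaneous pH jump at NH4Cl application or washout
#'
#' On NH4Cl application NH3 enters and binds H+, alkalinizing the cell by
#' an amount set by the buffering capacity; on washout the accumulated
#' NH4+ leaves as NH3, depositing its protons and acidifying. The
#' post-jump pH solves the buffering balance
#' \deqn{\bar\beta (pH_{after} - pH_{before}) = \pm [NH_4^+]_i}
#' where the ammonium load is evaluated at the post-jump pH for
#' application ("on") and at the pre-jump pH for washout ("off"), and
#' \eqn{\bar\beta} is the total buffering capacity at the midpoint pH.
#' The balance is solved by bisection to `tol`.
#'
#' @param ph_before pH immediately before the jump.
#' @param params a [cell_params()] object (supplies the buffering model).
#' @param nh4cl_mM total extracellular NH4Cl during exposure, mM.
#' @param ph_o extracellular pH.
#' @param pka NH4+/NH3 pKa.
#' @param direction `"on"` (application, alkalinizes) or `"off"`
#'   (washout, acidifies).
#' @param co2_on is CO2/HCO3- present (affects the buffering capacity)?
#' @param beta optional fixed buffering capacity overriding the midpoint
#'   evaluation (useful for closed-form checks).
#' @param tol solver tolerance in pH units.
#' @param max_iter bisection iteration bound.
#' @return The post-equilibration pH.
#' @export
#' @examples
#' p <- cell_params()
#' # washout from pH 7.0 with beta fixed at 123.6: drop of 49.45/123.6
#' nh4_step_jump(7.0, p, direction = "off", beta = 123.6)
nh4_step_jump <- function(ph_before, params, nh4cl_mM = 20, ph_o = 7.4,
                          pka = 9.2, direction = c("on", "off"),
                          co2_on = TRUE, beta = NULL,
                          tol = 1e-6, max_iter = 200L) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "phiflux_cell"), nh4cl_mM >= 0)
  if (nh4cl_mM == 0) return(ph_before)
  chem <- nh4_params(nh4cl_mM, pka, ph_o)
  bal <- function(ph_after) {
    bbar <- beta %||%
      beta_total(params, clamp_ph((ph_before + ph_after) / 2), co2_on)
    amt <- if (direction == "on") nh4_internal(ph_after, chem)
           else -nh4_internal(ph_before, chem)
    bbar * (ph_after - ph_before) - amt
  }
  lo <- if (direction == "on") ph_before else 4.5
  hi <- if (direction == "on") 10 else ph_before
  flo <- bal(lo); fhi <- bal(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("nh4_step_jump: no sign change on [", lo, ", ", hi,
         "]; ph_before=", signif(ph_before, 6),
         " direction=", direction, " nh4cl_mM=", nh4cl_mM,
         " f(lo)=", signif(flo, 4), " f(hi)=", signif(fhi, 4),
         call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- bal(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (flo * fm < 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  stop("nh4_step_jump: bisection did not converge in ", max_iter,
       " iterations (interval [", signif(lo, 8), ", ", signif(hi, 8), "])",
       call. = FALSE)
}

# beta_total is only defined on [5.5, 8.5]; during bisection the midpoint
# may transiently leave it, so evaluate at the clamped pH.
clamp_ph <- function(ph) pmin(8.5, pmax(5.5, ph))
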