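#' Cell parameters for the transporter-driven pH regulation model
#'
#' A simulated cell is described by two acid extruders and a constant
#' background acid load. The Na+/HCO3- co-transporter (NBC) and the Na+/H+
#' exchanger (NHE) each import base at a rate linear in the distance of
#' intracellular pH below a set point, and switch off above it:
#' \deqn{J_{NBC} = g\,a_{nbc}\,\max(0, pH_{set,nbc} - pH_i)}
#' \deqn{J_{NHE} = a_{nhe}\,\max(0, pH_{set,nhe} - pH_i)}
#' NBC activity requires extracellular Na+ and CO2/HCO3-; NHE requires Na+
#' and is blocked by dimethylamiloride (DMA). The genotype multiplier `g`
#' scales NBC capacity (risk-allele carriers express more transporter).
#'
#' @param a_nbc NBC flux slope, mmol/L/min per pH unit.
#' @param g genotype expression multiplier (dimensionless, > 0; values
#'   above 1 model risk-allele carriers).
#' @param ph_set_nbc pH at which NBC flux reaches zero.
#' @param a_nhe NHE flux slope, mmol/L/min per pH unit.
#' @param ph_set_nhe pH at which NHE flux reaches zero.
#' @param j_load constant background acid-loading flux, mmol/L/min.
#' @param beta_i intrinsic (non-CO2) buffering capacity, mmol/L per pH unit.
#' @param hco3_coeff dissolved CO2 concentration term of the open-system
#'   bicarbonate buffer, mmol/L (about 0.03 mmol/L/mmHg x 40 mmHg).
#' @param pk_co2 pK of the CO2/HCO3- buffer pair.
#' @return An object of class `phiflux_cell`.
#' @seealso [scenario_params()] for the cohort default parameter sets.
#' @export
#' @examples
#' p <- cell_params(a_nbc = 6, g = 1.33)
#' transporter_flux(p, ph = 7.0, co2_on = TRUE, dma_on = TRUE, na_on = TRUE)
cell_params <- function(a_nbc = 6, g = 1, ph_set_nbc = 7.45,
                        a_nhe = 6, ph_set_nhe = 7.10,
                        j_load = 2.1, beta_i = 15,
                        hco3_coeff = 1.2, pk_co2 = 6.1) {
  stopifnot(
    a_nbc >= 0, a_nhe >= 0, j_load >= 0, beta_i >= 0, hco3_coeff >= 0,
    g > 0,
    ph_set_nbc >= 6 && ph_set_nbc <= 8,
    ph_set_nhe >= 6 && ph_set_nhe <= 8
  )
  structure(
    list(a_nbc = a_nbc, g = g, ph_set_nbc = ph_set_nbc,
         a_nhe = a_nhe, ph_set_nhe = ph_set_nhe,
         j_load = j_load, beta_i = beta_i,
         hco3_coeff = hco3_coeff, pk_co2 = pk_co2),
    class = "phiflux_cell"
  )
}

#' Default parameter sets for the two cell-type scenarios
#'
#' `vsmc` models vascular smooth muscle cells, where NBC and NHE capacities
#' are comparable and the NHE set point sits below the NBC-determined
#' plateau, so the genotype effect on plateau pHi persists even without
#' NHE inhibition. `vec` models vascular endothelial cells, with about
#' four-fold NHE dominance, larger overall transport capacity (faster
#' recovery), and an NHE set point above the NBC plateau, so the genotype
#' effect is masked unless NHE is blocked with DMA.
#'
#' The genotype multipliers are calibrated so that, under CO2/HCO3- with
#' DMA, the risk-vs-protective difference in analytic plateau pHi is
#' 0.087 (vsmc) and 0.082 (vec).
#'
#' @param scenario `"vsmc"` or `"vec"`.
#' @param genotype `"protective"` (g = 1) or `"risk"` (scenario-specific
#'   risk multiplier).
#' @return A `phiflux_cell` object.
#' @export
#' @examples
#' dp <- scenario_params("vsmc", "risk")
#' pp <- scenario_params("vsmc", "protective")
#' analytic_plateau(dp, dma_on = TRUE) - analytic_plateau(pp, dma_on = TRUE)
scenario_params <- function(scenario = c("vsmc", "vec"),
                            genotype = c("protective", "risk")) {
  scenario <- match.arg(scenario)
  genotype <- match.arg(genotype)
  g <- if (genotype == "risk") genotype_multiplier(scenario) else 1
  switch(scenario,
    vsmc = cell_params(a_nbc = 6, g = g, ph_set_nbc = 7.45,
                       a_nhe = 6, ph_set_nhe = 7.10, j_load = 2.1),
    vec  = cell_params(a_nbc = 12, g = g, ph_set_nbc = 7.45,
                       a_nhe = 48, ph_set_nhe = 7.25, j_load = 4.2)
  )
}

#' @rdname scenario_params
#' @export
genotype_multiplier <- function(scenario = c("vsmc", "vec")) {
  switch(match.arg(scenario), vsmc = 1.33, vec = 1.306)
}

#' Net acid-base flux at a given intracellular pH
#'
#' Sum of the NBC and NHE base import minus the constant background acid
#' load, under the stated condition flags. Vectorized over `ph`.
#'
#' @param params a [cell_params()] object.
#' @param ph intracellular pH, in \[5.5, 8.5\].
#' @param co2_on is CO2/HCO3- present (required for NBC flux)?
#' @param dma_on is the Na+/H+ exchanger inhibited by DMA?
#' @param na_on is extracellular Na+ present (required for both
#'   transporters)?
#' @return Net flux in mmol/L/min (positive = net base uptake).
#' @export
transporter_flux <- function(params, ph, co2_on = TRUE, dma_on = FALSE,
                             na_on = TRUE) {
  stopifnot(inherits(params, "phiflux_cell"), all(ph >= 5.5 & ph <= 8.5))
  j_nbc <- if (co2_on && na_on)
    params$g * params$a_nbc * pmax(0, params$ph_set_nbc - ph) else 0
  j_nhe <- if (na_on && !dma_on)
    params$a_nhe * pmax(0, params$ph_set_nhe - ph) else 0
  j_nbc + j_nhe - params$j_load
}

#' Total buffering capacity at a given pH
#'
#' Intrinsic buffering plus, when CO2/HCO3- is present, the open-system
#' bicarbonate term `ln(10) * hco3_coeff * 10^(ph - pk_co2)`, which grows
#' ten-fold per pH unit and dominates near physiological pH.
#'
#' @inheritParams transporter_flux
#' @return Buffering capacity in mmol/L per pH unit. Vectorized over `ph`.
#' @export
beta_total <- function(params, ph, co2_on = TRUE) {
  stopifnot(inherits(params, "phiflux_cell"), all(ph >= 5.5 & ph <= 8.5))
  co2 <- if (co2_on)
    log(10) * params$hco3_coeff * 10^(ph - params$pk_co2) else 0
  params$beta_i + co2
}

#' Closed-form steady-state (plateau) pH
#'
#' The root of `transporter_flux(ph) = 0` on \[5.5, 8.5\]. The flux is a
#' continuous, non-increasing piecewise-linear function of pH, so the root
#' is found exactly on the linear piece where the sign changes. With DMA
#' and an active NBC this reduces to
#' `ph_set_nbc - j_load / (g * a_nbc)`.
#'
#' @inheritParams transporter_flux
#' @return The plateau pH. Errors when no active transporter can balance
#'   the acid load within \[5.5, 8.5\].
#' @export
#' @examples
#' p <- scenario_params("vsmc", "risk")
#' analytic_plateau(p, dma_on = TRUE) # 7.45 - 2.1 / (1.33 * 6)
analytic_plateau <- function(params, co2_on = TRUE, dma_on = FALSE,
                             na_on = TRUE) {
  stopifnot(inherits(params, "phiflux_cell"))
  nbc_act <- co2_on && na_on && params$a_nbc > 0
  nhe_act <- na_on && !dma_on && params$a_nhe > 0
  if (!nbc_act && !nhe_act)
    stop("no active transporter: plateau undefined", call. = FALSE)
  # breakpoints of the piecewise-linear flux, in increasing pH order
  brk <- sort(unique(c(5.5, 8.5,
                       if (nbc_act) params$ph_set_nbc,
                       if (nhe_act) params$ph_set_nhe)))
  f <- function(ph) transporter_flux(params, ph, co2_on, dma_on, na_on)
  for (i in seq_len(length(brk) - 1)) {
    lo <- brk[i]; hi <- brk[i + 1]
    flo <- f(lo); fhi <- f(hi)
    if (flo == 0) return(lo)
    if (flo > 0 && fhi <= 0) {
      # linear on [lo, hi]: interpolate the zero crossing exactly
      return(lo + flo * (hi - lo) / (flo - fhi))
    }
  }
  if (f(8.5) == 0) return(8.5)
  stop("transporter flux has no zero in [5.5, 8.5]; ",
       "acid load exceeds transport capacity on the whole range",
       call. = FALSE)
}
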