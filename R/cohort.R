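#' Specification of a synthetic genotype cohort
#'
#' Describes a cohort of simulated cells split into risk-allele carriers
#' (genotype multiplier g = scenario risk value) and protective-allele
#' homozygotes (g = 1), with multiplicative per-cell jitter on the
#' transport capacities and the acid load.
#'
#' @param scenario `"vsmc"` or `"vec"` (see [scenario_params()]).
#' @param n_risk,n_protective cells per genotype group (>= 1 each).
#' @param jitter_cv coefficient of variation of the lognormal per-cell
#'   jitter applied independently to `a_nbc`, `a_nhe` and `j_load`
#'   (in \[0, 0.5\]).
#' @param noise_cv photometric noise CV passed to the optics model.
#' @param seed integer seed; every cell derives its own stream from the
#'   seed and its label, so traces do not depend on generation order.
#' @return A list of class `phiflux_cohort_spec`.
#' @export
cohort_spec <- function(scenario = c("vsmc", "vec"), n_risk = 5,
                        n_protective = 7, jitter_cv = 0.03,
                        noise_cv = 0.005, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_risk >= 1, n_protective >= 1,
            jitter_cv >= 0 && jitter_cv <= 0.5, noise_cv >= 0)
  structure(list(scenario = scenario, n_risk = n_risk,
                 n_protective = n_protective, jitter_cv = jitter_cv,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "phiflux_cohort_spec")
}

#' Generate a synthetic cohort of fluorescence traces with ground truth
#'
#' For each cell, scenario default parameters are jittered, the prepulse
#' protocol is integrated with [simulate_phi_trace()], and a noisy
#' fluorescence recording is rendered with [render_fluorescence()]. The
#' returned ground-truth table holds each cell's parameters and its
#' analytic baseline and plateau pH under the protocol's baseline and
#' recovery condition flags, so pipeline estimates can be checked against
#' the generator.
#'
#' @param spec a [cohort_spec()].
#' @param condition protocol template name passed to
#'   [default_protocol()].
#' @param protocol optional explicit [protocol_spec()] overriding the
#'   template.
#' @param optics optional [optics_params()]; its `noise_cv` is taken from
#'   `spec` unless supplied explicitly.
#' @return A list with `traces` (named list of [fluorescence_trace()]s)
#'   and `truth` (data.frame: cell_id, genotype, jittered parameters,
#'   analytic baseline and plateau pH).
#' @export
#' @examples
#' co <- make_cohort(cohort_spec("vsmc", 2, 2, seed = 42))
#' co$truth[, c("cell_id", "genotype", "plateau_true")]
make_cohort <- function(spec, condition = "co2_dma", protocol = NULL,
                        optics = NULL) {
  stopifnot(inherits(spec, "phiflux_cohort_spec"))
  protocol <- protocol %||% default_protocol(condition)
  optics <- optics %||% optics_params(noise_cv = spec$noise_cv)
  seg <- protocol$segments
  base_flags <- seg[seg$name == "baseline", ][1, ]
  rec_flags <- seg[seg$name == "recovery", ][1, ]
  labels <- c(sprintf("risk_%02d", seq_len(spec$n_risk)),
              sprintf("protective_%02d", seq_len(spec$n_protective)))
  genotype <- rep(c("risk", "protective"),
                  c(spec$n_risk, spec$n_protective))
  traces <- vector("list", length(labels))
  names(traces) <- labels
  truth <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cell_seed <- derive_seed(spec$seed, labels[i])
    res <- with_seed(cell_seed, {
      jit <- rlnorm_cv(3, spec$jitter_cv)
      base <- scenario_params(spec$scenario, genotype[i])
      p <- cell_params(a_nbc = base$a_nbc * jit[1], g = base$g,
                       ph_set_nbc = base$ph_set_nbc,
                       a_nhe = base$a_nhe * jit[2],
                       ph_set_nhe = base$ph_set_nhe,
                       j_load = base$j_load * jit[3],
                       beta_i = base$beta_i,
                       hco3_coeff = base$hco3_coeff,
                       pk_co2 = base$pk_co2)
      phi <- simulate_phi_trace(p, protocol)
      fl <- render_fluorescence(phi, optics,
                                seed = derive_seed(cell_seed, "noise"))
      list(p = p, fl = fl)
    })
    p <- res$p
    traces[[i]] <- res$fl
    truth[[i]] <- data.frame(
      cell_id = labels[i], genotype = genotype[i],
      a_nbc = p$a_nbc, a_nhe = p$a_nhe, j_load = p$j_load, g = p$g,
      baseline_true = analytic_plateau(p, base_flags$co2_on,
                                       base_flags$dma_on,
                                       base_flags$na_on),
      plateau_true = analytic_plateau(p, rec_flags$co2_on,
                                      rec_flags$dma_on, rec_flags$na_on)
    )
  }
  list(traces = traces, truth = do.call(rbind, truth))
}
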