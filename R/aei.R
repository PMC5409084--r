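#' Normalized allele ratio from chromatogram peak heights
#'
#' The allele-A / allele-B peak-height ratio in the test material (cDNA
#' or FAIRE-enriched DNA) divided by the same ratio in the paired genomic
#' DNA. Genomic DNA of a heterozygote carries the two alleles 1:1, so the
#' normalization cancels allele-specific peak-height bias of the
#' sequencing chemistry; 1 means balanced representation, > 1 means
#' allele A over-represented in the test material.
#'
#' @param test_a,test_b peak heights of alleles A and B in the test
#'   material.
#' @param gdna_a,gdna_b peak heights of the same alleles in the paired
#'   genomic DNA. All heights must be positive; vectorized.
#' @return Normalized ratio(s), `(test_a/test_b) / (gdna_a/gdna_b)`.
#' @export
#' @examples
#' normalized_allele_ratio(120, 80, 100, 100) # 1.5
normalized_allele_ratio <- function(test_a, test_b, gdna_a, gdna_b) {
  h <- cbind(test_a, test_b, gdna_a, gdna_b)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("data error: all four peak heights must be positive",
         call. = FALSE)
  (test_a / test_b) / (gdna_a / gdna_b)
}

#' Cohort-level allelic imbalance
#'
#' Per-sample normalized ratios are combined on the log scale (ratios are
#' multiplicative): the geometric mean ratio is reported and departure
#' from balance is tested with a paired t-test of the log-ratios against
#' zero, equivalent to pairing each sample's test material with its own
#' genomic DNA.
#'
#' @param quartets data.frame with columns `sample_id`, `test_a`,
#'   `test_b`, `gdna_a`, `gdna_b` (>= 2 rows).
#' @return A list of class `phiflux_imbalance`: `ratios` (per sample),
#'   `geometric_mean`, `t`, `df`, `p`.
#' @export
cohort_imbalance <- function(quartets) {
  stopifnot(is.data.frame(quartets),
            all(c("test_a", "test_b", "gdna_a", "gdna_b") %in%
                  names(quartets)))
  if (nrow(quartets) < 2)
    stop("insufficient data: need >= 2 samples", call. = FALSE)
  ratios <- normalized_allele_ratio(quartets$test_a, quartets$test_b,
                                    quartets$gdna_a, quartets$gdna_b)
  lr <- log(ratios)
  if (stats::sd(lr) == 0)
    stop("degenerate: zero variance of log-ratios", call. = FALSE)
  ht <- stats::t.test(lr)
  structure(list(ratios = stats::setNames(ratios,
                                          quartets$sample_id %||% NULL),
                 geometric_mean = exp(mean(lr)),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "phiflux_imbalance")
}

#' Simulate chromatogram peak-height quartets
#'
#' Synthetic heterozygote samples with a true allelic expression fold
#' `fold` (allele A over B in the test material) and independent
#' unit-mean lognormal measurement noise on every peak height. The
#' genomic-DNA pair is balanced by construction.
#'
#' @param n number of samples.
#' @param fold true allelic fold change (> 0).
#' @param noise_cv peak-height noise CV.
#' @param base_height mean peak height, arbitrary units.
#' @param seed integer seed (NULL = current RNG state).
#' @return data.frame ready for [cohort_imbalance()].
#' @export
simulate_peak_quartets <- function(n, fold = 1.3, noise_cv = 0.1,
                                   base_height = 1000, seed = NULL) {
  stopifnot(n >= 1, fold > 0, noise_cv >= 0, base_height > 0)
  with_seed(seed, {
    eta <- matrix(rlnorm_cv(4 * n, noise_cv), ncol = 4)
    data.frame(sample_id = sprintf("s%02d", seq_len(n)),
               test_a = base_height * fold * eta[, 1],
               test_b = base_height * eta[, 2],
               gdna_a = base_height * eta[, 3],
               gdna_b = base_height * eta[, 4])
  })
}
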