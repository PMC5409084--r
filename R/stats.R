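#' Repeated-measures two-way ANOVA on a group x time series matrix
#'
#' Mixed-design ANOVA with genotype group as the between-subject factor
#' and time as the within-subject factor, computed from the standard
#' sums-of-squares decomposition: the group effect is tested against
#' subjects-within-group variation, the time and group-by-time effects
#' against the residual within-subject variation. No sphericity
#' correction is applied.
#'
#' @param m numeric matrix, one row per cell, one column per timepoint
#'   (no missing values; all cells share the common grid).
#' @param group factor or character of length `nrow(m)` with two or more
#'   levels, each with at least 2 cells.
#' @return data.frame with one row per effect (`group`, `time`,
#'   `group:time`): `df1`, `df2`, `F` and `p`.
#' @export
rm_two_way_anova <- function(m, group) {
  m <- as.matrix(m)
  group <- factor(group)
  stopifnot(nrow(m) == length(group), !anyNA(m))
  if (nlevels(group) < 2)
    stop("insufficient data: need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2))
    stop("insufficient data: every group needs >= 2 cells", call. = FALSE)
  n <- nrow(m); tt <- ncol(m); k <- nlevels(group)
  grand <- mean(m)
  subj_mean <- rowMeans(m)
  time_mean <- colMeans(m)
  grp_mean <- tapply(subj_mean, group, mean)
  # cell means per group x time
  gt_mean <- apply(m, 2, function(col) tapply(col, group, mean))
  n_g <- as.vector(table(group))
  ss_total <- sum((m - grand)^2)
  ss_between_subj <- tt * sum((subj_mean - grand)^2)
  ss_group <- tt * sum(n_g * (grp_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_time <- n * sum((time_mean - grand)^2)
  ss_int <- sum(n_g * (gt_mean - outer(grp_mean, time_mean, `+`) + grand)^2)
  ss_err <- ss_total - ss_group - ss_subj_within - ss_time - ss_int
  df_group <- k - 1
  df_subj <- n - k
  df_time <- tt - 1
  df_int <- (k - 1) * (tt - 1)
  df_err <- (n - k) * (tt - 1)
  f_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  f_time <- (ss_time / df_time) / (ss_err / df_err)
  f_int <- (ss_int / df_int) / (ss_err / df_err)
  out <- data.frame(
    effect = c("group", "time", "group:time"),
    df1 = c(df_group, df_time, df_int),
    df2 = c(df_subj, df_err, df_err),
    F = c(f_group, f_time, f_int)
  )
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  attr(out, "ss") <- c(group = ss_group, subj_within = ss_subj_within,
                       time = ss_time, interaction = ss_int,
                       error = ss_err, total = ss_total)
  out
}

#' Compare net-base-uptake-vs-pH slopes between two groups
#'
#' Fits uptake against pH by ordinary least squares in each group and
#' tests the slope difference through the interaction term of the pooled
#' model `uptake ~ ph + group + ph:group`.
#'
#' @param a,b per-window uptake estimates for each group: either
#'   [net_base_uptake()] results (their `estimates` tables are used) or
#'   data.frames with columns `mean_ph` (or `ph`) and `uptake`. Each
#'   needs >= 3 estimates spanning >= 2 distinct pH values.
#' @return A list of class `phiflux_slopes`: `groups` (per-group slope
#'   and intercept with standard errors) and `difference` (slope and
#'   intercept differences with SE, t, df and two-sided p). In the
#'   noiseless degenerate case (zero residual variance) p is reported as
#'   0 for a non-zero difference and 1 for a zero difference.
#' @export
compare_slopes <- function(a, b) {
  take <- function(x, lab) {
    if (inherits(x, "phiflux_uptake")) x <- x$estimates
    stopifnot(is.data.frame(x))
    ph <- x[["mean_ph"]] %||% x[["ph"]]
    if (is.null(ph) || is.null(x[["uptake"]]))
      stop("need columns mean_ph/ph and uptake", call. = FALSE)
    if (length(ph) < 3 || length(unique(ph)) < 2)
      stop("degenerate design: need >= 3 estimates over >= 2 distinct ",
           "pH values per group", call. = FALSE)
    data.frame(ph = ph, uptake = x[["uptake"]], group = lab)
  }
  d <- rbind(take(a, "a"), take(b, "b"))
  d$group <- factor(d$group, levels = c("a", "b"))
  pooled <- stats::lm(uptake ~ ph * group, data = d)
  if (any(is.na(stats::coef(pooled))))
    stop("degenerate design: pooled model is rank deficient",
         call. = FALSE)
  per_group <- do.call(rbind, lapply(split(d, d$group), function(g) {
    f <- stats::lm(uptake ~ ph, data = g)
    # zero-residual fits are legitimate here (noise-free oracles);
    # summary.lm warns about them
    cf <- suppressWarnings(summary(f)$coefficients)
    data.frame(group = g$group[1],
               intercept = cf[1, 1], intercept_se = cf[1, 2],
               slope = cf[2, 1], slope_se = cf[2, 2])
  }))
  rownames(per_group) <- NULL
  cf <- suppressWarnings(summary(pooled)$coefficients)
  df <- stats::df.residual(pooled)
  mk <- function(est, se) {
    if (!is.finite(se) || se == 0) {
      list(estimate = est, se = 0,
           t = if (est == 0) 0 else sign(est) * Inf,
           p = if (est == 0) 1 else 0)
    } else {
      tv <- est / se
      list(estimate = est, se = se, t = tv,
           p = 2 * stats::pt(-abs(tv), df))
    }
  }
  # coefficient rows: groupb = intercept difference, ph:groupb = slope diff
  structure(list(
    groups = per_group,
    difference = list(
      slope = mk(unname(cf["ph:groupb", 1]), unname(cf["ph:groupb", 2])),
      intercept = mk(unname(cf["groupb", 1]), unname(cf["groupb", 2])),
      df = df)
  ), class = "phiflux_slopes")
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided rank-sum test. With a combined sample size of at most 16
#' and no ties the null distribution of U is enumerated exhaustively
#' over all group assignments and the p-value is twice the smaller tail
#' (capped at 1). Larger or tied samples use the normal approximation
#' with tie and continuity corrections.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_max largest combined sample size for the enumeration
#'   branch.
#' @return A list with `U` (for sample `a`), `p` and `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney <- function(a, b, exact_max = 16) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (na + nb <= exact_max && !ties) {
    combos <- utils::combn(na + nb, na)
    us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    return(list(U = u, p = p, method = "exact enumeration"))
  }
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  nn <- na + nb
  sigma2 <- na * nb / 12 *
    ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
  if (sigma2 == 0) return(list(U = u, p = 1,
                               method = "normal approximation"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Paired t-test and Bonferroni adjustment
#'
#' `paired_t()` is the one-sample t-test on within-pair differences;
#' `bonferroni()` multiplies each p-value by the number of tests, capped
#' at 1.
#'
#' @param a,b paired numeric samples of equal length >= 2.
#' @return `paired_t()`: list with `t`, `df`, `p` and `mean_diff`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate: zero variance of paired differences", call. = FALSE)
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' @rdname paired_t
#' @param pvals p-values to adjust.
#' @param m number of tests (defaults to `length(pvals)`).
#' @return `bonferroni()`: adjusted p-values `pmin(1, m * pvals)`.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(m >= 1, all(pvals >= 0 & pvals <= 1))
  pmin(1, m * pvals)
}

#' Genotype contrast of cohort-level means
#'
#' Group means with SEM and the risk-minus-protective difference (with
#' the SEM of a difference of independent means) for plateau and
#' baseline pH, per condition.
#'
#' @param cells data.frame with columns `genotype` (values `risk` /
#'   `protective`), `plateau_ph`, `baseline_ph` and optionally
#'   `condition`.
#' @return data.frame with one row per condition and quantity: group
#'   means, SEMs, `delta` (risk - protective) and `delta_sem`.
#' @export
cohort_contrast <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("genotype", "plateau_ph", "baseline_ph") %in%
                  names(cells)))
  if (!"condition" %in% names(cells)) cells$condition <- "default"
  out <- list()
  for (cond in unique(cells$condition)) {
    d <- cells[cells$condition == cond, ]
    for (what in c("plateau_ph", "baseline_ph")) {
      xr <- d[[what]][d$genotype == "risk"]
      xp <- d[[what]][d$genotype == "protective"]
      if (length(xr) < 2 || length(xp) < 2)
        stop("insufficient data: need >= 2 cells per genotype in ",
             "condition '", cond, "'", call. = FALSE)
      sem <- function(x) stats::sd(x) / sqrt(length(x))
      out[[length(out) + 1]] <- data.frame(
        condition = cond, quantity = what,
        mean_risk = mean(xr), sem_risk = sem(xr), n_risk = length(xr),
        mean_protective = mean(xp), sem_protective = sem(xp),
        n_protective = length(xp),
        delta = mean(xr) - mean(xp),
        delta_sem = sqrt(sem(xr)^2 + sem(xp)^2)
      )
    }
  }
  do.call(rbind, out)
}
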