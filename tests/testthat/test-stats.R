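test_that("mixed ANOVA matches a brute-force SS decomposition", {
  # 2 cells per group x 3 timepoints, hand-checkable numbers
  m <- rbind(c(1, 2, 3), c(2, 3, 5), c(4, 6, 7), c(5, 6, 9))
  g <- c("a", "a", "b", "b")
  res <- rm_two_way_anova(m, g)

  grand <- mean(m)
  subj <- rowMeans(m); tim <- colMeans(m)
  grp <- tapply(subj, g, mean)
  ss_group <- 3 * sum(2 * (grp - grand)^2)
  ss_subj <- 3 * sum((subj - grand)^2) - ss_group
  ss_time <- 4 * sum((tim - grand)^2)
  gt <- rbind(colMeans(m[1:2, ]), colMeans(m[3:4, ]))
  ss_int <- 2 * sum((gt - outer(grp, tim, `+`) + grand)^2)
  ss_err <- sum((m - grand)^2) - ss_group - ss_subj - ss_time - ss_int
  expect_equal(res$F[res$effect == "group"],
               (ss_group / 1) / (ss_subj / 2))
  expect_equal(res$F[res$effect == "time"],
               (ss_time / 2) / (ss_err / 4))
  expect_equal(res$F[res$effect == "group:time"],
               (ss_int / 2) / (ss_err / 4))

  # independent oracle: base aov with an Error(subject) stratum
  d <- data.frame(y = as.vector(t(m)),
                  time = factor(rep(1:3, 4)),
                  subj = factor(rep(1:4, each = 3)),
                  grp = factor(rep(g, each = 3)))
  aov_fit <- summary(aov(y ~ grp * time + Error(subj), data = d))
  f_aov_grp <- aov_fit[["Error: subj"]][[1]]["grp", "F value"]
  f_aov_int <- aov_fit[["Error: Within"]][[1]]["grp:time", "F value"]
  expect_equal(res$F[res$effect == "group"], f_aov_grp,
               tolerance = 1e-9)
  expect_equal(res$F[res$effect == "group:time"], f_aov_int,
               tolerance = 1e-9)
})

test_that("ANOVA partition sums to the total and is location invariant", {
  set.seed(21)
  m <- matrix(rnorm(7 * 12), nrow = 7) +
    outer(rep(c(0, 0.5), c(3, 4)), seq(0, 1, length.out = 12))
  g <- rep(c("risk", "protective"), c(3, 4))
  res <- rm_two_way_anova(m, g)
  ss <- attr(res, "ss")
  expect_equal(ss[["total"]],
               sum(ss[c("group", "subj_within", "time", "interaction",
                        "error")]),
               tolerance = 1e-9)
  res2 <- rm_two_way_anova(m + 17.3, g)
  expect_equal(res$F, res2$F, tolerance = 1e-9)
  # identical groups: zero between-group SS
  m2 <- rbind(m[1:3, ], m[1:3, ])
  res3 <- rm_two_way_anova(m2, rep(c("a", "b"), each = 3))
  expect_equal(res3$F[res3$effect == "group"], 0)
  expect_error(rm_two_way_anova(m, rep("a", 7)), "insufficient")
  expect_error(rm_two_way_anova(m, rep(c("a", "b"), c(1, 6))),
               "insufficient")
})

test_that("slope comparison recovers known differences", {
  ph <- c(6.6, 6.8, 7.0, 7.2)
  a <- data.frame(ph = ph, uptake = 80 - 10 * ph)
  b <- data.frame(ph = ph, uptake = 108 - 14 * ph)
  res <- compare_slopes(a, b)
  expect_equal(res$groups$slope, c(-10, -14), tolerance = 1e-9)
  expect_equal(res$difference$slope$estimate, -4, tolerance = 1e-9)
  expect_equal(res$difference$slope$se, 0)
  expect_equal(res$difference$slope$p, 0)
  # identical groups: zero difference, p = 1
  set.seed(3)
  noisy <- data.frame(ph = rep(ph, 2),
                      uptake = 80 - 10 * rep(ph, 2) + rnorm(8, sd = 1))
  same <- compare_slopes(noisy, noisy)
  expect_equal(same$difference$slope$estimate, 0, tolerance = 1e-12)
  expect_equal(same$difference$slope$p, 1, tolerance = 1e-9)
})

test_that("slope-comparison t equals the textbook interaction formula", {
  set.seed(9)
  ph <- rep(seq(6.6, 7.2, by = 0.1), 2)
  ya <- 60 - 8 * ph[1:7] + rnorm(7, sd = 0.5)
  yb <- 70 - 9.5 * ph[1:7] + rnorm(7, sd = 0.5)
  res <- compare_slopes(data.frame(ph = ph[1:7], uptake = ya),
                        data.frame(ph = ph[1:7], uptake = yb))
  # hand oracle: separate OLS fits, pooled residual variance
  fa <- lm(ya ~ ph[1:7]); fb <- lm(yb ~ ph[1:7])
  sxx <- sum((ph[1:7] - mean(ph[1:7]))^2)
  s2 <- (sum(residuals(fa)^2) + sum(residuals(fb)^2)) / (14 - 4)
  se <- sqrt(s2 / sxx + s2 / sxx)
  t_hand <- (coef(fb)[2] - coef(fa)[2]) / se
  expect_equal(res$difference$slope$t, unname(t_hand),
               tolerance = 1e-9)
  expect_equal(res$difference$df, 10)
})

test_that("Mann-Whitney exact branch matches enumeration and examples", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / choose(6, 3))
  expect_match(res$method, "exact")
  # full-tie case falls back to the approximation with U = n1*n2/2
  tied <- mann_whitney(rep(1, 4), rep(1, 5))
  expect_equal(tied$U, 10)
  expect_equal(tied$p, 1)
})

test_that("exact p agrees with the distribution oracle for all small n", {
  set.seed(31)
  for (na in 1:5) for (nb in na:(10 - na)) {
    a <- rnorm(na); b <- rnorm(nb)
    got <- mann_whitney(a, b)
    ref <- suppressWarnings(
      wilcox.test(a, b, exact = TRUE, correct = FALSE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12,
                 label = sprintf("p at n=(%d,%d)", na, nb))
    expect_equal(got$U, unname(ref$statistic))
  }
})

test_that("approximate and exact p agree for moderate samples", {
  set.seed(17)
  reps <- replicate(20, {
    a <- rnorm(8); b <- rnorm(8, mean = 0.5)
    ex <- mann_whitney(a, b, exact_max = 16)$p
    ap <- mann_whitney(a, b, exact_max = 0)$p
    abs(ex - ap)
  })
  expect_lt(max(reps), 0.02)
})

test_that("paired t and Bonferroni follow their definitions", {
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, 2)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_equal(bonferroni(c(0.03, 0.6), 2), c(0.06, 1.0))
  expect_equal(bonferroni(0.2, 10), 1)
})

test_that("cohort contrast computes group means, deltas and SEMs", {
  cells <- data.frame(
    genotype = rep(c("risk", "protective"), each = 2),
    plateau_ph = c(7.187, 7.187, 7.10, 7.10),
    baseline_ph = c(7.187, 7.187, 7.10, 7.10))
  cc <- cohort_contrast(cells)
  plat <- cc[cc$quantity == "plateau_ph", ]
  expect_equal(plat$delta, 0.087, tolerance = 1e-12)
  expect_equal(plat$delta_sem, 0)
  # swapping labels negates the difference
  cells2 <- cells
  cells2$genotype <- rev(cells$genotype)
  cc2 <- cohort_contrast(cells2)
  expect_equal(cc2$delta[cc2$quantity == "plateau_ph"], -0.087,
               tolerance = 1e-12)
  expect_error(cohort_contrast(cells[c(1, 3, 4), ]), "insufficient")
})

test_that("plateau contrast test has calibrated type-I error under null", {
  # both genotype groups drawn from identical parameters; analytic
  # plateaus with per-cell jitter stand in for the measured plateaus
  n_rep <- 500
  rejections <- 0
  for (r in seq_len(n_rep)) {
    plat <- phiflux:::with_seed(80000 + r, {
      sapply(seq_len(12), function(i) {
        jit <- phiflux:::rlnorm_cv(3, 0.03)
        p <- cell_params(a_nbc = 6 * jit[1], g = 1,
                         a_nhe = 6 * jit[2], j_load = 2.1 * jit[3])
        analytic_plateau(p, dma_on = TRUE)
      })
    })
    pv <- mann_whitney(plat[1:5], plat[6:12])$p
    if (pv < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("the default VSMC genotype effect is usually detected at 5+7", {
  hits <- sapply(1:20, function(r) {
    plat <- phiflux:::with_seed(90000 + r, {
      sapply(seq_len(12), function(i) {
        jit <- phiflux:::rlnorm_cv(3, 0.03)
        g <- if (i <= 5) 1.33 else 1
        p <- cell_params(a_nbc = 6 * jit[1], g = g,
                         a_nhe = 6 * jit[2], j_load = 2.1 * jit[3])
        analytic_plateau(p, dma_on = TRUE)
      })
    })
    mann_whitney(plat[1:5], plat[6:12])$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
})
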