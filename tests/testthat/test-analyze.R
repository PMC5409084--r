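test_that("conversion inverts the optics exactly at zero noise", {
  phi <- vsmc_phi()
  fl <- vsmc_fluor_clean()
  fit <- fit_calibration(extract_calibration_points(fl))
  phi2 <- convert_trace(fl, fit)
  expect_lt(max(abs(phi2$ph_i - phi$ph_i)), 1e-9)
})

test_that("conversion reports bad F440 samples and commutes with slicing", {
  fl <- vsmc_fluor_clean()
  fit <- fit_calibration(extract_calibration_points(fl))
  bad <- fl
  bad$f440[17] <- 0
  expect_error(convert_trace(bad, fit), "index 17")
  sliced <- convert_trace(trace_window(fl, 100, 400), fit)
  full <- trace_window(convert_trace(fl, fit), 100, 400)
  expect_equal(sliced$ph_i, full$ph_i)
})

test_that("buffering capacity reproduces the defining formula", {
  # synthetic two-phase trace: plateau at 7.0 then washout to 6.6
  prot <- protocol_spec(data.frame(
    name = c("baseline", "nh4cl", "na_free", "recovery"),
    start_s = c(0, 60, 120, 180), end_s = c(60, 120, 180, 400),
    co2_on = TRUE, dma_on = FALSE,
    na_on = c(TRUE, TRUE, FALSE, TRUE),
    nh4cl_mM = c(0, 20, 0, 0), ph_o = 7.4))
  tt <- seq(0, 399, by = 3)
  ph <- ifelse(tt < 120, ifelse(tt < 60, 7.2, 7.0),
               ifelse(tt < 180, 6.6, 6.6 + (tt - 180) * 1e-4))
  phi <- phi_trace(tt, ph, prot)
  buf <- buffering_capacity(phi)
  expect_equal(buf$ph_pre, 7.0)
  expect_equal(buf$ph_post, 6.6)
  expect_equal(buf$beta, nh4_internal(7.0) / 0.4, tolerance = 1e-12)
  expect_equal(round(buf$beta, 1), 123.6)
  expect_equal(buf$ph_mid, 6.8)
  expect_lt(buf$dph, 0)

  flat <- phi_trace(tt, rep(7.0, length(tt)), prot)
  expect_error(buffering_capacity(flat), "undefined")
})

test_that("washout beta estimates the simulator buffering within 10%", {
  an <- vsmc_analysis_clean()
  p <- scenario_params("vsmc", "protective")
  truth <- beta_total(p, an$buffering$ph_mid, co2_on = TRUE)
  expect_lt(abs(an$buffering$beta - truth) / truth, 0.10)
})

test_that("beta in CO2/HCO3- exceeds beta without it on a matched cell", {
  # gentle acid load so the CO2-free prepulse stays in the dye range
  p <- cell_params(a_nbc = 6, a_nhe = 6, j_load = 1.0)
  bs <- sapply(c(TRUE, FALSE), function(co2) {
    prot <- default_protocol(if (co2) "co2" else "free")
    phi <- simulate_phi_trace(p, prot)
    buffering_capacity(phi)$beta
  })
  expect_gt(bs[1], bs[2])
})

test_that("net base uptake equals slope times buffering", {
  prot <- protocol_spec(data.frame(
    name = c("baseline", "nh4cl", "na_free", "recovery"),
    start_s = c(0, 60, 120, 180), end_s = c(60, 120, 180, 480),
    co2_on = TRUE, dma_on = FALSE, na_on = c(TRUE, TRUE, FALSE, TRUE),
    nh4cl_mM = c(0, 20, 0, 0), ph_o = 7.4))
  tt <- seq(0, 479, by = 3)
  # constant pH: zero uptake everywhere
  flat <- phi_trace(tt, rep(6.9, length(tt)), prot)
  up0 <- net_base_uptake(flat, beta_constant(50))
  expect_true(all(abs(up0$profile$uptake) < 1e-12))
  # linear ramp at 0.002 pH/s with beta 50: uptake 6 mmol/L/min
  ramp <- ifelse(tt < 180, 6.6, pmin(6.6 + 0.002 * (tt - 180), 8.2))
  phi <- phi_trace(tt, ramp, prot)
  up <- net_base_uptake(phi, beta_constant(50))
  expect_equal(unique(round(up$estimates$uptake, 9)), 6)
  expect_true(all(abs(up$profile$uptake - 6) < 1e-9))
  # window count: 300 s of recovery in 15-s blocks
  expect_equal(nrow(up$estimates), 20)
})

test_that("binned uptake matches the simulator flux on clean traces", {
  an <- vsmc_analysis_clean()
  p <- scenario_params("vsmc", "protective")
  up <- net_base_uptake(an$phi, function(ph) beta_total(p, ph))
  plat <- analytic_plateau(p, dma_on = TRUE)
  prof <- up$profile[up$profile$n >= 2 &
                       up$profile$bin_center < plat - 0.05, ]
  expect_gte(nrow(prof), 4)
  flux <- transporter_flux(p, prof$bin_center, co2_on = TRUE,
                           dma_on = TRUE, na_on = TRUE)
  expect_true(all(abs(prof$uptake - flux) / flux < 0.05))
})

test_that("uptake declines with pH on simulated recoveries", {
  an <- vsmc_analysis_clean()
  prof <- an$uptake$profile[an$uptake$profile$n >= 2, ]
  expect_true(all(diff(prof$uptake) < 0))
})

test_that("plateau and baseline are 1-min means with noise tolerance", {
  prot <- recovery_only_protocol(300)
  tt <- seq(0, 299, by = 3)
  const <- phi_trace(tt, rep(7.2, length(tt)),
                     protocol_spec(data.frame(
                       name = c("baseline", "recovery"),
                       start_s = c(0, 100), end_s = c(100, 300),
                       co2_on = TRUE, dma_on = FALSE, na_on = TRUE,
                       nh4cl_mM = 0, ph_o = 7.4)))
  res <- plateau_ph(const)
  expect_equal(res$plateau_ph, 7.2)
  expect_equal(res$baseline_ph, 7.2)

  # noise-free simulated DMA recovery lands on the analytic plateau
  an <- vsmc_analysis_clean()
  p <- scenario_params("vsmc", "protective")
  expect_equal(an$plateau$plateau_ph,
               analytic_plateau(p, dma_on = TRUE), tolerance = 1e-3)

  # read noise moves a 20+-sample plateau mean by well under 0.01
  phi <- vsmc_phi()
  opt <- optics_params()
  truth_fit <- fit_calibration(
    data.frame(buffer_ph = c(6.5, 7.5),
               ratio = opt$intercept + opt$slope * c(6.5, 7.5)))
  devs <- sapply(1:5, function(k) {
    noisy <- convert_trace(render_fluorescence(phi, opt, seed = 700 + k),
                           truth_fit)
    plateau_ph(noisy)$plateau_ph - plateau_ph(phi)$plateau_ph
  })
  expect_true(all(abs(devs) < 0.01))

  short <- protocol_spec(data.frame(
    name = c("baseline", "recovery"), start_s = c(0, 30),
    end_s = c(30, 90), co2_on = TRUE, dma_on = FALSE, na_on = TRUE,
    nh4cl_mM = 0, ph_o = 7.4))
  expect_error(plateau_ph(phi_trace(seq(0, 89, 3), rep(7, 30), short)),
               "insufficient")
})

test_that("recovery grid follows the half-open 280-point convention", {
  phi <- vsmc_phi()
  rw <- recovery_window(phi)
  expect_length(rw, 280)
  expect_equal(as.numeric(names(rw)[1]), 63)
  expect_equal(as.numeric(names(rw)[280]), 900)
  # a trace already sampled on the grid is returned unchanged
  rec_start <- 525
  on_grid <- phi$ph_i[match(rec_start + as.numeric(names(rw)),
                            phi$time_s)]
  expect_equal(unname(rw), on_grid)
  # small grids: (0, 30] by 3 gives 10 points
  expect_length(recovery_window(phi, 0, 30, 3), 10)
  expect_error(recovery_window(phi, 60, 5000, 3), "insufficient")
})

test_that("derived quantities are invariant to uniform time shifts", {
  phi <- vsmc_phi()
  prot <- trace_protocol(phi)
  seg <- prot$segments
  seg$start_s <- seg$start_s + 500
  seg$end_s <- seg$end_s + 500
  shifted <- phi_trace(phi$time_s + 500, phi$ph_i,
                       protocol_spec(seg, prot$sampling))
  expect_equal(buffering_capacity(shifted)$beta,
               buffering_capacity(phi)$beta)
  expect_equal(plateau_ph(shifted)$plateau_ph,
               plateau_ph(phi)$plateau_ph)
  expect_equal(unname(recovery_window(shifted)),
               unname(recovery_window(phi)))
  b <- beta_constant(40)
  expect_equal(net_base_uptake(shifted, b)$profile,
               net_base_uptake(phi, b)$profile)
})
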