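test_that("active abundance scales counts by the active fraction into cells per litre", {
  ab <- active_abundance(16.2e3, 1.2e3, 0.90)
  expect_equal(ab$mean, 1.458e7)
  expect_equal(ab$sd, 1.08e6)
  expect_equal(active_abundance(16.2e3, active_fraction = 0)$mean, 0)
  # SD scales linearly with the count SD
  expect_equal(active_abundance(16.2e3, 2.4e3)$sd,
               2 * active_abundance(16.2e3, 1.2e3)$sd)
})

test_that("contribution reconciles cell, abundance and bulk units", {
  pct <- contribution(4.6, 1.458e7, 448)
  expect_equal(pct, 14.97, tolerance = 1e-2)
  expect_equal(contribution(0, 1.458e7, 448), 0)
  expect_error(contribution(4.6, 1.458e7, 0), "positive")
  # scale invariance under pmol <-> fmol with matching conversion
  expect_equal(contribution(4.6, 1.458e7, 448, "pmol"),
               contribution(4600, 1.458e7, 448, "fmol"))
})

test_that("a synthetic community where cells are the whole bulk contributes 100%", {
  # homogeneous population, no background, no depletion, no inactive cells
  cfg <- sim_config(seed = 5, n_cells = 30, noise = FALSE,
                    inactive_fraction = 0, non_algal_poc_umol_l = 0,
                    growth_gsd = 1, length_gsd = 1, width_ratio_gsd = 1,
                    dic_excess_t2 = 4.4,
                    nh4_excess_halflife_h = Inf, no3_excess_halflife_h = Inf,
                    treatments = "control")
  sim <- simulate_experiment(cfg)
  cr <- cell_rate_table(sim$cells, sim$pools)
  ps <- population_summary(cr)
  br <- bulk_rate_table(sim$bulk[sim$bulk$timepoint != "T0", ], sim$pools)
  for (tp in c("T1", "T2")) {
    cell_rate <- ps$active$fix_c_pmol_d[ps$active$timepoint == tp]
    bulk_rate <- br$assim_umol_l_d[br$timepoint == tp]
    pct <- contribution(cell_rate, sim$truth$abundance_per_l, bulk_rate)
    expect_equal(pct, 100, tolerance = 1e-9)
  }
})

test_that("contribution under Poisson image noise is unbiased", {
  set.seed(404)
  # known fraction q of bulk uptake; ratio estimated from Poisson count pairs
  q <- 0.3
  n_rep <- 1000
  counts <- 5e3
  cell_excess <- 1.2
  pool <- 4.0
  est <- replicate(n_rep, {
    f_meas <- rpois(1, counts * cell_excess / 100) / counts
    cell_rate <- (100 * f_meas / pool) * 27.5 / 1.25
    true_cell_rate <- (cell_excess / pool) * 27.5 / 1.25
    bulk <- true_cell_rate * 1e-6 * 1.458e7 / q
    contribution(cell_rate, 1.458e7, bulk)
  })
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 100 * q), 3 * mc_se)
})

test_that("quadrature propagation reproduces the delta-method limits", {
  pct <- contribution(4.6, active_abundance(16.2e3, 1.2e3)$mean, 448)
  sd_pct <- propagate_contribution_uncertainty(
    pct, c(4.6, 16.2e3, 448), c(3.46, 1.2e3, 101))
  expect_equal(sd_pct, 11.8, tolerance = 0.05)
  # all SDs zero -> zero
  expect_equal(propagate_contribution_uncertainty(15, c(1, 2, 3), c(0, 0, 0)), 0)
  # single dominant term -> percent * relative SD of that term
  expect_equal(propagate_contribution_uncertainty(15, c(4.6, 1, 1), c(3.46, 0, 0)),
               15 * 3.46 / 4.6)
  # symmetric in its arguments
  expect_equal(
    propagate_contribution_uncertainty(10, c(2, 5), c(0.2, 0.4)),
    propagate_contribution_uncertainty(10, c(5, 2), c(0.4, 0.2)))
  expect_error(propagate_contribution_uncertainty(10, c(-1, 2), c(0, 0)),
               "positive")
})

test_that("POC-corrected abundance rescales by the standing-stock change", {
  expect_equal(poc_corrected_abundance(1.458e7, 2849, 2849), 1.458e7)
  expect_equal(poc_corrected_abundance(1.458e7, 2849, 2849 / 2), 1.458e7 / 2)
  expect_error(poc_corrected_abundance(1, 0, 1), "positive")
  # sweep: POC ratio in [0.47, 0.8] keeps the C contribution within 7-12%
  for (r in seq(0.47, 0.8, by = 0.03)) {
    ab <- poc_corrected_abundance(active_abundance(16.2e3)$mean, 1, r)
    pct <- contribution(4.6, ab, 448)
    expect_gte(pct, 7)
    expect_lte(pct, 12)
  }
})

test_that("contribution table combines summaries, bulk rates and abundance", {
  cell_summary <- data.frame(treatment = "control", timepoint = "T2", n = 44,
                             fix_c_pmol_d = 4.6, fix_c_pmol_d_sd = 3.46)
  bulk <- data.frame(treatment = "control", timepoint = "T2", substrate = "DIC",
                     assim_umol_l_d = 448, assim_umol_l_d_sd = 101)
  ct <- contribution_table(cell_summary, bulk)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$percent, 14.97, tolerance = 0.01)
  expect_equal(ct$sd_percent, 11.8, tolerance = 0.05)
  # with POC series, the corrected-abundance variant is added
  ct2 <- contribution_table(cell_summary, bulk,
                            poc_by_timepoint = c(T0 = 2849, T2 = 1900))
  expect_equal(ct2$abundance_source, c("counts", "poc_corrected"))
  expect_equal(ct2$percent[2], ct2$percent[1] * 1900 / 2849)
})
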