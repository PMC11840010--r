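test_that("closed-form cell excess matches a numerical time integral of uptake", {
  # independent oracle: integrate the instantaneous incorporation flux
  oracle <- function(excess0, k, mu, t) {
    r <- mu * log(2)
    stats::integrate(function(s) excess0 * exp(-k * s) * r * exp(r * s),
                     0, t, rel.tol = 1e-12)$value / exp(r * t)
  }
  for (k in c(0, 0.2, 1.386)) {
    for (mu in c(0.05, 0.47, 1.386 / log(2), 3)) {
      got <- tracer_cell_excess(4.4, k, mu, 1.25)
      want <- oracle(4.4, k, mu, 1.25)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  # k = 0 reduces to the textbook inversion
  expect_equal(tracer_cell_excess(4.4, 0, 0.47, 1.25),
               4.4 * (1 - 2^(-0.47 * 1.25)), tolerance = 1e-12)
  expect_equal(tracer_cell_excess(4.4, 0.3, 0, 1.25), 0)
})

test_that("a fixed seed fixes every simulator output byte", {
  cfg <- sim_config(seed = 99, n_cells = 60)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  cells <- data.frame(cell_id = 1:5, frac13c = runif(5, 0.01, 0.05),
                      frac15n = runif(5, 0.004, 0.02),
                      length_um = rep(14, 5), width_um = rep(9, 5))
  f1 <- render_sims_images(cells, cfg)
  f2 <- render_sims_images(cells, cfg)
  expect_identical(f1, f2)
  # different seed changes the draw
  expect_false(identical(s1$cells$frac13c,
                         simulate_experiment(sim_config(seed = 100, n_cells = 60))$cells$frac13c))
})

test_that("all-inactive population leaves only background labelling", {
  cfg <- sim_config(seed = 3, n_cells = 40, inactive_fraction = 1,
                    noise = FALSE, treatments = "control")
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$cells$mu_true == 0))
  expect_equal(sim$cells$frac13c, rep(0.0111, 40))
  expect_equal(sim$truth$bulk$true_algal_c_umol_l_d, c(0, 0))
  expect_true(all(sim$truth$bulk$true_bulk_c_umol_l_d > 0))  # background only
  expect_equal(sim$truth$bulk$true_contribution_pct, c(0, 0))
})

test_that("noise-free single cell: the pipeline recovers the planted growth rate exactly", {
  cfg <- sim_config(seed = 8, n_cells = 1, inactive_fraction = 0,
                    noise = FALSE, treatments = "control",
                    dic_excess_t2 = 4.4)  # non-depleting pool
  sim <- simulate_experiment(cfg)
  cr <- cell_rate_table(sim$cells, sim$pools)
  expect_equal(cr$mu_c, sim$truth$cells$mu_true, tolerance = 1e-12)
})

test_that("default configuration reproduces the study conditions", {
  cfg <- sim_config()
  expect_equal(cfg$n_cells, 244L)
  expect_equal(cfg$inactive_fraction, 0.10)
  expect_equal(cfg$t1_h, 6)
  expect_equal(cfg$t2_h, 30)
  # lognormal growth parameters target mean 0.47, SD 0.24 day-1
  sdlog <- log(cfg$growth_gsd)
  mean_mu <- cfg$growth_median * exp(sdlog^2 / 2)
  sd_mu <- mean_mu * sqrt(exp(sdlog^2) - 1)
  expect_equal(mean_mu, 0.47, tolerance = 0.01)
  expect_equal(sd_mu, 0.24, tolerance = 0.01)
  # N pools start from the tracer-mixing arithmetic
  sim <- simulate_experiment(sim_config(seed = 1, n_cells = 20))
  expect_equal(sim$truth$pools$NO3$excess0,
               tracer_pool_mixing(0.05, 0.36, 10, 98)$excess)
  expect_error(sim_config(inactive_fraction = 2))
})

test_that("classification on the default simulation recovers the inactive fraction", {
  sim <- simulate_experiment(sim_config(seed = 21))
  cr <- cell_rate_table(sim$cells, sim$pools)
  n <- nrow(cr)
  n_inactive <- sum(!cr$active)
  # binomial 95% CI around 10% at n = 244
  ci <- qbinom(c(0.025, 0.975), n, 0.10)
  expect_gte(n_inactive, ci[1])
  expect_lte(n_inactive, ci[2])
  # and classification agrees with the ground truth almost everywhere
  expect_gt(mean(cr$active == sim$truth$cells$active_true), 0.97)
})

test_that("rendered rasters have Poisson-consistent totals and clean backgrounds", {
  cfg <- sim_config(seed = 17, counts_per_cell = 5000, background_per_pixel = 0)
  cells <- data.frame(cell_id = 1:12, frac13c = 0.02, frac15n = 0.01,
                      length_um = 16, width_um = 10)
  fields <- render_sims_images(cells, cfg)
  total12 <- sum(vapply(fields, function(f) sum(f$images$c12n14), numeric(1)))
  expected <- nrow(cells) * cfg$counts_per_cell
  expect_lt(abs(total12 - expected), 3 * sqrt(expected))
  # zero-background mode: mask-complement pixels are all zero
  for (f in fields) {
    bg <- f$labels == 0
    expect_true(all(f$images$c12n14[bg] == 0))
    expect_true(all(f$images$c13n14[bg] == 0))
  }
  # label mask covers each cell once
  ids <- sort(as.integer(unlist(lapply(
    fields, function(f) setdiff(unique(as.vector(f$labels)), 0)))))
  expect_equal(ids, 1:12)
})

test_that("high-count limit: empirical ROI fraction converges to the true fraction", {
  cfg <- sim_config(seed = 23, counts_per_cell = 1e6)
  cells <- data.frame(cell_id = 1L, frac13c = 0.03, frac15n = 0.008,
                      length_um = 20, width_um = 12)
  f <- render_sims_images(cells, cfg)[[1]]
  out <- roi_quantify(f$images, f$labels)
  expect_lt(abs(out$frac13c - 0.03), 0.001)   # within 0.1 percentage points
  expect_lt(abs(out$frac15n - 0.008), 0.001)
})

test_that("overcrowded rasters fail loudly", {
  cfg <- sim_config(seed = 2, raster_size = 32L)
  cells <- data.frame(cell_id = 1:2, frac13c = 0.02, frac15n = NA,
                      length_um = 30, width_um = 30)
  expect_error(render_sims_images(cells, cfg), "raster|placed|overcrowded")
})

test_that("end-to-end over replicate seeds: contribution estimate tracks the truth", {
  # small bottle noise isolates the estimator itself (bottle-level biomass
  # noise adds a known ratio bias tested separately)
  errs <- vapply(1:12, function(s) {
    sim <- simulate_experiment(sim_config(seed = 1000 + s, n_cells = 80,
                                          bottle_cv = 0.05,
                                          treatments = "control"))
    cr <- cell_rate_table(sim$cells, sim$pools)
    ps <- population_summary(cr)
    br <- bulk_rate_table(sim$bulk[sim$bulk$timepoint != "T0", ], sim$pools)
    i <- ps$active$timepoint == "T2"
    j <- br$timepoint == "T2"
    pct <- contribution(ps$active$fix_c_pmol_d[i],
                        sim$truth$abundance_per_l * 0.9,
                        br$assim_umol_l_d[j])
    truth <- sim$truth$bulk$true_contribution_pct[
      sim$truth$bulk$treatment == "control" & sim$truth$bulk$timepoint == "T2"]
    pct - truth
  }, numeric(1))
  # unbiased within MC error plus the small documented pool-averaging bias
  mc_se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * mc_se + 0.5)
})
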