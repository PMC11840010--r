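test_that("ROI quantification recovers exact fractions from uniform images", {
  fx <- uniform_roi_images(c12 = 99, c13 = 1, c15 = 0)
  out <- roi_quantify(fx$images, fx$labels)
  expect_equal(nrow(out), 1)
  expect_equal(out$frac13c, 0.01)
  expect_equal(out$frac15n, 0)
  expect_equal(out$roi_pixels, 64)
  # count-sum estimator agrees on uniform images
  expect_equal(roi_quantify(fx$images, fx$labels, method = "count_sum")$frac13c,
               0.01)
})

test_that("ROI quantification handles empty masks, zero ROIs and shape mismatch", {
  fx <- uniform_roi_images()
  empty <- matrix(0L, 16, 16)
  expect_equal(nrow(roi_quantify(fx$images, empty)), 0)
  # an ROI whose denominators are all zero is skipped with a warning
  labels2 <- fx$labels
  labels2[14:15, 14:15] <- 2L   # outside the non-zero region
  expect_warning(out <- roi_quantify(fx$images, labels2), "all-zero")
  expect_equal(out$cell_id, 1)
  expect_error(roi_quantify(fx$images, matrix(0L, 8, 8)), "shape")
})

test_that("ROI mean of Poisson images is within binomial error of the true fraction", {
  set.seed(303)
  size <- 32
  labels <- matrix(0L, size, size)
  labels[5:28, 5:28] <- 1L
  npix <- sum(labels == 1)
  f <- 0.05
  total_per_pixel <- 2e4 / npix  # >= 1e4 total counts in the ROI
  imgs <- list(
    c12n14 = matrix(rpois(size^2, total_per_pixel * (1 - f)), size),
    c13n14 = matrix(rpois(size^2, total_per_pixel * f), size),
    c12n15 = matrix(0, size, size))
  out <- roi_quantify(imgs, labels)
  se <- sqrt(f * (1 - f) / 2e4)
  expect_lt(abs(out$frac13c - f), 3 * se * sqrt(npix / (npix - 1)) * 2)
})

test_that("cylindrical biovolume and its scaling law", {
  expect_equal(biovolume_cylinder(1, 2), pi)
  expect_equal(biovolume_cylinder(16.0, 10.6), 1411.95, tolerance = 1e-2)
  expect_equal(biovolume_cylinder(10, 4), 4 * biovolume_cylinder(10, 2))
  expect_error(biovolume_cylinder(0, 1), "positive")
})

test_that("dry weight and elemental content chain", {
  expect_equal(cell_dry_weight(1414), 459.27, tolerance = 1e-2)
  expect_equal(cell_dry_weight(0), 0)
  # unit identity: density 1000 kg m-3 and dry fraction 1 give pg == um^3
  expect_equal(cell_dry_weight(123.4, 1000, 1), 123.4)

  comp <- cell_elemental_content(459.3)
  expect_equal(comp$content_C, 27.53, tolerance = 1e-2)
  expect_equal(comp$content_N, 1.312, tolerance = 1e-3)
  expect_equal(comp$content_P, 0.5932, tolerance = 1e-3)
  expect_equal(unlist(cell_elemental_content(0)[c("content_C", "content_N", "content_P")]),
               c(content_C = 0, content_N = 0, content_P = 0))
  # linearity: doubling biovolume doubles every content
  c1 <- cell_elemental_content(cell_dry_weight(700))
  c2 <- cell_elemental_content(cell_dry_weight(1400))
  expect_equal(c2$content_C, 2 * c1$content_C)
  expect_equal(c2$content_P, 2 * c1$content_P)
})

test_that("cell fixation rate and its saturation case", {
  expect_equal(cell_fixation_rate(0, 3.9, 27.5, 1.25), 0)
  # fully labelled cell turns over its whole content in dt
  expect_equal(cell_fixation_rate(3.9, 3.9, 27.5, 1.25), 22.0)
  # inversion oracle targeting the observed ~4.6 pmol C cell-1 d-1 magnitude
  f <- 1 - 2^(-0.27 * 1.25)
  expect_equal(cell_fixation_rate(f * 3.9, 3.9, 27.5, 1.25), 27.5 * f / 1.25)
  expect_equal(cell_fixation_rate(f * 3.9, 3.9, 27.5, 1.25), 4.60, tolerance = 0.01)
  expect_error(cell_fixation_rate(1, -1, 27.5, 1.25), "positive")
})

test_that("fixation and growth equations are mutually consistent on noise-free cells", {
  # fixation * dt / content == 1 - 2^(-growth * dt), exactly
  pool <- 4.4
  content <- 27.5
  for (mu in c(0.05, 0.27, 0.47, 1.3)) {
    for (dt in c(0.25, 1.25)) {
      excess <- pool * (1 - 2^(-mu * dt))
      fix <- cell_fixation_rate(excess, pool, content, dt)
      g <- cell_growth_rate(pool, excess, dt)
      expect_equal(fix * dt / content, 1 - 2^(-g * dt), tolerance = 1e-12)
      expect_equal(g, mu, tolerance = 1e-12)
    }
  }
})

test_that("C:N assimilation ratio averages per cell, excluding zero N rates", {
  expect_equal(suppressWarnings(assimilation_cn_ratio(5, 5)), 1)
  expect_equal(assimilation_cn_ratio(9.7, 0.183), 53.0, tolerance = 0.01)
  expect_equal(assimilation_cn_ratio(c(2, 4), c(0.1, 0.2)),
               c(20, 20))  # scale-free
  expect_warning(r <- assimilation_cn_ratio(c(1, 2), c(0.5, 0)), "excluded")
  expect_equal(r, c(2, NA))
})

test_that("EDS stoichiometry: per-cell ratios, Redfield reference, edge cases", {
  rec <- data.frame(atom_pct_c = 66, atom_pct_n = 10, atom_pct_p = 0.5)
  st <- stoichiometry_from_eds(rec)
  expect_equal(st$per_cell$cn, 6.6)
  expect_equal(st$per_cell$np, 20)
  expect_true(is.na(st$summary$sd[1]))  # single cell: SD undefined
  expect_equal(st$summary$redfield, c(6.6, 116, 16))

  # mass fractions 0.72 / 0.04 / 0.04 imply atomic C:N ~21.0, C:P ~46.4
  mol <- c(C = 0.72 / 12.011, N = 0.04 / 14.007, P = 0.04 / 30.974)
  rec2 <- data.frame(atom_pct_c = 100 * mol["C"] / sum(mol),
                     atom_pct_n = 100 * mol["N"] / sum(mol),
                     atom_pct_p = 100 * mol["P"] / sum(mol))
  st2 <- stoichiometry_from_eds(rec2)
  expect_equal(st2$per_cell$cn, 20.99, tolerance = 0.01)
  expect_equal(st2$per_cell$cp, 46.42, tolerance = 0.01)

  expect_warning(st3 <- stoichiometry_from_eds(
    data.frame(atom_pct_c = c(66, 50), atom_pct_n = c(10, 0),
               atom_pct_p = c(0.5, 1))), "excluded")
  expect_equal(nrow(st3$per_cell), 1)
})

test_that("stoichiometry of cells generated at exact Redfield atom% returns Redfield", {
  # C:N:P = 106:16:1 scaled to atom% with an arbitrary O complement
  base <- c(C = 6.6, N = 1, P = 1 / 16)
  rec <- data.frame(atom_pct_c = rep(base["C"], 5) * 10,
                    atom_pct_n = rep(base["N"], 5) * 10,
                    atom_pct_p = rep(base["P"], 5) * 10)
  st <- stoichiometry_from_eds(rec)
  expect_equal(st$summary$mean, c(6.6, 105.6, 16), tolerance = 1e-12)
  expect_equal(st$summary$sd, c(0, 0, 0))
})

test_that("population summary reports active and full populations", {
  cells <- data.frame(
    treatment = "control", timepoint = "T2",
    active = rep(c(TRUE, FALSE), c(220, 24)),
    mu_c = c(rnorm(220, 0.47, 0.1), rep(0, 24)))
  ps <- population_summary(cells)
  expect_equal(ps$active$n, 220)
  expect_equal(ps$all$n, 244)
  # all active -> summaries identical
  cells2 <- cells[cells$active, ]
  ps2 <- population_summary(cells2)
  expect_equal(ps2$active, ps2$all)
  # empty active set -> empty summary with warning
  cells$active <- FALSE
  expect_warning(ps3 <- population_summary(cells), "empty")
  expect_equal(nrow(ps3$active), 0)
})

test_that("cell rate table wires pools, activity and composition together", {
  pool <- 4.0
  mu <- c(0.3, 0.6)
  excess <- pool * (1 - 2^(-mu * 1.25))
  cells <- data.frame(cell_id = 1:3, treatment = "control", timepoint = "T2",
                      frac13c = c(0.0111 + excess / 100, 0.0111),
                      frac15n = NA_real_,
                      length_um = c(16, 16, NA), width_um = c(10.6, 8, NA))
  pools <- data.frame(treatment = "control", substrate = "DIC",
                      timepoint = c("T1", "T2"), excess = c(4.4, 3.6))
  tab <- cell_rate_table(cells, pools)
  expect_equal(tab$active, c(TRUE, TRUE, FALSE))
  expect_equal(tab$mu_c[1:2], mu, tolerance = 1e-9)
  expect_true(tab$geometry_imputed[3])
  expect_equal(tab$biovolume_um3[3],
               mean(biovolume_cylinder(c(16, 16), c(10.6, 8))))
  # population-mean content applied to every cell
  expect_equal(length(unique(tab$content_c_pmol)), 1)
  # per-cell option uses own geometry
  tab2 <- cell_rate_table(cells, pools, content = "per_cell")
  expect_gt(tab2$content_c_pmol[1], tab2$content_c_pmol[2])
  # atom% supplied as fraction column is rejected
  cells$frac13c[1] <- 1.11
  expect_error(cell_rate_table(cells, pools), "fraction")
})
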