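test_that("ddPCR Poisson inversion matches closed form and guards saturation", {
  expect_equal(ddpcr_lambda(droplet_counts(10000, 0))$lambda, 0)
  expect_equal(round(ddpcr_lambda(droplet_counts(10000, 3935))$lambda, 3),
               0.500)
  expect_error(ddpcr_lambda(droplet_counts(10000, 10000)), "saturated")
  ci <- ddpcr_lambda(droplet_counts(10000, 3935))
  expect_true(ci$ci_lower < ci$lambda && ci$lambda < ci$ci_upper)
})

test_that("ddPCR inversion is unbiased against the droplet simulator", {
  for (lam in c(0.1, 0.5, 1.0)) {
    est <- vapply(1:60, function(i) {
      d <- simulate_droplet_assay(round(lam * 1e4), 1e4,
                                  seed = round(lam * 1000) + i)
      ddpcr_lambda(d)$lambda
    }, numeric(1))
    q <- 1 - exp(-lam)
    se_one <- sqrt(q * (1 - q) / 1e4) / (1 - q)
    expect_lt(abs(mean(est) - lam), 3 * se_one / sqrt(60))
  }
})

test_that("duplex referencing converts lambda ratios to copies per cell", {
  target <- droplet_counts(1e6, round(1e6 * (1 - exp(-0.5))))
  reference <- droplet_counts(1e6, round(1e6 * (1 - exp(-0.00303))))
  expect_equal(round(ddpcr_copies_per_cell(target, reference, 2)), 330)
  same <- droplet_counts(10000, 3000)
  expect_equal(ddpcr_copies_per_cell(same, same, 2), 2)
  expect_error(ddpcr_copies_per_cell(same, droplet_counts(10000, 0)),
               "reference")
})

test_that("standard curve fitting recovers slope and efficiency", {
  pts <- data.frame(copies = c(100, 1000, 10000),
                    cq = c(30.00, 26.68, 23.36))
  sc <- suppressWarnings(fit_standard_curve(pts))
  expect_equal(round(sc$slope, 3), -3.320)
  expect_equal(round(sc$efficiency, 2), 2.00)
  expect_equal(sc$r_squared, 1)
  expect_error(fit_standard_curve(pts[1:2, ]), ">= 3")
  expect_error(
    fit_standard_curve(data.frame(copies = c(100, 100, 100),
                                  cq = c(30, 30.1, 29.9))),
    "log10")
})

test_that("single-cell inversion is the exact inverse of simulation", {
  curve <- standard_curve(slope = -3.4, intercept = 37.5)
  for (copies in c(10, 330, 471, 1025, 5000)) {
    cq <- simulate_qpcr_cq(copies, curve, noise_sd = 0)
    est <- qpcr_copies_single_cell(cq, curve)
    expect_lt(abs(est$copies - copies) / copies, 1e-9)
  }
  # one cycle lower at E = 2 doubles the estimate
  curve2 <- standard_curve(slope = -1 / log10(2), intercept = 38)
  cq330 <- simulate_qpcr_cq(330, curve2, 0)
  expect_equal(round(qpcr_copies_single_cell(cq330 - 1, curve2)$copies), 660)
  # pooled 1, 2, 4 cells keep their ratios (linearity)
  cqs <- simulate_qpcr_cq(c(330, 660, 1320), curve2, 0)
  est <- qpcr_copies_single_cell(cqs, curve2)$copies
  expect_equal(est / est[1], c(1, 2, 4))
  # no-amplification sentinel reports 0 with a flag
  na_est <- qpcr_copies_single_cell(NA_real_, curve2)
  expect_equal(na_est$copies, 0)
  expect_true(na_est$no_amplification)
})

test_that("cohort statistics use sample SD and handle singletons", {
  co <- data.frame(mouse_id = "m1", age_group = "young",
                   copy_number = c(400, 500, 600))
  st <- cohort_stats(co)
  expect_equal(st$mean_copies, 500)
  expect_equal(st$sd_copies, 100)
  expect_equal(st$cv, 0.2)
  same <- data.frame(mouse_id = "m1", age_group = "young",
                     copy_number = rep(700, 5))
  expect_equal(cohort_stats(same)$cv, 0)
  single <- data.frame(mouse_id = "m1", age_group = "young",
                       copy_number = 500)
  st1 <- cohort_stats(single)
  expect_true(is.na(st1$sd_copies) && is.na(st1$cv))
})

test_that("CV is scale invariant", {
  co <- generate_cohort(cohort_config(n_mice = 2, cells_per_mouse = 30))
  st <- cohort_stats(co)
  co2 <- co
  co2$copy_number <- co2$copy_number * 7
  st2 <- cohort_stats(co2)
  expect_equal(st2$cv, st$cv)
})

test_that("WGS copy number inverts the generative read fraction", {
  expect_equal(wgs_copy_number(0, 1e6), 0)
  expect_equal(round(wgs_copy_number(10000, 1e6, unit_length = 43000,
                                     non_rdna_genome_length = 5.3e9)),
               1245)
  # algebraic identity: self-consistent mode inverts p = C*u/(G + C*u)
  for (copies in seq(0, 2000, length.out = 20)) {
    p <- copies * 43000 / (5.3e9 + copies * 43000)
    est <- wgs_copy_number(p * 1e8, 1e8)
    expect_equal(est, copies, tolerance = 1e-8)
  }
  # stochastic round trip at the BALB/cA-like copy number
  sim <- simulate_wgs_readcounts(642, 43000, 5.3e9, 1e6, seed = 7)
  est <- wgs_copy_number(sim$rdna_reads, sim$total_mapped_reads)
  p <- 642 * 43000 / (5.3e9 + 642 * 43000)
  se_copies <- sqrt(p * (1 - p) / 1e6) * 5.3e9 / 43000 / (1 - p)^2
  expect_lt(abs(est - 642), 3 * se_copies)
  expect_error(wgs_copy_number(1e6, 1e6), "fraction")
})
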