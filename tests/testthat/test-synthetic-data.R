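test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- cohort_config(n_mice = 2, cells_per_mouse = 20)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  u <- default_unit_model()
  expect_identical(
    simulate_amplicon_pileup(u, "28S", "old", depth = 500, seed = 11),
    simulate_amplicon_pileup(u, "28S", "old", depth = 500, seed = 11))
  expect_identical(
    simulate_droplet_assay(5000, 10000, seed = 3),
    simulate_droplet_assay(5000, 10000, seed = 3))
  curve <- standard_curve(slope = -1 / log10(2), intercept = 38)
  expect_identical(simulate_qpcr_cq(330, curve, noise_sd = 0.2, seed = 5),
                   simulate_qpcr_cq(330, curve, noise_sd = 0.2, seed = 5))
})

test_that("cohort copy numbers recover the configured mean and CV", {
  cfg <- cohort_config(mean_copies_young = 471, cv_young = 0.3,
                       n_mice = 1, cells_per_mouse = 1000)
  co <- generate_cohort(cfg)
  young <- co$copy_number[co$age_group == "young"]
  # CLT tolerance: SE of the mean is mean*cv/sqrt(n); 5% is ~7 SEs
  expect_lt(abs(mean(young) - 471) / 471, 0.05)
  se_mean <- 471 * 0.3 / sqrt(1000)
  expect_lt(abs(mean(young) - 471), 3 * se_mean)
  expect_lt(abs(sd(young) / mean(young) - 0.3), 0.05)
})

test_that("configured CV ordering carries through to sampled cohorts", {
  cfg <- cohort_config(cv_young = 0.35, cv_old = 0.20,
                       n_mice = 1, cells_per_mouse = 1000)
  co <- generate_cohort(cfg)
  cv <- tapply(co$copy_number, co$age_group,
               function(x) sd(x) / mean(x))
  expect_lt(cv[["old"]], cv[["young"]])
})

test_that("droplet occupancy follows the Poisson limit", {
  # empty reaction and saturation limits
  expect_equal(simulate_droplet_assay(0, 10000, seed = 1)$n_positive, 0L)
  expect_equal(simulate_droplet_assay(10000 * 50, 100, seed = 1)$n_positive,
               100L)
  # positive fraction ~ 1 - exp(-lambda) at lambda = 0.5
  q_true <- 1 - exp(-0.5)
  fracs <- vapply(1:100, function(i) {
    d <- simulate_droplet_assay(5000, 10000, seed = 1000 + i)
    d$n_positive / d$n_total
  }, numeric(1))
  se <- sqrt(q_true * (1 - q_true) / 10000) / sqrt(100)
  expect_lt(abs(mean(fracs) - q_true), 3 * se)
})

test_that("qPCR Cq simulation follows the standard curve", {
  curve <- standard_curve(slope = -1 / log10(2), intercept = 38)
  expect_equal(simulate_qpcr_cq(1000, curve, noise_sd = 0),
               38 - log10(1000) / log10(2))
  # one doubling at E = 2 is exactly one cycle
  expect_equal(simulate_qpcr_cq(200, curve, 0) - simulate_qpcr_cq(400, curve, 0),
               1)
  expect_true(is.na(simulate_qpcr_cq(0, curve, 0)))
})

test_that("pileup recovers planted variant frequency at high depth", {
  u <- single_variant_model(freq_young = 0.001, freq_old = 0.42)
  e <- 5e-4
  pu <- simulate_amplicon_pileup(u, "28S", "old", depth = 1e5,
                                 error_floor = e, seed = 42)
  tr <- mutation_rate_track(pu, "o1", "old")
  expected <- 0.42 + (1 - 0.42) * e
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(tr$rate[4614] - expected), 3 * se)
  # noiseless generator is exactly clean
  pu0 <- simulate_amplicon_pileup(variant_free_model(), "28S", "young",
                                  depth = 1000, error_floor = 0, seed = 1)
  expect_true(all(mutation_rate_track(pu0)$rate == 0))
})

test_that("WGS read counts follow the closed-form read fraction", {
  expect_equal(
    simulate_wgs_readcounts(0, 43000, 5.3e9, 1e6, seed = 1)$rdna_reads, 0L)
  p <- 642 * 43000 / (5.3e9 + 642 * 43000)
  reads <- vapply(1:50, function(i)
    simulate_wgs_readcounts(642, 43000, 5.3e9, 1e6,
                            seed = i)$rdna_reads, integer(1))
  se <- sqrt(p * (1 - p) / 1e6) / sqrt(50)
  expect_lt(abs(mean(reads) / 1e6 - p), 3 * se)
  # doubling copies ~ doubles the expected fraction in the small-p regime
  p2 <- 2 * 642 * 43000 / (5.3e9 + 2 * 642 * 43000)
  expect_lt(abs(p2 / p - 2), 0.02)
})

test_that("cohort config rejects invalid settings and round-trips via YAML", {
  expect_error(cohort_config(n_mice = 0), "n_mice")
  expect_error(cohort_config(cv_young = -1), "cv_young")
  expect_error(cohort_config(methylated_fraction_old = 1.4),
               "methylated_fraction_old")
  cfg <- cohort_config(n_mice = 3, cells_per_mouse = 7, seed = 99)
  path <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  expect_equal(read_cohort_config(path), cfg)
})
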