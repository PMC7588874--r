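test_that("default digest yields the 4.0/2.4 kb probe fragments", {
  u <- default_unit_model()
  d <- digest_unit(u, c("BamHI", "NdeI"))
  probe_frag <- d$fragments[d$fragments$overlaps_probe, ]
  expect_equal(probe_frag$length[1], 4000L)
  d2 <- digest_unit(u, c("BamHI", "NdeI"), with_bamhi2 = TRUE)
  probe_frag2 <- d2$fragments[d2$fragments$overlaps_probe &
                              d2$fragments$start <= 2000, ]
  expect_equal(probe_frag2$length[1], 2400L)
  expect_error(digest_unit(u, "EcoRI"), "unknown enzyme")
})

test_that("fragment lengths always sum to the unit length", {
  u <- default_unit_model()
  set.seed(3)
  for (i in 1:25) {
    n_sites <- sample(1:8, 1)
    sites <- data.frame(
      enzyme = "BamHI", label = paste0("s", seq_len(n_sites)),
      position = sample(43000L, n_sites),
      methylation_sensitive = sample(c(TRUE, FALSE), n_sites, replace = TRUE))
    m <- build_unit_model(43000L, sites, probe_interval = c(2000L, 2200L))
    meth <- sites$position[sites$methylation_sensitive &
                           runif(n_sites) < 0.5]
    d <- digest_unit(m, "BamHI", methylated_sites = meth)
    expect_equal(sum(d$fragments$length), 43000L)
    expect_true(all(diff(d$fragments$start) > 0))
    expect_true(all(d$fragments$start[-1] == d$fragments$end[-nrow(d$fragments)] + 1))
  }
})

test_that("methylation blocks cuts; unmethylated sites add exactly one", {
  u <- default_unit_model()
  all_sites <- digest_unit(u, c("BamHI", "NdeI", "SacII"))
  blocked <- digest_unit(u, c("BamHI", "NdeI", "SacII"),
                         methylated_sites = 2501L)
  no_sacii <- digest_unit(u, c("BamHI", "NdeI"))
  # blocking the SacII site is the same as omitting the enzyme
  expect_equal(blocked$fragments, no_sacii$fragments)
  # the unmethylated SacII cut adds exactly one fragment
  expect_equal(nrow(all_sites$fragments), nrow(no_sacii$fragments) + 1)
})

test_that("band intensities reflect copy-weighted state fractions", {
  u <- default_unit_model()
  cells0 <- data.frame(copy_number = rep(1000L, 4), bamhi2_fraction = 0,
                       methylated_fraction = 0, active_fraction = 0.5)
  lane0 <- band_profile(cells0, u)
  expect_equal(unname(lane0$intensities["4.0kb"]), 4000)
  expect_true(is.na(lane0$intensities["2.4kb"]) ||
              lane0$intensities["2.4kb"] == 0)
  cells_half <- transform(cells0, bamhi2_fraction = 0.5)
  lane_half <- band_profile(cells_half, u)
  expect_equal(unname(lane_half$intensities["4.0kb"]),
               unname(lane_half$intensities["2.4kb"]))
  # doubling copies doubles rDNA bands but not SWI5
  cells2 <- transform(cells_half, copy_number = copy_number * 2L)
  lane2 <- band_profile(cells2, u)
  expect_equal(unname(lane2$intensities["4.0kb"]),
               2 * unname(lane_half$intensities["4.0kb"]))
  expect_equal(lane2$intensities[["SWI5"]], lane_half$intensities[["SWI5"]])
})

test_that("Southern relative values are SWI5- and young-normalized", {
  u <- default_unit_model()
  mk <- function(copies) {
    data.frame(copy_number = copies, bamhi2_fraction = 0.5,
               methylated_fraction = 0, active_fraction = 0.5)
  }
  lanes <- list(y1 = band_profile(mk(rep(500L, 3)), u, lane = "y1"),
                y2 = band_profile(mk(rep(500L, 3)), u, lane = "y2"),
                o1 = band_profile(mk(rep(1000L, 3)), u, lane = "o1"))
  rel <- relative_copy_number_southern(lanes, young_ids = c("y1", "y2"))
  expect_equal(rel$relative_value[rel$sample_id == "o1"], c(2, 2))
  young_vals <- rel$relative_value[rel$sample_id %in% c("y1", "y2")]
  expect_equal(mean(young_vals[rel$band[rel$sample_id %in% c("y1", "y2")] ==
                               "4.0kb"]), 1)
  # all-identical lanes are all exactly 1
  same <- list(a = lanes$y1, b = lanes$y1, c = lanes$y1)
  rel_same <- relative_copy_number_southern(same, young_ids = c("a", "b", "c"))
  expect_true(all(rel_same$relative_value == 1))
})

test_that("methylation ratio spans the blocking and digestion limits", {
  u <- default_unit_model()
  mk <- function(meth) {
    data.frame(copy_number = rep(1000L, 5), bamhi2_fraction = 0.4,
               methylated_fraction = meth, active_fraction = 0.5)
  }
  # fully methylated: SacII cuts nothing, ratio 1
  expect_equal(sacii_methylation_assay(mk(1), u)$pooled_ratio, 1)
  # fully unmethylated: complete digestion, ratio 0
  expect_equal(sacii_methylation_assay(mk(0), u)$pooled_ratio, 0)
  # direct arithmetic on hand-built lanes
  plus <- structure(list(lane = "p",
                         intensities = c("4.0kb" = 10, SWI5 = 8)),
                    class = "lane_quant")
  minus <- structure(list(lane = "m",
                          intensities = c("4.0kb" = 50, SWI5 = 8)),
                     class = "lane_quant")
  expect_equal(unname(methylation_undigested_ratio(plus, minus, "4.0kb")),
               0.2)
  # monotone in the population methylated fraction
  grid <- seq(0.05, 0.95, by = 0.15)
  ratios <- vapply(grid, function(m)
    sacii_methylation_assay(mk(m), u)$pooled_ratio, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("psoralen active/inactive ratio follows a/(1-a)", {
  expect_equal(psoralen_active_ratio(60, 40), 1.5)
  expect_error(psoralen_active_ratio(60, 0), "> 0")
  cells <- data.frame(copy_number = rep(800L, 6), bamhi2_fraction = 0.5,
                      methylated_fraction = 0.1, active_fraction = 0.5)
  expect_equal(psoralen_ratio_cells(cells), 1)
  cells$active_fraction <- 0.4
  expect_equal(psoralen_ratio_cells(cells), 0.4 / 0.6)
})
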