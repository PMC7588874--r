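test_that("mutation rate pools substitutions and indels over depth", {
  p <- make_pileup(ref = c("A", "C", "G"), nonref = c(2L, 0L, 0L),
                   depth = c(1000L, 10L, 10L))
  tr <- mutation_rate_track(p)
  expect_equal(tr$rate[1], 0.002)
  expect_equal(tr$rate[2:3], c(0, 0))
  # indels count toward the pooled rate
  p2 <- make_pileup(ref = c("A", "A"), nonref = c(1L, 0L),
                    depth = c(10L, 10L), del = c(1L, 0L), ins = c(0L, 2L))
  tr2 <- mutation_rate_track(p2)
  expect_equal(tr2$rate[1], 0.2)   # 1 substitution + 1 deletion of 10
  expect_equal(tr2$rate[2], 0.2)   # 2 insertions of 10
  # a fixed difference reads rate 1
  p3 <- make_pileup(ref = "A", nonref = 10L, depth = 10L)
  expect_equal(mutation_rate_track(p3)$rate, 1)
  # zero-depth positions are masked, not zero
  p4 <- make_pileup(ref = c("A", "A"), depth = c(0L, 10L))
  expect_true(is.na(mutation_rate_track(p4)$rate[1]))
})

test_that("rate conservation: reference fraction + pooled rate is 1", {
  set.seed(7)
  for (i in 1:20) {
    n <- 30
    depth <- sample(50:200, n, replace = TRUE)
    del <- rbinom(n, 3, 0.3)
    nonref <- rbinom(n, 5, 0.3)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    p <- make_pileup(ref, nonref = nonref, depth = depth, del = del)
    tr <- mutation_rate_track(p)
    bases <- c("A", "C", "G", "T")
    ref_count <- as.matrix(p[, bases])[cbind(seq_len(n), match(ref, bases))]
    expect_equal(ref_count / p$depth + tr$rate, rep(1, n))
  }
})

test_that("control-gene threshold is the filtered maximum", {
  t1 <- make_track(c(0.0005, 0.0011, 0.0028))
  expect_equal(control_gene_threshold(t1), 0.0028)
  t2 <- make_track(c(0.0005, 0.95, 0.0011))
  expect_equal(control_gene_threshold(t2), 0.0011)
  expect_equal(control_gene_threshold(make_track(c(0, 0, 0))), 0)
  expect_error(control_gene_threshold(make_track(c(NA, 0.95))), "usable")
})

test_that("age-differential calling reproduces the published arithmetic", {
  young <- list(make_track(0.000, "y1", "young", positions = 4614),
                make_track(0.001, "y2", "young", positions = 4614))
  old <- list(make_track(0.441, "o1", "old", positions = 4614),
              make_track(0.396, "o2", "old", positions = 4614))
  calls <- call_age_differential_sites(young, old, threshold = 0.0028)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 4614L)
  expect_equal(calls$old_mean, 0.4185)
  expect_equal(calls$difference, 0.418)
  expect_true(calls$passes)
  expect_equal(calls$yeast_position, 3295L)
  rep <- report_age_calls(calls)
  expect_equal(rep$old_mean, 0.419)
  expect_equal(rep$difference, 0.418)
  # null case: no call
  flat <- call_age_differential_sites(
    list(make_track(0.002, "y1"), make_track(0.002, "y2")),
    list(make_track(0.002, "o1"), make_track(0.002, "o2")),
    threshold = 0.0028)
  expect_equal(nrow(flat), 0)
})

test_that("calling excludes fixed differences and unseparated groups", {
  # rate > 0.9 in any sample excludes the position
  young <- list(make_track(c(0.95, 0.001), "y1"),
                make_track(c(0.94, 0.001), "y2"))
  old <- list(make_track(c(0.96, 0.30), "o1", "old"),
              make_track(c(0.95, 0.28), "o2", "old"))
  calls <- call_age_differential_sites(young, old, 0.0028)
  expect_false(1L %in% calls$position)
  expect_true(2L %in% calls$position)
  # overlapping groups fail the separation requirement
  y <- list(make_track(0.10, "y1"), make_track(0.30, "y2"))
  o <- list(make_track(0.25, "o1", "old"), make_track(0.40, "o2", "old"))
  sep <- call_age_differential_sites(y, o, 0.0028)
  expect_false(sep$passes)
  nosep <- call_age_differential_sites(y, o, 0.0028,
                                       require_separation = FALSE)
  expect_true(nosep$passes)
  expect_error(call_age_differential_sites(list(), list(), 0.0028),
               "samples per group")
})

test_that("young-high sites are called with negative difference", {
  young <- list(make_track(0.036, "y1", positions = 3094),
                make_track(0.038, "y2", positions = 3094))
  old <- list(make_track(0.009, "o1", "old", positions = 3094),
              make_track(0.007, "o2", "old", positions = 3094))
  calls <- call_age_differential_sites(young, old, 0.0028)
  rep <- report_age_calls(calls)
  expect_equal(rep$difference, -0.029)
  expect_true(calls$passes)
  expect_true(is.na(calls$yeast_position))  # 3094 is not conserved in yeast
})

test_that("hotspot window sums match a brute-force double loop", {
  rates <- rep(0.001, 40)
  rates[5] <- 0.01
  rates[25] <- 0.004
  w <- hotspot_window_sums(make_track(rates), threshold = 0.0028)
  expect_equal(w$summed_rate, c(0.010, 0.004))
  expect_equal(w$window_start, c(1L, 21L))
  expect_false(any(w$partial))
  # all sub-threshold rates give zero sums
  expect_true(all(hotspot_window_sums(make_track(rep(0.001, 40)),
                                      0.0028)$summed_rate == 0))
  # oracle equivalence on random instances, including a partial tail window
  set.seed(11)
  for (i in 1:10) {
    n <- sample(30:75, 1)
    r <- runif(n, 0, 0.02)
    r[sample(n, 2)] <- 0.95   # fixed differences must be excluded
    tr <- make_track(r)
    w <- hotspot_window_sums(tr, threshold = 0.0028, width = 20)
    brute <- vapply(seq(1, n, 20), function(s) {
      sum_w <- 0
      for (pos in s:min(s + 19, n)) {
        if (r[pos] > 0.0028 && r[pos] <= 0.9) sum_w <- sum_w + r[pos]
      }
      sum_w
    }, numeric(1))
    expect_equal(w$summed_rate, brute)
    expect_equal(w$partial[nrow(w)], n %% 20 != 0)
  }
})

test_that("merging tracks adds their window sums (linearity)", {
  r1 <- c(rep(0.01, 5), rep(0, 35))
  r2 <- c(rep(0, 20), rep(0.02, 5), rep(0, 15))
  w1 <- hotspot_window_sums(make_track(r1), 0.0028)
  w2 <- hotspot_window_sums(make_track(r2), 0.0028)
  merged <- hotspot_window_sums(list(make_track(r1), make_track(r2)), 0.0028)
  expect_equal(merged$summed_rate, w1$summed_rate + w2$summed_rate)
})

test_that("restriction-site summary reproduces the published group averages", {
  pos <- c(5052L, 5053L, 5054L)
  tracks <- list(
    make_track(c(0.23, 0.00, 0.00), "y1", "young", positions = pos),
    make_track(c(0.27, 0.00, 0.00), "y2", "young", positions = pos),
    make_track(c(0.35, 0.19, 0.19), "o1", "old", positions = pos),
    make_track(c(0.32, 0.16, 0.16), "o2", "old", positions = pos))
  s <- restriction_site_variant_summary(tracks, pos)
  expect_equal(sort(s$per_sample$rate_sum), sort(c(0.23, 0.27, 0.73, 0.64)))
  avg <- s$group_average
  expect_equal(avg$avg_rate_sum[avg$age_group == "young"], 0.25)
  expect_equal(avg$avg_rate_sum[avg$age_group == "old"], 0.685)
  # all-zero site
  zero <- restriction_site_variant_summary(
    list(make_track(c(0, 0, 0), "s1", "young", positions = pos)), pos)
  expect_equal(zero$group_average$avg_rate_sum, 0)
  expect_error(
    restriction_site_variant_summary(tracks, c(5052L, 9999L)), "9999")
})

test_that("TSV and SAM encodings of the same reads give identical pileups", {
  fx <- write_sam_fixture()
  tsv <- sam_fixture_pileup_tsv(fx$dir, fx$refseq)
  p_tsv <- pileup_from_alignments(tsv)
  p_sam <- pileup_from_alignments(fx$sam, reference = fx$fasta)
  cols <- c("position", "ref", "A", "C", "G", "T", "ins", "del", "depth")
  expect_equal(p_sam[, cols], p_tsv[, cols], ignore_attr = TRUE)
  # counting: 1 substituted read of 4 at position 5
  expect_equal(p_sam$G[5], 1)
  expect_equal(p_sam$depth[5], 4)
  tr <- mutation_rate_track(p_sam)
  expect_equal(tr$rate[5], 0.25)
  expect_true(all(tr$rate[-5] == 0))
  expect_error(pileup_from_alignments(fx$sam, reference = fx$fasta,
                                      seqname = "nope"), "not found")
})
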