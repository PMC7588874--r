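#!/usr/bin/env Rscript
# Amplicon mutation-rate analysis: per-position tracks for 28S and the
# ATP5b control, the learned artifact threshold, age-differential calls,
# the BamHI-site variant summary, and 20-bp hot-spot window sums.

library(rDNAge)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20200368

for (strain in c("BALB/cA", "C57BL/6")) {
  unit <- default_unit_model(strain = strain)
  cfg <- default_strain_configs(seed)[[strain]]
  mk <- function(locus, age, i) {
    pu <- simulate_amplicon_pileup(
      unit, locus, age, depth = cfg$depth, error_floor = cfg$error_floor,
      seed = substream_seed(seed, paste("mut", strain, locus, age, i)))
    mutation_rate_track(pu, sprintf("%s%d", substr(age, 1, 1), i), age)
  }
  young <- lapply(1:2, function(i) mk("28S", "young", i))
  old <- lapply(1:2, function(i) mk("28S", "old", i))
  ctrl <- c(lapply(1:2, function(i) mk("ATP5b", "young", i)),
            lapply(1:2, function(i) mk("ATP5b", "old", i)))
  thr <- control_gene_threshold(ctrl)
  calls <- report_age_calls(call_age_differential_sites(young, old, thr))
  tag <- gsub("[^A-Za-z0-9]", "", strain)
  utils::write.table(calls, file.path(out, paste0("age_calls_", tag, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  site <- restriction_site_variant_summary(c(young, old),
                                           c(5052L, 5053L, 5054L))
  utils::write.table(site$per_sample,
                     file.path(out, paste0("bamhi_site_", tag, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hot <- hotspot_window_sums(old, thr, width = 20)
  write_bedgraph(hot, file.path(out, paste0("hotspots_", tag, ".bedgraph")))
  message(sprintf(
    "%s: threshold %.2g; %d candidate site(s), %d passing; BamHI-site avg young %.3f / old %.3f",
    strain, thr, nrow(calls), sum(calls$passes),
    site$group_average$avg_rate_sum[site$group_average$age_group == "young"],
    site$group_average$avg_rate_sum[site$group_average$age_group == "old"]))
}
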