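#!/usr/bin/env Rscript
# Copy-number quantification: the ddPCR anchor for the qPCR standard,
# per-mouse single-cell statistics, and the WGS read-fraction estimates.

library(rDNAge)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20200368

## 1. Absolute anchor by duplex ddPCR (RPE1-like control line, RNase P
## reference at 2 copies/cell).
tgt <- simulate_droplet_assay(round(0.5 * 2e4), 2e4,
                              seed = substream_seed(seed, "ddpcr/target"))
ref <- simulate_droplet_assay(round(0.00303 * 2e4), 2e4,
                              seed = substream_seed(seed, "ddpcr/reference"))
anchor <- ddpcr_copies_per_cell(tgt, ref, reference_copies_per_cell = 2)
message(sprintf("ddPCR anchor: %.0f rDNA copies per control cell", anchor))

## 2. Single-cell qPCR against a fitted standard curve; verify the
## 1-2-4-cell linearity before trusting per-cell numbers.
curve <- suppressWarnings(fit_standard_curve(data.frame(
  copies = c(100, 1000, 10000), cq = c(30.00, 26.68, 23.36))))
cq124 <- simulate_qpcr_cq(round(anchor) * c(1, 2, 4), curve, noise_sd = 0)
est124 <- qpcr_copies_single_cell(cq124, curve)$copies
message(sprintf("pooled 1/2/4 cells estimate in ratio %s (linearity check)",
                paste(round(est124 / est124[1], 2), collapse = ":")))

## 3. Per-mouse single-cell statistics for both strains.
stats <- do.call(rbind, lapply(names(default_strain_configs(seed)), function(s) {
  cohort <- read_tsv_file <- utils::read.table(
    file.path(out, paste0("cohort_", gsub("[^A-Za-z0-9]", "", s), ".tsv")),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  cbind(strain = s, cohort_stats(cohort))
}))
utils::write.table(stats, file.path(out, "copy_number_stats.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
young <- tapply(stats$mean_copies[stats$age_group == "young"],
                stats$strain[stats$age_group == "young"], mean)
message(sprintf("strain ratio (young means): %.2f",
                young[["C57BL/6"]] / young[["BALB/cA"]]))

## 4. WGS read-fraction estimates at the two published WGS copy numbers.
wgs <- do.call(rbind, lapply(c(BALB = 642, C57 = 1412), function(copies) {
  sim <- simulate_wgs_readcounts(copies, 43000, 5.3e9, 1e6,
                                 seed = substream_seed(seed, paste0("wgs", copies)))
  data.frame(true_copies = copies,
             rdna_reads = sim$rdna_reads,
             estimate = wgs_copy_number(sim$rdna_reads, sim$total_mapped_reads))
}))
utils::write.table(wgs, file.path(out, "wgs_estimates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("WGS estimates: %s",
                paste(round(wgs$estimate), collapse = ", ")))
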