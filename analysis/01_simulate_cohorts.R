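#!/usr/bin/env Rscript
# Simulate the two-strain young/old cohorts and write them to disk.
# The BALB/cA-like strain starts at 471 copies/cell (young) and the
# C57BL/6-like strain at 1,025; old groups gain copies (x1.2) but lose
# cell-to-cell dispersion (CV 0.35 -> 0.20).

library(rDNAge)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20200368

configs <- default_strain_configs(seed = seed)
for (strain in names(configs)) {
  cfg <- configs[[strain]]
  cohort <- generate_cohort(cfg)
  tag <- gsub("[^A-Za-z0-9]", "", strain)
  write_cohort(cohort, file.path(out, paste0("cohort_", tag, ".tsv")))
  write_cohort_config(cfg, file.path(out, paste0("config_", tag, ".yaml")))
  gm <- cohort_group_means(cohort)
  message(sprintf(
    "%s: young mean %.0f copies (CV %.2f), old mean %.0f copies (CV %.2f)",
    strain,
    gm$mean_copies[gm$age_group == "young"], gm$mean_cv[gm$age_group == "young"],
    gm$mean_copies[gm$age_group == "old"], gm$mean_cv[gm$age_group == "old"]))
}

unit <- default_unit_model()
write_unit_model(unit, file.path(out, "unit_model"))
message("unit model written (probe fragment ",
        probe_fragment_length(unit), " bp without BamHI-2, ",
        probe_fragment_length(unit, with_bamhi2 = TRUE), " bp with it)")
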