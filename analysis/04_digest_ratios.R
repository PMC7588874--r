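#!/usr/bin/env Rscript
# Southern-style readouts from the simulated cohorts: relative copy number
# (BamHI/NdeI bands over SWI5), SacII methylation ratios, and psoralen
# active/inactive ratios, with the two-sided t test on each age contrast.

library(rDNAge)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (strain in c("BALB/cA", "C57BL/6")) {
  tag <- gsub("[^A-Za-z0-9]", "", strain)
  cohort <- utils::read.table(file.path(out, paste0("cohort_", tag, ".tsv")),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  unit <- default_unit_model(strain = strain)
  by_mouse <- split(cohort, cohort$mouse_id)

  lanes <- lapply(by_mouse, function(cells)
    band_profile(cells, unit, c("BamHI", "NdeI"), lane = cells$mouse_id[1]))
  young_ids <- unique(cohort$mouse_id[cohort$age_group == "young"])
  southern <- relative_copy_number_southern(lanes, young_ids)
  utils::write.table(southern,
                     file.path(out, paste0("southern_relative_", tag, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ratios <- do.call(rbind, lapply(by_mouse, function(cells) {
    data.frame(mouse_id = cells$mouse_id[1],
               age_group = cells$age_group[1],
               methylation_ratio =
                 sacii_methylation_assay(cells, unit)$pooled_ratio,
               active_inactive_ratio = psoralen_ratio_cells(cells))
  }))
  utils::write.table(ratios, file.path(out, paste0("ratios_", tag, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  young <- ratios$age_group == "young"
  t_meth <- two_sided_t(ratios$methylation_ratio[young],
                        ratios$methylation_ratio[!young])
  t_act <- two_sided_t(ratios$active_inactive_ratio[young],
                       ratios$active_inactive_ratio[!young])
  message(sprintf(
    "%s: methylation ratio young %.3f vs old %.3f (p = %.2g); active/inactive young %.2f vs old %.2f (p = %.2g)",
    strain,
    mean(ratios$methylation_ratio[young]),
    mean(ratios$methylation_ratio[!young]), t_meth$p,
    mean(ratios$active_inactive_ratio[young]),
    mean(ratios$active_inactive_ratio[!young]), t_act$p))
}
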