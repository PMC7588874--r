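#!/usr/bin/env Rscript
# Small quantitative stages: housekeeping-normalized 28S expression and the
# pre-45S/28S ratio on simulated Cq tables, and chronological life-span
# survival curves for a wild-type-like and a short-lived mutant-like strain.

library(rDNAge)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20200368

## Relative expression: old cells transcribe slightly less 28S and clearly
## less pre-45S (new synthesis) per housekeeping transcript.
samples <- c("y1", "y2", "y3", "y4", "o1", "o2", "o3", "o4")
age <- ifelse(grepl("^y", samples), "young", "old")
base_cq <- list("28S" = 12, pre45S = 22, GAPDH = 18, B2M = 19, Actb = 17)
shift <- list("28S" = 0.3, pre45S = 1.0, GAPDH = 0, B2M = 0, Actb = 0)
cq <- do.call(rbind, lapply(names(base_cq), function(g) {
  set.seed(substream_seed(seed, paste("cq", g)))  # technical scatter
  data.frame(sample_id = samples, age_group = age, target = g,
             cq = base_cq[[g]] + ifelse(age == "old", shift[[g]], 0) +
               stats::rnorm(length(samples), 0, 0.05))
}))
rel28 <- relative_expression_table(cq, target = "28S")
utils::write.table(rel28, file.path(out, "expression_28S.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (hk in unique(rel28$housekeeping)) {
  d <- rel28[rel28$housekeeping == hk, ]
  message(sprintf("28S vs %s: old/young relative amount %.2f", hk,
                  mean(d$relative_amount[d$age_group == "old"])))
}
rel45 <- relative_expression_table(cq, target = "pre45S",
                                   housekeeping = "GAPDH")
ratio <- premature_to_mature_ratio(
  rel45$relative_amount,
  rel28$relative_amount[rel28$housekeeping == "GAPDH"],
  young = rel45$age_group == "young")
message(sprintf("pre-45S/28S ratio, old relative to young: %.2f",
                mean(ratio[rel45$age_group == "old"])))

## Chronological life span: nine replicate series per strain; the
## mutant-like strain loses viability faster after day 5.
days <- seq(3, 17, by = 2)
mk_series <- function(strain, i, halflife) {
  set.seed(substream_seed(seed, paste("cls", strain, i)))
  cfu <- round(500 * 2^(-(days - 3) / halflife) *
                 exp(stats::rnorm(length(days), 0, 0.08)))
  cfu[1] <- 500
  data.frame(day = days, cfu = pmax(cfu, 0))
}
for (strain in c("WT", "A3295G")) {
  hl <- if (strain == "WT") 6 else 3.5
  surv <- survival_summary(lapply(1:9, function(i) mk_series(strain, i, hl)))
  utils::write.table(surv, file.path(out, paste0("survival_", strain, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: survival at day 9 = %.2f +/- %.2f (n = 9)", strain,
                  surv$mean_survival[surv$day == 9],
                  surv$sd_survival[surv$day == 9]))
}
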