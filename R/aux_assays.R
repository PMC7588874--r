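#' Relative expression by the comparative Cq method
#'
#' `dCq = target_cq - housekeeping_cq` per sample; the relative amount is
#' `efficiency^-(dCq - reference_delta)`, i.e. 1 for a sample whose dCq
#' equals the reference dCq and 0.5 for one cycle more (at E = 2). Adding a
#' constant to both Cq values (an instrument offset) cancels.
#'
#' @param target_cq target Cq value(s).
#' @param housekeeping_cq housekeeping-gene Cq value(s), same length.
#' @param efficiency amplification efficiency (default 2, no correction).
#' @param reference_delta the reference sample's (or group-mean) dCq.
#' @return numeric vector of relative amounts.
#' @export
relative_expression <- function(target_cq, housekeeping_cq, efficiency = 2,
                                reference_delta = 0) {
  if (anyNA(target_cq) || anyNA(housekeeping_cq)) {
    stop("missing Cq measurement", call. = FALSE)
  }
  check_in_range(efficiency, 1 + 1e-9, 2.2, "efficiency")
  dcq <- target_cq - housekeeping_cq
  efficiency^(-(dcq - reference_delta))
}

#' Per-housekeeping-gene normalized expression for a Cq table
#'
#' Normalizes a target transcript against each housekeeping gene
#' separately (the three normalizations are reported side by side, never
#' averaged), relative to the mean dCq of the reference (young) group.
#'
#' @param cq_table data.frame with columns `sample_id`, `age_group`,
#'   `target`, `cq` (one row per sample x gene).
#' @param target target transcript name (e.g. `"28S"`, `"pre45S"`).
#' @param housekeeping housekeeping gene names.
#' @param reference_group age group whose mean dCq anchors the scale.
#' @param efficiency amplification efficiency.
#' @return data.frame: `sample_id`, `age_group`, `housekeeping`,
#'   `relative_amount`.
#' @export
relative_expression_table <- function(cq_table, target = "28S",
                                      housekeeping = c("GAPDH", "B2M", "Actb"),
                                      reference_group = "young",
                                      efficiency = 2) {
  stopifnot(all(c("sample_id", "age_group", "target", "cq") %in%
                names(cq_table)))
  tgt <- cq_table[cq_table$target == target, ]
  if (nrow(tgt) == 0) stop(sprintf("no Cq rows for target '%s'", target),
                           call. = FALSE)
  out <- lapply(housekeeping, function(hk) {
    hkd <- cq_table[cq_table$target == hk, ]
    m <- match(tgt$sample_id, hkd$sample_id)
    if (anyNA(m)) {
      stop(sprintf("missing housekeeping '%s' measurement for sample(s): %s",
                   hk, paste(tgt$sample_id[is.na(m)], collapse = ", ")),
           call. = FALSE)
    }
    dcq <- tgt$cq - hkd$cq[m]
    ref <- mean(dcq[tgt$age_group == reference_group])
    data.frame(sample_id = tgt$sample_id, age_group = tgt$age_group,
               housekeeping = hk,
               relative_amount = efficiency^(-(dcq - ref)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Premature-to-mature rRNA ratio
#'
#' Ratio of relative pre-45S to relative 28S amounts per sample, expressed
#' relative to the mean ratio of the young group (so the young-group mean
#' of reported ratios is exactly 1).
#'
#' @param rel_pre45S relative pre-45S amounts (per sample).
#' @param rel_28S relative 28S amounts (same length, all > 0).
#' @param young logical vector marking the young samples.
#' @return numeric vector of normalized ratios.
#' @export
premature_to_mature_ratio <- function(rel_pre45S, rel_28S,
                                      young = rep(TRUE, length(rel_28S))) {
  if (any(rel_28S <= 0)) stop("rel_28S must be > 0", call. = FALSE)
  if (!any(young)) stop("young group is empty", call. = FALSE)
  ratio <- rel_pre45S / rel_28S
  ratio / mean(ratio[young])
}

#' Chronological life-span survival curve
#'
#' Survival of stationary-phase yeast: colony-forming units at each
#' sampling day normalized to the day-3 culture, so survival at day 3 is
#' exactly 1. Values above 1 (regrowth after day 3) are allowed and
#' flagged, not clipped.
#'
#' @param series data.frame with columns `day` (integer, strictly
#'   increasing, day 3 present) and `cfu` (>= 0).
#' @return a `survival_curve` data.frame: `day`, `cfu`, `survival`,
#'   `above_one`.
#' @export
chronological_survival <- function(series) {
  stopifnot(all(c("day", "cfu") %in% names(series)))
  if (is.unsorted(series$day, strictly = TRUE)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  if (!3 %in% series$day) stop("day 3 measurement is required", call. = FALSE)
  anchor <- series$cfu[series$day == 3]
  if (anchor <= 0) stop("day 3 CFU must be > 0", call. = FALSE)
  out <- data.frame(day = series$day, cfu = series$cfu,
                    survival = series$cfu / anchor)
  out$above_one <- out$survival > 1
  class(out) <- c("survival_curve", class(out))
  out
}

#' Summarize replicate survival curves
#'
#' Per-day mean and SD of survival over replicate series (e.g. the nine
#' replicate life-span experiments of one strain).
#'
#' @param series_list list of data.frames accepted by
#'   [chronological_survival()].
#' @return data.frame: `day`, `n`, `mean_survival`, `sd_survival`.
#' @export
survival_summary <- function(series_list) {
  curves <- lapply(series_list, chronological_survival)
  all <- do.call(rbind, lapply(curves, function(x) x[, c("day", "survival")]))
  days <- sort(unique(all$day))
  data.frame(
    day = days,
    n = as.integer(tapply(all$survival, all$day, length)[as.character(days)]),
    mean_survival = as.numeric(tapply(all$survival, all$day, mean)[as.character(days)]),
    sd_survival = as.numeric(tapply(all$survival, all$day, stats::sd)[as.character(days)]))
}
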