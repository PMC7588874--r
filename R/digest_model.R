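#' In-silico restriction digest of one rDNA unit
#'
#' Cuts the (linear) unit at every site of the requested enzymes, except
#' methylation-sensitive sites whose position is listed in
#' `methylated_sites` (CpG methylation blocks e.g. SacII). A site at
#' position `p` cuts between `p - 1` and `p`. Fragments are returned in
#' coordinate order and always tile the unit exactly.
#'
#' @param unit an `rdna_unit_model`.
#' @param enzymes character vector of enzyme names; must appear in the
#'   unit's site table (BamHI also covers the polymorphic BamHI-2 site).
#' @param methylated_sites integer positions of methylation-blocked sites.
#' @param with_bamhi2 does this unit copy carry the polymorphic BamHI-2
#'   site? (Only meaningful when the model defines `bamhi2_position`.)
#' @return a `digest_result`: `fragments` data.frame (`start`, `end`,
#'   `length`, `overlaps_probe`), `enzymes`, `blocked_sites`.
#' @export
digest_unit <- function(unit, enzymes, methylated_sites = integer(0),
                        with_bamhi2 = FALSE) {
  stopifnot(inherits(unit, "rdna_unit_model"))
  known <- unique(unit$sites$enzyme)
  unknown <- setdiff(enzymes, known)
  if (length(unknown)) {
    stop("unknown enzyme name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  s <- unit$sites[unit$sites$enzyme %in% enzymes, , drop = FALSE]
  blocked <- s$methylation_sensitive & s$position %in% methylated_sites
  cuts <- s$position[!blocked]
  if (with_bamhi2 && !is.null(unit$bamhi2_position) &&
      "BamHI" %in% enzymes) {
    cuts <- c(cuts, unit$bamhi2_position)
  }
  cuts <- sort(unique(cuts[cuts > 1]))  # a cut at 1 leaves no left fragment
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, unit$unit_length)
  probe <- unit$probe_interval
  frags <- data.frame(start = as.integer(starts), end = as.integer(ends),
                      length = as.integer(ends - starts + 1L),
                      overlaps_probe = starts <= probe[2] & ends >= probe[1])
  structure(list(fragments = frags, enzymes = enzymes,
                 blocked_sites = s$position[blocked]),
            class = "digest_result")
}

#' Length of the probe-detected fragment after a digest
#'
#' @inheritParams digest_unit
#' @return fragment length in bp (integer scalar).
#' @export
probe_fragment_length <- function(unit, enzymes = c("BamHI", "NdeI"),
                                  methylated_sites = integer(0),
                                  with_bamhi2 = FALSE) {
  d <- digest_unit(unit, enzymes, methylated_sites, with_bamhi2)
  hits <- d$fragments[d$fragments$overlaps_probe, , drop = FALSE]
  # the probe is short relative to fragments; take the fragment holding its start
  hit <- hits[hits$start <= unit$probe_interval[1] &
              hits$end >= unit$probe_interval[1], , drop = FALSE]
  as.integer(hit$length[1])
}

#' Southern-lane band intensities from a cell population
#'
#' Each cell's copies are partitioned over unit states -- with/without the
#' polymorphic BamHI-2 site and methylated/unmethylated at the
#' methylation-sensitive sites (treated as independent per-copy states) --
#' and each state's digest contributes its probe-detected fragment to the
#' band of that fragment length. Band intensity is proportional to the
#' number of probe-hybridizing copies (one short probe, one hybridization
#' per fragment), not to fragment length. The single-copy loading control
#' (SWI5) contributes 2 copies per diploid cell and is unaffected by rDNA
#' copy number.
#'
#' @param cells data.frame of cells (`copy_number`, `bamhi2_fraction`,
#'   `methylated_fraction`; e.g. one mouse's rows from [generate_cohort()]).
#' @param unit an `rdna_unit_model`.
#' @param enzymes enzymes applied to the lane.
#' @param lane lane label.
#' @param exposure single multiplicative exposure constant for the lane.
#' @return a `lane_quant`: `lane` label plus named `intensities` (band
#'   labels such as `"4.0kb"`, `"2.4kb"`, and `"SWI5"`).
#' @export
band_profile <- function(cells, unit, enzymes = c("BamHI", "NdeI"),
                         lane = "lane", exposure = 1) {
  stopifnot(inherits(unit, "rdna_unit_model"))
  check_in_range(cells$bamhi2_fraction, 0, 1, "bamhi2_fraction")
  check_in_range(cells$methylated_fraction, 0, 1, "methylated_fraction")
  meth_positions <- unit$sites$position[unit$sites$methylation_sensitive]
  has_b2 <- !is.null(unit$bamhi2_position)
  states <- expand.grid(bamhi2 = if (has_b2) c(FALSE, TRUE) else FALSE,
                        methylated = c(FALSE, TRUE))
  intensities <- c(SWI5 = 2 * nrow(cells) * exposure)
  for (k in seq_len(nrow(states))) {
    st <- states[k, ]
    len <- probe_fragment_length(
      unit, enzymes,
      methylated_sites = if (st$methylated) meth_positions else integer(0),
      with_bamhi2 = st$bamhi2)
    label <- sprintf("%.1fkb", len / 1000)
    w_b <- if (st$bamhi2) cells$bamhi2_fraction else 1 - cells$bamhi2_fraction
    if (!has_b2) w_b <- rep(1, nrow(cells))
    w_m <- if (st$methylated) cells$methylated_fraction
           else 1 - cells$methylated_fraction
    weight <- sum(cells$copy_number * w_b * w_m) * exposure
    intensities[label] <- sum(intensities[label], weight, na.rm = TRUE)
  }
  structure(list(lane = lane, intensities = intensities),
            class = "lane_quant")
}

#' @export
print.lane_quant <- function(x, ...) {
  cat(sprintf("lane '%s': %s\n", x$lane,
              paste(sprintf("%s=%.4g", names(x$intensities), x$intensities),
                    collapse = ", ")))
  invisible(x)
}

#' Relative rDNA copy number from Southern band intensities
#'
#' Each lane's rDNA band intensity is normalized by its single-copy SWI5
#' band, then expressed relative to the mean of the normalized values over
#' the young samples (so the young group mean is exactly 1). Computed
#' separately for each requested band (upper 4.0 kb and lower 2.4 kb).
#'
#' @param lanes named list of `lane_quant` objects (names = sample ids).
#' @param young_ids sample ids of the young group.
#' @param bands band labels to report.
#' @return data.frame: `sample_id`, `band`, `relative_value`.
#' @export
relative_copy_number_southern <- function(lanes, young_ids,
                                          bands = c("4.0kb", "2.4kb")) {
  if (length(young_ids) == 0) stop("young_ids must be non-empty",
                                   call. = FALSE)
  stopifnot(all(young_ids %in% names(lanes)))
  norm <- function(lane, band) {
    swi5 <- lane$intensities[["SWI5"]]
    if (is.na(swi5) || swi5 == 0) {
      stop(sprintf("lane '%s' has zero SWI5 intensity", lane$lane),
           call. = FALSE)
    }
    b <- lane$intensities[band]
    if (is.na(b)) b <- 0
    unname(b) / swi5
  }
  out <- do.call(rbind, lapply(bands, function(band) {
    vals <- vapply(lanes, norm, numeric(1), band = band)
    young_mean <- mean(vals[young_ids])
    data.frame(sample_id = names(lanes), band = band,
               relative_value = unname(vals / young_mean),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Methylation ratio from paired SacII+/SacII- lanes
#'
#' For each band that survives the methylation-sensitive digest, the
#' SWI5-normalized intensity in the digested (+) lane is divided by that in
#' the undigested (-) lane. A fully methylated population digests nothing
#' (ratio 1); a fully unmethylated one digests everything (ratio 0).
#'
#' @param plus_lane `lane_quant` for the SacII-digested lane.
#' @param minus_lane `lane_quant` for the SacII-free lane.
#' @param band_labels bands to report (default the two arrowhead bands).
#' @return named numeric vector of ratios (one per band).
#' @export
methylation_undigested_ratio <- function(plus_lane, minus_lane,
                                         band_labels = c("4.0kb", "2.4kb")) {
  get <- function(lane, band) {
    v <- lane$intensities[band]
    if (is.na(v)) 0 else unname(v)
  }
  swi5p <- get(plus_lane, "SWI5")
  swi5m <- get(minus_lane, "SWI5")
  if (swi5p == 0 || swi5m == 0) {
    stop("zero SWI5 intensity in a lane", call. = FALSE)
  }
  vapply(band_labels, function(band) {
    denom <- get(minus_lane, band)
    if (denom == 0) {
      stop(sprintf("band '%s' absent from the undigested lane", band),
           call. = FALSE)
    }
    (get(plus_lane, band) / swi5p) / (denom / swi5m)
  }, numeric(1))
}

#' SacII methylation assay on a cell population
#'
#' Convenience wrapper producing the paired BamHI+NdeI (+/- SacII) lanes
#' from one sample's cells and the undigested-band ratios, plus a pooled
#' ratio over the reported bands (intensity-weighted, equal to the
#' population's copy-weighted methylated fraction).
#'
#' @inheritParams band_profile
#' @param band_labels bands to report.
#' @return list: `plus`, `minus` (lane_quant), `ratios` (per band),
#'   `pooled_ratio`.
#' @export
sacii_methylation_assay <- function(cells, unit, lane = "sample",
                                    band_labels = c("4.0kb", "2.4kb")) {
  minus <- band_profile(cells, unit, c("BamHI", "NdeI"),
                        lane = paste0(lane, "_SacII-"))
  plus_all <- band_profile(cells, unit, c("BamHI", "NdeI", "SacII"),
                           lane = paste0(lane, "_SacII+"))
  ratios <- methylation_undigested_ratio(plus_all, minus, band_labels)
  get <- function(lane, bands) {
    v <- lane$intensities[bands]
    sum(v[!is.na(v)])
  }
  pooled <- (get(plus_all, band_labels) / plus_all$intensities[["SWI5"]]) /
            (get(minus, band_labels) / minus$intensities[["SWI5"]])
  list(plus = plus_all, minus = minus, ratios = ratios,
       pooled_ratio = unname(pooled))
}

#' Active-to-inactive rDNA ratio (psoralen cross-linking)
#'
#' Psoralen intercalates into non-nucleosomal, transcriptionally active
#' rDNA, retarding its migration: the upper band reports active copies and
#' the lower band inactive ones. The statistic is simply their intensity
#' ratio; driven from a per-copy active fraction `a`, its expectation is
#' `a / (1 - a)`.
#'
#' @param active_intensity upper (active) band intensity.
#' @param inactive_intensity lower (inactive) band intensity (> 0).
#' @return the ratio (numeric scalar).
#' @export
psoralen_active_ratio <- function(active_intensity, inactive_intensity) {
  if (inactive_intensity <= 0) {
    stop("inactive band intensity must be > 0", call. = FALSE)
  }
  active_intensity / inactive_intensity
}

#' Psoralen assay on a cell population
#'
#' Band intensities are the copy-weighted active and inactive fractions
#' over the sample's cells.
#'
#' @param cells data.frame with `copy_number` and `active_fraction`.
#' @return the active/inactive ratio (numeric scalar).
#' @export
psoralen_ratio_cells <- function(cells) {
  check_in_range(cells$active_fraction, 0, 1, "active_fraction")
  active <- sum(cells$copy_number * cells$active_fraction)
  inactive <- sum(cells$copy_number * (1 - cells$active_fraction))
  psoralen_active_ratio(active, inactive)
}
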