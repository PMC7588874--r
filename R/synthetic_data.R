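#' Cohort configuration
#'
#' Parameters of one synthetic mouse cohort: a strain label, young/old
#' per-cell copy-number means and coefficients of variation, group sizes,
#' and the young/old per-copy state fractions (methylated, transcription
#' active, carrying the BamHI-2 site), plus the amplicon sequencing depth
#' and error floor.
#'
#' Defaults follow the two study strains: young means 471 (BALB/cA-like)
#' and 1,025 (C57BL/6-like) copies per cell, an old/young mean ratio of
#' 1.2, and cell-to-cell CVs of 0.35 (young) and 0.20 (old) so that old
#' cohorts have more copies but less dispersion.
#'
#' @param strain strain label.
#' @param mean_copies_young,mean_copies_old mean copies per cell (> 0).
#' @param cv_young,cv_old cell-to-cell coefficient of variation (> 0).
#' @param n_mice mice per age group (>= 1).
#' @param cells_per_mouse cells assayed per mouse (>= 1).
#' @param methylated_fraction_young,methylated_fraction_old mean per-copy
#'   SacII-methylated fraction in `[0, 1]`.
#' @param active_fraction_young,active_fraction_old mean transcription-active
#'   fraction in `[0, 1]`.
#' @param bamhi2_fraction_young,bamhi2_fraction_old mean fraction of copies
#'   carrying the BamHI-2 site in `[0, 1]`.
#' @param error_floor per-base sequencing/PCR error rate in `[0, 0.25]`.
#' @param depth amplicon reads per position (> 0).
#' @param n_droplets droplets per ddPCR assay.
#' @param seed integer root seed for the cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(strain = "BALB/cA",
                          mean_copies_young = 471,
                          mean_copies_old = round(471 * 1.2),
                          cv_young = 0.35,
                          cv_old = 0.20,
                          n_mice = 4,
                          cells_per_mouse = 50,
                          methylated_fraction_young = 0.10,
                          methylated_fraction_old = 0.25,
                          active_fraction_young = 0.50,
                          active_fraction_old = 0.40,
                          bamhi2_fraction_young = 0.50,
                          bamhi2_fraction_old = 0.35,
                          error_floor = 5e-4,
                          depth = 1e4,
                          n_droplets = 20000,
                          seed = 20200368) {
  check_positive(mean_copies_young, "mean_copies_young")
  check_positive(mean_copies_old, "mean_copies_old")
  check_positive(cv_young, "cv_young")
  check_positive(cv_old, "cv_old")
  if (n_mice < 1) stop("field 'n_mice' must be >= 1", call. = FALSE)
  if (cells_per_mouse < 1) {
    stop("field 'cells_per_mouse' must be >= 1", call. = FALSE)
  }
  for (f in c("methylated_fraction_young", "methylated_fraction_old",
              "active_fraction_young", "active_fraction_old",
              "bamhi2_fraction_young", "bamhi2_fraction_old")) {
    check_in_range(get(f), 0, 1, f)
  }
  check_in_range(error_floor, 0, 0.25, "error_floor")
  check_positive(depth, "depth")
  check_positive(n_droplets, "n_droplets")
  structure(list(
    strain = strain,
    mean_copies_young = mean_copies_young,
    mean_copies_old = mean_copies_old,
    cv_young = cv_young, cv_old = cv_old,
    n_mice = as.integer(n_mice),
    cells_per_mouse = as.integer(cells_per_mouse),
    methylated_fraction_young = methylated_fraction_young,
    methylated_fraction_old = methylated_fraction_old,
    active_fraction_young = active_fraction_young,
    active_fraction_old = active_fraction_old,
    bamhi2_fraction_young = bamhi2_fraction_young,
    bamhi2_fraction_old = bamhi2_fraction_old,
    error_floor = error_floor,
    depth = depth,
    n_droplets = as.integer(n_droplets),
    seed = as.integer(seed)), class = "cohort_config")
}

#' Default configurations for the two study strains
#'
#' @param seed integer root seed shared by both strain configs.
#' @return named list of two `cohort_config` objects.
#' @export
default_strain_configs <- function(seed = 20200368) {
  list(
    "BALB/cA" = cohort_config(strain = "BALB/cA",
                              mean_copies_young = 471,
                              mean_copies_old = round(471 * 1.2),
                              seed = seed),
    "C57BL/6" = cohort_config(strain = "C57BL/6",
                              mean_copies_young = 1025,
                              mean_copies_old = round(1025 * 1.2),
                              seed = seed))
}

# log-normal parameters moment-matched to a mean and CV
lnorm_params <- function(mean, cv) {
  sdlog2 <- log(1 + cv^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# per-cell state fractions scatter around the group mean as a Beta with a
# fixed concentration; degenerate means 0/1 stay exact
rbeta_mean <- function(n, mean, concentration = 80) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Generate a synthetic cohort of mice with per-cell copy numbers
#'
#' Per-cell copy numbers are drawn from a log-normal distribution
#' moment-matched to the configured group mean and CV and rounded half-up
#' to integers; per-cell state fractions (BamHI-2, methylated,
#' transcription-active) scatter around the configured group means. The
#' same config (including its seed) always reproduces the same cohort.
#'
#' @param config a [cohort_config()].
#' @return a data.frame with one row per cell: `mouse_id`, `strain`,
#'   `age_group`, `sex`, `cell_id`, `copy_number`, `bamhi2_fraction`,
#'   `methylated_fraction`, `active_fraction`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- list(
    young = list(mean = config$mean_copies_young, cv = config$cv_young,
                 meth = config$methylated_fraction_young,
                 act = config$active_fraction_young,
                 bam = config$bamhi2_fraction_young),
    old = list(mean = config$mean_copies_old, cv = config$cv_old,
               meth = config$methylated_fraction_old,
               act = config$active_fraction_old,
               bam = config$bamhi2_fraction_old))
  out <- lapply(names(groups), function(age) {
    g <- groups[[age]]
    p <- lnorm_params(g$mean, g$cv)
    with_seed(substream_seed(config$seed,
                             paste("cohort", config$strain, age, sep = "/")), {
      do.call(rbind, lapply(seq_len(config$n_mice), function(i) {
        n <- config$cells_per_mouse
        copies <- round_half_up(stats::rlnorm(n, p$meanlog, p$sdlog))
        data.frame(
          mouse_id = sprintf("%s_%s_%d", gsub("[^A-Za-z0-9]", "", config$strain),
                             age, i),
          strain = config$strain,
          age_group = age,
          sex = if (i %% 2 == 1) "m" else "f",
          cell_id = sprintf("c%03d", seq_len(n)),
          copy_number = as.integer(copies),
          bamhi2_fraction = rbeta_mean(n, g$bam),
          methylated_fraction = rbeta_mean(n, g$meth),
          active_fraction = rbeta_mean(n, g$act),
          stringsAsFactors = FALSE)
      }))
    })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a droplet digital PCR partitioning
#'
#' Each template copy lands in one of `n_droplets` partitions uniformly at
#' random; a droplet is positive if it holds at least one copy. The positive
#' fraction therefore converges to `1 - exp(-lambda)` with
#' `lambda = total_copies / n_droplets`.
#'
#' @param total_copies template copies in the reaction (>= 0).
#' @param n_droplets number of droplets (> 0).
#' @param seed optional integer seed.
#' @return a `droplet_counts` list with `n_total` and `n_positive`.
#' @export
simulate_droplet_assay <- function(total_copies, n_droplets, seed = NULL) {
  check_positive(total_copies, "total_copies", strict = FALSE)
  check_positive(n_droplets, "n_droplets")
  n_positive <- with_seed(seed, {
    if (total_copies == 0) {
      0L
    } else {
      occupied <- unique(sample.int(n_droplets, total_copies, replace = TRUE))
      length(occupied)
    }
  })
  droplet_counts(n_total = n_droplets, n_positive = n_positive)
}

#' Simulate a qPCR quantification cycle
#'
#' `Cq = intercept + slope * log10(copies) + Normal(0, noise_sd)`. A zero
#' copy input yields no amplification, signalled as `NA` (the sentinel
#' understood by [qpcr_copies_single_cell()]), never as a finite cycle.
#'
#' @param copies template copies (vectorized; >= 0).
#' @param curve a [standard_curve()].
#' @param noise_sd cycle noise SD (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of Cq values (`NA` = no amplification).
#' @export
simulate_qpcr_cq <- function(copies, curve, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  check_positive(copies, "copies", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  with_seed(seed, {
    cq <- curve$intercept + curve$slope * log10(copies)
    if (noise_sd > 0) cq <- cq + stats::rnorm(length(copies), 0, noise_sd)
    cq[copies == 0] <- NA_real_
    cq
  })
}

#' Simulate an amplicon deep-sequencing pileup
#'
#' At each locus position the planted variant (if any) contributes
#' `Binomial(depth, f)` alternate-base reads, where `f` is the variant's
#' frequency for the requested age group; the remaining reference-derived
#' reads acquire errors at the per-base `error_floor`, spread uniformly over
#' the three non-reference bases. The expected non-reference rate at a
#' variant position is therefore `f + (1 - f) * error_floor`. The generator
#' is substitution-only: insertion and deletion columns are present (they
#' are counted by [mutation_rate_track()]) but zero.
#'
#' @param model an `rdna_unit_model`.
#' @param locus one of the model's loci (e.g. `"28S"`, `"ATP5b"`).
#' @param age_group `"young"` or `"old"` (selects variant frequencies).
#' @param depth reads per position (> 0).
#' @param error_floor per-base error rate in `[0, 0.25]`.
#' @param seed optional integer seed.
#' @return a pileup data.frame: `locus`, `position`, `ref`, `A`, `C`, `G`,
#'   `T`, `ins`, `del`, `depth`.
#' @export
simulate_amplicon_pileup <- function(model, locus, age_group = c("young", "old"),
                                     depth = 1e4, error_floor = 5e-4,
                                     seed = NULL) {
  stopifnot(inherits(model, "rdna_unit_model"))
  age_group <- match.arg(age_group)
  if (!locus %in% names(model$locus_lengths)) {
    stop(sprintf("unknown locus '%s'", locus), call. = FALSE)
  }
  check_positive(depth, "depth")
  check_in_range(error_floor, 0, 0.25, "error_floor")
  n <- model$locus_lengths[[locus]]
  ref <- model$reference[[locus]]
  v <- model$variants[model$variants$locus == locus, ]
  f <- numeric(n)
  alt <- rep(NA_character_, n)
  if (nrow(v)) {
    f[v$position] <- if (age_group == "young") v$freq_young else v$freq_old
    alt[v$position] <- v$alt
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    n_var <- stats::rbinom(n, depth, f)
    n_err <- stats::rbinom(n, depth - n_var, error_floor)
    # split errors over the three non-reference bases without a per-site loop
    e1 <- stats::rbinom(n, n_err, 1 / 3)
    e2 <- stats::rbinom(n, n_err - e1, 1 / 2)
    e3 <- n_err - e1 - e2
    counts <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, bases))
    ref_idx <- match(ref, bases)
    err <- cbind(e1, e2, e3)
    for (b in 1:4) {
      rows <- which(ref_idx == b)
      counts[rows, b] <- depth - n_var[rows] - n_err[rows]
      others <- setdiff(1:4, b)
      for (j in 1:3) counts[rows, others[j]] <- err[rows, j]
    }
    has_var <- which(n_var > 0)
    for (i in has_var) {
      counts[i, alt[i]] <- counts[i, alt[i]] + n_var[i]
    }
    data.frame(locus = locus, position = seq_len(n), ref = ref,
               A = counts[, "A"], C = counts[, "C"],
               G = counts[, "G"], T = counts[, "T"],
               ins = 0L, del = 0L, depth = as.integer(depth),
               stringsAsFactors = FALSE)
  })
}

#' Simulate whole-genome sequencing read counts for the rDNA array
#'
#' The rDNA read count is `Binomial(total_reads, p)` with
#' `p = copies * unit_length / (non_rdna_genome_length + copies * unit_length)`
#' -- the fraction of the (rDNA-inclusive) genome occupied by the array.
#'
#' @param copies_per_cell rDNA copies per cell (>= 0).
#' @param unit_length rDNA unit length in bp.
#' @param non_rdna_genome_length bp of genome outside the rDNA array.
#' @param total_reads total mapped reads.
#' @param seed optional integer seed.
#' @return list with `rdna_reads` and `total_mapped_reads`.
#' @export
simulate_wgs_readcounts <- function(copies_per_cell, unit_length,
                                    non_rdna_genome_length, total_reads,
                                    seed = NULL) {
  check_positive(copies_per_cell, "copies_per_cell", strict = FALSE)
  check_positive(unit_length, "unit_length")
  check_positive(non_rdna_genome_length, "non_rdna_genome_length")
  check_positive(total_reads, "total_reads")
  rdna_bp <- copies_per_cell * unit_length
  p <- rdna_bp / (non_rdna_genome_length + rdna_bp)
  rdna_reads <- with_seed(seed, stats::rbinom(1, total_reads, p))
  list(rdna_reads = rdna_reads, total_mapped_reads = as.integer(total_reads))
}

#' Write a cohort table as TSV
#' @param cohort data.frame from [generate_cohort()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) write_tsv(cohort, path)

#' Write a pileup table as TSV
#' @param pileup data.frame from [simulate_amplicon_pileup()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pileup <- function(pileup, path) write_tsv(pileup, path)

#' Write a cohort configuration as YAML
#' @param config a [cohort_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a cohort configuration from YAML
#' @param path YAML file written by [write_cohort_config()].
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}
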