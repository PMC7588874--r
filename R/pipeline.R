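#' Default pipeline configuration
#'
#' Nested list of everything [run_pipeline()] needs: the per-strain cohort
#' configurations, the amplicon sequencing settings, the qPCR standard
#' curve used for single-cell simulation, and the WGS constants (mouse
#' non-rDNA genome length and rDNA unit length).
#'
#' @param seed integer root seed; every stochastic stage derives its own
#'   substream from it.
#' @return a nested configuration list.
#' @export
default_pipeline_config <- function(seed = 20200368) {
  list(
    seed = as.integer(seed),
    strains = default_strain_configs(seed = seed),
    samples_per_group = 2,          # sequenced mice per age group
    qpcr = list(slope = -1 / log10(2), intercept = 38, noise_sd = 0.1),
    wgs = list(unit_length = 43000, non_rdna_genome_length = 5.3e9,
               total_reads = 1e6),
    bamhi_site_positions = c(5052L, 5053L, 5054L),
    hotspot_window = 20L,
    real_mode = NULL)
}

#' Load a pipeline configuration
#'
#' @param config `NULL` (defaults), a YAML file path, or a ready list.
#' @param seed optional seed overriding the config's.
#' @return configuration list.
#' @export
load_pipeline_config <- function(config = NULL, seed = NULL) {
  if (is.null(config)) {
    cfg <- default_pipeline_config(seed = if (is.null(seed)) 20200368 else seed)
  } else if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    raw <- yaml::read_yaml(config)
    cfg <- utils::modifyList(default_pipeline_config(), raw)
    cfg$strains <- lapply(cfg$strains, function(s) {
      if (inherits(s, "cohort_config")) s else do.call(cohort_config, s)
    })
  } else {
    cfg <- utils::modifyList(default_pipeline_config(), config)
  }
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg$strains <- lapply(cfg$strains, function(s) {
      s$seed <- as.integer(seed); s
    })
  }
  cfg
}

#' Classical two-sample t test
#'
#' Two-sided Student t test, equal-variance by default (Welch behind the
#' flag). Degenerate input (fewer than two values in a group) is an error;
#' two identical zero-variance groups return `t = 0`, `p = 1`.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param var_equal pool the variances (classical Student) or not (Welch).
#' @return list with `t`, `p`, `df`.
#' @export
two_sided_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
    }
    stop("both groups are constant with different means; t undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Format age-differential calls for reporting
#'
#' Reporting rule for the age-differential call table: per-sample rates and
#' group means are rounded half-up at 3 decimals, while the difference is
#' the full-precision `old_mean - young_mean` rounded with the statistical
#' round-half-even convention ([base::round()]). The mixed rule is
#' deliberate: group means of two 3-decimal rates land on exact halves,
#' which reporting resolves upward (0.4185 prints as 0.419), whereas
#' differences print under round-half-even (0.0345 prints as 0.034, and
#' 0.418 and -0.029 are unaffected). The full-precision difference remains
#' in the unformatted calls.
#'
#' @param calls data.frame from [call_age_differential_sites()].
#' @param digits decimals (default 3).
#' @return the calls with reporting-rounded rate columns and difference.
#' @export
report_age_calls <- function(calls, digits = 3) {
  out <- calls
  rate_cols <- grep("^(young|old)_", names(out), value = TRUE)
  rate_cols <- setdiff(rate_cols, c("young_mean", "old_mean"))
  for (cc in rate_cols) out[[cc]] <- round_half_up(out[[cc]], digits)
  out$young_mean <- round_half_up(calls$young_mean, digits)
  out$old_mean <- round_half_up(calls$old_mean, digits)
  out$difference <- round(calls$old_mean - calls$young_mean, digits)
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate (or load) cohorts for both strains, compute per-mouse
#' copy-number statistics, amplicon mutation-rate tracks with the
#' control-gene threshold and age-differential calls, the BamHI-site
#' variant summary, 20-bp hot-spot window sums, and the Southern-derived
#' ratio panels (relative copy number, SacII methylation, psoralen
#' active/inactive), then write the report tables and a manifest. All
#' randomness derives from the config seed, so a fixed seed reproduces
#' byte-identical outputs.
#'
#' @param config `NULL`, YAML path, or list (see [load_pipeline_config()]).
#' @param out_dir output directory (created).
#' @param seed optional seed override.
#' @return invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = "results", seed = NULL) {
  cfg <- load_pipeline_config(config, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("stage: cohorts")
  cohorts <- lapply(cfg$strains, function(sc) {
    if (!is.null(cfg$real_mode$cohort_tsv)) {
      path <- cfg$real_mode$cohort_tsv
      if (!file.exists(path)) {
        stop(sprintf("real-mode input not found: %s", path), call. = FALSE)
      }
      read_tsv(path)
    } else {
      generate_cohort(sc)
    }
  })
  cohort_all <- do.call(rbind, cohorts)

  message("stage: copy number")
  stats_by_strain <- lapply(cohorts, cohort_stats)
  stats_tbl <- do.call(rbind, Map(function(s, nm) {
    cbind(strain = nm, s)
  }, stats_by_strain, names(stats_by_strain)))
  rownames(stats_tbl) <- NULL

  message("stage: mutation calling")
  mut <- lapply(names(cfg$strains), function(strain) {
    sc <- cfg$strains[[strain]]
    unit <- default_unit_model(strain = strain)
    mk_tracks <- function(locus, age) {
      lapply(seq_len(cfg$samples_per_group), function(i) {
        sid <- sprintf("%s%d", substr(age, 1, 1), i)
        pu <- simulate_amplicon_pileup(
          unit, locus, age, depth = sc$depth, error_floor = sc$error_floor,
          seed = substream_seed(cfg$seed,
                                paste("pileup", strain, locus, age, i,
                                      sep = "/")))
        mutation_rate_track(pu, sample_id = sid, age_group = age)
      })
    }
    young28 <- mk_tracks("28S", "young")
    old28 <- mk_tracks("28S", "old")
    ctrl <- c(mk_tracks("ATP5b", "young"), mk_tracks("ATP5b", "old"))
    thr <- control_gene_threshold(ctrl)
    calls <- call_age_differential_sites(young28, old28, thr)
    site <- restriction_site_variant_summary(c(young28, old28),
                                             cfg$bamhi_site_positions)
    hot <- hotspot_window_sums(old28, thr, width = cfg$hotspot_window)
    list(strain = strain, unit = unit, threshold = thr, calls = calls,
         site_summary = site, hotspots = hot,
         tracks = list(young = young28, old = old28, control = ctrl))
  })
  names(mut) <- names(cfg$strains)

  message("stage: digest ratios")
  ratios <- do.call(rbind, lapply(names(cohorts), function(strain) {
    co <- cohorts[[strain]]
    unit <- default_unit_model(strain = strain)
    by_mouse <- split(co, co$mouse_id)
    do.call(rbind, lapply(by_mouse, function(cells) {
      meth <- sacii_methylation_assay(cells, unit, lane = cells$mouse_id[1])
      data.frame(strain = strain,
                 mouse_id = cells$mouse_id[1],
                 age_group = cells$age_group[1],
                 methylation_ratio = meth$pooled_ratio,
                 active_inactive_ratio = psoralen_ratio_cells(cells),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(ratios) <- NULL
  southern <- do.call(rbind, lapply(names(cohorts), function(strain) {
    co <- cohorts[[strain]]
    unit <- default_unit_model(strain = strain)
    lanes <- lapply(split(co, co$mouse_id), function(cells) {
      band_profile(cells, unit, c("BamHI", "NdeI"), lane = cells$mouse_id[1])
    })
    young_ids <- unique(co$mouse_id[co$age_group == "young"])
    cbind(strain = strain,
          relative_copy_number_southern(lanes, young_ids))
  }))
  rownames(southern) <- NULL

  results <- list(config = cfg, cohorts = cohorts, stats = stats_tbl,
                  mutations = mut, ratios = ratios, southern = southern)
  files <- write_report_tables(results, out_dir)
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("rDNAge")),
    strains = names(cfg$strains),
    thresholds = lapply(mut, function(m) m$threshold),
    files = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}

#' Write the pipeline report tables
#'
#' Emits `copy_number_stats.tsv` (per-mouse mean/SD/CV), `age_calls.tsv`
#' (age-differential sites with half-up 3 d.p. rounding; the printed
#' difference is the difference of the rounded group means),
#' `site_summary.tsv` (per-sample BamHI-site rate sums and group
#' averages), `hotspots.bedgraph` (20-bp window sums, BALB/cA-like
#' strain), and `ratios.tsv` (methylation and active/inactive ratios plus
#' Southern relative values).
#'
#' @param results list produced inside [run_pipeline()].
#' @param out_dir output directory.
#' @return character vector of files written.
#' @export
write_report_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(out_dir, "copy_number_stats.tsv")
  stats_tbl <- results$stats
  stats_tbl$mean_copies <- round_half_up(stats_tbl$mean_copies, 1)
  stats_tbl$sd_copies <- round_half_up(stats_tbl$sd_copies, 1)
  stats_tbl$cv <- round_half_up(stats_tbl$cv, 3)
  write_tsv(stats_tbl, f1)

  f2 <- file.path(out_dir, "age_calls.tsv")
  calls <- do.call(rbind, lapply(results$mutations, function(m) {
    fc <- report_age_calls(m$calls)
    if (nrow(fc) == 0) return(NULL)
    cbind(strain = m$strain, fc)
  }))
  if (is.null(calls)) {
    # header-only file when nothing is called
    calls <- data.frame(strain = character(), position = integer(),
                        young_mean = numeric(), old_mean = numeric(),
                        difference = numeric(), passes = logical(),
                        yeast_position = integer())
  }
  write_tsv(calls, f2)

  f3 <- file.path(out_dir, "site_summary.tsv")
  site <- do.call(rbind, lapply(results$mutations, function(m) {
    ps <- m$site_summary$per_sample
    ga <- m$site_summary$group_average
    ps$group_avg <- round_half_up(
      ga$avg_rate_sum[match(ps$age_group, ga$age_group)], 3)
    ps$rate_sum <- round_half_up(ps$rate_sum, 3)
    cbind(strain = m$strain, ps)
  }))
  rownames(site) <- NULL
  write_tsv(site, f3)

  f4 <- file.path(out_dir, "hotspots.bedgraph")
  write_bedgraph(results$mutations[[1]]$hotspots, f4, locus = "28S")

  f5 <- file.path(out_dir, "ratios.tsv")
  rt <- results$ratios
  rt$methylation_ratio <- round_half_up(rt$methylation_ratio, 4)
  rt$active_inactive_ratio <- round_half_up(rt$active_inactive_ratio, 4)
  write_tsv(rt, f5)

  f6 <- file.path(out_dir, "southern_relative.tsv")
  sv <- results$southern
  sv$relative_value <- round_half_up(sv$relative_value, 4)
  write_tsv(sv, f6)

  c(f1, f2, f3, f4, f5, f6)
}
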