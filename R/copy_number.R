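#' Droplet digital PCR partition counts
#'
#' @param n_total droplets read (> 0).
#' @param n_positive droplets containing >= 1 template (in `[0, n_total]`).
#' @return a `droplet_counts` object.
#' @export
droplet_counts <- function(n_total, n_positive) {
  check_positive(n_total, "n_total")
  if (n_positive < 0 || n_positive > n_total) {
    stop("field 'n_positive' must be in [0, n_total]", call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total),
                 n_positive = as.integer(n_positive)),
            class = "droplet_counts")
}

#' Poisson inversion of ddPCR partition counts
#'
#' With templates distributed over droplets at random, the positive fraction
#' `q = n_positive / n_total` estimates `1 - exp(-lambda)`, so the mean
#' copies per droplet is `lambda = -log(1 - q)`. A 95% confidence interval
#' is propagated from the binomial standard error of `q` through the same
#' transform.
#'
#' @param counts a [droplet_counts()].
#' @return list with `lambda`, `ci_lower`, `ci_upper`, and `total_copies`
#'   (`lambda * n_total`).
#' @export
ddpcr_lambda <- function(counts) {
  stopifnot(inherits(counts, "droplet_counts"))
  if (counts$n_positive == counts$n_total) {
    stop("saturated assay: every droplet positive, lambda undefined",
         call. = FALSE)
  }
  q <- counts$n_positive / counts$n_total
  se <- sqrt(q * (1 - q) / counts$n_total)
  lam <- -log(1 - q)
  bounds <- -log(1 - pmin(pmax(q + c(-1.96, 1.96) * se, 0), 1 - 1e-12))
  list(lambda = lam,
       ci_lower = bounds[1], ci_upper = bounds[2],
       total_copies = lam * counts$n_total)
}

#' Copies per cell from a duplex ddPCR assay
#'
#' The target concentration is referenced to a single-copy duplex reference
#' (RNase P, at a known diploid copy number):
#' `copies = reference_copies_per_cell * lambda_target / lambda_reference`.
#'
#' @param target [droplet_counts()] for the rDNA target channel.
#' @param reference [droplet_counts()] for the reference channel.
#' @param reference_copies_per_cell copies of the reference per cell
#'   (default 2, diploid single-copy gene).
#' @return copies per cell (numeric; round at report time).
#' @export
ddpcr_copies_per_cell <- function(target, reference,
                                  reference_copies_per_cell = 2) {
  lam_t <- ddpcr_lambda(target)$lambda
  lam_r <- ddpcr_lambda(reference)$lambda
  if (lam_r == 0) {
    stop("no reference signal: reference lambda is 0", call. = FALSE)
  }
  reference_copies_per_cell * lam_t / lam_r
}

#' qPCR standard curve
#'
#' A calibration line `Cq = intercept + slope * log10(copies)`; the
#' amplification efficiency is `E = 10^(-1/slope)` (E = 2 for perfect
#' doubling, slope about -3.32).
#'
#' @param slope cycles per log10(copies), must be < 0.
#' @param intercept cycles at 1 copy.
#' @param r_squared fit R^2 (optional).
#' @return a `standard_curve` object with derived `efficiency`.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.finite(slope) || slope >= 0) {
    stop("field 'slope' must be < 0", call. = FALSE)
  }
  eff <- 10^(-1 / slope)
  if (eff <= 1 || eff > 2.2) {
    stop(sprintf("implied efficiency %.3f outside (1, 2.2]", eff),
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 efficiency = eff, r_squared = r_squared),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Cq = %.3f %+.3f log10(copies); E = %.3f%s\n",
              x$intercept, x$slope, x$efficiency,
              if (is.na(x$r_squared)) "" else sprintf(", r2 = %.4f", x$r_squared)))
  invisible(x)
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Ordinary least squares of Cq on log10(copies).
#'
#' @param points data.frame (or list of pairs) with columns `copies` and
#'   `cq`; at least 3 points spanning at least 2 log10 units.
#' @return a [standard_curve()].
#' @export
fit_standard_curve <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("copies", "cq") %in% names(points)))
  if (nrow(points) < 3) {
    stop("need >= 3 dilution points to fit a standard curve", call. = FALSE)
  }
  lx <- log10(points$copies)
  if (diff(range(lx)) < 2) {
    stop("dilution series must span >= 2 log10 units of copies",
         call. = FALSE)
  }
  fit <- stats::lm(cq ~ lx, data = data.frame(cq = points$cq, lx = lx))
  standard_curve(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared)
}

#' Copy number of a single cell from its Cq
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept) / slope)`.
#' The no-amplification sentinel (`NA` Cq) is reported as 0 copies with a
#' `no_amplification` flag.
#'
#' @param cq Cq value(s); `NA` = no amplification.
#' @param curve a [standard_curve()].
#' @return data.frame with `cq`, `copies`, `no_amplification`.
#' @export
qpcr_copies_single_cell <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((cq - curve$intercept) / curve$slope)
  flag <- is.na(cq)
  copies[flag] <- 0
  data.frame(cq = cq, copies = copies, no_amplification = flag)
}

#' Per-mouse copy-number statistics
#'
#' Per mouse: number of cells, mean copies, sample SD (n - 1 denominator)
#' and CV = SD / mean. Mice with a single cell get `NA` SD and CV, never
#' zero. Per-group grand means (over per-mouse means) are attached as the
#' `"group_means"` attribute and also returned by [cohort_group_means()].
#'
#' @param cohort data.frame with at least `mouse_id`, `age_group`,
#'   `copy_number` (e.g. from [generate_cohort()]).
#' @return data.frame with one row per mouse: `mouse_id`, `age_group`,
#'   `n_cells`, `mean_copies`, `sd_copies`, `cv`.
#' @export
cohort_stats <- function(cohort) {
  stopifnot(all(c("mouse_id", "age_group", "copy_number") %in% names(cohort)))
  by_mouse <- split(cohort, cohort$mouse_id)
  out <- do.call(rbind, lapply(by_mouse, function(d) {
    m <- mean(d$copy_number)
    s <- if (nrow(d) >= 2) stats::sd(d$copy_number) else NA_real_
    data.frame(mouse_id = d$mouse_id[1],
               age_group = d$age_group[1],
               n_cells = nrow(d),
               mean_copies = m,
               sd_copies = s,
               cv = s / m,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$age_group, out$mouse_id), ]
  rownames(out) <- NULL
  gm <- tapply(out$mean_copies, out$age_group, mean)
  gcv <- tapply(out$cv, out$age_group, mean, na.rm = TRUE)
  attr(out, "group_means") <- data.frame(
    age_group = names(gm),
    mean_copies = as.numeric(gm),
    mean_cv = as.numeric(gcv[names(gm)]),
    stringsAsFactors = FALSE)
  out
}

#' Per-group grand means of a cohort
#' @param cohort data.frame as for [cohort_stats()].
#' @return data.frame with `age_group`, `mean_copies`, `mean_cv`.
#' @export
cohort_group_means <- function(cohort) {
  attr(cohort_stats(cohort), "group_means")
}

#' Copy number from a whole-genome sequencing read fraction
#'
#' With `f = rdna_reads / total_mapped_reads`:
#' * self-consistent mode (default): the rDNA array contributes its own
#'   mass to the denominator, so
#'   `copies = f * non_rdna_genome_length / ((1 - f) * unit_length)` —
#'   the exact inverse of the generative
#'   `p = C*u / (G + C*u)`;
#' * simple mode: `copies = f * total_genome_length / unit_length`.
#'
#' @param rdna_reads reads mapping to the rDNA unit.
#' @param total_mapped_reads all mapped reads (> 0).
#' @param unit_length rDNA unit length in bp.
#' @param non_rdna_genome_length bp outside the array (self-consistent mode).
#' @param mode `"self_consistent"` or `"simple"`.
#' @param total_genome_length total genome bp (simple mode; defaults to
#'   `non_rdna_genome_length`).
#' @return copies per cell (numeric).
#' @export
wgs_copy_number <- function(rdna_reads, total_mapped_reads,
                            unit_length = 43000,
                            non_rdna_genome_length = 5.3e9,
                            mode = c("self_consistent", "simple"),
                            total_genome_length = non_rdna_genome_length) {
  mode <- match.arg(mode)
  check_positive(total_mapped_reads, "total_mapped_reads")
  if (rdna_reads < 0 || rdna_reads > total_mapped_reads) {
    stop("field 'rdna_reads' must be in [0, total_mapped_reads]",
         call. = FALSE)
  }
  f <- rdna_reads / total_mapped_reads
  if (f >= 1) stop("rDNA read fraction of 1: copy number undefined",
                   call. = FALSE)
  switch(mode,
         self_consistent = f * non_rdna_genome_length / ((1 - f) * unit_length),
         simple = f * total_genome_length / unit_length)
}

#' Read droplet count tables (assay_id, n_total, n_positive)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_droplet_tsv <- function(path) read_tsv(path)

#' Read a Cq table (mouse_id, cell_id, target, cq)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cq_tsv <- function(path) read_tsv(path)

#' Read a WGS read-count summary (sample_id, rdna_reads, total_mapped_reads)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_wgs_tsv <- function(path) read_tsv(path)
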