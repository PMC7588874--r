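#' Mouse 28S to yeast 25S position lookup
#'
#' Static map of the conserved age-differential 28S positions onto the
#' budding-yeast 25S coordinate (A4614 -> A3295, A3291 -> A2131); positions
#' absent from the map (e.g. 3094) are not conserved in yeast.
#'
#' @return named integer vector (names = mouse 28S positions).
#' @export
mouse_to_yeast_25s <- function() {
  c("4614" = 3295L, "3291" = 2131L)
}

#' Read a pileup TSV
#'
#' Expected columns: `position`, `ref`, `A`, `C`, `G`, `T`, `ins`, `del`,
#' `depth` (a `locus` column is carried through when present).
#'
#' @param path TSV path.
#' @return pileup data.frame.
#' @export
read_pileup_tsv <- function(path) {
  p <- read_tsv(path)
  need <- c("position", "ref", "A", "C", "G", "T", "ins", "del", "depth")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("pileup TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p
}

#' Build a pileup from aligned reads
#'
#' Accumulates per-position base, insertion and deletion counts from aligned
#' amplicon reads against a reference. Two encodings are accepted: a
#' position/base TSV (`position`, `ref`, `A`..`T`, `ins`, `del`, `depth`;
#' the synthetic-mode default) or a SAM file, which is converted and piled
#' up through Rsamtools (soft-clipped bases are ignored; an insertion is
#' counted at the position preceding the inserted bases). Positions with no
#' coverage are kept with zero depth so downstream masking is explicit.
#'
#' @param alignments path to a SAM file or a pileup TSV.
#' @param reference path to the reference FASTA (required for SAM input).
#' @param format `"tsv"` or `"sam"`; guessed from the file extension by
#'   default.
#' @param seqname reference sequence (locus) to pile up; defaults to the
#'   first sequence in the FASTA.
#' @return pileup data.frame as from [read_pileup_tsv()].
#' @export
pileup_from_alignments <- function(alignments, reference = NULL,
                                   format = c("auto", "tsv", "sam"),
                                   seqname = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", alignments, ignore.case = TRUE)) "sam"
              else "tsv"
  }
  if (format == "tsv") {
    p <- read_pileup_tsv(alignments)
    if (nrow(p) == 0) warning("empty alignment input: empty pileup")
    return(p)
  }
  pileup_from_sam(alignments, reference, seqname)
}

pileup_from_sam <- function(sam_path, reference, seqname = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("Biostrings", quietly = TRUE)) {
    stop("SAM input requires the Rsamtools and Biostrings packages",
         call. = FALSE)
  }
  if (is.null(reference)) {
    stop("SAM input requires a reference FASTA", call. = FALSE)
  }
  ref_set <- Biostrings::readDNAStringSet(reference)
  if (is.null(seqname)) seqname <- names(ref_set)[1]
  seqname <- sub("\\s.*", "", seqname)
  names(ref_set) <- sub("\\s.*", "", names(ref_set))
  if (!seqname %in% names(ref_set)) {
    stop(sprintf("reference name '%s' not found in FASTA", seqname),
         call. = FALSE)
  }
  ref_chars <- strsplit(as.character(ref_set[[seqname]]), "")[[1]]
  n <- length(ref_chars)
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(),
                          overwrite = TRUE, indexDestination = TRUE)
  param <- Rsamtools::PileupParam(max_depth = 10^6,
                                  min_base_quality = 0L,
                                  min_mapq = 0L,
                                  min_nucleotide_depth = 0L,
                                  distinguish_strands = FALSE,
                                  distinguish_nucleotides = TRUE,
                                  include_deletions = TRUE,
                                  include_insertions = TRUE)
  res <- Rsamtools::pileup(bam, pileupParam = param)
  res <- res[res$seqnames == seqname, , drop = FALSE]
  if (nrow(res) == 0) warning("empty alignment input: empty pileup")
  counts <- matrix(0L, nrow = n, ncol = 6,
                   dimnames = list(NULL, c("A", "C", "G", "T", "ins", "del")))
  key <- c(A = "A", C = "C", G = "G", T = "T", "+" = "ins", "-" = "del")
  nuc <- key[as.character(res$nucleotide)]
  keep <- !is.na(nuc) & res$pos >= 1 & res$pos <= n
  for (i in which(keep)) {
    counts[res$pos[i], nuc[i]] <- counts[res$pos[i], nuc[i]] + res$count[i]
  }
  depth <- rowSums(counts[, c("A", "C", "G", "T", "del"), drop = FALSE])
  data.frame(locus = seqname, position = seq_len(n), ref = ref_chars,
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], ins = counts[, "ins"], del = counts[, "del"],
             depth = as.integer(depth), stringsAsFactors = FALSE)
}

#' Per-position mutation-rate track from a pileup
#'
#' The mutation rate at a position is the fraction of reads differing from
#' the reference: (non-reference base count + insertions + deletions) /
#' depth, pooling substitutions, insertions and deletions into one rate
#' (per-class rates are retained as columns). Positions with zero depth are
#' masked (`NA` rate), never reported as zero.
#'
#' @param pileup pileup data.frame (see [read_pileup_tsv()]).
#' @param sample_id sample label carried on the track.
#' @param age_group `"young"` or `"old"`.
#' @return a track data.frame: `sample_id`, `age_group`, `locus`,
#'   `position`, `rate`, `sub_rate`, `ins_rate`, `del_rate`, `depth`.
#' @export
mutation_rate_track <- function(pileup, sample_id = "sample",
                                age_group = c("young", "old")) {
  age_group <- match.arg(age_group)
  bases <- c("A", "C", "G", "T")
  cm <- as.matrix(pileup[, bases])
  ref_idx <- match(pileup$ref, bases)
  total_bases <- rowSums(cm)
  ref_count <- cm[cbind(seq_len(nrow(cm)), ref_idx)]
  nonref <- total_bases - ref_count
  depth <- pileup$depth
  rate <- pmin((nonref + pileup$ins + pileup$del) / depth, 1)
  rate[depth == 0] <- NA_real_
  data.frame(sample_id = sample_id,
             age_group = age_group,
             locus = if ("locus" %in% names(pileup)) pileup$locus else NA,
             position = pileup$position,
             rate = rate,
             sub_rate = ifelse(depth == 0, NA_real_, nonref / depth),
             ins_rate = ifelse(depth == 0, NA_real_, pileup$ins / depth),
             del_rate = ifelse(depth == 0, NA_real_, pileup$del / depth),
             depth = depth,
             stringsAsFactors = FALSE)
}

#' Artifact threshold from a control gene
#'
#' The screen threshold for age-differential sites is the maximum
#' per-position rate observed anywhere on the single-copy control locus
#' (ATP5b), after excluding fixed differences (rates > `max_rate`): any
#' rate below it is attributable to PCR/sequencing artifacts.
#'
#' @param control_tracks a track data.frame or list of them (control locus).
#' @param max_rate fixed-difference exclusion bound (default 0.9).
#' @return the rate threshold (numeric scalar).
#' @export
control_gene_threshold <- function(control_tracks, max_rate = 0.9) {
  if (is.data.frame(control_tracks)) control_tracks <- list(control_tracks)
  rates <- unlist(lapply(control_tracks, function(t) t$rate))
  rates <- rates[!is.na(rates) & rates <= max_rate]
  if (length(rates) == 0) {
    stop("control locus has no usable positions", call. = FALSE)
  }
  max(rates)
}

#' Call age-differential sites between young and old samples
#'
#' Per position: positions where any sample's rate exceeds `max_rate` are
#' excluded as fixed differences from the reference; group means and their
#' difference (old - young, full precision) are computed; a site passes
#' when `|difference| > threshold` and, optionally, the groups are
#' separated (the minimum rate of the higher-mean group exceeds the maximum
#' of the lower-mean group). Candidate sites (those clearing the
#' `|difference|` screen) are returned sorted by `|difference|` descending,
#' with per-sample rates and the packaged yeast 25S position where the 28S
#' position is conserved.
#'
#' @param young,old lists of track data.frames (>= 2 samples per group by
#'   default; see `min_samples`).
#' @param threshold rate threshold, e.g. from [control_gene_threshold()].
#' @param max_rate fixed-difference exclusion bound (default 0.9).
#' @param require_separation also require group separation for `passes`
#'   (default TRUE).
#' @param min_samples minimum samples per group (default 2).
#' @param yeast_map named vector mapping 28S positions to yeast 25S.
#' @return data.frame: `position`, one `young_<id>`/`old_<id>` column per
#'   sample, `young_mean`, `old_mean`, `difference`, `passes`,
#'   `yeast_position`.
#' @export
call_age_differential_sites <- function(young, old, threshold,
                                        max_rate = 0.9,
                                        require_separation = TRUE,
                                        min_samples = 2,
                                        yeast_map = mouse_to_yeast_25s()) {
  if (is.data.frame(young)) young <- list(young)
  if (is.data.frame(old)) old <- list(old)
  if (length(young) < min_samples || length(old) < min_samples) {
    stop(sprintf("need >= %d samples per group", min_samples), call. = FALSE)
  }
  rate_matrix <- function(tracks) {
    pos <- tracks[[1]]$position
    m <- matrix(unlist(lapply(tracks, function(t) {
      stopifnot(identical(t$position, pos))
      t$rate
    })), nrow = length(pos))
    rownames(m) <- pos
    m
  }
  ym <- rate_matrix(young)
  om <- rate_matrix(old)
  stopifnot(nrow(ym) == nrow(om))
  colnames(ym) <- paste0("young_", vapply(young, function(t)
    t$sample_id[1], character(1)))
  colnames(om) <- paste0("old_", vapply(old, function(t)
    t$sample_id[1], character(1)))
  all_rates <- cbind(ym, om)
  usable <- apply(all_rates, 1, function(r)
    all(!is.na(r)) && all(r <= max_rate))
  young_mean <- rowMeans(ym)
  old_mean <- rowMeans(om)
  difference <- old_mean - young_mean
  separated <- vapply(seq_len(nrow(ym)), function(i) {
    if (old_mean[i] >= young_mean[i]) min(om[i, ]) > max(ym[i, ])
    else min(ym[i, ]) > max(om[i, ])
  }, logical(1))
  candidate <- usable & abs(difference) > threshold
  passes <- candidate & (!require_separation | separated)
  idx <- which(candidate)
  idx <- idx[order(-abs(difference[idx]))]
  pos <- as.integer(rownames(ym))
  out <- data.frame(position = pos[idx],
                    ym[idx, , drop = FALSE],
                    young_mean = young_mean[idx],
                    om[idx, , drop = FALSE],
                    old_mean = old_mean[idx],
                    difference = difference[idx],
                    passes = passes[idx],
                    yeast_position = unname(yeast_map[as.character(pos[idx])]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Sum above-threshold mutation rates in tiling 20-bp windows
#'
#' Non-overlapping windows anchored at position 1; within each window only
#' rates above `threshold` (and at most `max_rate`, excluding fixed
#' differences) contribute to the sum. A final partial window is kept and
#' flagged. A list of tracks (e.g. the two mice of one panel) is merged by
#' adding their window sums.
#'
#' @param track a track data.frame or list of them.
#' @param threshold inclusion threshold (rates must exceed it).
#' @param width window width in bp (default 20).
#' @param max_rate fixed-difference exclusion bound (default 0.9).
#' @return data.frame: `window_start`, `window_end`, `width`, `summed_rate`,
#'   `partial`.
#' @export
hotspot_window_sums <- function(track, threshold, width = 20,
                                max_rate = 0.9) {
  if (width < 1) stop("field 'width' must be >= 1", call. = FALSE)
  if (!is.data.frame(track)) {
    parts <- lapply(track, hotspot_window_sums, threshold = threshold,
                    width = width, max_rate = max_rate)
    out <- parts[[1]]
    for (p in parts[-1]) {
      stopifnot(identical(p$window_start, out$window_start))
      out$summed_rate <- out$summed_rate + p$summed_rate
    }
    return(out)
  }
  n <- max(track$position)
  r <- rep(0, n)
  ok <- !is.na(track$rate) & track$rate > threshold & track$rate <= max_rate
  r[track$position[ok]] <- track$rate[ok]
  starts <- seq(1L, n, by = width)
  ends <- pmin(starts + width - 1L, n)
  sums <- vapply(seq_along(starts), function(i)
    sum(r[starts[i]:ends[i]]), numeric(1))
  data.frame(window_start = starts, window_end = ends,
             width = ends - starts + 1L,
             summed_rate = sums,
             partial = (ends - starts + 1L) < width)
}

#' Summed variant rates over a restriction site
#'
#' For each sample, sums the per-position mutation rates over the given
#' site positions (e.g. the three mutated bases of the polymorphic BamHI
#' recognition sequence at 28S 5052--5054); per group, averages these sums.
#'
#' @param tracks list of track data.frames (each with `sample_id` and
#'   `age_group`).
#' @param site_positions 1-based positions of the site on the track's locus.
#' @return list with `per_sample` (sample_id, age_group, rate_sum) and
#'   `group_average` (age_group, avg_rate_sum).
#' @export
restriction_site_variant_summary <- function(tracks, site_positions) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  per_sample <- do.call(rbind, lapply(tracks, function(t) {
    hit <- match(site_positions, t$position)
    if (anyNA(hit)) {
      stop("site position(s) missing from track: ",
           paste(site_positions[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    data.frame(sample_id = t$sample_id[1],
               age_group = t$age_group[1],
               rate_sum = sum(t$rate[hit]),
               stringsAsFactors = FALSE)
  }))
  avg <- tapply(per_sample$rate_sum, per_sample$age_group, mean)
  list(per_sample = per_sample,
       group_average = data.frame(age_group = names(avg),
                                  avg_rate_sum = as.numeric(avg),
                                  stringsAsFactors = FALSE))
}

#' Write window sums as BedGraph (locus-local coordinates)
#'
#' @param windows data.frame from [hotspot_window_sums()].
#' @param path output path.
#' @param locus track name used in the BedGraph line.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(windows, path, locus = "28S") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s window sums\"", locus),
             con)
  # BedGraph is 0-based half-open
  writeLines(sprintf("%s\t%d\t%d\t%g", locus,
                     windows$window_start - 1L, windows$window_end,
                     windows$summed_rate), con)
  invisible(path)
}
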