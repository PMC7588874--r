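#' rDNA repeat-unit model
#'
#' One rDNA repeat unit (~43 kb in mouse: the 45S pre-rRNA gene plus the
#' intergenic spacer) is described by its length, its restriction-site
#' coordinates, the Southern-probe interval, an optional polymorphic internal
#' BamHI site ("BamHI-2") carried by a subset of copies, and a table of
#' per-copy sequence variants on the amplicon loci (18S, 5.8S, 28S, and the
#' ATP5b control) with their population frequencies in young and old animals.
#'
#' Coordinates are 1-based. A restriction site at position `p` cuts between
#' `p - 1` and `p`, so fragments are maximal runs `[cut_i, cut_{i+1} - 1]`.
#'
#' @param unit_length unit length in bp (integer > 0).
#' @param sites data.frame with columns `enzyme`, `label`, `position`
#'   (1-based bp), `methylation_sensitive` (logical).
#' @param bamhi2_position 1-based bp of the polymorphic BamHI-2 site, or
#'   `NULL` if the model carries none.
#' @param probe_interval closed 1-based interval `c(start, end)` of the
#'   Southern probe.
#' @param variants data.frame with columns `locus`, `position` (1-based on
#'   the locus-local coordinate), `ref`, `alt`, `freq_young`, `freq_old`.
#' @param locus_lengths named integer vector of amplicon locus lengths.
#' @return an object of class `rdna_unit_model`.
#' @seealso [default_unit_model()], [digest_unit()]
#' @export
build_unit_model <- function(unit_length, sites, bamhi2_position = NULL,
                             probe_interval, variants = NULL,
                             locus_lengths = default_locus_lengths()) {
  check_positive(unit_length, "unit_length")
  stopifnot(is.data.frame(sites),
            all(c("enzyme", "label", "position", "methylation_sensitive")
                %in% names(sites)))
  check_in_range(sites$position, 1, unit_length, "sites$position")
  if (!is.null(bamhi2_position)) {
    check_in_range(bamhi2_position, 1, unit_length, "bamhi2_position")
  }
  if (length(probe_interval) != 2) {
    stop("field 'probe_interval' must be c(start, end)", call. = FALSE)
  }
  if (probe_interval[1] > probe_interval[2]) {
    stop("field 'probe_interval' has start > end", call. = FALSE)
  }
  check_in_range(probe_interval, 1, unit_length, "probe_interval")
  if (!is.null(variants)) {
    stopifnot(is.data.frame(variants),
              all(c("locus", "position", "ref", "alt",
                    "freq_young", "freq_old") %in% names(variants)))
    check_in_range(variants$freq_young, 0, 1, "variants$freq_young")
    check_in_range(variants$freq_old, 0, 1, "variants$freq_old")
    for (loc in unique(variants$locus)) {
      if (!loc %in% names(locus_lengths)) {
        stop(sprintf("field 'variants$locus' has unknown locus '%s'", loc),
             call. = FALSE)
      }
      check_in_range(variants$position[variants$locus == loc],
                     1, locus_lengths[[loc]],
                     sprintf("variants$position (locus %s)", loc))
    }
  } else {
    variants <- data.frame(locus = character(), position = integer(),
                           ref = character(), alt = character(),
                           freq_young = numeric(), freq_old = numeric())
  }
  model <- structure(
    list(unit_length = as.integer(unit_length),
         sites = sites,
         bamhi2_position = if (is.null(bamhi2_position)) NULL
                           else as.integer(bamhi2_position),
         probe_interval = as.integer(probe_interval),
         variants = variants,
         locus_lengths = locus_lengths),
    class = "rdna_unit_model")
  model$reference <- build_reference_sequences(model)
  model
}

#' Default amplicon locus lengths (bp)
#'
#' Local coordinate lengths for the sequenced amplicons: 18S, 5.8S, 28S
#' (sized to carry the full 28S-local coordinate range of the variant table)
#' and the single-copy ATP5b control amplicon.
#'
#' @return named integer vector.
#' @export
default_locus_lengths <- function() {
  c("18S" = 1870L, "5.8S" = 157L, "28S" = 5100L, "ATP5b" = 400L)
}

#' Default rDNA unit fixture
#'
#' Geometry chosen so that the probe-detected BamHI--NdeI fragment is
#' 4,000 bp for copies without the BamHI-2 site and 2,400 bp for copies
#' carrying it, with one methylation-sensitive SacII site inside the probe
#' fragment (unmethylated copies digest away from the 4.0/2.4 kb bands).
#' The BALB/cA-like variant table carries the known age-differential 28S
#' sites (4614 and 3291, old-high; 3094, young-high) and the three mutated
#' bases of the polymorphic BamHI recognition sequence at 28S 5050--5055
#' (GGATCC -> GGGGTC), with frequencies matching the group means used as
#' simulation truth. The C57BL/6-like table has no age-differential sites
#' (none were found in that strain) and its own BamHI-site frequencies.
#'
#' @param with_bamhi2 include the polymorphic BamHI-2 coordinate in the
#'   model (per-copy presence is still decided by the cohort's
#'   `bamhi2_fraction`).
#' @param strain which strain's variant frequencies to install.
#' @return an `rdna_unit_model`.
#' @export
default_unit_model <- function(with_bamhi2 = TRUE,
                               strain = c("BALB/cA", "C57BL/6")) {
  strain <- match.arg(strain)
  sites <- data.frame(
    enzyme = c("BamHI", "NdeI", "SacII"),
    label = c("BamHI-1", "NdeI-1", "SacII-1"),
    position = c(1001L, 5001L, 2501L),
    methylation_sensitive = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  variants <- if (strain == "BALB/cA") {
    data.frame(
      locus = rep("28S", 6),
      position = c(4614L, 3291L, 3094L, 5052L, 5053L, 5054L),
      ref = c("A", "A", "C", "A", "T", "C"),
      alt = c("G", "G", "T", "G", "G", "T"),
      freq_young = c(0.001, 0.001, 0.037, 0.25, 0.00, 0.00),
      freq_old   = c(0.419, 0.035, 0.008, 0.335, 0.175, 0.175),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      locus = rep("28S", 3),
      position = c(5052L, 5053L, 5054L),
      ref = c("A", "T", "C"),
      alt = c("G", "G", "T"),
      freq_young = c(0.235, 0.100, 0.095),
      freq_old   = c(0.210, 0.085, 0.085),
      stringsAsFactors = FALSE)
  }
  build_unit_model(unit_length = 43000L,
                   sites = sites,
                   bamhi2_position = if (with_bamhi2) 3401L else NULL,
                   probe_interval = c(2000L, 2200L),
                   variants = variants)
}

# deterministic synthetic reference base per locus position; variant ref
# bases (and the GGATCC BamHI motif on 28S) are imposed afterwards so the
# sequence realizes the model's coordinates
build_reference_sequences <- function(model) {
  refs <- lapply(names(model$locus_lengths), function(loc) {
    n <- model$locus_lengths[[loc]]
    bases <- with_seed(substream_seed(7919L, paste0("reference/", loc)),
                       sample(c("A", "C", "G", "T"), n, replace = TRUE))
    v <- model$variants[model$variants$locus == loc, ]
    if (nrow(v)) bases[v$position] <- v$ref
    bases
  })
  names(refs) <- names(model$locus_lengths)
  if ("28S" %in% names(refs) && model$locus_lengths[["28S"]] >= 5055) {
    motif <- c("G", "G", "A", "T", "C", "C")
    idx <- 5050:5055
    v28 <- model$variants[model$variants$locus == "28S", ]
    planted <- intersect(idx, v28$position)
    keep <- setdiff(idx, planted)   # don't overwrite declared variant refs
    refs[["28S"]][keep] <- motif[match(keep, idx)]
  }
  refs
}

#' @export
print.rdna_unit_model <- function(x, ...) {
  cat(sprintf("rDNA unit model: %d bp, %d fixed site(s)%s, probe [%d, %d]\n",
              x$unit_length, nrow(x$sites),
              if (is.null(x$bamhi2_position)) ""
              else sprintf(" + polymorphic BamHI-2 @%d", x$bamhi2_position),
              x$probe_interval[1], x$probe_interval[2]))
  cat(sprintf("  %d variant(s) across loci: %s\n", nrow(x$variants),
              paste(names(x$locus_lengths), collapse = ", ")))
  invisible(x)
}

#' Write a unit model to disk
#'
#' Writes the synthetic amplicon reference sequences as FASTA (one record
#' per locus), a full-length unit sequence with the restriction motifs
#' planted at their coordinates, and the site/variant tables as TSV.
#'
#' @param model an `rdna_unit_model`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_unit_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "amplicon_reference.fasta")
  seqs <- vapply(model$reference, paste, character(1), collapse = "")
  write_fasta(seqs, fa)
  unit_fa <- file.path(dir, "unit_sequence.fasta")
  write_fasta(c(rDNA_unit = unit_sequence(model)), unit_fa)
  sites_tsv <- file.path(dir, "sites.tsv")
  write_tsv(model$sites, sites_tsv)
  var_tsv <- file.path(dir, "variants.tsv")
  write_tsv(model$variants, var_tsv)
  invisible(c(fa, unit_fa, sites_tsv, var_tsv))
}

# recognition motifs for the enzymes the model knows about
enzyme_motifs <- c(BamHI = "GGATCC", NdeI = "CATATG", SacII = "CCGCGG")

unit_sequence <- function(model) {
  bases <- with_seed(substream_seed(7919L, "reference/unit"),
                     sample(c("A", "C", "G", "T"), model$unit_length,
                            replace = TRUE))
  plant <- function(bases, pos, motif) {
    idx <- pos:(pos + nchar(motif) - 1)
    idx <- idx[idx <= length(bases)]
    bases[idx] <- strsplit(motif, "")[[1]][seq_along(idx)]
    bases
  }
  for (i in seq_len(nrow(model$sites))) {
    bases <- plant(bases, model$sites$position[i],
                   enzyme_motifs[[model$sites$enzyme[i]]])
  }
  if (!is.null(model$bamhi2_position)) {
    bases <- plant(bases, model$bamhi2_position, enzyme_motifs[["BamHI"]])
  }
  paste(bases, collapse = "")
}

# FASTA writing goes through Biostrings when installed; the fallback is the
# plain two-line record format
write_fasta <- function(seqs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names(seqs)
    Biostrings::writeXStringSet(x, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
      writeLines(c(paste0(">", nm), seqs[[nm]]), con)
    }
  }
  invisible(path)
}
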