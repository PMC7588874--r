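# Shared in-code fixtures: hand-built tracks, pileups, and a tiny SAM/FASTA
# pair used by the dual-reader equivalence test.

# a mutation-rate track with explicit per-position rates
make_track <- function(rates, sample_id = "s", age_group = "young",
                       positions = seq_along(rates), depth = 10000) {
  data.frame(sample_id = sample_id, age_group = age_group, locus = "28S",
             position = positions, rate = rates,
             sub_rate = rates, ins_rate = 0, del_rate = 0,
             depth = depth, stringsAsFactors = FALSE)
}

# a pileup with the given reference and non-reference counts
make_pileup <- function(ref, nonref = rep(0L, length(ref)),
                        depth = rep(10L, length(ref)),
                        ins = rep(0L, length(ref)),
                        del = rep(0L, length(ref)),
                        alt = "G") {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = length(ref), ncol = 4,
                   dimnames = list(NULL, bases))
  for (i in seq_along(ref)) {
    counts[i, ref[i]] <- depth[i] - nonref[i] - del[i]
    if (nonref[i] > 0) {
      a <- if (alt == ref[i]) setdiff(bases, ref[i])[1] else alt
      counts[i, a] <- nonref[i]
    }
  }
  data.frame(locus = "28S", position = seq_along(ref), ref = ref,
             A = counts[, "A"], C = counts[, "C"],
             G = counts[, "G"], T = counts[, "T"],
             ins = ins, del = del, depth = depth,
             stringsAsFactors = FALSE)
}

# single-variant unit model used by the recovery tests
single_variant_model <- function(freq_young = 0.001, freq_old = 0.42,
                                 position = 4614L) {
  build_unit_model(
    unit_length = 43000L,
    sites = data.frame(enzyme = c("BamHI", "NdeI", "SacII"),
                       label = c("BamHI-1", "NdeI-1", "SacII-1"),
                       position = c(1001L, 5001L, 2501L),
                       methylation_sensitive = c(FALSE, FALSE, TRUE),
                       stringsAsFactors = FALSE),
    bamhi2_position = 3401L,
    probe_interval = c(2000L, 2200L),
    variants = data.frame(locus = "28S", position = position,
                          ref = "A", alt = "G",
                          freq_young = freq_young, freq_old = freq_old,
                          stringsAsFactors = FALSE))
}

variant_free_model <- function() {
  build_unit_model(
    unit_length = 43000L,
    sites = data.frame(enzyme = c("BamHI", "NdeI", "SacII"),
                       label = c("BamHI-1", "NdeI-1", "SacII-1"),
                       position = c(1001L, 5001L, 2501L),
                       methylation_sensitive = c(FALSE, FALSE, TRUE),
                       stringsAsFactors = FALSE),
    bamhi2_position = 3401L,
    probe_interval = c(2000L, 2200L))
}

# write a 20-bp reference FASTA and a matching SAM with 3 reference reads
# and 1 read carrying an A->G substitution at position 5
write_sam_fixture <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  refseq <- "ACGTACGTACGTACGTACGT"
  fa <- file.path(dir, "amp.fasta")
  writeLines(c(">amp", refseq), fa)
  mut <- refseq
  substr(mut, 5, 5) <- "G"
  qual <- strrep("I", 20)
  sam <- file.path(dir, "reads.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:amp\tLN:20",
    sprintf("r1\t0\tamp\t1\t60\t20M\t*\t0\t0\t%s\t%s", refseq, qual),
    sprintf("r2\t0\tamp\t1\t60\t20M\t*\t0\t0\t%s\t%s", refseq, qual),
    sprintf("r3\t0\tamp\t1\t60\t20M\t*\t0\t0\t%s\t%s", refseq, qual),
    sprintf("r4\t0\tamp\t1\t60\t20M\t*\t0\t0\t%s\t%s", mut, qual)),
    sam)
  list(dir = dir, fasta = fa, sam = sam, refseq = refseq)
}

# the TSV pileup equivalent of the SAM fixture above
sam_fixture_pileup_tsv <- function(dir, refseq) {
  ref <- strsplit(refseq, "")[[1]]
  p <- make_pileup(ref, depth = rep(4L, 20))
  p$position <- seq_along(ref)
  p[5, "A"] <- 3L
  p[5, "G"] <- 1L
  p$locus <- "amp"
  path <- file.path(dir, "pileup.tsv")
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
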