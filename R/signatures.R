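# Breakpoint signature classification.
#
# The signature is computed purely in read coordinates, from the two
# CIGAR-derived read intervals: an overlap between the segments is
# microhomology of that length (tolerant of imperfect homology, which
# the aligner absorbs into either alignment), exact adjacency is a blunt
# joint, and a gap is a non-homologous insertion of the gap length.

# Vectorised classification from read intervals (original orientation).
classify_intervals <- function(start1, end1, start2, end2) {
  a_first <- start1 <= start2
  a1 <- fifelse(a_first, start1, start2)
  b1 <- fifelse(a_first, end1, end2)
  a2 <- fifelse(a_first, start2, start1)
  b2 <- fifelse(a_first, end2, end1)
  ov <- b1 - a2
  cls <- fifelse(ov > 0L, "microhomology",
                 fifelse(ov == 0L, "blunt", "insertion"))
  list(class = cls, length = abs(ov))
}

#' Classify one split read's breakpoint signature
#'
#' @param split_read one-row split-read data.frame (as produced by
#'   [extract_split_reads]), or a list with `read_start_1`, `read_end_1`,
#'   `read_start_2`, `read_end_2`.
#' @return list with `class` (`"microhomology"`, `"blunt"` or
#'   `"insertion"`) and `length` (bases; 0 iff blunt).
#' @export
classify_junction <- function(split_read) {
  s <- as.list(split_read)
  r <- classify_intervals(s$read_start_1, s$read_end_1,
                          s$read_start_2, s$read_end_2)
  # segments must jointly tile the read (overlap or gap allowed)
  lo <- min(s$read_start_1, s$read_start_2)
  hi <- max(s$read_end_1, s$read_end_2)
  if (lo != 0L || (!is.null(s$read_length) && hi != s$read_length))
    stop("segments do not tile the read; split read should have been filtered")
  list(class = r$class, length = r$length)
}

#' Build a signature spectrum
#'
#' Counts junctions by signed signature length: negative = insertion
#' length, 0 = blunt, positive = microhomology length. The display cap
#' groups values beyond +/-`cap` for plotting (mirroring the reporting
#' convention of up to 20 bases); raw signed lengths are preserved.
#'
#' @param junctions junction data.frame with `class`, `length` and
#'   grouping columns.
#' @param by optional character vector of grouping columns present in
#'   `junctions` (e.g. `"sample_id"` or a `day` column).
#' @param cap display cap for `capped_length` (default 20).
#' @return data.frame with grouping columns, `signed_length`,
#'   `capped_length` and `count`; counts sum to the junction count of
#'   each group.
#' @export
build_spectrum <- function(junctions, by = NULL, cap = 20L) {
  jn <- as.data.frame(junctions)
  if (!nrow(jn)) {
    out <- data.frame(signed_length = integer(), capped_length = integer(),
                      count = integer())
    for (b in rev(by)) out[[b]] <- character()
    return(out[, c(by, "signed_length", "capped_length", "count"),
               drop = FALSE])
  }
  signed <- ifelse(jn$class == "insertion", -jn$length, jn$length)
  dt <- data.table(jn[, by, drop = FALSE], signed_length = signed)
  spec <- dt[, .(count = .N), by = c(by, "signed_length")]
  spec[, capped_length := pmax(pmin(signed_length, cap), -cap)]
  data.table::setorderv(spec, c(by, "signed_length"))
  as.data.frame(spec[, c(by, "signed_length", "capped_length", "count"),
                     with = FALSE])
}

#' Extract flanking sequence around each junction breakend
#'
#' Collects the `flank` bases of reference sequence centred on each
#' breakend (so a breakend at position p yields [p - flank/2,
#' p + flank/2)), uppercased, clipped at contig ends with a warning.
#' Output is written as FASTA consumable by external motif tools.
#'
#' @param junctions junction data.frame.
#' @param genome a [genome_model].
#' @param flank total window width in bp (default 100).
#' @param path optional FASTA output path.
#' @return A `Biostrings::DNAStringSet`, two entries per junction (one
#'   per breakend), named `readid_a` / `readid_b`.
#' @export
extract_junction_flanks <- function(junctions, genome, flank = 100L,
                                    path = NULL) {
  flank <- as.integer(flank)
  if (flank < 2L) stop("flank must be at least 2 bp")
  jn <- as.data.frame(junctions)
  contig <- c(jn$contig_a, jn$contig_b)
  pos <- c(jn$pos_a, jn$pos_b)
  nm <- c(paste0(jn$read_id, "_a"), paste0(jn$read_id, "_b"))
  lens <- contig_lengths(genome)
  if (any(is.na(match(contig, names(lens)))) ||
      any(pos < 0L | pos >= lens[contig]))
    stop("breakend outside contig bounds")
  half <- flank %/% 2L
  s0 <- pos - half
  e0 <- pos + (flank - half)
  clipped <- s0 < 0L | e0 > lens[contig]
  if (any(clipped))
    warning(sum(clipped), " flank(s) clipped at contig ends")
  s0 <- pmax(s0, 0L)
  e0 <- pmin(e0, lens[contig])
  seqs <- toupper(substring(genome$contigs[contig], s0 + 1L, e0))
  dss <- Biostrings::DNAStringSet(setNames(seqs, nm))
  if (!is.null(path)) Biostrings::writeXStringSet(dss, path)
  dss
}

gc_fraction <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  as.numeric(Biostrings::letterFrequency(x, "GC", as.prob = TRUE))
}

#' Rank-sum test for GC bias between called and simulated junctions
#'
#' Two-sided two-sample Wilcoxon rank-sum test on per-flank GC
#' fractions, used to check that the stringent filter does not favour
#' AT- or GC-rich regions. Exact p-values are used for small tie-free
#' samples, the tie-corrected normal approximation otherwise.
#'
#' @param called_flanks,simulated_flanks `DNAStringSet`s (or character
#'   vectors) of flanking sequences, or numeric GC fractions directly.
#' @return list of class `stat_result`: `statistic` (`"W"`), `value`,
#'   `p_value`, `n` (per group), `sidedness`.
#' @export
gc_bias_test <- function(called_flanks, simulated_flanks) {
  gc1 <- if (is.numeric(called_flanks)) called_flanks
  else gc_fraction(called_flanks)
  gc2 <- if (is.numeric(simulated_flanks)) simulated_flanks
  else gc_fraction(simulated_flanks)
  if (length(gc1) < 2L || length(gc2) < 2L)
    stop("both groups need n >= 2")
  exact <- min(length(gc1), length(gc2)) <= 10L &&
    !anyDuplicated(c(gc1, gc2))
  w <- suppressWarnings(
    wilcox.test(gc1, gc2, alternative = "two.sided", exact = exact))
  stat_result("W", unname(w$statistic), w$p.value,
              c(length(gc1), length(gc2)), "two.sided")
}

stat_result <- function(statistic, value, p_value, n, sidedness) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, value = value, p_value = p_value,
                 n = n, sidedness = sidedness), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %g, p = %g (%s; n = %s)\n", x$statistic, x$value,
              x$p_value, x$sidedness, paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' Write a signature spectrum as TSV
#' @param spectrum result of [build_spectrum].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(spectrum, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
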