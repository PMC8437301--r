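# Planting rearrangements with controlled breakpoint signatures.
#
# A planted event is a junction between two reference loci A and B,
# carried by one chimeric read of length L whose junction sits at read
# offset o. In read coordinates segment A covers [0, e1) and segment B
# covers [s2, L):
#   microhomology m : e1 = o + m, s2 = o      (segments overlap by m)
#   blunt           : e1 = o,     s2 = o
#   insertion s     : e1 = o,     s2 = o + s  (gap filled by novel bases)
# Microhomology is planted by editing the reference so both loci carry
# the same seed k-mer at their junction-adjacent positions, so the
# classifier is exercised against genuine sequence structure.

SIG_CLASSES <- c("microhomology", "blunt", "insertion")

empty_truth <- function() {
  data.frame(read_id = character(), contig_a = character(), pos_a = integer(),
             strand_a = character(), contig_b = character(), pos_b = integer(),
             strand_b = character(), class = character(), length = integer(),
             inserted_seq = character(), read_offset = integer(),
             read_length = integer(), recoverable = logical(),
             stringsAsFactors = FALSE)
}

# Reference footprint (0-based half-open) of a junction segment of
# aligned length `len` anchored at junction-proximal base `pos0`.
# side "a": the junction lies at the read-right end of the segment;
# side "b": at the read-left end.
segment_footprint <- function(pos0, strand, len, side) {
  if ((side == "a") == (strand == "+")) c(pos0 - len + 1L, pos0 + 1L)
  else c(pos0, pos0 + len)
}

replace_bases <- function(seq, start0, bases) {
  substr(seq, start0 + 1L, start0 + nchar(bases)) <- bases
  seq
}

#' Plant one rearrangement with a controlled breakpoint signature
#'
#' Chooses (or takes) two breakend loci, edits the reference where needed
#' (shared microhomology seed k-mer at both loci), and returns the truth
#' record for the single carrier read together with the edited genome.
#'
#' @param genome a [genome_model].
#' @param class `"microhomology"`, `"blunt"` or `"insertion"`.
#' @param length signature length in bases (0 iff blunt; 1-20 for
#'   microhomology; >= 1 for insertion).
#' @param locus_a,locus_b optional lists `list(contig, pos, strand)` with
#'   0-based junction-proximal positions; drawn at random when `NULL`.
#' @param read_offset junction position within the carrier read (read
#'   bases before the junction); random when `NULL`.
#' @param read_length carrier read length (default 126, as for the
#'   Illumina reads the pipeline was designed around).
#' @param mapq mapping quality both segments will report.
#' @param min_segment_length threshold used to set the `recoverable` flag.
#' @param seed integer seed.
#' @return `list(genome = edited genome_model, event = one-row truth
#'   data.frame)`.
#' @export
plant_rearrangement <- function(genome, class, length,
                                locus_a = NULL, locus_b = NULL,
                                read_offset = NULL, read_length = 126L,
                                mapq = 60L, min_segment_length = 40L,
                                seed = NULL) {
  class <- match.arg(class, SIG_CLASSES)
  length <- as.integer(length)
  if (class == "blunt" && length != 0L) stop("blunt signature has length 0")
  if (class != "blunt" && length < 1L) stop("signature length must be >= 1")
  if (class == "microhomology" && length > 20L)
    stop("microhomology length capped at 20")
  with_seed(seed, {
    L <- as.integer(read_length)
    m <- if (class == "microhomology") length else 0L
    s_ins <- if (class == "insertion") length else 0L
    o <- as.integer(read_offset %||%
                      sample(seq(20L, L - 20L - m - s_ins), 1L))
    e1 <- o + m
    len1 <- e1
    s2 <- o + s_ins
    len2 <- L - s2
    if (len1 < 1L || len2 < 1L || e1 > L)
      stop("requested signature does not fit within the read (sizing error)")
    if (class == "microhomology" && (m > o || m > L - e1 + m))
      stop("requested microhomology longer than flank (sizing error)")

    margin <- L + 40L
    locus_a <- locus_a %||% random_locus(genome, len1, "a", margin)
    locus_b <- locus_b %||% random_locus(genome, len2, "b", margin)
    check_locus(genome, locus_a, len1, "a")
    check_locus(genome, locus_b, len2, "b")

    inserted <- NA_character_
    if (class == "microhomology") {
      h <- random_dna(m, gc = 0.5)
      genome <- plant_kmer(genome, locus_a, m, "a", h)
      genome <- plant_kmer(genome, locus_b, m, "b", h)
    } else if (class == "insertion") {
      inserted <- novel_insert(genome, locus_a, locus_b, s_ins)
    }
    event <- data.frame(
      read_id = NA_character_,
      contig_a = locus_a$contig, pos_a = as.integer(locus_a$pos),
      strand_a = locus_a$strand,
      contig_b = locus_b$contig, pos_b = as.integer(locus_b$pos),
      strand_b = locus_b$strand,
      class = class, length = length, inserted_seq = inserted,
      read_offset = o, read_length = L,
      recoverable = len1 >= min_segment_length && len2 >= min_segment_length,
      stringsAsFactors = FALSE)
    list(genome = genome, event = event)
  })
}

random_locus <- function(genome, len, side, margin,
                         contigs = names(genome$contigs)) {
  lens <- contig_lengths(genome)[contigs]
  ok <- lens > 2L * margin
  if (!any(ok)) stop("contigs too short to place a locus")
  cn <- sample(names(lens)[ok], 1L, prob = lens[ok])
  pos <- sample(seq(margin, lens[[cn]] - margin - 1L), 1L)
  list(contig = cn, pos = pos, strand = sample(c("+", "-"), 1L))
}

check_locus <- function(genome, locus, len, side) {
  clen <- contig_lengths(genome)[[locus$contig]]
  fp <- segment_footprint(locus$pos, locus$strand, len, side)
  if (fp[1] < 0L || fp[2] > clen)
    stop("segment footprint exceeds contig bounds (sizing error)")
  if (!genome$circular[[locus$contig]] &&
      (locus$pos < 40L || locus$pos > clen - 41L))
    stop("locus must lie >= 40bp from the ends of a linear contig")
}

# Write the read-space homology seed `h` into the reference at the
# junction-adjacent positions of one locus.
plant_kmer <- function(genome, locus, m, side, h) {
  seq <- genome$contigs[[locus$contig]]
  bases <- if (locus$strand == "+") h else revcomp(h)
  start0 <- if ((side == "a") == (locus$strand == "+"))
    locus$pos - m + 1L else locus$pos
  genome$contigs[[locus$contig]] <- replace_bases(seq, start0, bases)
  genome
}

# Base continuing flank A past the junction, in read space.
flank_continuation_a <- function(genome, locus) {
  seq <- genome$contigs[[locus$contig]]
  if (locus$strand == "+") substr(seq, locus$pos + 2L, locus$pos + 2L)
  else revcomp(substr(seq, locus$pos, locus$pos))
}

# Base preceding flank B before the junction, in read space.
flank_preceding_b <- function(genome, locus) {
  seq <- genome$contigs[[locus$contig]]
  if (locus$strand == "+") substr(seq, locus$pos, locus$pos)
  else revcomp(substr(seq, locus$pos + 2L, locus$pos + 2L))
}

# Insert sequence whose boundary bases extend neither flank, so the
# novel bases cannot be absorbed into either alignment.
novel_insert <- function(genome, locus_a, locus_b, s) {
  ins <- strsplit(random_dna(s, gc = 0.5), "")[[1]]
  avoid1 <- flank_continuation_a(genome, locus_a)
  ins[1] <- sample(setdiff(DNA_BASES, avoid1), 1L)
  avoid2 <- flank_preceding_b(genome, locus_b)
  if (s == 1L) {
    pick <- setdiff(DNA_BASES, c(avoid1, avoid2))
    ins[1] <- sample(pick, 1L)
  } else {
    ins[s] <- sample(setdiff(DNA_BASES, avoid2), 1L)
  }
  paste(ins, collapse = "")
}

# Reference intervals (0-based half-open, +/- 2bp guard) touched by an
# event's two segments; used to keep planted events from trampling each
# other's reference edits.
event_footprints <- function(ev) {
  L <- ev$read_length; o <- ev$read_offset
  m <- if (ev$class == "microhomology") ev$length else 0L
  s_ins <- if (ev$class == "insertion") ev$length else 0L
  fa <- segment_footprint(ev$pos_a, ev$strand_a, o + m, "a")
  fb <- segment_footprint(ev$pos_b, ev$strand_b, L - o - s_ins, "b")
  data.frame(contig = c(ev$contig_a, ev$contig_b),
             start = c(fa[1], fb[1]) - 2L, end = c(fa[2], fb[2]) + 2L,
             stringsAsFactors = FALSE)
}

#' Plant a batch of rearrangements at non-colliding loci
#'
#' Plants events one by one at random loci, rejecting any event whose
#' segment footprints overlap a previously planted event's footprints
#' (so reference edits never invalidate earlier events), plus any event
#' rejected by the optional `accept` predicate.
#'
#' @param genome a [genome_model].
#' @param classes,lengths vectors of signature classes and lengths, one
#'   entry per event.
#' @param read_length carrier read length.
#' @param accept optional predicate `function(event) TRUE/FALSE` applied
#'   before an event is committed (e.g. coding-depletion thinning).
#' @param max_tries resampling attempts per event before erroring.
#' @param seed integer seed.
#' @return `list(genome = edited genome, truth = combined truth table)`.
#' @export
plant_rearrangements <- function(genome, classes, lengths,
                                 read_length = 126L, accept = NULL,
                                 max_tries = 100L, seed = NULL) {
  stopifnot(length(classes) == length(lengths))
  with_seed(seed, {
    used <- list()
    rows <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        pl <- plant_rearrangement(genome, classes[i], lengths[i],
                                  read_length = read_length)
        fps <- event_footprints(pl$event)
        clash <- any(vapply(seq_len(nrow(fps)), function(k) {
          u <- used[[fps$contig[k]]]
          !is.null(u) && any(u[, 1] < fps$end[k] & u[, 2] > fps$start[k])
        }, logical(1)))
        if (clash) next
        if (!is.null(accept) && !isTRUE(accept(pl$event))) next
        genome <- pl$genome
        rows[[i]] <- pl$event
        for (k in seq_len(nrow(fps))) {
          used[[fps$contig[k]]] <- rbind(used[[fps$contig[k]]],
                                         c(fps$start[k], fps$end[k]))
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place event ", i, " after ", max_tries,
                    " attempts")
    }
    truth <- do.call(rbind, rows)
    truth$read_id <- sprintf("junc%05d", seq_len(nrow(truth)))
    list(genome = genome, truth = truth)
  })
}

# Build the chimeric read sequence for one truth event from the (edited)
# genome. Returns list(read, seg1 = c(rs, re), seg2 = c(rs, re)).
chimeric_read <- function(genome, ev) {
  L <- ev$read_length
  o <- ev$read_offset
  m <- if (ev$class == "microhomology") ev$length else 0L
  s_ins <- if (ev$class == "insertion") ev$length else 0L
  e1 <- o + m
  s2 <- o + s_ins
  fa <- segment_footprint(ev$pos_a, ev$strand_a, e1, "a")
  fb <- segment_footprint(ev$pos_b, ev$strand_b, L - s2, "b")
  sa <- ref_extract(genome$contigs[[ev$contig_a]], fa[1], fa[2])
  if (ev$strand_a == "-") sa <- revcomp(sa)
  sb <- ref_extract(genome$contigs[[ev$contig_b]], fb[1], fb[2])
  if (ev$strand_b == "-") sb <- revcomp(sb)
  if (m > 0L && substr(sa, o + 1L, e1) != substr(sb, 1L, m))
    stop("internal error: planted microhomology seeds disagree")
  read <- paste0(substr(sa, 1L, o),
                 if (s_ins > 0L) ev$inserted_seq else "",
                 sb)
  stopifnot(nchar(read) == L)
  list(read = read, seg1 = c(0L, e1), seg2 = c(s2, L))
}
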