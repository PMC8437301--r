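# Split-read fixture synthesis: already-aligned SAM records for planted
# junctions plus contiguous background reads, with a truth table. Reads
# are emitted aligned (rather than as FASTQ through an external aligner)
# so fixtures are deterministic and self-contained; an optional FASTQ
# export is provided for users who want to exercise a real aligner.

#' Synthesize split-read SAM records for planted events
#'
#' Every event yields one chimeric read emitted as a soft-clipped primary
#' alignment plus one supplementary alignment with mutual `SA:Z` tags.
#' Background reads align contiguously with no clipping. An event whose
#' junction cannot yield two segments of at least `min_segment_length`
#' read bases is flagged `recoverable = FALSE` in the truth table, never
#' dropped silently.
#'
#' @param genome the (edited) [genome_model] the events refer to.
#' @param events truth `data.frame` of planted events (rows as returned
#'   by [plant_rearrangement]; optional `mapq_a`/`mapq_b` columns override
#'   per-segment mapping quality).
#' @param read_length background read length.
#' @param n_background number of contiguously aligned background reads.
#' @param mapq mapping quality for background reads and default for
#'   event segments.
#' @param base_error uniform substitution rate applied to read sequences
#'   (default 0; fixture reads are error-free).
#' @param seed integer seed.
#' @return `list(records, contigs, truth)` where `records` is a SAM
#'   record `data.table` (see [read_sam]), `contigs` the `@SQ` lengths and
#'   `truth` the completed truth table with carrier read ids.
#' @export
synthesize_split_reads <- function(genome, events = empty_truth(),
                                   read_length = 126L, n_background = 1000L,
                                   mapq = 60L, base_error = 0,
                                   seed = NULL) {
  with_seed(seed, {
    contigs <- contig_lengths(genome)
    recs <- list(empty_sam_records())
    events <- as.data.frame(events)
    if (nrow(events)) {
      if (is.null(events$read_id) || anyNA(events$read_id))
        events$read_id <- sprintf("junc%05d", seq_len(nrow(events)))
      if (is.null(events$mapq_a)) events$mapq_a <- mapq
      if (is.null(events$mapq_b)) events$mapq_b <- mapq
      ev_recs <- lapply(seq_len(nrow(events)), function(i)
        event_sam_records(genome, events[i, ]))
      recs <- c(recs, ev_recs)
    }
    if (n_background > 0L) {
      recs <- c(recs, list(
        background_records(genome, n_background, read_length, mapq)))
    }
    records <- rbindlist(recs, fill = TRUE)
    if (base_error > 0 && nrow(records))
      records$seq <- mutate_bases(records$seq, base_error)
    list(records = records, contigs = contigs, truth = events)
  })
}

# Two SAM records (primary soft-clipped + supplementary) for one event.
event_sam_records <- function(genome, ev) {
  cr <- chimeric_read(genome, ev)
  L <- ev$read_length
  seg_rec <- function(interval, contig, pos0, strand, mapq) {
    len <- interval[2] - interval[1]
    side <- if (interval[1] == 0L) "a" else "b"
    fp <- segment_footprint(pos0, strand, len, side)
    rs <- interval[1]; re <- interval[2]
    if (strand == "+") {
      cl <- rs; cr2 <- L - re; seqs <- cr$read
    } else {
      cl <- L - re; cr2 <- rs; seqs <- revcomp(cr$read)
    }
    cig <- paste0(if (cl > 0L) paste0(cl, "S"), len, "M",
                  if (cr2 > 0L) paste0(cr2, "S"))
    list(rname = contig, pos = fp[1], strand = strand, mapq = mapq,
         cigar = cig, seq = seqs)
  }
  r1 <- seg_rec(cr$seg1, ev$contig_a, ev$pos_a, ev$strand_a, ev$mapq_a)
  r2 <- seg_rec(cr$seg2, ev$contig_b, ev$pos_b, ev$strand_b, ev$mapq_b)
  sa_of <- function(r) sprintf("%s,%d,%s,%s,%d,0;", r$rname, r$pos + 1L,
                               r$strand, r$cigar, r$mapq)
  flag <- function(r, supp) (if (r$strand == "-") FLAG_REVERSE else 0L) +
    (if (supp) FLAG_SUPPLEMENTARY else 0L)
  data.table(
    qname = ev$read_id,
    flag = c(flag(r1, FALSE), flag(r2, TRUE)),
    rname = c(r1$rname, r2$rname), pos = c(r1$pos, r2$pos),
    mapq = as.integer(c(r1$mapq, r2$mapq)),
    cigar = c(r1$cigar, r2$cigar), seq = c(r1$seq, r2$seq),
    sa = c(sa_of(r2), sa_of(r1)))
}

background_records <- function(genome, n, read_length, mapq) {
  lens <- contig_lengths(genome)
  ok <- lens >= read_length + 2L
  lens <- lens[ok]
  cn <- sample(names(lens), n, replace = TRUE, prob = lens)
  pos <- floor(runif(n) * (lens[cn] - read_length))
  seqs <- substring(genome$contigs[cn], pos + 1L, pos + read_length)
  data.table(qname = sprintf("bg%07d", seq_len(n)), flag = 0L,
             rname = cn, pos = as.integer(pos), mapq = as.integer(mapq),
             cigar = paste0(read_length, "M"), seq = seqs,
             sa = NA_character_)
}

# Non-split reads carrying one small insertion or deletion (for IPMR).
indel_records <- function(genome, n, read_length, mapq) {
  if (n == 0L) return(empty_sam_records())
  lens <- contig_lengths(genome)
  lens <- lens[lens >= read_length + 20L]
  cn <- sample(names(lens), n, replace = TRUE, prob = lens)
  pos <- floor(runif(n) * (lens[cn] - read_length - 10L))
  k1 <- sample(20:(read_length - 20L), n, replace = TRUE)
  is_del <- runif(n) < 0.5
  sz <- sample(1:3, n, replace = TRUE)
  seqs <- character(n); cig <- character(n)
  for (i in seq_len(n)) {
    s <- genome$contigs[[cn[i]]]
    if (is_del[i]) {
      cig[i] <- sprintf("%dM%dD%dM", k1[i], sz[i], read_length - k1[i])
      seqs[i] <- paste0(substring(s, pos[i] + 1L, pos[i] + k1[i]),
                        substring(s, pos[i] + k1[i] + sz[i] + 1L,
                                  pos[i] + read_length + sz[i]))
    } else {
      cig[i] <- sprintf("%dM%dI%dM", k1[i], sz[i], read_length - k1[i] - sz[i])
      seqs[i] <- paste0(substring(s, pos[i] + 1L, pos[i] + k1[i]),
                        random_dna(sz[i]),
                        substring(s, pos[i] + k1[i] + 1L,
                                  pos[i] + read_length - sz[i]))
    }
  }
  data.table(qname = sprintf("ind%06d", seq_len(n)), flag = 0L,
             rname = cn, pos = as.integer(pos), mapq = as.integer(mapq),
             cigar = cig, seq = seqs, sa = NA_character_)
}

mutate_bases <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- sample(DNA_BASES, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Export synthesized reads as FASTQ
#'
#' For users who want to push fixture reads through a real aligner
#' instead of consuming the emitted alignments.
#'
#' @param records SAM record table from [synthesize_split_reads].
#' @param path output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(records, path) {
  records <- as.data.frame(records)
  prim <- bitwAnd(records$flag, FLAG_SUPPLEMENTARY) == 0L
  r <- records[prim, , drop = FALSE]
  seq <- ifelse(bitwAnd(r$flag, FLAG_REVERSE) > 0L, revcomp(r$seq), r$seq)
  writeLines(as.vector(rbind(paste0("@", r$qname), seq, "+",
                             strrep("I", nchar(seq)))), path)
  invisible(path)
}

#' Draw random breakpoint signatures
#'
#' Signature mix loosely following the observed junction spectrum:
#' predominantly microhomology-mediated (lengths 1-20, geometrically
#' decaying), with minorities of blunt joints and short non-homologous
#' insertions (1-5 bp).
#'
#' @param n number of signatures.
#' @param p_blunt,p_insertion class probabilities (rest microhomology).
#' @return data.frame with `class` and `length` columns.
#' @export
random_signatures <- function(n, p_blunt = 0.15, p_insertion = 0.15) {
  cls <- sample(SIG_CLASSES, n, replace = TRUE,
                prob = c(1 - p_blunt - p_insertion, p_blunt, p_insertion))
  len <- integer(n)
  is_mh <- cls == "microhomology"
  len[is_mh] <- sample(1:20, sum(is_mh), replace = TRUE,
                       prob = 0.75^(1:20))
  is_in <- cls == "insertion"
  len[is_in] <- sample(1:5, sum(is_in), replace = TRUE)
  data.frame(class = cls, length = len, stringsAsFactors = FALSE)
}

#' Ageing time-course design
#'
#' Defaults mirror the study layout: six daily timepoints, eight
#' replicate pools, 126 nt reads. Junction and indel rates are expected
#' events per mapped read and may be scalar or one value per day.
#'
#' @param days timepoint labels (days of chronological ageing).
#' @param replicates replicate pools per timepoint.
#' @param junction_rate expected junctions per mapped read, recycled
#'   across days. The study-scale magnitude is ~3e-3; the default scales
#'   it up per-day from 1e-3 so age-dependent accumulation is visible at
#'   fixture depth.
#' @param indel_rate expected indel-bearing reads per mapped read.
#' @param background_reads mapped (non-split) reads per sample.
#' @param read_length read length (126, as in the study design).
#' @param coding_depletion multiplier on the probability of placing a
#'   junction breakend inside a CDS (1 = uniform; <1 plants depletion).
#' @param genotype genotype label for the metadata table.
#' @param seed integer seed.
#' @return A list of class `ageing_design`.
#' @export
ageing_design <- function(days = 0:5, replicates = 8L,
                          junction_rate = 1e-3 * 2^(0:5),
                          indel_rate = 5e-4,
                          background_reads = 5000L, read_length = 126L,
                          coding_depletion = 1, genotype = "wt",
                          seed = 1L) {
  stopifnot(all(junction_rate >= 0), all(indel_rate >= 0),
            read_length > 2L * 40L, replicates >= 1L)
  structure(list(
    days = days, replicates = as.integer(replicates),
    junction_rate = rep_len(junction_rate, length(days)),
    indel_rate = rep_len(indel_rate, length(days)),
    background_reads = as.integer(background_reads),
    read_length = as.integer(read_length),
    coding_depletion = coding_depletion,
    genotype = genotype, seed = seed), class = "ageing_design")
}

#' Simulate an ageing time-course of split-read samples
#'
#' One SAM fixture per (day, replicate) sample: Poisson-drawn numbers of
#' planted junctions (each supported by exactly one read, emulating rare
#' heterogeneous rearrangements) and indel-bearing reads on top of
#' contiguous background reads. Junction loci are uniform over the
#' genome except for the configurable coding-depletion factor.
#'
#' @param design an [ageing_design].
#' @param genome a [genome_model].
#' @param dir output directory for SAM, truth and metadata files; `NULL`
#'   keeps everything in memory.
#' @return list with `samples` (metadata data.frame: `sample_id`,
#'   `replicate`, `day`, `genotype`, `mapped_reads`, `path`), `truth`
#'   (combined truth table with `sample_id`), and, when `dir` is `NULL`,
#'   `sams` (named list of SAM record bundles).
#' @export
simulate_ageing_series <- function(design, genome, dir = NULL) {
  stopifnot(inherits(design, "ageing_design"))
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- list(); truths <- list(); sams <- list()
  with_seed(design$seed, {
    for (di in seq_along(design$days)) {
      for (r in seq_len(design$replicates)) {
        sid <- sprintf("d%d_r%d", design$days[di], r)
        n_j <- rpois(1L, design$junction_rate[di] * design$background_reads)
        n_i <- rpois(1L, design$indel_rate[di] * design$background_reads)
        ev <- plant_events(genome, n_j, design)
        g_ed <- ev$genome
        syn <- synthesize_split_reads(g_ed, ev$events,
                                      read_length = design$read_length,
                                      n_background = design$background_reads)
        syn$records <- rbindlist(list(
          syn$records,
          indel_records(g_ed, n_i, design$read_length, 60L)), fill = TRUE)
        mapped <- design$background_reads + n_j + n_i
        if (nrow(syn$truth)) syn$truth$sample_id <- sid
        path <- NA_character_
        if (!is.null(dir)) {
          path <- file.path(dir, paste0(sid, ".sam"))
          write_sam(syn$records, syn$contigs, path)
        } else sams[[sid]] <- syn
        samples[[sid]] <- data.frame(
          sample_id = sid, replicate = r, day = design$days[di],
          genotype = design$genotype, mapped_reads = mapped,
          path = path, stringsAsFactors = FALSE)
        truths[[sid]] <- syn$truth
      }
    }
  })
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  truth <- rbindlist(truths, fill = TRUE)
  if (!is.null(dir)) {
    write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out <- list(samples = samples, truth = as.data.frame(truth))
  if (is.null(dir)) out$sams <- sams
  out
}

# Plant n events with random signatures into (a per-sample copy of) the
# genome, honouring the coding-depletion factor via rejection sampling.
plant_events <- function(genome, n, design) {
  if (n == 0L)
    return(list(genome = genome, events = empty_truth()))
  sigs <- random_signatures(n)
  cds <- features_granges(genome, "CDS")
  accept <- NULL
  if (design$coding_depletion < 1) {
    accept <- function(ev) !breakend_in_cds(ev, cds) ||
      runif(1L) < design$coding_depletion
  }
  pb <- plant_rearrangements(genome, sigs$class, sigs$length,
                             read_length = design$read_length,
                             accept = accept)
  list(genome = pb$genome, events = pb$truth)
}

breakend_in_cds <- function(ev, cds) {
  if (!length(cds)) return(FALSE)
  pts <- GenomicRanges::GRanges(
    c(ev$contig_a, ev$contig_b),
    IRanges::IRanges(c(ev$pos_a, ev$pos_b) + 1L, width = 1L))
  length(GenomicRanges::findOverlaps(pts, cds,
                                     ignore.strand = TRUE)) > 0L
}
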