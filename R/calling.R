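# Single-split-read junction calling.
#
# A junction is called from exactly one read aligning in two pieces: a
# soft-clipped primary alignment and one supplementary alignment. The
# stringent filter (both segments >= 40 aligned bases, mapping quality
# equal to the aligner's maximum, each segment clipped on exactly one
# side) trades sensitivity for a conservative call set with no false
# positives on rearrangement-free data.

#' Junction filter configuration
#'
#' @param min_segment_length minimum aligned read bases per segment
#'   (default 40).
#' @param required_mapq mapping quality both segments must equal
#'   (default 60, the maximum score given by BWA-MEM; configurable for
#'   other aligners).
#' @param forbid_double_clipped reject reads in which a segment is
#'   clipped on both of its ends (default `TRUE`).
#' @param end_window size of the contig-end exclusion window used by the
#'   circularity filter (default 126 bp, one read length).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_segment_length = 40L, required_mapq = 60L,
                          forbid_double_clipped = TRUE, end_window = 126L) {
  stopifnot(min_segment_length >= 1L)
  structure(list(min_segment_length = as.integer(min_segment_length),
                 required_mapq = as.integer(required_mapq),
                 forbid_double_clipped = isTRUE(forbid_double_clipped),
                 end_window = as.integer(end_window)),
            class = "filter_config")
}

#' Extract split reads from parsed alignment records
#'
#' Keeps reads with exactly one primary and exactly one supplementary
#' alignment; reads with more than one supplementary are discarded and
#' counted. Secondary and unmapped records are ignored. Read intervals
#' are derived from each record's CIGAR and expressed in original-read
#' orientation (reverse-strand records are flipped).
#'
#' @param records SAM record `data.table` from [read_sam] (or the list
#'   returned by [read_sam] itself).
#' @return list with `splits` (one row per split read: per-segment
#'   contig, 0-based ref interval, strand, mapq, read interval, clip
#'   counts) and `counts` (named tallies: `n_records`, `n_multi_supp`,
#'   `n_parse_errors`).
#' @export
extract_split_reads <- function(records) {
  if (is.list(records) && !is.data.frame(records) &&
      !data.table::is.data.table(records))
    records <- records$records
  rec <- data.table::as.data.table(records)
  out_counts <- c(n_records = nrow(rec), n_multi_supp = 0L,
                  n_parse_errors = 0L)
  if (!nrow(rec))
    return(list(splits = empty_splits(), counts = out_counts))
  rec <- rec[bitwAnd(flag, FLAG_SECONDARY) == 0L &
               bitwAnd(flag, FLAG_UNMAPPED) == 0L]
  cs <- cigar_stats(rec$cigar)
  bad <- !cs$valid
  out_counts["n_parse_errors"] <- sum(bad)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable CIGAR skipped")
    rec <- rec[!bad]; cs <- cs[!bad]
  }
  rec[, `:=`(is_supp = bitwAnd(flag, FLAG_SUPPLEMENTARY) > 0L,
             strand = fifelse(bitwAnd(flag, FLAG_REVERSE) > 0L, "-", "+"),
             clip_left = cs$clip_left, clip_right = cs$clip_right,
             qwidth = cs$qwidth, rwidth = cs$rwidth,
             read_length = cs$read_length)]
  # original-read-orientation interval consumed by the alignment
  rec[, `:=`(read_start = fifelse(strand == "+", clip_left,
                                  clip_right),
             read_end = fifelse(strand == "+", read_length - clip_right,
                                read_length - clip_left))]
  tab <- rec[, .(n_prim = sum(!is_supp), n_supp = sum(is_supp)),
             by = qname]
  out_counts["n_multi_supp"] <- nrow(tab[n_supp > 1L])
  keep <- tab[n_prim == 1L & n_supp == 1L, qname]
  if (!length(keep))
    return(list(splits = empty_splits(), counts = out_counts))
  rec <- rec[qname %in% keep]
  data.table::setorder(rec, qname, is_supp)
  p <- rec[is_supp == FALSE]
  s <- rec[is_supp == TRUE]
  splits <- data.table(
    read_id = p$qname, read_length = p$read_length,
    contig_1 = p$rname, ref_start_1 = p$pos,
    ref_end_1 = p$pos + p$rwidth, strand_1 = p$strand, mapq_1 = p$mapq,
    read_start_1 = p$read_start, read_end_1 = p$read_end,
    clip_left_1 = p$clip_left, clip_right_1 = p$clip_right,
    contig_2 = s$rname, ref_start_2 = s$pos,
    ref_end_2 = s$pos + s$rwidth, strand_2 = s$strand, mapq_2 = s$mapq,
    read_start_2 = s$read_start, read_end_2 = s$read_end,
    clip_left_2 = s$clip_left, clip_right_2 = s$clip_right)
  list(splits = splits, counts = out_counts)
}

empty_splits <- function() {
  data.table(
    read_id = character(), read_length = integer(),
    contig_1 = character(), ref_start_1 = integer(), ref_end_1 = integer(),
    strand_1 = character(), mapq_1 = integer(), read_start_1 = integer(),
    read_end_1 = integer(), clip_left_1 = integer(), clip_right_1 = integer(),
    contig_2 = character(), ref_start_2 = integer(), ref_end_2 = integer(),
    strand_2 = character(), mapq_2 = integer(), read_start_2 = integer(),
    read_end_2 = integer(), clip_left_2 = integer(), clip_right_2 = integer())
}

# Junction-proximal reference coordinate (0-based) of one segment given
# its read interval, strand and ref extent. The junction side is the
# clipped side of the segment in read space.
proximal_coord <- function(read_start, read_end, read_length,
                           strand, ref_start, ref_end) {
  side_right <- read_start == 0L  # junction at read-right end
  fifelse(side_right == (strand == "+"), ref_end - 1L, ref_start)
}

#' Filter split reads and emit breakpoint junctions
#'
#' Applies the stringent single-read criteria: both segments must have
#' at least `min_segment_length` aligned read bases, both must carry
#' mapping quality exactly `required_mapq`, and neither segment may be
#' clipped on both of its ends. Passing reads are emitted as junctions
#' with junction-proximal breakend coordinates in canonical order and a
#' breakpoint signature classified from the read intervals.
#'
#' @param splits split-read table from [extract_split_reads].
#' @param config a [filter_config].
#' @param genome optional [genome_model] (or named contig lengths) used
#'   for canonical contig ranking; defaults to order of appearance.
#' @param sample_id sample label stored on emitted junctions.
#' @return list with `junctions` (data.frame: `contig_a`, `pos_a`,
#'   `strand_a`, `contig_b`, `pos_b`, `strand_b`, `class`, `length`,
#'   `read_id`, `sample_id`) and `rejections` (data.frame: `read_id`,
#'   `reason` in `short_segment`, `low_mapq`, `double_clipped`).
#' @export
filter_split_reads <- function(splits, config = filter_config(),
                               genome = NULL, sample_id = NA_character_) {
  if (is.list(splits) && !is.data.frame(splits)) splits <- splits$splits
  sp <- data.table::as.data.table(splits)
  if (!nrow(sp))
    return(list(junctions = empty_junctions(), rejections = empty_rejections()))
  len1 <- sp$read_end_1 - sp$read_start_1
  len2 <- sp$read_end_2 - sp$read_start_2
  short <- len1 < config$min_segment_length |
    len2 < config$min_segment_length
  lowq <- sp$mapq_1 != config$required_mapq |
    sp$mapq_2 != config$required_mapq
  dbl <- (sp$clip_left_1 > 0L & sp$clip_right_1 > 0L) |
    (sp$clip_left_2 > 0L & sp$clip_right_2 > 0L)
  if (!config$forbid_double_clipped) dbl <- rep(FALSE, nrow(sp))
  reason <- rep(NA_character_, nrow(sp))
  reason[dbl] <- "double_clipped"
  reason[lowq] <- "low_mapq"
  reason[short] <- "short_segment"
  pass <- is.na(reason)
  rejections <- data.frame(read_id = sp$read_id[!pass],
                           reason = reason[!pass],
                           stringsAsFactors = FALSE)
  sp <- sp[pass]
  if (!nrow(sp))
    return(list(junctions = empty_junctions(), rejections = rejections))
  sig <- classify_intervals(sp$read_start_1, sp$read_end_1,
                            sp$read_start_2, sp$read_end_2)
  pos1 <- proximal_coord(sp$read_start_1, sp$read_end_1, sp$read_length,
                         sp$strand_1, sp$ref_start_1, sp$ref_end_1)
  pos2 <- proximal_coord(sp$read_start_2, sp$read_end_2, sp$read_length,
                         sp$strand_2, sp$ref_start_2, sp$ref_end_2)
  jn <- data.frame(
    contig_a = sp$contig_1, pos_a = pos1, strand_a = sp$strand_1,
    contig_b = sp$contig_2, pos_b = pos2, strand_b = sp$strand_2,
    class = sig$class, length = sig$length,
    read_id = sp$read_id, sample_id = sample_id,
    stringsAsFactors = FALSE)
  jn <- canonicalize_junctions(jn, genome)
  list(junctions = jn, rejections = rejections)
}

empty_junctions <- function() {
  data.frame(contig_a = character(), pos_a = integer(), strand_a = character(),
             contig_b = character(), pos_b = integer(), strand_b = character(),
             class = character(), length = integer(), read_id = character(),
             sample_id = character(), stringsAsFactors = FALSE)
}

empty_rejections <- function() {
  data.frame(read_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Put junction breakends into canonical order
#'
#' Orders the two breakends of every junction by (contig rank,
#' coordinate), ties broken by strand, so equivalent junctions compare
#' equal regardless of which segment was the primary alignment.
#'
#' @param jn junction data.frame.
#' @param genome a [genome_model] (or named vector) fixing contig rank;
#'   defaults to order of first appearance.
#' @return The reordered junction data.frame.
#' @export
canonicalize_junctions <- function(jn, genome = NULL) {
  if (!nrow(jn)) return(jn)
  ranks <- if (inherits(genome, "genome_model")) contig_rank(genome)
  else if (!is.null(genome) && !is.null(names(genome)))
    setNames(seq_along(genome), names(genome))
  else {
    u <- unique(c(jn$contig_a, jn$contig_b))
    setNames(seq_along(u), u)
  }
  ra <- ranks[jn$contig_a]; rb <- ranks[jn$contig_b]
  swap <- rb < ra | (rb == ra & (jn$pos_b < jn$pos_a |
    (jn$pos_b == jn$pos_a & jn$strand_b < jn$strand_a)))
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp <- jn[swap, c("contig_a", "pos_a", "strand_a")]
    jn[swap, c("contig_a", "pos_a", "strand_a")] <-
      jn[swap, c("contig_b", "pos_b", "strand_b")]
    jn[swap, c("contig_b", "pos_b", "strand_b")] <- tmp
  }
  jn
}

#' Drop circular-contig end artifacts
#'
#' A read spanning the linearisation point of a circular contig (the
#' mitochondrial chromosome) aligns to both the start and the end of the
#' reference contig and would be miscalled as a junction. Junctions whose
#' two breakends lie on the same circular contig, one within `end_window`
#' of position 0 and the other within `end_window` of the contig end, are
#' removed; everything else is untouched.
#'
#' @param junctions junction data.frame.
#' @param genome a [genome_model] with circularity flags.
#' @param end_window window size in bp (default from [filter_config]).
#' @return Filtered junction data.frame.
#' @export
apply_circularity_filter <- function(junctions, genome, end_window = 126L) {
  if (!nrow(junctions)) return(junctions)
  lens <- contig_lengths(genome)
  circ <- names(genome$circular)[genome$circular]
  same_circ <- junctions$contig_a == junctions$contig_b &
    junctions$contig_a %in% circ
  if (!any(same_circ)) return(junctions)
  lo <- pmin(junctions$pos_a, junctions$pos_b)
  hi <- pmax(junctions$pos_a, junctions$pos_b)
  clen <- lens[junctions$contig_a]
  drop <- same_circ & lo < end_window & hi >= clen - end_window
  junctions[!drop, , drop = FALSE]
}

#' Count indel-bearing non-split reads
#'
#' Counts reads that are not split reads (no supplementary alignment)
#' and whose CIGAR contains at least one insertion or deletion op; each
#' read is counted once regardless of the number of indel ops.
#'
#' @param records SAM record table from [read_sam] (or its list).
#' @return Integer count.
#' @export
count_indel_reads <- function(records) {
  if (is.list(records) && !is.data.frame(records) &&
      !data.table::is.data.table(records))
    records <- records$records
  rec <- data.table::as.data.table(records)
  if (!nrow(rec)) return(0L)
  rec <- rec[bitwAnd(flag, FLAG_SECONDARY) == 0L &
               bitwAnd(flag, FLAG_UNMAPPED) == 0L]
  split_q <- unique(rec$qname[bitwAnd(rec$flag, FLAG_SUPPLEMENTARY) > 0L])
  prim <- rec[bitwAnd(flag, FLAG_SUPPLEMENTARY) == 0L &
                !(qname %in% split_q)]
  has_indel <- grepl("[0-9]+[ID]", prim$cigar)
  length(unique(prim$qname[has_indel]))
}

#' Call junctions and per-sample metrics from one alignment file
#'
#' Composition extract -> filter -> circularity filter, plus mapped-read
#' and indel-read tallies.
#'
#' @param x SAM/BAM path, SAM lines, or a [read_sam] result.
#' @param genome a [genome_model] (contigs must match the `@SQ` header).
#' @param config a [filter_config].
#' @param sample_meta optional one-row data.frame / list with
#'   `sample_id`, `replicate`, `day`, `genotype`.
#' @return list with `junctions`, `rejections`, `metrics` (one-row
#'   data.frame: `sample_id`, `day`, `genotype`, `replicate`,
#'   `mapped_reads`, `junction_count`, `indel_read_count`) and `counts`.
#' @export
call_sample <- function(x, genome, config = filter_config(),
                        sample_meta = NULL) {
  if (is.character(x) && length(x) == 1L && !file.exists(x))
    stop("alignment file not found: ", x)
  parsed <- if (is.list(x) && !is.null(x$records)) x else read_sam(x)
  if (length(parsed$contigs)) {
    unknown <- setdiff(names(parsed$contigs), names(genome$contigs))
    if (length(unknown))
      stop("alignment header contigs not in genome: ",
           paste(unknown, collapse = ", "))
  }
  rec <- parsed$records
  mapped <- length(unique(
    rec$qname[bitwAnd(rec$flag, FLAG_UNMAPPED) == 0L &
                bitwAnd(rec$flag, FLAG_SECONDARY) == 0L]))
  sid <- sample_meta$sample_id %||% NA_character_
  ex <- extract_split_reads(rec)
  fl <- filter_split_reads(ex$splits, config, genome, sample_id = sid)
  jn <- apply_circularity_filter(fl$junctions, genome, config$end_window)
  metrics <- data.frame(
    sample_id = sid,
    day = sample_meta$day %||% NA,
    genotype = sample_meta$genotype %||% NA_character_,
    replicate = sample_meta$replicate %||% NA,
    mapped_reads = mapped,
    junction_count = nrow(jn),
    indel_read_count = count_indel_reads(rec),
    stringsAsFactors = FALSE)
  list(junctions = jn, rejections = fl$rejections, metrics = metrics,
       counts = ex$counts)
}

#' Write junctions as BEDPE
#'
#' Standard 10-column BEDPE (0-based half-open single-base intervals per
#' breakend) plus `class`, `length` and `sample_id` columns.
#'
#' @param junctions junction data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(junctions, path) {
  df <- data.frame(
    chrom1 = junctions$contig_a, start1 = junctions$pos_a,
    end1 = junctions$pos_a + 1L,
    chrom2 = junctions$contig_b, start2 = junctions$pos_b,
    end2 = junctions$pos_b + 1L,
    name = junctions$read_id, score = rep(".", nrow(junctions)),
    strand1 = junctions$strand_a, strand2 = junctions$strand_b,
    class = junctions$class, length = junctions$length,
    sample_id = junctions$sample_id, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read junctions from BEDPE written by [write_bedpe]
#' @param path BEDPE path.
#' @return Junction data.frame.
#' @export
read_bedpe <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom1", "start1", "end1", "chrom2",
                                 "start2", "end2", "name", "score",
                                 "strand1", "strand2", "class", "length",
                                 "sample_id"))
  data.frame(contig_a = df$chrom1, pos_a = df$start1, strand_a = df$strand1,
             contig_b = df$chrom2, pos_b = df$start2, strand_b = df$strand2,
             class = df$class, length = df$length, read_id = df$name,
             sample_id = df$sample_id, stringsAsFactors = FALSE)
}
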