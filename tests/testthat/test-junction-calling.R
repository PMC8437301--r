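# Hand-written SAM fixtures: a split read is a soft-clipped primary plus
# one supplementary alignment with mutual SA tags.
sam_fixture <- function(records, contigs = c(chrI = 100000, chrII = 100000,
                                             mito = 6000)) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
    records)
}

rec <- function(qname, flag, rname, pos1, mapq, cigar, seq = NULL,
                sa = NULL) {
  cg <- oracle_cigar(cigar)
  L <- cg$qwidth + cg$clip_left + cg$clip_right
  if (is.null(seq)) seq <- strrep("A", L)
  line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  qname, flag, rname, pos1, mapq, cigar, seq,
                  strrep("I", nchar(seq)))
  if (!is.null(sa)) line <- paste0(line, "\tSA:Z:", sa)
  line
}

test_that("unclipped linear streams yield no split reads", {
  sam <- sam_fixture(c(rec("r1", 0, "chrI", 100, 60, "126M"),
                       rec("r2", 0, "chrII", 5000, 60, "126M")))
  ex <- extract_split_reads(read_sam(sam))
  expect_equal(nrow(ex$splits), 0L)
})

test_that("CIGAR read intervals follow the soft-clip arithmetic", {
  sam <- sam_fixture(c(
    rec("r1", 0, "chrI", 1001, 60, "60S66M",
        sa = "chrII,5001,+,60M66S,60,0;"),
    rec("r1", 2048, "chrII", 5001, 60, "60M66S",
        sa = "chrI,1001,+,60S66M,60,0;")))
  ex <- extract_split_reads(read_sam(sam))
  expect_equal(nrow(ex$splits), 1L)
  s <- ex$splits
  expect_equal(c(s$read_start_1, s$read_end_1), c(60, 126))
  expect_equal(c(s$read_start_2, s$read_end_2), c(0, 60))
  expect_equal(s$ref_start_1, 1000)  # 0-based conversion
  expect_equal(s$ref_end_1, 1066)
})

test_that("reverse-strand supplementary intervals are flipped to read orientation", {
  # same read, supplementary aligned on minus strand: SAM-orientation
  # clips mirror the original-read clips
  sam <- sam_fixture(c(
    rec("r1", 0, "chrI", 1001, 60, "60S66M",
        sa = "chrII,5001,-,66S60M,60,0;"),
    rec("r1", 2048 + 16, "chrII", 5001, 60, "66S60M",
        sa = "chrI,1001,+,60S66M,60,0;")))
  s <- extract_split_reads(read_sam(sam))$splits
  expect_equal(c(s$read_start_2, s$read_end_2), c(0, 60))
  expect_equal(s$strand_2, "-")
  iv <- oracle_read_interval(2048 + 16, "66S60M")
  expect_equal(c(s$read_start_2, s$read_end_2), iv)
})

test_that("reads with more than one supplementary are discarded and counted", {
  sam <- sam_fixture(c(
    rec("r1", 0, "chrI", 1001, 60, "60S66M"),
    rec("r1", 2048, "chrII", 5001, 60, "60M66S"),
    rec("r1", 2048, "chrII", 9001, 60, "80S46M")))
  ex <- extract_split_reads(read_sam(sam))
  expect_equal(nrow(ex$splits), 0L)
  expect_equal(unname(ex$counts["n_multi_supp"]), 1L)
})

test_that("secondary alignments are ignored", {
  sam <- sam_fixture(c(
    rec("r1", 0, "chrI", 1001, 60, "60S66M",
        sa = "chrII,5001,+,60M66S,60,0;"),
    rec("r1", 2048, "chrII", 5001, 60, "60M66S",
        sa = "chrI,1001,+,60S66M,60,0;"),
    rec("r1", 256, "chrII", 7001, 0, "126M")))
  ex <- extract_split_reads(read_sam(sam))
  expect_equal(nrow(ex$splits), 1L)
})

test_that("filter rejects by segment length, mapq and double clipping", {
  mk <- function(len1, len2, mq1, mq2, double2 = FALSE) {
    # len1 left part of the read, len2 right part
    cig1 <- sprintf("%dM%dS", len1, 126 - len1)
    cig2 <- if (double2)
      sprintf("%dS%dM%dS", 126 - len2 - 5, len2, 5)
    else sprintf("%dS%dM", 126 - len2, len2)
    sam <- sam_fixture(c(
      rec("r1", 0, "chrI", 1001, mq1, cig1),
      rec("r1", 2048, "chrII", 5001, mq2, cig2)))
    filter_split_reads(extract_split_reads(read_sam(sam)))
  }
  r <- mk(39, 80, 60, 60)
  expect_equal(nrow(r$junctions), 0L)
  expect_equal(r$rejections$reason, "short_segment")
  r <- mk(66, 60, 60, 59)
  expect_equal(r$rejections$reason, "low_mapq")
  r <- mk(66, 60, 60, 60, double2 = TRUE)
  expect_equal(r$rejections$reason, "double_clipped")
  r <- mk(66, 65, 60, 60)  # 5bp microhomology overlap
  expect_equal(nrow(r$junctions), 1L)
  expect_equal(r$junctions$class, "microhomology")
  expect_equal(r$junctions$length, 5L)
})

test_that("junction-proximal coordinates sit at the clipped side", {
  sam <- sam_fixture(c(
    rec("r1", 0, "chrI", 1001, 60, "66M60S",
        sa = "chrII,5001,+,66S60M,60,0;"),
    rec("r1", 2048, "chrII", 5001, 60, "66S60M",
        sa = "chrI,1001,+,66M60S,60,0;")))
  r <- filter_split_reads(extract_split_reads(read_sam(sam)))
  # segment 1 [0,66) ends at chrI:1000+66-1; segment 2 [66,126) starts
  # at chrII:5000
  expect_equal(r$junctions$pos_a, 1065)
  expect_equal(r$junctions$pos_b, 5000)
})

test_that("tightening the filter never increases the junction count", {
  g <- small_genome()
  pb <- plant_batch(g, rep(c("microhomology", "blunt"), 10),
                    rep(c(4, 0), 10), seed = 31)
  syn <- synthesize_split_reads(pb$genome, pb$truth, n_background = 200,
                                seed = 32)
  ex <- extract_split_reads(syn$records)
  n_at <- function(min_len) {
    nrow(filter_split_reads(ex$splits,
                            filter_config(min_segment_length = min_len))$junctions)
  }
  counts <- vapply(c(1, 20, 40, 60, 63), n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("circularity filter drops only same-circular-contig end junctions", {
  g <- small_genome()
  mlen <- contig_lengths(g)[["mito"]]
  jn <- data.frame(
    contig_a = c("mito", "mito", "chrI"),
    pos_a = c(50, 50, 10),
    strand_a = "+",
    contig_b = c("mito", "chrI", "chrI"),
    pos_b = c(mlen - 30, 1000, 59990),
    strand_b = "+",
    class = "blunt", length = 0L, read_id = c("a", "b", "c"),
    sample_id = NA_character_, stringsAsFactors = FALSE)
  out <- apply_circularity_filter(jn, g, end_window = 500)
  expect_equal(out$read_id, c("b", "c"))
  # a genuine internal mito junction is kept
  jn2 <- jn[1, ]; jn2$pos_a <- 2000; jn2$pos_b <- 4000
  expect_equal(nrow(apply_circularity_filter(jn2, g, 500)), 1L)
})

test_that("indel-bearing reads are counted once each, split reads excluded", {
  sam <- sam_fixture(c(
    rec("r1", 0, "chrI", 101, 60, "50M"),
    rec("r2", 0, "chrI", 201, 60, "20M1I30M"),
    rec("r3", 0, "chrI", 301, 60, "25M2D26M"),
    rec("r4", 0, "chrI", 401, 60, "20M1I30M5S",
        sa = "chrII,1001,+,45S5M,60,0;"),
    rec("r4", 2048, "chrII", 1001, 60, "45S5M"),
    rec("r5", 0, "chrI", 501, 60, "10M1I10M2D10M")))
  expect_equal(count_indel_reads(read_sam(sam)), 3L)
  sam2 <- sam_fixture(rec("r1", 0, "chrI", 101, 60, "50M"))
  expect_equal(count_indel_reads(read_sam(sam2)), 0L)
})

test_that("call_sample recovers planted recoverable events exactly", {
  g <- small_genome(seed = 17)
  classes <- c(rep("microhomology", 6), rep("blunt", 2),
               rep("insertion", 2))
  lengths <- c(1, 3, 5, 10, 15, 20, 0, 0, 1, 4)
  pb <- plant_batch(g, classes, lengths, seed = 18)
  syn <- synthesize_split_reads(pb$genome, pb$truth, n_background = 500,
                                seed = 19)
  res <- call_sample(list(records = syn$records, contigs = syn$contigs),
                     pb$genome)
  expect_equal(nrow(res$junctions), 10L)
  expect_true(all(match_truth(res$junctions, pb$truth, pb$genome,
                              tol = 0)))
  expect_equal(res$metrics$mapped_reads, 510L)
})

test_that("unrecoverable events are not called and empty input is clean", {
  g <- small_genome()
  pl <- plant_rearrangement(g, "blunt", 0, read_offset = 20, seed = 3)
  expect_false(pl$event$recoverable)
  syn <- synthesize_split_reads(pl$genome, pl$event, n_background = 50,
                                seed = 4)
  res <- call_sample(list(records = syn$records, contigs = syn$contigs),
                     pl$genome)
  expect_equal(nrow(res$junctions), 0L)
  empty <- list(records = juncture:::empty_sam_records(),
                contigs = contig_lengths(g))
  res0 <- call_sample(empty, g)
  expect_equal(res0$metrics$junction_count, 0L)
  expect_equal(res0$metrics$indel_read_count, 0L)
})

test_that("call_sample validates file existence and contig consistency", {
  g <- small_genome()
  expect_error(call_sample("/nonexistent/file.sam", g), "not found")
  sam <- sam_fixture(rec("r1", 0, "chrX", 101, 60, "50M"),
                     contigs = c(chrX = 1000))
  expect_error(call_sample(read_sam(sam), g), "contig")
})

test_that("bedpe round-trips junctions", {
  g <- small_genome()
  pb <- plant_batch(g, c("microhomology", "insertion"), c(7, 2), seed = 5)
  syn <- synthesize_split_reads(pb$genome, pb$truth, n_background = 20,
                                seed = 6)
  res <- call_sample(list(records = syn$records, contigs = syn$contigs),
                     pb$genome, sample_meta = list(sample_id = "s1"))
  p <- tempfile(fileext = ".bedpe")
  write_bedpe(res$junctions, p)
  back <- read_bedpe(p)
  expect_equal(back, res$junctions)
})

test_that("malformed CIGARs are skipped with a warning and counted", {
  sam <- sam_fixture(c(rec("r1", 0, "chrI", 101, 60, "50M"),
                       "rX\t0\tchrI\t201\t60\tBADCIGAR\t*\t0\t0\tAAAA\tIIII"))
  expect_warning(ex <- extract_split_reads(read_sam(sam)), "CIGAR")
  expect_equal(unname(ex$counts["n_parse_errors"]), 1L)
})
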