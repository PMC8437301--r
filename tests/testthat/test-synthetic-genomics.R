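test_that("generated genomes hit the target GC within binomial error", {
  g <- generate_genome(contig_lengths = c(chrI = 10000), gc = 0.5,
                       mito_length = 0, n_genes = 0, n_trnas = 0,
                       seed = 7)
  n_gc <- sum(strsplit(g$contigs[["chrI"]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(n_gc - 5000), 3 * sqrt(10000 * 0.25))
})

test_that("genome generation is byte-identical for a fixed seed", {
  g1 <- small_genome(seed = 7)
  g2 <- small_genome(seed = 7)
  expect_identical(g1, g2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome(g1, f1); write_genome(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(g1$contigs, small_genome(seed = 8)$contigs))
})

test_that("gene models carry flanking UTRs and never overlap", {
  g <- generate_genome(contig_lengths = c(chrI = 100000, chrII = 80000),
                       mito_length = 5000, n_genes = 20, n_trnas = 0,
                       seed = 11)
  ann <- g$annotations
  expect_equal(sum(ann$kind == "CDS"), 20)
  expect_equal(sum(ann$kind == "5UTR"), 20)
  expect_equal(sum(ann$kind == "3UTR"), 20)
  # brute-force overlap check across whole gene spans
  genes <- ann[ann$kind == "gene", ]
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (i >= j || genes$contig[i] != genes$contig[j]) next
      expect_true(genes$end[i] <= genes$start[j] ||
                    genes$end[j] <= genes$start[i])
    }
  }
  # each gene's parts tile its span in transcription order
  for (gid in genes$gene_id) {
    parts <- ann[ann$gene_id == gid & ann$kind != "gene", ]
    span <- genes[genes$gene_id == gid, ]
    expect_equal(sum(parts$end - parts$start), span$end - span$start)
  }
  expect_identical(names(which(g$circular)), "mito")
})

test_that("gff3/fasta round-trip preserves the genome model", {
  g <- small_genome(seed = 5)
  fa <- tempfile(fileext = ".fa"); gf <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff3 = gf)
  g2 <- read_genome(fa, gf, circular = "mito")
  expect_identical(g2$contigs, g$contigs)
  expect_identical(g2$circular, g$circular)
  a1 <- g$annotations[order(g$annotations$contig, g$annotations$start,
                            g$annotations$kind), ]
  a2 <- g2$annotations[order(g2$annotations$contig, g2$annotations$start,
                             g2$annotations$kind), ]
  expect_equal(a2$start, a1$start)
  expect_equal(a2$end, a1$end)
  expect_equal(a2$kind, a1$kind)
})

test_that("planted microhomology is verbatim shared sequence at both loci", {
  g <- small_genome()
  pl <- plant_rearrangement(g, "microhomology", 5, read_offset = 61,
                            locus_a = list(contig = "chrI", pos = 20000,
                                           strand = "+"),
                            locus_b = list(contig = "chrII", pos = 9000,
                                           strand = "+"),
                            seed = 3)
  sa <- substr(pl$genome$contigs[["chrI"]], 20000 - 5 + 2, 20000 + 1)
  sb <- substr(pl$genome$contigs[["chrII"]], 9000 + 1, 9000 + 5)
  expect_identical(sa, sb)
  expect_equal(nchar(sa), 5)
})

test_that("blunt chimeras are exact flank concatenation", {
  g <- small_genome()
  pl <- plant_rearrangement(g, "blunt", 0, read_offset = 63,
                            locus_a = list(contig = "chrI", pos = 30000,
                                           strand = "+"),
                            locus_b = list(contig = "chrII", pos = 5000,
                                           strand = "+"))
  cr <- juncture:::chimeric_read(pl$genome, pl$event)
  flank_a <- substr(g$contigs[["chrI"]], 30000 - 63 + 2, 30000 + 1)
  flank_b <- substr(g$contigs[["chrII"]], 5000 + 1, 5000 + 63)
  expect_identical(cr$read, paste0(flank_a, flank_b))
})

test_that("insertion chimeras contain novel bases at neither flank", {
  g <- small_genome()
  pl <- plant_rearrangement(g, "insertion", 3, read_offset = 60,
                            locus_a = list(contig = "chrI", pos = 25000,
                                           strand = "+"),
                            locus_b = list(contig = "chrI", pos = 45000,
                                           strand = "+"),
                            seed = 9)
  cr <- juncture:::chimeric_read(pl$genome, pl$event)
  ins <- substr(cr$read, 61, 63)
  expect_identical(ins, pl$event$inserted_seq)
  # first inserted base does not extend flank A, last does not prefix B
  cont_a <- substr(g$contigs[["chrI"]], 25000 + 2, 25000 + 2)
  pre_b <- substr(g$contigs[["chrI"]], 45000, 45000)
  expect_false(substr(ins, 1, 1) == cont_a)
  expect_false(substr(ins, 3, 3) == pre_b)
})

test_that("microhomology longer than a flank is a sizing error", {
  g <- small_genome()
  expect_error(plant_rearrangement(g, "microhomology", 15,
                                   read_offset = 10),
               "sizing|flank")
  expect_error(plant_rearrangement(g, "microhomology", 25), "capped")
})

test_that("synthesized SAM has correct split-read geometry", {
  g <- small_genome()
  pl <- plant_rearrangement(g, "microhomology", 5, read_offset = 61,
                            seed = 21)
  syn <- synthesize_split_reads(pl$genome, pl$event, n_background = 50,
                                seed = 22)
  ev_recs <- syn$records[syn$records$qname == pl$event$read_id |
                           startsWith(syn$records$qname, "junc"), ]
  expect_equal(nrow(ev_recs), 2L)
  ivs <- lapply(seq_len(2), function(i)
    oracle_read_interval(ev_recs$flag[i], ev_recs$cigar[i]))
  lens <- sort(vapply(ivs, diff, numeric(1)))
  expect_equal(lens, c(65, 66))  # segments for m=5, o=61, L=126
  lo <- ivs[[which.min(vapply(ivs, `[`, numeric(1), 1))]]
  hi <- ivs[[which.max(vapply(ivs, `[`, numeric(1), 1))]]
  expect_equal(lo[2] - hi[1], 5)  # overlap = microhomology
  expect_false(anyNA(ev_recs$sa))
})

test_that("event fixtures with no events contain no clipped alignments", {
  g <- small_genome()
  syn <- synthesize_split_reads(g, n_background = 1000, seed = 5)
  expect_false(any(grepl("[SH]", syn$records$cigar)))
  expect_equal(nrow(syn$truth), 0L)
})

test_that("events too short to recover are flagged, not dropped", {
  g <- small_genome()
  pl <- plant_rearrangement(g, "microhomology", 5, read_offset = 10)
  expect_false(pl$event$recoverable)  # 10 + 5 < 40
  syn <- synthesize_split_reads(pl$genome, pl$event, n_background = 10)
  expect_equal(nrow(syn$truth), 1L)
  expect_false(syn$truth$recoverable)
  expect_equal(sum(grepl("S", syn$records$cigar)), 2L)  # still emitted
})

test_that("synthesis is deterministic for a fixed seed", {
  g <- small_genome()
  s1 <- synthesize_split_reads(g, n_background = 100, seed = 77)
  s2 <- synthesize_split_reads(g, n_background = 100, seed = 77)
  expect_identical(s1, s2)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(s1$records, s1$contigs, f1)
  write_sam(s2$records, s2$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ageing series honours design shape and rates", {
  g <- small_genome()
  d0 <- ageing_design(days = 0:2, replicates = 2, junction_rate = 0,
                      indel_rate = 0, background_reads = 200, seed = 4)
  r0 <- simulate_ageing_series(d0, g)
  expect_equal(nrow(r0$samples), 6L)
  expect_equal(nrow(r0$truth), 0L)

  d <- ageing_design(days = 0:5, replicates = 8,
                     junction_rate = 2e-3 * 2^(0:5),
                     background_reads = 600, seed = 10)
  r <- simulate_ageing_series(d, g)
  expect_equal(nrow(r$samples), 48L)  # 6 days x 8 replicates
  counts <- table(factor(r$truth$sample_id,
                         levels = r$samples$sample_id))
  per_day <- tapply(as.integer(counts),
                    r$samples$day[match(names(counts),
                                        r$samples$sample_id)], mean)
  # doubling rates: day-5 mean junction count far above day-0
  expect_gt(per_day[["5"]], 4 * max(per_day[["0"]], 0.5))
})

test_that("fastq export carries one entry per synthesized read", {
  g <- small_genome()
  pl <- plant_rearrangement(g, "blunt", 0, read_offset = 50, seed = 2)
  syn <- synthesize_split_reads(pl$genome, pl$event, n_background = 20,
                                seed = 3)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(syn$records, fq)
  lines <- readLines(fq)
  expect_equal(length(lines), 4L * 21L)
  expect_true(all(nchar(lines[seq(2, length(lines), 4)]) == 126L))
})
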