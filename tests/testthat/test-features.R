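jn_at <- function(contig, pos, g, sample_id = NA_character_) {
  canonicalize_junctions(data.frame(
    contig_a = contig, pos_a = as.integer(pos), strand_a = "+",
    contig_b = contig, pos_b = as.integer(pos) + 5000L, strand_b = "+",
    class = "blunt", length = 0L,
    read_id = sprintf("j%04d", seq_along(pos)),
    sample_id = sample_id, stringsAsFactors = FALSE), g)
}

test_that("feature intersection matches a brute-force interval oracle", {
  g <- small_genome(seed = 3)
  jn <- simulate_random_junctions(g, 1000, seed = 4)
  for (kind in c("CDS", "3UTR", "tRNA")) {
    feat_gr <- features_granges(g, kind)
    feat_df <- g$annotations[g$annotations$kind == kind, ]
    for (fl in c(0L, 500L)) {
      got <- juncture:::junction_hits_features(jn, feat_gr, flank = fl)
      want <- oracle_junction_hits(jn, feat_df, flank = fl)
      expect_identical(got, want)
    }
  }
})

test_that("feature windows are half-open at +/- flank", {
  g <- small_genome(seed = 3)
  tr <- g$annotations[g$annotations$kind == "tRNA", ][1, ]
  gr <- features_granges(g, "tRNA")[1]
  mk <- function(pos) data.frame(
    contig_a = tr$contig, pos_a = as.integer(pos), strand_a = "+",
    contig_b = "chrII", pos_b = 100L, strand_b = "+", class = "blunt",
    length = 0L, read_id = "x", sample_id = NA, stringsAsFactors = FALSE)
  # 499 bp downstream of the feature end is inside; 501 is not
  expect_true(juncture:::junction_hits_features(mk(tr$end + 498), gr, 500))
  expect_false(juncture:::junction_hits_features(mk(tr$end + 500), gr, 500))
})

test_that("coding depletion test: degenerate and extreme cases", {
  g <- small_genome(seed = 5)
  # CDS covering (almost) the whole genome: all proportions near 1
  whole <- GenomicRanges::GRanges(
    names(g$contigs),
    IRanges::IRanges(1, contig_lengths(g)), strand = "+")
  jsets <- lapply(1:4, function(s) simulate_random_junctions(g, 50, seed = s))
  props <- vapply(jsets, function(j)
    mean(juncture:::junction_hits_features(j, whole)), numeric(1))
  expect_true(all(props == 1))
  # complete separation gives the minimal U statistic
  obs <- c(0.1, 0.12, 0.11, 0.09, 0.1, 0.13, 0.08, 0.1)
  expc <- obs + 0.2
  w <- suppressWarnings(wilcox.test(obs, expc, alternative = "less"))
  expect_equal(unname(w$statistic), 0)
  expect_error(coding_depletion_test(jsets[1:2], g), "3 replicates")
})

test_that("planted coding depletion is detected by the one-sided U test", {
  g <- small_genome(seed = 6)
  obs_sets <- lapply(1:8, function(s)
    simulate_random_junctions(g, 500, coding_depletion = 0.5,
                              seed = 100 + s))
  r <- coding_depletion_test(obs_sets, g, seed = 7)
  expect_lt(r$test$p_value, 0.01)
  expect_lt(mean(r$observed), mean(r$expected))
})

test_that("empty replicate junction sets are dropped with a warning", {
  g <- small_genome(seed = 6)
  sets <- c(lapply(1:3, function(s)
    simulate_random_junctions(g, 50, seed = s)),
    list(juncture:::empty_junctions()))
  expect_warning(r <- coding_depletion_test(sets, g, seed = 1),
                 "dropped")
  expect_equal(r$test$n, c(3, 3))
})

test_that("gene-end profiles are strand-oriented with outside positive", {
  g <- small_genome(seed = 8)
  cds <- features_granges(g, "CDS")
  minus <- cds[as.character(GenomicRanges::strand(cds)) == "-"][1]
  # 0-based gene end of a minus-strand CDS is its start coordinate
  end0 <- GenomicRanges::start(minus) - 1L
  jn <- jn_at(as.character(GenomicRanges::seqnames(minus)), end0 - 100, g)
  pr <- gene_end_profile(jn, minus, flank = 500)
  expect_equal(pr$end$positions, 100L)  # downstream => outside => +100
  expect_equal(sum(pr$end$counts$count), 1L)
  # binned counts conserve the positional counts
  expect_equal(sum(pr$end$binned$count), sum(pr$end$counts$count))
  # defaults follow the published analysis
  expect_equal(formals(gene_end_profile)$flank, 500L)
  expect_equal(formals(gene_end_profile)$smooth, 10L)
  expect_equal(formals(gene_end_profile)$bin, 250L)
  # no junctions: flat zero profile
  pr0 <- gene_end_profile(juncture:::empty_junctions(), cds)
  expect_true(all(pr0$start$counts$count == 0))
  unstranded <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 10))
  expect_error(gene_end_profile(jn, unstranded), "strand")
})

test_that("gene-end profile is invariant under genome mirroring", {
  g <- small_genome(seed = 13)
  jn <- simulate_random_junctions(g, 300, seed = 14)
  pr <- gene_end_profile(jn, g, flank = 400)
  # mirror: flip every coordinate and strand
  lens <- contig_lengths(g)
  ann <- g$annotations
  ann2 <- ann
  ann2$start <- lens[ann$contig] - ann$end
  ann2$end <- lens[ann$contig] - ann$start
  ann2$strand <- ifelse(ann$strand == "+", "-", "+")
  g2 <- genome_model(vapply(g$contigs, juncture:::revcomp, character(1)),
                     g$circular, ann2)
  jn2 <- jn
  jn2$pos_a <- lens[jn$contig_a] - 1L - jn$pos_a
  jn2$pos_b <- lens[jn$contig_b] - 1L - jn$pos_b
  pr2 <- gene_end_profile(jn2, g2, flank = 400)
  expect_equal(sort(pr2$end$positions), sort(pr$end$positions))
  expect_equal(sort(pr2$start$positions), sort(pr$start$positions))
})

test_that("utr outliers exceed mean + 2 population SDs strictly", {
  g <- small_genome(seed = 15)
  utr <- features_granges(g, "3UTR")
  # no junctions: zero counts everywhere, SD = 0, nothing flagged
  r0 <- utr_outlier_genes(juncture:::empty_junctions(), utr)
  expect_false(any(r0$outlier))
  # one UTR with 10 junctions among zeros
  target <- utr[1]
  pos <- GenomicRanges::start(target) - 1L + seq_len(10)
  jn <- jn_at(as.character(GenomicRanges::seqnames(target)), pos, g)
  r <- utr_outlier_genes(jn, utr)
  n <- length(utr)
  mu <- 10 / n
  sdev <- sqrt(mean((r$count - mu)^2))
  expect_identical(which(r$outlier), which(r$count > mu + 2 * sdev))
  expect_true(r$outlier[r$gene_id == target$gene_id])
  expect_error(utr_outlier_genes(jn, utr[0]), "UTR")
})

test_that("sample metrics divide by mapped reads and Day-0 medians", {
  s <- data.frame(
    sample_id = paste0("s", 1:6),
    day = c(0, 0, 0, 3, 3, 3), genotype = "wt", replicate = c(1:3, 1:3),
    mapped_reads = c(1e6, 1e6, 1e6, 2e6, 1e6, 1e6),
    junction_count = c(4, 5, 6, 20, 20, 30),
    indel_read_count = c(0, 2, 4, 8, 8, 8))
  m <- compute_sample_metrics(s)
  expect_equal(m$jpmr[4], 1e-5)  # 20 / 2e6
  expect_equal(m$jpmr[2], 5e-6)
  # Day-0 median replicate has relative JPMR exactly 1
  expect_equal(m$relative_jpmr[2], 1)
  expect_equal(m$relative_ipmr[2], 1)
  expect_equal(m$relative_jpmr[6], (30 / 1e6) / (5 / 1e6))
  s0 <- s[s$day == 3, ]
  expect_error(compute_sample_metrics(s0), "Day-0")
  expect_error(compute_sample_metrics(transform(s, mapped_reads = 0)))
})

test_that("feature JPMR counts flank windows and pairs days", {
  g <- small_genome(seed = 16)
  tr <- features_granges(g, "tRNA")
  samples <- data.frame(
    sample_id = c("d0_r1", "d0_r2", "d0_r3", "d3_r1", "d3_r2", "d3_r3"),
    day = c(0, 0, 0, 3, 3, 3), genotype = "wt", replicate = c(1:3, 1:3),
    mapped_reads = 1e5)
  # day-3 samples get junctions at tRNAs, day-0 only far away
  far <- jn_at("chrI", 30000, g, sample_id = "d0_r1")
  near <- do.call(rbind, lapply(c("d3_r1", "d3_r2", "d3_r3"), function(s)
    jn_at(as.character(GenomicRanges::seqnames(tr))[1:6],
          GenomicRanges::start(tr)[1:6] + 10L, g, sample_id = s)))
  # give day 0 a nonzero baseline at one tRNA for normalisation
  base <- do.call(rbind, lapply(c("d0_r1", "d0_r2", "d0_r3"), function(s)
    jn_at(as.character(GenomicRanges::seqnames(tr))[1],
          GenomicRanges::start(tr)[1] + 10L, g, sample_id = s)))
  fj <- feature_jpmr(rbind(far, near, base), tr, samples, flank = 500)
  ps <- fj$per_sample
  expect_true(all(ps$feature_count[ps$day == 3] >= 6))
  expect_equal(mean(ps$relative_feature_jpmr[ps$day == 0]), 1)
  expect_lt(fj$test$p_value, 0.05)
  expect_equal(fj$test$statistic, "T")
  # junctions far from features score zero
  fj0 <- feature_jpmr(far, tr, samples[samples$day == 0, ][1:2, ],
                      flank = 500, compare_days = c(0, 0))
  expect_warning(
    feature_jpmr(far, tr, samples[c(1, 4), ], flank = 500),
    "paired")
  expect_error(feature_jpmr(far, tr[0], samples), "empty")
})

test_that("normalised feature coverage is mean depth over mapped reads", {
  g <- generate_genome(contig_lengths = c(chrA = 20000), mito_length = 0,
                       n_genes = 3, n_trnas = 0, seed = 17)
  feats <- GenomicRanges::GRanges("chrA", IRanges::IRanges(101, 103),
                                  gene_id = "g1")
  depth <- list(chrA = rep(0, 20000))
  depth$chrA[101:103] <- c(2, 4, 6)
  nc <- normalised_feature_coverage(depth, feats, mapped_reads = 100)
  expect_equal(nc$normalised_coverage, 0.04)  # mean(2,4,6)/100
  # uniform depth: every feature scores d/N
  depth_u <- list(chrA = rep(7, 20000))
  feats2 <- features_granges(g, "CDS")
  nc2 <- normalised_feature_coverage(depth_u, feats2, mapped_reads = 70)
  expect_true(all(nc2$normalised_coverage == 0.1))
  # identical conditions: t statistic 0
  cmp <- compare_feature_coverage(nc2, nc2)
  expect_equal(cmp$test$value, 0)
  bad <- GenomicRanges::GRanges("chrA", IRanges::IRanges(19999, 20005))
  expect_error(normalised_feature_coverage(depth_u, bad, 1), "outside")
})

test_that("junction categories split mito and nuclear pairs", {
  g <- small_genome()
  jn <- data.frame(
    contig_a = c("chrI", "mito", "mito"), pos_a = c(1, 2, 3),
    strand_a = "+",
    contig_b = c("chrII", "chrI", "mito"), pos_b = c(5, 6, 7),
    strand_b = "+", class = "blunt", length = 0L,
    read_id = c("a", "b", "c"), sample_id = "s1",
    stringsAsFactors = FALSE)
  jc <- junction_categories(jn, g)
  expect_equal(sort(jc$category),
               sort(c("nDNA-nDNA", "mtDNA-nDNA", "mtDNA-mtDNA")))
  expect_true(all(jc$count == 1))
})
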