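# Feature-level analyses: coding-region depletion against matched
# random junction sets, gene-end junction profiles, 3'UTR outlier genes,
# JPMR/IPMR ageing metrics and normalised per-feature coverage.

# Does either breakend of each junction fall within features +/- flank?
# Windows are half-open: [start - flank, end + flank) in 0-based
# coordinates; the boundary base belongs to the window start side.
junction_hits_features <- function(junctions, features, flank = 0L) {
  if (!nrow(junctions)) return(logical())
  if (!length(features)) return(rep(FALSE, nrow(junctions)))
  fs <- GenomicRanges::resize(features,
                              GenomicRanges::width(features) + 2L * flank,
                              fix = "center", ignore.strand = TRUE)
  pts <- GenomicRanges::GRanges(
    c(junctions$contig_a, junctions$contig_b),
    IRanges::IRanges(c(junctions$pos_a, junctions$pos_b) + 1L, width = 1L))
  hit <- IRanges::overlapsAny(pts, fs, ignore.strand = TRUE)
  n <- nrow(junctions)
  hit[seq_len(n)] | hit[n + seq_len(n)]
}

#' Coding-region depletion test
#'
#' For each replicate junction set, the proportion of junctions with at
#' least one breakend inside a CDS is compared with the proportion in a
#' matched-size set of randomly located nuclear junctions, using a
#' one-sided two-sample Mann-Whitney U test of observed < expected.
#'
#' @param junction_sets list of junction data.frames, one per replicate.
#' @param genome a [genome_model] whose CDS annotations define coding
#'   regions.
#' @param simulator function `(genome, n)` returning a random junction
#'   set; defaults to [simulate_random_junctions].
#' @param seed integer seed for the simulated sets.
#' @return list: `observed`, `expected` (per-replicate proportions) and
#'   `test` (a `stat_result` with the U statistic).
#' @export
coding_depletion_test <- function(junction_sets, genome,
                                  simulator = NULL, seed = NULL) {
  if (length(junction_sets) < 3L)
    stop("need at least 3 replicates")
  cds <- features_granges(genome, "CDS")
  simulator <- simulator %||%
    function(g, n) simulate_random_junctions(g, n, nuclear_only = TRUE)
  empty <- vapply(junction_sets, function(j) nrow(j) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " replicate(s) with no junctions dropped")
    junction_sets <- junction_sets[!empty]
  }
  prop_in_cds <- function(jn) mean(junction_hits_features(jn, cds))
  observed <- vapply(junction_sets, prop_in_cds, numeric(1))
  expected <- with_seed(seed, vapply(junction_sets, function(jn)
    prop_in_cds(simulator(genome, nrow(jn))), numeric(1)))
  w <- suppressWarnings(
    wilcox.test(observed, expected, alternative = "less"))
  list(observed = unname(observed), expected = unname(expected),
       test = stat_result("U", unname(w$statistic), w$p.value,
                          c(length(observed), length(expected)), "less"))
}

#' Junction profile around gene starts and ends
#'
#' Collects junction breakends within `flank` bp of CDS start and end
#' positions, records their strand-oriented relative positions
#' (negative = inside the gene, positive = outside), and returns raw
#' positional counts, a sliding-mean track and binned counts.
#'
#' @param junctions junction data.frame.
#' @param genome a [genome_model] with stranded CDS features (or a
#'   `GRanges` of CDS features).
#' @param flank window half-width around each gene boundary (default 500).
#' @param smooth sliding-mean window width in bp (default 10).
#' @param bin bin width in bp for binned counts (default 250).
#' @return list of class `feature_profile` with elements `start` and
#'   `end`, each a list holding `positions` (relative position of every
#'   collected breakend), `counts` (per-position data.frame),
#'   `smoothed`, and `binned` (counts per `bin`-bp bin).
#' @export
gene_end_profile <- function(junctions, genome, flank = 500L,
                             smooth = 10L, bin = 250L) {
  cds <- if (inherits(genome, "GRanges")) genome
  else features_granges(genome, "CDS")
  if (!length(cds)) stop("no CDS features")
  strand <- as.character(GenomicRanges::strand(cds))
  if (any(strand == "*")) stop("CDS features must be stranded")
  # 0-based boundary coordinates
  s0 <- GenomicRanges::start(cds) - 1L
  e0 <- GenomicRanges::end(cds)  # one past last base
  gene_start <- ifelse(strand == "+", s0, e0 - 1L)
  gene_end <- ifelse(strand == "+", e0 - 1L, s0)
  contig <- as.character(GenomicRanges::seqnames(cds))
  be <- data.frame(contig = c(junctions$contig_a, junctions$contig_b),
                   pos = c(junctions$pos_a, junctions$pos_b))
  collect <- function(anchor, inward_sign) {
    rel <- integer(0)
    for (i in seq_along(anchor)) {
      sel <- be$contig == contig[i] & abs(be$pos - anchor[i]) <= flank
      if (!any(sel)) next
      delta <- be$pos[sel] - anchor[i]
      if (strand[i] == "-") delta <- -delta
      # delta > 0 is downstream of the boundary in gene orientation;
      # flip so positive always means outside the gene
      rel <- c(rel, delta * inward_sign)
    }
    profile_tracks(rel, flank, smooth, bin)
  }
  structure(list(start = collect(gene_start, -1L),
                 end = collect(gene_end, 1L),
                 flank = flank, smooth = smooth, bin = bin),
            class = "feature_profile")
}

profile_tracks <- function(rel, flank, smooth, bin) {
  pos <- seq(-flank, flank)
  counts <- tabulate(match(rel, pos), nbins = length(pos))
  sm <- as.numeric(stats::filter(counts, rep(1 / smooth, smooth),
                                 sides = 2))
  brk <- seq(-flank, flank + bin, by = bin)
  binned <- data.frame(
    bin_start = brk[-length(brk)],
    count = as.integer(table(cut(rel, breaks = brk, right = FALSE,
                                 include.lowest = FALSE))))
  list(positions = rel,
       counts = data.frame(position = pos, count = counts),
       smoothed = data.frame(position = pos, mean = sm),
       binned = binned)
}

#' 3'UTR outlier genes
#'
#' Counts junctions at each 3'UTR and flags genes whose count exceeds
#' the population mean by more than two population standard deviations
#' (strict inequality; a zero-variance population flags nothing).
#'
#' @param junctions junction data.frame.
#' @param genome a [genome_model] with 3'UTR annotations (or a `GRanges`
#'   of 3'UTR features carrying `gene_id`).
#' @return data.frame with `gene_id`, `utr_length`, `count`, `outlier`;
#'   attributes `mean` and `sd` hold the population statistics.
#' @export
utr_outlier_genes <- function(junctions, genome) {
  utr <- if (inherits(genome, "GRanges")) genome
  else features_granges(genome, "3UTR")
  if (!length(utr)) stop("no 3'UTR features")
  pts <- GenomicRanges::GRanges(
    c(junctions$contig_a, junctions$contig_b),
    IRanges::IRanges(c(junctions$pos_a, junctions$pos_b) + 1L, width = 1L))
  counts <- GenomicRanges::countOverlaps(utr, pts, ignore.strand = TRUE)
  mu <- mean(counts)
  # population SD (divisor n)
  sdev <- sqrt(mean((counts - mu)^2))
  thr <- mu + 2 * sdev
  data.frame(gene_id = utr$gene_id,
             utr_length = GenomicRanges::width(utr),
             count = as.integer(counts),
             outlier = if (sdev == 0) rep(FALSE, length(counts))
             else counts > thr,
             stringsAsFactors = FALSE) -> out
  attr(out, "mean") <- mu
  attr(out, "sd") <- sdev
  out
}

#' Per-sample ageing metrics (JPMR, IPMR and Day-0-relative versions)
#'
#' JPMR (junctions per mapped read) and IPMR (indel-bearing reads per
#' mapped read) per sample, plus versions divided by the Day-0 median
#' of the same genotype.
#'
#' @param samples data.frame with `sample_id`, `day`, `genotype`,
#'   `replicate`, `mapped_reads`, `junction_count`, `indel_read_count`
#'   (as assembled from [call_sample] metrics rows).
#' @param day0 value of `day` identifying the reference timepoint
#'   (default 0).
#' @return The input with `jpmr`, `ipmr`, `relative_jpmr`,
#'   `relative_ipmr` columns appended.
#' @export
compute_sample_metrics <- function(samples, day0 = 0) {
  s <- as.data.frame(samples)
  stopifnot(all(s$mapped_reads > 0))
  s$jpmr <- s$junction_count / s$mapped_reads
  s$ipmr <- s$indel_read_count / s$mapped_reads
  s$relative_jpmr <- NA_real_
  s$relative_ipmr <- NA_real_
  for (g in unique(s$genotype)) {
    sel <- s$genotype == g
    ref <- sel & s$day == day0
    if (!any(ref))
      stop("no Day-", day0, " sample for genotype ", g)
    mj <- median(s$jpmr[ref])
    mi <- median(s$ipmr[ref])
    s$relative_jpmr[sel] <- if (mj > 0) s$jpmr[sel] / mj else NA_real_
    s$relative_ipmr[sel] <- if (mi > 0) s$ipmr[sel] / mi else NA_real_
  }
  s
}

#' Junction pair-category counts per sample
#'
#' Splits each sample's junctions into nDNA-nDNA, mtDNA-nDNA and
#' mtDNA-mtDNA categories.
#'
#' @param junctions junction data.frame with `sample_id`.
#' @param genome a [genome_model].
#' @return data.frame `sample_id`, `category`, `count`.
#' @export
junction_categories <- function(junctions, genome) {
  circ <- names(genome$circular)[genome$circular]
  m <- (junctions$contig_a %in% circ) + (junctions$contig_b %in% circ)
  lev <- c("nDNA-nDNA", "mtDNA-nDNA", "mtDNA-mtDNA")
  dt <- data.table(sample_id = junctions$sample_id,
                   category = lev[m + 1L])
  out <- dt[, .(count = .N), by = .(sample_id, category)]
  as.data.frame(out)
}

#' Feature-level JPMR with paired between-day tests
#'
#' Counts junctions with at least one breakend within `flank` bp of any
#' feature in the set, per sample, divides by mapped reads, normalises
#' to the mean feature-level JPMR at Day 0 of the same genotype, and
#' compares two chosen days with a paired t-test across replicates.
#'
#' @param junctions junction data.frame with `sample_id`.
#' @param features `GRanges` feature set (e.g.
#'   `features_granges(genome, "tRNA")`).
#' @param samples sample metadata data.frame (`sample_id`, `day`,
#'   `genotype`, `replicate`, `mapped_reads`).
#' @param flank half-open window extension in bp (default 500).
#' @param compare_days length-2 vector of days for the paired test
#'   (default the two extreme days present).
#' @param day0 reference day for normalisation (default 0).
#' @return list: `per_sample` (data.frame with `feature_jpmr`,
#'   `relative_feature_jpmr`) and `test` (paired `stat_result`, or
#'   `NULL` with a warning when fewer than 2 replicate pairs exist).
#' @export
feature_jpmr <- function(junctions, features, samples, flank = 500L,
                         compare_days = NULL, day0 = 0) {
  if (!length(features)) stop("feature set is empty")
  s <- as.data.frame(samples)
  cnt <- vapply(s$sample_id, function(sid) {
    jn <- junctions[junctions$sample_id == sid, , drop = FALSE]
    if (!nrow(jn)) return(0L)
    sum(junction_hits_features(jn, features, flank = flank))
  }, integer(1))
  s$feature_count <- unname(cnt)
  s$feature_jpmr <- s$feature_count / s$mapped_reads
  s$relative_feature_jpmr <- NA_real_
  for (g in unique(s$genotype)) {
    sel <- s$genotype == g
    ref <- sel & s$day == day0
    m0 <- mean(s$feature_jpmr[ref])
    s$relative_feature_jpmr[sel] <-
      if (isTRUE(m0 > 0)) s$feature_jpmr[sel] / m0 else NA_real_
  }
  compare_days <- compare_days %||% range(s$day)
  a <- s[s$day == compare_days[1], ]
  b <- s[s$day == compare_days[2], ]
  key <- intersect(paste(a$genotype, a$replicate),
                   paste(b$genotype, b$replicate))
  test <- NULL
  if (length(key) < 2L) {
    warning("fewer than 2 replicate pairs; paired test skipped")
  } else {
    av <- a$feature_jpmr[match(key, paste(a$genotype, a$replicate))]
    bv <- b$feature_jpmr[match(key, paste(b$genotype, b$replicate))]
    d <- bv - av
    if (sd(d) == 0) {
      # zero-variance paired differences: degenerate t
      test <- if (mean(d) == 0) stat_result("T", 0, 1, length(key),
                                            "two.sided")
      else stat_result("T", sign(mean(d)) * Inf, 0, length(key),
                       "two.sided")
    } else {
      tt <- t.test(bv, av, paired = TRUE)
      test <- stat_result("T", unname(tt$statistic), tt$p.value,
                          length(key), "two.sided")
    }
  }
  list(per_sample = s, test = test)
}

#' Normalised per-feature coverage
#'
#' Mean per-base depth over each feature span divided by the sample's
#' total mapped reads. With two conditions, per-feature differences are
#' summarised by a one-sample t-test on the paired differences.
#'
#' @param depth named list of per-base depth vectors (one per contig)
#'   or a bedGraph path.
#' @param features `GRanges` feature set.
#' @param mapped_reads total mapped reads for the sample.
#' @param genome a [genome_model] (needed when `depth` is a file path).
#' @return data.frame `gene_id`, `mean_depth`, `normalised_coverage`.
#' @export
normalised_feature_coverage <- function(depth, features, mapped_reads,
                                        genome = NULL) {
  if (is.character(depth)) depth <- as_depth_list(depth, genome)
  contig <- as.character(GenomicRanges::seqnames(features))
  s <- GenomicRanges::start(features)   # 1-based
  e <- GenomicRanges::end(features)
  md <- vapply(seq_along(features), function(i) {
    tr <- depth[[contig[i]]]
    if (is.null(tr) || e[i] > length(tr))
      stop("feature outside depth track")
    mean(tr[s[i]:e[i]])
  }, numeric(1))
  data.frame(gene_id = features$gene_id %||% as.character(seq_along(features)),
             mean_depth = md,
             normalised_coverage = md / mapped_reads,
             stringsAsFactors = FALSE)
}

#' Paired comparison of normalised feature coverage between conditions
#'
#' @param cov_a,cov_b results of [normalised_feature_coverage] for the
#'   two conditions (matched on `gene_id`).
#' @return list: `differences` (b - a per feature), `test` (one-sample
#'   t `stat_result` on the differences).
#' @export
compare_feature_coverage <- function(cov_a, cov_b) {
  key <- intersect(cov_a$gene_id, cov_b$gene_id)
  d <- cov_b$normalised_coverage[match(key, cov_b$gene_id)] -
    cov_a$normalised_coverage[match(key, cov_a$gene_id)]
  if (sd(d) == 0) {
    test <- stat_result("T", 0, 1, length(d), "two.sided")
  } else {
    tt <- t.test(d)
    test <- stat_result("T", unname(tt$statistic), tt$p.value,
                        length(d), "two.sided")
  }
  list(differences = setNames(d, key), test = test)
}
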