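# Rearrangement hotspot detection: junctions binned into 20 kb
# window-pair matrices per timepoint, element-wise old/young ratios
# (T5/T0), and a global hotspot score per bin (mean ratio of the bin
# against all windows genome-wide).

#' Genome binning scheme
#'
#' @param genome a [genome_model].
#' @param window_size window size in bp (default 20000).
#' @return data.frame `bins` with `contig`, `win` (0-based window index
#'   within contig), `start`, `end` (0-based half-open; last partial
#'   window included), one row per genome-wide bin in canonical order.
#' @export
genome_bins <- function(genome, window_size = 20000L) {
  if (window_size <= 0L) stop("window size must be positive")
  lens <- contig_lengths(genome)
  do.call(rbind, lapply(names(lens), function(cn) {
    nw <- ceiling(lens[[cn]] / window_size)
    s <- (seq_len(nw) - 1L) * window_size
    data.frame(contig = cn, win = seq_len(nw) - 1L, start = s,
               end = pmin(s + window_size, lens[[cn]]),
               stringsAsFactors = FALSE)
  }))
}

bin_index <- function(bins, contig, pos, window_size) {
  key <- paste(bins$contig, bins$win)
  match(paste(contig, pos %/% window_size), key)
}

#' Bin junctions into a window-pair count matrix
#'
#' Each junction increments exactly one cell, addressed by the windows
#' containing its two breakend coordinates, stored once in canonical
#' order (bin index a <= b over the genome-wide bin ranking).
#'
#' @param junctions junction data.frame.
#' @param genome a [genome_model].
#' @param window_size window size in bp (default 20000).
#' @return An object of class `junction_matrix`: list with `counts`
#'   (upper-triangular dense matrix, bins x bins), `bins`,
#'   `window_size`, `n_junctions`.
#' @export
bin_junctions <- function(junctions, genome, window_size = 20000L) {
  bins <- genome_bins(genome, window_size)
  nb <- nrow(bins)
  ia <- bin_index(bins, junctions$contig_a, junctions$pos_a, window_size)
  ib <- bin_index(bins, junctions$contig_b, junctions$pos_b, window_size)
  if (anyNA(ia) || anyNA(ib)) stop("junction coordinate outside genome")
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  counts <- matrix(0L, nb, nb)
  if (length(lo)) {
    tab <- table(factor(lo + (hi - 1L) * nb, levels = seq_len(nb * nb)))
    counts <- matrix(as.integer(tab), nb, nb)
  }
  rownames(counts) <- colnames(counts) <- paste(bins$contig, bins$win,
                                                sep = ":")
  structure(list(counts = counts, bins = bins,
                 window_size = as.integer(window_size),
                 n_junctions = nrow(junctions)),
            class = "junction_matrix")
}

#' @export
print.junction_matrix <- function(x, ...) {
  cat("junction_matrix:", nrow(x$bins), "bins of", x$window_size, "bp;",
      x$n_junctions, "junction(s)\n")
  invisible(x)
}

#' Element-wise old/young ratio matrix
#'
#' Divides the old (late-timepoint) count matrix by the young
#' (day-zero) matrix cell by cell, with a pseudocount added to both
#' numerator and denominator. With `pseudocount = 0`, zero-denominator
#' cells are masked (`NA`) rather than infinite and are excluded from
#' downstream means.
#'
#' @param mat_old,mat_young `junction_matrix` objects on the same
#'   binning scheme.
#' @param pseudocount nonnegative pseudocount (default 1).
#' @return An object of class `ratio_matrix`: list with `ratio` (dense
#'   upper-triangular matrix, masked cells `NA`), `bins`,
#'   `window_size`, `pseudocount`.
#' @export
old_young_ratio <- function(mat_old, mat_young, pseudocount = 1) {
  stopifnot(inherits(mat_old, "junction_matrix"),
            inherits(mat_young, "junction_matrix"))
  if (!identical(dim(mat_old$counts), dim(mat_young$counts)) ||
      mat_old$window_size != mat_young$window_size)
    stop("matrices have mismatched shape or window size")
  num <- mat_old$counts + pseudocount
  den <- mat_young$counts + pseudocount
  ratio <- ifelse(den == 0, NA_real_, num / den)
  ratio[lower.tri(ratio)] <- NA_real_
  structure(list(ratio = ratio, bins = mat_old$bins,
                 window_size = mat_old$window_size,
                 pseudocount = pseudocount),
            class = "ratio_matrix")
}

#' Global hotspot score per bin
#'
#' For every genome-wide bin, the mean old/young ratio of that bin
#' against all windows of all chromosomes (the symmetrised ratio row),
#' masked cells excluded. Bins are ranked by descending score.
#'
#' @param ratio a `ratio_matrix` from [old_young_ratio].
#' @param include_diagonal include the bin's own diagonal cell in its
#'   mean (default `TRUE`).
#' @return data.frame with `contig`, `win`, `start`, `end`, `score`,
#'   `rank` (1 = strongest hotspot; `NA` score for fully masked bins).
#' @export
global_hotspot_score <- function(ratio, include_diagonal = TRUE) {
  stopifnot(inherits(ratio, "ratio_matrix"))
  m <- ratio$ratio
  full <- m
  full[lower.tri(full)] <- t(m)[lower.tri(m)]
  if (!include_diagonal) diag(full) <- NA_real_
  score <- rowMeans(full, na.rm = TRUE)
  score[!is.finite(score)] <- NA_real_
  out <- cbind(ratio$bins,
               data.frame(score = unname(score)))
  out$rank <- rank(-out$score, ties.method = "min", na.last = "keep")
  out
}

#' Intra-chromosomal distance distributions at and away from hotspots
#'
#' Partitions intra-chromosomal junction breakend distances by whether
#' either breakend falls in a hotspot bin, and compares the two strata
#' with a two-sided two-sample Wilcoxon rank-sum test.
#'
#' @param junctions junction data.frame.
#' @param hotspot_bins data.frame with `contig`, `win` rows defining
#'   hotspot bins (e.g. top rows of [global_hotspot_score]).
#' @param window_size window size used to address bins.
#' @return list: `hotspot_distances`, `other_distances`, `test`
#'   (a `stat_result` with the W statistic).
#' @export
distance_distributions <- function(junctions, hotspot_bins,
                                   window_size = 20000L) {
  jn <- junctions[junctions$contig_a == junctions$contig_b, , drop = FALSE]
  if (!nrow(jn)) stop("no intra-chromosomal junctions")
  d <- abs(jn$pos_b - jn$pos_a)
  hs_key <- paste(hotspot_bins$contig, hotspot_bins$win)
  in_hs <- paste(jn$contig_a, jn$pos_a %/% window_size) %in% hs_key |
    paste(jn$contig_b, jn$pos_b %/% window_size) %in% hs_key
  if (!any(in_hs) || all(in_hs))
    stop("one distance stratum is empty")
  w <- suppressWarnings(
    wilcox.test(d[in_hs], d[!in_hs], alternative = "two.sided"))
  list(hotspot_distances = d[in_hs], other_distances = d[!in_hs],
       test = stat_result("W", unname(w$statistic), w$p.value,
                          c(sum(in_hs), sum(!in_hs)), "two.sided"))
}

#' Per-bin median read-depth ratio (repeat-expansion check)
#'
#' Computes the per-bin median of per-base depth for an old and a young
#' sample and their ratio; a bin whose ratio rises with age would
#' indicate repeat expansion rather than junction formation.
#'
#' @param depth_old,depth_young named lists of per-base numeric depth
#'   vectors (one per contig, full contig length), or bedGraph file
#'   paths readable by `rtracklayer`.
#' @param genome a [genome_model].
#' @param window_size window size in bp (default 20000).
#' @return data.frame with `contig`, `win`, `start`, `end`,
#'   `median_old`, `median_young`, `ratio` (`NA` where the young median
#'   is 0).
#' @export
coverage_ratio <- function(depth_old, depth_young, genome,
                           window_size = 20000L) {
  depth_old <- as_depth_list(depth_old, genome)
  depth_young <- as_depth_list(depth_young, genome)
  lens <- contig_lengths(genome)
  for (cn in names(lens)) {
    if (length(depth_old[[cn]]) != lens[[cn]] ||
        length(depth_young[[cn]]) != lens[[cn]])
      stop("depth track length mismatch for contig ", cn)
  }
  bins <- genome_bins(genome, window_size)
  med <- function(track) {
    vapply(seq_len(nrow(bins)), function(i) {
      v <- track[[bins$contig[i]]][(bins$start[i] + 1L):bins$end[i]]
      median(v)
    }, numeric(1))
  }
  mo <- med(depth_old); my <- med(depth_young)
  cbind(bins, data.frame(median_old = mo, median_young = my,
                         ratio = ifelse(my == 0, NA_real_, mo / my)))
}

as_depth_list <- function(x, genome) {
  if (is.list(x) && !is.null(names(x))) return(x)
  if (is.character(x) && length(x) == 1L) {
    gr <- rtracklayer::import(x, format = "bedGraph")
    lens <- contig_lengths(genome)
    out <- lapply(names(lens), function(cn) {
      v <- numeric(lens[[cn]])
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == cn]
      if (length(sub)) {
        s <- GenomicRanges::start(sub); e <- GenomicRanges::end(sub)
        for (i in seq_along(sub)) v[s[i]:e[i]] <- sub$score[i]
      }
      v
    })
    names(out) <- names(lens)
    return(out)
  }
  stop("unsupported depth track input")
}

#' Write a junction or ratio matrix as long-format TSV
#'
#' Columns `contig_a`, `win_a`, `contig_b`, `win_b`, `value`; zero /
#' masked cells omitted.
#'
#' @param x a `junction_matrix` or `ratio_matrix`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (inherits(x, "junction_matrix")) x$counts else x$ratio
  idx <- which(!is.na(m) & m != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  b <- x$bins
  df <- data.frame(contig_a = b$contig[idx[, 1]], win_a = b$win[idx[, 1]],
                   contig_b = b$contig[idx[, 2]], win_b = b$win[idx[, 2]],
                   value = m[idx], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a junction-level ageing series with a planted global hotspot
#'
#' Background junctions are placed uniformly at all days; from
#' `hotspot_from_day` onward, extra junctions link one chosen bin to a
#' set of remote partner bins, creating an age-associated global
#' hotspot. Works at the junction level (coordinates only), which is
#' the granularity the hotspot matrices consume.
#'
#' @param genome a [genome_model].
#' @param days timepoints (default 0:5).
#' @param n_background background junctions per day.
#' @param hotspot_bin list(contig, win) of the planted bin; default the
#'   middle bin of the first nuclear contig.
#' @param n_partners number of remote partner bins (default 25).
#' @param n_hotspot_junctions hotspot-linked junctions per late day.
#' @param hotspot_from_day first day with hotspot junctions (default 3).
#' @param window_size bin size (default 20000).
#' @param seed integer seed.
#' @return list: `junctions_by_day` (named list of junction
#'   data.frames), `hotspot_bin`, `partner_bins`.
#' @export
simulate_hotspot_series <- function(genome, days = 0:5,
                                    n_background = 300L,
                                    hotspot_bin = NULL, n_partners = 25L,
                                    n_hotspot_junctions = 60L,
                                    hotspot_from_day = 3,
                                    window_size = 20000L, seed = NULL) {
  bins <- genome_bins(genome, window_size)
  nuc <- bins[bins$contig %in% nuclear_contigs(genome), , drop = FALSE]
  with_seed(seed, {
    if (is.null(hotspot_bin)) {
      i <- nuc[nuc$contig == nuc$contig[1], ]
      hotspot_bin <- as.list(i[ceiling(nrow(i) / 2), c("contig", "win")])
    }
    hs_row <- which(bins$contig == hotspot_bin$contig &
                      bins$win == hotspot_bin$win)
    cand <- which(!(nuc$contig == hotspot_bin$contig &
                      abs(nuc$win - hotspot_bin$win) <= 1L))
    if (length(cand) < n_partners)
      stop("genome too small for ", n_partners, " partner bins")
    partners <- nuc[cand[sample.int(length(cand), n_partners)],
                    c("contig", "win")]
    pos_in_bin <- function(b) {
      as.integer(b$start + floor(runif(nrow(b)) * (b$end - b$start)))
    }
    out <- lapply(days, function(d) {
      jn <- simulate_random_junctions(genome, n_background,
                                      nuclear_only = TRUE)
      if (d >= hotspot_from_day && n_hotspot_junctions > 0L) {
        pk <- partners[sample(nrow(partners), n_hotspot_junctions,
                              replace = TRUE), , drop = FALSE]
        pk <- merge(pk, bins, by = c("contig", "win"), sort = FALSE)
        hsb <- bins[rep(hs_row, n_hotspot_junctions), , drop = FALSE]
        extra <- data.frame(
          contig_a = hsb$contig, pos_a = pos_in_bin(hsb), strand_a = "+",
          contig_b = pk$contig, pos_b = pos_in_bin(pk), strand_b = "+",
          class = "blunt", length = 0L,
          read_id = sprintf("hs_d%s_%04d", d,
                            seq_len(n_hotspot_junctions)),
          sample_id = NA_character_, stringsAsFactors = FALSE)
        jn <- rbind(jn, canonicalize_junctions(extra, genome))
      }
      jn
    })
    names(out) <- paste0("day", days)
    list(junctions_by_day = out, hotspot_bin = hotspot_bin,
         partner_bins = partners)
  })
}
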