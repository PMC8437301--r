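# Simulation-based null models: randomly located junction sets, a
# read-share admixture model for the expected chromosome-pair junction
# distribution, and the planted-insertion validation harness for the
# calling pipeline.

#' Simulate randomly located junctions
#'
#' Draws each junction's two breakends independently and uniformly over
#' contig positions, choosing contigs in proportion to their length.
#' Used to build the matched random sets for intersection analyses; only
#' nuclear junctions are simulated by default, matching how the real
#' nuclear junction sets are compared.
#'
#' @param genome a [genome_model].
#' @param n number of junctions (matched to the observed set size).
#' @param nuclear_only exclude circular (mitochondrial) contigs.
#' @param coding_depletion optional multiplier <= 1 on the probability
#'   of accepting a junction with a breakend inside a CDS (1 = uniform);
#'   used to plant depletion signal in synthetic series.
#' @param seed integer seed.
#' @return Junction data.frame (class/length set to blunt/0).
#' @export
simulate_random_junctions <- function(genome, n, nuclear_only = TRUE,
                                      coding_depletion = 1, seed = NULL) {
  stopifnot(n >= 0)
  lens <- contig_lengths(genome)
  if (nuclear_only) lens <- lens[!genome$circular[names(lens)]]
  if (!length(lens)) stop("genome has no nuclear contig")
  if (n == 0L) return(empty_junctions())
  with_seed(seed, {
    draw <- function(k) {
      cn <- sample(names(lens), k, replace = TRUE, prob = lens)
      pos <- as.integer(floor(runif(k) * lens[cn]))
      data.frame(contig = cn, pos = pos, stringsAsFactors = FALSE)
    }
    a <- draw(n); b <- draw(n)
    jn <- data.frame(
      contig_a = a$contig, pos_a = a$pos, strand_a = "+",
      contig_b = b$contig, pos_b = b$pos, strand_b = "+",
      class = "blunt", length = 0L,
      read_id = sprintf("sim%06d", seq_len(n)),
      sample_id = NA_character_, stringsAsFactors = FALSE)
    if (coding_depletion < 1) {
      cds <- features_granges(genome, "CDS")
      while (TRUE) {
        in_cds <- junction_hits_features(jn, cds, flank = 0L)
        reject <- in_cds & runif(nrow(jn)) >= coding_depletion
        if (!any(reject)) break
        repl <- draw(2L * sum(reject))
        k <- sum(reject)
        jn$contig_a[reject] <- repl$contig[seq_len(k)]
        jn$pos_a[reject] <- repl$pos[seq_len(k)]
        jn$contig_b[reject] <- repl$contig[k + seq_len(k)]
        jn$pos_b[reject] <- repl$pos[k + seq_len(k)]
      }
    }
    canonicalize_junctions(jn, genome)
  })
}

#' Expected junction distribution under random DNA-end admixture
#'
#' Per-contig mapped-read counts are converted to proportions of the
#' total; each junction's two ends are then assumed to join randomly,
#' each end drawn independently with probability equal to its contig's
#' read share. Reports the closed-form expectation for every contig pair
#' (n * 2 * p_i * p_j for i != j, n * p_i^2 for i = j) alongside
#' Monte-Carlo means and standard deviations.
#'
#' @param per_contig_read_counts named numeric vector of mapped reads
#'   per contig (>= 0, not all zero).
#' @param n_junctions number of junctions per simulation.
#' @param n_sims number of simulations (default 1000).
#' @param seed integer seed.
#' @return data.frame with `contig_i`, `contig_j`, `expected`,
#'   `mc_mean`, `mc_sd`, `n_sims`; `expected` sums to `n_junctions`.
#' @export
admixture_expectation <- function(per_contig_read_counts, n_junctions,
                                  n_sims = 1000L, seed = NULL) {
  counts <- per_contig_read_counts
  stopifnot(all(counts >= 0), sum(counts) > 0)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  p <- counts / sum(counts)
  k <- length(p)
  nms <- names(p) %||% as.character(seq_len(k))
  pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  expected <- ifelse(pairs[, 1] == pairs[, 2],
                     n_junctions * p[pairs[, 1]]^2,
                     n_junctions * 2 * p[pairs[, 1]] * p[pairs[, 2]])
  with_seed(seed, {
    sims <- matrix(0, n_sims, nrow(pairs))
    pair_id <- function(i, j) {
      lo <- pmin(i, j); hi <- pmax(i, j)
      match(paste(lo, hi), paste(pairs[, 1], pairs[, 2]))
    }
    for (s in seq_len(n_sims)) {
      e1 <- sample.int(k, n_junctions, replace = TRUE, prob = p)
      e2 <- sample.int(k, n_junctions, replace = TRUE, prob = p)
      tab <- tabulate(pair_id(e1, e2), nbins = nrow(pairs))
      sims[s, ] <- tab
    }
    data.frame(
      contig_i = nms[pairs[, 1]], contig_j = nms[pairs[, 2]],
      expected = unname(expected),
      mc_mean = colMeans(sims), mc_sd = apply(sims, 2, sd),
      n_sims = n_sims, stringsAsFactors = FALSE)
  })
}

#' Observed vs expected junction category fractions
#'
#' Summarises junctions into the three pair categories
#' (nuclear-nuclear, mito-nuclear, mito-mito) and compares their
#' fractions with the admixture expectation.
#'
#' @param junctions observed junction data.frame.
#' @param admixture result of [admixture_expectation].
#' @param genome a [genome_model] (for circularity flags).
#' @return data.frame with `category`, `observed_fraction`,
#'   `expected_fraction`.
#' @export
pair_category_fractions <- function(junctions, admixture, genome) {
  circ <- names(genome$circular)[genome$circular]
  categ <- function(ca, cb) {
    m <- (ca %in% circ) + (cb %in% circ)
    c("nDNA-nDNA", "mtDNA-nDNA", "mtDNA-mtDNA")[m + 1L]
  }
  lev <- c("nDNA-nDNA", "mtDNA-nDNA", "mtDNA-mtDNA")
  obs <- table(factor(categ(junctions$contig_a, junctions$contig_b),
                      levels = lev))
  exp_cat <- tapply(admixture$expected,
                    factor(categ(admixture$contig_i, admixture$contig_j),
                           levels = lev), sum)
  exp_cat[is.na(exp_cat)] <- 0
  data.frame(category = names(obs),
             observed_fraction = as.numeric(obs) / max(sum(obs), 1L),
             expected_fraction = as.numeric(exp_cat) / sum(admixture$expected),
             stringsAsFactors = FALSE)
}

#' Planted-insertion validation harness
#'
#' Emulates the pipeline-validation design: random reference-derived
#' fragments (default one hundred 100 bp sequences) are inserted at
#' random genomic locations, each insertion creating two novel junctions
#' (one at each flank of the inserted fragment). Carrier split reads are
#' synthesized, the full calling pipeline is run, and recovered
#' junctions are scored against the truth within a breakend tolerance.
#'
#' @param genome a [genome_model].
#' @param n_events number of planted insertions (default 100).
#' @param fragment_length inserted fragment length (default 100 bp).
#' @param n_background background reads mixed in.
#' @param tolerance breakend match tolerance in bp (default 5).
#' @param config a [filter_config].
#' @param seed integer seed.
#' @return list: `sensitivity` (recovered truth junctions / total),
#'   `n_recovered`, `n_truth`, `n_false_positive`, `junctions`, `truth`.
#' @export
validation_harness <- function(genome, n_events = 100L,
                               fragment_length = 100L,
                               n_background = 2000L, tolerance = 5L,
                               config = filter_config(), seed = NULL) {
  with_seed(seed, {
    L <- 126L
    events <- vector("list", 2L * n_events)
    g <- genome
    if (n_events > 0L) {
      for (i in seq_len(n_events)) {
        # fragment [fs, fs+len) copied from a random nuclear locus and
        # inserted at site q: junction 1 = (q-1 | fragment start),
        # junction 2 = (fragment end | q)
        src <- random_locus(g, fragment_length + L, "b", L + 60L,
                            contigs = nuclear_contigs(g))
        site <- random_locus(g, L, "a", L + 60L,
                             contigs = nuclear_contigs(g))
        fs <- src$pos
        q <- site$pos
        o1 <- sample(45:(L - 45L), 1L)
        events[[2L * i - 1L]] <- data.frame(
          read_id = sprintf("ins%03d_left", i),
          contig_a = site$contig, pos_a = q - 1L, strand_a = "+",
          contig_b = src$contig, pos_b = fs, strand_b = "+",
          class = "blunt", length = 0L, inserted_seq = NA_character_,
          read_offset = o1, read_length = L, recoverable = TRUE,
          stringsAsFactors = FALSE)
        o2 <- sample(45:(L - 45L), 1L)
        events[[2L * i]] <- data.frame(
          read_id = sprintf("ins%03d_right", i),
          contig_a = src$contig, pos_a = fs + fragment_length - 1L,
          strand_a = "+",
          contig_b = site$contig, pos_b = q, strand_b = "+",
          class = "blunt", length = 0L, inserted_seq = NA_character_,
          read_offset = o2, read_length = L, recoverable = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    truth <- if (n_events > 0L) do.call(rbind, events) else empty_truth()
    syn <- synthesize_split_reads(g, truth, read_length = L,
                                  n_background = n_background)
    res <- call_sample(list(records = syn$records, contigs = syn$contigs),
                       g, config)
    jn <- res$junctions
    truth_c <- canonicalize_junctions(
      as.data.frame(truth)[, names(empty_junctions())[1:8]], g)
    matched <- logical(nrow(truth_c))
    fp <- rep(TRUE, nrow(jn))
    if (nrow(jn) && nrow(truth_c)) {
      for (t in seq_len(nrow(truth_c))) {
        hit <- which(jn$contig_a == truth_c$contig_a[t] &
                       jn$contig_b == truth_c$contig_b[t] &
                       abs(jn$pos_a - truth_c$pos_a[t]) <= tolerance &
                       abs(jn$pos_b - truth_c$pos_b[t]) <= tolerance)
        if (length(hit)) {
          matched[t] <- TRUE
          fp[hit] <- FALSE
        }
      }
    }
    list(sensitivity = if (nrow(truth_c)) mean(matched) else NA_real_,
         n_recovered = sum(matched), n_truth = nrow(truth_c),
         n_false_positive = if (nrow(jn)) sum(fp) else 0L,
         junctions = jn, truth = truth)
  })
}
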