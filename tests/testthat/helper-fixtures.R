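# Shared fixtures and independent brute-force oracles. Oracles are
# deliberately naive re-implementations (loops, string scans) kept
# separate from the package's vectorised code paths.

small_genome <- function(seed = 42, ...) {
  generate_genome(contig_lengths = c(chrI = 60000, chrII = 40000),
                  mito_length = 6000, n_genes = 20, n_trnas = 6,
                  seed = seed, ...)
}

# Plant a batch of events with the given classes/lengths into a genome,
# returning the edited genome and combined truth table.
plant_batch <- function(genome, classes, lengths, seed = 1,
                        read_length = 126L) {
  pb <- plant_rearrangements(genome, classes, lengths,
                             read_length = read_length, seed = seed)
  list(genome = pb$genome, truth = pb$truth)
}

# -- independent CIGAR oracle: slow per-op walk ------------------------
oracle_cigar <- function(cigar) {
  if (cigar == "*") return(NULL)
  lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " ")[[1]])
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
  stopifnot(length(lens) == length(ops))
  list(lens = lens, ops = ops,
       clip_left = if (ops[1] %in% c("S", "H")) lens[1] else 0L,
       clip_right = if (length(ops) > 1 && ops[length(ops)] %in% c("S", "H"))
         lens[length(ops)] else 0L,
       qwidth = sum(lens[ops %in% c("M", "I", "=", "X")]),
       rwidth = sum(lens[ops %in% c("M", "D", "N", "=", "X")]),
       has_indel = any(ops %in% c("I", "D")))
}

# Read interval in original-read orientation, from a raw SAM record.
oracle_read_interval <- function(flag, cigar) {
  cg <- oracle_cigar(cigar)
  L <- cg$qwidth + cg$clip_left + cg$clip_right
  if (bitwAnd(flag, 16L) > 0L)
    c(cg$clip_right, L - cg$clip_left)
  else c(cg$clip_left, L - cg$clip_right)
}

# -- independent filter oracle: re-evaluate every predicate from the
#    raw SAM records of one read ---------------------------------------
oracle_filter_read <- function(recs, min_len = 40L, mapq = 60L) {
  prim <- recs[bitwAnd(recs$flag, 2048L) == 0L, , drop = FALSE]
  supp <- recs[bitwAnd(recs$flag, 2048L) > 0L, , drop = FALSE]
  if (nrow(prim) != 1L || nrow(supp) != 1L) return("not_split")
  verdict <- "pass"
  for (i in 1:2) {
    r <- rbind(prim, supp)[i, ]
    cg <- oracle_cigar(r$cigar)
    if (cg$clip_left > 0L && cg$clip_right > 0L) verdict <- "double_clipped"
  }
  for (i in 1:2) {
    r <- rbind(prim, supp)[i, ]
    if (r$mapq != mapq) verdict <- "low_mapq"
  }
  for (i in 1:2) {
    r <- rbind(prim, supp)[i, ]
    iv <- oracle_read_interval(r$flag, r$cigar)
    if (iv[2] - iv[1] < min_len) verdict <- "short_segment"
  }
  verdict
}

# -- brute-force interval overlap oracle -------------------------------
oracle_point_in_windows <- function(contig, pos, feat, flank = 0L) {
  any(feat$contig == contig & pos >= feat$start - flank &
        pos < feat$end + flank)
}

oracle_junction_hits <- function(jn, feat, flank = 0L) {
  vapply(seq_len(nrow(jn)), function(i) {
    oracle_point_in_windows(jn$contig_a[i], jn$pos_a[i], feat, flank) ||
      oracle_point_in_windows(jn$contig_b[i], jn$pos_b[i], feat, flank)
  }, logical(1))
}

oracle_gc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  mean(ch %in% c("G", "C"))
}

# Match called junctions against a truth table; returns per-truth-row
# logical (coordinates within tol, class and length exact).
match_truth <- function(junctions, truth, genome, tol = 0L,
                        check_signature = TRUE) {
  tr <- canonicalize_junctions(
    truth[, c("contig_a", "pos_a", "strand_a", "contig_b", "pos_b",
              "strand_b", "class", "length")], genome)
  vapply(seq_len(nrow(tr)), function(i) {
    hit <- junctions$contig_a == tr$contig_a[i] &
      junctions$contig_b == tr$contig_b[i] &
      abs(junctions$pos_a - tr$pos_a[i]) <= tol &
      abs(junctions$pos_b - tr$pos_b[i]) <= tol
    if (check_signature)
      hit <- hit & junctions$class == tr$class[i] &
        junctions$length == tr$length[i]
    any(hit)
  }, logical(1))
}
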