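# SAM text I/O and CIGAR arithmetic.
#
# Junction evidence lives entirely in CIGAR strings of soft-clipped split
# reads, so the parser keeps exact per-op arithmetic: read-consuming ops
# are M/I/=/X (plus S for the SEQ field), reference-consuming ops are
# M/D/N/=/X. Coordinates are converted from SAM 1-based to 0-based
# half-open at parse time.

FLAG_UNMAPPED <- 4L
FLAG_REVERSE <- 16L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

# Per-record CIGAR summaries, vectorised over unique strings.
# Returns a data.table aligned with `cigar`:
#   clip_left/right      leading/trailing clip length (S or H)
#   sclip_left/right     soft-clip-only lengths (bases present in SEQ)
#   qwidth               read bases consumed by the alignment (M/I/=/X)
#   rwidth               reference bases consumed (M/D/N/=/X)
#   read_length          full original read length (incl. S and H clips)
#   has_indel            any I or D op
#   valid                syntactically valid CIGAR
cigar_stats <- function(cigar) {
  u <- unique(cigar)
  toks <- regmatches(u, gregexpr("[0-9]+[MIDNSHP=X]", u))
  one <- function(tk, cg) {
    if (!length(tk) || nchar(paste(tk, collapse = "")) != nchar(cg))
      return(c(NA_integer_, NA, NA, NA, NA, NA, NA, NA, 0L))
    n <- nchar(tk)
    len <- as.integer(substr(tk, 1L, n - 1L))
    op <- substr(tk, n, n)
    k <- length(op)
    cl <- if (op[1] %in% c("S", "H")) len[1] else 0L
    cr <- if (k > 1L && op[k] %in% c("S", "H")) len[k] else 0L
    scl <- if (op[1] == "S") len[1] else 0L
    scr <- if (k > 1L && op[k] == "S") len[k] else 0L
    qw <- sum(len[op %in% c("M", "I", "=", "X")])
    rw <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    tot <- qw + cl + cr
    c(cl, cr, scl, scr, qw, rw, tot, any(op %in% c("I", "D")), 1L)
  }
  m <- t(mapply(one, toks, u, USE.NAMES = FALSE))
  i <- match(cigar, u)
  data.table(
    clip_left = as.integer(m[i, 1]), clip_right = as.integer(m[i, 2]),
    sclip_left = as.integer(m[i, 3]), sclip_right = as.integer(m[i, 4]),
    qwidth = as.integer(m[i, 5]), rwidth = as.integer(m[i, 6]),
    read_length = as.integer(m[i, 7]),
    has_indel = as.logical(m[i, 8]), valid = as.logical(m[i, 9]))
}

#' Read alignment records from SAM (or BAM)
#'
#' Parses the 11 mandatory fields plus the `SA:Z` tag. `.bam` paths are
#' read through Rsamtools; anything else is treated as SAM text. A
#' character vector that is not an existing file path is interpreted as
#' SAM lines directly.
#'
#' @param x SAM file path, BAM file path, or character vector of SAM lines.
#' @return A list with `header` (character vector of header lines),
#'   `contigs` (named integer vector from `@SQ` lines) and `records`
#'   (a `data.table` with `qname`, `flag`, `rname`, `pos` (0-based start),
#'   `mapq`, `cigar`, `seq`, `sa`).
#' @export
read_sam <- function(x) {
  if (length(x) == 1L && file.exists(x) &&
      grepl("\\.bam$", x, ignore.case = TRUE)) {
    return(read_bam_records(x))
  }
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  rec <- lines[!is_hdr]
  rec <- rec[nzchar(rec)]
  contigs <- parse_sq_header(header)
  if (!length(rec)) {
    return(list(header = header, contigs = contigs, records = empty_sam_records()))
  }
  f <- data.table::tstrsplit(rec, "\t", fixed = TRUE, keep = 1:10)
  sa <- rep(NA_character_, length(rec))
  hit <- regexpr("SA:Z:[^\t]+", rec)
  has <- hit > 0L
  sa[has] <- substring(rec[has], hit[has] + 5L,
                       hit[has] + attr(hit, "match.length")[has] - 1L)
  list(header = header, contigs = contigs,
       records = data.table(
         qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
         pos = as.integer(f[[4]]) - 1L, mapq = as.integer(f[[5]]),
         cigar = f[[6]], seq = f[[10]], sa = sa))
}

empty_sam_records <- function() {
  data.table(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), sa = character())
}

parse_sq_header <- function(header) {
  sq <- header[startsWith(header, "@SQ")]
  if (!length(sq)) return(setNames(integer(), character()))
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  setNames(ln, sn)
}

read_bam_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "SA")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  contigs <- setNames(as.integer(hdr$targets), names(hdr$targets))
  keep <- !is.na(b$pos)
  list(header = character(), contigs = contigs,
       records = data.table(
         qname = b$qname[keep], flag = as.integer(b$flag[keep]),
         rname = as.character(b$rname[keep]), pos = b$pos[keep] - 1L,
         mapq = as.integer(b$mapq[keep]), cigar = b$cigar[keep],
         seq = as.character(b$seq[keep]),
         sa = (b$tag$SA %||% rep(NA_character_, sum(keep)))[keep]))
}

#' Write SAM records to a file
#'
#' @param records a `data.table`/`data.frame` in the layout returned by
#'   [read_sam] (`pos` 0-based; `sa` optional).
#' @param contigs named integer vector of contig lengths for `@SQ` lines.
#' @param path output path.
#' @param sort sort records by (contig, position) before writing.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, contigs, path, sort = TRUE) {
  records <- as.data.frame(records)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      as.integer(contigs)))
  if (nrow(records)) {
    if (sort) {
      o <- order(match(records$rname, names(contigs)), records$pos)
      records <- records[o, , drop = FALSE]
    }
    qual <- strrep("I", nchar(records$seq))
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     records$qname, records$flag, records$rname,
                     records$pos + 1L, records$mapq, records$cigar,
                     records$seq, qual)
    if (!is.null(records$sa)) {
      has <- !is.na(records$sa)
      lines[has] <- paste0(lines[has], "\tSA:Z:", records$sa[has])
    }
  } else lines <- character()
  writeLines(c(header, lines), path)
  invisible(path)
}
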