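#' Genome model: contigs, circularity flags and feature annotations
#'
#' A `genome_model` bundles contig sequences (plain uppercase A/C/G/T
#' strings), a circularity flag per contig (at most one contig, the
#' mitochondrial stand-in, may be circular) and a feature table
#' (`contig`, `start`, `end`, `strand`, `kind`, `gene_id`) with 0-based
#' half-open coordinates and `kind` in `CDS`, `5UTR`, `3UTR`, `tRNA`,
#' `gene`.
#'
#' @param contigs named character vector of contig sequences.
#' @param circular named logical vector (same names); at most one `TRUE`.
#' @param annotations feature `data.frame` as described above (may be empty).
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(contigs, circular = NULL,
                         annotations = empty_annotations()) {
  stopifnot(is.character(contigs), length(contigs) >= 1L,
            !is.null(names(contigs)), !anyDuplicated(names(contigs)))
  if (is.null(circular)) {
    circular <- setNames(rep(FALSE, length(contigs)), names(contigs))
  }
  circular <- circular[names(contigs)]
  if (sum(circular) > 1L)
    stop("at most one contig may be flagged circular")
  g <- structure(
    list(contigs = contigs, circular = circular,
         annotations = as.data.frame(annotations)),
    class = "genome_model")
  validate_genome(g)
  g
}

empty_annotations <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), gene_id = character(),
             stringsAsFactors = FALSE)
}

validate_genome <- function(g) {
  ann <- g$annotations
  if (nrow(ann)) {
    lens <- contig_lengths(g)
    if (!all(ann$contig %in% names(lens)))
      stop("annotation on unknown contig")
    if (any(ann$start < 0L | ann$end > lens[ann$contig] | ann$start >= ann$end))
      stop("feature outside contig bounds or start >= end")
    # same-kind, same-strand features must not overlap
    key <- split(seq_len(nrow(ann)), paste(ann$contig, ann$kind, ann$strand))
    for (idx in key) {
      if (length(idx) < 2L) next
      o <- order(ann$start[idx])
      s <- ann$start[idx][o]; e <- ann$end[idx][o]
      if (any(s[-1] < e[-length(e)]))
        stop("overlapping features of the same kind and strand")
    }
  }
  invisible(g)
}

#' @export
print.genome_model <- function(x, ...) {
  lens <- contig_lengths(x)
  cat("genome_model:", length(lens), "contig(s),",
      sum(lens), "bp total\n")
  for (nm in names(lens))
    cat(sprintf("  %s  %d bp%s\n", nm, lens[[nm]],
                if (x$circular[[nm]]) "  (circular)" else ""))
  cat("  features:", nrow(x$annotations), "\n")
  invisible(x)
}

#' Contig lengths of a genome_model
#' @param genome a [genome_model].
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  vapply(genome$contigs, nchar, integer(1))
}

contig_rank <- function(genome) {
  setNames(seq_along(genome$contigs), names(genome$contigs))
}

nuclear_contigs <- function(genome) {
  names(genome$contigs)[!genome$circular]
}

#' Generate a synthetic annotated genome
#'
#' Draws i.i.d. bases at a target GC fraction for a set of nuclear contigs
#' plus one small circular contig standing in for the mitochondrial
#' chromosome, then places non-overlapping gene models (5'UTR, CDS, 3'UTR,
#' whole-gene span) and tRNA genes on the nuclear contigs.
#'
#' @param contig_lengths integer vector of nuclear contig lengths (bp,
#'   each >= 1000); names become contig names (default `chrI`, `chrII`, ...).
#' @param gc target GC fraction in (0, 1). Default 0.36, typical of the
#'   fission-yeast genome.
#' @param mito_length length of the circular mitochondrial contig (0 to omit).
#' @param n_genes number of gene models to place across nuclear contigs;
#'   the default (one per 4 kb) gives the dense, largely coding genome
#'   typical of yeasts.
#' @param cds_length,utr5_length,utr3_length gene part lengths (bp).
#' @param n_trnas number of 80 bp tRNA genes placed in intergenic space.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return A [genome_model].
#' @export
generate_genome <- function(contig_lengths = c(chrI = 1e6, chrII = 1e6, chrIII = 1e6),
                            gc = 0.36, mito_length = 20000L,
                            n_genes = round(sum(contig_lengths) / 4000),
                            cds_length = 1200L,
                            utr5_length = 150L, utr3_length = 300L,
                            n_trnas = 20L, seed = NULL) {
  stopifnot(all(contig_lengths >= 1000), gc > 0, gc < 1)
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", as.roman(seq_along(contig_lengths)))
  with_seed(seed, {
    contigs <- vapply(contig_lengths, random_dna, character(1), gc = gc)
    circular <- setNames(rep(FALSE, length(contigs)), names(contigs))
    if (mito_length > 0) {
      contigs <- c(contigs, mito = random_dna(mito_length, gc))
      circular <- c(circular, mito = TRUE)
    }
    ann <- place_genes(names(contig_lengths), contig_lengths, n_genes,
                       cds_length, utr5_length, utr3_length, n_trnas)
    genome_model(contigs, circular, ann)
  })
}

# Non-overlapping gene placement: genes are allotted to contigs in
# proportion to length, then laid left to right with random intergenic
# gaps; tRNAs go into leftover intergenic space.
place_genes <- function(contig_names, contig_lengths, n_genes,
                        cds_length, utr5_length, utr3_length, n_trnas) {
  if (n_genes == 0L && n_trnas == 0L) return(empty_annotations())
  unit <- utr5_length + cds_length + utr3_length
  share <- contig_lengths / sum(contig_lengths)
  per_contig <- diff(round(cumsum(c(0, share)) * n_genes))
  per_trna <- diff(round(cumsum(c(0, share)) * n_trnas))
  rows <- list()
  for (ci in seq_along(contig_names)) {
    k <- per_contig[ci]; kt <- per_trna[ci]
    len <- contig_lengths[ci]
    need <- k * unit + kt * 80L
    if (need > 0.8 * len)
      stop("n_genes infeasible for contig lengths")
    # random non-overlapping starts: spread slack as random gaps
    blocks <- c(rep(unit, k), rep(80L, kt))
    if (!length(blocks)) next
    blocks <- blocks[sample.int(length(blocks))]  # interleave tRNAs among genes
    slack <- len - sum(blocks)
    gaps <- floor(slack * diff(c(0, sort(runif(length(blocks))))))
    starts <- cumsum(gaps) + cumsum(c(0L, blocks[-length(blocks)]))
    is_gene <- blocks == unit
    gi <- cumsum(is_gene)
    for (b in seq_along(blocks)) {
      s <- as.integer(starts[b]); strand <- sample(c("+", "-"), 1L)
      cn <- contig_names[ci]
      if (is_gene[b]) {
        id <- sprintf("%s.g%03d", cn, gi[b])
        e <- s + unit
        if (strand == "+") {
          p5 <- c(s, s + utr5_length)
          cds <- c(p5[2], p5[2] + cds_length)
          p3 <- c(cds[2], e)
        } else {
          p3 <- c(s, s + utr3_length)
          cds <- c(p3[2], p3[2] + cds_length)
          p5 <- c(cds[2], e)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cn,
          start = c(s, p5[1], cds[1], p3[1]),
          end = c(e, p5[2], cds[2], p3[2]),
          strand = strand,
          kind = c("gene", "5UTR", "CDS", "3UTR"),
          gene_id = id, stringsAsFactors = FALSE)
      } else {
        id <- sprintf("%s.t%03d", cn, b)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cn, start = s, end = s + 80L, strand = strand,
          kind = "tRNA", gene_id = id, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a genome_model to FASTA (and optionally GFF3)
#'
#' @param genome a [genome_model].
#' @param fasta output FASTA path.
#' @param gff3 optional GFF3 path for the annotations.
#' @return Invisibly, the FASTA path.
#' @export
write_genome <- function(genome, fasta, gff3 = NULL) {
  dss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dss, fasta)
  if (!is.null(gff3)) write_annotations_gff3(genome, gff3)
  invisible(fasta)
}

#' @rdname write_genome
#' @export
write_annotations_gff3 <- function(genome, gff3) {
  ann <- genome$annotations
  gr <- GenomicRanges::GRanges(
    ann$contig,
    IRanges::IRanges(ann$start + 1L, ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- gff3_type(ann$kind)
  S4Vectors::mcols(gr)$ID <- paste0(ann$gene_id, ":", ann$kind)
  S4Vectors::mcols(gr)$gene_id <- ann$gene_id
  S4Vectors::mcols(gr)$phase <- ifelse(ann$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(gff3)
}

gff3_type <- function(kind) {
  map <- c(CDS = "CDS", `5UTR` = "five_prime_UTR", `3UTR` = "three_prime_UTR",
           tRNA = "tRNA", gene = "gene")
  unname(map[kind])
}

#' Read a genome_model from FASTA (and optionally GFF3)
#'
#' @param fasta FASTA path.
#' @param gff3 optional GFF3 annotation path (types as written by
#'   [write_annotations_gff3]).
#' @param circular character vector of contig names flagged circular.
#' @return A [genome_model].
#' @export
read_genome <- function(fasta, gff3 = NULL, circular = "mito") {
  dss <- Biostrings::readDNAStringSet(fasta)
  names(dss) <- sub("\\s.*$", "", names(dss))
  contigs <- as.character(dss)
  circ <- setNames(names(contigs) %in% circular, names(contigs))
  ann <- empty_annotations()
  if (!is.null(gff3)) {
    gr <- rtracklayer::import(gff3, format = "gff3")
    inv <- c(CDS = "CDS", five_prime_UTR = "5UTR", three_prime_UTR = "3UTR",
             tRNA = "tRNA", gene = "gene")
    kind <- inv[as.character(gr$type)]
    keep <- !is.na(kind)
    gr <- gr[keep]
    gid <- gr$gene_id
    if (is.null(gid)) gid <- sub(":.*$", "", gr$ID %||% as.character(seq_along(gr)))
    ann <- data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      kind = unname(kind[keep]),
      gene_id = gid, stringsAsFactors = FALSE)
  }
  genome_model(contigs, circ, ann)
}

#' Features of one kind as GRanges
#'
#' @param genome a [genome_model] (or a feature `data.frame` with the same
#'   annotation columns).
#' @param kind feature kind to select, e.g. `"CDS"`; `NULL` keeps all.
#' @return A `GRanges` (1-based closed coordinates) with `gene_id`, `kind`.
#' @export
features_granges <- function(genome, kind = NULL) {
  ann <- if (inherits(genome, "genome_model")) genome$annotations else genome
  if (!is.null(kind)) ann <- ann[ann$kind %in% kind, , drop = FALSE]
  GenomicRanges::GRanges(
    ann$contig, IRanges::IRanges(ann$start + 1L, ann$end),
    strand = ann$strand, gene_id = ann$gene_id, kind = ann$kind)
}
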