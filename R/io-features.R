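#' Genome layout: chromosome lengths and assembly gaps
#'
#' The layout drives positional randomization, density binning, and the
#' effective (gap-excluded) chromosome lengths. Gaps are runs of unknown
#' sequence (N-gaps) that reads cannot align to; they are excluded from
#' randomization space and from effective length.
#'
#' @param lengths named vector of chromosome lengths in bp.
#' @param gaps gap intervals: a `GRanges`, or a data.frame with `chrom`,
#'   `start`, `end` in 0-based half-open coordinates. Overlapping gaps are
#'   unioned and clipped to the chromosome.
#' @return an object of class `genome_layout` with elements `lengths`
#'   (named integer) and `gaps` (reduced `GRanges`).
#' @export
genome_layout <- function(lengths, gaps = NULL) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  si <- GenomeInfoDb::Seqinfo(seqnames = names(lengths), seqlengths = lengths)
  if (is.null(gaps)) {
    gr <- GenomicRanges::GRanges(seqinfo = si)
  } else {
    if (is.data.frame(gaps)) {
      gr <- GenomicRanges::GRanges(gaps$chrom,
                                   IRanges::IRanges(start = gaps$start + 1, end = gaps$end))
    } else {
      gr <- gaps
    }
    GenomeInfoDb::seqlevels(gr) <- names(lengths)
    GenomeInfoDb::seqinfo(gr) <- si
    gr <- GenomicRanges::trim(gr)
    gr <- GenomicRanges::reduce(gr)
  }
  structure(list(lengths = lengths, gaps = gr), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$lengths), "chromosomes,",
      sum(x$lengths), "bp,", length(x$gaps), "gap intervals\n")
  invisible(x)
}

#' Effective chromosome lengths (gaps excluded)
#' @param layout a [genome_layout()].
#' @return named numeric vector of length minus gap bp per chromosome.
#' @export
effective_lengths <- function(layout) {
  gap_bp <- rep(0, length(layout$lengths))
  names(gap_bp) <- names(layout$lengths)
  if (length(layout$gaps)) {
    tab <- tapply(BiocGenerics::width(layout$gaps),
                  as.character(GenomeInfoDb::seqnames(layout$gaps)), sum)
    gap_bp[names(tab)] <- tab
  }
  layout$lengths - gap_bp
}

#' Read a genome layout from a FASTA index and optional gaps BED
#'
#' @param fai path to a `.fai`-style table (name, length in the first two
#'   columns).
#' @param gaps_bed optional BED3 file of assembly gaps.
#' @return a [genome_layout()].
#' @export
read_genome_layout <- function(fai, gaps_bed = NULL) {
  tab <- utils::read.table(fai, header = FALSE, colClasses = c("character", "numeric"),
                           fill = TRUE)[, 1:2]
  gaps <- if (!is.null(gaps_bed)) rtracklayer::import(gaps_bed, format = "BED") else NULL
  genome_layout(stats::setNames(tab[[2]], tab[[1]]), gaps)
}

# whole chromosomes as GRanges
chromosome_ranges <- function(layout) {
  GenomicRanges::GRanges(names(layout$lengths),
                         IRanges::IRanges(1, layout$lengths),
                         seqinfo = GenomeInfoDb::Seqinfo(names(layout$lengths),
                                                         layout$lengths))
}

#' Genomic feature classes for overlap analysis
#'
#' From gene/exon/CDS intervals derives the four classes used to localize
#' SVs: introns (gene space not covered by exons) and intergenic space
#' (chromosome not covered by genes). Intervals of the same class are
#' unioned, exons are clipped to genes and CDS to exons, so the identities
#' `introns + exons == genes` (in bp) and `intergenic == genome - genes`
#' hold by construction.
#'
#' @param genes,exons,cds `GRanges`, or data.frames with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates.
#' @param genome a [genome_layout()].
#' @return object of class `feature_set`: list of reduced `GRanges` for
#'   `genes`, `exons`, `cds`, `introns`, `intergenic`.
#' @export
feature_set <- function(genes, exons, cds, genome) {
  si <- GenomeInfoDb::Seqinfo(names(genome$lengths), genome$lengths)
  conv <- function(x) {
    if (is.data.frame(x)) {
      x <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
    }
    x <- GenomicRanges::granges(x)
    GenomeInfoDb::seqlevels(x) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(x) <- si
    GenomicRanges::reduce(GenomicRanges::trim(x))
  }
  genes <- conv(genes)
  exons <- GenomicRanges::intersect(conv(exons), genes)
  cds <- GenomicRanges::intersect(conv(cds), exons)
  introns <- GenomicRanges::setdiff(genes, exons)
  intergenic <- GenomicRanges::setdiff(chromosome_ranges(genome), genes)
  structure(list(genes = genes, exons = exons, cds = cds,
                 introns = introns, intergenic = intergenic),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  for (cl in names(x))
    cat(sprintf("  %-10s %6d intervals %12.0f bp\n", cl, length(x[[cl]]),
                sum(BiocGenerics::width(x[[cl]]))))
  invisible(x)
}

#' Read gene annotation into a feature set
#'
#' Accepts either a GFF3 file holding `gene`, `exon` and `CDS` rows, or a
#' named list of three BED files.
#'
#' @param path GFF3 path, or a named list/vector with elements `genes`,
#'   `exons`, `cds` of BED paths.
#' @param genome a [genome_layout()].
#' @return a [feature_set()].
#' @export
read_features <- function(path, genome) {
  if (is.list(path) || (is.character(path) && length(path) == 3)) {
    path <- as.list(path)
    stopifnot(all(c("genes", "exons", "cds") %in% names(path)))
    g <- rtracklayer::import(path$genes, format = "BED")
    e <- rtracklayer::import(path$exons, format = "BED")
    cd <- rtracklayer::import(path$cds, format = "BED")
  } else {
    gff <- rtracklayer::import(path, format = "GFF3")
    type <- as.character(gff$type)
    g <- gff[type == "gene"]
    e <- gff[type == "exon"]
    cd <- gff[type == "CDS"]
  }
  feature_set(g, e, cd, genome)
}
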