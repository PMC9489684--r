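#' Mean quality score of a read
#'
#' Computed in probability space, the long-read convention: per-base Phred
#' scores are converted to error probabilities, averaged, and converted
#' back (`-10 log10(mean(10^(-q/10)))`). An arithmetic mean of the Phred
#' values is available as a switch.
#'
#' @param q numeric vector of per-base Phred scores.
#' @param arithmetic use the arithmetic mean of Phred values instead.
#' @return the mean quality score (NA for an empty read).
#' @export
mean_read_quality <- function(q, arithmetic = FALSE) {
  if (length(q) == 0) return(NA_real_)
  if (arithmetic) return(mean(q))
  -10 * log10(mean(10^(-q / 10)))
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `length`, `mean_quality`, and the
#'   per-base qualities as a list column `quals`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as.list(as(Biostrings::quality(x), "IntegerList"))
  out <- data.frame(read_id = names(x), length = Biostrings::width(x),
                    mean_quality = vapply(quals, mean_read_quality, 1.0),
                    stringsAsFactors = FALSE)
  out$quals <- quals
  out
}

#' Filter and crop long reads
#'
#' Keeps reads whose mean quality score is strictly greater than
#' `min_mean_q` (computed on the full read), then crops `crop` bp from each
#' end; reads with nothing left after cropping are dropped.
#'
#' @param reads data.frame from [read_fastq()] (needs `length` and
#'   `mean_quality`; `quals` is cropped too when present).
#' @param min_mean_q quality threshold (strict; default 6).
#' @param crop bases removed from head and tail (default 100).
#' @return the filtered data.frame with updated `length` (and `quals`).
#' @export
filter_and_crop <- function(reads, min_mean_q = 6, crop = 100) {
  keep <- reads$mean_quality > min_mean_q & reads$length > 2 * crop
  out <- reads[keep, , drop = FALSE]
  if (!is.null(out$quals)) {
    out$quals <- lapply(out$quals, function(q) q[(crop + 1):(length(q) - crop)])
  }
  out$length <- out$length - 2L * as.integer(crop)
  rownames(out) <- NULL
  out
}

#' Read-length N50
#'
#' The smallest length L such that reads of length >= L together contain at
#' least half of all sequenced bases.
#'
#' @param lengths numeric vector of read lengths (bp).
#' @return the N50 in bp (NA for an empty input).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) return(NA_real_)
  stopifnot(all(lengths > 0))
  l <- sort(lengths, decreasing = TRUE)
  l[which(cumsum(l) >= sum(l) / 2)[1]]
}

#' Per-read alignment error profile
#'
#' Decomposes alignment errors into insertion, deletion and mismatch rates.
#' Rates are fractions of aligned read bases (matches + mismatches +
#' inserted bases). Mismatches come from extended CIGAR `X` operations when
#' the alignment uses `=`/`X`; otherwise they are recovered from the `NM`
#' edit distance (NM minus inserted minus deleted bases). Only mapped
#' primary alignments are profiled; records with neither extended CIGAR nor
#' `NM` are skipped and counted.
#'
#' @param x path to a SAM file, or a data.frame with columns `cigar` and
#'   optionally `nm` and `flag`.
#' @return list with `per_read` (data.frame: `cigar`-derived
#'   `aligned_bases`, `insertion_rate`, `deletion_rate`, `mismatch_rate`,
#'   `total_rate`), `median` (named cohort medians), and `n_skipped`.
#' @export
alignment_error_profile <- function(x) {
  if (is.character(x)) {
    bam <- Rsamtools::asBam(x, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
    rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "cigar"), tag = "NM"))[[1]]
    d <- data.frame(cigar = rec$cigar, flag = rec$flag, stringsAsFactors = FALSE)
    d$nm <- if (!is.null(rec$tag$NM)) rec$tag$NM else NA_integer_
  } else {
    d <- x
    if (is.null(d$flag)) d$flag <- 0L
    if (is.null(d$nm)) d$nm <- NA_integer_
  }
  primary <- !is.na(d$cigar) & bitwAnd(d$flag, 0x4L) == 0L &
    bitwAnd(d$flag, 0x100L) == 0L & bitwAnd(d$flag, 0x800L) == 0L
  d <- d[primary, , drop = FALSE]
  ops <- GenomicAlignments::cigarOpTable(d$cigar)
  has_ext <- (ops[, "="] + ops[, "X"]) > 0
  usable <- has_ext | !is.na(d$nm)
  n_skipped <- sum(!usable)
  d <- d[usable, , drop = FALSE]
  ops <- ops[usable, , drop = FALSE]
  ins <- ops[, "I"]
  del <- ops[, "D"]
  mism <- ifelse(has_ext[usable], ops[, "X"], pmax(0L, d$nm - ins - del))
  aligned <- ops[, "M"] + ops[, "="] + ops[, "X"] + ins
  per_read <- data.frame(aligned_bases = aligned,
                         insertion_rate = ins / aligned,
                         deletion_rate = del / aligned,
                         mismatch_rate = mism / aligned)
  per_read$total_rate <- per_read$insertion_rate + per_read$deletion_rate +
    per_read$mismatch_rate
  med <- vapply(per_read[c("insertion_rate", "deletion_rate", "mismatch_rate",
                           "total_rate")], stats::median, 1.0)
  list(per_read = per_read, median = med, n_skipped = n_skipped)
}

#' Simulate read alignments at known error rates
#'
#' Generates extended-CIGAR alignment records where each aligned read base
#' is independently an insertion, a mismatch, or a match, and deletions are
#' interleaved at the given per-base rate — a generative stand-in for real
#' alignments used to check that [alignment_error_profile()] recovers the
#' injected rates. Purely synthetic.
#'
#' @param n_reads number of reads.
#' @param read_length aligned read length (bases).
#' @param ins_rate,del_rate,mism_rate per-base event rates.
#' @param seed RNG seed.
#' @return data.frame with `cigar`, `nm`, `flag` usable directly by
#'   [alignment_error_profile()].
#' @export
simulate_read_alignments <- function(n_reads, read_length = 5000,
                                     ins_rate = 0.02, del_rate = 0.03,
                                     mism_rate = 0.02, seed = 1) {
  set.seed(seed)
  mk <- function() {
    u <- stats::runif(read_length)
    state <- ifelse(u < ins_rate, "I",
                    ifelse(u < ins_rate + mism_rate, "X", "="))
    ndel <- stats::rbinom(1, read_length, del_rate)
    if (ndel > 0) {
      at <- sort(sample.int(read_length, min(ndel, read_length)))
      out <- character(2 * length(at) + 1)
      prev <- 0
      segs <- character(0)
      bounds <- c(at, read_length + 1)
      for (j in seq_along(at)) {
        segs <- c(segs, state[(prev + 1):(at[j])], "D")
        prev <- at[j]
      }
      if (prev < read_length) segs <- c(segs, state[(prev + 1):read_length])
      state <- segs
    }
    r <- rle(state)
    nm <- sum(r$lengths[r$values %in% c("I", "X", "D")])
    data.frame(cigar = paste0(paste0(r$lengths, r$values, collapse = ""), ""),
               nm = nm, flag = 0L, stringsAsFactors = FALSE)
  }
  do.call(rbind, replicate(n_reads, mk(), simplify = FALSE))
}
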