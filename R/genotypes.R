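#' Biallelic genotype codes
#'
#' Genotypes are represented throughout as the strings `"0/0"`, `"0/1"`,
#' `"1/1"` and `"./."` (missing). `0` denotes the reference allele and `1`
#' the alternative allele of a biallelic SV site.
#'
#' @format A character vector of the four valid codes.
#' @export
GT_CODES <- c("0/0", "0/1", "1/1", "./.")

#' Normalize genotype strings
#'
#' Maps phased separators to unphased (`"0|1"` -> `"0/1"`), orders the
#' alleles (`"1/0"` -> `"0/1"`), and collapses anything containing a missing
#' allele or an allele index above 1 (multi-allelic leftovers) to `"./."`.
#'
#' @param gt character vector of raw GT strings (NA allowed).
#' @return character vector using only the four codes in [GT_CODES].
#' @export
normalize_gt <- function(gt) {
  gt <- as.character(gt)
  gt[is.na(gt) | gt == ""] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"
  gt[!(gt %in% c("0/0", "0/1", "1/1"))] <- "./."
  gt
}

#' Alternative-allele dosage of a genotype
#'
#' @param gt character vector of genotype codes.
#' @return integer vector: 0, 1, 2, or `NA` for missing.
#' @export
gt_dosage <- function(gt) {
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  out <- unname(map[gt])
  out
}

#' Genotype code from an alternative-allele dosage
#'
#' @param d integer vector of dosages (0, 1, 2 or NA).
#' @return character vector of genotype codes.
#' @export
dosage_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d)] <- c("0/0", "0/1", "1/1")[d[!is.na(d)] + 1L]
  out
}
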