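#' Read a structural-variant VCF
#'
#' Parses a (possibly multi-sample) VCF of DEL/INS structural variants.
#' Records are filtered on ingest following the study's calling contract:
#' `SVTYPE` must be `DEL` or `INS`, `|SVLEN|` must be at least `min_svlen`
#' (the caller's 50 bp floor), and only autosomal records are kept, since
#' diploid genotypes are assumed throughout. Negative `SVLEN` (a common
#' deletion convention) is stored as its absolute value. Multi-allelic
#' records are reduced to their first alternative allele; genotypes that
#' reference a dropped allele become missing.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param min_svlen minimum SV length in bp (default 50).
#' @return a list with elements
#'   \describe{
#'     \item{samples}{character vector of sample IDs (may be empty).}
#'     \item{records}{data.frame of surviving records: `chrom`, `pos`, `id`,
#'       `svtype`, `svlen`, `end`, plus any panel INFO fields present
#'       (`ac`, `an`, `category`, `mie_families`, `mie_eval`).}
#'     \item{gt}{normalized genotype character matrix (records x samples).}
#'     \item{skipped}{data.frame of drop reasons and counts.}
#'   }
#' @seealso [as_sv_calls()], [read_sv_panel()], [write_sv_vcf()]
#' @export
read_sv_vcf <- function(path, min_svlen = 50) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  n <- nrow(fix)
  has_gt <- !is.null(v@gt) && ncol(v@gt) > 1
  samples <- if (has_gt) colnames(v@gt)[-1] else character()

  empty <- list(samples = samples,
                records = data.frame(chrom = character(), pos = integer(),
                                     id = character(), svtype = character(),
                                     svlen = integer(), end = integer(),
                                     stringsAsFactors = FALSE),
                gt = matrix(character(), nrow = 0, ncol = length(samples),
                            dimnames = list(NULL, samples)),
                skipped = data.frame(reason = character(), n = integer()))
  if (n == 0) return(empty)

  first_field <- function(x) {
    x <- as.character(x)
    sub(",.*$", "", x)
  }
  svtype <- first_field(vcfR::extract.info(v, "SVTYPE"))
  svlen <- suppressWarnings(as.numeric(first_field(vcfR::extract.info(v, "SVLEN"))))
  endf <- suppressWarnings(as.numeric(first_field(vcfR::extract.info(v, "END"))))

  reason <- rep(NA_character_, n)
  reason[is.na(reason) & (is.na(svtype) | is.na(svlen))] <- "missing SVTYPE/SVLEN"
  reason[is.na(reason) & !(svtype %in% c("DEL", "INS"))] <- "SVTYPE not DEL/INS"
  reason[is.na(reason) & abs(svlen) < min_svlen] <- sprintf("SVLEN below %d", min_svlen)
  reason[is.na(reason) & !is_autosome(fix[, "CHROM"])] <- "non-autosome"
  keep <- is.na(reason)
  tab <- table(reason[!keep])
  skipped <- data.frame(reason = names(tab), n = as.integer(tab),
                        stringsAsFactors = FALSE)
  if (!any(keep)) stop("no usable DEL/INS records in ", path)

  pos <- as.integer(fix[, "POS"])
  svl <- as.integer(round(abs(svlen)))
  records <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                        id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                    paste(fix[, "CHROM"], pos, svtype, sep = "_"),
                                    fix[, "ID"]),
                        svtype = svtype, svlen = svl,
                        end = ifelse(svtype == "DEL", pos + svl, pos),
                        stringsAsFactors = FALSE)

  # optional panel INFO fields, used by read_sv_panel()
  opt_int <- function(tag) suppressWarnings(as.integer(vcfR::extract.info(v, tag)))
  info_keys <- paste(fix[, "INFO"], collapse = ";")
  if (grepl("AC=", info_keys, fixed = TRUE)) records$ac <- opt_int("AC")
  if (grepl("AN=", info_keys, fixed = TRUE)) records$an <- opt_int("AN")
  if (grepl("MAF_CATEGORY=", info_keys, fixed = TRUE))
    records$category <- as.character(vcfR::extract.info(v, "MAF_CATEGORY"))
  if (grepl("MIE_FAMILIES=", info_keys, fixed = TRUE))
    records$mie_families <- opt_int("MIE_FAMILIES")
  if (grepl("MIE_EVAL=", info_keys, fixed = TRUE)) records$mie_eval <- opt_int("MIE_EVAL")

  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- matrix(normalize_gt(gt), nrow = n, dimnames = list(NULL, samples))
  } else {
    gt <- matrix(character(), nrow = n, ncol = 0)
  }
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  gt <- gt[keep, , drop = FALSE]
  list(samples = samples, records = records, gt = gt, skipped = skipped)
}

#' Flatten a read VCF into per-sample SV calls
#'
#' Produces the long "one row per carrier observation" table the merge step
#' consumes: every (record, sample) pair whose genotype carries at least one
#' alternative allele becomes one call.
#'
#' @param x result of [read_sv_vcf()].
#' @return data.frame with columns `chrom`, `pos`, `svtype`, `svlen`, `end`,
#'   `sample_id`, `gt`.
#' @export
as_sv_calls <- function(x) {
  rec <- x$records
  if (nrow(rec) == 0 || length(x$samples) == 0) {
    return(data.frame(chrom = character(), pos = integer(), svtype = character(),
                      svlen = integer(), end = integer(), sample_id = character(),
                      gt = character(), stringsAsFactors = FALSE))
  }
  dos <- matrix(gt_dosage(x$gt), nrow = nrow(rec))
  idx <- which(!is.na(dos) & dos > 0, arr.ind = TRUE)
  out <- data.frame(chrom = rec$chrom[idx[, 1]], pos = rec$pos[idx[, 1]],
                    svtype = rec$svtype[idx[, 1]], svlen = rec$svlen[idx[, 1]],
                    end = rec$end[idx[, 1]], sample_id = x$samples[idx[, 2]],
                    gt = x$gt[idx], stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$sample_id), , drop = FALSE]
}

#' Read a merged SV panel from VCF
#'
#' Reconstructs an [sv_panel()] written by [write_sv_vcf()], including the
#' allele-frequency and Mendelian-error INFO fields. `af`, `maf` and `mac`
#' are recomputed from `AC`/`AN` so the round trip is exact.
#'
#' @inheritParams read_sv_vcf
#' @return an `sv_panel`.
#' @export
read_sv_panel <- function(path, min_svlen = 50) {
  x <- read_sv_vcf(path, min_svlen = min_svlen)
  sites <- x$records
  names(sites)[names(sites) == "id"] <- "site_id"
  if (!is.null(sites$ac) && !is.null(sites$an)) {
    sites$af <- ifelse(sites$an > 0, sites$ac / sites$an, NA_real_)
    sites$mac <- pmin(sites$ac, sites$an - sites$ac)
    sites$maf <- pmin(sites$af, 1 - sites$af)
    sites$founders_absent <- !is.na(sites$ac) & sites$ac == 0
  }
  if (!is.null(sites$mie_families) && !is.null(sites$mie_eval)) {
    sites$error_family_ratio <- ifelse(sites$mie_eval > 0,
                                       sites$mie_families / sites$mie_eval, NA_real_)
  }
  sv_panel(sites, x$gt)
}

#' Write an SV panel to VCF
#'
#' Emits a VCF 4.2 file with symbolic ALT alleles (`<DEL>`/`<INS>`), the
#' `SVTYPE`/`SVLEN`/`END` structural INFO fields (deletions get negative
#' `SVLEN`, the usual caller convention), founder-based `AC`/`AN`/`AF`,
#' `MAF_CATEGORY`, and the trio-QC fields `MIE_FAMILIES` (number of families
#' with a Mendelian inheritance error at the site) and `MIE_EVAL` (families
#' evaluated). Unsorted panels are sorted with a notice.
#'
#' @param panel an `sv_panel`.
#' @param path output path.
#' @param contigs optional named vector of chromosome lengths (or a
#'   [genome_layout()]) for `##contig` header lines.
#' @return the path, invisibly.
#' @export
write_sv_vcf <- function(panel, path, contigs = NULL) {
  sites <- panel$sites
  o <- order(sites$chrom, sites$pos, sites$svtype)
  if (!identical(o, seq_len(nrow(sites)))) {
    message("write_sv_vcf: input not sorted by (chrom, pos); sorting")
    panel <- sort_panel(panel)
    sites <- panel$sites
  }
  if (inherits(contigs, "genome_layout")) contigs <- contigs$lengths
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length; negative for deletions\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternative allele count among founders\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called allele number among founders\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Founder allele frequency AC/AN\">",
    "##INFO=<ID=MAF_CATEGORY,Number=1,Type=String,Description=\"singleton, rare, low or common\">",
    "##INFO=<ID=MIE_FAMILIES,Number=1,Type=Integer,Description=\"Number of families with a Mendelian inheritance error\">",
    "##INFO=<ID=MIE_EVAL,Number=1,Type=Integer,Description=\"Number of families evaluated for MIE\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (ncol(panel$gt) > 0) c("FORMAT", colnames(panel$gt))),
          collapse = "\t")
  )
  body <- character()
  if (nrow(sites) > 0) {
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", sites$svtype,
                    ifelse(sites$svtype == "DEL", -sites$svlen, sites$svlen),
                    sites$end)
    add <- function(info, tag, val, fmt) {
      ok <- !is.na(val)
      info[ok] <- paste0(info[ok], ";", tag, "=", sprintf(fmt, val[ok]))
      info
    }
    info <- add(info, "AC", sites$ac, "%d")
    info <- add(info, "AN", sites$an, "%d")
    ok <- !is.na(sites$af)
    info[ok] <- paste0(info[ok], ";AF=",
                       format(signif(sites$af[ok], 6), scientific = FALSE, trim = TRUE))
    info <- add(info, "MAF_CATEGORY", sites$category, "%s")
    info <- add(info, "MIE_FAMILIES", sites$mie_families, "%d")
    info <- add(info, "MIE_EVAL", sites$mie_eval, "%d")
    fields <- cbind(sites$chrom, sites$pos, sites$site_id, "N",
                    paste0("<", sites$svtype, ">"), ".", "PASS", info)
    if (ncol(panel$gt) > 0) fields <- cbind(fields, "GT", panel$gt)
    body <- apply(fields, 1, paste, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
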