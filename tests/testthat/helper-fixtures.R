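# shared fixture builders, all generated in code

# minimal panel: n founder-genotyped samples at hand-specified sites
fixture_panel <- function(sites, gt_rows, samples) {
  gt <- matrix(unlist(gt_rows), nrow = length(gt_rows), byrow = TRUE,
               dimnames = list(NULL, samples))
  sv_panel(sites, gt)
}

# a VCF line set with given INFO/GT fields, written to a temp file
write_vcf_text <- function(body, samples = c("S1", "S2"), path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# independent gamete-enumeration oracle for Mendelian consistency
oracle_mie <- function(f, m, o) {
  alleles <- list(c(0, 0), c(0, 1), c(1, 1))
  fo <- alleles[[f + 1]]
  mo <- alleles[[m + 1]]
  consistent <- FALSE
  for (a in fo) for (b in mo) if (a + b == o) consistent <- TRUE
  !consistent
}

# genotype codes for a dosage triple
gt_of <- function(d) c("0/0", "0/1", "1/1")[d + 1]

# small deterministic carrier-call table
make_calls <- function(chrom, pos, svtype, svlen, sample_id, gt = "0/1") {
  data.frame(chrom = chrom, pos = pos, svtype = svtype, svlen = svlen,
             sample_id = sample_id, gt = gt, stringsAsFactors = FALSE)
}
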