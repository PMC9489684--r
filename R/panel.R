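#' Construct an SV panel object
#'
#' An `sv_panel` bundles a table of nonredundant SV sites with the
#' per-sample genotype matrix over those sites. Allele-frequency fields
#' (`ac`, `an`, `af`, `mac`, `maf`, `category`) and Mendelian-error fields
#' (`mie_families`, `mie_eval`, `error_family_ratio`) start as `NA` and are
#' filled by [compute_af()], [categorize_maf()] and [mie_by_site()].
#'
#' @param sites data.frame with at least `chrom`, `pos` (1-based VCF
#'   position), `svtype` (`"DEL"` or `"INS"`), `svlen` (positive bp).
#' @param gt character genotype matrix, one row per site, one column per
#'   sample (column names are the sample IDs).
#' @return an object of class `sv_panel`.
#' @export
sv_panel <- function(sites, gt) {
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(gt))
  if (ncol(gt) > 0 && is.null(colnames(gt)))
    stop("genotype matrix must carry sample IDs as column names")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$pos <- as.integer(sites$pos)
  sites$svlen <- as.integer(sites$svlen)
  if (is.null(sites$end)) {
    sites$end <- ifelse(sites$svtype == "DEL", sites$pos + sites$svlen, sites$pos)
  }
  sites$end <- as.integer(sites$end)
  if (is.null(sites$site_id)) {
    sites$site_id <- paste(sites$chrom, sites$pos, sites$svtype, sep = "_")
  }
  n <- nrow(sites)
  for (col in c("ac", "an", "mac", "mie_families", "mie_eval", "n_members")) {
    if (is.null(sites[[col]])) sites[[col]] <- rep(NA_integer_, n)
  }
  for (col in c("af", "maf", "error_family_ratio")) {
    if (is.null(sites[[col]])) sites[[col]] <- rep(NA_real_, n)
  }
  if (is.null(sites$category)) sites$category <- rep(NA_character_, n)
  if (is.null(sites$founders_absent)) sites$founders_absent <- rep(NA, n)
  gt <- matrix(normalize_gt(gt), nrow = nrow(sites),
               dimnames = list(sites$site_id, colnames(gt)))
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt), class = "sv_panel")
}

#' @export
print.sv_panel <- function(x, ...) {
  n <- nrow(x$sites)
  cat("sv_panel:", n, "sites x", ncol(x$gt), "samples\n")
  if (n > 0) {
    cat("  types:", paste(sprintf("%s=%d", names(table(x$sites$svtype)),
                                  table(x$sites$svtype)), collapse = ", "), "\n")
    if (any(!is.na(x$sites$category)))
      cat("  categories:", paste(sprintf("%s=%d", names(table(x$sites$category)),
                                         table(x$sites$category)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample IDs of a panel
#' @param panel an `sv_panel`.
#' @return character vector of sample IDs (genotype-matrix columns).
#' @export
panel_samples <- function(panel) colnames(panel$gt)

# order panel sites by (chrom, pos); keeps gt rows in step
sort_panel <- function(panel) {
  o <- order(panel$sites$chrom, panel$sites$pos, panel$sites$svtype)
  panel$sites <- panel$sites[o, , drop = FALSE]
  rownames(panel$sites) <- NULL
  panel$gt <- panel$gt[o, , drop = FALSE]
  panel
}

is_autosome <- function(chrom) grepl("^[0-9]+$", sub("^chr", "", chrom))
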