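#' Merge parameters for SV clustering
#'
#' Mirrors the distance/type contract of the multi-sample SV merging used
#' to build the nonredundant panel: calls of the same type within
#' `max_dist` bp of each other (single linkage on start positions) are one
#' site; by default 1 kb with type agreement required, the published
#' setting for this analysis.
#'
#' @param max_dist maximum start-position distance in bp for linking two
#'   calls (default 1000).
#' @param require_type_match must SVTYPE agree within a cluster (default
#'   TRUE).
#' @param min_size optional bp filter applied to input calls.
#' @param min_callers minimum number of distinct carrier samples for a
#'   site to be kept (default 1).
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(max_dist = 1000, require_type_match = TRUE,
                         min_size = NULL, min_callers = 1) {
  stopifnot(max_dist >= 0, min_callers >= 1)
  structure(list(max_dist = max_dist, require_type_match = require_type_match,
                 min_size = min_size, min_callers = min_callers),
            class = "merge_params")
}

# lower median: element floor((n+1)/2) of the sorted values; deterministic
# and always an observed member value (ties resolve to the smaller).
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

#' Merge per-sample SV calls into a nonredundant panel
#'
#' Single-linkage clustering within each (chromosome, SV type) stratum: two
#' calls are linked iff their start positions differ by at most
#' `params$max_dist`. Each cluster becomes one panel site whose
#' representative position and length are the lower medians of the member
#' values. A sample with several member calls in one cluster contributes
#' its highest-dosage genotype; samples with no member call are recorded as
#' homozygous reference (or missing, with `absent_as_missing = TRUE`, for
#' workflows that re-genotype merged sites instead).
#'
#' @param calls data.frame of carrier calls with columns `chrom`, `pos`,
#'   `svtype`, `svlen`, `sample_id` and `gt` (see [as_sv_calls()]).
#' @param params a [merge_params()].
#' @param samples sample IDs for the genotype matrix columns; defaults to
#'   the sorted unique sample IDs seen in `calls`.
#' @param absent_as_missing record samples without a member call as `"./."`
#'   instead of `"0/0"`.
#' @return an [sv_panel()] sorted by (chrom, pos), with `n_members` filled
#'   and an attribute `membership`: for each input call row, the row index
#'   of the panel site it was merged into.
#' @export
merge_calls <- function(calls, params = merge_params(), samples = NULL,
                        absent_as_missing = FALSE) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  if (nrow(calls) == 0) {
    return(sv_panel(data.frame(chrom = character(), pos = integer(),
                               svtype = character(), svlen = integer()),
                    matrix(character(), 0, length(samples),
                           dimnames = list(NULL, samples))))
  }
  stopifnot(all(calls$svtype %in% c("DEL", "INS")), all(calls$svlen >= 1),
            all(calls$sample_id %in% samples))
  if (!is.null(params$min_size)) calls <- calls[calls$svlen >= params$min_size, ]

  stratum <- if (params$require_type_match) paste(calls$chrom, calls$svtype)
             else calls$chrom
  o <- order(stratum, calls$pos, calls$svlen, calls$sample_id)
  pos_o <- calls$pos[o]
  str_o <- stratum[o]
  new_cluster <- c(TRUE, str_o[-1] != str_o[-length(str_o)] |
                     diff(pos_o) > params$max_dist)
  clust_o <- cumsum(new_cluster)
  clust <- integer(nrow(calls))
  clust[o] <- clust_o
  n_clust <- max(clust_o)

  cf <- factor(clust, levels = seq_len(n_clust))
  rep_pos <- as.integer(tapply(calls$pos, cf, lower_median))
  rep_len <- as.integer(tapply(calls$svlen, cf, lower_median))
  rep_chrom <- as.character(tapply(calls$chrom, cf, `[`, 1))
  rep_type <- as.character(tapply(calls$svtype, cf, `[`, 1))
  n_members <- as.integer(tabulate(clust, n_clust))

  dos <- gt_dosage(calls$gt)
  dos[is.na(dos)] <- 0L
  samp_idx <- match(calls$sample_id, samples)
  dmat <- matrix(NA_integer_, n_clust, length(samples),
                 dimnames = list(NULL, samples))
  # highest dosage per (cluster, sample); process in increasing dosage order
  ord <- order(dos)
  dmat[cbind(clust[ord], samp_idx[ord])] <- dos[ord]
  gt <- matrix(if (absent_as_missing) "./." else "0/0",
               n_clust, length(samples), dimnames = list(NULL, samples))
  gt[!is.na(dmat)] <- dosage_gt(dmat[!is.na(dmat)])

  keep <- vapply(split(calls$sample_id, cf),
                 function(s) length(unique(s)), 1L) >= params$min_callers
  sites <- data.frame(chrom = rep_chrom, pos = rep_pos, svtype = rep_type,
                      svlen = rep_len, n_members = n_members,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  panel <- sort_panel(sv_panel(sites, gt))
  # membership: map each input call's cluster to the sorted site row
  clust_to_row <- rep(NA_integer_, n_clust)
  clust_to_row[which(keep)] <- match(
    paste(rep_chrom, rep_pos, rep_type)[keep],
    paste(panel$sites$chrom, panel$sites$pos, panel$sites$svtype))
  attr(panel, "membership") <- clust_to_row[clust]
  panel
}

#' Extract panel sites as per-sample carrier calls
#'
#' Inverse-direction helper used for idempotence checks and cross-panel
#' matching: every non-reference, non-missing genotype becomes one call.
#'
#' @param panel an `sv_panel`.
#' @return data.frame in the [merge_calls()] input format.
#' @export
panel_calls <- function(panel) {
  dos <- matrix(gt_dosage(panel$gt), nrow = nrow(panel$sites))
  idx <- which(!is.na(dos) & dos > 0, arr.ind = TRUE)
  s <- panel$sites
  data.frame(chrom = s$chrom[idx[, 1]], pos = s$pos[idx[, 1]],
             svtype = s$svtype[idx[, 1]], svlen = s$svlen[idx[, 1]],
             end = s$end[idx[, 1]], sample_id = colnames(panel$gt)[idx[, 2]],
             gt = panel$gt[idx], stringsAsFactors = FALSE)
}

#' Founder-based allele frequencies
#'
#' Computes AC/AN/AF and the minor-allele statistics on the founder subset
#' of the cohort (fathers and mothers), so that alleles shared between
#' parents and offspring are not double counted. `AN` is twice the number
#' of founders with a non-missing genotype. Sites with no alternative
#' allele among founders are flagged `founders_absent` (offspring-only
#' observations); they stay in the repository but are excluded from the
#' frequency panel by [frequency_panel()].
#'
#' @param panel an `sv_panel`.
#' @param founders a [cohort()] or a character vector of founder IDs.
#' @return the panel with `ac`, `an`, `af`, `mac`, `maf`,
#'   `founders_absent` filled in `sites`.
#' @export
compute_af <- function(panel, founders) {
  if (inherits(founders, "cohort")) founders <- founders$founders
  founders <- intersect(colnames(panel$gt), founders)
  if (length(founders) == 0) stop("no founder genotypes present in panel")
  dos <- matrix(gt_dosage(panel$gt[, founders, drop = FALSE]),
                nrow = nrow(panel$sites))
  an <- 2L * as.integer(rowSums(!is.na(dos)))
  ac <- as.integer(rowSums(dos, na.rm = TRUE))
  af <- ifelse(an > 0, ac / an, NA_real_)
  panel$sites$ac <- ac
  panel$sites$an <- an
  panel$sites$af <- af
  panel$sites$mac <- pmin(ac, an - ac)
  panel$sites$maf <- pmin(af, 1 - af)
  panel$sites$founders_absent <- an == 0L | ac == 0L
  panel
}

#' Restrict a panel to rows
#' @param panel an `sv_panel`.
#' @param idx logical or integer row index over sites.
#' @return the subset `sv_panel`.
#' @export
subset_panel <- function(panel, idx) {
  panel$sites <- panel$sites[idx, , drop = FALSE]
  rownames(panel$sites) <- NULL
  panel$gt <- panel$gt[idx, , drop = FALSE]
  attr(panel, "membership") <- NULL
  panel
}

#' Frequency panel: sites segregating among founders
#' @param panel panel with allele frequencies computed.
#' @return the subset of sites not flagged `founders_absent`.
#' @export
frequency_panel <- function(panel) {
  stopifnot(!all(is.na(panel$sites$founders_absent)))
  subset_panel(panel, !panel$sites$founders_absent)
}

#' MAF category of biallelic sites
#'
#' Categories follow the panel's published boundaries: singleton
#' (minor allele count 1), rare (MAC > 1 and MAF < 0.01), low
#' (0.01 <= MAF < 0.05) and common (MAF >= 0.05), with singleton taking
#' precedence. Sites with MAC 0 or undefined MAF get `NA`.
#'
#' @param mac minor allele counts.
#' @param maf minor allele frequencies.
#' @return character vector of categories.
#' @export
maf_category <- function(mac, maf) {
  out <- rep(NA_character_, length(mac))
  ok <- !is.na(mac) & !is.na(maf) & mac >= 1
  out[ok & mac == 1] <- "singleton"
  rest <- ok & mac > 1
  out[rest & maf < 0.01] <- "rare"
  out[rest & maf >= 0.01 & maf < 0.05] <- "low"
  out[rest & maf >= 0.05] <- "common"
  out
}

#' @rdname maf_category
#' @param panel an `sv_panel` with `mac`/`maf` computed.
#' @return `categorize_maf`: the panel with `sites$category` filled.
#' @export
categorize_maf <- function(panel) {
  panel$sites$category <- maf_category(panel$sites$mac, panel$sites$maf)
  panel
}

#' MAF categories in canonical order
#' @export
MAF_CATEGORIES <- c("singleton", "rare", "low", "common")

#' Category proportions from counts
#'
#' @param counts named (or canonically ordered) vector of site counts per
#'   MAF category.
#' @return data.frame with `category`, `count`, `proportion` (fractions
#'   summing to 1).
#' @export
category_proportions <- function(counts) {
  if (is.null(names(counts))) names(counts) <- MAF_CATEGORIES[seq_along(counts)]
  counts <- counts[MAF_CATEGORIES[MAF_CATEGORIES %in% names(counts)]]
  data.frame(category = names(counts), count = as.integer(counts),
             proportion = as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}

#' Summary tables for a categorized panel
#'
#' @param panel an `sv_panel` with AF and categories computed.
#' @return list with `per_type` (site counts by SVTYPE), `per_category`
#'   ([category_proportions()] over categorized sites), `per_sample`
#'   (number of sites where each sample carries at least one alternative
#'   allele), and `size_by_category` (svlen quartiles per category).
#' @export
panel_summary <- function(panel) {
  s <- panel$sites
  dos <- matrix(gt_dosage(panel$gt), nrow = nrow(s))
  per_sample <- colSums(!is.na(dos) & dos > 0)
  names(per_sample) <- colnames(panel$gt)
  cat_counts <- table(factor(s$category, levels = MAF_CATEGORIES))
  size_by_cat <- do.call(rbind, lapply(MAF_CATEGORIES, function(cc) {
    x <- s$svlen[!is.na(s$category) & s$category == cc]
    data.frame(category = cc, n = length(x),
               q25 = if (length(x)) unname(stats::quantile(x, .25)) else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               q75 = if (length(x)) unname(stats::quantile(x, .75)) else NA_real_)
  }))
  list(per_type = table(s$svtype),
       per_category = category_proportions(cat_counts),
       per_sample = per_sample,
       size_by_category = size_by_cat)
}
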