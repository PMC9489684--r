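#' Cross-merge two SV panels
#'
#' Matches the sites of two allele-frequency panels with the same
#' distance/type clustering used to build each panel ([merge_calls()] on
#' the union). Only sites detected in a panel (AF > 0) enter the matching;
#' a merged cluster holding sites from both panels is "shared". When a
#' cluster holds several sites from one panel they are collapsed to one
#' for counting, keeping the comparison at the nonredundant-site level.
#'
#' @param panel_a,panel_b `sv_panel`s with `af` computed.
#' @param params a [merge_params()].
#' @return list of class `cross_merge`: `matched` (data.frame with
#'   `a_idx`, `b_idx`, `svtype`, `af_a`, `af_b`, `maf_a`, `category_a`),
#'   `a_only_idx`, `b_only_idx` (site row indices into the AF-positive
#'   subsets), `n_shared`, `n_a_only`, `n_b_only`, `shared_fraction_a`,
#'   and the AF-positive subsets `sub_a`, `sub_b`.
#' @export
cross_merge <- function(panel_a, panel_b, params = merge_params()) {
  stopifnot(!all(is.na(panel_a$sites$af)), !all(is.na(panel_b$sites$af)))
  sub_a <- subset_panel(panel_a, !is.na(panel_a$sites$af) & panel_a$sites$af > 0)
  sub_b <- subset_panel(panel_b, !is.na(panel_b$sites$af) & panel_b$sites$af > 0)
  mk <- function(p, tag) {
    s <- p$sites
    data.frame(chrom = s$chrom, pos = s$pos, svtype = s$svtype,
               svlen = s$svlen, sample_id = tag, gt = "0/1",
               src_idx = seq_len(nrow(s)), stringsAsFactors = FALSE)
  }
  calls <- rbind(mk(sub_a, "panelA"), mk(sub_b, "panelB"))
  merged <- merge_calls(calls, params, samples = c("panelA", "panelB"))
  member <- attr(merged, "membership")
  from_a <- calls$sample_id == "panelA"
  clusters <- split(seq_len(nrow(calls)), member)
  a_in <- vapply(clusters, function(ix) any(from_a[ix]), TRUE)
  b_in <- vapply(clusters, function(ix) any(!from_a[ix]), TRUE)
  shared <- a_in & b_in
  first_idx <- function(ix, a_side) {
    sel <- ix[from_a[ix] == a_side]
    calls$src_idx[sel[1]]
  }
  matched <- do.call(rbind, lapply(clusters[shared], function(ix) {
    ai <- first_idx(ix, TRUE)
    bi <- first_idx(ix, FALSE)
    data.frame(a_idx = ai, b_idx = bi, svtype = sub_a$sites$svtype[ai],
               af_a = sub_a$sites$af[ai], af_b = sub_b$sites$af[bi],
               maf_a = sub_a$sites$maf[ai],
               category_a = sub_a$sites$category[ai], stringsAsFactors = FALSE)
  }))
  if (is.null(matched))
    matched <- data.frame(a_idx = integer(), b_idx = integer(),
                          svtype = character(), af_a = numeric(),
                          af_b = numeric(), maf_a = numeric(),
                          category_a = character(), stringsAsFactors = FALSE)
  rownames(matched) <- NULL
  a_only_idx <- sort(unique(unlist(lapply(clusters[a_in & !b_in], function(ix)
    calls$src_idx[ix[from_a[ix]]]))))
  b_only_idx <- sort(unique(unlist(lapply(clusters[b_in & !a_in], function(ix)
    calls$src_idx[ix[!from_a[ix]]]))))
  n_shared <- sum(shared)
  n_a_only <- sum(a_in & !b_in)
  n_b_only <- sum(b_in & !a_in)
  structure(list(matched = matched, a_only_idx = as.integer(a_only_idx),
                 b_only_idx = as.integer(b_only_idx), n_shared = n_shared,
                 n_a_only = n_a_only, n_b_only = n_b_only,
                 shared_fraction_a = shared_fraction(n_shared, n_a_only),
                 sub_a = sub_a, sub_b = sub_b),
            class = "cross_merge")
}

#' Shared fraction of a panel
#'
#' @param n_shared sites found in both panels.
#' @param n_unique sites found only in the focal panel.
#' @return `n_shared / (n_shared + n_unique)`.
#' @export
shared_fraction <- function(n_shared, n_unique) n_shared / (n_shared + n_unique)

#' @export
print.cross_merge <- function(x, ...) {
  cat(sprintf("cross_merge: %d shared, %d A-only, %d B-only (shared fraction of A: %.1f%%)\n",
              x$n_shared, x$n_a_only, x$n_b_only, 100 * x$shared_fraction_a))
  invisible(x)
}

#' Allele-frequency correlation of matched common SVs
#'
#' Pearson correlation between the two panels' alternative-allele
#' frequencies, per SV type, restricted to matched pairs whose panel-A MAF
#' is at least `maf_floor` (common SVs).
#'
#' @param cm a [cross_merge()] result (or its `matched` data.frame).
#' @param maf_floor minimum panel-A MAF (default 0.05).
#' @return data.frame per svtype: `svtype`, `n`, `r`, `p_value`; `r` is
#'   `NA` (with reason in `note`) for degenerate inputs (< 3 pairs or zero
#'   variance).
#' @export
af_correlation <- function(cm, maf_floor = 0.05) {
  m <- if (inherits(cm, "cross_merge")) cm$matched else cm
  m <- m[!is.na(m$maf_a) & m$maf_a >= maf_floor & !is.na(m$af_b), , drop = FALSE]
  rows <- lapply(c("DEL", "INS"), function(tp) {
    sub <- m[m$svtype == tp, , drop = FALSE]
    n <- nrow(sub)
    if (n < 3)
      return(data.frame(svtype = tp, n = n, r = NA_real_, p_value = NA_real_,
                        note = "fewer than 3 matched common pairs"))
    if (stats::sd(sub$af_a) == 0 || stats::sd(sub$af_b) == 0)
      return(data.frame(svtype = tp, n = n, r = NA_real_, p_value = NA_real_,
                        note = "zero variance"))
    ct <- stats::cor.test(sub$af_a, sub$af_b, method = "pearson")
    data.frame(svtype = tp, n = n, r = unname(ct$estimate),
               p_value = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' MAF-category composition of shared vs unique sites
#'
#' @param cm a [cross_merge()] result.
#' @return data.frame: `set` ("unique" or "shared"), `n`, and one
#'   proportion column per MAF category (each set's proportions sum to 1).
#' @export
category_sharing <- function(cm) {
  cat_a <- cm$sub_a$sites$category
  mk <- function(set, cats) {
    cats <- factor(cats[!is.na(cats)], levels = MAF_CATEGORIES)
    n <- length(cats)
    props <- if (n > 0) as.numeric(table(cats)) / n else rep(NA_real_, 4)
    stats::setNames(data.frame(set, n, t(props), stringsAsFactors = FALSE),
                    c("set", "n", MAF_CATEGORIES))
  }
  rbind(mk("unique", cat_a[cm$a_only_idx]),
        mk("shared", cat_a[cm$matched$a_idx]))
}

#' Full two-panel comparison report
#'
#' @param panel_a,panel_b `sv_panel`s with AF (and, for the category
#'   breakdown, categories) computed.
#' @param params a [merge_params()].
#' @param maf_floor MAF floor for the AF correlation.
#' @return list: `counts` (n_shared/n_a_only/n_b_only/shared_fraction_a),
#'   `category_breakdown`, `af_correlation`, and the underlying
#'   `cross_merge`.
#' @export
comparison_report <- function(panel_a, panel_b, params = merge_params(),
                              maf_floor = 0.05) {
  cm <- cross_merge(panel_a, panel_b, params)
  list(counts = data.frame(n_shared = cm$n_shared, n_a_only = cm$n_a_only,
                           n_b_only = cm$n_b_only,
                           shared_fraction_a = cm$shared_fraction_a),
       category_breakdown = category_sharing(cm),
       af_correlation = af_correlation(cm, maf_floor),
       cross_merge = cm)
}
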