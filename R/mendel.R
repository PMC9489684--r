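#' Mendelian consistency of a trio genotype combination
#'
#' A trio combination is a Mendelian inheritance error (MIE) when no choice
#' of one transmitted allele per parent reproduces the offspring genotype.
#' The consistent offspring sets are: 0/0 x 0/0 -> {0/0};
#' 0/0 x 0/1 -> {0/0, 0/1}; 0/0 x 1/1 -> {0/1};
#' 0/1 x 0/1 -> {0/0, 0/1, 1/1}; 0/1 x 1/1 -> {0/1, 1/1};
#' 1/1 x 1/1 -> {1/1}. Combinations with any missing member are not
#' evaluable and return `NA` — missing data is never counted as an error.
#'
#' @param father,mother,offspring genotype code vectors (see [GT_CODES]);
#'   recycled to a common length.
#' @return logical vector: `TRUE` for an MIE, `FALSE` for a consistent
#'   combination, `NA` when not evaluable.
#' @export
is_mie <- function(father, mother, offspring) {
  n <- max(length(father), length(mother), length(offspring))
  fd <- rep_len(gt_dosage(father), n)
  md <- rep_len(gt_dosage(mother), n)
  od <- rep_len(gt_dosage(offspring), n)
  # allowed[f+1, m+1]: bitmask over offspring dosage {0,1,2}
  transmit <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  allowed <- outer(0:2, 0:2, Vectorize(function(f, m) {
    sum(2L^unique(as.vector(outer(transmit[[f + 1]], transmit[[m + 1]], `+`))))
  }))
  out <- rep(NA, n)
  ok <- !is.na(fd) & !is.na(md) & !is.na(od)
  out[ok] <- bitwAnd(allowed[cbind(fd[ok] + 1L, md[ok] + 1L)], 2L^od[ok]) == 0L
  out
}

# evaluable trio-site mask: all members called and (unless included) the
# site segregates in the trio, i.e. not all three homozygous reference
trio_evaluable <- function(fd, md, od, include_triple_ref = FALSE) {
  ev <- !is.na(fd) & !is.na(md) & !is.na(od)
  if (!include_triple_ref) ev <- ev & !(fd == 0L & md == 0L & od == 0L)
  ev
}

#' Per-trio Mendelian inheritance error rates
#'
#' For each trio, the MIE rate is the number of MIEs divided by the number
#' of evaluated trio-site genotype combinations. A combination is evaluated
#' when all three genotypes are called and, by default, at least one member
#' carries the alternative allele — panel sites where the whole trio is
#' homozygous reference are not calls in the trio and would deflate the
#' rate (`include_triple_ref = TRUE` restores them).
#'
#' @param panel an `sv_panel`.
#' @param ch a [cohort()].
#' @param include_triple_ref also evaluate all-homozygous-reference
#'   combinations.
#' @return data.frame per trio: `offspring_id`, `n_mie`, `n_evaluated`,
#'   `mie_rate` (`NA` when nothing is evaluable).
#' @export
mie_by_trio <- function(panel, ch, include_triple_ref = FALSE) {
  gt <- panel$gt
  tr <- ch$trios
  res <- lapply(seq_len(nrow(tr)), function(i) {
    fd <- gt_dosage(gt[, tr$father_id[i]])
    md <- gt_dosage(gt[, tr$mother_id[i]])
    od <- gt_dosage(gt[, tr$offspring_id[i]])
    ev <- trio_evaluable(fd, md, od, include_triple_ref)
    mie <- is_mie(dosage_gt(fd), dosage_gt(md), dosage_gt(od))
    n_ev <- sum(ev)
    n_mie <- sum(mie[ev], na.rm = TRUE)
    data.frame(offspring_id = tr$offspring_id[i], n_mie = n_mie,
               n_evaluated = n_ev,
               mie_rate = if (n_ev > 0) n_mie / n_ev else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-site error family ratio
#'
#' The error family ratio of a site is the number of trios showing an MIE
#' there divided by the number of trios evaluable there. The counts are
#' written onto the panel (`mie_families`, `mie_eval`,
#' `error_family_ratio`) and travel into the VCF INFO fields.
#'
#' @inheritParams mie_by_trio
#' @return the panel with the per-site MIE fields filled.
#' @export
mie_by_site <- function(panel, ch, include_triple_ref = FALSE) {
  tr <- ch$trios
  n_sites <- nrow(panel$sites)
  n_mie <- integer(n_sites)
  n_ev <- integer(n_sites)
  for (i in seq_len(nrow(tr))) {
    fd <- gt_dosage(panel$gt[, tr$father_id[i]])
    md <- gt_dosage(panel$gt[, tr$mother_id[i]])
    od <- gt_dosage(panel$gt[, tr$offspring_id[i]])
    ev <- trio_evaluable(fd, md, od, include_triple_ref)
    mie <- is_mie(dosage_gt(fd), dosage_gt(md), dosage_gt(od))
    n_ev <- n_ev + ev
    n_mie <- n_mie + (ev & !is.na(mie) & mie)
  }
  panel$sites$mie_families <- n_mie
  panel$sites$mie_eval <- n_ev
  panel$sites$error_family_ratio <- ifelse(n_ev > 0, n_mie / n_ev, NA_real_)
  panel
}

#' Expected offspring genotype distribution under Mendelian transmission
#'
#' Each parent transmits one of its two alleles uniformly at random.
#'
#' @param father,mother single genotype codes (non-missing).
#' @return named numeric triple of probabilities over `0/0`, `0/1`, `1/1`.
#' @export
expected_offspring_distribution <- function(father, mother) {
  pf <- gt_dosage(father) / 2
  pm <- gt_dosage(mother) / 2
  if (is.na(pf) || is.na(pm)) stop("expected distribution undefined for missing parent")
  c("0/0" = (1 - pf) * (1 - pm),
    "0/1" = pf * (1 - pm) + (1 - pf) * pm,
    "1/1" = pf * pm)
}

#' Observed vs expected offspring genotypes by parental pair
#'
#' Tabulates, for each unordered parental genotype pair, the observed
#' offspring genotype frequencies across all evaluated trio-site
#' combinations, next to the Mendelian expectation. Parental pairs are
#' unordered (0/0 x 0/1 and 0/1 x 0/0 are one row).
#'
#' @inheritParams mie_by_trio
#' @return data.frame, one row per parental pair present: `pair`, `n`,
#'   `obs_00`, `obs_01`, `obs_11`, `exp_00`, `exp_01`, `exp_11`.
#' @export
combo_table <- function(panel, ch, include_triple_ref = FALSE) {
  tr <- ch$trios
  acc <- list()
  for (i in seq_len(nrow(tr))) {
    fd <- gt_dosage(panel$gt[, tr$father_id[i]])
    md <- gt_dosage(panel$gt[, tr$mother_id[i]])
    od <- gt_dosage(panel$gt[, tr$offspring_id[i]])
    ev <- trio_evaluable(fd, md, od, include_triple_ref)
    acc[[i]] <- data.frame(lo = pmin(fd, md)[ev], hi = pmax(fd, md)[ev], od = od[ev])
  }
  d <- do.call(rbind, acc)
  if (is.null(d) || nrow(d) == 0) {
    return(data.frame(pair = character(), n = integer(),
                      obs_00 = numeric(), obs_01 = numeric(), obs_11 = numeric(),
                      exp_00 = numeric(), exp_01 = numeric(), exp_11 = numeric()))
  }
  key <- paste(d$lo, d$hi, sep = "x")
  rows <- lapply(sort(unique(key)), function(k) {
    sub <- d[key == k, ]
    obs <- tabulate(sub$od + 1L, 3L) / nrow(sub)
    ex <- expected_offspring_distribution(dosage_gt(sub$lo[1]), dosage_gt(sub$hi[1]))
    data.frame(pair = paste(dosage_gt(sub$lo[1]), dosage_gt(sub$hi[1]), sep = " x "),
               n = nrow(sub),
               obs_00 = obs[1], obs_01 = obs[2], obs_11 = obs[3],
               exp_00 = unname(ex[1]), exp_01 = unname(ex[2]), exp_11 = unname(ex[3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
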