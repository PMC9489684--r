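#' Genomic intervals occupied by panel sites
#'
#' Applies the coordinate convention used throughout: a DEL reported at VCF
#' position p (padding base) deletes the 0-based half-open interval
#' \[p, p+L), i.e. 1-based \[p+1, p+L\]; an INS is the single breakpoint
#' base following p.
#'
#' @param panel an `sv_panel`.
#' @return a `GRanges`, one range per site, in site order.
#' @export
panel_ranges <- function(panel) {
  s <- panel$sites
  del <- s$svtype == "DEL"
  GenomicRanges::GRanges(s$chrom,
                         IRanges::IRanges(start = s$pos + 1L,
                                          end = ifelse(del, s$pos + s$svlen,
                                                       s$pos + 1L)))
}

FEATURE_CLASSES <- c("intergenic", "intron", "exon", "cds")

#' Classify panel sites by genomic feature overlap
#'
#' Flags each site for overlap (>= 1 bp) with intergenic space, introns,
#' exons and CDS. A deletion uses its full interval, an insertion its
#' breakpoint, so one SV can carry several flags (the classes are not
#' exclusive) and every site on an annotated chromosome carries at least
#' one.
#'
#' @param panel an `sv_panel`.
#' @param features a [feature_set()].
#' @return data.frame of logical columns `intergenic`, `intron`, `exon`,
#'   `cds` plus `unclassified` (site on a chromosome absent from the
#'   annotation), one row per site.
#' @export
classify_overlaps <- function(panel, features) {
  gr <- panel_ranges(panel)
  known <- as.character(GenomicRanges::seqnames(gr)) %in%
    GenomeInfoDb::seqlevels(features$genes)
  flag <- function(f) {
    out <- rep(FALSE, length(gr))
    out[known] <- suppressWarnings(IRanges::overlapsAny(gr[known], f))
    out
  }
  out <- data.frame(intergenic = flag(features$intergenic),
                    intron = flag(features$introns),
                    exon = flag(features$exons),
                    cds = flag(features$cds))
  out$unclassified <- !known
  out
}

#' Randomize SV positions on the genome
#'
#' Re-places every SV uniformly at random, preserving its length and type,
#' by default on its own chromosome (stratified mode, which preserves the
#' chromosome composition of the panel). Placements that would overrun the
#' chromosome end or intersect an assembly gap are rejected and resampled.
#'
#' @param panel an `sv_panel`.
#' @param genome a [genome_layout()] covering all panel chromosomes.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (so a caller can seed once and draw many permutations).
#' @param stratify_chrom keep each SV on its own chromosome (default);
#'   otherwise chromosomes are resampled proportionally to length.
#' @return the panel with `pos` and `end` replaced.
#' @export
randomize_positions <- function(panel, genome, seed = NULL,
                                stratify_chrom = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  s <- panel$sites
  n <- nrow(s)
  if (n == 0) return(panel)
  if (!all(s$chrom %in% names(genome$lengths)))
    stop("panel chromosomes missing from genome layout")
  chrom <- s$chrom
  if (!stratify_chrom) {
    chrom <- sample(names(genome$lengths), n, replace = TRUE,
                    prob = genome$lengths)
  }
  span <- ifelse(s$svtype == "DEL", s$svlen, 1L)
  p_max <- genome$lengths[chrom] - span
  if (any(p_max < 0)) stop("SV longer than its chromosome; cannot randomize")
  pos <- integer(n)
  todo <- rep(TRUE, n)
  for (iter in 1:1000) {
    k <- sum(todo)
    if (k == 0) break
    prop <- as.integer(floor(stats::runif(k, 0, p_max[todo] + 1)))
    if (length(genome$gaps)) {
      gr <- GenomicRanges::GRanges(chrom[todo],
                                   IRanges::IRanges(prop + 1L, prop + span[todo]))
      bad <- suppressWarnings(IRanges::overlapsAny(gr, genome$gaps))
    } else bad <- rep(FALSE, k)
    idx <- which(todo)
    pos[idx[!bad]] <- prop[!bad]
    todo[idx[!bad]] <- FALSE
  }
  if (any(todo)) stop("no feasible gap-free placement for some SVs")
  panel$sites$chrom <- chrom
  panel$sites$pos <- pos
  panel$sites$end <- ifelse(s$svtype == "DEL", pos + s$svlen, pos)
  panel
}

count_feature_overlaps <- function(panel, features) {
  fl <- classify_overlaps(panel, features)
  vapply(FEATURE_CLASSES, function(cl) sum(fl[[cl]]), 1L)
}

#' Positional-randomization enrichment test
#'
#' For each feature class, compares the observed number of SVs overlapping
#' the class with its expectation under `n_perm` random re-placements of
#' the SVs ([randomize_positions()]). The enrichment score is
#' observed/expected; the p-value is the two-sided empirical
#' `2 * min(#\{perm >= obs\} + 1, #\{perm <= obs\} + 1) / (n_perm + 1)`,
#' capped at 1, so with 1000 permutations and no exceedances the floor is
#' about 0.002.
#'
#' @param panel an `sv_panel`.
#' @param features a [feature_set()].
#' @param genome a [genome_layout()].
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the whole permutation stream.
#' @param stratify_chrom passed to [randomize_positions()].
#' @return data.frame, one row per feature class: `feature_class`,
#'   `observed`, `expected`, `score`, `perm_min`, `perm_max` (extreme
#'   permutation scores), `n_perm`, `p_value`.
#' @export
enrichment_test <- function(panel, features, genome, n_perm = 1000,
                            seed = NULL, stratify_chrom = TRUE) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- count_feature_overlaps(panel, features)
  perm <- matrix(NA_integer_, n_perm, length(FEATURE_CLASSES),
                 dimnames = list(NULL, FEATURE_CLASSES))
  for (b in seq_len(n_perm)) {
    rp <- randomize_positions(panel, genome, seed = NULL,
                              stratify_chrom = stratify_chrom)
    perm[b, ] <- count_feature_overlaps(rp, features)
  }
  expected <- colMeans(perm)
  res <- lapply(FEATURE_CLASSES, function(cl) {
    e <- expected[[cl]]
    o <- obs[[cl]]
    p <- min(1, 2 * min(sum(perm[, cl] >= o) + 1, sum(perm[, cl] <= o) + 1) /
               (n_perm + 1))
    data.frame(feature_class = cl, observed = o, expected = e,
               score = if (e > 0) o / e else NA_real_,
               perm_min = if (e > 0) min(perm[, cl]) / e else NA_real_,
               perm_max = if (e > 0) max(perm[, cl]) / e else NA_real_,
               n_perm = n_perm, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' MAF-category composition per feature class
#'
#' @param panel a categorized `sv_panel`.
#' @param features a [feature_set()] (or precomputed [classify_overlaps()]
#'   flags).
#' @return data.frame, one row per feature class: `n` plus one proportion
#'   column per MAF category; proportions sum to 1 within a row (`NA` row
#'   for an empty class).
#' @export
maf_by_feature <- function(panel, features) {
  fl <- if (is.data.frame(features)) features else classify_overlaps(panel, features)
  cat <- factor(panel$sites$category, levels = MAF_CATEGORIES)
  rows <- lapply(FEATURE_CLASSES, function(cl) {
    sel <- fl[[cl]] & !is.na(cat)
    n <- sum(sel)
    props <- if (n > 0) as.numeric(table(cat[sel])) / n else rep(NA_real_, 4)
    stats::setNames(data.frame(cl, n, t(props), stringsAsFactors = FALSE),
                    c("feature_class", "n", MAF_CATEGORIES))
  })
  do.call(rbind, rows)
}

#' SV density per genomic bin and across chromosomes
#'
#' Counts panel sites in half-open bins (default 2 Mb; the last bin of a
#' chromosome is truncated) and compares the per-bin counts across
#' chromosomes with a Kruskal-Wallis rank-sum test. Per-chromosome totals
#' are reported against gap-excluded effective lengths for density
#' regression.
#'
#' @param panel an `sv_panel`.
#' @param genome a [genome_layout()].
#' @param bin bin width in bp.
#' @return list: `bins` (chrom, bin_start, bin_end, count), `per_chrom`
#'   (chrom, n_sv, effective_length), and `test` (the `htest`; `NULL` with
#'   fewer than two chromosomes).
#' @export
chromosome_density <- function(panel, genome, bin = 2e6) {
  eff <- effective_lengths(genome)
  bins <- do.call(rbind, lapply(names(genome$lengths), function(ch) {
    len <- genome$lengths[[ch]]
    start <- seq(0, len - 1, by = bin)
    data.frame(chrom = ch, bin_start = start,
               bin_end = pmin(start + bin, len), stringsAsFactors = FALSE)
  }))
  s <- panel$sites
  key <- paste(bins$chrom, bins$bin_start)
  site_key <- paste(s$chrom, floor(s$pos / bin) * bin)
  bins$count <- as.integer(table(factor(site_key, levels = key)))
  per_chrom <- data.frame(chrom = names(genome$lengths),
                          n_sv = as.integer(table(factor(s$chrom,
                                                         levels = names(genome$lengths)))),
                          effective_length = as.numeric(eff),
                          stringsAsFactors = FALSE)
  test <- if (length(genome$lengths) > 1)
    stats::kruskal.test(bins$count, factor(bins$chrom)) else NULL
  list(bins = bins, per_chrom = per_chrom, test = test)
}
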