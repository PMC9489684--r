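#' Toy genome layout for simulations
#'
#' @param n_chrom number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of each chromosome in bp.
#' @param gaps optional gap intervals (see [genome_layout()]).
#' @return a [genome_layout()].
#' @export
toy_genome <- function(n_chrom = 2, chrom_length = 1e7, gaps = NULL) {
  genome_layout(stats::setNames(rep(chrom_length, n_chrom),
                                paste0("chr", seq_len(n_chrom))), gaps)
}

#' Simulation configuration for a synthetic trio cohort
#'
#' Defines the statistical structure the analysis assumes: biallelic DEL/INS
#' sites whose size spectrum mixes a broad log-uniform background with two
#' narrow peaks around 300 bp and 6 kb (emulating the Alu and LINE-1
#' transposon peaks of real SV spectra), allele frequencies skewed toward
#' rare alleles (Beta(0.3, 1.5), mimicking the decreasing MAF histogram of
#' population panels), founder genotypes in Hardy-Weinberg proportions,
#' Mendelian transmission to offspring, and independent per-genotype error
#' and missingness injection. The genotyping-error model is a symmetric
#' uniform replacement by one of the two other non-missing genotypes: the
#' simplest model under which the MIE rate is a monotone function of the
#' error rate. It is this package's own construction, not an empirical
#' error model.
#'
#' @param n_trios number of parent-offspring trios.
#' @param n_sites number of SV sites.
#' @param genome a [genome_layout()]; default two 10-Mb chromosomes.
#' @param size_weights weights of the three size components (log-uniform
#'   50-10,000 bp; Normal(300, 30); Normal(6000, 300)); must sum to 1.
#' @param af_shape1,af_shape2 Beta parameters of the true allele-frequency
#'   distribution on (0, 1).
#' @param del_ins_ratio probability that a site is a DEL.
#' @param genotype_error_rate per-genotype probability of replacement by a
#'   uniformly random different non-missing genotype.
#' @param missing_rate per-genotype probability of a missing call.
#' @param min_spacing required start-position separation (bp, exclusive) of
#'   same-type sites on a chromosome; the default 1000 matches the merge
#'   distance, making the truth panel identifiable by construction.
#'   Lowering it below the merge distance is the documented stress-test
#'   mode in which neighbouring sites collapse.
#' @param couple_size_af if TRUE, couple size to frequency (larger SVs
#'   assigned to rarer alleles) — a stress mode for category-size
#'   diagnostics, not a default claim about real data.
#' @param seed RNG seed; every generator is a pure function of
#'   (config, seed).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 111, n_sites = 2000, genome = toy_genome(),
                       size_weights = c(loguniform = 0.7, alu = 0.2, line1 = 0.1),
                       af_shape1 = 0.3, af_shape2 = 1.5, del_ins_ratio = 0.5,
                       genotype_error_rate = 0, missing_rate = 0,
                       min_spacing = 1000, couple_size_af = FALSE, seed = 1) {
  stopifnot(abs(sum(size_weights) - 1) < 1e-8,
            genotype_error_rate >= 0, missing_rate >= 0,
            genotype_error_rate + missing_rate <= 1,
            del_ins_ratio >= 0, del_ins_ratio <= 1, n_trios >= 1, n_sites >= 0)
  structure(list(n_trios = n_trios, n_sites = n_sites, genome = genome,
                 size_weights = size_weights, af_shape1 = af_shape1,
                 af_shape2 = af_shape2, del_ins_ratio = del_ins_ratio,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, min_spacing = min_spacing,
                 couple_size_af = couple_size_af, seed = seed),
            class = "sim_config")
}

# draw n SV lengths from the three-component size mixture, clamped to >= 50
sample_svlen <- function(n, w) {
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  len <- numeric(n)
  len[comp == 1] <- exp(stats::runif(sum(comp == 1), log(50), log(10000)))
  len[comp == 2] <- stats::rnorm(sum(comp == 2), 300, 30)
  len[comp == 3] <- stats::rnorm(sum(comp == 3), 6000, 300)
  pmax(50L, as.integer(round(len)))
}

#' Simulate SV site definitions
#'
#' Sites are placed uniformly on the non-gap genome (chromosomes weighted
#' by non-gap length), DEL intervals never overrun their chromosome, and
#' same-type sites on a chromosome are separated by more than
#' `min_spacing` bp so the downstream merge is unambiguous by construction.
#' Each site carries its true allele frequency for later recovery checks.
#'
#' @param config a [sim_config()].
#' @return data.frame of site truth: `site_id`, `chrom`, `pos` (1-based),
#'   `svtype`, `svlen`, `end`, `true_af`, sorted by (chrom, pos).
#' @export
simulate_sites <- function(config) {
  set.seed(config$seed)
  n <- config$n_sites
  if (n == 0) {
    return(data.frame(site_id = character(), chrom = character(), pos = integer(),
                      svtype = character(), svlen = integer(), end = integer(),
                      true_af = numeric(), stringsAsFactors = FALSE))
  }
  g <- config$genome
  eff <- effective_lengths(g)
  svtype <- ifelse(stats::runif(n) < config$del_ins_ratio, "DEL", "INS")
  svlen <- sample_svlen(n, config$size_weights)
  true_af <- stats::rbeta(n, config$af_shape1, config$af_shape2)
  if (config$couple_size_af) {
    # larger SVs to rarer alleles: pair descending lengths with ascending AF
    svlen <- sort(svlen, decreasing = TRUE)[rank(true_af, ties.method = "first")]
  }
  chrom <- character(n)
  pos <- integer(n)
  placed <- list()  # accepted starts per (chrom, type)
  gapdf <- as.data.frame(g$gaps)  # 1-based closed intervals per chromosome
  gaps_by_chrom <- split(gapdf[c("start", "end")], as.character(gapdf$seqnames))
  max_try <- 200L
  for (i in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(max_try)) {
      ch <- sample(names(g$lengths), 1, prob = eff)
      room <- g$lengths[[ch]] - (if (svtype[i] == "DEL") svlen[i] else 0L)
      if (room < 1) next
      p <- as.integer(floor(stats::runif(1, 1, room + 1)))  # 1-based VCF pos
      gp <- gaps_by_chrom[[ch]]
      if (!is.null(gp) && any(p >= gp$start & p <= gp$end)) next
      key <- paste(ch, svtype[i])
      prev <- placed[[key]]
      if (!is.null(prev) && any(abs(prev - p) <= config$min_spacing)) next
      placed[[key]] <- c(prev, p)
      chrom[i] <- ch
      pos[i] <- p
      done <- TRUE
      break
    }
    if (!done) stop("could not place ", n, " sites with min_spacing = ",
                    config$min_spacing, "; reduce n_sites or enlarge the genome")
  }
  out <- data.frame(site_id = sprintf("S%05d", seq_len(n)), chrom = chrom,
                    pos = pos, svtype = svtype, svlen = svlen,
                    end = ifelse(svtype == "DEL", pos + svlen, pos),
                    true_af = true_af, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate trio genotypes at given sites
#'
#' Founders draw genotypes from Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) at each site's true allele frequency; each offspring
#' receives one allele drawn uniformly from each parent. Error injection
#' then replaces each genotype independently with probability
#' `genotype_error_rate` by a uniformly chosen different non-missing
#' genotype, and sets it missing with probability `missing_rate` (the two
#' events are disjoint). With both rates zero every trio is
#' Mendelian-consistent at every site by construction.
#'
#' @param sites data.frame from [simulate_sites()].
#' @param ch a [cohort()] (see [make_trio_cohort()]).
#' @param config a [sim_config()].
#' @return list with `gt` (site x sample genotype character matrix),
#'   `error` and `missing` (logical flag matrices of the injected events).
#' @export
simulate_genotypes <- function(sites, ch, config) {
  set.seed(config$seed + 1L)
  n_sites <- nrow(sites)
  tr <- ch$trios
  samples <- ch$samples
  dos <- matrix(NA_integer_, n_sites, length(samples),
                dimnames = list(sites$site_id, samples))
  q <- sites$true_af
  hw <- cbind((1 - q)^2, 2 * q * (1 - q), q^2)
  for (f in ch$founders) {
    u <- stats::runif(n_sites)
    dos[, f] <- ifelse(u < hw[, 1], 0L, ifelse(u < hw[, 1] + hw[, 2], 1L, 2L))
  }
  transmit <- function(d) ifelse(d == 0L, 0L, ifelse(d == 2L, 1L,
                                                     stats::rbinom(length(d), 1, 0.5)))
  for (i in seq_len(nrow(tr))) {
    dos[, tr$offspring_id[i]] <-
      transmit(dos[, tr$father_id[i]]) + transmit(dos[, tr$mother_id[i]])
  }
  gt <- matrix(dosage_gt(dos), n_sites, length(samples),
               dimnames = dimnames(dos))
  u <- matrix(stats::runif(length(gt)), n_sites)
  e <- config$genotype_error_rate
  m <- config$missing_rate
  err <- u < e
  mis <- u >= e & u < e + m
  if (any(err)) {
    idx <- which(err)
    shift <- sample.int(2, length(idx), replace = TRUE)  # one of the two others
    cur <- match(gt[idx], c("0/0", "0/1", "1/1")) - 1L
    gt[idx] <- dosage_gt((cur + shift) %% 3L)
  }
  gt[mis] <- "./."
  list(gt = gt, error = err, missing = mis)
}

#' Write a simulated cohort to disk
#'
#' Emits the three files downstream stages consume: a multi-sample VCF, a
#' PED pedigree, and a truth TSV holding the per-site true allele
#' frequencies together with injected error/missing counts.
#'
#' @param sites data.frame from [simulate_sites()].
#' @param geno result of [simulate_genotypes()].
#' @param ch the [cohort()].
#' @param out_dir output directory.
#' @param config the [sim_config()] (for contig headers).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return named list of file paths (`vcf`, `ped`, `truth`).
#' @export
emit_cohort <- function(sites, geno, ch, out_dir, config, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir, " is not empty; set overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sv_panel(sites[c("site_id", "chrom", "pos", "svtype", "svlen", "end")],
                    geno$gt)
  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                ped = file.path(out_dir, "cohort.ped"),
                truth = file.path(out_dir, "truth.tsv"))
  write_sv_vcf(panel, paths$vcf, contigs = config$genome)
  write_ped(ch, paths$ped)
  truth <- sites
  truth$n_error <- rowSums(geno$error)
  truth$n_missing <- rowSums(geno$missing)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Simulate a gene annotation over a toy genome
#'
#' Places `n_genes` non-overlapping genes of equal size (total gene space =
#' `coverage` of the genome), each with 2-10 exons whose union respects the
#' feature-set identities; the CDS is the central 80% of the gene clipped
#' to exons.
#'
#' @param genome a [genome_layout()].
#' @param n_genes number of genes.
#' @param coverage fraction of the genome covered by genes (default 0.3).
#' @param seed RNG seed.
#' @return a [feature_set()].
#' @export
simulate_annotation <- function(genome, n_genes = 50, coverage = 0.3, seed = 1) {
  set.seed(seed)
  if (n_genes == 0)
    return(feature_set(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                       GenomicRanges::GRanges(), genome))
  total <- sum(genome$lengths)
  glen <- as.integer(floor(coverage * total / n_genes))
  if (glen < 20) stop("gene length too small; raise coverage or lower n_genes")
  chroms <- sample(names(genome$lengths), n_genes, replace = TRUE,
                   prob = genome$lengths)
  starts <- integer(n_genes)
  placed <- list()
  for (i in seq_len(n_genes)) {
    ok <- FALSE
    for (try in 1:500) {
      s <- as.integer(floor(stats::runif(1, 1, genome$lengths[[chroms[i]]] - glen)))
      prev <- placed[[chroms[i]]]
      if (!is.null(prev) && any(s <= prev[, 2] + 1 & s + glen >= prev[, 1] - 1)) next
      placed[[chroms[i]]] <- rbind(prev, c(s, s + glen - 1L))
      starts[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) stop("gene density infeasible; lower n_genes or coverage")
  }
  genes <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, width = glen))
  exon_list <- lapply(seq_len(n_genes), function(i) {
    k <- sample(2:10, 1)
    b <- sort(sample.int(glen - 1L, 2L * k)) + starts[i] - 1L
    IRanges::IRanges(start = b[seq(1, 2 * k, 2)] + 1L, end = b[seq(2, 2 * k, 2)])
  })
  exons <- GenomicRanges::GRanges(rep(chroms, vapply(exon_list, length, 1L)),
                                  do.call(c, exon_list))
  core <- GenomicRanges::GRanges(chroms,
                                 IRanges::IRanges(starts + as.integer(0.1 * glen),
                                                  starts + as.integer(0.9 * glen)))
  cds <- GenomicRanges::intersect(exons, core)
  feature_set(genes, exons, cds, genome)
}

#' Simulate, genotype and package a full cohort in one call
#'
#' @param config a [sim_config()].
#' @return list with `sites` (truth table), `geno`, `cohort`, and `panel`
#'   (the truth genotypes as an [sv_panel()], before any merging).
#' @export
simulate_cohort <- function(config) {
  ch <- make_trio_cohort(config$n_trios)
  sites <- simulate_sites(config)
  geno <- simulate_genotypes(sites, ch, config)
  panel <- sv_panel(sites[c("site_id", "chrom", "pos", "svtype", "svlen", "end")],
                    geno$gt)
  list(sites = sites, geno = geno, cohort = ch, panel = panel)
}
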