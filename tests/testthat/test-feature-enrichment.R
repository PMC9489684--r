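toy_fs <- function(g) {
  feature_set(genes = data.frame(chrom = "chr1", start = 1000, end = 3000),
              exons = data.frame(chrom = "chr1", start = c(1000, 2500),
                                 end = c(1500, 3000)),
              cds = data.frame(chrom = "chr1", start = 1000, end = 1500),
              genome = g)
}

test_that("overlap classification uses intervals for DELs and points for INSs", {
  g <- genome_layout(c(chr1 = 10000))
  fs <- toy_fs(g)
  p <- fixture_panel(data.frame(chrom = "chr1",
                                pos = c(1400L, 5000L, 1100L, 2400L),
                                svtype = c("DEL", "INS", "INS", "DEL"),
                                svlen = c(200L, 100L, 60L, 60L)),
                     list("0/1", "0/1", "0/1", "0/1"), "S1"); p <- sort_panel(p)
  fl <- classify_overlaps(p, fs)
  rn <- p$sites$pos
  # DEL [1401,1600] spans the exon/intron boundary at 1500
  i <- which(rn == 1400)
  expect_true(fl$exon[i] && fl$intron[i] && fl$cds[i] && !fl$intergenic[i])
  # INS point deep in intergenic space
  i <- which(rn == 5000)
  expect_true(fl$intergenic[i] && !fl$exon[i] && !fl$intron[i])
  # INS point inside the CDS exon
  i <- which(rn == 1100)
  expect_true(fl$exon[i] && fl$cds[i] && !fl$intron[i])
  # DEL [2401,2460] wholly intronic
  i <- which(rn == 2400)
  expect_true(fl$intron[i] && !fl$exon[i] && !fl$intergenic[i])
  expect_true(all(fl$intergenic | fl$intron | fl$exon | fl$cds))
  # unknown chromosome is reported unclassified
  p2 <- fixture_panel(data.frame(chrom = "chr9", pos = 100L, svtype = "INS",
                                 svlen = 60L), list("0/1"), "S1")
  expect_true(classify_overlaps(p2, fs)$unclassified)
})

test_that("classification is invariant to fragmenting feature intervals", {
  g <- genome_layout(c(chr1 = 10000))
  fs_split <- feature_set(genes = data.frame(chrom = "chr1", start = 1000, end = 3000),
                          exons = data.frame(chrom = "chr1",
                                             start = c(1000, 1200, 2500),
                                             end = c(1200, 1500, 3000)),
                          cds = data.frame(chrom = "chr1", start = c(1000, 1250),
                                           end = c(1250, 1500)),
                          genome = g)
  cfg <- sim_config(n_trios = 2, n_sites = 150, genome = toy_genome(1, 10000),
                    min_spacing = 0, seed = 41)
  sim <- simulate_cohort(cfg)
  expect_equal(classify_overlaps(sim$panel, fs_split),
               classify_overlaps(sim$panel, toy_fs(g)))
})

test_that("randomization preserves chromosomes, lengths and stays out of gaps", {
  g <- toy_genome(2, 1e6, gaps = data.frame(chrom = "chr1", start = 4e5, end = 6e5))
  cfg <- sim_config(n_trios = 2, n_sites = 200, genome = g, seed = 42)
  sim <- simulate_cohort(cfg)
  rp <- randomize_positions(sim$panel, g, seed = 7)
  expect_equal(rp$sites$chrom, sim$panel$sites$chrom)
  expect_equal(rp$sites$svlen, sim$panel$sites$svlen)
  expect_equal(rp$sites$svtype, sim$panel$sites$svtype)
  hits <- IRanges::overlapsAny(panel_ranges(rp), g$gaps)
  expect_false(any(hits))
  # reproducible under a fixed seed
  rp2 <- randomize_positions(sim$panel, g, seed = 7)
  expect_equal(rp$sites$pos, rp2$sites$pos)
  # an SV longer than its chromosome cannot be placed
  long <- fixture_panel(data.frame(chrom = "chr1", pos = 10L, svtype = "DEL",
                                   svlen = 2e6L), list("0/1"), "S1")
  expect_error(randomize_positions(long, g), "longer than its chromosome")
})

test_that("randomized positions are uniform on a gap-free chromosome", {
  g <- toy_genome(1, 1e7)
  p <- fixture_panel(data.frame(chrom = "chr1",
                                pos = rep(100L, 10000), svtype = "INS",
                                svlen = 100L),
                     as.list(rep("0/1", 10000)), "S1")
  rp <- randomize_positions(p, g, seed = 43)
  ks <- suppressWarnings(stats::ks.test(rp$sites$pos / 1e7, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("enrichment scores are calibrated on uniform panels and detect planted signal", {
  g <- toy_genome(2, 5e6)
  fs <- simulate_annotation(g, n_genes = 30, coverage = 0.3, seed = 44)
  # pooled over a few independent uniform panels: p-values mostly above 0.05
  # (a calibrated test is allowed its ~5% of small ones) and envelopes
  # bracket the null score of 1
  pvals <- NULL
  envs <- NULL
  for (seed in 45:47) {
    cfg <- sim_config(n_trios = 2, n_sites = 250, genome = g, seed = seed)
    sim <- simulate_cohort(cfg)
    et <- enrichment_test(sim$panel, fs, g, n_perm = 99, seed = seed + 100)
    pvals <- c(pvals, et$p_value)
    envs <- c(envs, et$perm_min <= 1 & et$perm_max >= 1)
  }
  expect_true(all(pvals > 0 & pvals <= 1))
  expect_gte(sum(pvals > 0.05), 10)
  expect_true(all(envs))
  cfg <- sim_config(n_trios = 2, n_sites = 250, genome = g, seed = 45)
  sim <- simulate_cohort(cfg)
  # a feature covering the whole genome leaves nothing intergenic
  all_gene <- feature_set(genes = data.frame(chrom = rep(c("chr1", "chr2"), 1),
                                             start = 0, end = 5e6),
                          exons = data.frame(chrom = c("chr1", "chr2"),
                                             start = 0, end = 5e6),
                          cds = data.frame(chrom = c("chr1", "chr2"),
                                           start = 0, end = 5e6),
                          genome = g)
  et2 <- enrichment_test(sim$panel, all_gene, g, n_perm = 19, seed = 47)
  expect_equal(et2$observed[et2$feature_class == "intergenic"], 0L)
  expect_equal(et2$score[et2$feature_class == "exon"], 1)
  expect_equal(et2$p_value[et2$feature_class == "exon"], 1)
  # planted signal: all SVs in intergenic space drive p to the floor
  inter <- as.data.frame(fs$intergenic)
  big <- inter[inter$width > 2000, ]
  set.seed(48)
  rows <- big[sample(nrow(big), 150, replace = TRUE), ]
  planted <- fixture_panel(
    data.frame(chrom = as.character(rows$seqnames),
               pos = as.integer(rows$start + floor(runif(150) * (rows$width - 1000)) + 500),
               svtype = "INS", svlen = 100L),
    as.list(rep("0/1", 150)), "S1")
  et3 <- enrichment_test(sort_panel(planted), fs, g, n_perm = 199, seed = 49)
  expect_gt(et3$score[et3$feature_class == "intergenic"], 1)
  expect_equal(et3$p_value[et3$feature_class == "intergenic"], 2 / 200)
})

test_that("MAF-by-feature proportions are row-normalized", {
  g <- genome_layout(c(chr1 = 10000))
  fs <- toy_fs(g)
  p <- fixture_panel(data.frame(chrom = "chr1", pos = c(1100L, 5000L),
                                svtype = "INS", svlen = 60L),
                     list(c("0/1", rep("0/0", 9)),
                          rep(c("0/1", "0/0"), c(6, 4))),
                     paste0("F", 1:10))
  p <- categorize_maf(compute_af(p, paste0("F", 1:10)))
  tab <- maf_by_feature(p, fs)
  cds_row <- tab[tab$feature_class == "cds", ]
  expect_equal(unname(unlist(cds_row[MAF_CATEGORIES])), c(1, 0, 0, 0))
  expect_true(all(abs(rowSums(tab[tab$n > 0, MAF_CATEGORIES]) - 1) < 1e-12))
  expect_true(all(is.na(tab[tab$n == 0, MAF_CATEGORIES])))
})

test_that("chromosome density bins and rank test behave on uniform panels", {
  g <- toy_genome(3, 7e6)
  cfg <- sim_config(n_trios = 2, n_sites = 600, genome = g, min_spacing = 0,
                    seed = 50)
  sim <- simulate_cohort(cfg)
  cd <- chromosome_density(sim$panel, g, bin = 2e6)
  expect_equal(nrow(cd$bins), 3 * ceiling(7e6 / 2e6))
  expect_equal(sum(cd$bins$count), 600)
  expect_equal(max(cd$bins$bin_end), 7e6)  # truncated final bin
  expect_equal(sum(cd$per_chrom$n_sv), 600)
  expect_gt(cd$test$p.value, 0.01)
  # single-bin chromosome is handled
  g1 <- toy_genome(1, 1.5e6)
  p1 <- fixture_panel(data.frame(chrom = "chr1", pos = 100L, svtype = "INS",
                                 svlen = 60L), list("0/1"), "S1")
  cd1 <- chromosome_density(p1, g1, bin = 2e6)
  expect_equal(nrow(cd1$bins), 1)
  expect_null(cd1$test)
})
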