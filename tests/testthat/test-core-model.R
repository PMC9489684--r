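test_that("genotype codes, dosage and normalization behave", {
  expect_equal(gt_dosage(c("0/0", "0/1", "1/1", "./.")), c(0L, 1L, 2L, NA))
  expect_equal(normalize_gt(c("0|1", "1/0", "1|1", NA, "1/2", ".")),
               c("0/1", "0/1", "1/1", "./.", "./.", "./."))
  expect_equal(dosage_gt(c(0, 1, 2, NA)), c("0/0", "0/1", "1/1", "./."))
})

test_that("SV VCF ingest applies sign, length, type and autosome filters", {
  path <- write_vcf_text(c(
    "chr1\t100\tv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-4900\tGT\t0/1\t0|0",
    "chr1\t5000\tv2\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=49\tGT\t1/1\t0/1",
    "chrX\t200\tv3\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300\tGT\t0/1\t./.",
    "chr2\t300\tv4\tN\tA,<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=60,70\tGT\t1/2\t0/1",
    "chr2\t900\tv5\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;SVLEN=500\tGT\t0/1\t0/1"))
  x <- read_sv_vcf(path)
  expect_equal(x$records$id, c("v1", "v4"))
  # negative DEL SVLEN stored as absolute value; END = pos + svlen
  expect_equal(x$records$svlen[1], 4900L)
  expect_equal(x$records$end[1], 5000L)
  # INS end == pos
  expect_equal(x$records$end[2], 300L)
  # skip reasons recorded
  expect_setequal(x$skipped$reason,
                  c("non-autosome", "SVLEN below 50", "SVTYPE not DEL/INS"))
  # multi-allelic genotype referencing the dropped allele becomes missing
  expect_equal(unname(x$gt[2, ]), c("./.", "0/1"))
  # a file with no usable record is a hard error
  bad <- write_vcf_text("chrX\t1000\tv\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300\tGT\t0/1\t0/1")
  expect_error(read_sv_vcf(bad), "no usable")
})

test_that("panel VCF round-trip is lossless for all typed fields", {
  cfg <- sim_config(n_trios = 5, n_sites = 10, seed = 11)
  sim <- simulate_cohort(cfg)
  p <- categorize_maf(compute_af(sim$panel, sim$cohort))
  p <- mie_by_site(p, sim$cohort)
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(p, path, cfg$genome)
  p2 <- read_sv_panel(path)
  cols <- c("chrom", "pos", "svtype", "svlen", "end", "ac", "an", "af",
            "mac", "maf", "category", "mie_families", "mie_eval",
            "error_family_ratio")
  expect_equal(p2$sites[cols], p$sites[cols])
  expect_equal(p2$gt, p$gt)
  # and a second pass is byte-identical
  path2 <- tempfile(fileext = ".vcf")
  write_sv_vcf(p2, path2, cfg$genome)
  expect_identical(readLines(path2), readLines(path))
})

test_that("empty panels produce valid header-only VCFs", {
  p0 <- sv_panel(data.frame(chrom = character(), pos = integer(),
                            svtype = character(), svlen = integer()),
                 matrix(character(), 0, 0))
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(p0, path)
  expect_equal(nrow(read_sv_vcf(path)$records), 0)
})

test_that("unsorted panels are sorted on write with a notice", {
  p <- fixture_panel(data.frame(chrom = c("chr2", "chr1"), pos = c(500L, 900L),
                                svtype = "DEL", svlen = c(100L, 120L)),
                     list("0/1", "1/1"), "S1")
  path <- tempfile(fileext = ".vcf")
  expect_message(write_sv_vcf(p, path), "sorting")
  expect_equal(read_sv_vcf(path)$records$chrom, c("chr1", "chr2"))
})

test_that("pedigree parsing builds trios and founders and validates", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("FAM1\tF\t0\t0\t1\t-9",
               "FAM1\tM\t0\t0\t2\t-9",
               "FAM1\tC\tF\tM\t1\t-9",
               "FAM2\tLONER\t0\t0\t1\t-9"), ped)
  ch <- read_pedigree(ped)
  expect_equal(nrow(ch$trios), 1)
  expect_setequal(ch$founders, c("F", "M", "LONER"))
  # absent parent is a hard error
  writeLines(c("FAM1\tC\tF\tM\t1\t-9"), ped)
  expect_error(read_pedigree(ped), "absent parent")
  # duplicate individual IDs are a hard error
  writeLines(c("FAM1\tA\t0\t0\t1\t-9", "FAM2\tA\t0\t0\t1\t-9"), ped)
  expect_error(read_pedigree(ped), "duplicate")
})

test_that("a synthetic 111-family pedigree yields 111 trios and 222 founders", {
  ch <- make_trio_cohort(111)
  ped <- tempfile(fileext = ".ped")
  write_ped(ch, ped)
  ch2 <- read_pedigree(ped)
  expect_equal(length(ch2$samples), 333)
  expect_equal(nrow(ch2$trios), 111)
  expect_equal(length(ch2$founders), 222)
})

test_that("feature sets derive introns and intergenic space by set algebra", {
  g <- genome_layout(c(chr1 = 1000))
  # gene [100,300), exons [100,150) and [250,300) -> intron [150,250)
  fs <- feature_set(genes = data.frame(chrom = "chr1", start = 100, end = 300),
                    exons = data.frame(chrom = "chr1", start = c(100, 250),
                                       end = c(150, 300)),
                    cds = data.frame(chrom = "chr1", start = 100, end = 150),
                    genome = g)
  intr <- as.data.frame(fs$introns)
  expect_equal(c(intr$start, intr$end), c(151, 250))  # 1-based closed [151,250]
  inter <- as.data.frame(fs$intergenic)
  expect_equal(inter$start, c(1, 301))
  expect_equal(inter$end, c(100, 1000))
  # single-exon gene covering itself has no introns
  fs2 <- feature_set(genes = data.frame(chrom = "chr1", start = 100, end = 200),
                     exons = data.frame(chrom = "chr1", start = 100, end = 200),
                     cds = data.frame(chrom = "chr1", start = 120, end = 180),
                     genome = g)
  expect_equal(length(fs2$introns), 0)
})

test_that("interval identities hold for simulated annotations", {
  g <- toy_genome(2, 1e6)
  bp <- function(gr) sum(BiocGenerics::width(gr))
  for (seed in 1:3) {
    fs <- simulate_annotation(g, n_genes = 20, coverage = 0.25, seed = seed)
    expect_equal(bp(fs$introns) + bp(fs$exons), bp(fs$genes))
    expect_equal(bp(fs$intergenic), sum(g$lengths) - bp(fs$genes))
    expect_equal(length(GenomicRanges::intersect(fs$intergenic, fs$genes)), 0)
    # gene bp fraction close to requested coverage
    expect_lt(abs(bp(fs$genes) / sum(g$lengths) - 0.25), 0.02)
  }
})

test_that("GFF3 features load and are clipped consistently", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", 101, 300, ".", "+", ".", "ID=g1", sep = "\t"),
               paste("chr1", "src", "exon", 101, 150, ".", "+", ".", "Parent=g1", sep = "\t"),
               paste("chr1", "src", "exon", 251, 300, ".", "+", ".", "Parent=g1", sep = "\t"),
               paste("chr1", "src", "CDS", 121, 150, ".", "+", ".", "Parent=g1", sep = "\t")),
             gff)
  fs <- read_features(gff, genome_layout(c(chr1 = 1000)))
  expect_equal(sum(BiocGenerics::width(fs$genes)), 200)
  expect_equal(sum(BiocGenerics::width(fs$exons)), 100)
  expect_equal(sum(BiocGenerics::width(fs$introns)), 100)
  expect_equal(sum(BiocGenerics::width(fs$cds)), 30)
})

test_that("genome layout excludes gaps from effective lengths", {
  g <- genome_layout(c(chr1 = 1000, chr2 = 500),
                     gaps = data.frame(chrom = "chr1", start = c(100, 150),
                                       end = c(200, 250)))
  # overlapping/adjacent gaps are unioned: [100,250) = 150 bp
  expect_equal(unname(effective_lengths(g)), c(850, 500))
  fai <- tempfile()
  writeLines(c("chr1\t1000\t10\t60\t61", "chr2\t500\t10\t60\t61"), fai)
  g2 <- read_genome_layout(fai)
  expect_equal(g2$lengths, c(chr1 = 1000, chr2 = 500))
})

test_that("DEL coordinate convention maps VCF pos to a half-open interval of width L", {
  p <- fixture_panel(data.frame(chrom = "chr1", pos = 100L, svtype = "DEL",
                                svlen = 40L), list("0/1"), "S1")
  gr <- panel_ranges(p)
  # VCF pos 100 with padding base deletes 0-based [100, 140): 1-based [101,140]
  expect_equal(BiocGenerics::start(gr), 101)
  expect_equal(BiocGenerics::end(gr), 140)
  expect_equal(BiocGenerics::width(gr), 40)
})
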