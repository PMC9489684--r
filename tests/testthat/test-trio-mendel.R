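test_that("Mendelian consistency matches gamete enumeration for all 27 combos", {
  for (f in 0:2) for (m in 0:2) for (o in 0:2) {
    expect_equal(is_mie(gt_of(f), gt_of(m), gt_of(o)), oracle_mie(f, m, o),
                 info = sprintf("f=%d m=%d o=%d", f, m, o))
  }
})

test_that("Mendelian check is symmetric in the parents and NA on missing data", {
  for (f in 0:2) for (m in 0:2) for (o in 0:2) {
    expect_equal(is_mie(gt_of(f), gt_of(m), gt_of(o)),
                 is_mie(gt_of(m), gt_of(f), gt_of(o)))
  }
  expect_true(is.na(is_mie("./.", "0/1", "0/1")))
  expect_true(is.na(is_mie("0/1", "./.", "0/1")))
  expect_true(is.na(is_mie("0/1", "0/1", "./.")))
  # canonical spot checks
  expect_true(is_mie("0/0", "0/0", "0/1"))
  expect_true(is_mie("0/0", "1/1", "0/0"))
  expect_true(is_mie("0/0", "1/1", "1/1"))
  expect_false(is_mie("0/1", "0/1", "1/1"))
})

test_that("per-trio MIE rates use the segregating-site denominator", {
  samples <- c("F", "M", "C")
  ch <- cohort(samples, data.frame(father_id = "F", mother_id = "M",
                                   offspring_id = "C"))
  p <- fixture_panel(data.frame(chrom = "chr1",
                                pos = seq(1000L, by = 2000L, length.out = 5),
                                svtype = "DEL", svlen = 100L),
                     list(c("0/0", "0/0", "0/1"),   # MIE
                          c("0/1", "0/1", "1/1"),   # consistent
                          c("0/0", "0/0", "0/0"),   # triple-ref: not evaluated
                          c("./.", "0/1", "0/1"),   # missing: not evaluated
                          c("0/0", "1/1", "0/1")),  # consistent
                     samples)
  r <- mie_by_trio(p, ch)
  expect_equal(r$n_evaluated, 3L)
  expect_equal(r$n_mie, 1L)
  expect_equal(r$mie_rate, 1 / 3)
  # with triple-reference sites included the denominator grows
  r2 <- mie_by_trio(p, ch, include_triple_ref = TRUE)
  expect_equal(r2$n_evaluated, 4L)
  # rate agrees with direct division on larger simulated data
  cfg <- sim_config(n_trios = 15, n_sites = 400, genotype_error_rate = 0.05,
                    seed = 31)
  sim <- simulate_cohort(cfg)
  rr <- mie_by_trio(sim$panel, sim$cohort)
  expect_equal(rr$mie_rate, rr$n_mie / rr$n_evaluated)
})

test_that("per-trio MIE counts agree with a brute-force per-site oracle", {
  cfg <- sim_config(n_trios = 6, n_sites = 150, genotype_error_rate = 0.08,
                    missing_rate = 0.05, seed = 32)
  sim <- simulate_cohort(cfg)
  r <- mie_by_trio(sim$panel, sim$cohort)
  for (i in seq_len(nrow(sim$cohort$trios))) {
    tr <- sim$cohort$trios[i, ]
    fd <- gt_dosage(sim$panel$gt[, tr$father_id])
    md <- gt_dosage(sim$panel$gt[, tr$mother_id])
    od <- gt_dosage(sim$panel$gt[, tr$offspring_id])
    n_mie <- 0L; n_ev <- 0L
    for (s in seq_along(fd)) {
      if (is.na(fd[s]) || is.na(md[s]) || is.na(od[s])) next
      if (fd[s] == 0 && md[s] == 0 && od[s] == 0) next
      n_ev <- n_ev + 1L
      if (oracle_mie(fd[s], md[s], od[s])) n_mie <- n_mie + 1L
    }
    expect_equal(r$n_mie[i], n_mie)
    expect_equal(r$n_evaluated[i], n_ev)
  }
})

test_that("error family ratios count MIE trios over evaluable trios per site", {
  samples <- c("F1", "M1", "C1", "F2", "M2", "C2", "F3", "M3", "C3")
  ch <- cohort(samples,
               data.frame(father_id = c("F1", "F2", "F3"),
                          mother_id = c("M1", "M2", "M3"),
                          offspring_id = c("C1", "C2", "C3")))
  p <- fixture_panel(data.frame(chrom = "chr1", pos = c(1000L, 4000L),
                                svtype = "INS", svlen = 200L),
                     list(c("0/0", "0/0", "0/1",  # trio1 MIE
                            "0/1", "0/1", "0/0",  # trio2 consistent
                            "./.", "0/1", "0/1"), # trio3 not evaluable
                          c("0/0", "0/0", "0/0",  # trio1 triple-ref
                            "0/1", "0/1", "1/1",  # trio2 consistent
                            "1/1", "0/0", "0/1")),# trio3 consistent
                     samples)
  p <- mie_by_site(p, ch)
  expect_equal(p$sites$mie_families, c(1L, 0L))
  expect_equal(p$sites$mie_eval, c(2L, 2L))
  expect_equal(p$sites$error_family_ratio, c(0.5, 0))
  # e = 0 simulation: ratio 0 wherever evaluable
  cfg <- sim_config(n_trios = 20, n_sites = 100, seed = 33)
  sim <- simulate_cohort(cfg)
  ps <- mie_by_site(sim$panel, sim$cohort)
  expect_true(all(ps$sites$error_family_ratio == 0, na.rm = TRUE))
})

test_that("expected offspring distributions are the Punnett-square triples", {
  expect_equal(unname(expected_offspring_distribution("0/1", "0/1")),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(expected_offspring_distribution("0/0", "1/1")), c(0, 1, 0))
  expect_equal(unname(expected_offspring_distribution("0/0", "0/1")),
               c(0.5, 0.5, 0))
  expect_error(expected_offspring_distribution("./.", "0/1"), "missing")
})

test_that("combo tables tabulate unordered parental pairs with expectations", {
  samples <- c("F", "M", "C")
  ch <- cohort(samples, data.frame(father_id = "F", mother_id = "M",
                                   offspring_id = "C"))
  p <- fixture_panel(data.frame(chrom = "chr1", pos = 1000L, svtype = "DEL",
                                svlen = 100L),
                     list(c("0/1", "0/1", "0/0")), samples)
  tab <- combo_table(p, ch)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pair, "0/1 x 0/1")
  expect_equal(c(tab$obs_00, tab$obs_01, tab$obs_11), c(1, 0, 0))
  expect_equal(c(tab$exp_00, tab$exp_01, tab$exp_11), c(0.25, 0.5, 0.25))
  # unordered: swapped parents land in the same row
  p2 <- fixture_panel(data.frame(chrom = "chr1", pos = c(1000L, 3000L),
                                 svtype = "DEL", svlen = 100L),
                      list(c("0/0", "0/1", "0/0"),
                           c("0/1", "0/0", "0/0")), samples)
  tab2 <- combo_table(p2, ch)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$n, 2L)
})

test_that("observed offspring frequencies match expectation on clean simulations", {
  cfg <- sim_config(n_trios = 100, n_sites = 500, seed = 34)
  sim <- simulate_cohort(cfg)
  tab <- combo_table(sim$panel, sim$cohort)
  # no all-reference pair row: those combinations are excluded
  expect_false("0/0 x 0/0" %in% tab$pair[tab$obs_00 == 1 & tab$exp_00 == 1 & tab$n == 0])
  for (i in seq_len(nrow(tab))) {
    for (col in c("00", "01", "11")) {
      o <- tab[[paste0("obs_", col)]][i]
      e <- tab[[paste0("exp_", col)]][i]
      sd3 <- 3 * sqrt(max(e * (1 - e), 1e-9) / tab$n[i])
      expect_lt(abs(o - e), max(sd3, 0.02))
    }
  }
})

test_that("MIE rates rise with injected error and fall with missingness coverage", {
  rates <- sapply(c(0, 0.02, 0.05), function(e) {
    cfg <- sim_config(n_trios = 20, n_sites = 500, genotype_error_rate = e,
                      seed = 35)
    sim <- simulate_cohort(cfg)
    mean(mie_by_trio(sim$panel, sim$cohort)$mie_rate, na.rm = TRUE)
  })
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) > 0))
  # n_evaluated shrinks roughly by (1-m)^3
  n_ev <- sapply(c(0, 0.3), function(m) {
    cfg <- sim_config(n_trios = 20, n_sites = 500, missing_rate = m, seed = 36)
    sim <- simulate_cohort(cfg)
    sum(mie_by_trio(sim$panel, sim$cohort)$n_evaluated)
  })
  expect_equal(n_ev[2] / n_ev[1], 0.7^3, tolerance = 0.1)
})
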