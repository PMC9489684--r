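#' Configuration for an end-to-end pipeline run
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param merge a [merge_params()].
#' @param n_perm permutations for the enrichment stage.
#' @param n_genes genes in the simulated annotation.
#' @param compare_keep fraction of panel sites retained in the second panel
#'   of the demo cross-panel comparison.
#' @param out_dir output directory.
#' @param overwrite overwrite an existing non-empty `out_dir`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(n_trios = 20, n_sites = 500,
                                        genotype_error_rate = 0.02),
                       merge = merge_params(), n_perm = 200, n_genes = 50,
                       compare_keep = 0.6, out_dir = tempfile("triosv_run_"),
                       overwrite = FALSE) {
  structure(list(sim = sim, merge = merge, n_perm = n_perm, n_genes = n_genes,
                 compare_keep = compare_keep, out_dir = out_dir,
                 overwrite = overwrite),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a trio cohort, writes and re-reads its VCF/PED, merges the
#' per-sample calls into a nonredundant panel, computes founder allele
#' frequencies and MAF categories, profiles Mendelian inheritance errors,
#' runs the positional-randomization enrichment test against a simulated
#' annotation, performs a demo cross-panel comparison, and writes a
#' manifest with every seed and parameter. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @param ped_path optional path to an existing PED file to use instead of
#'   the simulated pedigree (the Mendelian stage fails, naming itself, if
#'   the file does not exist).
#' @return named list of output paths, invisibly; the outputs land in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, ped_path = NULL) {
  out <- config$out_dir
  if (dir.exists(out) && length(list.files(out)) > 0 && !config$overwrite)
    stop("output directory ", out, " is not empty; set overwrite = TRUE")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  sim <- with_stage("simulate", {
    s <- simulate_cohort(config$sim)
    s$paths <- emit_cohort(s$sites, s$geno, s$cohort,
                           file.path(out, "cohort"), config$sim,
                           overwrite = TRUE)
    s
  })

  ingest <- with_stage("ingest", {
    vcf <- read_sv_vcf(sim$paths$vcf)
    ped <- if (is.null(ped_path)) sim$paths$ped else ped_path
    if (!file.exists(ped)) stop("pedigree file not found: ", ped)
    list(vcf = vcf, cohort = read_pedigree(ped))
  })

  panel <- with_stage("merge", {
    calls <- as_sv_calls(ingest$vcf)
    merge_calls(calls, config$merge, samples = ingest$cohort$samples)
  })

  panel <- with_stage("allele_frequency", {
    p <- categorize_maf(compute_af(panel, ingest$cohort))
    summ <- panel_summary(frequency_panel(p))
    write_tsv(summ$per_category, file.path(out, "af_categories.tsv"))
    write_tsv(data.frame(sample_id = names(summ$per_sample),
                         n_sv = as.integer(summ$per_sample)),
              file.path(out, "per_sample_counts.tsv"))
    p
  })

  panel <- with_stage("mendel", {
    p <- mie_by_site(panel, ingest$cohort)
    write_tsv(mie_by_trio(p, ingest$cohort), file.path(out, "mie_per_trio.tsv"))
    write_tsv(combo_table(p, ingest$cohort), file.path(out, "mie_combos.tsv"))
    p
  })

  with_stage("enrichment", {
    ann <- simulate_annotation(config$sim$genome, n_genes = config$n_genes,
                               seed = config$sim$seed + 2L)
    enr <- enrichment_test(frequency_panel(panel), ann, config$sim$genome,
                           n_perm = config$n_perm, seed = config$sim$seed + 3L)
    write_tsv(enr, file.path(out, "enrichment.tsv"))
  })

  with_stage("compare", {
    fp <- frequency_panel(panel)
    set.seed(config$sim$seed + 4L)
    keep <- stats::runif(nrow(fp$sites)) < config$compare_keep
    cmp <- comparison_report(fp, subset_panel(fp, keep), config$merge)
    write_tsv(cmp$counts, file.path(out, "compare_counts.tsv"))
    write_tsv(cmp$category_breakdown, file.path(out, "compare_categories.tsv"))
    write_tsv(cmp$af_correlation, file.path(out, "compare_af_correlation.tsv"))
  })

  vcf_out <- file.path(out, "panel.af.vcf")
  with_stage("write_panel", write_sv_vcf(panel, vcf_out, config$sim$genome))

  manifest <- list(
    package_version = as.character(utils::packageVersion("triosv")),
    seed = config$sim$seed,
    derived_seeds = list(genotypes = config$sim$seed + 1L,
                         annotation = config$sim$seed + 2L,
                         enrichment = config$sim$seed + 3L,
                         compare_subsample = config$sim$seed + 4L),
    sim = config$sim[setdiff(names(config$sim), "genome")],
    genome = as.list(config$sim$genome$lengths),
    merge = unclass(config$merge),
    n_perm = config$n_perm, n_genes = config$n_genes,
    compare_keep = config$compare_keep,
    input_checksums = as.list(tools::md5sum(unlist(sim$paths))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel_vcf = vcf_out, out_dir = out,
                 cohort = sim$paths,
                 tables = file.path(out, c("af_categories.tsv",
                                           "per_sample_counts.tsv",
                                           "mie_per_trio.tsv", "mie_combos.tsv",
                                           "enrichment.tsv", "compare_counts.tsv",
                                           "manifest.json"))))
}
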