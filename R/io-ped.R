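#' Construct a cohort from an explicit trio table
#'
#' A cohort is the pedigree structure of the study: an ordered sample list,
#' the parent-offspring trios, and the founder set (individuals with no
#' parents in the pedigree). Allele frequencies are always computed on
#' founders, so that alleles transmitted to offspring are not double
#' counted.
#'
#' @param samples ordered character vector of sample IDs.
#' @param trios data.frame with columns `father_id`, `mother_id`,
#'   `offspring_id`.
#' @param founders character vector of founder IDs; defaults to the union of
#'   fathers and mothers.
#' @return an object of class `cohort`.
#' @export
cohort <- function(samples, trios, founders = NULL) {
  trios <- as.data.frame(trios, stringsAsFactors = FALSE)
  stopifnot(all(c("father_id", "mother_id", "offspring_id") %in% names(trios)))
  if (is.null(founders)) founders <- unique(c(trios$father_id, trios$mother_id))
  if (anyDuplicated(samples)) stop("duplicate sample IDs in cohort")
  missing <- setdiff(unique(unlist(trios[c("father_id", "mother_id", "offspring_id")])),
                     samples)
  if (length(missing)) stop("trio members absent from sample list: ",
                            paste(missing, collapse = ", "))
  bad <- trios$father_id == trios$mother_id | trios$father_id == trios$offspring_id |
    trios$mother_id == trios$offspring_id
  if (any(bad)) stop("trio with non-distinct member IDs")
  if (length(intersect(founders, trios$offspring_id)))
    stop("founder set overlaps offspring set")
  structure(list(samples = samples, trios = trios, founders = founders),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", length(x$samples), "samples,", nrow(x$trios), "trios,",
      length(x$founders), "founders\n")
  invisible(x)
}

#' Read a pedigree (PED) file into a cohort
#'
#' Expects the 6-column PED dialect (family, individual, father, mother,
#' sex, phenotype) with `"0"` for an unknown parent. Every row with both
#' parents known becomes one trio; individuals with both parents unknown
#' are founders.
#'
#' @param path path to a whitespace-delimited PED file.
#' @return a [cohort()].
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  if (anyDuplicated(ped$id)) stop("duplicate individual IDs in ", path)
  has_both <- ped$father != "0" & ped$mother != "0"
  ref_parents <- unique(c(ped$father[ped$father != "0"], ped$mother[ped$mother != "0"]))
  absent <- setdiff(ref_parents, ped$id)
  if (length(absent)) stop("pedigree references absent parent IDs: ",
                           paste(absent, collapse = ", "))
  trios <- data.frame(father_id = ped$father[has_both],
                      mother_id = ped$mother[has_both],
                      offspring_id = ped$id[has_both], stringsAsFactors = FALSE)
  founders <- ped$id[ped$father == "0" & ped$mother == "0"]
  cohort(samples = ped$id, trios = trios, founders = founders)
}

#' Write a cohort as a PED file
#'
#' @param ch a [cohort()].
#' @param path output path.
#' @param family optional family IDs per trio; defaults to `FAM<i>`.
#' @return the path, invisibly.
#' @export
write_ped <- function(ch, path, family = NULL) {
  tr <- ch$trios
  if (is.null(family)) family <- sprintf("FAM%04d", seq_len(nrow(tr)))
  fam_of <- c(stats::setNames(rep(family, 3),
                              c(tr$father_id, tr$mother_id, tr$offspring_id)))
  rows <- lapply(ch$samples, function(s) {
    i <- match(s, tr$offspring_id)
    c(if (!is.na(fam_of[s])) fam_of[s] else s, s,
      if (!is.na(i)) tr$father_id[i] else "0",
      if (!is.na(i)) tr$mother_id[i] else "0", "0", "-9")
  })
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Build the sample IDs of a synthetic trio cohort
#'
#' @param n_trios number of parent-offspring trios.
#' @return a [cohort()] with samples `T<i>_F`, `T<i>_M`, `T<i>_C`.
#' @export
make_trio_cohort <- function(n_trios) {
  stopifnot(n_trios >= 1)
  fam <- sprintf("T%04d", seq_len(n_trios))
  trios <- data.frame(father_id = paste0(fam, "_F"), mother_id = paste0(fam, "_M"),
                      offspring_id = paste0(fam, "_C"), stringsAsFactors = FALSE)
  samples <- as.vector(t(as.matrix(trios[c("father_id", "mother_id", "offspring_id")])))
  cohort(samples = samples, trios = trios)
}
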