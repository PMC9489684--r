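---
title: "Trio-based structural-variant panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based structural-variant panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triosv)
```

# The analysis

`triosv` implements the population-genetic core of a trio-based
structural-variant (SV) panel study: per-sample deletion/insertion calls
(each at least 50 bp) from a cohort of parent–offspring trios are merged
into a nonredundant panel; allele frequencies are computed on the founders
only; panel quality is profiled through Mendelian inheritance errors
(MIEs); the genomic localization of the SVs is tested by positional
randomization; and the panel is compared against a second cohort's panel.
Every stage is exercisable on synthetic cohorts generated in the package,
so the full pipeline is testable without any external data.

# Panel construction

## Merging model

Per-sample calls are clustered by single linkage within each
(chromosome, SV type) stratum: two calls are linked when their start
positions differ by at most `max_dist` (default 1000 bp), and linkage is
transitive. This is the operational meaning we give the published
distance/type merging contract ("1 kb, one supporting sample, type must
match"); the reference merging tool's internal heuristics are not
reproduced bit-for-bit because only the option string is public, and
single linkage is deterministic, order-invariant and testable. Insertions
are compared by start position only — insertion length similarity is
deliberately not required, matching the disabled size criterion of the
published setting.

Each cluster becomes one site whose representative position and length are
the *lower medians* of the member values (the element at position
`floor((n+1)/2)` of the sorted values). The lower median is always an
observed member value and breaks even-cluster ties toward the smaller
coordinate, which makes merging deterministic.

A sample with several calls inside one cluster contributes its
highest-dosage genotype. A sample with *no* call in a cluster is recorded
as homozygous reference by default. The study re-genotyped merged sites
with a joint call, which we do not reproduce; treating absence as `0/0` is
the conservative stand-in and `absent_as_missing = TRUE` provides the
alternative reading.

## Founder allele frequencies and MAF categories

Offspring carry one allele from each parent, so counting them would double
count transmitted alleles. All frequencies are therefore computed on
founders: `AN` is twice the number of founders with a non-missing
genotype, `AC` the summed alternative dosage, `AF = AC/AN`,
`MAF = min(AF, 1 - AF)`. A site never observed in a founder
(`AC == 0`) is flagged `founders_absent` and excluded from the frequency
panel while staying in the repository.

Categories follow the published boundaries with singleton precedence:
singleton (`MAC == 1`), rare (`MAC > 1` and `MAF < 0.01`), low
(`0.01 <= MAF < 0.05`), common (`MAF >= 0.05`). A boundary value of
exactly 0.05 is common. Sites with `MAC == 0` (including fixed sites with
`AF == 1`) have no minor allele to categorize and stay `NA`.

# Mendelian inheritance errors

A trio genotype combination is an MIE when no assignment of one
transmitted allele per parent reproduces the offspring genotype; the
implementation is checked in the tests against an independent exhaustive
gamete enumeration over all 27 non-missing combinations, and is symmetric
in the parents.

Two conventions needed fixing where the source material is silent:

* **Denominator.** The per-trio MIE rate divides by the number of
  *evaluated* trio-site combinations: all three genotypes called and, by
  default, not all three homozygous reference. Triple-reference
  combinations are not calls in an SV panel and would deflate the rate;
  `include_triple_ref = TRUE` restores them.
* **Missing data.** A combination with any missing member is not
  evaluable and never counts as an error.

The per-site *error family ratio* is the fraction of evaluable trios
showing an MIE at the site; it is stored on the panel and serialized into
the VCF (`MIE_FAMILIES`, `MIE_EVAL`). Observed-vs-expected offspring
genotype tables are tabulated per *unordered* parental pair, with
expectations from uniform gamete transmission.

# Feature enrichment by positional randomization

Gene annotations are reduced to four classes — intergenic, intron, exon,
CDS — with introns defined as gene-minus-exon and intergenic as
chromosome-minus-gene, so the bp identities `intron + exon = gene` and
`intergenic = genome − gene` hold exactly. Deletions overlap by interval
(>= 1 bp of a half-open interval), insertions by their breakpoint, and one
SV may carry several flags, so class percentages can sum past 100%.

The null model re-places each SV uniformly at random *on its own
chromosome*, preserving length and type and rejecting placements that
cross the chromosome end or an assembly gap. Stratifying by chromosome
preserves the panel's chromosome composition; gaps are excluded because
reads cannot align there. Both decisions were open — the source describes
only "randomizing the position of the SVs" — and a genome-wide mode
(`stratify_chrom = FALSE`) is provided.

The enrichment score is observed/expected with the expectation a mean over
`n_perm` permutations. The empirical two-sided p-value uses the plus-one
correction, `2 * min(#{perm >= obs} + 1, #{perm <= obs} + 1) / (n_perm + 1)`,
capped at 1: it can never be zero, and at `n_perm = 1000` its floor is
about 0.002, the reporting floor of a 1000-permutation bootstrap. Note the
permutation scores of a *calibrated* null still dip below 0.05 about 5% of
the time; the test suite therefore checks calibration pooled across
feature classes and replicate runs rather than demanding that every
p-value clear 0.05.

# Cross-panel comparison

Two frequency panels are matched with the same clustering used to build
them, on the union of their sites; only sites "detected" (`AF > 0`) enter.
A cluster containing sites from both panels is shared; several same-panel
sites in one cluster collapse to one for counting, keeping the comparison
at the nonredundant-site level. The allele-frequency correlation is the
Pearson correlation of alternative-allele frequencies (not minor-allele
frequencies — the axis choice was open and is documented here) on matched
pairs with focal-panel MAF of at least 0.05. Degenerate inputs (fewer than
3 pairs, zero variance) are reported as undefined rather than computed.

# Long-read QC statistics

* **Mean read quality** is computed in probability space
  (`-10 log10` of the mean per-base error probability), the long-read
  community convention; an arithmetic-mean switch exists. Filtering is
  strict (`> 6`), and surviving reads lose 100 bp at each end.
* **N50** is the smallest read length such that reads at least that long
  contain half the sequenced bases.
* **Alignment error rates** decompose into insertion, deletion and
  mismatch fractions of *aligned read bases* (matches + mismatches +
  inserted bases). The source does not state its denominator; aligned read
  bases is our documented choice. Mismatches come from extended CIGAR
  `X` operations when present, otherwise from the `NM` tag minus indel
  bases; only mapped primary alignments are profiled.

# The synthetic cohort generator

The generator defines the study conditions under which everything is
tested:

| parameter | default | rationale |
|---|---|---|
| sites | biallelic DEL/INS, svlen >= 50 bp | the panel's calling contract |
| size mixture | 0.7 log-uniform 50–10,000 bp; 0.2 N(300, 30); 0.1 N(6000, 300) | broad background plus the Alu (~300 bp) and LINE-1 (~6 kb) transposon peaks of real SV size spectra |
| true AF | Beta(0.3, 1.5) | skewed toward rare alleles, mimicking the decreasing MAF histogram of population panels; the exact shape is a free parameter, not an empirical claim |
| founders | Hardy–Weinberg proportions at true AF | random mating |
| offspring | one uniformly drawn allele per parent | Mendelian transmission |
| genotype error `e` | replacement by a uniformly chosen *different* non-missing genotype, prob. `e` | the simplest model that makes the MIE rate a strictly monotone function of `e`; it is this package's construction, no quantitative error model is published |
| missingness `m` | `./.` with prob. `m`, disjoint from the error event | keeps `e + m <= 1` interpretable |
| site spacing | same-type sites > 1000 bp apart | spacing beyond the merge distance makes the truth panel identifiable by construction; lowering `min_spacing` is the documented stress mode |

What the generator does *not* emulate: linkage disequilibrium, locus- or
coverage-dependent genotyping error, allele dropout, breakpoint
uncertainty (truth positions are exact, so merging recovers sites
perfectly at zero error), reference bias between insertions and deletions,
and de novo SVs (real de novo rates are far below the genotyping error
rates simulated here). Passing tests therefore demonstrate the
correctness of the bookkeeping, the estimators and the randomization
machinery under a clean generative model — not robustness to the
correlated error structure of real long-read call sets.

`couple_size_af = TRUE` is a stress mode that pairs larger SVs with rarer
alleles so that size-by-category diagnostics have a known direction; it is
not a claim about real data.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF positions use the
  padding-base convention (a DEL at POS p deletes 0-based `[p, p+L)`),
  BED is 0-based half-open, GFF3 1-based closed.
* Deletion `SVLEN` may arrive with either sign and is stored positive;
  it is written back negative, the common caller convention.
* Multi-allelic records are reduced to their first alternative allele on
  ingest; genotypes referencing a dropped allele become missing (the MIE
  model is biallelic).
* `AF` is serialized at 6 significant digits but recomputed as `AC/AN` on
  read, so VCF round trips are exact for all typed fields.
* Division-by-zero cases (no evaluable trios, `AN == 0`, empty feature
  classes, < 3 correlation pairs, zero variance) are reported as `NA`
  with a reason, never silently dropped.
* All generators and the permutation stream are pure functions of their
  seed; the pipeline manifest records every derived seed.

# Problem sizes

The shipped analyses and tests use sizes chosen to make every property
sharp while staying desk-scale: demo cohorts of 20 trios x 500 sites on a
2 x 10 Mb toy genome; recovery suites at 100 trios x 2000 sites (three
seeds, four error rates); enrichment calibration pooled over 20 runs of
200 sites at 200 permutations, with 1000 permutations in the analysis
scripts where the 0.002 p-value floor itself is of interest.

# Known limitations

* The merge is a faithful *model* of the published distance/type
  clustering, not a re-implementation of the reference tool's code; site
  counts on pathological inputs (chains of calls each within 1 kb of the
  next) depend on the single-linkage convention documented above.
* Only autosomal, diploid, biallelic DEL/INS sites are supported;
  inversions, duplications, breakends and sex chromosomes are out of
  scope.
* Absent-call genotypes default to homozygous reference rather than
  re-genotyped evidence, which deflates AF estimates for sites with poor
  capture in some samples; use `absent_as_missing = TRUE` to treat
  absence as missingness instead.
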