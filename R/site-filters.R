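# Genotype recalibration and high-quality SNP filtering.
#
# All filters are pure functions of the genotype matrix and are idempotent;
# filter_high_quality() additionally returns an auditable per-rule report.

#' Per-locus allele and genotype frequencies
#'
#' Computes, over non-missing calls at each locus, the reference and
#' alternate allele frequencies (`f_A`, `f_a`, from allele counts with a
#' `2 * n_called` denominator), the observed heterozygote proportion
#' `f_Aa`, the minor allele frequency and the missing-call fraction.
#' Loci with zero non-missing calls are flagged `undefined` rather than
#' dropped, so downstream funnels stay auditable.
#'
#' @param m A [genotype_matrix()].
#' @return `data.frame` with one row per locus: `f_A`, `f_a`, `f_Aa`,
#'   `maf`, `missing_frac`, `n_called`, `undefined`.
#' @export
locus_stats <- function(m) {
  if (n_accessions(m) < 1) stop("matrix has no accessions")
  calls <- m$calls
  n_called <- colSums(!is.na(calls))
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_homalt <- colSums(calls == 2L, na.rm = TRUE)
  f_a <- ifelse(n_called > 0, (2 * n_homalt + n_het) / (2 * n_called), NA)
  f_A <- 1 - f_a
  f_Aa <- ifelse(n_called > 0, n_het / n_called, NA)
  data.frame(
    f_A = f_A, f_a = f_a, f_Aa = f_Aa,
    maf = pmin(f_A, f_a),
    missing_frac = 1 - n_called / nrow(calls),
    n_called = n_called,
    undefined = n_called == 0
  )
}

#' Recalibrate missing genotypes using read depth
#'
#' In a merged multi-sample VCF, an accession that contributed no variant
#' record at a site appears as a missing genotype even when its alignments
#' cover the site well -- in which case the accession most plausibly matches
#' the reference. This recalibration sets a missing call to homozygous
#' reference when the accession's read depth at the locus is at least
#' `min_depth`; missing calls with lower depth stay missing, and no
#' non-missing call is ever altered.
#'
#' @param m A [genotype_matrix()] with a depth matrix.
#' @param min_depth Minimum supporting depth (default 5).
#' @return A `genotype_matrix` with recalibrated calls.
#' @export
recalibrate_missing <- function(m, min_depth = 5L) {
  if (is.null(m$depth))
    stop("no depth matrix present: skip recalibration for this input")
  if (min_depth < 1) stop("min_depth must be >= 1")
  fix <- is.na(m$calls) & !is.na(m$depth) & m$depth >= min_depth
  m$calls[fix] <- 0L
  m
}

#' High-quality SNP filter
#'
#' Removes loci that are non-biallelic, have minor allele frequency below
#' `maf_min`, or missing-data fraction exceeding `missing_max`. Thresholds
#' are boundary-exclusive: a locus at exactly `maf == maf_min` or
#' `missing_frac == missing_max` is retained. Rules are applied in the fixed
#' order non-biallelic, MAF, missingness, and the report attributes each
#' removed locus to the first rule that rejects it; the retained set does
#' not depend on the order.
#'
#' Loci with zero called genotypes have undefined frequencies and are
#' removed under the missingness rule (their missing fraction is 1).
#'
#' @param m A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.02).
#' @param missing_max Maximum fraction of missing calls (default 0.10).
#' @param biallelic_only Remove loci whose ALT field lists several alleles
#'   (default `TRUE`).
#' @return List with elements `matrix` (filtered `genotype_matrix`) and
#'   `report` (a `filter_report`, see [filter_report()]).
#' @export
filter_high_quality <- function(m, maf_min = 0.02, missing_max = 0.10,
                                biallelic_only = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1)
    stop("missing_max must be in [0, 1]")
  st <- locus_stats(m)
  multi <- grepl(",", m$loci$alt, fixed = TRUE)
  fail_bi <- biallelic_only & multi
  # undefined loci (no calls) fall to the missingness rule, not MAF
  fail_maf <- !fail_bi & !st$undefined & st$maf < maf_min
  fail_miss <- !fail_bi & !fail_maf & st$missing_frac > missing_max
  keep <- !(fail_bi | fail_maf | fail_miss)
  rep <- filter_report(n_loci(m),
                       c(non_biallelic = sum(fail_bi),
                         maf = sum(fail_maf),
                         missingness = sum(fail_miss)))
  list(matrix = subset_loci(m, keep), report = rep)
}

#' Per-rule filter report
#'
#' Audit-trail container for filtering funnels: input locus count, removals
#' attributed per rule (in application order) and output count.
#'
#' @param n_input Number of loci entering the filter.
#' @param removed Named integer vector of per-rule removal counts.
#' @return Object of class `filter_report`.
#' @export
filter_report <- function(n_input, removed) {
  n_out <- n_input - sum(removed)
  stopifnot(n_out >= 0)
  structure(list(n_input_loci = as.integer(n_input),
                 n_removed_by_rule = removed,
                 n_output_loci = as.integer(n_out)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input_loci, "loci in ->",
      x$n_output_loci, "out\n")
  for (nm in names(x$n_removed_by_rule))
    cat(sprintf("  - %-14s removed %d\n", nm, x$n_removed_by_rule[[nm]]))
  invisible(x)
}

#' Drop loci on unanchored scaffolds or contigs
#'
#' Retains only loci whose chromosome name belongs to the supplied set of
#' anchored chromosome names.
#'
#' @param m A [genotype_matrix()].
#' @param anchored_names Character vector of anchored chromosome names.
#' @return A filtered `genotype_matrix`.
#' @export
drop_unanchored <- function(m, anchored_names) {
  if (length(anchored_names) == 0)
    stop("anchored_names must be non-empty")
  subset_loci(m, m$loci$chrom %in% anchored_names)
}

#' Drop loci with any missing call
#'
#' Retains only fully-called loci, so that every accession contributes
#' equally to downstream panel-design comparisons.
#'
#' @param m A [genotype_matrix()].
#' @return A filtered `genotype_matrix`.
#' @export
drop_any_missing <- function(m) {
  subset_loci(m, colSums(is.na(m$calls)) == 0L)
}
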