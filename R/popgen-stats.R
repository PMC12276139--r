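# Per-accession heterozygosity, per-locus inbreeding coefficient Fis and
# windowed Tajima's D, summarized per population.
#
# Fis = 1 - f_Aa / (2 f_A f_a) measures departure from Hardy-Weinberg
# genotype proportions: negative values indicate heterozygote excess, the
# hallmark of clonal propagation; Tajima's D contrasts mean pairwise
# diversity (pi) with Watterson's estimator (S / a1): positive D reflects a
# deficit of rare alleles, as expected when lineages are propagated
# vegetatively rather than resampled through meiosis.

#' Per-accession heterozygosity
#'
#' Heterozygosity of each accession as a percentage: 100 x (number of
#' heterozygous calls) / (callable-site denominator). The denominator is
#' caller-supplied (e.g. callable genome positions per accession); when
#' omitted, the total number of loci in the matrix is used for every
#' accession, with a warning, which makes the values comparable within the
#' matrix but not across datasets.
#'
#' @param m A [genotype_matrix()].
#' @param denom_per_accession Optional numeric vector (recycled or named by
#'   accession) of callable-site counts; must be positive.
#' @return `data.frame`: `accession`, `n_het`, `denom`, `het_pct`.
#' @export
individual_heterozygosity <- function(m, denom_per_accession = NULL) {
  n_het <- rowSums(m$calls == 1L, na.rm = TRUE)
  if (is.null(denom_per_accession)) {
    warning("no callable-site denominators supplied; using total locus ",
            "count (", n_loci(m), ") for every accession")
    denom <- rep(n_loci(m), n_accessions(m))
  } else {
    denom <- denom_per_accession
    if (!is.null(names(denom))) denom <- denom[m$accessions]
    denom <- rep_len(as.numeric(denom), n_accessions(m))
  }
  if (any(!is.finite(denom)) || any(denom <= 0))
    stop("denominators must be positive for every accession")
  data.frame(accession = m$accessions,
             n_het = n_het,
             denom = denom,
             het_pct = 100 * n_het / denom,
             row.names = NULL)
}

#' Per-locus inbreeding coefficient
#'
#' `Fis = 1 - f_Aa / (2 * f_A * f_a)` from the observed heterozygote
#' proportion and allele frequencies. Undefined (returned as `NA`) at loci
#' monomorphic among called genotypes (`f_A * f_a == 0`) or with no calls;
#' undefined values are excluded from all summaries, never coerced to 0.
#'
#' @param stats A `data.frame` from [locus_stats()] (columns `f_A`, `f_a`,
#'   `f_Aa`), or equivalent.
#' @return Numeric vector of Fis values (NA where undefined).
#' @export
locus_fis <- function(stats) {
  denom <- 2 * stats$f_A * stats$f_a
  ifelse(is.na(denom) | denom == 0, NA_real_, 1 - stats$f_Aa / denom)
}

#' Fis distributions per population
#'
#' Computes per-locus Fis within each population's accession subset, using
#' only loci polymorphic within that subset, and summarizes each
#' distribution by its mean.
#'
#' @param m A [genotype_matrix()].
#' @param groups Named character vector mapping accession ID to population
#'   label; accessions absent from `groups` are ignored.
#' @param min_group_size Minimum accessions per population (default 2).
#' @return List of class `population_summary_list`: per label, a list with
#'   `fis` (per-locus values at within-group polymorphic loci), `mean_fis`
#'   and `n_accessions`.
#' @export
fis_distribution <- function(m, groups, min_group_size = 2L) {
  groups <- groups[names(groups) %in% m$accessions]
  labs <- unique(unname(groups))
  out <- lapply(labs, function(g) {
    ids <- names(groups)[groups == g]
    if (length(ids) < min_group_size)
      stop("population '", g, "' has fewer than ", min_group_size,
           " accessions")
    sub <- subset_accessions(m, ids)
    st <- locus_stats(sub)
    fis <- locus_fis(st)
    poly <- !is.na(fis)
    list(label = g,
         fis = fis[poly],
         mean_fis = if (any(poly)) mean(fis[poly]) else NA_real_,
         n_accessions = length(ids))
  })
  names(out) <- labs
  class(out) <- "population_summary_list"
  out
}

# Constants of Tajima's (1989) D statistic for n sampled haplotypes.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D per population
#'
#' Tiles each chromosome into non-overlapping windows of `window_bp` and,
#' within each population, computes the number of segregating sites S, the
#' mean pairwise diversity `pi` (from allele frequencies with the
#' n/(n-1) small-sample correction) and Tajima's D. The haplotype sample
#' size per window is fixed to `2 x (minimum called accessions across the
#' window's loci)`, keeping the normalizing constants consistent within a
#' window; loci called in fewer accessions than that minimum do not occur
#' by construction. Windows with `S == 0`, fewer than `min_loci` usable
#' loci, or fewer than 4 haplotypes are flagged undefined (`tajima_d = NA`).
#'
#' @param m A [genotype_matrix()] with loci sorted by coordinate.
#' @param groups Named character vector accession -> population label.
#' @param window_bp Window width in bp (default 10000).
#' @param min_group_size Minimum accessions per population (default 2).
#' @param min_loci Minimum loci for a window to be evaluated (default 1).
#' @return `data.frame` of class `window_stats`: `population`, `chrom`,
#'   `start`, `end` (1-based inclusive), `n_loci`, `n_hap`, `S`, `pi`,
#'   `theta_w`, `tajima_d`.
#' @export
tajimas_d <- function(m, groups, window_bp = 10000L, min_group_size = 2L,
                      min_loci = 1L) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  groups <- groups[names(groups) %in% m$accessions]
  labs <- unique(unname(groups))
  res <- list()
  for (g in labs) {
    ids <- names(groups)[groups == g]
    if (length(ids) < min_group_size)
      stop("population '", g, "' has fewer than ", min_group_size,
           " accessions")
    sub <- subset_accessions(m, ids)
    win_id <- paste(sub$loci$chrom, (sub$loci$pos - 1L) %/% window_bp)
    for (w in unique(win_id)) {
      j <- which(win_id == w)
      chrom <- sub$loci$chrom[j[1]]
      w0 <- (sub$loci$pos[j[1]] - 1L) %/% window_bp
      calls <- sub$calls[, j, drop = FALSE]
      n_called <- colSums(!is.na(calls))
      n_hap <- 2L * min(n_called)
      row <- list(population = g, chrom = chrom,
                  start = w0 * window_bp + 1L,
                  end = (w0 + 1L) * window_bp,
                  n_loci = length(j), n_hap = n_hap,
                  S = NA_integer_, pi = NA_real_, theta_w = NA_real_,
                  tajima_d = NA_real_)
      if (n_hap >= 2L && length(j) >= min_loci) {
        p <- colSums(calls, na.rm = TRUE) / (2 * n_called)
        seg <- p > 0 & p < 1
        S <- sum(seg)
        pi <- sum(2 * p[seg] * (1 - p[seg])) * n_hap / (n_hap - 1)
        cons <- if (n_hap >= 2) tajima_constants(n_hap) else NULL
        theta_w <- S / cons$a1
        row$S <- S; row$pi <- pi; row$theta_w <- theta_w
        if (S > 0 && n_hap >= 4L) {
          v <- cons$e1 * S + cons$e2 * S * (S - 1)
          row$tajima_d <- (pi - theta_w) / sqrt(v)
        }
      }
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(res, as.data.frame))
  out <- out[order(out$population, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Population summaries of Fis and Tajima's D
#'
#' Convenience wrapper combining [fis_distribution()] and [tajimas_d()]
#' into one per-population table of means (undefined values excluded).
#'
#' @inheritParams tajimas_d
#' @param window_bp Window width for Tajima's D.
#' @return `data.frame`: `population`, `n_accessions`, `n_fis_loci`,
#'   `mean_fis`, `n_windows`, `mean_tajima_d`.
#' @export
population_summary <- function(m, groups, window_bp = 10000L) {
  fis <- fis_distribution(m, groups)
  wd <- tajimas_d(m, groups, window_bp = window_bp)
  labs <- names(fis)
  do.call(rbind, lapply(labs, function(g) {
    dsub <- wd$tajima_d[wd$population == g]
    dsub <- dsub[!is.na(dsub)]
    data.frame(population = g,
               n_accessions = fis[[g]]$n_accessions,
               n_fis_loci = length(fis[[g]]$fis),
               mean_fis = fis[[g]]$mean_fis,
               n_windows = length(dsub),
               mean_tajima_d = if (length(dsub)) mean(dsub) else NA_real_)
  }))
}
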