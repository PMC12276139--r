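# Diagnostic SNP panel design.
#
# Panel A distinguishes cultivar groups: after repeat masking and
# genotype-pattern deduplication, loci whose genotype is uniform within a
# group but differs in at least one outside accession are ranked by how
# many outside accessions differ, the top `top_n` per group are merged, and
# the merged list is thinned by distance (<= min_pair_dist_bp pairs removed
# outright, then one SNP per thin_window_bp).
#
# Panel B serves pedigree analysis: only loci homozygous in every accession
# survive, then the same dedup and distance-thinning machinery is applied.

#' Panel design parameters
#'
#' @param flank_bp Repeat-mask flanking width in bp (default 100).
#' @param top_n Number of top-ranked SNPs kept per group (default 50).
#' @param min_pair_dist_bp Pairs of panel SNPs at most this many bp apart
#'   are both removed (default 100).
#' @param thin_window_bp Window width for one-SNP-per-window thinning
#'   (default 100000).
#' @param maf_min Minimum minor allele frequency expected of the input
#'   matrix (default 0.02); checked, not applied.
#' @param rng_seed Seed for the random choices (pattern dedup); recorded in
#'   the panel provenance.
#' @return List of class `panel_params`.
#' @export
panel_params <- function(flank_bp = 100L, top_n = 50L,
                         min_pair_dist_bp = 100L,
                         thin_window_bp = 100000L,
                         maf_min = 0.02, rng_seed = 1L) {
  stopifnot(flank_bp >= 0, top_n >= 1, min_pair_dist_bp >= 1,
            thin_window_bp >= 1, min_pair_dist_bp <= thin_window_bp)
  structure(list(flank_bp = as.integer(flank_bp),
                 top_n = as.integer(top_n),
                 min_pair_dist_bp = as.integer(min_pair_dist_bp),
                 thin_window_bp = as.integer(thin_window_bp),
                 maf_min = maf_min,
                 rng_seed = as.integer(rng_seed)),
            class = "panel_params")
}

#' Remove SNPs inside repeats and their flanking regions
#'
#' Drops loci whose position falls within any repeat interval expanded by
#' `flank_bp` on both sides (position-inclusive at the expanded bounds).
#'
#' @param m A [genotype_matrix()].
#' @param repeats An [interval_set()] of repeat regions (0-based half-open).
#' @param flank_bp Flanking width in bp (default 100).
#' @return A filtered `genotype_matrix`.
#' @export
mask_repeats <- function(m, repeats, flank_bp = 100L) {
  if (nrow(repeats) == 0 || n_loci(m) == 0) return(m)
  expanded <- repeats
  expanded$start <- pmax(0L, repeats$start - as.integer(flank_bp))
  expanded$end <- repeats$end + as.integer(flank_bp)
  hit <- interval_contains(expanded, m$loci$chrom, m$loci$pos)
  subset_loci(m, !hit)
}

#' Deduplicate identical genotype patterns
#'
#' Among loci sharing an identical genotype vector across all accessions,
#' exactly one is retained, chosen uniformly at random under `rng_seed`.
#' The input must be fully called (apply [drop_any_missing()] first).
#'
#' @param m A fully-called [genotype_matrix()].
#' @param rng_seed Seed for the uniform choice.
#' @return A filtered `genotype_matrix`, still coordinate-sorted.
#' @export
dedup_patterns <- function(m, rng_seed = 1L) {
  if (anyNA(m$calls)) stop("dedup_patterns requires a fully-called matrix")
  if (n_loci(m) == 0) return(m)
  key <- apply(m$calls, 2, paste, collapse = "")
  # choices depend only on genomic coordinates, not on column order
  keep <- with_local_seed(rng_seed, {
    vapply(split(seq_len(n_loci(m)), key), function(idx) {
      idx <- idx[order(m$loci$chrom[idx], m$loci$pos[idx])]
      if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
    }, integer(1))
  })
  subset_loci(m, sort(unname(keep)))
}

#' Per-group diagnostic candidate sets
#'
#' A locus is a candidate for group `g` when its genotype is identical
#' across all accessions of `g` and at least one accession outside `g`
#' carries a different genotype. The input must be fully called.
#'
#' @param m A fully-called [genotype_matrix()].
#' @param groups Named character vector accession -> group label; only
#'   accessions named here participate, and every label becomes a group.
#' @return Named list per group: integer vector of candidate locus indices
#'   (columns of `m$calls`), with attribute `shared` giving the group's
#'   shared genotype code at each candidate.
#' @export
group_diagnostic_sets <- function(m, groups) {
  if (anyNA(m$calls))
    stop("group_diagnostic_sets requires a fully-called matrix")
  groups <- groups[names(groups) %in% m$accessions]
  labs <- unique(unname(groups))
  member_rows <- lapply(labs, function(g)
    match(names(groups)[groups == g], m$accessions))
  names(member_rows) <- labs
  other_rows <- lapply(labs, function(g)
    match(names(groups)[groups != g], m$accessions))
  names(other_rows) <- labs

  out <- lapply(labs, function(g) {
    rows <- member_rows[[g]]
    if (length(rows) < 2)
      stop("group '", g, "' has fewer than 2 accessions")
    sub <- m$calls[rows, , drop = FALSE]
    uniform <- colSums(sub != sub[rep(1L, nrow(sub)), , drop = FALSE]) == 0L
    shared <- sub[1L, ]
    oth <- m$calls[other_rows[[g]], , drop = FALSE]
    divergent <- colSums(oth != matrix(shared, nrow = nrow(oth),
                                       ncol = ncol(oth), byrow = TRUE)) > 0L
    idx <- which(uniform & divergent)
    attr(idx, "shared") <- shared[idx]
    idx
  })
  names(out) <- labs
  out
}

#' Rank candidates and keep the top N per group
#'
#' The genotypic-divergence score of a candidate locus for group `g` is the
#' number of accessions outside `g` whose genotype differs from the group's
#' shared genotype. Candidates are sorted by descending score with
#' deterministic (chrom, pos) tie-breaking, and the top `top_n` per group
#' are retained.
#'
#' @param candidates Output of [group_diagnostic_sets()].
#' @param m The fully-called [genotype_matrix()] the candidates refer to.
#' @param groups Named character vector accession -> group label.
#' @param params A [panel_params()].
#' @return `data.frame` of panel entries: `chrom`, `pos`, `ref`, `alt`,
#'   `group`, `score`, `locus_idx`.
#' @export
rank_and_select <- function(candidates, m, groups, params = panel_params()) {
  groups <- groups[names(groups) %in% m$accessions]
  pieces <- lapply(names(candidates), function(g) {
    idx <- candidates[[g]]
    if (length(idx) == 0)
      return(NULL)
    shared <- attr(idx, "shared")
    oth <- m$calls[match(names(groups)[groups != g], m$accessions),
                   idx, drop = FALSE]
    score <- colSums(oth != matrix(shared, nrow = nrow(oth),
                                   ncol = ncol(oth), byrow = TRUE))
    ent <- data.frame(chrom = m$loci$chrom[idx], pos = m$loci$pos[idx],
                      ref = m$loci$ref[idx], alt = m$loci$alt[idx],
                      group = g, score = as.integer(score),
                      locus_idx = as.integer(idx),
                      stringsAsFactors = FALSE)
    ent <- ent[order(-ent$score, ent$chrom, ent$pos), , drop = FALSE]
    utils::head(ent, params$top_n)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      group = character(0), score = integer(0),
                      locus_idx = integer(0))
  rownames(out) <- NULL
  out
}

#' Distance-thin a panel entry list
#'
#' Two passes. Pass 1: on each chromosome, every entry that has another
#' entry within `min_pair_dist_bp` (inclusive) is removed -- both members
#' of a close pair go, matching a removal (not keep-first) rule. Pass 2:
#' each chromosome is tiled into `thin_window_bp` windows anchored at
#' position 1 and only the highest-scored entry per window survives (ties
#' broken toward the smallest position).
#'
#' @param entries `data.frame` of panel entries (needs `chrom`, `pos`,
#'   `score`; see [rank_and_select()]).
#' @param params A [panel_params()].
#' @return Filtered entry `data.frame`, coordinate-sorted.
#' @export
distance_thin <- function(entries, params = panel_params()) {
  if (nrow(entries) == 0) return(entries)
  entries <- entries[order(entries$chrom, entries$pos), , drop = FALSE]
  # pass 1: drop both members of any pair <= min_pair_dist_bp apart
  close_pair <- logical(nrow(entries))
  for (ch in unique(entries$chrom)) {
    i <- which(entries$chrom == ch)
    if (length(i) < 2) next
    d <- diff(entries$pos[i])
    hit <- d <= params$min_pair_dist_bp
    close_pair[i[c(hit, FALSE)]] <- close_pair[i[c(hit, FALSE)]] | TRUE
    close_pair[i[c(FALSE, hit)]] <- close_pair[i[c(FALSE, hit)]] | TRUE
  }
  entries <- entries[!close_pair, , drop = FALSE]
  if (nrow(entries) == 0) return(entries)
  # pass 2: one entry per thin window, highest score, then smallest pos
  win <- paste(entries$chrom, (entries$pos - 1L) %/% params$thin_window_bp)
  keep <- vapply(split(seq_len(nrow(entries)), win), function(idx) {
    idx[order(-entries$score[idx], entries$pos[idx])][1]
  }, integer(1))
  out <- entries[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design the cultivar-diagnostic SNP panel (Panel A)
#'
#' Full workflow: repeat masking with flanks, genotype-pattern dedup,
#' per-group diagnostic candidate discovery, divergence ranking with top-N
#' selection, merge across groups, then distance thinning of the merged
#' list. The input matrix is expected to be pre-filtered (anchored
#' chromosomes, no missing calls, MAF at least `params$maf_min`).
#'
#' @param m A fully-called [genotype_matrix()].
#' @param groups Named character vector accession -> cultivar group.
#' @param repeats An [interval_set()] of repeat regions (possibly empty).
#' @param params A [panel_params()].
#' @return Object of class `snp_panel`: list with `entries` (`data.frame`
#'   as from [rank_and_select()]), `mode = "A"`, `funnel` (named step
#'   counts), `params`.
#' @export
design_panel_a <- function(m, groups, repeats = interval_set(),
                           params = panel_params()) {
  if (anyNA(m$calls))
    stop("design_panel_a requires a fully-called matrix; ",
         "apply drop_any_missing() first")
  funnel <- c(input = n_loci(m))
  m1 <- mask_repeats(m, repeats, params$flank_bp)
  funnel["after_repeat_mask"] <- n_loci(m1)
  m2 <- dedup_patterns(m1, params$rng_seed)
  funnel["after_pattern_dedup"] <- n_loci(m2)
  cand <- group_diagnostic_sets(m2, groups)
  funnel["candidates_all_groups"] <- length(unique(unlist(cand)))
  ranked <- rank_and_select(cand, m2, groups, params)
  funnel["after_top_n_merge"] <- nrow(ranked)
  # a locus can qualify for several groups (uniform in each, divergent
  # outside); keep its best-scoring attribution so the merged panel holds
  # each SNP once
  ranked <- ranked[order(-ranked$score, ranked$chrom, ranked$pos), ,
                   drop = FALSE]
  ranked <- ranked[!duplicated(ranked[c("chrom", "pos")]), , drop = FALSE]
  funnel["after_attribution_dedup"] <- nrow(ranked)
  thinned <- distance_thin(ranked, params)
  funnel["after_distance_thin"] <- nrow(thinned)
  for (g in unique(unname(groups)))
    if (!any(thinned$group == g))
      warning("group '", g, "' ends with 0 panel SNPs")
  # re-index entries against the input matrix
  thinned$locus_idx <- match(paste(thinned$chrom, thinned$pos),
                             paste(m$loci$chrom, m$loci$pos))
  structure(list(entries = thinned, mode = "A", funnel = funnel,
                 params = params),
            class = "snp_panel")
}

#' Design the homozygous pedigree SNP panel (Panel B)
#'
#' Drops every locus carrying at least one heterozygous or missing call,
#' deduplicates identical genotype patterns, and distance-thins, yielding a
#' panel of fully homozygous SNPs suited to pedigree analysis. The input is
#' expected to be MAF-prefiltered.
#'
#' @param m A [genotype_matrix()].
#' @param params A [panel_params()].
#' @return Object of class `snp_panel` with `mode = "B"`; entries carry
#'   `group = NA` and `score = 0`.
#' @export
design_panel_b <- function(m, params = panel_params()) {
  funnel <- c(input = n_loci(m))
  hom <- colSums(m$calls == 1L, na.rm = TRUE) == 0L &
    colSums(is.na(m$calls)) == 0L
  m1 <- subset_loci(m, hom)
  funnel["after_homozygous_filter"] <- n_loci(m1)
  m2 <- dedup_patterns(m1, params$rng_seed)
  funnel["after_pattern_dedup"] <- n_loci(m2)
  entries <- data.frame(chrom = m2$loci$chrom, pos = m2$loci$pos,
                        ref = m2$loci$ref, alt = m2$loci$alt,
                        group = rep(NA_character_, n_loci(m2)),
                        score = rep(0L, n_loci(m2)),
                        locus_idx = seq_len(n_loci(m2)),
                        stringsAsFactors = FALSE)
  thinned <- distance_thin(entries, params)
  funnel["after_distance_thin"] <- nrow(thinned)
  thinned$locus_idx <- match(paste(thinned$chrom, thinned$pos),
                             paste(m$loci$chrom, m$loci$pos))
  structure(list(entries = thinned, mode = "B", funnel = funnel,
                 params = params),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel %s: %d SNPs\n", x$mode, nrow(x$entries)))
  if (x$mode == "A" && nrow(x$entries))
    print(table(x$entries$group))
  cat("funnel:\n")
  for (nm in names(x$funnel))
    cat(sprintf("  %-24s %d\n", nm, x$funnel[[nm]]))
  invisible(x)
}

#' Validate a designed panel against its constraints
#'
#' Checks that (i) no two panel SNPs on one chromosome are within
#' `min_pair_dist_bp` of each other, (ii) no thinning window holds more
#' than one SNP, (iii) no two panel SNPs share an identical genotype
#' vector, and (iv) for Panel B, that every call at panel loci is
#' homozygous and non-missing.
#'
#' @param panel An `snp_panel`.
#' @param m The [genotype_matrix()] the panel was designed from.
#' @param params A [panel_params()]; defaults to the panel's own.
#' @return Named logical vector of check results (`TRUE` = pass), with
#'   class `panel_validation`.
#' @export
validate_panel <- function(panel, m, params = panel$params) {
  e <- panel$entries
  checks <- c(pair_distance = TRUE, one_per_window = TRUE,
              unique_patterns = TRUE, homozygous = TRUE)
  if (nrow(e) >= 2) {
    for (ch in unique(e$chrom)) {
      p <- sort(e$pos[e$chrom == ch])
      if (length(p) >= 2 && any(diff(p) <= params$min_pair_dist_bp))
        checks["pair_distance"] <- FALSE
      win <- (p - 1L) %/% params$thin_window_bp
      if (anyDuplicated(win)) checks["one_per_window"] <- FALSE
    }
  }
  idx <- e$locus_idx
  if (anyNA(idx))
    stop("panel entries do not match the supplied matrix")
  if (length(idx) >= 2) {
    pat <- apply(m$calls[, idx, drop = FALSE], 2, paste, collapse = ",")
    if (anyDuplicated(pat)) checks["unique_patterns"] <- FALSE
  }
  if (identical(panel$mode, "B") && length(idx)) {
    sub <- m$calls[, idx, drop = FALSE]
    if (anyNA(sub) || any(sub == 1L)) checks["homozygous"] <- FALSE
  }
  class(checks) <- c("panel_validation", class(checks))
  checks
}
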