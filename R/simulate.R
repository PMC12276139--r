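# Forward-in-time simulator of partially clonal germplasm cohorts.
#
# Populations are simulated forward for T generations: each offspring is,
# with probability c (the clonality rate), a verbatim copy of one random
# parent, and otherwise the union of gametes from two distinct random
# parents; every offspring is then hit by heterozygosity-gain mutations
# (HOM -> HET at rate mu per locus per generation). Mutation input is thus
# identical across clonality rates -- only the fate of the mutations
# differs: under sexual reproduction segregation resolves heterozygotes,
# while clonal copying protects them. Long-term clonality accumulates shared
# heterozygous sites (Meselson-type divergence between the two alleles of a
# lineage) and erodes rare alleles -- the negative-Fis / positive-Tajima's-D
# signature the analysis functions are designed to detect. Group-diagnostic
# loci, repeat intervals, missing calls with read depths and truth-derived
# ancestry (Q) tables are layered on so every pipeline stage has realistic
# work and a known answer.

#' Simulation configuration
#'
#' Defaults emulate a pineapple germplasm cohort: four cultivar groups
#' ('Smooth Cayenne', 'Queen', 'Singapore Spanish', 'Mordilona-related'),
#' two wild varieties (bracteatus, microstachys), and F1 hybrids between
#' 'Smooth Cayenne' and 'Mordilona-related'. The 'Queen', 'Singapore
#' Spanish', 'Smooth Cayenne' and microstachys groups are clonal
#' (`clonality = 1`), the remainder sexual, mirroring the reproductive
#' histories the statistics are meant to tell apart. Ancestral allele
#' frequencies follow a neutral-like site-frequency law (density
#' proportional to 1/p, truncated below at `freq_law$lo`), under which a
#' random-mating population shows Tajima's D near 0.
#'
#' @param pops `data.frame` with columns `name`, `n` (diploid accessions),
#'   `clonality` (c in `[0,1]`), `cultivar` (logical: participates in
#'   diagnostic-locus planting and panel design).
#' @param n_loci Total background loci (default 5000).
#' @param chromosomes Named integer vector of chromosome lengths in bp;
#'   names not listed in `anchored` count as unanchored scaffolds.
#' @param anchored Character vector of anchored chromosome names.
#' @param unanchored_frac Fraction of background loci placed on unanchored
#'   scaffolds (default 0.04).
#' @param freq_law Ancestral allele-frequency law:
#'   `list(kind = "sfs", lo = 0.001)`, `list(kind = "uniform", lo, hi)` or
#'   `list(kind = "beta", a, b)`.
#' @param fst Balding-Nichols differentiation of per-population founder
#'   frequencies around the ancestral frequency (0 = none; default 0.1).
#' @param generations Forward generations T (default 200).
#' @param het_gain_rate Per-locus, per-generation HOM -> HET mutation rate
#'   applied to every offspring (default 1e-3).
#' @param n_diagnostic_per_group Planted diagnostic loci per cultivar group
#'   (default 10), spaced more than `diag_spacing_bp` apart genome-wide.
#' @param diag_spacing_bp Minimum spacing of planted diagnostics
#'   (default 110000, i.e. wider than the 100 kb thinning window).
#' @param n_hybrids Number of planted F1 hybrids (default 5).
#' @param hybrid_parents Character vector of two population names.
#' @param missing_rate Fraction of calls set missing (default 0.03).
#' @param depth_mean,depth_size Negative-binomial read-depth law
#'   (mean / dispersion; defaults 12 and 3).
#' @param low_depth_missing_frac Of the missing calls, the fraction whose
#'   depth is overwritten with a low value (< 3), so that depth-assisted
#'   recalibration can rescue only the remainder (default 0.7).
#' @param n_repeats,repeat_len_bp Repeat intervals per anchored chromosome
#'   and their length (defaults 8 and 2000).
#' @param Ks Ancestry table resolutions to emit (default `c(5, 6, 7)`).
#' @param q_purity Own-component proportion of a definitive accession's
#'   truth-derived Q row (default 0.95).
#' @param rng_seed Master seed; the full output is a pure function of the
#'   configuration.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(
    pops = data.frame(
      name = c("SmoothCayenne", "Queen", "SingaporeSpanish",
               "Mordilona", "bracteatus", "microstachys"),
      n = c(15L, 20L, 12L, 16L, 6L, 9L),
      clonality = c(1, 1, 1, 0, 0, 1),
      cultivar = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    n_loci = 5000L,
    chromosomes = c(LG01 = 6e6, LG02 = 6e6, LG03 = 6e6, LG04 = 6e6,
                    LG05 = 6e6, scaffold_1 = 5e5),
    anchored = c("LG01", "LG02", "LG03", "LG04", "LG05"),
    unanchored_frac = 0.04,
    freq_law = list(kind = "sfs", lo = 0.001),
    fst = 0.1,
    generations = 200L,
    het_gain_rate = 1e-3,
    n_diagnostic_per_group = 10L,
    diag_spacing_bp = 110000L,
    n_hybrids = 5L,
    hybrid_parents = c("SmoothCayenne", "Mordilona"),
    missing_rate = 0.03,
    depth_mean = 12, depth_size = 3,
    low_depth_missing_frac = 0.7,
    n_repeats = 8L, repeat_len_bp = 2000L,
    Ks = c(5L, 6L, 7L),
    q_purity = 0.95,
    rng_seed = 1L) {
  stopifnot(is.data.frame(pops),
            all(c("name", "n", "clonality", "cultivar") %in% names(pops)),
            all(pops$n >= 2), all(pops$clonality >= 0 & pops$clonality <= 1),
            n_loci >= 1, length(chromosomes) >= 1,
            all(anchored %in% names(chromosomes)),
            missing_rate >= 0, missing_rate < 1,
            generations >= 0, het_gain_rate >= 0, het_gain_rate <= 1,
            n_hybrids >= 0, q_purity > 0.5, q_purity <= 1)
  if (n_hybrids > 0 && !all(hybrid_parents %in% pops$name))
    stop("hybrid_parents must name two simulated populations")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

draw_ancestral_freqs <- function(L, law) {
  switch(law$kind,
    sfs = {
      lo <- if (is.null(law$lo)) 0.001 else law$lo
      lo^(1 - stats::runif(L))
    },
    uniform = stats::runif(L, law$lo, law$hi),
    beta = stats::rbeta(L, law$a, law$b),
    stop("unknown freq_law kind: ", law$kind))
}

# one gamete per individual from a diploid dosage matrix
draw_gametes <- function(g) {
  het <- g == 1L
  out <- (g == 2L) * 1L
  if (any(het))
    out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

# forward-simulate one population; returns n x L dosage matrix
simulate_pop <- function(n, freqs, clonality, generations, het_gain_rate) {
  L <- length(freqs)
  G <- matrix(stats::rbinom(n * L, 2L, rep(freqs, each = n)), nrow = n)
  if (generations == 0) return(G)
  for (t in seq_len(generations)) {
    is_clone <- stats::runif(n) < clonality
    p1 <- sample.int(n, n, replace = TRUE)
    G_new <- G[p1, , drop = FALSE]
    if (any(!is_clone)) {
      rows <- which(!is_clone)
      p2 <- sample.int(n, length(rows), replace = TRUE)
      # distinct parents (self-incompatibility)
      clash <- p2 == p1[rows]
      while (any(clash) && n > 1) {
        p2[clash] <- sample.int(n, sum(clash), replace = TRUE)
        clash <- p2 == p1[rows]
      }
      G_new[rows, ] <- draw_gametes(G[p1[rows], , drop = FALSE]) +
        draw_gametes(G[p2, , drop = FALSE])
    }
    if (het_gain_rate > 0) {
      hom <- G_new != 1L
      mut <- hom & matrix(stats::runif(length(G_new)) < het_gain_rate,
                          nrow = n)
      G_new[mut] <- 1L
    }
    G <- G_new
  }
  G
}

#' Simulate one admixed genotype vector
#'
#' Each of the two allele draws at a locus first selects a source
#' population according to the ancestry proportions `q_row`, then draws the
#' allele as Bernoulli(population alternate-allele frequency).
#'
#' @param q_row Numeric ancestry proportions over populations; must sum
#'   to 1.
#' @param pop_freqs Populations x loci matrix of alternate-allele
#'   frequencies.
#' @return Integer dosage vector of length `ncol(pop_freqs)`.
#' @export
simulate_admixed <- function(q_row, pop_freqs) {
  if (abs(sum(q_row) - 1) > 1e-8) stop("q_row must sum to 1")
  L <- ncol(pop_freqs)
  g <- integer(L)
  for (draw in 1:2) {
    src <- sample.int(length(q_row), L, replace = TRUE, prob = q_row)
    g <- g + stats::rbinom(L, 1L, pop_freqs[cbind(src, seq_len(L))])
  }
  g
}

# truth-derived Q tables: one component per group; when K is smaller than
# the number of groups, trailing (non-cultivar) groups share the last
# component, as structure inference at low K would merge them.
emit_q_tables <- function(cfg, group_of, hybrid_rows) {
  n_groups <- nrow(cfg$pops)
  acc <- names(group_of)
  out <- list()
  for (K in cfg$Ks) {
    comp_of <- pmin(seq_len(n_groups), K)
    names(comp_of) <- cfg$pops$name
    Q <- matrix((1 - cfg$q_purity) / (K - 1), nrow = length(acc), ncol = K)
    for (i in seq_along(acc)) {
      g <- group_of[[i]]
      if (g == "HYBRID") {
        pa <- comp_of[[cfg$hybrid_parents[1]]]
        pb <- comp_of[[cfg$hybrid_parents[2]]]
        Q[i, ] <- 0.02 / (K - 2)
        Q[i, pa] <- 0.49
        Q[i, pb] <- 0.49
      } else {
        Q[i, comp_of[[g]]] <- cfg$q_purity
      }
    }
    Q <- Q / rowSums(Q)
    out[[as.character(K)]] <- ancestry_table(Q, acc)
  }
  out
}

#' Simulate a germplasm cohort
#'
#' Runs the forward simulator for every configured population, plants
#' group-diagnostic loci for the cultivar groups, appends F1 hybrids,
#' applies missingness with correlated read depths, draws repeat intervals
#' and emits truth-derived ancestry tables. The result is fully determined
#' by the configuration (including its `rng_seed`).
#'
#' Planted diagnostic loci are homozygous-alternate in every member of
#' their group and homozygous-reference outside it, except that one
#' (rotating) outside accession is set heterozygous per locus so that the
#' loci of one group do not share a single genotype pattern (which the
#' panel workflow's pattern-deduplication step would otherwise collapse to
#' one representative).
#'
#' @param cfg A [sim_config()].
#' @return List with elements `matrix` (a [genotype_matrix()] with depth),
#'   `truth` (list: `groups` named accession -> group vector with hybrids
#'   labelled `"HYBRID"`, `diagnostics` data.frame of planted loci,
#'   `clonality` named per-population rates, `Q` the true ancestry rows),
#'   `repeats` (an [interval_set()]), and `qtables` (named list of
#'   [ancestry_table()] per K).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$rng_seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  chroms <- cfg$chromosomes
  anchored <- cfg$anchored
  unanch <- setdiff(names(chroms), anchored)
  n_groups <- nrow(cfg$pops)
  cultivars <- cfg$pops$name[cfg$pops$cultivar]
  n_diag <- cfg$n_diagnostic_per_group * length(cultivars)

  # -- locus coordinates ---------------------------------------------------
  # diagnostic slots: a genome-wide grid with > diag_spacing_bp spacing
  grid <- do.call(rbind, lapply(anchored, function(ch) {
    pos <- seq(150000L, chroms[[ch]] - 150000L, by = cfg$diag_spacing_bp)
    data.frame(chrom = ch, pos = as.integer(pos))
  }))
  if (n_diag > nrow(grid))
    stop("chromosome layout too small for ", n_diag, " diagnostic loci")
  diag_slots <- grid[sort(sample.int(nrow(grid), n_diag)), , drop = FALSE]

  n_bg_unanch <- if (length(unanch))
    round(cfg$n_loci * cfg$unanchored_frac) else 0L
  n_bg_anch <- cfg$n_loci - n_bg_unanch
  bg_chrom_a <- sample(anchored, n_bg_anch, replace = TRUE,
                       prob = chroms[anchored])
  bg_pos_a <- vapply(bg_chrom_a, function(ch)
    sample.int(chroms[[ch]], 1L), integer(1))
  bg_chrom_u <- if (n_bg_unanch)
    sample(unanch, n_bg_unanch, replace = TRUE, prob = chroms[unanch])
    else character(0)
  bg_pos_u <- vapply(bg_chrom_u, function(ch)
    sample.int(chroms[[ch]], 1L), integer(1))

  loci <- data.frame(
    chrom = c(diag_slots$chrom, bg_chrom_a, bg_chrom_u),
    pos = as.integer(c(diag_slots$pos, bg_pos_a, bg_pos_u)),
    stringsAsFactors = FALSE)
  is_diag <- c(rep(TRUE, n_diag), rep(FALSE, cfg$n_loci))
  dup <- duplicated(loci[c("chrom", "pos")])
  loci <- loci[!dup, , drop = FALSE]
  is_diag <- is_diag[!dup]
  L <- nrow(loci)
  refalt <- matrix(c("A", "G", "C", "T")[
    cbind(sample.int(4, L, replace = TRUE),
          sample.int(4, L, replace = TRUE))], ncol = 2)
  flip <- refalt[, 1] == refalt[, 2]
  refalt[flip, 2] <- c(A = "G", G = "A", C = "T", T = "C")[refalt[flip, 1]]
  loci$ref <- refalt[, 1]
  loci$alt <- refalt[, 2]

  # -- per-population genotypes -------------------------------------------
  base_p <- draw_ancestral_freqs(L, cfg$freq_law)
  pop_freqs <- matrix(NA_real_, nrow = n_groups, ncol = L,
                      dimnames = list(cfg$pops$name, NULL))
  for (i in seq_len(n_groups)) {
    pop_freqs[i, ] <- if (cfg$fst > 0) {
      f <- cfg$fst
      stats::rbeta(L, base_p * (1 - f) / f, (1 - base_p) * (1 - f) / f)
    } else base_p
  }
  pop_freqs[is.na(pop_freqs)] <- 0

  calls <- NULL
  acc <- character(0)
  group_of <- character(0)
  for (i in seq_len(n_groups)) {
    g <- simulate_pop(cfg$pops$n[i], pop_freqs[i, ],
                      cfg$pops$clonality[i], cfg$generations,
                      cfg$het_gain_rate)
    calls <- rbind(calls, g)
    ids <- sprintf("%s_%02d", cfg$pops$name[i], seq_len(cfg$pops$n[i]))
    acc <- c(acc, ids)
    group_of <- c(group_of, stats::setNames(rep(cfg$pops$name[i],
                                                cfg$pops$n[i]), ids))
  }
  if (cfg$n_hybrids > 0) {
    pa <- match(cfg$hybrid_parents[1], cfg$pops$name)
    pb <- match(cfg$hybrid_parents[2], cfg$pops$name)
    for (h in seq_len(cfg$n_hybrids)) {
      q <- numeric(n_groups); q[pa] <- 0.5; q[pb] <- 0.5
      calls <- rbind(calls, simulate_admixed(q, pop_freqs))
      id <- sprintf("Hybrid_%02d", h)
      acc <- c(acc, id)
      group_of <- c(group_of, stats::setNames("HYBRID", id))
    }
  }
  storage.mode(calls) <- "integer"

  # -- plant diagnostic loci ----------------------------------------------
  diag_tab <- NULL
  if (n_diag > 0) {
    diag_idx <- which(is_diag)
    assign_grp <- rep(cultivars, each = cfg$n_diagnostic_per_group)
    for (d in seq_along(diag_idx)) {
      j <- diag_idx[d]
      g <- assign_grp[d]
      inside <- group_of == g
      calls[, j] <- 0L
      calls[inside, j] <- 2L
      outs <- which(!inside)
      calls[outs[((d - 1L) %% length(outs)) + 1L], j] <- 1L
    }
    diag_tab <- data.frame(chrom = loci$chrom[diag_idx],
                           pos = loci$pos[diag_idx],
                           group = assign_grp, stringsAsFactors = FALSE)
  }

  # -- depth and missingness ----------------------------------------------
  n_acc <- length(acc)
  depth <- matrix(stats::rnbinom(n_acc * L, mu = cfg$depth_mean,
                                 size = cfg$depth_size),
                  nrow = n_acc)
  storage.mode(depth) <- "integer"
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n_acc * L) < cfg$missing_rate,
                   nrow = n_acc)
    lowdp <- miss & matrix(stats::runif(n_acc * L) <
                             cfg$low_depth_missing_frac, nrow = n_acc)
    depth[lowdp] <- sample(0:2, sum(lowdp), replace = TRUE)
    calls[miss] <- NA_integer_
  }

  gm <- genotype_matrix(calls = calls, loci = loci, accessions = acc,
                        depth = depth)

  # -- repeat intervals, avoiding planted diagnostics ---------------------
  reps <- NULL
  for (ch in anchored) {
    starts <- sample.int(chroms[[ch]] - cfg$repeat_len_bp,
                         cfg$n_repeats)
    if (!is.null(diag_tab)) {
      dpos <- diag_tab$pos[diag_tab$chrom == ch]
      ok <- vapply(starts, function(s) {
        !any(dpos > s - 1000L - 100L &
               dpos <= s + cfg$repeat_len_bp + 1000L)
      }, logical(1))
      starts <- starts[ok]
    }
    if (length(starts))
      reps <- rbind(reps, data.frame(chrom = ch, start = starts,
                                     end = starts + cfg$repeat_len_bp))
  }
  repeats <- if (is.null(reps)) interval_set()
             else interval_set(reps$chrom, reps$start, reps$end)

  qtables <- emit_q_tables(cfg, group_of, NULL)

  list(matrix = gm,
       truth = list(groups = group_of,
                    diagnostics = diag_tab,
                    clonality = stats::setNames(cfg$pops$clonality,
                                                cfg$pops$name),
                    Q = qtables),
       repeats = repeats,
       qtables = qtables)
}
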