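# Fixture builders and independent oracles shared across test files.
# Everything is generated in code under fixed seeds; no files are shipped.

# random genotype matrix with unique sorted coordinates
random_gm <- function(n_acc, n_loci, seed, missing_rate = 0.1,
                      with_depth = TRUE, chroms = c("LG01", "LG02"),
                      chrom_len = 1e6L) {
  withr::with_seed(seed, {
    chrom <- sample(chroms, n_loci, replace = TRUE)
    pos <- integer(n_loci)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      pos[sel] <- sample.int(chrom_len, sum(sel))
    }
    calls <- matrix(sample(0:2, n_acc * n_loci, replace = TRUE),
                    nrow = n_acc)
    if (missing_rate > 0)
      calls[runif(n_acc * n_loci) < missing_rate] <- NA_integer_
    depth <- if (with_depth)
      matrix(rnbinom(n_acc * n_loci, mu = 10, size = 3), nrow = n_acc)
    else NULL
    genotype_matrix(
      calls = calls,
      loci = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G"),
      accessions = sprintf("acc%03d", seq_len(n_acc)),
      depth = depth)
  })
}

# tiny single-population simulation config used by the statistics tests
single_pop_cfg <- function(seed, n = 30L, clonality = 0, mu = 0,
                           generations = 0L, n_loci = 2000L,
                           freq_law = list(kind = "sfs", lo = 0.001)) {
  sim_config(
    pops = data.frame(name = "P1", n = as.integer(n),
                      clonality = clonality, cultivar = FALSE),
    n_loci = as.integer(n_loci), chromosomes = c(LG01 = 2e7),
    anchored = "LG01", unanchored_frac = 0, freq_law = freq_law,
    fst = 0, generations = as.integer(generations), het_gain_rate = mu,
    n_diagnostic_per_group = 0L, n_hybrids = 0L, missing_rate = 0,
    n_repeats = 0L, Ks = 5L, rng_seed = seed)
}

# 4-cultivar-group cohort with planted diagnostics, fully called,
# mid-range background frequencies (no incidental group-fixed loci)
four_group_cfg <- function(seed, n_per_group = 17L, n_loci = 5000L) {
  sim_config(
    pops = data.frame(
      name = c("SmoothCayenne", "Queen", "SingaporeSpanish", "Mordilona"),
      n = n_per_group, clonality = 0, cultivar = TRUE),
    n_loci = as.integer(n_loci),
    chromosomes = c(LG01 = 6e6, LG02 = 6e6, LG03 = 6e6, LG04 = 6e6,
                    LG05 = 6e6),
    anchored = paste0("LG0", 1:5), unanchored_frac = 0,
    freq_law = list(kind = "uniform", lo = 0.35, hi = 0.65),
    fst = 0, generations = 0L, het_gain_rate = 0,
    n_diagnostic_per_group = 10L, n_hybrids = 0L,
    missing_rate = 0, n_repeats = 8L, Ks = 5L, rng_seed = seed)
}

# mean per-seed Fis and Tajima's D of a single simulated population
pop_fis_d <- function(cfg, window_bp = 10000L) {
  sim <- simulate_cohort(cfg)
  g <- sim$truth$groups
  fis <- fis_distribution(sim$matrix, g)[[1]]$mean_fis
  wd <- tajimas_d(sim$matrix, g, window_bp = window_bp)
  c(fis = fis, d = mean(wd$tajima_d, na.rm = TRUE))
}

# brute-force pairwise-difference pi over expanded haplotypes
pi_bruteforce <- function(calls) {
  n_hap <- 2L * nrow(calls)
  hap <- matrix(0L, nrow = n_hap, ncol = ncol(calls))
  for (i in seq_len(nrow(calls))) {
    g <- calls[i, ]
    a1 <- as.integer(g >= 1)  # unphased: allocation does not matter
    a2 <- as.integer(g == 2)
    a1[g == 1L] <- 1L
    a2[g == 1L] <- 0L
    hap[2 * i - 1, ] <- a1
    hap[2 * i, ] <- a2
  }
  tot <- 0
  for (i in seq_len(n_hap - 1))
    for (j in (i + 1):n_hap)
      tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / choose(n_hap, 2)
}

# orthogonal-Procrustes RMSD between two configurations (rows = points)
procrustes_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$v %*% t(s$u)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# write a VCF body from raw text lines (for parser edge cases)
write_vcf_text <- function(lines, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}
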