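test_that("individual heterozygosity is a simple calibrated percentage", {
  calls <- rbind(c(rep(1L, 3), rep(0L, 7)),   # 3 HET
                 rep(0L, 10))                  # 0 HET
  m <- genotype_matrix(calls,
                       data.frame(chrom = "LG01", pos = 1:10 * 50L,
                                  ref = "A", alt = "G"),
                       c("a1", "a2"))
  h <- individual_heterozygosity(m, c(300, 300))
  expect_equal(h$het_pct, c(1.0, 0))
  expect_error(individual_heterozygosity(m, c(0, 300)), "positive")
  expect_warning(individual_heterozygosity(m), "denominators")
})

test_that("Fis formula hits the closed-form anchor points", {
  st <- data.frame(f_A = 0.5, f_a = 0.5, f_Aa = 0.5)
  expect_equal(locus_fis(st), 0)                      # exact HWE
  expect_equal(locus_fis(transform(st, f_Aa = 1)), -1)  # all het
  expect_equal(locus_fis(data.frame(f_A = 0.7, f_a = 0.3, f_Aa = 0)), 1)
  # monomorphic -> undefined
  expect_true(is.na(locus_fis(data.frame(f_A = 1, f_a = 0, f_Aa = 0))))
})

test_that("Fis is bounded above by 1 and decreases with heterozygosity", {
  withr::with_seed(31, {
    for (k in 1:50) {
      fa <- runif(1, 0.05, 0.95)
      faa <- runif(1, 0, min(1, 2 * min(fa, 1 - fa)))
      v <- locus_fis(data.frame(f_A = 1 - fa, f_a = fa, f_Aa = faa))
      expect_lte(v, 1)
    }
  })
  # strict monotonicity at fixed allele frequency
  grid <- seq(0, 0.5, by = 0.05)
  vals <- locus_fis(data.frame(f_A = 0.5, f_a = 0.5, f_Aa = grid))
  expect_true(all(diff(vals) < 0))
})

test_that("clonal groups show heterozygote excess in fis_distribution", {
  # identical columns incl. shared HETs across clones
  col <- c(1L, 1L, 1L, 1L)
  calls <- cbind(col, col, c(0L, 0L, 0L, 0L), c(2L, 1L, 2L, 1L))
  m <- genotype_matrix(calls,
                       data.frame(chrom = "LG01", pos = 1:4 * 100L,
                                  ref = "A", alt = "G"),
                       paste0("c", 1:4))
  g <- stats::setNames(rep("clone", 4), m$accessions)
  fd <- fis_distribution(m, g)
  expect_lt(fd$clone$mean_fis, 0)
  expect_true(all(fd$clone$fis < 0))
  expect_error(fis_distribution(m, g[1]), "fewer than")
})

test_that("a Hardy-Weinberg population has mean Fis near -1/(2n-1)", {
  sim <- simulate_cohort(single_pop_cfg(5, n = 30L))
  fd <- fis_distribution(sim$matrix, sim$truth$groups)
  expect_lt(abs(fd$P1$mean_fis), 0.02)
})

test_that("windowed Tajima's D matches the hand-computed 4-haplotype case", {
  # 2 diploids, one segregating site at p = 0.5:
  # pi = 2*0.5*0.5*4/3 = 2/3, theta_w = 6/11, D = (2/3 - 6/11)/sqrt(e1)
  m <- genotype_matrix(rbind(2L, 0L),
                       data.frame(chrom = "LG01", pos = 500L,
                                  ref = "A", alt = "G"),
                       c("a1", "a2"))
  g <- stats::setNames(rep("P", 2), m$accessions)
  wd <- tajimas_d(m, g, window_bp = 1000L)
  expect_equal(wd$n_hap, 4L)
  expect_equal(wd$S, 1L)
  expect_equal(wd$pi, 2 / 3)
  expect_equal(wd$theta_w, 6 / 11)
  a1 <- 1 + 1 / 2 + 1 / 3
  b1 <- 5 / (3 * 3)
  c1 <- b1 - 1 / a1
  e1 <- c1 / a1
  expect_equal(wd$tajima_d, (2 / 3 - 6 / 11) / sqrt(e1))
  expect_gt(wd$tajima_d, 0)
})

test_that("windows without segregating sites are flagged undefined", {
  m <- genotype_matrix(rbind(c(0L, 2L), c(0L, 2L)),
                       data.frame(chrom = "LG01", pos = c(10L, 20L),
                                  ref = "A", alt = "G"),
                       c("a1", "a2"))
  g <- stats::setNames(rep("P", 2), m$accessions)
  wd <- tajimas_d(m, g, window_bp = 1000L)
  expect_equal(wd$S, 0L)  # monomorphic within group at both loci
  expect_true(is.na(wd$tajima_d))
})

test_that("windowed pi equals brute-force pairwise differences", {
  for (s in 1:10) {
    n <- sample(2:5, 1)  # <= 10 haplotypes
    L <- sample(3:12, 1)
    m <- random_gm(n, L, seed = 400 + s, missing_rate = 0,
                   chroms = "LG01", chrom_len = 5000L)
    g <- stats::setNames(rep("P", n), m$accessions)
    wd <- tajimas_d(m, g, window_bp = 10000L)  # one window
    expect_equal(wd$pi, pi_bruteforce(m$calls), tolerance = 1e-10)
  }
})

test_that("statistics are invariant to accession order", {
  m <- random_gm(12, 80, seed = 19, missing_rate = 0.05)
  g <- stats::setNames(rep(c("A", "B"), each = 6), m$accessions)
  perm <- withr::with_seed(1, sample(12))
  mp <- subset_accessions(m, perm)
  s1 <- population_summary(m, g)
  s2 <- population_summary(mp, g)
  expect_equal(s1[order(s1$population), ], s2[order(s2$population), ],
               ignore_attr = TRUE)
})

test_that("clonality leaves the expected Fis / D signatures", {
  sexual <- pop_fis_d(single_pop_cfg(23, clonality = 0, mu = 1e-3,
                                     generations = 120L))
  clonal <- pop_fis_d(single_pop_cfg(23, clonality = 1, mu = 1e-3,
                                     generations = 120L))
  expect_lt(clonal[["fis"]], sexual[["fis"]])
  expect_gt(clonal[["d"]], sexual[["d"]])
  expect_lt(clonal[["fis"]], -0.2)
  expect_gt(clonal[["d"]], 0)
})
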