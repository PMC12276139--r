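make_gm <- function(calls, depth = NULL, chrom = NULL) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  genotype_matrix(calls,
                  data.frame(chrom = if (is.null(chrom)) "LG01" else chrom,
                             pos = seq_len(L) * 100L, ref = "A", alt = "G"),
                  sprintf("a%02d", seq_len(nrow(calls))),
                  depth = depth)
}

test_that("locus_stats computes allele and genotype frequencies", {
  m <- make_gm(cbind(c(0L, 1L, 2L)))
  st <- locus_stats(m)
  expect_equal(st$f_a, 0.5)
  expect_equal(st$f_Aa, 1 / 3)
  expect_equal(st$missing_frac, 0)

  m <- make_gm(cbind(c(1L, 1L)))
  st <- locus_stats(m)
  expect_equal(st$f_a, 0.5)
  expect_equal(st$f_Aa, 1)

  # zero-call locus is flagged undefined, not dropped
  m <- make_gm(cbind(c(NA_integer_, NA_integer_), c(0L, 1L)))
  st <- locus_stats(m)
  expect_true(st$undefined[1])
  expect_false(st$undefined[2])
  expect_equal(nrow(st), 2L)
})

test_that("locus_stats agrees with a brute-force allele tally", {
  withr::with_seed(11, {
    g <- sample(c(0:2, NA), 1000, replace = TRUE)
  })
  m <- make_gm(cbind(g))
  st <- locus_stats(m)
  called <- g[!is.na(g)]
  # oracle: count alleles one genotype at a time
  alt <- 0; tot <- 0; het <- 0
  for (x in called) {
    alt <- alt + x
    het <- het + (x == 1)
    tot <- tot + 2
  }
  expect_equal(st$f_a, alt / tot)
  expect_equal(st$f_Aa, het / length(called))
  expect_equal(st$n_called, length(called))
  expect_equal(st$f_A + st$f_a, 1, tolerance = 1e-12)
})

test_that("missing-genotype recalibration follows the depth rule", {
  calls <- cbind(c(NA_integer_, NA_integer_, 1L))
  depth <- cbind(c(12L, 2L, 9L))
  m <- recalibrate_missing(make_gm(calls, depth), min_depth = 5L)
  expect_equal(unname(m$calls[, 1]), c(0L, NA_integer_, 1L))

  # matrix without missing calls is untouched
  m0 <- make_gm(cbind(c(0L, 1L, 2L)), cbind(c(3L, 30L, 1L)))
  expect_true(gm_identical(recalibrate_missing(m0, 5L), m0))

  expect_error(recalibrate_missing(make_gm(cbind(c(0L, NA)))), "depth")
})

test_that("recalibration never alters non-missing calls or adds missingness", {
  for (s in 1:5) {
    m <- random_gm(10, 50, seed = 200 + s, missing_rate = 0.2)
    r <- recalibrate_missing(m, 5L)
    was_called <- !is.na(m$calls)
    expect_identical(r$calls[was_called], m$calls[was_called])
    expect_lte(sum(is.na(r$calls)), sum(is.na(m$calls)))
    # idempotent
    expect_true(gm_identical(recalibrate_missing(r, 5L), r))
  }
})

test_that("high-quality filter thresholds are boundary-exclusive", {
  # 500 accessions: 19/1000 alleles -> maf 0.019 (removed),
  # 20/1000 -> 0.020 (retained)
  calls19 <- c(rep(1L, 19), rep(0L, 481))
  calls20 <- c(rep(1L, 20), rep(0L, 480))
  m <- make_gm(cbind(calls19, calls20))
  res <- filter_high_quality(m)
  expect_equal(n_loci(res$matrix), 1L)
  expect_equal(locus_stats(res$matrix)$maf, 0.02)
  expect_equal(unname(res$report$n_removed_by_rule["maf"]), 1L)

  # missingness: exactly 10% retained, above removed
  na <- NA_integer_
  c10 <- c(rep(na, 100), rep(1L, 450), rep(0L, 450))   # 0.100
  c101 <- c(rep(na, 101), rep(1L, 450), rep(0L, 449))  # 0.101
  m <- make_gm(cbind(c10, c101))
  res <- filter_high_quality(m)
  expect_equal(n_loci(res$matrix), 1L)
  expect_equal(res$matrix$loci$pos, 100L)
})

test_that("non-biallelic records are removed first in the report", {
  m <- make_gm(cbind(c(0L, 1L), c(0L, 1L), c(0L, 0L)))
  m$loci$alt[2] <- "G,T"
  res <- filter_high_quality(m)
  expect_equal(unname(res$report$n_removed_by_rule["non_biallelic"]), 1L)
  expect_equal(unname(res$report$n_removed_by_rule["maf"]), 1L)  # monomorphic
  expect_equal(res$report$n_output_loci, 1L)
  expect_equal(res$report$n_input_loci -
                 sum(res$report$n_removed_by_rule),
               res$report$n_output_loci)
})

test_that("filters match brute-force predicate re-evaluation", {
  m <- random_gm(40, 500, seed = 3, missing_rate = 0.12)
  res <- filter_high_quality(m, maf_min = 0.02, missing_max = 0.10)
  # oracle: re-evaluate all three predicates per locus, independently
  keep <- logical(n_loci(m))
  for (j in seq_len(n_loci(m))) {
    g <- m$calls[, j]
    called <- g[!is.na(g)]
    fa <- sum(called) / (2 * length(called))
    maf <- min(fa, 1 - fa)
    miss <- mean(is.na(g))
    keep[j] <- length(called) > 0 && maf >= 0.02 && miss <= 0.10 &&
      !grepl(",", m$loci$alt[j])
  }
  expect_equal(res$matrix$loci$pos, m$loci$pos[keep])

  # drop_any_missing
  dm <- drop_any_missing(m)
  expect_equal(dm$loci$pos,
               m$loci$pos[colSums(is.na(m$calls)) == 0])

  # drop_unanchored via set-membership recount
  du <- drop_unanchored(m, "LG01")
  expect_equal(n_loci(du), sum(m$loci$chrom == "LG01"))
  expect_true(all(du$loci$chrom == "LG01"))
})

test_that("filters are idempotent and retained set is order-independent", {
  m <- random_gm(25, 300, seed = 17, missing_rate = 0.15)
  f1 <- filter_high_quality(m)$matrix
  expect_true(gm_identical(filter_high_quality(f1)$matrix, f1))
  expect_true(gm_identical(drop_any_missing(drop_any_missing(m)),
                           drop_any_missing(m)))

  # applying the single-rule filters in either order gives the same loci
  a <- drop_any_missing(drop_unanchored(m, "LG02"))
  b <- drop_unanchored(drop_any_missing(m), "LG02")
  expect_true(gm_identical(a, b))
})

test_that("all-anchored and fully-called inputs pass through unchanged", {
  m <- random_gm(10, 50, seed = 5, missing_rate = 0)
  expect_true(gm_identical(drop_any_missing(m), m))
  expect_true(gm_identical(drop_unanchored(m, c("LG01", "LG02")), m))
  expect_error(drop_unanchored(m, character(0)), "non-empty")
})
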