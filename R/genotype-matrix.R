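# Core data model: a genotype matrix of coded biallelic SNP calls.
#
# Calls are stored as an integer matrix (accessions x loci) counting copies of
# the alternate allele: 0 = homozygous reference, 1 = heterozygous,
# 2 = homozygous alternate, NA = missing. Loci are kept coordinate-sorted.

#' Genotype codes
#'
#' Integer codes used throughout the package for diploid biallelic calls:
#' `HOM_REF = 0L`, `HET = 1L`, `HOM_ALT = 2L`, missing = `NA_integer_`.
#' The code equals the number of alternate-allele copies carried.
#'
#' @format Named integer vector of length 3.
#' @export
GENO_CODES <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)

#' Construct a genotype matrix
#'
#' The central container of the package: an accessions x loci matrix of coded
#' biallelic genotype calls with locus coordinates and, optionally, per-call
#' read depth. Loci are sorted by (chromosome, position) on construction and
#' duplicate coordinates are an error.
#'
#' @param calls Integer matrix, accessions in rows and loci in columns, with
#'   entries in \{0, 1, 2, NA\} (alternate-allele dosage; NA = missing call).
#' @param loci `data.frame` with one row per locus and columns `chrom`
#'   (character), `pos` (1-based position, integer), `ref` and `alt`
#'   (allele strings; `alt` may hold a comma-separated list for
#'   multi-allelic records retained by [read_vcf()]).
#' @param accessions Character vector of unique accession identifiers, one
#'   per row of `calls`.
#' @param depth Optional non-negative integer matrix of per-call read depths
#'   with the same dimensions as `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `loci`, `accessions` and `depth` (possibly `NULL`).
#' @examples
#' gm <- genotype_matrix(
#'   calls = rbind(c(0L, 1L), c(2L, NA)),
#'   loci = data.frame(chrom = "LG01", pos = c(100L, 200L),
#'                     ref = "A", alt = "G"),
#'   accessions = c("acc1", "acc2")
#' )
#' n_loci(gm)
#' @export
genotype_matrix <- function(calls, loci, accessions, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$ref <- as.character(loci$ref)
  loci$alt <- as.character(loci$alt)
  accessions <- as.character(accessions)

  if (nrow(calls) != length(accessions))
    stop("calls must have one row per accession")
  if (ncol(calls) != nrow(loci))
    stop("calls must have one column per locus")
  if (anyDuplicated(accessions))
    stop("duplicate accession IDs")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("calls must be 0, 1, 2 or NA")
  if (nrow(loci) && any(loci$pos < 1L))
    stop("locus positions must be >= 1")
  if (nrow(loci) && any(loci$ref == loci$alt))
    stop("ref allele equal to alt allele")
  if (anyDuplicated(loci[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) locus coordinates")

  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(calls)))
      stop("depth dimensions must match calls")
    if (any(depth < 0L, na.rm = TRUE))
      stop("depths must be non-negative")
  }

  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  calls <- calls[, ord, drop = FALSE]
  if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  dimnames(calls) <- list(accessions, NULL)
  if (!is.null(depth)) dimnames(depth) <- list(accessions, NULL)

  structure(list(calls = calls, loci = loci, accessions = accessions,
                 depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%s depth)\n",
              n_accessions(x), n_loci(x),
              if (is.null(x$depth)) "no" else "with"))
  if (n_loci(x)) {
    chroms <- unique(x$loci$chrom)
    cat(sprintf("  chromosomes: %s\n",
                paste(utils::head(chroms, 6), collapse = ", ")))
    miss <- mean(is.na(x$calls))
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  }
  invisible(x)
}

#' Number of loci / accessions
#' @param m A `genotype_matrix`.
#' @return Integer count.
#' @export
n_loci <- function(m) nrow(m$loci)

#' @rdname n_loci
#' @export
n_accessions <- function(m) length(m$accessions)

#' Subset a genotype matrix
#'
#' Restrict a genotype matrix to a subset of loci (by column index) or
#' accessions (by ID or index). Locus order is preserved, so coordinate
#' sorting is maintained.
#'
#' @param m A `genotype_matrix`.
#' @param keep Logical or integer index over loci (for `subset_loci`) or a
#'   character/integer/logical index over accessions (for
#'   `subset_accessions`).
#' @return A `genotype_matrix`.
#' @export
subset_loci <- function(m, keep) {
  if (is.logical(keep)) keep <- which(keep)
  structure(list(
    calls = m$calls[, keep, drop = FALSE],
    loci = {
      l <- m$loci[keep, , drop = FALSE]
      rownames(l) <- NULL
      l
    },
    accessions = m$accessions,
    depth = if (is.null(m$depth)) NULL else m$depth[, keep, drop = FALSE]
  ), class = "genotype_matrix")
}

#' @rdname subset_loci
#' @export
subset_accessions <- function(m, keep) {
  if (is.character(keep)) {
    idx <- match(keep, m$accessions)
    if (anyNA(idx)) stop("unknown accession ID(s): ",
                         paste(keep[is.na(idx)], collapse = ", "))
    keep <- idx
  }
  if (is.logical(keep)) keep <- which(keep)
  structure(list(
    calls = m$calls[keep, , drop = FALSE],
    loci = m$loci,
    accessions = m$accessions[keep],
    depth = if (is.null(m$depth)) NULL else m$depth[keep, , drop = FALSE]
  ), class = "genotype_matrix")
}

#' Test two genotype matrices for equality of modelled fields
#' @param a,b `genotype_matrix` objects.
#' @return Logical scalar.
#' @export
gm_identical <- function(a, b) {
  isTRUE(all.equal(a$accessions, b$accessions)) &&
    isTRUE(all.equal(a$loci[c("chrom", "pos", "ref", "alt")],
                     b$loci[c("chrom", "pos", "ref", "alt")],
                     check.attributes = FALSE)) &&
    identical(unname(a$calls), unname(b$calls)) &&
    identical(is.null(a$depth), is.null(b$depth)) &&
    (is.null(a$depth) || identical(unname(a$depth), unname(b$depth)))
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
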