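# Readers and writers for the standard formats the pipeline touches:
# VCF (GT/DP), BED3 repeat intervals, ADMIXTURE-style Q matrices and
# accession -> group label tables.

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or bgzipped) and maps diploid GT fields to
#' alternate-allele dosage codes: `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./.` (and half-calls such as `./1`) `-> NA`. Phase
#' separators (`|`) are accepted and ignored; the data model is unphased.
#' `FORMAT/DP` is read into the depth matrix when present at every record.
#'
#' @param path Path to a VCF file.
#' @param biallelic_only Drop records whose ALT column lists more than one
#'   allele (default `TRUE`). When multi-allelic records are retained, calls
#'   involving allele indices above 1 are coded missing.
#' @return A [genotype_matrix()].
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samp <- colnames(v@gt)
    samp <- samp[samp != "FORMAT"]
    return(genotype_matrix(
      calls = matrix(integer(0), nrow = length(samp), ncol = 0),
      loci = data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0)),
      accessions = if (is.null(samp)) character(0) else samp))
  }
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(loci[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) records in VCF: ", path)

  keep <- rep(TRUE, nrow(loci))
  if (biallelic_only) keep <- !grepl(",", loci$alt, fixed = TRUE)

  gt <- vcfR::extract.gt(v, element = "GT")
  # strip phase, normalise allele order so 1/0 == 0/1
  code_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- matrix(code_gt(gt), nrow = nrow(gt), ncol = ncol(gt))
  calls <- t(calls)  # accessions x loci
  accessions <- colnames(gt)

  depth <- NULL
  fmt <- vcfR::extract.gt(v, element = "DP")
  if (!all(is.na(fmt))) {
    depth <- t(matrix(suppressWarnings(as.integer(fmt)),
                      nrow = nrow(fmt), ncol = ncol(fmt)))
  }

  m <- genotype_matrix(calls = calls[, keep, drop = FALSE],
                       loci = loci[keep, , drop = FALSE],
                       accessions = accessions,
                       depth = if (is.null(depth)) NULL
                               else depth[, keep, drop = FALSE])
  m
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one sample column per accession with GT (and DP when the matrix
#' carries depths). The writer is lossless for the fields of the data model:
#' `write_vcf()` followed by [read_vcf()] reproduces the matrix exactly.
#'
#' @param m A [genotype_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  has_dp <- !is.null(m$depth)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pinepop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$accessions), collapse = "\t"))
  writeLines(hdr, con)
  if (n_loci(m) == 0) return(invisible(path))

  gt_str <- matrix(c("0/0", "0/1", "1/1")[m$calls + 1L],
                   nrow = nrow(m$calls))
  gt_str[is.na(m$calls)] <- "./."
  if (has_dp) {
    dp <- m$depth
    dp_str <- ifelse(is.na(dp), ".", as.character(dp))
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = nrow(gt_str))
  }
  fmt <- if (has_dp) "GT:DP" else "GT"
  body <- vapply(seq_len(n_loci(m)), function(j) {
    paste(c(m$loci$chrom[j], m$loci$pos[j], ".", m$loci$ref[j],
            m$loci$alt[j], ".", "PASS", ".", fmt, gt_str[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Interval sets (BED-style, 0-based half-open)
#'
#' A normalized set of genomic intervals: per chromosome, intervals are
#' sorted and overlapping/adjacent-overlap runs are merged. Used to carry
#' repeat-region annotations into [mask_repeats()].
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open bounds, `start < end`.
#' @return An object of class `interval_set`: a `data.frame` with columns
#'   `chrom`, `start`, `end`, normalized.
#' @export
interval_set <- function(chrom = character(0), start = integer(0),
                         end = integer(0)) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  if (any(start >= end))
    stop("interval with start >= end at index ",
         which(start >= end)[1])
  if (length(chrom) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  # merge per chromosome with IRanges (1-based closed internally)
  pieces <- lapply(split(seq_along(chrom), chrom), function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start[idx] + 1L,
                                           end = end[idx]))
    data.frame(chrom = chrom[idx[1]],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Read a BED3 file of intervals
#'
#' Reads the first three columns of a BED file (0-based half-open) and
#' returns a normalized [interval_set()] (sorted, overlaps merged).
#'
#' @param path Path to a BED file; an empty file yields an empty set.
#' @return An `interval_set`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) &
                 !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) return(interval_set())
  parts <- strsplit(lines, "[ \t]+")
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3))
    stop("BED line ", which(nf < 3)[1], " has fewer than 3 fields")
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric BED coordinates at line ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end")
  interval_set(chrom, start, end)
}

#' Membership of positions in an interval set
#'
#' @param iv An [interval_set()].
#' @param chrom Chromosome name (scalar or vector recycled against `pos`).
#' @param pos 1-based positions.
#' @return Logical vector: `TRUE` where the base at `pos` lies inside an
#'   interval.
#' @export
interval_contains <- function(iv, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  out <- logical(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}

#' Read an ADMIXTURE-style Q matrix
#'
#' Q files carry no accession IDs (one whitespace-delimited row of K
#' ancestry proportions per individual), so the ordered accession ID list
#' must be supplied by the caller. Rows must sum to 1 within `tol`; they
#' are renormalized to sum exactly 1.
#'
#' @param path Path to the `.Q` file.
#' @param accession_ids Ordered accession IDs, one per row.
#' @param tol Tolerance on the row sums (default `1e-4`).
#' @return An object of class `ancestry_table`: list with `K`, matrix `Q`
#'   (rownames = accession IDs) and `accessions`.
#' @export
read_qmatrix <- function(path, accession_ids, tol = 1e-4) {
  if (!file.exists(path)) stop("Q matrix not found: ", path)
  q <- as.matrix(utils::read.table(path, header = FALSE))
  ancestry_table(q, accession_ids, tol = tol)
}

#' @rdname read_qmatrix
#' @param Q Numeric matrix of ancestry proportions (accessions x K).
#' @export
ancestry_table <- function(Q, accession_ids, tol = 1e-4) {
  Q <- as.matrix(Q)
  storage.mode(Q) <- "double"
  accession_ids <- as.character(accession_ids)
  if (nrow(Q) != length(accession_ids))
    stop("Q has ", nrow(Q), " rows but ", length(accession_ids),
         " accession IDs were supplied")
  if (any(Q < 0)) stop("negative ancestry proportion")
  rs <- rowSums(Q)
  off <- which(abs(rs - 1) > tol)
  if (length(off))
    stop("Q row ", off[1], " sums to ", format(rs[off[1]]),
         " (tolerance ", tol, ")")
  Q <- Q / rs
  dimnames(Q) <- list(accession_ids, paste0("C", seq_len(ncol(Q))))
  structure(list(K = ncol(Q), Q = Q, accessions = accession_ids),
            class = "ancestry_table")
}

#' Read an accession-to-group label table
#'
#' Two-column tab-separated file: accession ID, group label. No header.
#'
#' @param path Path to the TSV.
#' @return Named character vector mapping accession ID to group label.
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("accession", "group"))
  stats::setNames(tab$group, tab$accession)
}

#' @rdname read_groups
#' @param groups Named character vector (names = accession IDs).
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(names(groups), unname(groups)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
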