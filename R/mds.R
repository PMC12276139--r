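# Genotype distances over a panel and classical (Torgerson) MDS.

#' Pairwise genotype distance over panel loci
#'
#' Mean per-locus Manhattan distance between alternate-allele dosages:
#' `d(i, j) = sum_l |c_il - c_jl| / L` with dosages in \{0, 1, 2\}, so the
#' maximum distance is 2 (opposite homozygotes at every locus). An
#' alternative mismatch-proportion metric counts any genotype difference
#' as 1.
#'
#' @param m A [genotype_matrix()].
#' @param panel Optional `snp_panel`; when supplied, distances are computed
#'   over the panel's loci only (which must be fully called in `m`).
#' @param metric `"manhattan"` (allele-count, default) or `"mismatch"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames =
#'   accession IDs.
#' @export
genotype_distance <- function(m, panel = NULL,
                              metric = c("manhattan", "mismatch")) {
  metric <- match.arg(metric)
  calls <- m$calls
  if (!is.null(panel)) {
    idx <- panel$entries$locus_idx
    if (anyNA(idx)) stop("panel loci not found in matrix")
    calls <- calls[, idx, drop = FALSE]
  }
  if (anyNA(calls)) stop("missing call on a panel locus")
  if (ncol(calls) == 0) stop("no loci to compute distances over")
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(m$accessions, m$accessions))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- abs(calls[i, ] - calls[j, ])
      val <- if (metric == "manhattan") sum(diffs) else sum(diffs > 0)
      d[i, j] <- d[j, i] <- val / ncol(calls)
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix (`-0.5 * J D^2 J`),
#' eigendecomposes it, and returns coordinates given by the top-`k`
#' eigenvectors scaled by the square roots of their eigenvalues. Negative
#' eigenvalues among the top `k` (non-Euclidean input) are truncated to
#' zero with a warning. For reproducible plots, each axis's sign is fixed
#' so that its largest-magnitude loading is positive.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Embedding dimension (default 2); must be `< nrow(d)`.
#' @return Object of class `mds_embedding`: list with `points`
#'   (n x k coordinate matrix), `eig` (all eigenvalues, descending) and
#'   `accessions`.
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of accessions")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  vals <- eg$values
  lam <- vals[seq_len(k)]
  if (any(lam < 0)) {
    warning("negative eigenvalue(s) among the top ", k,
            "; truncated to zero (non-Euclidean distances)")
    lam <- pmax(lam, 0)
  }
  pts <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  for (j in seq_len(k)) {
    imax <- which.max(abs(pts[, j]))
    if (pts[imax, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eig = vals,
                 accessions = rownames(d)),
            class = "mds_embedding")
}

#' Relative stress of an embedding
#'
#' Root-mean-square relative distortion between input distances and the
#' embedded Euclidean distances, over all pairs with nonzero input
#' distance. Near 0 for Euclidean-embeddable inputs at sufficient rank.
#'
#' @param d Input distance matrix.
#' @param emb An `mds_embedding`.
#' @return Numeric scalar.
#' @export
mds_stress <- function(d, emb) {
  dd <- as.matrix(stats::dist(emb$points))
  num <- (dd - d)[upper.tri(d)]
  den <- d[upper.tri(d)]
  ok <- den > 0
  sqrt(mean((num[ok] / den[ok])^2))
}
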