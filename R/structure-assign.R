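# Population assignment from ancestry (Q) proportions: each group is tied
# to its representative ancestry component per K, and an accession is a
# definitive group member only when it carries more than `threshold` of the
# group's component at EVERY evaluated K; everything else is a hybrid.

#' Map ancestry components to named groups
#'
#' For each K and each group, picks the component with the highest mean
#' proportion among that group's seed (reference) accessions. If two groups
#' claim the same component at some K, the group with the higher mean wins
#' and the other is left unmapped with a warning.
#'
#' @param tables Named list of [ancestry_table()] objects; names are the K
#'   values as character (e.g. `list("5" = q5, "6" = q6)`).
#' @param seeds Named character vector mapping seed accession IDs to group
#'   labels; every group needs at least one seed.
#' @return Object of class `component_mapping`: per K, a named integer
#'   vector `group -> component index` (NA when unmapped).
#' @export
map_components <- function(tables, seeds) {
  if (length(seeds) == 0) stop("no seed accessions supplied")
  groups <- unique(unname(seeds))
  out <- lapply(tables, function(tab) {
    idx <- match(names(seeds), tab$accessions)
    if (anyNA(idx))
      stop("seed accession(s) absent from Q table: ",
           paste(names(seeds)[is.na(idx)], collapse = ", "))
    means <- t(vapply(groups, function(g) {
      colMeans(tab$Q[idx[seeds == g], , drop = FALSE])
    }, numeric(tab$K)))
    best <- apply(means, 1, which.max)
    score <- means[cbind(seq_along(groups), best)]
    mapping <- stats::setNames(as.integer(best), groups)
    # resolve collisions: highest mean keeps the component
    for (comp in unique(best[duplicated(best)])) {
      claim <- which(best == comp)
      loser <- claim[-which.max(score[claim])]
      warning("component ", comp, " claimed by several groups; leaving ",
              paste(groups[loser], collapse = ", "), " unmapped")
      mapping[loser] <- NA_integer_
    }
    mapping
  })
  names(out) <- names(tables)
  class(out) <- "component_mapping"
  out
}

#' Assign accessions to populations by ancestry threshold
#'
#' An accession is assigned to group `g` if and only if its proportion of
#' the `g`-representative component is strictly greater than `threshold` at
#' every K provided; otherwise it is labelled `"HYBRID"`. With the default
#' threshold this is the "more than 70% of the characteristic genetic
#' component at each K" rule.
#'
#' @param tables Named list of [ancestry_table()] objects keyed by K.
#' @param mapping A `component_mapping` from [map_components()], with an
#'   entry for every K in `tables`.
#' @param threshold Strict lower bound on the component proportion
#'   (default 0.70).
#' @return `data.frame`: `accession`, `label` (group or `"HYBRID"`), and a
#'   `support_K<k>` column per K holding the proportion of the assigned (or
#'   best) group's component.
#' @export
assign_populations <- function(tables, mapping, threshold = 0.70) {
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)")
  ks <- names(tables)
  if (!all(ks %in% names(mapping)))
    stop("mapping lacks K value(s): ",
         paste(setdiff(ks, names(mapping)), collapse = ", "))
  acc <- tables[[1]]$accessions
  for (tab in tables)
    if (!identical(tab$accessions, acc))
      stop("Q tables disagree on accession order")
  groups <- names(mapping[[ks[1]]])

  # support[i, g, k]: accession i's proportion of group g's component at K k
  support <- array(NA_real_, dim = c(length(acc), length(groups),
                                     length(ks)),
                   dimnames = list(acc, groups, ks))
  for (k in ks) {
    map_k <- mapping[[k]]
    for (g in groups) {
      comp <- map_k[[g]]
      support[, g, k] <- if (is.na(comp)) 0 else tables[[k]]$Q[, comp]
    }
  }
  ok <- apply(support > threshold, c(1, 2), all)  # strict at every K
  label <- vapply(seq_along(acc), function(i) {
    hits <- which(ok[i, ])
    if (length(hits) == 1) groups[hits] else "HYBRID"
  }, character(1))
  best <- vapply(seq_along(acc), function(i) {
    if (label[i] != "HYBRID") match(label[i], groups)
    else which.max(apply(support[i, , , drop = FALSE], 2, min))
  }, integer(1))
  sup <- vapply(ks, function(k)
    support[cbind(seq_along(acc), best, match(k, ks))], numeric(length(acc)))
  sup <- matrix(sup, nrow = length(acc))
  out <- data.frame(accession = acc, label = label,
                    stringsAsFactors = FALSE)
  colnames(sup) <- paste0("support_K", ks)
  cbind(out, as.data.frame(sup))
}
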