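# End-to-end orchestration: simulate or ingest -> recalibrate -> filter ->
# population statistics -> ancestry assignment -> panel design -> MDS, with
# one configuration object, per-stage funnels and a machine-readable report.

#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: MAF minimum
#' 0.02, missingness maximum 0.10, ancestry threshold 0.70, repeat flank
#' 100 bp, top 50 SNPs per group, 100 bp pair distance, 100 kb thinning
#' window. Input is either a [sim_config()] (`simulate = TRUE`) or a set
#' of file paths (VCF, BED, Q files keyed by K, group-label TSV).
#'
#' @param out_dir Output directory (created if absent).
#' @param simulate Use the built-in simulator (default `TRUE`).
#' @param sim A [sim_config()]; its `rng_seed` is overridden by `seed`.
#' @param vcf,bed,groups_file Input paths when `simulate = FALSE`.
#' @param q_files Named character vector of Q-matrix paths keyed by K.
#' @param anchored Anchored chromosome names; default taken from the
#'   simulation config when simulating.
#' @param min_depth Depth threshold for missing-genotype recalibration.
#' @param maf_min,missing_max High-quality filter thresholds.
#' @param assign_threshold Strict ancestry-proportion threshold.
#' @param window_bp Tajima's D window width.
#' @param panel A [panel_params()]; its seed is derived from `seed`.
#' @param seed Master seed; every stage's randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            sim = sim_config(),
                            vcf = NULL, bed = NULL, groups_file = NULL,
                            q_files = NULL,
                            anchored = NULL,
                            min_depth = 5L,
                            maf_min = 0.02, missing_max = 0.10,
                            assign_threshold = 0.70,
                            window_bp = 10000L,
                            panel = panel_params(),
                            seed = 1L) {
  if (assign_threshold < 0 || assign_threshold >= 1)
    stop("assign_threshold must be in [0, 1)")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1)
    stop("missing_max must be in [0, 1]")
  if (!simulate && (is.null(vcf) || is.null(groups_file)))
    stop("file-based runs need at least vcf and groups_file")
  if (is.null(anchored) && simulate) anchored <- sim$anchored
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic per-stage seeds derived from the master seed
stage_seed <- function(master, stage) {
  offs <- c(simulate = 11L, dedup = 23L, panel = 37L)
  (as.integer(master) * 101L + offs[[stage]]) %% 2000000011L
}

#' Run the full pipeline
#'
#' Executes every stage and writes: the filtered VCF, per-population
#' statistic TSVs, the assignment TSV, panel TSVs and VCFs, MDS
#' coordinates, and a JSON run report with per-stage funnels, panel sizes,
#' the seed registry and md5 checksums of every output. Re-running with
#' the same configuration reproduces identical checksums.
#'
#' @param cfg A [pipeline_config()].
#' @return The run report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  report <- list(seed = cfg$seed, stages = list())

  # -- stage: acquire ------------------------------------------------------
  if (cfg$simulate) {
    sim <- cfg$sim
    sim$rng_seed <- stage_seed(cfg$seed, "simulate")
    cohort <- simulate_cohort(sim)
    m <- cohort$matrix
    repeats <- cohort$repeats
    qtables <- cohort$qtables
    groups_truth <- cohort$truth$groups
    write_vcf(m, out("input.vcf"))
    write_groups(groups_truth, out("groups.tsv"))
  } else {
    m <- read_vcf(cfg$vcf)
    repeats <- if (!is.null(cfg$bed)) read_bed(cfg$bed) else interval_set()
    groups_truth <- read_groups(cfg$groups_file)
    qtables <- NULL
    if (!is.null(cfg$q_files)) {
      qtables <- lapply(cfg$q_files, read_qmatrix,
                        accession_ids = m$accessions)
      names(qtables) <- names(cfg$q_files)
    }
  }
  report$stages$input <- list(n_accessions = n_accessions(m),
                              n_loci = n_loci(m))

  # -- stage: recalibrate --------------------------------------------------
  if (!is.null(m$depth)) {
    before <- sum(is.na(m$calls))
    m <- recalibrate_missing(m, cfg$min_depth)
    report$stages$recalibrate <- list(
      min_depth = cfg$min_depth,
      missing_before = before, missing_after = sum(is.na(m$calls)))
  }

  # -- stage: high-quality filter -----------------------------------------
  hq <- filter_high_quality(m, cfg$maf_min, cfg$missing_max)
  mf <- hq$matrix
  write_vcf(mf, out("filtered.vcf"))
  report$stages$filter <- unclass(hq$report)

  # -- stage: population statistics ---------------------------------------
  groups_def <- groups_truth[groups_truth != "HYBRID"]
  summ <- population_summary(mf, groups_def, window_bp = cfg$window_bp)
  utils::write.table(summ, out("population_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$stages$popgen <- summ

  # -- stage: ancestry assignment -----------------------------------------
  if (!is.null(qtables)) {
    mapping <- map_components(qtables, groups_def)
    assign <- assign_populations(qtables, mapping, cfg$assign_threshold)
    utils::write.table(assign, out("assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$assign <- list(
      threshold = cfg$assign_threshold,
      n_definitive = sum(assign$label != "HYBRID"),
      n_hybrid = sum(assign$label == "HYBRID"))
  }

  # -- stage: panel design -------------------------------------------------
  cultivar_groups <- if (cfg$simulate)
    cfg$sim$pops$name[cfg$sim$pops$cultivar]
  else unique(unname(groups_def))
  panel_groups <- groups_def[groups_def %in% cultivar_groups]
  mp <- subset_accessions(m, names(panel_groups))
  if (!is.null(cfg$anchored)) mp <- drop_unanchored(mp, cfg$anchored)
  mp <- drop_any_missing(mp)
  st <- locus_stats(mp)
  mp <- subset_loci(mp, !st$undefined & st$maf >= cfg$panel$maf_min)
  pp <- cfg$panel
  pp$rng_seed <- stage_seed(cfg$seed, "panel")
  panel_a <- design_panel_a(mp, panel_groups, repeats, pp)
  panel_b <- design_panel_b(mp, pp)
  write_panel(panel_a, mp, out("panel_A"))
  write_panel(panel_b, mp, out("panel_B"))
  report$stages$panel_a <- list(funnel = as.list(panel_a$funnel),
                                size = nrow(panel_a$entries),
                                per_group = as.list(table(
                                  panel_a$entries$group)))
  report$stages$panel_b <- list(funnel = as.list(panel_b$funnel),
                                size = nrow(panel_b$entries))

  # -- stage: MDS ----------------------------------------------------------
  if (nrow(panel_a$entries) >= 3) {
    d <- genotype_distance(mp, panel_a)
    emb <- classical_mds(d, k = 2L)
    coords <- data.frame(accession = emb$accessions,
                         group = unname(panel_groups[emb$accessions]),
                         dim1 = emb$points[, 1], dim2 = emb$points[, 2])
    utils::write.table(coords, out("mds.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$stages$mds <- list(k = 2, stress = mds_stress(d, emb),
                              eig_top = emb$eig[1:2])
  }

  # -- report --------------------------------------------------------------
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "report.json"]
  sums <- tools::md5sum(sort(files))
  report$checksums <- as.list(stats::setNames(unname(sums),
                                              basename(names(sums))))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Write a panel as TSV (+ genotype columns) and VCF subset
#'
#' @param panel An `snp_panel`.
#' @param m The matrix the panel indexes into.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.vcf`.
#' @return `prefix`, invisibly.
#' @export
write_panel <- function(panel, m, prefix) {
  e <- panel$entries
  tab <- e[c("chrom", "pos", "ref", "alt", "group", "score")]
  if (nrow(e)) {
    gts <- t(m$calls[, e$locus_idx, drop = FALSE])
    colnames(gts) <- m$accessions
    tab <- cbind(tab, gts)
  }
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(e)) write_vcf(subset_loci(m, e$locus_idx), paste0(prefix, ".vcf"))
  invisible(prefix)
}
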