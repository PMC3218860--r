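#' Pipeline run configuration
#'
#' Bundles the synthetic-study configuration with every analysis
#' parameter at its standard default: 5% FDR region calling (150-bp
#' windows vs a 50-kb background), 20-bp peak windows with a 75-bp
#' local-maximum radius, the >= 200-bp overlap rule, match thresholds
#' 0.04 (affinity cohorts) and 0.003 (site-density matrix), +/-250-bp and
#' +/-75-bp score windows, cohorts of 200 and 1,000, top-400 temporal
#' regions, and ten scrambled PWMs filtered at similarity p < 0.05.
#'
#' @param seed master seed for simulation and scrambling.
#' @param sim a [simulation_config()] (seeded from `seed` if omitted).
#' @param fdr accessible-region FDR.
#' @param region_window_bp,background_bp,merge_gap region-caller geometry.
#' @param peak_window_bp,peak_near_bp peak-detection geometry.
#' @param min_overlap_bp ChIP/region overlap rule threshold.
#' @param scan_p,match_p scan thresholds for cohorts and site counting.
#' @param affinity_window_bp,near_bp score-query half windows.
#' @param chip_cohort_size,access_cohort_size cohort sizes (Fig. 3 / S6
#'   style).
#' @param n_top temporal top-region count.
#' @param n_scrambles,similarity_alpha,similarity_n_perm scrambled-PWM
#'   null parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = simulation_config(seed = seed),
                       fdr = 0.05, region_window_bp = 150,
                       background_bp = 50000, merge_gap = 50,
                       peak_window_bp = 20, peak_near_bp = 75,
                       min_overlap_bp = 200, scan_p = 0.04,
                       match_p = 0.003, affinity_window_bp = 250,
                       near_bp = 75, chip_cohort_size = 200,
                       access_cohort_size = 1000, n_top = 400,
                       n_scrambles = 10, similarity_alpha = 0.05,
                       similarity_n_perm = 200) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[accessmap] %s: %s", stage,
                               paste0(..., collapse = "")))
}

#' Run the full synthetic-study pipeline
#'
#' simulate -> write inputs -> call accessible regions (both replicates,
#' concordant) -> detect and rank accessibility peaks -> scan genuine and
#' scrambled PWMs -> overlap statistics -> ChIP-rank accessibility curves
#' -> affinity-cohort tables -> accessibility-rank matrices -> temporal
#' ratio correlations. All intermediates are written as BED/bedGraph/TSV
#' under `out_dir` together with a `manifest.json`; re-running with the
#' same configuration reproduces byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param verbose log stage progress to stderr.
#' @return invisibly, a list with the in-memory results (`study`,
#'   `regions`, `peaks`, `overlap`, `coverage`, `curves`, `affinity`,
#'   `rank_matrix`, `temporal`, `table1`).
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "accessmap",
                   version = as.character(utils::packageVersion("accessmap")),
                   seed = config$seed, stages = list())
  note <- function(stage, counts) {
    manifest$stages[[stage]] <<- counts
    stage_log(verbose, stage, paste(names(counts), unlist(counts),
                                    sep = "=", collapse = " "))
  }

  study <- simulate_study(config$sim)
  write_study(study, file.path(out_dir, "data"))
  note("simulate", list(regions = nrow(study$regions),
                        factors = length(study$pwms),
                        planted_sites = nrow(study$planted)))

  stages <- config$sim$stages
  regions <- list()
  for (stage in stages) {
    reps <- lapply(study$tracks[[stage]], call_accessible_regions,
                   fdr = config$fdr, window_bp = config$region_window_bp,
                   background_bp = config$background_bp,
                   merge_gap = config$merge_gap)
    regions[[stage]] <- concordant_regions(reps[[1]], reps[[2]])
    rg <- regions[[stage]]
    utils::write.table(rg, file.path(out_dir,
                                     sprintf("regions_%s.tsv", stage)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(rg, file.path(out_dir, sprintf("regions_%s.bed", stage)))
  }
  note("callregions", lapply(regions, nrow))

  track1 <- study$tracks[[stages[1]]][[1]]
  peaks <- rank_peaks(detect_peaks(track1, regions[[stages[1]]],
                                   window_bp = config$peak_window_bp,
                                   near_bp = config$peak_near_bp))
  utils::write.table(peaks, file.path(out_dir, "access_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("peaks", list(peaks = nrow(peaks)))

  # per-factor scans and affinity tables; scrambles share the genuine
  # score distribution (column permutation leaves it unchanged)
  chip1 <- study$chip[[stages[1]]]
  acc1 <- regions[[stages[1]]]
  affinity <- list()
  table1 <- list()
  matches_p003 <- list()
  surfaces <- list()
  codes_list <- lapply(study$sequence, seq_to_codes)
  for (f in seq_along(study$pwms)) {
    m <- study$pwms[[f]]
    dist <- study$dists[[m$name]]
    genuine <- scan_match_mid_cohort(study$sequence, m, dist,
                                     p_max = config$scan_p,
                                     codes_list = codes_list)
    scrams <- scramble_pwm(m, n = config$n_scrambles,
                           others = study$pwms[-f],
                           alpha = config$similarity_alpha,
                           seed = sub_seed(config$seed, 71 + f),
                           n_perm = config$similarity_n_perm)
    # scrambles share the genuine score distribution (0-order background)
    scr_matches <- do.call(rbind, lapply(scrams, function(s)
      scan_match_mid_cohort(study$sequence, s, dist,
                            p_max = config$scan_p,
                            codes_list = codes_list)))
    surf <- chip_score_surface(chip1[chip1$factor == m$name, , drop = FALSE])
    surfaces[[m$name]] <- surf
    affinity[[m$name]] <- affinity_cohort_analysis(
      genuine, scr_matches, acc1, surf,
      window_bp = config$affinity_window_bp)
    comp <- compartment_of(genuine$chrom, genuine$mid, acc1)
    table1[[m$name]] <- data.frame(
      factor = m$name, cohort = rep(c(-5L, -4L, -3L, -2L), 2),
      compartment = rep(c("accessible", "closed"), each = 4),
      n_matches = as.integer(t(vapply(
        c("accessible", "closed"),
        function(cp) vapply(c(-5L, -4L, -3L, -2L), function(co)
          sum(comp == cp & genuine$cohort == co, na.rm = TRUE), 0),
        numeric(4)))), stringsAsFactors = FALSE)
    s003 <- score_threshold(dist, config$match_p)
    matches_p003[[m$name]] <- genuine[genuine$logodds >= s003,
                                      c("chrom", "mid")]
  }
  affinity <- do.call(rbind, affinity)
  rownames(affinity) <- NULL
  table1 <- do.call(rbind, table1)
  rownames(table1) <- NULL
  utils::write.table(affinity, file.path(out_dir, "affinity_cohorts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table1, file.path(out_dir, "match_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("scan_affinity", list(factors = length(surfaces),
                             affinity_rows = nrow(affinity)))

  # overlap of 1% FDR ChIP peaks with accessible chromatin, per factor
  genome_bp <- sum(unclass(config$sim$genome))
  acc_cov <- coverage_bp(acc1)
  overlap <- do.call(rbind, lapply(names(surfaces), function(fac) {
    pk <- chip_fdr_subset(chip1[chip1$factor == fac, , drop = FALSE], "1%")
    ov <- chip_overlap_fraction(pk, acc1,
                                min_overlap_bp = config$min_overlap_bp)
    chip_cov <- coverage_bp(pk)
    ov_bp <- chip_cov + acc_cov -
      coverage_bp(rbind(pk[, c("chrom", "start", "end")],
                        acc1[, c("chrom", "start", "end")]))
    data.frame(factor = fac, n_peaks = nrow(pk),
               fraction_overlapping = ov$fraction,
               hypergeom_p = hypergeom_overlap_pvalue(
                 genome_bp, chip_cov, acc_cov, max(0, ov_bp)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(overlap, file.path(out_dir, "chip_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  chip_pts <- chip_fdr_subset(chip1, "1%")
  coverage <- binding_coverage_of_peaks(
    peaks, data.frame(chrom = chip_pts$chrom,
                      position = chip_pts$peak_position),
    config$sim$genome, cohort_size = config$access_cohort_size)
  utils::write.table(coverage, file.path(out_dir, "peak_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("overlap", list(factors = nrow(overlap),
                       coverage_cohorts = nrow(coverage)))

  tracks_by_stage <- lapply(study$tracks, `[[`, 1)
  curves <- do.call(rbind, lapply(names(surfaces), function(fac) {
    pk <- chip_fdr_subset(chip1[chip1$factor == fac, , drop = FALSE], "25%")
    cv <- chip_rank_accessibility_curves(pk, tracks_by_stage, acc1,
                                         cohort_size =
                                           config$chip_cohort_size)
    cv$factor <- fac
    cv
  }))
  utils::write.table(curves, file.path(out_dir, "chip_rank_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("cohorts", list(rows = nrow(curves)))

  rank_matrix <- accessibility_rank_matrix(
    peaks, surfaces, matches_p003, near_bp = config$near_bp,
    p_match = config$match_p, cohort_size = config$chip_cohort_size)
  utils::write.table(rank_matrix$correlations,
                     file.path(out_dir, "rank_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rank_matrix$chip_matrix,
                     file.path(out_dir, "rank_chip_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = FALSE)
  utils::write.table(rank_matrix$count_matrix,
                     file.path(out_dir, "rank_count_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = FALSE)
  note("rankmatrix", list(factors = nrow(rank_matrix$correlations),
                          cohorts = rank_matrix$n_cohorts))

  chip2 <- study$chip[[stages[2]]]
  temporal <- do.call(rbind, lapply(names(surfaces), function(fac) {
    cx <- chip1[chip1$factor == fac, , drop = FALSE]
    cy <- chip2[chip2$factor == fac, , drop = FALSE]
    top <- top_bound_regions(cx, n = min(config$n_top, nrow(cx)),
                             genome = config$sim$genome)
    sr <- stage_ratio_correlation(top, cx, cy,
                                  tracks_by_stage[[stages[1]]],
                                  tracks_by_stage[[stages[2]]])
    data.frame(factor = fac, stage_x = stages[1], stage_y = stages[2],
               r = sr$r, n = sr$n, stringsAsFactors = FALSE)
  }))
  utils::write.table(temporal, file.path(out_dir, "temporal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("temporal", list(factors = nrow(temporal)))

  manifest$parameters <- config[!vapply(config, is.object, TRUE) &
                                  !names(config) %in% "sim"]
  sim_cfg <- config$sim
  manifest$parameters$sim <- sim_cfg[!vapply(sim_cfg, is.object, TRUE) &
                                       !names(sim_cfg) %in%
                                       c("pwm_set", "genome")]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("manifest", list(stages = length(manifest$stages)))
  invisible(list(study = study, regions = regions, peaks = peaks,
                 overlap = overlap, coverage = coverage, curves = curves,
                 affinity = affinity, rank_matrix = rank_matrix,
                 temporal = temporal, table1 = table1))
}

#' Collate a pipeline run into a human-readable report
#'
#' Reads the tables a [run_pipeline()] call wrote under `run_dir` and
#' writes `report.txt` with sections for the overlap statistics, the
#' ChIP-rank accessibility curves, the affinity-cohort comparison, the
#' accessibility-rank correlations and the temporal ratio correlations.
#' Missing tables are noted and skipped. Regeneration is idempotent.
#'
#' @param run_dir directory of a completed (possibly partial) run.
#' @return invisibly, the report lines.
#' @export
make_report <- function(run_dir) {
  out <- c("accessmap pipeline report", "=========================")
  grab <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p)
  }
  ov <- grab("chip_overlap.tsv")
  if (!is.null(ov)) {
    out <- c(out, "", "ChIP peak overlap with accessible chromatin:",
             sprintf("  mean fraction %.3f over %d factors (range %.3f-%.3f)",
                     mean(ov$fraction_overlapping), nrow(ov),
                     min(ov$fraction_overlapping),
                     max(ov$fraction_overlapping)))
  } else out <- c(out, "", "[chip_overlap.tsv missing - section skipped]")
  cov <- grab("peak_coverage.tsv")
  if (!is.null(cov) && nrow(cov)) {
    full <- cov[!cov$partial, , drop = FALSE]
    out <- c(out, "", "Binding coverage of ranked accessibility peaks:",
             sprintf("  top cohort %.3f, last full cohort %.3f (%d cohorts)",
                     full$fraction_covered[1],
                     full$fraction_covered[nrow(full)], nrow(full)))
  }
  cu <- grab("chip_rank_curves.tsv")
  if (!is.null(cu)) {
    s1 <- cu[!cu$partial & cu$stage == cu$stage[1], , drop = FALSE]
    out <- c(out, "", "ChIP-rank accessibility curves (first stage):",
             sprintf("  %d factor x cohort rows; top-cohort median %.1f",
                     nrow(cu), s1$median[1]))
  } else out <- c(out, "", "[chip_rank_curves.tsv missing - section skipped]")
  af <- grab("affinity_cohorts.tsv")
  if (!is.null(af)) {
    g <- af[af$motif_kind == "genuine" & !is.na(af$median), , drop = FALSE]
    acc <- g[g$compartment == "accessible", ]
    clo <- g[g$compartment == "closed", ]
    out <- c(out, "", "Affinity cohorts (genuine motifs):",
             sprintf("  accessible median of medians %.2f vs closed %.2f",
                     stats::median(acc$median), stats::median(clo$median)))
  } else out <- c(out, "", "[affinity_cohorts.tsv missing - section skipped]")
  rc <- grab("rank_correlations.tsv")
  if (!is.null(rc))
    out <- c(out, "", "Accessibility-rank correlations:",
             sprintf("  r(ChIP, density) %.2f-%.2f; r(sites, density) %.2f-%.2f",
                     min(rc$r_chip), max(rc$r_chip),
                     min(rc$r_count, na.rm = TRUE),
                     max(rc$r_count, na.rm = TRUE)))
  tm <- grab("temporal.tsv")
  if (!is.null(tm))
    out <- c(out, "", "Temporal ratio correlations:",
             sprintf("  r = %.2f-%.2f over %d factor/stage pairs",
                     min(tm$r), max(tm$r), nrow(tm)))
  else out <- c(out, "", "[temporal.tsv missing - section skipped]")
  writeLines(out, file.path(run_dir, "report.txt"))
  invisible(out)
}
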