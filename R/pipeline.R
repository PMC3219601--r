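#' Pipeline configuration
#'
#' Bundles a [synthetic_design()] (or paths to pre-generated inputs written
#' by [run_pipeline()] itself) with the analysis parameters of every stage.
#' Defaults are the conventional values of the emulated study: +/-20 kb TSS
#' window, GSC fractions 0.2/0.4, raw p < 0.01 for differential expression,
#' top/bottom 10% outcome strata, and the p < 0.01 / OR > 2 signature filter.
#'
#' @param design a [synthetic_design()] describing the inputs to generate.
#' @param window TSS half-window in bp.
#' @param region_fraction,subregion_fraction GSC block parameters.
#' @param gsc_samples GSC null samples.
#' @param alpha per-gene significance level.
#' @param dependent_method criterion for knockdown dependence (see
#'   [dependent_genes()]).
#' @param stratify_fraction outcome stratum size.
#' @param p_cut,or_cut signature-association filters.
#' @param flank profile half-width in bp.
#' @param out_dir if non-NULL, all generated inputs and stage tables are
#'   written there (each stage's output independently re-consumable).
#' @param seed root seed; defaults to the design's.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(design = synthetic_design(),
                            window = 20000,
                            region_fraction = 0.2, subregion_fraction = 0.4,
                            gsc_samples = 200,
                            alpha = 0.01,
                            dependent_method = "attenuation",
                            stratify_fraction = 0.10,
                            p_cut = 0.01, or_cut = 2.0,
                            flank = 2000,
                            out_dir = NULL,
                            seed = design$seed) {
  .assert(inherits(design, "synthetic_design"),
          "pipeline_config: design must be a synthetic_design")
  .assert(window > 0 && alpha > 0 && alpha < 1 &&
            stratify_fraction > 0 && stratify_fraction <= 0.5,
          "pipeline_config: invalid parameter")
  design$seed <- seed
  structure(list(design = design, window = window,
                 region_fraction = region_fraction,
                 subregion_fraction = subregion_fraction,
                 gsc_samples = gsc_samples, alpha = alpha,
                 dependent_method = dependent_method,
                 stratify_fraction = stratify_fraction,
                 p_cut = p_cut, or_cut = or_cut, flank = flank,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the integrative pipeline end to end
#'
#' Generates the synthetic inputs, then runs all analysis stages in
#' dependency order: motif screen of the ERa cistrome (whole and after
#' member-level subtraction of FoxA1), GSC overlap significance of ERa vs
#' PBX1, the three-way Venn partition, differential expression with the
#' dependent-gene call, the TSS-window radar table, accessibility profiles
#' per site class, and the expression-stratified outcome analysis. The
#' returned report carries every stage table, a provenance block, and three
#' qualitative checks mirroring the headline structure of the emulated
#' study: dependent genes enriched at PBX1-unique and PBX1+ERa classes,
#' greatest openness at shared PBX1+FoxA1 sites, and poorer outcome in high
#' expressers.
#'
#' @param config a [pipeline_config()].
#' @return A `run_report` (list of stage results; see Details).
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "run_pipeline: need a pipeline_config")
  design <- config$design
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  # --- generate -------------------------------------------------------------
  log_("generating synthetic inputs (seed %d)", design$seed)
  gen <- gen_genome(design)
  cis <- gen_cistromes(design)
  pwm <- pbx1_like_pwm()
  pl <- plant_motifs(gen$genome, cis$truth, pwm, design$motif_plant_prob,
                     seed = .stage_seed(design$seed, 3))
  genome <- pl$genome
  ann <- gen_gene_annotation(design, pl$truth, window = config$window)
  expr <- gen_expression(design)
  track <- gen_track(design, pl$truth, gen$domain)
  cohort <- gen_cohort(design)
  if (!is.null(out)) {
    write_genome_fasta(genome, file.path(out, "genome.fa"))
    for (f in names(cis$sets)) {
      write_bed(cis$sets[[f]], file.path(out, paste0(f, ".bed")))
    }
    utils::write.table(pl$truth, file.path(out, "sites_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ann$genes), file.path(out, "tss.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_expression_study(expr$study, out)
    write_wig(track, file.path(out, "faire.wig"))
    write_cohort(cohort, file.path(out, "cohort.tsv"))
    writeLines(c(paste("responsive", ann$truth$responsive, sep = "\t"),
                 paste("dependent", ann$truth$dependent, sep = "\t")),
               file.path(out, "genes_truth.tsv"))
  }

  # --- motif screen ---------------------------------------------------------
  log_("motif screen")
  threshold <- pwm_threshold(pwm)
  era <- cis$sets$ERa; foxa1 <- cis$sets$FoxA1; pbx1 <- cis$sets$PBX1
  era_minus_foxa1 <- subtract_members(era, foxa1)
  screen_era <- screen_cistrome(era, genome, pwm, threshold)
  screen_era_nofoxa1 <- screen_cistrome(era_minus_foxa1, genome, pwm, threshold)
  screen_pbx1 <- screen_cistrome(pbx1, genome, pwm, threshold)
  screen_cmp <- compare_screen_fractions(screen_era, screen_era_nofoxa1)

  # --- overlap significance -------------------------------------------------
  log_("GSC overlap test (%d samples)", config$gsc_samples)
  gsc <- gsc_test(era, pbx1, gen$domain,
                  region_fraction = config$region_fraction,
                  subregion_fraction = config$subregion_fraction,
                  n_samples = config$gsc_samples,
                  seed = .stage_seed(config$seed, 8))
  overlap_frac <- nrow(intersect_members(era, pbx1)) / nrow(era)

  # --- venn partition -------------------------------------------------------
  log_("venn partition")
  vp <- venn_partition(list(ERa = era, FoxA1 = foxa1, PBX1 = pbx1))
  if (!is.null(out)) write_venn_beds(vp, file.path(out, "venn_classes"))

  # --- differential expression ----------------------------------------------
  log_("differential expression")
  study <- median_reference_normalize(filter_detected(expr$study))
  de_ctrl <- two_class_ttest(study, list(c("siCTRL", "O"), c("siCTRL", "E2")),
                             alpha = config$alpha)
  de_kd <- two_class_ttest(study, list(c("siPBX1", "O"), c("siPBX1", "E2")),
                           alpha = config$alpha)
  anova4 <- four_class_anova(study, alpha = config$alpha)
  resp <- dependent_genes(de_ctrl, de_kd, method = config$dependent_method)

  # --- radar ----------------------------------------------------------------
  log_("TSS-window enrichment (radar)")
  null_genes <- setdiff(ann$genes$gene_id, resp$responsive_all)
  radar <- radar_table(vp,
                       list(all = resp$responsive_all,
                            dependent = resp$dependent),
                       null_genes, ann$genes, window = config$window)

  # --- accessibility profiles -----------------------------------------------
  log_("accessibility profiles")
  prof_classes <- c("FoxA1+PBX1", "PBX1", "FoxA1")
  profiles <- lapply(prof_classes, function(cl) {
    sites <- venn_class_sites(vp, cl)
    aggregate_profile(track, sites, flank = config$flank)
  })
  names(profiles) <- prof_classes
  peak_heights <- vapply(profiles, function(p) max(p$mean_signal), 0)

  # --- outcome --------------------------------------------------------------
  log_("outcome analysis")
  strata <- stratify(cohort, config$stratify_fraction)
  outcome <- lapply(attr(cohort, "years"), function(y)
    fisher_outcome(cohort, strata, y))
  names(outcome) <- paste0("y", attr(cohort, "years"))
  km_high <- km_estimate(cohort$time[cohort$id %in% strata$high],
                         cohort$event[cohort$id %in% strata$high])
  km_low <- km_estimate(cohort$time[cohort$id %in% strata$low],
                        cohort$event[cohort$id %in% strata$low])
  sig <- signature_association(resp$dependent, ann$truth$dependent,
                               ann$genes$gene_id,
                               p_cut = config$p_cut, or_cut = config$or_cut)

  # --- qualitative checks ---------------------------------------------------
  dep_rows <- radar[radar$set == "dependent", ]
  ratio_of <- function(cl) dep_rows$ratio[dep_rows$class == cl]
  enriched <- c("PBX1", "ERa+PBX1")
  others <- setdiff(dep_rows$class[dep_rows$flag == "ok"], enriched)
  checks <- list(
    dependent_enriched_at_pbx1_classes =
      all(vapply(enriched, ratio_of, 0) > 1.5) &&
      all(vapply(others, ratio_of, 0) < 1.5),
    openness_greatest_at_shared =
      peak_heights[["FoxA1+PBX1"]] > peak_heights[["PBX1"]] &&
      peak_heights[["PBX1"]] > peak_heights[["FoxA1"]],
    poor_outcome_in_high_expressers =
      outcome$y5$odds_ratio > 1 && outcome$y5$p_value < 0.05)

  report <- structure(list(
    provenance = list(seed = config$seed, config = config,
                      package_version = as.character(utils::packageVersion("cistrometry")),
                      timestamp = format(Sys.time())),
    screen = list(era = screen_era, era_minus_foxa1 = screen_era_nofoxa1,
                  pbx1 = screen_pbx1, comparison = screen_cmp),
    gsc = gsc, overlap_fraction = overlap_frac,
    venn = vp, venn_summary = summary(vp),
    de = list(ctrl = de_ctrl, kd = de_kd, anova = anova4, responsive = resp),
    radar = radar,
    profiles = profiles, peak_heights = peak_heights,
    outcome = list(comparisons = outcome, km_high = km_high, km_low = km_low,
                   signature = sig, strata = strata),
    truth = list(sites = pl$truth, genes = ann$truth,
                 cohort_high = attr(cohort, "truth_high")),
    checks = checks), class = "run_report")
  if (!is.null(out)) {
    utils::write.table(radar, file.path(out, "radar.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summary(vp), file.path(out, "venn_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== cistrometry run report ==\n")
  cat(sprintf("seed %d, package %s\n", x$provenance$seed,
              x$provenance$package_version))
  cat(sprintf("\nMotif screen: ERa %.1f%% with hit; ERa minus FoxA1 %.1f%% (Fisher p = %.3g)\n",
              100 * x$screen$era$fraction,
              100 * x$screen$era_minus_foxa1$fraction,
              x$screen$comparison$p_value))
  cat(sprintf("ERa/PBX1 member overlap: %.1f%% of ERa sites; GSC p %s %.4g (z = %.1f)\n",
              100 * x$overlap_fraction,
              if (x$gsc$p_value <= 1 / (x$gsc$n_samples + 1)) "<=" else "=",
              x$gsc$p_value, x$gsc$z))
  cat("\nVenn classes (counts per reference factor):\n")
  print(x$venn_summary)
  cat("\n"); print(x$de$responsive)
  cat(sprintf("\nOpenness peak heights: %s\n",
              paste(sprintf("%s=%.2f", names(x$peak_heights), x$peak_heights),
                    collapse = ", ")))
  y5 <- x$outcome$comparisons$y5
  cat(sprintf("Outcome (year 5): OR = %.2f, p = %.3g; signature association OR = %.1f, p = %.3g\n",
              y5$odds_ratio, y5$p_value, x$outcome$signature$odds_ratio,
              x$outcome$signature$p_value))
  cat("\nQualitative checks:\n")
  for (nm in names(x$checks)) {
    cat(sprintf("  %-40s %s\n", nm, if (isTRUE(x$checks[[nm]])) "PASS" else "FAIL"))
  }
  invisible(x)
}
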