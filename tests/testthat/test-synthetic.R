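small_design <- function(seed = 1, n_genes = 400, n_responsive = 60,
                         cohort_n = 120, ...) {
  synthetic_design(seed = seed, chrom_lengths = c(cS = 2e6),
                   n_genes = n_genes, n_responsive = n_responsive,
                   cohort_n = cohort_n, ...)
}

test_that("generators are deterministic under the design seed", {
  d <- small_design(seed = 42)
  g1 <- gen_genome(d); g2 <- gen_genome(d)
  expect_identical(g1$genome, g2$genome)
  c1 <- gen_cistromes(d); c2 <- gen_cistromes(d)
  expect_identical(c1$truth, c2$truth)
  e1 <- gen_expression(d); e2 <- gen_expression(d)
  expect_identical(e1$study$matrix, e2$study$matrix)
  t1 <- gen_track(d, c1$truth, g1$domain)
  t2 <- gen_track(d, c1$truth, g1$domain)
  expect_identical(t1$values, t2$values)
  k1 <- gen_cohort(d); k2 <- gen_cohort(d)
  expect_identical(as.data.frame(k1), as.data.frame(k2))
  # different seed, different data
  expect_false(identical(gen_genome(small_design(seed = 43))$genome, g1$genome))
  # BED bytes are identical across runs
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_bed(c1$sets$PBX1, p1); write_bed(c2$sets$PBX1, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("genome composition follows the designed GC content", {
  d <- synthetic_design(seed = 7, chrom_lengths = c(cS = 1e6), gc = 0.6)
  g <- gen_genome(d)$genome[["cS"]]
  counts <- table(strsplit(g, "")[[1]])
  expect_equal(sum(counts), 1e6)
  gc <- sum(counts[c("C", "G")]) / 1e6
  expect_lt(abs(gc - 0.6), 0.01)
  d0 <- synthetic_design(seed = 7, chrom_lengths = c(cS = 1e5), gc = 0)
  expect_setequal(names(table(strsplit(gen_genome(d0)$genome[["cS"]], "")[[1]])),
                  c("A", "T"))
})

test_that("cistrome generator plants loci non-overlapping with exact class structure", {
  counts <- c("ERa" = 0, "FoxA1" = 0, "PBX1" = 0, "ERa+FoxA1" = 0,
              "ERa+PBX1" = 0, "FoxA1+PBX1" = 0, "ERa+FoxA1+PBX1" = 10)
  d <- synthetic_design(seed = 9, chrom_lengths = c(cS = 1e6),
                        venn_counts = counts)
  cis <- gen_cistromes(d)
  expect_equal(as.data.frame(cis$sets$ERa)[, 1:3],
               as.data.frame(cis$sets$PBX1)[, 1:3])
  expect_equal(nrow(cis$sets$FoxA1), 10)
  # loci never collide across classes
  d2 <- small_design(seed = 10)
  tr <- gen_cistromes(d2)$truth
  all_loci <- interval_set(tr$chrom, tr$start, tr$end)
  m <- cistrometry:::.merge_intervals(all_loci)
  expect_equal(sum(m$end - m$start), nrow(tr) * d2$peak_width)
  # an over-crowded domain errors out
  expect_error(gen_cistromes(synthetic_design(
    seed = 1, chrom_lengths = c(cS = 100000))), "too small")
})

test_that("motif planting hits its designed per-class probability", {
  d <- synthetic_design(seed = 13, chrom_lengths = c(cS = 4e6),
                        venn_counts = c("PBX1" = 400, "ERa" = 200, "FoxA1" = 0,
                                        "ERa+FoxA1" = 0, "ERa+PBX1" = 0,
                                        "FoxA1+PBX1" = 0, "ERa+FoxA1+PBX1" = 0))
  gen <- gen_genome(d)
  cis <- gen_cistromes(d)
  pwm <- pbx1_like_pwm()
  probs <- c("PBX1" = 0.85, "ERa" = 0, "FoxA1" = 0, "ERa+FoxA1" = 0,
             "ERa+PBX1" = 0, "FoxA1+PBX1" = 0, "ERa+FoxA1+PBX1" = 0)
  pl <- plant_motifs(gen$genome, cis$truth, pwm, probs, seed = 5)
  thr <- pwm_threshold(pwm)
  # prob 1 per planted site: every planted site is a hit at the consensus score
  planted_sites <- cis$truth[pl$truth$planted, ]
  ps <- interval_set(planted_sites$chrom, planted_sites$start, planted_sites$end)
  expect_equal(screen_cistrome(ps, pl$genome, pwm, thr)$fraction, 1)
  # screen fraction of the PBX1 cistrome ~ 0.85 (within binomial tolerance)
  fr <- screen_cistrome(cis$sets$PBX1, pl$genome, pwm, thr)$fraction
  expect_lt(abs(fr - 0.85), 0.05)
  # prob 0: fraction equals the background false-positive rate of the
  # threshold (~1e-4 per window, ~390 windows per 200 bp peak, both strands)
  fr0 <- screen_cistrome(cis$sets$ERa, gen$genome, pwm, thr)$fraction
  expect_lt(fr0, 0.15)
})

test_that("expression generator plants a recoverable dependent fraction", {
  d <- small_design(seed = 17, n_genes = 2000, n_responsive = 300)
  ge <- gen_expression(d)
  expect_length(ge$truth$responsive, 300)
  expect_length(ge$truth$dependent, round(0.71 * 300))
  de_c <- two_class_ttest(ge$study, list(c("siCTRL", "O"), c("siCTRL", "E2")))
  de_k <- two_class_ttest(ge$study, list(c("siPBX1", "O"), c("siPBX1", "E2")))
  rg <- dependent_genes(de_c, de_k)
  # recovered responsive set is dominated by the planted one
  expect_gt(mean(rg$responsive_all %in% ge$truth$responsive), 0.8)
  expect_lt(abs(rg$dependent_fraction - 0.71), 0.08)
  # zero effect: responsive set is at the type-I rate
  d0 <- small_design(seed = 19, n_genes = 2000, effect_size = 0)
  ge0 <- gen_expression(d0)
  de0 <- two_class_ttest(ge0$study, list(c("siCTRL", "O"), c("siCTRL", "E2")))
  expect_lt(mean(de0$significant), 0.02)
})

test_that("track generator reflects the designed class amplitudes", {
  d <- small_design(seed = 23)
  gen <- gen_genome(d)
  cis <- gen_cistromes(d)
  tr <- gen_track(d, cis$truth, gen$domain)
  vp <- venn_partition(cis$sets)
  hts <- sapply(c("FoxA1+PBX1", "PBX1", "FoxA1"), function(cl)
    max(aggregate_profile(tr, venn_class_sites(vp, cl), flank = 1000)$mean_signal))
  expect_true(hts[["FoxA1+PBX1"]] > hts[["PBX1"]])
  expect_true(hts[["PBX1"]] > hts[["FoxA1"]])
  # zero amplitudes give a flat-noise track
  d0 <- small_design(seed = 23)
  d0$openness_amplitudes[] <- 0
  tr0 <- gen_track(d0, cis$truth, gen$domain)
  pr0 <- aggregate_profile(tr0, venn_class_sites(vp, "PBX1"), flank = 1000)
  expect_lt(max(pr0$mean_signal) - min(pr0$mean_signal), 0.5)
})

test_that("cohort generator links events to the top expressers consistently", {
  d <- small_design(seed = 29, cohort_n = 400)
  co <- gen_cohort(d)
  # statuses are monotone by construction and match the time column
  expect_equal(co$status_y5 == "event", co$time <= 5 & co$event == 1)
  s <- stratify(co, 0.10)
  expect_setequal(s$high, attr(co, "truth_high"))
  ev_hi <- mean(co$status_y1[match(s$high, co$id)] == "event")
  ev_lo <- mean(co$status_y1[match(s$low, co$id)] == "event")
  expect_gt(ev_hi, ev_lo)
  # zero probabilities: no events at all
  d0 <- small_design(seed = 31, event_prob_high = 0, event_prob_low = 0)
  co0 <- gen_cohort(d0)
  expect_true(all(co0$status_y5 == "event-free"))
})
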