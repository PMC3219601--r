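test_that("TRANSFAC parsing: toy record, negative counts, round trip", {
  txt <- c("ID  toyAT", "P0  A C G T",
           "01  10 0 0 0  A", "02  0 0 0 10  T", "XX", "//")
  pwm <- parse_transfac(text = txt)
  expect_equal(pwm$id, "toyAT")
  expect_equal(pwm_length(pwm), 2)
  expect_equal(pwm_consensus(pwm), "AT")

  expect_error(parse_transfac(text = c("01  10 0 -1 0")), "negative")
  expect_error(parse_transfac(text = c("01  10 x 0 0")), "non-numeric")
  expect_error(parse_transfac(text = c("ID  empty", "XX")), "no position lines")

  set.seed(3)
  rnd <- new_pwm("rnd", matrix(sample(0:30, 40, TRUE), 10, 4))
  p <- withr::local_tempfile(fileext = ".transfac")
  write_transfac(rnd, p)
  expect_equal(parse_transfac(p)$counts, rnd$counts)
})

test_that("window scoring follows the smoothed log2-odds rule", {
  # uniform counts => smoothed frequencies equal the background => score 0
  flat <- new_pwm("flat", matrix(5, 4, 4))
  for (w in c("ACGT", "TTTT", "GCGC")) {
    expect_equal(score_window(w, flat), 0)
  }
  # consensus of a degenerate PWM: L * log2((11/14)/0.25), hand-derived from
  # counts 10 + pseudocount 1 over row total 10 + 4
  pwm <- toy_pwm("TGAT")
  expect_equal(score_window("TGAT", pwm), 4 * log2((11 / 14) / 0.25),
               tolerance = 1e-12)
  # N contributes exactly 0
  expect_equal(score_window("TGAN", pwm), 3 * log2((11 / 14) / 0.25),
               tolerance = 1e-12)
  expect_error(score_window("TGATT", pwm), "length")
})

test_that("reverse-complement symmetry: rc window under rc PWM scores identically", {
  set.seed(11)
  pwm <- new_pwm("rnd", matrix(sample(0:20, 32, TRUE), 8, 4))
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]), collapse = "")
    expect_equal(score_window(w, pwm),
                 score_window(rc, reverse_complement_pwm(pwm)),
                 tolerance = 1e-12)
  }
})

test_that("the DP threshold hits its target per-window false-positive rate", {
  pwm <- pbx1_like_pwm()
  thr <- pwm_threshold(pwm, p = 1e-4)
  # exhaustive check on a smaller matrix: enumerate all 4^L windows
  small <- toy_pwm("TGA")
  t2 <- pwm_threshold(small, p = 0.05)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases)
  scores <- apply(grid, 1, function(r) score_window(paste(r, collapse = ""), small))
  expect_lte(mean(scores >= t2), 0.05)
  # t2 is the *smallest* such threshold at the DP resolution
  expect_gt(mean(scores >= t2 - 0.01), 0.05)
  # consensus of the bundled matrix clears its default threshold comfortably
  expect_gt(score_window(pwm_consensus(pwm), pwm), thr)
})

test_that("cistrome screening agrees with the window-exhaustive oracle", {
  set.seed(21)
  gen <- gen_genome(synthetic_design(seed = 21, chrom_lengths = c(chrT = 50000)))
  pwm <- pbx1_like_pwm()
  peaks <- interval_set("chrT", s <- sort(sample(0:49800, 30)), s + 200,
                        label = "toy")
  res <- screen_cistrome(peaks, gen$genome, pwm, threshold = 6)
  oracle_best <- sapply(seq_len(nrow(peaks)), function(i) {
    oracle_best_score(substr(gen$genome[["chrT"]], peaks$start[i] + 1,
                             peaks$end[i]), pwm)
  })
  expect_equal(res$best_scores, oracle_best, tolerance = 1e-10)
  expect_equal(res$n_with_hit, sum(oracle_best >= 6))

  # threshold limits
  expect_equal(screen_cistrome(peaks, gen$genome, pwm, threshold = Inf)$fraction, 0)
  expect_equal(screen_cistrome(peaks, gen$genome, pwm, threshold = -Inf)$fraction, 1)
  # fraction is monotone non-increasing in the threshold
  fr <- sapply(c(-5, 0, 5, 10), function(t)
    screen_cistrome(peaks, gen$genome, pwm, threshold = t)$fraction)
  expect_true(all(diff(fr) <= 0))
  # out-of-bounds peak is named
  expect_error(screen_cistrome(interval_set("chrT", 49990, 50200), gen$genome, pwm, 5),
               "outside genome bounds")
})

test_that("strand-symmetric scanning: planted strand does not matter", {
  d <- synthetic_design(seed = 5, chrom_lengths = c(chrT = 60000),
                        venn_counts = c("PBX1" = 40, "ERa" = 0, "FoxA1" = 0,
                                        "ERa+FoxA1" = 0, "ERa+PBX1" = 0,
                                        "FoxA1+PBX1" = 0, "ERa+FoxA1+PBX1" = 0))
  gen <- gen_genome(d)
  cis <- gen_cistromes(d)
  pwm <- pbx1_like_pwm()
  cons <- pwm_consensus(pwm)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", cons), "")[[1]]), collapse = "")
  gf <- gr <- gen$genome
  for (i in seq_len(nrow(cis$truth))) {
    p0 <- cis$truth$start[i] + 50 + 1
    substr(gf[["chrT"]], p0, p0 + nchar(cons) - 1) <- cons
    substr(gr[["chrT"]], p0, p0 + nchar(cons) - 1) <- rc
  }
  thr <- pwm_threshold(pwm)
  expect_equal(screen_cistrome(cis$sets$PBX1, gf, pwm, thr)$n_with_hit,
               screen_cistrome(cis$sets$PBX1, gr, pwm, thr)$n_with_hit)
})

test_that("screen-fraction comparison equals the exact hypergeometric tail", {
  # identical proportions => p = 1
  a <- structure(list(n_peaks = 100, n_with_hit = 85), class = "motif_screen")
  b <- structure(list(n_peaks = 100, n_with_hit = 85), class = "motif_screen")
  expect_equal(compare_screen_fractions(a, b)$p_value, 1)
  # small table vs direct enumeration
  a <- structure(list(n_peaks = 10, n_with_hit = 9), class = "motif_screen")
  b <- structure(list(n_peaks = 10, n_with_hit = 1), class = "motif_screen")
  expect_equal(compare_screen_fractions(a, b)$p_value,
               oracle_fisher_p(9, 1, 1, 9), tolerance = 1e-12)
  # large separation is overwhelmingly significant
  a <- structure(list(n_peaks = 5000, n_with_hit = 4250), class = "motif_screen")
  b <- structure(list(n_peaks = 5000, n_with_hit = 2000), class = "motif_screen")
  expect_lt(compare_screen_fractions(a, b)$p_value, 1e-50)
})

test_that("FASTA round trip preserves sequences and names", {
  g <- c(chrA = "ACGTACGTNN", chrB = "TTTTGGGG")
  p <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, p)
  expect_equal(read_genome_fasta(p), g)
})
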